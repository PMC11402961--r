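# Conformer-derived representations: histogrammed weighted atom-centred
# symmetry functions (H-wACSF) and atom-averaged SOAP power spectra.
# Both are implemented from their definitions: no descriptor library for
# these exists in this R environment.

ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                    Ca = 20, Br = 35, I = 53)

atomic_number <- function(elements) {
  z <- ATOMIC_NUMBERS[elements]
  if (anyNA(z)) stop("unknown element(s): ",
                     paste(unique(elements[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Atom-centred symmetry-function parameters
#'
#' Defaults (cutoff 0.6 nm, 8 evenly spaced radial centres, radial width
#' eta = 80 nm^-2, four angular (zeta, lambda) combinations with angular
#' eta = 8 nm^-2, 10 histogram bins) are conventional mid-range choices and
#' are config-exposed: the originally optimised values are not published in
#' a usable form.
#'
#' @param cutoff_nm Radial cutoff (nm).
#' @param radial_centers Gaussian centres mu (nm) within \[0, cutoff\].
#' @param radial_eta Radial Gaussian width eta (nm^-2).
#' @param angular_params Data frame with columns `zeta`, `lambda`, `eta`.
#' @param n_hist_bins Histogram bins per symmetry function (>= 4).
#' @return A list of class `acsf_params`.
#' @export
acsf_params <- function(cutoff_nm = 0.6,
                        radial_centers = seq(0, cutoff_nm, length.out = 8),
                        radial_eta = 80,
                        angular_params = expand.grid(zeta = c(1, 4),
                                                     lambda = c(-1, 1),
                                                     eta = 8),
                        n_hist_bins = 10) {
  stopifnot(cutoff_nm > 0, all(radial_centers >= 0),
            all(radial_centers <= cutoff_nm), radial_eta > 0,
            n_hist_bins >= 4,
            all(c("zeta", "lambda", "eta") %in% names(angular_params)))
  structure(list(cutoff_nm = cutoff_nm,
                 radial_centers = radial_centers,
                 radial_eta = radial_eta,
                 angular_params = as.data.frame(angular_params),
                 n_hist_bins = as.integer(n_hist_bins)),
            class = "acsf_params")
}

cosine_cutoff <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)

# Per-atom weighted symmetry-function values: one row per atom, one column
# per function (radial functions first, then angular). Weights are the
# neighbour atomic numbers.
acsf_atom_values <- function(conf, params) {
  stopifnot(inherits(conf, "conformer"), inherits(params, "acsf_params"))
  n <- nrow(conf$xyz)
  z <- atomic_number(conf$elements)
  rc <- params$cutoff_nm
  n_rad <- length(params$radial_centers)
  n_ang <- nrow(params$angular_params)
  vals <- matrix(0, n, n_rad + n_ang)
  if (n == 1) return(vals)
  D <- as.matrix(stats::dist(conf$xyz))
  FC <- cosine_cutoff(D, rc); diag(FC) <- 0
  for (i in seq_len(n)) {
    r <- D[i, -i]; w <- z[-i]; fc <- FC[i, -i]
    for (k in seq_len(n_rad)) {
      mu <- params$radial_centers[k]
      vals[i, k] <- sum(w * exp(-params$radial_eta * (r - mu)^2) * fc)
    }
    nb <- which(D[i, ] < rc & seq_len(n) != i)
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      for (p in seq_len(ncol(pairs))) {
        j <- pairs[1, p]; k <- pairs[2, p]
        rij <- D[i, j]; rik <- D[i, k]; rjk <- D[j, k]
        cosv <- sum((conf$xyz[j, ] - conf$xyz[i, ]) *
                      (conf$xyz[k, ] - conf$xyz[i, ])) / (rij * rik)
        cosv <- max(-1, min(1, cosv))
        for (a in seq_len(n_ang)) {
          ap <- params$angular_params[a, ]
          g <- 2^(1 - ap$zeta) * z[j] * z[k] * (1 + ap$lambda * cosv)^ap$zeta *
            exp(-ap$eta * (rij^2 + rik^2 + rjk^2)) *
            FC[i, j] * FC[i, k] * cosine_cutoff(rjk, rc)
          vals[i, n_rad + a] <- vals[i, n_rad + a] + g
        }
      }
    }
  }
  colnames(vals) <- c(sprintf("rad%02d", seq_len(n_rad)),
                      sprintf("ang%02d", seq_len(n_ang)))
  vals
}

# Normalised histogram of `values` over [0, hi] with linear interpolation
# between bin centres, so the descriptor is continuous in the atomic
# coordinates (a hard histogram would jump when a value crosses a bin
# edge). Values outside the range are clamped. Proportions sum to 1.
hist_proportions <- function(values, hi, n_bins) {
  if (hi <= 0) hi <- 1e-12
  centers <- seq(hi / (2 * n_bins), hi - hi / (2 * n_bins), length.out = n_bins)
  out <- numeric(n_bins)
  pos <- pmin(pmax(values, centers[1]), centers[n_bins])
  width <- centers[2] - centers[1]
  lo <- pmin(pmax(floor((pos - centers[1]) / width) + 1, 1), n_bins - 1)
  frac <- (pos - centers[lo]) / width
  for (i in seq_along(pos)) {
    out[lo[i]] <- out[lo[i]] + (1 - frac[i])
    out[lo[i] + 1] <- out[lo[i] + 1] + frac[i]
  }
  out / length(values)
}

#' Freeze H-wACSF histogram ranges on a training set
#'
#' Binning needs a shared per-function range across molecules; this records
#' the maximum of each symmetry function over a reference set of conformers,
#' to be passed to [compute_hwacsf()] for every molecule thereafter.
#'
#' @param conformers List of [conformer()]s.
#' @param params [acsf_params()].
#' @return Named numeric vector of per-function maxima.
#' @export
hwacsf_ranges <- function(conformers, params = acsf_params()) {
  stopifnot(length(conformers) >= 1)
  maxima <- sapply(conformers, function(cf) {
    apply(acsf_atom_values(cf, params), 2, max)
  })
  apply(matrix(maxima, ncol = length(conformers)), 1, max) |>
    stats::setNames(colnames(acsf_atom_values(conformers[[1]], params)))
}

#' Histogrammed weighted atom-centred symmetry functions
#'
#' Computes, for every atom, weighted radial functions
#' \eqn{\sum_j Z_j e^{-\eta (r_{ij}-\mu)^2} f_c(r_{ij})} and weighted angular
#' functions over atom triples (weights = neighbour atomic numbers, cosine
#' cutoff \eqn{f_c}), then bins each function's per-atom values into a
#' fixed-length normalised histogram. The result has length
#' `(n_radial + n_angular) * n_hist_bins` regardless of molecule size.
#'
#' @param conf A [conformer()].
#' @param params [acsf_params()].
#' @param ranges Optional frozen per-function maxima from [hwacsf_ranges()];
#'   if `NULL`, each function is binned over its own per-molecule range.
#' @return Named numeric vector (histogram proportions).
#' @export
compute_hwacsf <- function(conf, params = acsf_params(), ranges = NULL) {
  vals <- acsf_atom_values(conf, params)
  n_bins <- params$n_hist_bins
  out <- numeric(0)
  for (k in seq_len(ncol(vals))) {
    hi <- if (is.null(ranges)) max(vals[, k]) else ranges[[k]]
    h <- hist_proportions(vals[, k], hi, n_bins)
    names(h) <- sprintf("%s_bin%02d", colnames(vals)[k], seq_len(n_bins))
    out <- c(out, h)
  }
  out
}

#' SOAP parameters
#'
#' Defaults (cutoff 0.6 nm, 6 radial basis functions, angular order 4, atom
#' Gaussian width 0.05 nm) are conventional mid-range values, config-exposed;
#' the originally optimised set is not published in a usable form.
#'
#' @param cutoff_nm Environment cutoff (nm).
#' @param n_max Number of radial basis functions.
#' @param l_max Maximum spherical-harmonic order (<= 6).
#' @param atom_sigma_nm Width of the atomic Gaussians (nm).
#' @param weight_by_z Weight each atomic Gaussian by its atomic number.
#' @return A list of class `soap_params`.
#' @export
soap_params <- function(cutoff_nm = 0.6, n_max = 6, l_max = 4,
                        atom_sigma_nm = 0.05, weight_by_z = TRUE) {
  stopifnot(cutoff_nm > 0, n_max >= 2, l_max >= 0, l_max <= 6,
            atom_sigma_nm > 0)
  structure(list(cutoff_nm = cutoff_nm, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), atom_sigma_nm = atom_sigma_nm,
                 weight_by_z = weight_by_z),
            class = "soap_params")
}

# Associated Legendre P_l^m(x) (Condon-Shortley) for all l<=lmax, m<=l.
# Returns list P[[l+1]][[m+1]] of vectors matching x.
assoc_legendre <- function(x, lmax) {
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- vector("list", l + 1)
  P[[1]][[1]] <- rep(1, length(x))
  if (lmax == 0) return(P)
  s <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:lmax) {
    if (m > 0) {
      P[[m + 1]][[m + 1]] <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    }
    if (m < lmax) {
      P[[m + 2]][[m + 1]] <- x * (2 * m + 1) * P[[m + 1]][[m + 1]]
    }
    if (m + 2 <= lmax) {
      for (l in (m + 2):lmax) {
        P[[l + 1]][[m + 1]] <- ((2 * l - 1) * x * P[[l]][[m + 1]] -
                                  (l + m - 1) * P[[l - 1]][[m + 1]]) / (l - m)
      }
    }
  }
  P
}

# Real spherical harmonics evaluated at unit vectors (rows of `dirs`);
# returns a matrix nrow(dirs) x (lmax+1)^2, columns ordered (l, m=-l..l).
real_sph_harm <- function(dirs, lmax) {
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- assoc_legendre(ct, lmax)
  out <- matrix(0, nrow(dirs), (lmax + 1)^2)
  col <- 0L
  for (l in 0:lmax) {
    for (m in (-l):l) {
      col <- col + 1L
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- N * P[[l + 1]][[am + 1]]
      out[, col] <- if (m == 0) base
      else if (m > 0) sqrt(2) * base * cos(am * phi)
      else sqrt(2) * base * sin(am * phi)
    }
  }
  out
}

# Modified spherical Bessel i_l(x) scaled by exp(-x): e^{-x} i_l(x), stable
# for large x. Vectorised over x.
msph_bessel_scaled <- function(x, l) {
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- (x[small]^l / dfact) * exp(-x[small])
  }
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) *
      besselI(xs, l + 0.5, expon.scaled = TRUE)
  }
  out
}

# Orthonormalised Gaussian radial basis evaluated on the quadrature grid.
# Returns list(r = nodes, w = weights, B = n_max x Q matrix).
soap_radial_basis <- function(params, n_quad = 201) {
  rc <- params$cutoff_nm
  r <- seq(0, rc, length.out = n_quad)
  h <- r[2] - r[1]
  w <- rep(c(2, 4), length.out = n_quad); w[1] <- 1; w[n_quad] <- 1
  w <- w * h / 3  # composite Simpson (n_quad odd)
  centers <- seq(0, rc, length.out = params$n_max)
  sb <- if (params$n_max > 1) centers[2] - centers[1] else rc / 2
  G <- t(sapply(centers, function(mu) exp(-(r - mu)^2 / (2 * sb^2))))
  S <- G %*% diag(w * r^2) %*% t(G)
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  Sinv_half <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
  list(r = r, w = w, B = Sinv_half %*% G)
}

#' Atom-averaged SOAP power spectrum
#'
#' Expands the Gaussian-smeared neighbour density of every atomic
#' environment in an orthonormal radial basis and real spherical harmonics,
#' forms the rotationally invariant power spectrum
#' \eqn{p_{nn'l} = \sum_m c_{nlm} c_{n'lm}} per atom, and averages over
#' atoms, giving a fixed-length molecular descriptor invariant to rotation,
#' translation and permutation of identical atoms.
#'
#' @param conf A [conformer()].
#' @param params [soap_params()].
#' @return Named numeric vector of length
#'   `n_max * (n_max + 1) / 2 * (l_max + 1)`.
#' @export
compute_soap_avg <- function(conf, params = soap_params()) {
  stopifnot(inherits(conf, "conformer"), inherits(params, "soap_params"))
  n <- nrow(conf$xyz)
  lmax <- params$l_max; nmax <- params$n_max
  alpha <- 1 / (2 * params$atom_sigma_nm^2)
  rc <- params$cutoff_nm
  w_z <- if (params$weight_by_z) atomic_number(conf$elements) else rep(1, n)
  quad <- soap_radial_basis(params)
  Bw <- sweep(quad$B, 2, quad$w * quad$r^2, "*")  # n_max x Q
  n_pairs <- nmax * (nmax + 1) / 2
  p_sum <- numeric(n_pairs * (lmax + 1))
  pair_i <- which(upper.tri(diag(nmax), diag = TRUE), arr.ind = TRUE)
  central_I0 <- as.numeric(Bw %*% exp(-alpha * quad$r^2))  # l = 0 only
  for (i in seq_len(n)) {
    disp <- sweep(conf$xyz, 2, conf$xyz[i, ], "-")
    rj <- sqrt(rowSums(disp^2))
    nb <- which(rj <= rc)
    C <- matrix(0, nmax, (lmax + 1)^2)  # c_{n, lm}
    far <- nb[rj[nb] > 1e-10]
    near <- nb[rj[nb] <= 1e-10]
    for (j in near) {  # central atom: only l = 0 survives
      C[, 1] <- C[, 1] + w_z[j] * sqrt(4 * pi) * central_I0
    }
    if (length(far) > 0) {
      dirs <- disp[far, , drop = FALSE] / rj[far]
      Y <- real_sph_harm(dirs, lmax)
      for (k in seq_along(far)) {
        j <- far[k]
        # K_l(r, rj) = 4*pi * exp(-alpha (r - rj)^2) * [e^{-x} i_l(x)],
        # x = 2 alpha r rj  (exactly exp(-alpha(r^2+rj^2)) i_l(x))
        x <- 2 * alpha * quad$r * rj[j]
        env <- 4 * pi * exp(-alpha * (quad$r - rj[j])^2)
        col <- 0L
        for (l in 0:lmax) {
          Inl <- as.numeric(Bw %*% (env * msph_bessel_scaled(x, l)))
          for (m in (-l):l) {
            col <- col + 1L
            C[, col] <- C[, col] + w_z[j] * Inl * Y[k, col]
          }
        }
      }
    }
    # power spectrum for environment i
    col0 <- 0L
    for (l in 0:lmax) {
      cols <- col0 + seq_len(2 * l + 1)
      M <- C[, cols, drop = FALSE] %*% t(C[, cols, drop = FALSE])
      p_sum[(l * n_pairs) + seq_len(n_pairs)] <-
        p_sum[(l * n_pairs) + seq_len(n_pairs)] +
        M[cbind(pair_i[, 1], pair_i[, 2])]
      col0 <- col0 + 2L * l + 1L
    }
  }
  p <- p_sum / n
  names(p) <- unlist(lapply(0:lmax, function(l) {
    sprintf("soap_l%d_n%d_n%d", l, pair_i[, 1], pair_i[, 2])
  }))
  p
}
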