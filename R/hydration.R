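# Trajectory-derived hydration descriptors: the water-solute distance
# probability histogram P(d), solvation-shell minima, hydration numbers,
# hydrogen-bond counts, size metrics and the ten hydration indices.

# Evenly spaced frame sample (all frames when fewer than n_samples exist).
sample_frame_indices <- function(n_frames, n_samples) {
  if (n_frames <= n_samples) return(seq_len(n_frames))
  unique(round(seq(1, n_frames, length.out = n_samples)))
}

#' Water-solute distance probability histogram P(d)
#'
#' Collects all pairwise minimum-image distances between every water oxygen
#' and every solute atom over sampled frames, discards distances at or above
#' `d_cut`, and normalises to the probability density
#' \deqn{P(d) = n_d / (\Delta d \sum_i n_i)}
#' with uniform bin width \eqn{\Delta d = d_{cut} / n_{bins}}, so that
#' \eqn{\sum P(d)\,\Delta d = 1} whenever any distance falls below the
#' cutoff. Defaults (100 bins, 0.5 nm cutoff, hence 0.005 nm bins) follow
#' the published protocol.
#'
#' @param traj An [iri_trajectory()].
#' @param n_bins Number of uniform bins.
#' @param d_cut Cutoff distance \eqn{D_{cut}} (nm).
#' @param n_samples Frames sampled (evenly spaced; all if fewer exist).
#' @return An object of class `hydration_histogram`: list with `bin_edges`,
#'   `bin_centers`, `counts`, `density` (nm^-1), `n_distances`, `d_cut`.
#' @export
hydration_histogram <- function(traj, n_bins = 100, d_cut = 0.5,
                                n_samples = 100) {
  stopifnot(inherits(traj, "iri_trajectory"), n_bins >= 1, d_cut > 0)
  dd <- d_cut / n_bins
  counts <- integer(n_bins)
  for (fi in sample_frame_indices(length(traj$frames), n_samples)) {
    f <- traj$frames[[fi]]
    if (nrow(f$water_oxygen_xyz) == 0) next
    d <- pair_dists_pbc(f$water_oxygen_xyz, f$solute_xyz, f$box)
    d <- d[d < d_cut]
    if (length(d) > 0) {
      idx <- pmin(floor(d / dd) + 1L, n_bins)
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  n_tot <- sum(counts)
  if (n_tot == 0) {
    warning("no water-solute distances below d_cut = ", d_cut, " nm")
    density <- numeric(n_bins)
  } else {
    density <- counts / (dd * n_tot)
  }
  structure(list(
    bin_edges = seq(0, d_cut, length.out = n_bins + 1),
    bin_centers = seq(dd / 2, d_cut - dd / 2, length.out = n_bins),
    counts = counts, density = density, n_distances = n_tot,
    d_cut = d_cut, n_bins = as.integer(n_bins)
  ), class = "hydration_histogram")
}

#' @export
print.hydration_histogram <- function(x, ...) {
  cat("<hydration_histogram> ", x$n_bins, " bins to ", x$d_cut, " nm, ",
      x$n_distances, " distances\n", sep = "")
  invisible(x)
}

#' Solvation-shell minima from a hydration histogram
#'
#' Smooths the density with a centred moving average and locates the first
#' local minimum after the first local maximum (first-shell boundary) and
#' the next such minimum (second-shell boundary), reported at bin centres.
#' The histogram should extend beyond the descriptor range (>= 0.6 nm) since
#' the second-shell minimum often lies past 0.5 nm.
#'
#' @param hist A [hydration_histogram()] computed over a detection range.
#' @param smooth_window Centred moving-average window (bins).
#' @return Named numeric vector `c(shell1 = , shell2 = )` (nm).
#' @export
solvation_shell_minima <- function(hist, smooth_window = 5) {
  stopifnot(inherits(hist, "hydration_histogram"))
  if (hist$n_distances == 0) stop("empty histogram: no distances to analyse")
  s <- as.numeric(stats::filter(hist$density, rep(1 / smooth_window, smooth_window),
                                sides = 2))
  # shrink the window at the edges instead of dropping bins
  half <- (smooth_window - 1) %/% 2
  n <- length(s)
  for (i in which(is.na(s))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    s[i] <- mean(hist$density[lo:hi])
  }
  ds <- diff(s)
  # candidate turning points from sign changes of the smoothed slope
  state <- "rising0"  # before the first peak
  minima <- numeric(0)
  for (i in seq_along(ds)) {
    if (state %in% c("rising0", "rising") && ds[i] < 0) {
      state <- "falling"
    } else if (state == "falling" && ds[i] > 0) {
      minima <- c(minima, hist$bin_centers[i])
      state <- "rising"
      if (length(minima) == 2) break
    }
  }
  if (length(minima) < 1) stop("no first-shell minimum found within detection range")
  if (length(minima) < 2) stop("no second-shell minimum found within detection range")
  c(shell1 = minima[1], shell2 = minima[2])
}

#' Hydration number at a cutoff
#'
#' Mean number of water molecules whose oxygen lies within `cutoff` of the
#' solute (nearest-solute-atom minimum-image distance), averaged over
#' `n_samples` evenly spaced frames.
#'
#' @param traj An [iri_trajectory()].
#' @param cutoff Distance cutoff (nm).
#' @param n_samples Frames sampled.
#' @return Mean water count (scalar).
#' @export
hydration_number <- function(traj, cutoff, n_samples = 100) {
  stopifnot(inherits(traj, "iri_trajectory"), cutoff > 0)
  idx <- sample_frame_indices(length(traj$frames), n_samples)
  counts <- vapply(idx, function(fi) {
    f <- traj$frames[[fi]]
    if (nrow(f$water_oxygen_xyz) == 0) return(0)
    d <- pair_dists_pbc(f$water_oxygen_xyz, f$solute_xyz, f$box)
    sum(apply(d, 1, min) < cutoff)
  }, numeric(1))
  mean(counts)
}

# Solute covalent connectivity, donors (heavy atom + attached H) and
# acceptors (N/O/F) from elements + geometry of the first frame.
solute_hbond_sites <- function(frame) {
  el <- frame$solute_elements
  xyz <- frame$solute_xyz
  n <- length(el)
  acc <- which(el %in% c("N", "O", "F"))
  donors <- list()
  if (n > 1) {
    d <- pair_dists_pbc(xyz, xyz, frame$box)
    rcov <- covalent_radius_A(el) / 10  # nm
    for (a in acc) {
      hs <- which(el == "H" & seq_len(n) != a &
                    d[a, ] < 1.3 * (rcov[a] + rcov))
      for (h in hs) donors[[length(donors) + 1L]] <- c(D = a, H = h)
    }
  }
  list(acceptors = acc, donors = donors)
}

#' Water-solute hydrogen-bond count
#'
#' Mean number of water-solute hydrogen bonds per frame under geometric
#' criteria: donor-acceptor distance <= `dist_max` nm and
#' hydrogen-donor-acceptor angle <= `angle_max` degrees. Both directions are
#' counted: water as donor to solute N/O/F acceptors, and solute N/O/F-H
#' groups as donors to water oxygens. Solute donors/acceptors are perceived
#' from elements and covalent-distance connectivity.
#'
#' @param traj An [iri_trajectory()].
#' @param n_samples Frames sampled.
#' @param dist_max Donor-acceptor distance criterion (nm).
#' @param angle_max H-donor-acceptor angle criterion (degrees).
#' @return Mean hydrogen-bond count.
#' @export
hbond_count <- function(traj, n_samples = 100, dist_max = 0.35,
                        angle_max = 30) {
  stopifnot(inherits(traj, "iri_trajectory"))
  sites <- solute_hbond_sites(traj$frames[[1]])
  if (length(sites$acceptors) == 0 && length(sites$donors) == 0) return(0)
  cos_min <- cos(angle_max * pi / 180)
  idx <- sample_frame_indices(length(traj$frames), n_samples)
  per_frame <- vapply(idx, function(fi) {
    f <- traj$frames[[fi]]
    nw <- nrow(f$water_oxygen_xyz)
    if (nw == 0) return(0)
    count <- 0L
    # water as donor
    for (a in sites$acceptors) {
      apos <- f$solute_xyz[a, ]
      dv <- disp_pbc(apos, f$water_oxygen_xyz, f$box)  # O_w -> A is -dv rows
      dOA <- sqrt(rowSums(dv^2))
      for (w in which(dOA <= dist_max)) {
        ow <- f$water_oxygen_xyz[w, ]
        to_a <- -dv[w, ] / dOA[w]  # unit O_w -> A (min image)
        for (hrow in c(2 * w - 1, 2 * w)) {
          hv <- disp_pbc(ow, f$water_hydrogen_xyz[hrow, , drop = FALSE], f$box)[1, ]
          hv <- hv / sqrt(sum(hv^2))
          if (sum(hv * to_a) >= cos_min) count <- count + 1L
        }
      }
    }
    # solute as donor
    for (dh in sites$donors) {
      dpos <- f$solute_xyz[dh[["D"]], ]
      hv <- disp_pbc(dpos, f$solute_xyz[dh[["H"]], , drop = FALSE], f$box)[1, ]
      hv <- hv / sqrt(sum(hv^2))
      wv <- disp_pbc(dpos, f$water_oxygen_xyz, f$box)
      dDW <- sqrt(rowSums(wv^2))
      for (w in which(dDW <= dist_max)) {
        if (sum(hv * wv[w, ] / dDW[w]) >= cos_min) count <- count + 1L
      }
    }
    as.numeric(count)
  }, numeric(1))
  mean(per_frame)
}

#' Molecular size metrics: vdW volume, SASA, molecular weight
#'
#' Grid-based van der Waals volume (0.02 nm grid, Bondi radii) and
#' Shrake-Rupley solvent-accessible surface area (0.14 nm probe, 960 sphere
#' points) from the conformer, plus the formula weight from the SMILES.
#'
#' @param conf A [conformer()] (with hydrogens, nm coordinates).
#' @param smiles The molecule's SMILES (for the formula weight).
#' @param grid_spacing_A Volume grid spacing (Angstrom).
#' @param probe_radius_A SASA probe radius (Angstrom).
#' @return Named vector `c(volume = , sasa = , mw = )` in Angstrom^3,
#'   Angstrom^2, g/mol.
#' @export
size_metrics <- function(conf, smiles, grid_spacing_A = 0.2,
                         probe_radius_A = 1.4) {
  stopifnot(inherits(conf, "conformer"))
  xyz <- conf$xyz * 10  # Angstrom
  radii <- vdw_radius_A(conf$elements)
  vol <- vdw_volume_grid(xyz, radii, grid_spacing_A)
  sasa <- shrake_rupley_sasa(xyz, radii, probe_radius_A)
  desc <- compute_standard_descriptors(smiles)
  c(volume = vol, sasa = sasa, mw = desc$MolWt[1])
}

vdw_volume_grid <- function(xyz_A, radii_A, spacing = 0.2) {
  lo <- apply(xyz_A, 2, min) - max(radii_A) - spacing
  hi <- apply(xyz_A, 2, max) + max(radii_A) + spacing
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  occupied <- rep(FALSE, nrow(pts))
  for (a in seq_len(nrow(xyz_A))) {
    d2 <- (pts[, 1] - xyz_A[a, 1])^2 + (pts[, 2] - xyz_A[a, 2])^2 +
      (pts[, 3] - xyz_A[a, 3])^2
    occupied <- occupied | (d2 <= radii_A[a]^2)
  }
  sum(occupied) * spacing^3
}

# Deterministic golden-spiral unit sphere points.
sphere_points <- function(n = 960) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shrake_rupley_sasa <- function(xyz_A, radii_A, probe = 1.4, n_points = 960) {
  sp <- sphere_points(n_points)
  r_ext <- radii_A + probe
  total <- 0
  for (a in seq_len(nrow(xyz_A))) {
    pts <- sweep(sp * r_ext[a], 2, xyz_A[a, ], "+")
    accessible <- rep(TRUE, n_points)
    for (b in seq_len(nrow(xyz_A))) {
      if (b == a) next
      d2 <- (pts[, 1] - xyz_A[b, 1])^2 + (pts[, 2] - xyz_A[b, 2])^2 +
        (pts[, 3] - xyz_A[b, 3])^2
      accessible <- accessible & (d2 > r_ext[b]^2)
      if (!any(accessible)) break
    }
    total <- total + sum(accessible) / n_points * 4 * pi * r_ext[a]^2
  }
  total
}

# Fixed order of the ten hydration-number cutoff specifications.
hydration_cutoff_specs <- function(fixed_cutoffs_nm = seq(0.20, 0.50, by = 0.05)) {
  c(sprintf("c%03.0f", fixed_cutoffs_nm * 100), "shell1", "shell2", "hbond")
}

#' Full hydration profile of one compound
#'
#' Computes the ten hydration numbers (seven fixed cutoffs, the first- and
#' second-shell minima cutoffs detected from a wide-range histogram, and the
#' hydrogen-bond count) plus the three size metrics, averaged over sampled
#' trajectory frames.
#'
#' @param traj An [iri_trajectory()].
#' @param conf A [conformer()] for the size metrics.
#' @param smiles The compound SMILES.
#' @param config An [iri_config()].
#' @param shell_cutoffs Optional `c(shell1 =, shell2 =)` override (nm); when
#'   `NULL` they are detected via [solvation_shell_minima()].
#' @return An object of class `hydration_profile`: list with
#'   `hydration_numbers` (named length-10), `size_metrics`, `shell_minima`.
#' @export
hydration_profile <- function(traj, conf, smiles, config = iri_config(),
                              shell_cutoffs = NULL) {
  dd <- config$histogram_cutoff_nm / config$histogram_bins
  if (is.null(shell_cutoffs)) {
    detect <- hydration_histogram(
      traj, n_bins = round(config$shell_detect_cutoff_nm / dd),
      d_cut = config$shell_detect_cutoff_nm,
      n_samples = config$n_conformations
    )
    shell_cutoffs <- solvation_shell_minima(detect, config$shell_smooth_window)
  }
  cutoffs <- c(config$fixed_cutoffs_nm, shell_cutoffs[["shell1"]],
               shell_cutoffs[["shell2"]])
  hn <- vapply(cutoffs, function(ct) {
    hydration_number(traj, ct, n_samples = config$n_conformations)
  }, numeric(1))
  hb <- hbond_count(traj, n_samples = config$n_conformations,
                    dist_max = config$hbond_dist_max_nm,
                    angle_max = config$hbond_angle_max_deg)
  numbers <- stats::setNames(c(hn, hb),
                             hydration_cutoff_specs(config$fixed_cutoffs_nm))
  structure(list(hydration_numbers = numbers,
                 size_metrics = size_metrics(conf, smiles),
                 shell_minima = shell_cutoffs),
            class = "hydration_profile")
}

#' Hydration indices
#'
#' The ten hydration numbers of a profile divided by one size metric. Only
#' the volume-normalised indices feed the learned models; SASA- and
#' MW-normalised variants serve the correlation report.
#'
#' @param profile A [hydration_profile()].
#' @param metric `"volume"`, `"sasa"` or `"mw"`.
#' @return Named numeric vector of length 10.
#' @export
hydration_indices <- function(profile, metric = c("volume", "sasa", "mw")) {
  metric <- match.arg(metric)
  stopifnot(inherits(profile, "hydration_profile"))
  m <- profile$size_metrics[[metric]]
  if (!is.finite(m) || m <= 0) stop("size metric '", metric, "' must be positive")
  profile$hydration_numbers / m
}

#' Correlations between %MGS and hydration quantities
#'
#' One Pearson correlation per (quantity, cutoff spec, metric) cell:
#' hydration numbers at each of the ten cutoff specifications, and hydration
#' indices under each size metric. Constant columns yield an `undefined`
#' flag rather than an error. This is the tabular form of the hydration
#' correlation heatmap.
#'
#' @param compounds Compound tibble with `mgs_percent` (>= 3 rows).
#' @param profiles List of [hydration_profile()]s matching `compounds` rows.
#' @param path Optional CSV output path.
#' @return A tibble with columns `quantity`, `cutoff_spec`, `metric`, `pcc`,
#'   `undefined`.
#' @export
hydration_correlation_report <- function(compounds, profiles, path = NULL) {
  stopifnot(nrow(compounds) >= 3, length(profiles) == nrow(compounds),
            all(!is.na(compounds$mgs_percent)))
  mgs <- compounds$mgs_percent
  specs <- names(profiles[[1]]$hydration_numbers)
  safe_pcc <- function(x) {
    if (stats::sd(x) < 1e-12 || stats::sd(mgs) < 1e-12) {
      return(c(NA_real_, TRUE))
    }
    c(stats::cor(x, mgs), FALSE)
  }
  rows <- list()
  for (sp in specs) {
    x <- vapply(profiles, function(p) p$hydration_numbers[[sp]], numeric(1))
    r <- safe_pcc(x)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "hydration_number", cutoff_spec = sp, metric = NA_character_,
      pcc = r[1], undefined = as.logical(r[2]))
    for (met in c("volume", "sasa", "mw")) {
      xi <- vapply(profiles, function(p) {
        p$hydration_numbers[[sp]] / p$size_metrics[[met]]
      }, numeric(1))
      ri <- safe_pcc(xi)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = "hydration_index", cutoff_spec = sp, metric = met,
        pcc = ri[1], undefined = as.logical(ri[2]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
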