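# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# A small rigid two-atom solute near the centre of a 4 nm box.
tiny_solute <- function() {
  conformer(c("C", "O"), rbind(c(2, 2, 2), c(2.14, 2, 2)))
}

# A slightly larger solute for hydration tests (formate-like fragment).
acid_solute <- function() {
  conformer(c("C", "O", "O", "H"),
            rbind(c(2.00, 2.00, 2.00),
                  c(2.12, 2.06, 2.00),
                  c(2.00, 1.86, 2.00),
                  c(1.93, 2.07, 2.00)))
}

# Cached synthetic SAR tables + standard-descriptor block.
cached_sar <- function(n = 63, noise_sd = 10, seed = 1, skip = 0) {
  key <- sprintf("sar_%d_%s_%d_%d", n, noise_sd, seed, skip)
  cache_get(key, function() generate_sar_dataset(n, noise_sd, seed, skip = skip))
}

cached_standard_block <- function(sar) {
  key <- paste0("std_", rlang::hash(sar$smiles))
  cache_get(key, function() featurize(sar, "standard"))
}

cached_conformers <- function(smiles, seed = 5) {
  key <- paste0("conf_", rlang::hash(list(smiles, seed)))
  cache_get(key, function() generate_conformers(smiles, seed = seed))
}

# ---- independent oracles -------------------------------------------------

# Minimum-image distance by explicit per-component arithmetic (scalar loop).
oracle_min_image_dist <- function(a, b, box) {
  s <- 0
  for (k in 1:3) {
    d <- a[k] - b[k]
    while (d > box[k] / 2) d <- d - box[k]
    while (d < -box[k] / 2) d <- d + box[k]
    s <- s + d^2
  }
  sqrt(s)
}

# Brute-force double-loop histogram counts over (water, solute-atom) pairs.
oracle_histogram_counts <- function(traj, n_bins, d_cut, n_samples = 100) {
  dd <- d_cut / n_bins
  counts <- integer(n_bins)
  idx <- iriscreen:::sample_frame_indices(length(traj$frames), n_samples)
  for (fi in idx) {
    f <- traj$frames[[fi]]
    nw <- nrow(f$water_oxygen_xyz)
    ns <- nrow(f$solute_xyz)
    if (nw == 0) next
    for (w in seq_len(nw)) {
      for (s in seq_len(ns)) {
        d <- oracle_min_image_dist(f$water_oxygen_xyz[w, ], f$solute_xyz[s, ], f$box)
        if (d < d_cut) {
          b <- min(floor(d / dd) + 1L, n_bins)
          counts[b] <- counts[b] + 1L
        }
      }
    }
  }
  counts
}

# Brute-force per-frame count of waters with nearest-solute distance < cutoff.
oracle_hydration_counts <- function(traj, cutoff) {
  vapply(traj$frames, function(f) {
    nw <- nrow(f$water_oxygen_xyz)
    if (nw == 0) return(0)
    n_in <- 0
    for (w in seq_len(nw)) {
      dmin <- Inf
      for (s in seq_len(nrow(f$solute_xyz))) {
        d <- oracle_min_image_dist(f$water_oxygen_xyz[w, ], f$solute_xyz[s, ], f$box)
        dmin <- min(dmin, d)
      }
      if (dmin < cutoff) n_in <- n_in + 1
    }
    n_in
  }, numeric(1))
}

# Build a hydration_histogram object with a planted density (for minima
# detection tests).
planted_histogram <- function(density, d_cut) {
  n <- length(density)
  dd <- d_cut / n
  density <- density / (sum(density) * dd)
  structure(list(
    bin_edges = seq(0, d_cut, length.out = n + 1),
    bin_centers = seq(dd / 2, d_cut - dd / 2, length.out = n),
    counts = round(density * dd * 1e6), density = density,
    n_distances = 1e6, d_cut = d_cut, n_bins = n
  ), class = "hydration_histogram")
}

# Random rigid rotation matrix (seeded by caller).
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
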