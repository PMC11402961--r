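# Hydration histogram, shell minima, hydration numbers, hydrogen bonds,
# size metrics, indices and the correlation report.

test_that("a single water-solute distance lands in one bin at density 1/bin width", {
  frame <- solvated_frame(
    solute_elements = "C", solute_xyz = matrix(c(2, 2, 2), 1),
    water_oxygen_xyz = matrix(c(2.252, 2, 2), 1),
    water_hydrogen_xyz = rbind(c(2.31, 2.05, 2), c(2.31, 1.95, 2)),
    box = c(4, 4, 4))
  traj <- iri_trajectory(list(frame))
  h <- hydration_histogram(traj, n_bins = 100, d_cut = 0.5)
  expect_equal(h$n_distances, 1)
  expect_equal(sum(h$density > 0), 1)
  hot <- which(h$density > 0)
  expect_true(h$bin_edges[hot] <= 0.252 && 0.252 < h$bin_edges[hot + 1])
  expect_equal(h$density[hot], 1 / 0.005, tolerance = 1e-12)  # 200 nm^-1
  expect_equal(sum(h$density) * 0.005, 1, tolerance = 1e-12)
  # default binning: 100 bins over 0.5 nm => 0.005 nm bins
  expect_equal(diff(h$bin_edges)[1], 0.005)
})

test_that("histogram counts equal a brute-force double loop with explicit minimum image", {
  traj <- generate_solvated_trajectory(
    acid_solute(),
    shells = list(list(inner_nm = 0.22, outer_nm = 0.34, n_waters = 6),
                  list(inner_nm = 0.38, outer_nm = 0.48, n_waters = 8)),
    n_bulk_waters = 15, box_nm = 3, n_frames = 4, seed = 21)
  h <- hydration_histogram(traj, n_bins = 60, d_cut = 0.6)
  expect_identical(h$counts, oracle_histogram_counts(traj, 60, 0.6))
  expect_equal(sum(h$density) * (0.6 / 60), 1, tolerance = 1e-12)
})

test_that("an empty-shell trajectory warns and yields a zero histogram", {
  traj <- generate_solvated_trajectory(
    tiny_solute(), shells = list(), n_bulk_waters = 5, box_nm = 4,
    n_frames = 2, seed = 5)
  expect_warning(h <- hydration_histogram(traj, 100, 0.2), "no water-solute")
  expect_equal(h$n_distances, 0)
  expect_true(all(h$density == 0))
})

test_that("solvation-shell minima are recovered from planted bimodal densities", {
  centers <- seq(0.005, 0.795, by = 0.01)  # 80 bins to 0.8 nm
  # piecewise-linear density with vertices planted at the shell minima
  # slopes symmetric around each vertex so the smoothing window does not
  # displace the minima
  bimodal <- approx(x = c(0, 0.28, 0.34, 0.40, 0.47, 0.54, 0.80),
                    y = c(0.1, 3.0, 0.5, 2.0, 0.3, 2.0, 2.0),
                    xout = centers)$y
  mins <- solvation_shell_minima(planted_histogram(bimodal, 0.8))
  expect_lt(abs(mins[["shell1"]] - 0.34), 0.0101)  # within one bin width
  expect_lt(abs(mins[["shell2"]] - 0.47), 0.0101)

  expect_error(solvation_shell_minima(planted_histogram(centers, 0.8)),
               "first-shell")  # monotonically increasing
  # one peak, one minimum: the first shell is found, the second errors
  single_peak <- approx(x = c(0, 0.30, 0.45, 0.80), y = c(0.1, 3.0, 0.4, 1.8),
                        xout = centers)$y
  expect_error(solvation_shell_minima(planted_histogram(single_peak, 0.8)),
               "second-shell")
})

test_that("hydration numbers count waters by nearest-solute distance", {
  traj <- generate_solvated_trajectory(
    acid_solute(),
    shells = list(list(inner_nm = 0.25, outer_nm = 0.30, n_waters = 4)),
    n_bulk_waters = 12, box_nm = 4, n_frames = 6, seed = 31)
  expect_equal(hydration_number(traj, 0.30), 4)
  # brute-force equality and monotonicity over increasing cutoffs
  cutoffs <- seq(0.20, 0.50, by = 0.05)
  hn <- vapply(cutoffs, function(ct) hydration_number(traj, ct), numeric(1))
  oracle <- vapply(cutoffs, function(ct) mean(oracle_hydration_counts(traj, ct)),
                   numeric(1))
  expect_equal(hn, oracle)
  expect_true(all(diff(hn) >= 0))

  dry <- generate_solvated_trajectory(tiny_solute(), list(), 0, 4, 2, seed = 1)
  expect_equal(hydration_number(dry, 0.5), 0)
})

test_that("hydrogen bonds satisfy both geometric criteria", {
  # water donating to a carboxylate-like oxygen: O_w at 0.28 nm, H on the axis
  solute <- list(elements = c("C", "O"), xyz = rbind(c(2, 2, 2), c(2.123, 2, 2)))
  ow <- c(2.123 + 0.28, 2, 2)
  h_on_axis <- ow - c(0.09572, 0, 0)           # points straight at the acceptor
  h_other <- ow + c(0.09572 * cos(104.52 * pi / 180),
                    0.09572 * sin(104.52 * pi / 180), 0)
  frame <- solvated_frame(solute$elements, solute$xyz,
                          matrix(ow, 1), rbind(h_on_axis, h_other), c(4, 4, 4))
  traj <- iri_trajectory(list(frame))
  expect_equal(hbond_count(traj), 1.0)

  # rotate the donating hydrogen to 60 degrees: criterion violated
  h_rot <- ow + 0.09572 * c(-cos(60 * pi / 180), sin(60 * pi / 180), 0)
  frame2 <- solvated_frame(solute$elements, solute$xyz,
                           matrix(ow, 1), rbind(h_rot, h_other), c(4, 4, 4))
  expect_equal(hbond_count(iri_trajectory(list(frame2))), 0.0)

  # an alkane solute has no donors or acceptors
  alkane <- solvated_frame(c("C", "C"), rbind(c(2, 2, 2), c(2.15, 2, 2)),
                           matrix(ow, 1), rbind(h_on_axis, h_other), c(4, 4, 4))
  expect_equal(hbond_count(iri_trajectory(list(alkane))), 0.0)
})

test_that("size metrics behave as geometry dictates", {
  confs <- cached_conformers("NCC(=O)O", seed = 9)  # glycine
  sm <- size_metrics(confs[[1]], "NCC(=O)O")
  expect_equal(sm[["mw"]], 75.07, tolerance = 1e-3)
  expect_gt(sm[["volume"]], 0)
  expect_gt(sm[["sasa"]], 0)

  # single carbon: grid volume within 5% of the vdW sphere volume
  single <- conformer("C", matrix(c(0, 0, 0), 1))
  vol <- iriscreen:::vdw_volume_grid(matrix(c(0, 0, 0), 1), 1.70)
  expect_equal(vol, 4 / 3 * pi * 1.70^3, tolerance = 0.05)

  # doubling all coordinates (fixed radii) increases the surface area
  big <- conformer(confs[[1]]$elements, confs[[1]]$xyz * 2)
  expect_gt(iriscreen:::shrake_rupley_sasa(big$xyz * 10,
                                           iriscreen:::vdw_radius_A(big$elements)),
            iriscreen:::shrake_rupley_sasa(confs[[1]]$xyz * 10,
                                           iriscreen:::vdw_radius_A(confs[[1]]$elements)))
})

test_that("hydration indices divide the ten numbers by one size metric", {
  numbers <- stats::setNames(c(0, 1, 2.5, 4, 6, 8, 10, 3.2, 7.5, 1.5),
                             iriscreen:::hydration_cutoff_specs())
  profile <- structure(list(hydration_numbers = numbers,
                            size_metrics = c(volume = 100, sasa = 250, mw = 120),
                            shell_minima = c(shell1 = 0.34, shell2 = 0.46)),
                       class = "hydration_profile")
  idx <- hydration_indices(profile, "mw")
  expect_length(idx, 10)
  expect_equal(idx[["c030"]], 2.5 / 120)
  expect_equal(unname(idx["c045"] * 120), 8)
  expect_equal(unname(hydration_indices(structure(list(
    hydration_numbers = numbers, size_metrics = c(volume = 100, sasa = 1, mw = 1)),
    class = "hydration_profile"), "volume")[["c050"]]), 0.1)  # 10 / 100
  # inverse operation recovers the numbers for random profiles
  set.seed(3)
  for (rep in 1:5) {
    profile$hydration_numbers <- stats::setNames(runif(10, 0, 20), names(numbers))
    for (m in c("volume", "sasa", "mw")) {
      expect_equal(hydration_indices(profile, m) * profile$size_metrics[[m]],
                   profile$hydration_numbers)
    }
  }
  expect_equal(unname(hydration_indices(structure(list(
    hydration_numbers = numbers * 0,
    size_metrics = c(volume = 50, sasa = 1, mw = 1)), class = "hydration_profile"),
    "volume")), rep(0, 10))
  profile$size_metrics["volume"] <- 0
  expect_error(hydration_indices(profile, "volume"), "positive")
})

test_that("full profiles assemble ten numbers from a shell-structured trajectory", {
  # single-atom solute: all-pairs distances coincide with nearest distances,
  # so the planted gap shows up cleanly in the histogram
  traj <- generate_solvated_trajectory(
    conformer("C", matrix(c(1.6, 1.6, 1.6), 1)),
    shells = list(list(inner_nm = 0.25, outer_nm = 0.32, n_waters = 15),
                  list(inner_nm = 0.40, outer_nm = 0.50, n_waters = 25)),
    n_bulk_waters = 25, box_nm = 3.2, n_frames = 40, seed = 41)
  confs <- cached_conformers("OC=O", seed = 9)
  prof <- hydration_profile(traj, confs[[1]], "OC=O")
  expect_length(prof$hydration_numbers, 10)
  expect_named(prof$hydration_numbers, iriscreen:::hydration_cutoff_specs())
  # detected first-shell boundary sits in the planted gap (0.32, 0.40)
  expect_gt(prof$shell_minima[["shell1"]], 0.31)
  expect_lt(prof$shell_minima[["shell1"]], 0.41)
  # fixed-cutoff numbers are monotone
  fixed <- prof$hydration_numbers[1:7]
  expect_true(all(diff(fixed) >= 0))
  expect_equal(unname(prof$hydration_numbers[["c035"]]), 15)  # first shell planted
})

test_that("correlation report matches a hand-rolled covariance formula", {
  set.seed(12)
  n <- 10
  specs <- iriscreen:::hydration_cutoff_specs()
  profiles <- lapply(seq_len(n), function(i) {
    structure(list(
      hydration_numbers = stats::setNames(runif(10, 0, 15), specs),
      size_metrics = c(volume = runif(1, 80, 150), sasa = runif(1, 150, 300),
                       mw = runif(1, 80, 200))), class = "hydration_profile")
  })
  compounds <- tibble::tibble(id = sprintf("c%02d", 1:n), smiles = "CCO",
                              mgs_percent = runif(n, 10, 100))
  rep_tbl <- hydration_correlation_report(compounds, profiles)
  expect_equal(nrow(rep_tbl), 10 * 4)  # numbers + three index metrics
  hand_pcc <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  }
  for (row in sample(nrow(rep_tbl), 8)) {
    r <- rep_tbl[row, ]
    x <- vapply(profiles, function(p) {
      v <- p$hydration_numbers[[r$cutoff_spec]]
      if (r$quantity == "hydration_index") v <- v / p$size_metrics[[r$metric]]
      v
    }, numeric(1))
    expect_equal(r$pcc, hand_pcc(x, compounds$mgs_percent), tolerance = 1e-12)
  }

  # perfect and anti-perfect construction
  prof2 <- profiles
  for (i in seq_len(n)) {
    prof2[[i]]$hydration_numbers[["c020"]] <- compounds$mgs_percent[i]
    prof2[[i]]$hydration_numbers[["c025"]] <- -compounds$mgs_percent[i] + 120
    prof2[[i]]$hydration_numbers[["c030"]] <- 7  # constant -> undefined
  }
  rep2 <- hydration_correlation_report(compounds, prof2)
  get <- function(spec) rep2[rep2$quantity == "hydration_number" &
                               rep2$cutoff_spec == spec, ]
  expect_equal(get("c020")$pcc, 1.0, tolerance = 1e-12)
  expect_equal(get("c025")$pcc, -1.0, tolerance = 1e-12)
  expect_true(get("c030")$undefined)
  expect_true(is.na(get("c030")$pcc))
})
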