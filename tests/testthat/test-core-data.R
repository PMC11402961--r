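# Compound tables, trajectory/conformer IO and configuration.

test_that("compound tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,mgs,sd",
               "a1,NC(C)C(=O)O,35.2,4.1",
               "a2,OCC(O)CO,88.0,9.5",
               "a3,CC(=O)NC1CCCCC1,61.5,7.2"), path)
  tbl <- read_compound_table(path, "Amino")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$id, c("a1", "a2", "a3"))
  expect_equal(tbl$mgs_percent, c(35.2, 88.0, 61.5))

  out <- withr::local_tempfile(fileext = ".csv")
  write_compound_table(tbl, out)
  back <- read_compound_table(out, "Amino")
  expect_equal(back$smiles, tbl$smiles)
  expect_equal(back$mgs_percent, tbl$mgs_percent)
  expect_equal(back$mgs_sd, tbl$mgs_sd)
})

test_that("malformed compound tables fail with row/column identification", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,mgs,sd",
               "ok,CCO,50,5",
               "bad,C1CC,40,5"), path)
  expect_error(read_compound_table(path, "Amino"), "row 2.*bad")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,mgs", "a,CCO,50"), path2)
  expect_error(read_compound_table(path2, "Amino"), "sd")

  # measured dataset must carry %MGS; a library need not
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,mgs,sd", "a,CCO,,"), path3)
  expect_error(read_compound_table(path3, "Amino"), "without %MGS")
  expect_silent(lib <- read_compound_table(path3, "library"))
  expect_true(is.na(lib$mgs_percent))
})

test_that("missing replicate SD on a measured compound warns but is kept", {
  tbl <- tibble::tibble(id = c("a", "b"), smiles = c("CCO", "CCN"),
                        dataset_tag = "Glyco2", mgs_percent = c(50, 60),
                        mgs_sd = c(5, NA))
  expect_warning(out <- as_compound_table(tbl), "replicate SD")
  expect_equal(nrow(out), 2)
})

test_that("trajectories round-trip through GRO and extended XYZ", {
  traj <- generate_solvated_trajectory(
    tiny_solute(), shells = list(list(inner_nm = 0.25, outer_nm = 0.32, n_waters = 3)),
    n_bulk_waters = 8, box_nm = 4, n_frames = 5, seed = 11)
  for (fmt in c("gro", "xyz")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trajectory(traj, path)
    back <- read_trajectory(path)
    expect_length(back$frames, 5)
    tol <- if (fmt == "gro") 6e-4 else 1e-6  # declared text precision
    for (fi in seq_len(5)) {
      expect_equal(back$frames[[fi]]$solute_xyz, traj$frames[[fi]]$solute_xyz,
                   tolerance = tol, ignore_attr = TRUE)
      expect_equal(back$frames[[fi]]$water_oxygen_xyz,
                   traj$frames[[fi]]$water_oxygen_xyz,
                   tolerance = tol, ignore_attr = TRUE)
      expect_equal(back$frames[[fi]]$box, traj$frames[[fi]]$box,
                   tolerance = 1e-5)
      # atom bookkeeping: waters x 3 + solute = total
      expect_equal(nrow(back$frames[[fi]]$water_hydrogen_xyz),
                   2 * nrow(back$frames[[fi]]$water_oxygen_xyz))
      expect_equal(length(back$frames[[fi]]$solute_elements), 2)
    }
  }
})

test_that("trajectory parsing errors identify the offending frame", {
  traj <- generate_solvated_trajectory(
    tiny_solute(), shells = list(), n_bulk_waters = 4, box_nm = 4,
    n_frames = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, path)
  lines <- readLines(path)
  # each frame: title + count + 14 atoms + box = 17 lines; drop an atom in frame 3
  f3 <- 2 * 17 + 1
  lines <- lines[-(f3 + 2)]
  lines[f3 + 1] <- sprintf("%5d", 13)
  writeLines(lines, path)
  expect_error(read_trajectory(path), "frame 3")

  path2 <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, path2)
  lines <- readLines(path2)
  writeLines(lines[-17], path2)  # remove first box line
  expect_error(read_trajectory(path2), "box")
})

test_that("conformers round-trip through XYZ and read from PDB", {
  conf <- tiny_solute()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_conformer(conf, path)
  back <- read_conformer(path)
  expect_equal(back$elements, conf$elements)
  expect_equal(back$xyz, conf$xyz, tolerance = 1e-7)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  MOL A   1      20.000  20.000  20.000  1.00  0.00           C",
    "ATOM      2  O1  MOL A   1      21.400  20.000  20.000  1.00  0.00           O",
    "END"), pdb)
  cpdb <- read_conformer(pdb)
  expect_equal(cpdb$elements, c("C", "O"))
  expect_equal(cpdb$xyz[2, 1] - cpdb$xyz[1, 1], 0.14, tolerance = 1e-9)
})

test_that("configuration files override defaults and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "histogram_bins = 50",
               "fixed_cutoffs_nm = 0.2, 0.3, 0.4", "seed = 7"), path)
  cfg <- read_iri_config(path)
  expect_equal(cfg$histogram_bins, 50L)
  expect_equal(cfg$fixed_cutoffs_nm, c(0.2, 0.3, 0.4))
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$activity_threshold_mgs, 70)  # untouched default

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("no_such_key = 1", bad)
  expect_error(read_iri_config(bad), "unknown config key")
})
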