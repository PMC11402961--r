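# Seed selection, library-construction filters and the screening cascade.

test_that("seed selection takes activity order statistics with id tie-breaks", {
  sar <- cached_sar(n = 30, noise_sd = 10, seed = 17)
  seeds <- select_seeds(sar, screen_config())
  expect_equal(nrow(seeds), 20)
  expect_equal(sum(seeds$role == "active"), 15)
  asc <- sort(sar$mgs_percent)
  expect_setequal(seeds$mgs_percent[seeds$role == "active"], asc[1:15])
  expect_setequal(seeds$mgs_percent[seeds$role == "inactive"], rev(asc)[1:5])
  expect_error(select_seeds(sar[1:10, ]), "at least 20")

  # duplicate %MGS at the boundary: deterministic id-order tie-break
  dup <- tibble::tibble(id = sprintf("x%02d", 1:21), smiles = "CCO",
                        mgs_percent = c(1:14, rep(50, 3), 80:83))
  s <- select_seeds(dup, screen_config(n_active_seeds = 15, n_inactive_seeds = 5))
  expect_true("x15" %in% s$id[s$role == "active"])  # first of the tied 50s
  expect_false(any(c("x16", "x17") %in% s$id[s$role == "active"]))

  # brute-force sorting oracle over random tables
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(25:60, 1)
    tbl <- tibble::tibble(id = sprintf("r%03d", sample(n)), smiles = "CCO",
                          mgs_percent = round(runif(n, 0, 110), 1))
    s <- select_seeds(tbl, screen_config())
    ord <- tbl[order(tbl$mgs_percent, tbl$id), ]
    expect_identical(s$id[s$role == "active"], ord$id[1:15])
    ord2 <- tbl[order(-tbl$mgs_percent, tbl$id), ]
    expect_identical(s$id[s$role == "inactive"], ord2$id[1:5])
  }
})

test_that("library filters remove overlap, co-salts, dissimilar and greasy compounds", {
  training <- c("NC(C)C(=O)O", "NC(CC(C)C)C(=O)O", "NC(CO)C(=O)O")
  seeds <- training[1:2]
  candidates <- c(
    "NC(C)C(=O)O",          # hard overlap with training
    "CC(N)C(=O)O.Cl",       # co-salt: fingerprint-similar but multi-fragment
    "N[C@@H](C)C(=O)O",     # stereoisomer: similar, new canonical form -> kept
    "c1ccc2ccccc2c1",       # dissimilar to every seed
    "C1CC",                 # invalid
    "CCCCCCCCCCC(N)C(=O)O"  # dissimilar and greasy
  )
  lib <- suppressWarnings(
    build_prediction_library(candidates, seeds, training, screen_config()))
  audit <- attr(lib, "audit")
  expect_equal(sum(audit$removed) + nrow(lib), length(candidates))
  expect_equal(audit$removed[audit$filter == "invalid_smiles"], 1)
  expect_equal(lib$smiles, iriscreen:::canonical_smiles("N[C@@H](C)C(=O)O")[1])
  expect_false("NC(C)C(=O)O" %in% lib$smiles)
  expect_equal(audit$removed[audit$filter == "multi_fragment"], 1)
  expect_equal(audit$removed[audit$filter == "training_overlap"], 1)
  expect_false(any(grepl(".", lib$smiles, fixed = TRUE)))
  expect_true(all(lib$logp <= 1.8))
  expect_true(all(lib$max_tanimoto > 0.7))

  # brute-force predicate oracle on a constructed candidate set
  cands2 <- c("NC(CS)C(=O)O", "NC(C)C(=O)O", "OCC(O)CO", "NC(CCC)C(=O)O.Br")
  lib2 <- build_prediction_library(cands2, seeds, training, screen_config())
  can2 <- iriscreen:::canonical_smiles(cands2)
  keep_oracle <- vapply(seq_along(cands2), function(i) {
    sims <- vapply(seeds, function(s) tanimoto(cands2[i], s), numeric(1))
    max(sims) > 0.7 &&
      !(can2[i] %in% iriscreen:::canonical_smiles(training)) &&
      !grepl(".", can2[i], fixed = TRUE) &&
      compute_standard_descriptors(cands2[i])$MolLogP <= 1.8
  }, logical(1))
  expect_setequal(lib2$smiles, can2[keep_oracle])
})

screening_unit_fixture <- function() {
  cache_get("screen_unit", function() {
    sar <- cached_sar(n = 63, noise_sd = 10, seed = 1)
    ens <- train_ensemble(sar, list(standard = cached_standard_block(sar),
                                    standard2 = cached_standard_block(sar)),
                          model_config("regression", seed = 5))
    lib <- cached_sar(n = 12, noise_sd = 10, seed = 2, skip = 100)
    lib_blocks <- list(standard = featurize(lib, "standard"),
                       standard2 = featurize(lib, "standard"))
    list(ens = ens, lib = lib, lib_blocks = lib_blocks)
  })
}

test_that("screening ranks survivors and drops uncertain predictions", {
  fx <- screening_unit_fixture()
  scr <- screen_library(fx$lib, fx$ens, fx$lib_blocks,
                        screen_config(n_top = 3, n_bottom = 3))
  expect_equal(nrow(scr), 12)
  surv <- scr[!scr$uncertain, ]
  expect_gte(nrow(surv), 7)  # in-domain members agree for most candidates
  expect_true(all(diff(scr$ensemble_mean) >= 0))  # ranked ascending
  expect_identical(surv$id[surv$selected == "top" & !is.na(surv$selected)],
                   utils::head(surv$id, 3))
  # sorting oracle: top selections have the lowest surviving means
  expect_equal(sort(surv$ensemble_mean[which(surv$selected == "top")]),
               sort(surv$ensemble_mean)[1:3])

  # degenerate selection size covers the whole surviving library
  expect_warning(
    whole <- screen_library(fx$lib, fx$ens, fx$lib_blocks,
                            screen_config(n_top = 10, n_bottom = 10)),
    "whole surviving library")
  expect_true(all(!is.na(whole$selected[!whole$uncertain])))
})

test_that("the uncertainty filter excludes high-SD predictions from selection", {
  fx <- screening_unit_fixture()
  scr <- screen_library(fx$lib, fx$ens, fx$lib_blocks,
                        screen_config(n_top = 2, n_bottom = 2,
                                      uncertainty_sd_max = 15))
  expect_true(all(is.na(scr$selected[scr$uncertain])))
  # with an impossible SD ceiling everything is filtered -> error
  expect_error(screen_library(fx$lib, fx$ens, fx$lib_blocks,
                              screen_config(uncertainty_sd_max = 1e-9)),
               "uncertainty filter")
})
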