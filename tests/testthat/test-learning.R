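# Scaling, labelling, SMOTE, network training and LOO cross validation.

test_that("Min-Max scaling maps to [0,1] and inverts exactly", {
  sc <- minmax_fit(matrix(c(0, 50, 100), ncol = 1))
  expect_equal(as.numeric(minmax_apply(sc, matrix(c(0, 50, 100), ncol = 1))),
               c(0, 0.5, 1))
  expect_warning(sc2 <- minmax_fit(cbind(a = c(7, 7, 7), b = 1:3)), "constant")
  expect_equal(as.numeric(minmax_apply(sc2, cbind(c(7, 7, 7), 1:3))[, 1]),
               c(0, 0, 0))
  expect_error(minmax_apply(list(), matrix(1:4, 2)), "fitted")

  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(rnorm(60), 10)
    sc <- minmax_fit(m)
    expect_equal(minmax_invert(sc, minmax_apply(sc, m)), m, tolerance = 1e-10)
  }
})

test_that("activity labels follow the strict threshold with inactive boundary", {
  expect_equal(label_activity(5, 70), "active")
  expect_equal(label_activity(70, 70), "inactive")
  expect_equal(label_activity(c(69.99, 70.01), 70), c("active", "inactive"))
  expect_error(label_activity(-1), "negative")

  # sweeping the threshold gives a monotone non-decreasing active fraction
  sar <- cached_sar(n = 63, noise_sd = 10, seed = 1)
  fractions <- vapply(c(50, 60, 70, 80, 90), function(th) {
    mean(label_activity(sar$mgs_percent, th) == "active")
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
  # counting oracle at one threshold
  expect_equal(fractions[3], sum(sar$mgs_percent < 70) / nrow(sar))
})

test_that("SMOTE balances classes with synthetic points on minority segments", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(16, 5), 4))
  y <- c(rep("inactive", 10), rep("active", 4))
  bal <- smote_balance(X, y, seed = 6)
  expect_equal(unname(table(bal$labels)["active"]),
               unname(table(bal$labels)["inactive"]))
  expect_equal(nrow(bal$features), 20)
  # every synthetic row lies on a segment between two original minority rows
  minors <- X[y == "active", , drop = FALSE]
  synth <- bal$features[15:20, , drop = FALSE]
  on_segment <- function(p) {
    for (i in 1:3) for (j in (i + 1):4) {
      a <- minors[i, ]; b <- minors[j, ]
      u <- sum((p - a) * (b - a)) / sum((b - a)^2)
      if (u > -1e-9 && u < 1 + 1e-9 &&
          sqrt(sum((p - (a + u * (b - a)))^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))

  expect_identical(smote_balance(X, y, seed = 6), smote_balance(X, y, seed = 6))
  balanced <- smote_balance(X[1:8, ], rep(c("active", "inactive"), each = 4), seed = 1)
  expect_equal(nrow(balanced$features), 8)  # no-op on balanced input
  expect_error(smote_balance(X, rep("active", 14), seed = 1), "both classes")
  expect_error(smote_balance(X, c(rep("inactive", 13), "active"), seed = 1),
               "at least 2")
})

test_that("the network fits separable and representable toy problems", {
  set.seed(9)
  X <- rbind(matrix(rnorm(50, -2, 0.5), 25), matrix(rnorm(50, 2, 0.5), 25))
  X <- minmax_apply(minmax_fit(X), X)
  y <- rep(c("active", "inactive"), each = 25)
  fit <- train_model(X, y, model_config("classification", seed = 3))
  expect_equal(mean(predict(fit, X, type = "class") == y), 1.0)

  set.seed(10)
  Xr <- matrix(runif(600), 200, 3)
  yr <- Xr[, 1]
  fitr <- train_model(Xr, yr, model_config("regression", seed = 3))
  expect_lt(mean((predict(fitr, Xr) - yr)^2), 1e-3)

  # determinism: same seed and data give identical predictions
  fitr2 <- train_model(Xr, yr, model_config("regression", seed = 3))
  expect_identical(predict(fitr, Xr), predict(fitr2, Xr))
  expect_error(train_model(Xr, yr[-1], model_config()), "differ in length")
  expect_error(train_model(Xr[1:5, ], yr[1:5], model_config()), "at least 10")
})

test_that("leave-one-out returns one isolated prediction per compound", {
  sar <- cached_sar(n = 12, noise_sd = 0, seed = 6)
  fb <- cached_standard_block(sar)
  res <- loo_cv(sar, fb, model_config("regression", seed = 2))
  expect_s3_class(res, "iri_loo")
  expect_equal(nrow(res), 12)
  expect_setequal(res$id, sar$id)
  expect_error(loo_cv(sar[1:8, ], fb[1:8, ], model_config()), "at least 10")

  # leakage probe: corrupting the held-out target never changes its fold
  X <- iriscreen:::feature_matrix(fb, sar$id)
  cfg <- model_config("regression", seed = 2)
  for (i in c(1, 7, 12)) {
    mgs2 <- sar$mgs_percent
    mgs2[i] <- 119
    expect_identical(iriscreen:::loo_fold(X, sar$mgs_percent, i, cfg),
                     iriscreen:::loo_fold(X, mgs2, i, cfg))
  }
})

test_that("classification LOO applies fold-local SMOTE and thresholding", {
  sar <- cached_sar(n = 24, noise_sd = 10, seed = 13)
  fb <- cached_standard_block(sar)
  cfg <- model_config("classification", seed = 4)
  res <- loo_cv(sar, fb, cfg)
  expect_equal(nrow(res), 24)
  expect_true(all(res$prediction >= 0 & res$prediction <= 1))
  expect_identical(res$predicted_label,
                   ifelse(res$prediction > 0.5, "active", "inactive"))
  expect_identical(res$observed_label, label_activity(sar$mgs_percent, 70))
  g <- glance(res)
  expect_true(all(c("sensitivity", "specificity", "precision", "f_score") %in% names(g)))
})

test_that("multi-block LOO lines up per-model predictions", {
  sar <- cached_sar(n = 12, noise_sd = 0, seed = 6)
  fb <- cached_standard_block(sar)
  vocab <- build_clique_vocabulary(sar$smiles)
  blocks <- list(standard = fb, cliques = featurize(sar, "cliques", vocab = vocab))
  pm <- loo_cv_blocks(sar, blocks, model_config("regression", seed = 2))
  expect_named(pm, c("id", "observed", "standard", "cliques"))
  expect_equal(pm$observed, sar$mgs_percent)
  expect_false(identical(pm$standard, pm$cliques))
})
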