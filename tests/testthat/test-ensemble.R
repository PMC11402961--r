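# Voting, ensemble statistics, metrics and the exhaustive subset search.

test_that("majority voting follows the count with ties going inactive", {
  expect_equal(majority_vote(c("active", "inactive")), "inactive")
  expect_equal(majority_vote(rep("active", 3)), "active")
  expect_error(majority_vote(character(0)), "no votes")

  # all 2^3 patterns of three voters against a brute-force count oracle
  patterns <- expand.grid(rep(list(c("active", "inactive")), 3),
                          stringsAsFactors = FALSE)
  for (r in seq_len(nrow(patterns))) {
    votes <- unlist(patterns[r, ])
    expected <- if (sum(votes == "active") > sum(votes == "inactive")) {
      "active"
    } else {
      "inactive"
    }
    expect_equal(majority_vote(votes), expected)
    expect_equal(majority_vote(sample(votes)), expected)  # order-free
  }
})

test_that("ensemble regression reports mean and population SD", {
  expect_equal(ensemble_regress(c(20, 20, 20)), c(mean = 20, sd = 0))
  er <- ensemble_regress(c(10, 20, 30))
  expect_equal(er[["mean"]], 20)
  expect_equal(er[["sd"]], sqrt(200 / 3), tolerance = 1e-9)  # 8.1650
  expect_equal(ensemble_regress(c(30, 10, 20)), er)
  expect_equal(ensemble_regress(c(10, 20, 30), "sample")[["sd"]], 10)
  expect_error(ensemble_regress(5), "at least 2")
})

test_that("classification metrics are the standard confusion ratios", {
  perfect <- classification_metrics(c("active", "inactive", "active"),
                                    c("active", "inactive", "active"))
  expect_equal(as.numeric(perfect[1, 1:4]), rep(1, 4))

  # TP=3, FP=1, FN=2, TN=4
  truth <- c(rep("active", 5), rep("inactive", 5))
  pred <- c("active", "active", "active", "inactive", "inactive",
            "active", rep("inactive", 4))
  m <- classification_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f_score, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)

  # a published ensemble row is internally consistent under this definition:
  # precision 0.82 with sensitivity 0.62 gives an F-score that prints as 0.71
  expect_equal(round(2 * 0.82 * 0.62 / (0.82 + 0.62), 2), 0.71)

  # zero denominators are flagged undefined, never silently zero
  none_pred <- classification_metrics(truth, rep("inactive", 10))
  expect_true(is.na(none_pred$precision))
  expect_true("precision" %in% attr(none_pred, "undefined"))
})

test_that("regression metrics match hand computation and affine invariance", {
  ident <- regression_metrics(c(10, 50, 90), c(10, 50, 90))
  expect_equal(ident$mse, 0)
  expect_equal(ident$pcc, 1.0)
  m <- regression_metrics(c(0, 50, 100), c(10, 50, 90))
  expect_equal(m$mse, 200 / 3, tolerance = 1e-9)  # 66.667
  expect_equal(m$pcc, 1.0, tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(20); p <- rnorm(20)
  expect_equal(regression_metrics(y, p)$pcc,
               regression_metrics(y, 3 * p + 7)$pcc, tolerance = 1e-12)
  const <- regression_metrics(y, rep(1, 20))
  expect_true(is.na(const$pcc))
  expect_true("pcc" %in% attr(const, "undefined"))
})

test_that("subset search enumerates and ranks every combination", {
  set.seed(14)
  obs <- runif(30, 10, 100)
  per_model <- tibble::tibble(id = sprintf("c%02d", 1:30), observed = obs)
  quality <- c(2, 5, 8, 12, 20, 35)
  for (m in 1:6) {
    per_model[[paste0("m", m)]] <- obs + rnorm(30, 0, quality[m])
  }
  res3 <- search_ensembles(per_model[, c("id", "observed", "m1", "m2", "m3")],
                           task = "regression")
  expect_equal(nrow(res3), 1)
  res <- search_ensembles(per_model, task = "regression")
  expect_equal(nrow(res), choose(6, 3) + choose(6, 4) + choose(6, 5) + choose(6, 6))
  expect_equal(nrow(res), 42)
  expect_true(all(res$pcc[1] >= res$pcc))
  expect_error(search_ensembles(per_model[, 1:4], task = "regression"),
               "at least min_size")

  # classification ranking by F-score
  per_clf <- per_model
  per_clf[paste0("m", 1:6)] <- lapply(per_model[paste0("m", 1:6)], function(x) {
    pmin(pmax(1 - x / 100, 0.01), 0.99)
  })
  resc <- search_ensembles(per_clf, task = "classification",
                           activity_threshold = 70)
  expect_equal(nrow(resc), 42)
  expect_true(all(resc$f_score[1] >= resc$f_score, na.rm = TRUE))
  g <- glance(resc)
  expect_equal(g$n_subsets, 42)
})

test_that("consensus predictions combine members per task", {
  per_model <- tibble::tibble(id = c("a", "b"), observed = c(30, 90),
                              m1 = c(10, 80), m2 = c(20, 90), m3 = c(30, 100))
  reg <- consensus_predictions(per_model, c("m1", "m2", "m3"), task = "regression")
  expect_equal(reg$ensemble_mean, c(20, 90))
  expect_equal(reg$ensemble_sd, c(sqrt(200 / 3), sqrt(200 / 3)), tolerance = 1e-9)
  clf <- consensus_predictions(
    tibble::tibble(id = "a", m1 = 0.9, m2 = 0.2, m3 = 0.4),
    c("m1", "m2", "m3"), task = "classification")
  expect_equal(clf$consensus, "inactive")  # 1 active vs 2 inactive
})
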