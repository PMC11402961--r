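# Ensemble combination (majority vote / mean-SD), performance metrics and
# exhaustive ensemble-combination search.

#' Majority vote with inactive tie-break
#'
#' Modal class over the votes; an exact tie defaults to `inactive` (the
#' conservative call for a screening pipeline whose positive class is
#' `active`).
#'
#' @param votes Character vector of `"active"` / `"inactive"` (>= 1 vote).
#' @return A single class label.
#' @export
majority_vote <- function(votes) {
  if (length(votes) == 0) stop("no votes to count")
  votes <- as.character(votes)
  stopifnot(all(votes %in% c("active", "inactive")))
  n_act <- sum(votes == "active")
  n_inact <- length(votes) - n_act
  if (n_act > n_inact) "active" else "inactive"
}

#' Ensemble regression prediction with uncertainty
#'
#' Arithmetic mean of the member predictions; the (population) standard
#' deviation across members estimates the prediction uncertainty.
#'
#' @param predictions Numeric vector of per-model %MGS predictions (>= 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named vector `c(mean = , sd = )`.
#' @export
ensemble_regress <- function(predictions, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(predictions) < 2) stop("ensemble needs at least 2 predictions")
  m <- mean(predictions)
  s <- stats::sd(predictions)
  if (sd_type == "population") {
    s <- s * sqrt((length(predictions) - 1) / length(predictions))
  }
  c(mean = m, sd = s)
}

#' Classification performance metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP) and
#' F-score (harmonic mean of precision and sensitivity), with `active` as
#' the positive class. A zero denominator yields `NA` with the corresponding
#' name listed in `attr(, "undefined")` -- never silently 0.
#'
#' @param truth,predicted Character vectors of `"active"` / `"inactive"`,
#'   equal length; `truth` must contain both classes.
#' @return A tibble of class `metrics_report` with columns `sensitivity`,
#'   `specificity`, `precision`, `f_score`, `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(all(c(truth, predicted) %in% c("active", "inactive")))
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  tp <- sum(truth == "active" & predicted == "active")
  fp <- sum(truth == "inactive" & predicted == "active")
  fn <- sum(truth == "active" & predicted == "inactive")
  tn <- sum(truth == "inactive" & predicted == "inactive")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  out <- tibble::tibble(sensitivity = sens, specificity = spec,
                        precision = prec, f_score = f,
                        tp = tp, fp = fp, fn = fn, tn = tn)
  undef <- c("sensitivity", "specificity", "precision", "f_score")[
    is.na(c(sens, spec, prec, f))]
  attr(out, "undefined") <- undef
  class(out) <- c("metrics_report", class(out))
  out
}

#' Regression performance metrics
#'
#' Mean squared error and Pearson correlation on the %MGS scale (never on
#' scaled targets). A constant truth or prediction vector gives `pcc = NA`
#' flagged in `attr(, "undefined")`.
#'
#' @param truth,predicted Numeric %MGS vectors, equal length >= 3.
#' @return A tibble with columns `mse`, `pcc`.
#' @export
regression_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 3)
  mse <- mean((truth - predicted)^2)
  undef <- character(0)
  if (stats::sd(truth) < 1e-12 || stats::sd(predicted) < 1e-12) {
    pcc <- NA_real_
    undef <- "pcc"
  } else {
    pcc <- stats::cor(truth, predicted)
  }
  out <- tibble::tibble(mse = mse, pcc = pcc)
  attr(out, "undefined") <- undef
  class(out) <- c("metrics_report", class(out))
  out
}

#' Exhaustive ensemble-combination search
#'
#' Evaluates every subset of `min_size` or more models from a multi-model
#' leave-one-out prediction table ([loo_cv_blocks()] output or any tibble
#' with `observed` plus per-model prediction columns). Classification
#' subsets are combined by per-compound majority vote (ties -> inactive) and
#' ranked by F-score (ties broken by higher precision); regression subsets
#' are combined by the per-compound mean and ranked by PCC (ties broken by
#' lower MSE).
#'
#' @param per_model An `iri_loo_multi` tibble, or a tibble with columns
#'   `observed` and one numeric column per model.
#' @param task `"classification"` or `"regression"`; taken from the input's
#'   attributes when present.
#' @param min_size Smallest subset size (default 3).
#' @param activity_threshold %MGS threshold for deriving labels
#'   (classification).
#' @param prob_threshold Per-model probability threshold (classification).
#' @return A tibble of class `iri_ensemble_search`, one row per subset,
#'   ranked best first: `members` (comma-separated), `n_models`, and the
#'   task's metric columns.
#' @export
search_ensembles <- function(per_model, task = NULL, min_size = 3,
                             activity_threshold = 70, prob_threshold = 0.5) {
  task <- task %||% attr(per_model, "task") %||% "regression"
  activity_threshold <- attr(per_model, "threshold") %||% activity_threshold
  prob_threshold <- attr(per_model, "prob_threshold") %||% prob_threshold
  stopifnot("observed" %in% names(per_model))
  model_cols <- setdiff(names(per_model), c("id", "observed"))
  M <- length(model_cols)
  if (M < min_size) {
    stop("need at least min_size = ", min_size, " models, got ", M)
  }
  observed <- per_model$observed
  rows <- list()
  for (size in min_size:M) {
    combos <- utils::combn(model_cols, size, simplify = FALSE)
    for (members in combos) {
      P <- as.matrix(per_model[, members, drop = FALSE])
      if (task == "classification") {
        labels <- ifelse(P > prob_threshold, "active", "inactive")
        consensus <- apply(labels, 1, majority_vote)
        truth <- label_activity(observed, activity_threshold)
        met <- classification_metrics(truth, consensus)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          members = paste(members, collapse = ","), n_models = size,
          sensitivity = met$sensitivity, specificity = met$specificity,
          precision = met$precision, f_score = met$f_score)
      } else {
        mean_pred <- rowMeans(P)
        met <- regression_metrics(observed, mean_pred)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          members = paste(members, collapse = ","), n_models = size,
          mse = met$mse, pcc = met$pcc)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- if (task == "classification") {
    dplyr::arrange(out, dplyr::desc(.data$f_score), dplyr::desc(.data$precision))
  } else {
    dplyr::arrange(out, dplyr::desc(.data$pcc), .data$mse)
  }
  attr(out, "task") <- task
  class(out) <- c("iri_ensemble_search", class(out))
  out
}

#' Consensus predictions for a fixed model subset
#'
#' Combines the chosen model columns of a multi-model prediction table:
#' majority vote over thresholded per-model labels (classification) or
#' ensemble mean and population SD (regression).
#'
#' @inheritParams search_ensembles
#' @param members Character vector of model column names (>= 2).
#' @return A tibble: `id`, `observed` if present, and `consensus` (label) or
#'   `ensemble_mean`/`ensemble_sd` (%MGS).
#' @export
consensus_predictions <- function(per_model, members, task = NULL,
                                  prob_threshold = 0.5) {
  task <- task %||% attr(per_model, "task") %||% "regression"
  prob_threshold <- attr(per_model, "prob_threshold") %||% prob_threshold
  stopifnot(length(members) >= 2, all(members %in% names(per_model)))
  P <- as.matrix(per_model[, members, drop = FALSE])
  out <- tibble::tibble(id = per_model$id %||% seq_len(nrow(P)))
  if ("observed" %in% names(per_model)) out$observed <- per_model$observed
  if (task == "classification") {
    labels <- ifelse(P > prob_threshold, "active", "inactive")
    out$consensus <- apply(labels, 1, majority_vote)
  } else {
    out$ensemble_mean <- rowMeans(P)
    out$ensemble_sd <- apply(P, 1, function(x) {
      stats::sd(x) * sqrt((length(x) - 1) / length(x))
    })
  }
  out
}
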