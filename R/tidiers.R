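# broom-style tidiers for fitted objects and result tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a leave-one-out result
#'
#' @param x An `iri_loo` tibble.
#' @param ... Unused.
#' @return The per-compound prediction tibble (already tidy).
#' @export
tidy.iri_loo <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row performance summary of a leave-one-out run
#'
#' Regression: MSE and PCC on the %MGS scale. Classification: sensitivity,
#' specificity, precision and F-score of the thresholded predictions.
#'
#' @param x An `iri_loo` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.iri_loo <- function(x, ...) {
  if (identical(attr(x, "task"), "classification")) {
    met <- classification_metrics(x$observed_label, x$predicted_label)
    tibble::tibble(n = nrow(x), sensitivity = met$sensitivity,
                   specificity = met$specificity, precision = met$precision,
                   f_score = met$f_score)
  } else {
    met <- regression_metrics(x$observed, x$prediction)
    tibble::tibble(n = nrow(x), mse = met$mse, pcc = met$pcc)
  }
}

#' Tidy a trained network
#'
#' One row per layer with parameter counts -- the useful summary for a
#' fully-connected network.
#'
#' @param x An `iri_mlp` fit.
#' @param ... Unused.
#' @return A tibble with `layer`, `n_in`, `n_out`, `n_parameters`.
#' @export
tidy.iri_mlp <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$par$W),
    n_in = vapply(x$par$W, nrow, integer(1)),
    n_out = vapply(x$par$W, ncol, integer(1)),
    n_parameters = vapply(x$par$W, length, integer(1)) +
      vapply(x$par$b, length, integer(1))
  )
}

#' One-row training summary of a fitted network
#'
#' @param x An `iri_mlp` fit.
#' @param ... Unused.
#' @return A tibble with task, epochs run, best epoch and validation loss.
#' @export
glance.iri_mlp <- function(x, ...) {
  tibble::tibble(task = x$cfg$task, epochs_run = x$epochs_run,
                 best_epoch = x$best_epoch, val_loss = x$val_loss)
}

#' Tidy an ensemble-combination search
#'
#' @param x An `iri_ensemble_search` tibble.
#' @param ... Unused.
#' @return The ranked subset tibble.
#' @export
tidy.iri_ensemble_search <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Best-subset summary of an ensemble search
#'
#' @param x An `iri_ensemble_search` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of subsets evaluated and the top
#'   subset's members and metrics.
#' @export
glance.iri_ensemble_search <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_subsets = nrow(x)), x[1, ])
}
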