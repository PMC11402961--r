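# Virtual-screening cascade: seed selection, library construction filters,
# full-data ensemble training, uncertainty filtering and top/bottom
# selection.

#' Screening configuration
#'
#' Defaults follow the published cascade: 15 most / 5 least active seed
#' compounds, Tanimoto similarity > 0.7 to a seed, calculated logP <= 1.8,
#' ensemble-SD uncertainty cut at 15 %MGS, and a prediction set of the ten
#' most and ten least active survivors.
#'
#' @param n_active_seeds,n_inactive_seeds Seed counts.
#' @param tanimoto_min Minimum (exclusive) similarity to any seed.
#' @param logp_max Maximum calculated logP kept.
#' @param uncertainty_sd_max Maximum ensemble SD (%MGS) kept.
#' @param n_top,n_bottom Selection sizes (most / least active).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_active_seeds = 15, n_inactive_seeds = 5,
                          tanimoto_min = 0.7, logp_max = 1.8,
                          uncertainty_sd_max = 15, n_top = 10, n_bottom = 10) {
  stopifnot(n_active_seeds >= 1, n_inactive_seeds >= 1,
            tanimoto_min > 0, tanimoto_min <= 1,
            uncertainty_sd_max > 0, n_top >= 1, n_bottom >= 1)
  structure(list(n_active_seeds = as.integer(n_active_seeds),
                 n_inactive_seeds = as.integer(n_inactive_seeds),
                 tanimoto_min = tanimoto_min, logp_max = logp_max,
                 uncertainty_sd_max = uncertainty_sd_max,
                 n_top = as.integer(n_top), n_bottom = as.integer(n_bottom)),
            class = "screen_config")
}

#' Select similarity-search seeds from a training set
#'
#' The `n_active_seeds` lowest-%MGS (most active) and `n_inactive_seeds`
#' highest-%MGS (least active) training compounds, with ties at either cut
#' broken deterministically by id order.
#'
#' @param training Compound tibble with `mgs_percent`.
#' @param cfg A [screen_config()].
#' @return A tibble `id`, `smiles`, `mgs_percent`, `role`
#'   (`"active"`/`"inactive"`).
#' @export
select_seeds <- function(training, cfg = screen_config()) {
  stopifnot(all(!is.na(training$mgs_percent)))
  n_needed <- cfg$n_active_seeds + cfg$n_inactive_seeds
  if (nrow(training) < n_needed) {
    stop("training set has ", nrow(training), " compounds; need at least ", n_needed)
  }
  asc <- training[order(training$mgs_percent, training$id), ]
  active <- asc[seq_len(cfg$n_active_seeds), ]
  desc <- training[order(-training$mgs_percent, training$id), ]
  inactive <- desc[seq_len(cfg$n_inactive_seeds), ]
  dplyr::bind_rows(
    dplyr::mutate(active[, c("id", "smiles", "mgs_percent")], role = "active"),
    dplyr::mutate(inactive[, c("id", "smiles", "mgs_percent")], role = "inactive")
  )
}

#' Build the filtered prediction library
#'
#' Applies the library-construction cascade to candidate SMILES, keeping a
#' candidate iff (1) its maximum Tanimoto similarity to any seed exceeds
#' `tanimoto_min`, (2) its canonical SMILES is not in the canonical training
#' set (hard overlap), (3) it is a single fragment (no `.` in the canonical
#' SMILES -- the structural signal for co-salts/co-additives), and (4) its
#' calculated logP is at most `logp_max`. Unparseable candidates are skipped
#' with a warning. Filters are applied in that order; the audit reports how
#' many candidates each filter removed (first failing filter counts).
#'
#' @param candidates Character vector of SMILES, or a tibble with `id` and
#'   `smiles`.
#' @param seeds Seed SMILES (e.g. `select_seeds(...)$smiles`).
#' @param training Training SMILES for the overlap filter.
#' @param cfg A [screen_config()].
#' @return A tibble of surviving candidates (`id`, `smiles` canonical,
#'   `max_tanimoto`, `logp`) with the audit in `attr(, "audit")`.
#' @export
build_prediction_library <- function(candidates, seeds, training,
                                     cfg = screen_config()) {
  if (!is.data.frame(candidates)) {
    candidates <- tibble::tibble(id = sprintf("cand%04d", seq_along(candidates)),
                                 smiles = as.character(candidates))
  }
  stopifnot(nrow(candidates) >= 1, length(seeds) >= 1)
  can <- canonical_smiles(candidates$smiles)
  invalid <- is.na(can)
  if (any(invalid)) {
    warning(sum(invalid), " candidate(s) with unparseable SMILES skipped")
  }
  lib <- candidates[!invalid, , drop = FALSE]
  lib$smiles <- can[!invalid]
  audit <- tibble::tibble(filter = "invalid_smiles", removed = sum(invalid))

  lib$max_tanimoto <- if (nrow(lib)) max_tanimoto_to_seeds(lib$smiles, seeds) else numeric(0)
  keep <- lib$max_tanimoto > cfg$tanimoto_min
  audit <- dplyr::bind_rows(audit, tibble::tibble(
    filter = "tanimoto_to_seed", removed = sum(!keep)))
  lib <- lib[keep, , drop = FALSE]

  train_can <- unique(canonical_smiles(training))
  keep <- !(lib$smiles %in% train_can)
  audit <- dplyr::bind_rows(audit, tibble::tibble(
    filter = "training_overlap", removed = sum(!keep)))
  lib <- lib[keep, , drop = FALSE]

  keep <- !grepl(".", lib$smiles, fixed = TRUE)
  audit <- dplyr::bind_rows(audit, tibble::tibble(
    filter = "multi_fragment", removed = sum(!keep)))
  lib <- lib[keep, , drop = FALSE]

  lib$logp <- if (nrow(lib)) compute_standard_descriptors(lib$smiles)$MolLogP else numeric(0)
  keep <- lib$logp <= cfg$logp_max
  audit <- dplyr::bind_rows(audit, tibble::tibble(
    filter = "logp", removed = sum(!keep)))
  lib <- lib[keep, , drop = FALSE]

  out <- tibble::as_tibble(lib)
  attr(out, "audit") <- audit
  out
}

#' Train a full-data regression ensemble for screening
#'
#' One network per representation, trained on the entire training set (no
#' leave-one-out at screening time) with the same preprocessing as a CV
#' fold applied once globally: Min-Max feature and target scaling fitted on
#' the full set.
#'
#' @param compounds Training compound tibble (`id`, `mgs_percent`).
#' @param blocks Named list of feature blocks aligned with `compounds`.
#' @param cfg A [model_config()] (task `"regression"`).
#' @return An object of class `iri_ensemble` holding per-block fits and
#'   scalers.
#' @export
train_ensemble <- function(compounds, blocks, cfg = model_config("regression")) {
  stopifnot(cfg$task == "regression", length(blocks) >= 2,
            !is.null(names(blocks)))
  mgs <- compounds$mgs_percent
  stopifnot(all(!is.na(mgs)))
  yscaler <- suppressWarnings(minmax_fit(matrix(mgs, ncol = 1)))
  ys <- minmax_apply(yscaler, matrix(mgs, ncol = 1))[, 1]
  members <- lapply(seq_along(blocks), function(b) {
    X <- feature_matrix(blocks[[b]], compounds$id)
    xscaler <- suppressWarnings(minmax_fit(X))
    bcfg <- cfg
    bcfg$seed <- derive_seed(cfg$seed, 9000L + b)
    fit <- train_model(minmax_apply(xscaler, X), ys, bcfg)
    list(name = names(blocks)[b], fit = fit, xscaler = xscaler)
  })
  structure(list(members = stats::setNames(members, names(blocks)),
                 yscaler = yscaler, cfg = cfg),
            class = "iri_ensemble")
}

#' Predict %MGS for new compounds with a trained ensemble
#'
#' @param object An [train_ensemble()] fit.
#' @param newblocks Named list of feature blocks for the new compounds (same
#'   names and feature sets as at training).
#' @param ids Optional compound ids (taken from the blocks' `id` column when
#'   present).
#' @param ... Unused.
#' @return A tibble: `id`, one column per member model, `ensemble_mean`,
#'   `ensemble_sd` (population SD), all in %MGS.
#' @export
predict.iri_ensemble <- function(object, newblocks, ids = NULL, ...) {
  stopifnot(setequal(names(newblocks), names(object$members)))
  if (is.null(ids)) {
    first <- newblocks[[1]]
    ids <- if (is.data.frame(first) && "id" %in% names(first)) {
      first$id
    } else {
      sprintf("cand%04d", seq_len(nrow(first)))
    }
  }
  P <- sapply(names(object$members), function(nm) {
    mem <- object$members[[nm]]
    X <- feature_matrix(newblocks[[nm]], ids)
    pred_s <- predict(mem$fit, minmax_apply(mem$xscaler, X))
    minmax_invert(object$yscaler, matrix(pred_s, ncol = 1))[, 1]
  })
  P <- matrix(P, nrow = length(ids), dimnames = list(NULL, names(object$members)))
  out <- tibble::as_tibble(as.data.frame(P))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  out$ensemble_mean <- rowMeans(P)
  out$ensemble_sd <- apply(P, 1, function(x) {
    stats::sd(x) * sqrt((length(x) - 1) / length(x))
  })
  out
}

#' Screen a prediction library
#'
#' Ranks library candidates by consensus predicted %MGS, removes predictions
#' with ensemble SD above `uncertainty_sd_max` (high-uncertainty
#' predictions), and marks the `n_top` most active (lowest predicted %MGS)
#' and `n_bottom` least active survivors as the prediction set.
#'
#' @param library Tibble of candidates (`id`, `smiles`).
#' @param ensemble An [train_ensemble()] fit.
#' @param blocks Named list of candidate feature blocks matching the
#'   ensemble's members.
#' @param cfg A [screen_config()].
#' @return A tibble of class `iri_screen`, ranked by predicted %MGS
#'   ascending: predictions plus `uncertain` (dropped by the SD filter) and
#'   `selected` (`"top"`, `"bottom"`, or `NA`).
#' @export
screen_library <- function(library, ensemble, blocks, cfg = screen_config()) {
  stopifnot(nrow(library) >= 1)
  preds <- predict(ensemble, blocks, ids = library$id)
  out <- dplyr::left_join(library[, c("id", "smiles")], preds, by = "id")
  out$uncertain <- out$ensemble_sd > cfg$uncertainty_sd_max
  surviving <- which(!out$uncertain)
  if (length(surviving) == 0) {
    stop("no candidates survive the uncertainty filter (SD <= ",
         cfg$uncertainty_sd_max, " %MGS)")
  }
  out <- out[order(out$ensemble_mean, out$id), ]
  out$selected <- NA_character_
  surv_idx <- which(!out$uncertain)
  if (cfg$n_top + cfg$n_bottom >= length(surv_idx)) {
    warning("selection sizes cover the whole surviving library (",
            length(surv_idx), " candidates)")
    out$selected[surv_idx] <- "top"
    out$selected[utils::tail(surv_idx, cfg$n_bottom)] <- "bottom"
  } else {
    out$selected[utils::head(surv_idx, cfg$n_top)] <- "top"
    out$selected[utils::tail(surv_idx, cfg$n_bottom)] <- "bottom"
  }
  class(out) <- c("iri_screen", class(out))
  out
}
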