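#' Featurize a compound table
#'
#' One entry point for all six representations. Takes a compound tibble
#' first and returns a feature block: a tibble with the `id` column followed
#' by named numeric feature columns, ready for [loo_cv()],
#' [loo_cv_blocks()] or [train_ensemble()].
#'
#' Blocks and their extra inputs:
#' * `standard` -- none (computed from SMILES).
#' * `cliques` -- `vocab`; if omitted, a vocabulary is built from the input
#'   compounds themselves.
#' * `hwacsf` -- `conformers` (named by compound id), optional `ranges` from
#'   [hwacsf_ranges()] (defaults to ranges frozen on the supplied
#'   conformers).
#' * `soap` -- `conformers` (named by compound id).
#' * `hydration_histogram` -- `histograms`: named list of
#'   [hydration_histogram()]s (bin densities become the features).
#' * `hydration_indices` -- `profiles`: named list of
#'   [hydration_profile()]s; volume-normalised indices are used.
#'
#' @param compounds Compound tibble (`id`, `smiles`).
#' @param block Representation name.
#' @param vocab Optional [build_clique_vocabulary()] result.
#' @param conformers Named list of [conformer()]s keyed by compound id.
#' @param histograms Named list of [hydration_histogram()]s keyed by id.
#' @param profiles Named list of [hydration_profile()]s keyed by id.
#' @param acsf,soap Parameter objects ([acsf_params()], [soap_params()]).
#' @param ranges Optional frozen H-wACSF histogram ranges.
#' @return A tibble (`id` + features) with the block name in
#'   `attr(, "block")`.
#' @export
featurize <- function(compounds,
                      block = c("standard", "cliques", "hwacsf", "soap",
                                "hydration_histogram", "hydration_indices"),
                      vocab = NULL, conformers = NULL, histograms = NULL,
                      profiles = NULL, acsf = acsf_params(),
                      soap = soap_params(), ranges = NULL) {
  block <- match.arg(block)
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  ids <- compounds$id
  need_named <- function(lst, what) {
    if (is.null(lst)) stop("block '", block, "' needs ", what)
    missing <- setdiff(ids, names(lst))
    if (length(missing) > 0) {
      stop("missing ", what, " for id(s): ", paste(missing, collapse = ", "))
    }
    lst[ids]
  }
  features <- switch(
    block,
    standard = compute_standard_descriptors(compounds$smiles),
    cliques = {
      if (is.null(vocab)) vocab <- build_clique_vocabulary(compounds$smiles)
      clique_fingerprint(compounds$smiles, vocab)
    },
    hwacsf = {
      confs <- need_named(conformers, "conformers")
      if (is.null(ranges)) ranges <- hwacsf_ranges(confs, acsf)
      rows <- lapply(confs, compute_hwacsf, params = acsf, ranges = ranges)
      tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
    },
    soap = {
      confs <- need_named(conformers, "conformers")
      rows <- lapply(confs, compute_soap_avg, params = soap)
      tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
    },
    hydration_histogram = {
      hists <- need_named(histograms, "hydration histograms")
      rows <- lapply(hists, function(h) {
        stats::setNames(h$density, sprintf("pd_bin%03d", seq_along(h$density)))
      })
      tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
    },
    hydration_indices = {
      profs <- need_named(profiles, "hydration profiles")
      rows <- lapply(profs, hydration_indices, metric = "volume")
      tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
    }
  )
  out <- dplyr::bind_cols(tibble::tibble(id = ids), features)
  attr(out, "block") <- block
  out
}

#' Write / read a feature block CSV
#'
#' Plain CSV with `id` followed by named feature columns.
#'
#' @param features A feature block tibble.
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_block <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_block
#' @export
read_feature_block <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
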