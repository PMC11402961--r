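#' Read a compound structure-activity table
#'
#' Reads a CSV with header `id,smiles,mgs,sd[,concentration_mM]` into a
#' validated compound tibble. `mgs` is the mean grain size of ice crystals
#' after annealing relative to a negative control (%, lower = more active
#' inhibitor); `sd` its replicate standard deviation. Every SMILES is parsed
#' and canonicalised; an unparseable SMILES is an error naming the row.
#'
#' @param path CSV file path.
#' @param dataset_tag One of `"Amino"`, `"Glyco"`, `"Glyco2"`, `"Combined"`,
#'   `"library"`. Measured datasets must carry `mgs` values; a screening
#'   `library` may leave `mgs`/`sd` empty.
#' @return A tibble with columns `id`, `smiles` (canonical), `dataset_tag`,
#'   `mgs_percent`, `mgs_sd`, `concentration_mM`.
#' @export
#' @seealso [write_compound_table()], [as_compound_table()]
read_compound_table <- function(path, dataset_tag = c("Amino", "Glyco", "Glyco2",
                                                      "Combined", "library")) {
  dataset_tag <- match.arg(dataset_tag)
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(c("id", "smiles", "mgs", "sd"), names(raw))
  if (length(missing_cols) > 0) {
    stop("compound table '", path, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"concentration_mm" %in% names(raw)) raw$concentration_mm <- NA_real_
  as_compound_table(
    tibble::tibble(
      id = as.character(raw$id),
      smiles = as.character(raw$smiles),
      dataset_tag = dataset_tag,
      mgs_percent = as.numeric(raw$mgs),
      mgs_sd = as.numeric(raw$sd),
      concentration_mM = as.numeric(raw$concentration_mm)
    )
  )
}

#' Validate a data frame as a compound table
#'
#' Canonicalises SMILES (errors name the offending rows), checks that
#' `mgs_percent`/`mgs_sd` are non-negative where present, and that measured
#' (non-library) datasets have an `mgs_percent` for every compound. A measured
#' compound lacking a replicate SD is kept (literature rows may not report
#' one) with a warning.
#'
#' @param x A data frame with at least `id` and `smiles`; optional
#'   `dataset_tag`, `mgs_percent`, `mgs_sd`, `concentration_mM`.
#' @return A validated compound tibble.
#' @export
as_compound_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "smiles") %in% names(x)))
  x <- tibble::as_tibble(x)
  if (!"dataset_tag" %in% names(x)) x$dataset_tag <- "library"
  if (!"mgs_percent" %in% names(x)) x$mgs_percent <- NA_real_
  if (!"mgs_sd" %in% names(x)) x$mgs_sd <- NA_real_
  if (!"concentration_mM" %in% names(x)) x$concentration_mM <- NA_real_
  tags <- unique(x$dataset_tag)
  bad_tag <- setdiff(tags, c("Amino", "Glyco", "Glyco2", "Combined", "library"))
  if (length(bad_tag) > 0) stop("unknown dataset_tag: ", paste(bad_tag, collapse = ", "))
  if (anyDuplicated(x$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  x$smiles <- assert_valid_smiles(x$smiles, ids = x$id, context = "compound table")
  measured <- x$dataset_tag != "library"
  if (any(measured & is.na(x$mgs_percent))) {
    stop("measured compounds without %MGS: ",
         paste(x$id[measured & is.na(x$mgs_percent)], collapse = ", "))
  }
  if (any(x$mgs_percent < 0, na.rm = TRUE)) {
    stop("negative %MGS for id(s): ",
         paste(x$id[!is.na(x$mgs_percent) & x$mgs_percent < 0], collapse = ", "))
  }
  if (any(x$mgs_sd < 0, na.rm = TRUE)) {
    stop("negative %MGS SD for id(s): ",
         paste(x$id[!is.na(x$mgs_sd) & x$mgs_sd < 0], collapse = ", "))
  }
  no_sd <- measured & !is.na(x$mgs_percent) & is.na(x$mgs_sd)
  if (any(no_sd)) {
    warning(sum(no_sd), " measured compound(s) lack a replicate SD; ",
            "they are excluded from noise-ceiling analysis")
  }
  x[, c("id", "smiles", "dataset_tag", "mgs_percent", "mgs_sd", "concentration_mM")]
}

#' Write a compound table to CSV
#'
#' Inverse of [read_compound_table()]: writes the
#' `id,smiles,mgs,sd,concentration_mM` schema.
#'
#' @param compounds A compound tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "smiles") %in% names(compounds)))
  out <- tibble::tibble(
    id = compounds$id,
    smiles = compounds$smiles,
    mgs = if ("mgs_percent" %in% names(compounds)) compounds$mgs_percent else NA_real_,
    sd = if ("mgs_sd" %in% names(compounds)) compounds$mgs_sd else NA_real_,
    concentration_mM = if ("concentration_mM" %in% names(compounds)) {
      compounds$concentration_mM
    } else NA_real_
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
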