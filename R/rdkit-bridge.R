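# Batched bridge to the RDKit helper (inst/python/rdkit_tools.py). One python
# process per request; results are memoised for the session so repeated
# featurisation of the same SMILES costs one call.

.bridge_cache <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "rdkit_tools.py", package = "iriscreen")
  if (!nzchar(path)) {
    stop("rdkit_tools.py not found; is iriscreen installed correctly?")
  }
  path
}

python_binary <- function() {
  getOption("iriscreen.python", Sys.getenv("IRISCREEN_PYTHON", "python"))
}

#' Is the RDKit back end available?
#'
#' `iriscreen` delegates SMILES parsing, standard descriptors, clique
#' decomposition, Morgan fingerprints and fixture conformer embedding to a
#' Python RDKit helper shipped with the package. This checks that `python`
#' (or `options(iriscreen.python = ...)`) can import RDKit.
#'
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function() {
  if (!is.null(.bridge_cache$available)) {
    return(.bridge_cache$available)
  }
  ok <- tryCatch({
    res <- suppressWarnings(system2(
      python_binary(), c("-c", shQuote("import rdkit")),
      stdout = FALSE, stderr = FALSE
    ))
    identical(res, 0L)
  }, error = function(e) FALSE)
  .bridge_cache$available <- ok
  ok
}

rdkit_call <- function(op, ..., .cache = TRUE) {
  req <- c(list(op = op), list(...))
  key <- rlang::hash(req)
  if (.cache && !is.null(.bridge_cache[[key]])) {
    return(.bridge_cache[[key]])
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    python_binary(), bridge_script(),
    stdin = infile, stdout = outfile, stderr = errfile
  ))
  if (!identical(status, 0L) || !file.exists(outfile) || file.size(outfile) == 0) {
    err <- if (file.exists(errfile)) readLines(errfile, warn = FALSE) else character(0)
    stop("RDKit bridge failed (op '", op, "'): ",
         paste(utils::head(err, 3), collapse = "; "))
  }
  res <- jsonlite::read_json(outfile)
  if (!is.null(res$error)) {
    stop("RDKit bridge error: ", res$error)
  }
  if (.cache) assign(key, res, envir = .bridge_cache)
  res
}

# Canonicalise a SMILES vector; invalid entries come back as NA with the
# offending indices in attr "bad".
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  res <- rdkit_call("canonical", smiles = as.list(as.character(smiles)))
  out <- vapply(res$results, function(r) {
    if (isTRUE(r$ok)) r$canonical else NA_character_
  }, character(1))
  structure(out, bad = which(is.na(out)))
}

# Stop with row-identifying messages when any SMILES fails to parse.
assert_valid_smiles <- function(smiles, ids = NULL, context = "SMILES") {
  can <- canonical_smiles(smiles)
  bad <- attr(can, "bad")
  if (length(bad) > 0) {
    labels <- if (is.null(ids)) paste0("row ", bad) else {
      paste0("row ", bad, " (id '", ids[bad], "')")
    }
    stop(context, ": unparseable SMILES ",
         paste0(labels, ": '", smiles[bad], "'", collapse = "; "))
  }
  as.character(can)
}
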