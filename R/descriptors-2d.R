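#' The frozen standard-descriptor list
#'
#' The 45 physicochemical property names that make up the `standard`
#' representation, in column order. The list is a package constant: it
#' includes molecular weight, heavy-atom count, ring counts, hydrogen-bond
#' donor/acceptor counts, topological polar surface area, calculated logP
#' and rotatable-bond count, plus connectivity/shape indices.
#'
#' @return Character vector of length 45.
#' @export
standard_descriptor_names <- function() {
  c("MolWt", "ExactMolWt", "HeavyAtomMolWt", "HeavyAtomCount", "NumHeteroatoms",
    "NumValenceElectrons", "NumRadicalElectrons", "NumHDonors", "NumHAcceptors",
    "NHOHCount", "NOCount", "NumRotatableBonds", "RingCount", "NumAromaticRings",
    "NumAliphaticRings", "NumSaturatedRings", "NumAromaticCarbocycles",
    "NumAromaticHeterocycles", "NumAliphaticCarbocycles",
    "NumAliphaticHeterocycles", "NumSaturatedCarbocycles",
    "NumSaturatedHeterocycles", "FractionCSP3", "TPSA", "LabuteASA", "MolLogP",
    "MolMR", "BalabanJ", "BertzCT", "HallKierAlpha", "Kappa1", "Kappa2",
    "Kappa3", "Chi0", "Chi1", "Chi0n", "Chi1n", "Chi2n", "Chi0v", "Chi1v",
    "Chi2v", "qed", "FpDensityMorgan1", "FpDensityMorgan2", "FpDensityMorgan3")
}

#' Standard physicochemical descriptors
#'
#' Computes the frozen 45-property `standard` representation for each SMILES
#' (see [standard_descriptor_names()]). Descriptors are computed on the
#' canonical molecule, so any SMILES spelling of the same structure yields
#' the same row.
#'
#' @param smiles Character vector of SMILES.
#' @return A tibble, one row per input, 45 named numeric columns.
#' @export
#' @examples
#' \dontrun{
#' compute_standard_descriptors("C")$MolWt  # 16.043
#' }
compute_standard_descriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  assert_valid_smiles(smiles, context = "standard descriptors")
  res <- rdkit_call("descriptors", smiles = as.list(as.character(smiles)))
  nms <- unlist(res$names)
  rows <- lapply(res$results, function(r) {
    if (!isTRUE(r$ok)) stop("descriptor computation failed: ", r$error)
    as.numeric(unlist(r$values))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- nms
  out <- tibble::as_tibble(as.data.frame(m))
  stopifnot(identical(names(out), standard_descriptor_names()))
  out
}

#' Build a clique vocabulary from a dataset
#'
#' Decomposes every molecule into its simple rings (smallest set of smallest
#' rings, merging rings that share more than two atoms) plus every non-ring
#' bond as a two-atom fragment, canonicalises the fragment SMILES and
#' returns the deduplicated vocabulary in lexicographic order.
#'
#' @param smiles Character vector of SMILES (at least one).
#' @return An object of class `clique_vocabulary`: list with `fragments`
#'   (ordered character vector) and `source_size`.
#' @export
build_clique_vocabulary <- function(smiles) {
  if (length(smiles) < 1) stop("need at least one SMILES to build a vocabulary")
  assert_valid_smiles(smiles, context = "clique vocabulary")
  res <- rdkit_call("cliques", smiles = as.list(as.character(smiles)))
  frags <- unlist(lapply(res$results, function(r) {
    if (!isTRUE(r$ok)) stop("clique decomposition failed: ", r$error)
    unlist(r$fragments)
  }))
  structure(list(fragments = sort(unique(frags)),
                 source_size = length(smiles)),
            class = "clique_vocabulary")
}

#' @export
print.clique_vocabulary <- function(x, ...) {
  cat("<clique_vocabulary> ", length(x$fragments), " fragments from ",
      x$source_size, " molecule(s)\n", sep = "")
  invisible(x)
}

#' Write / read a clique vocabulary (one fragment SMILES per line)
#'
#' @param vocab A `clique_vocabulary`.
#' @param path File path.
#' @return `path` (write) or a `clique_vocabulary` (read).
#' @export
write_clique_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "clique_vocabulary"))
  writeLines(vocab$fragments, path)
  invisible(path)
}

#' @rdname write_clique_vocabulary
#' @param source_size Number of molecules the vocabulary was built from
#'   (metadata only).
#' @export
read_clique_vocabulary <- function(path, source_size = NA_integer_) {
  stopifnot(file.exists(path))
  structure(list(fragments = readLines(path, warn = FALSE),
                 source_size = source_size),
            class = "clique_vocabulary")
}

# Per-molecule clique fragment multisets (internal; one bridge call).
clique_fragments <- function(smiles) {
  res <- rdkit_call("cliques", smiles = as.list(as.character(smiles)))
  lapply(res$results, function(r) {
    if (!isTRUE(r$ok)) stop("clique decomposition failed: ", r$error)
    unlist(r$fragments) %||% character(0)
  })
}

#' Clique fingerprints against a vocabulary
#'
#' Encodes each molecule as a count vector over the vocabulary's fragment
#' order. Fragments absent from the vocabulary (out-of-vocabulary) are
#' ignored with a warning.
#'
#' @param smiles Character vector of SMILES.
#' @param vocab A [build_clique_vocabulary()] result.
#' @return A tibble, one row per molecule, one integer column per fragment
#'   (columns named `clique_001`... with fragment SMILES stored in
#'   `attr(,"fragments")`).
#' @export
clique_fingerprint <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "clique_vocabulary"), length(vocab$fragments) >= 1)
  assert_valid_smiles(smiles, context = "clique fingerprint")
  frag_lists <- clique_fragments(smiles)
  m <- matrix(0L, nrow = length(smiles), ncol = length(vocab$fragments))
  oov <- character(0)
  for (i in seq_along(frag_lists)) {
    tab <- table(frag_lists[[i]])
    known <- intersect(names(tab), vocab$fragments)
    oov <- union(oov, setdiff(names(tab), vocab$fragments))
    if (length(known) > 0) {
      m[i, match(known, vocab$fragments)] <- as.integer(tab[known])
    }
  }
  if (length(oov) > 0) {
    warning(length(oov), " fragment(s) outside the vocabulary were ignored: ",
            paste(utils::head(oov, 5), collapse = ", "),
            if (length(oov) > 5) ", ..." else "")
  }
  colnames(m) <- sprintf("clique_%03d", seq_along(vocab$fragments))
  out <- tibble::as_tibble(as.data.frame(m))
  attr(out, "fragments") <- vocab$fragments
  out
}

# Morgan (radius 2, 2048 bit) on-bit sets, one integer vector per SMILES.
morgan_bits <- function(smiles, radius = 2, n_bits = 2048) {
  res <- rdkit_call("morgan", smiles = as.list(as.character(smiles)),
                    radius = radius, n_bits = n_bits)
  lapply(res$results, function(r) {
    if (!isTRUE(r$ok)) stop("fingerprint failed: ", r$error)
    as.integer(unlist(r$bits) %||% integer(0))
  })
}

#' Tanimoto similarity between two molecules
#'
#' Jaccard coefficient |A ∩ B| / |A ∪ B| over circular (Morgan) fingerprint
#' bit sets, radius 2, 2048 bits — the convention used for the screening
#' library's similarity-to-seed filter.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(smiles_a, smiles_b) {
  assert_valid_smiles(c(smiles_a, smiles_b), context = "tanimoto")
  bits <- morgan_bits(c(smiles_a, smiles_b))
  a <- bits[[1]]; b <- bits[[2]]
  un <- length(union(a, b))
  if (un == 0) return(1)
  length(intersect(a, b)) / un
}

# Max Tanimoto of each candidate to any seed, in one bridge round trip.
max_tanimoto_to_seeds <- function(candidates, seeds) {
  bits <- morgan_bits(c(candidates, seeds))
  cb <- bits[seq_along(candidates)]
  sb <- bits[length(candidates) + seq_along(seeds)]
  vapply(cb, function(a) {
    best <- 0
    for (b in sb) {
      un <- length(union(a, b))
      sim <- if (un == 0) 1 else length(intersect(a, b)) / un
      if (sim > best) best <- sim
    }
    best
  }, numeric(1))
}
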