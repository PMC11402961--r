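#' Generate a solvated trajectory with planted hydration shells
#'
#' Builds a seeded, fully synthetic solute-in-water trajectory in which the
#' number of water molecules at given distances from the solute is known by
#' construction: for each shell, exactly `n_waters` water oxygens have a
#' nearest-solute-atom (minimum-image) distance inside `[inner_nm, outer_nm)`
#' in every frame, and bulk waters lie beyond the outermost shell. Water
#' geometry is rigid (O-H 0.09572 nm, H-O-H 104.52 deg) with random
#' orientation. Waters are kept a small margin (0.002 nm) away from shell
#' boundaries so that text round-trips at GRO precision cannot move them
#' across a boundary. This generator makes no attempt at physically realistic
#' water structure; it exists so the hydration analysis can be checked
#' against planted truth.
#'
#' @param solute A [conformer()] or list with `elements` and `xyz` (nm);
#'   placed as given (coordinates should sit near the box centre).
#' @param shells List of shells, each `list(inner_nm=, outer_nm=, n_waters=)`.
#' @param n_bulk_waters Waters placed beyond the outermost shell.
#' @param box_nm Cubic box edge (nm), or length-3 vector.
#' @param n_frames Number of frames.
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return An [iri_trajectory()] with the shell specification in `metadata`.
#' @export
generate_solvated_trajectory <- function(solute, shells, n_bulk_waters = 50,
                                         box_nm = 4, n_frames = 10, seed = 1L) {
  if (!inherits(solute, "conformer")) solute <- conformer(solute$elements, solute$xyz)
  box <- if (length(box_nm) == 1) rep(box_nm, 3) else as.numeric(box_nm)
  stopifnot(length(box) == 3, all(box > 0), n_frames >= 1, n_bulk_waters >= 0)
  shells <- lapply(shells, function(s) {
    stopifnot(s$inner_nm > 0, s$outer_nm > s$inner_nm, s$n_waters >= 0)
    s
  })
  if (length(shells) > 1) {
    iv <- t(vapply(shells, function(s) c(s$inner_nm, s$outer_nm), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) stop("shells overlap")
  }
  outermost <- if (length(shells)) max(vapply(shells, `[[`, numeric(1), "outer_nm")) else 0
  if (outermost > min(box) / 2) stop("outermost shell exceeds half the box")
  margin <- 0.002
  set.seed(as.integer(seed))
  solute_wrapped <- wrap_coords(solute$xyz, box)

  place_water <- function(rmin, rmax) {
    # rejection-sample an O position whose min-image distance to the nearest
    # solute atom falls in [rmin, rmax); the radial draw is triangular
    # (peaked mid-band) so planted shells look like solvation peaks rather
    # than flat plateaus
    for (it in 1:10000) {
      anchor <- solute_wrapped[sample.int(nrow(solute_wrapped), 1), ]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- rmin + (rmax - rmin) * mean(stats::runif(2))
      pos <- (anchor + r * u) %% box
      dmin <- min(pair_dists_pbc(matrix(pos, 1), solute_wrapped, box))
      if (dmin >= rmin && dmin < rmax) return(pos)
    }
    stop("could not place water in band [", rmin, ", ", rmax, ")")
  }
  water_hydrogens <- function(o_pos) {
    # rigid TIP-like geometry, random orientation
    b <- 0.09572; half <- 104.52 / 2 * pi / 180
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    h1 <- o_pos + b * (cos(half) * u + sin(half) * v)
    h2 <- o_pos + b * (cos(half) * u - sin(half) * v)
    rbind(h1 %% box, h2 %% box)
  }

  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    o_list <- list(); h_list <- list()
    for (s in shells) {
      if (s$n_waters == 0) next
      for (w in seq_len(s$n_waters)) {
        o <- place_water(s$inner_nm + margin, s$outer_nm - margin)
        o_list[[length(o_list) + 1L]] <- o
        h_list[[length(h_list) + 1L]] <- water_hydrogens(o)
      }
    }
    if (n_bulk_waters > 0) {
      placed <- 0L
      for (it in 1:100000) {
        if (placed >= n_bulk_waters) break
        pos <- stats::runif(3) * box
        dmin <- min(pair_dists_pbc(matrix(pos, 1), solute_wrapped, box))
        if (dmin > outermost + 2 * margin) {
          o_list[[length(o_list) + 1L]] <- pos
          h_list[[length(h_list) + 1L]] <- water_hydrogens(pos)
          placed <- placed + 1L
        }
      }
      if (placed < n_bulk_waters) stop("could not place all bulk waters")
    }
    frames[[fi]] <- solvated_frame(
      solute_elements = solute$elements,
      solute_xyz = solute_wrapped,
      water_oxygen_xyz = if (length(o_list)) do.call(rbind, o_list) else matrix(0, 0, 3),
      water_hydrogen_xyz = if (length(h_list)) do.call(rbind, h_list) else matrix(0, 0, 3),
      box = box
    )
  }
  iri_trajectory(frames, metadata = list(shells = shells, seed = as.integer(seed),
                                         n_bulk_waters = n_bulk_waters,
                                         origin = "iriscreen synthetic generator"))
}

# Enumerable amino-acid-like scaffold family used by the SAR generator.
sar_scaffold_family <- function() {
  templates <- c(
    "NC(%s)C(=O)O",   # alpha amino acid
    "NCC(%s)C(=O)O",  # beta amino acid
    "NC(%s)C(=O)OC",  # methyl ester
    "NC(%s)CO",       # amino alcohol
    "CNC(%s)C(=O)O",  # N-methylated
    "NC(%s)C(=O)OCC"  # ethyl ester
  )
  side_chains <- c(
    "C", "CC", "CCC", "CC(C)C", "CCCC", "CO", "CCO", "CS", "CCS",
    "CC(=O)N", "CCC(=O)N", "CC(=O)O", "CCC(=O)O", "CCCCN", "CC(C)O",
    "CSC", "CCSC", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccc(O)cc1", "Cc1ccncc1",
    "Cc1cccnc1", "Cc1ccco1", "Cc1cccs1"
  )
  grid <- expand.grid(template = templates, side = side_chains,
                      stringsAsFactors = FALSE)
  sprintf(grid$template, grid$side)
}

# Frozen standardisation constants for the three generating descriptors
# (roughly centre/scale of the scaffold family; never refit).
SAR_STANDARDISATION <- list(
  MolWt = c(center = 140, scale = 45),
  TPSA = c(center = 70, scale = 25),
  MolLogP = c(center = -1.2, scale = 1.2)
)

# Generating weights on the standardised (MolWt, TPSA, MolLogP) scale:
# polar surface area raises activity (lower %MGS); size and lipophilicity
# lower it.
SAR_COEFFICIENTS <- c(intercept = 0.25, MolWt = 1.0, TPSA = -1.3, MolLogP = 0.8)

#' Generate a synthetic structure-activity dataset
#'
#' Emulates a measured IRI activity table: SMILES drawn from a built-in
#' enumerable family of amino-acid-like scaffolds; the true activity is a
#' logistic function of a fixed linear combination of three standard
#' descriptors (molecular weight, topological polar surface area, calculated
#' logP), rescaled to \[5, 110\] %MGS; the observed `mgs_percent` adds
#' Gaussian assay noise (clamped to \[0, 120\]) and `mgs_sd` is drawn from a
#' positive (gamma) distribution with mean `noise_sd`, mimicking replicate
#' SDs. Defaults mirror the measured amino-acid dataset this generator
#' stands in for: 63 compounds, 10 %MGS assay noise.
#'
#' @param n_compounds Number of compounds (>= 10).
#' @param noise_sd Gaussian assay noise SD (%MGS); 0 gives exactly the
#'   logistic surface.
#' @param seed Integer seed.
#' @param skip Skip this many scaffolds from the head of the (deduplicated)
#'   family first -- used to build candidate libraries disjoint from a
#'   training set drawn with `skip = 0`.
#' @param dataset_tag Tag stored on the records.
#' @return A compound tibble with extra columns `true_mgs` (noise-free
#'   activity) and attributes `generating_coefficients`,
#'   `generating_descriptors` (standardised design matrix), `noise_sd`.
#' @export
generate_sar_dataset <- function(n_compounds = 63, noise_sd = 10, seed = 1L,
                                 skip = 0, dataset_tag = "Amino") {
  if (n_compounds < 10) stop("n_compounds must be at least 10")
  stopifnot(noise_sd >= 0)
  smiles_all <- sar_scaffold_family()
  can <- canonical_smiles(smiles_all)
  can <- can[!is.na(can)]
  can <- can[!duplicated(can)]
  # fixed deterministic shuffle (hash order) so that any contiguous slice
  # of the family -- e.g. a training set and a disjoint candidate library --
  # spans the same backbone/side-chain chemistry
  can <- can[order(vapply(can, rlang::hash, character(1)))]
  if (skip + n_compounds > length(can)) {
    stop("scaffold family exhausted: asked for ", skip + n_compounds,
         " of ", length(can), " unique scaffolds")
  }
  smiles <- can[(skip + 1):(skip + n_compounds)]
  desc <- compute_standard_descriptors(smiles)
  Z <- vapply(names(SAR_STANDARDISATION), function(nm) {
    st <- SAR_STANDARDISATION[[nm]]
    (desc[[nm]] - st[["center"]]) / st[["scale"]]
  }, numeric(n_compounds))
  Z <- matrix(Z, ncol = 3, dimnames = list(NULL, names(SAR_STANDARDISATION)))
  z <- SAR_COEFFICIENTS[["intercept"]] +
    as.numeric(Z %*% SAR_COEFFICIENTS[names(SAR_STANDARDISATION)])
  true_mgs <- 5 + 105 * stats::plogis(z)
  set.seed(as.integer(seed))
  mgs <- pmin(pmax(true_mgs + stats::rnorm(n_compounds, 0, noise_sd), 0), 120)
  sds <- if (noise_sd > 0) {
    stats::rgamma(n_compounds, shape = 4, scale = noise_sd / 4)
  } else {
    rep(0, n_compounds)
  }
  out <- tibble::tibble(
    id = sprintf("SAR%03d", skip + seq_len(n_compounds)),
    smiles = smiles,
    dataset_tag = dataset_tag,
    mgs_percent = mgs,
    mgs_sd = sds,
    concentration_mM = 20,
    true_mgs = true_mgs
  )
  attr(out, "generating_coefficients") <- SAR_COEFFICIENTS
  attr(out, "generating_descriptors") <- Z
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("iri_sar", class(out))
  out
}

#' Deterministic 3D conformers for a set of SMILES
#'
#' Embeds each molecule (with explicit hydrogens) using RDKit's distance
#' geometry with a seed derived per molecule, returning nm-coordinate
#' [conformer()] objects. Used to supply the conformer-based descriptors with
#' inputs when no simulation snapshot is available (fixture plumbing, not a
#' simulation substitute).
#'
#' @param smiles Character vector of SMILES.
#' @param seed Integer seed.
#' @return A named list of [conformer()]s (names = input SMILES).
#' @export
generate_conformers <- function(smiles, seed = 1L) {
  res <- rdkit_call("embed", smiles = as.list(as.character(smiles)),
                    seed = as.integer(seed))
  out <- lapply(seq_along(res$results), function(i) {
    r <- res$results[[i]]
    if (!isTRUE(r$ok)) stop("conformer embedding failed for '", smiles[i],
                            "': ", r$error)
    xyz <- matrix(unlist(r$xyz_angstrom), ncol = 3, byrow = TRUE) / 10
    conformer(unlist(r$elements), xyz)
  })
  stats::setNames(out, smiles)
}
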