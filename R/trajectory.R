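#' Construct a single solvated frame
#'
#' One snapshot of a solute in water: solute atoms, water oxygens, two water
#' hydrogens per oxygen (rows `2i-1`, `2i` of `water_hydrogen_xyz` belong to
#' water `i`), and an orthorhombic box. All coordinates and box edges in nm.
#' Virtual sites of four-site water models are not represented; only O and
#' the two H of each water are kept.
#'
#' @param solute_elements Character vector of element symbols.
#' @param solute_xyz Numeric matrix (n_solute x 3), nm.
#' @param water_oxygen_xyz Numeric matrix (n_water x 3), nm.
#' @param water_hydrogen_xyz Numeric matrix (2*n_water x 3), nm.
#' @param box Numeric length-3 vector of box edge lengths (nm).
#' @return A list of class `solvated_frame`.
#' @export
solvated_frame <- function(solute_elements, solute_xyz, water_oxygen_xyz,
                           water_hydrogen_xyz, box) {
  solute_xyz <- matrix(as.numeric(solute_xyz), ncol = 3)
  water_oxygen_xyz <- matrix(as.numeric(water_oxygen_xyz), ncol = 3)
  water_hydrogen_xyz <- matrix(as.numeric(water_hydrogen_xyz), ncol = 3)
  box <- as.numeric(box)
  stopifnot(
    length(solute_elements) == nrow(solute_xyz),
    nrow(water_hydrogen_xyz) == 2 * nrow(water_oxygen_xyz),
    length(box) == 3
  )
  if (!all(is.finite(solute_xyz)) || !all(is.finite(water_oxygen_xyz)) ||
      !all(is.finite(water_hydrogen_xyz))) {
    stop("non-finite coordinates in frame")
  }
  if (!all(box > 0)) stop("box edges must be positive")
  structure(list(
    solute_elements = as.character(solute_elements),
    solute_xyz = solute_xyz,
    water_oxygen_xyz = water_oxygen_xyz,
    water_hydrogen_xyz = water_hydrogen_xyz,
    box = box
  ), class = "solvated_frame")
}

#' Construct a trajectory
#'
#' An ordered list of [solvated_frame()]s with constant solute composition,
#' plus free-form metadata (e.g. temperature, origin).
#'
#' @param frames List of `solvated_frame` objects (at least one).
#' @param metadata Named list.
#' @return An object of class `iri_trajectory`.
#' @export
iri_trajectory <- function(frames, metadata = list()) {
  stopifnot(is.list(frames), length(frames) >= 1)
  n_solute <- vapply(frames, function(f) nrow(f$solute_xyz), integer(1))
  if (length(unique(n_solute)) != 1) {
    stop("solute atom count varies across frames: ",
         paste(unique(n_solute), collapse = ", "))
  }
  structure(list(frames = frames, metadata = metadata), class = "iri_trajectory")
}

#' @export
print.iri_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat("<iri_trajectory> ", length(x$frames), " frame(s), ",
      nrow(f1$solute_xyz), " solute atoms, ",
      nrow(f1$water_oxygen_xyz), " waters, box ",
      paste(sprintf("%.3f", f1$box), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}

#' @export
length.iri_trajectory <- function(x) length(x$frames)

#' Read a solvated trajectory
#'
#' Reads a multi-frame GRO file (fixed-column, one box line per frame;
#' waters identified by residue name) or an extended-XYZ file (comment line
#' carries a `Lattice="lx 0 0 0 ly 0 0 0 lz"` box and
#' `Properties=...:mol:I:1`; a per-atom molecule tag of 0 marks solute atoms,
#' positive tags group water molecules; coordinates in Angstrom, converted to
#' nm). Solute = all non-water atoms. Atom counts must be constant across
#' frames.
#'
#' @param path File path.
#' @param format `"gro"` or `"xyz"`; default guessed from the extension.
#' @param water_residues Residue names treated as water in GRO input.
#' @return An [iri_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "xyz"),
                            water_residues = c("SOL", "HOH", "WAT", "TIP4")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  }
  lines <- readLines(path, warn = FALSE)
  frames <- if (format == "gro") {
    parse_gro_frames(lines, water_residues)
  } else {
    parse_extxyz_frames(lines)
  }
  counts <- vapply(frames, function(f) {
    nrow(f$solute_xyz) + 3L * nrow(f$water_oxygen_xyz)
  }, integer(1))
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop("inconsistent atom count at frame ", bad, " (", counts[bad],
         " vs ", counts[1], ")")
  }
  iri_trajectory(frames, metadata = list(source = path, format = format))
}

parse_gro_frames <- function(lines, water_residues) {
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  n_expect <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    frame_idx <- frame_idx + 1L
    if (i + 1L > length(lines)) stop("truncated GRO frame ", frame_idx)
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("bad atom-count line in GRO frame ", frame_idx)
    if (is.na(n_expect)) n_expect <- natoms
    if (natoms != n_expect) {
      stop("inconsistent atom count at frame ", frame_idx,
           " (", natoms, " vs ", n_expect, ")")
    }
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    if (is.na(box_line) || !nzchar(trimws(box_line))) {
      stop("missing box line in GRO frame ", frame_idx)
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
    if (length(box) < 3 || anyNA(box[1:3])) {
      stop("missing box line in GRO frame ", frame_idx)
    }
    resname <- trimws(substr(atom_lines, 6, 10))
    atomname <- trimws(substr(atom_lines, 11, 15))
    resid <- trimws(substr(atom_lines, 1, 5))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(c(x, y, z))) stop("unparseable coordinates in GRO frame ", frame_idx)
    xyz <- cbind(x, y, z)
    is_water <- toupper(resname) %in% toupper(water_residues)
    # Group water atoms into molecules by runs of (resid, resname).
    run_id <- cumsum(c(TRUE, resid[-1] != resid[-length(resid)] |
                         resname[-1] != resname[-length(resname)]))
    o_xyz <- NULL; h_xyz <- NULL
    for (rid in unique(run_id[is_water])) {
      sel <- which(run_id == rid)
      names_sel <- atomname[sel]
      o_sel <- sel[grepl("^O", names_sel, ignore.case = TRUE)]
      h_sel <- sel[grepl("^H", names_sel, ignore.case = TRUE)]
      # virtual sites (MW etc.) of 4-site models are dropped
      if (length(o_sel) != 1 || length(h_sel) != 2) {
        stop("water residue with ", length(o_sel), " O and ", length(h_sel),
             " H atoms in GRO frame ", frame_idx)
      }
      o_xyz <- rbind(o_xyz, xyz[o_sel, , drop = FALSE])
      h_xyz <- rbind(h_xyz, xyz[h_sel, , drop = FALSE])
    }
    solute_sel <- which(!is_water)
    frames[[frame_idx]] <- solvated_frame(
      solute_elements = element_from_atomname(atomname[solute_sel]),
      solute_xyz = xyz[solute_sel, , drop = FALSE],
      water_oxygen_xyz = if (is.null(o_xyz)) matrix(0, 0, 3) else o_xyz,
      water_hydrogen_xyz = if (is.null(h_xyz)) matrix(0, 0, 3) else h_xyz,
      box = box[1:3]
    )
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(frames) == 0) stop("no frames found in GRO file")
  frames
}

parse_extxyz_frames <- function(lines) {
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  n_expect <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_idx <- frame_idx + 1L
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop("bad atom-count line in XYZ frame ", frame_idx)
    if (is.na(n_expect)) n_expect <- natoms
    if (natoms != n_expect) {
      stop("inconsistent atom count at frame ", frame_idx,
           " (", natoms, " vs ", n_expect, ")")
    }
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
    if (length(m) == 0) stop("missing Lattice box in XYZ frame ", frame_idx)
    lat <- as.numeric(strsplit(gsub('Lattice="|"', "", m), "\\s+")[[1]])
    if (length(lat) != 9) stop("Lattice must have 9 components (frame ", frame_idx, ")")
    if (any(abs(lat[c(2, 3, 4, 6, 7, 8)]) > 1e-9)) {
      stop("only orthorhombic boxes are supported (frame ", frame_idx, ")")
    }
    box_nm <- lat[c(1, 5, 9)] / 10
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    tok <- strsplit(trimws(atom_lines), "\\s+")
    if (any(lengths(tok) < 5)) {
      stop("XYZ atom lines need 'element x y z mol' (frame ", frame_idx, ")")
    }
    el <- vapply(tok, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(tok, `[`, 2:4))),
                  ncol = 3, byrow = TRUE) / 10
    mol <- as.integer(vapply(tok, `[[`, "", 5))
    solute_sel <- which(mol == 0L)
    o_xyz <- NULL; h_xyz <- NULL
    for (mid in sort(unique(mol[mol > 0L]))) {
      sel <- which(mol == mid)
      o_sel <- sel[el[sel] == "O"]
      h_sel <- sel[el[sel] == "H"]
      if (length(o_sel) != 1 || length(h_sel) != 2) {
        stop("water molecule tag ", mid, " has ", length(o_sel), " O and ",
             length(h_sel), " H atoms in XYZ frame ", frame_idx)
      }
      o_xyz <- rbind(o_xyz, xyz[o_sel, , drop = FALSE])
      h_xyz <- rbind(h_xyz, xyz[h_sel, , drop = FALSE])
    }
    frames[[frame_idx]] <- solvated_frame(
      solute_elements = el[solute_sel],
      solute_xyz = xyz[solute_sel, , drop = FALSE],
      water_oxygen_xyz = if (is.null(o_xyz)) matrix(0, 0, 3) else o_xyz,
      water_hydrogen_xyz = if (is.null(h_xyz)) matrix(0, 0, 3) else h_xyz,
      box = box_nm
    )
    i <- i + 2L + natoms
  }
  if (length(frames) == 0) stop("no frames found in XYZ file")
  frames
}

#' Write a trajectory to GRO or extended XYZ
#'
#' GRO output uses residue `MOL` for the solute and `SOL`/`OW`/`HW1`/`HW2`
#' for waters, nm coordinates with three decimals. Extended-XYZ output writes
#' Angstrom coordinates with a `Lattice` box and a per-atom molecule tag
#' (0 = solute, k > 0 = water k).
#'
#' @param traj An [iri_trajectory()].
#' @param path Output path.
#' @param format `"gro"` or `"xyz"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "gro", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "iri_trajectory"))
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  }
  out <- character(0)
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    ns <- nrow(f$solute_xyz); nw <- nrow(f$water_oxygen_xyz)
    if (format == "gro") {
      block <- c(sprintf("iriscreen frame %d", fi), sprintf("%5d", ns + 3L * nw))
      at <- 0L
      for (a in seq_len(ns)) {
        at <- at + 1L
        block <- c(block, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                  1L, "MOL", paste0(f$solute_elements[a], a),
                                  at, f$solute_xyz[a, 1], f$solute_xyz[a, 2],
                                  f$solute_xyz[a, 3]))
      }
      for (w in seq_len(nw)) {
        res <- w + 1L
        oh <- rbind(f$water_oxygen_xyz[w, ],
                    f$water_hydrogen_xyz[2 * w - 1, ],
                    f$water_hydrogen_xyz[2 * w, ])
        nm <- c("OW", "HW1", "HW2")
        for (k in 1:3) {
          at <- at + 1L
          block <- c(block, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                    res %% 100000L, "SOL", nm[k], at %% 100000L,
                                    oh[k, 1], oh[k, 2], oh[k, 3]))
        }
      }
      block <- c(block, sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]))
    } else {
      lat <- sprintf('Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f"',
                     f$box[1] * 10, f$box[2] * 10, f$box[3] * 10)
      block <- c(sprintf("%d", ns + 3L * nw),
                 paste0(lat, " Properties=species:S:1:pos:R:3:mol:I:1"))
      for (a in seq_len(ns)) {
        block <- c(block, sprintf("%-2s %14.6f %14.6f %14.6f %d",
                                  f$solute_elements[a], f$solute_xyz[a, 1] * 10,
                                  f$solute_xyz[a, 2] * 10, f$solute_xyz[a, 3] * 10, 0L))
      }
      for (w in seq_len(nw)) {
        oh <- rbind(f$water_oxygen_xyz[w, ],
                    f$water_hydrogen_xyz[2 * w - 1, ],
                    f$water_hydrogen_xyz[2 * w, ])
        el <- c("O", "H", "H")
        for (k in 1:3) {
          block <- c(block, sprintf("%-2s %14.6f %14.6f %14.6f %d",
                                    el[k], oh[k, 1] * 10, oh[k, 2] * 10,
                                    oh[k, 3] * 10, w))
        }
      }
    }
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a single conformer (XYZ or PDB)
#'
#' Plain XYZ (Angstrom) or PDB `ATOM`/`HETATM` records. Coordinates are
#' converted to nm internally.
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the extension.
#' @return A list of class `conformer` with `elements` and `xyz` (nm).
#' @export
read_conformer <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") {
    natoms <- as.integer(trimws(lines[1]))
    tok <- strsplit(trimws(lines[3:(2 + natoms)]), "\\s+")
    el <- vapply(tok, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(tok, `[`, 2:4))), ncol = 3, byrow = TRUE)
  } else {
    rec <- lines[grepl("^(ATOM|HETATM)", lines)]
    if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
    el <- trimws(substr(rec, 77, 78))
    fallback <- element_from_atomname(substr(rec, 13, 16))
    el <- ifelse(nzchar(el), paste0(toupper(substr(el, 1, 1)),
                                    tolower(substr(el, 2, 2))), fallback)
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
  }
  conformer(el, xyz / 10)
}

#' Construct a conformer
#'
#' @param elements Element symbols.
#' @param xyz Coordinate matrix (nm).
#' @return A list of class `conformer`.
#' @export
conformer <- function(elements, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(elements) >= 1, length(elements) == nrow(xyz),
            all(is.finite(xyz)))
  structure(list(elements = as.character(elements), xyz = xyz),
            class = "conformer")
}

#' Write a conformer to plain XYZ (Angstrom)
#'
#' @param conf A [conformer()].
#' @param path Output path.
#' @param comment Comment line.
#' @return `path`, invisibly.
#' @export
write_conformer <- function(conf, path, comment = "iriscreen conformer") {
  stopifnot(inherits(conf, "conformer"))
  lines <- c(sprintf("%d", length(conf$elements)), comment,
             sprintf("%-2s %14.6f %14.6f %14.6f", conf$elements,
                     conf$xyz[, 1] * 10, conf$xyz[, 2] * 10, conf$xyz[, 3] * 10))
  writeLines(lines, path)
  invisible(path)
}
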