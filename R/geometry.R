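# Periodic-geometry primitives shared by the fixture generator and the
# hydration analysis. Boxes are orthorhombic, lengths in nm.

# Wrap coordinates into [0, box) per dimension.
wrap_coords <- function(xyz, box) {
  stopifnot(ncol(xyz) == 3, length(box) == 3)
  sweep(xyz, 2, box, function(x, b) x - b * floor(x / b))
}

# All pairwise minimum-image distances between rows of A and rows of B.
pair_dists_pbc <- function(A, B, box) {
  A <- matrix(as.numeric(A), ncol = 3)
  B <- matrix(as.numeric(B), ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Minimum-image displacement vectors from a single point to rows of B.
disp_pbc <- function(point, B, box) {
  B <- matrix(as.numeric(B), ncol = 3)
  d <- sweep(B, 2, as.numeric(point), "-")
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

element_from_atomname <- function(name) {
  name <- trimws(name)
  two <- c("Cl", "Br", "Na", "Mg", "Ca", "Zn", "Fe", "Si", "Se")
  first2 <- substr(gsub("[^A-Za-z].*$", "", name), 1, 2)
  first2 <- paste0(toupper(substr(first2, 1, 1)), tolower(substr(first2, 2, 2)))
  ifelse(first2 %in% two, first2, toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1)))
}

# Bondi van der Waals radii (Angstrom), used by size metrics and H-bond
# connectivity perception.
VDW_RADII_A <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                 S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

COVALENT_RADII_A <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                      P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

vdw_radius_A <- function(elements) {
  r <- VDW_RADII_A[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

covalent_radius_A <- function(elements) {
  r <- COVALENT_RADII_A[elements]
  r[is.na(r)] <- 0.76
  unname(r)
}
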