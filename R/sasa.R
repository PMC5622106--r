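# Shrake-Rupley solvent-accessible surface area with a polar /
# non-polar partition, and interface burial on dimerisation by the
# subtraction scheme SASA(A) + SASA(B) - SASA(AB).

#' Default atomic radii (Angstrom) by element
#'
#' A standard protein atomic-radii table keyed by element symbol; any
#' equivalently named vector can be supplied to [atom_sasa()].
#' @export
DEFAULT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, SE = 1.90)

# quasi-uniform points on the unit sphere (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# element symbol per atom: prefer the elesy column, fall back to the
# first alphabetic character of the atom name
.atom_elements <- function(atom) {
  el <- toupper(trimws(atom$elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", atom$elety[miss]))
    el[miss] <- toupper(substr(nm, 1, 1))
  }
  el
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the structure: each atom's sphere is
#' expanded by the probe radius and sampled with `n_points`
#' quasi-uniform surface points; the accessible area is the fraction
#' of points not inside any other expanded sphere, times the expanded
#' sphere's area. Totals are partitioned into polar (N, O by default,
#' plus hydrogens bonded-by-name to them when present) and non-polar
#' contributions.
#'
#' @param pdb a bio3d pdb object or PDB-format file path.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @param radii named radii table by element; unknown elements are an
#'   error naming the atom.
#' @param polar_elements elements counted as polar (default N, O; S
#'   is treated as non-polar).
#' @return a `sasa_result`: per-atom areas and `total`, `polar`,
#'   `nonpolar` totals (Angstrom^2).
#' @export
atom_sasa <- function(pdb, probe = 1.4, n_points = 960,
                      radii = DEFAULT_RADII,
                      polar_elements = c("N", "O")) {
  stopifnot(probe > 0, n_points > 1)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  n <- nrow(atom)
  if (n == 0L) stop("structure has no ATOM records")
  el <- .atom_elements(atom)
  unknown <- !(el %in% names(radii))
  if (any(unknown))
    stop("no radius for element '", el[which(unknown)[1]], "' (atom ",
         atom$elety[which(unknown)[1]], " in residue ",
         atom$resid[which(unknown)[1]], atom$resno[which(unknown)[1]], ")")
  r <- radii[el] + probe
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists via squared-distance threshold
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & d2 > 0)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  polar <- el %in% polar_elements
  structure(list(atom_area = area, elements = el, polar = polar,
                 total = sum(area), polar_area = sum(area[polar]),
                 nonpolar_area = sum(area[!polar]),
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result> %d atoms: total %.1f A^2 (polar %.1f, non-polar %.1f)\n",
    length(x$atom_area), x$total, x$polar_area, x$nonpolar_area))
  invisible(x)
}

#' Surface area buried on dimerisation
#'
#' `buried = SASA(A) + SASA(B) - SASA(AB)`: the accessible area lost
#' when the two subunits associate. Non-negative up to point-sampling
#' noise.
#'
#' @param A,B,AB subunit and dimer structures; `AB` must contain
#'   exactly the atoms of `A` plus `B`.
#' @inheritParams atom_sasa
#' @return buried area in Angstrom^2, with attribute `components`.
#' @export
buried_surface <- function(A, B, AB, probe = 1.4, n_points = 960,
                           radii = DEFAULT_RADII) {
  as_pdb <- function(x) if (is.character(x))
    bio3d::read.pdb(x, verbose = FALSE) else x
  A <- as_pdb(A); B <- as_pdb(B); AB <- as_pdb(AB)
  na <- sum(A$atom$type == "ATOM"); nb <- sum(B$atom$type == "ATOM")
  nab <- sum(AB$atom$type == "ATOM")
  if (na + nb != nab)
    stop(sprintf("atom mismatch: |A| + |B| = %d but |AB| = %d", na + nb, nab))
  sa <- atom_sasa(A, probe, n_points, radii)
  sb <- atom_sasa(B, probe, n_points, radii)
  sab <- atom_sasa(AB, probe, n_points, radii)
  structure(sa$total + sb$total - sab$total,
            components = c(A = sa$total, B = sb$total, AB = sab$total))
}
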