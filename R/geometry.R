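# Geometric kernels for the per-frame observables. All inputs are plain
# numeric 3-vectors / n x 3 matrices in Angstrom; angle outputs are degrees.

#' Minimum pairwise distance between two atom sets
#'
#' Chemically equivalent atoms (the two carboxylate oxygens of Asp/Glu)
#' are passed as a set and the minimum over all cross pairs is taken,
#' the standard convention for group-to-group contact distances.
#'
#' @param set_a,set_b numeric 3-vectors or `n x 3` matrices.
#' @return minimum Euclidean distance (Angstrom).
#' @export
min_pair_distance <- function(set_a, set_b) {
  a <- as_coord_matrix(set_a, "set_a")
  b <- as_coord_matrix(set_b, "set_b")
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

as_coord_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 3L || nrow(x) < 1L)
    stop(what, " must be a non-empty set of 3-D points")
  storage.mode(x) <- "double"
  x
}

#' Signed torsion (dihedral) angle
#'
#' IUPAC-signed torsion of the plane (p1,p2,p3) against (p2,p3,p4),
#' in degrees in (-180, 180]. Used for side-chain rotamer readouts such
#' as the Gln C-CA-CG-CD pseudo-dihedral.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-10)
    stop("degenerate geometry: torsion axis points coincide")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: collinear points in torsion")
  b2h <- b2 / sqrt(sum(b2^2))
  atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Helix rotation angle in the membrane plane
#'
#' Measures rotation of a helix about the membrane normal: a tangent
#' vector is taken as the XY-projected difference of the CA positions of
#' two consecutive residues (default S324(7.47) -> L325(7.48) at the
#' bottom of TM7), and the signed angle from the reference frame's
#' vector to the mobile frame's vector is returned. Positive =
#' counter-clockwise when viewed down the +z axis (from the
#' extracellular side); set `sign = -1` to flip the convention.
#'
#' @param frame a `kor_frame` already superposed onto `reference`.
#' @param reference the reference `kor_frame`.
#' @param map a [residue_map()].
#' @param res_a,res_b Ballesteros-Weinstein codes of the tangent pair.
#' @param sign +1 (default) or -1, orientation convention.
#' @return signed angle in degrees in (-180, 180].
#' @export
xy_rotation_angle <- function(frame, reference, map,
                              res_a = "7.47", res_b = "7.48", sign = 1) {
  v_ref <- (resolve_atom(map, res_b, "CA", reference) -
            resolve_atom(map, res_a, "CA", reference))[1:2]
  v_mob <- (resolve_atom(map, res_b, "CA", frame) -
            resolve_atom(map, res_a, "CA", frame))[1:2]
  if (sqrt(sum(v_ref^2)) < 1e-10 || sqrt(sum(v_mob^2)) < 1e-10)
    stop("degenerate geometry: zero-length XY projection of helix tangent")
  ang <- atan2(v_ref[1] * v_mob[2] - v_ref[2] * v_mob[1],
               sum(v_ref * v_mob)) * 180 / pi
  sign * ang
}

#' Vertical (membrane-normal) displacement of an atom selection
#'
#' Mean z of the selected atoms in `frame` minus the same mean in
#' `reference`. Under the membrane-aligned convention used throughout
#' (+z extracellular), negative values are displacements toward the
#' intracellular side ("downward"), e.g. of the W287(6.48) indole ring.
#'
#' @param frame,reference superposed and reference `kor_frame`s.
#' @param map a [residue_map()].
#' @param selection data.frame (or list of pairs) with columns `code`
#'   and `atom_name`.
#' @return signed displacement in Angstrom.
#' @export
z_displacement <- function(frame, reference, map, selection) {
  sel <- as.data.frame(selection)
  if (nrow(sel) == 0L) stop("empty atom selection")
  zf <- mapply(function(code, at) resolve_atom(map, code, at, frame)[3],
               sel$code, sel$atom_name)
  zr <- mapply(function(code, at) resolve_atom(map, code, at, reference)[3],
               sel$code, sel$atom_name)
  mean(zf) - mean(zr)
}

# Atom-set conventions for the named interactions (captions name chemical
# groups; the minimum over equivalent oxygens realizes them).
asp_carboxylate_atoms <- function() c("OD1", "OD2")
glu_carboxylate_atoms <- function() c("OE1", "OE2")
thr_hydroxyl_atoms <- function() "OG1"
lys_amine_atoms <- function() "NZ"
trp_ring_atoms <- function()
  c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
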