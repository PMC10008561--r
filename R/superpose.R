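# Rigid-body superposition (Kabsch). Analysis-time alignment mirrors the
# simulation protocol: frames are least-squares fitted on the Calpha atoms of
# TM2, TM3 and TM5 before any rotation/displacement metric is read out, so
# those metrics are expressed in the membrane-fixed frame of the reference
# structure (+z pointing extracellular, OPM convention).

#' Alignment specification
#'
#' @param reference a `kor_frame` ([get_frame()]) serving as the fixed
#'   reference (typically frame 1 or the crystal structure).
#' @param residue_numbers integer vector of residue numbers whose CA
#'   atoms define the superposition (default: TM2/TM3/TM5 ranges from
#'   the shipped config).
#' @param chain_id chain the selection lives on.
#' @param atom_name atom used for fitting, "CA" by default.
#' @return An `alignment_spec` list.
#' @export
alignment_spec <- function(reference, residue_numbers, chain_id = "A",
                           atom_name = "CA") {
  stopifnot(inherits(reference, "kor_frame"))
  idx <- selection_indices(reference, residue_numbers, chain_id, atom_name)
  if (length(idx) < 3L)
    stop("alignment selection resolves to fewer than 3 atoms")
  structure(list(reference = reference,
                 residue_numbers = as.integer(residue_numbers),
                 chain_id = chain_id, atom_name = atom_name),
            class = "alignment_spec")
}

selection_indices <- function(frame, residue_numbers, chain_id, atom_name) {
  which(frame$atoms$chain_id == chain_id &
        frame$atoms$residue_number %in% residue_numbers &
        frame$atoms$atom_name == atom_name)
}

#' Kabsch optimal rotation
#'
#' Least-squares rotation (proper, det = +1) mapping centered `mobile`
#' onto centered `target`.
#'
#' @param mobile,target `n x 3` matrices of paired coordinates.
#' @return `3 x 3` rotation matrix `R` such that `mobile %*% R`
#'   approximates `target` after centering.
#' @keywords internal
kabsch_rotation <- function(mobile, target) {
  h <- crossprod(mobile, target)          # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))          # guard against reflection
  # maximizes trace(R' H) over proper rotations; use as mobile %*% R
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose a frame onto a reference
#'
#' Rigid-body (rotation + translation, no scaling or reflection)
#' least-squares fit of the selected CA atoms onto the reference; the
#' whole frame is transformed and the RMSD over the selection returned.
#'
#' @param frame a `kor_frame` to transform.
#' @param spec an [alignment_spec()].
#' @return list with `frame` (transformed `kor_frame`), `rmsd`
#'   (Angstrom, over the selection), `rotation` and `translation`.
#' @export
superpose_frame <- function(frame, spec) {
  stopifnot(inherits(frame, "kor_frame"), inherits(spec, "alignment_spec"))
  idx_m <- selection_indices(frame, spec$residue_numbers, spec$chain_id,
                             spec$atom_name)
  idx_r <- selection_indices(spec$reference, spec$residue_numbers,
                             spec$chain_id, spec$atom_name)
  if (length(idx_m) != length(idx_r) || length(idx_m) < 3L)
    stop("alignment selection not resolvable in both frames")
  mob <- frame$xyz[idx_m, , drop = FALSE]
  tgt <- spec$reference$xyz[idx_r, , drop = FALSE]
  cm <- colMeans(mob); ct <- colMeans(tgt)
  mob_c <- sweep(mob, 2, cm); tgt_c <- sweep(tgt, 2, ct)
  # collinearity check: rank of centered selection must be >= 2
  if (sum(svd(mob_c)$d > 1e-8 * max(1, max(abs(mob_c)))) < 2L)
    stop("degenerate alignment: selected atoms are collinear")
  rot <- kabsch_rotation(mob_c, tgt_c)
  new_xyz <- sweep(frame$xyz, 2, cm) %*% rot
  new_xyz <- sweep(new_xyz, 2, ct, `+`)
  fitted <- new_xyz[idx_m, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - tgt)^2)))
  list(frame = structure(list(atoms = frame$atoms, xyz = new_xyz),
                         class = "kor_frame"),
       rmsd = rmsd, rotation = rot, translation = ct - cm %*% rot)
}
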