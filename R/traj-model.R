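#' Multi-frame structure container
#'
#' A `kor_trajectory` stores an ordered set of frames (e.g. saved MD
#' snapshots) sharing one atom table. Coordinates are kept as a
#' `n_atoms x 3 x n_frames` array in Angstrom; atom identity
#' (`chain_id`, `residue_number`, `atom_name`) is unique within a frame
#' and identical across frames, mirroring how a multi-MODEL PDB file is
#' laid out.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`.
#' @param xyz numeric array `c(nrow(atoms), 3, n_frames)` (a single
#'   `n x 3` matrix is promoted to one frame).
#' @param replicate_id character scalar identifying the simulation
#'   replicate this trajectory came from.
#' @param condition character scalar, typically the bound ligand name.
#' @return An object of class `kor_trajectory`.
#' @export
kor_trajectory <- function(atoms, xyz, replicate_id = "rep1",
                           condition = "unknown") {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_name", "residue_name", "chain_id", "residue_number")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), ncol(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (dim(xyz)[1] != nrow(atoms))
    stop("coordinate array and atom table disagree on atom count")
  if (dim(xyz)[3] < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (any(!nzchar(atoms$atom_name))) stop("empty atom_name in atom table")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) identity within a frame: ",
         key[anyDuplicated(key)])
  structure(
    list(atoms = atoms, xyz = xyz,
         replicate_id = as.character(replicate_id),
         condition = as.character(condition)),
    class = "kor_trajectory")
}

#' @export
print.kor_trajectory <- function(x, ...) {
  cat(sprintf("<kor_trajectory> %d frames, %d atoms, replicate '%s', condition '%s'\n",
              n_frames(x), nrow(x$atoms), x$replicate_id, x$condition))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `kor_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame from a trajectory
#'
#' @param traj a `kor_trajectory`.
#' @param i 1-based frame index.
#' @return A `kor_frame`: list with the atom table and an `n x 3`
#'   coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  structure(list(atoms = traj$atoms, xyz = traj$xyz[, , i, drop = TRUE]),
            class = "kor_frame")
}

# ---- multi-model PDB I/O ---------------------------------------------------
# Deliberately minimal dialect: only ATOM/HETATM, MODEL, ENDMDL records are
# honored (TER, REMARK etc. are skipped). Coordinates are the standard
# fixed columns 31-54, occupancies/B-factors are not retained.

parse_atom_line <- function(line, lineno) {
  x <- suppressWarnings(c(
    as.numeric(substr(line, 31, 38)),
    as.numeric(substr(line, 39, 46)),
    as.numeric(substr(line, 47, 54))))
  if (any(is.na(x)))
    stop(sprintf("malformed coordinate field at line %d: '%s'", lineno, line))
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (is.na(resno))
    stop(sprintf("malformed residue number at line %d: '%s'", lineno, line))
  list(atom_name = trimws(substr(line, 13, 16)),
       residue_name = trimws(substr(line, 18, 20)),
       chain_id = trimws(substr(line, 22, 22)),
       residue_number = resno,
       x = x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL tags
#' yields a single-frame trajectory. All models must contain the same
#' atoms in the same order.
#'
#' @param path path to a PDB file.
#' @param replicate_id,condition metadata attached to the trajectory.
#' @return A [kor_trajectory()].
#' @export
read_multimodel_pdb <- function(path, replicate_id = "rep1",
                                condition = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- NULL
  saw_model_tag <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      saw_model_tag <- TRUE
      cur <- list()
    } else if (startsWith(r, "ENDMDL")) {
      models[[length(models) + 1L]] <- cur
      cur <- NULL
    } else if (r == "ATOM  " || r == "HETATM") {
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1L]] <- parse_atom_line(lines[i], i)
    }
  }
  if (!is.null(cur) && length(cur)) models[[length(models) + 1L]] <- cur
  if (!length(models) || !length(models[[1]]))
    stop("no ATOM/HETATM records found in ", path)
  first <- models[[1]]
  atoms <- data.frame(
    atom_name = vapply(first, `[[`, "", "atom_name"),
    residue_name = vapply(first, `[[`, "", "residue_name"),
    chain_id = vapply(first, `[[`, "", "chain_id"),
    residue_number = vapply(first, function(a) a$residue_number, 1L),
    stringsAsFactors = FALSE)
  nat <- nrow(atoms)
  xyz <- array(NA_real_, dim = c(nat, 3L, length(models)))
  for (m in seq_along(models)) {
    blk <- models[[m]]
    if (length(blk) != nat)
      stop(sprintf("inconsistent atom sets across MODELs: model %d has %d atoms, model 1 has %d",
                   m, length(blk), nat))
    ids <- vapply(blk, function(a)
      paste(a$chain_id, a$residue_number, a$atom_name), "")
    ref_ids <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
    if (!identical(ids, ref_ids))
      stop(sprintf("inconsistent atom ordering/identity in MODEL %d", m))
    xyz[, , m] <- t(vapply(blk, `[[`, numeric(3), "x"))
  }
  if (!saw_model_tag && length(models) != 1L)
    stop("internal: untagged file produced multiple models")
  kor_trajectory(atoms, xyz, replicate_id, condition)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [kor_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "kor_trajectory"))
  if (n_frames(traj) < 1L) stop("refusing to write an empty trajectory")
  a <- traj$atoms
  # PDB atom-name justification: names of <4 chars start in column 14
  nm <- ifelse(nchar(a$atom_name) >= 4L, substr(a$atom_name, 1, 4),
               sprintf(" %-3s", a$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", m), con)
    xyzm <- traj$xyz[, , m, drop = TRUE]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)), nm, a$residue_name, a$chain_id, a$residue_number,
      xyzm[, 1], xyzm[, 2], xyzm[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- residue map -----------------------------------------------------------

#' Ballesteros-Weinstein residue map
#'
#' Maps generic GPCR residue codes ("2.39", "7.47", loop labels like
#' "ECL2") to concrete (chain, residue number, residue name) triples, so
#' analysis code can address residues by position in the fold rather
#' than author numbering.
#'
#' @param codes character vector of Ballesteros-Weinstein codes.
#' @param chain_id character vector (recycled) of chain identifiers.
#' @param residue_number integer vector of residue numbers.
#' @param residue_name character vector of 3-letter residue names.
#' @return A `residue_map` data.frame.
#' @export
residue_map <- function(codes, chain_id, residue_number, residue_name) {
  if (anyDuplicated(codes)) stop("duplicate Ballesteros-Weinstein codes")
  out <- data.frame(code = as.character(codes),
                    chain_id = as.character(chain_id),
                    residue_number = as.integer(residue_number),
                    residue_name = as.character(residue_name),
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_map", class(out))
  out
}

#' Default residue map for human KOR
#'
#' Author numbering of the residues used by the state-classification
#' metrics: T94(2.39), Q115(2.60), K227(5.39), W287(6.48), E297(6.58),
#' Y320(7.43), S324(7.47), L325(7.48), D334(8.47), all on chain A.
#'
#' @return A [residue_map()].
#' @export
default_kor_residue_map <- function() {
  residue_map(
    codes = c("2.39", "2.60", "5.39", "6.48", "6.58",
              "7.43", "7.47", "7.48", "8.47"),
    chain_id = "A",
    residue_number = c(94L, 115L, 227L, 287L, 297L, 320L, 324L, 325L, 334L),
    residue_name = c("THR", "GLN", "LYS", "TRP", "GLU",
                     "TYR", "SER", "LEU", "ASP"))
}

#' Resolve a residue-map code to an atom position
#'
#' @param map a [residue_map()].
#' @param code Ballesteros-Weinstein code present in `map`.
#' @param atom_name PDB atom name (e.g. "CA", "OD1").
#' @param frame a `kor_frame` from [get_frame()].
#' @return numeric length-3 position (Angstrom).
#' @export
resolve_atom <- function(map, code, atom_name, frame) {
  row <- map[map$code == code, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown Ballesteros-Weinstein code: ", code)
  idx <- which(frame$atoms$chain_id == row$chain_id &
               frame$atoms$residue_number == row$residue_number &
               frame$atoms$atom_name == atom_name)
  if (length(idx) == 0L)
    stop(sprintf("atom '%s' not found for residue %s%d (code %s)",
                 atom_name, row$chain_id, row$residue_number, code))
  as.numeric(frame$xyz[idx[1], ])
}

# ---- config ----------------------------------------------------------------

#' Read a receptor analysis configuration (YAML)
#'
#' The config carries the residue map, the transmembrane-helix residue
#' ranges used for superposition, and the classification thresholds; see
#' `system.file("extdata", "kor_config.yaml", package = "korbias")` for
#' the reference layout.
#'
#' @param path path to a YAML file.
#' @return list with elements `residue_map` (a [residue_map()]),
#'   `alignment_residues` (integer vector), `alignment_chain`, and
#'   `metric_config` (a [metric_config()]).
#' @export
read_kor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rm_tab <- cfg$residue_map
  map <- residue_map(
    codes = vapply(rm_tab, `[[`, "", "code"),
    chain_id = vapply(rm_tab, `[[`, "", "chain"),
    residue_number = vapply(rm_tab, function(x) as.integer(x$resno), 1L),
    residue_name = vapply(rm_tab, `[[`, "", "resname"))
  align <- unlist(lapply(cfg$alignment$tm_ranges,
                         function(r) seq.int(r[[1]], r[[2]])))
  mc_args <- cfg$thresholds
  mc <- do.call(metric_config, mc_args[names(mc_args) %in%
                                         names(formals(metric_config))])
  list(residue_map = map,
       alignment_residues = as.integer(align),
       alignment_chain = cfg$alignment$chain %||% "A",
       metric_config = mc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
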