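# Frame metric extraction, three-state classification and occupancy
# statistics for the intracellular coupling interface.

#' Classification thresholds and metric parameters
#'
#' Defaults implement the published rule: a frame is occluded when the
#' T94(2.39)-D334(8.47) oxygen distance is below 3.5 Angstrom, otherwise
#' alternative when the TM7 rotation is below -20 degrees, otherwise
#' canonical. The remaining parameters control the supporting
#' binding-pocket readouts: the K227-E297 salt-bridge cutoff, the cutoff
#' below which the W287 ring counts as displaced "downward", and the
#' circular window beyond which the Q115 rotamer counts as rotated away
#' from its crystallographic orientation (towards TM1).
#'
#' @param occluded_distance_cutoff Angstrom, strict upper bound for the
#'   occluded state (default 3.5).
#' @param tm7_rotation_cutoff degrees, strict upper bound for the
#'   alternative state (default -20).
#' @param salt_bridge_cutoff Angstrom (default 4.0).
#' @param w287_down_cutoff Angstrom; ring displacements at or below this
#'   count as downward (default -0.5).
#' @param q115_window degrees; dihedral excursions larger than this from
#'   the reference value, measured on the circle, count as rotated
#'   towards TM1 (default 60).
#' @param tm7_sign +1 or -1, orientation convention passed to
#'   [xy_rotation_angle()].
#' @return A `metric_config` list.
#' @export
metric_config <- function(occluded_distance_cutoff = 3.5,
                          tm7_rotation_cutoff = -20,
                          salt_bridge_cutoff = 4.0,
                          w287_down_cutoff = -0.5,
                          q115_window = 60,
                          tm7_sign = 1) {
  stopifnot(occluded_distance_cutoff > 0, salt_bridge_cutoff > 0,
            is.finite(tm7_rotation_cutoff), q115_window > 0,
            tm7_sign %in% c(-1, 1))
  structure(list(occluded_distance_cutoff = occluded_distance_cutoff,
                 tm7_rotation_cutoff = tm7_rotation_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 w287_down_cutoff = w287_down_cutoff,
                 q115_window = q115_window,
                 tm7_sign = tm7_sign),
            class = "metric_config")
}

#' State labels
#' @return character vector of the three state names, in precedence order.
#' @export
state_levels <- function() c("occluded", "alternative", "canonical")

#' Compute per-frame geometric metrics
#'
#' Superposes every frame onto the alignment reference, then evaluates
#' the five observables: the minimum T94 hydroxyl to D334 carboxylate
#' oxygen distance, the TM7 rotation angle at S324/L325, the Q115
#' C-CA-CG-CD dihedral, the minimum K227 amine to E297 carboxylate
#' oxygen distance, and the mean vertical displacement of the W287
#' indole ring.
#'
#' @param traj a [kor_trajectory()].
#' @param map a [residue_map()] (default [default_kor_residue_map()]).
#' @param spec an [alignment_spec()]; default aligns to frame 1 on the
#'   CA atoms of the configured TM2/TM3/TM5 ranges.
#' @param config a [metric_config()] (only `tm7_sign` is used here).
#' @return data.frame of class `frame_metrics` with columns
#'   `frame_index`, `t94_d334_distance`, `tm7_rotation`,
#'   `q115_dihedral`, `k227_e297_distance`, `w287_z_displacement`, and
#'   `alignment_rmsd`.
#' @export
compute_frame_metrics <- function(traj, map = default_kor_residue_map(),
                                  spec = NULL,
                                  config = metric_config()) {
  stopifnot(inherits(traj, "kor_trajectory"))
  if (is.null(spec)) {
    cfg <- read_kor_config(system.file("extdata", "kor_config.yaml",
                                       package = "korbias"))
    spec <- alignment_spec(get_frame(traj, 1L), cfg$alignment_residues,
                           cfg$alignment_chain)
  }
  ref <- spec$reference
  w287_sel <- data.frame(code = "6.48", atom_name = trp_ring_atoms())
  nfr <- n_frames(traj)
  out <- data.frame(frame_index = seq_len(nfr),
                    t94_d334_distance = NA_real_, tm7_rotation = NA_real_,
                    q115_dihedral = NA_real_, k227_e297_distance = NA_real_,
                    w287_z_displacement = NA_real_, alignment_rmsd = NA_real_)
  for (i in seq_len(nfr)) {
    sup <- superpose_frame(get_frame(traj, i), spec)
    fr <- sup$frame
    t94 <- resolve_atom(map, "2.39", thr_hydroxyl_atoms(), fr)
    d334 <- t(vapply(asp_carboxylate_atoms(),
                     function(a) resolve_atom(map, "8.47", a, fr), numeric(3)))
    k227 <- resolve_atom(map, "5.39", lys_amine_atoms(), fr)
    e297 <- t(vapply(glu_carboxylate_atoms(),
                     function(a) resolve_atom(map, "6.58", a, fr), numeric(3)))
    q115 <- lapply(c("C", "CA", "CG", "CD"),
                   function(a) resolve_atom(map, "2.60", a, fr))
    out$t94_d334_distance[i] <- min_pair_distance(t94, d334)
    out$tm7_rotation[i] <- xy_rotation_angle(fr, ref, map,
                                             sign = config$tm7_sign)
    out$q115_dihedral[i] <- dihedral_angle(q115[[1]], q115[[2]],
                                           q115[[3]], q115[[4]])
    out$k227_e297_distance[i] <- min_pair_distance(k227, e297)
    out$w287_z_displacement[i] <- z_displacement(fr, ref, map, w287_sel)
    out$alignment_rmsd[i] <- sup$rmsd
  }
  class(out) <- c("frame_metrics", class(out))
  out
}

#' Classify frames into intracellular conformational states
#'
#' Precedence is fixed: occluded if `t94_d334_distance <
#' occluded_distance_cutoff` (strict), otherwise alternative if
#' `tm7_rotation < tm7_rotation_cutoff` (strict), otherwise canonical.
#'
#' @param metrics a `frame_metrics` data.frame (or any data.frame with
#'   `t94_d334_distance` and `tm7_rotation` columns).
#' @param config a [metric_config()].
#' @return factor of labels with levels [state_levels()].
#' @export
classify_frames <- function(metrics, config = metric_config()) {
  d <- metrics$t94_d334_distance
  r <- metrics$tm7_rotation
  stopifnot(all(is.finite(d)), all(is.finite(r)))
  lab <- ifelse(d < config$occluded_distance_cutoff, "occluded",
         ifelse(r < config$tm7_rotation_cutoff, "alternative", "canonical"))
  factor(lab, levels = state_levels())
}

#' Per-replicate and pooled state occupancy
#'
#' @param labels named list: one factor/character vector of state labels
#'   per replicate, or a data.frame with columns `replicate` and `state`.
#' @return A `state_occupancy` list with `per_replicate` (one fraction
#'   row per replicate), `pooled` (frame-weighted over all frames),
#'   `replicate_mean` (unweighted mean of replicate fractions) and
#'   `n_frames`.
#' @export
occupancy <- function(labels) {
  if (is.data.frame(labels))
    labels <- split(as.character(labels$state), labels$replicate)
  if (!length(labels)) stop("at least one replicate required")
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    names(labels) <- paste0("rep", seq_along(labels))
  lv <- state_levels()
  per <- t(vapply(labels, function(x) {
    if (!length(x)) stop("empty replicate in occupancy()")
    x <- factor(as.character(x), levels = lv)
    if (anyNA(x)) stop("unknown state label in occupancy()")
    as.numeric(table(x)) / length(x)
  }, numeric(3)))
  colnames(per) <- lv
  nfr <- vapply(labels, length, 1L)
  pooled <- colSums(per * nfr) / sum(nfr)
  structure(list(per_replicate = per, pooled = pooled,
                 replicate_mean = colMeans(per), n_frames = nfr),
            class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat("<state_occupancy>", length(x$n_frames), "replicate(s),",
      sum(x$n_frames), "frames\n")
  cat("pooled: ", paste(sprintf("%s %.1f%%", names(x$pooled),
                                100 * x$pooled), collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of frames satisfying a threshold predicate
#'
#' Used for readouts reported as "% of simulation time", e.g. the
#' fraction of frames with the W287 ring displaced downward, or with the
#' Q115 dihedral rotated away from its reference orientation.
#'
#' @param series named list of numeric vectors, one per replicate.
#' @param predicate a function of a numeric vector returning logicals,
#'   or a string like "< 2.5" / ">= -0.5" applied to the values.
#' @return named numeric vector of per-replicate fractions.
#' @export
fraction_satisfying <- function(series, predicate) {
  if (is.numeric(series)) series <- list(rep1 = series)
  if (!length(series)) stop("empty series")
  if (is.character(predicate)) {
    pr <- predicate
    predicate <- function(x) eval(parse(text = paste("x", pr)))
  }
  vapply(series, function(x) {
    if (!length(x)) stop("empty replicate series")
    mean(predicate(x))
  }, numeric(1))
}

#' Circular distance helper for rotamer windows
#'
#' Absolute angular separation of two angles on the circle, in
#' degrees in [0, 180].
#' @param a,b angles in degrees.
#' @return absolute circular difference.
#' @export
circular_difference <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# ---- cross-condition statistics -------------------------------------------

#' Compare per-replicate fractions between two conditions
#'
#' Nonparametric two-sided comparison of replicate-level summaries
#' (e.g. state occupancies) between two ligand conditions.
#' `method = "exact-rank"` enumerates all assignments of the pooled
#' values to the two groups and computes the exact two-sided rank-sum
#' (Mann-Whitney) p-value, with midranks for ties; feasible for group
#' sizes up to about 12. `method = "permutation"` is a seeded
#' Monte-Carlo permutation test on the difference of means.
#'
#' @param frac_a,frac_b numeric vectors of per-replicate fractions.
#' @param method "exact-rank" or "permutation".
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed optional integer seed for the permutation method.
#' @return list with `p_value`, `method`, `statistic` and (possibly) a
#'   `warning` field; groups with fewer than 2 values per side return
#'   p = 1 with a warning flag rather than failing mid-pipeline.
#' @export
compare_conditions <- function(frac_a, frac_b,
                               method = c("exact-rank", "permutation"),
                               n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  frac_a <- as.numeric(frac_a); frac_b <- as.numeric(frac_b)
  if (length(frac_a) < 2L || length(frac_b) < 2L)
    return(list(p_value = 1, method = method, statistic = NA_real_,
                warning = "fewer than 2 values per group; p set to 1"))
  if (method == "exact-rank") {
    exact_rank_test(frac_a, frac_b)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    obs <- mean(frac_a) - mean(frac_b)
    pool <- c(frac_a, frac_b)
    n1 <- length(frac_a); n <- length(pool)
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n1)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs) - 1e-12)
        cnt <- cnt + 1L
    }
    # add-one correction keeps the Monte-Carlo p strictly positive
    list(p_value = (cnt + 1) / (n_perm + 1), method = method,
         statistic = obs, n_perm = n_perm)
  }
}

exact_rank_test <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  rk <- rank(pool)                      # midranks under ties
  w_obs <- sum(rk[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- colSums(matrix(rk[combs], nrow = n1))
  p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
  list(p_value = p, method = "exact-rank", statistic = w_obs,
       n_assignments = ncol(combs))
}

#' Normalized 2-D histogram of two metric series
#'
#' Density table behind the distance-vs-rotation state maps: bin masses
#' sum to 1; bin edges are returned alongside.
#'
#' @param x,y equal-length numeric vectors.
#' @param nbins integer vector of length 2 (bins in x and y), or a list
#'   with explicit `x`/`y` break vectors.
#' @return list with `density` (matrix, rows = x bins), `x_breaks`,
#'   `y_breaks`.
#' @export
density_2d <- function(x, y, nbins = c(50L, 50L)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("empty input")
  if (is.list(nbins)) {
    bx <- nbins$x; by <- nbins$y
  } else {
    pad <- function(v) if (diff(range(v)) == 0) range(v) + c(-0.5, 0.5) else range(v)
    rx <- pad(x); ry <- pad(y)
    bx <- seq(rx[1], rx[2], length.out = nbins[1] + 1L)
    by <- seq(ry[1], ry[2], length.out = nbins[2] + 1L)
  }
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- matrix(0, nrow = length(bx) - 1L, ncol = length(by) - 1L)
  for (k in seq_along(ix))
    dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + 1
  list(density = dens / length(x), x_breaks = bx, y_breaks = by)
}
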