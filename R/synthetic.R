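# Seeded generators with known ground truth. Frames are not simulated
# physically: atoms are placed analytically so that each geometric metric
# equals its per-state target plus Gaussian noise. Downstream code consumes
# the metrics, not the physics, so this keeps tests exact and fast.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' State prescription for the trajectory generator
#'
#' Defines, per conformational state, the target values of the
#' classifier metrics, the per-metric Gaussian noise, and the label
#' process (a fixed label sequence or a first-order Markov chain).
#' Default targets place each state comfortably on its side of the
#' classification thresholds: occluded at 2.8 Angstrom / -30 degrees,
#' alternative at 6.0 / -40, canonical at 6.0 / 0; default noise is
#' 0.3 Angstrom on distances and 5 degrees on angles.
#'
#' @param targets data.frame with one row per state (rownames from
#'   [state_levels()]) and columns `t94_d334`, `tm7_rotation`,
#'   `q115_dihedral`, `k227_e297`, `w287_z`.
#' @param noise_sd named list/vector: `distance`, `rotation`,
#'   `dihedral`, `salt_bridge`, `z_disp`.
#' @param labels character vector of state labels (fixed sequence), or
#'   `NULL` to use `transition` + `n_frames`.
#' @param transition 3x3 row-stochastic matrix over
#'   occluded/alternative/canonical (used when `labels` is `NULL`).
#' @param n_frames number of frames when simulating from `transition`.
#' @param config [metric_config()] used to validate that targets sit on
#'   the correct side of the thresholds.
#' @return A `state_prescription` list.
#' @export
state_prescription <- function(targets = NULL,
                               noise_sd = c(distance = 0.3, rotation = 5,
                                            dihedral = 5, salt_bridge = 0.3,
                                            z_disp = 0.2),
                               labels = NULL, transition = NULL,
                               n_frames = 1000L,
                               config = metric_config()) {
  if (is.null(targets)) {
    targets <- data.frame(
      t94_d334 = c(2.8, 6.0, 6.0),
      tm7_rotation = c(-30, -40, 0),
      q115_dihedral = c(-60, 120, -60),
      k227_e297 = c(6.0, 3.0, 3.0),
      w287_z = c(-1.0, -1.0, 0),
      row.names = state_levels())
  }
  stopifnot(all(state_levels() %in% rownames(targets)))
  targets <- targets[state_levels(), , drop = FALSE]
  noise_sd <- as.list(noise_sd)
  if (any(unlist(noise_sd) < 0)) stop("noise SDs must be >= 0")
  # targets must realize the states they claim under the classifier
  dcut <- config$occluded_distance_cutoff
  rcut <- config$tm7_rotation_cutoff
  if (!(targets["occluded", "t94_d334"] < dcut))
    stop("occluded target distance must lie below the occluded cutoff")
  if (!(targets["alternative", "t94_d334"] >= dcut &&
        targets["alternative", "tm7_rotation"] < rcut))
    stop("alternative targets inconsistent with the classification rule")
  if (!(targets["canonical", "t94_d334"] >= dcut &&
        targets["canonical", "tm7_rotation"] >= rcut))
    stop("canonical targets inconsistent with the classification rule")
  if (is.null(labels)) {
    if (is.null(transition))
      transition <- matrix(1 / 3, 3, 3,
                           dimnames = list(state_levels(), state_levels()))
    transition <- as.matrix(transition)
    if (any(abs(rowSums(transition) - 1) > 1e-8))
      stop("transition matrix rows must sum to 1")
    stopifnot(n_frames >= 1L)
  } else {
    labels <- as.character(labels)
    if (!all(labels %in% state_levels()))
      stop("unknown labels in fixed label sequence")
  }
  structure(list(targets = targets, noise_sd = noise_sd, labels = labels,
                 transition = transition, n_frames = as.integer(n_frames),
                 config = config),
            class = "state_prescription")
}

# Fixed scaffold geometry shared by reference and frames. The anchor Calpha
# atoms (stand-ins for the TM2/TM3/TM5 alignment selection) are identical in
# every frame, so analysis-time superposition exactly removes any rigid
# motion applied to a frame.
synthetic_scaffold <- function() {
  tm_res <- list(tm2 = 85:91, tm3 = 140:146, tm5 = 230:236)
  anchors <- do.call(rbind, lapply(seq_along(tm_res), function(k) {
    res <- tm_res[[k]]
    ctr <- c(15 * cos(2 * pi * k / 3), 15 * sin(2 * pi * k / 3), 0)
    i <- seq_along(res)
    data.frame(atom_name = "CA", residue_name = "ALA", chain_id = "A",
               residue_number = res,
               x = ctr[1] + 2.3 * cos(1.75 * i),
               y = ctr[2] + 2.3 * sin(1.75 * i),
               z = ctr[3] + 1.5 * (i - mean(i)))
  }))
  list(anchors = anchors,
       t94_og1 = c(-4, 6, -13),
       d334_dir = c(1, 0, 0),           # OD1 along +x from the hydroxyl
       s324_ca = c(10, 0, -14),
       tangent_len = 1.5,               # XY length of the S324->L325 vector
       q115_origin = c(-8, -8, 5),
       k227_nz = c(6, 10, 8),
       e297_dir = c(0, 1, 0),
       w287_center = c(2, -3, -2),
       ref_q115 = -60,                  # crystallographic rotamer reference
       ref_salt = 3.0,
       ref_dist = 6.0)                  # canonical-like reference distance
}

metric_atom_rows <- function() {
  sc <- synthetic_scaffold()
  rbind(
    data.frame(atom_name = "OG1", residue_name = "THR", chain_id = "A",
               residue_number = 94L),
    data.frame(atom_name = c("C", "CA", "CG", "CD"), residue_name = "GLN",
               chain_id = "A", residue_number = 115L),
    data.frame(atom_name = "NZ", residue_name = "LYS", chain_id = "A",
               residue_number = 227L),
    data.frame(atom_name = trp_ring_atoms(), residue_name = "TRP",
               chain_id = "A", residue_number = 287L),
    data.frame(atom_name = c("OE1", "OE2"), residue_name = "GLU",
               chain_id = "A", residue_number = 297L),
    data.frame(atom_name = "CA", residue_name = "SER", chain_id = "A",
               residue_number = 324L),
    data.frame(atom_name = "CA", residue_name = "LEU", chain_id = "A",
               residue_number = 325L),
    data.frame(atom_name = c("OD1", "OD2"), residue_name = "ASP",
               chain_id = "A", residue_number = 334L))
}

# Coordinates of the metric atoms realizing given metric values.
place_metric_atoms <- function(dist_t94, rot_tm7, dih_q115, dist_salt, z_w287) {
  sc <- synthetic_scaffold()
  deg <- pi / 180
  # T94 hydroxyl fixed; D334 OD1 at the target distance, OD2 farther
  od1 <- sc$t94_og1 + dist_t94 * sc$d334_dir
  od2 <- od1 + c(0.8, 1.2, 0)
  # Q115 pseudo-dihedral construction (C, CA, CG, CD)
  o <- sc$q115_origin
  q_c <- o + c(0, 1, 0); q_ca <- o; q_cg <- o + c(1.5, 0, 0)
  q_cd <- q_cg + c(0, cos(dih_q115 * deg), sin(dih_q115 * deg))
  # K227 amine fixed; E297 OE1 at the salt-bridge distance, OE2 farther
  oe1 <- sc$k227_nz + dist_salt * sc$e297_dir
  oe2 <- oe1 + c(0.5, 1.0, 0)
  # S324/L325 tangent pair rotated by the target angle in XY
  a <- rot_tm7 * deg
  l325 <- sc$s324_ca + c(sc$tangent_len * cos(a), sc$tangent_len * sin(a), -1.5)
  # W287 ring (planar-ish hexagon + bridge atoms) shifted vertically
  ring_a <- seq(0, 2 * pi, length.out = 10)[1:9]
  ring <- cbind(sc$w287_center[1] + 1.7 * cos(ring_a),
                sc$w287_center[2] + 1.7 * sin(ring_a),
                sc$w287_center[3] + z_w287)
  rbind(sc$t94_og1,
        q_c, q_ca, q_cg, q_cd,
        sc$k227_nz,
        ring,
        oe1, oe2,
        sc$s324_ca, l325,
        od1, od2)
}

simulate_labels <- function(pres) {
  if (!is.null(pres$labels)) return(pres$labels)
  p <- pres$transition
  lv <- state_levels()
  # start from the stationary distribution of the chain
  ev <- eigen(t(p))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- pmax(stat / sum(stat), 0); stat <- stat / sum(stat)
  out <- character(pres$n_frames)
  out[1] <- sample(lv, 1, prob = stat)
  for (i in seq_len(pres$n_frames - 1L))
    out[i + 1L] <- sample(lv, 1, prob = p[out[i], ])
  out
}

#' Simulate a trajectory with planted conformational states
#'
#' Emits a reduced-topology multi-frame structure containing exactly the
#' atoms the classifier metrics need, plus a fixed set of anchor CA
#' atoms for superposition. Each frame's metrics equal the prescribed
#' per-state targets plus Gaussian noise; truth labels and truth metrics
#' are returned alongside. Optionally each frame is given a random rigid
#' motion (rotation + translation), which analysis-time superposition
#' removes exactly since the anchors carry no noise.
#'
#' @param pres a [state_prescription()].
#' @param seed integer seed; the generator is a pure function of
#'   (prescription, seed).
#' @param replicate_id,condition metadata for the trajectory.
#' @param rigid_jitter apply a random rigid motion per frame (default
#'   `TRUE`).
#' @return list with `trajectory` ([kor_trajectory()]), `reference`
#'   (`kor_frame`, the canonical-like alignment reference),
#'   `alignment_residues` (anchor residue numbers), `labels` (factor),
#'   `metrics` (truth metric table), `prescription`.
#' @export
simulate_trajectory <- function(pres, seed = 1L, replicate_id = "rep1",
                                condition = "synthetic",
                                rigid_jitter = TRUE) {
  stopifnot(inherits(pres, "state_prescription"))
  sc <- synthetic_scaffold()
  atoms <- rbind(sc$anchors[, c("atom_name", "residue_name", "chain_id",
                                "residue_number")],
                 metric_atom_rows())
  anchor_xyz <- as.matrix(sc$anchors[, c("x", "y", "z")])
  ref_xyz <- rbind(anchor_xyz,
                   place_metric_atoms(sc$ref_dist, 0, sc$ref_q115,
                                      sc$ref_salt, 0))
  reference <- structure(list(atoms = atoms, xyz = unname(ref_xyz)),
                         class = "kor_frame")
  with_seed(seed, {
    labels <- simulate_labels(pres)
    nfr <- length(labels)
    tg <- pres$targets[labels, , drop = FALSE]
    ns <- pres$noise_sd
    truth <- data.frame(
      frame_index = seq_len(nfr), state = labels,
      t94_d334_distance = tg$t94_d334 + stats::rnorm(nfr, 0, ns$distance),
      tm7_rotation = tg$tm7_rotation + stats::rnorm(nfr, 0, ns$rotation),
      q115_dihedral = tg$q115_dihedral + stats::rnorm(nfr, 0, ns$dihedral),
      k227_e297_distance = tg$k227_e297 + stats::rnorm(nfr, 0, ns$salt_bridge),
      w287_z_displacement = tg$w287_z + stats::rnorm(nfr, 0, ns$z_disp))
    truth$t94_d334_distance <- pmax(truth$t94_d334_distance, 0.1)
    truth$k227_e297_distance <- pmax(truth$k227_e297_distance, 0.1)
    xyz <- array(NA_real_, dim = c(nrow(atoms), 3L, nfr))
    for (i in seq_len(nfr)) {
      fr <- rbind(anchor_xyz,
                  place_metric_atoms(truth$t94_d334_distance[i],
                                     truth$tm7_rotation[i],
                                     truth$q115_dihedral[i],
                                     truth$k227_e297_distance[i],
                                     truth$w287_z_displacement[i]))
      if (rigid_jitter) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        th <- stats::runif(1, -pi, pi)
        k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        rot <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
        fr <- fr %*% t(rot)
        fr <- sweep(fr, 2, stats::rnorm(3, 0, 5), `+`)
      }
      xyz[, , i] <- fr
    }
    traj <- kor_trajectory(atoms, xyz, replicate_id, condition)
    list(trajectory = traj, reference = reference,
         alignment_residues = sc$anchors$residue_number,
         labels = factor(labels, levels = state_levels()),
         metrics = truth, prescription = pres)
  })
}

#' Assay prescription for the dose-response generator
#'
#' @param truth data.frame with columns `ligand`, `pathway`, `logtau`,
#'   `logKA` (one row per ligand/pathway).
#' @param n shared transducer slope.
#' @param emax system maximum (100).
#' @param log_conc numeric grid of log10 molar concentrations (>= 4
#'   values).
#' @param replicates number of independent experiments.
#' @param noise_sd Gaussian response noise, in % of Emax.
#' @return An `assay_prescription` list.
#' @export
assay_prescription <- function(truth, n = 1, emax = 100,
                               log_conc = seq(-11, -4, by = 1),
                               replicates = 3L, noise_sd = 2) {
  stopifnot(is.data.frame(truth),
            all(c("ligand", "pathway", "logtau", "logKA") %in% names(truth)))
  if (length(log_conc) < 4L) stop("need at least 4 concentrations")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(n > 0, replicates >= 1L)
  structure(list(truth = truth, n = n, emax = emax,
                 log_conc = sort(log_conc),
                 replicates = as.integer(replicates), noise_sd = noise_sd),
            class = "assay_prescription")
}

#' Simulate dose-response data from the operational model
#'
#' @param pres an [assay_prescription()].
#' @param seed integer seed.
#' @return list with `data` (data.frame `ligand`, `pathway`,
#'   `replicate`, `log_conc_M`, `response`) and `truth` (the
#'   prescription's parameter table, with the implied `log_tau_KA`).
#' @export
simulate_dose_response <- function(pres, seed = 1L) {
  stopifnot(inherits(pres, "assay_prescription"))
  with_seed(seed, {
    rows <- list()
    for (j in seq_len(nrow(pres$truth))) {
      tr <- pres$truth[j, ]
      mu <- operational_response(pres$log_conc, tr$logtau, tr$logKA,
                                 n = pres$n, emax = pres$emax)
      for (r in seq_len(pres$replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ligand = tr$ligand, pathway = tr$pathway, replicate = r,
          log_conc_M = pres$log_conc,
          response = mu + stats::rnorm(length(mu), 0, pres$noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    truth <- pres$truth
    truth$log_tau_KA <- truth$logtau - truth$logKA
    list(data = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate competition-binding data
#'
#' Generates a one-site competition curve whose IC50 follows from the
#' planted Ki by the inverse Cheng-Prusoff relation,
#' `IC50 = Ki * (1 + L/Kd)`.
#'
#' @param logKi log10 molar planted inhibition constant.
#' @param radioligand_conc,kd molar radioligand concentration and Kd.
#' @param top,bottom curve plateaus (CPM).
#' @param log_conc grid of cold-ligand log10 molar concentrations.
#' @param replicates number of replicates.
#' @param noise_sd Gaussian CPM noise.
#' @param seed integer seed.
#' @return list with `data` (`log_conc_M`, `cpm`, `replicate`) and
#'   `truth` (logKi, logIC50, top, bottom).
#' @export
simulate_competition <- function(logKi, radioligand_conc, kd,
                                 top = 2000, bottom = 200,
                                 log_conc = seq(-12, -5, by = 0.5),
                                 replicates = 2L, noise_sd = 0,
                                 seed = 1L) {
  log_ic50 <- logKi + log10(1 + radioligand_conc / kd)
  with_seed(seed, {
    mu <- bottom + (top - bottom) / (1 + 10^((log_conc - log_ic50)))
    rows <- lapply(seq_len(replicates), function(r)
      data.frame(log_conc_M = log_conc,
                 cpm = mu + stats::rnorm(length(mu), 0, noise_sd),
                 replicate = r))
    list(data = do.call(rbind, rows),
         truth = list(logKi = logKi, logIC50 = log_ic50,
                      top = top, bottom = bottom))
  })
}

#' Simulate dissociation time-course data
#'
#' One-phase exponential decay from planted `Y0`, `NS` and `koff`.
#'
#' @param koff dissociation rate, min^-1.
#' @param Y0 signal at t = 0 (CPM).
#' @param NS nonspecific plateau (CPM).
#' @param times minutes (default 2 min to 2 h).
#' @param replicates number of replicates.
#' @param noise_sd Gaussian CPM noise.
#' @param seed integer seed.
#' @return list with `data` (`time_min`, `cpm`, `replicate`) and
#'   `truth` (koff, t_half, Y0, NS).
#' @export
simulate_dissociation <- function(koff, Y0 = 3000, NS = 300,
                                  times = c(2, 5, 10, 20, 30, 45, 60, 90, 120),
                                  replicates = 2L, noise_sd = 0, seed = 1L) {
  stopifnot(koff > 0, all(times >= 0))
  with_seed(seed, {
    mu <- (Y0 - NS) * exp(-koff * times) + NS
    rows <- lapply(seq_len(replicates), function(r)
      data.frame(time_min = times,
                 cpm = mu + stats::rnorm(length(mu), 0, noise_sd),
                 replicate = r))
    list(data = do.call(rbind, rows),
         truth = list(koff = koff, t_half = log(2) / koff, Y0 = Y0, NS = NS))
  })
}
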