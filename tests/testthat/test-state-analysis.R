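test_that("classification follows the occluded > alternative > canonical precedence", {
  cfg <- metric_config()
  m <- data.frame(t94_d334_distance = c(3.0, 4.0, 4.0, 3.5, 3.49999),
                  tm7_rotation = c(-45, -45, 0, -45, 10))
  expect_equal(as.character(classify_frames(m, cfg)),
               c("occluded",     # distance rule dominates rotation
                 "alternative",
                 "canonical",
                 "alternative",  # boundary: strict < at 3.5
                 "occluded"))
  # strict < on the rotation boundary too
  m2 <- data.frame(t94_d334_distance = 5, tm7_rotation = c(-20, -20.0001))
  expect_equal(as.character(classify_frames(m2, cfg)),
               c("canonical", "alternative"))
})

test_that("occluded label wins for any sub-cutoff distance on random metric grids", {
  cfg <- metric_config()
  set.seed(14)
  m <- data.frame(t94_d334_distance = runif(500, 0.5, 8),
                  tm7_rotation = runif(500, -180, 180))
  lab <- classify_frames(m, cfg)
  sub <- m$t94_d334_distance < cfg$occluded_distance_cutoff
  expect_true(all(lab[sub] == "occluded"))
  expect_true(!any(lab[!sub] == "occluded"))
  # permuting frames permutes labels identically
  perm <- sample(nrow(m))
  expect_identical(classify_frames(m[perm, ], cfg), lab[perm])
})

test_that("occupancy computes per-replicate and frame-weighted pooled fractions", {
  occ <- occupancy(list(r1 = c("occluded", "occluded", "alternative",
                               "canonical")))
  expect_equal(unname(occ$per_replicate[1, ]), c(0.5, 0.25, 0.25))
  occ2 <- occupancy(list(a = "occluded", b = "canonical"))
  expect_equal(unname(occ2$pooled), c(0.5, 0, 0.5))
  # frame-weighted pooling: 3 frames vs 1 frame
  occ3 <- occupancy(list(a = rep("occluded", 3), b = "canonical"))
  expect_equal(unname(occ3$pooled), c(0.75, 0, 0.25))
  expect_equal(unname(occ3$replicate_mean), c(0.5, 0, 0.5))
  # fractions always sum to one
  expect_equal(unname(rowSums(occ3$per_replicate)), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(occ3$pooled), 1, tolerance = 1e-12)
  expect_error(occupancy(list()), "at least one")
  expect_error(occupancy(list(a = character(0))), "empty")
})

test_that("fraction_satisfying counts threshold exceedances per replicate", {
  expect_equal(unname(fraction_satisfying(c(1, 2, 3, 4), "< 2.5")), 0.5)
  expect_equal(unname(fraction_satisfying(c(1, 2), "< 10")), 1)
  set.seed(3)
  x <- rnorm(200)
  expect_equal(unname(fraction_satisfying(x, "< 0.3")),
               sum(x < 0.3) / 200)
  f <- fraction_satisfying(list(a = c(-1, -1, 0.2), b = c(0, -2)),
                           function(v) v <= -0.5)
  expect_equal(unname(f), c(2 / 3, 1 / 2))
  expect_error(fraction_satisfying(list(), "< 1"), "empty")
})

test_that("circular rotamer windows measure separation on the circle", {
  expect_equal(circular_difference(170, -170), 20)
  expect_equal(circular_difference(-60, -60), 0)
  expect_equal(circular_difference(0, 180), 180)
})

test_that("exact rank test reproduces enumerated p-values and handles ties", {
  res <- compare_conditions(c(1, 2, 3), c(4, 5, 6), method = "exact-rank")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$n_assignments, choose(6, 3))
  res_tie <- compare_conditions(c(1, 1), c(1, 1), method = "exact-rank")
  expect_equal(res_tie$p_value, 1)
  # oracle: exact Mann-Whitney from stats:: on tie-free data
  set.seed(19)
  for (k in 1:12) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    mine <- compare_conditions(x, y, method = "exact-rank")$p_value
    oracle <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo permutation test agrees with the exact result and is seeded", {
  r1 <- compare_conditions(c(1, 2, 3), c(4, 5, 6), method = "permutation",
                           n_perm = 20000, seed = 77)
  expect_lt(abs(r1$p_value - 0.1), 0.02)
  r2 <- compare_conditions(c(1, 2, 3), c(4, 5, 6), method = "permutation",
                           n_perm = 20000, seed = 77)
  expect_identical(r1$p_value, r2$p_value)
  # undersized groups return p = 1 with a warning flag, not an error
  small <- compare_conditions(1, c(2, 3), method = "exact-rank")
  expect_equal(small$p_value, 1)
  expect_match(small$warning, "fewer than 2")
})

test_that("density_2d is a normalized histogram matching a counting oracle", {
  one <- density_2d(0.3, -2, nbins = c(4, 4))
  expect_equal(sum(one$density), 1)
  expect_equal(max(one$density), 1)
  set.seed(4)
  x <- runif(300); y <- rnorm(300)
  d <- density_2d(x, y, nbins = c(6, 5))
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  # counting oracle on one interior cell
  cx <- c(d$x_breaks[3], d$x_breaks[4]); cy <- c(d$y_breaks[2], d$y_breaks[3])
  expected <- sum(x >= cx[1] & x < cx[2] & y >= cy[1] & y < cy[2]) / 300
  expect_equal(d$density[3, 2], expected, tolerance = 1e-12)
  expect_error(density_2d(1:3, 1:4), "equal length")
})

test_that("zero-noise planted trajectories are classified perfectly", {
  labels <- rep(c("occluded", "alternative", "canonical"), times = c(10, 10, 10))
  pres <- state_prescription(labels = labels,
                             noise_sd = c(distance = 0, rotation = 0,
                                          dihedral = 0, salt_bridge = 0,
                                          z_disp = 0))
  sim <- simulate_trajectory(pres, seed = 23)
  spec <- alignment_spec(sim$reference, sim$alignment_residues)
  m <- compute_frame_metrics(sim$trajectory, spec = spec)
  expect_identical(as.character(classify_frames(m)), labels)
  occ <- occupancy(list(r1 = classify_frames(m)))
  expect_equal(unname(occ$pooled), rep(1 / 3, 3), tolerance = 1e-12)
  # recovered metrics equal the generator's truth
  expect_lt(max(abs(m$t94_d334_distance - sim$metrics$t94_d334_distance)), 1e-3)
  expect_lt(max(abs(m$tm7_rotation - sim$metrics$tm7_rotation)), 0.1)
  expect_lt(max(abs(m$q115_dihedral - sim$metrics$q115_dihedral)), 0.1)
})

test_that("Markov-planted occupancy is recovered within binomial error under noise", {
  p <- matrix(c(0.80, 0.15, 0.05,
                0.10, 0.80, 0.10,
                0.05, 0.20, 0.75), 3, 3, byrow = TRUE,
              dimnames = list(state_levels(), state_levels()))
  pres <- state_prescription(transition = p, n_frames = 1200)
  sim <- simulate_trajectory(pres, seed = 31)
  spec <- alignment_spec(sim$reference, sim$alignment_residues)
  m <- compute_frame_metrics(sim$trajectory, spec = spec)
  occ <- occupancy(list(r1 = classify_frames(m)))
  planted <- table(factor(sim$labels, levels = state_levels())) / 1200
  for (s in state_levels()) {
    tol <- 3 * sqrt(planted[[s]] * (1 - planted[[s]]) / 1200) + 1e-9
    expect_lt(abs(occ$pooled[[s]] - planted[[s]]), max(tol, 0.01))
  }
})
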