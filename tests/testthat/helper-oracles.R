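# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force minimum cross-pair distance
oracle_min_dist <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  best <- Inf
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# 2-D signed rotation angle oracle via individual atan2 angles
oracle_xy_angle <- function(v_ref, v_mob) {
  a <- atan2(v_mob[2], v_mob[1]) - atan2(v_ref[2], v_ref[1])
  a <- a * 180 / pi
  ((a + 180) %% 360) - 180
}

# random rigid transform applied to an n x 3 matrix (rows = points)
random_rigid <- function(pts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -pi, pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  rot <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  sweep(pts %*% t(rot), 2, rnorm(3, 0, 10), `+`)
}

# tiny multi-model PDB fixture written in code (2 models x 5 atoms)
write_fixture_pdb <- function(path) {
  lines <- c(
    "REMARK synthetic two-model fixture",
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CB  ALA A   1       2.500  -1.250   0.125  1.00  0.00",
    "ATOM      3  CA  GLY A   2      -4.250   5.000   6.750  1.00  0.00",
    "ATOM      4  OG1 THR A   3       0.001   0.002   0.003  1.00  0.00",
    "HETATM    5  ZN  ZN  A   9       9.999  -9.999   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       1.100   2.100   3.100  1.00  0.00",
    "ATOM      2  CB  ALA A   1       2.600  -1.150   0.225  1.00  0.00",
    "ATOM      3  CA  GLY A   2      -4.150   5.100   6.850  1.00  0.00",
    "ATOM      4  OG1 THR A   3       0.101   0.102   0.103  1.00  0.00",
    "HETATM    5  ZN  ZN  A   9      10.099  -9.899   0.100  1.00  0.00",
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

# noise-free dose-response records from explicit logistic parameters
make_logistic_data <- function(bottom, top, logEC50, hill = 1,
                               x = seq(-11, -5, by = 0.75),
                               ligand = "L", pathway = "P") {
  data.frame(ligand = ligand, pathway = pathway, log_conc_M = x,
             response = bottom + (top - bottom) /
               (1 + 10^((logEC50 - x) * hill)),
             stringsAsFactors = FALSE)
}
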