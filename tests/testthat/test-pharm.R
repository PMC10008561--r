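test_that("operational_response implements the Black-Leff form and its limits", {
  # X -> +Inf plateau is Emax*tau^n/(tau^n+1); tau = 1, n = 1 -> 50
  expect_equal(operational_response(5, logtau = 0, logKA = -8), 50,
               tolerance = 1e-6)
  # X -> -Inf gives 0
  expect_equal(operational_response(-40, logtau = 0.7, logKA = -8), 0,
               tolerance = 1e-10)
  # half-maximal response at 10^X = KA/(tau+1) for n = 1
  logtau <- 0.5; logKA <- -7.5
  tau <- 10^logtau
  x50 <- log10(10^logKA / (tau + 1))
  ymax <- 100 * tau / (tau + 1)
  expect_equal(operational_response(x50, logtau, logKA), ymax / 2,
               tolerance = 1e-9)
  expect_error(operational_response(-8, 0, -8, n = -1))
})

test_that("logistic fits recover noise-free parameters and flag degeneracies", {
  d <- make_logistic_data(bottom = 0, top = 100, logEC50 = -8)
  fit <- fit_logistic(d, hill_fixed = 1)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$logEC50, -8, tolerance = 1e-6)
  # variable slope recovers a non-unit hill
  d2 <- make_logistic_data(bottom = 5, top = 95, logEC50 = -7.2, hill = 1.6)
  fit2 <- fit_logistic(d2)
  expect_equal(fit2$hill, 1.6, tolerance = 1e-4)
  # flat data flagged, not an error
  flat <- data.frame(ligand = "L", pathway = "P",
                     log_conc_M = seq(-10, -5), response = 42)
  expect_equal(fit_logistic(flat)$flag, "degenerate")
  # EC50 ratio of two curves generated 1 log unit apart
  da <- make_logistic_data(0, 100, -8, ligand = "A")
  db <- make_logistic_data(0, 100, -7, ligand = "B")
  fits <- fit_logistic(rbind(da, db), hill_fixed = 1)
  ratio <- 10^(fits$logEC50[fits$ligand == "B"] -
                 fits$logEC50[fits$ligand == "A"])
  expect_equal(ratio, 10, tolerance = 1e-6)
})

test_that("normalization rescales to the reference plateau and is idempotent", {
  ref <- make_logistic_data(bottom = 500, top = 2000, logEC50 = -8,
                            ligand = "ref")
  test <- make_logistic_data(bottom = 500, top = 1250, logEC50 = -7,
                             ligand = "test")
  test$response[1] <- 1250    # one explicit mid-scale raw point
  raw <- rbind(ref, test)
  norm <- normalize_to_reference(raw, "ref")
  # a raw count of 1250 against plateau 2000 / baseline 500 maps to 50%
  expect_equal(norm$response[norm$ligand == "test"][1], 50, tolerance = 1e-6)
  # reference fitted plateau maps to 100, fitted baseline to 0
  ref_refit <- fit_logistic(norm[norm$ligand == "ref", ])
  expect_equal(ref_refit$top, 100, tolerance = 1e-6)
  expect_equal(ref_refit$bottom, 0, tolerance = 1e-6)
  # an all-baseline ligand maps to 0 throughout
  flat <- data.frame(ligand = "dead", pathway = "P",
                     log_conc_M = seq(-11, -5, by = 0.75), response = 500)
  norm2 <- normalize_to_reference(rbind(ref, flat), "ref")
  expect_equal(norm2$response[norm2$ligand == "dead"],
               rep(0, 9), tolerance = 1e-6)
  # idempotence
  again <- normalize_to_reference(norm, "ref")
  expect_equal(again$response, norm$response, tolerance = 1e-6)
  expect_error(normalize_to_reference(ref, "absent"), "absent")
})

test_that("operational fits recover planted parameters on noise-free data", {
  truth <- data.frame(ligand = c("ref", "test"), pathway = "G",
                      logtau = c(0.5, -0.3), logKA = c(-8, -7))
  ds <- simulate_dose_response(
    assay_prescription(truth, noise_sd = 0,
                       log_conc = seq(-11, -4, by = 0.5)), seed = 1)
  fit <- fit_operational(ds$data)
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_equal(co$logtau[co$ligand == "ref"], 0.5, tolerance = 1e-3)
  expect_equal(co$logKA[co$ligand == "ref"], -8, tolerance = 1e-3)
  expect_equal(co$logtau[co$ligand == "test"], -0.3, tolerance = 1e-3)
  expect_equal(co$logKA[co$ligand == "test"], -7, tolerance = 1e-3)
  expect_equal(fit$n, 1, tolerance = 1e-4)
  # fitted EC50 equals the analytic KA/(tau+1) relation for n = 1
  for (lg in c("ref", "test")) {
    lt <- co$logtau[co$ligand == lg]; lk <- co$logKA[co$ligand == lg]
    ec50_closed <- 10^lk / (10^lt + 1)
    ymax <- 100 * 10^lt / (10^lt + 1)
    f <- function(x) operational_response(x, lt, lk, n = fit$n) - ymax / 2
    ec50_curve <- 10^stats::uniroot(f, c(-14, -2), tol = 1e-12)$root
    expect_equal(ec50_curve / ec50_closed, 1, tolerance = 1e-6)
  }
})

test_that("repeated operational fits are deterministic", {
  truth <- data.frame(ligand = "ref", pathway = rep(c("G", "arr"), each = 1),
                      logtau = 1, logKA = -8)
  truth <- rbind(truth, truth); truth$pathway <- c("G", "G", "arr", "arr")
  truth$ligand <- c("ref", "other", "ref", "other")
  ds <- simulate_dose_response(assay_prescription(truth, noise_sd = 1),
                               seed = 12)
  f1 <- fit_operational(ds$data[ds$data$pathway == "G", ])
  f2 <- fit_operational(ds$data[ds$data$pathway == "G", ])
  expect_identical(transduction_coefficient(f1, "ref")$value,
                   transduction_coefficient(f2, "ref")$value)
})

test_that("transduction coefficient arithmetic and error propagation", {
  # value = logtau - logKA
  truth <- data.frame(ligand = c("a", "b"), pathway = "G",
                      logtau = c(0.5, 0), logKA = c(-8, -7))
  ds <- simulate_dose_response(assay_prescription(truth, noise_sd = 1),
                               seed = 42)
  fit <- fit_operational(ds$data)
  co <- fit$coefficients
  expect_equal(co$log_tau_KA, co$logtau - co$logKA, tolerance = 1e-12)
  # se of the difference comes from the joint covariance
  off <- 1L
  for (i in seq_len(nrow(co))) {
    it <- off + 2L * i - 1L; ik <- off + 2L * i
    v <- fit$vcov
    expect_equal(co$se_log_tau_KA[i],
                 sqrt(v[it, it] + v[ik, ik] - 2 * v[it, ik]),
                 tolerance = 1e-10)
  }
  tc <- transduction_coefficient(fit, "a")
  expect_equal(tc$value, co$log_tau_KA[co$ligand == "a"])
  expect_error(transduction_coefficient(fit, "zzz"), "not in fit")
})

test_that("delta and ddelta log follow the stated difference/propagation rules", {
  mk <- function(v, se, lig, pw)
    structure(list(value = v, se = se, ligand = lig, pathway = pw),
              class = "transduction_coefficient")
  d0 <- delta_log(mk(8.5, 0.1, "ref", "G"), mk(8.5, 0.1, "ref", "G"))
  expect_identical(d0$value, 0)   # reference vs itself: exactly zero
  expect_identical(d0$se, 0)
  d1 <- delta_log(mk(9.0, 0.1, "t", "G"), mk(8.5, 0.1, "ref", "G"))
  expect_equal(d1$value, 0.5)
  expect_equal(d1$se, sqrt(0.02))
  expect_error(delta_log(mk(9, 0.1, "t", "G"), mk(8.5, 0.1, "ref", "arr")),
               "same pathway")
  # spec'd error propagation for independent components
  expect_equal(sqrt(0.1^2 + 0.2^2), sqrt(0.05), tolerance = 1e-12)
  d2 <- delta_log(mk(8.222, 0.15, "t", "arr"), mk(8.5, 0.1, "ref", "arr"))
  dd <- ddelta_log(d1, d2)
  expect_equal(dd$value, 0.5 - (-0.278))
  expect_equal(dd$se, sqrt(d1$se^2 + d2$se^2))
  # swapping pathway order negates the value
  dd_swap <- ddelta_log(d2, d1)
  expect_equal(dd_swap$value, -dd$value)
  expect_error(ddelta_log(d1, delta_log(mk(8, 0.1, "other", "arr"),
                                        mk(8.5, 0.1, "ref", "arr"))),
               "same ligand")
})

test_that("bias factors exponentiate ddelta with symmetric-in-log t intervals", {
  bf0 <- bias_factor(list(value = 0, se = 0.1), df = 4)
  expect_equal(bf0$bias_factor, 1)
  expect_true(bf0$ci_low <= 1 && 1 <= bf0$ci_high)
  bf1 <- bias_factor(list(value = 1, se = 0.05), df = 4)
  expect_equal(bf1$bias_factor, 10)
  # reciprocal antisymmetry
  bfp <- bias_factor(list(value = 0.35, se = 0.1), df = 6)
  bfm <- bias_factor(list(value = -0.35, se = 0.1), df = 6)
  expect_equal(bfp$bias_factor, 1 / bfm$bias_factor, tolerance = 1e-12)
  expect_equal(bfp$ci_low, 1 / bfm$ci_high, tolerance = 1e-12)
  # interval is 10^(dd +/- t se)
  tq <- qt(0.975, 6)
  expect_equal(bfp$ci_low, 10^(0.35 - tq * 0.1), tolerance = 1e-12)
  expect_warning(bias_factor(list(value = 0.5, se = -1)), "omitted")
})

test_that("potency fold changes reproduce ratio arithmetic", {
  f <- potency_fold_change(108e-9, 1.32e-9)
  expect_equal(f$fold, 108 / 1.32, tolerance = 1e-12)
  expect_equal(f$fold_rounded, 82)
  expect_equal(potency_fold_change(210e-9, 3.91e-9)$fold_rounded, 54)
  expect_equal(potency_fold_change(5e-9, 5e-9)$fold, 1)
  expect_equal(f$log10_fold, log10(108 / 1.32), tolerance = 1e-12)
  expect_error(potency_fold_change(-1, 2), "positive")
  m <- potency_fold_matrix(c(G = 1.32e-9, arr = 1.28e-9),
                           matrix(c(108e-9, 298e-9), 1, 2,
                                  dimnames = list("W287A", c("G", "arr"))))
  expect_equal(round(m$fold["W287A", "arr"]), 233)
  expect_equal(m$log10_fold, log10(m$fold))
})

test_that("the full bias pipeline returns 1 for the reference and recovers planted bias", {
  truth <- data.frame(
    ligand = c("ref", "biased", "ref", "biased"),
    pathway = c("G", "G", "arr", "arr"),
    logtau = c(0.8, 0.6, 0.8, 0.0),
    logKA = c(-8, -8.2, -8, -7.6))
  planted_dd <- with(truth, {
    lr <- logtau - logKA
    (lr[2] - lr[1]) - (lr[4] - lr[3])
  })
  ds <- simulate_dose_response(assay_prescription(truth, noise_sd = 2),
                               seed = 99)
  for (mode in c("per-experiment", "global")) {
    ba <- compute_bias(ds$data, "ref", "G", "arr", mode = mode)
    tab <- ba$table
    expect_identical(tab$bias_factor[tab$ligand == "ref"], 1)
    expect_identical(tab$ddelta[tab$ligand == "ref"], 0)
    expect_equal(tab$ddelta[tab$ligand == "biased"], planted_dd,
                 tolerance = 0.15)
    expect_true(all(tab$ci_low <= tab$bias_factor + 1e-12 &
                      tab$bias_factor <= tab$ci_high + 1e-12))
  }
})

test_that("log(tau/KA) recovery holds across seeded noisy simulations", {
  truth <- data.frame(ligand = c("ref", "test"), pathway = "G",
                      logtau = c(0.7, 0.4), logKA = c(-8, -7.2))
  pres <- assay_prescription(truth, log_conc = seq(-11, -4, length.out = 8),
                             replicates = 3, noise_sd = 2)
  hits <- 0L
  n_sim <- 30L
  for (s in seq_len(n_sim)) {
    ds <- simulate_dose_response(pres, seed = 1000 + s)
    fit <- fit_operational(ds$data)
    co <- fit$coefficients
    err <- max(abs(co$log_tau_KA - (truth$logtau - truth$logKA)))
    if (is.finite(err) && err < 0.1) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})
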