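# Dose-response fitting and operational-model bias quantification.
#
# The central quantity is the transduction coefficient log(tau/KA) from the
# Black-Leff operational model; ligand bias is the between-pathway difference
# of reference-normalized coefficients, DeltaDeltalog(tau/KA), and the bias
# factor is 10^DeltaDeltalog.

#' Operational-model response
#'
#' Evaluates the Black-Leff operational model in its log-concentration
#' form:
#' `B = 10^(X*n) * 10^(logtau*n); Y = Emax*B / (B + (10^X + 10^logKA)^n)`
#' where `X` is log10 molar agonist concentration, `tau` the operational
#' efficacy, `KA` the functional dissociation constant (molar) and `n`
#' the transducer slope. For `n = 1` the EC50 is `KA/(tau+1)` and the
#' asymptotic maximum is `Emax*tau/(tau+1)`.
#'
#' @param X numeric vector, log10 molar concentration.
#' @param logtau log10 efficacy.
#' @param logKA log10 molar functional dissociation constant.
#' @param n transducer (Hill) slope, > 0.
#' @param emax system maximal response (fixed at 100 throughout the
#'   bias pipeline).
#' @return numeric vector of responses (% of system maximum).
#' @export
operational_response <- function(X, logtau, logKA, n = 1, emax = 100) {
  stopifnot(n > 0)
  b <- 10^(X * n) * 10^(logtau * n)
  emax * b / (b + (10^X + 10^logKA)^n)
}

#' Four-parameter (or fixed-slope) logistic dose-response fit
#'
#' Fits `Y = bottom + (top - bottom) / (1 + 10^((logEC50 - X) * hill))`
#' per (ligand, pathway) group by least squares.
#'
#' @param data data.frame with columns `ligand`, `pathway`,
#'   `log_conc_M`, `response` (a `replicate` column is allowed and
#'   pooled).
#' @param hill_fixed numeric to fix the slope (e.g. 1), or `NULL` for a
#'   variable slope.
#' @return data.frame with one row per (ligand, pathway): estimates,
#'   standard errors, `converged` and `flag` columns. Degenerate inputs
#'   (flat responses) yield `flag = "degenerate"` instead of an error;
#'   fits whose logEC50 falls more than 2 log units outside the tested
#'   range are flagged "extrapolated".
#' @export
fit_logistic <- function(data, hill_fixed = NULL) {
  check_dr_columns(data)
  groups <- split(data, list(data$ligand, data$pathway), drop = TRUE)
  rows <- lapply(groups, function(g) {
    out <- data.frame(ligand = g$ligand[1], pathway = g$pathway[1],
                      bottom = NA_real_, top = NA_real_,
                      logEC50 = NA_real_, hill = NA_real_,
                      se_bottom = NA_real_, se_top = NA_real_,
                      se_logEC50 = NA_real_, se_hill = NA_real_,
                      converged = FALSE, flag = "", stringsAsFactors = FALSE)
    x <- g$log_conc_M; y <- g$response
    if (length(unique(x)) < 4L) {
      out$flag <- "fewer than 4 concentrations"; return(out)
    }
    if (diff(range(y)) < 1e-8 * max(1, max(abs(y)))) {
      out$bottom <- out$top <- mean(y)
      out$flag <- "degenerate"; return(out)
    }
    start <- list(bottom = min(y), top = max(y),
                  logEC50 = stats::median(x))
    lower <- c(-Inf, -Inf, -Inf); upper <- c(Inf, Inf, Inf)
    if (is.null(hill_fixed)) {
      start$hill <- 1; lower <- c(lower, 0.1); upper <- c(upper, 10)
    }
    resid_fn <- function(p) {
      h <- if (is.null(hill_fixed)) p[["hill"]] else hill_fixed
      y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
             (1 + 10^((p[["logEC50"]] - x) * h)))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 5)) {
      out$flag <- "non-convergence"; return(out)
    }
    est <- fit$par
    se <- nlslm_se(fit)
    out$bottom <- est[["bottom"]]; out$top <- est[["top"]]
    out$logEC50 <- est[["logEC50"]]
    out$hill <- if (is.null(hill_fixed)) est[["hill"]] else hill_fixed
    out$se_bottom <- se[["bottom"]]; out$se_top <- se[["top"]]
    out$se_logEC50 <- se[["logEC50"]]
    out$se_hill <- if (is.null(hill_fixed)) se[["hill"]] else 0
    out$converged <- TRUE
    if (out$logEC50 < min(x) - 2 || out$logEC50 > max(x) + 2)
      out$flag <- "extrapolated"
    if (out$top < out$bottom) {   # keep top >= bottom by swapping roles
      tmp <- out$top; out$top <- out$bottom; out$bottom <- tmp
      tmp <- out$se_top; out$se_top <- out$se_bottom; out$se_bottom <- tmp
      out$hill <- -out$hill
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_dr_columns <- function(data, need = c("ligand", "pathway",
                                            "log_conc_M", "response")) {
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dose-response data lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(data$response))) stop("non-finite responses")
  invisible(TRUE)
}

# SEs and covariance from an nls.lm fit (hessian = J'J at the optimum).
nlslm_vcov <- function(fit) {
  dfree <- length(fit$fvec) - length(fit$par)
  resvar <- fit$deviance / max(dfree, 1L)
  h <- fit$hessian
  v <- tryCatch(solve(h), error = function(e) pinv(h))
  v * resvar
}

nlslm_se <- function(fit) {
  v <- nlslm_vcov(fit)
  se <- sqrt(pmax(diag(v), 0))
  names(se) <- names(fit$par)
  se
}

# Moore-Penrose pseudo-inverse; used when the J'J is singular (parameter
# ridges, e.g. a full agonist's tau/KA trade-off).
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Normalize raw responses to a reference full agonist
#'
#' Rescales responses within each pathway so the reference ligand's
#' fitted top is 100% and its fitted baseline 0%, the convention used
#' when assay output is expressed as "% reference stimulation". The
#' operation is idempotent.
#'
#' @param raw data.frame with columns `ligand`, `pathway`,
#'   `log_conc_M`, `response` (and optionally `replicate`).
#' @param reference_ligand name of the reference (full agonist).
#' @return the same data.frame with `response` rescaled to percent.
#' @export
normalize_to_reference <- function(raw, reference_ligand) {
  check_dr_columns(raw)
  if (!reference_ligand %in% raw$ligand)
    stop("reference ligand '", reference_ligand, "' absent from data")
  out <- raw
  for (pw in unique(raw$pathway)) {
    sel_ref <- raw$ligand == reference_ligand & raw$pathway == pw
    if (!any(sel_ref)) stop("reference ligand absent from pathway ", pw)
    ref_fit <- fit_logistic(raw[sel_ref, , drop = FALSE])
    if (!ref_fit$converged[1])
      stop("reference ligand has no defined plateau in pathway ", pw,
           " (", ref_fit$flag[1], ")")
    sel <- out$pathway == pw
    out$response[sel] <- 100 * (out$response[sel] - ref_fit$bottom[1]) /
      (ref_fit$top[1] - ref_fit$bottom[1])
  }
  out
}

#' Global operational-model fit for one pathway
#'
#' Fits the Black-Leff model jointly across all ligands within one
#' pathway: per-ligand `logtau` and `logKA`, one shared slope `n`, and
#' `Emax` fixed (100 by default). For a full agonist `tau` and `KA`
#' trade off along a ridge; a soft upper bound (`logtau <= 3`) keeps
#' the fit bounded, and the well-determined combination
#' `log(tau/KA)` is always reported with its standard error taken from
#' the joint covariance (pseudo-inverted along ridges).
#'
#' @param data dose-response data.frame (single pathway) with columns
#'   `ligand`, `pathway`, `log_conc_M`, `response`.
#' @param emax fixed system maximum (default 100).
#' @param shared_n fit one slope for all ligands (default `TRUE`); if
#'   `FALSE`, `n` is fixed at `n_value`.
#' @param n_value slope value when `shared_n = FALSE` (default 1).
#' @param logtau_max soft identifiability bound on logtau (default 3).
#' @return An `operational_fit` list: `coefficients` (per-ligand
#'   data.frame with `logtau`, `logKA`, `log_tau_KA` and SEs), `n`,
#'   `se_n`, `pathway`, `vcov`, `converged`, `flag`.
#' @export
fit_operational <- function(data, emax = 100, shared_n = TRUE, n_value = 1,
                            logtau_max = 3) {
  check_dr_columns(data)
  pw <- unique(data$pathway)
  if (length(pw) != 1L)
    stop("fit_operational expects a single pathway; got: ",
         paste(pw, collapse = ", "))
  ligands <- unique(data$ligand)
  nl <- length(ligands)
  lig_idx <- match(data$ligand, ligands)
  x <- data$log_conc_M; y <- data$response

  # start values: logKA near the upper tested range, logtau neutral
  start <- numeric(0)
  if (shared_n) start <- c(n = 1)
  for (lg in ligands) {
    xs <- x[data$ligand == lg]
    start <- c(start, 0, stats::median(xs) + 0.5)
  }
  names(start) <- c(if (shared_n) "n",
                    paste0(rep(c("logtau_", "logKA_"), nl),
                           rep(seq_len(nl), each = 2)))
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  if (shared_n) { lower[1] <- 0.1; upper[1] <- 10 }
  tau_pos <- (if (shared_n) 1L else 0L) + 2L * seq_len(nl) - 1L
  upper[tau_pos] <- logtau_max

  unpack <- function(p) {
    n <- if (shared_n) p[[1]] else n_value
    off <- if (shared_n) 1L else 0L
    list(n = n,
         logtau = p[off + 2 * seq_len(nl) - 1],
         logKA = p[off + 2 * seq_len(nl)])
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    y - operational_response(x, q$logtau[lig_idx], q$logKA[lig_idx],
                             n = q$n, emax = emax)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(coefficients = NULL, pathway = pw,
                          converged = FALSE, flag = "non-convergence"),
                     class = "operational_fit"))
  q <- unpack(fit$par)
  v <- nlslm_vcov(fit)
  off <- if (shared_n) 1L else 0L
  coefs <- data.frame(ligand = ligands, pathway = pw,
                      logtau = q$logtau, logKA = q$logKA,
                      log_tau_KA = q$logtau - q$logKA,
                      se_logtau = NA_real_, se_logKA = NA_real_,
                      se_log_tau_KA = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nl)) {
    it <- off + 2L * i - 1L; ik <- off + 2L * i
    coefs$se_logtau[i] <- sqrt(max(v[it, it], 0))
    coefs$se_logKA[i] <- sqrt(max(v[ik, ik], 0))
    coefs$se_log_tau_KA[i] <-
      sqrt(max(v[it, it] + v[ik, ik] - 2 * v[it, ik], 0))
  }
  flag <- ""
  if (any(abs(q$logtau - logtau_max) < 1e-6))
    flag <- "logtau at identifiability bound; log_tau_KA remains valid"
  structure(list(coefficients = coefs,
                 n = q$n,
                 se_n = if (shared_n) sqrt(max(v[1, 1], 0)) else 0,
                 pathway = pw, vcov = v,
                 n_obs = length(y), converged = !(fit$info %in% c(0, 5)),
                 flag = flag, deviance = fit$deviance),
            class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("<operational_fit> pathway '%s', n = %.3f, %s\n", x$pathway,
              x$n, if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

#' Transduction coefficient log(tau/KA)
#'
#' @param fit an `operational_fit` from [fit_operational()].
#' @param ligand ligand name present in the fit.
#' @return list of class `transduction_coefficient` with `value`, `se`,
#'   `ligand`, `pathway`.
#' @export
transduction_coefficient <- function(fit, ligand) {
  stopifnot(inherits(fit, "operational_fit"))
  i <- match(ligand, fit$coefficients$ligand)
  if (is.na(i)) stop("ligand '", ligand, "' not in fit")
  structure(list(value = fit$coefficients$log_tau_KA[i],
                 se = fit$coefficients$se_log_tau_KA[i],
                 ligand = ligand, pathway = fit$pathway),
            class = "transduction_coefficient")
}

#' Reference-normalized transduction coefficient
#'
#' `Delta log(tau/KA) = log(tau/KA)_test - log(tau/KA)_reference` within
#' one pathway; `se = sqrt(se_test^2 + se_ref^2)`.
#'
#' @param test,ref `transduction_coefficient` objects from the same
#'   pathway.
#' @return list with `value`, `se`, `ligand`, `reference`, `pathway`.
#' @export
delta_log <- function(test, ref) {
  if (!identical(test$pathway, ref$pathway))
    stop("delta_log requires coefficients from the same pathway (got '",
         test$pathway, "' vs '", ref$pathway, "')")
  same <- identical(test$ligand, ref$ligand)
  list(value = if (same) 0 else test$value - ref$value,
       se = if (same) 0 else sqrt(test$se^2 + ref$se^2),
       ligand = test$ligand, reference = ref$ligand,
       pathway = test$pathway)
}

#' Between-pathway bias difference
#'
#' `DeltaDelta log(tau/KA) = Delta log(pathway 1) - Delta log(pathway 2)`
#' for one ligand; by the convention used here pathway 1 is the G
#' protein pathway and pathway 2 the arrestin pathway, so positive
#' values mean G-protein bias.
#'
#' @param d_path1,d_path2 results of [delta_log()] for the same ligand
#'   in two pathways.
#' @return list with `value`, `se`, `ligand`, `pathway_order`.
#' @export
ddelta_log <- function(d_path1, d_path2) {
  if (!identical(d_path1$ligand, d_path2$ligand))
    stop("ddelta_log requires the same ligand in both pathways")
  list(value = d_path1$value - d_path2$value,
       se = sqrt(d_path1$se^2 + d_path2$se^2),
       ligand = d_path1$ligand,
       pathway_order = c(d_path1$pathway, d_path2$pathway))
}

#' Bias factor with confidence interval
#'
#' `bias factor = 10^DeltaDeltalog(tau/KA)`, with a symmetric-in-log t
#' interval `10^(DeltaDelta +/- t(df) * se)`.
#'
#' @param ddelta result of [ddelta_log()] (or a list with `value`, `se`).
#' @param level confidence level (default 0.95).
#' @param df degrees of freedom for the t quantile.
#' @return list of class `bias_result` with `bias_factor`, `ci_low`,
#'   `ci_high`, `ddelta`, `se`, `level`, `df`.
#' @export
bias_factor <- function(ddelta, level = 0.95, df = 4) {
  dd <- ddelta$value; se <- ddelta$se
  bf <- 10^dd
  if (is.na(se) || se < 0) {
    warning("non-positive/undefined se; confidence interval omitted")
    ci <- c(NA_real_, NA_real_)
  } else if (se == 0) {
    ci <- c(bf, bf)       # exact by construction (reference vs itself)
  } else {
    tq <- stats::qt(1 - (1 - level) / 2, df)
    ci <- 10^(dd + c(-1, 1) * tq * se)
  }
  structure(list(bias_factor = bf, ci_low = ci[1], ci_high = ci[2],
                 ddelta = dd, se = se, level = level, df = df,
                 ligand = ddelta$ligand,
                 pathway_order = ddelta$pathway_order),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result> %s: bias factor %.3g (%.3g-%.3g), ddlog = %.3f +/- %.3f\n",
              x$ligand %||% "?", x$bias_factor, x$ci_low, x$ci_high,
              x$ddelta, x$se))
  invisible(x)
}

#' Potency fold change between receptor variants
#'
#' @param ec50_variant,ec50_wt EC50 values (same units, > 0).
#' @return list with `fold` (variant/wt), `fold_rounded` (nearest
#'   integer, the reporting convention), and `log10_fold` (for
#'   heatmaps).
#' @export
potency_fold_change <- function(ec50_variant, ec50_wt) {
  if (any(c(ec50_variant, ec50_wt) <= 0))
    stop("EC50 values must be positive")
  f <- ec50_variant / ec50_wt
  list(fold = f, fold_rounded = round(f), log10_fold = log10(f))
}

#' Mutant-vs-wild-type fold-change matrix
#'
#' Builds the (variant x pathway/transducer) potency fold-change table
#' behind mutagenesis heatmaps.
#'
#' @param ec50_wt named numeric vector (names = pathways), molar EC50s
#'   of the wild-type receptor.
#' @param ec50_mut matrix or data.frame (variants x pathways) of molar
#'   EC50s.
#' @return list with matrices `fold` and `log10_fold`.
#' @export
potency_fold_matrix <- function(ec50_wt, ec50_mut) {
  ec50_mut <- as.matrix(ec50_mut)
  if (is.null(colnames(ec50_mut)) || !all(colnames(ec50_mut) %in% names(ec50_wt)))
    stop("column names of ec50_mut must match names of ec50_wt")
  wt <- ec50_wt[colnames(ec50_mut)]
  fold <- sweep(ec50_mut, 2, wt, `/`)
  list(fold = fold, log10_fold = log10(fold))
}

#' Full bias-quantification pipeline
#'
#' Runs the operational-model analysis end to end: per-pathway global
#' fits, transduction coefficients, reference-normalized Delta log,
#' between-pathway DeltaDelta log, and bias factors with confidence
#' intervals.
#'
#' Two averaging modes are provided. `"per-experiment"` (default when a
#' `replicate` column is present) fits each independent experiment
#' separately, computes Delta log within each experiment, and averages
#' across experiments with the empirical standard error — this matches
#' the practice of averaging transduction coefficients across
#' experiments. `"global"` fits all data at once and takes the standard
#' errors from the joint fit covariance.
#'
#' @param data dose-response data.frame with columns `ligand`,
#'   `pathway`, `replicate`, `log_conc_M`, `response`.
#' @param reference_ligand the reference full agonist (bias factor = 1
#'   by construction).
#' @param pathway_g,pathway_arr names of the two pathways; DeltaDelta
#'   log is `Delta(pathway_g) - Delta(pathway_arr)` so bias factors > 1
#'   indicate G-protein bias.
#' @param mode "per-experiment" or "global".
#' @param level confidence level for bias-factor intervals.
#' @return list of class `bias_analysis` with `fits` (per pathway or
#'   per experiment), `delta` (per ligand/pathway), `table` (one row
#'   per ligand: ddelta, se, bias factor, CI), `mode`.
#' @export
compute_bias <- function(data, reference_ligand,
                         pathway_g, pathway_arr,
                         mode = c("per-experiment", "global"),
                         level = 0.95) {
  mode <- match.arg(mode)
  check_dr_columns(data)
  if (!all(c(pathway_g, pathway_arr) %in% data$pathway))
    stop("pathways not both present in data")
  if (!reference_ligand %in% data$ligand)
    stop("reference ligand absent from data")
  if (mode == "per-experiment" && !"replicate" %in% names(data)) {
    mode <- "global"
  }
  ligands <- unique(data$ligand)
  pws <- c(pathway_g, pathway_arr)

  if (mode == "global") {
    fits <- lapply(pws, function(pw)
      fit_operational(data[data$pathway == pw, , drop = FALSE]))
    names(fits) <- pws
    dof <- sum(vapply(fits, function(f) f$n_obs, 1)) -
      sum(vapply(fits, function(f) nrow(f$coefficients) * 2 + 1, 1))
    delta <- list()
    for (pw in pws) {
      ref_tc <- transduction_coefficient(fits[[pw]], reference_ligand)
      delta[[pw]] <- lapply(ligands, function(lg)
        delta_log(transduction_coefficient(fits[[pw]], lg), ref_tc))
      names(delta[[pw]]) <- ligands
    }
    rows <- lapply(ligands, function(lg) {
      dd <- ddelta_log(delta[[pathway_g]][[lg]], delta[[pathway_arr]][[lg]])
      bf <- bias_factor(dd, level = level, df = max(dof, 1))
      data.frame(ligand = lg, delta_g = delta[[pathway_g]][[lg]]$value,
                 se_delta_g = delta[[pathway_g]][[lg]]$se,
                 delta_arr = delta[[pathway_arr]][[lg]]$value,
                 se_delta_arr = delta[[pathway_arr]][[lg]]$se,
                 ddelta = dd$value, se_ddelta = dd$se,
                 bias_factor = bf$bias_factor,
                 ci_low = bf$ci_low, ci_high = bf$ci_high,
                 stringsAsFactors = FALSE)
    })
  } else {
    reps <- sort(unique(data$replicate))
    # per-experiment Delta log for every ligand/pathway
    dmat <- array(NA_real_, dim = c(length(ligands), 2L, length(reps)),
                  dimnames = list(ligands, pws, as.character(reps)))
    fits <- list()
    for (r in seq_along(reps)) {
      for (pw in pws) {
        sub <- data[data$replicate == reps[r] & data$pathway == pw, ,
                    drop = FALSE]
        f <- fit_operational(sub)
        fits[[paste(pw, reps[r], sep = "/")]] <- f
        if (!f$converged) next
        ref_tc <- transduction_coefficient(f, reference_ligand)
        for (lg in intersect(ligands, f$coefficients$ligand)) {
          dmat[lg, pw, r] <-
            delta_log(transduction_coefficient(f, lg), ref_tc)$value
        }
      }
    }
    delta <- list()
    for (pw in pws) {
      delta[[pw]] <- lapply(ligands, function(lg) {
        v <- dmat[lg, pw, ]; v <- v[is.finite(v)]
        list(value = mean(v),
             se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
             n_experiments = length(v), ligand = lg,
             reference = reference_ligand, pathway = pw)
      })
      names(delta[[pw]]) <- ligands
    }
    rows <- lapply(ligands, function(lg) {
      dg <- delta[[pathway_g]][[lg]]; da <- delta[[pathway_arr]][[lg]]
      dd <- list(value = dg$value - da$value,
                 se = sqrt(dg$se^2 + da$se^2), ligand = lg,
                 pathway_order = pws)
      dof <- max(dg$n_experiments + da$n_experiments - 2L, 1L)
      bf <- bias_factor(dd, level = level, df = dof)
      data.frame(ligand = lg, delta_g = dg$value, se_delta_g = dg$se,
                 delta_arr = da$value, se_delta_arr = da$se,
                 ddelta = dd$value, se_ddelta = dd$se,
                 bias_factor = bf$bias_factor,
                 ci_low = bf$ci_low, ci_high = bf$ci_high,
                 stringsAsFactors = FALSE)
    })
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(fits = fits, delta = delta, table = tab, mode = mode,
                 reference_ligand = reference_ligand,
                 pathway_order = pws, level = level),
            class = "bias_analysis")
}

#' @export
print.bias_analysis <- function(x, ...) {
  cat(sprintf("<bias_analysis> reference '%s', pathways %s vs %s, mode %s\n",
              x$reference_ligand, x$pathway_order[1], x$pathway_order[2],
              x$mode))
  print(x$table, digits = 3)
  invisible(x)
}
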