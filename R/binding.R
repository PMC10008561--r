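# Radioligand binding: competition (one-site Ki via Cheng-Prusoff) and
# dissociation kinetics (one-phase exponential decay), plus the expression
# normalization used for single-point binding.

#' Cheng-Prusoff correction
#'
#' Converts a competition IC50 to an inhibition constant:
#' `Ki = IC50 / (1 + L / Kd)` with `L` the radioligand concentration and
#' `Kd` its dissociation constant.
#'
#' @param ic50 molar IC50 (> 0).
#' @param radioligand_conc molar radioligand concentration `L` (> 0).
#' @param kd molar radioligand `Kd` (> 0).
#' @return molar Ki.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, kd) {
  if (any(c(ic50, radioligand_conc, kd) <= 0))
    stop("cheng_prusoff requires positive inputs")
  ic50 / (1 + radioligand_conc / kd)
}

#' One-site competition-binding fit
#'
#' Fits the one-site competition curve (logistic in log concentration
#' with slope fixed at -1 unless `variable_slope`) and converts the
#' fitted IC50 to Ki by [cheng_prusoff()]. In log10 the correction is a
#' constant offset, so `se(logKi) = se(logIC50)`.
#'
#' @param data data.frame with columns `log_conc_M` (cold ligand) and
#'   `cpm` (bound signal); a `replicate` column is pooled.
#' @param radioligand_conc molar radioligand concentration.
#' @param kd molar radioligand Kd.
#' @param variable_slope if `TRUE`, the slope is fitted rather than
#'   fixed at -1.
#' @return list of class `ki_fit` with `logKi`, `se_logKi`, `Ki`,
#'   `logIC50`, `top`, `bottom`, `hill`, `converged`, `flag`.
#' @export
fit_one_site_ki <- function(data, radioligand_conc, kd,
                            variable_slope = FALSE) {
  stopifnot(all(c("log_conc_M", "cpm") %in% names(data)))
  df <- data.frame(ligand = "cold", pathway = "binding",
                   log_conc_M = data$log_conc_M, response = data$cpm)
  fit <- fit_logistic(df, hill_fixed = if (variable_slope) NULL else -1)
  out <- list(logKi = NA_real_, se_logKi = NA_real_, Ki = NA_real_,
              logIC50 = fit$logEC50[1], se_logIC50 = fit$se_logEC50[1],
              top = fit$top[1], bottom = fit$bottom[1], hill = fit$hill[1],
              converged = fit$converged[1], flag = fit$flag[1])
  if (isTRUE(out$converged) && out$flag != "degenerate") {
    shift <- log10(1 + radioligand_conc / kd)
    out$logKi <- out$logIC50 - shift
    out$se_logKi <- out$se_logIC50
    out$Ki <- 10^out$logKi
  }
  class(out) <- "ki_fit"
  out
}

#' @export
print.ki_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<ki_fit> logKi = %.3f +/- %.3f (Ki = %.3g M)%s\n",
                x$logKi, x$se_logKi, x$Ki,
                if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  else cat("<ki_fit> not converged:", x$flag, "\n")
  invisible(x)
}

#' One-phase exponential dissociation fit
#'
#' Fits `Y(t) = (Y0 - NS) * exp(-koff * t) + NS` to a dissociation
#' time course (t = 0 at excess cold-ligand addition) and reports the
#' dissociation half-life `t_half = ln(2)/koff`.
#'
#' @param data data.frame with columns `time_min` and `cpm`; a
#'   `replicate` column is pooled.
#' @param ns_fixed optional fixed nonspecific plateau (CPM), e.g. from
#'   a blocker-defined value; default estimates NS as a free parameter.
#' @return list of class `dissociation_fit` with `Y0`, `NS`, `koff`
#'   (min^-1), `t_half` (min), standard errors, `converged`, `flag`.
#' @export
fit_dissociation <- function(data, ns_fixed = NULL) {
  stopifnot(all(c("time_min", "cpm") %in% names(data)))
  t <- data$time_min; y <- data$cpm
  if (any(t < 0)) stop("negative time points")
  if (length(unique(t)) < 4L)
    return(structure(list(converged = FALSE,
                          flag = "fewer than 4 time points"),
                     class = "dissociation_fit"))
  span <- max(y) - min(y)
  start <- c(Y0 = max(y), koff = log(2) / max(stats::median(t), 1e-6))
  if (is.null(ns_fixed)) start <- c(start, NS = min(y))
  resid_fn <- function(p) {
    ns <- if (is.null(ns_fixed)) p[["NS"]] else ns_fixed
    y - ((p[["Y0"]] - ns) * exp(-p[["koff"]] * t) + ns)
  }
  lower <- c(-Inf, 1e-8, if (is.null(ns_fixed)) -Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5))
    return(structure(list(converged = FALSE, flag = "non-convergence"),
                     class = "dissociation_fit"))
  se <- nlslm_se(fit)
  koff <- fit$par[["koff"]]
  flag <- ""
  if (span < 1e-8 * max(1, max(abs(y)))) flag <- "degenerate (flat data)"
  if (koff <= 1e-8) flag <- "koff at lower bound"
  se_koff <- se[["koff"]]
  structure(list(Y0 = fit$par[["Y0"]],
                 NS = if (is.null(ns_fixed)) fit$par[["NS"]] else ns_fixed,
                 koff = koff, t_half = log(2) / koff,
                 se_Y0 = se[["Y0"]],
                 se_NS = if (is.null(ns_fixed)) se[["NS"]] else 0,
                 se_koff = se_koff,
                 se_t_half = log(2) / koff^2 * se_koff,
                 converged = TRUE, flag = flag),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<dissociation_fit> koff = %.4g min^-1, t1/2 = %.3g min%s\n",
                x$koff, x$t_half,
                if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  else cat("<dissociation_fit> not converged:", x$flag, "\n")
  invisible(x)
}

#' Expression normalization of bound counts
#'
#' Single-point binding signals are reported per microgram of total
#' membrane protein ("CPM / ug total protein").
#'
#' @param cpm counts per minute (>= 0).
#' @param total_protein micrograms of total protein (> 0).
#' @return counts per microgram.
#' @export
normalize_expression <- function(cpm, total_protein) {
  if (any(total_protein <= 0)) stop("total_protein must be positive")
  cpm / total_protein
}
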