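#' Trapezoidal AUC over a window
#'
#' Linear trapezoidal integral of a concentration-time profile between `t0`
#' and `t1`; endpoints off the sampling grid are linearly interpolated.
#'
#' @param profile an `fv_profile` (or data frame with `time_h`, `conc_ng_ml`).
#' @param t0,t1 window bounds, h, within the profile span.
#' @return AUC, ng.h/mL.
#' @export
auc_trapezoid <- function(profile, t0, t1) {
  t <- profile$time_h
  c_ <- profile$conc_ng_ml
  if (t0 >= t1) stop("t0 must be below t1")
  if (t0 < min(t) - 1e-9 || t1 > max(t) + 1e-9)
    stop("AUC window outside the simulated profile")
  keep <- t > t0 & t < t1
  tt <- c(t0, t[keep], t1)
  cc <- c(stats::approx(t, c_, t0)$y, c_[keep], stats::approx(t, c_, t1)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' AUC extrapolated to infinity
#'
#' Standard non-compartmental extrapolation for a single-dose profile:
#' AUC(0-tlast) by the trapezoid plus C(tlast)/lambda_z, with the terminal
#' rate constant lambda_z from a log-linear fit over the terminal phase
#' (default: the last third of the post-Tmax points).
#'
#' @param profile a single-dose `fv_profile`.
#' @param terminal_frac fraction of post-Tmax points used in the lambda_z fit.
#' @return AUC(0-inf), ng.h/mL, with attributes `lambda_z` (1/h) and
#'   `extrap_fraction`. A warning is raised if the extrapolated fraction
#'   exceeds 20%.
#' @export
auc_to_infinity <- function(profile, terminal_frac = 1/3) {
  t <- profile$time_h
  c_ <- profile$conc_ng_ml
  imax <- which.max(c_)
  post <- seq(imax + 1, length(t))
  if (length(post) < 3)
    stop("need at least 3 terminal points past Tmax for extrapolation")
  start <- min(max(1, floor(length(post) * (1 - terminal_frac)) + 1),
               length(post) - 2)
  idx <- post[seq(start, length(post))]
  idx <- idx[c_[idx] > 0]
  if (length(idx) < 3) stop("too few positive terminal points for lambda_z")
  fit <- stats::lm(log(c_[idx]) ~ t[idx])
  lz <- -unname(stats::coef(fit)[2])
  if (!is.finite(lz) || lz <= 0)
    stop("non-monotone terminal phase: lambda_z extrapolation failed")
  auc_last <- auc_trapezoid(profile, t[1], t[length(t)])
  tail_auc <- c_[length(t)] / lz
  auc <- auc_last + tail_auc
  frac <- tail_auc / auc
  if (frac > 0.20)
    warning(sprintf("extrapolated AUC fraction %.0f%% exceeds 20%%", 100 * frac))
  structure(auc, lambda_z = lz, extrap_fraction = frac)
}

#' Trough and peak of a steady-state window
#'
#' Cmax is the maximum over the window; Cmin is the concentration at the
#' window end, i.e. the pre-dose trough of the next interval.
#'
#' @param window_profile an `fv_profile` restricted to one dosing interval
#'   (see [steady_state_window()]).
#' @return A list with `cmin` and `cmax` (ng/mL).
#' @export
trough_and_peak <- function(window_profile) {
  list(cmin = window_profile$conc_ng_ml[nrow(window_profile)],
       cmax = max(window_profile$conc_ng_ml))
}

#' Population summary of per-subject PK metrics
#'
#' Arithmetic mean, SD, CV%, and empirical 5th/95th percentiles per metric,
#' pooling all subjects (the trial structure is retained as per-trial means
#' for reporting).
#'
#' @param metrics an `fv_metrics` data frame from [population_metrics()].
#' @return An object of class `fv_pksummary`: a data frame with one row per
#'   metric (cmax, cmin, auc) and columns mean, sd, cv_pct, p5, p95, n;
#'   per-trial means in attribute `trial_means`, window tag in `window`.
#' @export
summarize_pk <- function(metrics) {
  if (nrow(metrics) < 2) stop("need at least 2 subjects to summarize")
  vars <- c("cmax", "cmin", "auc")
  one <- function(v) {
    x <- metrics[[v]]
    m <- mean(x)
    s <- stats::sd(x)
    data.frame(metric = v, mean = m, sd = s,
               cv_pct = if (m > 0) 100 * s / m else NA_real_,
               p5 = unname(stats::quantile(x, 0.05)),
               p95 = unname(stats::quantile(x, 0.95)),
               n = length(x))
  }
  out <- do.call(rbind, lapply(vars, one))
  trial_means <- stats::aggregate(metrics[vars], list(trial = metrics$trial),
                                  mean)
  structure(out, class = c("fv_pksummary", "data.frame"),
            window = attr(metrics, "window"),
            n_trials = length(unique(metrics$trial)),
            trial_means = trial_means)
}

#' Fold ratio of population means between two groups
#'
#' Ratio of population-mean metric values (group A over group B). The two
#' summaries must report the same AUC window.
#'
#' @param summary_a,summary_b `fv_pksummary` objects.
#' @param metric one of `"auc"`, `"cmax"`, `"cmin"`.
#' @return The fold ratio (numeric).
#' @export
fold_ratio <- function(summary_a, summary_b, metric = "auc") {
  metric <- match.arg(metric, c("auc", "cmax", "cmin"))
  wa <- attr(summary_a, "window")
  wb <- attr(summary_b, "window")
  if (!identical(wa, wb))
    stop(sprintf("mismatched AUC windows: %s vs %s", wa, wb))
  ma <- summary_a$mean[summary_a$metric == metric]
  mb <- summary_b$mean[summary_b$metric == metric]
  ma / mb
}

#' @export
print.fv_pksummary <- function(x, digits = 4, ...) {
  cat(sprintf("Population PK summary (n = %d, %d trials, AUC window %s)\n",
              x$n[1], attr(x, "n_trials"), attr(x, "window")))
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}
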