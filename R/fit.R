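#' Fit the fluvoxamine population PBPK model
#'
#' The central model constructor. Starting from the published fluvoxamine
#' parameterization ([fluvoxamine_compound()]), it calibrates the two
#' quantities the literature does not give directly:
#' \enumerate{
#'   \item the split and absolute scale of hepatic intrinsic clearance
#'     ([calibrate_elimination()]): the CYP2D6 fraction metabolized is set
#'     from the observed single-dose PM/EM AUC fold (2.1), and the total
#'     scale from the observed mean 100 mg single-dose AUC(0-inf) of
#'     1308 ng.h/mL in young adult males;
#'   \item the geriatric hepatic activity scalar ([calibrate_aging()]): tuned
#'     so mean oral clearance in a 65-98 y population is 50% of the 18-65 y
#'     mean, the reported age effect for fluvoxamine.
#' }
#'
#' @param compound starting `fv_compound`.
#' @param aging starting `fv_aging` model (decline rates kept as given).
#' @param observed_auc single-dose AUC anchor, ng.h/mL.
#' @param pm_em_ratio single-dose PM/EM AUC fold anchor.
#' @param target_cl_fraction geriatric/younger mean clearance target.
#' @param seed integer seed controlling every calibration population.
#' @param n_trials,subjects_per_trial structure of the AUC-anchor population.
#' @param settings solver settings used for calibration and downstream
#'   simulation defaults.
#' @return An object of class `fvpbpk` with components `compound` (calibrated),
#'   `aging` (calibrated), `calibration`, `aging_calibration`, `settings`,
#'   `anchors`, `seed`. Methods: [print.fvpbpk()], [summary.fvpbpk()],
#'   [coef.fvpbpk()], [predict.fvpbpk()], [simulate.fvpbpk()],
#'   [plot.fvpbpk()], [residuals.fvpbpk()].
#' @examples
#' \donttest{
#' fit <- fit_fluvoxamine(seed = 1)
#' coef(fit)
#' predict(fit, data.frame(daily_dose = 100, age = 75, phenotype = "EM"))
#' }
#' @export
fit_fluvoxamine <- function(compound = fluvoxamine_compound(),
                            aging = aging_model(),
                            observed_auc = 1308,
                            pm_em_ratio = 2.1,
                            target_cl_fraction = 0.5,
                            seed = 1L,
                            n_trials = 10, subjects_per_trial = 10,
                            settings = solver_settings()) {
  cal <- calibrate_elimination(compound, observed_auc = observed_auc,
                               pm_em_ratio = pm_em_ratio, seed = seed,
                               n_trials = n_trials,
                               subjects_per_trial = subjects_per_trial,
                               aging = aging, settings = settings)
  acal <- calibrate_aging(cal$compound, aging,
                          target_cl_fraction = target_cl_fraction,
                          seed = seed)
  structure(list(compound = cal$compound,
                 aging = acal$aging,
                 calibration = cal,
                 aging_calibration = acal,
                 settings = settings,
                 anchors = list(observed_auc = observed_auc,
                                pm_em_ratio = pm_em_ratio,
                                target_cl_fraction = target_cl_fraction),
                 seed = seed),
            class = "fvpbpk")
}

#' @export
print.fvpbpk <- function(x, ...) {
  cat("Fluvoxamine population PBPK model (calibrated)\n")
  cat(sprintf("  fm,CYP2D6 = %.4f (from PM/EM fold %.2f)\n",
              x$calibration$fm, x$anchors$pm_em_ratio))
  cat(sprintf("  CYP2D6 pathway scalar = %.3f; non-CYP2D6 CLint = %.2f uL/min/mg\n",
              x$calibration$cyp2d6_scalar, x$calibration$clint_additional))
  cat(sprintf("  AUC anchor: simulated %.0f vs observed %.0f ng.h/mL (%.1f%%)\n",
              x$calibration$sim_auc, x$calibration$observed_auc,
              100 * x$calibration$residual))
  cat(sprintf("  Geriatric activity scalar = %.3f (CL ratio %.3f, target %.2f)\n",
              x$aging_calibration$scalar, x$aging_calibration$achieved_ratio,
              x$anchors$target_cl_fraction))
  invisible(x)
}

#' @rdname print.fvpbpk
#' @param object,x an `fvpbpk` fit.
#' @param ... unused.
#' @export
summary.fvpbpk <- function(object, ...) {
  print(object)
  cat("\nCompound:\n")
  print(object$compound)
  cat("\nAging model:\n")
  a <- object$aging
  cat(sprintf("  liver mass decline %.3f/y, flow decline %.3f/y above %g y;\n",
              a$liver_mass_decline, a$flow_decline, a$reference_age))
  cat(sprintf("  geriatric activity scalar %.3f at/above %g y\n",
              a$activity_scalar, a$geriatric_age))
  invisible(object)
}

#' Calibrated parameters of a fitted model
#' @param object an `fvpbpk` fit.
#' @param ... unused.
#' @return Named numeric vector: fm_2d6, cyp2d6_scalar,
#'   clint_additional_uL_min_mg, aging_scalar.
#' @export
coef.fvpbpk <- function(object, ...) {
  c(fm_2d6 = object$calibration$fm,
    cyp2d6_scalar = object$calibration$cyp2d6_scalar,
    clint_additional_uL_min_mg = object$calibration$clint_additional,
    aging_scalar = object$aging_calibration$scalar)
}

#' Calibration anchor residuals
#' @param object an `fvpbpk` fit.
#' @param ... unused.
#' @return Named numeric vector of relative residuals at the two calibration
#'   anchors (simulated/target - 1).
#' @export
residuals.fvpbpk <- function(object, ...) {
  c(auc_anchor = object$calibration$residual,
    aging_anchor = object$aging_calibration$residual)
}

# reference subject (population-mean deviates) for typical-value prediction
reference_subject <- function(age, sex, weight, phenotype, aging,
                              phenotypes = phenotype_params()) {
  over <- max(age - aging$reference_age, 0)
  data.frame(
    trial = 1L, subject = 1L, age = age, sex = sex, weight = weight,
    height = if (sex == "F") 163 else 176,
    liver_mass = 1650 * (weight / 70)^0.85 *
      max(1 - aging$liver_mass_decline * over, 0.2),
    mppgl = 40,
    q_hepatic = 84 * (weight / 70)^0.75 *
      max(1 - aging$flow_decline * over, 0.2),
    activity = 1,
    phenotype = phenotype,
    cyp2d6_abundance = unname(phenotypes$means[phenotype]),
    geriatric = age >= aging$geriatric_age)
}

#' Typical-subject steady-state prediction
#'
#' Deterministic prediction for reference subjects (population-mean physiology
#' and activity): simulates the regimen implied by each row's daily dose and
#' returns steady-state Cmax, Cmin and interval AUC, plus the subject's oral
#' clearance and hepatic availability.
#'
#' @param object an `fvpbpk` fit.
#' @param newdata data frame with columns `daily_dose` (mg/day) and optionally
#'   `age` (default 75), `sex` ("M"/"F", default "F"), `weight` (kg, default
#'   by sex), `phenotype` (default "EM").
#' @param days days of dosing before the reported interval.
#' @param ... unused.
#' @return `newdata` augmented with cl_oral_L_h, fh, cmax, cmin, auc, window.
#' @export
predict.fvpbpk <- function(object, newdata, days = 14, ...) {
  if (missing(newdata))
    newdata <- data.frame(daily_dose = c(50, 100, 150, 200))
  nd <- newdata
  if (is.null(nd$age)) nd$age <- 75
  if (is.null(nd$sex)) nd$sex <- "F"
  if (is.null(nd$weight)) nd$weight <- ifelse(nd$sex == "F", 66, 81)
  if (is.null(nd$phenotype)) nd$phenotype <- "EM"
  out <- nd
  out$cl_oral_L_h <- out$fh <- out$cmax <- out$cmin <- out$auc <- NA_real_
  out$window <- NA_character_
  for (i in seq_len(nrow(nd))) {
    subj <- reference_subject(nd$age[i], nd$sex[i], nd$weight[i],
                              nd$phenotype[i], object$aging)
    cl <- whole_liver_clint(subj, object$compound, object$aging)
    reg <- regimen_for_daily_dose(nd$daily_dose[i], days)
    m <- population_metrics(subj, object$compound, object$aging,
                            reg, settings = object$settings)
    out$cl_oral_L_h[i] <- cl$cl_oral_plasma
    out$fh[i] <- cl$fh
    out$cmax[i] <- m$cmax[1]
    out$cmin[i] <- m$cmin[1]
    out$auc[i] <- m$auc[1]
    out$window[i] <- attr(m, "window")
  }
  out
}

#' Simulate population exposure from a fitted model
#'
#' Monte-Carlo counterpart of [predict.fvpbpk()]: builds a seeded virtual
#' population and returns per-subject steady-state (or single-dose) metrics.
#'
#' @param object an `fvpbpk` fit.
#' @param nsim number of populations to simulate (stacked with a `sim` index).
#' @param seed integer seed; `sim` replicates use `seed + sim - 1`.
#' @param daily_dose total daily dose, mg/day.
#' @param age_range two-element age window, years.
#' @param phenotype_mode population phenotype mode (see [population_spec()]).
#' @param prop_female fraction female.
#' @param n_trials,subjects_per_trial population structure.
#' @param days days of dosing.
#' @param ... unused.
#' @return An `fv_metrics` data frame (with `sim` column when `nsim > 1`).
#' @export
simulate.fvpbpk <- function(object, nsim = 1, seed = object$seed,
                            daily_dose = 100,
                            age_range = c(65, 98),
                            phenotype_mode = "default_mix",
                            prop_female = 0.5,
                            n_trials = 10, subjects_per_trial = 10,
                            days = 14, ...) {
  reg <- regimen_for_daily_dose(daily_dose, days)
  sims <- lapply(seq_len(nsim), function(s) {
    pop <- build_population(
      population_spec(n_trials, subjects_per_trial, age_range[1], age_range[2],
                      prop_female, phenotype_mode, seed = seed + s - 1),
      object$aging)
    m <- population_metrics(pop, object$compound, object$aging, reg,
                            settings = object$settings)
    m$sim <- s
    m
  })
  out <- do.call(rbind, sims)
  if (nsim == 1) out$sim <- NULL
  attr(out, "window") <- attr(sims[[1]], "window")
  class(out) <- c("fv_metrics", "data.frame")
  out
}

#' Plot simulated steady-state concentration-time profiles
#'
#' Mean profile with the 5th-95th percentile band over the final dosing
#' interval for a seeded population, with the therapeutic window drawn as
#' horizontal broken lines.
#'
#' @param x an `fvpbpk` fit.
#' @param daily_dose total daily dose, mg/day.
#' @param phenotype_mode population phenotype mode.
#' @param age_range age window, years.
#' @param seed population seed.
#' @param n_trials,subjects_per_trial population structure.
#' @param days days of dosing.
#' @param window therapeutic window drawn on the plot.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, a data frame time_h / mean / p5 / p95.
#' @export
plot.fvpbpk <- function(x, daily_dose = 100, phenotype_mode = "default_mix",
                        age_range = c(65, 98), seed = x$seed,
                        n_trials = 10, subjects_per_trial = 10, days = 14,
                        window = therapeutic_window(), ...) {
  reg <- regimen_for_daily_dose(daily_dose, days)
  pop <- build_population(
    population_spec(n_trials, subjects_per_trial, age_range[1], age_range[2],
                    0.5, phenotype_mode, seed = seed), x$aging)
  cl <- whole_liver_clint(pop, x$compound, x$aging)
  profs <- lapply(seq_len(nrow(pop)), function(i) {
    p <- simulate_profile(pop[i, , drop = FALSE], x$compound,
                          cl[i, , drop = FALSE], reg, x$settings)
    steady_state_window(p, reg$interval_h, x$settings)$conc_ng_ml
  })
  mat <- do.call(cbind, profs)
  t_rel <- seq(0, reg$interval_h, by = x$settings$output_grid_h)
  stats_df <- data.frame(time_h = t_rel,
                         mean = rowMeans(mat),
                         p5 = apply(mat, 1, stats::quantile, 0.05),
                         p95 = apply(mat, 1, stats::quantile, 0.95))
  graphics::plot(stats_df$time_h, stats_df$mean, type = "n",
                 ylim = c(0, max(stats_df$p95, window$high) * 1.05),
                 xlab = "Time within dosing interval (h)",
                 ylab = "Fluvoxamine plasma concentration (ng/mL)", ...)
  graphics::polygon(c(stats_df$time_h, rev(stats_df$time_h)),
                    c(stats_df$p5, rev(stats_df$p95)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(stats_df$time_h, stats_df$mean, lwd = 2, col = "steelblue4")
  graphics::abline(h = c(window$low, window$high), lty = 2)
  invisible(stats_df)
}
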