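#' Dosing regimen
#'
#' Oral doses at t = 0, tau, 2 tau, ...; twice-daily dosing means
#' `interval_h = 12`. The daily-dose scheme of the dosing studies maps 50 and
#' 100 mg/day to once daily and 150 and 200 mg/day to divided twice-daily
#' doses (75 and 100 mg every 12 h).
#'
#' @param dose_mg dose per administration, mg.
#' @param interval_h dosing interval, h.
#' @param n_doses number of administrations.
#' @param duration_h simulated duration (default `n_doses * interval_h`);
#'   extend it for single-dose designs that need a long terminal phase.
#' @return An object of class `fv_regimen`.
#' @export
dose_regimen <- function(dose_mg, interval_h = 24, n_doses = 1,
                         duration_h = NULL) {
  stopifnot(dose_mg >= 0, interval_h > 0, n_doses >= 1) # 0 = null-input control
  if (is.null(duration_h)) duration_h <- n_doses * interval_h
  if (duration_h < (n_doses - 1) * interval_h + interval_h)
    stop("duration_h must cover the last dosing interval")
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = as.integer(n_doses), duration_h = duration_h,
                 route = "oral"),
            class = "fv_regimen")
}

#' Map a total daily dose to the study regimen
#'
#' 50 and 100 mg/day are once daily; 150 and 200 mg/day are given as two
#' divided doses (75 and 100 mg every 12 h). The exposure window follows the
#' interval: AUC(0-24) for once-daily, AUC(0-12) for twice-daily regimens.
#'
#' @param daily_dose_mg total daily dose, mg.
#' @param days number of days of dosing (default 14, beyond 10 elimination
#'   half-lives even for elderly PMs).
#' @return An `fv_regimen`.
#' @export
regimen_for_daily_dose <- function(daily_dose_mg, days = 14) {
  stopifnot(daily_dose_mg > 0, days >= 1)
  if (daily_dose_mg > 100)
    dose_regimen(daily_dose_mg / 2, interval_h = 12, n_doses = 2 * days)
  else
    dose_regimen(daily_dose_mg, interval_h = 24, n_doses = days)
}

#' Solver settings
#'
#' @param rel_tol,abs_tol integrator tolerances (`abs_tol` in ng of compound).
#' @param output_grid_h sampling step of the returned profile, h.
#' @param max_sim_days cap on simulated duration.
#' @param ss_convergence_tol fractional change in interval AUC below which the
#'   final dosing interval is accepted as steady state.
#' @return An object of class `fv_solver`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-2,
                            output_grid_h = 0.25, max_sim_days = 14,
                            ss_convergence_tol = 0.05) {
  stopifnot(rel_tol > 0, abs_tol > 0, output_grid_h > 0,
            max_sim_days > 0, ss_convergence_tol > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 output_grid_h = output_grid_h, max_sim_days = max_sim_days,
                 ss_convergence_tol = ss_convergence_tol),
            class = "fv_solver")
}

#' Simulate a plasma concentration-time profile for one subject
#'
#' Integrates the minimal PBPK system: a gut depot with first-order absorption
#' (each dose enters as fa fg fh x dose, i.e. first-pass loss is applied as a
#' dose-availability multiplier), a central compartment of volume
#' (Vss - Vsac) x weight exchanging with a peripheral compartment of volume
#' Vsac x weight at the inter-compartmental clearance Q, and elimination from
#' the central compartment at the hepatic blood clearance (converted to plasma
#' terms via the blood-to-plasma ratio) plus any renal clearance. In saturable
#' mode the CYP2D6 share of intrinsic clearance is concentration-dependent,
#' CLint,2D6(C) = CLint,2D6 x Km / (Km + Cu), with Cu the unbound plasma
#' concentration in uM, re-wrapped in the well-stirred model at every step;
#' the dose-availability multiplier keeps its linear-limit value.
#'
#' @param subject one-row subject data frame (a row of an `fv_population`).
#' @param compound a calibrated `fv_compound`.
#' @param clearances the matching one-row `fv_clearances`.
#' @param regimen an `fv_regimen`.
#' @param settings an `fv_solver`.
#' @param saturable logical; use Michaelis-Menten CYP2D6 elimination.
#' @return A data frame of class `fv_profile` with columns `time_h` and
#'   `conc_ng_ml`, and attributes `dose_times`, `interval_h`, `vc_ml`.
#' @export
simulate_profile <- function(subject, compound, clearances, regimen,
                             settings = solver_settings(),
                             saturable = FALSE) {
  stopifnot(nrow(subject) == 1, nrow(clearances) == 1)
  validate_compound(compound)
  if (regimen$duration_h > settings$max_sim_days * 24)
    stop("regimen duration exceeds max_sim_days")
  ds <- compound$distribution
  vc_ml <- (ds$vss_L_kg - ds$vsac_L_kg) * subject$weight * 1000
  vp_ml <- ds$vsac_L_kg * subject$weight * 1000
  q_ml <- ds$q_inter_L_h * 1000
  bp <- compound$bp_ratio
  renal_ml <- compound$elimination$renal_cl_L_h * 1000
  ka <- compound$absorption$ka_per_h
  fafgfh <- compound$absorption$fa * compound$absorption$fg * clearances$fh
  dose_ng <- regimen$dose_mg * 1e6 * fafgfh
  dose_times <- seq(0, by = regimen$interval_h,
                    length.out = regimen$n_doses)

  if (!saturable) {
    cl_ml <- clearances$cl_hepatic_blood * bp * 1000 + renal_ml
    deriv <- function(t, y, p) {
      cc <- y[2] / vc_ml
      cp <- y[3] / vp_ml
      list(c(-ka * y[1],
             ka * y[1] - q_ml * (cc - cp) - cl_ml * cc,
             q_ml * (cc - cp)))
    }
  } else {
    km <- km_ng_ml(compound) # Km as unbound plasma concentration, ng/mL
    clint_2d6 <- clearances$clint_2d6_u
    clint_add <- clearances$clint_add_u
    fub <- clearances$fu_b
    qh <- subject$q_hepatic
    fup <- compound$fup
    deriv <- function(t, y, p) {
      cc <- y[2] / vc_ml
      cp <- y[3] / vp_ml
      cu <- fup * cc
      clint <- clint_2d6 * km / (km + cu) + clint_add
      clh <- qh * fub * clint / (qh + fub * clint)
      list(c(-ka * y[1],
             ka * y[1] - q_ml * (cc - cp) - (clh * bp * 1000 + renal_ml) * cc,
             q_ml * (cc - cp)))
    }
  }

  times <- seq(0, regimen$duration_h, by = settings$output_grid_h)
  events <- data.frame(var = "gut", time = dose_times, value = dose_ng,
                       method = "add")
  out <- try(deSolve::lsoda(c(gut = 0, central = 0, peripheral = 0),
                            times, deriv, parms = NULL,
                            rtol = settings$rel_tol, atol = settings$abs_tol,
                            events = list(data = events)),
             silent = TRUE)
  istate <- if (inherits(out, "try-error")) -1L else attr(out, "istate")[1]
  if (inherits(out, "try-error") || istate < 0 || nrow(out) < length(times))
    stop(sprintf("solver failed for subject %s under %g mg q%gh",
                 subject$subject, regimen$dose_mg, regimen$interval_h))
  conc <- pmax(out[, "central"] / vc_ml, 0)
  prof <- data.frame(time_h = out[, "time"], conc_ng_ml = conc)
  structure(prof, class = c("fv_profile", "data.frame"),
            dose_times = dose_times, interval_h = regimen$interval_h,
            vc_ml = vc_ml,
            amounts = data.frame(time_h = out[, "time"],
                                 gut = out[, "gut"],
                                 central = out[, "central"],
                                 peripheral = out[, "peripheral"]),
            dose_ng = dose_ng,
            subject = subject$subject)
}

#' Extract the final (steady-state) dosing interval
#'
#' Returns the last complete dosing interval of a multiple-dose profile.
#' If the interval AUC still differs from the preceding interval's by more
#' than the solver's `ss_convergence_tol`, a warning is raised (steady state
#' not attained), not an error.
#'
#' @param profile an `fv_profile` from a multiple-dose simulation.
#' @param interval_h dosing interval (defaults to the profile's attribute).
#' @param settings an `fv_solver` (for the convergence tolerance).
#' @return An `fv_profile` restricted to the final interval, with attribute
#'   `window` = c(start, end) and `converged` (logical).
#' @export
steady_state_window <- function(profile, interval_h = attr(profile, "interval_h"),
                                settings = solver_settings()) {
  t_end <- max(profile$time_h)
  if (t_end < 2 * interval_h)
    stop("profile must span at least 2 complete dosing intervals")
  w1 <- c(t_end - interval_h, t_end)
  w0 <- w1 - interval_h
  auc1 <- auc_trapezoid(profile, w1[1], w1[2])
  auc0 <- auc_trapezoid(profile, w0[1], w0[2])
  converged <- abs(auc1 - auc0) <= settings$ss_convergence_tol * auc0
  if (!converged)
    warning(sprintf("interval AUC still changing by %.1f%%: steady state not attained",
                    100 * abs(auc1 / auc0 - 1)))
  keep <- profile$time_h >= w1[1] & profile$time_h <= w1[2]
  out <- profile[keep, , drop = FALSE]
  attrs <- attributes(profile)
  for (a in setdiff(names(attrs), c("names", "row.names", "class")))
    attr(out, a) <- attrs[[a]]
  attr(out, "window") <- w1
  attr(out, "converged") <- converged
  out
}

#' Simulate a population and summarize per-subject exposure metrics
#'
#' Runs the ODE engine for every subject of a population under one regimen and
#' returns per-subject Cmax, Cmin and AUC on the requested window.
#'
#' Windows: `"auto"` uses the final dosing interval for multiple-dose regimens
#' (steady state; tag `0-24` or `0-12` by interval) and full-profile AUC with
#' terminal extrapolation (`0-inf`) for single doses; `"0-24"`, `"0-12"`,
#' `"0-96"` are fixed windows from time zero; `"0-inf"` forces extrapolation.
#' For steady-state windows Cmin is the end-of-interval (pre-dose) trough; for
#' single-dose windows it is the concentration at the window end.
#'
#' @param pop an `fv_population`.
#' @param compound a calibrated `fv_compound`.
#' @param aging an `fv_aging` model.
#' @param regimen an `fv_regimen`.
#' @param window one of `"auto"`, `"0-12"`, `"0-24"`, `"0-96"`, `"0-inf"`.
#' @param settings an `fv_solver`.
#' @param saturable logical, passed to [simulate_profile()].
#' @return A data frame (class `fv_metrics`): trial, subject, phenotype, age,
#'   cmax, cmin, auc, plus the window tag as attribute `window`.
#' @export
population_metrics <- function(pop, compound, aging, regimen,
                               window = "auto",
                               settings = solver_settings(),
                               saturable = FALSE) {
  window <- match.arg(window, c("auto", "0-12", "0-24", "0-96", "0-inf"))
  multi <- regimen$n_doses > 1
  if (window == "auto")
    window <- if (multi) paste0("0-", regimen$interval_h) else "0-inf"
  cl <- whole_liver_clint(pop, compound, aging)
  n <- nrow(pop)
  cmax <- cmin <- auc <- numeric(n)
  for (i in seq_len(n)) {
    prof <- simulate_profile(pop[i, , drop = FALSE], compound,
                             cl[i, , drop = FALSE], regimen, settings,
                             saturable = saturable)
    if (multi) {
      wnd <- steady_state_window(prof, regimen$interval_h, settings)
      tp <- trough_and_peak(wnd)
      cmax[i] <- tp$cmax
      cmin[i] <- tp$cmin
      w <- attr(wnd, "window")
      auc[i] <- auc_trapezoid(prof, w[1], w[2])
    } else {
      cmax[i] <- max(prof$conc_ng_ml)
      if (window == "0-inf") {
        auc[i] <- suppressWarnings(auc_to_infinity(prof))
        cmin[i] <- prof$conc_ng_ml[nrow(prof)]
      } else {
        t1 <- as.numeric(sub("0-", "", window))
        auc[i] <- auc_trapezoid(prof, 0, t1)
        cmin[i] <- stats::approx(prof$time_h, prof$conc_ng_ml, t1)$y
      }
    }
  }
  structure(data.frame(trial = pop$trial, subject = pop$subject,
                       phenotype = pop$phenotype, age = pop$age,
                       cmax = cmax, cmin = cmin, auc = auc),
            class = c("fv_metrics", "data.frame"), window = window)
}
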