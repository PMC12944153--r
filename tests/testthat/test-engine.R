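engine_compound <- function(clint_add = 40, scalar = 3, ...) {
  fluvoxamine_compound(clint_additional = clint_add, cyp2d6_scalar = scalar, ...)
}

test_that("zero dose yields an identically zero profile", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  prof <- simulate_profile(subj, cpd, cl, dose_regimen(0, n_doses = 3,
                                                       interval_h = 24))
  expect_true(all(prof$conc_ng_ml == 0))
})

test_that("IV-like limit matches the one-compartment closed form within 0.5%", {
  # very fast absorption, no first-pass, negligible peripheral exchange
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cpd$absorption$ka_per_h <- 500
  cpd$distribution$q_inter_L_h <- 1e-9
  cl <- whole_liver_clint(subj, cpd)
  cl$fh <- 1
  reg <- dose_regimen(100, n_doses = 1, duration_h = 96)
  prof <- simulate_profile(subj, cpd, cl, reg)
  v_ml <- 15 * 70 * 1000
  cl_ml <- cl$cl_hepatic_blood * 1.5 * 1000
  auc_engine <- auc_trapezoid(prof, 0, 96) +
    prof$conc_ng_ml[nrow(prof)] * v_ml / cl_ml # analytic tail of the 1-cpt decay
  expect_equal(auc_engine, 100e6 / cl_ml, tolerance = 0.005)
  # profile shape matches the closed form pointwise
  oracle <- one_cpt_oral_conc(prof$time_h, 100e6, 1, 500, cl_ml, v_ml)
  expect_lt(max(abs(prof$conc_ng_ml[-1] - oracle[-1]) / max(oracle)), 0.005)
})

test_that("engine reproduces the linear three-state closed form", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  reg <- dose_regimen(100, interval_h = 24, n_doses = 5)
  prof <- simulate_profile(subj, cpd, cl, reg)
  oracle <- linear3_profile(prof$time_h, cpd$absorption$ka_per_h,
                            15 * 70 * 1000, 6 * 70 * 1000, 0.5 * 1000,
                            cl$cl_hepatic_blood * 1.5 * 1000,
                            attr(prof, "dose_ng"), attr(prof, "dose_times"))
  expect_lt(max(abs(prof$conc_ng_ml - oracle)) / max(oracle), 0.005)
})

test_that("exposure is dose-proportional in the linear regime", {
  subj <- synthetic_subject(age = 75)
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  m50 <- population_metrics(subj, cpd, aging_model(), regimen_for_daily_dose(50))
  m100 <- population_metrics(subj, cpd, aging_model(), regimen_for_daily_dose(100))
  expect_equal(m100$auc / m50$auc, 2, tolerance = 0.02)
  expect_equal(m100$cmax / m50$cmax, 2, tolerance = 0.02)
  expect_equal(m100$cmin / m50$cmin, 2, tolerance = 0.02)
})

test_that("saturable and linear modes agree within 3% at the highest dose", {
  fit <- test_fit()
  subj <- synthetic_subject(age = 75)
  cl <- whole_liver_clint(subj, fit$compound, fit$aging)
  reg <- regimen_for_daily_dose(200) # 100 mg q12h, the highest studied dose
  lin <- simulate_profile(subj, fit$compound, cl, reg, fit$settings,
                          saturable = FALSE)
  sat <- simulate_profile(subj, fit$compound, cl, reg, fit$settings,
                          saturable = TRUE)
  w <- c(max(lin$time_h) - 12, max(lin$time_h))
  auc_lin <- auc_trapezoid(lin, w[1], w[2])
  auc_sat <- auc_trapezoid(sat, w[1], w[2])
  expect_lt(abs(auc_sat / auc_lin - 1), 0.03)
  expect_gte(auc_sat, auc_lin) # saturation can only slow elimination
})

test_that("mass balance holds along the whole profile", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  prof <- simulate_profile(subj, cpd, cl, dose_regimen(100, 24, 5))
  am <- attr(prof, "amounts")
  # sampled states at a dose instant are pre-dose: count doses strictly before
  dosed <- attr(prof, "dose_ng") *
    findInterval(am$time_h, attr(prof, "dose_times"), left.open = TRUE)
  in_body <- am$gut + am$central + am$peripheral
  expect_true(all(in_body <= dosed + 1e-6 * max(dosed)))
  eliminated <- dosed - in_body
  expect_true(all(diff(eliminated) > -1e-6 * max(dosed)))
})

test_that("profiles are non-negative, start at zero and are seed-free deterministic", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  reg <- dose_regimen(50, 12, 28)
  p1 <- simulate_profile(subj, cpd, cl, reg)
  p2 <- simulate_profile(subj, cpd, cl, reg)
  expect_identical(p1$conc_ng_ml, p2$conc_ng_ml)
  expect_true(all(p1$conc_ng_ml >= 0))
  expect_equal(p1$conc_ng_ml[1], 0)
})

test_that("steady-state window reproduces the one-compartment accumulation index", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cpd$distribution$q_inter_L_h <- 1e-9 # detach the peripheral compartment
  cl <- whole_liver_clint(subj, cpd)
  tau <- 24
  reg <- dose_regimen(100, tau, 14)
  prof <- simulate_profile(subj, cpd, cl, reg)
  wnd <- steady_state_window(prof, tau)
  expect_true(attr(wnd, "converged"))
  v_ml <- 15 * 70 * 1000
  cl_ml <- cl$cl_hepatic_blood * 1.5 * 1000
  k <- cl_ml / v_ml
  # accumulation index on the trough: Cmin_ss / Cmin_single = 1/(1 - e^-k tau)
  cmin_single <- stats::approx(prof$time_h, prof$conc_ng_ml, tau)$y
  racc <- 1 / (1 - exp(-k * tau))
  expect_equal(trough_and_peak(wnd)$cmin / cmin_single, racc, tolerance = 0.01)
  # and the SS extremes match the superposition closed form
  ora <- one_cpt_ss_cmax_cmin(attr(prof, "dose_ng"), 1,
                              cpd$absorption$ka_per_h, cl_ml, v_ml, tau)
  tp <- trough_and_peak(wnd)
  expect_equal(tp$cmax, ora$cmax, tolerance = 0.01)
  expect_equal(tp$cmin, ora$cmin, tolerance = 0.01)
})

test_that("steady-state window validates its input and flags non-convergence", {
  subj <- synthetic_subject()
  cpd <- engine_compound()
  cl <- whole_liver_clint(subj, cpd)
  single <- simulate_profile(subj, cpd, cl, dose_regimen(100, 24, 1))
  expect_error(steady_state_window(single, 24), "2 complete dosing intervals")
  # a periodic profile is already at steady state: equal window AUCs, no warning
  tt <- seq(0, 96, by = 0.25)
  periodic <- data.frame(time_h = tt, conc_ng_ml = 50 + 10 * sin(2 * pi * tt / 24))
  expect_silent(wnd <- steady_state_window(periodic, 24))
  expect_equal(auc_trapezoid(periodic, 48, 72), auc_trapezoid(periodic, 72, 96),
               tolerance = 1e-9)
  # truncating dosing far from steady state raises the warning
  short <- simulate_profile(subj, cpd, cl, dose_regimen(100, 24, 3))
  expect_warning(steady_state_window(short, 24,
                                     solver_settings(ss_convergence_tol = 1e-4)),
                 "steady state")
})

test_that("elderly 14-day regimens reach the steady-state convergence criterion", {
  fit <- test_fit()
  subj <- synthetic_subject(age = 85, abundance = 8 * 4 / 11, phenotype = "IM")
  cl <- whole_liver_clint(subj, fit$compound, fit$aging)
  prof <- simulate_profile(subj, fit$compound, cl, regimen_for_daily_dose(100),
                           fit$settings)
  wnd <- steady_state_window(prof, 24, fit$settings)
  expect_true(attr(wnd, "converged"))
})

test_that("regimen construction validates and maps daily doses to the dosing scheme", {
  r50 <- regimen_for_daily_dose(50)
  expect_equal(r50$dose_mg, 50)
  expect_equal(r50$interval_h, 24)
  r150 <- regimen_for_daily_dose(150)
  expect_equal(r150$dose_mg, 75)
  expect_equal(r150$interval_h, 12)
  expect_equal(r150$n_doses, 28L)
  expect_error(dose_regimen(50, -1), "interval_h")
  expect_error(dose_regimen(50, 24, 2, duration_h = 24), "duration")
})
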