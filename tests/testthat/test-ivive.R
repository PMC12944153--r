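calibrated_compound <- function(clint_add = 0, scalar = 1) {
  fluvoxamine_compound(clint_additional = clint_add, cyp2d6_scalar = scalar)
}

test_that("enzyme-level intrinsic clearance is the linear Michaelis-Menten limit", {
  expect_equal(clint_per_pmol(70, 38.6), 70 / 38.6, tolerance = 1e-12)
  expect_equal(clint_per_pmol(1, 1), 1)
  expect_equal(clint_per_pmol(140, 38.6), 2 * clint_per_pmol(70, 38.6))
})

test_that("whole-liver scaling reproduces the hand-computed reference subject", {
  subj <- synthetic_subject(abundance = 8, activity = 1)
  cl <- whole_liver_clint(subj, calibrated_compound())
  # (70/38.6) uL/min/pmol x 8 pmol/mg x 40 mg/g x 1650 g -> L/h
  expect_equal(cl$clint_2d6_u, (70 / 38.6) * 8 * 40 * 1650 * 60 / 1e6,
               tolerance = 1e-9)
  expect_equal(cl$clint_2d6_u, 57.45, tolerance = 1e-3)
  expect_equal(cl$clint_add_u, 0)
  expect_equal(cl$fm_2d6, 1)
})

test_that("whole-liver clearance is linear in each scaling factor and zero for PMs", {
  cpd <- calibrated_compound(clint_add = 10)
  base <- whole_liver_clint(synthetic_subject(), cpd)
  dbl_ab <- whole_liver_clint(synthetic_subject(abundance = 16), cpd)
  expect_equal(dbl_ab$clint_2d6_u, 2 * base$clint_2d6_u)
  s2 <- synthetic_subject()
  s2$mppgl <- 80
  expect_equal(whole_liver_clint(s2, cpd)$clint_total_u, 2 * base$clint_total_u)
  s3 <- synthetic_subject()
  s3$liver_mass <- 825
  expect_equal(whole_liver_clint(s3, cpd)$clint_total_u, base$clint_total_u / 2)
  pm <- synthetic_subject(abundance = 0, phenotype = "PM")
  expect_equal(whole_liver_clint(pm, cpd)$clint_2d6_u, 0)
  expect_gt(whole_liver_clint(pm, cpd)$clint_total_u, 0)
})

test_that("well-stirred model honours its flow and clearance limits", {
  ws0 <- wellstirred(90, 0.0933, 0)
  expect_equal(ws0$cl_hepatic_blood, 0)
  expect_equal(ws0$fh, 1)
  wsinf <- wellstirred(90, 0.0933, 1e9)
  expect_equal(wsinf$cl_hepatic_blood, 90, tolerance = 1e-5)
  expect_lt(wsinf$fh, 1e-5)
  ws <- wellstirred(90, 0.0933, 500)
  expect_lt(ws$cl_hepatic_blood, 90)
  expect_equal(ws$cl_hepatic_blood, 90 * 0.0933 * 500 / (90 + 0.0933 * 500))
})

test_that("geriatric activity scalar multiplies both pathways for elderly subjects only", {
  cpd <- calibrated_compound(clint_add = 10)
  aging <- aging_model(activity_scalar = 0.5)
  old <- synthetic_subject(age = 75)
  young <- synthetic_subject(age = 30)
  cl_old <- whole_liver_clint(old, cpd, aging)
  cl_young <- whole_liver_clint(young, cpd, aging)
  expect_equal(cl_old$clint_total_u, 0.5 * cl_young$clint_total_u)
  expect_equal(cl_old$fm_2d6, cl_young$fm_2d6) # split untouched
})

test_that("fm inversion matches a brute-force scan of the well-stirred fold", {
  expect_equal(fm_from_ratio(2.1), 1 - 1 / 2.1, tolerance = 1e-12)
  expect_equal(fm_from_ratio(1), 0)
  # brute force: scan fm, compute the PM/EM fold 1/(1-fm), invert
  grid <- seq(0, 0.99, by = 1e-4)
  folds <- 1 / (1 - grid)
  best <- grid[which.min(abs(folds - 2.1))]
  expect_equal(fm_from_ratio(2.1), best, tolerance = 1e-4)
  # residual PM activity shifts the required fm up
  expect_equal(fm_from_ratio(2.1, a_pm = 0.1), (1 - 1 / 2.1) / 0.9)
  expect_error(fm_from_ratio(0.8), "ratio")
})

test_that("oral steady-state exposure obeys the well-stirred AUC identity", {
  # engine AUC(0-inf) must equal fa fg D / (fup CLint) in the linear regime;
  # a faster-equilibrating peripheral compartment keeps the NCA tail
  # truncation below the identity tolerance
  cpd <- calibrated_compound(clint_add = 40, scalar = 3)
  cpd$distribution$q_inter_L_h <- 50
  for (ab in c(4, 8, 16)) {
    subj <- synthetic_subject(abundance = ab)
    cl <- whole_liver_clint(subj, cpd)
    reg <- dose_regimen(100, n_doses = 1, duration_h = 240)
    prof <- simulate_profile(subj, cpd, cl, reg,
                             solver_settings(max_sim_days = 14))
    auc <- suppressWarnings(auc_to_infinity(prof))
    analytic <- 1 * 1 * 100e6 / (0.14 * cl$clint_total_u * 1000)
    expect_equal(as.numeric(auc), analytic, tolerance = 0.02)
  }
})

test_that("hepatic clearance rises and exposure falls with abundance", {
  cpd <- calibrated_compound(clint_add = 20)
  abs_seq <- c(2, 4, 8, 16, 32)
  cls <- sapply(abs_seq, function(ab)
    whole_liver_clint(synthetic_subject(abundance = ab), cpd)$cl_hepatic_blood)
  expect_true(all(diff(cls) > 0))
  aucs <- sapply(abs_seq, function(ab) {
    subj <- synthetic_subject(abundance = ab)
    cl <- whole_liver_clint(subj, cpd)
    prof <- simulate_profile(subj, cpd, cl, dose_regimen(50, n_doses = 1,
                                                         duration_h = 96))
    auc_trapezoid(prof, 0, 96)
  })
  expect_true(all(diff(aucs) < 0))
})

test_that("elimination calibration hits the single-dose AUC anchor", {
  cal <- calibrate_elimination(seed = 11, n_trials = 5, subjects_per_trial = 10)
  expect_equal(cal$fm, 1 - 1 / 2.1, tolerance = 1e-12)
  expect_lt(abs(cal$residual), 0.01)
  expect_equal(cal$sim_auc, 1308, tolerance = 0.011)
  expect_gt(cal$clint_additional, 0)
  # the calibrated compound carries the fm split
  subj <- synthetic_subject()
  expect_equal(whole_liver_clint(subj, cal$compound)$fm_2d6, cal$fm,
               tolerance = 1e-9)
  expect_error(calibrate_elimination(pm_em_ratio = 0.9), "infeasible")
  expect_error(calibrate_elimination(observed_auc = -5), "infeasible")
})

test_that("aging calibration reaches the target clearance fraction", {
  cal <- calibrate_elimination(seed = 11, n_trials = 5, subjects_per_trial = 10)
  acal <- calibrate_aging(cal$compound, target_cl_fraction = 0.5, seed = 11,
                          n_trials = 20)
  expect_lt(abs(acal$achieved_ratio - 0.5), 0.01)
  expect_true(acal$scalar > 0 && acal$scalar < 1)
  # with no physiological decline, a target of 1 needs no geriatric effect
  flat <- aging_model(liver_mass_decline = 0, flow_decline = 0)
  acal1 <- calibrate_aging(cal$compound, flat, target_cl_fraction = 1,
                           seed = 11, n_trials = 20)
  expect_equal(acal1$scalar, 1, tolerance = 0.02)
  expect_error(calibrate_aging(cal$compound, target_cl_fraction = 0),
               "target_cl_fraction")
  expect_error(calibrate_aging(cal$compound, target_cl_fraction = 0.5,
                               bounds = c(2, 3)), "no aging scalar")
})

test_that("calibration report JSON carries the fitted constants", {
  cal <- calibrate_elimination(seed = 11, n_trials = 5, subjects_per_trial = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$fm, cal$fm, tolerance = 1e-9)
  expect_equal(x$clint_additional_uL_min_mg, cal$clint_additional,
               tolerance = 1e-9)
})
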