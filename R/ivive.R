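#' Intrinsic clearance per pmol of enzyme
#'
#' Low-concentration (linear) limit of Michaelis-Menten kinetics:
#' CLint = Vmax / Km, in uL/min/pmol enzyme when Vmax is in pmol/min/pmol and
#' Km in uM (pmol/uL).
#'
#' @param vmax maximum metabolic rate, pmol/min/pmol enzyme.
#' @param km Michaelis constant, uM.
#' @return Intrinsic clearance, uL/min/pmol.
#' @examples
#' clint_per_pmol(70, 38.6) # about 1.813
#' @export
clint_per_pmol <- function(vmax, km) {
  stopifnot(vmax > 0, km > 0)
  vmax / km
}

#' Well-stirred liver model
#'
#' Hepatic blood clearance and availability:
#' CLh = Q fu_b CLint / (Q + fu_b CLint), Fh = Q / (Q + fu_b CLint).
#'
#' @param q_hepatic hepatic blood flow, L/h.
#' @param fu_b fraction unbound in blood.
#' @param clint_u unbound intrinsic clearance, L/h.
#' @return A list with `cl_hepatic_blood` (L/h) and `fh`.
#' @export
wellstirred <- function(q_hepatic, fu_b, clint_u) {
  stopifnot(all(q_hepatic > 0), all(fu_b > 0), all(clint_u >= 0))
  denom <- q_hepatic + fu_b * clint_u
  list(cl_hepatic_blood = q_hepatic * fu_b * clint_u / denom,
       fh = q_hepatic / denom)
}

# uL/min total over the liver -> L/h
.uLmin_to_Lh <- 60 / 1e6

#' Whole-liver intrinsic clearance and hepatic clearance per subject
#'
#' Scales enzyme-level kinetics to the whole liver:
#' CLint(CYP2D6) = (Vmax/Km) x scalar x abundance x MPPGL x liver mass, and
#' the lumped non-CYP2D6 pathway CLint = clint_additional x activity x MPPGL x
#' liver mass (the subject's shared hepatic activity deviate scales both
#' pathways; for CYP2D6 it is already contained in the sampled abundance).
#' The geriatric activity scalar of the aging model multiplies the total for
#' subjects at/above the geriatric age. Hepatic blood clearance and
#' availability follow from the well-stirred model, and the apparent oral
#' plasma clearance is fup x CLint_total / (fa fg).
#'
#' @param pop an `fv_population` (or any data frame with the same columns).
#' @param compound a calibrated `fv_compound` (`clint_additional` set).
#' @param aging an `fv_aging` model supplying the geriatric activity scalar.
#' @return A data frame (class `fv_clearances`), one row per subject:
#'   clint_2d6_u, clint_add_u, clint_total_u, fm_2d6, fu_b, cl_hepatic_blood,
#'   fh, cl_oral_plasma (all clearances L/h).
#' @export
whole_liver_clint <- function(pop, compound, aging = aging_model()) {
  validate_compound(compound)
  ca <- compound$elimination$clint_additional_uL_min_mg
  if (is.na(ca))
    stop("compound is uncalibrated: run calibrate_elimination() or fit_fluvoxamine()")
  p <- compound$elimination$pathways$CYP2D6
  geri_fac <- ifelse(pop$age >= aging$geriatric_age, aging$activity_scalar, 1)
  per_mg_2d6 <- clint_per_pmol(p$vmax_pmol_min_pmol, p$km_uM) * p$scalar *
    pop$cyp2d6_abundance                       # uL/min/mg
  scale_liver <- pop$mppgl * pop$liver_mass * .uLmin_to_Lh
  clint_2d6 <- per_mg_2d6 * scale_liver * geri_fac
  clint_add <- ca * pop$activity * scale_liver * geri_fac
  clint_tot <- clint_2d6 + clint_add
  fub <- fu_blood(compound)
  ws <- wellstirred(pop$q_hepatic, fub, clint_tot)
  fafg <- compound$absorption$fa * compound$absorption$fg
  out <- data.frame(
    subject = pop$subject,
    clint_2d6_u = clint_2d6,
    clint_add_u = clint_add,
    clint_total_u = clint_tot,
    fm_2d6 = ifelse(clint_tot > 0, clint_2d6 / clint_tot, 0),
    fu_b = fub,
    cl_hepatic_blood = ws$cl_hepatic_blood,
    fh = ws$fh,
    cl_oral_plasma = compound$fup * clint_tot / fafg
  )
  class(out) <- c("fv_clearances", "data.frame")
  out
}

#' Fraction metabolized by CYP2D6 from a PM/EM exposure ratio
#'
#' Inverts the well-stirred oral-exposure relation: if PMs retain a residual
#' CYP2D6 activity fraction `a_pm` of the EM level, the PM/EM AUC fold is
#' 1 / (1 - fm (1 - a_pm)), hence fm = (1 - 1/ratio) / (1 - a_pm).
#'
#' @param ratio PM/EM oral AUC fold (> 1 for any CYP2D6 contribution).
#' @param a_pm residual PM activity as a fraction of EM (default 0).
#' @return fm, the fraction of intrinsic clearance via CYP2D6 in EMs.
#' @examples
#' fm_from_ratio(2.1) # 0.5238
#' @export
fm_from_ratio <- function(ratio, a_pm = 0) {
  stopifnot(ratio >= 1, a_pm >= 0, a_pm < 1)
  (1 - 1 / ratio) / (1 - a_pm)
}

#' Calibrate the elimination model against clinical anchors
#'
#' Two-step calibration of the unknowns of the elimination model:
#' \enumerate{
#'   \item the CYP2D6 fraction metabolized `fm` is set analytically from the
#'     observed single-dose PM/EM AUC fold (default 2.1) via [fm_from_ratio()];
#'   \item the absolute scale of total intrinsic clearance is found by a 1-D
#'     search so that the simulated population-mean single-dose AUC(0-inf) in
#'     a design matching the 100 mg single-dose reference study (uniform-EM
#'     males aged 24-30) matches the observed mean (default 1308 ng.h/mL)
#'     within 1%. Because AUC is inversely proportional to the clearance scale
#'     in the linear regime, the search is a secant iteration that converges
#'     in about two simulation rounds.
#' }
#' The scale is then split into a scalar on the CYP2D6 pathway and the lumped
#' non-CYP2D6 `clint_additional` so that the EM-population fm equals the
#' calibrated value.
#'
#' @param compound an `fv_compound` (defaults used as the starting point).
#' @param observed_auc observed mean single-dose AUC(0-inf), ng.h/mL.
#' @param pm_em_ratio observed single-dose PM/EM AUC fold.
#' @param a_pm residual PM CYP2D6 activity fraction.
#' @param seed seed for the calibration population.
#' @param n_trials,subjects_per_trial calibration population structure.
#' @param aging aging model (inert here: the calibration population is young).
#' @param settings solver settings.
#' @return A list of class `fv_calibration`: the calibrated `compound`, `fm`,
#'   `cyp2d6_scalar`, `clint_additional`, the simulated anchor AUC, the
#'   relative residual, and the iteration count.
#' @export
calibrate_elimination <- function(compound = fluvoxamine_compound(),
                                  observed_auc = 1308,
                                  pm_em_ratio = 2.1,
                                  a_pm = 0,
                                  seed = 1L,
                                  n_trials = 10, subjects_per_trial = 10,
                                  aging = aging_model(),
                                  settings = solver_settings()) {
  if (observed_auc <= 0) stop("infeasible anchor: observed AUC must be positive")
  if (pm_em_ratio < 1)
    stop("infeasible anchor: PM/EM ratio below 1 implies negative fm")
  fm <- fm_from_ratio(pm_em_ratio, a_pm)
  phen <- phenotype_params()
  per_mg_2d6_base <- clint_per_pmol(
    compound$elimination$pathways$CYP2D6$vmax_pmol_min_pmol,
    compound$elimination$pathways$CYP2D6$km_uM) * phen$means[["EM"]]

  spec <- population_spec(n_trials = n_trials,
                          subjects_per_trial = subjects_per_trial,
                          age_min = 24, age_max = 30, prop_female = 0,
                          phenotype_mode = "uniform_EM", seed = seed)
  pop <- build_population(spec, aging, phen)
  regimen <- dose_regimen(100, interval_h = 24, n_doses = 1, duration_h = 120)

  set_total <- function(total_per_mg) {
    cpd <- compound
    if (fm > 0)
      cpd$elimination$pathways$CYP2D6$scalar <- fm * total_per_mg / per_mg_2d6_base
    else
      cpd$elimination$pathways$CYP2D6$scalar <- 0
    cpd$elimination$clint_additional_uL_min_mg <- (1 - fm) * total_per_mg
    cpd
  }
  mean_auc <- function(cpd) {
    m <- population_metrics(pop, cpd, aging, regimen, window = "0-inf",
                            settings = settings)
    mean(m$auc)
  }

  total <- 30 # uL/min/mg starting guess (typical-magnitude hepatic CLint)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cpd <- set_total(total)
    m <- mean_auc(cpd)
    resid <- (m - observed_auc) / observed_auc
    if (abs(resid) < 0.01 || iter >= 8L) break
    total <- total * m / observed_auc # AUC scales as 1/CLint in the linear regime
  }
  if (abs(resid) > 0.05)
    stop(sprintf("calibration failed to reach the AUC anchor (residual %.1f%%)",
                 100 * resid))
  structure(list(compound = cpd,
                 fm = fm,
                 cyp2d6_scalar = cpd$elimination$pathways$CYP2D6$scalar,
                 clint_additional = cpd$elimination$clint_additional_uL_min_mg,
                 sim_auc = m,
                 observed_auc = observed_auc,
                 pm_em_ratio = pm_em_ratio,
                 residual = resid,
                 iterations = iter,
                 seed = seed),
            class = "fv_calibration")
}

#' Calibrate the geriatric activity scalar
#'
#' Tunes the single free aging scalar by a 1-D root find (`uniroot`) so that
#' the mean apparent oral clearance of a mixed-phenotype 65-98 y population is
#' `target_cl_fraction` times the 18-65 y mean, within 2%. Oral clearance is
#' available in closed form per subject (fup x CLint / fa fg), so no ODE
#' integration is needed here.
#'
#' @param compound a calibrated `fv_compound`.
#' @param aging starting `fv_aging` model (declines are kept; only the
#'   activity scalar is tuned).
#' @param target_cl_fraction target geriatric/younger mean clearance ratio in
#'   (0, 1\].
#' @param seed seed for the two calibration populations.
#' @param n_trials,subjects_per_trial population structure (default 40 x 10
#'   subjects for a stable mean; clearance-only, so cheap).
#' @param bounds search interval for the scalar.
#' @return A list of class `fv_aging_calibration`: the calibrated `aging`
#'   model, `scalar`, the achieved ratio, and the residual.
#' @export
calibrate_aging <- function(compound, aging = aging_model(),
                            target_cl_fraction = 0.5,
                            seed = 1L,
                            n_trials = 40, subjects_per_trial = 10,
                            bounds = c(0.02, 5)) {
  if (!(target_cl_fraction > 0 && target_cl_fraction <= 1))
    stop("target_cl_fraction must be in (0, 1]")
  young <- build_population(
    population_spec(n_trials, subjects_per_trial, 18, 65, 0.5,
                    "default_mix", seed = seed), aging)
  old <- build_population(
    population_spec(n_trials, subjects_per_trial, 65, 98, 0.5,
                    "default_mix", seed = seed), aging)
  cl_young <- mean(whole_liver_clint(young, compound, aging)$cl_oral_plasma)
  ratio_at <- function(s) {
    ag <- aging
    ag$activity_scalar <- s
    mean(whole_liver_clint(old, compound, ag)$cl_oral_plasma) / cl_young
  }
  f <- function(s) ratio_at(s) - target_cl_fraction
  if (f(bounds[1]) * f(bounds[2]) > 0)
    stop("calibration error: no aging scalar in bounds reaches the target ",
         "clearance fraction ", target_cl_fraction,
         " (ratio spans ", signif(ratio_at(bounds[1]), 3), "-",
         signif(ratio_at(bounds[2]), 3), ")")
  root <- stats::uniroot(f, bounds, tol = 1e-6)
  ag <- aging
  ag$activity_scalar <- root$root
  achieved <- ratio_at(root$root)
  resid <- achieved / target_cl_fraction - 1
  if (abs(resid) > 0.02)
    stop("calibration error: aging scalar did not reach the target within 2%")
  structure(list(aging = ag, scalar = root$root,
                 achieved_ratio = achieved,
                 target = target_cl_fraction, residual = resid, seed = seed),
            class = "fv_aging_calibration")
}

#' Write a calibration report as JSON
#'
#' @param calibration an `fv_calibration` (and optionally the aging
#'   calibration) as returned by the calibrators or stored in a fitted model.
#' @param path output JSON path.
#' @param aging_calibration optional `fv_aging_calibration`.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibration, path, aging_calibration = NULL) {
  x <- list(
    fm = calibration$fm,
    cyp2d6_scalar = calibration$cyp2d6_scalar,
    clint_additional_uL_min_mg = calibration$clint_additional,
    auc_anchor = list(observed = calibration$observed_auc,
                      simulated = calibration$sim_auc,
                      residual = calibration$residual),
    pm_em_ratio_anchor = calibration$pm_em_ratio
  )
  if (!is.null(aging_calibration))
    x$aging <- list(scalar = aging_calibration$scalar,
                    target_cl_fraction = aging_calibration$target,
                    achieved_ratio = aging_calibration$achieved_ratio,
                    residual = aging_calibration$residual)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
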