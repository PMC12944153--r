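#' Fluvoxamine compound model
#'
#' Builds the fluvoxamine parameterization used throughout the package:
#' physicochemistry (MW 318.3 g/mol, logP 3, pKa 8.7 as a monoprotic base),
#' plasma binding (fup 0.14, blood-to-plasma ratio 1.5), first-order oral
#' absorption derived from effective intestinal permeability, a minimal PBPK
#' distribution model (Vss 21 L/kg, inter-compartmental clearance 0.5 L/h,
#' peripheral volume 6 L/kg) and CYP2D6 Michaelis-Menten elimination
#' (Vmax 70 pmol/min/pmol enzyme, Km 38.6 uM).
#'
#' The non-CYP2D6 intrinsic clearance (`clint_additional`, uL/min/mg microsomal
#' protein) and the scalar on the CYP2D6 pathway are unknown a priori and are
#' set by [calibrate_elimination()] (or [fit_fluvoxamine()]); until then
#' `clint_additional` is `NA` and simulation refuses to run.
#'
#' @param clint_additional non-CYP2D6 unbound intrinsic clearance, uL/min/mg
#'   microsomal protein. `NA` until calibrated.
#' @param cyp2d6_scalar dimensionless multiplier on the CYP2D6 pathway
#'   (absorbs the unknown absolute in-vivo abundance scale).
#' @param renal_cl renal clearance, L/h (fluvoxamine renal elimination is
#'   negligible; default 0).
#' @param fa,fg fraction absorbed and gut availability (defaults 1: high
#'   permeability base, near-complete absorption).
#' @param gut_radius_cm effective small-intestinal radius used to convert
#'   permeability to a first-order absorption rate.
#' @return An object of class `fv_compound` (a validated nested list).
#' @examples
#' cpd <- fluvoxamine_compound()
#' cpd$distribution$vss_L_kg     # 21
#' cpd$elimination$pathways$CYP2D6$km_uM  # 38.6
#' @export
fluvoxamine_compound <- function(clint_additional = NA_real_,
                                 cyp2d6_scalar = 1,
                                 renal_cl = 0,
                                 fa = 1, fg = 1,
                                 gut_radius_cm = 1.75) {
  peff <- 5.67e-4 # cm/s, predicted effective human intestinal permeability
  cpd <- structure(list(
    name = "fluvoxamine",
    mw_g_mol = 318.3,
    logp = 3,
    pka = 8.7,
    fup = 0.14,
    bp_ratio = 1.5,
    absorption = list(
      model = "first_order",
      fa = fa,
      fg = fg,
      ka_per_h = ka_from_peff(peff, gut_radius_cm),
      peff_cm_s = peff,
      # provenance only: the Papp -> Peff regression is not re-derived
      mdck_papp_cm_s = 31.7e-6,
      mdck_scalar = 1.3983
    ),
    distribution = list(
      vss_L_kg = 21,
      q_inter_L_h = 0.5,
      vsac_L_kg = 6
    ),
    elimination = list(
      pathways = list(
        CYP2D6 = list(enzyme = "CYP2D6",
                      vmax_pmol_min_pmol = 70,
                      km_uM = 38.6,
                      scalar = cyp2d6_scalar)
      ),
      clint_additional_uL_min_mg = clint_additional,
      renal_cl_L_h = renal_cl
    )
  ), class = "fv_compound")
  validate_compound(cpd)
  cpd
}

validate_compound <- function(cpd) {
  stopifnot(inherits(cpd, "fv_compound"))
  if (!(cpd$mw_g_mol > 0)) stop("molecular weight must be positive")
  if (!(cpd$fup > 0 && cpd$fup <= 1)) stop("fup must be in (0, 1]")
  if (!(cpd$bp_ratio > 0)) stop("blood-to-plasma ratio must be positive")
  ab <- cpd$absorption
  if (!(ab$fa > 0 && ab$fa <= 1)) stop("fa must be in (0, 1]")
  if (!(ab$fg > 0 && ab$fg <= 1)) stop("fg must be in (0, 1]")
  if (!(ab$ka_per_h > 0)) stop("ka must be positive")
  ds <- cpd$distribution
  if (!(ds$vss_L_kg > ds$vsac_L_kg && ds$vsac_L_kg > 0))
    stop("distribution volumes must satisfy vss > vsac > 0")
  if (!(ds$q_inter_L_h > 0)) stop("inter-compartmental clearance must be positive")
  p <- cpd$elimination$pathways$CYP2D6
  if (!(p$vmax_pmol_min_pmol > 0 && p$km_uM > 0)) stop("Vmax and Km must be positive")
  if (p$scalar < 0) stop("CYP2D6 pathway scalar must be non-negative")
  ca <- cpd$elimination$clint_additional_uL_min_mg
  if (!is.na(ca) && ca < 0) stop("clint_additional must be non-negative")
  invisible(cpd)
}

#' First-order absorption rate from effective intestinal permeability
#'
#' Uses the cylindrical-gut relation ka = 2 Peff / R, converted from per-second
#' to per-hour.
#'
#' @param peff_cm_s effective human intestinal permeability, cm/s.
#' @param radius_cm effective intestinal radius, cm.
#' @return Absorption rate constant, 1/h.
#' @examples
#' ka_from_peff(5.67e-4, 1.75) # about 2.33 per hour
#' @export
ka_from_peff <- function(peff_cm_s, radius_cm) {
  if (!(is.numeric(peff_cm_s) && peff_cm_s > 0))
    stop("peff must be positive")
  if (!(is.numeric(radius_cm) && radius_cm > 0))
    stop("radius must be positive")
  2 * peff_cm_s / radius_cm * 3600
}

#' Unbound fraction in blood
#'
#' fu_blood = fup / (B/P): the unbound fraction referenced to whole blood,
#' the binding term entering the well-stirred liver model.
#'
#' @param compound an `fv_compound`.
#' @return Fraction unbound in blood.
#' @examples
#' fu_blood(fluvoxamine_compound()) # 0.14 / 1.5
#' @export
fu_blood <- function(compound) {
  validate_compound(compound)
  compound$fup / compound$bp_ratio
}

#' Km expressed as an unbound plasma concentration in ng/mL
#' @param compound an `fv_compound`.
#' @return Km in ng/mL (Km_uM x MW).
#' @keywords internal
km_ng_ml <- function(compound) {
  compound$elimination$pathways$CYP2D6$km_uM * compound$mw_g_mol
}

#' Write / read a compound definition as YAML
#'
#' Round-trip serialization of the compound block; all units are explicit in
#' the field names.
#'
#' @param compound an `fv_compound`.
#' @param path file path of the YAML document.
#' @return `write_compound_yaml` returns `path` invisibly;
#'   `read_compound_yaml` returns an `fv_compound`.
#' @export
write_compound_yaml <- function(compound, path) {
  validate_compound(compound)
  yaml::write_yaml(unclass(compound), path, precision = 15L)
  invisible(path)
}

#' @rdname write_compound_yaml
#' @export
read_compound_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cpd <- structure(x, class = "fv_compound")
  ca <- cpd$elimination$clint_additional_uL_min_mg
  if (is.null(ca)) cpd$elimination$clint_additional_uL_min_mg <- NA_real_
  validate_compound(cpd)
  cpd
}

#' @export
print.fv_compound <- function(x, ...) {
  cat("Fluvoxamine compound model (minimal PBPK)\n")
  cat(sprintf("  MW %.1f g/mol, logP %g, pKa %g (base); fup %.2f, B/P %.1f\n",
              x$mw_g_mol, x$logp, x$pka, x$fup, x$bp_ratio))
  cat(sprintf("  Absorption: first-order, ka %.3f 1/h (fa %.2f, fg %.2f)\n",
              x$absorption$ka_per_h, x$absorption$fa, x$absorption$fg))
  cat(sprintf("  Distribution: Vss %g L/kg, Q %g L/h, Vsac %g L/kg\n",
              x$distribution$vss_L_kg, x$distribution$q_inter_L_h,
              x$distribution$vsac_L_kg))
  p <- x$elimination$pathways$CYP2D6
  cat(sprintf("  CYP2D6: Vmax %g pmol/min/pmol, Km %g uM (scalar %.3f)\n",
              p$vmax_pmol_min_pmol, p$km_uM, p$scalar))
  ca <- x$elimination$clint_additional_uL_min_mg
  cat(sprintf("  Non-CYP2D6 CLint: %s uL/min/mg\n",
              if (is.na(ca)) "uncalibrated" else sprintf("%.2f", ca)))
  invisible(x)
}
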