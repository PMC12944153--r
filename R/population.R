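#' Virtual population specification
#'
#' Describes one simulated trial population: its size and trial structure
#' (default 10 trials of 10 subjects), the age window, the sex mix, and the
#' CYP2D6 phenotype mode (the default mixed-frequency population or a uniform
#' single-phenotype population).
#'
#' @param n_trials,subjects_per_trial trial structure; the total population is
#'   their product.
#' @param age_min,age_max age window in years (e.g. 18-65 for younger adults,
#'   65-98 for the geriatric population).
#' @param prop_female fraction of female subjects in \[0, 1\].
#' @param phenotype_mode one of `"default_mix"`, `"uniform_EM"`, `"uniform_IM"`,
#'   `"uniform_PM"`, `"uniform_UM"`.
#' @param seed integer seed; every attribute family is drawn from its own named
#'   stream derived from this seed, so two specs differing only in
#'   `phenotype_mode` yield subject-matched populations.
#' @return An object of class `fv_popspec`.
#' @examples
#' population_spec(age_min = 65, age_max = 98, phenotype_mode = "uniform_PM",
#'                 seed = 11)
#' @export
population_spec <- function(n_trials = 10, subjects_per_trial = 10,
                            age_min = 18, age_max = 65,
                            prop_female = 0.5,
                            phenotype_mode = c("default_mix", "uniform_EM",
                                               "uniform_IM", "uniform_PM",
                                               "uniform_UM"),
                            seed = 1L) {
  phenotype_mode <- match.arg(phenotype_mode)
  if (!(n_trials >= 1 && subjects_per_trial >= 1))
    stop("n_trials and subjects_per_trial must be at least 1")
  if (age_min > age_max) stop("age_min must not exceed age_max")
  if (prop_female < 0 || prop_female > 1)
    stop("prop_female must be in [0, 1]")
  structure(list(
    n_trials = as.integer(n_trials),
    subjects_per_trial = as.integer(subjects_per_trial),
    n_subjects = as.integer(n_trials) * as.integer(subjects_per_trial),
    age_min = age_min, age_max = age_max,
    prop_female = prop_female,
    phenotype_mode = phenotype_mode,
    seed = as.integer(seed)
  ), class = "fv_popspec")
}

#' Aging model
#'
#' Age-dependent physiology: linear fractional declines in liver mass and
#' hepatic blood flow per year above a reference age, plus a single geriatric
#' hepatic activity scalar applied to the total intrinsic metabolic clearance
#' of subjects at or above the geriatric age. The scalar is the one free
#' parameter tuned by [calibrate_aging()] so that mean oral clearance in the
#' 65-98 y population is a target fraction (default 50%) of the 18-65 y mean.
#'
#' @param liver_mass_decline fractional liver-mass loss per year above
#'   `reference_age` (default 0.005/y, i.e. about 20% by age 80).
#' @param flow_decline fractional hepatic blood flow loss per year above
#'   `reference_age` (default 0.010/y, about 40% by age 80).
#' @param activity_scalar dimensionless multiplier on total hepatic intrinsic
#'   clearance for geriatric subjects (1 = no extra geriatric effect).
#' @param reference_age age in years below which no decline applies.
#' @param geriatric_age age at/above which `activity_scalar` applies.
#' @return An object of class `fv_aging`.
#' @export
aging_model <- function(liver_mass_decline = 0.005,
                        flow_decline = 0.010,
                        activity_scalar = 1,
                        reference_age = 40,
                        geriatric_age = 65) {
  stopifnot(liver_mass_decline >= 0, flow_decline >= 0, activity_scalar > 0,
            reference_age > 0, geriatric_age >= reference_age)
  # declines must keep physiology positive up to age 98 (floored at 20%)
  structure(list(liver_mass_decline = liver_mass_decline,
                 flow_decline = flow_decline,
                 activity_scalar = activity_scalar,
                 reference_age = reference_age,
                 geriatric_age = geriatric_age),
            class = "fv_aging")
}

#' CYP2D6 phenotype parameters
#'
#' Phenotype-specific hepatic CYP2D6 abundance means (pmol per mg microsomal
#' protein) with a common between-subject CV, and the default phenotype
#' frequency mix. Defaults: EM 8 pmol/mg (literature-typical), UM = 2 x EM
#' (functional gene duplication), IM = 0.3636 x EM (the value for which the
#' well-stirred model gives an IM/EM exposure fold of 1.5 at fm = 0.524),
#' PM = 0; CV 60% for all non-PM phenotypes; Caucasian-like frequencies
#' EM 0.80, IM 0.10, PM 0.07, UM 0.03.
#'
#' @param em_mean EM abundance mean, pmol/mg.
#' @param im_frac,um_frac IM and UM means as fractions of the EM mean.
#' @param pm_mean PM abundance mean (0: complete loss of function).
#' @param cv between-subject coefficient of variation of the shared hepatic
#'   activity deviate (log-normal).
#' @param freqs named frequency vector over EM/IM/PM/UM summing to 1.
#' @return A list of class `fv_phenotypes`.
#' @export
phenotype_params <- function(em_mean = 8, im_frac = 4/11, um_frac = 2,
                             pm_mean = 0, cv = 0.60,
                             freqs = c(EM = 0.80, IM = 0.10, PM = 0.07,
                                       UM = 0.03)) {
  stopifnot(em_mean > 0, im_frac > 0, um_frac > 0, pm_mean >= 0, cv >= 0)
  freqs <- freqs[c("EM", "IM", "PM", "UM")]
  if (anyNA(freqs) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must cover EM/IM/PM/UM and sum to 1")
  means <- c(EM = em_mean, IM = im_frac * em_mean, PM = pm_mean,
             UM = um_frac * em_mean)
  structure(list(means = means, cv = cv, freqs = freqs),
            class = "fv_phenotypes")
}

# named RNG substreams: one seed per attribute family, derived from the spec
# seed, so adding an attribute (or switching phenotype mode) never shifts the
# draws of the others
.stream_offsets <- c(age = 1, sex = 2, size = 3, liver = 4, mppgl = 5,
                     flow = 6, activity = 7, phenotype = 8)

stream_seed <- function(seed, name) {
  off <- .stream_offsets[[name]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483629)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# inverse-CDF truncated normal (lower truncation only)
rtnorm_lower <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Sample demographics for a population spec
#'
#' Age is uniform on the spec's window; sex is Bernoulli(`prop_female`);
#' weight is drawn from sex-specific normal models (males N(81, 12^2) kg,
#' females N(66, 11^2) kg) truncated below at 35 kg; height is the sex mean
#' (176 cm male, 163 cm female).
#'
#' @param spec an `fv_popspec`.
#' @return A data frame with columns age, sex, weight, height.
#' @export
sample_demographics <- function(spec) {
  stopifnot(inherits(spec, "fv_popspec"))
  n <- spec$n_subjects
  age <- with_stream(spec$seed, "age",
                     stats::runif(n, spec$age_min, spec$age_max))
  female <- with_stream(spec$seed, "sex", stats::runif(n) < spec$prop_female)
  sex <- ifelse(female, "F", "M")
  weight <- with_stream(spec$seed, "size", {
    u <- stats::runif(n)
    wm <- stats::qnorm(stats::pnorm(35, 81, 12) + u * (1 - stats::pnorm(35, 81, 12)), 81, 12)
    wf <- stats::qnorm(stats::pnorm(35, 66, 11) + u * (1 - stats::pnorm(35, 66, 11)), 66, 11)
    ifelse(female, wf, wm)
  })
  height <- ifelse(female, 163, 176)
  data.frame(age = age, sex = sex, weight = weight, height = height)
}

# deterministic part of the physiology model given pre-drawn deviates
physiology_from_deviates <- function(age, weight, aging,
                                     liver_dev, mppgl, flow_dev) {
  over <- pmax(age - aging$reference_age, 0)
  liver_fac <- pmax(1 - aging$liver_mass_decline * over, 0.2)
  flow_fac <- pmax(1 - aging$flow_decline * over, 0.2)
  liver_mass <- 1650 * (weight / 70)^0.85 * liver_fac * liver_dev
  # hepatic flow as ~25% of an allometric cardiac output (~336 L/h at 70 kg)
  q_hepatic <- 84 * (weight / 70)^0.75 * flow_fac * flow_dev
  if (any(liver_mass <= 0) || any(q_hepatic <= 0) || any(mppgl <= 0))
    stop("internal error: non-positive physiology (aging model misconfigured)")
  data.frame(liver_mass = liver_mass, mppgl = mppgl, q_hepatic = q_hepatic)
}

#' Derive hepatic physiology from demographics
#'
#' Liver mass scales allometrically with body weight (1650 g at 70 kg,
#' exponent 0.85) and declines with age above the aging model's reference age;
#' MPPGL is log-normal (mean 40 mg/g, CV 30%); hepatic blood flow is a fixed
#' fraction of an age-declining allometric cardiac output (84 L/h at 70 kg).
#' Between-subject variability on liver mass and flow is log-normal (CV 15%).
#' Deviates are drawn from the current RNG state.
#'
#' @param age,sex,weight,height demographic vectors (equal length; `sex` and
#'   `height` enter only through `weight` here and are accepted for interface
#'   completeness).
#' @param aging an `fv_aging` model.
#' @return A data frame with columns liver_mass (g), mppgl (mg/g),
#'   q_hepatic (L/h).
#' @export
derive_physiology <- function(age, sex, weight, height, aging = aging_model()) {
  n <- length(age)
  stopifnot(length(weight) == n)
  liver_dev <- rlnorm_mean_cv(n, 1, 0.15)
  mppgl <- rlnorm_mean_cv(n, 40, 0.30)
  flow_dev <- rlnorm_mean_cv(n, 1, 0.15)
  physiology_from_deviates(age, weight, aging, liver_dev, mppgl, flow_dev)
}

#' Sample CYP2D6 abundance for given phenotypes
#'
#' Log-normal draw around the phenotype-specific mean with the configured CV.
#' A zero phenotype mean (the PM default) gives a degenerate draw of exactly 0.
#' When `activity` deviates are supplied (as [build_population()] does), the
#' abundance is the phenotype mean times the subject's shared hepatic activity
#' deviate, so that both elimination pathways co-vary within a subject.
#'
#' @param phenotype character vector of labels in EM/IM/PM/UM.
#' @param params an `fv_phenotypes` parameter set.
#' @param activity optional vector of log-normal activity deviates (mean 1);
#'   drawn from the current RNG state when omitted.
#' @return Numeric vector of abundances, pmol per mg microsomal protein.
#' @export
sample_cyp2d6_abundance <- function(phenotype, params = phenotype_params(),
                                    activity = NULL) {
  bad <- setdiff(unique(phenotype), names(params$means))
  if (length(bad)) stop("unknown phenotype label: ", paste(bad, collapse = ", "))
  n <- length(phenotype)
  if (is.null(activity)) activity <- rlnorm_mean_cv(n, 1, params$cv)
  unname(params$means[phenotype] * activity)
}

#' Build a virtual population
#'
#' Generates the full subject table for a spec: demographics, hepatic
#' physiology (with age-dependent decline from the aging model), the shared
#' hepatic activity deviate, phenotype labels (mixed or uniform) and CYP2D6
#' abundance, grouped into trials. Deterministic given the spec seed; all
#' attribute families use independent named substreams, so populations built
#' from specs that differ only in phenotype mode are subject-matched.
#'
#' @param spec an `fv_popspec`.
#' @param aging an `fv_aging` model (declines enter the physiology here; the
#'   geriatric activity scalar is applied later, at the clearance stage).
#' @param phenotypes an `fv_phenotypes` parameter set.
#' @return A data frame of class `fv_population`, one row per subject, with
#'   the spec and phenotype parameters attached as attributes.
#' @examples
#' pop <- build_population(population_spec(seed = 7))
#' nrow(pop)         # 100
#' table(pop$trial)  # 10 trials of 10
#' @export
build_population <- function(spec, aging = aging_model(),
                             phenotypes = phenotype_params()) {
  stopifnot(inherits(spec, "fv_popspec"), inherits(aging, "fv_aging"),
            inherits(phenotypes, "fv_phenotypes"))
  n <- spec$n_subjects
  demo <- sample_demographics(spec)
  liver_dev <- with_stream(spec$seed, "liver", rlnorm_mean_cv(n, 1, 0.15))
  mppgl <- with_stream(spec$seed, "mppgl", rlnorm_mean_cv(n, 40, 0.30))
  flow_dev <- with_stream(spec$seed, "flow", rlnorm_mean_cv(n, 1, 0.15))
  phys <- physiology_from_deviates(demo$age, demo$weight, aging,
                                   liver_dev, mppgl, flow_dev)
  activity <- with_stream(spec$seed, "activity",
                          rlnorm_mean_cv(n, 1, phenotypes$cv))
  phenotype <- if (spec$phenotype_mode == "default_mix") {
    with_stream(spec$seed, "phenotype", {
      u <- stats::runif(n)
      cuts <- cumsum(phenotypes$freqs)
      names(cuts)[findInterval(u, c(0, cuts[-length(cuts)]))]
    })
  } else {
    rep(sub("uniform_", "", spec$phenotype_mode), n)
  }
  abundance <- sample_cyp2d6_abundance(phenotype, phenotypes, activity)
  pop <- data.frame(
    trial = rep(seq_len(spec$n_trials), each = spec$subjects_per_trial),
    subject = seq_len(n),
    age = demo$age, sex = demo$sex, weight = demo$weight, height = demo$height,
    liver_mass = phys$liver_mass, mppgl = phys$mppgl,
    q_hepatic = phys$q_hepatic,
    activity = activity,
    phenotype = phenotype,
    cyp2d6_abundance = abundance,
    geriatric = demo$age >= aging$geriatric_age
  )
  structure(pop, class = c("fv_population", "data.frame"),
            spec = spec, phenotypes = phenotypes)
}

#' Write / read a population as CSV
#'
#' One row per subject (trial, demographics, physiology, phenotype,
#' abundance); plain text, suitable for external inspection.
#'
#' @param pop an `fv_population`.
#' @param path CSV file path.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` returns a plain data frame.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
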