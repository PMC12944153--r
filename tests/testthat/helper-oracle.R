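# Independent closed-form PK oracles used to check the ODE engine and the
# NCA metrics. These never touch the deSolve path.

# one-compartment first-order oral model: C(t) after a single dose
one_cpt_oral_conc <- function(t, dose_ng, f, ka, cl_ml_h, v_ml) {
  k <- cl_ml_h / v_ml
  f * dose_ng * ka / (v_ml * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

# one-compartment multiple dosing by superposition
one_cpt_oral_conc_multi <- function(t, dose_ng, f, ka, cl_ml_h, v_ml,
                                    tau, n_doses) {
  conc <- numeric(length(t))
  for (j in seq_len(n_doses) - 1) {
    td <- t - j * tau
    ok <- td >= 0
    conc[ok] <- conc[ok] + one_cpt_oral_conc(td[ok], dose_ng, f, ka,
                                             cl_ml_h, v_ml)
  }
  conc
}

# steady-state one-compartment extremes over a dosing interval (absorption
# assumed complete within the interval; exact superposition limits)
one_cpt_ss_cmax_cmin <- function(dose_ng, f, ka, cl_ml_h, v_ml, tau) {
  k <- cl_ml_h / v_ml
  tmax <- log(ka / k * (1 - exp(-k * tau)) / (1 - exp(-ka * tau))) / (ka - k)
  css <- function(t) {
    f * dose_ng * ka / (v_ml * (ka - k)) *
      (exp(-k * t) / (1 - exp(-k * tau)) - exp(-ka * t) / (1 - exp(-ka * tau)))
  }
  list(cmax = css(tmax), cmin = css(tau), tmax = tmax)
}

# general linear 3-state (gut/central/peripheral) model solved by eigen
# decomposition; doses (ng, availability included) enter the gut at dose_times
linear3_profile <- function(times, ka, vc_ml, vp_ml, q_ml_h, cl_ml_h,
                            dose_ng, dose_times) {
  M <- rbind(c(-ka, 0, 0),
             c(ka, -(q_ml_h + cl_ml_h) / vc_ml, q_ml_h / vp_ml),
             c(0, q_ml_h / vc_ml, -q_ml_h / vp_ml))
  eg <- eigen(M)
  V <- eg$vectors
  Vi <- solve(V)
  propagate <- function(a0, dt) {
    if (dt == 0) return(a0)
    Re(V %*% (exp(eg$values * dt) * (Vi %*% a0)))
  }
  conc <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    past <- dose_times[dose_times <= t]
    a <- c(0, 0, 0)
    t_prev <- 0
    for (td in past) {
      a <- propagate(a, td - t_prev)
      a[1] <- a[1] + dose_ng
      t_prev <- td
    }
    a <- propagate(a, t - t_prev)
    conc[i] <- a[2] / vc_ml
  }
  conc
}

# hand-built subject row and clearance row for direct engine tests
synthetic_subject <- function(weight = 70, age = 30, phenotype = "EM",
                              abundance = 8, activity = 1) {
  data.frame(trial = 1L, subject = 1L, age = age, sex = "M", weight = weight,
             height = 176, liver_mass = 1650, mppgl = 40, q_hepatic = 84,
             activity = activity, phenotype = phenotype,
             cyp2d6_abundance = abundance, geriatric = age >= 65)
}

# cache: one fully calibrated fit shared across test files
.fit_cache <- new.env(parent = emptyenv())
test_fit <- function() {
  if (is.null(.fit_cache$fit))
    .fit_cache$fit <- fit_fluvoxamine(seed = 42)
  .fit_cache$fit
}
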