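#' Read and validate a run configuration
#'
#' YAML configuration for the command-line runner (`inst/cli/fvpbpk.R`).
#' Recognized top-level keys: `seed`, `out_dir`, `study`
#' (verification | age | phenotype), `doses`, `anchors` (observed_auc,
#' pm_em_ratio, target_cl_fraction), `population` (n_trials,
#' subjects_per_trial), `solver` (rel_tol, abs_tol, output_grid_h,
#' max_sim_days, ss_convergence_tol). Unknown keys are rejected before any
#' computation.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A validated list of class `fv_runconfig`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("seed", "out_dir", "study", "doses", "anchors", "population",
             "solver")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, out_dir = "fvpbpk-out", study = "phenotype",
                   doses = c(50, 100, 150, 200),
                   anchors = list(observed_auc = 1308, pm_em_ratio = 2.1,
                                  target_cl_fraction = 0.5),
                   population = list(n_trials = 10L, subjects_per_trial = 10L),
                   solver = list())
  cfg <- utils::modifyList(defaults, cfg)
  bad_anchor <- setdiff(names(cfg$anchors),
                        c("observed_auc", "pm_em_ratio", "target_cl_fraction"))
  if (length(bad_anchor))
    stop("unknown anchors keys: ", paste(bad_anchor, collapse = ", "))
  if (!cfg$study %in% c("verification", "age", "phenotype"))
    stop("study must be one of verification, age, phenotype")
  if (!length(cfg$doses) || any(cfg$doses <= 0))
    stop("doses must be a non-empty vector of positive daily doses")
  if (cfg$anchors$pm_em_ratio < 1)
    stop("anchors$pm_em_ratio must be at least 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg$solver <- do.call(solver_settings, cfg$solver)
  structure(cfg, class = "fv_runconfig")
}
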