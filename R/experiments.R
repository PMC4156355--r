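# Declarative scenario runner: builds the layout, applies remodeling, paces
# to (approximate) steady state, and computes the biomarker report.  A
# scenario spec fully determines the run given the code version.

#' Intercellular-coupling levels (cm^2/ms)
#'
#' Named diffusion coefficients for the coupling conditions studied: normal
#' coupling, mild uncoupling, the two-fold connexin-43-loss reduction used in
#' the heart-failure strand, and severe uncoupling.
#' @export
UNCOUPLING_LEVELS <- c(none = 0.0006, mild = 0.00045, `normal-HF` = 0.0003,
                       severe = 0.00025)

#' Declarative scenario specification
#'
#' @param model_id `"GPB"` or `"ORd"`.
#' @param composition Node counts per class; default is the model's standard
#'   transmural composition.
#' @param remodeling Remodeling mode (see [build_profile()]).
#' @param uncoupling One of `"none"` (D = 0.0006 cm^2/ms), `"mild"`
#'   (0.00045), `"normal-HF"` (0.0003), `"severe"` (0.00025).
#' @param fibrosis `NULL`, `list(type = "diffuse", fraction =, seed =)`, or
#'   `list(type = "patchy", size =, start =)`.
#' @param pacing List with `BCL`, `n_beats` and optionally `dt`.
#' @param measure_erp Also run the S1-S2 ERP search from the steady state.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(model_id, composition = NULL,
                          remodeling = "CONTROL", uncoupling = "none",
                          fibrosis = NULL,
                          pacing = list(BCL = 1000, n_beats = 30),
                          measure_erp = FALSE) {
  uncoupling <- match.arg(uncoupling, names(UNCOUPLING_LEVELS))
  stopifnot(remodeling %in% REMODELING_MODES)
  structure(list(model_id = model_id, composition = composition,
                 remodeling = remodeling, uncoupling = uncoupling,
                 fibrosis = fibrosis, pacing = pacing,
                 measure_erp = measure_erp),
            class = "scenario_spec")
}

.layout_from_spec <- function(spec) {
  lay <- build_transmural_layout(spec$model_id, spec$composition,
                                 D_myo = UNCOUPLING_LEVELS[[spec$uncoupling]])
  if (!is.null(spec$fibrosis)) {
    fb <- spec$fibrosis
    lay <- switch(fb$type,
      diffuse = insert_diffuse_fibrosis(lay, fb$fraction, fb$seed),
      patchy = insert_patchy_fibrosis(lay, fb$size, fb$start),
      stop("unknown fibrosis type: ", fb$type, call. = FALSE))
  }
  lay
}

.config_from_spec <- function(spec) {
  p <- spec$pacing
  sim_config(dt = if (is.null(p$dt)) 0.02 else p$dt,
             BCL = if (is.null(p$BCL)) 1000 else p$BCL,
             n_beats = if (is.null(p$n_beats)) 30 else p$n_beats)
}

#' Run a complete strand scenario
#'
#' Builds the layout (including fibrosis), applies the remodeling profile,
#' paces to approximate steady state and computes the biomarker report;
#' optionally runs the S1-S2 ERP search from the steady-state checkpoint.
#' Propagation failure during the final beat is reported in-band: the report
#' is produced with `NA` conduction velocity rather than an error.
#'
#' @param spec A `scenario_spec`.
#' @return List with `report` (a `biomarker_report`), `paced` (the
#'   [pace_to_steady_state()] result), `erp` (ms or `NULL`) and `manifest`
#'   (the spec plus run metadata).
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  lay <- .layout_from_spec(spec)
  cfg <- .config_from_spec(spec)
  profile <- build_profile(spec$model_id, spec$remodeling)
  paced <- pace_to_steady_state(lay, cfg, profile)
  erp <- NULL
  if (isTRUE(spec$measure_erp)) {
    erp <- measure_erp(lay, paced$nodes, cfg)
  }
  report <- biomarker_report(paced$last, paced$stim_time, lay, erp = erp)
  manifest <- list(spec = unclass(spec), dt = cfg$dt,
                   diff_scale = cfg$diff_scale,
                   convergence = paced$convergence,
                   package_version = as.character(utils::packageVersion("hfstrand")))
  list(report = report, paced = paced, erp = erp, manifest = manifest)
}

#' Diffuse-fibrosis sweep over fractions, seeds and coupling levels
#'
#' Runs the base scenario for every combination of fibrotic fraction, seed
#' and uncoupling level, collecting APD dispersion, TDR and CV.  Individual
#' failed runs are logged, excluded and counted.  When both 10% and 20%
#' fractions are present, a Welch t-test on APD dispersion and TDR between
#' the two fibrotic contents (pooled over seeds) is reported per coupling
#' level.
#'
#' @param base_spec `scenario_spec` whose fibrosis/uncoupling fields will be
#'   overridden.
#' @param fractions Fibrotic fractions (e.g. `c(0.1, 0.2)`).
#' @param seeds Integer seeds (>= 2 for statistics).
#' @param uncoupling_levels Subset of `names(UNCOUPLING_LEVELS)`.
#' @return List with `runs` (one row per run), `summary` (mean +/- SD per
#'   cell of the grid), `tests` (Welch tests 10% vs 20%) and `n_failed`.
#' @export
run_fibrosis_sweep <- function(base_spec, fractions = c(0.1, 0.2),
                               seeds = 1:5, uncoupling_levels = "none") {
  if (!length(seeds)) stop("need at least one seed", call. = FALSE)
  grid <- expand.grid(fraction = fractions, seed = seeds,
                      uncoupling = uncoupling_levels,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  n_failed <- 0L
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    sp <- base_spec
    sp$uncoupling <- g$uncoupling
    sp$fibrosis <- list(type = "diffuse", fraction = g$fraction,
                        seed = g$seed)
    res <- tryCatch(run_scenario(sp), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      message(sprintf("run failed (fraction %.2f seed %d %s): %s",
                      g$fraction, g$seed, g$uncoupling, conditionMessage(res)))
      next
    }
    s <- res$report$summary
    rows[[k]] <- data.frame(fraction = g$fraction, seed = g$seed,
                            uncoupling = g$uncoupling,
                            APD_dispersion = s$APD_dispersion, TDR = s$TDR,
                            CV = s$CV)
  }
  runs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  summary <- NULL
  tests <- list()
  if (!is.null(runs)) {
    summary <- do.call(rbind, lapply(
      split(runs, list(runs$fraction, runs$uncoupling), drop = TRUE),
      function(d) data.frame(
        fraction = d$fraction[1], uncoupling = d$uncoupling[1], n = nrow(d),
        APD_dispersion_mean = mean(d$APD_dispersion),
        APD_dispersion_sd = if (nrow(d) > 1) stats::sd(d$APD_dispersion)
                            else NA_real_,
        TDR_mean = mean(d$TDR),
        TDR_sd = if (nrow(d) > 1) stats::sd(d$TDR) else NA_real_,
        CV_mean = mean(d$CV))))
    rownames(summary) <- NULL
    if (all(c(0.1, 0.2) %in% runs$fraction)) {
      for (u in unique(runs$uncoupling)) {
        a <- runs[runs$fraction == 0.1 & runs$uncoupling == u, ]
        b <- runs[runs$fraction == 0.2 & runs$uncoupling == u, ]
        if (nrow(a) >= 2 && nrow(b) >= 2) {
          tests[[u]] <- list(
            APD_dispersion = two_sample_ttest(a$APD_dispersion,
                                              b$APD_dispersion),
            TDR = two_sample_ttest(a$TDR, b$TDR))
        }
      }
    }
  }
  list(runs = runs, summary = summary, tests = tests, n_failed = n_failed)
}

#' Scenario matrix covering the in-scope experiments
#'
#' Enumerates the scenario specifications behind each in-scope experiment of
#' the simulation study: the two-class and three-class remodeling
#' comparisons, the heterogeneous-remodeling variants, the fibrosis and
#' uncoupling combinations, and the safety-factor fiber.
#'
#' @return Named list of `scenario_spec` objects (the safety-factor entry
#'   carries its own composition).
#' @export
scenario_matrix <- function() {
  list(
    gpb_control = scenario_spec("GPB"),
    gpb_hf = scenario_spec("GPB", remodeling = "HF_HOMOG"),
    gpb_hf_ncx = scenario_spec("GPB", remodeling = "HF_HET_NCX"),
    gpb_hf_serca = scenario_spec("GPB", remodeling = "HF_HET_SERCA"),
    gpb_hf_both = scenario_spec("GPB", remodeling = "HF_HET_BOTH"),
    ord_control = scenario_spec("ORd", c(ENDO = 82, EPI = 83),
                                pacing = list(BCL = 1000, n_beats = 50)),
    ord_hf = scenario_spec("ORd", c(ENDO = 82, EPI = 83), "HF_HOMOG",
                           pacing = list(BCL = 1000, n_beats = 50)),
    ord_m_control = scenario_spec("ORd",
                                  pacing = list(BCL = 1000, n_beats = 50)),
    ord_m_hf = scenario_spec("ORd", remodeling = "HF_HOMOG",
                             pacing = list(BCL = 1000, n_beats = 50)),
    gpb_hf_fib10 = scenario_spec("GPB", remodeling = "HF_HOMOG",
                                 fibrosis = list(type = "diffuse",
                                                 fraction = 0.1, seed = 1)),
    gpb_hf_fib10_unc = scenario_spec("GPB", remodeling = "HF_HOMOG",
                                     uncoupling = "normal-HF",
                                     fibrosis = list(type = "diffuse",
                                                     fraction = 0.1,
                                                     seed = 1)),
    gpb_hf_fib20 = scenario_spec("GPB", remodeling = "HF_HOMOG",
                                 fibrosis = list(type = "diffuse",
                                                 fraction = 0.2, seed = 1)),
    sf_fiber_control = scenario_spec("GPB", c(ENDO = 900)),
    sf_fiber_hf = scenario_spec("GPB", c(ENDO = 900),
                                remodeling = "HF_HOMOG"),
    sf_fiber_hf_patchy = scenario_spec("GPB", c(ENDO = 900),
                                       remodeling = "HF_HOMOG",
                                       fibrosis = list(type = "patchy",
                                                       size = 25,
                                                       start = 438)))
}
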