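# Heavy strand simulations are shared across test files through a lazy cache
# so each unique scenario is paced once per test run.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# paced GPB transmural strand (82 endo + 83 epi), 30 pre-pacing beats
gpb_paced <- function(mode = "CONTROL") {
  cached(paste0("gpb_", mode), {
    lay <- build_transmural_layout("GPB")
    cfg <- sim_config(n_beats = 30)
    paced <- pace_to_steady_state(lay, cfg, build_profile("GPB", mode))
    list(lay = lay, cfg = cfg, paced = paced,
         report = biomarker_report(paced$last, paced$stim_time, lay))
  })
}

gpb_erp <- function(mode = "CONTROL") {
  cached(paste0("erp_", mode), {
    run <- gpb_paced(mode)
    measure_erp(run$lay, run$paced$nodes, run$cfg)
  })
}

# diffuse-fibrosis dispersion for one configuration
fib_disp <- function(fraction, seed, uncoupling = "none") {
  cached(sprintf("fib_%g_%d_%s", fraction, seed, uncoupling), {
    sp <- scenario_spec("GPB", remodeling = "HF_HOMOG",
                        uncoupling = uncoupling,
                        fibrosis = list(type = "diffuse", fraction = fraction,
                                        seed = seed))
    res <- run_scenario(sp)
    c(APD_dispersion = res$report$summary$APD_dispersion,
      TDR = res$report$summary$TDR, CV = res$report$summary$CV)
  })
}

# ORd strands with and without the midmyocardial block, 20 pre-pacing beats
ord_strand <- function(with_m, mode) {
  cached(sprintf("ord_%d_%s", with_m, mode), {
    comp <- if (with_m) NULL else c(ENDO = 82, EPI = 83)
    sp <- scenario_spec("ORd", comp, remodeling = mode,
                        pacing = list(BCL = 1000, n_beats = 15))
    run_scenario(sp)$report$summary
  })
}

# single-cell paced APD90
cell_apd <- function(model, class, mode = "CONTROL", n_beats = 30) {
  cached(sprintf("cell_%s_%s_%s", model, class, mode), {
    p <- default_params(model, class)
    if (mode != "CONTROL") p <- apply_profile(p, build_profile(model, mode))
    amp <- if (model == "ORd") 52 else 20
    dur <- if (model == "ORd") 1 else 2
    r <- pace_cell(init_state(model, class), p, BCL = 1000,
                   n_beats = n_beats, stim_amp = amp, stim_dur = dur)
    apd90(r$vm, r$times, r$stim_time)
  })
}

# finely sampled propagating beat on a 900-cell endocardial fiber for
# safety-factor work; returns the trace set and layout
sf_fiber <- function(mode = "HF_HOMOG", cluster = NULL) {
  cached(sprintf("sf_%s_%s", mode, if (is.null(cluster)) "none" else cluster), {
    lay <- build_transmural_layout("GPB", c(ENDO = 900))
    if (!is.null(cluster)) lay <- insert_patchy_fibrosis(lay, cluster, 438)
    cfg <- sim_config(n_beats = 3)
    nodes <- make_node_states(lay, build_profile("GPB", mode))
    pre <- solve_strand(lay, nodes, cfg, 2000, stim_times = c(0, 1000),
                        t0 = 0, sample_interval = 1000, record_cai = FALSE)
    tr <- solve_strand(lay, pre$nodes, cfg, 400, stim_times = 2000, t0 = 2000,
                       track_from = 2000, sample_interval = 0.05,
                       record_cai = FALSE)
    list(tr = tr, lay = lay)
  })
}

# small uniform GPB strand with a finely sampled beat (solver/biomarker
# verification work)
small_strand <- function() {
  cached("small_strand", {
    lay <- build_transmural_layout("GPB", c(ENDO = 30))
    cfg <- sim_config(n_beats = 3)
    nodes <- make_node_states(lay)
    pre <- solve_strand(lay, nodes, cfg, 2000, stim_times = c(0, 1000),
                        t0 = 0, sample_interval = 1000, record_cai = FALSE)
    tr <- solve_strand(lay, pre$nodes, cfg, 120, stim_times = 2000, t0 = 2000,
                       track_from = 2000, sample_interval = 0.05,
                       record_cai = FALSE)
    list(tr = tr, lay = lay, cfg = cfg)
  })
}
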