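# Monodomain strand driver: node assembly, pacing protocols, ERP search and
# axial-current reconstruction on top of the compiled operator-split kernel.

# Diffusion calibration constant (dimensionless).  The cable equation is
# integrated as dV/dt = -I_ion + I_stim + kappa * d/dx( D dV/dx ): the
# surface-to-volume ratio and specific capacitance are folded into kappa,
# calibrated once so that the normal-coupling GPB transmural strand
# (D = 0.0006 cm^2/ms) conducts at 50 cm/s, the experimental transmural
# velocity the diffusion coefficient was chosen to reproduce.  See the
# methods vignette for the calibration run.
DIFF_CALIBRATION <- 1.0329

#' Simulation configuration for strand runs
#'
#' @param dt Time step, ms (at most 0.02 ms).
#' @param BCL Basic cycle length, ms.
#' @param n_beats Number of pre-pacing beats used by
#'   [pace_to_steady_state()].
#' @param stim_nodes 1-based indices of stimulated nodes (endocardial end).
#'   Fibroblast nodes among them are skipped: fibroblasts are never
#'   stimulated directly.
#' @param stim_amp Stimulus amplitude, uA/uF (positive = depolarizing).
#' @param stim_dur Stimulus duration, ms.
#' @param sample_interval Trace sampling interval, ms.
#' @param diff_scale Diffusion calibration constant; the package default
#'   reproduces 50 cm/s at D = 0.0006 cm^2/ms in the normal GPB strand.
#' @param fib_cap_coupling If `TRUE`, the diffusion-operator row of each
#'   fibroblast node is scaled by the myocyte/fibroblast capacitance ratio
#'   (~22): per unit of its own 6.3-pF membrane a fibroblast charges far
#'   more easily.  The default `FALSE` treats all nodes alike, which is the
#'   reading under which the diffuse-fibrosis dispersion results and the
#'   resting-potential elevation reproduce; see the methods vignette.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.02, BCL = 1000, n_beats = 30,
                       stim_nodes = 1:3, stim_amp = 40, stim_dur = 2,
                       sample_interval = 0.5, diff_scale = DIFF_CALIBRATION,
                       fib_cap_coupling = FALSE) {
  stopifnot(dt > 0, dt <= 0.02, BCL > 0, n_beats >= 1,
            sample_interval >= dt)
  structure(list(dt = dt, BCL = BCL, n_beats = n_beats,
                 stim_nodes = stim_nodes, stim_amp = stim_amp,
                 stim_dur = stim_dur, sample_interval = sample_interval,
                 diff_scale = diff_scale, fib_cap_coupling = fib_cap_coupling),
            class = "sim_config")
}

# membrane capacitance (pF) of the myocyte model vs the fibroblast
.MYO_CAP <- c(GPB = 138.10, ORd = 153.34)
.FIB_CAP <- 6.3

# per-node scaling of the diffusion-operator row: reference myocyte
# capacitance over the node capacitance.  Fibroblast nodes have ~22x less
# membrane to charge, so per unit of their own capacitance they couple more
# strongly; disabled (all 1) when fib_cap_coupling = FALSE.
.node_cap_scale <- function(layout, config) {
  s <- rep(1, layout$n_nodes)
  if (isTRUE(config$fib_cap_coupling)) {
    fib <- layout$node_class == "FIBROBLAST"
    s[fib] <- .MYO_CAP[[layout$model_id]] / .FIB_CAP
  }
  s
}

#' Assemble per-node membrane states and parameters for a strand
#'
#' Builds, for every node of the layout, the matching membrane model
#' (myocyte model of the layout's `model_id` for `ENDO`/`MID`/`EPI` nodes,
#' fibroblast model for `FIBROBLAST` nodes), its published initial state and
#' its parameter set, with an optional heart-failure remodeling profile
#' applied class-wise to the myocyte nodes.
#'
#' @param layout A `strand_layout`.
#' @param profile Optional `remodeling_profile`.
#' @return A `node_set`: integer `model` per node, `state` matrix
#'   (states x nodes, padded), `params` matrix (params x nodes, padded).
#' @export
make_node_states <- function(layout, profile = NULL) {
  stopifnot(inherits(layout, "strand_layout"))
  n <- layout$n_nodes
  nmax_s <- max(vapply(c("GPB", "ORd", "FIB"),
                       function(m) model_nstates_cpp(MODEL_IDS[[m]]), 1L))
  nmax_p <- max(lengths(lapply(c("GPB", "ORd", "FIB"), .param_names)))
  state <- matrix(0, nmax_s, n)
  params <- matrix(0, nmax_p, n)
  model <- integer(n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    cl <- layout$node_class[i]
    if (cl == "FIBROBLAST") {
      mid <- "FIB"; pcl <- "FIBROBLAST"
    } else {
      mid <- layout$model_id; pcl <- cl
    }
    key <- paste(mid, pcl)
    if (is.null(cache[[key]])) {
      p <- default_params(mid, pcl)
      if (!is.null(profile) && mid != "FIB") {
        p <- apply_profile(p, profile, pcl)
      }
      cache[[key]] <- list(y = unname(init_state(mid, pcl)$y), p = unname(p))
    }
    ent <- cache[[key]]
    model[i] <- MODEL_IDS[[mid]]
    state[seq_along(ent$y), i] <- ent$y
    params[seq_along(ent$p), i] <- ent$p
  }
  structure(list(model = model, state = state, params = params),
            class = "node_set")
}

# stimulated nodes: configured indices, minus fibroblast nodes
.stim_idx0 <- function(layout, config) {
  idx <- config$stim_nodes
  idx <- idx[idx >= 1 & idx <= layout$n_nodes]
  idx <- idx[layout$node_class[idx] != "FIBROBLAST"]
  as.integer(idx - 1L)
}

#' Integrate the monodomain equation over a strand
#'
#' Operator-split integration: explicit ionic sub-step per node (Rush-Larsen
#' gates, forward-Euler concentrations), then an implicit (backward Euler)
#' diffusion solve on the tridiagonal system from the per-element diffusion
#' coefficients with sealed (zero-flux) ends.  Stimuli of the configured
#' amplitude/duration are injected at the configured nodes at each time in
#' `stim_times`.
#'
#' @param layout A `strand_layout`.
#' @param nodes A `node_set` (modified state is returned, input unchanged).
#' @param config A `sim_config`.
#' @param duration Simulated time, ms.
#' @param stim_times Absolute onset times of stimuli, ms.
#' @param t0 Absolute start time, ms.
#' @param track_from Absolute time from which per-node upstroke markers (max
#'   dV/dt time/value, max/min V) are tracked at solver resolution.
#' @param sample_interval Trace sampling interval; defaults to the config's.
#' @param record_cai Record the intracellular Ca2+ transient.
#' @return A `trace_set`: `times` (ms), `vm` and optionally `cai`
#'   (samples x nodes), per-node `upstroke_time`, `dvdt_max`, `vmax`,
#'   `vmin`, the final `nodes`, and bookkeeping (`layout`, `stim_times`,
#'   `dt`, `diff_scale`).
#' @export
solve_strand <- function(layout, nodes, config, duration,
                         stim_times = numeric(0), t0 = 0,
                         track_from = t0,
                         sample_interval = config$sample_interval,
                         record_cai = TRUE) {
  stopifnot(inherits(layout, "strand_layout"), inherits(nodes, "node_set"),
            length(nodes$model) == layout$n_nodes)
  D_eff <- layout$D_elem * config$diff_scale
  res <- strand_solve_cpp(nodes$model, nodes$state, nodes$params, D_eff,
                          layout$dx, config$dt, t0, duration,
                          .stim_idx0(layout, config), stim_times,
                          config$stim_amp, config$stim_dur,
                          sample_interval, track_from, record_cai,
                          .node_cap_scale(layout, config))
  nodes$state <- res$state
  structure(list(times = as.numeric(res$times), vm = res$vm,
                 cai = if (record_cai) res$cai else NULL,
                 upstroke_time = as.numeric(res$upstroke_time),
                 dvdt_max = as.numeric(res$dvdt_max),
                 vmax = as.numeric(res$vmax), vmin = as.numeric(res$vmin),
                 nodes = nodes, layout = layout, stim_times = stim_times,
                 t0 = t0, dt = config$dt, diff_scale = config$diff_scale,
                 cap_scale = .node_cap_scale(layout, config)),
            class = "trace_set")
}

#' Pace a strand to (approximate) steady state
#'
#' Applies `config$n_beats` stimuli at the basic cycle length, records the
#' last two beats and reports the pacing convergence as the largest
#' per-myocyte-node |APD90(last) - APD90(previous)|.
#'
#' @inheritParams solve_strand
#' @param profile Optional remodeling profile used to build the nodes when
#'   `nodes` is not supplied.
#' @return List with `nodes` (end state), `last` and `prev` (trace sets of
#'   the final and penultimate beats), `stim_time` (onset of the final
#'   beat), `apd_last`, `apd_prev` (per-node APD90, NA on fibroblast or
#'   non-captured nodes) and `convergence` (ms).
#' @export
pace_to_steady_state <- function(layout, config, profile = NULL,
                                 nodes = make_node_states(layout, profile)) {
  n_beats <- config$n_beats
  BCL <- config$BCL
  t0 <- 0
  if (n_beats > 2) {
    pre <- solve_strand(layout, nodes, config, (n_beats - 2) * BCL,
                        stim_times = BCL * (seq_len(n_beats - 2) - 1),
                        t0 = t0, sample_interval = BCL, record_cai = FALSE)
    nodes <- pre$nodes
    t0 <- (n_beats - 2) * BCL
  }
  k <- min(n_beats, 2)
  prev <- NULL
  if (k == 2) {
    prev <- solve_strand(layout, nodes, config, BCL, stim_times = t0,
                         t0 = t0, track_from = t0)
    nodes <- prev$nodes
    t0 <- t0 + BCL
  }
  last <- solve_strand(layout, nodes, config, BCL, stim_times = t0,
                       t0 = t0, track_from = t0)
  myo <- layout$node_class != "FIBROBLAST"
  apd_of <- function(tr, stim_time) {
    vapply(seq_len(layout$n_nodes), function(i) {
      if (!myo[i]) return(NA_real_)
      apd90(tr$vm[, i], tr$times, stim_time)
    }, 1.0)
  }
  apd_last <- apd_of(last, t0)
  apd_prev <- if (!is.null(prev)) apd_of(prev, t0 - BCL) else apd_last
  conv <- suppressWarnings(max(abs(apd_last - apd_prev), na.rm = TRUE))
  list(nodes = last$nodes, last = last, prev = prev, stim_time = t0,
       apd_last = apd_last, apd_prev = apd_prev,
       convergence = if (is.finite(conv)) conv else NA_real_)
}

# fresh upward crossing of `thr` at sampled trace v(t) strictly after t_min
.crosses_up_after <- function(v, t, thr, t_min) {
  i <- which(t[-1] > t_min & v[-1] >= thr & v[-length(v)] < thr)
  length(i) > 0
}

#' Effective refractory period by S1-S2 bisection
#'
#' From a steady-state checkpoint, delivers an S1 at time 0 and an S2 after a
#' coupling interval; the S2 "propagates" when the depolarization wavefront
#' produces a fresh upward crossing of -20 mV at the far-end measurement node
#' (the last myocyte node).  The minimal propagating interval is found by
#' bisection to 1 ms.
#'
#' @param layout A `strand_layout`.
#' @param nodes Steady-state `node_set` checkpoint (taken just before a
#'   stimulus); re-used unchanged for every trial.
#' @param config A `sim_config`.
#' @param bracket Initial S2 search interval `c(lo, hi)` in ms; `hi` must
#'   propagate.
#' @param settle_ms Extra simulated time after S2 used to detect far-end
#'   arrival.
#' @return The ERP in ms (the minimal propagating S2 interval, 1-ms
#'   resolution), with attribute `trials` (number of S2 trials).
#' @export
measure_erp <- function(layout, nodes, config, bracket = c(150, config$BCL),
                        settle_ms = 400) {
  far <- max(which(layout$node_class != "FIBROBLAST"))
  test <- function(interval) {
    tr <- solve_strand(layout, nodes, config, interval + settle_ms,
                       stim_times = c(0, interval), t0 = 0,
                       track_from = interval, sample_interval = 1,
                       record_cai = FALSE)
    .crosses_up_after(tr$vm[, far], tr$times, -20, interval + 2)
  }
  lo <- floor(bracket[1]); hi <- ceiling(bracket[2])
  trials <- 0L
  if (!{trials <- trials + 1L; test(hi)}) {
    stop(sprintf("S2 does not propagate within [%d, %d] ms", lo, hi),
         call. = FALSE)
  }
  if ({trials <- trials + 1L; test(lo)}) {
    # bracket lower end already propagates: ERP <= lo
    return(structure(lo, trials = trials))
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    trials <- trials + 1L
    if (test(mid)) hi <- mid else lo <- mid
  }
  structure(hi, trials = trials)
}

#' Axial currents entering and leaving each node
#'
#' Reconstructs, from sampled membrane-potential traces, the discrete axial
#' fluxes `D * (V_neighbor - V_i) / dx^2` (uA/uF) across the two elements
#' touching each node, sign-resolved into a current entering the node
#' (`I_in`, depolarizing contributions from either neighbor) and a current
#' leaving it (`I_out`).  Boundary nodes have one-sided fluxes.
#'
#' @param traces A `trace_set` (fine sampling recommended for safety-factor
#'   work).
#' @param layout The strand layout the traces came from.
#' @return List of matrices `I_in`, `I_out` (samples x nodes).
#' @export
axial_currents <- function(traces, layout = traces$layout) {
  vm <- traces$vm
  n <- ncol(vm)
  D <- layout$D_elem * traces$diff_scale
  cs <- traces$cap_scale
  if (is.null(cs)) cs <- rep(1, n)
  dx2 <- layout$dx^2
  I_in <- matrix(0, nrow(vm), n)
  I_out <- matrix(0, nrow(vm), n)
  for (i in seq_len(n)) {
    if (i > 1) {
      jl <- cs[i] * D[i - 1] * (vm[, i - 1] - vm[, i]) / dx2
      I_in[, i] <- I_in[, i] + pmax(jl, 0)
      I_out[, i] <- I_out[, i] + pmax(-jl, 0)
    }
    if (i < n) {
      jr <- cs[i] * D[i] * (vm[, i + 1] - vm[, i]) / dx2
      I_in[, i] <- I_in[, i] + pmax(jr, 0)
      I_out[, i] <- I_out[, i] + pmax(-jr, 0)
    }
  }
  list(I_in = I_in, I_out = I_out)
}
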