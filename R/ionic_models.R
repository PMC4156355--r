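# Membrane-model registries and the uniform cell-level stepping interface.
#
# Three membrane formulations are available:
#   "GPB" - Grandi-Pasqualini-Bers human ventricular myocyte (endo/epi),
#           extended with a late Na+ current so heart-failure I_NaL scaling
#           has a target parameter;
#   "ORd" - O'Hara-Rudy human ventricular myocyte (endo/M/epi);
#   "FIB" - MacCannell active ventricular fibroblast (C_m = 6.3 pF).
# A passive linear membrane ("PAS", I_ion = g*(V - E)) is provided for
# numerical verification of the cable solver.

MODEL_IDS <- c(PAS = 0L, GPB = 1L, ORd = 2L, FIB = 3L)
CLASS_IDS <- c(ENDO = 1L, MID = 2L, EPI = 3L, FIBROBLAST = 4L)

.gpb_state_names <- c(
  "V_m", "m", "h", "j", "d", "f", "fcaB_j", "fcaB_sl", "x_tos", "y_tos",
  "x_tof", "y_tof", "x_kr", "x_ks", "ryr_r", "ryr_o", "ryr_i", "NaB_j",
  "NaB_sl", "TnCL", "TnCHc", "TnCHm", "CaM", "Myo_c", "Myo_m", "SRB",
  "SLL_j", "SLL_sl", "SLH_j", "SLH_sl", "Csqn_b", "Ca_sr", "Na_j", "Na_sl",
  "Na_i", "K_i", "Ca_j", "Ca_sl", "Ca_i", "mL", "hL")

.ord_state_names <- c(
  "V_m", "Na_i", "Na_ss", "K_i", "K_ss", "Ca_i", "Ca_ss", "Ca_nsr", "Ca_jsr",
  "m", "h_f", "h_s", "j", "h_sp", "j_p", "mL", "hL", "hL_p", "a", "i_F",
  "i_S", "a_p", "i_Fp", "i_Sp", "d", "f_f", "f_s", "f_caf", "f_cas", "j_ca",
  "n_ca", "f_fp", "f_cafp", "x_rf", "x_rs", "x_s1", "x_s2", "x_k1",
  "J_relnp", "J_relp", "CaMK_t")

.fib_state_names <- c("V_m", "r_Kv", "s_Kv")

.gpb_param_names <- c(
  "GNa", "GNaB", "IbarNaK", "GKr", "GKs", "GKp", "GtoSlow", "GtoFast", "GK1",
  "GClCa", "GClB", "PCa", "PK", "PNa", "IbarNCX", "ksat", "nu", "Kdact",
  "IbarSLCaP", "GCaB", "Vmax_SERCA", "Kmf", "Kmr", "hill_SERCA", "ks_rel",
  "koCa", "kom", "kiCa", "kim", "EC50_SR", "leak_const", "GNaL", "tau_hL",
  "KmNaip", "KmKo", "KmCai", "KmCao", "KmNai", "KmNao", "KmPCa")

.ord_param_names <- c(
  "GNa", "GNaL", "tau_hL", "Gto", "PCa", "GKr", "GKs", "GK1", "Gncx", "Pnak",
  "GKb", "PNab", "PCab", "GpCa", "Jup_base", "leak_base", "CaMK_scale",
  "Jrel_EC50", "Jrel_scale", "cmdn_max", "is_epi")

.fib_param_names <- c(
  "gKv", "gK1", "gbNa", "INaK_max", "KmK", "KmNa", "K_o", "Na_o", "K_i",
  "Na_i", "C_m")

.state_names <- function(model_id) {
  switch(model_id,
    GPB = .gpb_state_names, ORd = .ord_state_names, FIB = .fib_state_names,
    PAS = "V_m")
}
.param_names <- function(model_id) {
  switch(model_id,
    GPB = .gpb_param_names, ORd = .ord_param_names, FIB = .fib_param_names,
    PAS = c("g_leak", "E_leak"))
}

.check_model_class <- function(model_id, cell_class) {
  model_id <- match.arg(model_id, names(MODEL_IDS))
  cell_class <- match.arg(cell_class, names(CLASS_IDS))
  ok <- switch(model_id,
    GPB = cell_class %in% c("ENDO", "EPI"),
    ORd = cell_class %in% c("ENDO", "MID", "EPI"),
    FIB = cell_class == "FIBROBLAST",
    PAS = TRUE)
  if (!ok) {
    stop(sprintf(
      "unsupported model/class pair (%s, %s)%s", model_id, cell_class,
      if (model_id == "GPB" && cell_class == "MID")
        ": the GPB formulation has no M-cell variant" else ""),
      call. = FALSE)
  }
  list(model_id = model_id, cell_class = cell_class)
}

#' Default ionic parameter set for a model / cell-class pair
#'
#' Returns the published baseline parameters (conductances, permeabilities,
#' pump and SR-flux magnitudes) of the requested membrane model, with the
#' transmural cell-class multipliers already applied.  Heart-failure
#' remodeling rescales entries of this vector (see [apply_profile()]).
#'
#' @param model_id `"GPB"`, `"ORd"`, `"FIB"` or `"PAS"`.
#' @param cell_class `"ENDO"`, `"MID"`, `"EPI"` or `"FIBROBLAST"`.
#' @return Named numeric vector of class `ionic_params` with attributes
#'   `model_id` and `cell_class`.
#' @export
default_params <- function(model_id, cell_class = "ENDO") {
  mc <- .check_model_class(model_id, cell_class)
  p <- model_default_params_cpp(MODEL_IDS[[mc$model_id]],
                                CLASS_IDS[[mc$cell_class]])
  names(p) <- .param_names(mc$model_id)
  structure(p, model_id = mc$model_id, cell_class = mc$cell_class,
            class = c("ionic_params", "numeric"))
}

#' Initial membrane state for a model / cell-class pair
#'
#' Returns the published resting initial conditions of the base model; these
#' are intended as a starting point for pre-pacing, not as a steady state of
#' a remodeled cell.
#'
#' @inheritParams default_params
#' @return A `membrane_state` object: named state vector `y` (first entry
#'   `V_m`, mV; gates dimensionless; concentrations mM), simulation time `t`
#'   (ms) and identifiers.
#' @examples
#' st <- init_state("ORd", "EPI")
#' range(st$y[c("m", "h_f", "d")])
#' @export
init_state <- function(model_id, cell_class = "ENDO") {
  mc <- .check_model_class(model_id, cell_class)
  y <- model_init_cpp(MODEL_IDS[[mc$model_id]])
  names(y) <- .state_names(mc$model_id)
  structure(list(model_id = mc$model_id, cell_class = mc$cell_class,
                 y = y, t = 0),
            class = "membrane_state")
}

#' Advance a single cell's membrane kinetics by one time step
#'
#' Advances gating variables (exact exponential / Rush-Larsen update) and
#' ionic concentrations (forward Euler) by `dt` and performs the explicit
#' membrane update `V <- V + dt * (-I_ion + I_stim)`.
#'
#' @param state A `membrane_state`.
#' @param params Matching `ionic_params`.
#' @param I_stim Stimulus current, uA/uF (positive = depolarizing).
#' @param dt Time step, ms; must be positive and at most 0.02 ms for gating
#'   accuracy.
#' @return List with the advanced `state` and the total transmembrane ionic
#'   current `I_ion` (uA/uF) evaluated at the pre-step state.
#' @export
ionic_step <- function(state, params, I_stim = 0, dt = 0.02) {
  stopifnot(inherits(state, "membrane_state"))
  if (!(dt > 0 && dt <= 0.02)) {
    stop("dt must be in (0, 0.02] ms for gating accuracy", call. = FALSE)
  }
  if (attr(params, "model_id") != state$model_id) {
    stop("params belong to model ", attr(params, "model_id"),
         ", state to ", state$model_id, call. = FALSE)
  }
  res <- cell_step_cpp(MODEL_IDS[[state$model_id]], unname(state$y),
                       unname(params), I_stim, dt)
  y <- res$y
  if (any(!is.finite(y))) {
    stop(sprintf("non-finite state after step (model %s, t = %.3f ms)",
                 state$model_id, state$t + dt), call. = FALSE)
  }
  names(y) <- names(state$y)
  state$y <- y
  state$t <- state$t + dt
  list(state = state, I_ion = res$Iion)
}

#' Component currents of the active fibroblast membrane
#'
#' Evaluates the four fibroblast currents at the present state: the time- and
#' voltage-dependent K+ current, the inward-rectifier K+ current, the Na+/K+
#' pump current and the background Na+ current.  Their sum is the fibroblast
#' total ionic current.
#'
#' @param state A fibroblast `membrane_state`.
#' @param params Fibroblast `ionic_params` (defaults to the published set).
#' @return Named numeric vector `c(I_Kv, I_K1, I_NaK, I_bNa)` in uA/uF.
#' @export
fibroblast_currents <- function(state, params = default_params("FIB", "FIBROBLAST")) {
  stopifnot(inherits(state, "membrane_state"))
  if (state$model_id != "FIB") {
    stop("fibroblast_currents requires a FIB state, got ", state$model_id,
         call. = FALSE)
  }
  fib_currents_cpp(unname(state$y), unname(params))
}

#' Pure derivative evaluation of a membrane model
#'
#' Exposes the model right-hand side for reference integrations with a stiff
#' ODE solver (e.g. `deSolve::lsoda`).  `dy[1]` is `dV_m/dt`.
#'
#' @param model_id Model identifier.
#' @param y Unnamed state vector (first entry `V_m`).
#' @param params Parameter vector.
#' @param I_stim Stimulus current, uA/uF.
#' @return List with `dy` and `Iion`.
#' @export
cell_rhs <- function(model_id, y, params, I_stim = 0) {
  cell_rhs_cpp(MODEL_IDS[[model_id]], unname(y), unname(params), I_stim)
}

#' Pace a single cell at a fixed cycle length
#'
#' Convenience wrapper over the strand engine with a single node: applies
#' `n_beats` stimuli at basic cycle length `BCL` and returns the sampled
#' trace of the final beat together with the end state.
#'
#' @inheritParams ionic_step
#' @param BCL Basic cycle length, ms.
#' @param n_beats Number of stimuli.
#' @param stim_amp,stim_dur Stimulus amplitude (uA/uF) and duration (ms).
#' @param sample_interval Sampling interval of the returned final-beat trace
#'   (ms).
#' @return List with `state`, and final-beat `times`, `vm`, `cai` (ms, mV,
#'   mM), plus the beat onset time `stim_time`.
#' @export
pace_cell <- function(state, params, BCL = 1000, n_beats = 100, dt = 0.02,
                      stim_amp = 40, stim_dur = 2, sample_interval = 0.5) {
  stopifnot(inherits(state, "membrane_state"), n_beats >= 1)
  model <- MODEL_IDS[[state$model_id]]
  ns <- length(state$y)
  st <- matrix(unname(state$y), ncol = 1)
  pm <- matrix(unname(params), ncol = 1)
  t0 <- state$t
  if (n_beats > 1) {
    pre <- strand_solve_cpp(model, st, pm, numeric(0), 0.01, dt, t0,
                            (n_beats - 1) * BCL, 0L,
                            t0 + BCL * (seq_len(n_beats - 1) - 1),
                            stim_amp, stim_dur, BCL, t0, FALSE, 1.0)
    st <- pre$state
    t0 <- t0 + (n_beats - 1) * BCL
  }
  last <- strand_solve_cpp(model, st, pm, numeric(0), 0.01, dt, t0, BCL, 0L,
                           t0, stim_amp, stim_dur, sample_interval, t0, TRUE,
                           1.0)
  y <- as.numeric(last$state[, 1])
  names(y) <- names(state$y)
  state$y <- y
  state$t <- t0 + BCL
  list(state = state, times = as.numeric(last$times),
       vm = as.numeric(last$vm[, 1]), cai = as.numeric(last$cai[, 1]),
       stim_time = t0, upstroke_time = last$upstroke_time[1])
}
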