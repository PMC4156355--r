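test_that("model/class registry accepts supported pairs and rejects others", {
  expect_error(init_state("GPB", "MID"), "GPB, MID")
  expect_error(default_params("GPB", "MID"), "no M-cell")
  expect_error(init_state("FIB", "ENDO"), "FIB, ENDO")
  st <- init_state("ORd", "EPI")
  gates <- setdiff(names(st$y),
                   c("V_m", "Na_i", "Na_ss", "K_i", "K_ss", "Ca_i", "Ca_ss",
                     "Ca_nsr", "Ca_jsr", "J_relnp", "J_relp", "CaMK_t"))
  expect_true(all(st$y[gates] >= 0 & st$y[gates] <= 1))
  conc <- c("Na_i", "K_i", "Ca_i", "Ca_nsr", "Ca_jsr")
  expect_true(all(st$y[conc] > 0))
  expect_equal(length(st$y), 41)
})

test_that("ionic_step validates dt and model/params pairing", {
  st <- init_state("GPB", "ENDO")
  p <- default_params("GPB", "ENDO")
  expect_error(ionic_step(st, p, dt = 0.05), "dt")
  expect_error(ionic_step(st, p, dt = -1), "dt")
  expect_error(ionic_step(st, default_params("ORd", "ENDO")), "model")
  out <- ionic_step(st, p, I_stim = 0, dt = 0.02)
  expect_s3_class(out$state, "membrane_state")
  expect_true(is.finite(out$I_ion))
})

test_that("unstimulated membranes hold their rest (equilibrium persistence)", {
  for (mc in list(c("GPB", "ENDO"), c("ORd", "ENDO"), c("FIB", "FIBROBLAST"))) {
    st <- init_state(mc[1], mc[2])
    p <- default_params(mc[1], mc[2])
    # let the published initial conditions relax, then watch 10 s
    r1 <- pace_cell(st, p, BCL = 5000, n_beats = 1, stim_amp = 0)
    r2 <- pace_cell(r1$state, p, BCL = 10000, n_beats = 1, stim_amp = 0)
    drift <- abs(tail(r2$vm, 1) - r2$vm[1])
    expect_lt(drift, 0.5)
    # instantaneous dV/dt at the settled state
    dv <- abs(diff(tail(r2$vm, 3)) / 0.5)
    expect_true(all(dv < 0.01))
  }
})

test_that("fibroblast component currents behave as the formulation dictates", {
  st <- init_state("FIB", "FIBROBLAST")
  p <- default_params("FIB", "FIBROBLAST")
  # settle to the unstimulated equilibrium: component currents sum to ~0
  r <- pace_cell(st, p, BCL = 5000, n_beats = 1, stim_amp = 0)
  cur <- fibroblast_currents(r$state)
  expect_named(cur, c("I_Kv", "I_K1", "I_NaK", "I_bNa"))
  expect_lt(abs(sum(cur)), 0.01)
  # hyperpolarized: the inward rectifier carries inward (negative) current
  st$y["V_m"] <- -90
  expect_lt(fibroblast_currents(st)[["I_K1"]], 0)
  # depolarized to 0 mV with gates at their 0-mV steady state: net outward
  st$y["V_m"] <- 0
  st$y["r_Kv"] <- 1 / (1 + exp(-(0 + 20) / 11))
  st$y["s_Kv"] <- 1 / (1 + exp((0 + 23) / 7))
  expect_gt(sum(fibroblast_currents(st)), 0)
  expect_error(fibroblast_currents(init_state("GPB", "ENDO")), "FIB")
})

test_that("gates stay in [0,1] under paced stepping (boundedness property)", {
  cases <- list(c("GPB", "ENDO"), c("GPB", "EPI"), c("ORd", "ENDO"),
                c("ORd", "MID"), c("ORd", "EPI"))
  gate_idx <- list(
    GPB = c(2:14, 40, 41),          # HH gates, RyR handled separately
    ORd = 10:38)
  for (mc in cases) {
    p <- default_params(mc[1], mc[2])
    amp <- if (mc[1] == "ORd") 52 else 20
    r <- pace_cell(init_state(mc[1], mc[2]), p, BCL = 500, n_beats = 3,
                   stim_amp = amp, stim_dur = 1)
    g <- r$state$y[gate_idx[[mc[1]]]]
    expect_true(all(g >= 0 & g <= 1 + 1e-9),
                label = paste(mc[1], mc[2], "gates bounded"))
  }
})

test_that("fixed-step kernels match a stiff-solver reference integration", {
  for (model in c("GPB", "ORd")) {
    p <- default_params(model, "ENDO")
    amp <- if (model == "ORd") 52 else 20
    dur <- if (model == "ORd") 1 else 2
    dt <- if (model == "ORd") 0.005 else 0.02
    r <- pace_cell(init_state(model, "ENDO"), p, BCL = 1000, n_beats = 20,
                   dt = dt, stim_amp = amp, stim_dur = dur)
    y0 <- unname(r$state$y)
    f <- function(t, y, parms) {
      list(cell_rhs(model, y, p, if (t < dur) amp else 0)$dy)
    }
    out <- deSolve::lsoda(y0, seq(0, 1000, by = 0.5), f, NULL,
                          rtol = 1e-8, atol = 1e-8, maxsteps = 500000)
    a_ref <- apd90(out[, 2], out[, 1], 0)
    r2 <- pace_cell(r$state, p, BCL = 1000, n_beats = 1, dt = dt,
                    stim_amp = amp, stim_dur = dur)
    a_fix <- apd90(r2$vm, r2$times, r2$stim_time)
    expect_lt(abs(a_fix - a_ref), 2, label = paste(model, "APD90 vs reference"))
    vm_fix <- approx(r2$times - r2$stim_time, r2$vm, out[, 1])$y
    mask <- out[, 1] > 10  # away from the upstroke
    expect_lt(max(abs(vm_fix - out[, 2])[mask]), 1,
              label = paste(model, "V_m vs reference"))
  }
})

test_that("ORd transmural classes order as midmyocardial > endo, epi", {
  a_mid <- cell_apd("ORd", "MID")
  expect_gt(a_mid, cell_apd("ORd", "ENDO"))
  expect_gt(a_mid, cell_apd("ORd", "EPI"))
})
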