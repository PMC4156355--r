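# passive-strand helpers: model id 0 is a linear membrane I_ion = g*(V - E)
passive_nodes <- function(n, v0, g = 0, E = 0) {
  state <- matrix(v0, nrow = 1, ncol = n)
  params <- matrix(rep(c(g, E), n), nrow = 2)
  structure(list(model = rep(0L, n), state = state, params = params),
            class = "node_set")
}
passive_layout <- function(n, D = 0.0006, dx = 0.01) {
  lay <- build_transmural_layout("GPB", c(ENDO = n), D_myo = D, dx = dx)
  lay
}

test_that("pure diffusion preserves a uniform profile to machine precision", {
  lay <- passive_layout(20)
  cfg <- sim_config(stim_amp = 0, diff_scale = 1)
  nodes <- passive_nodes(20, v0 = -70)
  tr <- solve_strand(lay, nodes, cfg, 10, record_cai = FALSE)
  expect_true(all(abs(tr$vm - (-70)) < 1e-9))
})

test_that("sealed ends conserve the spatial mean and flatten a bump", {
  n <- 40
  lay <- passive_layout(n)
  cfg <- sim_config(stim_amp = 0, diff_scale = 1)
  x <- seq_len(n)
  v0 <- -80 + 30 * exp(-((x - 20)^2) / 8)
  nodes <- passive_nodes(n, v0 = 0)
  nodes$state[1, ] <- v0
  tr <- solve_strand(lay, nodes, cfg, 200, record_cai = FALSE)
  v_end <- tr$vm[nrow(tr$vm), ]
  expect_lt(abs(mean(v_end) - mean(v0)), 1e-9)
  expect_lt(max(v_end) - min(v_end), 0.5)  # nearly uniform after 200 ms
})

test_that("implicit diffusion matches a fine-dt explicit reference", {
  n <- 20
  D <- 0.0006
  dx <- 0.01
  g <- 0.05
  E <- -80
  x <- seq_len(n)
  v0 <- -80 + 25 * exp(-((x - 10)^2) / 4)
  lay <- passive_layout(n, D = D, dx = dx)
  cfg <- sim_config(dt = 0.005, stim_amp = 0, diff_scale = 1)
  nodes <- passive_nodes(n, v0 = 0, g = g, E = E)
  nodes$state[1, ] <- v0
  tr <- solve_strand(lay, nodes, cfg, 20, record_cai = FALSE)
  v_impl <- tr$vm[nrow(tr$vm), ]
  # brute-force reference: explicit Euler at dt/100 on the same stencil
  v <- v0
  dt_ref <- 0.005 / 100
  r <- D * dt_ref / dx^2
  for (k in seq_len(20 / dt_ref)) {
    lap <- c(v[2] - v[1], v[-(1:2)] - 2 * v[2:(n - 1)] + v[1:(n - 2)],
             v[n - 1] - v[n])
    v <- v + r / dt_ref * dt_ref * lap - dt_ref * g * (v - E)
  }
  expect_lt(max(abs(v_impl - v)), 0.1)
})

test_that("implicit diffusion obeys the discrete maximum principle at any dt", {
  n <- 30
  for (dt in c(0.01, 0.02)) {
    lay <- passive_layout(n)
    cfg <- sim_config(dt = dt, stim_amp = 0, diff_scale = 1)
    x <- seq_len(n)
    v0 <- -85 + 100 * (x == 15)  # extreme spike
    nodes <- passive_nodes(n, v0 = 0)
    nodes$state[1, ] <- v0
    tr <- solve_strand(lay, nodes, cfg, 5, sample_interval = dt,
                       record_cai = FALSE)
    expect_true(all(tr$vm <= max(v0) + 1e-9))
    expect_true(all(tr$vm >= min(v0) - 1e-9))
  }
})

test_that("identical configurations produce bit-identical traces", {
  lay <- build_transmural_layout("GPB", c(ENDO = 10, EPI = 10))
  cfg <- sim_config(n_beats = 1)
  t1 <- solve_strand(lay, make_node_states(lay), cfg, 400, stim_times = 0)
  t2 <- solve_strand(lay, make_node_states(lay), cfg, 400, stim_times = 0)
  expect_identical(t1$vm, t2$vm)
  expect_identical(t1$nodes$state, t2$nodes$state)
})

test_that("solver reports non-finite membrane potential with context", {
  lay <- passive_layout(5)
  cfg <- sim_config(stim_amp = 1e12, stim_dur = 5, stim_nodes = 1,
                    diff_scale = 1)
  nodes <- passive_nodes(5, v0 = -80, g = 1e9, E = 1e30)
  expect_error(solve_strand(lay, nodes, cfg, 5, stim_times = 0), "non-finite")
})

test_that("conduction velocity rises with the diffusion coefficient", {
  cvs <- vapply(c(0.00025, 0.0003, 0.00045, 0.0006), function(D) {
    cached(sprintf("cv_D_%g", D), {
      lay <- build_transmural_layout("GPB", D_myo = D)
      cfg <- sim_config(n_beats = 5)
      tr <- solve_strand(lay, make_node_states(lay), cfg, 5000,
                         stim_times = seq(0, 4000, by = 1000), t0 = 0,
                         track_from = 4000, sample_interval = 1000,
                         record_cai = FALSE)
      conduction_velocity(tr, lay)
    })
  }, 1.0)
  expect_true(all(diff(cvs) > 0))
  # continuous-cable limit: CV scales ~ sqrt(D)
  ratio <- cvs[4] / cvs[2]
  expect_lt(abs(ratio - sqrt(2)) / sqrt(2), 0.10)
})

test_that("pace_to_steady_state reports a convergence metric", {
  run <- gpb_paced("CONTROL")
  expect_true(is.finite(run$paced$convergence))
  expect_lt(run$paced$convergence, 1)
  expect_equal(run$paced$stim_time, 29000)
  # single-beat pacing degenerates gracefully: no previous beat to compare
  lay <- build_transmural_layout("GPB", c(ENDO = 5, EPI = 5))
  one <- pace_to_steady_state(lay, sim_config(n_beats = 1))
  expect_null(one$prev)
})

test_that("S1-S2 bisection honors its bracket contract", {
  run <- gpb_paced("CONTROL")
  erp <- gpb_erp("CONTROL")
  expect_true(erp > 150 && erp <= 1000)
  expect_equal(erp, round(erp))  # 1-ms resolution
  # a bracket whose upper end cannot propagate raises an error
  expect_error(measure_erp(run$lay, run$paced$nodes, run$cfg,
                           bracket = c(30, 50)),
               "does not propagate")
})

test_that("axial currents are sign-resolved node fluxes", {
  lay <- passive_layout(2)
  tr <- structure(list(times = c(0, 1), vm = matrix(c(-60, -60, -80, -80), 2),
                       layout = lay, diff_scale = 1, cap_scale = c(1, 1)),
                  class = "trace_set")
  ax <- axial_currents(tr, lay)
  # node 1 is higher: current leaves node 1 and enters node 2
  expect_true(all(ax$I_out[, 1] > 0))
  expect_true(all(ax$I_in[, 2] > 0))
  expect_true(all(ax$I_in[, 1] == 0))
  expect_true(all(ax$I_out[, 2] == 0))
  # uniform potential: no axial current anywhere
  tru <- structure(list(times = c(0, 1), vm = matrix(-70, 2, 2),
                        layout = lay, diff_scale = 1, cap_scale = c(1, 1)),
                   class = "trace_set")
  axu <- axial_currents(tru, lay)
  expect_true(all(axu$I_in == 0) && all(axu$I_out == 0))
})
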