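test_that("APD90 recovers the closed-form value of a trapezoidal AP", {
  t <- seq(0, 400, by = 0.5)
  v <- ifelse(t < 10, -85,
       ifelse(t < 11, -85 + 120 * (t - 10),
       ifelse(t < 261, 35,
       ifelse(t < 311, 35 - 120 * (t - 261) / 50, -85))))
  # rest -85, peak +35, V90 = -73; plateau 250 ms then 45 of the 50-ms fall
  expect_lt(abs(apd90(v, t, 9) - 295), 1)
  # subthreshold trace is flagged as no-capture
  flat <- rep(-85, length(t)) + 2 * exp(-((t - 20)^2) / 10)
  a <- apd90(flat, t, 9)
  expect_true(is.na(a))
  expect_true(isTRUE(attr(a, "no_capture")))
})

test_that("APD90 is robust to the sampling interval (interpolation contract)", {
  # a conducted strand beat, finely sampled, downsampled to 0.5 and 1 ms
  run <- cached("apd_sampling", {
    lay <- build_transmural_layout("GPB", c(ENDO = 40))
    cfg <- sim_config(n_beats = 4)
    pre <- solve_strand(lay, make_node_states(lay), cfg, 3000,
                        stim_times = c(0, 1000, 2000), t0 = 0,
                        sample_interval = 1000, record_cai = FALSE)
    solve_strand(lay, pre$nodes, cfg, 1000, stim_times = 3000, t0 = 3000,
                 track_from = 3000, sample_interval = 0.1, record_cai = FALSE)
  })
  v <- run$vm[, 20]
  t <- run$times
  a <- vapply(c(1, 5, 10), function(by) {
    k <- seq(1, length(t), by = by)
    apd90(v[k], t[k], 3000)
  }, 1.0)
  expect_lt(max(a) - min(a), 1)
})

test_that("dispersion uses the interior slice only and ignores NA nodes", {
  expect_equal(dispersion(rep(7, 165)), 0)
  vals <- rep(100, 165)
  vals[3] <- 150     # edge extreme must be excluded
  vals[50] <- 120
  vals[100] <- 100
  expect_equal(dispersion(vals), 20)
  vals[60] <- NA     # fibroblast node
  expect_equal(dispersion(vals), 20)
  # permutation invariance of the interior
  interior <- vals[16:150]
  vals2 <- vals
  vals2[16:150] <- sample(interior)
  expect_equal(dispersion(vals2), dispersion(vals))
  expect_error(dispersion(rep(1, 30)), "edge_exclude")
})

test_that("repolarization time decomposes into delay plus APD90", {
  # uniform APD, finite conduction delay: TDR equals the activation spread
  apd <- rep(200, 165)
  up <- 1000 + (0:164) * 0.2
  rts <- repolarization_time(apd, up, 1000)
  expect_equal(tdr(rts), (150 - 16) * 0.2)
  # no conduction delay: TDR equals APD dispersion
  apd2 <- 200 + sin(seq_len(165))
  rts2 <- repolarization_time(apd2, rep(1000, 165), 1000)
  expect_equal(tdr(rts2), dispersion(apd2))
})

test_that("TDR is bounded by activation spread plus APD dispersion", {
  run <- gpb_paced("CONTROL")
  rep_ <- run$report
  act <- run$paced$last$upstroke_time
  act_spread <- dispersion(act)
  expect_lte(rep_$summary$TDR,
             act_spread + rep_$summary$APD_dispersion + 1e-9)
})

test_that("CaTD80 and AP-Ca delay recover closed-form synthetic values", {
  t <- seq(0, 500, by = 0.5)
  ca <- ifelse(t < 50, 1e-4,
        ifelse(t < 60, 1e-4 + 7e-4 * (t - 50) / 10,
        ifelse(t < 260, 8e-4 - 7e-4 * (t - 60) / 200, 1e-4)))
  # 80% recovery level 2.4e-4 is crossed at t = 220; upstroke sample 50.5
  expect_lt(abs(catd80(ca, t, 45) - (220 - 50.5)), 1)
  flat <- rep(1e-4, length(t))
  expect_true(is.na(catd80(flat, t, 45)))
  # identical upstroke shapes give zero AP-Ca delay
  v <- -85 + 1e5 * ca
  expect_equal(ap_ca_delay(v, ca, t, 45), 0)
})

test_that("conduction velocity follows from upstroke times and reports block", {
  lay <- build_transmural_layout("GPB")
  fake <- structure(list(upstroke_time = 1000 + (0:164) * 0.2,
                         vmax = rep(40, 165), layout = lay),
                    class = "trace_set")
  expect_equal(conduction_velocity(fake, lay), 50)
  blocked <- fake
  blocked$vmax[100:165] <- -79
  expect_error(conduction_velocity(blocked, lay), "last activated node: 99")
})

test_that("safety factor exceeds 1 in uniform propagation and matches the brute-force path", {
  s <- small_strand()
  sf <- safety_factor(s$tr, s$lay, nodes_idx = 10:20)
  expect_true(all(sf > 1))
  for (node in c(12, 16)) {
    bf <- safety_factor_bruteforce(s$tr, node, s$lay)
    fast <- safety_factor(s$tr, s$lay, nodes_idx = node)
    expect_lt(abs(fast - bf) / bf, 0.01)
  }
  # axial inflow precedes the local upstroke at a mid-strand node
  ax <- axial_currents(s$tr, s$lay)
  node <- 15
  up <- s$tr$upstroke_time[node]
  before <- s$tr$times < up & s$tr$times > up - 2
  expect_gt(max(ax$I_in[before, node]), 0)
})

test_that("Welch two-sample test matches a hand-computed example", {
  expect_equal(two_sample_ttest(c(1, 1, 1), c(1, 1, 1)), list(t = 0, p = 1))
  res <- two_sample_ttest(c(0, 0, 0), c(1, 1, 1) + c(1e-6, -1e-6, 0))
  expect_lt(res$p, 0.001)
  # hand-computed Welch statistic for A = 1:4, B = {2,4,6,8,10}
  A <- 1:4
  B <- c(2, 4, 6, 8, 10)
  se2 <- var(A) / 4 + var(B) / 5
  t_hand <- (mean(A) - mean(B)) / sqrt(se2)
  df_hand <- se2^2 / ((var(A) / 4)^2 / 3 + (var(B) / 5)^2 / 4)
  p_hand <- 2 * pt(t_hand, df_hand)
  res <- two_sample_ttest(A, B)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
})

test_that("biomarker reports assemble per-node values and export to text", {
  run <- gpb_paced("CONTROL")
  rep_ <- run$report
  expect_s3_class(rep_, "biomarker_report")
  expect_equal(nrow(rep_$per_node), 165)
  myo <- rep_$per_node$class != "FIBROBLAST"
  expect_true(all(is.finite(rep_$per_node$APD90[myo])))
  expect_true(all(rep_$per_node$RT[myo] >= rep_$per_node$APD90[myo]))
  expect_true(rep_$summary$APD_dispersion >= 0 && rep_$summary$TDR >= 0)
  path <- tempfile(fileext = ".tsv")
  write_report(rep_, path)
  lines <- readLines(path)
  expect_equal(length(grep("^# ", lines)), length(rep_$summary))
  expect_equal(length(lines), 1 + 165 + 1 + length(rep_$summary))
  unlink(path)
})
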