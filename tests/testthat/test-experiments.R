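test_that("a scenario spec fully determines the run (byte-identical reports)", {
  sp <- scenario_spec("GPB", c(ENDO = 20, EPI = 20),
                      pacing = list(BCL = 1000, n_beats = 2))
  r1 <- run_scenario(sp)
  r2 <- run_scenario(sp)
  expect_identical(r1$report$per_node, r2$report$per_node)
  expect_identical(r1$report$summary, r2$report$summary)
})

test_that("manifests carry everything needed to regenerate a run", {
  sp <- scenario_spec("GPB", c(ENDO = 20, EPI = 20),
                      remodeling = "HF_HOMOG", uncoupling = "mild",
                      fibrosis = list(type = "diffuse", fraction = 0.1,
                                      seed = 3),
                      pacing = list(BCL = 1000, n_beats = 2))
  r1 <- run_scenario(sp)
  sp2 <- do.call(scenario_spec, r1$manifest$spec[
    c("model_id", "composition", "remodeling", "uncoupling", "fibrosis",
      "pacing", "measure_erp")])
  r2 <- run_scenario(sp2)
  expect_identical(r1$report$summary, r2$report$summary)
})

test_that("fibrosis sweeps validate inputs and flag degenerate statistics", {
  base <- scenario_spec("GPB", remodeling = "HF_HOMOG")
  expect_error(run_fibrosis_sweep(base, seeds = integer(0)), "seed")
  small <- scenario_spec("GPB", c(ENDO = 20, EPI = 20),
                         remodeling = "HF_HOMOG",
                         pacing = list(BCL = 1000, n_beats = 2))
  res <- run_fibrosis_sweep(small, fractions = 0.1, seeds = 5)
  expect_equal(nrow(res$summary), 1)
  expect_true(is.na(res$summary$APD_dispersion_sd))
  expect_length(res$tests, 0)
})

test_that("the scenario matrix covers every in-scope experiment family", {
  m <- scenario_matrix()
  modes <- vapply(m, function(s) s$remodeling, "")
  expect_true(all(c("CONTROL", "HF_HOMOG", "HF_HET_NCX", "HF_HET_SERCA",
                    "HF_HET_BOTH") %in% modes))
  # two-class and three-class transmural strands in both models
  expect_true(any(vapply(m, function(s) s$model_id == "ORd" &&
                           is.null(s$composition), TRUE)))
  expect_true(any(vapply(m, function(s) s$model_id == "ORd" &&
                           !is.null(s$composition), TRUE)))
  # diffuse fibrosis with and without uncoupling, both fractions
  fib <- Filter(function(s) !is.null(s$fibrosis) &&
                  s$fibrosis$type == "diffuse", m)
  expect_true(any(vapply(fib, function(s) s$fibrosis$fraction == 0.1, TRUE)))
  expect_true(any(vapply(fib, function(s) s$fibrosis$fraction == 0.2, TRUE)))
  expect_true(any(vapply(fib, function(s) s$uncoupling != "none", TRUE)))
  # safety-factor fiber: 900 endocardial cells, with a 25-node cluster case
  sf <- Filter(function(s) !is.null(s$composition) &&
                 identical(unname(s$composition), 900), m)
  expect_gte(length(sf), 3)
  expect_true(any(vapply(sf, function(s) !is.null(s$fibrosis) &&
                           s$fibrosis$type == "patchy" &&
                           s$fibrosis$size == 25, TRUE)))
})

test_that("uncoupling levels map to the published diffusion coefficients", {
  expect_equal(unname(UNCOUPLING_LEVELS[c("none", "mild", "normal-HF",
                                          "severe")]),
               c(0.0006, 0.00045, 0.0003, 0.00025))
})
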