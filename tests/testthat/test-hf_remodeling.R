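test_that("homogeneous heart-failure factor tables carry the published values", {
  pr <- build_profile("GPB", "HF_HOMOG")
  f <- pr$factors
  expect_equal(f$I_NaL, 2.00)
  expect_equal(f$tau_hL, 2.00)
  expect_equal(f$I_to, 0.40)
  expect_equal(f$I_K1, 0.68)
  expect_equal(f$I_NaK, 0.90)
  expect_equal(f$I_Nab, 0.0)
  expect_equal(f$I_Cab, 1.53)
  expect_equal(f$I_NCX, 1.75)
  expect_equal(f$J_SERCA, 0.50)
  expect_equal(f$I_leak, 3.00)
  expect_equal(f$EC_50SR, 0.89)

  po <- build_profile("ORd", "HF_HOMOG")$factors
  expect_equal(po$I_NaL, 1.80)
  expect_equal(po$tau_hL, 1.80)
  expect_equal(po$I_NaK, 0.70)
  expect_equal(po$I_Nab, 1.00)
  expect_equal(po$I_leak, 1.30)
  expect_equal(po$CaMKa, 1.50)
  expect_equal(po$Jrel_NP_Ca_sens, 0.80)
})

test_that("heterogeneous modes override only NCX/SERCA with class factors", {
  pr <- build_profile("ORd", "HF_HET_BOTH")
  expect_equal(pr$factors$I_NCX[["EPI"]], 2.00)
  expect_equal(pr$factors$I_NCX[["MID"]], 1.60)
  expect_equal(pr$factors$I_NCX[["ENDO"]], 1.60)
  expect_equal(pr$factors$J_SERCA[["EPI"]], 0.75)
  expect_equal(pr$factors$J_SERCA[["MID"]], 0.60)
  expect_equal(pr$factors$J_SERCA[["ENDO"]], 0.45)
  # all remaining entries equal the homogeneous profile
  hom <- build_profile("ORd", "HF_HOMOG")$factors
  for (nm in setdiff(names(pr$factors), c("I_NCX", "J_SERCA"))) {
    expect_equal(pr$factors[[nm]], hom[[nm]], label = nm)
  }
  # composition: HET_NCX == HOMOG with only the NCX entry replaced
  pn <- build_profile("GPB", "HF_HET_NCX")$factors
  hg <- build_profile("GPB", "HF_HOMOG")$factors
  expect_equal(pn$J_SERCA, hg$J_SERCA)
  expect_equal(pn$I_NCX[["ENDO"]], 1.6)
  expect_error(build_profile("GPB", "HF_SOMETHING"), "mode")
})

test_that("apply_profile rescales the mapped parameters and nothing else", {
  p <- default_params("GPB", "ENDO")
  hf <- apply_profile(p, build_profile("GPB", "HF_HOMOG"))
  expect_equal(unname(hf["GNaL"]), unname(2 * p["GNaL"]))
  expect_equal(unname(hf["Vmax_SERCA"]), unname(0.5 * p["Vmax_SERCA"]))
  expect_equal(unname(hf["GNaB"]), 0)
  expect_equal(unname(hf["GCaB"]), unname(1.53 * p["GCaB"]))
  expect_equal(unname(hf["EC50_SR"]), unname(0.89 * p["EC50_SR"]))
  # untouched parameters identical, input unchanged
  expect_identical(hf["GNa"], p["GNa"])
  expect_identical(unname(p["GNaB"]), 0.597e-3)

  ctrl <- apply_profile(p, build_profile("GPB", "CONTROL"))
  expect_identical(as.numeric(ctrl), as.numeric(p))

  po <- default_params("ORd", "ENDO")
  het <- apply_profile(po, build_profile("ORd", "HF_HET_SERCA"), "ENDO")
  expect_equal(unname(het["Jup_base"]), unname(0.45 * po["Jup_base"]))
  expect_equal(unname(het["Gncx"]), unname(1.75 * po["Gncx"]))
})

test_that("heart-failure remodeling prolongs the single-cell APD90 everywhere", {
  for (mc in list(c("GPB", "ENDO"), c("GPB", "EPI"), c("ORd", "ENDO"),
                  c("ORd", "MID"), c("ORd", "EPI"))) {
    expect_gt(cell_apd(mc[1], mc[2], "HF_HOMOG"),
              cell_apd(mc[1], mc[2], "CONTROL"),
              label = paste("HF APD90 >", mc[1], mc[2]))
  }
})
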