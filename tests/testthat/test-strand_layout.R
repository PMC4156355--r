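test_that("transmural compositions build the published geometries", {
  lay <- build_transmural_layout("GPB", D_myo = 0.0006, dx = 0.01)
  expect_equal(lay$n_nodes, 165)
  expect_equal((lay$n_nodes - 1) * lay$dx, 1.64)  # end-to-end distance, cm
  expect_equal(lay$node_class[82], "ENDO")
  expect_equal(lay$node_class[83], "EPI")
  expect_true(all(lay$D_elem == 0.0006))

  lo <- build_transmural_layout("ORd")
  expect_equal(lo$n_nodes, 170)
  expect_equal(as.numeric(table(lo$node_class)[c("ENDO", "MID", "EPI")]),
               c(60, 45, 65))
  expect_equal(lo$node_class[60], "ENDO")
  expect_equal(lo$node_class[61], "MID")
  expect_equal(lo$node_class[105], "MID")
  expect_equal(lo$node_class[106], "EPI")

  tiny <- build_transmural_layout("GPB", c(ENDO = 1, EPI = 1))
  expect_equal(tiny$n_nodes, 2)
  expect_length(tiny$D_elem, 1)

  expect_error(build_transmural_layout("GPB", c(ENDO = 60, MID = 45, EPI = 65)),
               "GPB")
  expect_error(build_transmural_layout("GPB", c(ENDO = 0, EPI = 5)), ">= 1")
})

test_that("diffuse fibrosis draws the exact seeded node set and D/3 elements", {
  lay <- build_transmural_layout("GPB")
  f10 <- insert_diffuse_fibrosis(lay, 0.10, seed = 7)
  expect_equal(sum(f10$node_class == "FIBROBLAST"), 17)  # round(16.5)
  f10b <- insert_diffuse_fibrosis(lay, 0.10, seed = 7)
  expect_identical(f10$node_class, f10b$node_class)
  expect_identical(f10$D_elem, f10b$D_elem)
  f10c <- insert_diffuse_fibrosis(lay, 0.10, seed = 8)
  expect_false(identical(f10$node_class, f10c$node_class))

  f20 <- insert_diffuse_fibrosis(lay, 0.20, seed = 3)
  expect_equal(sum(f20$node_class == "FIBROBLAST"), 33)
  fib <- f20$node_class == "FIBROBLAST"
  adj <- fib[-165] | fib[-1]
  expect_true(all(f20$D_elem[adj] == 0.0006 / 3))
  expect_true(all(f20$D_elem[!adj] == 0.0006))
  # non-fibroblast nodes keep their class
  expect_identical(f20$node_class[!fib], lay$node_class[!fib])
  expect_identical(f20$underlying_class, lay$node_class)

  expect_identical(insert_diffuse_fibrosis(lay, 0, seed = 1), lay)
  expect_error(insert_diffuse_fibrosis(lay, 0.6, seed = 1), "fraction")
  expect_error(insert_diffuse_fibrosis(lay, 0.1), "seed")
})

test_that("patchy fibrosis places contiguous clusters and respects bounds", {
  lay <- build_transmural_layout("GPB", c(ENDO = 900))
  cl <- insert_patchy_fibrosis(lay, 25, 438)
  expect_equal(which(cl$node_class == "FIBROBLAST"), 438:462)
  one <- insert_patchy_fibrosis(lay, 1, 100)
  expect_equal(sum(one$node_class == "FIBROBLAST"), 1)
  two <- insert_patchy_fibrosis(cl, 25, 700)
  expect_equal(sum(two$node_class == "FIBROBLAST"), 50)
  expect_error(insert_patchy_fibrosis(lay, 25, 890), "overflow")
})

test_that("the interface rule keeps fibroblast-internal elements at D_myo", {
  lay <- build_transmural_layout("GPB", c(ENDO = 100))
  cl <- insert_patchy_fibrosis(lay, 10, 40)
  expect_true(all(cl$D_elem[40:48] == 0.0006 / 3))  # internal, "any" rule
  ifc <- fibrosis_d_rule(cl, "interface")
  expect_true(all(ifc$D_elem[40:48] == 0.0006))     # internal back to D_myo
  expect_equal(ifc$D_elem[39], 0.0006 / 3)          # interfaces stay reduced
  expect_equal(ifc$D_elem[49], 0.0006 / 3)
})

test_that("uncoupling rescales myocyte and fibroblast-adjacent elements", {
  lay <- build_transmural_layout("GPB")
  un <- uncoupling_variant(lay, 0.0003)
  expect_true(all(un$D_elem == 0.0003))
  f <- insert_diffuse_fibrosis(lay, 0.1, seed = 2)
  fu <- uncoupling_variant(f, 0.0003)
  fib <- fu$node_class == "FIBROBLAST"
  adj <- fib[-165] | fib[-1]
  expect_true(all(abs(fu$D_elem[adj] - 0.0001) < 1e-12))
  expect_true(all(fu$D_elem[!adj] == 0.0003))
  same <- uncoupling_variant(lay, lay$D_myo)
  expect_identical(same$D_elem, lay$D_elem)
})

test_that("fibroblast positions are approximately uniform across seeds", {
  lay <- build_transmural_layout("GPB")
  counts <- c(0, 0, 0)
  for (s in 1:11) {
    f <- insert_diffuse_fibrosis(lay, 0.1, seed = s)
    pos <- which(f$node_class == "FIBROBLAST")
    counts <- counts + c(sum(pos <= 55), sum(pos > 55 & pos <= 110),
                         sum(pos > 110))
  }
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("layouts serialize to a plain-text table and restore losslessly", {
  lay <- insert_diffuse_fibrosis(build_transmural_layout("GPB"), 0.1, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_equal(back$n_nodes, lay$n_nodes)
  expect_identical(back$node_class, lay$node_class)
  expect_equal(back$D_elem, lay$D_elem)
  expect_equal(back$dx, lay$dx)
  expect_equal(back$seed, lay$seed)
  unlink(path)
})
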