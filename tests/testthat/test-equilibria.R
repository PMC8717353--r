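# Equilibrium finding and local stability typing.

test_that("the symmetric weak-benefit linear model has its four hand-derived equilibria", {
  p <- list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5)
  eq <- findEquilibria("case_1_1_1", p, box = c(0, 5))
  expect_identical(nrow(eq), 4L)
  expect_setequal(eq$class, c("origin", "axis_1", "axis_2", "interior"))
  inter <- eq[eq$class == "interior", ]
  expect_equal(c(inter$N1, inter$N2), c(2, 2), tolerance = 1e-8)
  expect_identical(inter$type, "stable_node")
  expect_identical(eq$type[eq$class == "origin"], "unstable_node")
  expect_identical(unique(eq$type[grepl("^axis", eq$class)]), "saddle")
  # hand-differentiated Jacobian at the interior equilibrium
  J <- evalJacobian("case_1_1_1", p, c(2, 2))
  expect_equal(J, matrix(c(-2, 1, 1, -2), 2), tolerance = 1e-8)
})

test_that("the obligate strong-benefit linear model has an interior saddle at (0.5, 0.5)", {
  eq <- findEquilibria("case_1_1_1",
                       list(r1 = -0.5, r2 = -0.5, b12 = 2, b21 = 2),
                       box = c(0, 5))
  inter <- eq[eq$class == "interior", ]
  expect_identical(nrow(inter), 1L)
  expect_equal(c(inter$N1, inter$N2), c(0.5, 0.5), tolerance = 1e-8)
  expect_identical(inter$type, "saddle")
})

test_that("single-species equilibrium is the largest root on the own axis, zero when obligate", {
  expect_equal(singleSpeciesEquilibrium("case_1_1_1",
                                        list(r1 = 1, r2 = 1), 1), 1,
               tolerance = 1e-8)
  expect_equal(singleSpeciesEquilibrium("case_1_1_1",
                                        list(r1 = -0.5, r2 = 1), 1), 0)
  expect_equal(singleSpeciesEquilibrium("case_3_1", list(K1 = 2), 1), 2,
               tolerance = 1e-6)
})

test_that("eigenvalue classification covers nodes, spirals, saddles and flags nonhyperbolic pairs", {
  expect_identical(classifyEigenvalues(c(-1, -2)), "stable_node")
  expect_identical(classifyEigenvalues(c(1, 2)), "unstable_node")
  expect_identical(classifyEigenvalues(c(-1, 2)), "saddle")
  expect_identical(classifyEigenvalues(c(-1 + 2i, -1 - 2i)), "stable_spiral")
  expect_identical(classifyEigenvalues(c(1 + 2i, 1 - 2i)), "unstable_spiral")
  expect_identical(classifyEigenvalues(c(0 + 1i, 0 - 1i)), "nonhyperbolic")
  expect_identical(classifyEigenvalues(c(0, -1)), "nonhyperbolic")
})

test_that("equilibrium sets are stable under grid refinement", {
  p <- canonicalParams("holland_deangelis_eq13_bidir",
                       "five_interior_equilibria")
  s1 <- analysisSettings(grid_equilibria = 96)
  s2 <- analysisSettings(grid_equilibria = 160)
  e1 <- findEquilibria("holland_deangelis_eq13_bidir", p, c(0, 5), s1)
  e2 <- findEquilibria("holland_deangelis_eq13_bidir", p, c(0, 5), s2)
  expect_identical(nrow(e1), nrow(e2))
  o1 <- order(e1$N1, e1$N2); o2 <- order(e2$N1, e2$N2)
  expect_equal(e1$N1[o1], e2$N1[o2], tolerance = 1e-6)
  expect_identical(e1$type[o1], e2$type[o2])
})
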