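# Event-detecting integration, basin mapping, separatrices, oscillation.

test_that("integration detects convergence, unbounded growth and extinction events", {
  # weak symmetric benefit: orbit settles at the interior node (2, 2)
  tr <- integrateModel("case_1_1_1", list(r1 = 1, r2 = 1,
                                          b12 = 0.5, b21 = 0.5),
                       c(0.2, 3), t_max = 300, box = c(0, 20))
  expect_identical(tr$terminal_event, "converged")
  expect_equal(tr$final, c(2, 2), tolerance = 1e-3, ignore_attr = TRUE)

  # strong benefit: the mutual amplification diverges
  tr <- integrateModel("case_1_1_1", list(r1 = 1, r2 = 1, b12 = 2, b21 = 2),
                       c(1, 1), t_max = 300, box = c(0, 20))
  expect_identical(tr$terminal_event, "unbounded")

  # obligate pair with rapid decay: both cross the extinction floor
  tr <- integrateModel("case_1_1_1", list(r1 = -2, r2 = -2,
                                          b12 = 0.1, b21 = 0.1),
                       c(0.3, 0.3), t_max = 300, box = c(0, 20))
  expect_identical(tr$terminal_event, "extinct")
  expect_setequal(tr$extinct_species, 1:2)

  # slow obligate decay instead converges onto the stable origin
  tr <- integrateModel("case_1_1_1", list(r1 = -0.5, r2 = -0.5,
                                          b12 = 0.5, b21 = 0.5),
                       c(0.3, 0.3), t_max = 300, box = c(0, 20))
  expect_identical(tr$terminal_event, "converged")
  expect_equal(tr$final, c(0, 0), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("trajectories remain nonnegative and inside the event budget", {
  tr <- integrateModel("case_1_2", canonicalParams("case_1_2", "SC"),
                       c(0.05, 4), t_max = 200, box = c(0, 10),
                       keep_series = TRUE)
  expect_true(all(tr$series$N1 >= 0))
  expect_true(all(tr$series$N2 >= 0))
  expect_identical(tr$terminal_event, "converged")
})

test_that("basin maps split a threshold system into collapse and coexistence basins", {
  p <- canonicalParams("case_1_2", "HD SC & SC/E threshold")
  bm <- basinMap("case_1_2", p, box = c(0, 5), grid_n = 15, t_max = 200)
  labs <- unique(bm$grid$label)
  # collapse basin is labelled by the stable origin equilibrium
  expect_true(any(grepl("^eq_origin", labs)))
  expect_true(any(grepl("^eq_interior", labs)))
  # everything is labelled: no horizon cells at this horizon
  expect_false("horizon" %in% labs)
  # the all-high corner coexists, the all-low corner collapses
  hi <- bm$grid$label[bm$grid$N1_0 == 5 & bm$grid$N2_0 == 5]
  expect_match(hi, "^eq_interior")
  # interior cells at the smallest sampled densities collapse
  small <- min(bm$grid$N1_0[bm$grid$N1_0 > 0])
  lo <- bm$grid$label[bm$grid$N1_0 == small & bm$grid$N2_0 == small]
  expect_match(lo, "^eq_origin")
})

test_that("the separatrix through the linear obligate saddle is consistent with the basin map", {
  p <- list(r1 = -0.5, r2 = -0.5, b12 = 2, b21 = 2)
  eq <- findEquilibria("case_1_1_1", p, box = c(0, 3))
  sad <- eq[eq$type == "saddle" & eq$class == "interior", ]
  expect_identical(nrow(sad), 1L)
  sep <- separatrix("case_1_1_1", p, sad, box = c(0, 3))
  expect_length(sep$branches, 2)
  bm <- basinMap("case_1_1_1", p, box = c(0, 3), grid_n = 15, t_max = 200)
  expect_gt(separatrixConsistency(sep, bm), 0.8)
  # non-saddle input is rejected
  inter <- eq[eq$class == "origin", ]
  expect_error(separatrix("case_1_1_1", p, inter), "saddle")
})

test_that("oscillation detection separates damped spirals from monotone nodes", {
  pnf <- canonicalParams("neuhauser_fargione_eq9", "damped_oscillation")
  o <- detectOscillation("neuhauser_fargione_eq9", pnf, c(0.6, 0.3),
                         t_max = 300)
  expect_identical(o$status, "damped")
  o2 <- detectOscillation("case_1_2", canonicalParams("case_1_2", "SC"),
                          c(0.3, 2.5))
  expect_identical(o2$status, "none")
})
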