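# Outcome classification, threshold probes, coexistence character, sweeps.

test_that("coexistence character distinguishes mutualistic from parasitic equilibria", {
  # weak symmetric benefit: both above their partner-free densities
  ch <- coexistenceCharacter("case_1_1_1",
                             list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
                             c(2, 2))
  expect_identical(ch$character, "mutualistic")
  # exploitation pulls the plant below its partner-free density and the
  # off-diagonal benefit to the plant turns negative
  pp <- canonicalParams("neuhauser_fargione_eq9", "parasitic_coexistence")
  eq <- findEquilibria("neuhauser_fargione_eq9", pp)
  ii <- eq[eq$class == "interior", ]
  ch2 <- coexistenceCharacter("neuhauser_fargione_eq9", pp,
                              c(ii$N1, ii$N2))
  expect_identical(ch2$character, "parasitic")
  expect_false(ch2$above_alone[1])
  # boundary states are rejected
  expect_error(coexistenceCharacter("case_1_1_1",
                                    list(r1 = 1, r2 = 1,
                                         b12 = 0.5, b21 = 0.5),
                                    c(0, 1)), "interior")
})

test_that("threshold probes type partner thresholds, Allee effects and overexploitation", {
  # partner threshold: collapse tracks the partner's density, not one's own
  p <- canonicalParams("case_1_2", "partner_threshold")
  rep <- classifyDynamics("case_1_2", p, grid_n = 15,
                          probe_thresholds = TRUE)
  expect_identical(rep$threshold_type, "partner_threshold")

  # own-density Allee effect: pollination benefit vanishes at low density
  ph <- canonicalParams("hale_eq19_7_pollination", "own_density_allee")
  rh <- classifyDynamics("hale_eq19_7_pollination", ph, grid_n = 15,
                         probe_thresholds = TRUE)
  expect_identical(rh$threshold_type, "own_density_allee")

  # overexploitation: collapse for partner density *above* the critical value
  pu <- canonicalParams("holland_deangelis_eq13_7_unidir",
                        "overexploitation")
  ru <- classifyDynamics("holland_deangelis_eq13_7_unidir", pu,
                         grid_n = 15, probe_thresholds = TRUE)
  expect_identical(ru$threshold_type, "overexploitation")

  # no saddle-split basin structure: no threshold reported
  rs <- classifyDynamics("case_1_1_1",
                         list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
                         grid_n = 13, probe_thresholds = TRUE)
  expect_identical(rs$threshold_type, "none")
})

test_that("outcome labels are invariant under doubling grid and horizon", {
  cases <- list(
    list("case_1_1_1", canonicalParams("case_1_1_1", "UC/E threshold")),
    list("case_1_2", canonicalParams("case_1_2", "HD SC & SC/E threshold")))
  for (cs in cases) {
    r1 <- classifyDynamics(cs[[1]], cs[[2]], grid_n = 11, t_max = 150,
                           probe_thresholds = FALSE)
    r2 <- classifyDynamics(cs[[1]], cs[[2]], grid_n = 22, t_max = 300,
                           probe_thresholds = FALSE)
    expect_identical(r1$outcome_label, r2$outcome_label, info = cs[[1]])
  }
})

test_that("parameter sweeps bracket the regime change of the linear model", {
  sw <- sweepParameter("case_1_1_1", list(r1 = 1, r2 = 1),
                       c("b12", "b21"), values = c(0.5, 0.8, 1.2, 2),
                       grid_n = 11)
  expect_identical(sw$table$label, c("SC", "SC", "UC", "UC"))
  expect_identical(nrow(sw$brackets), 1L)
  expect_equal(c(sw$brackets$lower, sw$brackets$upper), c(0.8, 1.2))
})

test_that("critical benefit bisection reports a bracketing error on one-sided brackets", {
  expect_error(
    criticalBenefitStrength("case_1_1_1", list(r1 = 1, r2 = 1),
                            c("b12", "b21"), bracket = c(0.1, 0.5),
                            iterations = 5),
    "bracket")
})
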