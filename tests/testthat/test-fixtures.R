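# The canonical fixture registry: coverage, validity, lookup errors.

test_that("the fixture registry covers every generic-case audit cell", {
  fx <- listFixtures()
  # single-case models with both-species coverage
  keys <- paste(fx$model, fx$regime, sep = "|")
  single <- c("case_1_1_1|SC", "case_1_1_1|UC",
              "case_1_1_1|UC/E threshold", "case_1_1_1|E",
              "case_1_2|SC", "case_1_2|HD SC & SC/E threshold")
  # asymmetric pairings: at least one plain regime and one threshold/UC
  pairs <- c("case_1_1_1:case_1_2", "case_1_1_2:case_1_1_1",
             "case_1_1_2:case_1_2", "case_1_1_3:case_1_1_1",
             "case_1_1_3:case_1_2", "case_1_2:case_1_1_1",
             "case_2_1:case_1_1_1", "case_2_1:case_1_2",
             "case_2_2:case_1_1_1", "case_2_2:case_1_2",
             "case_3_1:case_1_1_1", "case_3_1:case_1_2",
             "case_3_2:case_1_1_1", "case_3_2:case_1_2",
             "case_3_3:case_1_1_1", "case_3_3:case_1_2")
  expect_true(all(single %in% keys))
  for (pm in pairs)
    expect_gte(sum(fx$model == pm), 2)
  # every literature model with a distinct qualitative repertoire has a
  # fixture (the early linear-benefit variants are regime-equivalent to
  # the linear generic case and are pinned through it)
  lit <- c("wright_eq7", "zhang_eq8", "neuhauser_fargione_eq9",
           "graves_eq10", "thompson_eq11_12",
           "holland_deangelis_eq13_bidir",
           "holland_deangelis_eq13_7_unidir", "fishman_hadany_eq14_15",
           "kang_eq16", "martignoni_eq17_18", "hale_eq19_7_pollination",
           "hale_eq20_7_dispersal")
  expect_true(all(lit %in% fx$model))
  expect_identical(nrow(fx), 58L)
})

test_that("every committed parameter set validates against its model schema", {
  fx <- listFixtures()
  for (i in seq_len(nrow(fx))) {
    m <- getModel(fx$model[i])
    p <- canonicalParams(fx$model[i], fx$regime[i])
    expect_silent(validateParams(m, p))
  }
})

test_that("fixture labels come from the closed outcome vocabulary", {
  vocab <- c("SC", "UC", "E", "UC/E threshold", "SC/E threshold",
             "HD SC & SC/E threshold", "HD UC & UC/SC threshold",
             "multi-attractor")
  fx <- listFixtures()
  expect_true(all(fx$expected_label %in% vocab))
  thr <- fx$expected_threshold[!is.na(fx$expected_threshold)]
  expect_true(all(thr %in% c("partner_threshold", "own_density_allee",
                             "overexploitation")))
})

test_that("unknown fixture lookups fail with the covered regimes in the message", {
  expect_error(canonicalParams("case_1_1_1", "nope"),
               'regimes covered.*"SC"')
  expect_error(canonicalParams("not_a_model", "SC"), "covered models")
})
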