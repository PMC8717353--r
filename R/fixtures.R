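# Canonical fixture registry: curated parameterizations, found once by
# numerical search (seeded) or hand algebra and committed together with the
# qualitative regime they reproduce.  `classifyDynamics` on a fixture's
# parameters yields the fixture's expected outcome label (tested).

# each entry: model id, regime key, expected classifyDynamics label,
# expected threshold_type probe (or NA), parameter list, short provenance
.fixture <- function(model, regime, label, params, threshold = NA_character_,
                     note = "") {
  list(model = model, regime = regime, expected_label = label,
       expected_threshold = threshold, params = params, note = note)
}

.fixtureRegistry <- local({
  reg <- list(
    ## ---- generic-case audit: single-case symmetric pairs -----------------
    .fixture("case_1_1_1", "SC", "SC",
             list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
             note = "facultative pair, weak linear benefit"),
    .fixture("case_1_1_1", "UC", "UC",
             list(r1 = 1, r2 = 1, b12 = 2, b21 = 2),
             note = "facultative pair, strong linear benefit"),
    .fixture("case_1_1_1", "UC/E threshold", "UC/E threshold",
             list(r1 = -0.5, r2 = -0.5, b12 = 2, b21 = 2),
             note = "obligate pair, strong benefit; interior saddle (0.5, 0.5)"),
    .fixture("case_1_1_1", "E", "E",
             list(r1 = -0.5, r2 = -0.5, b12 = 0.5, b21 = 0.5),
             note = "obligate pair, weak benefit"),
    .fixture("case_1_2", "SC", "SC",
             list(r1 = 1, r2 = 1, b12 = 1, b21 = 1,
                  h12 = 1, h21 = 1, s1 = 1, s2 = 1),
             note = paste("symmetric saturating benefit; interior",
                          "equilibrium at the golden ratio (non-oscillatory",
                          "stable node)")),
    .fixture("case_1_2", "HD SC & SC/E threshold", "HD SC & SC/E threshold",
             list(r1 = -0.5, r2 = -0.5, b12 = 4, b21 = 4,
                  h12 = 1, h21 = 1, s1 = 1, s2 = 1),
             note = paste("obligate saturating pair; collapse below a",
                          "saddle (symmetric joint threshold, so the",
                          "directional probes report none)")),
    .fixture("case_1_2", "partner_threshold", "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 4, h12 = 1, s1 = 1,
                  r2 = -0.05, b21 = 0.4, h21 = 1, s2 = 0.1),
             threshold = "partner_threshold",
             note = paste("timescale-separated obligate pair: species 1",
                          "collapses when partner density falls below a",
                          "critical value regardless of its own density")),

    ## ---- generic-case audit: compound pairs ------------------------------
    .fixture("case_1_1_1:case_1_2", "SC", "SC",
             list(r1 = 1, b12 = 0.5, s1 = 1, th1 = 1,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_1_1_1:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 2, s1 = 1, th1 = 1,
                  r2 = -0.5, b21 = 4, h21 = 1, s2 = 1)),
    .fixture("case_1_1_2:case_1_1_1", "UC", "UC",
             list(r1 = 1, b12 = 2, s1 = 1, th1 = 0.5,
                  r2 = 1, b21 = 2, s2 = 1, th2 = 1)),
    .fixture("case_1_1_2:case_1_1_1", "UC/E threshold", "UC/E threshold",
             list(r1 = 1, b12 = 1, s1 = 1, th1 = 0.5,
                  r2 = -0.5, b21 = 0.3, s2 = 1, th2 = 1)),
    .fixture("case_1_1_2:case_1_2", "SC", "SC",
             list(r1 = 1, b12 = 0.5, s1 = 1, th1 = 0.5,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_1_1_2:case_1_2", "UC", "UC",
             list(r1 = 1, b12 = 1, s1 = 1, th1 = 0.5,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 0),
             note = "no self-limitation on species 2"),
    .fixture("case_1_1_2:case_1_2", "UC/E threshold", "UC/E threshold",
             list(r1 = 1, b12 = 1, s1 = 1, th1 = 0.5,
                  r2 = -0.5, b21 = 0.8, h21 = 1, s2 = 0)),
    .fixture("case_1_1_3:case_1_1_1", "SC", "SC",
             list(r1 = 1, b12 = 1, s1 = 1, th1 = 2,
                  r2 = 1, b21 = 1, s2 = 1, th2 = 1)),
    .fixture("case_1_1_3:case_1_1_1", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 2, s1 = 1, th1 = 2,
                  r2 = -0.5, b21 = 2, s2 = 1, th2 = 1)),
    .fixture("case_1_1_3:case_1_2", "SC", "SC",
             list(r1 = 1, b12 = 1, s1 = 1, th1 = 2,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_1_1_3:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 2, s1 = 1, th1 = 2,
                  r2 = -0.5, b21 = 4, h21 = 1, s2 = 1)),
    .fixture("case_1_2:case_1_1_1", "SC", "SC",
             list(r1 = 1, b12 = 1, h12 = 1, s1 = 1,
                  r2 = 1, b21 = 0.5, s2 = 1, th2 = 1)),
    .fixture("case_1_2:case_1_1_1", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 4, h12 = 1, s1 = 1,
                  r2 = -0.5, b21 = 1.2, s2 = 1, th2 = 1)),
    .fixture("case_2_1:case_1_1_1", "SC", "SC",
             list(r1 = 1, b12 = 1, h12 = 1, s1 = 1,
                  r2 = 1, b21 = 0.5, s2 = 1, th2 = 1)),
    .fixture("case_2_1:case_1_1_1", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 4, h12 = 1, s1 = 1,
                  r2 = -0.5, b21 = 1.2, s2 = 1, th2 = 1)),
    .fixture("case_2_1:case_1_2", "SC", "SC",
             list(r1 = 1, b12 = 1, h12 = 1, s1 = 1,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_2_1:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 4, h12 = 1, s1 = 1,
                  r2 = -0.5, b21 = 4, h21 = 1, s2 = 1)),
    .fixture("case_2_2:case_1_1_1", "SC", "SC",
             list(r1 = 1, b12 = 1, h12 = 1, s1 = 1,
                  r2 = 1, b21 = 0.5, s2 = 1, th2 = 1)),
    .fixture("case_2_2:case_1_1_1", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 8, h12 = 1, s1 = 1,
                  r2 = -0.5, b21 = 1.2, s2 = 1, th2 = 1)),
    .fixture("case_2_2:case_1_2", "SC", "SC",
             list(r1 = 1, b12 = 1, h12 = 1, s1 = 1,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_2_2:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, b12 = 8, h12 = 1, s1 = 1,
                  r2 = -0.5, b21 = 4, h21 = 1, s2 = 1)),
    .fixture("case_3_1:case_1_1_1", "SC", "SC",
             list(r1 = 1, K1 = 1, r2 = 1, b21 = 0.5, s2 = 1, th2 = 1)),
    .fixture("case_3_1:case_1_1_1", "UC", "UC",
             list(r1 = 1, K1 = 1, r2 = 1, b21 = 2, s2 = 1, th2 = 1)),
    .fixture("case_3_1:case_1_1_1", "UC/E threshold", "UC/E threshold",
             list(r1 = 1, K1 = 0, r2 = -0.5, b21 = 2, s2 = 1, th2 = 1),
             note = "species 1 obligate via K1 = 0"),
    .fixture("case_3_1:case_1_2", "SC", "SC",
             list(r1 = 1, K1 = 1, r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_3_1:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = 1, K1 = 0, r2 = -0.5, b21 = 4, h21 = 1, s2 = 1)),
    .fixture("case_3_2:case_1_1_1", "UC", "UC",
             list(r1 = 1, s1 = 1, b12 = 1, r2 = 1, b21 = 2, s2 = 1, th2 = 1)),
    .fixture("case_3_2:case_1_1_1", "HD UC & UC/SC threshold",
             "HD UC & UC/SC threshold",
             list(r1 = 1, s1 = 2, b12 = 1, r2 = 1, b21 = 0.1, s2 = 1, th2 = 1)),
    .fixture("case_3_2:case_1_2", "UC", "UC",
             list(r1 = 1, s1 = 1, b12 = 1, r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_3_2:case_1_2", "HD UC & UC/SC threshold",
             "HD UC & UC/SC threshold",
             list(r1 = 1, s1 = 2, b12 = 1, r2 = 1, b21 = 2, h21 = 20, s2 = 1)),
    .fixture("case_3_3:case_1_1_1", "SC", "SC",
             list(r1 = 1, s1 = 1, b12 = 1, h12 = 1,
                  r2 = 1, b21 = 0.5, s2 = 1, th2 = 1)),
    .fixture("case_3_3:case_1_1_1", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, s1 = 1, b12 = 3, h12 = 1,
                  r2 = 2, b21 = 0.3, s2 = 1, th2 = 1)),
    .fixture("case_3_3:case_1_2", "SC", "SC",
             list(r1 = 1, s1 = 1, b12 = 1, h12 = 1,
                  r2 = 1, b21 = 1, h21 = 1, s2 = 1)),
    .fixture("case_3_3:case_1_2", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold",
             list(r1 = -0.5, s1 = 1, b12 = 3, h12 = 1,
                  r2 = 2, b21 = 1, h21 = 1, s2 = 1)),

    ## ---- literature models ----------------------------------------------
    .fixture("wright_eq7", "SC", "SC", list(b12 = 0.5, b21 = 0.5)),
    .fixture("zhang_eq8", "multi-attractor", "multi-attractor",
             list(R1 = 1, R2 = 1, c1 = 3, c2 = 3,
                  a1 = 1, a2 = 1, bb1 = 1, bb2 = 1),
             note = paste("interior equilibria (2, 2) [saddle] and the",
                          "swapped pair ((3 +- sqrt(5))/2): bistable",
                          "dominance split by a separatrix")),
    .fixture("zhang_eq8", "E", "E",
             list(R1 = 1, R2 = 1, c1 = 2, c2 = 2,
                  a1 = 1, a2 = 1, bb1 = 0, bb2 = 0),
             note = paste("competitive exclusion: two stable single-species",
                          "states, winner set by initial densities")),
    .fixture("neuhauser_fargione_eq9", "SC", "SC", list(),
             note = "defaults; mutualistic stable coexistence"),
    .fixture("neuhauser_fargione_eq9", "damped_oscillation", "SC",
             list(r1 = 1.2, r2 = 0.14, g12 = 1.7, a21 = 2.7, a = 0.75),
             note = paste("weakly damped stable spiral (eigenvalues",
                          "~ -0.13 +- 0.26i): damped oscillations")),
    .fixture("neuhauser_fargione_eq9", "parasitic_coexistence", "SC",
             list(g12 = 1, a = 0.5),
             note = paste("exploitation cost pulls the plant below its",
                          "partner-free density: parasitic coexistence")),
    .fixture("graves_eq10", "HD SC & SC/E threshold", "HD SC & SC/E threshold",
             list(r11 = 2, r21 = 2), threshold = "own_density_allee",
             note = "obligate-obligate lichen pair with threshold collapse"),
    .fixture("thompson_eq11_12", "SC", "SC",
             list(d1max = 0.8, d2max = 0.8)),
    .fixture("thompson_eq11_12", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold", list(c1 = 4, c2 = 4)),
    .fixture("holland_deangelis_eq13_bidir", "SC", "SC",
             list(r1 = 1, r2 = 1, a12 = 2, a21 = 2, b12 = 0.5, b21 = 0.5)),
    .fixture("holland_deangelis_eq13_bidir", "five_interior_equilibria",
             "multi-attractor",
             list(r1 = -0.202, r2 = 0.618, c1 = 1, c2 = 1,
                  a12 = 3.911, a21 = 2.6, h1 = 0.488, h2 = 0.895,
                  s1 = 1.032, s2 = 0.49, q1 = 1, q2 = 1,
                  b12 = 0.695, b21 = 2.131, e1 = 0.485, e2 = 0.379),
             note = paste("exactly five interior equilibria in [0, 5]^2",
                          "(two stable, two saddles, one unstable spiral);",
                          "found by seeded search along the facultative",
                          "partner's nullcline arc; nullclines lobe-shaped")),
    .fixture("holland_deangelis_eq13_7_unidir", "overexploitation",
             "SC/E threshold",
             list(r1 = 0.5, a12 = 0.5, r2 = -0.3, a21 = 1, s2 = 0.3,
                  b12 = 2), threshold = "overexploitation",
             note = paste("consumer densities above a critical value",
                          "overexploit the resource and collapse the system")),
    .fixture("fishman_hadany_eq14_15", "HD SC & SC/E threshold",
             "HD SC & SC/E threshold", list(eta = 3, mu = 3),
             threshold = "own_density_allee"),
    .fixture("kang_eq16", "SC", "SC", list()),
    .fixture("martignoni_eq17_18", "SC", "SC", list()),
    .fixture("hale_eq19_7_pollination", "own_density_allee",
             "HD SC & SC/E threshold", list(bP = 2, phi = 2),
             threshold = "own_density_allee",
             note = paste("pollination benefit vanishes at low plant",
                          "density: emergent Allee effect in the plant")),
    .fixture("hale_eq20_7_dispersal", "SC", "SC", list())
  )
  names(reg) <- vapply(reg, function(f) paste(f$model, f$regime, sep = "|"),
                       character(1))
  reg
})

#' Canonical parameter set for a (model, regime) pair
#'
#' The registry stores one committed parameterization per qualitative regime
#' of each covered model.  Each set was found once (by hand algebra or a
#' seeded numerical search) and is frozen here together with the outcome
#' label that [classifyDynamics()] reproduces on it.
#'
#' @param model model id (see [listModels()]), including compound
#'   `"caseA:caseB"` pairings of the generic cases.
#' @param regime regime key, e.g. `"SC"`, `"UC/E threshold"`,
#'   `"five_interior_equilibria"`; see [listFixtures()].
#' @return named list of parameters (partial sets rely on schema defaults).
#' @examples
#' canonicalParams("case_1_1_1", "SC")
#' @export
canonicalParams <- function(model, regime) {
  key <- paste(model, regime, sep = "|")
  fx <- .fixtureRegistry[[key]]
  if (is.null(fx)) {
    have <- listFixtures()
    have <- have[have$model == model, ]
    msg <- if (nrow(have))
      paste0("regimes covered for '", model, "': ",
             paste(sprintf("\"%s\"", have$regime), collapse = ", "))
    else paste0("no fixtures for model '", model, "'; covered models: ",
                paste(unique(listFixtures()$model), collapse = ", "))
    stop("unknown fixture (", model, ", ", regime, "); ", msg, call. = FALSE)
  }
  fx$params
}

#' List all committed fixtures
#'
#' @return data.frame with columns `model`, `regime`, `expected_label`
#'   (the [classifyDynamics()] outcome label), `expected_threshold`
#'   (expected [thresholdType()] probe result or `NA`), and `note`.
#' @examples
#' head(listFixtures())
#' @export
listFixtures <- function() {
  do.call(rbind, lapply(unname(.fixtureRegistry), function(f)
    data.frame(model = f$model, regime = f$regime,
               expected_label = f$expected_label,
               expected_threshold = f$expected_threshold,
               note = f$note, stringsAsFactors = FALSE)))
}
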