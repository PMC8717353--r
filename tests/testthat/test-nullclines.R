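# Nullcline extraction and geometry summaries.

test_that("linear-benefit nullclines are increasing straight lines", {
  nc <- nullclines("case_1_1_1", list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
                   box = c(0, 5))
  kinds <- vapply(nc$N1, function(d) attr(d, "kind"), character(1))
  nt <- nc$N1[[which(kinds == "nontrivial")[1]]]
  g <- attr(nt, "geometry")
  expect_identical(g, c("increasing", "linear"))
  # the nontrivial N1-nullcline is s1 N1 = r1 + b12 N2 (contour polylines
  # carry jitter at the contouring-grid scale, hence the loose tolerance)
  expect_equal(nt$N1, 1 + 0.5 * nt$N2, tolerance = 1e-2)
})

test_that("saturating-benefit nullclines are increasing and concave up", {
  nc <- nullclines("case_1_2", canonicalParams("case_1_2", "SC"),
                   box = c(0, 5))
  kinds <- vapply(nc$N1, function(d) attr(d, "kind"), character(1))
  g <- attr(nc$N1[[which(kinds == "nontrivial")[1]]], "geometry")
  expect_identical(g[1], "increasing")
  expect_identical(g[2], "concave_up")
})

test_that("the five-equilibria consumer-resource fixture has lobe-shaped nullclines", {
  p <- canonicalParams("holland_deangelis_eq13_bidir",
                       "five_interior_equilibria")
  nc <- nullclines("holland_deangelis_eq13_bidir", p, box = c(0, 5))
  geoms <- c(vapply(nc$N1, function(d) attr(d, "geometry")[2], character(1)),
             vapply(nc$N2, function(d) attr(d, "geometry")[2], character(1)))
  expect_true("lobe" %in% geoms)
})

test_that("nullclines through an invalid subregion are clipped with a warning flag", {
  expect_warning(
    nc <- nullclines("case_3_1", list(r1 = 1, K1 = -0.5, r2 = 1, K2 = 1),
                     box = c(0, 4)),
    "clipped")
  expect_true(nc$clipped)
  # valid region is K1 + N2 > 0, i.e. N2 > 0.5
  for (d in c(nc$N1, nc$N2)) {
    if (attr(d, "kind") != "nontrivial") next
    expect_true(all(d$N2 > 0.5))
  }
})

test_that("every nullcline point satisfies its defining equation", {
  p <- canonicalParams("case_1_2", "HD SC & SC/E threshold")
  m <- getModel("case_1_2")
  pp <- validateParams(m, p)
  nc <- nullclines("case_1_2", p, box = c(0, 5))
  for (sp in 1:2) {
    for (d in nc[[sp]]) {
      if (attr(d, "kind") != "nontrivial") next
      idx <- seq(1, nrow(d), length.out = min(25, nrow(d)))
      for (i in idx) {
        st <- c(d$N1[round(i)], d$N2[round(i)])
        g <- m$growth(st, pp)
        expect_lt(abs(g[sp]), 1e-2)
      }
    }
  }
})
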