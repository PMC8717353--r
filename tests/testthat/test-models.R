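# Structural properties of the model registry.

test_that("registry lists all literature and generic models with complete schemas", {
  ids <- listModels()
  expect_length(ids, 28)
  expect_length(grep("^case_", ids), 9)
  for (id in ids) {
    m <- getModel(id)
    sc <- m$schema
    expect_false(any(duplicated(sc$name)), info = id)
    expect_true(all(nzchar(sc$description)), info = id)
    # defaults must themselves validate
    expect_silent(validateParams(m, list()))
  }
  expect_error(getModel("case_9_9"), "unknown model")
})

test_that("rhs component of every axis-invariant model vanishes on its own axis", {
  set.seed(0)
  for (id in listModels()) {
    m <- getModel(id)
    p <- validateParams(m, list())
    ai <- m$axis_invariant(p)
    for (k in 1:50) {
      v <- stats::runif(1, 0.01, 3)
      if (ai[1]) {
        st <- c(0, v)
        r <- tryCatch(evalRhs(m, p, st), error = function(e) NULL)
        if (!is.null(r)) expect_identical(r[1], 0, info = id)
      }
      if (ai[2]) {
        st <- c(v, 0)
        r <- tryCatch(evalRhs(m, p, st), error = function(e) NULL)
        if (!is.null(r)) expect_identical(r[2], 0, info = id)
      }
    }
  }
})

test_that("structurally symmetric models are equivariant under swapping species", {
  sym_models <- grep("^case_", listModels(), value = TRUE)
  set.seed(1)
  for (id in sym_models) {
    m <- getModel(id)
    p <- validateParams(m, list())
    for (k in 1:20) {
      st <- stats::runif(2, 0.05, 3)
      f <- tryCatch(evalRhs(m, p, st), error = function(e) NULL)
      g <- tryCatch(evalRhs(m, p, rev(st)), error = function(e) NULL)
      if (is.null(f) || is.null(g)) next
      expect_equal(f, rev(g), tolerance = 1e-12, info = id)
    }
  }
})

test_that("analytic Jacobians agree with finite differences on random interior states", {
  set.seed(2)
  with_jac <- Filter(function(id) !is.null(getModel(id)$jac), listModels())
  expect_gt(length(with_jac), 0)
  for (id in with_jac) {
    m <- getModel(id)
    p <- validateParams(m, list())
    for (k in 1:100) {
      st <- stats::runif(2, 0.05, 3)
      Ja <- evalJacobian(m, p, st)
      Jn <- evalJacobian(m, p, st, numeric_only = TRUE)
      expect_equal(Ja, Jn, tolerance = 1e-5, info = id)
    }
  }
})

test_that("obligacy follows the sign of growth alone, with the carrying-capacity convention", {
  expect_identical(unname(obligacy("case_1_2", list(r1 = -0.5))[1]),
                   "obligate")
  expect_identical(obligacy("case_1_1_1", list(r1 = 1, r2 = 1)),
                   c(N1 = "facultative", N2 = "facultative"))
  expect_identical(unname(obligacy("case_3_1", list(K1 = 0))[1]),
                   "obligate")
  expect_identical(unname(obligacy("case_3_1", list(K1 = 2))[1]),
                   "facultative")
})

test_that("compound case pairs expose a merged schema and per-species growth", {
  m <- pairCases("case_1_1_2", "case_1_2")
  expect_identical(m$id, "case_1_1_2:case_1_2")
  expect_true(all(c("r1", "b12", "th1", "r2", "b21", "h21") %in%
                    m$schema$name))
  p <- validateParams(m, list(r1 = 1, b12 = 1, s1 = 1, th1 = 0.5,
                              r2 = 1, b21 = 1, h21 = 1, s2 = 1))
  st <- c(1.3, 0.8)
  g <- m$growth(st, p)
  expect_equal(g[1], 1 + 1 * 0.8 - 1 * 1.3^0.5, tolerance = 1e-12)
  expect_equal(g[2], 1 + 1 * 1.3 / (1 + 1.3) - 1 * 0.8, tolerance = 1e-12)
  # compound models are reachable through the registry interface
  expect_silent(getModel("case_1_1_2:case_1_2"))
})

test_that("validity domains reject undefined states with an informative error", {
  # historical carrying-capacity form: K1 + N2 must stay positive
  expect_error(evalRhs("case_3_1", list(K1 = -2), c(1, 0.5)), "K1")
})

test_that("the model manifest serializes every registered model", {
  man <- modelManifest()
  expect_setequal(names(man), listModels())
  expect_true(all(vapply(man, function(m) nrow(m$parameters) > 0,
                         logical(1))))
})
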