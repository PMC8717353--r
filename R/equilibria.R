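# Equilibrium finding and local stability typing: the static phase-plane
# skeleton.  Interior candidates come from sign-change cells of both
# per-capita growth components on a coarse grid, polished by a damped Newton
# iteration; axis equilibria from 1-D root scans of per-capita growth along
# each axis.

#' Classify a pair of Jacobian eigenvalues
#'
#' @param eigenvalues complex (or numeric) vector of length 2.
#' @param tol_hyp hyperbolicity tolerance: any eigenvalue with
#'   `|Re| < tol_hyp * max(1, |lambda|)` makes the point nonhyperbolic.
#' @return one of `"stable_node"`, `"stable_spiral"`, `"unstable_node"`,
#'   `"unstable_spiral"`, `"saddle"`, `"nonhyperbolic"`.
#' @examples
#' classifyEigenvalues(c(-1, -3))        # stable_node
#' classifyEigenvalues(c(0.5, -1.5))     # saddle
#' classifyEigenvalues(complex(real = 0, imaginary = c(1, -1)))  # nonhyperbolic
#' @export
classifyEigenvalues <- function(eigenvalues, tol_hyp = 1e-6) {
  ev <- as.complex(eigenvalues)
  if (length(ev) != 2L || any(!is.finite(ev)))
    stop("two finite eigenvalues required")
  re <- Re(ev); im <- Im(ev)
  if (any(abs(re) < tol_hyp * pmax(1, Mod(ev)))) return("nonhyperbolic")
  if (all(re < 0)) return(if (any(im != 0)) "stable_spiral" else "stable_node")
  if (all(re > 0)) return(if (any(im != 0)) "unstable_spiral" else "unstable_node")
  "saddle"
}

# per-capita growth of species i along its own axis (partner absent)
axisGrowth <- function(model, params, i, x) {
  vapply(x, function(v) {
    st <- c(0, 0); st[i] <- v
    if (!isTRUE(model$validity(st, params))) return(NA_real_)
    if (!is.null(model$growth)) model$growth(st, params)[i]
    else if (v > 0) model$rhs(st, params)[i] / v
    else originGrowth(model, params)[i]
  }, numeric(1))
}

#' Single-species equilibrium density (carrying capacity alone)
#'
#' The largest nonnegative root of the per-capita growth of species `i` on
#' its own axis; `0` when no positive root exists (an obligate species
#' cannot persist alone).
#'
#' @inheritParams evalRhs
#' @param species 1 or 2.
#' @param upper upper end of the root scan (expanded automatically if a root
#'   sits near the edge).
#' @return a single nonnegative density.
#' @examples
#' singleSpeciesEquilibrium("case_1_1_1", list(r1 = 1, s1 = 1), 1)  # 1
#' @export
singleSpeciesEquilibrium <- function(model, params = list(), species,
                                     upper = 20) {
  model <- as_model(model)
  params <- validateParams(model, params)
  for (rep in 1:4) {
    x <- seq(0, upper, length.out = 801)[-1]
    g <- axisGrowth(model, params, species, x)
    ok <- which(!is.na(g))
    if (!length(ok)) return(0)
    roots <- numeric(0)
    sgn <- sign(g[ok])
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (k in flip) {
      lo <- x[ok[k]]; hi <- x[ok[k + 1]]
      r <- stats::uniroot(function(v) axisGrowth(model, params, species, v),
                          c(lo, hi), tol = 1e-12)$root
      roots <- c(roots, r)
    }
    exact <- x[ok][abs(g[ok]) < 1e-12]
    roots <- c(roots, exact)
    if (length(roots) && max(roots) < 0.9 * upper)
      return(max(roots))
    if (!length(roots)) return(0)
    upper <- upper * 10
    if (upper > 2e5) return(max(roots))
  }
  0
}

# damped Newton for F(x) = 0 in 2-D with finite-difference Jacobian
newton2 <- function(F, x0, tol = 1e-12, maxit = 60, lower = c(0, 0),
                    upper = c(Inf, Inf)) {
  x <- x0
  for (it in seq_len(maxit)) {
    f <- F(x)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) return(x)
    h <- 1e-7 * (1 + abs(x))
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- x[j] + h[j]
      fp <- F(xp)
      if (any(!is.finite(fp))) return(NULL)
      J[, j] <- (fp - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damping with projection into the admissible rectangle
    lam <- 1
    repeat {
      xn <- pmin(pmax(x + lam * step, lower), upper)
      fn <- tryCatch(F(xn), error = function(e) rep(NA_real_, 2))
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
      lam <- lam / 2
      if (lam < 1e-6) { xn <- NULL; break }
    }
    if (is.null(xn)) return(x)   # stalled; caller filters by residual
    x <- xn
  }
  x
}

#' Find all equilibria of a model in a box
#'
#' Returns the origin (for models whose axes are invariant), all axis
#' equilibria from a 1-D root scan of per-capita growth along each axis, and
#' all interior equilibria seeded from sign-change cells of both per-capita
#' growth components on a `grid_equilibria`-squared grid and polished by a
#' damped Newton iteration.  Each equilibrium carries its Jacobian
#' eigenvalues and local type.
#'
#' @inheritParams evalRhs
#' @param box numeric `c(0, L)` analysis box (per axis); `NULL` for
#'   [defaultBox()].
#' @param settings an [analysisSettings()] object.
#' @return a `data.frame` of class `equilibrium_set` with columns `N1`, `N2`,
#'   `residual`, `re1`, `im1`, `re2`, `im2`, `type`, `class`, sorted by
#'   (`class`, `N1`).
#' @examples
#' eq <- findEquilibria("case_1_1_1",
#'                      list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5))
#' eq[, c("N1", "N2", "type", "class")]
#' @export
findEquilibria <- function(model, params = list(), box = NULL,
                           settings = analysisSettings()) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  L <- box[2]
  # a singular corner (e.g. Case 3.1 with K = 0) removes the origin from the
  # validity domain; skip it instead of failing the whole search
  origin_ok <- isTRUE(model$validity(c(0, 0), params))
  ai <- model$axis_invariant(params)
  pts <- matrix(numeric(0), ncol = 2)

  if (all(ai)) {
    if (origin_ok) pts <- rbind(pts, c(0, 0))
    for (i in 1:2) {
      x <- seq(0, L, length.out = 601)[-1]
      g <- axisGrowth(model, params, i, x)
      ok <- which(!is.na(g))
      sgn <- sign(g[ok])
      flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      roots <- x[ok][sgn == 0]
      for (k in flip) {
        roots <- c(roots,
          stats::uniroot(function(v) axisGrowth(model, params, i, v),
                         c(x[ok[k]], x[ok[k + 1]]), tol = 1e-13)$root)
      }
      for (r in roots) {
        st <- c(0, 0); st[i] <- r
        pts <- rbind(pts, st)
      }
    }
  } else {
    # axes not invariant: treat the whole box uniformly through the rhs
  }

  # interior candidates: sign-change cells of both components
  n <- settings$grid_equilibria
  interiorF <- interiorField(model, params)
  lo <- L * 1e-7
  xs <- seq(lo, L, length.out = n)
  G1 <- outer(xs, xs, function(a, b) interiorF$f1(a, b))
  G2 <- outer(xs, xs, function(a, b) interiorF$f2(a, b))
  cand <- signChangeCells(xs, xs, G1, G2)
  Ffun <- function(x) c(interiorF$f1(x[1], x[2]), interiorF$f2(x[1], x[2]))
  for (k in seq_len(nrow(cand))) {
    x <- newton2(Ffun, cand[k, ], tol = settings$newton_tol * max(1, L),
                 lower = c(lo, lo), upper = c(L, L))
    if (is.null(x)) next
    if (max(abs(Ffun(x))) > 1e3 * settings$newton_tol * max(1, L)) next
    if (all(ai) && any(x < L * 1e-6)) next  # axis roots handled above
    pts <- rbind(pts, x)
  }

  # dedupe
  if (nrow(pts) > 1) {
    keep <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (keep[j] && sqrt(sum((pts[i, ] - pts[j, ])^2)) <
            settings$dedupe_frac * L) { keep[i] <- FALSE; break }
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }

  rows <- lapply(seq_len(nrow(pts)), function(k) {
    st <- pmax(pts[k, ], 0)
    res <- max(abs(rhsRaw(model, params, st)))
    J <- tryCatch(evalJacobian(model, params, st), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- as.complex(ev)
    atol <- L * 1e-7
    cls <- if (all(st <= atol)) "origin"
      else if (st[2] <= atol) "axis_1"
      else if (st[1] <= atol) "axis_2"
      else "interior"
    data.frame(N1 = st[1], N2 = st[2], residual = res,
               re1 = Re(ev[1]), im1 = Im(ev[1]),
               re2 = Re(ev[2]), im2 = Im(ev[2]),
               type = classifyEigenvalues(ev, settings$tol_hyp),
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(N1 = numeric(0), N2 = numeric(0), residual = numeric(0),
                      re1 = numeric(0), im1 = numeric(0), re2 = numeric(0),
                      im2 = numeric(0), type = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  ord <- order(match(out$class, c("origin", "axis_1", "axis_2", "interior")),
               out$N1, out$N2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "box") <- box
  attr(out, "model") <- model$id
  class(out) <- c("equilibrium_set", "data.frame")
  out
}

# the 2-D field whose zeros are interior equilibria: per-capita growth where
# available (avoids the trivial axis roots), raw rhs otherwise
interiorField <- function(model, params) {
  if (!is.null(model$growth)) {
    f <- function(a, b, i) {
      st <- c(a, b)
      if (!isTRUE(model$validity(st, params))) return(NA_real_)
      model$growth(st, params)[i]
    }
  } else {
    f <- function(a, b, i) {
      st <- c(a, b)
      if (!isTRUE(model$validity(st, params))) return(NA_real_)
      model$rhs(st, params)[i]
    }
  }
  list(f1 = function(a, b) mapply(f, a, b, MoreArgs = list(i = 1)),
       f2 = function(a, b) mapply(f, a, b, MoreArgs = list(i = 2)))
}

# cells of the (xs, ys) grid in which both fields change sign; returns cell
# centres as Newton starting points
signChangeCells <- function(xs, ys, G1, G2) {
  n <- length(xs); m <- length(ys)
  centres <- matrix(numeric(0), ncol = 2)
  s1 <- sign(G1); s2 <- sign(G2)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(m - 1)) {
      c1 <- s1[c(i, i + 1), c(j, j + 1)]
      c2 <- s2[c(i, i + 1), c(j, j + 1)]
      if (any(is.na(c1)) || any(is.na(c2))) next
      if (length(unique(as.vector(c1))) > 1 &&
          length(unique(as.vector(c2))) > 1)
        centres <- rbind(centres,
                         c((xs[i] + xs[i + 1]) / 2, (ys[j] + ys[j + 1]) / 2))
    }
  }
  centres
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set> model ", attr(x, "model"), ", box [0, ",
      format(attr(x, "box")[2], digits = 4), "]^2, ",
      nrow(x), " equilibria\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
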