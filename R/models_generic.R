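# Generic template models of pairwise mutualism, organised by the kind of
# intraspecific density dependence they assume:
#
#   Case 1  -- self-limitation in the population dynamics only
#     1.1.1   linear benefit, self-limitation exponent theta = 1
#     1.1.2   linear benefit, decelerating self-limitation (0 < theta < 1)
#     1.1.3   linear benefit, accelerating self-limitation (theta > 1)
#     1.2     benefit saturating in partner density (Holling type II)
#   Case 2  -- benefits saturate with recipient density
#     2.1     saturating in recipient density
#     2.2     saturating in recipient and partner density
#   Case 3  -- benefits reduce intraspecific density dependence
#     3.1     carrying capacity increases linearly with partner density
#     3.2     self-limitation decreases linearly with partner density
#     3.3     self-limitation reduction saturating in recipient + partner
#
# Each case defines the per-capita growth of one species as a function of its
# own density Ni and its partner's density Nj.  Symmetric models use the same
# case for both species; pairCases() builds mixed pairs.

.generic_case_ids <- c("case_1_1_1", "case_1_1_2", "case_1_1_3", "case_1_2",
                       "case_2_1", "case_2_2", "case_3_1", "case_3_2",
                       "case_3_3")

# per-capita growth g_i(Ni, Nj) and its partial derivatives, per case.
# p is the full parameter list; i is the focal species index (1 or 2).
caseGrowthFun <- function(case, i) {
  j <- 3L - i
  r <- paste0("r", i); b <- paste0("b", i, j); s <- paste0("s", i)
  th <- paste0("th", i); h <- paste0("h", i, j); K <- paste0("K", i)
  switch(case,
    case_1_1_1 = ,
    case_1_1_2 = ,
    case_1_1_3 = function(Ni, Nj, p)
      p[[r]] + p[[b]] * Nj - p[[s]] * Ni^p[[th]],
    case_1_2 = function(Ni, Nj, p)
      p[[r]] + p[[b]] * Nj / (p[[h]] + Nj) - p[[s]] * Ni,
    case_2_1 = function(Ni, Nj, p)
      p[[r]] + p[[b]] * Nj / (p[[h]] + Ni) - p[[s]] * Ni,
    case_2_2 = function(Ni, Nj, p)
      p[[r]] + p[[b]] * Nj / (p[[h]] + Ni + Nj) - p[[s]] * Ni,
    case_3_1 = function(Ni, Nj, p)
      p[[r]] * (1 - Ni / (p[[K]] + Nj)),
    case_3_2 = function(Ni, Nj, p)
      p[[r]] - (p[[s]] - p[[b]] * Nj) * Ni,
    case_3_3 = function(Ni, Nj, p)
      p[[r]] - (p[[s]] - p[[b]] * Nj / (p[[h]] + Ni + Nj)) * Ni,
    stop("unknown generic case '", case, "'"))
}

# analytic partials (dg/dNi, dg/dNj) for the generic cases
caseGrowthGrad <- function(case, i) {
  j <- 3L - i
  r <- paste0("r", i); b <- paste0("b", i, j); s <- paste0("s", i)
  th <- paste0("th", i); h <- paste0("h", i, j); K <- paste0("K", i)
  switch(case,
    case_1_1_1 = ,
    case_1_1_2 = ,
    case_1_1_3 = function(Ni, Nj, p)
      c(-p[[s]] * p[[th]] * Ni^(p[[th]] - 1), p[[b]]),
    case_1_2 = function(Ni, Nj, p)
      c(-p[[s]], p[[b]] * p[[h]] / (p[[h]] + Nj)^2),
    case_2_1 = function(Ni, Nj, p)
      c(-p[[b]] * Nj / (p[[h]] + Ni)^2 - p[[s]], p[[b]] / (p[[h]] + Ni)),
    case_2_2 = function(Ni, Nj, p) {
      D <- p[[h]] + Ni + Nj
      c(-p[[b]] * Nj / D^2 - p[[s]], p[[b]] * (p[[h]] + Ni) / D^2)
    },
    case_3_1 = function(Ni, Nj, p)
      c(-p[[r]] / (p[[K]] + Nj), p[[r]] * Ni / (p[[K]] + Nj)^2),
    case_3_2 = function(Ni, Nj, p)
      c(-(p[[s]] - p[[b]] * Nj), p[[b]] * Ni),
    case_3_3 = function(Ni, Nj, p) {
      D <- p[[h]] + Ni + Nj
      c(-p[[s]] + p[[b]] * Nj * (D - Ni) / D^2,
        p[[b]] * Ni * (D - Nj) / D^2)
    },
    stop("unknown generic case '", case, "'"))
}

# parameter descriptors needed by species i under a given case
caseSchema <- function(case, i) {
  j <- 3L - i
  r  <- paramFree(paste0("r", i), 1,
                  description = "intrinsic per-capita growth rate (<= 0: obligate)")
  b  <- paramDescriptor(paste0("b", i, j), 0.5, symbol = paste0("beta", i, j),
                        description = "mutualistic benefit coefficient")
  s  <- paramDescriptor(paste0("s", i), 1, lower = 0, lower_open = FALSE,
                        description = "self-limitation coefficient (0: no self-limitation)")
  h  <- paramDescriptor(paste0("h", i, j), 1,
                        description = "half-saturation constant of the benefit")
  K  <- paramFree(paste0("K", i), 1,
                  description = "carrying capacity (historical convention; <= 0: obligate)")
  th1 <- paramDescriptor(paste0("th", i), 1, symbol = paste0("theta", i),
                         lower = 1, upper = 1, lower_open = FALSE,
                         upper_open = FALSE,
                         description = "self-limitation exponent (fixed at 1)")
  th2 <- paramDescriptor(paste0("th", i), 0.5, symbol = paste0("theta", i),
                         lower = 0, upper = 1,
                         description = "self-limitation exponent (decelerating)")
  th3 <- paramDescriptor(paste0("th", i), 2, symbol = paste0("theta", i),
                         lower = 1,
                         description = "self-limitation exponent (accelerating)")
  switch(case,
    case_1_1_1 = rbind(r, b, s, th1),
    case_1_1_2 = rbind(r, b, s, th2),
    case_1_1_3 = rbind(r, b, s, th3),
    case_1_2 = rbind(r, b, h, s),
    case_2_1 = rbind(r, b, h, s),
    case_2_2 = rbind(r, b, h, s),
    case_3_1 = rbind(paramDescriptor(paste0("r", i), 1,
                       description = "intrinsic per-capita growth rate"), K),
    case_3_2 = rbind(r, s, b),
    case_3_3 = rbind(r, s, b, h),
    stop("unknown generic case '", case, "'"))
}

caseLabel <- function(case) {
  sub("^case_", "Case ", gsub("_", ".", sub("^case_", "", case)))
}

#' Build a (possibly mixed) generic-case model
#'
#' Assembles a two-species model in which species 1 follows one generic
#' template and species 2 another.  The nine registered `case_*` models are
#' the symmetric special case (`pairCases(x, x)`).
#'
#' @param case1,case2 generic case ids (one of `case_1_1_1` ... `case_3_3`).
#' @return a `model_spec` with id `"case1:case2"` (or the plain case id when
#'   both are equal).
#' @examples
#' m <- pairCases("case_1_2", "case_1_1_1")
#' m$id
#' @export
pairCases <- function(case1, case2 = case1) {
  if (!case1 %in% .generic_case_ids || !case2 %in% .generic_case_ids)
    stop("generic case ids must be among: ",
         paste(.generic_case_ids, collapse = ", "))
  g1 <- caseGrowthFun(case1, 1); g2 <- caseGrowthFun(case2, 2)
  d1 <- caseGrowthGrad(case1, 1); d2 <- caseGrowthGrad(case2, 2)
  schema <- rbind(caseSchema(case1, 1), caseSchema(case2, 2))
  id <- if (case1 == case2) case1 else paste0(case1, ":", case2)
  uses31 <- c(case1, case2) == "case_3_1"
  validity <- function(state, p) {
    if (uses31[1] && p$K1 + state[2] <= 0)
      return("K1 + N2 must be positive (singular carrying-capacity term)")
    if (uses31[2] && p$K2 + state[1] <= 0)
      return("K2 + N1 must be positive (singular carrying-capacity term)")
    TRUE
  }
  obligacy_rule <- NULL
  if (any(uses31)) {
    obligacy_rule <- function(p) {
      lab <- character(2)
      for (i in 1:2) {
        if (uses31[i]) {
          lab[i] <- if (p[[paste0("K", i)]] <= 0) "obligate" else "facultative"
        } else {
          lab[i] <- if (p[[paste0("r", i)]] <= 0) "obligate" else "facultative"
        }
      }
      lab
    }
  }
  growth <- function(state, p)
    c(g1(state[1], state[2], p), g2(state[2], state[1], p))
  jac <- function(state, p) {
    N1 <- state[1]; N2 <- state[2]
    gv <- c(g1(N1, N2, p), g2(N2, N1, p))
    # on an axis the rhs row reduces to (g_i, 0): guard the products so a
    # singular partial (e.g. Ni^(th-1) with th < 1 at Ni = 0) cannot leak NaN
    p1 <- if (N1 > 0) d1(N1, N2, p) else c(0, 0)   # (dg1/dN1, dg1/dN2)
    p2 <- if (N2 > 0) d2(N2, N1, p) else c(0, 0)   # (dg2/dN2, dg2/dN1)
    matrix(c(gv[1] + N1 * p1[1], N2 * p2[2],
             N1 * p1[2], gv[2] + N2 * p2[1]), 2, 2)
  }
  desc <- if (case1 == case2)
    paste0("Generic mutualism template, ", caseLabel(case1),
           " for both species")
  else paste0("Mixed generic pair: N1 follows ", caseLabel(case1),
              ", N2 follows ", caseLabel(case2))
  newModelSpec(id = id,
               source = paste0("generic templates (",
                               caseLabel(case1), " / ", caseLabel(case2), ")"),
               description = desc, schema = schema, growth = growth,
               jac = jac, validity = validity,
               obligacy_rule = obligacy_rule)
}

local({
  for (cs in .generic_case_ids) registerModel(pairCases(cs, cs))
})
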