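# Literature models of pairwise mutualism.  Each registration gives the
# per-capita growth rates of the two species in the notation of the original
# source (parameter names transliterated to ASCII), a parameter schema with
# sign constraints, and metadata on species roles and obligacy.

pd <- paramDescriptor   # local shorthands
pf <- paramFree

# --- Lotka-Volterra linear-benefit family -----------------------------------

registerModel(newModelSpec(
  id = "gause_witt_eq1",
  source = "Gause & Witt (1935), Eq. 1",
  description = "Lotka-Volterra mutual aid: linear benefit to growth rate and equilibrium density; facultative only",
  schema = rbind(pd("r1", 1, description = "intrinsic growth rate"),
                 pd("r2", 1, description = "intrinsic growth rate"),
                 pd("K1", 1, description = "carrying capacity"),
                 pd("K2", 1, description = "carrying capacity"),
                 pd("a12", 0.5, symbol = "alpha12",
                    description = "benefit coefficient on N1 from N2"),
                 pd("a21", 0.5, symbol = "alpha21",
                    description = "benefit coefficient on N2 from N1")),
  growth = function(s, p)
    c(p$r1 * (p$K1 + p$a12 * s[2] - s[1]) / p$K1,
      p$r2 * (p$K2 + p$a21 * s[1] - s[2]) / p$K2)))

registerModel(newModelSpec(
  id = "whittaker_eq2",
  source = "Whittaker (1975), Eq. 2",
  description = "Symbiont (N1) on host (N2): partner density sets the symbiont's equilibrium density; obligate symbiont when K1 = 0",
  species = c("Symbiont", "Host"),
  schema = rbind(pd("r1", 1, description = "symbiont intrinsic growth rate"),
                 pd("r2", 1, description = "host intrinsic growth rate"),
                 pd("K1", 1, lower_open = FALSE,
                    description = "symbiont carrying capacity (0: obligate)"),
                 pd("K2", 1, description = "host carrying capacity"),
                 pd("a12", 1, symbol = "alpha12",
                    description = "host benefit to symbiont equilibrium"),
                 pd("a21", 0.5, symbol = "alpha21",
                    description = "symbiont benefit to host (negative: parasitism)")),
  growth = function(s, p)
    c(p$r1 * (p$K1 + p$a12 * s[2] - s[1]) / (p$K1 + p$a12 * s[2]),
      p$r2 * (p$K2 + p$a21 * s[1] - s[2]) / p$K2),
  validity = function(s, p) {
    if (s[1] > 0 && p$K1 + p$a12 * s[2] <= 0)
      return("K1 + a12*N2 must be positive for the symbiont term")
    TRUE
  }))

registerModel(newModelSpec(
  id = "whittaker_eq3",
  source = "Whittaker (1975), Eq. 3",
  description = "Obligate symbiont (N1) on host (N2); host benefit limited by extrinsic intraspecific factors",
  species = c("Symbiont", "Host"),
  schema = rbind(pd("r1", 1, description = "symbiont intrinsic growth rate"),
                 pd("r2", 1, description = "host intrinsic growth rate"),
                 pd("a12", 1, symbol = "alpha12",
                    description = "host benefit to symbiont equilibrium"),
                 pd("K2", 1, description = "host carrying capacity"),
                 pd("a", 0.5, description = "symbiont benefit to host"),
                 pd("D", 1, description = "host-density scale limiting benefit")),
  growth = function(s, p)
    c(p$r1 * (p$a12 * s[2] - s[1]) / (p$a12 * s[2]),
      p$r2 * (p$K2 + p$a * p$D * s[1] / (p$D + s[2]) - s[2]) / p$K2),
  validity = function(s, p) {
    if (s[1] > 0 && s[2] <= 0)
      return("host density must be positive for the symbiont term")
    TRUE
  }))

registerModel(newModelSpec(
  id = "vandermeer_boucher_eq1",
  source = "Vandermeer & Boucher (1978), Eq. 1",
  description = "Linear benefits with explicit self-limitation; obligacy as negative carrying capacity K_i = r_i / a_ii",
  species = c("Legume", "Rhizobium"),
  schema = rbind(pf("r1", 1, description = "intrinsic growth rate (<= 0: obligate)"),
                 pf("r2", 1, description = "intrinsic growth rate (<= 0: obligate)"),
                 pd("a11", 1, symbol = "alpha11", description = "self-limitation"),
                 pd("a22", 1, symbol = "alpha22", description = "self-limitation"),
                 pd("a12", 0.5, symbol = "alpha12", description = "benefit coefficient"),
                 pd("a21", 0.5, symbol = "alpha21", description = "benefit coefficient")),
  growth = function(s, p)
    c(p$r1 + p$a12 * s[2] - p$a11 * s[1],
      p$r2 + p$a21 * s[1] - p$a22 * s[2])))

registerModel(newModelSpec(
  id = "addicott_eq4",
  source = "Addicott (1981), Eq. 4",
  description = "Benefit multiplies the per-capita growth rate only (low-density effect); nullclines are the lines Ni = Ki",
  species = c("Aphid", "Ant"),
  schema = rbind(pd("r1", 1, description = "intrinsic growth rate"),
                 pd("r2", 1, description = "intrinsic growth rate"),
                 pd("K1", 1, description = "carrying capacity"),
                 pd("K2", 1, description = "carrying capacity"),
                 pd("a12", 0.5, symbol = "alpha12", description = "benefit coefficient"),
                 pd("a21", 0.5, symbol = "alpha21", description = "benefit coefficient")),
  growth = function(s, p)
    c(p$r1 * (1 + p$a12 * s[2] / p$K1) * (p$K1 - s[1]) / p$K1,
      p$r2 * (1 + p$a21 * s[1] / p$K2) * (p$K2 - s[2]) / p$K2)))

# --- Saturating-benefit family ---------------------------------------------

registerModel(newModelSpec(
  id = "wolin_lawlor_eq5",
  source = "Wolin & Lawlor (1984), Eq. 5",
  description = "Partner density reduces intraspecific birth limitation, saturating to at most zero; facultative only",
  schema = rbind(pd("r1", 1, description = "intrinsic growth rate"),
                 pd("r2", 1, description = "intrinsic growth rate"),
                 pd("bb1", 1, symbol = "b1",
                    description = "density-dependent birth limitation"),
                 pd("bb2", 1, symbol = "b2",
                    description = "density-dependent birth limitation"),
                 pd("m1", 1, description = "benefit scale on limitation"),
                 pd("m2", 1, description = "benefit scale on limitation"),
                 pd("d1", 0.2, description = "density-dependent death rate"),
                 pd("d2", 0.2, description = "density-dependent death rate")),
  growth = function(s, p)
    c(p$r1 - p$bb1 * s[1] / (1 + p$m1 * s[2]) - p$d1 * s[1],
      p$r2 - p$bb2 * s[2] / (1 + p$m2 * s[1]) - p$d2 * s[2])))

registerModel(newModelSpec(
  id = "wolin_lawlor_eq6",
  source = "Wolin & Lawlor (1984), Eq. 6",
  description = "Partner density reduces birth limitation linearly, without bound",
  schema = rbind(pd("r1", 1, description = "intrinsic growth rate"),
                 pd("r2", 1, description = "intrinsic growth rate"),
                 pd("bb1", 1, symbol = "b1",
                    description = "density-dependent birth limitation"),
                 pd("bb2", 1, symbol = "b2",
                    description = "density-dependent birth limitation"),
                 pd("m1", 0.5, description = "benefit per partner on limitation"),
                 pd("m2", 0.5, description = "benefit per partner on limitation"),
                 pd("d1", 0.2, description = "density-dependent death rate"),
                 pd("d2", 0.2, description = "density-dependent death rate")),
  growth = function(s, p)
    c(p$r1 - (p$bb1 - p$m1 * s[2] + p$d1) * s[1],
      p$r2 - (p$bb2 - p$m2 * s[1] + p$d2) * s[2])))

registerModel(newModelSpec(
  id = "wright_eq7",
  source = "Wright (1989), Eq. 7",
  description = "Benefit saturates with partner density via a Holling type II handling-time response",
  schema = rbind(pf("r1", 1, description = "intrinsic growth rate"),
                 pf("r2", 1, description = "intrinsic growth rate"),
                 pd("c1", 1, description = "self-limitation coefficient"),
                 pd("c2", 1, description = "self-limitation coefficient"),
                 pd("b12", 1, description = "benefit per interaction"),
                 pd("b21", 1, description = "benefit per interaction"),
                 pd("a12", 1, description = "encounter (attack) rate"),
                 pd("a21", 1, description = "encounter (attack) rate"),
                 pd("h12", 0.5, description = "handling time"),
                 pd("h21", 0.5, description = "handling time")),
  growth = function(s, p)
    c(p$r1 - p$c1 * s[1] + p$b12 * p$a12 * s[2] / (1 + p$a12 * p$h12 * s[2]),
      p$r2 - p$c2 * s[2] + p$b21 * p$a21 * s[1] / (1 + p$a21 * p$h21 * s[1]))))

registerModel(newModelSpec(
  id = "zhang_eq8",
  source = "Zhang (2003), Eq. 8",
  description = "Phenomenological parabolic nullclines: mutualistic at low partner density, competitive at high partner density",
  schema = rbind(pd("R1", 1, description = "rate constant"),
                 pd("R2", 1, description = "rate constant"),
                 pd("c1", 1, description = "nullcline height"),
                 pd("c2", 1, description = "nullcline height"),
                 pd("a1", 1, description = "nullcline curvature"),
                 pd("a2", 1, description = "nullcline curvature"),
                 pf("bb1", 1, symbol = "b1",
                    description = "partner density of peak net effect (any sign)"),
                 pf("bb2", 1, symbol = "b2",
                    description = "partner density of peak net effect (any sign)")),
  growth = function(s, p)
    c(p$R1 * (p$c1 - s[1] - p$a1 * (s[2] - p$bb1)^2),
      p$R2 * (p$c2 - s[2] - p$a2 * (s[1] - p$bb2)^2))))

registerModel(newModelSpec(
  id = "neuhauser_fargione_eq9",
  source = "Neuhauser & Fargione (2004), Eq. 9",
  description = "Plant (N1) - mycorrhizae (N2): saturating benefit to plant equilibrium density plus a linear exploitation cost",
  species = c("Plant", "Mycorrhizae"),
  schema = rbind(pd("r1", 1, description = "plant intrinsic growth rate"),
                 pd("r2", 1, description = "fungus intrinsic growth rate"),
                 pd("K1", 1, description = "plant carrying capacity"),
                 pd("K2", 1, description = "fungus carrying capacity"),
                 pd("g12", 1, symbol = "gamma12",
                    description = "fungal benefit to plant equilibrium"),
                 pd("a21", 0.5, symbol = "alpha21",
                    description = "plant benefit to fungus equilibrium"),
                 pd("a", 0.1, description = "linear exploitation cost on plant")),
  growth = function(s, p)
    c(p$r1 * (p$K1 + p$g12 * s[2] - s[1]) / (p$K1 + p$g12 * s[2]) - p$a * s[2],
      p$r2 * (p$K2 + p$a21 * s[1] - s[2]) / p$K2)))

registerModel(newModelSpec(
  id = "graves_eq10",
  source = "Graves et al. (2006), Eq. 10",
  description = "Lichens: per-capita growth interpolates from r_i0 (partner absent) to r_i1 (partner abundant) with exponential saturation",
  schema = rbind(pf("r10", -0.2, description = "growth rate without partner (<= 0: obligate)"),
                 pf("r20", -0.2, description = "growth rate without partner (<= 0: obligate)"),
                 pd("r11", 1, description = "growth rate at saturating partner density"),
                 pd("r21", 1, description = "growth rate at saturating partner density"),
                 pd("k1", 1, description = "saturation rate with partner density"),
                 pd("k2", 1, description = "saturation rate with partner density"),
                 pd("a1", 1, description = "self-limitation coefficient"),
                 pd("a2", 1, description = "self-limitation coefficient")),
  growth = function(s, p)
    c(p$r10 + (p$r11 - p$r10) * (1 - exp(-p$k1 * s[2])) - p$a1 * s[1],
      p$r20 + (p$r21 - p$r20) * (1 - exp(-p$k2 * s[1])) - p$a2 * s[2])))

registerModel(newModelSpec(
  id = "thompson_eq11_12",
  source = "Thompson et al. (2006), Eqs. 11-12",
  description = "Hermit crab (N1) - anemone (N2): partner reduces death rate; crabs provide habitat (shell space) to anemones; optional immigration opens the system",
  species = c("HermitCrab", "Anemone"),
  schema = rbind(pd("rho1", 1, upper = 1, upper_open = FALSE,
                    description = "fraction of reproduction retained locally"),
                 pd("rho2", 1, upper = 1, upper_open = FALSE,
                    description = "fraction of reproduction retained locally"),
                 pd("bb1", 1, symbol = "b1", description = "per-capita birth rate"),
                 pd("bb2", 1, symbol = "b2", description = "per-capita birth rate"),
                 pd("I1", 0, lower_open = FALSE, description = "immigration rate"),
                 pd("I2", 0, lower_open = FALSE, description = "immigration rate"),
                 pd("S1", 5, description = "habitat (site) limit for crabs"),
                 pd("S2", 1, description = "baseline habitat limit for anemones"),
                 pd("d1min", 0.2, description = "death rate with abundant partner"),
                 pd("d1max", 1.5, description = "death rate without partner"),
                 pd("d2min", 0.2, description = "death rate with abundant partner"),
                 pd("d2max", 1.5, description = "death rate without partner"),
                 pd("c1", 1, description = "protection efficiency of anemones"),
                 pd("c2", 1, description = "protection efficiency of crabs")),
  rhs = function(s, p)
    c((p$rho1 * p$bb1 * s[1] + p$I1) * (1 - s[1] / p$S1) -
        (p$d1min + (p$d1max - p$d1min) / (1 + p$c1 * s[2])) * s[1],
      (p$rho2 * p$bb2 * s[2] + p$I2) * (1 - s[2] / (p$S2 + s[1])) -
        (p$d2min + (p$d2max - p$d2min) / (1 + p$c2 * s[1])) * s[2]),
  growth = function(s, p)   # per-capita form, valid for the closed system (Ii = 0)
    c(p$rho1 * p$bb1 * (1 - s[1] / p$S1) -
        (p$d1min + (p$d1max - p$d1min) / (1 + p$c1 * s[2])),
      p$rho2 * p$bb2 * (1 - s[2] / (p$S2 + s[1])) -
        (p$d2min + (p$d2max - p$d2min) / (1 + p$c2 * s[1]))),
  axis_invariant = function(p) c(p$I1 == 0, p$I2 == 0),
  validate_extra = function(p) {
    if (p$d1max < p$d1min || p$d2max < p$d2min)
      return("dimax must be >= dimin")
    TRUE
  }))

# --- Consumer-resource family ----------------------------------------------

hd_schema_common <- rbind(
  pf("r1", 1, description = "intrinsic growth rate (<= 0: obligate)"),
  pf("r2", 1, description = "intrinsic growth rate (<= 0: obligate)"),
  pd("c1", 1, description = "conversion efficiency of consumed resources"),
  pd("c2", 1, description = "conversion efficiency of consumed resources"),
  pd("a12", 1, description = "saturation level of benefit to N1"),
  pd("a21", 1, description = "saturation level of benefit to N2"),
  pd("h1", 0.3, description = "half-saturation density of N1 as a resource"),
  pd("h2", 0.3, description = "half-saturation density of N2 as a resource"),
  pd("s1", 1, description = "self-limitation coefficient"),
  pd("s2", 1, description = "self-limitation coefficient"))

registerModel(newModelSpec(
  id = "holland_deangelis_eq13_bidir",
  source = "Holland & DeAngelis (2010), Eq. 13 (bidirectional)",
  description = "Bidirectional consumer-resource mutualism: each species gains a saturating benefit from consuming the partner's resources and pays a saturating cost of being consumed",
  schema = rbind(hd_schema_common,
                 pd("q1", 1, description = "cost coefficient of provisioning N2"),
                 pd("q2", 1, description = "cost coefficient of provisioning N1"),
                 pd("b12", 1, symbol = "beta12",
                    description = "consumption pressure of N2 on N1's resources"),
                 pd("b21", 1, symbol = "beta21",
                    description = "consumption pressure of N1 on N2's resources"),
                 pd("e1", 0.3, description = "half-saturation of the cost to N1"),
                 pd("e2", 0.3, description = "half-saturation of the cost to N2")),
  growth = function(s, p)
    c(p$r1 + p$c1 * p$a12 * s[2] / (p$h2 + s[2]) -
        p$q1 * p$b12 * s[2] / (p$e1 + s[1]) - p$s1 * s[1],
      p$r2 + p$c2 * p$a21 * s[1] / (p$h1 + s[1]) -
        p$q2 * p$b21 * s[1] / (p$e2 + s[2]) - p$s2 * s[2])))

registerModel(newModelSpec(
  id = "holland_deangelis_eq13_7_unidir",
  source = "Holland & DeAngelis (2010), Eq. 13' (unidirectional)",
  description = "Unidirectional consumer-resource mutualism (e.g. plant-pollinator): only the resource species (N1) pays a consumption cost",
  species = c("Resource", "Consumer"),
  schema = rbind(hd_schema_common,
                 pd("q1", 1, description = "cost coefficient of provisioning N2"),
                 pd("b12", 1, symbol = "beta12",
                    description = "consumption pressure of N2 on N1's resources"),
                 pd("e1", 0.3, description = "half-saturation of the cost to N1")),
  growth = function(s, p)
    c(p$r1 + p$c1 * p$a12 * s[2] / (p$h2 + s[2]) -
        p$q1 * p$b12 * s[2] / (p$e1 + s[1]) - p$s1 * s[1],
      p$r2 + p$c2 * p$a21 * s[1] / (p$h1 + s[1]) - p$s2 * s[2])))

registerModel(newModelSpec(
  id = "fishman_hadany_eq14_15",
  source = "Fishman & Hadany (2010), Eqs. 14-15",
  description = "Plant (N1) - pollinator (N2) from individual-level foraging; both species obligate (pure death rates without the partner)",
  species = c("Plant", "Pollinator"),
  schema = rbind(pd("eta", 2, symbol = "eta",
                    description = "plant benefit per pollinator encounter"),
                 pd("mu", 2, symbol = "mu",
                    description = "pollinator benefit per plant encounter"),
                 pd("alpha", 1, description = "encounter rate"),
                 pd("beta", 1, description = "pollinator interference scale"),
                 pd("b", 0.5, description = "plant per-capita death rate"),
                 pd("cc", 0.5, symbol = "c", description = "plant self-limitation"),
                 pd("d", 0.5, description = "pollinator per-capita death rate")),
  growth = function(s, p) {
    den <- 1 + p$alpha * s[1] + p$alpha * p$beta * s[2]
    c(p$eta * p$alpha * s[2] / den - p$b - p$cc * s[1],
      p$mu * p$alpha * s[1] / den - p$d)
  }))

registerModel(newModelSpec(
  id = "kang_eq16",
  source = "Kang et al. (2011), Eq. 16",
  description = "Fungal garden (N1) - leaf-cutter ant (N2): sigmoidal benefit to the garden, linear rearing cost, both obligate",
  species = c("FungalGarden", "Ant"),
  schema = rbind(pd("rf", 2, description = "max fungal growth from ant farming"),
                 pd("rc", 0.2, description = "cost of rearing ant brood"),
                 pd("r", 1, description = "ant production per unit garden"),
                 pd("a", 1, description = "encounter/farming rate"),
                 pd("b", 1, description = "half-saturation of the sigmoidal benefit"),
                 pd("d1", 0.5, description = "garden self-limitation"),
                 pd("d2", 0.5, description = "ant self-limitation")),
  growth = function(s, p)
    c(p$rf * p$a * s[2]^2 / (p$b + p$a * s[2]^2) - p$rc * s[2] - p$d1 * s[1],
      p$r * p$a * s[1] - p$d2 * s[2])))

registerModel(newModelSpec(
  id = "martignoni_eq17_18",
  source = "Martignoni et al. (2020), Eqs. 17-18",
  description = "Plant (N1) - mycorrhizal fungus (N2): phosphorus-for-carbon exchange; fungus obligate",
  species = c("Plant", "Mycorrhizae"),
  schema = rbind(pd("rp", 1, description = "plant intrinsic growth rate"),
                 pd("qhp", 1, description = "plant gain per unit phosphorus"),
                 pd("qcp", 0.2, description = "plant cost per unit carbon"),
                 pd("qhm", 0.2, description = "fungal cost per unit phosphorus"),
                 pd("qcm", 1, description = "fungal gain per unit carbon"),
                 pd("alpha", 1, description = "phosphorus transfer rate"),
                 pd("beta", 0.5, description = "carbon transfer rate"),
                 pd("mup", 1, symbol = "mu_p", description = "plant self-limitation"),
                 pd("mum", 1, symbol = "mu_m", description = "fungal self-limitation"),
                 pd("d", 1, description = "plant-density scale of phosphorus uptake")),
  growth = function(s, p)
    c(p$rp + p$qhp * p$alpha * s[2] / (p$d + s[1]) - p$qcp * p$beta * s[2] -
        p$mup * s[1],
      p$qcm * p$beta * s[1] - p$qhm * p$alpha * s[1] / (p$d + s[1]) -
        p$mum * s[2])))

hale_anim_schema <- rbind(
  pd("bA", 1, description = "animal intrinsic birth rate"),
  pd("eps", 1, symbol = "epsilon",
     description = "animal benefit per foraging visit"),
  pd("a", 1, description = "visitation (attack) rate"),
  pd("h", 0.5, description = "handling time per plant visit"),
  pd("sA", 1, description = "animal self-limitation"),
  pd("dA", 0.5, description = "animal death rate"))

registerModel(newModelSpec(
  id = "hale_eq19_7_pollination",
  source = "Hale et al. (2021), Eq. 19 (pollination)",
  description = "Plant (P) - pollinator (A): plant benefit proportional to total visitation, vanishing at low plant density (emergent Allee effect)",
  species = c("Plant", "Pollinator"),
  schema = rbind(pd("bP", 1, description = "plant birth rate per successful ovule"),
                 pd("f", 0.2, description = "baseline (self-pollinated) seed set"),
                 pd("g", 1, description = "germination/recruitment probability"),
                 pd("phi", 1, symbol = "phi",
                    description = "pollination efficiency per visit"),
                 pd("sP", 1, description = "plant self-limitation"),
                 pd("dP", 0.5, description = "plant death rate"),
                 hale_anim_schema),
  growth = function(s, p) {
    P <- s[1]; A <- s[2]
    c(p$bP * (p$f + p$phi * p$a * A * P / (1 + p$a * p$h * P + p$a * A * P)) *
        p$g - p$sP * P - p$dP,
      p$bA + p$eps * p$a * P / (1 + p$a * p$h * P) - p$sA * A - p$dA)
  }))

registerModel(newModelSpec(
  id = "hale_eq20_7_dispersal",
  source = "Hale et al. (2021), Eq. 20 (seed dispersal)",
  description = "Plant (P) - seed disperser (A): disperser visitation reduces the plant's density-dependent seed mortality (Janzen-Connell release)",
  species = c("Plant", "Disperser"),
  schema = rbind(pd("bP", 1, description = "plant birth rate"),
                 pd("f", 0.8, description = "seed set"),
                 pd("g", 1, description = "germination/recruitment probability"),
                 pd("sigma", 0.8, symbol = "sigma",
                    description = "mortality reduction per disperser visit"),
                 pd("sP", 1, description = "plant density-dependent seed mortality"),
                 pd("dP", 0.5, description = "plant death rate"),
                 hale_anim_schema),
  growth = function(s, p) {
    P <- s[1]; A <- s[2]
    c(p$bP * p$f * p$g -
        (p$sP - p$sigma * p$a * A / (1 + p$a * p$h * P + p$a * A * P)) * P -
        p$dP,
      p$bA + p$eps * p$a * P / (1 + p$a * p$h * P) - p$sA * A - p$dA)
  }))

rm(pd, pf, hd_schema_common, hale_anim_schema)
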