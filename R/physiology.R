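#' Construct a microbe
#'
#' @param genotype Genotype name or `enz_genotype`.
#' @param pool_C,pool_N,pool_P Internal nutrient pools in fg. `NULL` N/P
#'   pools default to stoichiometric balance with `pool_C`.
#' @param config An `enz_config` (for the stoichiometric targets).
#' @return A list with class `"enz_microbe"`.
#' @export
microbe <- function(genotype, pool_C = 150, pool_N = NULL, pool_P = NULL,
                    config = scenario_config()) {
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  structure(list(
    genotype = genotype,
    pool_C = pool_C,
    pool_N = if (is.null(pool_N)) pool_C / config$CtoN_mic else pool_N,
    pool_P = if (is.null(pool_P)) pool_C / config$CtoP_mic else pool_P),
    class = "enz_microbe")
}

#' @export
print.enz_microbe <- function(x, ...) {
  cat(sprintf("<microbe %s C=%.3g N=%.3g P=%.3g>\n", format(x$genotype),
              x$pool_C, x$pool_N, x$pool_P))
  invisible(x)
}

#' Stoichiometric demand state of a microbe
#'
#' A nutrient is in demand when acquiring it would move the internal
#' stoichiometry toward the targets C:N = `CtoN_mic`, C:P = `CtoP_mic`:
#' N is in demand when C:N is at or above target, P when C:P is at or
#' above target, and C when either ratio is at or below target. Equality
#' counts as demand on both sides of a pair, so a perfectly balanced
#' microbe still feeds on everything. Ratios are compared by
#' cross-multiplication, so a zero N or P pool (ratio +Inf) simply puts
#' that nutrient in demand.
#'
#' @param m An `enz_microbe`.
#' @param config An `enz_config`.
#' @return Named logical vector `c(C =, N =, P =)`.
#' @export
compute_demand <- function(m, config) {
  C <- m$pool_C; N <- m$pool_N; P <- m$pool_P
  stopifnot(C >= 0, N >= 0, P >= 0)
  c(C = (C <= config$CtoN_mic * N) || (C <= config$CtoP_mic * P),
    N = C >= config$CtoN_mic * N,
    P = C >= config$CtoP_mic * P)
}

#' Michaelis-Menten product uptake
#'
#' Uptake scales with the cell's surface area (biomass to the 2/3 power)
#' and saturates in the local product concentration:
#' `EnzPerArea * AreaToMass * biomass^(2/3) * Vmax * P/(Km + P) * dt`,
#' clipped at the product actually present in the box. The engine applies
#' it only to nutrients currently in demand.
#'
#' @param biomass_C Microbial C biomass, fg.
#' @param product_in_box Product pool of the nutrient in the box, fg.
#' @param config An `enz_config`.
#' @return Mass taken up, fg.
#' @examples
#' cfg <- scenario_config()
#' uptake_amount(150, 1e6, cfg) # ~1.208 fg/min at saturation
#' @export
uptake_amount <- function(biomass_C, product_in_box, config) {
  stopifnot(biomass_C >= 0, product_in_box >= 0)
  u <- config$EnzPerArea * config$AreaToMass * biomass_C^(2 / 3) *
    config$Vmax_uptake * product_in_box /
    (config$Km_uptake + product_in_box) * config$dt
  pmin(u, product_in_box)
}

#' Ratio-equalizing cap on enzyme production (C:N pair)
#'
#' Secreting enzyme drains the internal pools at the enzyme's own
#' stoichiometry (C:N = `CtoN_enz`, richer in N than the cell target),
#' so production from a C-limited cell pushes C:N upward. The largest
#' secretion that leaves C:N exactly at the `CtoN_mic` target is
#' `(CtoN_mic * N - C) / (CtoN_mic / CtoN_enz - 1 - Resp_enz)`, clamped
#' at zero. The engine combines this with the analogous C:P guard (see
#' [production_caps()]) and uses the binding minimum.
#'
#' @param pool_C,pool_N Internal pools, fg.
#' @param config An `enz_config`. The constants must satisfy
#'   `CtoN_mic / CtoN_enz > 1 + Resp_enz`, enforced at config validation.
#' @return Maximum enzyme C mass, fg.
#' @examples
#' balanced_production_cap(150, 26, scenario_config()) # ~9.7674
#' @export
balanced_production_cap <- function(pool_C, pool_N, config) {
  denom <- config$CtoN_mic / config$CtoN_enz - 1 - config$Resp_enz
  if (denom <= 0) {
    stop("CtoN_mic/CtoN_enz must exceed 1 + Resp_enz", call. = FALSE)
  }
  pmax(0, (config$CtoN_mic * pool_N - pool_C) / denom)
}

#' Stoichiometric production caps for both nutrient pairs
#'
#' For each pair (C,N) and (C,P), the largest secretion that keeps a
#' nutrient currently *not* in demand from being pushed into demand.
#' Whether a pair binds depends on the direction the ratio moves under
#' the enzyme's cost stoichiometry: with the defaults, secretion raises
#' C:N (guarding N, the printed C:N formula) and lowers C:P (guarding C,
#' the analogous C:P form `(C - CtoP_mic*P) / (1 + Resp_enz -
#' CtoP_mic/CtoP_enz)`). Non-binding pairs return `Inf`.
#'
#' @inheritParams compute_demand
#' @return Named numeric `c(CN =, CP =)` of enzyme C mass caps.
#' @export
production_caps <- function(m, config) {
  d <- compute_demand(m, config)
  c(CN = pair_cap_r(m$pool_C, m$pool_N, config$CtoN_mic, config$CtoN_enz,
                    config$Resp_enz, d[["N"]], d[["C"]]),
    CP = pair_cap_r(m$pool_C, m$pool_P, config$CtoP_mic, config$CtoP_enz,
                    config$Resp_enz, d[["P"]], d[["C"]]))
}

pair_cap_r <- function(C, X, target, ctox_enz, resp, x_in_demand,
                       c_in_demand) {
  costC <- 1 + resp
  costX <- 1 / ctox_enz
  rising <- C * costX > X * costC
  if (rising && !x_in_demand) {
    denom <- target / ctox_enz - costC
    if (denom <= 0) return(0)
    return(max(0, (target * X - C) / denom))
  }
  if (!rising && !c_in_demand) {
    denom <- costC - target / ctox_enz
    if (denom <= 0) return(Inf)
    return(max(0, (C - target * X) / denom))
  }
  Inf
}

#' Pay the elemental cost of secreting enzyme
#'
#' Enzymes are protein: secreting `enzyme_C_mass` fg of enzyme (any of
#' the three types) deducts `(1 + Resp_enz) * E` carbon (the secreted
#' mass plus respiration overhead), `E / CtoN_enz` nitrogen, and
#' `E / CtoP_enz` phosphorus from the internal pools. The emission is
#' scaled down if any pool cannot cover its share, so pools never go
#' negative.
#'
#' @inheritParams compute_demand
#' @param enzyme_C_mass Intended enzyme C mass, fg.
#' @return List with the updated `microbe`, the `emitted` enzyme C mass,
#'   and the `respired` C.
#' @export
pay_enzyme_cost <- function(m, enzyme_C_mass, config) {
  stopifnot(enzyme_C_mass >= 0)
  cC <- 1 + config$Resp_enz
  cN <- 1 / config$CtoN_enz
  cP <- 1 / config$CtoP_enz
  E <- enzyme_C_mass
  if (E > 0) {
    E <- min(E, m$pool_C / cC, m$pool_N / cN, m$pool_P / cP)
    E <- max(E, 0)
  }
  m$pool_C <- max(0, m$pool_C - cC * E)
  m$pool_N <- max(0, m$pool_N - cN * E)
  m$pool_P <- max(0, m$pool_P - cP * E)
  list(microbe = m, emitted = E, respired = config$Resp_enz * E)
}

#' Basal maintenance metabolism
#'
#' Respire `BMR * pool_C * dt` fg C; N and P leak in proportion, by
#' `loss_factor * deltaC / CtoN_mic` and `loss_factor * deltaC /
#' CtoP_mic` (clamped at the pool). In the engine the leaked N and P
#' return to the resident box half as substrate and half as product
#' (same convention as death); the respired C leaves the system.
#'
#' @inheritParams compute_demand
#' @return List with the updated `microbe`, `respired_C`, `loss_N`,
#'   `loss_P`.
#' @export
maintenance_metabolism <- function(m, config) {
  dC <- config$BMR * m$pool_C * config$dt
  lN <- min(m$pool_N, config$loss_factor * dC / config$CtoN_mic)
  lP <- min(m$pool_P, config$loss_factor * dC / config$CtoP_mic)
  m$pool_C <- m$pool_C - dC
  m$pool_N <- m$pool_N - lN
  m$pool_P <- m$pool_P - lP
  list(microbe = m, respired_C = dC, loss_N = lN, loss_P = lP)
}

#' Death check
#'
#' A microbe dies deterministically when its biomass has fallen strictly
#' below `min_mass` (starvation), and otherwise dies with probability
#' `mortality_rate * dt` (random mortality; one draw from R's RNG). On
#' death the engine returns all internal pools to the resident box, half
#' as substrate and half as product per nutrient.
#'
#' @inheritParams compute_demand
#' @return `"alive"`, `"dead_starvation"`, or `"dead_random"`.
#' @export
check_death <- function(m, config) {
  if (m$pool_C < config$min_mass) return("dead_starvation")
  if (stats::runif(1) < config$mortality_rate * config$dt) {
    return("dead_random")
  }
  "alive"
}

#' Split a dividing microbe into two daughters
#'
#' Division triggers at `pool_C >= division_mass`; each daughter receives
#' exactly half of every pool. In the engine one daughter stays in place
#' and the other moves to a uniformly chosen neighbor box (its genotype
#' passing through mutation when enabled); if the target box is occupied,
#' one of the two microbes dies with probability 0.5 and its pools return
#' to the contested box.
#'
#' @inheritParams compute_demand
#' @return List of two daughter microbes, or `NULL` when below the
#'   division threshold.
#' @export
divide_microbe <- function(m, config) {
  if (m$pool_C < config$division_mass) return(NULL)
  half <- m
  half$pool_C <- m$pool_C / 2
  half$pool_N <- m$pool_N / 2
  half$pool_P <- m$pool_P / 2
  list(resident = half, disperser = half)
}

#' Constitutive enzyme production
#'
#' Every carried producer locus must emit `EConstit * pool_C * dt` fg of
#' enzyme per step, regardless of demand. The elemental cost of each
#' emission is paid through [pay_enzyme_cost()], which scales an emission
#' down when the internal pools cannot cover it -- the cell never borrows
#' mass, and one that chronically cannot pay shrinks toward starvation.
#'
#' @inheritParams compute_demand
#' @return List: updated `microbe` and `emissions`, a named numeric of
#'   enzyme C mass emitted per locus (zero for non-producer loci).
#' @export
constitutive_production <- function(m, config) {
  emissions <- c(C = 0, N = 0, P = 0)
  for (loc in c("C", "N", "P")) {
    if (unclass(m$genotype)[[loc]] == 1L) {
      target <- config$EConstit * m$pool_C * config$dt
      paid <- pay_enzyme_cost(m, target, config)
      m <- paid$microbe
      emissions[[loc]] <- paid$emitted
    }
  }
  list(microbe = m, emissions = emissions)
}

#' Facultative enzyme production
#'
#' For each carried locus whose nutrient is still in demand after this
#' step's uptake, up to `facultative_fraction` (1%) of that nutrient's
#' uptake funds extra enzyme. N and P budgets are accounted in N or P
#' mass and converted to enzyme C mass at `CtoN_enz` / `CtoP_enz`. Each
#' emission is further capped by the stoichiometric guards of
#' [production_caps()] so that no currently balanced nutrient is pushed
#' into demand, then paid through [pay_enzyme_cost()].
#'
#' @inheritParams compute_demand
#' @param uptake Named numeric `c(C =, N =, P =)`: this step's uptake of
#'   each nutrient, in that nutrient's mass units.
#' @return List: updated `microbe` and per-locus `emissions` (enzyme C
#'   mass).
#' @export
facultative_production <- function(m, uptake, config) {
  stopifnot(all(uptake >= 0))
  conv <- c(C = 1, N = config$CtoN_enz, P = config$CtoP_enz)
  emissions <- c(C = 0, N = 0, P = 0)
  for (loc in c("C", "N", "P")) {
    if (unclass(m$genotype)[[loc]] != 1L) next
    if (!compute_demand(m, config)[[loc]]) next
    budget <- config$facultative_fraction * uptake[[loc]] * conv[[loc]]
    if (budget <= 0) next
    E <- min(budget, production_caps(m, config))
    paid <- pay_enzyme_cost(m, E, config)
    m <- paid$microbe
    emissions[[loc]] <- paid$emitted
  }
  list(microbe = m, emissions = emissions)
}
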