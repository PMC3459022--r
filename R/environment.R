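#' Add substrate input to every box
#'
#' Each box gains `input_rate[n] * dt` fg of substrate for each nutrient
#' (box area is 1 um^2); nothing else changes. The inputs are tallied in
#' the ledger.
#'
#' @param lattice An `enz_lattice`.
#' @param config An `enz_config`.
#' @return The updated lattice.
#' @export
add_substrate <- function(lattice, config) {
  as_enz_lattice(cpp_process(lattice, config, "input"), config)
}

#' First-order pool decay
#'
#' A pool of mass `amount` loses `amount * rate * dt` in one step:
#' `remaining = amount * (1 - rate * dt)`. Applied by the engine to the
#' substrate, product, and enzyme pools of all nutrients each step; the
#' lost mass leaves the system and is tallied in the ledger.
#'
#' @param amount Pool mass in fg (vectorized).
#' @param rate Decay rate per minute.
#' @param dt Time step in minutes.
#' @return List with `remaining` and `lost` mass.
#' @examples
#' decay_pool(100, 0.01, 1) # 99 remaining, 1 lost
#' @export
decay_pool <- function(amount, rate, dt) {
  stopifnot(all(amount >= 0), rate >= 0, dt > 0)
  if (rate * dt > 1) {
    stop("decay rate * dt exceeds 1; the step would remove more than the ",
         "pool holds", call. = FALSE)
  }
  lost <- amount * rate * dt
  list(remaining = amount - lost, lost = lost)
}

#' One stochastic pairwise diffusion sweep
#'
#' Every box, visited in a fresh random order, picks one partner per
#' nutrient -- uniformly among its 8 neighbors, or uniformly over the
#' whole grid when `config$well_mixed` -- and `rate * dt * (high - low)`
#' moves from the higher- to the lower-concentration box. Transfers are
#' applied immediately (asynchronous sweep), so each pool's lattice total
#' is conserved exactly. At `rate * dt = 0.5` a two-box pair equilibrates
#' in a single 1-minute step. Substrate never diffuses.
#'
#' @inheritParams add_substrate
#' @param pool `"product"` or `"enzyme"` (all three nutrients of that
#'   pool type diffuse in the sweep).
#' @param rate Transfer fraction per minute; defaults to the config's
#'   rate for the pool. `rate * dt` must not exceed 0.5.
#' @return The updated lattice.
#' @export
diffuse_step <- function(lattice, config, pool = c("product", "enzyme"),
                         rate = NULL) {
  pool <- match.arg(pool, c("product", "enzyme", "substrate"))
  if (pool == "substrate") {
    stop("substrate does not diffuse", call. = FALSE)
  }
  if (is.null(rate)) {
    rate <- if (pool == "product") config$product_diffusion
            else config$enzyme_diffusion
  }
  if (rate * config$dt > 0.5) {
    stop("diffusion rate * dt exceeds 0.5; a transfer beyond half the ",
         "concentration difference would overshoot equilibrium",
         call. = FALSE)
  }
  as_enz_lattice(cpp_diffuse_pool(lattice, config, pool, rate), config)
}

#' Michaelis-Menten product formation
#'
#' Mass of product formed from substrate by enzyme in one step:
#' `min(enzyme * Vmax * substrate / (Km + substrate) * dt, substrate)`.
#' The formed amount is clipped at the available substrate so the pool can
#' never go negative; in the engine it is moved from the substrate to the
#' product pool of the same nutrient and accumulated into that nutrient's
#' depolymerization tally.
#'
#' @param enzyme Enzyme pool, fg (vectorized).
#' @param substrate Substrate pool, fg.
#' @inheritParams add_substrate
#' @return Product mass formed, fg.
#' @export
form_product <- function(enzyme, substrate, config) {
  stopifnot(all(enzyme >= 0), all(substrate >= 0))
  d <- enzyme * config$Vmax_formation * substrate /
    (config$Km_formation + substrate) * config$dt
  d[substrate == 0] <- 0
  pmin(d, substrate)
}

#' Run one named engine process on a lattice
#'
#' Test-level access to the engine's eleven per-step processes.
#'
#' @inheritParams add_substrate
#' @param process One of `"input"`, `"substrate_decay"`,
#'   `"product_decay"`, `"product_diffusion"`, `"enzyme_decay"`,
#'   `"enzyme_diffusion"`, `"product_formation"`,
#'   `"uptake_production"`, `"metabolism"`, `"death"`, `"reproduction"`.
#' @return The updated lattice.
#' @export
run_process <- function(lattice, config, process) {
  as_enz_lattice(cpp_process(lattice, config, process), config)
}
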