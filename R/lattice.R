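#' Create an empty lattice state
#'
#' The state is a flat list of nine per-box concentration pools (substrate,
#' enzyme, product for each of C, N, P; all in fg, stored column-major for
#' a `height x width` matrix), an integer genotype layer (0 = empty box,
#' 1..8 = genotype code), per-microbe internal pools, and a cumulative
#' mass-flux ledger.
#'
#' @param config An [scenario_config()] object.
#' @return A list with class `"enz_lattice"`; all pools zero, no microbes.
#' @export
new_lattice <- function(config) {
  n <- config$width * config$height
  z <- numeric(n)
  ledger <- stats::setNames(numeric(12), c(
    "input_C", "input_N", "input_P", "decay_C", "decay_N", "decay_P",
    "respiration_C", "enzyme_N_sequestered", "enzyme_P_sequestered",
    "depoly_C", "depoly_N", "depoly_P"))
  structure(list(
    substrate_C = z, substrate_N = z, substrate_P = z,
    enzyme_C = z, enzyme_N = z, enzyme_P = z,
    product_C = z, product_N = z, product_P = z,
    genotype = integer(n),
    pool_C = z, pool_N = z, pool_P = z,
    ledger = ledger),
    width = config$width, height = config$height,
    class = "enz_lattice")
}

as_enz_lattice <- function(state, config) {
  structure(state, width = config$width, height = config$height,
            class = "enz_lattice")
}

#' @export
print.enz_lattice <- function(x, ...) {
  cat("<enz_lattice ", attr(x, "height"), "x", attr(x, "width"),
      ", ", sum(x$genotype > 0), " microbes>\n", sep = "")
  invisible(x)
}

#' Seed a lattice with the initial microbial community
#'
#' Each box is independently occupied with probability
#' `config$init_density`; occupants draw a genotype uniformly from
#' `config$genotype_set` and start with C = `init_mass` fg, N = C /
#' `CtoN_mic`, P = C / `CtoP_mic` (stoichiometrically balanced). All
#' abiotic pools start at zero. Draws use R's global RNG; call
#' `set.seed()` first for reproducibility.
#'
#' @inheritParams new_lattice
#' @return An `enz_lattice` with microbes placed.
#' @export
initialize_lattice <- function(config) {
  lat <- new_lattice(config)
  n <- config$width * config$height
  occ <- stats::runif(n) < config$init_density
  k <- sum(occ)
  if (k > 0) {
    codes <- vapply(config$genotype_set,
                    function(nm) genotype_code(parse_genotype(nm)),
                    integer(1))
    lat$genotype[occ] <- codes[sample.int(length(codes), k, replace = TRUE)]
    lat$pool_C[occ] <- config$init_mass
    lat$pool_N[occ] <- config$init_mass / config$CtoN_mic
    lat$pool_P[occ] <- config$init_mass / config$CtoP_mic
  }
  lat
}

#' Extract one field of a lattice as a matrix
#'
#' @param lattice An `enz_lattice`.
#' @param field Field name, e.g. `"substrate_C"`, `"product_N"`,
#'   `"genotype"`, `"pool_C"`.
#' @return A `height x width` matrix.
#' @export
lattice_field <- function(lattice, field) {
  stopifnot(inherits(lattice, "enz_lattice"))
  if (!field %in% names(lattice) || field == "ledger") {
    stop("unknown lattice field: ", field, call. = FALSE)
  }
  matrix(lattice[[field]], nrow = attr(lattice, "height"))
}

#' Per-nutrient mass totals of a lattice state
#'
#' All three enzyme pools are carbon mass (enzymes are secreted as C;
#' their N and P content is booked as sequestered in the ledger), so they
#' count toward the C total only.
#'
#' @inheritParams lattice_field
#' @return Named numeric: total C, N, P currently on the lattice.
#' @export
mass_totals <- function(lattice) {
  c(C = sum(lattice$substrate_C) + sum(lattice$product_C) +
      sum(lattice$enzyme_C) + sum(lattice$enzyme_N) +
      sum(lattice$enzyme_P) + sum(lattice$pool_C),
    N = sum(lattice$substrate_N) + sum(lattice$product_N) +
      sum(lattice$pool_N),
    P = sum(lattice$substrate_P) + sum(lattice$product_P) +
      sum(lattice$pool_P))
}

#' Mass-balance closure between two states of the same run
#'
#' For each nutrient, the change in total lattice mass between `before`
#' and `after` must equal external input minus decay loss, respiration
#' (C), and enzyme sequestration (N, P) over the same interval, as
#' accumulated in the ledger.
#'
#' @param before,after `enz_lattice` states from the same run.
#' @return Named numeric of relative closure errors (|discrepancy| /
#'   max(total mass, 1)) for C, N, P.
#' @export
mass_balance_error <- function(before, after) {
  dtot <- mass_totals(after) - mass_totals(before)
  dled <- after$ledger - before$ledger
  expected <- c(
    C = dled[["input_C"]] - dled[["decay_C"]] - dled[["respiration_C"]],
    N = dled[["input_N"]] - dled[["decay_N"]] -
      dled[["enzyme_N_sequestered"]],
    P = dled[["input_P"]] - dled[["decay_P"]] -
      dled[["enzyme_P_sequestered"]])
  abs(dtot - expected) / pmax(mass_totals(after), 1)
}

#' Place a microbe on a lattice (helper for tests and small experiments)
#'
#' @inheritParams lattice_field
#' @param row,col 1-based box coordinates.
#' @param genotype Genotype name or `enz_genotype`.
#' @param pool_C,pool_N,pool_P Internal pools in fg; `NULL` pools default
#'   to stoichiometric balance with `pool_C`.
#' @param config The scenario configuration (for stoichiometric targets).
#' @return The modified lattice.
#' @export
place_microbe <- function(lattice, row, col, genotype, config,
                          pool_C = config$init_mass, pool_N = NULL,
                          pool_P = NULL) {
  h <- attr(lattice, "height")
  k <- row + (col - 1L) * h
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  lattice$genotype[k] <- genotype_code(genotype)
  lattice$pool_C[k] <- pool_C
  lattice$pool_N[k] <- if (is.null(pool_N)) pool_C / config$CtoN_mic
                       else pool_N
  lattice$pool_P[k] <- if (is.null(pool_P)) pool_C / config$CtoP_mic
                       else pool_P
  lattice
}
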