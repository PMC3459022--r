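#' Scenario configuration
#'
#' Builds a validated parameter set for a simulation run. Every argument has
#' the model's published default; pass only the fields you want to change.
#' Units: masses in fg, lengths in grid boxes (1 box = 1 um^2 of surface,
#' 1 um^3 of volume), time in minutes (`dt`) or model hours (run lengths).
#'
#' @param width,height Lattice dimensions in boxes (default 100 x 100, i.e.
#'   10,000 um^2 of grid area).
#' @param dt Time step in minutes (default 1).
#' @param input_rate Named numeric, substrate input per box per minute:
#'   0.1 fg C, 0.01 fg N, 0.001 fg P.
#' @param decay_rate First-order removal rate of substrate, enzyme, and
#'   product pools (0.01 / min).
#' @param product_diffusion Pairwise transfer fraction per minute for
#'   products (0.5, so two adjacent boxes equilibrate in one 1-min step).
#' @param enzyme_diffusion Transfer fraction per minute for enzymes (EDiff);
#'   the published sweep covers 1e-4, 1e-3, 1e-2. Default 1e-3 (sweep
#'   midpoint).
#' @param Vmax_formation,Km_formation Michaelis-Menten constants for product
#'   formation by enzymes: 10 fg/fg/min and 0.001 fg/um^3.
#' @param EnzPerArea,AreaToMass,Vmax_uptake,Km_uptake Uptake kinetics:
#'   uptake = EnzPerArea * AreaToMass * biomass^(2/3) * Vmax * P/(Km+P) * dt.
#' @param EConstit Constitutive enzyme production rate per carried producer
#'   locus, fg enzyme per fg biomass C per minute (default 1e-7; the sweep
#'   covers 1e-7 .. 1e-4).
#' @param facultative_fraction Fraction of the current step's uptake of a
#'   nutrient that may fund facultative production of that nutrient's enzyme
#'   (0.01).
#' @param CtoN_mic,CtoP_mic Microbial stoichiometric targets C:N = 6,
#'   C:P = 60.
#' @param CtoN_enz,CtoP_enz Enzyme stoichiometry C:N = 3.5, C:P = 200.
#' @param Resp_enz Extra C respired per unit enzyme C produced (0.1).
#' @param BMR Basal metabolic rate, 0.00015 fg C respired per fg C per min.
#' @param loss_factor N and P leak with maintenance respiration at
#'   `loss_factor` * deltaC / (C:nutrient target) (0.1).
#' @param division_mass,min_mass,init_mass Division threshold 300 fg C,
#'   starvation threshold 30 fg C, initial biomass 150 fg C.
#' @param init_density Initial occupancy probability per box (0.02).
#' @param mortality_rate Random per-minute death probability (3e-5).
#' @param mutation_rate Per-locus flip probability at division (1e-5).
#' @param mutation_enabled Apply mutation to the dispersing daughter?
#' @param well_mixed If `TRUE`, diffusion partners are drawn uniformly from
#'   the whole grid and `enzyme_diffusion` is forced to 0.5.
#' @param torus Toroidal wrap-around for neighbor interactions (default
#'   `TRUE`; set `FALSE` for bounded edges).
#' @param genotype_set Character vector of genotype names initially present.
#' @param run_hours Run length in model hours (60 steps each at dt = 1).
#' @param snapshot_interval_hours Raster snapshot cadence (1000 h).
#' @param metrics_window_hours Averaging window for reported diversity and
#'   depolymerization (10,000 h, clipped to the run length).
#' @param stop_when_extinct Terminate the loop early once no microbe
#'   remains (metrics for remaining hours are recorded as an extinct
#'   community).
#' @param seed Base RNG seed; replicate `k` uses `seed + k`.
#' @return A validated list with class `"enz_config"`.
#' @examples
#' cfg <- scenario_config(width = 50, height = 50, EConstit = 1e-5)
#' cfg$input_rate
#' @export
scenario_config <- function(width = 100L,
                            height = 100L,
                            dt = 1,
                            input_rate = c(C = 0.1, N = 0.01, P = 0.001),
                            decay_rate = 0.01,
                            product_diffusion = 0.5,
                            enzyme_diffusion = 1e-3,
                            Vmax_formation = 10,
                            Km_formation = 0.001,
                            EnzPerArea = 0.1,
                            AreaToMass = 0.0428,
                            Vmax_uptake = 10,
                            Km_uptake = 0.001,
                            EConstit = 1e-7,
                            facultative_fraction = 0.01,
                            CtoN_mic = 6,
                            CtoP_mic = 60,
                            CtoN_enz = 3.5,
                            CtoP_enz = 200,
                            Resp_enz = 0.1,
                            BMR = 0.00015,
                            loss_factor = 0.1,
                            division_mass = 300,
                            min_mass = 30,
                            init_mass = 150,
                            init_density = 0.02,
                            mortality_rate = 3e-5,
                            mutation_rate = 1e-5,
                            mutation_enabled = TRUE,
                            well_mixed = FALSE,
                            torus = TRUE,
                            genotype_set = genotype_names(),
                            run_hours = 100,
                            snapshot_interval_hours = 1000,
                            metrics_window_hours = 10000,
                            stop_when_extinct = FALSE,
                            seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              dt = dt, input_rate = input_rate, decay_rate = decay_rate,
              product_diffusion = product_diffusion,
              enzyme_diffusion = enzyme_diffusion,
              Vmax_formation = Vmax_formation, Km_formation = Km_formation,
              EnzPerArea = EnzPerArea, AreaToMass = AreaToMass,
              Vmax_uptake = Vmax_uptake, Km_uptake = Km_uptake,
              EConstit = EConstit,
              facultative_fraction = facultative_fraction,
              CtoN_mic = CtoN_mic, CtoP_mic = CtoP_mic,
              CtoN_enz = CtoN_enz, CtoP_enz = CtoP_enz,
              Resp_enz = Resp_enz, BMR = BMR, loss_factor = loss_factor,
              division_mass = division_mass, min_mass = min_mass,
              init_mass = init_mass, init_density = init_density,
              mortality_rate = mortality_rate,
              mutation_rate = mutation_rate,
              mutation_enabled = isTRUE(mutation_enabled),
              well_mixed = isTRUE(well_mixed), torus = isTRUE(torus),
              genotype_set = genotype_set, run_hours = run_hours,
              snapshot_interval_hours = snapshot_interval_hours,
              metrics_window_hours = metrics_window_hours,
              stop_when_extinct = isTRUE(stop_when_extinct),
              seed = as.integer(seed))
  if (cfg$well_mixed) cfg$enzyme_diffusion <- 0.5
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop("config field '", key, "': ", msg, call. = FALSE)
  }
  chk(cfg$width >= 1 && cfg$height >= 1, "width/height",
      "lattice must be at least 1 x 1")
  chk(cfg$dt > 0, "dt", "must be > 0")
  chk(is.numeric(cfg$input_rate) && length(cfg$input_rate) == 3 &&
        all(cfg$input_rate >= 0), "input_rate",
      "must be three non-negative rates (C, N, P)")
  names(cfg$input_rate) <- c("C", "N", "P")
  rates <- c(decay_rate = cfg$decay_rate,
             product_diffusion = cfg$product_diffusion,
             enzyme_diffusion = cfg$enzyme_diffusion,
             EConstit = cfg$EConstit, BMR = cfg$BMR,
             mortality_rate = cfg$mortality_rate,
             mutation_rate = cfg$mutation_rate,
             Resp_enz = cfg$Resp_enz, loss_factor = cfg$loss_factor,
             facultative_fraction = cfg$facultative_fraction,
             Vmax_formation = cfg$Vmax_formation,
             Vmax_uptake = cfg$Vmax_uptake,
             EnzPerArea = cfg$EnzPerArea, AreaToMass = cfg$AreaToMass)
  for (k in names(rates)) chk(rates[[k]] >= 0, k, "rate must be >= 0")
  for (k in c("CtoN_mic", "CtoP_mic", "CtoN_enz", "CtoP_enz",
              "Km_formation", "Km_uptake")) {
    chk(cfg[[k]] > 0, k, "must be > 0")
  }
  chk(cfg$decay_rate * cfg$dt <= 1, "decay_rate",
      "decay_rate * dt must not exceed 1")
  chk(cfg$product_diffusion * cfg$dt <= 0.5, "product_diffusion",
      "transfer fraction * dt must not exceed 0.5 (overshoot)")
  chk(cfg$enzyme_diffusion * cfg$dt <= 0.5, "enzyme_diffusion",
      "transfer fraction * dt must not exceed 0.5 (overshoot)")
  chk(cfg$mutation_rate <= 1, "mutation_rate", "must be a probability")
  chk(cfg$mortality_rate * cfg$dt <= 1, "mortality_rate",
      "mortality_rate * dt must be a probability")
  chk(cfg$init_density >= 0 && cfg$init_density <= 1, "init_density",
      "must be a probability")
  chk(cfg$CtoN_mic / cfg$CtoN_enz > 1 + cfg$Resp_enz, "CtoN_enz",
      paste0("stoichiometric constants must satisfy CtoN_mic/CtoN_enz > ",
             "1 + Resp_enz for the production cap to be well defined"))
  chk(cfg$division_mass > cfg$min_mass, "division_mass",
      "must exceed min_mass")
  chk(cfg$init_mass >= cfg$min_mass, "init_mass",
      "initial biomass below the starvation threshold")
  chk(length(cfg$genotype_set) >= 1, "genotype_set", "must be nonempty")
  bad <- setdiff(cfg$genotype_set, genotype_names())
  chk(length(bad) == 0, "genotype_set",
      paste0("unknown genotype name(s): ", paste(bad, collapse = ", ")))
  chk(cfg$run_hours > 0, "run_hours", "must be > 0")
  chk(cfg$snapshot_interval_hours >= 1, "snapshot_interval_hours",
      "must be >= 1")
  chk(cfg$metrics_window_hours >= 1, "metrics_window_hours", "must be >= 1")
  structure(cfg, class = "enz_config")
}

#' @export
print.enz_config <- function(x, ...) {
  cat("<enz_config ", x$width, "x", x$height,
      " EDiff=", format(x$enzyme_diffusion),
      " EConstit=", format(x$EConstit),
      if (x$well_mixed) " well-mixed",
      " genotypes=", length(x$genotype_set),
      " run_hours=", x$run_hours, ">\n", sep = "")
  invisible(x)
}

#' Load a scenario configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [scenario_config()]; all are optional and
#' missing keys take the published defaults. Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return An `enz_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$input_rate)) vals$input_rate <- unlist(vals$input_rate)
  do.call(scenario_config, vals)
}
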