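#' Scaled-down regime scenarios
#'
#' Five desk-scale scenario configurations that probe the model's
#' qualitative regimes on a 50 x 50 grid:
#' \describe{
#'   \item{low_diffusion}{EDiff 1e-4, EConstit 1e-7: generalist
#'     producers (`CNP`) sweep the community.}
#'   \item{high_production}{EConstit 1e-4: constitutive costs hand the
#'     advantage to cheaters, whose sweep collapses the whole community.
#'     Run for 8,000 h, the published horizon for this scenario.}
#'   \item{well_mixed}{whole-grid diffusion partners at EConstit 1e-5:
#'     producers lose their local advantage.}
#'   \item{two_type_harsh}{EDiff 1e-2, EConstit 1e-5 with only `CNP` and
#'     `cnp`, no mutation: cheaters sweep, then starve — extinction.}
#'   \item{eight_type_harsh}{the same conditions with all eight types:
#'     coalitions of partial producers can survive the bottleneck in a
#'     fraction of replicates.}
#' }
#' Extinction-bound scenarios stop stepping once the community is gone.
#'
#' @param width,height Grid size for the scaled runs.
#' @param hours Named numeric overriding per-scenario run lengths.
#' @param seed Base RNG seed stored in each config.
#' @return Named list of `enz_config`.
#' @export
regime_scenarios <- function(width = 50L, height = 50L, hours = NULL,
                             seed = 1L) {
  h <- list(low_diffusion = 4000, high_production = 8000,
            well_mixed = 8000, two_type_harsh = 5000,
            eight_type_harsh = 5000)
  for (nm in names(hours)) h[[nm]] <- hours[[nm]]
  common <- list(width = width, height = height, seed = seed,
                 stop_when_extinct = TRUE,
                 metrics_window_hours = 1000)
  mk <- function(run_hours, ...) {
    do.call(scenario_config,
            c(common, list(run_hours = run_hours), list(...)))
  }
  list(
    low_diffusion = mk(h$low_diffusion, enzyme_diffusion = 1e-4,
                       EConstit = 1e-7),
    high_production = mk(h$high_production, enzyme_diffusion = 1e-4,
                         EConstit = 1e-4),
    well_mixed = mk(h$well_mixed, EConstit = 1e-5, well_mixed = TRUE),
    two_type_harsh = mk(h$two_type_harsh, enzyme_diffusion = 1e-2,
                        EConstit = 1e-5,
                        genotype_set = c("CNP", "cnp"),
                        mutation_enabled = FALSE),
    eight_type_harsh = mk(h$eight_type_harsh, enzyme_diffusion = 1e-2,
                          EConstit = 1e-5))
}

#' Run the scaled regime suite
#'
#' Runs every regime scenario for `replicates` seeds and summarizes each
#' run: final population, extinction, the modal genotype, and the
#' generalist producer's share of the final community.
#'
#' @param base_seed Base seed (replicate `k` of every scenario uses
#'   `base_seed + k`).
#' @param replicates Seeds per scenario.
#' @param scenarios Optionally a subset of [regime_scenarios()] names.
#' @param width,height,hours Passed to [regime_scenarios()].
#' @return data.frame with one row per (scenario, replicate).
#' @export
run_regime_suite <- function(base_seed = 1L, replicates = 2L,
                             scenarios = NULL, width = 50L,
                             height = 50L, hours = NULL) {
  cfgs <- regime_scenarios(width = width, height = height,
                           hours = hours, seed = base_seed)
  if (!is.null(scenarios)) cfgs <- cfgs[scenarios]
  gn <- genotype_names()
  rows <- list()
  for (nm in names(cfgs)) {
    for (k in seq_len(replicates)) {
      run <- simulate_run(cfgs[[nm]], replicate = k)
      last <- run$metrics[nrow(run$metrics), ]
      counts <- as.numeric(last[gn])
      tot <- sum(counts)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, replicate = k,
        final_population = run$summary$final_population,
        extinct = run$summary$extinct,
        modal_genotype = if (tot > 0) gn[which.max(counts)]
                         else NA_character_,
        CNP_fraction = if (tot > 0) counts[gn == "CNP"] / tot else 0,
        cnp_fraction = if (tot > 0) counts[gn == "cnp"] / tot else 0,
        diversity = run$summary$diversity,
        depoly_C = run$summary$depoly[["C"]])
    }
  }
  do.call(rbind, rows)
}
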