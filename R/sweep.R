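#' Specify a factorial scenario sweep
#'
#' Defaults reproduce the published factorial design: enzyme diffusion
#' (EDiff) over 1e-4, 1e-3, 1e-2 crossed with constitutive production
#' (EConstit) over 1e-7 .. 1e-4.
#'
#' @param EDiff_values,EConstit_values Factor levels for the sweep.
#' @param replicates Replicates per cell.
#' @param base_config Template `enz_config`; each cell overrides its
#'   `enzyme_diffusion` and `EConstit`.
#' @return A list of class `"enz_sweep"`.
#' @export
sweep_spec <- function(EDiff_values = c(1e-4, 1e-3, 1e-2),
                       EConstit_values = c(1e-7, 1e-6, 1e-5, 1e-4),
                       replicates = 5L,
                       base_config = scenario_config()) {
  structure(list(EDiff_values = EDiff_values,
                 EConstit_values = EConstit_values,
                 replicates = as.integer(replicates),
                 base_config = base_config),
            class = "enz_sweep")
}

#' Run a scenario sweep
#'
#' Runs every (EDiff, EConstit, replicate) cell, optionally writing each
#' run's artifacts under `out_dir/EDiff<...>_EConstit<...>/rep<k>/`, and
#' aggregates per-cell means of window-averaged diversity and
#' depolymerization plus the across-cell diversity-depolymerization
#' Pearson correlations.
#'
#' @param sweep An [sweep_spec()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List: `summary` (one row per cell: factor levels, mean
#'   diversity, mean depolymerization per nutrient, replicate survival
#'   fraction), `correlations` (diversity vs depolymerization r and p
#'   per nutrient across cells), `runs` (per-run one-line records).
#' @export
run_sweep <- function(sweep, out_dir = NULL) {
  stopifnot(inherits(sweep, "enz_sweep"))
  cells <- expand.grid(EDiff = sweep$EDiff_values,
                       EConstit = sweep$EConstit_values)
  runs <- list()
  summary_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cfg <- sweep$base_config
    cfg$enzyme_diffusion <- cells$EDiff[ci]
    cfg$EConstit <- cells$EConstit[ci]
    cfg <- validate_config(unclass(cfg))
    div <- dep_C <- dep_N <- dep_P <- surv <- numeric(0)
    for (k in seq_len(sweep$replicates)) {
      run <- simulate_run(cfg, replicate = k)
      if (!is.null(out_dir)) {
        cell_dir <- file.path(out_dir,
                              sprintf("EDiff%g_EConstit%g",
                                      cells$EDiff[ci], cells$EConstit[ci]),
                              sprintf("rep%d", k))
        write_run(run, cell_dir)
      }
      s <- run$summary
      div <- c(div, s$diversity)
      dep_C <- c(dep_C, s$depoly[["C"]])
      dep_N <- c(dep_N, s$depoly[["N"]])
      dep_P <- c(dep_P, s$depoly[["P"]])
      surv <- c(surv, !s$extinct)
      runs[[length(runs) + 1L]] <- data.frame(
        EDiff = cells$EDiff[ci], EConstit = cells$EConstit[ci],
        replicate = k, diversity = s$diversity,
        depoly_C = s$depoly[["C"]], depoly_N = s$depoly[["N"]],
        depoly_P = s$depoly[["P"]], extinct = s$extinct)
    }
    summary_rows[[ci]] <- data.frame(
      EDiff = cells$EDiff[ci], EConstit = cells$EConstit[ci],
      diversity = mean(div), depoly_C = mean(dep_C),
      depoly_N = mean(dep_N), depoly_P = mean(dep_P),
      survival = mean(surv))
  }
  summary <- do.call(rbind, summary_rows)
  runs <- do.call(rbind, runs)
  correlations <- diversity_depoly_correlation(summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "sweep_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(runs, file.path(out_dir, "sweep_runs.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, correlations = correlations, runs = runs)
}

#' Diversity-depolymerization correlation across sweep cells
#'
#' Pearson correlation, across scenario cells, between mean community
#' diversity and mean depolymerization of each nutrient.
#'
#' @param summary A data.frame with columns `diversity`, `depoly_C`,
#'   `depoly_N`, `depoly_P` (one row per scenario cell).
#' @return data.frame with one row per nutrient: `nutrient`, `r`, `p`.
#' @export
diversity_depoly_correlation <- function(summary) {
  out <- lapply(c("C", "N", "P"), function(nu) {
    y <- summary[[paste0("depoly_", nu)]]
    ok <- is.finite(summary$diversity) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(summary$diversity[ok]) == 0 ||
        stats::sd(y[ok]) == 0) {
      return(data.frame(nutrient = nu, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(summary$diversity[ok], y[ok])
    data.frame(nutrient = nu, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}
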