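#' Simpson-type community diversity
#'
#' `1 - sum(p_i^2)` over genotype frequencies; 0 for a single type or an
#' empty community, approaching 1 - 1/8 = 0.875 for eight equal types.
#'
#' @param frequencies Non-negative genotype proportions. They must sum to
#'   1 (a count vector is also accepted and normalized), or be empty /
#'   all zero for an extinct community.
#' @return Diversity in \[0, 1).
#' @examples
#' diversity(rep(1 / 8, 8)) # 0.875
#' @export
diversity <- function(frequencies) {
  if (length(frequencies) == 0) return(0)
  if (any(frequencies < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  tot <- sum(frequencies)
  if (tot == 0) return(0)
  p <- frequencies / tot
  1 - sum(p^2)
}

#' Advance a lattice by whole time steps
#'
#' Runs the full per-minute process loop (input, decays, diffusions,
#' product formation, uptake and enzyme production, metabolism, death,
#' reproduction) `n_steps` times. Draws come from R's global RNG.
#'
#' @param lattice An `enz_lattice`.
#' @param config An `enz_config`.
#' @param n_steps Number of steps (minutes at `dt = 1`).
#' @return The updated lattice.
#' @export
step_lattice <- function(lattice, config, n_steps = 1L) {
  res <- cpp_simulate(lattice, config, as.integer(n_steps),
                      metrics_every = 0L, snapshot_every = 0L,
                      stop_when_extinct = FALSE)
  as_enz_lattice(res$state, config)
}

#' Run one replicate of a scenario
#'
#' Seeds the RNG with `config$seed + replicate`, initializes the lattice,
#' and executes `run_hours * 60 / dt` steps, recording community metrics
#' every model hour and a genotype raster snapshot every
#' `snapshot_interval_hours`. Reported summary diversity and
#' depolymerization are averaged over the final `metrics_window_hours`
#' (clipped to the run length).
#'
#' @param config An `enz_config`.
#' @param replicate Replicate index (added to the base seed).
#' @return A list of class `"enz_run"`:
#'   \describe{
#'     \item{metrics}{data.frame, one row per hour: `time_h`, counts per
#'       genotype, `total`, `diversity`, `depoly_C/N/P` (fg per hour),
#'       `density` (microbes per um^2).}
#'     \item{rasters}{list of `enz_raster` snapshots.}
#'     \item{final}{final `enz_lattice`.}
#'     \item{summary}{window-averaged diversity and depolymerization,
#'       final densities by genotype, extinction flag.}
#'   }
#' @export
simulate_run <- function(config, replicate = 0L) {
  set.seed(config$seed + as.integer(replicate))
  lat <- initialize_lattice(config)
  steps_per_hour <- round(60 / config$dt)
  n_steps <- as.integer(round(config$run_hours * steps_per_hour))
  snap_every <- as.integer(round(
    config$snapshot_interval_hours * steps_per_hour))
  res <- cpp_simulate(lat, config, n_steps,
                      metrics_every = steps_per_hour,
                      snapshot_every = snap_every,
                      stop_when_extinct = config$stop_when_extinct)
  m <- res$metrics
  area <- config$width * config$height
  metrics <- data.frame(time_h = m[, 1] / steps_per_hour)
  gn <- genotype_names()
  for (g in seq_len(8)) metrics[[gn[g]]] <- m[, 1 + g]
  metrics$total <- m[, 10]
  metrics$diversity <- m[, 11]
  metrics$depoly_C <- m[, 12]
  metrics$depoly_N <- m[, 13]
  metrics$depoly_P <- m[, 14]
  metrics$density <- metrics$total / area

  rasters <- Map(function(snap, step) {
    new_raster(snap, time_hours = step / steps_per_hour)
  }, res$snapshots, as.list(res$snapshot_steps))

  window <- min(config$metrics_window_hours, config$run_hours)
  in_win <- metrics$time_h > config$run_hours - window
  final <- as_enz_lattice(res$state, config)
  pop <- sum(final$genotype > 0)
  summary <- list(
    diversity = mean(metrics$diversity[in_win]),
    depoly = c(C = mean(metrics$depoly_C[in_win]),
               N = mean(metrics$depoly_N[in_win]),
               P = mean(metrics$depoly_P[in_win])),
    density_by_genotype = stats::setNames(
      as.numeric(metrics[nrow(metrics), gn]) / area, gn),
    final_population = pop,
    extinct = pop == 0,
    window_hours = window)

  structure(list(metrics = metrics, rasters = rasters, final = final,
                 summary = summary, config = config,
                 replicate = as.integer(replicate),
                 seed = config$seed + as.integer(replicate)),
            class = "enz_run")
}

#' @export
print.enz_run <- function(x, ...) {
  s <- x$summary
  cat("<enz_run ", x$config$run_hours, " h, replicate ", x$replicate,
      ": pop ", s$final_population,
      ", diversity ", signif(s$diversity, 3),
      ", depoly C ", signif(s$depoly[["C"]], 3), " fg/h",
      if (s$extinct) ", EXTINCT", ">\n", sep = "")
  invisible(x)
}

#' Genotype raster snapshot
#'
#' An integer `height x width` matrix: 0 = empty box, 1..8 = genotype
#' codes in the order of [genotype_names()].
#'
#' @param mat Integer matrix of categories in 0..8.
#' @param time_hours Model time of the slice.
#' @return An `enz_raster`.
#' @export
new_raster <- function(mat, time_hours = NA_real_) {
  stopifnot(is.matrix(mat), all(mat %in% 0:8))
  structure(matrix(as.integer(mat), nrow(mat)), time_hours = time_hours,
            class = "enz_raster")
}

#' @export
print.enz_raster <- function(x, ...) {
  cat("<enz_raster ", nrow(x), "x", ncol(x), " t=",
      attr(x, "time_hours"), " h, ", sum(x > 0), " microbes>\n", sep = "")
  invisible(x)
}

#' Extract the genotype raster of a lattice state
#'
#' @inheritParams step_lattice
#' @param time_hours Time stamp attached to the snapshot.
#' @return An `enz_raster`.
#' @export
as_raster <- function(lattice, time_hours = NA_real_) {
  new_raster(lattice_field(lattice, "genotype"), time_hours)
}
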