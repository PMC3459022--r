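#' Write a genotype raster as plain text
#'
#' Format: a header line `# raster width=W height=H time_h=T`, a legend
#' line mapping codes 1..8 to genotype names (0 is always empty), then
#' `H` rows of space-separated integers. Round-trips exactly through
#' [read_raster()].
#'
#' @param raster An `enz_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "enz_raster") || is.matrix(raster))
  legend <- paste(paste0(1:8, "=", genotype_names()), collapse = " ")
  header <- c(
    sprintf("# raster width=%d height=%d time_h=%s", ncol(raster),
            nrow(raster), format(attr(raster, "time_hours") %||% NA)),
    paste0("# legend 0=empty ", legend))
  rows <- apply(raster, 1, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a plain-text genotype raster
#'
#' @param path File written by [write_raster()].
#' @return An `enz_raster`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hd <- lines[1]
  get_num <- function(key) {
    m <- regmatches(hd, regexec(paste0(key, "=([0-9.NAe+-]+)"), hd))[[1]]
    if (length(m) < 2) stop("malformed raster header in ", path,
                            call. = FALSE)
    suppressWarnings(as.numeric(m[2]))
  }
  w <- as.integer(get_num("width"))
  h <- as.integer(get_num("height"))
  time_h <- get_num("time_h")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) != h) {
    stop("raster body has ", length(body), " rows, header says ", h,
         call. = FALSE)
  }
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.integer)
  if (any(lengths(vals) != w)) {
    stop("raster row width does not match header in ", path,
         call. = FALSE)
  }
  mat <- do.call(rbind, vals)
  if (!all(mat %in% 0:8)) {
    stop("raster contains codes outside 0..8", call. = FALSE)
  }
  new_raster(mat, time_hours = time_h)
}

#' Write the hourly metrics table of a run as CSV
#'
#' @param run An `enz_run` from [simulate_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(run, path) {
  utils::write.csv(run$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write all artifacts of a run into a directory
#'
#' Produces `metrics.csv`, one `raster_<hours>h.txt` per snapshot, and
#' `run_log.json` (seed, resolved configuration, mass-ledger totals,
#' extinction flag).
#'
#' @param run An `enz_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics(run, file.path(dir, "metrics.csv"))
  for (ras in run$rasters) {
    t <- attr(ras, "time_hours")
    write_raster(ras, file.path(dir, sprintf("raster_%sh.txt",
                                             format(t))))
  }
  cfg <- run$config
  log <- list(seed = run$seed, replicate = run$replicate,
              config = unclass(cfg),
              ledger = as.list(run$final$ledger),
              final_population = run$summary$final_population,
              extinct = run$summary$extinct,
              summary_diversity = run$summary$diversity,
              summary_depoly = as.list(run$summary$depoly))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read all raster snapshots of a run directory
#'
#' @param dir Directory written by [write_run()] (or any directory of
#'   `raster_*.txt` files).
#' @return Time-ordered list of `enz_raster`.
#' @export
read_run_rasters <- function(dir) {
  files <- list.files(dir, pattern = "^raster_.*\\.txt$",
                      full.names = TRUE)
  rasters <- lapply(files, read_raster)
  ord <- order(vapply(rasters, function(r) attr(r, "time_hours"),
                      numeric(1)))
  rasters[ord]
}

#' The published spatial-association ranking for different-genotype pairs
#'
#' The 28 different-genotype pairs with their published average z-score
#' (association strength, rounded to 2 decimals), significance flag, and
#' complementation score, shipped as a plain CSV. Useful for
#' re-computing the association-complementation correlation without
#' running the full sweep.
#'
#' @return data.frame: `type_a`, `type_b`, `score`, `significant`,
#'   `complementation`.
#' @export
published_association_table <- function() {
  path <- system.file("extdata", "published_association_table.csv",
                      package = "enzcomm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
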