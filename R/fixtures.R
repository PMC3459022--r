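#' Generate a synthetic genotype raster with controlled spatial structure
#'
#' Fixture rasters exercise the spatial-statistics layer without running
#' the simulator. Patterns (all using category codes 0..8, 0 = empty):
#' \describe{
#'   \item{random}{iid uniform draws from `categories` over every cell.}
#'   \item{aggregated}{`n_colonies` circular colonies (Chebyshev radius
#'     `colony_radius`) of categories cycled from `categories`, centers
#'     drawn uniformly, on an empty background.}
#'   \item{checkerboard}{the two first `categories` alternating by cell
#'     parity.}
#'   \item{interwoven}{thin alternating diagonal stripes of the two
#'     first `categories` separated by empty stripes (period 3 x
#'     `stripe_width`), mimicking interwoven filamentous coalitions.}
#' }
#' Draws use R's global RNG; seed it for reproducibility.
#'
#' @param pattern One of `"random"`, `"aggregated"`, `"checkerboard"`,
#'   `"interwoven"`.
#' @param categories Integer category codes (1..8) used by the pattern.
#' @param width,height Raster dimensions (at least 4 x 4).
#' @param n_colonies,colony_radius Aggregated-pattern parameters.
#' @param stripe_width Interwoven-pattern stripe thickness in cells.
#' @return An `enz_raster`.
#' @export
generate_fixture_raster <- function(pattern, categories = c(1L, 8L),
                                    width = 10L, height = 10L,
                                    n_colonies = 3L, colony_radius = 2L,
                                    stripe_width = 1L) {
  if (width < 4 || height < 4) {
    stop("fixture rasters must be at least 4 x 4", call. = FALSE)
  }
  stopifnot(all(categories %in% 1:8), length(categories) >= 1)
  mat <- matrix(0L, height, width)
  row <- matrix(rep(seq_len(height), width), height)
  col <- matrix(rep(seq_len(width), each = height), height)
  if (pattern == "random") {
    mat[] <- categories[sample.int(length(categories),
                                   width * height, replace = TRUE)]
  } else if (pattern == "aggregated") {
    for (i in seq_len(n_colonies)) {
      cat_i <- categories[(i - 1L) %% length(categories) + 1L]
      cr <- sample.int(height, 1L)
      cc <- sample.int(width, 1L)
      hit <- pmax(abs(row - cr), abs(col - cc)) <= colony_radius
      mat[hit] <- cat_i
    }
  } else if (pattern == "checkerboard") {
    if (length(categories) < 2) {
      stop("checkerboard needs two categories", call. = FALSE)
    }
    mat[] <- ifelse((row + col) %% 2L == 0L, categories[1],
                    categories[2])
  } else if (pattern == "interwoven") {
    if (length(categories) < 2) {
      stop("interwoven needs two categories", call. = FALSE)
    }
    phase <- ((row + col - 2L) %/% stripe_width) %% 3L
    mat[phase == 0L] <- categories[1]
    mat[phase == 1L] <- categories[2]
  } else {
    stop("unknown fixture pattern: ", pattern, call. = FALSE)
  }
  new_raster(mat)
}
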