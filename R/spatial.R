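#' Category levels used in spatial analysis
#'
#' Rasters carry nine categories: the eight genotypes plus empty boxes,
#' which are a first-class category throughout the spatial analysis.
#'
#' @return Named integer vector: codes 0..8 named "empty", "cnp", ...,
#'   "CNP".
#' @export
raster_categories <- function() {
  stats::setNames(0:8, c("empty", genotype_names()))
}

pair_table <- function() {
  idx <- which(upper.tri(matrix(0, 9, 9), diag = TRUE), arr.ind = TRUE)
  a <- idx[, "row"] - 1L
  b <- idx[, "col"] - 1L
  nm <- names(raster_categories())
  data.frame(cat_a = a, cat_b = b,
             pair = paste(nm[a + 1L], nm[b + 1L], sep = ":"),
             key = a * 9L + b)
}

#' Build a neighborhood join graph over a rectangular grid
#'
#' Joins every pair of cells at Chebyshev distance at most `radius`;
#' radius 1 on a bounded grid reproduces the 8-neighbor ("queen")
#' convention. Analysis graphs are non-toroidal by default.
#'
#' @param width,height Grid dimensions in cells.
#' @param radius Neighborhood radius in cells (>= 1, < min(width,
#'   height)).
#' @param torus Wrap around the edges?
#' @return A list of class `"enz_graph"`: `n_cells`, join endpoints
#'   `from` / `to` (1-based, column-major cell indices, `from < to`, each
#'   unordered pair once), `degrees`, and the join-structure constants
#'   used by the analytic moments.
#' @export
build_neighbor_graph <- function(width, height, radius = 1L,
                                 torus = FALSE) {
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (radius >= min(width, height)) {
    stop("radius must be smaller than the grid's shortest side",
         call. = FALSE)
  }
  n <- width * height
  dx <- rep(0:radius, each = 2L * radius + 1L)
  dy <- rep(seq(-radius, radius), radius + 1L)
  keep <- dx > 0L | (dx == 0L & dy > 0L)  # half-plane: each pair once
  dx <- dx[keep]; dy <- dy[keep]

  x <- rep(0:(width - 1L), each = height)
  y <- rep(0:(height - 1L), width)
  from <- integer(0); to <- integer(0)
  for (o in seq_along(dx)) {
    x2 <- x + dx[o]; y2 <- y + dy[o]
    if (torus) {
      x2 <- x2 %% width; y2 <- y2 %% height
      ok <- rep(TRUE, n)
    } else {
      ok <- x2 >= 0L & x2 < width & y2 >= 0L & y2 < height
    }
    k1 <- y[ok] + x[ok] * height + 1L
    k2 <- y2[ok] + x2[ok] * height + 1L
    from <- c(from, k1); to <- c(to, k2)
  }
  drop_self <- from != to
  from <- from[drop_self]; to <- to[drop_self]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- (a - 1) * n + b
  keep <- !duplicated(key)  # small tori can reach a cell two ways
  a <- a[keep]; b <- b[keep]
  deg <- tabulate(c(a, b), nbins = n)
  structure(list(n_cells = n, width = width, height = height,
                 radius = as.integer(radius), torus = torus,
                 metric = "chebyshev",
                 from = a, to = b, degrees = deg,
                 n_joins = length(a),
                 pairs_sharing = sum(choose(deg, 2))),
            class = "enz_graph")
}

#' @export
print.enz_graph <- function(x, ...) {
  cat("<enz_graph ", x$height, "x", x$width, " radius ", x$radius,
      if (x$torus) " torus", ", ", x$n_joins, " joins>\n", sep = "")
  invisible(x)
}

#' Observed join counts per unordered category pair
#'
#' Tallies, over every join of the graph, the unordered pair of category
#' labels at its two endpoints. Same-category joins count once per join;
#' the counts over all 45 pairs (9 categories including empty) partition
#' the total number of joins.
#'
#' @param raster An `enz_raster` (or integer matrix with values 0..8).
#' @param graph An `enz_graph` with matching dimensions.
#' @return Named integer vector over all 45 pairs.
#' @export
join_counts <- function(raster, graph) {
  labels <- as.integer(raster)
  if (length(labels) != graph$n_cells) {
    stop("raster dimensions do not match graph", call. = FALSE)
  }
  pt <- pair_table()
  la <- labels[graph$from]; lb <- labels[graph$to]
  key <- pmin(la, lb) * 9L + pmax(la, lb)
  counts <- tabulate(match(key, pt$key), nbins = nrow(pt))
  stats::setNames(counts, pt$pair)
}

falling <- function(n, k) prod(n - seq_len(k) + 1)

#' Analytic join-count moments and z-statistics
#'
#' For every unordered category pair, the expected join count and its
#' variance under the nonfree-sampling null -- a uniformly random
#' permutation of the observed labels across cells, category totals held
#' fixed (Cliff-Ord random labelling) -- computed exactly from the
#' category counts and the graph's join structure. The z-statistic is
#' `(observed - expected) / sqrt(variance)`.
#'
#' Pairs involving an absent category, or with null variance below
#' `1e-12`, are flagged (`assessable = FALSE`, z = NA). With
#' `null = "permutation"` the moments are instead estimated from
#' `n_perm` random label permutations (the same engine serves as the
#' testing oracle and as a fallback for degenerate analytic variances).
#'
#' @inheritParams join_counts
#' @param null `"analytic"` (exact permutation moments) or
#'   `"permutation"` (Monte-Carlo estimate; uses R's RNG).
#' @param n_perm Number of label permutations for the Monte-Carlo null.
#' @return A data.frame with one row per pair: `pair`, `cat_a`, `cat_b`,
#'   `observed`, `expected`, `variance`, `z`, `assessable`.
#' @export
join_count_z <- function(raster, graph,
                         null = c("analytic", "permutation"),
                         n_perm = 999) {
  null <- match.arg(null)
  labels <- as.integer(raster)
  obs <- join_counts(raster, graph)
  pt <- pair_table()
  if (null == "analytic") {
    mom <- join_count_moments(labels, graph)
  } else {
    mom <- permutation_join_moments(labels, graph, n_perm)
  }
  cat_counts <- tabulate(labels + 1L, nbins = 9L)
  present <- cat_counts[pt$cat_a + 1L] >= 1L & cat_counts[pt$cat_b + 1L] >= 1L
  assessable <- present & mom$variance > 1e-12
  z <- ifelse(assessable, (obs - mom$expected) / sqrt(mom$variance),
              NA_real_)
  data.frame(pair = pt$pair, cat_a = pt$cat_a, cat_b = pt$cat_b,
             observed = as.numeric(obs), expected = mom$expected,
             variance = mom$variance, z = z, assessable = assessable)
}

# Exact first and second moments of every pair's join count under random
# labelling. J = joins, T = unordered pairs of joins sharing one cell,
# Q = unordered pairs of disjoint joins; the second moment only needs
# the probabilities that 2, 3, or 4 fixed cells carry the right labels.
join_count_moments <- function(labels, graph) {
  n <- graph$n_cells
  J <- graph$n_joins
  Tt <- graph$pairs_sharing
  Q <- choose(J, 2) - Tt
  cnt <- tabulate(labels + 1L, nbins = 9L)
  pt <- pair_table()
  expected <- variance <- numeric(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    m <- cnt[pt$cat_a[i] + 1L]
    k <- cnt[pt$cat_b[i] + 1L]
    same <- pt$cat_a[i] == pt$cat_b[i]
    if (same) {
      p2 <- if (n >= 2) m * (m - 1) / falling(n, 2) else 0
      p3 <- if (n >= 3) m * (m - 1) * (m - 2) / falling(n, 3) else 0
      p4 <- if (n >= 4) {
        m * (m - 1) * (m - 2) * (m - 3) / falling(n, 4)
      } else 0
    } else {
      p2 <- if (n >= 2) 2 * m * k / falling(n, 2) else 0
      p3 <- if (n >= 3) {
        (m * k * (k - 1) + k * m * (m - 1)) / falling(n, 3)
      } else 0
      p4 <- if (n >= 4) {
        4 * m * (m - 1) * k * (k - 1) / falling(n, 4)
      } else 0
    }
    E <- J * p2
    E2 <- E + 2 * (Tt * p3 + Q * p4)
    expected[i] <- E
    variance[i] <- max(0, E2 - E^2)
  }
  list(expected = expected, variance = variance)
}

#' Monte-Carlo join-count moments under label permutation
#'
#' @inheritParams join_count_z
#' @param labels Integer label vector (0..8), one per cell.
#' @return List with per-pair `expected`, `variance`, and the
#'   `n_perm x 45` matrix of permuted counts.
#' @export
permutation_join_moments <- function(labels, graph, n_perm = 999) {
  pt <- pair_table()
  counts <- matrix(0, n_perm, nrow(pt))
  for (p in seq_len(n_perm)) {
    perm <- labels[sample.int(length(labels))]
    la <- perm[graph$from]; lb <- perm[graph$to]
    key <- pmin(la, lb) * 9L + pmax(la, lb)
    counts[p, ] <- tabulate(match(key, pt$key), nbins = nrow(pt))
  }
  list(expected = colMeans(counts),
       variance = apply(counts, 2, stats::var) * (n_perm - 1) / n_perm,
       counts = counts)
}

#' Temporally independent slice selection
#'
#' Successive raster snapshots are autocorrelated; the minimum spacing
#' for two slices to be treated as independent is
#' `N_t = (1 + r_t) / (1 - r_t)`, where `r_t` is the proportion of boxes
#' that retain the same category between consecutive snapshots.
#' Selection starts at the first slice and advances by `ceiling(N_t)`,
#' recomputing `r_t` at each selected slice; `r_t = 1` (a frozen
#' pattern, infinite interval) terminates the walk.
#'
#' @param rasters Time-ordered list of `enz_raster` (or integer
#'   matrices), e.g. snapshots 1,000 h apart.
#' @return Integer vector of selected slice indices.
#' @export
independence_indices <- function(rasters) {
  n <- length(rasters)
  if (n < 2) stop("need at least 2 snapshots", call. = FALSE)
  sel <- integer(0)
  t <- 1L
  while (t <= n) {
    sel <- c(sel, t)
    if (t == n) break
    r_t <- mean(as.integer(rasters[[t]]) == as.integer(rasters[[t + 1L]]))
    if (r_t >= 1) break
    t <- t + as.integer(ceiling((1 + r_t) / (1 - r_t)))
  }
  sel
}

#' Aggregate z-statistics into a chi-square test
#'
#' Squares and sums the z-statistics of one pair over time slices (and
#' replicates); under the null the sum follows a chi-square distribution
#' with degrees of freedom equal to the number of contributing slices.
#' Significance uses a Bonferroni cutoff of `alpha / n_pairs` (0.05 / 45
#' = 0.0011 by default).
#'
#' @param z_values Finite z-statistics of one pair (NAs are dropped).
#' @param alpha Family-wise error rate before correction.
#' @param n_pairs Number of pairs corrected for (45: all unordered pairs
#'   of 9 categories including empty).
#' @return List: `chi_sq`, `df`, `p`, `significant`, `cutoff`,
#'   `assessable` (FALSE when no slice contributed).
#' @export
aggregate_chi_square <- function(z_values, alpha = 0.05, n_pairs = 45) {
  z <- z_values[is.finite(z_values)]
  df <- length(z)
  cutoff <- alpha / n_pairs
  if (df == 0) {
    return(list(chi_sq = NA_real_, df = 0L, p = NA_real_,
                significant = FALSE, cutoff = cutoff, assessable = FALSE))
  }
  chi <- sum(z^2)
  p <- stats::pchisq(chi, df = df, lower.tail = FALSE)
  list(chi_sq = chi, df = df, p = p, significant = p < cutoff,
       cutoff = cutoff, assessable = TRUE)
}

#' Association scores from per-radius mean z and significance
#'
#' For each pair, the association score is the mean of its radius-wise
#' mean z-statistics over the radii with a significant positive
#' association (chi-square significant after Bonferroni and mean z > 0).
#' Pairs with no significant positive case carry an NA score and drop
#' out of the ranking.
#'
#' @param mean_z Numeric matrix, pairs x radii, of mean z per radius.
#' @param significant_positive Logical matrix of the same shape.
#' @return data.frame ranked by score: `pair`, `score`, `n_radii`,
#'   `mean_z_all` (unconditional mean over all radii).
#' @export
association_scores <- function(mean_z, significant_positive) {
  stopifnot(all(dim(mean_z) == dim(significant_positive)))
  score <- vapply(seq_len(nrow(mean_z)), function(i) {
    sel <- significant_positive[i, ] & is.finite(mean_z[i, ])
    if (!any(sel)) NA_real_ else mean(mean_z[i, sel])
  }, numeric(1))
  out <- data.frame(pair = rownames(mean_z), score = score,
                    n_radii = rowSums(significant_positive, na.rm = TRUE),
                    mean_z_all = rowMeans(mean_z, na.rm = TRUE))
  out[order(-out$score, out$pair), ]
}

#' Full spatial-association analysis of raster snapshots
#'
#' Runs the complete pipeline: select temporally independent slices per
#' replicate, compute multi-category join-count z-statistics at each
#' neighborhood radius, aggregate each (pair, radius) into a chi-square
#' over all selected slices and replicates, apply the Bonferroni cutoff,
#' and score pair associations.
#'
#' @param rasters A time-ordered list of `enz_raster` for one replicate,
#'   or a list of such lists for several replicates.
#' @param radii Neighborhood radii to analyze (default 1..5).
#' @param torus Treat the analysis grid as a torus? (Default `FALSE`.)
#' @param alpha Family-wise error rate (Bonferroni-corrected over 45
#'   pairs).
#' @param independent Apply temporal-independence slice selection
#'   (default); `FALSE` uses every slice.
#' @return List: `cases` (z per replicate x slice x radius x pair),
#'   `aggregates` (chi-square per pair x radius), `scores` (per-pair
#'   association scores with complementation where both categories are
#'   genotypes).
#' @export
spatial_association_analysis <- function(rasters, radii = 1:5,
                                         torus = FALSE, alpha = 0.05,
                                         independent = TRUE) {
  if (length(rasters) == 0) stop("no rasters supplied", call. = FALSE)
  if (!is.list(rasters[[1]])) rasters <- list(rasters)
  pt <- pair_table()
  cases <- list()
  for (rep_i in seq_along(rasters)) {
    slices <- rasters[[rep_i]]
    sel <- if (independent && length(slices) >= 2) {
      independence_indices(slices)
    } else {
      seq_along(slices)
    }
    for (s in sel) {
      ras <- slices[[s]]
      for (r in radii) {
        g <- build_neighbor_graph(ncol(ras), nrow(ras), r, torus)
        zt <- join_count_z(ras, g)
        cases[[length(cases) + 1L]] <- data.frame(
          replicate = rep_i, slice = s,
          time_h = attr(ras, "time_hours") %||% NA_real_,
          radius = r, pair = zt$pair, z = zt$z)
      }
    }
  }
  cases <- do.call(rbind, cases)

  n_r <- length(radii)
  mean_z <- matrix(NA_real_, nrow(pt), n_r,
                   dimnames = list(pt$pair, paste0("r", radii)))
  sig_pos <- matrix(FALSE, nrow(pt), n_r,
                    dimnames = dimnames(mean_z))
  aggregates <- list()
  for (j in seq_len(n_r)) {
    for (i in seq_len(nrow(pt))) {
      zi <- cases$z[cases$pair == pt$pair[i] & cases$radius == radii[j]]
      agg <- aggregate_chi_square(zi, alpha = alpha, n_pairs = nrow(pt))
      mz <- if (agg$df > 0) mean(zi[is.finite(zi)]) else NA_real_
      mean_z[i, j] <- mz
      sig_pos[i, j] <- isTRUE(agg$significant) && isTRUE(mz > 0)
      aggregates[[length(aggregates) + 1L]] <- data.frame(
        pair = pt$pair, radius = radii[j], chi_sq = agg$chi_sq,
        df = agg$df, p = agg$p, significant = agg$significant,
        mean_z = mz)[i, ]
    }
  }
  aggregates <- do.call(rbind, aggregates)
  rownames(aggregates) <- NULL

  scores <- association_scores(mean_z, sig_pos)
  gn <- genotype_names()
  nm <- names(raster_categories())
  comp <- vapply(scores$pair, function(p) {
    ab <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (all(ab %in% gn)) complementation_score(ab[1], ab[2]) else NA_integer_
  }, integer(1))
  scores$complementation <- comp
  rownames(scores) <- NULL
  list(cases = cases, aggregates = aggregates, scores = scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation of association strength with complementation
#'
#' Pearson correlation, across pairs of *different* genotypes, between
#' the spatial association score and the complementation score (number
#' of enzyme loci with different alleles).
#'
#' @param scores Numeric association scores, or the `scores` data.frame
#'   from [spatial_association_analysis()] (same-genotype and
#'   empty-involving pairs are dropped automatically).
#' @param complementation Complementation scores matching `scores` (not
#'   needed when `scores` is the pipeline data.frame).
#' @return List: `r`, `p` (two-sided), `n`, `assessable` (FALSE when
#'   fewer than 3 pairs or zero variance in either variable).
#' @export
complementation_correlation <- function(scores, complementation = NULL) {
  if (is.data.frame(scores)) {
    keep <- !is.na(scores$complementation) & scores$complementation > 0 &
      !is.na(scores$score)
    complementation <- scores$complementation[keep]
    scores <- scores$score[keep]
  }
  n <- length(scores)
  if (n < 3 || stats::sd(scores) == 0 || stats::sd(complementation) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, assessable = FALSE))
  }
  ct <- stats::cor.test(scores, complementation, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, assessable = TRUE)
}
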