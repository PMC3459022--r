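# Shared fixtures and independent oracles for the test suite.

# Small lattice configuration for engine tests.
tiny_config <- function(...) {
  scenario_config(width = 10L, height = 10L, run_hours = 2, ...)
}

# Brute-force join enumeration: all unordered cell pairs within Chebyshev
# distance `radius`, by direct double loop (independent of the package's
# offset-based construction).
brute_force_joins <- function(width, height, radius, torus = FALSE) {
  cells <- expand.grid(row = seq_len(height), col = seq_len(width))
  n <- nrow(cells)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dr <- abs(cells$row[i] - cells$row[j])
      dc <- abs(cells$col[i] - cells$col[j])
      if (torus) {
        dr <- min(dr, height - dr)
        dc <- min(dc, width - dc)
      }
      if (max(dr, dc) <= radius) {
        ki <- cells$row[i] + (cells$col[i] - 1) * height
        kj <- cells$row[j] + (cells$col[j] - 1) * height
        from <- c(from, min(ki, kj)); to <- c(to, max(ki, kj))
      }
    }
  }
  data.frame(from = from, to = to)
}

# Join counts straight from an edge list (oracle for join_counts()).
brute_force_join_counts <- function(labels, edges) {
  la <- labels[edges$from]; lb <- labels[edges$to]
  key <- paste(pmin(la, lb), pmax(la, lb))
  table(key)
}

# All distinct arrangements of a label multiset (recursive), for exact
# enumeration of join-count null moments on tiny rasters.
multiset_permutations <- function(labels) {
  labels <- sort(labels)
  res <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      idx <- which(remaining == v)[1]
      recurse(c(prefix, v), remaining[-idx])
    }
  }
  recurse(integer(0), labels)
  res
}

# Exact null moments of a pair's join count by full enumeration over all
# distinct label arrangements.
enumeration_moments <- function(labels, graph, cat_a, cat_b) {
  arr <- multiset_permutations(labels)
  vals <- vapply(arr, function(lab) {
    la <- lab[graph$from]; lb <- lab[graph$to]
    sum((pmin(la, lb) == min(cat_a, cat_b)) &
          (pmax(la, lb) == max(cat_a, cat_b)))
  }, numeric(1))
  c(expected = mean(vals),
    variance = mean(vals^2) - mean(vals)^2)
}
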