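test_that("neighbor graphs reproduce known join structures", {
  # 3x3 bounded, radius 1: queen contiguity — center degree 8, corner
  # degree 3, 20 joins in total (brute-force verified)
  g <- build_neighbor_graph(3, 3, 1, torus = FALSE)
  expect_identical(g$n_joins, 20L)
  expect_identical(g$degrees[5], 8L)  # center cell
  expect_identical(g$degrees[1], 3L)  # corner
  bf <- brute_force_joins(3, 3, 1)
  expect_identical(g$n_joins, nrow(bf))
  expect_setequal(paste(g$from, g$to), paste(bf$from, bf$to))

  # 4x4 torus radius 1: every cell degree 8, 16*8/2 = 64 joins
  gt <- build_neighbor_graph(4, 4, 1, torus = TRUE)
  expect_identical(gt$n_joins, 64L)
  expect_true(all(gt$degrees == 8L))

  # degenerate and invalid requests
  expect_error(build_neighbor_graph(1, 1, 1), "smaller")
  expect_error(build_neighbor_graph(6, 6, 6), "smaller")
  expect_error(build_neighbor_graph(6, 6, 0), ">= 1")
})

test_that("larger radii nest smaller ones", {
  for (r in 1:3) {
    g1 <- build_neighbor_graph(8, 7, r)
    g2 <- build_neighbor_graph(8, 7, r + 1)
    k1 <- paste(g1$from, g1$to)
    k2 <- paste(g2$from, g2$to)
    expect_true(all(k1 %in% k2))
    expect_gt(g2$n_joins, g1$n_joins)
  }
})

test_that("join counts match brute-force enumeration and partition the joins", {
  # uniform raster: all joins land on one same-category pair
  g <- build_neighbor_graph(5, 5, 1)
  uni <- new_raster(matrix(8L, 5, 5))
  jc <- join_counts(uni, g)
  expect_equal(unname(jc[["CNP:CNP"]]), g$n_joins)
  expect_equal(sum(jc), g$n_joins)

  # 4x4 checkerboard at radius 1: same-color joins only on diagonals
  set.seed(1)
  chk <- generate_fixture_raster("checkerboard", c(1L, 8L), 4, 4)
  g4 <- build_neighbor_graph(4, 4, 1)
  jc4 <- join_counts(chk, g4)
  bf <- brute_force_joins(4, 4, 1)
  oracle <- brute_force_join_counts(as.integer(chk), bf)
  expect_equal(unname(jc4[["cnp:cnp"]]), unname(oracle[["1 1"]]))
  expect_equal(unname(jc4[["CNP:CNP"]]), unname(oracle[["8 8"]]))
  expect_equal(unname(jc4[["cnp:CNP"]]), unname(oracle[["1 8"]]))
  expect_equal(sum(jc4), nrow(bf))

  # random rasters: counts always partition the join total
  for (s in 1:5) {
    set.seed(s)
    ras <- generate_fixture_raster("random", c(1L, 3L, 8L), 6, 5)
    g65 <- build_neighbor_graph(6, 5, 2)
    expect_equal(sum(join_counts(ras, g65)), g65$n_joins)
  }
})

test_that("analytic join-count moments equal exhaustive enumeration on tiny rasters", {
  # 3x3 raster, 9 cells, three categories x 3 cells: all 1680 distinct
  # label arrangements enumerated exactly
  g <- build_neighbor_graph(3, 3, 1)
  labels <- c(1L, 1L, 1L, 4L, 4L, 4L, 8L, 8L, 8L)
  ras <- new_raster(matrix(labels, 3, 3))
  zt <- join_count_z(ras, g)
  for (pr in list(c(1, 1), c(1, 4), c(4, 8), c(8, 8))) {
    mom <- enumeration_moments(labels, g, pr[1], pr[2])
    row <- zt[zt$cat_a == min(pr) & zt$cat_b == max(pr), ]
    expect_equal(row$expected, mom[["expected"]], tolerance = 1e-12)
    expect_equal(row$variance, mom[["variance"]], tolerance = 1e-12)
  }
  # also with an empty category in the mix (2x3 raster, 6 cells)
  g2 <- build_neighbor_graph(3, 2, 1)
  labels2 <- c(0L, 0L, 5L, 5L, 8L, 8L)
  ras2 <- new_raster(matrix(labels2, 2, 3))
  zt2 <- join_count_z(ras2, g2)
  for (pr in list(c(0, 0), c(0, 5), c(5, 8))) {
    mom <- enumeration_moments(labels2, g2, pr[1], pr[2])
    row <- zt2[zt2$cat_a == min(pr) & zt2$cat_b == max(pr), ]
    expect_equal(row$expected, mom[["expected"]], tolerance = 1e-12)
    expect_equal(row$variance, mom[["variance"]], tolerance = 1e-12)
  }
})

test_that("analytic moments match the permutation oracle on 10x10 rasters", {
  # the module's primary oracle: 999 seeded label permutations per
  # fixture pattern and radius; analytic E and Var within 3 MC SE
  patterns <- c("random", "aggregated", "interwoven")
  n_perm <- 999
  for (pat in patterns) {
    set.seed(2024)
    ras <- generate_fixture_raster(pat, c(1L, 8L), 10, 10)
    labels <- as.integer(ras)
    for (r in 1:3) {
      g <- build_neighbor_graph(10, 10, r)
      zt <- join_count_z(ras, g)
      set.seed(1000 + r)
      mc <- permutation_join_moments(labels, g, n_perm)
      for (i in which(zt$assessable)) {
        se_E <- sqrt(mc$variance[i] / n_perm)
        expect_lt(abs(zt$expected[i] - mc$expected[i]),
                  3 * se_E + 1e-9)
        # variance of the sample variance ~ 2 Var^2 / n for near-normal
        # counts; allow 4 SE to keep the flake rate negligible
        se_V <- sqrt(2 / n_perm) * mc$variance[i]
        expect_lt(abs(zt$variance[i] - mc$variance[i]),
                  4 * se_V + 1e-9)
      }
    }
  }
})

test_that("planted aggregation yields positive same-category z", {
  set.seed(99)
  ras <- generate_fixture_raster("aggregated", 8L, 12, 12,
                                 n_colonies = 3, colony_radius = 2)
  g <- build_neighbor_graph(12, 12, 1)
  zt <- join_count_z(ras, g)
  expect_gt(zt$z[zt$pair == "CNP:CNP"], 2)
})

test_that("random labelling calibrates same-category z to mean zero", {
  zs <- vapply(1:200, function(s) {
    set.seed(s)
    ras <- generate_fixture_raster("random", c(1L, 8L), 8, 8)
    g <- build_neighbor_graph(8, 8, 1)
    zt <- join_count_z(ras, g)
    zt$z[zt$pair == "CNP:CNP"]
  }, numeric(1))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 3 / sqrt(sum(!is.na(zs))))
})

test_that("absent categories are flagged not assessable", {
  ras <- new_raster(matrix(8L, 4, 4))
  g <- build_neighbor_graph(4, 4, 1)
  zt <- join_count_z(ras, g)
  expect_false(zt$assessable[zt$pair == "cnp:cnp"])
  expect_true(is.na(zt$z[zt$pair == "cnp:CNP"]))
  # a uniform raster also has zero variance for its own pair
  expect_false(zt$assessable[zt$pair == "CNP:CNP"])
})

test_that("temporal independence walks by ceil((1+r)/(1-r))", {
  a <- matrix(1L, 4, 4)
  b <- matrix(8L, 4, 4)
  # r = 0 between all consecutive slices: every slice selected
  expect_identical(independence_indices(list(a, b, a, b, a)),
                   c(1L, 2L, 3L, 4L, 5L))
  # r = 0.5: N = 3
  half <- a; half[1:8] <- 8L
  expect_identical(independence_indices(list(a, half, a, half, a,
                                             half, a)),
                   c(1L, 4L, 7L))
  # r = 1: frozen pattern terminates selection
  expect_identical(independence_indices(list(a, a, a, a)), 1L)
  # r = 0.6 -> ceil(4) = 4
  ras1 <- matrix(1L, 4, 5)
  ras2 <- ras1; ras2[1:8] <- 8L  # 8 of 20 changed: r = 0.6
  expect_identical(independence_indices(list(ras1, ras2, ras1, ras2,
                                             ras1, ras2)),
                   c(1L, 5L))
  expect_error(independence_indices(list(a)), "at least 2")
})

test_that("chi-square aggregation applies the published Bonferroni cutoff", {
  one <- aggregate_chi_square(2.0)
  expect_equal(one$chi_sq, 4.0)
  expect_identical(one$df, 1L)
  expect_equal(one$p, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(one$p, 0.0455, tolerance = 1e-3)
  expect_false(one$significant)  # 0.0455 > 0.0011
  expect_equal(one$cutoff, 0.05 / 45, tolerance = 1e-12)
  expect_equal(round(one$cutoff, 4), 0.0011)  # as printed

  none <- aggregate_chi_square(c(NA_real_, NA_real_))
  expect_false(none$assessable)
  expect_identical(none$df, 0L)

  zero <- aggregate_chi_square(rep(0, 5))
  expect_equal(zero$chi_sq, 0)
  expect_equal(zero$p, 1)
})

test_that("pooled squared z of standard normals follows chi-square", {
  set.seed(314)
  n <- 1e4
  z2 <- rnorm(n)^2
  ks <- suppressWarnings(stats::ks.test(z2, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("association scores average z over significant positive radii", {
  mean_z <- matrix(c(1, 2, 3, 4, 5,
                     0.5, 0.1, -0.2, 0.3, 0.2), 2, 5, byrow = TRUE,
                   dimnames = list(c("cnP:CNp", "cnp:cnp"),
                                   paste0("r", 1:5)))
  sig <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), 2, 5, byrow = TRUE,
                dimnames = dimnames(mean_z))
  sc <- association_scores(mean_z, sig)
  expect_equal(sc$score[sc$pair == "cnP:CNp"], 3.0)
  expect_true(is.na(sc$score[sc$pair == "cnp:cnp"]))
})

test_that("interwoven coalitions rank the cross pair above both same pairs", {
  set.seed(7)
  ras <- generate_fixture_raster("interwoven", c(3L, 6L), 12, 12)
  slices <- list(ras, ras, ras)  # identical slices; analysis treats the
                                 # first (r = 1 terminates the walk)
  out <- spatial_association_analysis(slices, radii = 1:2,
                                      alpha = 0.05)
  sc <- out$scores
  cross <- sc$mean_z_all[sc$pair == "cNp:CnP"]
  same1 <- sc$mean_z_all[sc$pair == "cNp:cNp"]
  same2 <- sc$mean_z_all[sc$pair == "CnP:CnP"]
  expect_gt(cross, same1)
  expect_gt(cross, same2)
  # permutation null agrees with the analytic z for the cross pair
  g <- build_neighbor_graph(12, 12, 1)
  za <- join_count_z(ras, g)
  set.seed(11)
  zp <- join_count_z(ras, g, null = "permutation", n_perm = 499)
  ia <- za$pair == "cNp:CnP"
  expect_equal(za$z[ia], zp$z[ia], tolerance = 0.15)
})

test_that("association rankings are invariant to category relabeling", {
  set.seed(15)
  ras <- generate_fixture_raster("aggregated", c(2L, 5L), 10, 10,
                                 n_colonies = 4, colony_radius = 2)
  g <- build_neighbor_graph(10, 10, 1)
  z1 <- join_count_z(ras, g)
  # swap categories 2 and 5
  m <- unclass(ras)
  m2 <- m
  m2[m == 2L] <- 5L
  m2[m == 5L] <- 2L
  z2 <- join_count_z(new_raster(m2), g)
  swap_pair <- function(p) {
    nm <- names(raster_categories())
    swap <- function(x) switch(x, cnP = "Cnp", Cnp = "cnP", x)
    ab <- vapply(strsplit(p, ":", fixed = TRUE)[[1]], swap, "")
    ord <- order(match(ab, nm))
    paste(ab[ord], collapse = ":")
  }
  for (p in c("cnP:cnP", "Cnp:Cnp", "cnP:Cnp", "empty:cnP")) {
    expect_equal(z1$z[z1$pair == p],
                 z2$z[z2$pair == swap_pair(p)], tolerance = 1e-12)
  }
})

test_that("the complementation correlation recovers perfect and published structure", {
  # perfectly increasing association with complementation: r = 1
  out <- complementation_correlation(c(0.1, 0.2, 0.3, 0.4),
                                     c(0, 1, 2, 3))
  expect_equal(out$r, 1)

  # zero variance: flagged, not an error
  flat <- complementation_correlation(c(0.2, 0.2, 0.2), c(1, 2, 3))
  expect_false(flat$assessable)

  # published 28-pair table: recomputing complementation from the
  # genotype names reproduces the printed scores, and the correlation
  # matches the printed r = 0.71 within rounding of the scores
  tab <- published_association_table()
  expect_identical(nrow(tab), 28L)
  comp <- mapply(complementation_score, tab$type_a, tab$type_b)
  expect_identical(unname(comp), tab$complementation)
  ct <- complementation_correlation(tab$score, tab$complementation)
  expect_equal(ct$r, 0.71, tolerance = 0.05)
  expect_lt(ct$p, 0.05)
})

test_that("shuffled complementation scores calibrate the correlation null", {
  set.seed(123)
  tab <- published_association_table()
  obs <- abs(complementation_correlation(tab$score,
                                         tab$complementation)$r)
  n_sh <- 999
  exceed <- 0L
  for (i in seq_len(n_sh)) {
    r_i <- complementation_correlation(tab$score,
                                       sample(tab$complementation))$r
    exceed <- exceed + (abs(r_i) >= obs)
  }
  # the observed association is far outside the shuffle null
  expect_lt(exceed / n_sh, 0.01)
})
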