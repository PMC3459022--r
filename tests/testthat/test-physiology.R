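cfg <- scenario_config()

test_that("stoichiometric demand follows the C:N = 6 and C:P = 60 targets", {
  # C:N = 7.5 > 6 puts N in demand; C:P exactly 60 counts as demand on
  # both sides of that pair
  d <- compute_demand(microbe("CNP", 150, 20, 2.5), cfg)
  expect_true(d[["N"]])
  expect_true(d[["P"]])
  expect_true(d[["C"]])  # via the C:P equality
  # exactly balanced: everything in demand, so a balanced microbe feeds
  d2 <- compute_demand(microbe("CNP", 150, 25, 2.5), cfg)
  expect_true(all(d2))
  # C-limited: C:N = 4.8 < 6, C:P = 48 < 60
  d3 <- compute_demand(microbe("CNP", 120, 25, 2.5), cfg)
  expect_identical(unname(d3), c(TRUE, FALSE, FALSE))
  # zero N pool with C present: ratio +Inf, N in demand
  d4 <- compute_demand(microbe("CNP", 150, 0, 2.5), cfg)
  expect_true(d4[["N"]])
})

test_that("uptake follows surface-scaled saturating kinetics", {
  # saturating product: 0.1 * 0.0428 * 150^(2/3) * 10 ~ 1.208 fg/min
  expect_equal(uptake_amount(150, 1e9, cfg), 1.20829, tolerance = 1e-4)
  expect_equal(uptake_amount(150, 0, cfg), 0)
  # at Km: half the saturating rate
  sat <- 0.1 * 0.0428 * 150^(2 / 3) * 10
  expect_equal(uptake_amount(150, cfg$Km_uptake, cfg),
               min(sat / 2, cfg$Km_uptake))
  # product-limited: cannot exceed what the box holds
  expect_equal(uptake_amount(150, 0.5, cfg) <= 0.5, TRUE)
})

test_that("the production cap equalizes C:N at its target exactly", {
  E <- balanced_production_cap(150, 26, cfg)
  expect_equal(E, (6 * 26 - 150) / (6 / 3.5 - 1.1), tolerance = 1e-12)
  expect_equal(E, 9.767442, tolerance = 1e-6)
  # paying 1.1E carbon and E/3.5 nitrogen lands on C:N = 6 exactly
  C2 <- 150 - 1.1 * E
  N2 <- 26 - E / 3.5
  expect_equal(C2 / N2, 6, tolerance = 1e-9)
  # already balanced or N-limited: cap clamps to zero
  expect_equal(balanced_production_cap(156, 26, cfg), 0)
  expect_equal(balanced_production_cap(200, 26, cfg), 0)
  # ill-posed stoichiometric constants are rejected
  bad <- unclass(cfg)
  bad$CtoN_enz <- 6
  expect_error(balanced_production_cap(150, 26, bad), "Resp_enz")
})

test_that("both pair guards activate on the correct side of their targets", {
  # C-limited cell (C:N < 6, falling? no: producing raises C:N): the
  # C:N guard binds at the printed formula
  m <- microbe("CNP", 150, 26, 2.5)
  caps <- production_caps(m, cfg)
  expect_equal(caps[["CN"]], balanced_production_cap(150, 26, cfg),
               tolerance = 1e-12)
  # P-demand cell with C:P well above target: secretion burns C toward
  # C-limitation; the analogous C:P form (C - 60P)/0.8 binds
  m2 <- microbe("CNP", 150, 20, 1)   # C:N = 7.5, C:P = 150
  caps2 <- production_caps(m2, cfg)
  expect_equal(caps2[["CP"]], (150 - 60 * 1) / 0.8, tolerance = 1e-12)
  # producing exactly that cap lands C:P on 60
  E <- caps2[["CP"]]
  expect_equal((150 - 1.1 * E) / (1 - E / 200), 60, tolerance = 1e-9)
})

test_that("enzyme secretion costs C, N, and P at protein stoichiometry", {
  m <- microbe("CNP", 150, 25, 2.5)
  out <- pay_enzyme_cost(m, 1, cfg)
  expect_equal(out$microbe$pool_C, 150 - 1.1)
  expect_equal(out$microbe$pool_N, 25 - 1 / 3.5)
  expect_equal(out$microbe$pool_P, 2.5 - 1 / 200)
  expect_equal(out$respired, 0.1)
  # zero emission: no change
  out0 <- pay_enzyme_cost(m, 0, cfg)
  expect_equal(out0$microbe, m)
  # 3.5 fg costs 3.85 C and exactly 1.0 N
  out2 <- pay_enzyme_cost(m, 3.5, cfg)
  expect_equal(m$pool_C - out2$microbe$pool_C, 3.85)
  expect_equal(m$pool_N - out2$microbe$pool_N, 1.0)
  # emission scales down rather than overdrawing a pool
  poor <- microbe("CNP", 150, 0.1, 2.5)
  out3 <- pay_enzyme_cost(poor, 3.5, cfg)
  expect_equal(out3$emitted, 0.1 * 3.5)
  expect_gte(out3$microbe$pool_N, 0)
})

test_that("constitutive production is mandatory, facultative follows the 1% rule", {
  # constitutive: EConstit * biomass per carried locus, none for cheaters
  cfg_hi <- scenario_config(EConstit = 1e-4)
  out <- constitutive_production(microbe("CNp", 150, 25, 2.5), cfg_hi)
  expect_equal(unname(out$emissions),
               c(150 * 1e-4, 150 * 1e-4 * (1 - 1.1e-4), 0),
               tolerance = 1e-6)  # second locus sees the reduced pool
  out0 <- constitutive_production(microbe("cnp", 150, 25, 2.5), cfg_hi)
  expect_equal(sum(out0$emissions), 0)
  # 1e-7 default: 1.5e-5 fg per carried locus
  outd <- constitutive_production(microbe("Cnp", 150, 25, 2.5), cfg)
  expect_equal(outd$emissions[["C"]], 1.5e-5, tolerance = 1e-9)

  # facultative: 1% of C uptake when C still in demand, no binding cap
  m <- microbe("Cnp", 120, 25, 2.5)  # C-limited
  fac <- facultative_production(m, c(C = 1, N = 0, P = 0), cfg)
  expect_equal(fac$emissions[["C"]], 0.01, tolerance = 1e-12)
  # N budget converts to enzyme C mass at CtoN_enz
  mN <- microbe("cNp", 180, 25, 3)   # N in demand (C:N = 7.2)
  facN <- facultative_production(mN, c(C = 0, N = 0.35, P = 0), cfg)
  expect_equal(facN$emissions[["N"]], 0.0035 * 3.5, tolerance = 1e-12)
  # nutrient no longer in demand: nothing
  mOK <- microbe("CNP", 150, 30, 3)  # C:N = 5 < 6, N not in demand
  facOK <- facultative_production(mOK, c(C = 0, N = 1, P = 0), cfg)
  expect_equal(facOK$emissions[["N"]], 0)
})

test_that("maintenance respires BMR and leaks N and P proportionally", {
  m <- microbe("CNP", 150, 25, 2.5)
  out <- maintenance_metabolism(m, cfg)
  expect_equal(out$respired_C, 0.0225)
  expect_equal(out$loss_N, 0.000375)
  expect_equal(out$loss_P, 0.0000375)
  m0 <- microbe("CNP", 0, 0, 0)
  out0 <- maintenance_metabolism(m0, cfg)
  expect_equal(out0$respired_C, 0)
  expect_equal(out0$microbe$pool_C, 0)
})

test_that("biomass under pure maintenance decays geometrically", {
  m <- microbe("CNP", 150, 25, 2.5)
  for (i in 1:1000) m <- maintenance_metabolism(m, cfg)$microbe
  expect_equal(m$pool_C, 150 * (1 - 0.00015)^1000, tolerance = 1e-9)
  expect_equal(m$pool_C, 129.1, tolerance = 1e-3)
})

test_that("death triggers strictly below the starvation threshold", {
  set.seed(1)
  expect_identical(check_death(microbe("cnp", 29.9), cfg),
                   "dead_starvation")
  cfg_nomort <- scenario_config(mortality_rate = 0)
  expect_identical(check_death(microbe("cnp", 30.0), cfg_nomort),
                   "alive")
})

test_that("random mortality occurs at its configured frequency", {
  # engine-level: immortal-by-starvation microbes, one death process
  # sweep across many boxes; deaths within 3 binomial SE of rate
  n_side <- 100L
  cfgm <- scenario_config(width = n_side, height = n_side,
                          mortality_rate = 3e-3)
  lat <- new_lattice(cfgm)
  lat$genotype <- rep(1L, n_side^2)
  lat$pool_C <- rep(150, n_side^2)
  set.seed(8)
  deaths <- 0
  for (i in 1:10) {
    out <- run_process(lat, cfgm, "death")
    deaths <- deaths + sum(out$genotype == 0)
  }
  trials <- 10 * n_side^2
  mu <- trials * 3e-3
  se <- sqrt(trials * 3e-3 * (1 - 3e-3))
  expect_lt(abs(deaths - mu), 3 * se)
})

test_that("division splits every pool in half at the 300 fg threshold", {
  m <- microbe("CNp", 300, 50, 5)
  d <- divide_microbe(m, cfg)
  expect_equal(d$resident$pool_C, 150)
  expect_equal(d$disperser$pool_C, 150)
  expect_equal(d$resident$pool_N, 25)
  expect_equal(d$resident$pool_P, 2.5)
  expect_null(divide_microbe(microbe("CNp", 299.9), cfg))
})

test_that("occupied-target division contests are fair coin flips", {
  # 3x3 torus fully occupied by cnp except a 300 fg CNP center; every
  # dispersal target is occupied, so each division is a contest
  cfg3 <- scenario_config(width = 3L, height = 3L, mutation_rate = 0,
                          mortality_rate = 0)
  base <- new_lattice(cfg3)
  base$genotype <- rep(1L, 9)
  base$pool_C <- rep(150, 9)
  base$pool_N <- rep(25, 9)
  base$pool_P <- rep(2.5, 9)
  base <- place_microbe(base, 2, 2, "CNP", cfg3, pool_C = 300,
                        pool_N = 50, pool_P = 5)
  set.seed(21)
  n_trials <- 20000L
  wins <- 0L
  for (i in seq_len(n_trials)) {
    out <- run_process(base, cfg3, "reproduction")
    # a win for the disperser puts a second CNP (code 8) on the grid
    wins <- wins + (sum(out$genotype == 8L) == 2L)
  }
  se <- sqrt(n_trials * 0.25)
  expect_lt(abs(wins - n_trials / 2), 3 * se)
})

test_that("a lone generalist grows to division on ample product", {
  cfgg <- scenario_config(width = 5L, height = 5L, mortality_rate = 0,
                          mutation_rate = 0)
  lat <- new_lattice(cfgg)
  lat$product_C <- rep(10, 25)
  lat$product_N <- rep(10, 25)
  lat$product_P <- rep(10, 25)
  lat <- place_microbe(lat, 3, 3, "CNP", cfgg)
  set.seed(2)
  lat <- step_lattice(lat, cfgg, 300)
  expect_gte(sum(lat$genotype > 0), 2)
})

test_that("a lone cheater with no ambient enzyme starves to death", {
  cfg_c <- scenario_config(width = 5L, height = 5L, mortality_rate = 0,
                          mutation_rate = 0)
  lat <- new_lattice(cfg_c)
  lat <- place_microbe(lat, 3, 3, "cnp", cfg_c)
  set.seed(2)
  # BMR alone takes ~ ln(5)/1.5e-4 ~ 10,730 min to cross 30 fg
  lat <- step_lattice(lat, cfg_c, 11000)
  expect_identical(sum(lat$genotype > 0), 0L)
})

test_that("no engine process drives any pool negative", {
  cfgn <- scenario_config(width = 8L, height = 8L, EConstit = 1e-4,
                          enzyme_diffusion = 1e-2)
  set.seed(4)
  lat <- initialize_lattice(cfgn)
  for (i in 1:200) lat <- step_lattice(lat, cfgn, 1)
  for (f in c("substrate_C", "substrate_N", "substrate_P", "enzyme_C",
              "enzyme_N", "enzyme_P", "product_C", "product_N",
              "product_P", "pool_C", "pool_N", "pool_P")) {
    expect_true(all(lat[[f]] >= 0), info = f)
  }
})
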