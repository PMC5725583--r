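reg <- seasonal_regime(0.5, 10, 1)

test_that("multinomial step reduces to the deterministic recursion as N grows", {
  sch <- recombination_scheme(0.1, 0.4, 0.5)
  x <- linkage_equilibrium_state(0.3, 0.4, 0.6)
  det <- apply_recombination(apply_selection(x, reg, 2), sch)
  expect_equal(wf_multinomial_step(x, sch, reg, t = 2, N = Inf), det,
               tolerance = 1e-14)
  # monomorphic states are absorbing
  mono <- c(1, 0, 0, 0, 0, 0, 0, 0)
  set.seed(8)
  expect_equal(wf_multinomial_step(mono, sch, reg, t = 1, N = 100), mono,
               ignore_attr = TRUE)
  # the sampling step is unbiased: replicate means approach the recursion
  set.seed(9)
  N <- 200; reps <- 3000
  draws <- replicate(reps, wf_multinomial_step(x, sch, reg, t = 2, N = N))
  se <- sqrt(det * (1 - det) / (N * reps))
  expect_true(all(abs(rowMeans(draws) - det) < 4 * se + 1e-12))
})

test_that("multinomial trajectories approach the deterministic orbit as N grows", {
  sch <- recombination_scheme(0.3, 0.3, 0.5)
  reg10 <- seasonal_regime(0.1, 10, 1)
  x0 <- linkage_equilibrium_state(0.5, 0.5, 0.5)
  det <- simulate_wf(x0, sch, reg10, N = Inf, generations = 10,
                     record_trajectory = TRUE)$trajectory
  set.seed(10)
  dev <- sapply(c(1e3, 1e5), function(N) {
    d <- replicate(20, {
      tr <- simulate_wf(x0, sch, reg10, N = N, generations = 10,
                        record_trajectory = TRUE)$trajectory
      max(abs(tr - det))
    })
    mean(d)
  })
  expect_true(dev[2] < dev[1] / 3) # deviation shrinks roughly like 1/sqrt(N)
})

test_that("mutation machinery has the stated event statistics", {
  lay <- layout_three_locus(0.5)
  pop <- init_population(lay, 50)
  # intensity 0: unchanged; intensity 1: exactly one event per locus
  set.seed(11)
  expect_equal(unclass(mutate_population(pop, 0)), unclass(pop))
  mut <- mutate_population(pop, 1)
  expect_equal(sum(unclass(mut) != unclass(pop)), 3L)
  # engine event counts over a long neutral run match N*mu per locus
  regn <- seasonal_regime(1e-9, 10, 1)
  par <- population_params(50, mutation_intensity = 0.1, burn_in = 0,
                           record = 4000)
  set.seed(12)
  r <- simulate_population(init_population(lay, 50), regn, par)
  expected <- 0.1 * 4000 * 3
  expect_true(abs(r$mutation_events - expected) < 4 * sqrt(expected))
  # per-copy variant has the same expectation
  set.seed(13)
  r2 <- simulate_population(init_population(lay, 50), regn, par,
                            mut_per_copy = TRUE)
  expect_true(abs(r2$mutation_events - expected) < 4 * sqrt(expected))
})

test_that("individual-based generations preserve degenerate and neutral structure", {
  lay <- layout_three_locus(0.5)
  # identical individuals reproduce themselves exactly
  pop <- init_population(lay, 40, rec_rates = 0.25, plast_freq = 1,
                         target_freq = 1)
  set.seed(14)
  off <- next_generation(pop, reg, t = 0)
  expect_equal(unclass(off), unclass(pop))
  # at a season boundary (s_t = 0) reproduction is neutral: allele
  # frequency changes stay within sampling noise
  set.seed(15)
  N <- 500
  pop <- init_population(lay, N, rec_rates = 0.2, plast_freq = 0.5,
                         target_freq = 0.5)
  devs <- replicate(40, {
    off <- next_generation(pop, reg, t = 0) # sin(0) = 0
    mean(off[, "T1"]) - mean(pop[, "T1"])
  })
  expect_true(abs(mean(devs)) < 4 * sqrt(0.25 / N / 40))
})

test_that("a linked modifier evolves higher recombination than an unlinked one", {
  # scaled-down ordering check: tighter linkage to the selected sequence
  # strengthens the indirect selection on the modifier
  set.seed(99)
  reg <- seasonal_regime(0.5, 10, 1)
  par <- population_params(500, 0.1, burn_in = 25000, record = 25000)
  mean_rate <- function(R) {
    st <- simulate_population(init_population(layout_three_locus(R), 500),
                              reg, par)$stationary
    sum(st$bin * st$mass)
  }
  expect_gt(mean_rate(0.01), mean_rate(0.5))
})

test_that("stationary recording loses no mass and pools across replicates", {
  lay <- layout_three_locus(0.5)
  par <- population_params(100, 0.1, burn_in = 200, record = 300)
  set.seed(16)
  st <- run_stationary_distribution(par, reg, replicates = 2)
  expect_equal(sum(st$mass), 1)
  expect_equal(st$replicate_count, 2L)
  expect_equal(sum(st$counts), 2 * 300 * 100)
  expect_true(stationary_mode(st) %in% st$bin)
})
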