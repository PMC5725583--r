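reg10 <- seasonal_regime(0.1, 10, 1)

test_that("linkage disequilibrium has the (M, d)-coupling sign convention", {
  le <- linkage_equilibrium_state(0.3, 0.4, 0.6)
  expect_equal(linkage_disequilibrium(le), 0, tolerance = 1e-15)
  x <- setNames(numeric(8), haplotype_names())
  x[c("r1Md", "r2Md")] <- 0.25
  x[c("r1ma", "r2ma")] <- 0.25
  expect_equal(linkage_disequilibrium(x), 0.25) # maximal coupling
  y <- setNames(numeric(8), haplotype_names())
  y[c("r1Ma", "r2Ma")] <- 0.25
  y[c("r1md", "r2md")] <- 0.25
  expect_equal(linkage_disequilibrium(y), -0.25) # maximal repulsion
  # other locus pairs work too
  expect_equal(linkage_disequilibrium(le, c("rec", "target")), 0,
               tolerance = 1e-15)
})

test_that("epistasis sign tracks the season and vanishes without plasticity", {
  expect_equal(epistasis_sign(reg10, 0), 0L) # season boundary
  expect_equal(epistasis_sign(reg10, 10 / 4), -1L) # s_t > 0
  expect_equal(epistasis_sign(reg10, 3 * 10 / 4), 1L) # s_t < 0
  reg_p0 <- seasonal_regime(0.1, 10, 0)
  expect_equal(epistasis_sign(reg_p0, 0:9), rep(0L, 10))
  # direct evaluation of the fitness products at the peak
  s <- 0.1
  expect_equal(sign((1 + 0) * (1 - s) - (1 - 0) * (1 + s)), -1)
})

test_that("relative fitness ratio is 1 under class symmetry and at equilibrium", {
  # identical internal composition in both modifier classes
  comp <- c(0.4, 0.1, 0.3, 0.2)
  x <- c(0.7 * comp, 0.3 * comp)
  traj <- do.call(rbind, replicate(10, x, simplify = FALSE))
  expect_equal(relative_fitness_ratio(traj, reg10), 1, tolerance = 1e-12)
  # converged coexistence orbit: the product over one full cycle is 1
  sch <- recombination_scheme(0.3, 0.3, 0.5)
  run <- evolve_deterministic(rep(1 / 8, 8), sch, reg10,
                              max_generations = 5e4)
  expect_equal(relative_fitness_ratio(run$orbit, reg10), 1,
               tolerance = 1e-6)
  # an absent allele is an error, not a silent NaN
  traj0 <- traj
  traj0[3, 5:8] <- 0
  traj0[3, ] <- traj0[3, ] / sum(traj0[3, ])
  expect_error(relative_fitness_ratio(traj0, reg10), "present")
})

test_that("cycling LD changes sign and opposes epistasis part of the cycle", {
  sch <- recombination_scheme(0.3, 0.3, 0.5)
  run <- evolve_deterministic(rep(1 / 8, 8), sch, reg10,
                              max_generations = 5e4)
  d <- cycle_diagnostics(run)
  expect_equal(nrow(d), 10L)
  expect_true(any(d$D > 0) && any(d$D < 0)) # LD cycles in sign
  expect_true(any(d$ED_sign < 0)) # epistasis-LD discrepancy windows exist
  expect_true(any(d$ED_sign > 0))
  expect_true(all(abs(d$D) <= 0.25))
  # the modifier marginal is constant over the cycle (identical alleles)
  expect_equal(d$freq_r2, rep(d$freq_r2[1], 10), tolerance = 1e-7)
  expect_error(cycle_diagnostics(list(converged = FALSE)), "converged")
})
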