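reg10 <- seasonal_regime(0.1, 10, 1)

test_that("with p = 0 the plasticity locus is a neutral spectator", {
  reg <- seasonal_regime(0.1, 10, 0)
  sch <- recombination_scheme(0.2, 0.2, 0.5)
  run <- evolve_deterministic(linkage_equilibrium_state(0.5, 0.37, 0.5), sch,
                              reg, max_generations = 2000,
                              min_generations = 1000,
                              record_trajectory = TRUE)
  fM <- rowSums(run$trajectory[, c(2, 4, 6, 8)])
  expect_true(max(abs(fM - 0.37)) < 1e-12)
})

test_that("polymorphism is lost without plasticity-target recombination", {
  sch <- recombination_scheme(0, 0, 0.5)
  run <- evolve_deterministic(linkage_equilibrium_state(0.5, 0.5, 0.5), sch,
                              reg10, max_generations = 2e5)
  expect_equal(run$status, "fixated")
})

test_that("a storing rate converges to a polymorphic periodic orbit", {
  sch <- recombination_scheme(0.3, 0.3, 0.5)
  run <- evolve_deterministic(rep(1 / 8, 8), sch, reg10,
                              max_generations = 5e4)
  expect_true(run$converged)
  orb <- run$orbit
  expect_equal(nrow(orb), 10L)
  fM <- rowSums(orb[, c(2, 4, 6, 8)])
  fd <- rowSums(orb[, c(3, 4, 7, 8)])
  expect_true(min(pmin(fM, 1 - fM), pmin(fd, 1 - fd)) >= 0.01)
  # the orbit really is a fixed point of the full-cycle map (phase-aligned)
  x <- orb[1, ]
  for (t in 0:9) {
    x <- apply_selection(x, reg10, t)
    x <- apply_recombination(x, sch)
  }
  expect_true(max(abs(x - orb[1, ])) < 1e-8)
})

test_that("analytic and finite-difference cycle Jacobians agree", {
  sch <- recombination_scheme(0.3, 0.3, 0.5)
  run <- evolve_deterministic(rep(1 / 8, 8), sch, reg10,
                              max_generations = 5e4)
  Ja <- cycle_jacobian(run, "analytic")
  Jf <- cycle_jacobian(run, "fd")
  expect_true(max(abs(Ja - Jf)) / max(abs(Ja)) < 1e-5)
  # a neutral direction exists at the modifier locus (identical alleles):
  # the leading eigenvalue of the coexistence orbit is exactly 1
  expect_equal(max(Mod(eigen(Ja, only.values = TRUE)$values)), 1,
               tolerance = 1e-6)
  expect_error(cycle_jacobian(list(converged = FALSE)), "converged")
})

test_that("with C = 1 the cycle map is pure recombination and its Jacobian is exact", {
  # sin(2 pi t) = 0 at every integer t, so selection is the identity and the
  # one-generation cycle Jacobian equals the recombination Jacobian; at zero
  # rates the map is the identity
  reg1 <- seasonal_regime(0.1, 1, 1)
  sch0 <- recombination_scheme(0, 0, 0)
  run <- evolve_deterministic(random_state(), sch0, reg1,
                              max_generations = 1100)
  J <- cycle_jacobian(run, "fd")
  Ja <- cycle_jacobian(run, "analytic")
  expect_true(max(abs(J - Ja)) < 1e-6)
})

test_that("identical rate alleles classify as neutral coexistence", {
  o <- classify_pair(0.3, 0.3, reg10, init_grid = 0.5,
                     max_generations = 5e4)
  expect_equal(o$classification, "coexistence")
  expect_equal(o$leading_eigenvalue_modulus, 1)
  # and a rate pair that cannot store classifies as no_polymorphism
  o0 <- classify_pair(0.0, 0.0, reg10, init_grid = 0.5,
                      max_generations = 5e4)
  expect_equal(o0$classification, "no_polymorphism")
})

test_that("iteration and boundary eigenvalues agree on invasion direction", {
  # mutual invasion between 0.3 and 0.45 at C = 10: both boundary
  # eigenvalues exceed 1 and the pair classifies as coexistence
  sch <- recombination_scheme(0.45, 0.3, 0.5)
  lam_a <- invasion_eigenvalue(sch, reg10, "r2", max_generations = 6e5)
  lam_b <- invasion_eigenvalue(sch, reg10, "r1", max_generations = 6e5)
  expect_true(lam_a > 1)
  expect_true(lam_b > 1)
  o <- classify_pair(0.45, 0.3, reg10, init_grid = c(0.25, 0.55, 0.85))
  expect_equal(o$classification, "coexistence")
})

test_that("ES search on a degenerate grid returns the lone viable rate", {
  es <- find_es_rate(reg10, rate_grid = 0.3, init_grid = 0.5,
                     max_generations = 5e4)
  expect_equal(es$es_rate, 0.3)
  # a lone rate that cannot sustain the polymorphism yields an empty result
  es0 <- find_es_rate(reg10, rate_grid = 0, init_grid = 0.5,
                      max_generations = 5e4)
  expect_length(es0$es_rate, 0)
})
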