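test_that("seasonal effect is sinusoidal, periodic and antisymmetric over half-cycles", {
  reg <- seasonal_regime(0.1, 10, 1)
  expect_equal(seasonal_effect(0, reg), 0)
  expect_equal(seasonal_effect(10 / 4, reg), 0.1) # t = C/4 hits the peak
  expect_equal(seasonal_effect(5, reg), 0, tolerance = 1e-15)
  for (C in c(10, 20, 40, 80)) {
    regC <- seasonal_regime(0.3, C, 1)
    t <- 0:(2 * C)
    expect_equal(seasonal_effect(t + C, regC), seasonal_effect(t, regC))
    expect_equal(seasonal_effect(t + C / 2, regC), -seasonal_effect(t, regC))
    expect_true(all(abs(seasonal_effect(t, regC)) <= 0.3 + 1e-15))
  }
  # phase offset shifts the season of generation zero
  regp <- seasonal_regime(0.1, 10, 1, phase = 3L)
  expect_equal(seasonal_effect(0, regp), seasonal_effect(3, reg))
})

test_that("haplotype fitness follows the buffered seasonal scheme", {
  expect_equal(haplotype_fitness("r1Ma", s_t = 0.1, p = 1), 1)
  expect_equal(haplotype_fitness("r2ma", s_t = 0.1, p = 0.37), 0.9)
  expect_equal(haplotype_fitness("r1md", s_t = -0.1, p = 0), 0.9)
  # fitness never depends on the modifier allele
  for (s in c(-0.3, 0, 0.2)) {
    for (p in c(0, 0.5, 1)) {
      w <- haplotype_fitness(1:8, s, p)
      expect_equal(w[1:4], w[5:8])
    }
  }
  # p = 1 makes every M-carrier neutral; p = 0 leaves only the target effect
  expect_equal(haplotype_fitness(c(2, 4, 6, 8), s_t = 0.27, p = 1), rep(1, 4))
  expect_equal(haplotype_fitness(1:8, s_t = 0.2, p = 0),
               rep(c(0.8, 0.8, 1.2, 1.2), 2))
})

test_that("selection renormalizes correctly and preserves degenerate states", {
  reg <- seasonal_regime(0.1, 10, 1)
  u <- rep(1 / 8, 8)
  # s_0 = 0: all fitnesses 1
  expect_equal(apply_selection(u, reg, 0), u)
  # hand-derived weights at the seasonal peak with p = 1
  x <- apply_selection(u, reg, 10 / 4)
  w <- rep(c(0.9, 1, 1.1, 1), 2)
  expect_equal(x, setNames(w / sum(w), haplotype_names()), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a monomorphic state is a fixed point of selection
  mono <- c(0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(apply_selection(mono, reg, 3), mono, ignore_attr = TRUE)
  expect_error(apply_selection(rep(0.2, 8), reg, 0), "sum to 1")
})

test_that("selection keeps states normalized and zero frequencies at zero", {
  set.seed(101)
  reg <- seasonal_regime(0.4, 20, 0.6)
  for (k in 1:25) {
    x <- random_state()
    x[sample(8, 2)] <- 0
    x <- x / sum(x)
    y <- apply_selection(x, reg, sample(0:40, 1))
    expect_equal(sum(y), 1, tolerance = 1e-12)
    expect_true(all(y[x == 0] == 0))
    expect_true(all(y >= 0))
  }
})

test_that("modifier marginal is untouched by selection when class compositions match", {
  set.seed(102)
  reg <- seasonal_regime(0.3, 10, 0.8)
  for (k in 1:10) {
    comp <- runif(4)
    comp <- comp / sum(comp)
    fr2 <- runif(1, 0.1, 0.9)
    x <- c((1 - fr2) * comp, fr2 * comp)
    y <- apply_selection(x, reg, sample(0:9, 1))
    expect_equal(sum(y[5:8]), fr2, tolerance = 1e-12)
  }
})

test_that("linkage-equilibrium constructor matches requested marginals", {
  x <- linkage_equilibrium_state(0.2, 0.6, 0.7)
  expect_equal(sum(x), 1)
  expect_equal(allele_freqs(x), c(r2 = 0.2, M = 0.6, d = 0.7))
})
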