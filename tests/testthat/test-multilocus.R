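test_that("multilocus fitness multiplies per-locus seasonal factors", {
  expect_equal(multilocus_fitness(c("a", "a"), "m", s_t = 0.1, p = 1), 0.81)
  expect_equal(multilocus_fitness(c("a", "d"), "m", s_t = 0.1, p = 1), 0.99)
  expect_equal(multilocus_fitness(c("d", "a", "d"), "M", s_t = 0.3, p = 1), 1)
  # additive variant
  expect_equal(multilocus_fitness(c("a", "a"), "m", 0.1, 1, mode = "additive"),
               0.8)
})

test_that("single-target multilocus fitness reduces exactly to the haplotype fitnesses", {
  for (s in c(-0.3, -0.1, 0, 0.1, 0.3)) {
    for (p in c(0, 0.4, 1)) {
      ht <- haplotype_table()
      for (i in 1:8) {
        expect_identical(
          multilocus_fitness(ht$target[i], ht$plasticity[i], s, p),
          haplotype_fitness(i, s, p)
        )
      }
    }
  }
})

test_that("co-segregation fraction counts aligned target haplotypes", {
  expect_equal(cosegregation_fraction(matrix(c(0, 1, 0, 1), ncol = 1)), 1)
  pop <- rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  expect_equal(cosegregation_fraction(pop), 1)
  pop <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(cosegregation_fraction(pop), 0.5)
  # layout-aware path
  lay <- layout_two_target("sequential", plast_target_rate = 0.2)
  p <- init_population(lay, 10, target_freq = c(0, 1))
  expect_equal(cosegregation_fraction(p), 0) # all (a, d): never aligned
})

test_that("genome layouts validate their interval control structure", {
  lay <- layout_three_locus(0.4)
  expect_s3_class(lay, "genome_layout")
  expect_equal(lay$intervals$rate[1], 0.4)
  expect_error(genome_layout(
    loci = data.frame(name = c("rec1", "P"), type = c("rec", "plasticity")),
    intervals = data.frame(rate = NA, control = "nope")
  ), "unknown modifier")
  sg <- layout_supergene(4, plast_target_rate = 0.1)
  expect_equal(sum(sg$loci$type == "target"), 4L)
  expect_equal(sum(sg$loci$type == "rec"), 3L)
  expect_equal(sg$intervals$control[nrow(sg$intervals)], "mod4")
})

test_that("two-target protocols produce well-formed stationary output", {
  set.seed(31)
  reg <- seasonal_regime(0.5, 10, 1)
  par <- population_params(150, 0.1, burn_in = 1500, record = 1500)
  seq_run <- run_two_target_protocol("sequential", par, reg, es_rate = 0.3,
                                     stage1_generations = 1500)
  expect_equal(sum(seq_run$stationary$mass), 1)
  expect_true(seq_run$coseg_mean >= 0 && seq_run$coseg_mean <= 1)
  expect_true(is.finite(seq_run$target_ld_mean))
  sim_run <- run_two_target_protocol("simultaneous", par, reg)
  expect_equal(sum(sim_run$stationary$mass), 1)
  expect_equal(colnames(sim_run$final_pop),
               c("rec2", "rec1", "P", "T1", "T2"))
})

test_that("clustered two-target populations show positive target-target LD and larger oscillations", {
  # a scaled-down comparison: with strong per-locus selection and a tight
  # cluster, the amplitude of per-locus frequency oscillations exceeds the
  # matched single-target case, and LD between targets is positive
  set.seed(32)
  reg <- seasonal_regime(0.5, 10, 1)
  N <- 500
  lay2 <- layout_two_target("sequential", plast_target_rate = 0.3)
  pop2 <- init_population(lay2, N, rec_rates = 0, plast_freq = 0.5,
                          target_freq = 0.5) # r' = 0: perfect cluster
  par <- population_params(N, 0, burn_in = 500, record = 3000)
  run2 <- simulate_population(pop2, reg, par, trace_every = 1L)
  lay1 <- layout_three_locus(0.5)
  pop1 <- init_population(lay1, N, rec_rates = 0.3, plast_freq = 0.5,
                          target_freq = 0.5)
  run1 <- simulate_population(pop1, reg, par, trace_every = 1L)
  amp <- function(tr) {
    f <- tr[, "freq_d_1"]
    f <- f[f > 0 & f < 1]
    stats::quantile(f, 0.95) - stats::quantile(f, 0.05)
  }
  expect_gt(amp(run2$trace), amp(run1$trace))
  expect_gt(run2$target_ld_mean, 0)
})
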