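## Cycle diagnostics: linkage disequilibrium, the sign of epistasis between
## the plasticity and target locus, and the geometric-mean relative fitness
## of competing recombination-modifier alleles.

#' Linkage disequilibrium between two loci of a haplotype state
#'
#' For the default plasticity-target pair,
#' `D = freq(M, d) - freq(M) * freq(d)`, bounded by +/- 0.25. The sign
#' convention couples the derived classes: positive D means excess of the
#' M.d (and m.a) combinations.
#'
#' @param x 8-haplotype frequency vector (canonical order, sum 1).
#' @param loci Which pair: any two of `"rec"`, `"plasticity"`, `"target"`
#'   (the derived classes are r2, M and d).
#' @return Signed D.
#' @examples
#' x <- c(0.5, 0, 0, 0.5, 0, 0, 0, 0) # half r1ma, half r1Md
#' linkage_disequilibrium(x) # 0.25: maximal coupling
#' @export
linkage_disequilibrium <- function(x, loci = c("plasticity", "target")) {
  check_state(x)
  stopifnot(length(loci) == 2L, all(loci %in% c("rec", "plasticity", "target")))
  ht <- haplotype_table()
  derived <- list(rec = ht$rec == 2L, plasticity = ht$plasticity == 1L,
                  target = ht$target == 1L)
  a <- derived[[loci[1]]]; b <- derived[[loci[2]]]
  sum(x[a & b]) - sum(x[a]) * sum(x[b])
}

#' Sign of epistasis between the plasticity and target locus
#'
#' Multiplicative (log-fitness) epistasis between the two selected loci:
#' the sign of `w_Md * w_ma - w_Ma * w_md`, which equals the sign of
#' `-2 s_t p`. It vanishes at season boundaries and whenever p = 0, and
#' flips each half-cycle: within a season, epistasis favors coupling of the
#' currently beneficial target allele with the non-plastic background.
#'
#' @param regime A [seasonal_regime()].
#' @param t Generation index (vectorized).
#' @return Integer sign(s) in `{-1, 0, 1}`.
#' @export
epistasis_sign <- function(regime, t) {
  s <- seasonal_effect(t, regime)
  ww <- (1 + s * (1 - regime$p)) * (1 - s) - (1 - s * (1 - regime$p)) * (1 + s)
  as.integer(sign(ifelse(abs(ww) < 1e-12, 0, ww)))
}

#' Geometric-mean relative fitness of two recombination-modifier alleles
#'
#' The per-cycle product, along a trajectory of haplotype states, of the
#' ratio of the modifier classes' fitness-weighted compositions times the
#' frequency correction `f_r1 / f_r2`. Each per-generation factor equals
#' the ratio of conditional mean fitnesses of r2- to r1-carriers, so the
#' product over a cycle equals the factor by which the r2:r1 odds change
#' over that cycle: a value above 1 predicts that r2 increases in
#' frequency, and the product over a full cycle of a periodic orbit with
#' both alleles at equilibrium is exactly 1.
#'
#' @param trajectory Matrix of haplotype states (rows = consecutive
#'   generations, canonical column order): pre-selection states, as
#'   recorded by `evolve_deterministic(..., record_trajectory = TRUE)`.
#' @param regime A [seasonal_regime()].
#' @param t0 Generation index of the first row.
#' @return The product of per-generation ratios over all rows.
#' @export
relative_fitness_ratio <- function(trajectory, regime, t0 = 0L) {
  trajectory <- as.matrix(trajectory)
  stopifnot(ncol(trajectory) == 8L)
  ratio <- 1
  for (k in seq_len(nrow(trajectory))) {
    x <- trajectory[k, ]
    f2 <- sum(x[5:8]); f1 <- sum(x[1:4])
    if (f1 <= 0 || f2 <= 0)
      stop("both modifier alleles must be present at every generation")
    w <- fitness_vector(seasonal_effect(t0 + k - 1L, regime), regime$p)
    num <- sum(x[5:8] * w[5:8])
    den <- sum(x[1:4] * w[1:4])
    ratio <- ratio * (num / den) * (f1 / f2)
  }
  ratio
}

#' Per-generation diagnostics over one environmental cycle
#'
#' Evaluates, for each phase of a converged periodic orbit: the seasonal
#' selection coefficient, plasticity-target linkage disequilibrium D, the
#' sign of epistasis E, the sign of the product E*D (generations with
#' E*D < 0 are those in which LD lags the sign change of epistasis and
#' selection favors more recombination), marginal allele frequencies and
#' mean fitness.
#'
#' @param orbit A converged [evolve_deterministic()] result.
#' @return A data.frame with one row per phase of the cycle.
#' @export
cycle_diagnostics <- function(orbit) {
  if (!isTRUE(orbit$converged))
    stop("cycle_diagnostics requires a converged periodic orbit")
  regime <- orbit$regime
  C <- regime$C
  rows <- lapply(seq_len(C), function(k) {
    x <- orbit$orbit[k, ]
    t <- k - 1L
    s <- regime$s_max * sin(2 * pi * t / C)
    D <- linkage_disequilibrium(x)
    ee <- -2 * s * regime$p
    E <- as.integer(sign(ifelse(abs(ee) < 1e-12, 0, ee)))
    af <- allele_freqs(x)
    data.frame(
      phase = t, s_t = s, D = D, E_sign = E,
      ED_sign = as.integer(sign(ifelse(abs(E * D) < 1e-12, 0, E * D))),
      freq_r2 = af[["r2"]], freq_M = af[["M"]], freq_d = af[["d"]],
      mean_fitness = sum(x * fitness_vector(s, regime$p))
    )
  })
  do.call(rbind, rows)
}
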