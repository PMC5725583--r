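## Genetic state space and seasonal fitness model.
##
## Canonical haplotype order, fixed project-wide:
##   r1ma, r1Ma, r1md, r1Md, r2ma, r2Ma, r2md, r2Md
## i.e. index = 4*(rec - 1) + 2*target + plasticity + 1, with
## rec in {1,2}, plasticity m=0 / M=1, target a=0 / d=1.

#' Canonical haplotype names
#'
#' The eight three-locus haplotypes in the fixed canonical order used by all
#' frequency vectors, recursion operators and Jacobians in the package.
#'
#' @return Character vector of length 8:
#'   `r1ma, r1Ma, r1md, r1Md, r2ma, r2Ma, r2md, r2Md`.
#' @export
haplotype_names <- function() {
  c("r1ma", "r1Ma", "r1md", "r1Md", "r2ma", "r2Ma", "r2md", "r2Md")
}

#' Haplotype composition table
#'
#' @return A data.frame with one row per canonical haplotype and columns
#'   `name`, `rec` (modifier allele, 1 or 2), `plasticity` (0 = m, 1 = M) and
#'   `target` (0 = a, 1 = d).
#' @export
haplotype_table <- function() {
  data.frame(
    name = haplotype_names(),
    rec = rep(1:2, each = 4L),
    plasticity = rep(c(0L, 1L, 0L, 1L), 2L),
    target = rep(c(0L, 0L, 1L, 1L), 2L),
    stringsAsFactors = FALSE
  )
}

#' Seasonal selection regime
#'
#' Bundles the parameters of the sinusoidal environmental forcing: the
#' maximum seasonal effect `s_max`, the period `C` in discrete generations,
#' and the plasticity effect `p` by which carriers of the plasticity allele M
#' buffer the seasonal effect. The phase offset fixes which point of the
#' season the generation counter t = 0 refers to; the default `phase = 0`
#' starts at a season boundary (selection coefficient zero, about to enter
#' the season favoring the derived target allele).
#'
#' @param s_max Maximum seasonal selection coefficient, in (0, 1).
#' @param C Environmental period in generations (positive integer).
#' @param p Plasticity effect in `[0, 1]`: p = 0 makes the plasticity locus
#'   selectively inert, p = 1 makes M-carriers fitness-neutral at the target
#'   locus.
#' @param phase Integer phase offset added to the generation counter.
#' @return An object of class `seasonal_regime`.
#' @examples
#' reg <- seasonal_regime(s_max = 0.1, C = 10, p = 1)
#' seasonal_effect(0:9, reg)
#' @export
seasonal_regime <- function(s_max, C, p = 1, phase = 0L) {
  stopifnot(is.numeric(s_max), length(s_max) == 1L, s_max > 0, s_max < 1)
  stopifnot(is.numeric(C), length(C) == 1L, C >= 1, C == round(C))
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  stopifnot(is.numeric(phase), length(phase) == 1L, phase == round(phase))
  structure(
    list(s_max = s_max, C = as.integer(C), p = p, phase = as.integer(phase)),
    class = "seasonal_regime"
  )
}

#' @export
print.seasonal_regime <- function(x, ...) {
  cat(sprintf(
    "Seasonal regime: s_max = %g, C = %d generations, p = %g, phase = %d\n",
    x$s_max, x$C, x$p, x$phase
  ))
  invisible(x)
}

#' Seasonal selection coefficient at a generation
#'
#' `s_t = s_max * sin(2 * pi * t / C)`, evaluated at `t + phase`. Periodic
#' with period `C` and bounded by `± s_max`; positive values favor the
#' derived target allele d, negative values the ancestral allele a.
#'
#' @param t Integer generation index (vectorized).
#' @param regime A [seasonal_regime()].
#' @return Numeric vector of signed selection coefficients.
#' @export
seasonal_effect <- function(t, regime) {
  stopifnot(inherits(regime, "seasonal_regime"))
  regime$s_max * sin(2 * pi * (t + regime$phase) / regime$C)
}

## fitness vector over the 8 canonical haplotypes at selection coefficient s
fitness_vector <- function(s, p) {
  sb <- s * (1 - p)
  rep(c(1 - s, 1 - sb, 1 + s, 1 + sb), 2L)
}

#' Haplotype fitness
#'
#' Fitness of a haplotype under the seasonal selection coefficient `s_t`:
#' `1 - s_t` for *ma*, `1 - s_t (1 - p)` for *Ma*, `1 + s_t` for *md* and
#' `1 + s_t (1 - p)` for *Md*, independent of the recombination-modifier
#' allele. With p = 1 the plasticity allele M fully shields its carriers from
#' seasonal selection; with p = 0 it has no effect.
#'
#' @param h Haplotype names (see [haplotype_names()]) or canonical indices.
#' @param s_t Signed selection coefficient with `|s_t| < 1`.
#' @param p Plasticity effect in `[0, 1]`.
#' @return Numeric vector of fitnesses, one per element of `h`.
#' @examples
#' haplotype_fitness("r1Ma", s_t = 0.1, p = 1) # exactly 1: fully buffered
#' haplotype_fitness(c("r2ma", "r1md"), s_t = 0.1, p = 0.5)
#' @export
haplotype_fitness <- function(h, s_t, p) {
  stopifnot(abs(s_t) < 1)
  if (is.character(h)) {
    idx <- match(h, haplotype_names())
    if (anyNA(idx)) stop("unknown haplotype name(s): ", paste(h[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(h)
    stopifnot(all(idx >= 1L & idx <= 8L))
  }
  fitness_vector(s_t, p)[idx]
}

## validate an 8-haplotype frequency vector
check_state <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) != 8L)
    stop("haplotype state must be a numeric vector of length 8")
  if (any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("haplotype frequencies must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop("haplotype frequencies must sum to 1 (tolerance ", tol, ")")
  invisible(x)
}

#' Apply one round of haploid selection
#'
#' Multiplies each haplotype frequency by its fitness at generation `t` and
#' renormalizes by the population mean fitness. Frequencies of zero stay
#' zero, and the recombination-modifier alleles are only indirectly selected:
#' if the plasticity/target composition is identical within the two modifier
#' classes, the modifier marginal is unchanged.
#'
#' @param x Numeric vector of 8 haplotype frequencies in canonical order,
#'   summing to 1 (tolerance 1e-9).
#' @param regime A [seasonal_regime()].
#' @param t Integer generation index at which selection acts.
#' @return Post-selection frequency vector (sums to 1).
#' @export
apply_selection <- function(x, regime, t) {
  stopifnot(inherits(regime, "seasonal_regime"))
  check_state(x)
  w <- fitness_vector(seasonal_effect(t, regime), regime$p)
  xw <- x * w
  xw / sum(xw)
}

#' Population mean fitness
#'
#' @inheritParams apply_selection
#' @return Mean fitness `sum(x * w)` at generation `t`.
#' @export
mean_fitness <- function(x, regime, t) {
  check_state(x)
  sum(x * fitness_vector(seasonal_effect(t, regime), regime$p))
}

#' Single-locus allele frequencies of a haplotype state
#'
#' @param x Numeric vector of 8 haplotype frequencies in canonical order.
#' @return Named numeric vector with the marginal frequencies of the r2
#'   modifier allele, the plasticity allele M and the derived target allele d
#'   (the complementary alleles are one minus these).
#' @export
allele_freqs <- function(x) {
  ht <- haplotype_table()
  c(
    r2 = sum(x[ht$rec == 2L]),
    M = sum(x[ht$plasticity == 1L]),
    d = sum(x[ht$target == 1L])
  )
}

#' Construct a linkage-equilibrium haplotype state
#'
#' Builds the 8-haplotype frequency vector whose three loci are independent
#' with the given allele frequencies. Useful for initializing deterministic
#' runs: the stability-analysis protocol initializes the plasticity and
#' target loci on a grid of frequencies with the invading modifier allele at
#' low frequency.
#'
#' @param f_r2 Frequency of the r2 modifier allele.
#' @param f_M Frequency of the plasticity allele M.
#' @param f_d Frequency of the derived target allele d.
#' @return Numeric vector of 8 frequencies in canonical order.
#' @export
linkage_equilibrium_state <- function(f_r2, f_M, f_d) {
  stopifnot(f_r2 >= 0, f_r2 <= 1, f_M >= 0, f_M <= 1, f_d >= 0, f_d <= 1)
  ht <- haplotype_table()
  fr <- ifelse(ht$rec == 2L, f_r2, 1 - f_r2)
  fp <- ifelse(ht$plasticity == 1L, f_M, 1 - f_M)
  ft <- ifelse(ht$target == 1L, f_d, 1 - f_d)
  setNames(fr * fp * ft, haplotype_names())
}
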