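## Recombination among the three loci (physical order:
## recombination modifier -- plasticity -- target).
##
## The modifier-plasticity interval recombines at the fixed rate R; the
## plasticity-target interval recombines at r1, r2 or r_c = (r1 + r2)/2
## according to the modifier alleles the two pairing chromosomes carry
## (additive recombination phenotype). Crossovers in the two intervals are
## independent Bernoulli events (no interference).

#' Recombination scheme for the three-locus model
#'
#' @param r1,r2 Recombination rates (in `[0, 0.5]`) between the plasticity
#'   and target locus produced by the two modifier alleles.
#' @param R Recombination rate between the modifier locus and the
#'   plasticity-target sequence; `R = 0.5` is an unlinked modifier.
#' @param locus_order Physical arrangement of the loci; only the canonical
#'   `recombination-plasticity-target` arrangement is implemented.
#' @return An object of class `recombination_scheme` with fields `r1`, `r2`,
#'   `R` and the derived heterozygous-pairing rate `r_c = (r1 + r2)/2`.
#' @examples
#' recombination_scheme(r1 = 0, r2 = 0.3)
#' @export
recombination_scheme <- function(r1, r2, R = 0.5,
                                 locus_order = c("recombination", "plasticity", "target")) {
  for (v in list(r1 = r1, r2 = r2, R = R)) {
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0, v <= 0.5)
  }
  if (!identical(locus_order, c("recombination", "plasticity", "target")))
    stop("only the recombination-plasticity-target arrangement is supported")
  structure(
    list(r1 = r1, r2 = r2, R = R, r_c = (r1 + r2) / 2, locus_order = locus_order),
    class = "recombination_scheme"
  )
}

#' @export
print.recombination_scheme <- function(x, ...) {
  cat(sprintf(
    "Recombination scheme: r1 = %g, r2 = %g (heterozygous r_c = %g), R = %g\n",
    x$r1, x$r2, x$r_c, x$R
  ))
  invisible(x)
}

## pairing-dependent plasticity-target rate for parental rec alleles (1/2)
pair_rate <- function(rec_i, rec_j, scheme) {
  ifelse(rec_i == rec_j, ifelse(rec_i == 1L, scheme$r1, scheme$r2), scheme$r_c)
}

#' Mechanistic recombination tensor
#'
#' Builds the quadratic-form representation of random mating plus
#' recombination: post-recombination frequencies are
#' `x'[g] = sum_{i,j} T[i + 8 (j - 1), g] * x[i] * x[j]`, summing over all
#' ordered parent pairs and the four crossover configurations of the two
#' intervals, with probabilities `{(1-R)(1-r), (1-R) r, R (1-r), R r}` where
#' `r` is the pairing-dependent plasticity-target rate. The offspring kept
#' for pair (i, j) is the product that carries parent i's modifier locus;
#' summation over ordered pairs recovers both reciprocal products.
#'
#' @param scheme A [recombination_scheme()].
#' @return A 64 x 8 numeric matrix.
#' @keywords internal
#' @export
recombination_tensor <- function(scheme) {
  stopifnot(inherits(scheme, "recombination_scheme"))
  ht <- haplotype_table()
  Tm <- matrix(0, 64L, 8L)
  R <- scheme$R
  for (j in 1:8) {
    for (i in 1:8) {
      r <- pair_rate(ht$rec[i], ht$rec[j], scheme)
      k <- i + 8L * (j - 1L)
      for (c1 in 0:1) {
        for (c2 in 0:1) {
          pr <- (if (c1) R else 1 - R) * (if (c2) r else 1 - r)
          pl <- if (c1) ht$plasticity[j] else ht$plasticity[i]
          tg <- if ((c1 + c2) %% 2L) ht$target[j] else ht$target[i]
          g <- 4L * (ht$rec[i] - 1L) + 2L * tg + pl + 1L
          Tm[k, g] <- Tm[k, g] + pr
        }
      }
    }
  }
  Tm
}

#' Recombine one pair of haplotypes
#'
#' Draws crossovers in the two intervals from the supplied uniform variates
#' (`u[1]` against `R`, `u[2]` against the pairing-dependent
#' plasticity-target rate) and returns the two reciprocal products. Passing
#' `u = c(1, 0)`, say, forces a crossover in the plasticity-target interval
#' only, which is convenient for enumerating crossover configurations.
#'
#' @param parent1,parent2 Haplotype names (see [haplotype_names()]).
#' @param scheme A [recombination_scheme()].
#' @param u Two uniform variates in `[0, 1)`; defaults to fresh draws.
#' @return Character vector of the two offspring haplotype names; the first
#'   carries `parent1`'s modifier locus.
#' @export
recombine_pair <- function(parent1, parent2, scheme, u = runif(2)) {
  stopifnot(inherits(scheme, "recombination_scheme"), length(u) == 2L)
  ht <- haplotype_table()
  i <- match(parent1, ht$name)
  j <- match(parent2, ht$name)
  if (is.na(i) || is.na(j)) stop("unknown haplotype name")
  r <- pair_rate(ht$rec[i], ht$rec[j], scheme)
  c1 <- u[1] < scheme$R
  c2 <- u[2] < r
  make <- function(a, b) { # offspring starting on parent a
    pl <- if (c1) ht$plasticity[b] else ht$plasticity[a]
    tg <- if (xor(c1, c2)) ht$target[b] else ht$target[a]
    haplotype_names()[4L * (ht$rec[a] - 1L) + 2L * tg + pl + 1L]
  }
  c(make(i, j), make(j, i))
}

#' Apply recombination to a haplotype distribution (mechanistic operator)
#'
#' Expectation over random mating pairs (drawn with replacement proportional
#' to frequency) of the crossover operator in [recombine_pair()]. This is
#' the source-of-truth recombination recursion; it conserves single-locus
#' allele frequencies exactly and is the identity on linkage-equilibrium
#' states.
#'
#' @param x Numeric vector of 8 haplotype frequencies (sum 1, tolerance
#'   1e-9), canonical order.
#' @param scheme A [recombination_scheme()].
#' @param tensor Optional precomputed [recombination_tensor()] for `scheme`.
#' @return Post-recombination frequency vector.
#' @export
apply_recombination <- function(x, scheme, tensor = NULL) {
  check_state(x)
  if (is.null(tensor)) tensor <- recombination_tensor(scheme)
  o <- as.vector(outer(x, x)) # o[i + 8 (j - 1)] = x_i x_j
  xp <- as.vector(crossprod(tensor, o))
  setNames(xp / sum(xp), haplotype_names())
}

#' Printed eight-equation recombination recursion (literal transcription)
#'
#' A literal transcription of the displayed eight-equation recursion for the
#' post-recombination haplotype frequencies, retained for cross-validation
#' against the mechanistic operator [apply_recombination()]. The displayed
#' equations contain typographical sign errors in several coefficients
#' (see [recursion_discrepancy_report()]); this function reproduces them
#' verbatim, except that the unreadable subscript "r1mcd" in the last
#' equation is read as r1md. Do not use this operator for analysis.
#'
#' @inheritParams apply_recombination
#' @param renormalize Renormalize the output to sum 1 (the raw transcription
#'   does not conserve total frequency at the typo terms). Default `FALSE`
#'   so discrepancies stay visible.
#' @return Frequency vector after the printed recursion.
#' @export
apply_recombination_printed <- function(x, scheme, renormalize = FALSE) {
  check_state(x)
  y <- as.numeric(x)
  r1 <- scheme$r1; r2 <- scheme$r2; rc <- scheme$r_c; R <- scheme$R
  y1 <- y[1]; y2 <- y[2]; y3 <- y[3]; y4 <- y[4]
  y5 <- y[5]; y6 <- y[6]; y7 <- y[7]; y8 <- y[8]
  xp <- numeric(8)
  xp[1] <- y1 * (1 - y7 - y8 - r1 * y4 - R * y6 +
                   (1 - R - rc + 2 * R * rc) * y7 + (1 - rc) * (1 - R) * y8) +
    y2 * (r1 * y3 + R * y5 + R * rc * y7) +
    y3 * ((R + rc - 2 * R * rc) * y5 + (1 - R) * rc * y6) +
    R * (1 - rc) * y4 * y5
  xp[2] <- y2 * (1 - y7 - y8 - r1 * y3 - R * y5 +
                   (1 - R) * (1 - rc) * y7 + (1 - R - rc + 2 * R * rc) * y8) +
    y1 * (r1 * y4 + R * y6 + R * rc * y8) +
    R * (1 - rc) * y3 * y6 +
    y4 * ((1 - R) * rc * y5 + (R + rc - 2 * R * rc) * y6)
  xp[3] <- y3 * (1 - R * y8 - y5 + (R * rc - R - rc) * y6 +
                   (1 - R - rc - 2 * R * rc) * y5 - r1 * y2) +
    y1 * (r1 * y4 + (R + rc - 2 * R * rc) * y7 + (1 - R) * rc * y8) +
    R * (1 - rc) * y2 * y7 +
    R * y4 * (rc * y5 + y7)
  xp[4] <- y4 * (1 - r1 * y1 - (R * rc - R - rc) * y5 -
                   (2 * R * rc - R - rc) * y6 - R * y7) +
    R * (1 - rc) * y1 * y8 +
    y2 * (r1 * y3 + (1 - R) * rc * y7 + (R + rc - 2 * R * rc) * y8) +
    R * y3 * (rc * y6 + y8)
  xp[5] <- y5 * (1 - R * y2 - (R + rc - R * rc) * y4 - r2 * y8 -
                   (2 * R * rc - R - rc) * y3) +
    y1 * (R * y6 + (R + rc - 2 * R * rc) * y7 + R * (1 - rc) * y8) +
    (1 - R) * rc * y2 * y7 +
    R * rc * y3 * y6 + r2 * y6 * y7
  xp[6] <- y6 * (1 - R * y1 - (R * rc - R - rc) * y3 -
                   (2 * R * rc - R - rc) * y4 - r2 * y7) +
    (1 - R) * rc * y1 * y8 +
    y2 * (R * y5 + R * (1 - rc) * y7 + (R + rc - 2 * R * rc) * y8) +
    y5 * (R * rc * y4 + r2 * y8)
  xp[7] <- y7 * (1 - (2 * R * rc - R - rc) * y1 - (R * rc - R - rc) * y2 -
                   R * y4 - r2 * y6) +
    R * rc * y1 * y8 +
    y3 * ((R + rc - 2 * R * rc) * y5 + R * (1 - rc) * y6 + R * y8) +
    y5 * ((1 - R) * rc * y4 + r2 * y8)
  xp[8] <- y8 * (1 - (R * rc - R - rc) * y1 - (R * rc - R - rc) * y2 -
                   R * y3 - r2 * y5) +
    y4 * (R * (1 - rc) * y5 + (R + rc - 2 * R * rc) * y6 + R * y7) +
    y7 * (r2 * y6 + R * rc * y2) +
    (1 - R) * rc * y3 * y6 # "r1mcd" read as r1md
  if (renormalize) xp <- xp / sum(xp)
  setNames(xp, haplotype_names())
}

#' Discrepancy report: printed recursion vs mechanistic operator
#'
#' Compares [apply_recombination_printed()] with [apply_recombination()] on
#' random normalized states and random schemes, and reports the largest
#' absolute per-haplotype discrepancy. Haplotypes flagged here correspond to
#' equations of the printed recursion whose coefficients disagree with the
#' first-principles crossover operator (typographical sign errors in the
#' source display); unflagged haplotypes agree to numerical precision.
#'
#' @param n_states Number of random states to compare.
#' @param seed RNG seed for reproducibility of the report.
#' @param tol Discrepancy above which a haplotype is flagged.
#' @return A data.frame with columns `haplotype`, `max_abs_diff`, `flagged`.
#' @export
recursion_discrepancy_report <- function(n_states = 1000, seed = 1, tol = 1e-12) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mx <- numeric(8)
  for (k in seq_len(n_states)) {
    sch <- recombination_scheme(
      r1 = runif(1, 0, 0.5), r2 = runif(1, 0, 0.5), R = runif(1, 0, 0.5)
    )
    x <- runif(8)
    x <- x / sum(x)
    a <- apply_recombination(x, sch)
    b <- apply_recombination_printed(x, sch)
    mx <- pmax(mx, abs(a - b))
  }
  data.frame(
    haplotype = haplotype_names(),
    max_abs_diff = as.numeric(mx),
    flagged = mx > tol,
    stringsAsFactors = FALSE
  )
}

#' Multilocus crossover between two haploid genomes
#'
#' Generalization of [recombine_pair()] to an arbitrary number of loci:
#' each inter-locus interval recombines independently with its own rate.
#' Rates for intervals controlled by a recombination-modifier locus should
#' be computed by the caller with the additive heterozygous rule (mean of
#' the two parental modifier alleles), as the individual-based engine does.
#'
#' @param parent1,parent2 Vectors of equal length: allele values per locus
#'   (any type; continuous modifier alleles and 0/1 alleles both work).
#' @param rates Per-interval recombination rates, length
#'   `length(parent1) - 1`, each in `[0, 0.5]`.
#' @param u Uniform variates, one per interval; defaults to fresh draws.
#' @return A list of the two reciprocal offspring; the first starts on
#'   `parent1`.
#' @export
multilocus_recombine <- function(parent1, parent2, rates,
                                 u = runif(length(rates))) {
  L <- length(parent1)
  if (length(parent2) != L) stop("parent genomes have different lengths")
  stopifnot(length(rates) == L - 1L, all(rates >= 0), all(rates <= 0.5))
  stopifnot(length(u) == L - 1L)
  cross <- u < rates
  from2 <- cumsum(c(FALSE, cross)) %% 2L == 1L # which loci come from the other parent
  off1 <- parent1
  off1[from2] <- parent2[from2]
  off2 <- parent2
  off2[from2] <- parent1[from2]
  list(off1, off2)
}
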