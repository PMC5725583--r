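## Finite-population Wright-Fisher engines: an 8-haplotype multinomial
## engine built on the deterministic recursion, and an individual-based
## engine with a continuum of recombination-rate alleles under recurrent
## mutation (compiled core).

#' Finite-population run parameters
#'
#' @param N Haploid population size (>= 2).
#' @param mutation_intensity Expected mutation events per locus per
#'   generation (the population-scaled rate N*mu, e.g. 0.1): each
#'   generation, each locus mutates in one uniformly chosen individual with
#'   this probability. Recombination-modifier mutants draw a fresh rate from
#'   U[0, 0.5]; plasticity and target mutants flip allele.
#' @param burn_in Generations discarded before recording (default 100 N).
#' @param record Generations of the recording window (default 100 N).
#' @return An object of class `population_params`.
#' @export
population_params <- function(N, mutation_intensity = 0.1,
                              burn_in = 100 * N, record = 100 * N) {
  stopifnot(N >= 2, N == round(N), mutation_intensity >= 0,
            mutation_intensity <= 1, burn_in >= 0, record >= 0)
  structure(list(N = as.integer(N), mutation_intensity = mutation_intensity,
                 burn_in = as.integer(burn_in), record = as.integer(record)),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Population parameters: N = %d, N*mu = %g, burn-in = %d, recording = %d generations\n",
              x$N, x$mutation_intensity, x$burn_in, x$record))
  invisible(x)
}

#' One Wright-Fisher generation by multinomial sampling of haplotypes
#'
#' Applies deterministic selection and recombination to the frequency
#' vector, then resamples `N` haploid individuals multinomially; the
#' deterministic step is recovered in the infinite-population limit
#' (`N = Inf` skips sampling).
#'
#' @param x 8-haplotype frequency vector (canonical order).
#' @param scheme A [recombination_scheme()].
#' @param regime A [seasonal_regime()].
#' @param t Generation index (sets the seasonal selection coefficient).
#' @param N Population size, or `Inf` for the deterministic limit.
#' @param tensor Optional precomputed [recombination_tensor()].
#' @return Next-generation frequency vector (counts / N).
#' @export
wf_multinomial_step <- function(x, scheme, regime, t, N, tensor = NULL) {
  if (is.null(tensor)) tensor <- recombination_tensor(scheme)
  y <- apply_selection(x, regime, t)
  z <- apply_recombination(y, scheme, tensor = tensor)
  if (!is.finite(N)) return(z)
  setNames(as.vector(rmultinom(1L, N, z)) / N, haplotype_names())
}

#' Multi-generation multinomial Wright-Fisher run
#'
#' @inheritParams wf_multinomial_step
#' @param generations Number of generations to simulate.
#' @param t0 Starting generation index.
#' @param record_trajectory Keep the per-generation frequency matrix.
#' @return List with `x_final` and optionally `trajectory`
#'   (`generations + 1` rows including the initial state).
#' @export
simulate_wf <- function(x0, scheme, regime, N, generations, t0 = 0L,
                        record_trajectory = FALSE) {
  tensor <- recombination_tensor(scheme)
  x <- x0
  traj <- if (record_trajectory)
    matrix(NA_real_, generations + 1L, 8L,
           dimnames = list(NULL, haplotype_names()))
  if (record_trajectory) traj[1L, ] <- x
  for (k in seq_len(generations)) {
    x <- wf_multinomial_step(x, scheme, regime, t0 + k - 1L, N, tensor = tensor)
    if (record_trajectory) traj[k + 1L, ] <- x
  }
  out <- list(x_final = x)
  if (record_trajectory) out$trajectory <- traj
  out
}

## ---------------------------------------------------------------------------
## Genome layouts for the individual-based engine

#' Genome layout for the individual-based engine
#'
#' Describes a haploid genome as an ordered sequence of loci (recombination
#' modifiers with continuous rate alleles, one plasticity locus, one or more
#' target loci) and the recombination rate of each inter-locus interval:
#' either a fixed rate or "controlled" by a named modifier locus, in which
#' case a mating pair recombines at the additive mean of its two modifier
#' alleles.
#'
#' @param loci data.frame with columns `name` and `type`
#'   (`"rec"`, `"plasticity"`, `"target"`).
#' @param intervals data.frame with one row per interval (between
#'   consecutive loci) and columns `rate` (fixed rate, `NA` if controlled)
#'   and `control` (modifier locus name, `NA` if fixed).
#' @return An object of class `genome_layout`.
#' @seealso [layout_three_locus()], [layout_two_target()],
#'   [layout_supergene()]
#' @export
genome_layout <- function(loci, intervals) {
  stopifnot(is.data.frame(loci), all(c("name", "type") %in% names(loci)))
  stopifnot(all(loci$type %in% c("rec", "plasticity", "target")))
  stopifnot(sum(loci$type == "plasticity") <= 1L)
  stopifnot(is.data.frame(intervals), nrow(intervals) == nrow(loci) - 1L,
            all(c("rate", "control") %in% names(intervals)))
  ctrl <- intervals$control
  bad <- !is.na(ctrl) & !(ctrl %in% loci$name[loci$type == "rec"])
  if (any(bad)) stop("interval controlled by unknown modifier locus")
  fixed <- is.na(ctrl)
  stopifnot(all(!is.na(intervals$rate[fixed])),
            all(intervals$rate[fixed] >= 0), all(intervals$rate[fixed] <= 0.5))
  structure(list(loci = loci, intervals = intervals), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", paste(x$loci$name, collapse = " - "), "\n")
  for (k in seq_len(nrow(x$intervals))) {
    lab <- if (is.na(x$intervals$control[k]))
      sprintf("fixed rate %g", x$intervals$rate[k])
    else sprintf("controlled by %s", x$intervals$control[k])
    cat(sprintf("  %s - %s: %s\n", x$loci$name[k], x$loci$name[k + 1L], lab))
  }
  invisible(x)
}

#' Standard three-locus layout
#'
#' Modifier - plasticity - target, with the modifier-plasticity interval at
#' the fixed rate `R` and the plasticity-target interval controlled by the
#' modifier.
#'
#' @param R Modifier-to-sequence recombination rate.
#' @return A [genome_layout()].
#' @export
layout_three_locus <- function(R = 0.5) {
  genome_layout(
    loci = data.frame(name = c("rec1", "P", "T1"),
                      type = c("rec", "plasticity", "target"),
                      stringsAsFactors = FALSE),
    intervals = data.frame(rate = c(R, NA), control = c(NA, "rec1"),
                           stringsAsFactors = FALSE)
  )
}

#' Two-target layouts
#'
#' `mode = "sequential"`: the plasticity-T1 distance is held at the fixed
#' rate `plast_target_rate` (typically the ES rate of the three-locus
#' analysis) and a single unlinked modifier `rec2` controls the T1-T2
#' interval (the evolvable inter-target rate r'). With
#' `placement = "between"` the new target sits between the plasticity locus
#' and T1, its interval to the plasticity locus evolvable and its interval
#' to T1 fixed.
#'
#' `mode = "simultaneous"`: two modifiers; `rec1` (at distance `R1` from
#' the selected sequence) controls plasticity-T1 and the unlinked `rec2`
#' controls T1-T2; both rates evolve at once.
#'
#' @param mode `"sequential"` or `"simultaneous"`.
#' @param plast_target_rate Fixed plasticity-first-target rate (sequential).
#' @param R1 Modifier-to-sequence rate of `rec1` (simultaneous;
#'   `R1 = 0.01` is the linked-modifier variant).
#' @param placement Where the new target is introduced (sequential).
#' @return A [genome_layout()].
#' @export
layout_two_target <- function(mode = c("sequential", "simultaneous"),
                              plast_target_rate = 0.2, R1 = 0.5,
                              placement = c("downstream", "between")) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  if (mode == "sequential") {
    if (placement == "downstream") {
      genome_layout(
        loci = data.frame(name = c("rec2", "P", "T1", "T2"),
                          type = c("rec", "plasticity", "target", "target"),
                          stringsAsFactors = FALSE),
        intervals = data.frame(rate = c(0.5, plast_target_rate, NA),
                               control = c(NA, NA, "rec2"),
                               stringsAsFactors = FALSE)
      )
    } else {
      genome_layout(
        loci = data.frame(name = c("rec2", "P", "T2", "T1"),
                          type = c("rec", "plasticity", "target", "target"),
                          stringsAsFactors = FALSE),
        intervals = data.frame(rate = c(0.5, NA, plast_target_rate),
                               control = c(NA, "rec2", NA),
                               stringsAsFactors = FALSE)
      )
    }
  } else {
    genome_layout(
      loci = data.frame(name = c("rec2", "rec1", "P", "T1", "T2"),
                        type = c("rec", "rec", "plasticity", "target", "target"),
                        stringsAsFactors = FALSE),
      intervals = data.frame(rate = c(0.5, R1, NA, NA),
                             control = c(NA, NA, "rec1", "rec2"),
                             stringsAsFactors = FALSE)
    )
  }
}

#' Supergene layout with n target loci
#'
#' Plasticity locus followed by `n_targets` target loci; the plasticity-T1
#' interval is fixed at `plast_target_rate` and each inter-target interval
#' T(i)-T(i+1) is controlled by its own unlinked modifier `mod(i+1)`.
#'
#' @param n_targets Number of target loci (>= 2).
#' @param plast_target_rate Fixed plasticity-T1 rate.
#' @return A [genome_layout()].
#' @export
layout_supergene <- function(n_targets, plast_target_rate = 0.2) {
  stopifnot(n_targets >= 2)
  mods <- paste0("mod", 2:n_targets)
  tars <- paste0("T", 1:n_targets)
  loci <- data.frame(
    name = c(mods, "P", tars),
    type = c(rep("rec", length(mods)), "plasticity", rep("target", n_targets)),
    stringsAsFactors = FALSE
  )
  nmod <- length(mods)
  rate <- c(rep(0.5, nmod), plast_target_rate, rep(NA, n_targets - 1L))
  control <- c(rep(NA, nmod + 1L), mods)
  genome_layout(loci, data.frame(rate = rate, control = control,
                                 stringsAsFactors = FALSE))
}

#' Initialize a haploid population
#'
#' @param layout A [genome_layout()].
#' @param N Population size.
#' @param rec_rates Initial recombination-modifier allele(s): scalar or
#'   named vector (per modifier locus). All individuals start monomorphic at
#'   these values.
#' @param plast_freq Initial frequency of the plasticity allele M (alleles
#'   drawn independently per individual; 0 gives a monomorphic m
#'   population).
#' @param target_freq Initial frequency of the derived allele d at each
#'   target locus (scalar or per-locus vector).
#' @return An N x L genotype matrix with the layout attached as attribute
#'   `layout`, class `haploid_pop`.
#' @export
init_population <- function(layout, N, rec_rates = 0, plast_freq = 0,
                            target_freq = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  L <- nrow(layout$loci)
  geno <- matrix(0, N, L, dimnames = list(NULL, layout$loci$name))
  recs <- layout$loci$name[layout$loci$type == "rec"]
  if (is.null(names(rec_rates))) rec_rates <- setNames(rep_len(rec_rates, length(recs)), recs)
  for (rn in recs) geno[, rn] <- rec_rates[[rn]]
  pl <- layout$loci$name[layout$loci$type == "plasticity"]
  if (length(pl)) geno[, pl] <- rbinom(N, 1L, plast_freq)
  tars <- layout$loci$name[layout$loci$type == "target"]
  target_freq <- rep_len(target_freq, length(tars))
  for (k in seq_along(tars)) geno[, tars[k]] <- rbinom(N, 1L, target_freq[k])
  structure(geno, layout = layout, class = c("haploid_pop", "matrix", "array"))
}

## translate a layout into the compiled engine's integer encoding
layout_codes <- function(layout) {
  type <- match(layout$loci$type, c("rec", "plasticity", "target")) - 1L
  ctrl <- match(layout$intervals$control, layout$loci$name) - 1L
  ctrl[is.na(ctrl)] <- -1L
  rate <- layout$intervals$rate
  rate[is.na(rate)] <- 0
  list(type = as.integer(type), ctrl = as.integer(ctrl), rate = as.numeric(rate))
}

#' Run the individual-based Wright-Fisher engine
#'
#' Per generation: (1) mutation introduces diversity at each locus with
#' chance `mutation_intensity` (one event hitting one uniformly chosen
#' individual; modifier mutants draw a fresh rate from U[0, 0.5], the other
#' loci flip allele; set `mut_per_copy = TRUE` for the alternative
#' per-individual rate `mutation_intensity / N`); (2) parent pairs are
#' rejection-sampled with replacement, accepted with probability equal to
#' fitness relative to the maximum fitness in the population; (3) the two
#' parental genomes recombine, each interval independently at its layout
#' rate (modifier-controlled intervals at the additive mean of the parental
#' alleles), and one of the two reciprocal products joins the next
#' generation, until N offspring are assembled.
#'
#' During the recording window the allele value of `record_locus` of every
#' individual is accumulated into a histogram at two-decimal resolution;
#' with two or more target loci the co-segregation fraction (haplotypes
#' all-a or all-d) and the linkage disequilibrium between the first two
#' targets are averaged over recorded generations.
#'
#' @param pop An [init_population()] genotype matrix (its attached layout is
#'   used).
#' @param regime A [seasonal_regime()]; with several target loci the same
#'   per-locus `s_max` applies to each (override via `s_max_each`).
#' @param params A [population_params()].
#' @param record_locus Modifier locus whose allele distribution is
#'   recorded; default the last modifier in the layout.
#' @param s_max_each Optional vector of per-target-locus maximum seasonal
#'   effects.
#' @param mut_per_copy Use the per-copy mutation variant.
#' @param fitness_mode `"multiplicative"` (per-locus factors multiply; the
#'   default, matching the single-target fitnesses applied per locus) or
#'   `"additive"` (1 plus the sum of per-locus effects).
#' @param trace_every Record a small summary (mean modifier allele, allele
#'   frequencies) every this many generations; 0 disables.
#' @param phase Seasonal phase of the first generation.
#' @return An object of class `ibm_run`: list with `stationary`
#'   (a `stationary_dist`), `coseg_mean`, `target_ld_mean`, `final_pop`,
#'   `trace`, `mutation_events`.
#' @export
simulate_population <- function(pop, regime, params,
                                record_locus = NULL, s_max_each = NULL,
                                mut_per_copy = FALSE,
                                fitness_mode = c("multiplicative", "additive"),
                                trace_every = 0L, phase = NULL) {
  fitness_mode <- match.arg(fitness_mode)
  layout <- attr(pop, "layout")
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "population_params"),
            inherits(regime, "seasonal_regime"))
  codes <- layout_codes(layout)
  recs <- layout$loci$name[layout$loci$type == "rec"]
  if (is.null(record_locus)) record_locus <- if (length(recs)) recs[length(recs)] else NA
  rl <- if (is.na(record_locus)) -1L else match(record_locus, layout$loci$name) - 1L
  if (!is.na(record_locus) && is.na(rl)) stop("unknown record_locus")
  ntar <- sum(layout$loci$type == "target")
  if (is.null(s_max_each)) s_max_each <- rep(regime$s_max, ntar)
  stopifnot(length(s_max_each) == ntar)
  if (is.null(phase)) phase <- regime$phase
  mut <- rep(params$mutation_intensity, nrow(layout$loci))

  res <- ibm_simulate_cpp(
    unclass(pop), codes$type, codes$ctrl, codes$rate,
    as.numeric(s_max_each), regime$C, regime$p, as.integer(phase),
    mut, mut_per_copy, params$burn_in, params$record, as.integer(rl),
    if (fitness_mode == "multiplicative") 0L else 1L, as.integer(trace_every)
  )
  hist <- res$hist
  mass <- if (sum(hist) > 0) hist / sum(hist) else hist
  stat <- structure(
    list(bin = seq(0, 0.5, by = 0.01), mass = mass, counts = hist,
         record_locus = record_locus, replicate_count = 1L,
         N = params$N, recorded_generations = params$record),
    class = "stationary_dist"
  )
  trace <- res$trace
  if (res$trace_rows > 0) {
    trace <- trace[seq_len(res$trace_rows), , drop = FALSE]
    colnames(trace) <- c("mean_rate", "freq_M",
                         paste0("freq_d_", seq_len(ncol(trace) - 2L)))
  } else trace <- NULL
  fp <- res$final_pop
  colnames(fp) <- layout$loci$name
  structure(
    list(stationary = stat, coseg_mean = res$coseg_mean,
         target_maf_mean = res$target_maf_mean,
         target_ld_mean = res$target_ld_mean,
         final_pop = structure(fp, layout = layout,
                               class = c("haploid_pop", "matrix", "array")),
         trace = trace, mutation_events = res$mutation_events,
         params = params, regime = regime, layout = layout),
    class = "ibm_run"
  )
}

#' @export
print.ibm_run <- function(x, ...) {
  cat(sprintf("Individual-based run: N = %d, %d + %d generations\n",
              x$params$N, x$params$burn_in, x$params$record))
  print(x$stationary)
  invisible(x)
}

#' @export
print.stationary_dist <- function(x, ...) {
  m <- stationary_mode(x)
  cat(sprintf(
    "Stationary distribution of %s (N = %d, %d recorded generations):\n",
    x$record_locus, x$N, x$recorded_generations))
  cat(sprintf("  mode at rate %.2f, mean rate %.3f, mass below 0.1: %.3f\n",
              m, sum(x$bin * x$mass), sum(x$mass[x$bin < 0.1])))
  invisible(x)
}

#' @export
plot.stationary_dist <- function(x, ...) {
  graphics::barplot(x$mass, names.arg = format(x$bin), las = 2,
                    ylab = "probability mass",
                    xlab = "recombination rate", ...)
  invisible(x)
}

#' Mode of a stationary recombination-rate distribution
#'
#' @param x A `stationary_dist` (from [simulate_population()] or
#'   [run_stationary_distribution()]).
#' @return The bin value (two-decimal rate) with the largest mass.
#' @export
stationary_mode <- function(x) {
  stopifnot(inherits(x, "stationary_dist"))
  x$bin[which.max(x$mass)]
}

#' Combine stationary distributions across replicates
#'
#' @param ... `stationary_dist` objects on the same bins.
#' @return A pooled `stationary_dist` (counts summed, mass renormalized).
#' @export
pool_stationary <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "stationary_dist"))
    xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, TRUE, "stationary_dist")))
  counts <- Reduce(`+`, lapply(xs, `[[`, "counts"))
  out <- xs[[1]]
  out$counts <- counts
  out$mass <- if (sum(counts) > 0) counts / sum(counts) else counts
  out$replicate_count <- sum(vapply(xs, `[[`, 1L, "replicate_count"))
  out$recorded_generations <- sum(vapply(xs, `[[`, 1L, "recorded_generations"))
  out
}

#' Stationary distribution of the plasticity-target recombination rate
#'
#' The standard single-target protocol: a population monomorphic at all
#' three loci (no recombination, allele m, allele a) evolves under
#' recurrent mutation, seasonal selection and drift; after the burn-in the
#' modifier-allele distribution is recorded at two-decimal resolution.
#'
#' @param params A [population_params()].
#' @param regime A [seasonal_regime()].
#' @param R Modifier-to-sequence recombination rate.
#' @param protocol `"monomorphic"` (the standard start) or a ready-made
#'   [init_population()] matrix.
#' @param replicates Number of independent replicate runs to pool.
#' @param ... Passed to [simulate_population()].
#' @return A `stationary_dist` with attribute `runs` holding the individual
#'   [simulate_population()] results.
#' @export
run_stationary_distribution <- function(params, regime, R = 0.5,
                                        protocol = "monomorphic",
                                        replicates = 1L, ...) {
  layout <- layout_three_locus(R)
  runs <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    pop <- if (inherits(protocol, "haploid_pop")) protocol
      else init_population(layout, params$N, rec_rates = 0, plast_freq = 0,
                           target_freq = 0)
    runs[[k]] <- simulate_population(pop, regime, params, ...)
  }
  out <- pool_stationary(lapply(runs, function(r) r$stationary))
  attr(out, "runs") <- runs
  out
}

#' One individual-based generation (reference surface)
#'
#' Runs a single generation of the individual-based engine with mutation
#' disabled: fitness-proportional (rejection) parent sampling, per-interval
#' crossover, one offspring per pair. Useful for unit-level checks against
#' the haplotype-frequency recursion.
#'
#' @param pop An [init_population()] matrix.
#' @param regime A [seasonal_regime()].
#' @param t Generation index (seasonal phase).
#' @param ... Passed to [simulate_population()].
#' @return The next-generation `haploid_pop` matrix.
#' @export
next_generation <- function(pop, regime, t = 0L, ...) {
  params <- population_params(nrow(pop), mutation_intensity = 0,
                              burn_in = 1L, record = 0L)
  simulate_population(pop, regime, params, phase = t, ...)$final_pop
}

#' Mutate a population in place (reference surface)
#'
#' One Bernoulli(`intensity`) mutation event per locus per call, hitting a
#' uniformly chosen individual: recombination-modifier loci draw a fresh
#' allele from U[0, 0.5], plasticity and target loci flip. With
#' `per_copy = TRUE` every copy mutates independently with probability
#' `intensity / N` instead.
#'
#' @param pop An [init_population()] matrix.
#' @param intensity Population-scaled mutation rate N*mu per locus.
#' @param per_copy Use the per-copy variant.
#' @return The mutated population matrix.
#' @export
mutate_population <- function(pop, intensity, per_copy = FALSE) {
  layout <- attr(pop, "layout")
  stopifnot(inherits(layout, "genome_layout"), intensity >= 0, intensity <= 1)
  N <- nrow(pop)
  for (l in seq_len(ncol(pop))) {
    is_rec <- layout$loci$type[l] == "rec"
    if (per_copy) {
      hit <- which(runif(N) < intensity / N)
      if (length(hit)) {
        if (is_rec) pop[hit, l] <- runif(length(hit), 0, 0.5)
        else pop[hit, l] <- 1 - pop[hit, l]
      }
    } else if (runif(1) < intensity) {
      i <- sample.int(N, 1L)
      if (is_rec) pop[i, l] <- runif(1, 0, 0.5)
      else pop[i, l] <- 1 - pop[i, l]
    }
  }
  pop
}
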