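## Deterministic (infinite-population) dynamics: periodic orbits of the
## selection + recombination map, their local stability over one full
## environmental cycle, and pairwise invasion analysis of recombination-rate
## alleles.

#' Evolve the deterministic three-locus recursion
#'
#' Iterates one generation of haploid selection followed by the mechanistic
#' recombination operator, until (i) the plasticity or target locus loses
#' its polymorphism (minor allele frequency below `fix_tol`), (ii) the
#' haplotype-frequency sequences of two consecutive environmental cycles
#' agree coordinate-wise within `cycle_tol` (a periodic equilibrium), or
#' (iii) `max_generations` is reached (flagged unconverged). At least
#' `min_generations` generations are always run before the cycle criterion
#' is applied.
#'
#' @param x0 Initial 8-haplotype frequency vector (canonical order, sum 1).
#' @param scheme A [recombination_scheme()].
#' @param regime A [seasonal_regime()]; its `phase` sets the season at which
#'   the run starts.
#' @param max_generations Iteration cap (>= 1000).
#' @param min_generations Minimum generations before testing for a cycle.
#' @param fix_tol Fixation threshold for the plasticity/target minor allele.
#' @param cycle_tol Cycle-repetition threshold (max absolute coordinate
#'   difference between same-phase states of consecutive cycles).
#' @param record_trajectory Keep the full per-generation state matrix.
#' @return An object of class `det_run` (and `periodic_orbit` when the cycle
#'   criterion was met) with elements `status` (`"converged"`, `"fixated"`
#'   or `"max_generations"`), `converged`, `generations_run`, `orbit` (the
#'   last full cycle, rows aligned so that row k is the state at seasonal
#'   phase k - 1), `x_final`, and optionally `trajectory`.
#' @examples
#' reg <- seasonal_regime(0.1, 10, 1)
#' sch <- recombination_scheme(0.3, 0.3, 0.5)
#' run <- evolve_deterministic(rep(1/8, 8), sch, reg, max_generations = 20000)
#' run$status
#' @export
evolve_deterministic <- function(x0, scheme, regime,
                                 max_generations = 1e5,
                                 min_generations = 1000,
                                 fix_tol = 1e-4, cycle_tol = 1e-8,
                                 record_trajectory = FALSE) {
  stopifnot(inherits(scheme, "recombination_scheme"),
            inherits(regime, "seasonal_regime"),
            max_generations >= min_generations)
  check_state(x0)
  Tm <- recombination_tensor(scheme)
  res <- det_evolve_cpp(as.numeric(x0), Tm, regime$s_max, regime$C, regime$p,
                        regime$phase, as.integer(max_generations),
                        as.integer(min_generations), fix_tol, cycle_tol,
                        record_trajectory)
  status <- c("converged", "fixated", "max_generations")[res$status + 1L]
  orbit <- res$orbit
  phases <- (res$orbit_t + regime$phase) %% regime$C
  if (nrow(orbit) == regime$C) {
    ord <- order(phases)
    orbit <- orbit[ord, , drop = FALSE]
    phases <- phases[ord]
  }
  colnames(orbit) <- haplotype_names()
  rownames(orbit) <- paste0("phase", phases)
  out <- list(
    status = status,
    converged = status == "converged",
    generations_run = res$generations,
    orbit = orbit,
    orbit_phases = phases,
    x_final = setNames(res$x_final, haplotype_names()),
    scheme = scheme, regime = regime,
    fix_tol = fix_tol, cycle_tol = cycle_tol
  )
  if (record_trajectory) {
    out$trajectory <- res$trajectory
    colnames(out$trajectory) <- haplotype_names()
  }
  class(out) <- if (out$converged) c("periodic_orbit", "det_run") else "det_run"
  out
}

#' @export
print.det_run <- function(x, ...) {
  cat(sprintf("Deterministic run: %s after %d generations\n",
              x$status, x$generations_run))
  af <- allele_freqs(x$x_final)
  cat(sprintf("  final allele frequencies: r2 = %.4g, M = %.4g, d = %.4g\n",
              af["r2"], af["M"], af["d"]))
  invisible(x)
}

## iterate the composed map over one full cycle starting at seasonal phase
## `phase0`; internals skip validation for speed
one_cycle_map <- function(x, scheme, regime, tensor, phase0 = 0L) {
  p <- regime$p
  for (t in seq_len(regime$C) - 1L) {
    s <- regime$s_max * sin(2 * pi * (t + phase0) / regime$C)
    w <- fitness_vector(s, p)
    x <- x * w
    x <- x / sum(x)
    x <- as.vector(crossprod(tensor, as.vector(outer(x, x))))
    x <- x / sum(x)
  }
  x
}

## per-generation Jacobians of the composed selection + recombination map
generation_jacobian <- function(x, scheme, regime, tensor, t) {
  w <- fitness_vector(seasonal_effect(t, regime), regime$p)
  W <- sum(x * w)
  Jsel <- diag(w / W) - (x * w) %o% w / W^2
  y <- x * w / W
  Jrec <- matrix(0, 8L, 8L)
  for (g in 1:8) {
    A <- matrix(tensor[, g], 8L, 8L) # A[i, j] multiplies x_i x_j
    Jrec[g, ] <- as.vector((A + t(A)) %*% y)
  }
  Jrec %*% Jsel
}

#' Cycle Jacobian of a periodic orbit
#'
#' Jacobian of the full-cycle map (selection followed by recombination,
#' iterated over the `C` generations of one environmental period) evaluated
#' along a converged periodic orbit, starting at seasonal phase 0. The
#' leading eigenvalue modulus of this matrix classifies local stability.
#' Two methods are provided and agree to about 1e-5 relative: the analytic
#' chain rule over per-generation Jacobians, and central finite differences
#' of the composed map (the map extends smoothly off the simplex because
#' the selection step renormalizes, so raw coordinate perturbations
#' differentiate the same map; set `project = TRUE` to renormalize
#' perturbed states instead, which differentiates the map restricted to the
#' simplex).
#'
#' @param orbit A converged [evolve_deterministic()] result.
#' @param method `"analytic"` (chain rule) or `"fd"` (central differences).
#' @param h Finite-difference step.
#' @param project For `method = "fd"`: renormalize perturbed states.
#' @return An 8 x 8 Jacobian matrix.
#' @export
cycle_jacobian <- function(orbit, method = c("analytic", "fd"), h = 1e-6,
                           project = FALSE) {
  method <- match.arg(method)
  if (!isTRUE(orbit$converged))
    stop("cycle_jacobian requires a converged periodic orbit")
  scheme <- orbit$scheme; regime <- orbit$regime
  tensor <- recombination_tensor(scheme)
  if (method == "analytic") {
    J <- diag(8)
    for (t in seq_len(regime$C) - 1L) {
      x <- orbit$orbit[t + 1L, ]
      ## per-generation J evaluated at the phase-t state; seasonal_effect is
      ## taken at absolute phase t (orbit rows are phase-aligned)
      w <- fitness_vector(regime$s_max * sin(2 * pi * t / regime$C), regime$p)
      W <- sum(x * w)
      Jsel <- diag(w / W) - (x * w) %o% w / W^2
      y <- x * w / W
      Jrec <- matrix(0, 8L, 8L)
      for (g in 1:8) {
        A <- matrix(tensor[, g], 8L, 8L)
        Jrec[g, ] <- as.vector((A + t(A)) %*% y)
      }
      J <- Jrec %*% Jsel %*% J
    }
    J
  } else {
    x0 <- orbit$orbit[1L, ]
    J <- matrix(0, 8L, 8L)
    for (i in 1:8) {
      up <- x0; up[i] <- up[i] + h
      dn <- x0; dn[i] <- dn[i] - h
      if (project) { up <- up / sum(up); dn <- dn / sum(dn) }
      J[, i] <- (one_cycle_map(up, scheme, regime, tensor) -
                   one_cycle_map(dn, scheme, regime, tensor)) / (2 * h)
    }
    J
  }
}

#' Leading eigenvalue for invasion of a rare modifier allele
#'
#' Computes the periodic orbit of the resident-only system (the invading
#' modifier allele held at frequency zero, which is invariant under the
#' dynamics), then the cycle Jacobian along that boundary orbit, and returns
#' the leading eigenvalue modulus of the invader block (the Jacobian is
#' block-triangular at the boundary). A modulus above 1 means the rare
#' allele grows over one environmental cycle.
#'
#' @param scheme A [recombination_scheme()]; the resident is the other
#'   allele than `invader`.
#' @param regime A [seasonal_regime()].
#' @param invader `"r2"` or `"r1"`: which modifier allele is rare.
#' @param init Initial plasticity and target allele frequencies (M, d) of
#'   the resident population, in linkage equilibrium.
#' @param ... Passed to [evolve_deterministic()].
#' @return Leading eigenvalue modulus of the invader block, or `NA` if the
#'   resident-only system does not reach a polymorphic periodic orbit.
#' @export
invasion_eigenvalue <- function(scheme, regime, invader = c("r2", "r1"),
                                init = c(0.5, 0.5), ...) {
  invader <- match.arg(invader)
  f_r2 <- if (invader == "r2") 0 else 1
  x0 <- linkage_equilibrium_state(f_r2, init[1], init[2])
  run <- evolve_deterministic(x0, scheme, regime, ...)
  if (!run$converged) return(NA_real_)
  J <- cycle_jacobian(run)
  idx <- if (invader == "r2") 5:8 else 1:4
  max(Mod(eigen(J[idx, idx], only.values = TRUE)$values))
}

## classify one invasion run. `invader` is "r1" or "r2".
##
## On a converged periodic orbit an allele either sits at a stationary
## intermediate frequency (balanced polymorphism at the modifier locus) or
## has decayed essentially to zero: under a 1e-8 cycle tolerance a
## geometrically decaying allele cannot stall at an appreciable frequency,
## so persistence is judged against the small `absorb_tol`. Runs that hit
## the generation cap are still in transit; there the conservative
## `persist_tol` rule applies (an invader counts as established only once
## it exceeds double its introduction frequency).
## Returns list(outcome, maf_min, invader_freq, converged).
analyze_invasion_run <- function(run, invader, persist_tol = 0.02,
                                 poly_tol = 0.01, absorb_tol = 1e-3) {
  if (run$status == "fixated") {
    return(list(outcome = "no_polymorphism", maf_min = NA_real_,
                invader_freq = NA_real_, converged = TRUE))
  }
  orb <- run$orbit
  fM <- rowSums(orb[, c(2, 4, 6, 8), drop = FALSE])
  fd <- rowSums(orb[, c(3, 4, 7, 8), drop = FALSE])
  maf_min <- min(pmin(fM, 1 - fM), pmin(fd, 1 - fd))
  f2 <- mean(rowSums(orb[, 5:8, drop = FALSE]))
  fi <- if (invader == "r2") f2 else 1 - f2
  tol <- if (run$converged) absorb_tol else persist_tol
  outcome <- if (maf_min < poly_tol) {
    "no_polymorphism"
  } else if (1 - fi <= tol) {
    "invader_fixed"
  } else if (fi <= tol) {
    "invader_excluded"
  } else {
    "intermediate"
  }
  list(outcome = outcome, maf_min = maf_min, invader_freq = fi,
       converged = run$converged)
}

## run one invasion direction over the initialization grid and aggregate
invasion_direction <- function(scheme, regime, invader, init_grid,
                               invader_freq, tensor, max_generations,
                               min_generations, fix_tol, cycle_tol,
                               persist_tol, poly_tol) {
  outcomes <- character(0)
  converged <- logical(0)
  for (g1 in init_grid) {
    for (g2 in init_grid) {
      f_r2 <- if (invader == "r2") invader_freq else 1 - invader_freq
      x0 <- linkage_equilibrium_state(f_r2, g1, g2)
      res <- det_evolve_cpp(as.numeric(x0), tensor, regime$s_max, regime$C,
                            regime$p, regime$phase,
                            as.integer(max_generations),
                            as.integer(min_generations), fix_tol, cycle_tol,
                            FALSE)
      status <- c("converged", "fixated", "max_generations")[res$status + 1L]
      run <- list(status = status, converged = status == "converged",
                  orbit = res$orbit)
      a <- analyze_invasion_run(run, invader, persist_tol, poly_tol)
      outcomes <- c(outcomes, a$outcome)
      converged <- c(converged, a$converged || status == "fixated")
    }
  }
  poly <- outcomes[outcomes != "no_polymorphism"]
  agg <- if (length(poly) == 0L) {
    "no_polymorphism"
  } else {
    names(sort(table(poly), decreasing = TRUE))[1L]
  }
  list(outcome = agg, outcomes = outcomes, all_converged = all(converged))
}

## periodic orbit of a resident-only boundary system (the other modifier
## allele held at exactly zero, which the dynamics preserve); NULL when no
## initialization reaches a polymorphic periodic orbit
resident_orbit <- function(scheme, regime, resident = c("r1", "r2"),
                           inits = list(c(0.5, 0.5), c(0.25, 0.75), c(0.75, 0.25)),
                           poly_tol = 0.01, ...) {
  resident <- match.arg(resident)
  f_r2 <- if (resident == "r1") 0 else 1
  for (g in inits) {
    run <- evolve_deterministic(linkage_equilibrium_state(f_r2, g[1], g[2]),
                                scheme, regime, ...)
    if (run$converged) {
      orb <- run$orbit
      fM <- rowSums(orb[, c(2, 4, 6, 8), drop = FALSE])
      fd <- rowSums(orb[, c(3, 4, 7, 8), drop = FALSE])
      if (min(pmin(fM, 1 - fM), pmin(fd, 1 - fd)) >= poly_tol) return(run)
    }
  }
  NULL
}

## leading eigenvalue modulus of the invader block of the cycle Jacobian
## along a boundary orbit
orbit_lambda <- function(orbit_run, invader) {
  J <- cycle_jacobian(orbit_run)
  idx <- if (invader == "r2") 5:8 else 1:4
  max(Mod(eigen(J[idx, idx], only.values = TRUE)$values))
}

#' Pairwise competition of two recombination-rate alleles
#'
#' Classifies the contest between two modifier alleles under a seasonal
#' regime, combining the two tools of the local stability analysis.
#'
#' When both alleles can, on their own, sustain the plasticity-target
#' polymorphism (each resident-only boundary system reaches a polymorphic
#' periodic orbit), the classification is decided by the leading
#' eigenvalues of the cycle Jacobian along the two boundary orbits: mutual
#' invasion means protected `coexistence`; one-sided invasion means the
#' invading allele displaces the other (`invader_fixes` / `resident_fixes`);
#' eigenvalues within `neutral_band` of 1 are treated as neutral and
#' classified as coexistence.
#'
#' When a resident cannot store alone (e.g. a non-recombining resident),
#' the contest is decided by direct iteration: plasticity and target
#' frequencies are initialized on a factorial grid (default 0.05 to 0.95 in
#' steps of 0.1), the invading allele enters at frequency `invader_freq` in
#' linkage equilibrium, and the system is evolved to fixation, a periodic
#' equilibrium, or the generation cap. On a converged attractor an allele
#' persists if its frequency is appreciable (above the absorbing
#' tolerance); on an unconverged run the conservative rule applies (an
#' invader counts as established only beyond `persist_tol`, double its
#' introduction frequency). The plasticity-target polymorphism must keep
#' minor allele frequency at least `poly_tol`, else the outcome is
#' `no_polymorphism`.
#'
#' @param r1 Resident recombination rate allele.
#' @param r2 Competing (invading) rate allele.
#' @param regime A [seasonal_regime()].
#' @param R Modifier-to-sequence recombination rate (0.5 = unlinked).
#' @param init_grid Plasticity/target initial allele frequencies (crossed
#'   factorially) for the iteration protocol.
#' @param invader_freq Initial frequency of the invading allele.
#' @param persist_tol Establishment threshold for unconverged runs.
#' @param poly_tol Minor-allele threshold for balanced polymorphism.
#' @param neutral_band Half-width of the eigenvalue band around 1 treated
#'   as selectively neutral.
#' @param max_generations,min_generations,fix_tol,cycle_tol Passed to the
#'   deterministic evolver.
#' @param ... Ignored (future extensions).
#' @return An object of class `invasion_outcome`: list with `r1`, `r2`,
#'   `classification` (one of `invader_fixes`, `resident_fixes`,
#'   `coexistence`, `no_polymorphism`), `leading_eigenvalue_modulus` (the
#'   boundary eigenvalue that informed the decision: the r2-into-r1
#'   direction when that boundary orbit exists, otherwise the reverse; NA
#'   when neither resident can store alone), and per-direction details.
#' @examples
#' \donttest{
#' reg <- seasonal_regime(0.1, 10, 1)
#' classify_pair(0, 0.3, reg, R = 0.5, init_grid = 0.5)
#' }
#' @export
classify_pair <- function(r1, r2, regime, R = 0.5,
                          init_grid = seq(0.05, 0.95, by = 0.1),
                          invader_freq = 0.01,
                          persist_tol = 0.02, poly_tol = 0.01,
                          neutral_band = 1e-6,
                          max_generations = 2e5, min_generations = 1000,
                          fix_tol = 1e-4, cycle_tol = 1e-8, ...) {
  stopifnot(inherits(regime, "seasonal_regime"))
  scheme <- recombination_scheme(r1, r2, R)
  tensor <- recombination_tensor(scheme)
  evolve_args <- list(max_generations = max_generations,
                      min_generations = min_generations,
                      fix_tol = fix_tol, cycle_tol = cycle_tol)

  finish <- function(classification, lamA, dirs, converged) {
    out <- list(r1 = r1, r2 = r2, classification = classification,
                leading_eigenvalue_modulus = lamA,
                directions = dirs, converged = converged)
    class(out) <- "invasion_outcome"
    out
  }

  if (isTRUE(all.equal(r1, r2))) {
    ## identical alleles: neutral; outcome hinges on whether the shared rate
    ## sustains the plasticity-target polymorphism
    orb <- do.call(resident_orbit,
                   c(list(scheme, regime, "r1", poly_tol = poly_tol),
                     evolve_args))
    cls <- if (is.null(orb)) "no_polymorphism" else "coexistence"
    return(finish(cls, if (is.null(orb)) NA_real_ else 1,
                  list(), TRUE))
  }

  orbA <- do.call(resident_orbit,
                  c(list(scheme, regime, "r1", poly_tol = poly_tol),
                    evolve_args))
  orbB <- do.call(resident_orbit,
                  c(list(scheme, regime, "r2", poly_tol = poly_tol),
                    evolve_args))
  lamA <- if (!is.null(orbA)) orbit_lambda(orbA, "r2") else NA_real_
  lamB <- if (!is.null(orbB)) orbit_lambda(orbB, "r1") else NA_real_

  if (!is.null(orbA) && !is.null(orbB)) {
    invA <- lamA > 1 + neutral_band
    invB <- lamB > 1 + neutral_band
    neuA <- abs(lamA - 1) <= neutral_band
    neuB <- abs(lamB - 1) <= neutral_band
    if (invA && invB) {
      return(finish("coexistence", lamA, list(lambda_A = lamA, lambda_B = lamB), TRUE))
    } else if (neuA || neuB) {
      ## marginal invasion: the neutral boundary behaves as a protected
      ## polymorphism
      return(finish("coexistence", lamA, list(lambda_A = lamA, lambda_B = lamB), TRUE))
    } else if (invA) {
      return(finish("invader_fixes", lamA, list(lambda_A = lamA, lambda_B = lamB), TRUE))
    } else if (invB) {
      return(finish("resident_fixes", lamA, list(lambda_A = lamA, lambda_B = lamB), TRUE))
    }
    ## both boundary orbits repel the rare allele: fall through to the
    ## iteration protocol for this (rare, bistable) edge case
  }

  dirA <- invasion_direction(scheme, regime, "r2", init_grid, invader_freq,
                             tensor, max_generations, min_generations,
                             fix_tol, cycle_tol, persist_tol, poly_tol)
  dirB <- invasion_direction(scheme, regime, "r1", init_grid, invader_freq,
                             tensor, max_generations, min_generations,
                             fix_tol, cycle_tol, persist_tol, poly_tol)

  persisting <- function(res, invader) {
    switch(res$outcome,
      invader_fixed = if (invader == "r2") "r2" else "r1",
      invader_excluded = if (invader == "r2") "r1" else "r2",
      intermediate = "both",
      no_polymorphism = "none"
    )
  }
  pA <- persisting(dirA, "r2")
  pB <- persisting(dirB, "r1")
  ## boundary eigenvalues refine directions whose resident can store alone:
  ## a positive boundary eigenvalue means the rare allele establishes even
  ## if the finite iteration horizon has not shown it yet
  if (!is.null(orbB) && pB %in% c("r2", "none")) {
    if (lamB > 1 + neutral_band || abs(lamB - 1) <= neutral_band) pB <- "both"
  }
  if (!is.null(orbA) && pA %in% c("r1", "none")) {
    if (lamA > 1 + neutral_band || abs(lamA - 1) <= neutral_band) pA <- "both"
  }
  classification <- if (pA == "none" && pB == "none") {
    "no_polymorphism"
  } else if (pA == "both" || pB == "both") {
    "coexistence"
  } else if (pA == "r2" && pB == "r1") {
    ## mutual invasion to fixation: protected polymorphism
    "coexistence"
  } else if (pA == "r1" && pB == "r2") {
    ## mutual exclusion within the horizon: near-neutral boundary, treated
    ## as protected polymorphism
    "coexistence"
  } else if (pA == "r2" || (pA == "none" && pB == "r2")) {
    "invader_fixes"
  } else {
    "resident_fixes"
  }
  ## report the boundary eigenvalue that informed the decision: the
  ## r2-into-r1 direction when that orbit exists, else the reverse
  finish(classification, if (!is.na(lamA)) lamA else lamB,
         list(A = dirA, B = dirB, lambda_A = lamA, lambda_B = lamB),
         dirA$all_converged && dirB$all_converged)
}

#' @export
print.invasion_outcome <- function(x, ...) {
  cat(sprintf("Invasion outcome r1 = %g vs r2 = %g: %s", x$r1, x$r2,
              x$classification))
  if (!is.na(x$leading_eigenvalue_modulus))
    cat(sprintf(" (|lambda| = %.6g)", x$leading_eigenvalue_modulus))
  cat("\n")
  invisible(x)
}

#' Competition of a resident rate against a grid of alternative rates
#'
#' Runs [classify_pair()] for one resident rate against each rate of a
#' grid, as in one column of the pairwise-competition diagram.
#'
#' @param resident Resident rate (r1).
#' @param invaders Vector of competing rates (r2 values).
#' @inheritParams classify_pair
#' @param ... Passed to [classify_pair()].
#' @return A data.frame with columns `r1`, `r2`, `classification`,
#'   `leading_eigenvalue_modulus`, `converged`.
#' @export
invasion_column <- function(resident, invaders, regime, R = 0.5, ...) {
  rows <- lapply(invaders, function(rv) {
    o <- classify_pair(resident, rv, regime, R = R, ...)
    data.frame(r1 = o$r1, r2 = o$r2, classification = o$classification,
               leading_eigenvalue_modulus = o$leading_eigenvalue_modulus,
               converged = o$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full pairwise competition grid
#'
#' Classifies every unordered pair of rates on a grid (each direction is
#' examined inside [classify_pair()]).
#'
#' @param rates Rate grid (two-digit precision is the conventional
#'   resolution).
#' @inheritParams classify_pair
#' @param ... Passed to [classify_pair()].
#' @return A data.frame as in [invasion_column()], one row per unordered
#'   pair with `r1 < r2`.
#' @export
invasion_grid <- function(rates, regime, R = 0.5, ...) {
  rates <- sort(unique(rates))
  rows <- list()
  for (i in seq_along(rates)) {
    for (j in seq_along(rates)) {
      if (j <= i) next
      o <- classify_pair(rates[i], rates[j], regime, R = R, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        r1 = o$r1, r2 = o$r2, classification = o$classification,
        leading_eigenvalue_modulus = o$leading_eigenvalue_modulus,
        converged = o$converged, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Evolutionarily stable recombination rate on a grid
#'
#' A rate is evolutionarily stable (ES) on the grid when no alternative
#' grid rate invades and displaces it. The certificate lists every pairwise
#' outcome used for the decision; rates all of whose pairings lose the
#' plasticity-target polymorphism are excluded from candidacy (no genomic
#' storage, hence no selection on recombination).
#'
#' @param regime A [seasonal_regime()].
#' @param R Modifier-to-sequence rate.
#' @param rate_grid Candidate rates.
#' @param pairs Optional precomputed [invasion_grid()] result for
#'   `rate_grid` (saves recomputation).
#' @param ... Passed to [classify_pair()].
#' @return An object of class `es_certificate`: list with `es_rate` (vector;
#'   empty when no rate qualifies, with all candidates displaced or no
#'   polymorphism anywhere), `certificate` (the pairwise table), and
#'   `rate_grid`.
#' @export
find_es_rate <- function(regime, R = 0.5, rate_grid = seq(0, 0.5, by = 0.01),
                         pairs = NULL, ...) {
  rates <- sort(unique(rate_grid))
  if (length(rates) == 1L) {
    ## degenerate grid: the lone rate is unbeatable by construction; it is
    ## reported as ES provided it sustains the storage polymorphism at all
    o <- classify_pair(rates, rates, regime, R = R, ...)
    es <- if (o$classification == "no_polymorphism") numeric(0) else rates
    out <- list(es_rate = es,
                certificate = data.frame(r1 = rates, r2 = rates,
                                         classification = o$classification,
                                         stringsAsFactors = FALSE),
                rate_grid = rates, regime = regime, R = R)
    class(out) <- "es_certificate"
    return(out)
  }
  if (is.null(pairs)) pairs <- invasion_grid(rates, regime, R = R, ...)
  displaced <- rep(FALSE, length(rates))
  polymorphic <- rep(FALSE, length(rates))
  for (k in seq_len(nrow(pairs))) {
    i <- which.min(abs(rates - pairs$r1[k]))
    j <- which.min(abs(rates - pairs$r2[k]))
    cls <- pairs$classification[k]
    if (cls == "invader_fixes") displaced[i] <- TRUE
    if (cls == "resident_fixes") displaced[j] <- TRUE
    if (cls %in% c("invader_fixes", "resident_fixes", "coexistence")) {
      polymorphic[i] <- TRUE; polymorphic[j] <- TRUE
    }
  }
  es <- rates[!displaced & polymorphic]
  out <- list(es_rate = es, certificate = pairs, rate_grid = rates,
              regime = regime, R = R)
  class(out) <- "es_certificate"
  out
}

#' @export
print.es_certificate <- function(x, ...) {
  if (length(x$es_rate) == 0L) {
    cat("No evolutionarily stable recombination rate on the grid",
        "(no rate both sustains polymorphism and resists displacement).\n")
  } else {
    cat("ES recombination rate(s) on the grid:",
        paste(format(x$es_rate), collapse = ", "), "\n")
  }
  tab <- table(x$certificate$classification)
  cat("Pairwise outcomes:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
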