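#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Haplotype index convention (0-based), fixed project-wide:
// 0 r1ma, 1 r1Ma, 2 r1md, 3 r1Md, 4 r2ma, 5 r2Ma, 6 r2md, 7 r2Md
// index = 4*(rec-1) + 2*target + plasticity

static inline void fitness8(double s, double p, double* w) {
  const double sb = s * (1.0 - p);
  w[0] = w[4] = 1.0 - s;
  w[1] = w[5] = 1.0 - sb;
  w[2] = w[6] = 1.0 + s;
  w[3] = w[7] = 1.0 + sb;
}

// One deterministic generation: selection at time t, then recombination via
// the quadratic-form tensor Tm (64 x 8, row index i + 8*j, 0-based parents i,j).
static void det_step(double* x, const double* Tm, double s, double p) {
  double w[8], y[8], z[8];
  fitness8(s, p, w);
  double W = 0.0;
  for (int g = 0; g < 8; ++g) W += x[g] * w[g];
  for (int g = 0; g < 8; ++g) y[g] = x[g] * w[g] / W;
  double o[64];
  for (int j = 0; j < 8; ++j)
    for (int i = 0; i < 8; ++i) o[i + 8 * j] = y[i] * y[j];
  for (int g = 0; g < 8; ++g) {
    const double* col = Tm + 64 * g;
    double acc = 0.0;
    for (int k = 0; k < 64; ++k) acc += col[k] * o[k];
    z[g] = acc;
  }
  double tot = 0.0;
  for (int g = 0; g < 8; ++g) tot += z[g];
  for (int g = 0; g < 8; ++g) x[g] = z[g] / tot;
}

// [[Rcpp::export]]
List det_evolve_cpp(NumericVector x0, NumericMatrix Tmat, double smax, int C,
                    double p, int phase, int max_gen, int min_gen,
                    double fix_tol, double cycle_tol, bool record_traj) {
  double x[8];
  for (int g = 0; g < 8; ++g) x[g] = x0[g];
  const double* Tm = &Tmat(0, 0); // 64 x 8, column-major: Tm[k + 64*g]

  const int nbuf = 2 * C;
  std::vector<double> buf((size_t)nbuf * 8, 0.0);
  NumericMatrix traj;
  if (record_traj) traj = NumericMatrix(max_gen + 1, 8);

  int status = 2; // 0 cycle-converged, 1 plasticity/target fixation, 2 max_gen
  int newest = max_gen - 1; // generation label of the last stored state
  int gens_run = max_gen;

  for (int gen = 0; gen < max_gen; ++gen) {
    int slot = gen % nbuf;
    for (int g = 0; g < 8; ++g) buf[(size_t)slot * 8 + g] = x[g];
    if (record_traj)
      for (int g = 0; g < 8; ++g) traj(gen, g) = x[g];

    // cycle-repetition check: states of the last two whole environmental
    // cycles agree coordinate-wise within cycle_tol
    if (gen >= min_gen && gen >= nbuf - 1 && (gen % C) == (C - 1)) {
      double md = 0.0;
      for (int k = 0; k < C; ++k) {
        int s1 = (gen - 2 * C + 1 + k) % nbuf;
        int s2 = (gen - C + 1 + k) % nbuf;
        for (int g = 0; g < 8; ++g) {
          double d = std::fabs(buf[(size_t)s1 * 8 + g] - buf[(size_t)s2 * 8 + g]);
          if (d > md) md = d;
        }
      }
      if (md < cycle_tol) { status = 0; newest = gen; gens_run = gen; break; }
    }

    double s = smax * std::sin(2.0 * M_PI * ((double)(gen + phase)) / (double)C);
    det_step(x, Tm, s, p);

    double fM = x[1] + x[3] + x[5] + x[7];
    double fd = x[2] + x[3] + x[6] + x[7];
    if (std::min(fM, 1.0 - fM) < fix_tol || std::min(fd, 1.0 - fd) < fix_tol) {
      status = 1; newest = gen; gens_run = gen + 1; break;
    }
  }

  // last (up to) C stored states, oldest first, with generation labels so the
  // caller can align phases
  int avail = std::min(newest + 1, C);
  int oldest = newest - avail + 1;
  NumericMatrix orbit(avail, 8);
  IntegerVector orbit_t(avail);
  for (int k = 0; k < avail; ++k) {
    int t = oldest + k;
    int slot = t % nbuf;
    orbit_t[k] = t;
    for (int g = 0; g < 8; ++g) orbit(k, g) = buf[(size_t)slot * 8 + g];
  }

  NumericVector xf(8);
  for (int g = 0; g < 8; ++g) xf[g] = x[g];

  List out = List::create(
      _["status"] = status, _["generations"] = gens_run, _["orbit"] = orbit,
      _["orbit_t"] = orbit_t, _["x_final"] = xf);
  if (record_traj) {
    int nrow = std::min(newest + 1, max_gen);
    NumericMatrix tr(nrow, 8);
    for (int t = 0; t < nrow; ++t)
      for (int g = 0; g < 8; ++g) tr(t, g) = traj(t, g);
    out["trajectory"] = tr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Individual-based Wright-Fisher engine.
//
// pop: N x L matrix, loci in physical order. locus_type: 0 = recombination
// modifier (continuous allele in [0, 0.5]), 1 = plasticity (0 = m, 1 = M),
// 2 = target (0 = a, 1 = d). interval_ctrl[k] (length L-1): 0-based column of
// the modifier controlling interval k, or -1 for a fixed rate
// interval_rate[k]. Heterozygous modifier pairings recombine at the additive
// mean of the two parental alleles.

static inline void mutate_one(NumericMatrix& pop, int i, int l,
                              const IntegerVector& locus_type) {
  if (locus_type[l] == 0) pop(i, l) = 0.5 * unif_rand();
  else pop(i, l) = 1.0 - pop(i, l);
}

// [[Rcpp::export]]
List ibm_simulate_cpp(NumericMatrix init_pop, IntegerVector locus_type,
                      IntegerVector interval_ctrl, NumericVector interval_rate,
                      NumericVector smax_target, int C, double p, int phase,
                      NumericVector mut_prob, bool mut_per_copy,
                      int n_burn, int n_record, int record_locus,
                      int fitness_mode, int trace_every) {
  const int N = init_pop.nrow(), L = init_pop.ncol();
  NumericMatrix pop = clone(init_pop);
  NumericMatrix newpop(N, L);
  std::vector<double> w((size_t)N);

  std::vector<int> tcols;
  int pcol = -1;
  for (int l = 0; l < L; ++l) {
    if (locus_type[l] == 2) tcols.push_back(l);
    else if (locus_type[l] == 1) pcol = l;
  }
  const int ntar = (int)tcols.size();

  NumericVector hist(51);
  double coseg_sum = 0.0; long coseg_n = 0;
  double ld_sum = 0.0; long ld_n = 0;
  std::vector<double> maf_sum(ntar > 0 ? ntar : 1, 0.0); long maf_n = 0;
  long mut_events = 0;
  const int total = n_burn + n_record;
  int ntrace = (trace_every > 0) ? (total / trace_every + 1) : 0;
  NumericMatrix trace(ntrace, 2 + ntar); // mean modifier allele, freq M, freq d per target
  int trace_row = 0;

  for (int gen = 0; gen < total; ++gen) {
    // mutation: one Bernoulli(Nmu) event per locus hitting one random copy,
    // or an optional per-copy rate Nmu/N
    if (mut_per_copy) {
      for (int l = 0; l < L; ++l) {
        double mu = mut_prob[l] / (double)N;
        if (mu <= 0) continue;
        for (int i = 0; i < N; ++i)
          if (unif_rand() < mu) { mutate_one(pop, i, l, locus_type); ++mut_events; }
      }
    } else {
      for (int l = 0; l < L; ++l) {
        if (mut_prob[l] > 0 && unif_rand() < mut_prob[l]) {
          int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
          mutate_one(pop, i, l, locus_type);
          ++mut_events;
        }
      }
    }

    // fitness of each individual at time t = gen + phase
    const double sinv = std::sin(2.0 * M_PI * ((double)(gen + phase)) / (double)C);
    double wmax = 0.0;
    for (int i = 0; i < N; ++i) {
      const double buff = (pcol >= 0 && pop(i, pcol) > 0.5) ? (1.0 - p) : 1.0;
      double wi;
      if (fitness_mode == 0) {
        wi = 1.0;
        for (int k = 0; k < ntar; ++k) {
          const double se = smax_target[k] * sinv * buff;
          wi *= (pop(i, tcols[k]) > 0.5) ? (1.0 + se) : (1.0 - se);
        }
      } else {
        wi = 1.0;
        for (int k = 0; k < ntar; ++k) {
          const double se = smax_target[k] * sinv * buff;
          wi += (pop(i, tcols[k]) > 0.5) ? se : -se;
        }
        if (wi < 0.0) wi = 0.0;
      }
      w[i] = wi;
      if (wi > wmax) wmax = wi;
    }

    // reproduction: rejection-sample parent pairs against wmax, independent
    // crossover per interval, keep one of the two reciprocal products
    for (int i = 0; i < N; ++i) {
      int p1, p2;
      do { p1 = (int)(unif_rand() * N); if (p1 >= N) p1 = N - 1; }
      while (unif_rand() * wmax > w[p1]);
      do { p2 = (int)(unif_rand() * N); if (p2 >= N) p2 = N - 1; }
      while (unif_rand() * wmax > w[p2]);

      int cur = (unif_rand() < 0.5) ? 0 : 1;
      newpop(i, 0) = cur ? pop(p2, 0) : pop(p1, 0);
      for (int l = 1; l < L; ++l) {
        const int c = interval_ctrl[l - 1];
        const double rate = (c >= 0) ? 0.5 * (pop(p1, c) + pop(p2, c))
                                     : interval_rate[l - 1];
        if (unif_rand() < rate) cur = 1 - cur;
        newpop(i, l) = cur ? pop(p2, l) : pop(p1, l);
      }
    }
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l) pop(i, l) = newpop(i, l);

    // recording window
    if (gen >= n_burn) {
      if (record_locus >= 0) {
        for (int i = 0; i < N; ++i) {
          int b = (int)std::floor(pop(i, record_locus) * 100.0 + 0.5);
          if (b < 0) b = 0; if (b > 50) b = 50;
          hist[b] += 1.0;
        }
      }
      if (ntar >= 1) {
        for (int k = 0; k < ntar; ++k) {
          double f = 0.0;
          for (int i = 0; i < N; ++i) f += pop(i, tcols[k]);
          f /= N;
          maf_sum[k] += std::min(f, 1.0 - f);
        }
        ++maf_n;
      }
      if (ntar >= 2) {
        int aligned = 0;
        double f1 = 0, f2 = 0, f12 = 0;
        for (int i = 0; i < N; ++i) {
          bool all0 = true, all1 = true;
          for (int k = 0; k < ntar; ++k) {
            if (pop(i, tcols[k]) > 0.5) all0 = false; else all1 = false;
          }
          if (all0 || all1) ++aligned;
          const bool d1 = pop(i, tcols[0]) > 0.5, d2 = pop(i, tcols[1]) > 0.5;
          if (d1) f1 += 1.0;
          if (d2) f2 += 1.0;
          if (d1 && d2) f12 += 1.0;
        }
        coseg_sum += (double)aligned / N; ++coseg_n;
        ld_sum += f12 / N - (f1 / N) * (f2 / N); ++ld_n;
      }
    }

    if (trace_every > 0 && (gen % trace_every) == 0 && trace_row < ntrace) {
      double m = 0.0;
      if (record_locus >= 0)
        for (int i = 0; i < N; ++i) m += pop(i, record_locus);
      trace(trace_row, 0) = m / N;
      double fM = 0.0;
      if (pcol >= 0) { for (int i = 0; i < N; ++i) fM += pop(i, pcol); }
      trace(trace_row, 1) = fM / N;
      for (int k = 0; k < ntar; ++k) {
        double fd = 0.0;
        for (int i = 0; i < N; ++i) fd += pop(i, tcols[k]);
        trace(trace_row, 2 + k) = fd / N;
      }
      ++trace_row;
    }
  }

  NumericVector maf_mean(ntar);
  for (int k = 0; k < ntar; ++k)
    maf_mean[k] = (maf_n > 0) ? maf_sum[k] / maf_n : NA_REAL;

  return List::create(
      _["final_pop"] = pop, _["hist"] = hist,
      _["target_maf_mean"] = maf_mean,
      _["coseg_mean"] = (coseg_n > 0) ? coseg_sum / coseg_n : NA_REAL,
      _["target_ld_mean"] = (ld_n > 0) ? ld_sum / ld_n : NA_REAL,
      _["mutation_events"] = (double)mut_events,
      _["trace"] = trace, _["trace_rows"] = trace_row);
}
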