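// Core simulation engine: colony work phases and the generation loop.
//
// Genotype layout (8 loci, fixed order everywhere):
//   0 theta1, 1 theta2 | 2 w11, 3 w21, 4 w12, 5 w22, 6 u1, 7 u2
// w_ji connects stimulus input j to output neuron i; u_i is the self-feedback
// weight of neuron i (identically 0 under the feedforward architecture).
// Threshold loci (0-1) and weight loci (2-7) form the two linkage groups.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64; standard normals via the
// Marsaglia-Tsang ziggurat (128 layers). One stream per exported call; the
// whole run is reproducible from one seed.
// ---------------------------------------------------------------------------
namespace zig {
static const double R = 3.442619855899;
static uint32_t kn[128];
static double wn[128], fn[128];
static bool ready = false;

static void init() {
  const double m1 = 2147483648.0;
  double dn = R, tn = R, vn = 9.91256303526217e-3;
  const double q = vn / std::exp(-0.5 * dn * dn);
  kn[0] = (uint32_t)((dn / q) * m1);
  kn[1] = 0;
  wn[0] = q / m1;
  wn[127] = dn / m1;
  fn[0] = 1.0;
  fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; --i) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    fn[i] = std::exp(-0.5 * dn * dn);
    wn[i] = dn / m1;
  }
  ready = true;
}
}  // namespace zig

struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    if (!zig::ready) zig::init();
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  inline uint32_t next32() { return (uint32_t)(next() >> 32); }

  // Lemire multiply-shift; bias O(n / 2^32) is negligible at simulation sizes.
  inline uint32_t bounded(uint32_t n) {
    const uint64_t m = (uint64_t)next32() * (uint64_t)n;
    return (uint32_t)(m >> 32);
  }

  double normal() {
    for (;;) {
      const int32_t hz = (int32_t)next32();
      const uint32_t iz = (uint32_t)hz & 127u;
      const uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < zig::kn[iz]) return hz * zig::wn[iz];
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(unif()) / zig::R;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? zig::R + x : -zig::R - x;
      }
      const double x = hz * zig::wn[iz];
      if (zig::fn[iz] + unif() * (zig::fn[iz - 1] - zig::fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }

  inline void normal2(double &z1, double &z2) {
    z1 = normal();
    z2 = normal();
  }
};

// ---------------------------------------------------------------------------
// Genome primitives
// ---------------------------------------------------------------------------
static const int NL = 8;  // loci per genotype

// Two linkage groups segregate independently. Per group: with prob 1-r the
// whole block comes from one uniformly chosen parent, with prob r every locus
// picks its parent independently.
static inline void inherit_geno(const double *m, const double *f, double r,
                                Xoshiro &rng, double *child) {
  if (rng.unif() >= r) {
    const double *p = (rng.unif() < 0.5) ? m : f;
    child[0] = p[0];
    child[1] = p[1];
  } else {
    child[0] = (rng.unif() < 0.5 ? m : f)[0];
    child[1] = (rng.unif() < 0.5 ? m : f)[1];
  }
  if (rng.unif() >= r) {
    const double *p = (rng.unif() < 0.5) ? m : f;
    for (int l = 2; l < NL; ++l) child[l] = p[l];
  } else {
    for (int l = 2; l < NL; ++l) child[l] = (rng.unif() < 0.5 ? m : f)[l];
  }
}

// Per-locus Gaussian perturbation with prob mu; thresholds clamped at 0.
// Feedforward genotypes mutate only their 6 expressed loci.
static inline void mutate_geno(double *g, double mu, double sigma_m,
                               bool recurrent, Xoshiro &rng) {
  const int L = recurrent ? 8 : 6;
  for (int l = 0; l < L; ++l)
    if (rng.unif() < mu) g[l] += sigma_m * rng.normal();
  if (g[0] < 0.0) g[0] = 0.0;
  if (g[1] < 0.0) g[1] = 0.0;
}

// ---------------------------------------------------------------------------
// Work phase
// ---------------------------------------------------------------------------
struct Recorder {
  // per-step history
  std::vector<double> h_s1, h_s2;
  std::vector<int> h_n1, h_n2, h_idle, h_pen;
  // per-assessment trace (small runs only)
  bool trace;
  std::vector<int> t_step, t_slot, t_worker, t_pen, t_action, t_coin;
  std::vector<double> t_st1, t_st2, t_E1, t_E2, t_s1a, t_s2a;
  std::vector<int> order_log;  // T x N, row-major by step

  Recorder() : trace(false) {}
};

struct WorkerTallies {
  std::vector<int> a1, a2, stays, switches;
  void init(int N) {
    a1.assign(N, 0);
    a2.assign(N, 0);
    stays.assign(N, 0);
    switches.assign(N, 0);
  }
};

// Simulate one work phase of T steps for N workers with genotype matrix
// geno (8 x N, column per worker). Tallies must be initialized by the caller.
static void run_phase(const double *geno, int N, int T, int c, double delta,
                      double alpha, double s1_0, double s2_0, double noise_sd,
                      bool recurrent, Xoshiro &rng, WorkerTallies &tal,
                      Recorder *rec) {
  double s1 = s1_0, s2 = s2_0;
  std::vector<int> order(N), last(N, 0), pen(N, 0);
  std::vector<double> pE1(N, 0.0), pE2(N, 0.0);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int t = 0; t < T; ++t) {
    // stimuli build up first, then workers are assessed sequentially
    s1 += delta;
    s2 += delta;
    // fresh uniform permutation (Fisher-Yates)
    for (int k = N - 1; k > 0; --k) {
      const int j = (int)rng.bounded((uint32_t)(k + 1));
      const int tmp = order[k];
      order[k] = order[j];
      order[j] = tmp;
    }
    int n1 = 0, n2 = 0, nidle = 0, npen = 0;
    if (rec && rec->trace)
      for (int i = 0; i < N; ++i) rec->order_log.push_back(order[i] + 1);

    for (int slot = 0; slot < N; ++slot) {
      const int w = order[slot];
      const double *g = geno + NL * w;
      int action = -1, coin = 0;  // action -1 = penalized, 0 = idle
      double st1 = NA_REAL, st2 = NA_REAL, E1 = NA_REAL, E2 = NA_REAL;

      if (pen[w] > 0) {
        // enforced inactivity after a task switch; prev_E held frozen
        --pen[w];
        ++npen;
      } else {
        double z1, z2;
        rng.normal2(z1, z2);
        st1 = s1 + noise_sd * z1;
        st2 = s2 + noise_sd * z2;
        E1 = g[2] * st1 + g[3] * st2;
        E2 = g[4] * st1 + g[5] * st2;
        if (recurrent) {
          E1 += g[6] * pE1[w];
          E2 += g[7] * pE2[w];
        }
        pE1[w] = E1;  // post-feedback energy carried to the next assessment
        pE2[w] = E2;
        const bool act1 = E1 > g[0], act2 = E2 > g[1];
        if (act1 && act2) {
          action = (rng.unif() < 0.5) ? 1 : 2;
          coin = action;
        } else if (act1) {
          action = 1;
        } else if (act2) {
          action = 2;
        } else {
          action = 0;
        }

        if (action == 0) {
          ++nidle;
        } else if (last[w] == action || last[w] == 0) {
          if (last[w] == action) ++tal.stays[w];
          last[w] = action;
          if (action == 1) {
            ++tal.a1[w];
            ++n1;
            s1 -= alpha;
            if (s1 < 0.0) s1 = 0.0;
          } else {
            ++tal.a2[w];
            ++n2;
            s2 -= alpha;
            if (s2 < 0.0) s2 = 0.0;
          }
        } else {
          // task switch: recorded at decision time
          ++tal.switches[w];
          last[w] = action;
          if (c == 0) {
            // no cost: the switch completes as a normal act in this step
            if (action == 1) {
              ++tal.a1[w];
              ++n1;
              s1 -= alpha;
              if (s1 < 0.0) s1 = 0.0;
            } else {
              ++tal.a2[w];
              ++n2;
              s2 -= alpha;
              if (s2 < 0.0) s2 = 0.0;
            }
          } else {
            pen[w] = c;  // decision step itself is act-free
            ++npen;
          }
        }
      }

      if (rec && rec->trace) {
        rec->t_step.push_back(t + 1);
        rec->t_slot.push_back(slot + 1);
        rec->t_worker.push_back(w + 1);
        rec->t_pen.push_back(action == -1 ? 1 : 0);
        rec->t_action.push_back(action);
        rec->t_coin.push_back(coin);
        rec->t_st1.push_back(st1);
        rec->t_st2.push_back(st2);
        rec->t_E1.push_back(E1);
        rec->t_E2.push_back(E2);
        rec->t_s1a.push_back(s1);
        rec->t_s2a.push_back(s2);
      }
    }

    if (rec) {
      rec->h_s1.push_back(s1);
      rec->h_s2.push_back(s2);
      rec->h_n1.push_back(n1);
      rec->h_n2.push_back(n2);
      rec->h_idle.push_back(nidle);
      rec->h_pen.push_back(npen);
    }
  }
}

// Colony summary from per-worker tallies: acts, work proportion p1,
// specialization D = Cbar / (q1^2 + q2^2) - 1 over workers with at least one
// consecutive pair of work decisions, fitness F = A1^beta * A2^(1-beta).
static void colony_metrics(const WorkerTallies &tal, int N, double beta,
                           double fmax, double *out /* A1 A2 p1 D F Frel */) {
  long A1 = 0, A2 = 0;
  double csum = 0.0;
  int nqual = 0;
  for (int w = 0; w < N; ++w) {
    A1 += tal.a1[w];
    A2 += tal.a2[w];
    const int ntr = tal.stays[w] + tal.switches[w];
    if (ntr > 0) {
      csum += (double)tal.stays[w] / (double)ntr;
      ++nqual;
    }
  }
  const double tot = (double)A1 + (double)A2;
  double p1 = NA_REAL, D = NA_REAL, F = 0.0;
  if (tot > 0) p1 = (double)A1 / tot;
  if (nqual > 0 && tot > 0) {
    const double q1 = (double)A1 / tot;
    const double pch = q1 * q1 + (1.0 - q1) * (1.0 - q1);
    D = (csum / nqual) / pch - 1.0;
  }
  if (A1 > 0 && A2 > 0)
    F = std::pow((double)A1, beta) * std::pow((double)A2, 1.0 - beta);
  out[0] = (double)A1;
  out[1] = (double)A2;
  out[2] = p1;
  out[3] = D;
  out[4] = F;
  out[5] = F / fmax;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

static List phase_result(const WorkerTallies &tal, int N, double beta,
                         double fmax, Recorder *rec) {
  IntegerMatrix workers(N, 4);
  colnames(workers) =
      CharacterVector::create("acts1", "acts2", "stays", "switches");
  for (int w = 0; w < N; ++w) {
    workers(w, 0) = tal.a1[w];
    workers(w, 1) = tal.a2[w];
    workers(w, 2) = tal.stays[w];
    workers(w, 3) = tal.switches[w];
  }
  double m[6];
  colony_metrics(tal, N, beta, fmax, m);
  List out = List::create(
      _["A1"] = m[0], _["A2"] = m[1], _["p1"] = m[2], _["D"] = m[3],
      _["F"] = m[4], _["F_rel"] = m[5], _["workers"] = workers);
  if (rec) {
    const int T = (int)rec->h_s1.size();
    NumericMatrix hist(T, 7);
    colnames(hist) = CharacterVector::create("step", "s1", "s2", "n_task1",
                                             "n_task2", "n_idle", "n_penalty");
    for (int t = 0; t < T; ++t) {
      hist(t, 0) = t + 1;
      hist(t, 1) = rec->h_s1[t];
      hist(t, 2) = rec->h_s2[t];
      hist(t, 3) = rec->h_n1[t];
      hist(t, 4) = rec->h_n2[t];
      hist(t, 5) = rec->h_idle[t];
      hist(t, 6) = rec->h_pen[t];
    }
    out["history"] = hist;
    if (rec->trace) {
      const int n = (int)rec->t_step.size();
      NumericMatrix tr(n, 12);
      colnames(tr) = CharacterVector::create(
          "step", "slot", "worker", "penalized", "s1_tilde", "s2_tilde", "E1",
          "E2", "action", "coin", "s1_after", "s2_after");
      for (int i = 0; i < n; ++i) {
        tr(i, 0) = rec->t_step[i];
        tr(i, 1) = rec->t_slot[i];
        tr(i, 2) = rec->t_worker[i];
        tr(i, 3) = rec->t_pen[i];
        tr(i, 4) = rec->t_st1[i];
        tr(i, 5) = rec->t_st2[i];
        tr(i, 6) = rec->t_E1[i];
        tr(i, 7) = rec->t_E2[i];
        tr(i, 8) = rec->t_action[i] == -1 ? NA_REAL : rec->t_action[i];
        tr(i, 9) = rec->t_coin[i] == 0 ? NA_REAL : rec->t_coin[i];
        tr(i, 10) = rec->t_s1a[i];
        tr(i, 11) = rec->t_s2a[i];
      }
      const int N2 = (int)(rec->order_log.size() / rec->h_s1.size());
      IntegerMatrix om((int)rec->h_s1.size(), N2);
      for (int t = 0, k = 0; t < (int)rec->h_s1.size(); ++t)
        for (int i = 0; i < N2; ++i, ++k) om(t, i) = rec->order_log[k];
      out["trace"] = tr;
      out["order"] = om;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_work_phase(NumericMatrix genotypes, int T, int c, double delta,
                    double alpha, double s1_0, double s2_0, double noise_sd,
                    bool recurrent, double beta, int seed,
                    bool history = false, bool trace = false) {
  if (genotypes.nrow() != NL) stop("genotypes must have 8 rows (loci)");
  const int N = genotypes.ncol();
  Xoshiro rng((uint64_t)(uint32_t)seed);
  WorkerTallies tal;
  tal.init(N);
  Recorder rec;
  rec.trace = trace;
  Recorder *rp = (history || trace) ? &rec : 0;
  if (trace && (double)N * (double)T > 2e5)
    stop("trace recording is limited to N*T <= 200000");
  const double fmax = (double)N * (double)T * std::pow(beta, beta) *
                      std::pow(1.0 - beta, 1.0 - beta);
  run_phase(REAL(genotypes), N, T, c, delta, alpha, s1_0, s2_0, noise_sd,
            recurrent, rng, tal, rp);
  return phase_result(tal, N, beta, fmax, rp);
}

// [[Rcpp::export]]
NumericMatrix cpp_make_workers(NumericVector mother, NumericVector father,
                               int N, double r, double mu, double sigma_m,
                               bool recurrent, int seed) {
  if (mother.size() != NL || father.size() != NL)
    stop("parent genotypes must have 8 loci");
  Xoshiro rng((uint64_t)(uint32_t)seed);
  NumericMatrix out(NL, N);
  for (int k = 0; k < N; ++k) {
    inherit_geno(REAL(mother), REAL(father), r, rng, &out(0, k));
    mutate_geno(&out(0, k), mu, sigma_m, recurrent, rng);
  }
  return out;
}

// Workers are built and the phase run from a single stream, mirroring one
// colony-generation of the evolution loop.
// [[Rcpp::export]]
List cpp_run_colony(NumericVector mother, NumericVector father, int N, int T,
                    int c, double delta, double alpha, double s1_0,
                    double s2_0, double noise_sd, bool recurrent, double beta,
                    double r, double mu, double sigma_m, int seed,
                    bool history = false, bool trace = false) {
  if (mother.size() != NL || father.size() != NL)
    stop("parent genotypes must have 8 loci");
  Xoshiro rng((uint64_t)(uint32_t)seed);
  std::vector<double> geno((size_t)NL * N);
  for (int k = 0; k < N; ++k) {
    inherit_geno(REAL(mother), REAL(father), r, rng, &geno[(size_t)NL * k]);
    mutate_geno(&geno[(size_t)NL * k], mu, sigma_m, recurrent, rng);
  }
  WorkerTallies tal;
  tal.init(N);
  Recorder rec;
  rec.trace = trace;
  Recorder *rp = (history || trace) ? &rec : 0;
  if (trace && (double)N * (double)T > 2e5)
    stop("trace recording is limited to N*T <= 200000");
  const double fmax = (double)N * (double)T * std::pow(beta, beta) *
                      std::pow(1.0 - beta, 1.0 - beta);
  run_phase(geno.data(), N, T, c, delta, alpha, s1_0, s2_0, noise_sd,
            recurrent, rng, tal, rp);
  List out = phase_result(tal, N, beta, fmax, rp);
  NumericMatrix gm(NL, N);
  std::copy(geno.begin(), geno.end(), gm.begin());
  out["genotypes"] = gm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_colony_metrics(IntegerVector a1, IntegerVector a2,
                                 IntegerVector stays, IntegerVector switches,
                                 double beta, double fmax) {
  const int N = a1.size();
  WorkerTallies tal;
  tal.init(N);
  for (int w = 0; w < N; ++w) {
    tal.a1[w] = a1[w];
    tal.a2[w] = a2[w];
    tal.stays[w] = stays[w];
    tal.switches[w] = switches[w];
  }
  double m[6];
  colony_metrics(tal, N, beta, fmax, m);
  NumericVector out = NumericVector::create(
      _["A1"] = m[0], _["A2"] = m[1], _["p1"] = m[2], _["D"] = m[3],
      _["F"] = m[4], _["F_rel"] = m[5]);
  return out;
}

// Full generation loop. mothers0/fathers0: 8 x M founder genotype matrices.
// Logs per-colony summaries every summary_every generations and parent allele
// snapshots every log_every generations (the final generation always logged).
// [[Rcpp::export]]
List cpp_run_evolution(NumericMatrix mothers0, NumericMatrix fathers0, int N,
                       int T, int G, double beta, int c, double r, double mu,
                       double sigma_m, double delta, double alpha, double s1_0,
                       double s2_0, double noise_sd, bool recurrent,
                       int summary_every, int log_every, int seed) {
  if (mothers0.nrow() != NL || fathers0.nrow() != NL)
    stop("parent matrices must have 8 rows (loci)");
  const int M = mothers0.ncol();
  if (fathers0.ncol() != M) stop("mothers and fathers must match in number");
  Xoshiro rng((uint64_t)(uint32_t)seed);

  const double fmax = (double)N * (double)T * std::pow(beta, beta) *
                      std::pow(1.0 - beta, 1.0 - beta);

  int nsum = 0, nlog = 0;
  for (int g = 0; g < G; ++g) {
    if (g % summary_every == 0 || g == G - 1) ++nsum;
    if (g % log_every == 0 || g == G - 1) ++nlog;
  }
  NumericMatrix summary(nsum * M, 8);
  colnames(summary) = CharacterVector::create("generation", "colony", "A1",
                                              "A2", "p1", "D", "F", "F_rel");
  NumericMatrix alleles(nlog * M, 18);
  {
    CharacterVector cn(18);
    cn[0] = "generation";
    cn[1] = "colony";
    const char *loci[8] = {"theta1", "theta2", "w11", "w21",
                           "w12",    "w22",    "u1",  "u2"};
    for (int l = 0; l < 8; ++l) {
      cn[2 + l] = std::string("mother_") + loci[l];
      cn[10 + l] = std::string("father_") + loci[l];
    }
    colnames(alleles) = cn;
  }

  std::vector<double> mom((size_t)NL * M), dad((size_t)NL * M);
  std::copy(mothers0.begin(), mothers0.end(), mom.begin());
  std::copy(fathers0.begin(), fathers0.end(), dad.begin());
  std::vector<double> sex((size_t)NL * 2 * M);
  std::vector<double> mom2((size_t)NL * M), dad2((size_t)NL * M);
  std::vector<double> geno((size_t)NL * N);
  std::vector<double> fit(M), cum(M);
  std::vector<int> perm(2 * M);
  WorkerTallies tal;

  int srow = 0, arow = 0;
  bool extinct = false;
  int extinct_gen = -1;

  for (int g = 0; g < G; ++g) {
    const bool do_sum = (g % summary_every == 0) || g == G - 1;
    const bool do_log = (g % log_every == 0) || g == G - 1;
    for (int col = 0; col < M; ++col) {
      const double *pm = &mom[(size_t)NL * col];
      const double *pf = &dad[(size_t)NL * col];
      for (int k = 0; k < N; ++k) {
        inherit_geno(pm, pf, r, rng, &geno[(size_t)NL * k]);
        mutate_geno(&geno[(size_t)NL * k], mu, sigma_m, recurrent, rng);
      }
      tal.init(N);
      run_phase(geno.data(), N, T, c, delta, alpha, s1_0, s2_0, noise_sd,
                recurrent, rng, tal, 0);
      double m[6];
      colony_metrics(tal, N, beta, fmax, m);
      fit[col] = m[4];
      if (do_sum) {
        summary(srow, 0) = g + 1;
        summary(srow, 1) = col + 1;
        for (int i = 0; i < 6; ++i) summary(srow, 2 + i) = m[i];
        ++srow;
      }
      if (do_log) {
        alleles(arow, 0) = g + 1;
        alleles(arow, 1) = col + 1;
        for (int l = 0; l < 8; ++l) {
          alleles(arow, 2 + l) = pm[l];
          alleles(arow, 10 + l) = pf[l];
        }
        ++arow;
      }
    }
    if (g % 50 == 0) Rcpp::checkUserInterrupt();

    // fitness-proportional production of 2M sexuals, random pairing
    double tot = 0.0;
    for (int col = 0; col < M; ++col) {
      tot += fit[col];
      cum[col] = tot;
    }
    if (tot <= 0.0) {
      extinct = true;
      extinct_gen = g + 1;
      break;
    }
    if (g == G - 1) break;  // no reproduction after the last logged phase
    for (int sx = 0; sx < 2 * M; ++sx) {
      const double u = rng.unif() * tot;
      int lo = 0, hi = M - 1;
      while (lo < hi) {
        const int mid = (lo + hi) / 2;
        if (cum[mid] > u)
          hi = mid;
        else
          lo = mid + 1;
      }
      inherit_geno(&mom[(size_t)NL * lo], &dad[(size_t)NL * lo], r, rng,
                   &sex[(size_t)NL * sx]);
      mutate_geno(&sex[(size_t)NL * sx], mu, sigma_m, recurrent, rng);
    }
    for (int i = 0; i < 2 * M; ++i) perm[i] = i;
    for (int k = 2 * M - 1; k > 0; --k) {
      const int j = (int)rng.bounded((uint32_t)(k + 1));
      const int tmp = perm[k];
      perm[k] = perm[j];
      perm[j] = tmp;
    }
    for (int col = 0; col < M; ++col) {
      std::copy(&sex[(size_t)NL * perm[2 * col]],
                &sex[(size_t)NL * perm[2 * col]] + NL, &mom2[(size_t)NL * col]);
      std::copy(&sex[(size_t)NL * perm[2 * col + 1]],
                &sex[(size_t)NL * perm[2 * col + 1]] + NL,
                &dad2[(size_t)NL * col]);
    }
    mom.swap(mom2);
    dad.swap(dad2);
  }

  NumericMatrix fm(NL, M), ff(NL, M);
  std::copy(mom.begin(), mom.end(), fm.begin());
  std::copy(dad.begin(), dad.end(), ff.begin());

  return List::create(
      _["summary"] = summary, _["alleles"] = alleles, _["n_summary"] = srow,
      _["n_alleles"] = arow, _["extinct"] = extinct,
      _["extinct_generation"] = extinct_gen, _["final_mothers"] = fm,
      _["final_fathers"] = ff);
}
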