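#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Forward-time individual-based simulator of two adjacent demes.
// Genotypes: IntegerMatrix K x (2*L); locus l (0-based) occupies columns
// 2l and 2l+1; allele states in 1..n_alleles. All evolutionary randomness
// comes from R's RNG (unif_rand), so set.seed() in R gives bit-identical
// trajectories. Sampling randomness uses a private xorshift stream so that
// recording samples never perturbs the evolutionary trajectory.

static inline int runif_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// private RNG for non-perturbing sampling
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int uniform_int(int n) { return (int)(next() % (uint64_t)n); }
  double uniform_double() { return (double)(next() >> 11) / 9007199254740992.0; }
};

// [[Rcpp::export]]
IntegerMatrix cpp_init_pop(int K, int n_loci, int n_alleles) {
  IntegerMatrix pop(K, 2 * n_loci);
  for (int j = 0; j < 2 * n_loci; ++j)
    for (int i = 0; i < K; ++i)
      pop(i, j) = 1 + runif_int(n_alleles);
  return pop;
}

struct ParentRef { const IntegerMatrix* pop; int row; };

// pool of random bits refilled 16 at a time from R's RNG, used for the
// per-locus gamete (maternal/paternal allele) choices
struct BitPool {
  uint32_t bits;
  int n;
  BitPool() : bits(0), n(0) {}
  int next() {
    if (n == 0) {
      bits = (uint32_t)(unif_rand() * 65536.0);
      if (bits > 65535u) bits = 65535u;
      n = 16;
    }
    int b = bits & 1u;
    bits >>= 1;
    --n;
    return b;
  }
};

static inline int reflect_step(int a, int n_alleles) {
  if (a == 1) return 2;
  if (a == n_alleles) return n_alleles - 1;
  return a + ((unif_rand() < 0.5) ? -1 : 1);
}

// stepwise mutation over one deme's freshly formed offspring: each of the
// 2K transmitted copies at locus l mutates independently with probability
// mu[l]. For small rates the per-copy Bernoulli scheme is realized
// equivalently (and much faster) by drawing the binomial number of mutant
// copies and placing them on a uniform without-replacement subset.
static void mutate_deme(IntegerMatrix& pop, const NumericVector& mu,
                        int n_alleles) {
  const int K = pop.nrow();
  const int L = mu.size();
  const int ncopy = 2 * K;
  std::vector<int> used;
  for (int l = 0; l < L; ++l) {
    const double ml = mu[l];
    if (ml <= 0.0) continue;
    if (ml > 0.05) {
      for (int c = 0; c < ncopy; ++c)
        if (unif_rand() < ml) {
          int i = c >> 1, col = 2 * l + (c & 1);
          pop(i, col) = reflect_step(pop(i, col), n_alleles);
        }
      continue;
    }
    int n_mut = (int)R::rbinom((double)ncopy, ml);
    used.clear();
    for (int k = 0; k < n_mut; ++k) {
      int c;
      bool dup;
      do {
        c = runif_int(ncopy);
        dup = false;
        for (size_t u = 0; u < used.size(); ++u)
          if (used[u] == c) { dup = true; break; }
      } while (dup);
      used.push_back(c);
      int i = c >> 1, col = 2 * l + (c & 1);
      pop(i, col) = reflect_step(pop(i, col), n_alleles);
    }
  }
}

static void step_core(const IntegerMatrix& pop1, const IntegerMatrix& pop2,
                      double m, const NumericVector& mu, int n_alleles,
                      IntegerMatrix& next1, IntegerMatrix& next2) {
  const int K1 = pop1.nrow(), K2 = pop2.nrow();
  const int L = mu.size();

  // migration: each individual relocates independently with probability m
  std::vector<ParentRef> res1, res2;
  res1.reserve(K1 + K2); res2.reserve(K1 + K2);
  for (int i = 0; i < K1; ++i) {
    if (m > 0.0 && unif_rand() < m) res2.push_back({&pop1, i});
    else res1.push_back({&pop1, i});
  }
  for (int i = 0; i < K2; ++i) {
    if (m > 0.0 && unif_rand() < m) res1.push_back({&pop2, i});
    else res2.push_back({&pop2, i});
  }
  if (res1.empty() || res2.empty())
    stop("empty deme: no post-migration residents to reproduce from");

  // reproduction (Wright-Fisher, selfing allowed): two parents uniform with
  // replacement among residents, one random allele per locus from each
  for (int d = 0; d < 2; ++d) {
    const std::vector<ParentRef>& res = d == 0 ? res1 : res2;
    IntegerMatrix& nxt = d == 0 ? next1 : next2;
    const int K = nxt.nrow();
    const int nres = (int)res.size();
    BitPool bp;
    for (int i = 0; i < K; ++i) {
      const ParentRef pa = res[runif_int(nres)];
      const ParentRef pb = res[runif_int(nres)];
      for (int l = 0; l < L; ++l) {
        nxt(i, 2 * l) = (*pa.pop)(pa.row, 2 * l + bp.next());
        nxt(i, 2 * l + 1) = (*pb.pop)(pb.row, 2 * l + bp.next());
      }
    }
    mutate_deme(nxt, mu, n_alleles);
  }
}

// [[Rcpp::export]]
List cpp_step_generation(IntegerMatrix pop1, IntegerMatrix pop2,
                         double m, NumericVector mu, int n_alleles) {
  IntegerMatrix next1(pop1.nrow(), pop1.ncol());
  IntegerMatrix next2(pop2.nrow(), pop2.ncol());
  step_core(pop1, pop2, m, mu, n_alleles, next1, next2);
  return List::create(next1, next2);
}

static void sample_rows(const IntegerMatrix& pop, int n, XorShift& rng,
                        IntegerMatrix& out, int at) {
  const int K = pop.nrow();
  std::vector<int> idx(K);
  for (int i = 0; i < K; ++i) idx[i] = i;
  // partial Fisher-Yates: first n entries are a uniform
  // without-replacement sample
  for (int i = 0; i < n; ++i) {
    int j = i + rng.uniform_int(K - i);
    std::swap(idx[i], idx[j]);
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < pop.ncol(); ++j)
      out(at + i, j) = pop(idx[i], j);
}

// Sampled genotypes represent the post-dispersal census at each site: the
// current cohort is partitioned by a realized dispersal event (each
// individual relocates with probability m, the migration rate in effect at
// that generation), and up to n_sample individuals are drawn without
// replacement from each realized patch. Under a total barrier (m = 0) this
// reduces to a plain without-replacement subsample of each deme. The
// realization uses the private sampling stream, so it never perturbs the
// evolutionary trajectory.
static List sample_postdispersal(const IntegerMatrix& pop1,
                                 const IntegerMatrix& pop2,
                                 int n_sample, double m, XorShift& rng) {
  const int K1 = pop1.nrow(), K2 = pop2.nrow();
  const int ncol = pop1.ncol();
  std::vector<std::pair<const IntegerMatrix*, int> > patch1, patch2;
  patch1.reserve(K1 + K2);
  patch2.reserve(K1 + K2);
  for (int i = 0; i < K1; ++i) {
    if (m > 0.0 && rng.uniform_double() < m) patch2.push_back({&pop1, i});
    else patch1.push_back({&pop1, i});
  }
  for (int i = 0; i < K2; ++i) {
    if (m > 0.0 && rng.uniform_double() < m) patch1.push_back({&pop2, i});
    else patch2.push_back({&pop2, i});
  }
  List out(2);
  for (int d = 0; d < 2; ++d) {
    std::vector<std::pair<const IntegerMatrix*, int> >& patch =
      d == 0 ? patch1 : patch2;
    const int np = (int)patch.size();
    const int n = np < n_sample ? np : n_sample;
    // partial Fisher-Yates over the realized patch
    for (int i = 0; i < n; ++i) {
      int j = i + rng.uniform_int(np - i);
      std::swap(patch[i], patch[j]);
    }
    IntegerMatrix smp(n, ncol);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < ncol; ++j)
        smp(i, j) = (*patch[i].first)(patch[i].second, j);
    out[d] = smp;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_scenario(int K, int n_loci, int n_alleles, NumericVector mu,
                      double m_before, double m_after, int t_barrier,
                      int t_end, IntegerVector sample_times, int n_sample,
                      double sample_seed) {
  IntegerMatrix pop1 = cpp_init_pop(K, n_loci, n_alleles);
  IntegerMatrix pop2 = cpp_init_pop(K, n_loci, n_alleles);
  IntegerMatrix buf1(K, 2 * n_loci), buf2(K, 2 * n_loci);

  std::vector<bool> want(t_end + 1, false);
  for (int i = 0; i < sample_times.size(); ++i) {
    int t = sample_times[i];
    if (t >= 1 && t <= t_end) want[t] = true;
  }

  List out;
  for (int t = 1; t <= t_end; ++t) {
    const double m = (t <= t_barrier) ? m_before : m_after;
    step_core(pop1, pop2, m, mu, n_alleles, buf1, buf2);
    std::swap(pop1, buf1);
    std::swap(pop2, buf2);
    if (want[t]) {
      // per-sampling-event stream: samples at a given generation are
      // identical whatever other generations are sampled
      XorShift srng(((uint64_t)sample_seed) * 2654435761ULL +
                    (uint64_t)t * 2246822519ULL);
      List smp = sample_postdispersal(pop1, pop2, n_sample, m, srng);
      out.push_back(List::create(_["t"] = t, _["deme1"] = smp[0],
                                 _["deme2"] = smp[1]));
    }
    if (t % 128 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
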