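// Forward-time Wright-Fisher engine: diploid, random mating with selfing,
// fitness-proportional parent sampling, Poisson crossovers on a uniform
// genetic map, infinite-sites mutation.  All randomness flows through R's
// RNG so set.seed() makes whole pipelines bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<char> > HapMat; // rows = haplotypes

static void make_gamete(const std::vector<char> &a, const std::vector<char> &b,
                        const std::vector<double> &pos, double map_length,
                        double region_length, std::vector<char> &out) {
  const size_t S = pos.size();
  out.resize(S);
  int ncx = (map_length > 0) ? (int) R::rpois(map_length) : 0;
  bool phase = unif_rand() < 0.5; // true -> start on a
  if (ncx == 0) {
    const std::vector<char> &src = phase ? a : b;
    std::copy(src.begin(), src.end(), out.begin());
    return;
  }
  std::vector<double> cx(ncx);
  for (int i = 0; i < ncx; ++i) cx[i] = unif_rand() * region_length;
  std::sort(cx.begin(), cx.end());
  for (size_t s = 0; s < S; ++s) {
    int k = (int) (std::upper_bound(cx.begin(), cx.end(), pos[s]) - cx.begin());
    bool ph = (k % 2 == 0) ? phase : !phase;
    out[s] = ph ? a[s] : b[s];
  }
}

// log-fitness of each diploid; the within-locus scheme contributes 0,
// (1+kappa)*eta/2 or eta for 0, 1 or 2 copies of allele 1
static void fitness(const HapMat &H, const std::vector<double> &eta,
                    const std::vector<double> &kappa, bool noise,
                    std::vector<double> &W) {
  const int N = (int) H.size() / 2;
  const size_t S = eta.size();
  std::vector<double> Y(N, 0.0);
  for (int k = 0; k < N; ++k) {
    const std::vector<char> &g1 = H[2 * k], &g2 = H[2 * k + 1];
    double y = 0.0;
    for (size_t i = 0; i < S; ++i) {
      if (eta[i] == 0.0) continue;
      int g = g1[i] + g2[i];
      if (g == 2) y += eta[i];
      else if (g == 1) y += 0.5 * (1.0 + kappa[i]) * eta[i];
    }
    Y[k] = y + (noise ? norm_rand() : 0.0);
  }
  double ymax = *std::max_element(Y.begin(), Y.end());
  W.resize(N);
  for (int k = 0; k < N; ++k) W[k] = std::exp(Y[k] - ymax);
}

static int sample_parent(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  return (int) (std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

static void purge(HapMat &H, std::vector<double> &pos,
                  std::vector<double> &eta, std::vector<double> &kappa) {
  const size_t S = pos.size(), n = H.size();
  std::vector<size_t> keep;
  keep.reserve(S);
  for (size_t s = 0; s < S; ++s) {
    int sum = 0;
    for (size_t r = 0; r < n; ++r) sum += H[r][s];
    if (sum > 0 && sum < (int) n) keep.push_back(s);
  }
  if (keep.size() == S) return;
  for (size_t r = 0; r < n; ++r) {
    for (size_t j = 0; j < keep.size(); ++j) H[r][j] = H[r][keep[j]];
    H[r].resize(keep.size());
  }
  for (size_t j = 0; j < keep.size(); ++j) {
    pos[j] = pos[keep[j]]; eta[j] = eta[keep[j]]; kappa[j] = kappa[keep[j]];
  }
  pos.resize(keep.size()); eta.resize(keep.size()); kappa.resize(keep.size());
}

static IntegerMatrix to_matrix(const HapMat &H) {
  const int n = (int) H.size(), S = n ? (int) H[0].size() : 0;
  IntegerMatrix out(n, S);
  for (int r = 0; r < n; ++r)
    for (int s = 0; s < S; ++s) out(r, s) = H[r][s];
  return out;
}

static NumericVector freqs_of(const HapMat &H) {
  const size_t n = H.size(), S = n ? H[0].size() : 0;
  NumericVector f(S);
  for (size_t s = 0; s < S; ++s) {
    int sum = 0;
    for (size_t r = 0; r < n; ++r) sum += H[r][s];
    f[s] = (double) sum / (double) n;
  }
  return f;
}

// [[Rcpp::export]]
List wf_sim_cpp(IntegerMatrix haps0, NumericVector pos0, NumericVector eta0,
                NumericVector kappa0, double region_length, double map_length,
                int n_gen, int N_out, int neutral_first_gens, bool noise,
                double mu, NumericVector eta_pool, NumericVector kappa_pool,
                int purge_every, bool record_freq, int keep_gen) {
  const int n0 = haps0.nrow();
  size_t S = haps0.ncol();
  HapMat H(n0, std::vector<char>(S));
  for (int r = 0; r < n0; ++r)
    for (size_t s = 0; s < S; ++s) H[r][s] = (char) haps0(r, s);
  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> kappa(kappa0.begin(), kappa0.end());
  if (eta.size() != S) { eta.assign(S, 0.0); kappa.assign(S, 0.0); }

  bool any_sel = false;
  for (size_t i = 0; i < eta.size(); ++i) if (eta[i] != 0.0) { any_sel = true; break; }

  List freq_rec;
  if (record_freq) {
    freq_rec = List(n_gen + 1);
    freq_rec[0] = freqs_of(H);
  }
  IntegerMatrix haps_keep;
  bool kept = false;

  size_t pool_used = 0;
  std::vector<double> W, cumw;
  HapMat next;
  std::vector<char> gam;

  for (int g = 1; g <= n_gen; ++g) {
    const int Ncur = (int) H.size() / 2;
    bool do_sel = (g > neutral_first_gens) && any_sel;
    if (do_sel) fitness(H, eta, kappa, noise, W);
    else W.assign(Ncur, 1.0);
    cumw.resize(Ncur);
    double acc = 0.0;
    for (int k = 0; k < Ncur; ++k) { acc += W[k]; cumw[k] = acc; }

    next.assign(2 * N_out, std::vector<char>());
    for (int k = 0; k < N_out; ++k) {
      int pa = sample_parent(cumw), pb = sample_parent(cumw);
      make_gamete(H[2 * pa], H[2 * pa + 1], pos, map_length, region_length, gam);
      next[2 * k] = gam;
      make_gamete(H[2 * pb], H[2 * pb + 1], pos, map_length, region_length, gam);
      next[2 * k + 1] = gam;
    }
    H.swap(next);

    if (mu > 0) {
      int nmut = (int) R::rpois(mu);
      for (int j = 0; j < nmut; ++j) {
        double p = unif_rand() * region_length;
        double e = 0.0, kp = 0.0;
        if (pool_used < (size_t) eta_pool.size()) {
          e = eta_pool[pool_used];
          kp = kappa_pool[pool_used];
          ++pool_used;
        }
        pos.push_back(p); eta.push_back(e); kappa.push_back(kp);
        int carrier = (int) (unif_rand() * (double) H.size());
        if (carrier >= (int) H.size()) carrier = (int) H.size() - 1;
        for (size_t r = 0; r < H.size(); ++r)
          H[r].push_back(r == (size_t) carrier ? 1 : 0);
        if (e != 0.0) any_sel = true;
      }
    }
    if (purge_every > 0 && (g % purge_every == 0 || g == n_gen))
      purge(H, pos, eta, kappa);

    if (record_freq) freq_rec[g] = freqs_of(H);
    if (keep_gen == g) { haps_keep = to_matrix(H); kept = true; }
  }

  List out = List::create(
    _["haplotypes"] = to_matrix(H),
    _["positions"] = NumericVector(pos.begin(), pos.end()),
    _["eta"] = NumericVector(eta.begin(), eta.end()),
    _["kappa"] = NumericVector(kappa.begin(), kappa.end()),
    _["pool_used"] = (double) pool_used);
  if (record_freq) out["freq"] = freq_rec;
  if (kept) out["haplotypes_keep"] = haps_keep;
  return out;
}

// one round of reproduction with explicit absolute fitnesses
// [[Rcpp::export]]
IntegerMatrix wf_next_gen_cpp(IntegerMatrix haps0, NumericVector pos0,
                              double region_length, double map_length,
                              NumericVector W, int N_out) {
  const int n0 = haps0.nrow();
  const size_t S = haps0.ncol();
  if ((int) W.size() != n0 / 2) stop("length(W) must equal the number of individuals");
  HapMat H(n0, std::vector<char>(S));
  for (int r = 0; r < n0; ++r)
    for (size_t s = 0; s < S; ++s) H[r][s] = (char) haps0(r, s);
  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<double> cumw(n0 / 2);
  double acc = 0.0;
  for (int k = 0; k < n0 / 2; ++k) {
    if (W[k] < 0) stop("negative fitness");
    acc += W[k]; cumw[k] = acc;
  }
  if (acc <= 0) stop("all fitnesses are zero; reduce the effect-size scale");
  HapMat next(2 * N_out);
  std::vector<char> gam;
  for (int k = 0; k < N_out; ++k) {
    int pa = sample_parent(cumw), pb = sample_parent(cumw);
    make_gamete(H[2 * pa], H[2 * pa + 1], pos, map_length, region_length, gam);
    next[2 * k] = gam;
    make_gamete(H[2 * pb], H[2 * pb + 1], pos, map_length, region_length, gam);
    next[2 * k + 1] = gam;
  }
  return to_matrix(next);
}
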