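// Forward Wright-Fisher simulator with infinite-sites mutation, uniform
// recombination and multiplicative selection at a single site. Positions are
// continuous on [0, seq_len); the beneficial allele is tracked as a flag per
// haplotype rather than as a list entry. Uses R's RNG throughout so results
// are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

typedef std::vector<double> Hap;

struct Population {
  std::vector<Hap> muts;  // sorted mutation positions per haplotype
  std::vector<char> ben;  // beneficial-allele carrier flag
};

static int sample_parent(const std::vector<double>& cumw) {
  double u = R::runif(0.0, cumw.back());
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// meiotic gamete from diploid parent p (haplotypes 2p, 2p+1)
static void make_gamete(const Population& pop, int p, double L, double rho,
                        double sel_pos, Hap& out, char& ben_out) {
  int h0 = 2 * p + (R::unif_rand() < 0.5 ? 0 : 1);
  int h1 = (h0 % 2 == 0) ? h0 + 1 : h0 - 1;
  int ncx = (int)R::rpois(rho * L);
  out.clear();
  if (ncx == 0) {
    out = pop.muts[h0];
    ben_out = pop.ben[h0];
    return;
  }
  std::vector<double> cx(ncx);
  for (int i = 0; i < ncx; ++i) cx[i] = R::runif(0.0, L);
  std::sort(cx.begin(), cx.end());
  cx.push_back(L + 1.0);
  double a = 0.0;
  int cur = h0;
  ben_out = 0;
  for (size_t k = 0; k < cx.size(); ++k) {
    double b = cx[k];
    const Hap& src = pop.muts[cur];
    Hap::const_iterator lo = std::lower_bound(src.begin(), src.end(), a);
    Hap::const_iterator hi = std::lower_bound(src.begin(), src.end(), b);
    out.insert(out.end(), lo, hi);
    if (sel_pos >= a && sel_pos < b && pop.ben[cur]) ben_out = 1;
    a = b;
    cur = (cur == h0) ? h1 : h0;
  }
}

static void next_generation(Population& pop, Population& next, int N,
                            double L, double mu, double rho, double s,
                            double sel_pos) {
  int twoN = 2 * N;
  std::vector<double> cumw(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (s > 0.0) {
      int nb = pop.ben[2 * i] + pop.ben[2 * i + 1];
      for (int k = 0; k < nb; ++k) w *= (1.0 + s);
    }
    acc += w;
    cumw[i] = acc;
  }
  next.muts.resize(twoN);
  next.ben.resize(twoN);
  for (int j = 0; j < twoN; ++j) {
    int p = sample_parent(cumw);
    make_gamete(pop, p, L, rho, sel_pos, next.muts[j], next.ben[j]);
    int nmut = (int)R::rpois(mu * L);
    for (int m = 0; m < nmut; ++m) {
      double x = R::runif(0.0, L);
      Hap& h = next.muts[j];
      h.insert(std::upper_bound(h.begin(), h.end(), x), x);
    }
  }
  std::swap(pop.muts, next.muts);
  std::swap(pop.ben, next.ben);
}

// drop mutations carried by every haplotype (fixed: no longer polymorphic)
static void purge_fixed(Population& pop) {
  std::unordered_map<double, int> cnt;
  for (size_t i = 0; i < pop.muts.size(); ++i)
    for (size_t k = 0; k < pop.muts[i].size(); ++k) cnt[pop.muts[i][k]]++;
  int twoN = (int)pop.muts.size();
  std::vector<double> fixed;
  for (std::unordered_map<double, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == twoN) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (size_t i = 0; i < pop.muts.size(); ++i) {
    Hap out;
    out.reserve(pop.muts[i].size());
    std::set_difference(pop.muts[i].begin(), pop.muts[i].end(),
                        fixed.begin(), fixed.end(), std::back_inserter(out));
    pop.muts[i].swap(out);
  }
}

// [[Rcpp::export(name = ".wf_sweep_sim")]]
List wf_sweep_sim(int n_diploid, double seq_len, double mu, double rho,
                  double s, double sel_pos, int n_sample, int burnin_gens,
                  int max_restarts, int max_sweep_gens) {
  RNGScope scope;
  int twoN = 2 * n_diploid;
  Population pop, scratch;
  pop.muts.assign(twoN, Hap());
  pop.ben.assign(twoN, 0);

  for (int g = 0; g < burnin_gens; ++g) {
    next_generation(pop, scratch, n_diploid, seq_len, mu, rho, 0.0, sel_pos);
    if ((g + 1) % 100 == 0) purge_fixed(pop);
  }
  purge_fixed(pop);

  int restarts = 0, sweep_gens = 0;
  if (s > 0.0) {
    Population saved = pop;  // rejection sampling restarts from here
    bool fixed = false;
    while (!fixed) {
      if (restarts > max_restarts)
        stop("beneficial allele failed to fix within max_restarts attempts");
      int h = (int)std::floor(R::unif_rand() * twoN);
      std::fill(pop.ben.begin(), pop.ben.end(), 0);
      pop.ben[h] = 1;
      sweep_gens = 0;
      while (true) {
        next_generation(pop, scratch, n_diploid, seq_len, mu, rho, s,
                        sel_pos);
        ++sweep_gens;
        if (sweep_gens % 100 == 0) purge_fixed(pop);
        int nb = 0;
        for (int i = 0; i < twoN; ++i) nb += pop.ben[i];
        if (nb == 0) {        // lost: restart from the saved neutral state
          pop = saved;
          ++restarts;
          break;
        }
        if (nb == twoN) {     // fixed
          fixed = true;
          break;
        }
        if (sweep_gens > max_sweep_gens)
          stop("sweep neither fixed nor lost within max_sweep_gens");
      }
    }
  }

  // sample n_sample haplotypes without replacement (partial Fisher-Yates)
  std::vector<int> idx(twoN);
  for (int i = 0; i < twoN; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + (int)std::floor(R::unif_rand() * (twoN - i));
    std::swap(idx[i], idx[j]);
  }

  std::unordered_map<double, int> cnt;
  for (int i = 0; i < n_sample; ++i)
    for (size_t k = 0; k < pop.muts[idx[i]].size(); ++k)
      cnt[pop.muts[idx[i]][k]]++;
  std::vector<double> segpos;
  for (std::unordered_map<double, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second > 0 && it->second < n_sample) segpos.push_back(it->first);
  std::sort(segpos.begin(), segpos.end());

  int S = (int)segpos.size();
  IntegerMatrix hap(n_sample, S);
  for (int i = 0; i < n_sample; ++i) {
    const Hap& h = pop.muts[idx[i]];
    for (size_t k = 0; k < h.size(); ++k) {
      std::vector<double>::iterator it =
          std::lower_bound(segpos.begin(), segpos.end(), h[k]);
      if (it != segpos.end() && *it == h[k])
        hap(i, (int)(it - segpos.begin())) = 1;
    }
  }

  return List::create(_["positions"] = NumericVector(segpos.begin(),
                                                     segpos.end()),
                      _["haplotypes"] = hap,
                      _["restarts"] = restarts,
                      _["sweep_generations"] = sweep_gens);
}
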