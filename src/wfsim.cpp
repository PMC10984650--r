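#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Wright-Fisher forward simulator of multiplicative purifying selection in a
// single selected region, with interleaved neutral sites used to measure the
// diversity reduction B.  Diploid N; each deleterious mutation costs s in
// heterozygotes and 2s in homozygotes, multiplicative across sites (fitness
// truncated at zero).  Mutations arise at per-gamete rate mu_del*L
// (deleterious) and mu_neutral*L (neutral) at uniform continuous positions,
// infinite-sites style.  Recombination is Poisson crossovers with expectation
// r_bp*L per meiosis.  Uses R's RNG, so runs are reproducible via set.seed().

namespace {

// xoshiro256+ for the simulator's inner loop: R's RNG is used only to seed
// the state, so runs remain reproducible under set.seed() while avoiding
// tens of millions of R RNG calls per replicate
struct XRng {
  uint64_t s[4];
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next(); // warm up
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int rpois_small(double lambda) { // Knuth; lambda is always tiny here
    double limit = std::exp(-lambda), prod = unif();
    int k = 0;
    while (prod > limit) { prod *= unif(); ++k; }
    return k;
  }
};

struct Registry {
  std::vector<double> pos; // position as fraction of L
  std::vector<char> sel;
  long created_sel = 0, created_neu = 0;
  long lost_sel = 0, lost_neu = 0;
  long fixed_sel = 0, fixed_neu = 0;
  int add_new(double p, bool is_sel) {
    pos.push_back(p);
    sel.push_back(is_sel ? 1 : 0);
    if (is_sel) ++created_sel; else ++created_neu;
    return (int)pos.size() - 1;
  }
  int add_kept(double p, bool is_sel) {
    pos.push_back(p);
    sel.push_back(is_sel ? 1 : 0);
    return (int)pos.size() - 1;
  }
};

// mutation ids sorted by position, selected and neutral kept separately so
// fitness evaluation never scans the neutral tracer sites
struct Hap {
  std::vector<int> sel, neu;
  void clear() { sel.clear(); neu.clear(); }
};

inline int weighted_pick(const std::vector<double> &cum, double total,
                         XRng &rng) {
  double u = rng.unif() * total;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// crossover walk over one (position-sorted) id vector
static void cross_walk(const std::vector<int> &v0, const std::vector<int> &v1,
                       const Registry &reg, const std::vector<double> &bp,
                       int start, std::vector<int> &out) {
  const std::vector<int> *vs[2] = { &v0, &v1 };
  size_t idx[2] = { 0, 0 };
  size_t bi = 0;
  int cur = start;
  double next = bp[0];
  while (true) {
    const std::vector<int> &h = *vs[cur];
    size_t &i = idx[cur];
    while (i < h.size() && reg.pos[h[i]] < next) { out.push_back(h[i]); ++i; }
    if (bi >= bp.size()) break;
    int oth = 1 - cur;
    const std::vector<int> &ho = *vs[oth];
    size_t &io = idx[oth];
    while (io < ho.size() && reg.pos[ho[io]] < next) ++io;
    cur = oth;
    ++bi;
    next = (bi < bp.size()) ? bp[bi] : 2.0; // past the end of the region
  }
}

void make_gamete_k(const Hap &h0, const Hap &h1, const Registry &reg,
                   int k, Hap &out, XRng &rng) {
  out.clear();
  int cur = (rng.unif() < 0.5) ? 0 : 1;
  if (k == 0) {
    out = (cur == 0) ? h0 : h1;
    return;
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = rng.unif(); // uniform per-bp rate
  std::sort(bp.begin(), bp.end());
  cross_walk(h0.sel, h1.sel, reg, bp, cur, out.sel);
  cross_walk(h0.neu, h1.neu, reg, bp, cur, out.neu);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".wf_forward_cpp")]]
List wf_forward_cpp(int N, double L, double mu_del, double s, double r_bp,
                    double mu_neutral, int burnin, int gens, int tick = 25) {
  if (N < 2) stop("wf_forward: N must be >= 2");
  const int H = 2 * N;
  const double Mtot = r_bp * L;
  const double mu_tot = (mu_del + mu_neutral) * L;
  const double p_del = mu_tot > 0 ? mu_del / (mu_del + mu_neutral) : 0.0;
  const int total_gens = burnin + gens;
  const double het_corr = (double)H / (H - 1);
  const double l1 = (s > 0) ? std::log1p(-s) : 0.0;
  const bool lethal_hom = (1.0 - 2.0 * s) <= 0.0;
  const double l2 = lethal_hom ? 0.0 : std::log1p(-2.0 * s);

  XRng rng;
  rng.seed_from_R();
  Registry reg;
  std::vector<Hap> pop(H), nxt(H);
  std::vector<double> cum(N), logw(N);
  std::vector<double> pi_samp, va_samp, wbar_samp;
  std::vector<int> gen_samp;
  std::vector<int> cnt, remap;
  long fix_sel_post = 0, fix_neu_post = 0;
  double wbar_cur = 1.0;

  // count frequencies, record a diversity/variance sample if sampling,
  // then drop lost and fixed mutations (compacting ids)
  auto do_tick = [&](int gen, bool sampling) {
    size_t R_ = reg.pos.size();
    cnt.assign(R_, 0);
    for (int h = 0; h < H; ++h) {
      for (int id : pop[h].sel) ++cnt[id];
      for (int id : pop[h].neu) ++cnt[id];
    }
    if (sampling) {
      double pisum = 0.0, vasum = 0.0;
      for (size_t id = 0; id < R_; ++id) {
        if (cnt[id] == 0 || cnt[id] == H) continue;
        double p = (double)cnt[id] / H;
        double h2 = 2.0 * p * (1.0 - p);
        if (reg.sel[id]) vasum += h2 * s * s;
        else pisum += h2 * het_corr;
      }
      pi_samp.push_back(pisum / L);
      va_samp.push_back(vasum);
      wbar_samp.push_back(wbar_cur);
      gen_samp.push_back(gen);
    }
    Registry nreg;
    nreg.created_sel = reg.created_sel; nreg.created_neu = reg.created_neu;
    nreg.lost_sel = reg.lost_sel; nreg.lost_neu = reg.lost_neu;
    nreg.fixed_sel = reg.fixed_sel; nreg.fixed_neu = reg.fixed_neu;
    remap.assign(R_, -1);
    for (size_t id = 0; id < R_; ++id) {
      if (cnt[id] == 0) {
        if (reg.sel[id]) ++nreg.lost_sel; else ++nreg.lost_neu;
      } else if (cnt[id] == H) {
        if (reg.sel[id]) { ++nreg.fixed_sel; if (sampling) ++fix_sel_post; }
        else { ++nreg.fixed_neu; if (sampling) ++fix_neu_post; }
      } else {
        remap[id] = nreg.add_kept(reg.pos[id], reg.sel[id]);
      }
    }
    auto compact_vec = [&](std::vector<int> &v) {
      size_t j = 0;
      for (size_t i = 0; i < v.size(); ++i) {
        int nid = remap[v[i]];
        if (nid >= 0) v[j++] = nid;
      }
      v.resize(j);
    };
    for (int h = 0; h < H; ++h) {
      compact_vec(pop[h].sel);
      compact_vec(pop[h].neu);
    }
    reg = std::move(nreg);
  };

  for (int gen = 1; gen <= total_gens; ++gen) {
    // --- fitness ---
    double maxlw = 0.0;
    if (s > 0) {
      maxlw = R_NegInf;
      for (int i = 0; i < N; ++i) {
        const std::vector<int> &a = pop[2 * i].sel, &b = pop[2 * i + 1].sel;
        int nhet = 0, nhom = 0;
        size_t ia = 0, ib = 0;
        while (ia < a.size() && ib < b.size()) {
          int va = a[ia], vb = b[ib];
          if (va == vb) { ++nhom; ++ia; ++ib; }
          else if (reg.pos[va] < reg.pos[vb]) { ++nhet; ++ia; }
          else { ++nhet; ++ib; }
        }
        nhet += (int)(a.size() - ia) + (int)(b.size() - ib);
        double lw = (lethal_hom && nhom > 0) ? R_NegInf : nhet * l1 + nhom * l2;
        logw[i] = lw;
        if (lw > maxlw) maxlw = lw;
      }
      if (!R_FINITE(maxlw))
        stop("wf_forward: mean fitness collapsed to zero (mutational meltdown)");
    } else {
      std::fill(logw.begin(), logw.end(), 0.0);
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = R_FINITE(logw[i]) ? std::exp(logw[i] - maxlw) : 0.0;
      tot += w;
      cum[i] = tot;
    }
    if (tot <= 0.0)
      stop("wf_forward: mean fitness collapsed to zero (mutational meltdown)");
    wbar_cur = std::exp(maxlw) * tot / N;

    // --- reproduction with mutation ---
    // fast path: with probability exp(-(Mtot + mu_tot)) a gamete has no
    // crossover and no new mutation, and is a plain copy of one parental
    // haplotype; the full Poisson machinery runs only otherwise
    const double p_quiet = std::exp(-(Mtot + mu_tot));
    for (int i = 0; i < N; ++i) {
      for (int h = 0; h < 2; ++h) {
        int par = weighted_pick(cum, tot, rng);
        Hap &out = nxt[2 * i + h];
        if (rng.unif() < p_quiet) {
          out = pop[2 * par + ((rng.unif() < 0.5) ? 0 : 1)];
          continue;
        }
        // condition on at least one event across (crossovers, mutations)
        int kx, km;
        do {
          kx = (Mtot > 0) ? rng.rpois_small(Mtot) : 0;
          km = (mu_tot > 0) ? rng.rpois_small(mu_tot) : 0;
        } while (kx == 0 && km == 0);
        make_gamete_k(pop[2 * par], pop[2 * par + 1], reg, kx, out, rng);
        for (int m = 0; m < km; ++m) {
          bool is_sel = rng.unif() < p_del;
          int id = reg.add_new(rng.unif(), is_sel);
          std::vector<int> &v = is_sel ? out.sel : out.neu;
          auto it = std::upper_bound(v.begin(), v.end(), id,
            [&](int lhs, int rhs) { return reg.pos[lhs] < reg.pos[rhs]; });
          v.insert(it, id);
        }
      }
    }
    pop.swap(nxt);

    // --- bookkeeping ---
    // force a tick at the burn-in boundary so post-burn-in fixation counts
    // start from a clean slate, and at the final generation
    if (gen % tick == 0 || gen == burnin || gen == total_gens)
      do_tick(gen, gen > burnin);
  }

  return List::create(
    _["pi"] = pi_samp, _["va"] = va_samp, _["wbar"] = wbar_samp,
    _["gen"] = gen_samp,
    _["fix_sel_post"] = (double)fix_sel_post,
    _["fix_neu_post"] = (double)fix_neu_post,
    _["created_sel"] = (double)reg.created_sel,
    _["created_neu"] = (double)reg.created_neu,
    _["lost_sel"] = (double)reg.lost_sel,
    _["lost_neu"] = (double)reg.lost_neu,
    _["fixed_sel"] = (double)reg.fixed_sel,
    _["fixed_neu"] = (double)reg.fixed_neu,
    _["seg_sel"] = (double)std::count(reg.sel.begin(), reg.sel.end(), (char)1),
    _["seg_neu"] = (double)std::count(reg.sel.begin(), reg.sel.end(), (char)0));

}
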