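// Diploid Wright-Fisher forward simulator with recombination, linked
// selection and an exon/intron mosaic genome. Supports multiple demes with
// piecewise-constant sizes, split events (a deme founded from a parent
// deme) and per-epoch migration. Fitness is multiplicative across sites:
// heterozygote 1 - s/2, homozygote 1 - s (s stored as a magnitude).
//
// Only exonic mutations are tracked (nonsynonymous / synonymous); introns
// act as recombination spacers. Fixed mutations are purged periodically
// and logged as substitutions.
//
// Storage is tuned for the gamete-assembly bottleneck (memory traffic):
// selected mutations (s > 0) are 64-bit keys packing (position << 32 | id);
// neutral mutations are bare 32-bit positions, with a global position->id
// map consulted only during the infrequent purge/tally passes. Gametes are
// assembled with binary searches and block copies per crossover segment.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t make_key(uint32_t pos, uint32_t id) {
  return (static_cast<uint64_t>(pos) << 32) | id;
}
inline uint32_t key_pos(uint64_t k) { return static_cast<uint32_t>(k >> 32); }
inline uint32_t key_id(uint64_t k) {
  return static_cast<uint32_t>(k & 0xffffffffu);
}

struct Hap {
  std::vector<uint64_t> sel;  // selected mutations, sorted by position
  std::vector<float> sels;    // their coefficients, parallel to sel
  std::vector<uint32_t> neu;  // neutral mutation positions, sorted
};

struct MutTable {
  std::vector<uint32_t> pos;
  std::vector<double> s;
  std::vector<uint8_t> cls;  // 0 = synonymous, 1 = nonsynonymous
};

struct SelModel {
  int kind;        // 0 neutral, 1 constant, 2 partial, 3 gamma
  double s_const;  // constant / partial
  double p_sel;    // partial
  double shape, scale_s;  // gamma (scale in homozygous s units)
};

struct Engine {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  double runif() { return unif(rng); }
  long long rint(long long n) {  // uniform in [0, n)
    return static_cast<long long>(runif() * n) % n;
  }
  int rpois(double lambda) {
    std::poisson_distribution<int> d(lambda);
    return d(rng);
  }
  double rgamma(double shape, double scale) {
    std::gamma_distribution<double> d(shape, scale);
    return d(rng);
  }
};

// Poisson sampler with fixed rate: cumulative-table inversion for small
// rates (the per-gamete crossover count), std::poisson otherwise
struct PoisFixed {
  std::vector<double> cdf;
  std::poisson_distribution<int> big;
  bool use_table = false;
  void init(double lambda) {
    if (lambda <= 0) { use_table = true; cdf.assign(1, 1.0); return; }
    if (lambda <= 30.0) {
      use_table = true;
      double p = std::exp(-lambda), c = p;
      cdf.push_back(c);
      for (int k = 1; c < 1.0 - 1e-13 && k < 200; ++k) {
        p *= lambda / k;
        c += p;
        cdf.push_back(c);
      }
    } else {
      big = std::poisson_distribution<int>(lambda);
    }
  }
  int draw(Engine& eng) {
    if (!use_table) return big(eng.rng);
    double u = eng.runif();
    size_t k = 0;
    while (k < cdf.size() - 1 && u > cdf[k]) ++k;
    return (int)k;
  }
};

double draw_s(const SelModel& m, Engine& eng) {
  switch (m.kind) {
    case 0: return 0.0;
    case 1: return m.s_const;
    case 2: return (eng.runif() < m.p_sel) ? m.s_const : 0.0;
    case 3: return std::min(1.0, eng.rgamma(m.shape, m.scale_s));
    default: stop("unknown selection model kind");
  }
  return 0.0;
}

// assemble a recombinant mosaic of strands (a, b): for each inter-breakpoint
// segment, binary-search the segment end in the active strand and block-copy
template <typename T, typename CutFn>
void merge_recomb(const std::vector<T>& a, const std::vector<T>& b,
                  const std::vector<uint32_t>& bp, int start_strand,
                  CutFn cut_of, std::vector<T>& out) {
  out.clear();
  if (bp.empty()) {
    const std::vector<T>& act = (start_strand == 0) ? a : b;
    out.assign(act.begin(), act.end());
    return;
  }
  out.reserve(std::max(a.size(), b.size()) + 4);
  size_t ia = 0, ib = 0;
  int strand = start_strand;
  for (size_t k = 0; k <= bp.size(); ++k) {
    const std::vector<T>& act = (strand == 0) ? a : b;
    const std::vector<T>& ina = (strand == 0) ? b : a;
    size_t& iact = (strand == 0) ? ia : ib;
    size_t& iina = (strand == 0) ? ib : ia;
    if (k == bp.size()) {
      out.insert(out.end(), act.begin() + iact, act.end());
      break;
    }
    T cut = cut_of(bp[k]);
    size_t ja = std::lower_bound(act.begin() + iact, act.end(), cut) -
                act.begin();
    out.insert(out.end(), act.begin() + iact, act.begin() + ja);
    iact = ja;
    iina = std::lower_bound(ina.begin() + iina, ina.end(), cut) -
           ina.begin();
    strand = 1 - strand;
  }
}

template <typename T>
void insert_sorted(std::vector<T>& v, T x) {
  v.insert(std::lower_bound(v.begin(), v.end(), x), x);
}

// product of heterozygous factors over one haplotype (tight, vectorizable)
double hap_het_product(const Hap& h) {
  double w = 1.0;
  for (float s : h.sels) w *= (1.0 - 0.5 * (double)s);
  return w;
}

// fitness of a diploid: product of both haplotypes' heterozygous factors,
// corrected at shared (homozygous) sites from (1-s/2)^2 to (1-s)
double fitness_of(const Hap& h1, const Hap& h2, double p1, double p2) {
  double w = p1 * p2;
  const std::vector<uint64_t>& A = h1.sel;
  const std::vector<uint64_t>& B = h2.sel;
  size_t i = 0, j = 0;
  const size_t m = A.size(), n = B.size();
  while (i < m && j < n) {
    uint64_t a = A[i], b = B[j];
    if (a == b) {
      double s = (double)h1.sels[i];
      double het2 = (1.0 - 0.5 * s) * (1.0 - 0.5 * s);
      w *= het2 > 0 ? (1.0 - s) / het2 : 0.0;
    }
    i += (a <= b);
    j += (b <= a);
  }
  return w < 0 ? 0.0 : w;
}

// merge the parallel coefficient array using the same crossover layout
void merge_recomb_pair(const Hap& p0, const Hap& p1,
                       const std::vector<uint32_t>& bp, int start_strand,
                       Hap& child) {
  child.sel.clear();
  child.sels.clear();
  if (bp.empty()) {
    const Hap& act = (start_strand == 0) ? p0 : p1;
    child.sel.assign(act.sel.begin(), act.sel.end());
    child.sels.assign(act.sels.begin(), act.sels.end());
    return;
  }
  child.sel.reserve(std::max(p0.sel.size(), p1.sel.size()) + 4);
  child.sels.reserve(child.sel.capacity());
  size_t ia = 0, ib = 0;
  int strand = start_strand;
  for (size_t k = 0; k <= bp.size(); ++k) {
    const Hap& act = (strand == 0) ? p0 : p1;
    const Hap& ina = (strand == 0) ? p1 : p0;
    size_t& iact = (strand == 0) ? ia : ib;
    size_t& iina = (strand == 0) ? ib : ia;
    if (k == bp.size()) {
      child.sel.insert(child.sel.end(), act.sel.begin() + iact,
                       act.sel.end());
      child.sels.insert(child.sels.end(), act.sels.begin() + iact,
                        act.sels.end());
      break;
    }
    uint64_t cut = make_key(bp[k], 0);
    size_t ja = std::lower_bound(act.sel.begin() + iact, act.sel.end(),
                                 cut) - act.sel.begin();
    child.sel.insert(child.sel.end(), act.sel.begin() + iact,
                     act.sel.begin() + ja);
    child.sels.insert(child.sels.end(), act.sels.begin() + iact,
                      act.sels.begin() + ja);
    iact = ja;
    iina = std::lower_bound(ina.sel.begin() + iina, ina.sel.end(), cut) -
           ina.sel.begin();
    strand = 1 - strand;
  }
}

}  // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(IntegerMatrix deme_sizes, IntegerVector parent_deme,
                 List mig_mats, IntegerVector mig_epoch, double L_total,
                 NumericVector exon_starts, NumericVector exon_ends,
                 double mu, double r, double p_ns, List ns_model,
                 List syn_model, int sample_n, int sample_deme,
                 int purge_every, int seed, Nullable<List> init_state,
                 bool return_state) {
  const int n_gens = deme_sizes.nrow() - 1;
  const int D = deme_sizes.ncol();
  if (L_total >= 2147483647.0) stop("sequence length must be < 2^31 bp");
  Engine eng;
  eng.rng.seed(static_cast<uint64_t>(seed));

  // exon map: cumulative exonic offsets for position drawing
  const int n_ex = exon_starts.size();
  std::vector<long long> ex_start(n_ex), ex_cum(n_ex + 1, 0);
  for (int k = 0; k < n_ex; ++k) {
    ex_start[k] = static_cast<long long>(exon_starts[k]);
    ex_cum[k + 1] =
        ex_cum[k] + static_cast<long long>(exon_ends[k] - exon_starts[k]);
  }
  const long long L_ex = ex_cum[n_ex];
  const long long L_tot = static_cast<long long>(L_total);

  SelModel ns{as<int>(ns_model["kind"]), as<double>(ns_model["s"]),
              as<double>(ns_model["p"]), as<double>(ns_model["shape"]),
              as<double>(ns_model["scale_s"])};
  SelModel syn{as<int>(syn_model["kind"]), as<double>(syn_model["s"]),
               as<double>(syn_model["p"]), as<double>(syn_model["shape"]),
               as<double>(syn_model["scale_s"])};

  MutTable mt;
  std::unordered_map<uint32_t, uint32_t> pos2id;  // occupied positions
  std::vector<std::vector<Hap>> pop(D), newpop(D);

  // substitution log
  std::vector<uint32_t> sub_pos;
  std::vector<double> sub_s;
  std::vector<uint8_t> sub_cls;
  std::vector<int> sub_gen;

  // initial state
  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector ipos = st["pos"];
    NumericVector is = st["s"];
    IntegerVector icls = st["cls"];
    for (int k = 0; k < ipos.size(); ++k) {
      mt.pos.push_back(static_cast<uint32_t>(ipos[k]));
      mt.s.push_back(is[k]);
      mt.cls.push_back(static_cast<uint8_t>(icls[k]));
      pos2id[mt.pos.back()] = k;
    }
    List haps = st["haplotypes"];  // one list per deme
    for (int d = 0; d < D; ++d) {
      List hd = haps[d];
      pop[d].resize(hd.size());
      for (int h = 0; h < hd.size(); ++h) {
        IntegerVector ids = hd[h];
        for (int k = 0; k < ids.size(); ++k) {
          uint32_t id = static_cast<uint32_t>(ids[k]);
          if (mt.s[id] > 0) {
            Hap& hp = pop[d][h];
            size_t at = std::lower_bound(hp.sel.begin(), hp.sel.end(),
                                         make_key(mt.pos[id], id)) -
                        hp.sel.begin();
            hp.sel.insert(hp.sel.begin() + at, make_key(mt.pos[id], id));
            hp.sels.insert(hp.sels.begin() + at, (float)mt.s[id]);
          } else {
            insert_sorted(pop[d][h].neu, mt.pos[id]);
          }
        }
      }
      if ((int)pop[d].size() != 2 * deme_sizes(0, d))
        stop("initial haplotype count does not match deme size");
    }
  } else {
    for (int d = 0; d < D; ++d)
      pop[d].assign(2 * (size_t)deme_sizes(0, d), Hap());
  }

  std::vector<std::vector<double>> cumw(D);
  std::vector<double> hetp;
  std::vector<uint32_t> bp;
  PoisFixed pois_cx;
  pois_cx.init(r * (double)L_tot);
  auto cut32 = [](uint32_t p) { return p; };

  auto purge = [&](int gen) {
    long long H = 0;
    for (int d = 0; d < D; ++d) H += pop[d].size();
    std::vector<int> cnt(mt.pos.size(), 0);
    for (int d = 0; d < D; ++d)
      for (const Hap& h : pop[d]) {
        for (uint64_t k : h.sel) ++cnt[key_id(k)];
        for (uint32_t p : h.neu) ++cnt[pos2id[p]];
      }
    // remap: -1 lost or fixed, >=0 new id
    std::vector<int> remap(mt.pos.size(), -1);
    MutTable nmt;
    std::vector<bool> fixed_pos_flag(mt.pos.size(), false);
    for (size_t id = 0; id < mt.pos.size(); ++id) {
      if (cnt[id] == 0) {
        pos2id.erase(mt.pos[id]);
      } else if (cnt[id] == H) {
        fixed_pos_flag[id] = true;
        pos2id.erase(mt.pos[id]);
        sub_pos.push_back(mt.pos[id]);
        sub_s.push_back(mt.s[id]);
        sub_cls.push_back(mt.cls[id]);
        sub_gen.push_back(gen);
      } else {
        remap[id] = nmt.pos.size();
        nmt.pos.push_back(mt.pos[id]);
        nmt.s.push_back(mt.s[id]);
        nmt.cls.push_back(mt.cls[id]);
      }
    }
    // rebuild the position map with the new ids
    for (auto& kv : pos2id) kv.second = remap[kv.second];
    bool any_fixed_sel = false, any_fixed_neu = false;
    for (size_t id = 0; id < mt.pos.size(); ++id) {
      if (fixed_pos_flag[id]) {
        if (mt.s[id] > 0) any_fixed_sel = true; else any_fixed_neu = true;
      }
    }
    for (int d = 0; d < D; ++d)
      for (Hap& h : pop[d]) {
        {
          size_t w = 0;
          for (size_t k = 0; k < h.sel.size(); ++k) {
            uint32_t oid = key_id(h.sel[k]);
            int nid = remap[oid];
            if (nid >= 0) {
              h.sels[w] = h.sels[k];
              h.sel[w++] = make_key(key_pos(h.sel[k]),
                                    static_cast<uint32_t>(nid));
            }
          }
          h.sel.resize(w);
          h.sels.resize(w);
        }
        if (any_fixed_neu) {
          size_t w = 0;
          for (size_t k = 0; k < h.neu.size(); ++k) {
            if (pos2id.find(h.neu[k]) != pos2id.end()) h.neu[w++] = h.neu[k];
          }
          h.neu.resize(w);
        }
      }
    (void)any_fixed_sel;
    mt = std::move(nmt);
  };

  for (int g = 1; g <= n_gens; ++g) {
    // fitness cumulants for demes that existed in the previous generation
    for (int d = 0; d < D; ++d) {
      int Nprev = deme_sizes(g - 1, d);
      cumw[d].assign(Nprev, 0.0);
      if (Nprev == 0) continue;
      hetp.resize(2 * (size_t)Nprev);
      for (int i = 0; i < 2 * Nprev; ++i) hetp[i] = hap_het_product(pop[d][i]);
      double acc = 0.0;
      for (int i = 0; i < Nprev; ++i) {
        acc += fitness_of(pop[d][2 * i], pop[d][2 * i + 1],
                          hetp[2 * i], hetp[2 * i + 1]);
        cumw[d][i] = acc;
      }
      if (acc <= 0.0) stop("all individuals in a deme have zero fitness");
    }

    const NumericMatrix mig = as<NumericMatrix>(mig_mats[mig_epoch[g - 1]]);

    for (int d = 0; d < D; ++d) {
      int Nd = deme_sizes(g, d);
      newpop[d].resize(2 * (size_t)Nd);  // keeps capacity across generations
      if (Nd == 0) continue;
      bool founding = (deme_sizes(g - 1, d) == 0);
      int founder_src = founding ? parent_deme[d] : d;
      if (founding && (founder_src < 0 || deme_sizes(g - 1, founder_src) == 0))
        stop("deme founded from an empty or undefined parent deme");

      for (int i = 0; i < Nd; ++i) {
        for (int side = 0; side < 2; ++side) {
          // choose source deme
          int src = founder_src;
          if (!founding && D > 1) {
            double u = eng.runif(), acc2 = 0.0;
            src = d;
            for (int s2 = 0; s2 < D; ++s2) {
              if (s2 == d || deme_sizes(g - 1, s2) == 0) continue;
              acc2 += mig(d, s2);
              if (u < acc2) { src = s2; break; }
            }
          }
          // choose parent by fitness
          const std::vector<double>& cw = cumw[src];
          double target = eng.runif() * cw.back();
          int p = std::lower_bound(cw.begin(), cw.end(), target) - cw.begin();
          if (p >= (int)cw.size()) p = cw.size() - 1;
          // recombinant gamete
          int ncx = (r > 0) ? pois_cx.draw(eng) : 0;
          bp.resize(ncx);
          for (int k = 0; k < ncx; ++k)
            bp[k] = static_cast<uint32_t>(1 + eng.rint(L_tot - 1));
          std::sort(bp.begin(), bp.end());
          int strand = (eng.runif() < 0.5) ? 0 : 1;
          Hap& child = newpop[d][2 * i + side];
          merge_recomb_pair(pop[src][2 * p], pop[src][2 * p + 1], bp,
                            strand, child);
          merge_recomb(pop[src][2 * p].neu, pop[src][2 * p + 1].neu, bp,
                       strand, cut32, child.neu);
        }
      }
    }
    pop.swap(newpop);

    // new mutations in offspring gametes
    for (int d = 0; d < D; ++d) {
      int Nd = deme_sizes(g, d);
      if (Nd == 0 || L_ex == 0 || mu <= 0) continue;
      int nmut = eng.rpois(2.0 * Nd * mu * (double)L_ex);
      for (int k = 0; k < nmut; ++k) {
        long long pos = -1;
        for (int tries = 0; tries < 100; ++tries) {
          long long e = eng.rint(L_ex);
          int ex = std::upper_bound(ex_cum.begin(), ex_cum.end(), e) -
                   ex_cum.begin() - 1;
          long long cand = ex_start[ex] + (e - ex_cum[ex]);
          if (pos2id.find(static_cast<uint32_t>(cand)) == pos2id.end()) {
            pos = cand;
            break;
          }
        }
        if (pos < 0) continue;  // saturated neighbourhood; drop mutation
        bool is_ns = eng.runif() < p_ns;
        double s = draw_s(is_ns ? ns : syn, eng);
        uint32_t id = static_cast<uint32_t>(mt.pos.size());
        uint32_t upos = static_cast<uint32_t>(pos);
        mt.pos.push_back(upos);
        mt.s.push_back(s);
        mt.cls.push_back(is_ns ? 1 : 0);
        pos2id[upos] = id;
        Hap& h = pop[d][eng.rint(2LL * Nd)];
        if (s > 0) {
          uint64_t key = make_key(upos, id);
          size_t at = std::lower_bound(h.sel.begin(), h.sel.end(), key) -
                      h.sel.begin();
          h.sel.insert(h.sel.begin() + at, key);
          h.sels.insert(h.sels.begin() + at, (float)s);
        } else {
          insert_sorted(h.neu, upos);
        }
      }
    }

    if (purge_every > 0 && (g % purge_every == 0)) purge(g);
  }
  purge(n_gens);

  // sample haplotypes without replacement from the sampled deme
  int H_d = pop[sample_deme].size();
  if (sample_n > H_d) stop("sample_n exceeds the number of haplotypes");
  std::vector<int> idx(H_d);
  for (int i = 0; i < H_d; ++i) idx[i] = i;
  for (int i = 0; i < sample_n; ++i) {
    int j = i + (int)eng.rint(H_d - i);
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> cnt_sample(mt.pos.size(), 0), cnt_deme(mt.pos.size(), 0),
      cnt_pop(mt.pos.size(), 0);
  auto tally = [&](const Hap& h, std::vector<int>& cnt) {
    for (uint64_t k : h.sel) ++cnt[key_id(k)];
    for (uint32_t p : h.neu) ++cnt[pos2id[p]];
  };
  for (int d = 0; d < D; ++d)
    for (const Hap& h : pop[d]) tally(h, cnt_pop);
  for (const Hap& h : pop[sample_deme]) tally(h, cnt_deme);
  for (int i = 0; i < sample_n; ++i)
    tally(pop[sample_deme][idx[i]], cnt_sample);

  int M = mt.pos.size();
  NumericVector out_pos(M), out_s(M);
  IntegerVector out_cls(M), out_cs(M), out_cd(M), out_cp(M);
  for (int k = 0; k < M; ++k) {
    out_pos[k] = (double)mt.pos[k];
    out_s[k] = mt.s[k];
    out_cls[k] = mt.cls[k];
    out_cs[k] = cnt_sample[k];
    out_cd[k] = cnt_deme[k];
    out_cp[k] = cnt_pop[k];
  }
  int S = sub_pos.size();
  NumericVector o_sub_pos(S), o_sub_s(S);
  IntegerVector o_sub_cls(S), o_sub_gen(S);
  for (int k = 0; k < S; ++k) {
    o_sub_pos[k] = (double)sub_pos[k];
    o_sub_s[k] = sub_s[k];
    o_sub_cls[k] = sub_cls[k];
    o_sub_gen[k] = sub_gen[k];
  }

  List state = R_NilValue;
  if (return_state) {
    List demes(D);
    for (int d = 0; d < D; ++d) {
      List hl(pop[d].size());
      for (size_t h = 0; h < pop[d].size(); ++h) {
        const Hap& hp = pop[d][h];
        IntegerVector ids(hp.sel.size() + hp.neu.size());
        size_t w = 0;
        for (uint64_t k : hp.sel) ids[w++] = (int)key_id(k);
        for (uint32_t p : hp.neu) ids[w++] = (int)pos2id[p];
        hl[h] = ids;
      }
      demes[d] = hl;
    }
    state = demes;
  }

  return List::create(
      _["pos"] = out_pos, _["s"] = out_s, _["cls"] = out_cls,
      _["count_sample"] = out_cs, _["count_deme"] = out_cd,
      _["count_pop"] = out_cp,
      _["substitutions"] =
          List::create(_["pos"] = o_sub_pos, _["s"] = o_sub_s,
                       _["cls"] = o_sub_cls, _["gen"] = o_sub_gen),
      _["haplotypes"] = state);
}
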