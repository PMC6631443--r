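// Core engines: counter-based RNG, paired-end read sampling, k-mer indexed
// seed-and-extend alignment with seeded tie-breaking, pileup accumulation and
// exact k-mer occurrence counting. All randomness flows through a
// splitmix64-style generator keyed on (master seed, round, record index) so
// that rounds are order-independent and byte-reproducible.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Stateful stream seeded from a hashed key; statistically independent across
// keys, deterministic across platforms (no dependence on R's RNG).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t key) : s(sm64(key)) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
  // Box-Muller; one draw per call (second value discarded for simplicity).
  double norm() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

static inline uint64_t key3(double seed, double round, uint64_t i) {
  uint64_t a = sm64((uint64_t)(int64_t)seed);
  uint64_t b = sm64(a ^ (uint64_t)(int64_t)round);
  return b ^ sm64(i + 0x632BE59BD9B4E019ULL);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------- sampling

// Draw paired-end fragments uniformly (with replacement) over sampling
// intervals, apply substitution errors, return mate sequences plus truth.
// Intervals are 0-based [start, start+len) over the concatenated genome and
// are guaranteed by the caller not to cross contig boundaries.
// [[Rcpp::export]]
List cpp_sample_pairs(CharacterVector haplotypes, IntegerVector iv_start0,
                      IntegerVector iv_len, int n_pairs, int read_len,
                      double ins_mean, double ins_sd, int ins_min, int ins_max,
                      double err_rate, double seed, double round) {
  int n_h = haplotypes.size();
  std::vector<std::string> haps(n_h);
  for (int h = 0; h < n_h; ++h) haps[h] = as<std::string>(haplotypes[h]);
  int n_iv = iv_start0.size();
  std::vector<double> cumlen(n_iv);
  double tot = 0;
  for (int i = 0; i < n_iv; ++i) { tot += iv_len[i]; cumlen[i] = tot; }
  if (tot <= 0) stop("no sampling intervals");

  CharacterVector seq1(n_pairs), seq2(n_pairs);
  IntegerVector frag_start(n_pairs), frag_len(n_pairs), hap_idx(n_pairs);
  LogicalVector flip(n_pairs);
  IntegerVector n_err(n_pairs);

  for (int i = 0; i < n_pairs; ++i) {
    Rng rng(key3(seed, round, (uint64_t)i));
    // interval weighted by length
    double u = rng.unif() * tot;
    int iv = (int)(std::lower_bound(cumlen.begin(), cumlen.end(), u) -
                   cumlen.begin());
    if (iv >= n_iv) iv = n_iv - 1;
    int ins = (int)std::lround(ins_mean + ins_sd * rng.norm());
    if (ins < ins_min) ins = ins_min;
    if (ins > ins_max) ins = ins_max;
    if (ins > iv_len[iv]) ins = iv_len[iv];
    if (ins < read_len) ins = read_len; // degenerate guard
    int span = iv_len[iv] - ins;
    int start = iv_start0[iv] + (span > 0 ? rng.below(span + 1) : 0);
    int hap = (n_h > 1) ? rng.below(n_h) : 0;
    const std::string &g = haps[hap];
    std::string left = g.substr(start, read_len);
    std::string right = revcomp(g.substr(start + ins - read_len, read_len));
    bool fl = rng.unif() < 0.5; // which physical end becomes mate 1
    std::string m1 = fl ? right : left;
    std::string m2 = fl ? left : right;
    int ne = 0;
    if (err_rate > 0) {
      for (int b = 0; b < read_len; ++b) {
        if (rng.unif() < err_rate) {
          int c = base_code(m1[b]);
          if (c >= 0) { m1[b] = CODE_BASE[(c + 1 + rng.below(3)) % 4]; ++ne; }
        }
      }
      for (int b = 0; b < read_len; ++b) {
        if (rng.unif() < err_rate) {
          int c = base_code(m2[b]);
          if (c >= 0) { m2[b] = CODE_BASE[(c + 1 + rng.below(3)) % 4]; ++ne; }
        }
      }
    }
    seq1[i] = m1; seq2[i] = m2;
    frag_start[i] = start; frag_len[i] = ins;
    hap_idx[i] = hap + 1; flip[i] = fl; n_err[i] = ne;
  }
  return List::create(_["seq1"] = seq1, _["seq2"] = seq2,
                      _["frag_start0"] = frag_start, _["frag_len"] = frag_len,
                      _["haplotype"] = hap_idx, _["flip"] = flip,
                      _["n_errors"] = n_err);
}

// ---------------------------------------------------------------- indexing

struct KIndex {
  int k;
  int glen;
  std::unordered_map<uint64_t, std::vector<int>> pos;
};

static inline bool pack_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string genome, int k) {
  if (k < 1 || k > 31) stop("index k must be in [1, 31]");
  KIndex *ix = new KIndex();
  ix->k = k;
  ix->glen = (int)genome.size();
  int n = ix->glen - k + 1;
  for (int p = 0; p < n; ++p) {
    uint64_t v;
    if (pack_kmer(genome.c_str() + p, k, v)) ix->pos[v].push_back(p);
  }
  XPtr<KIndex> ptr(ix, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP idx) { return XPtr<KIndex>(idx)->k; }

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP idx, std::string kmer) {
  XPtr<KIndex> ix(idx);
  uint64_t v;
  if ((int)kmer.size() != ix->k || !pack_kmer(kmer.c_str(), ix->k, v))
    return IntegerVector(0);
  auto it = ix->pos.find(v);
  if (it == ix->pos.end()) return IntegerVector(0);
  return wrap(it->second); // 0-based
}

// ------------------------------------------------------------- alignment

struct Cand { int pos; int strand; }; // strand 0 = forward, 1 = reverse

static inline int hamming(const std::string &g, int pos, const std::string &r) {
  int mm = 0;
  const char *gp = g.c_str() + pos;
  for (size_t i = 0; i < r.size(); ++i)
    if (gp[i] != r[i]) ++mm;
  return mm;
}

// contig containing [pos, pos+len): cstart sorted 0-based starts, cend ends.
static inline int contig_of(const std::vector<int> &cstart,
                            const std::vector<int> &cend, int pos, int len) {
  int lo = (int)(std::upper_bound(cstart.begin(), cstart.end(), pos) -
                 cstart.begin()) - 1;
  if (lo < 0) return -1;
  if (pos + len > cend[lo]) return -1;
  return lo;
}

// Seed-and-extend candidate gathering: three non-overlapping seeds at fixed
// offsets {0, L/3, 2L/3}; a placement is a candidate if any seed hits.
static void gather_cands(const KIndex &ix, const std::string &oread,
                         int strand, int L, const std::vector<int> &cstart,
                         const std::vector<int> &cend,
                         std::vector<Cand> &cands) {
  int k = ix.k;
  int offs[3] = {0, L / 3, (2 * L) / 3};
  for (int s = 0; s < 3; ++s) {
    int off = offs[s];
    if (off + k > L) continue;
    uint64_t v;
    if (!pack_kmer(oread.c_str() + off, k, v)) continue;
    auto it = ix.pos.find(v);
    if (it == ix.pos.end()) continue;
    for (int p : it->second) {
      int st = p - off;
      if (st < 0) continue;
      if (contig_of(cstart, cend, st, L) < 0) continue;
      cands.push_back({st, strand});
    }
  }
}

static void dedupe(std::vector<Cand> &c) {
  std::sort(c.begin(), c.end(), [](const Cand &a, const Cand &b) {
    return a.strand != b.strand ? a.strand < b.strand : a.pos < b.pos;
  });
  c.erase(std::unique(c.begin(), c.end(), [](const Cand &a, const Cand &b) {
            return a.pos == b.pos && a.strand == b.strand;
          }),
          c.end());
}

struct Scored { int pos; int strand; int mm; };

static void score_cands(const std::string &g, const std::string &fwd,
                        const std::string &rev, std::vector<Cand> &cands,
                        std::vector<Scored> &out) {
  dedupe(cands);
  out.clear();
  for (const Cand &c : cands) {
    const std::string &r = (c.strand == 0) ? fwd : rev;
    out.push_back({c.pos, c.strand, hamming(g, c.pos, r)});
  }
}

struct SingleHit {
  bool mapped; int pos; int strand; int mm; int mapq; int tie;
};

static SingleHit pick_best(const std::vector<Scored> &sc, int max_mm,
                           Rng &rng) {
  SingleHit h; h.mapped = false; h.pos = -1; h.strand = 0; h.mm = 0;
  h.mapq = 0; h.tie = 0;
  int best = max_mm + 1, second = max_mm + 1;
  for (const Scored &s : sc) {
    if (s.mm < best) { second = best; best = s.mm; }
    else if (s.mm < second) second = s.mm;
  }
  if (best > max_mm) return h;
  std::vector<int> ties;
  for (size_t i = 0; i < sc.size(); ++i)
    if (sc[i].mm == best) ties.push_back((int)i);
  int pick = (ties.size() > 1) ? ties[rng.below((int)ties.size())] : ties[0];
  h.mapped = true;
  h.pos = sc[pick].pos; h.strand = sc[pick].strand; h.mm = best;
  h.tie = (int)ties.size();
  if (h.tie > 1) h.mapq = 0;
  else if (second > max_mm) h.mapq = 60; // no competing placement observed
  else h.mapq = std::min(60, 10 * (second - best) + 20);
  return h;
}

// Independent single-end mapping of a batch of reads.
// [[Rcpp::export]]
List cpp_map_single(SEXP idx, std::string genome, CharacterVector reads,
                    IntegerVector contig_start0, IntegerVector contig_end0,
                    int max_mm, double seed, double round) {
  XPtr<KIndex> ix(idx);
  std::vector<int> cs(contig_start0.begin(), contig_start0.end());
  std::vector<int> ce(contig_end0.begin(), contig_end0.end());
  int n = reads.size();
  IntegerVector pos0(n), strand(n), mm(n), mapq(n), tie(n);
  LogicalVector mapped(n);
  std::vector<Cand> cands;
  std::vector<Scored> sc;
  for (int i = 0; i < n; ++i) {
    Rng rng(key3(seed, round, 0x51ED270B0000ULL + (uint64_t)i));
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    int L = (int)fwd.size();
    cands.clear();
    gather_cands(*ix, fwd, 0, L, cs, ce, cands);
    gather_cands(*ix, rev, 1, L, cs, ce, cands);
    score_cands(genome, fwd, rev, cands, sc);
    SingleHit h = pick_best(sc, max_mm, rng);
    mapped[i] = h.mapped; pos0[i] = h.pos; strand[i] = h.strand;
    mm[i] = h.mm; mapq[i] = h.mapq; tie[i] = h.tie;
  }
  return List::create(_["mapped"] = mapped, _["pos0"] = pos0,
                      _["strand"] = strand, _["mm"] = mm, _["mapq"] = mapq,
                      _["tie_count"] = tie);
}

// Joint paired-end mapping. Proper combinations (opposite strands, leftmost
// mate forward, implied insert within [ins_lo, ins_hi]) are preferred and
// scored jointly; joint ties are broken with a single draw so the pair moves
// as a unit. If no proper combination exists each mate is placed on its own
// best hit with MAPQ forced to 0.
// [[Rcpp::export]]
List cpp_map_pairs(SEXP idx, std::string genome, CharacterVector seq1,
                   CharacterVector seq2, IntegerVector contig_start0,
                   IntegerVector contig_end0, int max_mm, double ins_lo,
                   double ins_hi, double seed, double round) {
  XPtr<KIndex> ix(idx);
  std::vector<int> cs(contig_start0.begin(), contig_start0.end());
  std::vector<int> ce(contig_end0.begin(), contig_end0.end());
  int n = seq1.size();
  IntegerVector pos1(n), strand1(n), mm1(n), mapq1(n), tie1(n);
  IntegerVector pos2(n), strand2(n), mm2(n), mapq2(n), tie2(n);
  LogicalVector mapped1(n), mapped2(n), proper(n);

  std::vector<Cand> c1, c2;
  std::vector<Scored> s1, s2;
  for (int i = 0; i < n; ++i) {
    Rng rng(key3(seed, round, 0xA11C4ED0000ULL + (uint64_t)i));
    std::string f1 = as<std::string>(seq1[i]);
    std::string r1 = revcomp(f1);
    std::string f2 = as<std::string>(seq2[i]);
    std::string r2 = revcomp(f2);
    int L1 = (int)f1.size(), L2 = (int)f2.size();
    c1.clear(); c2.clear();
    gather_cands(*ix, f1, 0, L1, cs, ce, c1);
    gather_cands(*ix, r1, 1, L1, cs, ce, c1);
    gather_cands(*ix, f2, 0, L2, cs, ce, c2);
    gather_cands(*ix, r2, 1, L2, cs, ce, c2);
    score_cands(genome, f1, r1, c1, s1);
    score_cands(genome, f2, r2, c2, s2);

    // enumerate proper joint placements
    struct Joint { int i1, i2, mm; };
    std::vector<Joint> joints;
    for (size_t a = 0; a < s1.size(); ++a) {
      if (s1[a].mm > max_mm) continue;
      for (size_t b = 0; b < s2.size(); ++b) {
        if (s2[b].mm > max_mm) continue;
        if (s1[a].strand == s2[b].strand) continue;
        int fwpos, rvpos, Lr;
        if (s1[a].strand == 0) { fwpos = s1[a].pos; rvpos = s2[b].pos; Lr = L2; }
        else { fwpos = s2[b].pos; rvpos = s1[a].pos; Lr = L1; }
        if (rvpos < fwpos) continue;
        int ins = rvpos + Lr - fwpos;
        if (ins < ins_lo || ins > ins_hi) continue;
        if (contig_of(cs, ce, fwpos, ins) < 0) continue; // same contig
        joints.push_back({(int)a, (int)b, s1[a].mm + s2[b].mm});
      }
    }
    if (!joints.empty()) {
      int best = max_mm * 2 + 2, second = best;
      for (const Joint &j : joints) {
        if (j.mm < best) { second = best; best = j.mm; }
        else if (j.mm < second) second = j.mm;
      }
      std::vector<int> ties;
      for (size_t j = 0; j < joints.size(); ++j)
        if (joints[j].mm == best) ties.push_back((int)j);
      int pick = (ties.size() > 1) ? ties[rng.below((int)ties.size())]
                                   : ties[0];
      const Joint &J = joints[pick];
      int q;
      if (ties.size() > 1) q = 0;
      else if (second > max_mm * 2 + 1) q = 60;
      else q = std::min(60, 10 * (second - best) + 20);
      mapped1[i] = true; pos1[i] = s1[J.i1].pos; strand1[i] = s1[J.i1].strand;
      mm1[i] = s1[J.i1].mm; mapq1[i] = q; tie1[i] = (int)ties.size();
      mapped2[i] = true; pos2[i] = s2[J.i2].pos; strand2[i] = s2[J.i2].strand;
      mm2[i] = s2[J.i2].mm; mapq2[i] = q; tie2[i] = (int)ties.size();
      proper[i] = true;
    } else {
      SingleHit h1 = pick_best(s1, max_mm, rng);
      SingleHit h2 = pick_best(s2, max_mm, rng);
      mapped1[i] = h1.mapped; pos1[i] = h1.pos; strand1[i] = h1.strand;
      mm1[i] = h1.mm; mapq1[i] = 0; tie1[i] = h1.tie;
      mapped2[i] = h2.mapped; pos2[i] = h2.pos; strand2[i] = h2.strand;
      mm2[i] = h2.mm; mapq2[i] = 0; tie2[i] = h2.tie;
      proper[i] = false;
    }
  }
  return List::create(
      _["mapped1"] = mapped1, _["pos1_0"] = pos1, _["strand1"] = strand1,
      _["mm1"] = mm1, _["mapq1"] = mapq1, _["tie1"] = tie1,
      _["mapped2"] = mapped2, _["pos2_0"] = pos2, _["strand2"] = strand2,
      _["mm2"] = mm2, _["mapq2"] = mapq2, _["tie2"] = tie2,
      _["proper"] = proper);
}

// ---------------------------------------------------------------- pileup

// Accumulate per-position allele counts over the concatenated genome.
// Sequences arrive read-orientation; reverse-strand reads are complemented
// here. Non-ACGT read bases are skipped (do not count toward depth).
// [[Rcpp::export]]
List cpp_pileup(std::string genome, IntegerVector pos0, IntegerVector strand,
                CharacterVector seqs, IntegerVector mapq, int min_mapq) {
  int G = (int)genome.size();
  std::vector<int> cnt(4L * G, 0);
  std::vector<int> nq0(G, 0);
  int n = pos0.size();
  for (int i = 0; i < n; ++i) {
    if (mapq[i] < min_mapq) continue;
    std::string s = as<std::string>(seqs[i]);
    if (strand[i] == 1) s = revcomp(s);
    int p = pos0[i];
    if (p < 0 || p + (int)s.size() > G) stop("alignment beyond genome end");
    bool q0 = (mapq[i] == 0);
    for (size_t b = 0; b < s.size(); ++b) {
      int c = base_code(s[b]);
      if (c < 0) continue;
      cnt[(size_t)(p + b) * 4 + c]++;
      if (q0) nq0[p + b]++;
    }
  }
  std::vector<int> opos; std::vector<int> oa, oc, og, ot, oq;
  for (int p = 0; p < G; ++p) {
    int d = cnt[(size_t)p * 4] + cnt[(size_t)p * 4 + 1] +
            cnt[(size_t)p * 4 + 2] + cnt[(size_t)p * 4 + 3];
    if (d == 0) continue;
    opos.push_back(p);
    oa.push_back(cnt[(size_t)p * 4]);
    oc.push_back(cnt[(size_t)p * 4 + 1]);
    og.push_back(cnt[(size_t)p * 4 + 2]);
    ot.push_back(cnt[(size_t)p * 4 + 3]);
    oq.push_back(nq0[p]);
  }
  return List::create(_["pos0"] = wrap(opos), _["A"] = wrap(oa),
                      _["C"] = wrap(oc), _["G"] = wrap(og),
                      _["T"] = wrap(ot), _["n_mapq0"] = wrap(oq));
}

// ------------------------------------------------------------ mappability

// Exact-occurrence count of the k-mer starting at each position, counting
// matches on both strands genome-wide. A palindromic k-mer is not counted
// twice for the same site.
// String-hashed variant for windows too long to 2-bit pack.
static IntegerVector kmer_occ_long(const std::string &genome, int k) {
  int n = (int)genome.size() - k + 1;
  if (n < 1) stop("k larger than sequence");
  std::unordered_map<std::string, int> tab;
  tab.reserve((size_t)n * 2);
  for (int p = 0; p < n; ++p) tab[genome.substr(p, k)]++;
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    std::string fw = genome.substr(p, k);
    bool valid = true;
    for (char c : fw) if (base_code(c) < 0) { valid = false; break; }
    if (!valid) { out[p] = NA_INTEGER; continue; }
    std::string rc = revcomp(fw);
    int cnt = tab[fw];
    if (rc != fw) {
      auto it = tab.find(rc);
      if (it != tab.end()) cnt += it->second;
    }
    out[p] = cnt;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_occ(std::string genome, int k) {
  if (k < 1) stop("k must be positive");
  if (k > 31) return kmer_occ_long(genome, k);
  int n = (int)genome.size() - k + 1;
  if (n < 1) stop("k larger than sequence");
  std::unordered_map<uint64_t, int> tab;
  std::vector<uint64_t> packed(n);
  std::vector<char> ok(n, 0);
  for (int p = 0; p < n; ++p) {
    uint64_t v;
    if (pack_kmer(genome.c_str() + p, k, v)) {
      packed[p] = v; ok[p] = 1; tab[v]++;
    }
  }
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    if (!ok[p]) { out[p] = NA_INTEGER; continue; }
    // reverse complement of packed k-mer
    uint64_t v = packed[p], rc = 0;
    for (int i = 0; i < k; ++i) { rc = (rc << 2) | (3 - (v & 3)); v >>= 2; }
    int c = tab[packed[p]];
    if (rc != packed[p]) {
      auto it = tab.find(rc);
      if (it != tab.end()) c += it->second;
    }
    out[p] = c;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_derive_seed(double seed, double round) {
  // 31-bit positive seed derived for R-side RNG scoping
  return (double)(sm64(key3(seed, round, 0xDE5EEDULL)) & 0x7FFFFFFFULL);
}
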