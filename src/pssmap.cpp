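// Core index and search routines.
//
// Alphabet encoding used throughout: $=0 (sentinel), A=1, C=2, G=3, T=4,
// so that lexicographic order is $ < A < C < G < T and the complement of
// base b is 5-b.  The indexed text is genome ++ reverse_complement(genome)
// with a single sentinel appended at the end; '-'-strand hits are recovered
// from the second half by coordinate reflection.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- FM index

// Suffix array by prefix doubling: O(n log^2 n), robust on repetitive text.
static std::vector<int> suffix_array(const std::vector<int>& T) {
  const int n = (int)T.size();
  std::vector<int> sa(n), r(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; r[i] = T[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + k < n ? r[a + k] : -1;
      int rb = b + k < n ? r[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    r = tmp;
    if (r[sa[n - 1]] == n - 1 || k >= n) break;
  }
  return sa;
}

// Build BWT, C array, occurrence checkpoints and a position-sampled suffix
// array over text (values 1..4); the sentinel is appended here.
// [[Rcpp::export]]
List cpp_fm_build(IntegerVector text, int occ_rate, int sa_rate) {
  const int m = text.size();
  const int n = m + 1;
  std::vector<int> T(n);
  for (int i = 0; i < m; ++i) {
    if (text[i] < 1 || text[i] > 4) stop("text values must be in 1..4");
    T[i] = text[i];
  }
  T[m] = 0;  // sentinel

  std::vector<int> sa = suffix_array(T);

  IntegerVector bwt(n);
  for (int i = 0; i < n; ++i) bwt[i] = T[(sa[i] + n - 1) % n];

  IntegerVector C(5);
  {
    int cnt[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) cnt[T[i]]++;
    C[0] = 0;
    for (int b = 1; b < 5; ++b) C[b] = C[b - 1] + cnt[b - 1];
  }

  const int ncp = n / occ_rate + 1;
  IntegerMatrix occ(4, ncp);
  {
    int run[4] = {0, 0, 0, 0};
    for (int j = 0, i = 0; j < ncp; ++j) {
      for (int b = 0; b < 4; ++b) occ(b, j) = run[b];
      for (int s = 0; s < occ_rate && i < n; ++s, ++i)
        if (bwt[i] >= 1) run[bwt[i] - 1]++;
    }
  }

  // position-sampled SA: ranks whose suffix position is a multiple of sa_rate
  std::vector<int> keys, vals;
  for (int i = 0; i < n; ++i)
    if (sa[i] % sa_rate == 0) { keys.push_back(i); vals.push_back(sa[i]); }

  return List::create(_["bwt"] = bwt, _["C"] = C, _["occ"] = occ,
                      _["occ_rate"] = occ_rate,
                      _["ssa_keys"] = IntegerVector(keys.begin(), keys.end()),
                      _["ssa_vals"] = IntegerVector(vals.begin(), vals.end()),
                      _["sa_rate"] = sa_rate, _["n"] = n);
}

struct FM {
  const int* bwt;
  const int* C;
  const int* occ;  // 4 x ncp, column-major
  int occ_rate;
  const int* ssa_keys;
  const int* ssa_vals;
  int nssa;
  int sa_rate;
  int n;
};

static FM unpack(const List& idx) {
  FM f;
  f.bwt = INTEGER(((IntegerVector)idx["bwt"]));
  f.C = INTEGER(((IntegerVector)idx["C"]));
  f.occ = INTEGER(((IntegerMatrix)idx["occ"]));
  f.occ_rate = as<int>(idx["occ_rate"]);
  IntegerVector k = idx["ssa_keys"], v = idx["ssa_vals"];
  f.ssa_keys = INTEGER(k);
  f.ssa_vals = INTEGER(v);
  f.nssa = k.size();
  f.sa_rate = as<int>(idx["sa_rate"]);
  f.n = as<int>(idx["n"]);
  return f;
}

// occurrences of base b (1..4) in bwt[0 .. pos), pos in [0, n]
static inline int occ_count(const FM& f, int b, int pos) {
  int cp = pos / f.occ_rate;
  int cnt = f.occ[(size_t)cp * 4 + (b - 1)];
  for (int i = cp * f.occ_rate; i < pos; ++i)
    if (f.bwt[i] == b) cnt++;
  return cnt;
}

// backward-search interval update; interval [k,l] of suffix ranks, 0-based
static inline void bstep(const FM& f, int b, int k, int l, int* k2, int* l2) {
  *k2 = f.C[b] + occ_count(f, b, k);
  *l2 = f.C[b] + occ_count(f, b, l + 1) - 1;
}

// [[Rcpp::export]]
IntegerVector cpp_backward_step(List idx, int k, int l, int b) {
  FM f = unpack(idx);
  if (b < 1 || b > 4) stop("base must be in 1..4");
  if (k > l) return IntegerVector::create(1, 0);  // empty stays empty
  int k2, l2;
  bstep(f, b, k, l, &k2, &l2);
  return IntegerVector::create(k2, l2);
}

static inline int lf(const FM& f, int r) {
  int b = f.bwt[r];
  if (b == 0) return 0;
  return f.C[b] + occ_count(f, b, r);
}

// text position of the suffix with rank r
static int locate_rank(const FM& f, int r) {
  int steps = 0;
  for (;;) {
    const int* hit =
        std::lower_bound(f.ssa_keys, f.ssa_keys + f.nssa, r);
    if (hit != f.ssa_keys + f.nssa && *hit == r)
      return f.ssa_vals[hit - f.ssa_keys] + steps;
    r = lf(f, r);
    steps++;
  }
}

// [[Rcpp::export]]
int cpp_locate_rank(List idx, int r) {
  FM f = unpack(idx);
  if (r < 0 || r >= f.n) stop("rank out of range");
  return locate_rank(f, r);
}

// [[Rcpp::export]]
int cpp_lf(List idx, int r) {
  FM f = unpack(idx);
  if (r < 0 || r >= f.n) stop("rank out of range");
  return lf(f, r);
}

// ----------------------------------------------------- threshold tightening

// Forward scan of the read charging a forced score loss each time the
// current subsequence has no exact occurrence in the two-strand text.
// The prefix x[z..j] is tracked via backward search of its reverse
// complement (present in the index iff the prefix is).  Returns D of
// length L+1; D[i] applies to the prefix x[0..i-1].  read values 0 (=N)
// reset the stretch without charge.
// [[Rcpp::export]]
NumericVector cpp_tightening(List idx, IntegerVector read,
                             NumericVector charges, double cap) {
  FM f = unpack(idx);
  const int L = read.size();
  NumericVector D(L + 1);
  double committed = 0.0;
  int k = 0, l = f.n - 1;
  double stretch_min = R_PosInf;
  for (int j = 0; j < L; ++j) {
    int b = read[j];
    if (b == 0) {  // N: unconstrained, restart the stretch
      k = 0; l = f.n - 1; stretch_min = R_PosInf;
      D[j + 1] = committed;
      continue;
    }
    int k2, l2;
    bstep(f, 5 - b, k, l, &k2, &l2);  // extend pattern forward via RC
    stretch_min = std::min(stretch_min, charges[j]);
    if (k2 > l2) {  // no occurrence: one forced mismatch in the stretch
      committed += std::max(0.0, stretch_min);
      k = 0; l = f.n - 1; stretch_min = R_PosInf;
    } else {
      k = k2; l = l2;
    }
    D[j + 1] = committed;
  }
  if (R_finite(cap))
    for (int i = 0; i <= L; ++i) D[i] = std::min(D[i], cap);
  return D;
}

// ----------------------------------------------------------------- search

struct Edit {
  int16_t pos;  // read column (I) or insertion point dpos (D)
  int8_t op;    // 1 = I, 2 = D
};

struct Node {
  double off;    // offset from the best possible score over consumed columns
  double s;      // accumulated score incl. gap penalties
  double sp;     // PSSM part of the score (no gap penalties)
  int k, l;      // suffix-array interval
  int16_t i;     // next read column to consume; -1 when fully consumed
  uint8_t ai, ad;
  int8_t state;  // 0 match/mismatch, 1 insertion, 2 deletion
  uint32_t seq;  // FIFO tie-break among equal offsets
  Edit edits[4];
  uint8_t ne;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.off != b.off) return a.off < b.off;
    return a.seq < b.seq;
  }
};

// bounded double-ended priority queue keyed by (offset, seq)
struct Dheap {
  std::set<Node, NodeCmp> s;
  size_t cap;
  explicit Dheap(size_t cap_) : cap(cap_) {}
  void push(const Node& nd) {
    if (cap > 0 && s.size() >= cap) {
      auto worst = std::prev(s.end());
      if (!(NodeCmp()(nd, *worst))) return;  // new one is the worst: drop it
      s.erase(worst);
    }
    s.insert(nd);
  }
  bool empty() const { return s.empty(); }
  Node pop_min() {
    Node nd = *s.begin();
    s.erase(s.begin());
    return nd;
  }
};

struct Hit {
  int pos;     // 0-based forward-genome offset
  int strand;  // 0 = '+', 1 = '-'
  double score, pssm_score;
  int ai, ad;
  std::string cigar;
};

static std::string make_cigar(int L, const Edit* edits, int ne, bool minus) {
  // alignment ops in read coordinates (5'->3' of the read as searched)
  std::vector<std::pair<double, char>> ops;
  for (int c = 0; c < L; ++c) ops.push_back({(double)c, 'M'});
  for (int e = 0; e < ne; ++e) {
    if (edits[e].op == 1)
      ops[edits[e].pos].second = 'I';
    else
      ops.push_back({edits[e].pos - 0.5, 'D'});  // between columns
  }
  std::sort(ops.begin(), ops.end());
  if (minus) std::reverse(ops.begin(), ops.end());
  std::string out;
  int run = 0;
  char cur = 0;
  for (auto& oc : ops) {
    if (oc.second == cur) {
      run++;
    } else {
      if (run) out += std::to_string(run) + cur;
      cur = oc.second;
      run = 1;
    }
  }
  if (run) out += std::to_string(run) + cur;
  return out;
}

// Best-first PSSM search over the FM index (backward consumption of the
// read), with per-position thresholds T, global threshold t and linear
// gap penalties.  Emits located, validated, deduplicated hits.
// [[Rcpp::export]]
DataFrame cpp_search(List idx, NumericMatrix scores, NumericVector T,
                     double t, double rho_i, double rho_d, int heap_capacity,
                     int max_hits, int max_indels, bool indels, int gap_margin,
                     int forward_length, IntegerVector mask,
                     IntegerVector junctions) {
  FM f = unpack(idx);
  const int L = scores.nrow();
  const double eps = 1e-9;

  std::vector<double> colmax(L);
  for (int i = 0; i < L; ++i) {
    double m = scores(i, 0);
    for (int g = 1; g < 4; ++g) m = std::max(m, scores(i, g));
    colmax[i] = m;
  }
  // summax_suffix[j] = sum of column maxima over columns j..L-1
  std::vector<double> sms(L + 1, 0.0);
  for (int j = L - 1; j >= 0; --j) sms[j] = sms[j + 1] + colmax[j];

  if (max_indels > 4) max_indels = 4;

  Dheap heap((size_t)std::max(heap_capacity, 0));
  uint32_t seq = 0;
  Node root{};
  root.off = 0.0; root.s = 0.0; root.sp = 0.0;
  root.k = 0; root.l = f.n - 1;
  root.i = (int16_t)(L - 1);
  root.ai = root.ad = 0; root.state = 0; root.seq = seq++; root.ne = 0;
  heap.push(root);

  std::map<std::pair<int, int>, Hit> found;  // (pos, strand) -> best hit
  std::vector<std::pair<int, int>> order;    // emission order of loci
  const int* mk = INTEGER(mask);
  const int nmk = mask.size();
  const int* jn = INTEGER(junctions);
  const int njn = junctions.size();
  long expansions = 0;
  const long max_expansions = 50000000L;

  while (!heap.empty()) {
    Node nd = heap.pop_min();
    if (++expansions > max_expansions) break;

    if (nd.i < 0) {  // fully consumed: locate and report
      if (nd.s < t - eps) continue;
      const int mref = L - nd.ai + nd.ad;  // reference span
      for (int r = nd.k; r <= nd.l; ++r) {
        int p = locate_rank(f, r);
        int pos, strand;
        if (p + mref <= forward_length) {
          pos = p; strand = 0;
        } else if (p >= forward_length && p + mref <= 2 * forward_length) {
          pos = 2 * forward_length - p - mref; strand = 1;
        } else {
          continue;  // spans the strand junction or the sentinel
        }
        bool bad = false;
        // reject overlap with masked (former N) positions
        const int* lo = std::lower_bound(mk, mk + nmk, pos);
        if (lo != mk + nmk && *lo < pos + mref) bad = true;
        // reject spanning a chromosome junction
        for (int q = 0; q < njn && !bad; ++q)
          if (jn[q] > pos && jn[q] < pos + mref) bad = true;
        if (bad) continue;
        auto key = std::make_pair(pos, strand);
        auto it = found.find(key);
        if (it == found.end()) {
          Hit h;
          h.pos = pos; h.strand = strand;
          h.score = nd.s; h.pssm_score = nd.sp;
          h.ai = nd.ai; h.ad = nd.ad;
          h.cigar = make_cigar(L, nd.edits, nd.ne, strand == 1);
          found[key] = h;
          order.push_back(key);
          if ((int)found.size() >= max_hits) goto done;
        } else if (nd.s > it->second.score) {
          it->second.score = nd.s;
          it->second.pssm_score = nd.sp;
          it->second.ai = nd.ai; it->second.ad = nd.ad;
          it->second.cigar = make_cigar(L, nd.edits, nd.ne, strand == 1);
        }
      }
      continue;
    }

    const int i = nd.i;
    // match / mismatch branches: consume column i, step interval by g
    for (int g = 1; g <= 4; ++g) {
      int k2, l2;
      bstep(f, g, nd.k, nd.l, &k2, &l2);
      if (k2 > l2) continue;
      double s2 = nd.s + scores(i, g - 1);
      if (s2 < T[i] - eps) continue;
      Node ch = nd;
      ch.k = k2; ch.l = l2;
      ch.s = s2; ch.sp = nd.sp + scores(i, g - 1);
      ch.i = (int16_t)(i - 1);
      ch.state = 0;
      ch.off = sms[i] - s2;
      ch.seq = seq++;
      heap.push(ch);
    }
    if (indels && nd.ai + nd.ad < max_indels && i >= gap_margin &&
        i <= L - 1 - gap_margin) {
      // insertion: consume read column i without stepping the interval
      if (nd.state != 2) {
        double s2 = nd.s - rho_i;
        if (s2 >= T[i] - eps) {
          Node ch = nd;
          ch.s = s2;
          ch.i = (int16_t)(i - 1);
          ch.ai++; ch.state = 1;
          ch.off = sms[i] - s2;
          ch.seq = seq++;
          ch.edits[ch.ne].pos = (int16_t)i;
          ch.edits[ch.ne].op = 1;
          ch.ne++;
          heap.push(ch);
        }
      }
      // deletion: step the interval by any g without consuming a column
      if (nd.state != 1) {
        double s2 = nd.s - rho_d;
        double thr = (i + 1 <= L - 1) ? T[i + 1] : R_NegInf;
        if (s2 >= thr - eps) {
          for (int g = 1; g <= 4; ++g) {
            int k2, l2;
            bstep(f, g, nd.k, nd.l, &k2, &l2);
            if (k2 > l2) continue;
            Node ch = nd;
            ch.k = k2; ch.l = l2;
            ch.s = s2;
            ch.ad++; ch.state = 2;
            ch.off = sms[i + 1] - s2;
            ch.seq = seq++;
            ch.edits[ch.ne].pos = (int16_t)(i + 1);
            ch.edits[ch.ne].op = 2;
            ch.ne++;
            heap.push(ch);
          }
        }
      }
    }
  }
done:;

  const int nh = (int)order.size();
  IntegerVector pos(nh), strand(nh), ai(nh), ad(nh);
  NumericVector score(nh), pssm_score(nh);
  CharacterVector cigar(nh);
  for (int j = 0; j < nh; ++j) {
    const Hit& h = found[order[j]];
    pos[j] = h.pos;
    strand[j] = h.strand;
    score[j] = h.score;
    pssm_score[j] = h.pssm_score;
    ai[j] = h.ai;
    ad[j] = h.ad;
    cigar[j] = h.cigar;
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strand,
                           _["score"] = score, _["pssm_score"] = pssm_score,
                           _["a_i"] = ai, _["a_d"] = ad, _["cigar"] = cigar,
                           _["stringsAsFactors"] = false);
}

// Score every window of both strands (test oracle and denominator check).
// genome: values 1..4; returns windows with score >= t - 1e-9.
// [[Rcpp::export]]
DataFrame cpp_scan_windows(IntegerVector genome, NumericMatrix scores,
                           double t) {
  const int n = genome.size();
  const int L = scores.nrow();
  std::vector<int> pos, strand;
  std::vector<double> sc;
  const double eps = 1e-9;
  for (int p = 0; p + L <= n; ++p) {
    double s = 0.0;
    for (int i = 0; i < L; ++i) s += scores(i, genome[p + i] - 1);
    if (s >= t - eps) { pos.push_back(p); strand.push_back(0); sc.push_back(s); }
    // '-' strand: read aligns to the reverse complement of this window
    s = 0.0;
    for (int i = 0; i < L; ++i) s += scores(i, 4 - genome[p + L - 1 - i]);
    if (s >= t - eps) { pos.push_back(p); strand.push_back(1); sc.push_back(s); }
  }
  return DataFrame::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                           _["strand"] = IntegerVector(strand.begin(), strand.end()),
                           _["score"] = NumericVector(sc.begin(), sc.end()));
}
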