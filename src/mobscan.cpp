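#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Words are w-bit values (1 <= w <= 53) carried across the R boundary as
// doubles, which are exact in that range.

static inline uint64_t mask_w(int w) {
  return (w >= 64) ? ~0ULL : ((1ULL << w) - 1ULL);
}

static inline uint64_t rotl_w(uint64_t x, long long i, int w) {
  uint64_t m = mask_w(w);
  x &= m;
  int r = (int)(i % w);
  if (r == 0) return x;
  return ((x << r) | (x >> (w - r))) & m;
}

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static void load_codes(const NumericVector& codes, uint64_t out[4]) {
  if (codes.size() != 4) stop("base code table must have exactly 4 entries");
  for (int k = 0; k < 4; ++k) out[k] = (uint64_t)codes[k];
}

// [[Rcpp::export]]
NumericVector cpp_rotate_left(NumericVector x, NumericVector i, int w) {
  if (w < 1 || w > 53) stop("word width must be between 1 and 53 bits");
  R_xlen_t n = std::max(x.size(), i.size());
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    double xv = x[k % x.size()];
    double iv = i[k % i.size()];
    if (iv < 0) stop("rotation count must be non-negative");
    out[k] = (double)rotl_w((uint64_t)xv, (long long)iv, w);
  }
  return out;
}

static uint64_t hash_lgram_raw(const char* t, int L, const uint64_t code[4], int w) {
  uint64_t h = 0;
  for (int k = 0; k < L; ++k) {
    int b = base_index(t[k]);
    if (b < 0) stop("L-gram contains a base outside {A,C,G,T}");
    h ^= rotl_w(code[b], L - 1 - k, w);
  }
  return h;
}

// [[Rcpp::export]]
double cpp_hash_lgram(std::string t, NumericVector codes, int w) {
  uint64_t code[4];
  load_codes(codes, code);
  return (double)hash_lgram_raw(t.c_str(), (int)t.size(), code, w);
}

// [[Rcpp::export]]
double cpp_roll(double h, std::string out_base, std::string in_base, int L,
                NumericVector codes, int w) {
  uint64_t code[4];
  load_codes(codes, code);
  int bo = base_index(out_base[0]);
  int bi = base_index(in_base[0]);
  if (bo < 0 || bi < 0) stop("rolled bases must be in {A,C,G,T}");
  uint64_t hh = rotl_w((uint64_t)h, 1, w);
  return (double)((hh ^ rotl_w(code[bo], L, w) ^ code[bi]) & mask_w(w));
}

// Hash every window of s. Windows overlapping a non-ACGT character get NA.
// rolling = true chains hashes along maximal ACGT runs of length >= L;
// rolling = false evaluates the summation formula independently per window.
// [[Rcpp::export]]
NumericVector cpp_hash_windows(std::string s, int L, NumericVector codes, int w,
                               bool rolling) {
  uint64_t code[4];
  load_codes(codes, code);
  long long n = (long long)s.size();
  long long total = n - L + 1;
  if (total < 1) return NumericVector(0);
  NumericVector out(total, NA_REAL);
  const char* p = s.c_str();
  long long run_start = 0;
  while (run_start < n) {
    while (run_start < n && base_index(p[run_start]) < 0) ++run_start;
    long long run_end = run_start;
    while (run_end < n && base_index(p[run_end]) >= 0) ++run_end;
    long long run_len = run_end - run_start;
    if (run_len >= L) {
      if (rolling) {
        uint64_t h = hash_lgram_raw(p + run_start, L, code, w);
        out[run_start] = (double)h;
        for (long long j = run_start + 1; j + L <= run_end; ++j) {
          uint64_t hh = rotl_w(h, 1, w);
          h = (hh ^ rotl_w(code[base_index(p[j - 1])], L, w)
                  ^ code[base_index(p[j + L - 1])]) & mask_w(w);
          out[j] = (double)h;
        }
      } else {
        for (long long j = run_start; j + L <= run_end; ++j)
          out[j] = (double)hash_lgram_raw(p + j, L, code, w);
      }
    }
    run_start = run_end;
  }
  return out;
}

struct LgramIndex {
  std::string ref;
  int L;
  int w;
  uint64_t code[4];
  long long n_positions;
  std::unordered_map<uint64_t, std::vector<int> > tab;
};

// [[Rcpp::export]]
SEXP cpp_build_index(std::string ref, int L, NumericVector codes, int w) {
  LgramIndex* idx = new LgramIndex();
  idx->ref = ref;
  idx->L = L;
  idx->w = w;
  load_codes(codes, idx->code);
  idx->n_positions = 0;
  idx->tab.max_load_factor(0.75f);

  long long n = (long long)ref.size();
  const char* p = idx->ref.c_str();
  long long run_start = 0;
  while (run_start < n) {
    while (run_start < n && base_index(p[run_start]) < 0) ++run_start;
    long long run_end = run_start;
    while (run_end < n && base_index(p[run_end]) >= 0) ++run_end;
    if (run_end - run_start >= L) {
      uint64_t h = hash_lgram_raw(p + run_start, L, idx->code, w);
      idx->tab[h].push_back((int)run_start);
      idx->n_positions++;
      for (long long j = run_start + 1; j + L <= run_end; ++j) {
        uint64_t hh = rotl_w(h, 1, w);
        h = (hh ^ rotl_w(idx->code[base_index(p[j - 1])], L, w)
                ^ idx->code[base_index(p[j + L - 1])]) & mask_w(w);
        idx->tab[h].push_back((int)j);
        idx->n_positions++;
      }
    }
    run_start = run_end;
  }
  XPtr<LgramIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp_) {
  XPtr<LgramIndex> xp(xp_);
  return List::create(_["n_positions"] = (double)xp->n_positions,
                      _["n_buckets"] = (double)xp->tab.size(),
                      _["L"] = xp->L, _["w"] = xp->w,
                      _["ref_length"] = (double)xp->ref.size());
}

// Occurrence list (0-based, ascending) of one exact L-gram; string-verified.
// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp_, std::string gram) {
  XPtr<LgramIndex> xp(xp_);
  if ((int)gram.size() != xp->L) stop("query gram length differs from index L");
  for (char c : gram)
    if (base_index(c) < 0) stop("query gram contains a base outside {A,C,G,T}");
  uint64_t h = hash_lgram_raw(gram.c_str(), xp->L, xp->code, xp->w);
  std::vector<int> hits;
  auto it = xp->tab.find(h);
  if (it != xp->tab.end()) {
    for (int i : it->second)
      if (std::memcmp(xp->ref.c_str() + i, gram.c_str(), xp->L) == 0)
        hits.push_back(i);
  }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// Phase 1: map every valid query window onto its verified occurrence list in
// the reference. Hash hits are confirmed by direct base-string comparison so
// collisions can never create a false common L-gram.
// [[Rcpp::export]]
List cpp_find_common(SEXP xp_, std::string query) {
  XPtr<LgramIndex> xp(xp_);
  int L = xp->L, w = xp->w;
  long long n = (long long)query.size();
  long long total = n - L + 1;
  if (total < 0) total = 0;
  long long valid = 0, common = 0, multi = 0;

  std::vector<int> js;
  List occs_acc;
  std::vector<std::vector<int> > occ_store;

  const char* q = query.c_str();
  const char* r = xp->ref.c_str();
  long long run_start = 0;
  while (run_start < n) {
    while (run_start < n && base_index(q[run_start]) < 0) ++run_start;
    long long run_end = run_start;
    while (run_end < n && base_index(q[run_end]) >= 0) ++run_end;
    if (run_end - run_start >= L) {
      uint64_t h = hash_lgram_raw(q + run_start, L, xp->code, w);
      for (long long j = run_start; j + L <= run_end; ++j) {
        if (j > run_start) {
          uint64_t hh = rotl_w(h, 1, w);
          h = (hh ^ rotl_w(xp->code[base_index(q[j - 1])], L, w)
                  ^ xp->code[base_index(q[j + L - 1])]) & mask_w(w);
        }
        ++valid;
        auto it = xp->tab.find(h);
        if (it == xp->tab.end()) continue;
        std::vector<int> hits;
        for (int i : it->second)
          if (std::memcmp(r + i, q + j, L) == 0) hits.push_back(i);
        if (hits.empty()) continue;
        std::sort(hits.begin(), hits.end());
        ++common;
        if (hits.size() >= 2) ++multi;
        js.push_back((int)j);
        occ_store.push_back(std::move(hits));
      }
    }
    run_start = run_end;
  }

  List occs(occ_store.size());
  for (size_t k = 0; k < occ_store.size(); ++k) occs[k] = wrap(occ_store[k]);
  return List::create(
    _["j"] = wrap(js),
    _["occs"] = occs,
    _["stats"] = List::create(_["total"] = (double)total,
                              _["valid"] = (double)valid,
                              _["common"] = (double)common,
                              _["multi"] = (double)multi));
}

// Phase 2: greedy left-to-right chaining of common L-grams into colinear,
// disjoint conserved segment pairs. j must be ascending; occurrence lists
// ascending. Gap conditions: d2 <= delta1 and |d1 - d2| <= delta2 with
// d1 = k - i_last - L, d2 = j - j_last - L; extension also requires
// i_last < k. New segments start at the nearest admissible occurrence
// (ties to the smaller coordinate) at or beyond the reference frontier, so
// segments stay colinear and disjoint on both sides by construction.
// [[Rcpp::export]]
IntegerMatrix cpp_chain(IntegerVector j, List occs, int L, int delta1,
                        int delta2) {
  int n = j.size();
  std::vector<int> rs, re, qs, qe, na;
  long long ref_frontier = 0, query_frontier = 0;
  int idx = 0;
  while (true) {
    // (1) starting-point search
    int start = -1, i_star = -1;
    for (int t = idx; t < n; ++t) {
      if (j[t] < query_frontier) continue;
      IntegerVector oc = occs[t];
      long long best_d = -1;
      int best_i = -1;
      for (int u = 0; u < oc.size(); ++u) {
        int i = oc[u];
        if (i < ref_frontier) continue;
        long long d = llabs((long long)j[t] - (long long)i);
        if (best_i < 0 || d < best_d || (d == best_d && i < best_i)) {
          best_d = d;
          best_i = i;
        }
      }
      if (best_i >= 0) {
        start = t;
        i_star = best_i;
        break;
      }
    }
    if (start < 0) break;

    // (2) segment extension
    long long i_first = i_star, i_last = i_star;
    long long j_first = j[start], j_last = j[start];
    int anchors = 1;
    for (int t = start + 1; t < n; ++t) {
      long long d2 = (long long)j[t] - j_last - L;
      if (d2 > delta1) break;
      IntegerVector oc = occs[t];
      long long best_dev = -1;
      int best_k = -1;
      for (int u = 0; u < oc.size(); ++u) {
        int k = oc[u];
        if (k <= i_last) continue;
        long long d1 = (long long)k - i_last - L;
        long long dev = llabs(d1 - d2);
        if (dev > delta2) continue;
        if (best_k < 0 || dev < best_dev || (dev == best_dev && k < best_k)) {
          best_dev = dev;
          best_k = k;
        }
      }
      if (best_k >= 0) {
        i_last = best_k;
        j_last = j[t];
        ++anchors;
      }
    }

    // (3) mapping update
    rs.push_back((int)i_first);
    re.push_back((int)(i_last + L));
    qs.push_back((int)j_first);
    qe.push_back((int)(j_last + L));
    na.push_back(anchors);
    ref_frontier = i_last + L;
    query_frontier = j_last + L;
    while (idx < n && j[idx] < query_frontier) ++idx;
  }

  IntegerMatrix out((int)rs.size(), 5);
  for (size_t k = 0; k < rs.size(); ++k) {
    out(k, 0) = rs[k];
    out(k, 1) = re[k];
    out(k, 2) = qs[k];
    out(k, 3) = qe[k];
    out(k, 4) = na[k];
  }
  colnames(out) = CharacterVector::create("ref_start", "ref_end", "query_start",
                                          "query_end", "anchors");
  return out;
}
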