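#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
#include <numeric>
#ifdef __SSE2__
#include <emmintrin.h>
#endif

using namespace Rcpp;

// Local alignment under the LAST-style scoring contract: match +1,
// mismatch -1, affine gaps costing open + extend * length (a gap of
// length 1 costs open + extend). Scores are clamped at 0 (Smith-
// Waterman). Sequences must be A/C/G/T and are encoded to 0..3.

static inline void encode_seq(const char* s, int n, std::vector<int8_t>& out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    switch (s[i]) {
    case 'A': case 'a': out[i] = 0; break;
    case 'C': case 'c': out[i] = 1; break;
    case 'G': case 'g': out[i] = 2; break;
    case 'T': case 't': out[i] = 3; break;
    default:
      stop("sequence contains a non-ACGT character: '%c'", s[i]);
    }
  }
}

// scalar score-only Gotoh, O(n) memory
static int sw1(const int8_t* q, int m, const int8_t* t, int n,
               int match, int mismatch, int go, int ge,
               std::vector<int>& Hbuf, std::vector<int>& Ebuf) {
  Hbuf.assign(n + 1, 0); Ebuf.assign(n + 1, 0);
  int* H = Hbuf.data(); int* E = Ebuf.data();
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int hd = 0, hl = 0, f = 0;
    const int8_t qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      int hup = H[j];
      int e = std::max(E[j] - ge, hup - go);
      f = std::max(f - ge, hl - go);
      int h = hd + (qi == t[j - 1] ? match : -mismatch);
      h = std::max(h, e); h = std::max(h, f); h = std::max(h, 0);
      if (h > best) best = h;
      E[j] = e; hd = hup; hl = h; H[j] = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_pair")]]
int sw_score_pair(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int8_t> q, t;
  encode_seq(query.c_str(), (int)query.size(), q);
  encode_seq(target.c_str(), (int)target.size(), t);
  std::vector<int> Hbuf, Ebuf;
  return sw1(q.data(), (int)q.size(), t.data(), (int)t.size(),
             match, mismatch, gap_open + gap_extend, gap_extend, Hbuf, Ebuf);
}

#ifdef __SSE2__
// Inter-sequence vectorization: eight equal-length queries occupy the
// eight int16 lanes of each SSE2 register; one pass over the target
// scores all eight. Scores stay well inside int16 range for any input
// this package aligns (reads of a few kb under +/-1 scoring).
static void sw8(const __m128i* qprof, int m, const int8_t* t, int n,
                int match, int mismatch, int go, int ge,
                std::vector<__m128i>& Hv, std::vector<__m128i>& Ev,
                int16_t* best_out) {
  const __m128i zero = _mm_setzero_si128();
  const __m128i vgo  = _mm_set1_epi16((int16_t)go);
  const __m128i vge  = _mm_set1_epi16((int16_t)ge);
  const __m128i vmm  = _mm_set1_epi16((int16_t)(match + mismatch));
  const __m128i vmis = _mm_set1_epi16((int16_t)mismatch);
  Hv.assign(n + 1, zero); Ev.assign(n + 1, zero);
  __m128i best = zero;
  for (int i = 1; i <= m; ++i) {
    const __m128i qv = qprof[i - 1];
    __m128i hd = zero, hl = zero, f = zero;
    for (int j = 1; j <= n; ++j) {
      const __m128i tj = _mm_set1_epi16((int16_t)t[j - 1]);
      __m128i hup = Hv[j];
      __m128i e = _mm_max_epi16(_mm_subs_epi16(Ev[j], vge),
                                _mm_subs_epi16(hup, vgo));
      f = _mm_max_epi16(_mm_subs_epi16(f, vge), _mm_subs_epi16(hl, vgo));
      __m128i eq = _mm_cmpeq_epi16(qv, tj);
      __m128i sub = _mm_sub_epi16(_mm_and_si128(eq, vmm), vmis);
      __m128i h = _mm_adds_epi16(hd, sub);
      h = _mm_max_epi16(h, e);
      h = _mm_max_epi16(h, f);
      h = _mm_max_epi16(h, zero);
      best = _mm_max_epi16(best, h);
      Ev[j] = e; hd = hup; hl = h; Hv[j] = h;
    }
  }
  _mm_storeu_si128((__m128i*)best_out, best);
}
#endif

// Score every query against every target; returns a length(queries) x
// length(targets) integer matrix. Queries are grouped by length so runs
// of eight can take the vectorized kernel; leftovers fall back to the
// scalar loop. This is the batch kernel behind read assignment.
// [[Rcpp::export(name = ".sw_score_block")]]
IntegerMatrix sw_score_block(CharacterVector queries, CharacterVector targets,
                             int match, int mismatch, int gap_open, int gap_extend) {
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::vector<int8_t> > qs(nq);
  for (int i = 0; i < nq; ++i) {
    const char* s = CHAR(STRING_ELT(queries, i));
    encode_seq(s, (int)std::strlen(s), qs[i]);
  }
  std::vector<int> ord(nq);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return qs[a].size() < qs[b].size(); });
  const int go = gap_open + gap_extend, ge = gap_extend;
  IntegerMatrix out(nq, nt);
  std::vector<int8_t> t;
  std::vector<int> Hbuf, Ebuf;
#ifdef __SSE2__
  struct Group { int start; int m; std::vector<__m128i> prof; };
  std::vector<Group> groups;
  std::vector<char> vectorized(nq, 0);
  {
    int p = 0;
    while (p < nq) {
      int m = (int)qs[ord[p]].size();
      int pe = p;
      while (pe < nq && (int)qs[ord[pe]].size() == m) ++pe;
      int k = p;
      for (; k + 8 <= pe; k += 8) {
        Group g; g.start = k; g.m = m; g.prof.resize(m);
        for (int i = 0; i < m; ++i) {
          int16_t lane[8];
          for (int z = 0; z < 8; ++z) lane[z] = qs[ord[k + z]][i];
          g.prof[i] = _mm_loadu_si128((const __m128i*)lane);
        }
        for (int z = 0; z < 8; ++z) vectorized[k + z] = 1;
        groups.push_back(std::move(g));
      }
      p = pe;
    }
  }
  std::vector<__m128i> Hv, Ev;
#endif
  for (int jt = 0; jt < nt; ++jt) {
    const char* s = CHAR(STRING_ELT(targets, jt));
    int n = (int)std::strlen(s);
    encode_seq(s, n, t);
#ifdef __SSE2__
    for (size_t gi = 0; gi < groups.size(); ++gi) {
      int16_t best[8];
      sw8(groups[gi].prof.data(), groups[gi].m, t.data(), n,
          match, mismatch, go, ge, Hv, Ev, best);
      for (int z = 0; z < 8; ++z) out(ord[groups[gi].start + z], jt) = best[z];
    }
    for (int k = 0; k < nq; ++k) {
      if (vectorized[k]) continue;
      out(ord[k], jt) = sw1(qs[ord[k]].data(), (int)qs[ord[k]].size(),
                            t.data(), n, match, mismatch, go, ge, Hbuf, Ebuf);
    }
#else
    for (int k = 0; k < nq; ++k)
      out(ord[k], jt) = sw1(qs[ord[k]].data(), (int)qs[ord[k]].size(),
                            t.data(), n, match, mismatch, go, ge, Hbuf, Ebuf);
#endif
    if ((jt & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full alignment with coordinates and deterministic tie-breaking. Every
// DP state carries the start coordinates, column count and match count
// of the best path into it; among equal scores we prefer the smaller
// query start, then smaller target start, then fewer columns. A state
// can only be positive after at least one aligned column, so start
// coordinates are always defined on positive-scoring paths.
struct Cell {
  int score, qs, ts, cols, matches;
};

static inline bool better(const Cell& a, const Cell& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.qs != b.qs) return a.qs < b.qs;
  if (a.ts != b.ts) return a.ts < b.ts;
  return a.cols < b.cols;
}

// [[Rcpp::export(name = ".sw_align_full")]]
List sw_align_full(std::string query, std::string target,
                   int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int8_t> q, t;
  encode_seq(query.c_str(), (int)query.size(), q);
  encode_seq(target.c_str(), (int)target.size(), t);
  const int m = (int)q.size(), n = (int)t.size();
  const int go = gap_open + gap_extend, ge = gap_extend;

  std::vector<Cell> H(n + 1), E(n + 1);
  const Cell zero = {0, -1, -1, 0, 0};
  for (int j = 0; j <= n; ++j) { H[j] = zero; E[j] = zero; }

  Cell best = zero;
  int best_qe = 0, best_te = 0;

  for (int i = 1; i <= m; ++i) {
    Cell hdiag = zero, hleft = zero, f = zero;
    const int8_t qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      Cell hup = H[j];

      Cell e_ext = E[j]; e_ext.score -= ge; e_ext.cols += 1;
      Cell e_opn = hup;  e_opn.score -= go; e_opn.cols += 1;
      Cell e = better(e_opn, e_ext) ? e_opn : e_ext;

      Cell f_ext = f;     f_ext.score -= ge; f_ext.cols += 1;
      Cell f_opn = hleft; f_opn.score -= go; f_opn.cols += 1;
      Cell fc = better(f_opn, f_ext) ? f_opn : f_ext;

      bool is_match = (qi == t[j - 1]);
      Cell d = hdiag;
      d.score = hdiag.score + (is_match ? match : -mismatch);
      d.cols = hdiag.cols + 1;
      d.matches = hdiag.matches + (is_match ? 1 : 0);
      d.qs = hdiag.qs; d.ts = hdiag.ts;
      if (d.qs < 0) { d.qs = i - 1; d.ts = j - 1; }

      Cell h = d;
      if (better(e, h)) h = e;
      if (better(fc, h)) h = fc;
      if (h.score <= 0) h = zero;

      if (e.score <= 0) e = zero;
      if (fc.score <= 0) fc = zero;
      E[j] = e;
      f = fc;

      if (h.score > 0 &&
          (h.score > best.score ||
           (h.score == best.score &&
            (h.qs < best.qs ||
             (h.qs == best.qs && (h.ts < best.ts ||
              (h.ts == best.ts && h.cols < best.cols))))))) {
        best = h; best_qe = i; best_te = j;
      }
      hdiag = hup;
      hleft = h;
      H[j] = h;
    }
  }

  if (best.score <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0,
                        _["columns"] = 0, _["matches"] = 0);
  }
  return List::create(_["score"] = best.score,
                      _["q_start"] = best.qs, _["q_end"] = best_qe,
                      _["t_start"] = best.ts, _["t_end"] = best_te,
                      _["columns"] = best.cols, _["matches"] = best.matches);
}
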