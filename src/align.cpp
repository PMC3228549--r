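#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Dynamic-programming cores for local alignment.
//
// Two aligners are implemented separately:
//   * swg:  plain Smith-Waterman-Gotoh with affine gaps.
//   * flow: the flow-space assisted variant, where each cell additionally
//           considers homopolymer up-call / down-call corrections priced by
//           pre-computed penalty tables (Pd, Pu).
// Scores are integers; "infinite" penalties are any non-finite double in the
// 4 x m penalty matrices handed over from R.

static const int NEG = INT_MIN / 4;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int subst(char a, char b, int match, int mismatch) {
  return (a == b && is_acgt(a)) ? match : mismatch;
}

// Penalty tables converted to integers; INT_MAX marks an infinite entry.
struct PenTab {
  std::vector<int> pd, pu; // 4 * m, row-major by n (n = 1..4)
  int m;
  bool active;
  PenTab() : m(0), active(false) {}
  inline int PD(int n, int j) const { return pd[(size_t)(n - 1) * m + j]; }
  inline int PU(int n, int j) const { return pu[(size_t)(n - 1) * m + j]; }
};

static PenTab make_pentab(const NumericMatrix& Pd, const NumericMatrix& Pu) {
  PenTab t;
  t.m = Pd.ncol();
  t.pd.resize((size_t)4 * t.m, INT_MAX);
  t.pu.resize((size_t)4 * t.m, INT_MAX);
  for (int n = 0; n < 4; ++n) {
    for (int j = 0; j < t.m; ++j) {
      double d = Pd(n, j), u = Pu(n, j);
      if (R_finite(d)) { t.pd[(size_t)n * t.m + j] = (int)d; t.active = true; }
      if (R_finite(u)) { t.pu[(size_t)n * t.m + j] = (int)u; t.active = true; }
    }
  }
  return t;
}

// Traceback codes for the C (combined) state.
enum {
  TB_STOP = 0,
  TB_DIAG = 1,
  TB_H    = 2,  // gap in database string ('-' in db, consumes query)
  TB_E    = 3,  // gap in query string ('-' in query, consumes db)
  TB_UP   = 10, // TB_UP + n: up-call correction of size n
  TB_DOWN = 20  // TB_DOWN + n: down-call correction of size n
};

struct AlnResult {
  int score;
  int d0, d1, q0, q1;                 // 0-based half-open intervals
  std::string ad, aq;                 // gapped strings (query may be lower-case)
  std::vector<int> corr_j, corr_kind, corr_n, corr_pen; // kind: 1 up, 2 down
};

// Shared DP. When `pen` is inactive this is exactly Smith-Waterman-Gotoh.
static AlnResult align_dp(const std::string& d, const std::string& q,
                          int match, int mismatch, int g0, int ge,
                          const PenTab& pen, bool trace) {
  const int n = (int)d.size(), m = (int)q.size();
  const size_t W = (size_t)m + 1;
  std::vector<int> C((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      H((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> pc, pe, ph;
  if (trace) {
    pc.assign((size_t)(n + 1) * W, TB_STOP);
    pe.assign((size_t)(n + 1) * W, 0);
    ph.assign((size_t)(n + 1) * W, 0);
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    const char di = d[i - 1];
    for (int j = 1; j <= m; ++j) {
      // gap states (open preferred over extend on ties)
      int eo = C[rp + j] - g0, ee = E[rp + j] - ge;
      E[ro + j] = eo >= ee ? eo : ee;
      if (trace) pe[ro + j] = eo >= ee ? 0 : 1;
      int ho = C[ro + j - 1] - g0, he = H[ro + j - 1] - ge;
      H[ro + j] = ho >= he ? ho : he;
      if (trace) ph[ro + j] = ho >= he ? 0 : 1;

      const char qj = q[j - 1];
      int val = 0;
      unsigned char code = TB_STOP;
      int diag = C[rp + j - 1] + subst(di, qj, match, mismatch);
      if (diag > val) { val = diag; code = TB_DIAG; }
      if (pen.active) {
        // up-call: n inserted copies of q_j consume db bases d[i-n..i-1],
        // all of which must equal q_j (and be plain ACGT)
        if (is_acgt(qj)) {
          for (int nn = 1; nn <= 4 && i - nn >= 0; ++nn) {
            if (d[i - nn] != qj) break;
            int p = pen.PU(nn, j - 1);
            if (p == INT_MAX) continue; // monotone rule handled at build time
            int v = C[(size_t)(i - nn) * W + j] - p;
            if (v > val) { val = v; code = (unsigned char)(TB_UP + nn); }
          }
        }
        // down-call: last nn bases of the query homopolymer ending at j are
        // dropped against database gaps
        for (int nn = 1; nn <= 4 && j - nn >= 0; ++nn) {
          int p = pen.PD(nn, j - 1);
          if (p == INT_MAX) break;
          int v = C[ro + j - nn] - p;
          if (v > val) { val = v; code = (unsigned char)(TB_DOWN + nn); }
        }
      }
      // tie preference order: diag > up-call > down-call > db gap > query gap
      if (H[ro + j] > val) { val = H[ro + j]; code = TB_H; }
      if (E[ro + j] > val) { val = E[ro + j]; code = TB_E; }
      if (val <= 0) { val = 0; code = TB_STOP; }
      C[ro + j] = val;
      if (trace) pc[ro + j] = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }

  AlnResult res;
  res.score = best;
  if (!trace || best <= 0) {
    res.d0 = res.d1 = res.q0 = res.q1 = 0;
    return res;
  }
  // traceback
  std::string ad, aq;
  int i = bi, j = bj, state = 0; // 0 = C, 1 = E, 2 = H
  while (true) {
    const size_t ro = (size_t)i * W;
    if (state == 0) {
      unsigned char code = pc[ro + j];
      if (code == TB_STOP) break;
      if (code == TB_DIAG) {
        ad.push_back(d[i - 1]);
        aq.push_back(q[j - 1]);
        --i; --j;
      } else if (code >= TB_DOWN) {
        int nn = code - TB_DOWN;
        for (int t = 0; t < nn; ++t) {
          ad.push_back('-');
          aq.push_back((char)tolower(q[j - 1 - t]));
        }
        res.corr_j.push_back(j); res.corr_kind.push_back(2);
        res.corr_n.push_back(nn); res.corr_pen.push_back(pen.PD(nn, j - 1));
        j -= nn;
      } else if (code >= TB_UP) {
        int nn = code - TB_UP;
        for (int t = 0; t < nn; ++t) {
          ad.push_back(d[i - 1 - t]);
          aq.push_back((char)tolower(q[j - 1]));
        }
        res.corr_j.push_back(j); res.corr_kind.push_back(1);
        res.corr_n.push_back(nn); res.corr_pen.push_back(pen.PU(nn, j - 1));
        i -= nn;
      } else if (code == TB_H) {
        state = 2;
      } else { // TB_E
        state = 1;
      }
    } else if (state == 2) { // gap in db, consumes query
      ad.push_back('-');
      aq.push_back(q[j - 1]);
      unsigned char e = ph[ro + j];
      --j;
      if (e == 0) state = 0;
    } else { // gap in query, consumes db
      ad.push_back(d[i - 1]);
      aq.push_back('-');
      unsigned char e = pe[ro + j];
      --i;
      if (e == 0) state = 0;
    }
  }
  std::reverse(ad.begin(), ad.end());
  std::reverse(aq.begin(), aq.end());
  std::reverse(res.corr_j.begin(), res.corr_j.end());
  std::reverse(res.corr_kind.begin(), res.corr_kind.end());
  std::reverse(res.corr_n.begin(), res.corr_n.end());
  std::reverse(res.corr_pen.begin(), res.corr_pen.end());
  res.ad = ad; res.aq = aq;
  res.d0 = i; res.d1 = bi; res.q0 = j; res.q1 = bj;
  return res;
}

static List wrap_result(const AlnResult& r) {
  return List::create(
      _["score"] = r.score,
      _["db_start"] = r.d0, _["db_end"] = r.d1,
      _["q_start"] = r.q0, _["q_end"] = r.q1,
      _["aligned_db"] = r.ad, _["aligned_query"] = r.aq,
      _["corr_j"] = IntegerVector(r.corr_j.begin(), r.corr_j.end()),
      _["corr_kind"] = IntegerVector(r.corr_kind.begin(), r.corr_kind.end()),
      _["corr_n"] = IntegerVector(r.corr_n.begin(), r.corr_n.end()),
      _["corr_pen"] = IntegerVector(r.corr_pen.begin(), r.corr_pen.end()));
}

// [[Rcpp::export]]
List cpp_swg_align(std::string db, std::string query, int match, int mismatch,
                   int gap_open, int gap_extend, bool trace) {
  PenTab none;
  return wrap_result(align_dp(db, query, match, mismatch, gap_open, gap_extend,
                              none, trace));
}

// [[Rcpp::export]]
List cpp_flow_align(std::string db, std::string query, NumericMatrix Pd,
                    NumericMatrix Pu, int match, int mismatch, int gap_open,
                    int gap_extend, bool trace) {
  if (Pd.ncol() != (int)query.size() || Pu.ncol() != (int)query.size())
    stop("penalty table width does not match query length");
  PenTab t = make_pentab(Pd, Pu);
  return wrap_result(align_dp(db, query, match, mismatch, gap_open, gap_extend,
                              t, trace));
}

// Score-only batch: one query against many database strings.
// [[Rcpp::export]]
IntegerVector cpp_score_batch(CharacterVector dbs, std::string query,
                              NumericMatrix Pd, NumericMatrix Pu, int match,
                              int mismatch, int gap_open, int gap_extend,
                              bool use_pen) {
  PenTab t;
  if (use_pen) {
    if (Pd.ncol() != (int)query.size() || Pu.ncol() != (int)query.size())
      stop("penalty table width does not match query length");
    t = make_pentab(Pd, Pu);
  }
  int nd = dbs.size();
  IntegerVector out(nd);
  for (int i = 0; i < nd; ++i) {
    std::string d = as<std::string>(dbs[i]);
    out[i] = align_dp(d, query, match, mismatch, gap_open, gap_extend, t,
                      false).score;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Independent test oracle: exhaustive enumeration of local alignment paths.
// Enumerates every monotone move path (diagonal / db-consuming gap /
// query-consuming gap) from every start cell, scoring columns as rendered,
// and keeps the best prefix score seen. A sound upper bound
// (score + match * min(remaining)) prunes branches that cannot improve.
// Entirely independent of the Gotoh recurrences above.

struct EnumCtx {
  const std::string* d; const std::string* q;
  int n, m, match, mismatch, g0, ge, best;
};

static void enum_dfs(EnumCtx& c, int i, int j, int score, int last) {
  if (score > c.best) c.best = score;
  // no extension can exceed score + match * min(remaining); prune if it
  // cannot beat the best prefix already seen (gaps only lower the bound)
  if (score + c.match * std::min(c.n - i, c.m - j) <= c.best) return;
  if (i < c.n && j < c.m)
    enum_dfs(c, i + 1, j + 1,
             score + subst((*c.d)[i], (*c.q)[j], c.match, c.mismatch), 0);
  if (i < c.n) enum_dfs(c, i + 1, j, score - (last == 1 ? c.ge : c.g0), 1);
  if (j < c.m) enum_dfs(c, i, j + 1, score - (last == 2 ? c.ge : c.g0), 2);
}

// [[Rcpp::export]]
int cpp_enum_local_score(std::string db, std::string query, int match,
                         int mismatch, int gap_open, int gap_extend) {
  EnumCtx c;
  c.d = &db; c.q = &query;
  c.n = (int)db.size(); c.m = (int)query.size();
  c.match = match; c.mismatch = mismatch; c.g0 = gap_open; c.ge = gap_extend;
  c.best = 0;
  for (int i = 0; i <= c.n; ++i)
    for (int j = 0; j <= c.m; ++j) enum_dfs(c, i, j, 0, -1);
  return c.best;
}
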