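// Affine-gap pairwise alignment core (Gotoh algorithm) used by the
// seed-and-extend search engine and the reference-anchored projector.
//
// Gap cost convention matches BLAST: a gap of length k costs
// gap_open + k * gap_extend.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int q_start, q_end, s_start, s_end;  // 1-based inclusive
  std::string q_aln, s_aln;
};

// state codes for traceback
enum { FROM_STOP = 0, FROM_DIAG = 1, FROM_E = 2, FROM_F = 3 };

static AlnResult align_pair(const std::string& q, const std::string& s,
                            const std::vector<int>& qi,
                            const std::vector<int>& si,
                            const NumericMatrix& sub,
                            double go, double ge, bool local) {
  const int m = q.size(), n = s.size();
  const double open1 = go + ge;  // cost of a length-1 gap
  std::vector<double> Hprev(n + 1), Hcur(n + 1), E(n + 1);
  // traceback matrices: which state H came from, and whether E/F extended
  std::vector<unsigned char> tbH((m + 1) * (n + 1), FROM_STOP);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  for (int j = 0; j <= n; ++j) {
    Hprev[j] = local ? 0.0 : (j == 0 ? 0.0 : -(go + ge * j));
    E[j] = NEG_INF;
    if (!local && j > 0) tbH[j] = FROM_E, tbE[j] = 1;
  }
  std::vector<double> Fcol(n + 1, NEG_INF);

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = local ? 0.0 : -(go + ge * i);
    if (!local) { tbH[i * (n + 1)] = FROM_F; tbF[i * (n + 1)] = 1; }
    double Frow; // F for current column accumulates down rows: keep per column
    for (int j = 1; j <= n; ++j) {
      // E: gap in pattern (consume subject), horizontal
      double e_open = Hcur[j - 1] - open1;
      double e_ext = E[j - 1] - ge;
      double e = std::max(e_open, e_ext);
      tbE[i * (n + 1) + j] = (e_ext > e_open) ? 1 : 0;
      // F: gap in subject (consume pattern), vertical
      double f_open = Hprev[j] - open1;
      double f_ext = Fcol[j] - ge;
      double f = std::max(f_open, f_ext);
      tbF[i * (n + 1) + j] = (f_ext > f_open) ? 1 : 0;
      double diag = Hprev[j - 1] + sub(qi[i - 1], si[j - 1]);
      double h = diag;
      unsigned char from = FROM_DIAG;
      if (e > h) { h = e; from = FROM_E; }
      if (f > h) { h = f; from = FROM_F; }
      if (local && h <= 0) { h = 0.0; from = FROM_STOP; }
      Hcur[j] = h;
      E[j] = e;
      Fcol[j] = f;
      tbH[i * (n + 1) + j] = from;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur);
    (void)Frow;
  }
  if (!local) { best = Hprev[n]; bi = m; bj = n; }

  // traceback
  std::string qa, sa;
  int i = bi, j = bj;
  int state = 0;  // 0 = in H
  unsigned char cur;
  while (i > 0 || j > 0) {
    if (local && (i == 0 || j == 0)) break;
    cur = tbH[i * (n + 1) + j];
    if (local && cur == FROM_STOP) break;
    if (cur == FROM_DIAG) {
      qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
      --i; --j;
    } else if (cur == FROM_E) {
      // one or more subject-consuming steps
      while (j > 0) {
        qa.push_back('-'); sa.push_back(s[j - 1]);
        bool ext = tbE[i * (n + 1) + j];
        --j;
        if (!ext) break;
      }
    } else if (cur == FROM_F) {
      while (i > 0) {
        qa.push_back(q[i - 1]); sa.push_back('-');
        bool ext = tbF[i * (n + 1) + j];
        --i;
        if (!ext) break;
      }
    } else {
      break;  // FROM_STOP in global shouldn't happen
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  AlnResult r;
  r.score = best;
  r.q_start = i + 1; r.q_end = bi;
  r.s_start = j + 1; r.s_end = bj;
  r.q_aln = qa; r.s_aln = sa;
  return r;
}

static std::vector<int> encode(const std::string& x, const int* lut) {
  std::vector<int> v(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    v[i] = lut[(unsigned char)std::toupper(x[i])];
  }
  return v;
}

// [[Rcpp::export(name = ".cpp_align")]]
DataFrame cpp_align(CharacterVector patterns, std::string subject,
                    NumericMatrix sub, double gap_open, double gap_extend,
                    bool local) {
  CharacterVector alpha = rownames(sub);
  int lut[256];
  // unknown characters score as the matrix minimum (never favourable)
  int fallback = 0;
  double minv = R_PosInf;
  for (int a = 0; a < sub.nrow(); ++a) {
    for (int b = 0; b < sub.ncol(); ++b) {
      if (sub(a, b) < minv) minv = sub(a, b);
    }
  }
  // append a pseudo-row? simpler: map unknowns to the worst-scoring symbol
  int worst_idx = 0;
  double worst_rowmax = R_PosInf;
  for (int a = 0; a < sub.nrow(); ++a) {
    double rowmax = -R_PosInf;
    for (int b = 0; b < sub.ncol(); ++b) rowmax = std::max(rowmax, sub(a, b));
    if (rowmax < worst_rowmax) { worst_rowmax = rowmax; worst_idx = a; }
  }
  fallback = worst_idx;
  for (int c = 0; c < 256; ++c) lut[c] = fallback;
  for (int a = 0; a < alpha.size(); ++a) {
    std::string ch = as<std::string>(alpha[a]);
    if (ch.size() == 1) lut[(unsigned char)std::toupper(ch[0])] = a;
  }
  std::vector<int> si = encode(subject, lut);
  std::string s_up(subject);
  for (auto& c : s_up) c = std::toupper(c);

  int np = patterns.size();
  NumericVector score(np);
  IntegerVector q_start(np), q_end(np), s_start(np), s_end(np),
      align_length(np), n_ident(np), mismatches(np), gap_opens(np);
  CharacterVector q_aln(np), s_aln(np);
  for (int p = 0; p < np; ++p) {
    std::string q = as<std::string>(patterns[p]);
    std::string q_up(q);
    for (auto& c : q_up) c = std::toupper(c);
    std::vector<int> qi = encode(q, lut);
    AlnResult r = align_pair(q_up, s_up, qi, si, sub, gap_open, gap_extend,
                             local);
    score[p] = r.score;
    q_start[p] = r.q_start; q_end[p] = r.q_end;
    s_start[p] = r.s_start; s_end[p] = r.s_end;
    int len = r.q_aln.size(), ident = 0, mism = 0, opens = 0;
    bool in_gap_q = false, in_gap_s = false;
    for (int c = 0; c < len; ++c) {
      char a = r.q_aln[c], b = r.s_aln[c];
      if (a == '-') {
        if (!in_gap_q) { ++opens; in_gap_q = true; }
      } else in_gap_q = false;
      if (b == '-') {
        if (!in_gap_s) { ++opens; in_gap_s = true; }
      } else in_gap_s = false;
      if (a != '-' && b != '-') {
        if (a == b) ++ident; else ++mism;
      }
    }
    align_length[p] = len;
    n_ident[p] = ident;
    mismatches[p] = mism;
    gap_opens[p] = opens;
    q_aln[p] = r.q_aln;
    s_aln[p] = r.s_aln;
  }
  return DataFrame::create(
      _["score"] = score, _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end,
      _["align_length"] = align_length, _["n_ident"] = n_ident,
      _["mismatches"] = mismatches, _["gap_opens"] = gap_opens,
      _["q_aln"] = q_aln, _["s_aln"] = s_aln,
      _["stringsAsFactors"] = false);
}
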