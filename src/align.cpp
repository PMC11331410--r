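#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap global alignment and helpers.
//
// Scoring convention: a gap of length k scores gap_open + (k - 1) * gap_ext,
// i.e. gap_open is the score of a length-1 gap (defaults 1 / -2 / -4 / -1
// for match / mismatch / gap_open / gap_ext).
//
// Op codes used throughout: 1 = substitution, 2 = insertion (extra base in
// the pattern, absent from the subject), 3 = deletion (subject base absent
// from the pattern). For insertions `tpos` is the subject position
// immediately 5' of the inserted bases (0 = before the first subject base);
// for substitutions/deletions it is the (first) affected subject position,
// 1-based.

static const double NEG = -1e30;

static inline double max3(double a, double b, double c) {
  double m = a;
  if (b > m) m = b;
  if (c > m) m = c;
  return m;
}

// [[Rcpp::export(name = ".gotoh_align_batch")]]
List gotoh_align_batch(CharacterVector pattern, CharacterVector subject,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  int P = pattern.size();
  if (subject.size() != P)
    stop("pattern and subject must have equal length");

  NumericVector scores(P);
  IntegerVector aln_len(P);
  std::vector<int> o_pair, o_type, o_tpos;
  std::vector<std::string> o_ref, o_alt;

  for (int pp = 0; pp < P; ++pp) {
    std::string p = as<std::string>(pattern[pp]);
    std::string t = as<std::string>(subject[pp]);
    int n = (int)p.size(), m = (int)t.size();
    size_t W = (size_t)(m + 1);
    std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
        Iy((n + 1) * W, NEG);
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) Ix[i * W] = gap_open + (i - 1) * gap_ext;
    for (int j = 1; j <= m; ++j) Iy[j] = gap_open + (j - 1) * gap_ext;

    for (int i = 1; i <= n; ++i) {
      char pc = p[i - 1];
      for (int j = 1; j <= m; ++j) {
        double s = (pc == t[j - 1]) ? match : mismatch;
        size_t c = i * W + j, d = (i - 1) * W + (j - 1);
        size_t u = (i - 1) * W + j, l = i * W + (j - 1);
        M[c] = max3(M[d], Ix[d], Iy[d]) + s;
        Ix[c] = max3(M[u] + gap_open, Ix[u] + gap_ext, Iy[u] + gap_open);
        Iy[c] = max3(M[l] + gap_open, Iy[l] + gap_ext, Ix[l] + gap_open);
      }
    }

    size_t e = (size_t)n * W + m;
    double best = max3(M[e], Ix[e], Iy[e]);
    scores[pp] = best;

    // traceback; fixed priority M > Iy > Ix keeps output deterministic
    const double eps = 1e-9;
    std::vector<int> ctype, cj;  // per column, from the end
    std::vector<char> cp;        // pattern char for sub/ins columns
    int i = n, j = m, state;
    if (M[e] >= best - eps) state = 0;
    else if (Iy[e] >= best - eps) state = 2;
    else state = 1;
    while (i > 0 || j > 0) {
      size_t c = (size_t)i * W + j;
      if (state == 0) {
        double s = (p[i - 1] == t[j - 1]) ? match : mismatch;
        ctype.push_back(p[i - 1] == t[j - 1] ? 0 : 1);
        cj.push_back(j);
        cp.push_back(p[i - 1]);
        double want = M[c] - s;
        size_t d = (size_t)(i - 1) * W + (j - 1);
        if (M[d] >= want - eps) state = 0;
        else if (Iy[d] >= want - eps) state = 2;
        else state = 1;
        --i; --j;
      } else if (state == 1) {  // Ix: pattern base inserted after subject j
        ctype.push_back(2);
        cj.push_back(j);
        cp.push_back(p[i - 1]);
        size_t u = (size_t)(i - 1) * W + j;
        if (i == 1 && j == 0) { --i; continue; }
        if (Ix[u] + gap_ext >= Ix[c] - eps && i > 1) state = 1;
        else if (M[u] + gap_open >= Ix[c] - eps) state = 0;
        else if (Iy[u] + gap_open >= Ix[c] - eps) state = 2;
        else state = 1;
        --i;
      } else {  // Iy: subject base j deleted
        ctype.push_back(3);
        cj.push_back(j);
        cp.push_back('-');
        size_t l = (size_t)i * W + (j - 1);
        if (j == 1 && i == 0) { --j; continue; }
        if (Iy[l] + gap_ext >= Iy[c] - eps && j > 1) state = 2;
        else if (M[l] + gap_open >= Iy[c] - eps) state = 0;
        else if (Ix[l] + gap_open >= Iy[c] - eps) state = 1;
        else state = 2;
        --j;
      }
    }
    int ncol = (int)ctype.size();
    aln_len[pp] = ncol;

    // forward pass (columns are reversed); merge adjacent same-type gap runs
    int k = ncol - 1;
    while (k >= 0) {
      int ty = ctype[k];
      if (ty == 0) { --k; continue; }
      if (ty == 1) {
        o_pair.push_back(pp + 1);
        o_type.push_back(1);
        o_tpos.push_back(cj[k]);
        o_ref.push_back(std::string(1, t[cj[k] - 1]));
        o_alt.push_back(std::string(1, cp[k]));
        --k;
      } else if (ty == 2) {
        std::string ins;
        int tp = cj[k];
        while (k >= 0 && ctype[k] == 2 && cj[k] == tp) {
          ins.push_back(cp[k]);
          --k;
        }
        o_pair.push_back(pp + 1);
        o_type.push_back(2);
        o_tpos.push_back(tp);
        o_ref.push_back("");
        o_alt.push_back(ins);
      } else {
        std::string del;
        int tp = cj[k];
        int expect = tp;
        while (k >= 0 && ctype[k] == 3 && cj[k] == expect) {
          del.push_back(t[cj[k] - 1]);
          ++expect;
          --k;
        }
        o_pair.push_back(pp + 1);
        o_type.push_back(3);
        o_tpos.push_back(tp);
        o_ref.push_back(del);
        o_alt.push_back("");
      }
    }
  }

  return List::create(
      _["score"] = scores, _["aln_len"] = aln_len,
      _["ops"] = DataFrame::create(
          _["pair"] = wrap(o_pair), _["type"] = wrap(o_type),
          _["tpos"] = wrap(o_tpos), _["ref"] = wrap(o_ref),
          _["alt"] = wrap(o_alt), _["stringsAsFactors"] = false));
}

// Independent optimal-score oracle: classic O(n*m*(n+m)) gap-function DP,
// deliberately a different formulation from the Gotoh three-state recursion.
// [[Rcpp::export(name = ".nw_score_gapfn_batch")]]
NumericVector nw_score_gapfn_batch(CharacterVector pattern,
                                   CharacterVector subject, double match,
                                   double mismatch, double gap_open,
                                   double gap_ext) {
  int P = pattern.size();
  NumericVector out(P);
  for (int pp = 0; pp < P; ++pp) {
    std::string p = as<std::string>(pattern[pp]);
    std::string t = as<std::string>(subject[pp]);
    int n = (int)p.size(), m = (int)t.size();
    size_t W = (size_t)(m + 1);
    std::vector<double> S((n + 1) * W, NEG);
    S[0] = 0.0;
    for (int i = 1; i <= n; ++i) S[i * W] = gap_open + (i - 1) * gap_ext;
    for (int j = 1; j <= m; ++j) S[j] = gap_open + (j - 1) * gap_ext;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double s = (p[i - 1] == t[j - 1]) ? match : mismatch;
        double best = S[(i - 1) * W + (j - 1)] + s;
        for (int k = 1; k <= i; ++k) {
          double v = S[(i - k) * W + j] + gap_open + (k - 1) * gap_ext;
          if (v > best) best = v;
        }
        for (int k = 1; k <= j; ++k) {
          double v = S[i * W + (j - k)] + gap_open + (k - 1) * gap_ext;
          if (v > best) best = v;
        }
        S[i * W + j] = best;
      }
    }
    out[pp] = S[n * W + m];
  }
  return out;
}

// Apply variant ops to subject sequences; inverse of variant calling, used
// both by the simulator (planting edits) and by reconstruction checks.
// [[Rcpp::export(name = ".apply_calls_batch")]]
CharacterVector apply_calls_batch(CharacterVector subject, IntegerVector pair,
                                  IntegerVector type, IntegerVector tpos,
                                  CharacterVector ref, CharacterVector alt,
                                  bool check_ref) {
  int P = subject.size();
  int K = pair.size();
  CharacterVector out(P);
  int k = 0;
  for (int pp = 0; pp < P; ++pp) {
    std::string t = as<std::string>(subject[pp]);
    int m = (int)t.size();
    std::vector<std::string> insAfter(m + 1);
    std::vector<std::string> subAt(m + 1);
    std::vector<char> del(m + 1, 0);
    while (k < K && pair[k] == pp + 1) {
      int ty = type[k], tp = tpos[k];
      if (ty == 2) {
        if (tp < 0 || tp > m) stop("insertion tpos out of range");
        insAfter[tp] += as<std::string>(alt[k]);
      } else if (ty == 1) {
        if (tp < 1 || tp > m) stop("substitution tpos out of range");
        std::string r = as<std::string>(ref[k]);
        if (check_ref && r != t.substr(tp - 1, 1))
          stop("substitution ref does not match subject");
        subAt[tp] = as<std::string>(alt[k]);
      } else if (ty == 3) {
        std::string r = as<std::string>(ref[k]);
        int len = (int)r.size();
        if (tp < 1 || tp + len - 1 > m) stop("deletion out of range");
        if (check_ref && r != t.substr(tp - 1, len))
          stop("deletion ref does not match subject");
        for (int q = tp; q < tp + len; ++q) del[q] = 1;
      } else {
        stop("unknown op type");
      }
      ++k;
    }
    std::string res;
    res.reserve(t.size() + 8);
    res += insAfter[0];
    for (int j = 1; j <= m; ++j) {
      if (!del[j]) {
        if (!subAt[j].empty()) res += subAt[j];
        else res.push_back(t[j - 1]);
      }
      res += insAfter[j];
    }
    out[pp] = res;
  }
  if (k != K) stop("ops must be grouped by pair in ascending order");
  return out;
}
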