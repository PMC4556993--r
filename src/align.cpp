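#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Affine-gap alignment kernels. Convention: a gap of length k costs
// gap_open + (k - 1) * gap_extend, i.e. gap_open is the cost of the first
// gap column. Three-state DP (M = match/mismatch, X = gap in b, Y = gap in a).

static const double NEG = -1e18;

static inline void check_dna(const std::string &s) {
  for (char c : s) {
    char u = (char) toupper(c);
    if (u != 'A' && u != 'C' && u != 'G' && u != 'T' && u != 'N')
      stop("non-DNA character '%s'", std::string(1, c).c_str());
  }
}

struct AlnStats {
  double score;
  int cols, matches, mismatches, gapcols;
  int a_start, a_end, b_start, b_end; // 0-based half-open spans
};

// traceback codes: state M=0, X=1, Y=2; ptr packs previous state (0..2) or 3 = local start
static inline uint8_t pk(int prev) { return (uint8_t) prev; }

static AlnStats traceback(const std::string &a, const std::string &b,
                          const std::vector<uint8_t> &tbM,
                          const std::vector<uint8_t> &tbX,
                          const std::vector<uint8_t> &tbY,
                          int n, int i, int j, int state, double score,
                          bool local) {
  AlnStats st;
  st.score = score; st.cols = 0; st.matches = 0; st.mismatches = 0; st.gapcols = 0;
  st.a_end = i; st.b_end = j;
  while (i > 0 || j > 0) {
    uint8_t prev;
    if (state == 0) {
      prev = tbM[(size_t) i * (n + 1) + j];
      st.cols++;
      if (toupper(a[i - 1]) == toupper(b[j - 1])) st.matches++; else st.mismatches++;
      --i; --j;
    } else if (state == 1) {
      prev = tbX[(size_t) i * (n + 1) + j];
      st.cols++; st.gapcols++;
      --i;
    } else {
      prev = tbY[(size_t) i * (n + 1) + j];
      st.cols++; st.gapcols++;
      --j;
    }
    if (prev == 3) break;       // local alignment start
    state = prev;
    if (!local && i == 0 && j == 0) break;
    if (!local && state == 99) break;
  }
  st.a_start = i; st.b_start = j;
  return st;
}

static List stats_to_list(const AlnStats &st) {
  double ident = st.cols > 0 ? (double) st.matches / st.cols : 0.0;
  return List::create(
    _["score"] = st.score, _["cols"] = st.cols, _["matches"] = st.matches,
    _["mismatches"] = st.mismatches, _["gapcols"] = st.gapcols,
    _["identity"] = ident,
    _["a_start"] = st.a_start, _["a_end"] = st.a_end,
    _["b_start"] = st.b_start, _["b_end"] = st.b_end);
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, double match, double mismatch,
              double gap_open, double gap_extend) {
  check_dna(a); check_dna(b);
  int m = (int) a.size(), n = (int) b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  std::vector<double> M((size_t)(m + 1) * (n + 1), 0.0),
                      X((size_t)(m + 1) * (n + 1), NEG),
                      Y((size_t)(m + 1) * (n + 1), NEG);
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), 3),
                       tbX((size_t)(m + 1) * (n + 1), 3),
                       tbY((size_t)(m + 1) * (n + 1), 3);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t) i * (n + 1) + j;
      size_t d = (size_t)(i - 1) * (n + 1) + (j - 1);
      size_t u = (size_t)(i - 1) * (n + 1) + j;
      size_t l = (size_t) i * (n + 1) + (j - 1);
      bool eq = toupper(a[i - 1]) == toupper(b[j - 1]) &&
                toupper(a[i - 1]) != 'N';
      double s = eq ? match : mismatch;
      // M state: local restart allowed (prev = 3)
      double vM = s; uint8_t pM = 3;
      if (M[d] + s > vM) { vM = M[d] + s; pM = 0; }
      if (X[d] + s > vM) { vM = X[d] + s; pM = 1; }
      if (Y[d] + s > vM) { vM = Y[d] + s; pM = 2; }
      M[c] = vM; tbM[c] = pM;
      // X: gap in b (consume a_i)
      double vX = M[u] + gap_open; uint8_t pX = 0;
      if (X[u] + gap_extend > vX) { vX = X[u] + gap_extend; pX = 1; }
      X[c] = vX; tbX[c] = pX;
      // Y: gap in a (consume b_j)
      double vY = M[l] + gap_open; uint8_t pY = 0;
      if (Y[l] + gap_extend > vY) { vY = Y[l] + gap_extend; pY = 2; }
      Y[c] = vY; tbY[c] = pY;
      if (vM > best + 1e-12) { best = vM; bi = i; bj = j; } // ties: smallest end
    }
  }
  if (best <= 0.0) {
    AlnStats st; st.score = 0; st.cols = 0; st.matches = 0; st.mismatches = 0;
    st.gapcols = 0; st.a_start = 0; st.a_end = 0; st.b_start = 0; st.b_end = 0;
    return stats_to_list(st);
  }
  AlnStats st = traceback(a, b, tbM, tbX, tbY, n, bi, bj, 0, best, true);
  return stats_to_list(st);
}

// Query-global, target-local ("glocal") alignment: the whole query a is
// aligned; the target b contributes a free prefix and suffix.
// [[Rcpp::export(name = ".glocal_align")]]
List glocal_align(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend, bool with_path = false) {
  check_dna(a); check_dna(b);
  int m = (int) a.size(), n = (int) b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if (m > n) stop("query longer than target");
  std::vector<double> M((size_t)(m + 1) * (n + 1), NEG),
                      X((size_t)(m + 1) * (n + 1), NEG),
                      Y((size_t)(m + 1) * (n + 1), NEG);
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), 3),
                       tbX((size_t)(m + 1) * (n + 1), 3),
                       tbY((size_t)(m + 1) * (n + 1), 3);
  // free target prefix: row i = 0 is a zero-cost start in M-like limbo
  for (int j = 0; j <= n; ++j) M[(size_t) 0 * (n + 1) + j] = 0.0;
  // query consumed against nothing: leading gap in target
  for (int i = 1; i <= m; ++i) {
    size_t c = (size_t) i * (n + 1);
    X[c] = gap_open + (i - 1) * gap_extend;
    tbX[c] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t) i * (n + 1) + j;
      size_t d = (size_t)(i - 1) * (n + 1) + (j - 1);
      size_t u = (size_t)(i - 1) * (n + 1) + j;
      size_t l = (size_t) i * (n + 1) + (j - 1);
      bool eq = toupper(a[i - 1]) == toupper(b[j - 1]) &&
                toupper(a[i - 1]) != 'N';
      double s = eq ? match : mismatch;
      double vM = M[d] + s; uint8_t pM = 0;
      if (X[d] + s > vM) { vM = X[d] + s; pM = 1; }
      if (Y[d] + s > vM) { vM = Y[d] + s; pM = 2; }
      M[c] = vM; tbM[c] = pM;
      double vX = M[u] + gap_open; uint8_t pX = 0;
      if (X[u] + gap_extend > vX) { vX = X[u] + gap_extend; pX = 1; }
      X[c] = vX; tbX[c] = pX;
      double vY = M[l] + gap_open; uint8_t pY = 0;
      if (Y[l] + gap_extend > vY) { vY = Y[l] + gap_extend; pY = 2; }
      Y[c] = vY; tbY[c] = pY;
    }
  }
  // best end: whole query consumed (row m), any j, any state; ties -> smallest j
  double best = NEG; int bj = 0, bstate = 0;
  for (int j = 0; j <= n; ++j) {
    size_t c = (size_t) m * (n + 1) + j;
    if (M[c] > best + 1e-12) { best = M[c]; bj = j; bstate = 0; }
    if (X[c] > best + 1e-12) { best = X[c]; bj = j; bstate = 1; }
    if (Y[c] > best + 1e-12) { best = Y[c]; bj = j; bstate = 2; }
  }
  // traceback until the query is fully unwound (i reaches 0)
  AlnStats st; st.score = best; st.cols = 0; st.matches = 0;
  st.mismatches = 0; st.gapcols = 0;
  int i = m, j = bj, state = bstate;
  st.a_end = i; st.b_end = j;
  std::vector<int> pa, pb; // per-column query/target positions (0 = gap)
  while (i > 0) {
    uint8_t prev;
    size_t c = (size_t) i * (n + 1) + j;
    if (state == 0) {
      prev = tbM[c];
      st.cols++;
      if (toupper(a[i - 1]) == toupper(b[j - 1])) st.matches++; else st.mismatches++;
      if (with_path) { pa.push_back(i); pb.push_back(j); }
      --i; --j;
    } else if (state == 1) {
      prev = tbX[c];
      st.cols++; st.gapcols++;
      if (with_path) { pa.push_back(i); pb.push_back(0); }
      --i;
    } else {
      prev = tbY[c];
      st.cols++; st.gapcols++;
      if (with_path) { pa.push_back(0); pb.push_back(j); }
      --j;
    }
    state = prev;
  }
  st.a_start = 0; st.b_start = j;
  List out = stats_to_list(st);
  if (with_path) {
    IntegerMatrix path((int) pa.size(), 2);
    for (int k = (int) pa.size() - 1, r = 0; k >= 0; --k, ++r) {
      path(r, 0) = pa[k]; path(r, 1) = pb[k];
    }
    out["path"] = path;
  }
  return out;
}

// Longest adapter-prefix overlap at each read's 3' end with mismatch rate
// <= max_err_rate and overlap >= min_overlap; 0 when none qualifies.
// [[Rcpp::export(name = ".adapter_overlap")]]
IntegerVector adapter_overlap(CharacterVector seqs, std::string adapter,
                              int min_overlap, double max_err_rate) {
  std::string ad = adapter;
  for (auto &c : ad) c = (char) toupper(c);
  int la = (int) ad.size();
  IntegerVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (auto &c : s) c = (char) toupper(c);
    int n = (int) s.size();
    int lim = std::min(n, la);
    int best = 0;
    for (int ov = lim; ov >= min_overlap; --ov) {
      int mm = 0;
      int allowed = (int) std::floor(max_err_rate * ov + 1e-9);
      for (int k = 0; k < ov; ++k) {
        if (s[n - ov + k] != ad[k] && ++mm > allowed) break;
      }
      if (mm <= allowed) { best = ov; break; }
    }
    out[r] = best;
  }
  return out;
}

// All ungapped placements of each query in a subject with <= max_mm
// mismatches. N counts as a mismatch. Returns 0-based start positions.
// [[Rcpp::export(name = ".mismatch_scan")]]
DataFrame mismatch_scan(std::string subject, CharacterVector queries, int max_mm) {
  check_dna(subject);
  int n = (int) subject.size();
  std::string S = subject;
  for (auto &c : S) c = (char) toupper(c);
  std::vector<int> qidx, pos, mms;
  for (int q = 0; q < queries.size(); ++q) {
    std::string Q = as<std::string>(queries[q]);
    check_dna(Q);
    for (auto &c : Q) c = (char) toupper(c);
    int w = (int) Q.size();
    if (w == 0 || w > n) continue;
    for (int s = 0; s + w <= n; ++s) {
      int mm = 0;
      for (int k = 0; k < w; ++k) {
        char a = S[s + k], b = Q[k];
        if (a != b || a == 'N') {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) { qidx.push_back(q + 1); pos.push_back(s); mms.push_back(mm); }
    }
  }
  return DataFrame::create(_["query"] = qidx, _["pos"] = pos, _["mismatches"] = mms);
}
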