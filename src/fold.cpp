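#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximisation (Nussinov-style) over nested structures.
// Pair weights (kcal/mol-equivalent): GC -3, AU -2, GU -1; minimum hairpin
// loop of 3 unpaired bases (a pair (i,k) requires k - i - 1 >= 3).
// Tie-break: pairing i beats leaving i unpaired; among pairing partners the
// smallest k wins.

static inline double pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // not pairable
}

static void fill_tables(const std::string &s, std::vector<double> &W,
                        std::vector<int> &C, bool traceback) {
  const int n = (int) s.size();
  // W[i*n+j] = min energy of s[i..j]; C = chosen partner of i (-1 unpaired)
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = W[(i + 1) * n + j]; // i unpaired
      int choice = -1;
      for (int k = i + 4; k <= j; ++k) {
        double w = pair_weight(s[i], s[k]);
        if (w > 0) continue;
        double inner = (k - 1 >= i + 1) ? W[(i + 1) * n + (k - 1)] : 0.0;
        double outer = (k + 1 <= j) ? W[(k + 1) * n + j] : 0.0;
        double e = w + inner + outer;
        if (e < best - 1e-12) {            // strict improvement
          best = e; choice = k;
        } else if (e <= best + 1e-12 && choice == -1) {
          choice = k;                      // tie vs "i unpaired": prefer pairing
        }                                  // ties among k: smallest k (first seen)
      }
      W[i * n + j] = best;
      if (traceback) C[i * n + j] = choice;
    }
  }
}

static std::string to_rna(std::string s) {
  for (auto &c : s) {
    c = (char) toupper(c);
    if (c == 'T') c = 'U';
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("non-nucleotide character in sequence: '%s'", std::string(1, c).c_str());
  }
  return s;
}

// [[Rcpp::export(name = ".nussinov_energy")]]
double nussinov_energy(std::string seq) {
  std::string s = to_rna(seq);
  int n = (int) s.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 0.0;
  std::vector<double> W((size_t) n * n, 0.0);
  std::vector<int> C;
  fill_tables(s, W, C, false);
  return W[0 * n + (n - 1)];
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq) {
  std::string s = to_rna(seq);
  int n = (int) s.size();
  if (n == 0) stop("empty sequence");
  std::vector<double> W((size_t) n * n, 0.0);
  std::vector<int> C((size_t) n * n, -1);
  if (n > 1) fill_tables(s, W, C, true);
  // traceback with explicit stack
  std::vector<std::pair<int,int> > stack, pairs;
  if (n > 1) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int k = C[i * n + j];
    if (k < 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      pairs.push_back(std::make_pair(i, k));
      if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
      if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
    }
  }
  IntegerMatrix pm((int) pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    pm(p, 0) = pairs[p].first;
    pm(p, 1) = pairs[p].second;
  }
  double e = (n > 1) ? W[0 * n + (n - 1)] : 0.0;
  return List::create(_["energy"] = e, _["pairs"] = pm);
}
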