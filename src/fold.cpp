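#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Watson-Crick + GU wobble pairing; N pairs with nothing. Bases are coded
// A=0, C=1, G=2, T=3, other=4 and pairing resolved through a lookup table.
static const bool PAIRTAB[5][5] = {
  // A      C      G      T      N
  {false, false, false, true,  false},  // A
  {false, false, true,  false, false},  // C
  {false, true,  false, true,  false},  // G
  {true,  false, true,  false, false},  // T
  {false, false, false, false, false}   // N
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

// Nussinov maximum base-pairing with minimum loop length 3. Traceback is
// deterministic: at (i, j) a pairing of i is taken whenever one achieves the
// optimum, scanning partners from the outside in, which keeps stems
// contiguous (leftmost-pair rule).
// [[Rcpp::export(name = ".nussinov")]]
List nussinov(std::string s) {
  const int n = (int)s.size();
  const int MINLOOP = 3;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(s[i]);
  std::vector<int> M((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t)i * n + j]; };
  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = M[(size_t)(i + 1) * n + j];
      const bool *prow = PAIRTAB[code[i]];
      const int *rowi1 = &M[(size_t)(i + 1) * n];
      for (int k = i + MINLOOP + 1; k < j; ++k) {
        if (!prow[code[k]]) continue;
        int v = 1 + rowi1[k - 1] + M[(size_t)(k + 1) * n + j];
        if (v > best) best = v;
      }
      if (prow[code[j]]) {
        int v = 1 + rowi1[j - 1];
        if (v > best) best = v;
      }
      M[(size_t)i * n + j] = best;
    }
  }
  IntegerVector pt(n, -1);
  if (n > 1) {
    std::stack<std::pair<int, int> > st;
    st.push(std::make_pair(0, n - 1));
    while (!st.empty()) {
      int i = st.top().first, j = st.top().second;
      st.pop();
      if (i >= j || j - i < MINLOOP + 1) continue;
      int target = at(i, j);
      bool paired = false;
      for (int k = j; k >= i + MINLOOP + 1; --k) {
        if (!PAIRTAB[code[i]][code[k]]) continue;
        int v = 1 + (k - i >= 2 ? at(i + 1, k - 1) : 0) +
                (k < j ? at(k + 1, j) : 0);
        if (v == target) {
          pt[i] = k; pt[k] = i;
          if (k - i >= 2) st.push(std::make_pair(i + 1, k - 1));
          if (k < j) st.push(std::make_pair(k + 1, j));
          paired = true;
          break;
        }
      }
      if (!paired) st.push(std::make_pair(i + 1, j));
    }
  }
  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (pt[i] > i) { db[i] = '('; db[pt[i]] = ')'; ++npairs; }
    else if (pt[i] >= 0 && pt[i] < i) db[i] = ')';
  }
  return List::create(_["structure"] = db, _["n_pairs"] = npairs,
                      _["pairs"] = pt);
}
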