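// Global (Needleman-Wunsch) alignment with linear gap penalty and fixed,
// documented tie-breaking: prefer diagonal, then up (gap in the second
// sequence), then left. Traceback bytes keep memory at O(n*m).
#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, double match,
                  double mismatch, double gap) {
  size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<unsigned char> tb((n + 1) * (m + 1));  // 0 diag, 1 up, 2 left
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) { prev[j] = gap * (double)j; tb[j] = 2; }
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = gap * (double)i;
    tb[i * (m + 1)] = 1;
    char ca = a[i - 1];
    if (ca >= 'a') ca -= 32;
    for (size_t j = 1; j <= m; ++j) {
      char cb = b[j - 1];
      if (cb >= 'a') cb -= 32;
      double d = prev[j - 1] + (ca == cb ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; unsigned char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = dir;
    }
    prev.swap(cur);
  }
  double score = prev[m];
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      ra.push_back(a[--i] >= 'a' ? a[i] - 32 : a[i]);
      rb.push_back(b[--j] >= 'a' ? b[j] - 32 : b[j]);
    } else if (i > 0 && (dir == 1 || j == 0)) {
      ra.push_back(a[--i] >= 'a' ? a[i] - 32 : a[i]);
      rb.push_back('-');
    } else {
      ra.push_back('-');
      rb.push_back(b[--j] >= 'a' ? b[j] - 32 : b[j]);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aln1"] = ra, _["aln2"] = rb, _["score"] = score);
}
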