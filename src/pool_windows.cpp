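#include <Rcpp.h>
using namespace Rcpp;

// Pool read counts over depth-adaptive symmetric windows within blocks.
// For each focal site the window grows over consecutive same-block sites,
// adding the nearer flanking site (left on ties), until the pooled depth
// reaches min_depth or the block is exhausted.
// [[Rcpp::export]]
List pool_window_counts(IntegerMatrix n1, IntegerMatrix n,
                        IntegerVector block, int min_depth) {
  int S = n1.nrow(), I = n1.ncol();
  if (n.nrow() != S || n.ncol() != I || block.size() != S)
    stop("dimension mismatch");
  IntegerMatrix out1(S, I), outn(S, I);
  // block segment boundaries
  std::vector<int> seg_start(S), seg_end(S);
  for (int s = 0; s < S; ++s) {
    if (s == 0 || block[s] != block[s - 1]) seg_start[s] = s;
    else seg_start[s] = seg_start[s - 1];
  }
  for (int s = S - 1; s >= 0; --s) {
    if (s == S - 1 || block[s] != block[s + 1]) seg_end[s] = s;
    else seg_end[s] = seg_end[s + 1];
  }
  for (int j = 0; j < I; ++j) {
    for (int s = 0; s < S; ++s) {
      int bs = seg_start[s], be = seg_end[s];
      int l = s, r = s;
      long tot = n(s, j), tot1 = n1(s, j);
      while (tot < min_depth && (l > bs || r < be)) {
        bool take_left;
        if (l == bs) take_left = false;
        else if (r == be) take_left = true;
        else take_left = (s - (l - 1)) <= ((r + 1) - s);
        if (take_left) { --l; tot += n(l, j); tot1 += n1(l, j); }
        else           { ++r; tot += n(r, j); tot1 += n1(r, j); }
      }
      out1(s, j) = (int)tot1;
      outn(s, j) = (int)tot;
    }
  }
  return List::create(Named("n1") = out1, Named("n") = outn);
}
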