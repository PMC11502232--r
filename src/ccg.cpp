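#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Lag histogram of response spikes around trigger spikes.
// Bins are centred at j * bin for j = -J..J with J = round(half / bin);
// a lag l falls in bin j = llround(l / bin), i.e. bin j covers
// [j*bin - bin/2, j*bin + bin/2). Inputs need not be sorted.
// [[Rcpp::export(name = ".ccg_counts")]]
IntegerVector ccg_counts(NumericVector trigger, NumericVector response,
                         double bin, double half) {
  int J = (int)std::lround(half / bin);
  IntegerVector counts(2 * J + 1);
  if (trigger.size() == 0 || response.size() == 0) return counts;

  std::vector<double> trg(trigger.begin(), trigger.end());
  std::vector<double> rsp(response.begin(), response.end());
  if (!std::is_sorted(trg.begin(), trg.end())) std::sort(trg.begin(), trg.end());
  if (!std::is_sorted(rsp.begin(), rsp.end())) std::sort(rsp.begin(), rsp.end());

  double lo_off = -(J + 0.5) * bin, hi_off = (J + 0.5) * bin;
  size_t lo = 0;
  for (size_t i = 0; i < trg.size(); ++i) {
    double t = trg[i];
    while (lo < rsp.size() && rsp[lo] < t + lo_off) ++lo;
    for (size_t j = lo; j < rsp.size() && rsp[j] < t + hi_off; ++j) {
      int b = (int)std::lround((rsp[j] - t) / bin);
      if (b >= -J && b <= J) ++counts[b + J];
    }
  }
  return counts;
}

// Mass of the lag histogram inside |lag| <= cof_half together with the
// total count: returns c(inside, total). Used by the shuffle-null hot loop
// so no full histogram has to be materialised per shuffle.
// [[Rcpp::export(name = ".cofire_counts")]]
NumericVector cofire_counts(NumericVector trigger, NumericVector response,
                            double bin, double half, double cof_half) {
  IntegerVector counts = ccg_counts(trigger, response, bin, half);
  int J = (counts.size() - 1) / 2;
  int Jin = (int)std::lround(cof_half / bin);
  double inside = 0, total = 0;
  for (int j = -J; j <= J; ++j) {
    total += counts[j + J];
    if (j >= -Jin && j <= Jin) inside += counts[j + J];
  }
  return NumericVector::create(inside, total);
}
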