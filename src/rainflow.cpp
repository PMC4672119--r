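#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Four-point rainflow cycle extraction on a turning-point sequence.
// Whenever the inner range of the last four stacked reversals is the
// smallest, the inner pair is counted as one full cycle and removed.
// Remaining reversals (the residual) are counted pairwise as half-cycles.
// Returns a matrix with columns: amplitude (half range), mean (absolute
// midpoint of the pair) and weight (1 full, 0.5 half).
// [[Rcpp::export]]
NumericMatrix rainflow_cycles_cpp(NumericVector tp) {
  std::vector<double> st;
  st.reserve(tp.size());
  std::vector<double> amp, mean_, wt;

  for (R_xlen_t i = 0; i < tp.size(); ++i) {
    st.push_back(tp[i]);
    while (st.size() >= 4) {
      size_t n = st.size();
      double s1 = st[n - 4], s2 = st[n - 3], s3 = st[n - 2], s4 = st[n - 1];
      double r1 = std::fabs(s1 - s2);
      double r2 = std::fabs(s2 - s3);
      double r3 = std::fabs(s3 - s4);
      if (r2 <= r1 && r2 <= r3) {
        amp.push_back(r2 / 2.0);
        mean_.push_back(std::fabs((s2 + s3) / 2.0));
        wt.push_back(1.0);
        st.erase(st.begin() + (n - 3), st.begin() + (n - 1));
      } else {
        break;
      }
    }
  }
  // residual: consecutive pairs as half-cycles
  for (size_t i = 0; i + 1 < st.size(); ++i) {
    double r = std::fabs(st[i] - st[i + 1]);
    if (r > 0.0) {
      amp.push_back(r / 2.0);
      mean_.push_back(std::fabs((st[i] + st[i + 1]) / 2.0));
      wt.push_back(0.5);
    }
  }

  NumericMatrix out(amp.size(), 3);
  for (size_t i = 0; i < amp.size(); ++i) {
    out(i, 0) = amp[i];
    out(i, 1) = mean_[i];
    out(i, 2) = wt[i];
  }
  colnames(out) = CharacterVector::create("amplitude", "mean", "weight");
  return out;
}
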