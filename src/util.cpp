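// Small numeric kernels for the benchmark hot path.
#include <Rcpp.h>
using namespace Rcpp;

// log2(x + 1), single pass.
// [[Rcpp::export]]
NumericMatrix log2p1(const NumericMatrix& x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const double ln2 = 0.6931471805599453;
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = log1p(x[i]) / ln2;
  out.attr("dimnames") = x.attr("dimnames");
  return out;
}
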