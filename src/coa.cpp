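#include <Rcpp.h>
using namespace Rcpp;

// Centre-of-areas scores for a batch of output activation vectors.
// act: n x L activation strengths; M: G x L membership of each output set
// on the defuzzification grid; xs: the G grid abscissae.  For each row the
// clipped-max Mamdani envelope is formed on the grid and its centroid
// integral(x*mu)/integral(mu) returned, both integrals by the trapezoidal
// rule (half weight on the end points, where the shouldered sets carry
// mass); NA when nothing is activated.
// [[Rcpp::export]]
NumericVector coa_scores_cpp(NumericMatrix act, NumericMatrix M,
                             NumericVector xs) {
  const int n = act.nrow(), L = act.ncol(), G = xs.size();
  if (M.nrow() != G || M.ncol() != L)
    stop("membership grid dimensions do not match activations");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double num = 0.0, den = 0.0;
    for (int g = 0; g < G; ++g) {
      double mu = 0.0;
      for (int l = 0; l < L; ++l) {
        const double a = act(i, l);
        const double m = M(g, l);
        const double v = a < m ? a : m;
        if (v > mu) mu = v;
      }
      const double w = (g == 0 || g == G - 1) ? 0.5 : 1.0;
      num += w * xs[g] * mu;
      den += w * mu;
    }
    out[i] = den > 0.0 ? num / den : NA_REAL;
  }
  return out;
}
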