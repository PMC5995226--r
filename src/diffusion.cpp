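#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler diffusion along the rows of each column of `u`:
// every column is an independent 1D line of length nrow(u), solved with the
// Thomas algorithm for (I - r L + diag(sink)) u_new = u_old, r = D dt / h^2.
// `sink` holds the per-site implicit reaction term dt*(lambda + U*occupancy)
// (pass a 0x0 matrix for none); folding it into the diffusion solve instead
// of a separate pointwise divide keeps strong per-cell uptake coupled to the
// diffusive resupply within the step.
//
// boundary: 0 = no-flux (reflecting ghost), 1 = Dirichlet with ghost value g.
// With no-flux ends and zero sink the scheme conserves the line sum exactly
// (the system matrix is symmetric with unit row sums).
// [[Rcpp::export]]
NumericMatrix tridiag_diffuse(NumericMatrix u, double r, int boundary, double g,
                              NumericMatrix sink) {
  const int n = u.nrow();
  const int m = u.ncol();
  const bool has_sink = sink.nrow() == n && sink.ncol() == m;
  NumericMatrix out(n, m);

  if (n == 1) {
    for (int j = 0; j < m; ++j) {
      double s = has_sink ? sink(0, j) : 0.0;
      if (boundary == 1 && r > 0)
        out(0, j) = (u(0, j) + 2.0 * r * g) / (1.0 + 2.0 * r + s);
      else
        out(0, j) = u(0, j) / (1.0 + s);
    }
    return out;
  }
  if (r == 0.0 && !has_sink) {
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) out(i, j) = u(i, j);
    return out;
  }

  const double end_extra = (boundary == 1) ? 2.0 * r : r;
  std::vector<double> cp(n), dp(n);

  for (int j = 0; j < m; ++j) {
    double diag0 = 1.0 + end_extra + (has_sink ? sink(0, j) : 0.0);
    double d0 = u(0, j) + ((boundary == 1) ? r * g : 0.0);
    cp[0] = -r / diag0;
    dp[0] = d0 / diag0;
    for (int i = 1; i < n; ++i) {
      double diag_i = 1.0 + ((i == n - 1) ? end_extra : 2.0 * r) +
        (has_sink ? sink(i, j) : 0.0);
      double rhs = u(i, j) + ((i == n - 1 && boundary == 1) ? r * g : 0.0);
      double denom = diag_i + r * cp[i - 1];
      cp[i] = -r / denom;
      dp[i] = (rhs + r * dp[i - 1]) / denom;
    }
    out(n - 1, j) = dp[n - 1];
    for (int i = n - 2; i >= 0; --i)
      out(i, j) = dp[i] - cp[i] * out(i + 1, j);
  }
  return out;
}
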