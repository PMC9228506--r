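#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integrator on a sum-of-Gaussians
// potential plus a harmonic bias 0.5*k*(z-c)^2.  Draws noise from R's RNG
// stream so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
NumericVector langevin_overdamped(NumericVector heights, NumericVector centers,
                                  NumericVector widths, double k, double c,
                                  double kT, double gamma_, double dt,
                                  int n_steps, int burn_in, double z0,
                                  int stride) {
  const int ng = heights.size();
  double z = z0;
  const double sig = std::sqrt(2.0 * kT * dt / gamma_);
  const int n_keep = (n_steps - burn_in + stride - 1) / stride;
  NumericVector out(n_keep);
  int j = 0;
  for (int s = 0; s < n_steps; ++s) {
    double dU = k * (z - c);
    for (int g = 0; g < ng; ++g) {
      const double d = z - centers[g];
      const double w2 = widths[g] * widths[g];
      dU += heights[g] * std::exp(-d * d / (2.0 * w2)) * (-d / w2);
    }
    z += -(dt / gamma_) * dU + sig * norm_rand();
    if (s >= burn_in && (s - burn_in) % stride == 0) out[j++] = z;
  }
  return out;
}
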