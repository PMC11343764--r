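// Reaction-diffusion propagation of the QuaSSE D/E functions on a trait
// grid, backward in time along a branch.
//
// Operator splitting per step dt (Strang, second order):
//   reaction(dt/2) [ diffusion(dt) reaction(dt) ]^{n-1} diffusion(dt) reaction(dt/2)
//
// The reaction step solves, exactly and pointwise in x (lambda(x) constant
// within a step),
//   dE/dt = mu - (lambda+mu) E + lambda E^2
//   dD/dt = -(lambda+mu) D + 2 lambda E D
// via the constant-rate birth-death closed form; the per-point exponentials
// exp((lambda-mu) dt) are precomputed once per branch.  The diffusion step
// convolves both functions with a Gaussian kernel of variance sigma2*dt and
// mean -phi*dt (ancestral states lag the drift), applied spectrally; D and
// E are packed into one complex vector so each step costs one
// forward/inverse FFT pair (FFTW).

#include <Rcpp.h>
#include <fftw3.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// exact constant-rate update of (D, E) over tau, with A = exp((lambda-mu)*tau)
static inline void reaction_point(double &D, double &E, const double lam,
                                  const double mu, const double tau,
                                  const double A, const bool degenerate) {
  const double g0 = 1.0 - E;
  if (g0 < 1e-14) { E = 1.0; D = 0.0; return; }
  double Et, f;
  if (!degenerate) {
    const double c = mu - lam * E;
    const double den = lam * g0 * A - c;
    Et = (den != 0.0) ? (mu * g0 * A - c) / den : 1.0;
    if (Et < 0.0) Et = 0.0; else if (Et > 1.0) Et = 1.0;
    const double ratio = (1.0 - Et) / g0;
    f = ratio * ratio / A;
  } else {            // lambda == mu limit: dE/dt = lam (1-E)^2
    Et = 1.0 - g0 / (1.0 + lam * tau * g0);
    const double ratio = (1.0 - Et) / g0;
    f = ratio * ratio;
  }
  E = Et;
  D *= f;
}

struct FftwBuf {
  fftw_complex *z, *Z;
  fftw_plan fwd, bwd;
  int n;
  explicit FftwBuf(int n_) : n(n_) {
    z = fftw_alloc_complex(n);
    Z = fftw_alloc_complex(n);
    fwd = fftw_plan_dft_1d(n, z, Z, FFTW_FORWARD, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_1d(n, Z, z, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FftwBuf() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
    fftw_free(z);
    fftw_free(Z);
  }
};

// [[Rcpp::export]]
List quasse_propagate_cpp(NumericVector D0, NumericVector E0,
                          NumericVector lambda, double mu, double t_len,
                          double dt_max, double sigma2, double phi,
                          double dx, int nguard) {
  const int n = D0.size();
  if (E0.size() != n || lambda.size() != n)
    stop("D, E and lambda must share the grid length");
  if (t_len <= 0.0) stop("t_len must be > 0");
  if (dt_max <= 0.0) stop("dt must be > 0");

  const int nsteps = std::max(1, (int)std::ceil(t_len / dt_max - 1e-12));
  const double dt = t_len / nsteps;

  std::vector<double> D(D0.begin(), D0.end());
  std::vector<double> E(E0.begin(), E0.end());

  // spectral multiplier for one diffusion step: Gaussian characteristic
  // function at the grid frequencies; +i*omega*phi*dt shifts the function
  // centroid by -phi*dt per backward step
  std::vector<double> Mre(n), Mim(n);
  const double two_pi = 2.0 * M_PI;
  for (int k = 0; k < n; ++k) {
    const double kk = (k <= n / 2) ? (double)k : (double)k - (double)n;
    const double w = two_pi * kk / (n * dx);
    const double damp = std::exp(-0.5 * sigma2 * dt * w * w);
    Mre[k] = damp * std::cos(w * phi * dt);
    Mim[k] = damp * std::sin(w * phi * dt);
  }

  // per-point reaction precomputations
  std::vector<double> Afull(n), Ahalf(n);
  std::vector<char> degen(n);
  for (int i = 0; i < n; ++i) {
    const double r = lambda[i] - mu;
    degen[i] = std::fabs(r) <= 1e-9 * (lambda[i] + mu + 1.0);
    Afull[i] = std::exp(r * dt);
    Ahalf[i] = std::exp(r * dt * 0.5);
  }
  const double half = dt * 0.5;

  FftwBuf buf(n);
  const double inv_n = 1.0 / n;

  double log_scale = 0.0;
  for (int i = 0; i < n; ++i)
    reaction_point(D[i], E[i], lambda[i], mu, half, Ahalf[i], degen[i]);
  for (int s = 0; s < nsteps; ++s) {
    // diffusion: z = D + iE, convolve spectrally
    for (int i = 0; i < n; ++i) { buf.z[i][0] = D[i]; buf.z[i][1] = E[i]; }
    fftw_execute(buf.fwd);
    for (int k = 0; k < n; ++k) {
      const double re = buf.Z[k][0], im = buf.Z[k][1];
      buf.Z[k][0] = re * Mre[k] - im * Mim[k];
      buf.Z[k][1] = re * Mim[k] + im * Mre[k];
    }
    fftw_execute(buf.bwd);
    for (int i = 0; i < n; ++i) {
      double d = buf.z[i][0] * inv_n;
      double e = buf.z[i][1] * inv_n;
      D[i] = (d > 0.0) ? d : 0.0;
      E[i] = (e < 0.0) ? 0.0 : (e > 1.0 ? 1.0 : e);
    }
    // absorb wrapped mass of the localized D; E is near-flat at the edges
    // so circular wrap is harmless there and zeroing would bias extinction
    for (int i = 0; i < nguard; ++i) { D[i] = 0.0; D[n - 1 - i] = 0.0; }

    const bool last = s == nsteps - 1;
    const double tau = last ? half : dt;
    if (last)
      for (int i = 0; i < n; ++i)
        reaction_point(D[i], E[i], lambda[i], mu, tau, Ahalf[i], degen[i]);
    else
      for (int i = 0; i < n; ++i)
        reaction_point(D[i], E[i], lambda[i], mu, tau, Afull[i], degen[i]);

    if (((s & 15) == 0) || last) {
      double mx = 0.0;
      for (int i = 0; i < n; ++i) if (D[i] > mx) mx = D[i];
      if (mx > 0.0 && mx < 1e-130) {
        double tot = 0.0;
        for (int i = 0; i < n; ++i) tot += D[i];
        tot *= dx;
        for (int i = 0; i < n; ++i) D[i] /= tot;
        log_scale += std::log(tot);
      }
    }
  }
  return List::create(Named("D") = NumericVector(D.begin(), D.end()),
                      Named("E") = NumericVector(E.begin(), E.end()),
                      Named("log_scale") = log_scale);
}
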