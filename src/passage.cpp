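#include <Rcpp.h>
using namespace Rcpp;

// Batch first-passage simulation of a single hand-posture simulator.
//
// Euler-Maruyama walk between absorbing boundaries 0 (reject) and
// `threshold` (accept), drift `drift`, diffusion coefficient `noise`
// (evidence units per sqrt(second)).  A per-trial quit-time censors the
// walk: if it elapses before a boundary is reached the trial terminates
// as a quit.  Crossing is detected at step granularity; with
// bridge = true a Brownian-bridge hit test additionally detects
// within-step excursions (used when validating against the continuous
// closed forms).  A crossing and a quit in the same step resolve in
// favour of the crossing.
//
// events: 1 = accept (upper), 2 = reject (lower), 3 = quit.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List rcpp_passage_batch(int n, double drift, double threshold, double start,
                        double noise, double dt, NumericVector quit_times,
                        bool bridge) {
  if (quit_times.size() != n) stop("quit_times must have length n");
  IntegerVector event(n);
  NumericVector dtime(n);
  const double step_sd = noise * std::sqrt(dt);
  const double inv_s2dt = 1.0 / (noise * noise * dt);

  for (int i = 0; i < n; ++i) {
    const double tq = quit_times[i];
    double x = start;
    double t = 0.0;
    int ev = 0;
    while (ev == 0) {
      const double xprev = x;
      x += drift * dt + step_sd * norm_rand();
      t += dt;
      if (x >= threshold) {
        ev = 1;
      } else if (x <= 0.0) {
        ev = 2;
      } else if (bridge) {
        // probability a Brownian bridge between xprev and x (both interior)
        // touched a boundary within the step
        const double p_up = std::exp(-2.0 * (threshold - xprev) * (threshold - x) * inv_s2dt);
        const double p_lo = std::exp(-2.0 * xprev * x * inv_s2dt);
        const double u = unif_rand();
        if (u < p_up) ev = 1; else if (u < p_up + p_lo) ev = 2;
      }
      if (ev == 0 && t >= tq) ev = 3;
    }
    event[i] = ev;
    dtime[i] = (ev == 3) ? tq : t;
  }
  return List::create(_["event"] = event, _["time"] = dtime);
}
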