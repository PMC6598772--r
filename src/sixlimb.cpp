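#include <Rcpp.h>
using namespace Rcpp;

// Six coupled piecewise-linear phase oscillators generating metachronal
// waves: posterior limbs free-run, a limb's swing advance is divisively
// slowed while its posterior neighbour swings, and contralateral pairs
// are pulled to antiphase by a divisive sine term of strength alpha.
// Limb order is L1, L2, L3, R1, R2, R3; swing is theta < pi (mod 2pi).
// Time is in milliseconds; phases are radians and left unwrapped.

static inline bool in_swing(double th) {
  double m = th - 2.0 * M_PI * std::floor(th / (2.0 * M_PI));
  return m < M_PI;
}

static void deriv(const double* th, double* dth, double rate_sw,
                  double rate_st, double alpha) {
  // posterior neighbour index (-1 = none) and contralateral index
  static const int post[6] = {1, 2, -1, 4, 5, -1};
  static const int contra[6] = {3, 4, 5, 0, 1, 2};
  for (int i = 0; i < 6; ++i) {
    if (in_swing(th[i])) {
      double denom = 1.0 + alpha * std::sin(th[contra[i]] - th[i]);
      if (post[i] >= 0 && in_swing(th[post[i]])) denom += 1.0;
      dth[i] = rate_sw / denom;
    } else {
      dth[i] = rate_st;
    }
  }
}

// [[Rcpp::export(name = ".sixlimb_integrate")]]
NumericMatrix sixlimb_integrate(NumericVector theta0, double tau_swing,
                                double tau_stance, double alpha, double dt,
                                int n_steps, int thin, bool heun) {
  if (theta0.size() != 6) stop("theta0 must have length 6");
  if (dt <= 0 || tau_swing <= 0 || tau_stance <= 0)
    stop("dt and durations must be positive");
  // stability/accuracy bound for the fixed-step scheme
  if (dt > std::min(tau_swing, tau_stance) / 20.0)
    stop("dt too large: require dt <= min(tau_swing, tau_stance)/20");
  double rate_sw = M_PI / tau_swing;
  double rate_st = M_PI / tau_stance;

  int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, 6);
  double th[6], k1[6], k2[6], pred[6];
  for (int i = 0; i < 6; ++i) { th[i] = theta0[i]; out(0, i) = th[i]; }

  int row = 1;
  for (int t = 1; t <= n_steps; ++t) {
    deriv(th, k1, rate_sw, rate_st, alpha);
    if (heun) {
      for (int i = 0; i < 6; ++i) pred[i] = th[i] + dt * k1[i];
      deriv(pred, k2, rate_sw, rate_st, alpha);
      for (int i = 0; i < 6; ++i) th[i] += 0.5 * dt * (k1[i] + k2[i]);
    } else {
      for (int i = 0; i < 6; ++i) th[i] += dt * k1[i];
    }
    if (t % thin == 0 && row < n_out) {
      for (int i = 0; i < 6; ++i) out(row, i) = th[i];
      ++row;
    }
  }
  return out;
}

// Time-varying variant used by the synthetic behaviour generator:
// per-limb multiplicative modulation of swing and stance rates given on
// a coarse schedule (one value per output frame, linearly held).
// sched_* are n_frames x 6 multipliers applied to tau (>= values > 0).
// [[Rcpp::export(name = ".sixlimb_integrate_modulated")]]
NumericMatrix sixlimb_integrate_modulated(NumericVector theta0, double tau_swing,
                                          double tau_stance, double alpha,
                                          double dt, int n_steps, int thin,
                                          NumericMatrix sched_swing,
                                          NumericMatrix sched_stance) {
  if (theta0.size() != 6) stop("theta0 must have length 6");
  if (dt > std::min(tau_swing, tau_stance) / 20.0)
    stop("dt too large: require dt <= min(tau_swing, tau_stance)/20");
  int n_out = n_steps / thin + 1;
  if (sched_swing.nrow() < n_out || sched_stance.nrow() < n_out)
    stop("modulation schedule shorter than the output grid");
  NumericMatrix out(n_out, 6);
  static const int post[6] = {1, 2, -1, 4, 5, -1};
  static const int contra[6] = {3, 4, 5, 0, 1, 2};
  double th[6], k1[6], k2[6], pred[6];
  for (int i = 0; i < 6; ++i) { th[i] = theta0[i]; out(0, i) = th[i]; }

  int row = 1;
  for (int t = 1; t <= n_steps; ++t) {
    int fr = std::min((t - 1) / thin, n_out - 1);
    double rsw[6], rst[6];
    for (int i = 0; i < 6; ++i) {
      rsw[i] = M_PI / (tau_swing * sched_swing(fr, i));
      rst[i] = M_PI / (tau_stance * sched_stance(fr, i));
    }
    for (int stage = 0; stage < 2; ++stage) {
      const double* s = (stage == 0) ? th : pred;
      double* k = (stage == 0) ? k1 : k2;
      for (int i = 0; i < 6; ++i) {
        if (in_swing(s[i])) {
          double denom = 1.0 + alpha * std::sin(s[contra[i]] - s[i]);
          if (post[i] >= 0 && in_swing(s[post[i]])) denom += 1.0;
          k[i] = rsw[i] / denom;
        } else {
          k[i] = rst[i];
        }
      }
      if (stage == 0)
        for (int i = 0; i < 6; ++i) pred[i] = th[i] + dt * k1[i];
    }
    for (int i = 0; i < 6; ++i) th[i] += 0.5 * dt * (k1[i] + k2[i]);
    if (t % thin == 0 && row < n_out) {
      for (int i = 0; i < 6; ++i) out(row, i) = th[i];
      ++row;
    }
  }
  return out;
}
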