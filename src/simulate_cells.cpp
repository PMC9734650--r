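// Hybrid stochastic simulation of the SDE-driven transcription models:
// a continuous transcription-rate path K(t) (jump-decay or square-root
// diffusion) drives the discrete reactions
//   0 -> N (rate K(t)),  N -> M (rate beta per molecule),  M -> 0 (rate gamma).
// Reaction times are generated by inverting the integrated total propensity.
// For the jump-decay driver the transcription flux on each decay segment is
// K0 (1 - e^{-kappa tau}) / kappa and the inversion is exact via the Lambert
// W function; for the diffusion driver the flux is accumulated by the
// trapezoidal rule on a uniform grid of exactly sampled path values.
// Uses R's RNG throughout, so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// log of the principal-branch Lambert W with argument given in log space:
// returns y = log(W0(e^L)), i.e. solves e^y + y = L.  The residual is convex
// and increasing in y, so Newton converges globally with no clamping.
static double lambert_w0_loglog(double L) {
  double y = (L < 0.0) ? L : std::log(std::max(L - std::log(std::max(L, 1.1)), 0.5));
  for (int i = 0; i < 100; ++i) {
    double ey = std::exp(y);
    double dy = (ey + y - L) / (ey + 1.0);
    y -= dy;
    if (std::fabs(dy) <= 1e-15 * (1.0 + std::fabs(y))) break;
  }
  return y;
}

struct Recorder {
  const NumericVector& times;
  IntegerMatrix& nas;
  IntegerMatrix& mat;
  int cell, idx, n;
  Recorder(const NumericVector& t, IntegerMatrix& a, IntegerMatrix& b, int cell_)
    : times(t), nas(a), mat(b), cell(cell_), idx(0), n(t.size()) {}
  // state was constant on (from, to]; record all sample times in that window
  void advance(double to, int xN, int xM) {
    while (idx < n && times[idx] <= to + 1e-12) {
      nas(cell, idx) = xN;
      mat(cell, idx) = xM;
      ++idx;
    }
  }
  void finish(int xN, int xM) { advance(R_PosInf, xN, xM); }
};

// [[Rcpp::export]]
List simulate_gou_cells_cpp(double kappa, double theta, double a, double beta,
                            double gamma_, double t_end,
                            NumericVector record_times, int n_cells,
                            bool record_events) {
  IntegerMatrix nas(n_cells, record_times.size());
  IntegerMatrix mat(n_cells, record_times.size());
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_cell;
  RNGScope scope;
  for (int cell = 0; cell < n_cells; ++cell) {
    double K = R::rgamma(a / kappa, theta);   // stationary initial rate
    double t = 0.0;
    int xN = 0, xM = 0;
    Recorder rec(record_times, nas, mat, cell);
    double next_jump = R::rexp(1.0 / a);
    double E = R::rexp(1.0);                  // unit-exponential propensity target
    while (t < t_end) {
      double seg_end = std::min(next_jump, t_end);
      bool fired_to_seg_end = false;
      while (true) {
        double c = beta * xN + gamma_ * xM;
        double dt_seg = seg_end - t;
        double decay = std::exp(-kappa * dt_seg);
        double flux_seg = K * (1.0 - decay) / kappa + c * dt_seg;
        if (E > flux_seg) {                   // no reaction before segment end
          E -= flux_seg;
          rec.advance(seg_end, xN, xM);
          K *= decay;
          t = seg_end;
          fired_to_seg_end = true;
          break;
        }
        double tau;
        if (c <= 0.0) {
          // K (1 - e^{-kappa tau}) / kappa = E
          tau = -std::log1p(-E * kappa / K) / kappa;
        } else {
          // c tau + K (1 - e^{-kappa tau}) / kappa = E, via W0:
          // v e^v = (K/c) exp(-kappa (E - K/kappa) / c), v = (K/c) e^{-kappa tau}
          double L = std::log(K / c) - kappa * (E - K / kappa) / c;
          double logv = lambert_w0_loglog(L);
          tau = -(logv + std::log(c / K)) / kappa;
          if (tau < 0.0) tau = 0.0;
          if (tau > dt_seg) tau = dt_seg;     // numerical guard
        }
        double t_fire = t + tau;
        rec.advance(t_fire, xN, xM);
        double K_at = K * std::exp(-kappa * tau);
        double tot = K_at + c;
        double u = unif_rand() * tot;
        int type;
        if (u < K_at) { ++xN; type = 0; }
        else if (u < K_at + beta * xN) { --xN; ++xM; type = 1; }
        else { --xM; type = 2; }
        if (record_events) {
          ev_time.push_back(t_fire); ev_type.push_back(type); ev_cell.push_back(cell + 1);
        }
        K = K_at;
        t = t_fire;
        E = R::rexp(1.0);
      }
      if (fired_to_seg_end && t >= t_end) break;
      if (fired_to_seg_end && seg_end == next_jump) {
        K += R::rexp(theta);                  // exponential jump, mean theta
        next_jump = t + R::rexp(1.0 / a);
      }
    }
    rec.finish(xN, xM);
  }
  List out = List::create(_["nascent"] = nas, _["mature"] = mat);
  if (record_events) {
    out["events"] = DataFrame::create(_["cell"] = ev_cell, _["time"] = ev_time,
                                      _["reaction"] = ev_type);
  }
  return out;
}

// [[Rcpp::export]]
List simulate_cir_cells_cpp(double kappa, double theta, double a, double beta,
                            double gamma_, double t_end, double dt,
                            NumericVector record_times, int n_cells,
                            bool record_events) {
  IntegerMatrix nas(n_cells, record_times.size());
  IntegerMatrix mat(n_cells, record_times.size());
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_cell;
  const double df = 2.0 * a / kappa;
  RNGScope scope;
  for (int cell = 0; cell < n_cells; ++cell) {
    double K = R::rgamma(a / kappa, theta);
    double t = 0.0;
    int xN = 0, xM = 0;
    Recorder rec(record_times, nas, mat, cell);
    double E = R::rexp(1.0);
    while (t < t_end - 1e-12) {
      double step = std::min(dt, t_end - t);
      // exact transition: scaled noncentral chi-squared
      double decay = std::exp(-kappa * step);
      double cc = theta * (1.0 - decay) / 2.0;
      double Knext = cc * R::rnchisq(df, K * decay / cc);
      double slope = (Knext - K) / step;
      double tau0 = 0.0;
      while (true) {
        double c = beta * xN + gamma_ * xM;
        double A0 = K + slope * tau0 + c;           // propensity at tau0
        double A1 = Knext + c;                      // propensity at step end
        double flux = 0.5 * (A0 + A1) * (step - tau0);
        if (E > flux) {
          E -= flux;
          rec.advance(t + step, xN, xM);
          break;
        }
        // (slope/2) d^2 + A0 d = E, smaller positive root, stable form
        double disc = A0 * A0 + 2.0 * slope * E;
        if (disc < 0.0) disc = 0.0;
        double d = 2.0 * E / (A0 + std::sqrt(disc));
        if (d < 0.0) d = 0.0;
        double tau_f = tau0 + d;
        if (tau_f > step) tau_f = step;
        rec.advance(t + tau_f, xN, xM);
        double K_at = K + slope * tau_f;
        if (K_at < 0.0) K_at = 0.0;
        double tot = K_at + c;
        double u = unif_rand() * tot;
        int type;
        if (u < K_at) { ++xN; type = 0; }
        else if (u < K_at + beta * xN) { --xN; ++xM; type = 1; }
        else { --xM; type = 2; }
        if (record_events) {
          ev_time.push_back(t + tau_f); ev_type.push_back(type); ev_cell.push_back(cell + 1);
        }
        tau0 = tau_f;
        E = R::rexp(1.0);
      }
      K = Knext;
      t += step;
    }
    rec.finish(xN, xM);
  }
  List out = List::create(_["nascent"] = nas, _["mature"] = mat);
  if (record_events) {
    out["events"] = DataFrame::create(_["cell"] = ev_cell, _["time"] = ev_time,
                                      _["reaction"] = ev_type);
  }
  return out;
}
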