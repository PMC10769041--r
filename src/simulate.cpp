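#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the hybrid yaw-stabilization loop.
//
// States: v = plant output angular velocity (deg/s),
//         z = integrated delayed error (deg), shared by the PI integral
//             term and the saccade trigger.
// Flow:   dv/dt = kp*e_d + ki*z - cu*v,  dz/dt = e_d,
//         e_d(t) = e(t - nd*dt),  e(t) = setpoint(t) - v(t).
// Jump:   when |z| >= sigma at a sample, reset z = 0, v = 0 and (optionally)
//         flush the delay line; sigma = +Inf disables the jump map.
//
// The error history doubles as the delay line; flushing zeroes the entries
// still in transit. Event detection is at sample resolution. Divergence
// (only possible with sigma = Inf and unstable gains) truncates the run.
// [[Rcpp::export]]
List sim_hybrid_cpp(double kp, double ki, double cu, int nd, double sigma,
                    NumericVector sp, double dt, bool flush_delay,
                    double diverge_limit) {
  int n = sp.size();
  NumericVector out(n), integ(n), ehist(n);
  std::vector<double> sacc;
  double v = 0.0, z = 0.0;
  bool diverged = false;
  int last = n - 1;
  for (int i = 0; i < n; ++i) {
    out[i] = v;
    integ[i] = z;
    ehist[i] = sp[i] - v;
    if (i == n - 1) break;
    double v1, z1, h = dt;
    if (nd == 0) {
      // undelayed error: evaluate e = sp - v inside each RK4 stage
      double sp_mid = 0.5 * (sp[i] + sp[i + 1]);
      double k1v = kp * (sp[i] - v) + ki * z - cu * v;
      double k1z = sp[i] - v;
      double v2 = v + 0.5 * h * k1v, z2 = z + 0.5 * h * k1z;
      double k2v = kp * (sp_mid - v2) + ki * z2 - cu * v2;
      double k2z = sp_mid - v2;
      double v3 = v + 0.5 * h * k2v, z3 = z + 0.5 * h * k2z;
      double k3v = kp * (sp_mid - v3) + ki * z3 - cu * v3;
      double k3z = sp_mid - v3;
      double v4 = v + h * k3v, z4 = z + h * k3z;
      double k4v = kp * (sp[i + 1] - v4) + ki * z4 - cu * v4;
      double k4z = sp[i + 1] - v4;
      v1 = v + h / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
      z1 = z + h / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
    } else {
      // delayed error known at the step endpoints from the history buffer
      double e0 = (i - nd >= 0) ? ehist[i - nd] : 0.0;
      double e1 = (i + 1 - nd >= 0) ? ehist[i + 1 - nd] : 0.0;
      double em = 0.5 * (e0 + e1);
      double k1v = kp * e0 + ki * z - cu * v;
      double k2v = kp * em + ki * (z + 0.5 * h * e0) - cu * (v + 0.5 * h * k1v);
      double k3v = kp * em + ki * (z + 0.5 * h * em) - cu * (v + 0.5 * h * k2v);
      double k4v = kp * e1 + ki * (z + h * em) - cu * (v + h * k3v);
      v1 = v + h / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
      z1 = z + h / 6.0 * (e0 + 4 * em + e1);
    }
    if (!std::isfinite(v1) || !std::isfinite(z1) ||
        std::fabs(v1) > diverge_limit || std::fabs(z1) > diverge_limit) {
      diverged = true;
      last = i;
      for (int j = i + 1; j < n; ++j) {
        out[j] = NA_REAL;
        integ[j] = NA_REAL;
      }
      break;
    }
    v = v1;
    z = z1;
    if (R_finite(sigma) && std::fabs(z) >= sigma) {
      v = 0.0;
      z = 0.0;
      sacc.push_back((i + 1) * dt);
      if (flush_delay && nd > 0)
        for (int j = std::max(0, i + 1 - nd); j <= i; ++j) ehist[j] = 0.0;
    }
  }
  return List::create(_["output"] = out, _["integrator"] = integ,
                      _["saccade_times"] = wrap(sacc),
                      _["diverged"] = diverged, _["last_index"] = last + 1);
}
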