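#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monoexponential signal and its parameter derivatives.
// model: 0 = T1 saturation recovery S = M0 (1 - exp(-t/T)),
//        1 = T2 decay               S = M0 exp(-t/T).
static inline void model_terms(int model, double t, double m0, double tv,
                               double &f, double &dT) {
  double e = std::exp(-t / tv);
  if (model == 0) {            // T1
    f  = 1.0 - e;              // dS/dM0
    dT = -m0 * e * t / (tv * tv);
  } else {                     // T2
    f  = e;
    dT = m0 * e * t / (tv * tv);
  }
}

static inline double sse_at(const double *y, const double *t, int n,
                            int model, double m0, double tv) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = std::exp(-t[i] / tv);
    double S = (model == 0) ? m0 * (1.0 - e) : m0 * e;
    double r = S - y[i];
    s += r * r;
  }
  return s;
}

// Voxelwise gradient-descent fit of the monoexponential relaxation models.
//
// signals: n_time x n_vox matrix (one column per voxel).
// mode 0 ("raw"): raw steepest descent on the summed squared residuals with
//   a single shared learning rate; T clamped to positivity_floor.
// mode 1 ("scaled"): per-parameter steps scaled by the diagonal of the
//   Gauss-Newton Hessian, with backtracking on the loss and a cap on the
//   relative parameter change per iteration (step_cap).
//
// Early stop: relative parameter change < early_stop_tol (0 disables).
// trace: when true and n_vox == 1, the per-iteration SSE trajectory is
// returned (evaluated after each accepted update).
// [[Rcpp::export]]
List gd_fit_cpp(NumericMatrix signals, NumericVector times, int model,
                double m0_init, double t_init, int loop_limit,
                double learning_rate, double early_stop_tol,
                double positivity_floor, int mode, double step_cap,
                double scaled_rate, bool trace) {
  const int n = signals.nrow(), nv = signals.ncol();
  NumericVector m0_out(nv), t_out(nv), sse_out(nv);
  IntegerVector it_out(nv);
  LogicalVector conv_out(nv), degen_out(nv);
  std::vector<double> tr_buf;
  bool do_trace = trace && nv == 1;
  if (do_trace) tr_buf.reserve(loop_limit);

  const double *tt = REAL(times);

  for (int v = 0; v < nv; ++v) {
    const double *y = &signals(0, v);

    bool allzero = true;
    for (int i = 0; i < n; ++i)
      if (y[i] != 0.0) { allzero = false; break; }
    if (allzero) {
      m0_out[v] = 0.0; t_out[v] = NA_REAL; sse_out[v] = 0.0;
      it_out[v] = 0; conv_out[v] = false; degen_out[v] = true;
      continue;
    }

    double m0 = m0_init, tv = t_init;
    double L = sse_at(y, tt, n, model, m0, tv);
    int iters = loop_limit;
    bool converged = false;

    for (int it = 1; it <= loop_limit; ++it) {
      double gm = 0.0, gt = 0.0, dm = 0.0, dt2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double f, dT;
        model_terms(model, tt[i], m0, tv, f, dT);
        double S = (model == 0) ? m0 * f : m0 * f; // f already dS/dM0
        double r = S - y[i];
        gm += 2.0 * r * f;
        gt += 2.0 * r * dT;
        dm += 2.0 * f * f;
        dt2 += 2.0 * dT * dT;
      }

      double m0n, tvn;
      if (mode == 0) {
        m0n = m0 - learning_rate * gm;
        tvn = tv - learning_rate * gt;
        if (tvn < positivity_floor) tvn = positivity_floor;
        if (!std::isfinite(m0n) || !std::isfinite(tvn)) { iters = it; break; }
        double Ln = sse_at(y, tt, n, model, m0n, tvn);
        L = Ln;
      } else {
        if (dm < 1e-300) dm = 1e-300;
        if (dt2 < 1e-300) dt2 = 1e-300;
        double a = scaled_rate;
        bool ok = false;
        double Ln = L;
        for (int k = 0; k < 40; ++k) {
          double sm = a * gm / dm, st = a * gt / dt2;
          double cm = step_cap * std::max(std::fabs(m0), 1.0);
          double ct = step_cap * std::max(tv, positivity_floor);
          if (sm > cm) sm = cm; else if (sm < -cm) sm = -cm;
          if (st > ct) st = ct; else if (st < -ct) st = -ct;
          m0n = m0 - sm;
          tvn = tv - st;
          if (tvn < positivity_floor) tvn = positivity_floor;
          Ln = sse_at(y, tt, n, model, m0n, tvn);
          if (std::isfinite(Ln) && (Ln < L || Ln == 0.0)) { ok = true; break; }
          a *= 0.5;
        }
        if (!ok) { iters = it; converged = true; break; } // stalled at minimum
        L = Ln;
      }

      double rel = std::max(
        std::fabs(m0n - m0) / std::max(std::fabs(m0), 1e-12),
        std::fabs(tvn - tv) / std::max(std::fabs(tv), 1e-12));
      m0 = m0n; tv = tvn;
      if (do_trace) tr_buf.push_back(L);
      if (early_stop_tol > 0.0 && rel < early_stop_tol) {
        converged = true; iters = it; break;
      }
    }

    m0_out[v] = m0;
    t_out[v] = tv;
    it_out[v] = iters;
    conv_out[v] = converged;
    degen_out[v] = false;
    sse_out[v] = sse_at(y, tt, n, model, m0, tv);
  }

  List out = List::create(
    _["m0"] = m0_out, _["t_value"] = t_out, _["iterations"] = it_out,
    _["converged"] = conv_out, _["degenerate"] = degen_out,
    _["sse"] = sse_out);
  if (do_trace) out["trace"] = NumericVector(tr_buf.begin(), tr_buf.end());
  return out;
}
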