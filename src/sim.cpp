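#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of tau * dx/dt = f(W x + I(t)) - G x, f(u) = max(u, 0).
//
// Time axis: step s = 1..n_steps updates x_{s-1} -> x_s. The external drive
// at step s is base_input (plus noise) for s >= onset_step, zero before.
// Noise is redrawn from N(0, noise_sigma) for excitatory units every
// noise_period steps, counted from onset. Conditional rules add an input
// increment to a target unit while the network's current activation pattern
// equals the rule's trigger pattern.
//
// The activation pattern at step s marks unit i active iff the rectifier
// argument (W x_{s-1} + drive_s)_i > 0 -- the quantity whose sign gates the
// effective Jacobian. Pattern changes are logged as transitions at step s.
//
// Returns recorded states/drives/patterns at steps {0, stride, 2*stride, ...}
// plus the full transition log and the final state. Uses the R RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List sim_core(NumericMatrix W, NumericVector G, double tau,
              LogicalVector is_exc, NumericVector x0,
              NumericVector base_input, int n_steps, int onset_step,
              double noise_sigma, int noise_period, double dt,
              IntegerMatrix trig_patterns, IntegerVector trig_target,
              NumericVector trig_incr, int record_stride, bool record_state) {
  const int n = W.nrow();
  const int n_rules = trig_patterns.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> noise(n, 0.0);
  std::vector<int> pat(n, 0), prev_pat(n, 0);

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix X_rec(record_state ? n_rec : 1, record_state ? n : 1);
  NumericMatrix I_rec(record_state ? n_rec : 1, record_state ? n : 1);
  IntegerMatrix P_rec(n_rec, n);
  IntegerVector steps_rec(n_rec);

  std::vector<int> trans_step;
  std::vector<int> trans_from, trans_to; // flattened n-patterns

  std::vector<double> u(n), drive(n);

  for (int s = 0; s <= n_steps; ++s) {
    // drive at step s
    bool on = s >= onset_step;
    if (on && noise_sigma > 0.0 && ((s - onset_step) % noise_period == 0)) {
      for (int i = 0; i < n; ++i)
        noise[i] = is_exc[i] ? R::rnorm(0.0, noise_sigma) : 0.0;
    }
    for (int i = 0; i < n; ++i)
      drive[i] = on ? base_input[i] + (noise_sigma > 0.0 ? noise[i] : 0.0) : 0.0;
    // conditional rules act on the pattern the network currently occupies
    if (n_rules > 0 && s > 0) {
      for (int r = 0; r < n_rules; ++r) {
        bool match = true;
        for (int i = 0; i < n; ++i)
          if (trig_patterns(r, i) != prev_pat[i]) { match = false; break; }
        if (match) drive[trig_target[r]] += trig_incr[r];
      }
    }
    // rectifier argument and pattern
    for (int i = 0; i < n; ++i) {
      double acc = drive[i];
      for (int j = 0; j < n; ++j) acc += W(i, j) * x[j];
      u[i] = acc;
      pat[i] = acc > 0.0 ? 1 : 0;
    }
    if (s > 0) {
      bool changed = false;
      for (int i = 0; i < n; ++i)
        if (pat[i] != prev_pat[i]) { changed = true; break; }
      if (changed) {
        trans_step.push_back(s);
        for (int i = 0; i < n; ++i) {
          trans_from.push_back(prev_pat[i]);
          trans_to.push_back(pat[i]);
        }
      }
    }
    if (s % record_stride == 0) {
      int r = s / record_stride;
      steps_rec[r] = s;
      for (int i = 0; i < n; ++i) {
        P_rec(r, i) = pat[i];
        if (record_state) { X_rec(r, i) = x[i]; I_rec(r, i) = drive[i]; }
      }
    }
    prev_pat = pat;
    if (s == n_steps) break;
    // Euler update
    for (int i = 0; i < n; ++i) {
      double fu = u[i] > 0.0 ? u[i] : 0.0;
      x[i] += dt / tau * (fu - G[i] * x[i]);
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e100)
        stop("state of unit %d became non-finite at step %d: parameters outside the bounded regime",
             i + 1, s + 1);
    }
  }

  int n_tr = trans_step.size();
  IntegerMatrix Tf(n_tr, n), Tt(n_tr, n);
  for (int t = 0; t < n_tr; ++t)
    for (int i = 0; i < n; ++i) {
      Tf(t, i) = trans_from[(size_t)t * n + i];
      Tt(t, i) = trans_to[(size_t)t * n + i];
    }
  NumericVector x_final(x.begin(), x.end());
  return List::create(_["steps"] = steps_rec, _["X"] = X_rec, _["I"] = I_rec,
                      _["patterns"] = P_rec,
                      _["trans_step"] = IntegerVector(trans_step.begin(), trans_step.end()),
                      _["trans_from"] = Tf, _["trans_to"] = Tt,
                      _["x_final"] = x_final);
}
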