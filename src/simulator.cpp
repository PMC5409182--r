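#include <Rcpp.h>
using namespace Rcpp;

// Implicit (backward-Euler) integration of a passive branched cable with
// exponential-decay conductance synapses. Compartments are ordered so that
// parent[i] < i, which lets a Hines-style direct solve run in O(N) per
// step: leaf-to-root elimination followed by root-to-leaf substitution.
// Synaptic conductances are held at their step-start values in the matrix
// (they decay exactly between events) so the linear system stays symmetric
// positive definite and the scheme is unconditionally stable.

// [[Rcpp::export]]
List sim_tree_cpp(IntegerVector parent, NumericVector g_ax,
                  NumericVector cap, NumericVector gl,
                  double EL, double Ee, double Ei,
                  double dt, int nstep, double tau_e, double tau_i,
                  IntegerVector ev_step, IntegerVector ev_comp,
                  IntegerVector ev_type, NumericVector ev_q,
                  double I_amp, double I_freq,
                  NumericVector bg_ge, NumericVector bg_gi,
                  IntegerVector probes) {
  const int N = parent.size();
  std::vector<double> v(N, EL), ge(N, 0.0), gi(N, 0.0);
  std::vector<double> diag(N), off(N), rhs(N);
  const double fe = std::exp(-dt / tau_e), fi = std::exp(-dt / tau_i);
  NumericVector v_soma(nstep + 1);
  const int np = probes.size();
  NumericMatrix v_probe(nstep + 1, np);
  v_soma[0] = EL;
  for (int p = 0; p < np; ++p) v_probe(0, p) = EL;

  const int nev = ev_step.size();
  int iev = 0;
  const double two_pi = 2.0 * M_PI;

  for (int n = 0; n < nstep; ++n) {
    // apply the events scheduled for this step (increments Q, coincident
    // duplicates simply add)
    while (iev < nev && ev_step[iev] == n) {
      if (ev_type[iev] == 0) ge[ev_comp[iev]] += ev_q[iev];
      else                   gi[ev_comp[iev]] += ev_q[iev];
      ++iev;
    }
    if (iev < nev && ev_step[iev] < n)
      stop("event steps must be sorted");

    const double t_next = (n + 1) * dt;
    for (int i = 0; i < N; ++i) {
      const double get = ge[i] + bg_ge[i], git = gi[i] + bg_gi[i];
      diag[i] = cap[i] / dt + gl[i] + get + git;
      rhs[i] = cap[i] / dt * v[i] + gl[i] * EL + get * Ee + git * Ei;
      off[i] = 0.0;
    }
    if (I_amp != 0.0)
      rhs[0] += I_amp * std::sin(two_pi * I_freq * t_next);
    for (int i = 1; i < N; ++i) {
      const int p = parent[i];
      diag[i] += g_ax[i];
      diag[p] += g_ax[i];
      off[i] = -g_ax[i];
    }
    // Hines elimination (children have larger indices than their parent)
    for (int i = N - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = off[i] / diag[i];
      diag[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < N; ++i)
      v[i] = (rhs[i] - off[i] * v[parent[i]]) / diag[i];

    if (!(v[0] > -0.5 && v[0] < 0.5))
      stop("numerical instability: somatic potential out of bounds at t=%g s",
           t_next);

    for (int i = 0; i < N; ++i) { ge[i] *= fe; gi[i] *= fi; }
    v_soma[n + 1] = v[0];
    for (int p = 0; p < np; ++p) v_probe(n + 1, p) = v[probes[p]];
  }
  return List::create(_["v_soma"] = v_soma, _["v_probe"] = v_probe);
}
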