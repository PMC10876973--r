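#include <Rcpp.h>
using namespace Rcpp;

// Exponential-Euler integration of a single-compartment conductance neuron
// driven by binned synaptic impulses, with a point-dipole readout.
//
// Synaptic gates are differences of exponentials and therefore linear in the
// input spikes, so the population sums needed for the membrane equation
// (scalar gate sums) and for the dipole (direction-weighted gate sums) are
// propagated directly as eight exponential accumulators per population
// (rise/decay x {scalar, x, y, z}). Per-step cost is O(1) regardless of the
// number of synapses.
//
// impE / impI: nsteps x 4 matrices of per-step impulse sums
//   (count, sum of x, sum of y, sum of z of the synapse direction vectors).
// Units: conductances nS, capacitance nF, time ms, voltage mV.
// [[Rcpp::export(name = ".dipole_integrate_cpp")]]
List dipole_integrate_cpp(NumericMatrix impE, NumericMatrix impI,
                          double dt,
                          double gL, double Cm, double EL,
                          double gE, double tauE, double riseE, double normE,
                          double EE,
                          double gI, double tauI, double riseI, double normI,
                          double EI,
                          double V0, bool clamp, double Vclamp) {
  int n = impE.nrow();
  if (impI.nrow() != n) stop("impulse matrices must have equal length");
  NumericVector V(n);
  NumericMatrix Q(n, 3);
  double aEd = std::exp(-dt / tauE), aEr = std::exp(-dt / riseE);
  double aId = std::exp(-dt / tauI), aIr = std::exp(-dt / riseI);
  // accumulators: [decay, rise] x [s, x, y, z]
  double Ed[4] = {0, 0, 0, 0}, Er[4] = {0, 0, 0, 0};
  double Id[4] = {0, 0, 0, 0}, Ir[4] = {0, 0, 0, 0};
  double v = clamp ? Vclamp : V0;
  bool diverged = false;
  int div_step = -1;
  for (int t = 0; t < n; ++t) {
    for (int c = 0; c < 4; ++c) {
      double we = impE(t, c), wi = impI(t, c);
      Ed[c] = Ed[c] * aEd + we;  Er[c] = Er[c] * aEr + we;
      Id[c] = Id[c] * aId + wi;  Ir[c] = Ir[c] * aIr + wi;
    }
    double sE = (Ed[0] - Er[0]) / normE;   // summed E gate (peak-1 per spike)
    double sI = (Id[0] - Ir[0]) / normI;
    if (!clamp) {
      double ge = gE * sE, gi = gI * sI;
      double gtot = gL + ge + gi;
      double vinf = (gL * EL + ge * EE + gi * EI) / gtot;
      v = vinf + (v - vinf) * std::exp(-gtot * dt / Cm);
      if (std::fabs(v) > 200.0 && !diverged) { diverged = true; div_step = t; }
    }
    V[t] = v;
    double dfE = gE * (v - EE), dfI = gI * (v - EI);
    for (int c = 0; c < 3; ++c) {
      double sEc = (Ed[c + 1] - Er[c + 1]) / normE;
      double sIc = (Id[c + 1] - Ir[c + 1]) / normI;
      Q(t, c) = -(dfE * sEc + dfI * sIc);
    }
    if (diverged) break;
  }
  return List::create(_["V"] = V, _["Q"] = Q,
                      _["diverged"] = diverged, _["div_step"] = div_step);
}

// First-order recursive (AR(1)) filter with a time-varying coefficient:
// y[t] = a[t] * y[t-1] + x[t]. Used to synthesise signals whose spectrum
// follows a Lorentzian with a slowly drifting time constant.
// [[Rcpp::export(name = ".ar1_filter_cpp")]]
NumericVector ar1_filter_cpp(NumericVector x, NumericVector a) {
  int n = x.size();
  if (a.size() != n) stop("coefficient vector must match signal length");
  NumericVector y(n);
  double prev = 0.0;
  for (int t = 0; t < n; ++t) {
    prev = a[t] * prev + x[t];
    y[t] = prev;
  }
  return y;
}

// Discrete-time branching-network simulation (Rule #2): baseline Poisson
// drive plus Bernoulli spike propagation along the adjacency, spikes placed
// uniformly within the propagation window. Event-driven (cost scales with
// the number of spikes, not bins x neurons), so the bin can be made fine to
// keep same-bin spike merging negligible. Uses R's RNG so rasters are
// reproducible under set.seed().
// [[Rcpp::export(name = ".branching_sim_cpp")]]
List branching_sim_cpp(IntegerMatrix targets, int n_bins, int w_bins,
                       double p_base, double p_prop) {
  int N = targets.nrow(), d = targets.ncol();
  std::vector< std::vector<int> > pending(w_bins);  // circular buffer
  std::vector<char> hot(N, 0);                      // fired-this-bin flag
  std::vector<int> who, when, fired;
  for (int t = 0; t < n_bins; ++t) {
    int col = t % w_bins;
    fired.clear();
    // scheduled spikes arriving in this bin
    for (size_t k = 0; k < pending[col].size(); ++k) {
      int i = pending[col][k];
      if (!hot[i]) { hot[i] = 1; fired.push_back(i); }
    }
    pending[col].clear();
    // baseline Poisson drive (binomial count, then uniform neuron choice;
    // same-bin duplicates merge, which is negligible at p_base << 1)
    int nb = (int) R::rbinom((double) N, p_base);
    for (int k = 0; k < nb; ++k) {
      int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
      if (!hot[i]) { hot[i] = 1; fired.push_back(i); }
    }
    // propagate
    for (size_t k = 0; k < fired.size(); ++k) {
      int i = fired[k];
      who.push_back(i + 1);
      when.push_back(t + 1);
      for (int j = 0; j < d; ++j) {
        if (unif_rand() < p_prop) {
          int delay = 1 + (int)(unif_rand() * w_bins);
          if (delay > w_bins) delay = w_bins;
          pending[(t + delay) % w_bins].push_back(targets(i, j) - 1);
        }
      }
      hot[i] = 0;  // reset after the bin is assembled
    }
  }
  return List::create(_["neuron"] = wrap(who), _["bin"] = wrap(when));
}
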