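// Euler-scheme simulator for feedforward stacks of leaky integrate-and-fire
// layers. Synaptic transmission is an instantaneous delta current: a
// presynaptic spike adds the synaptic weight (mV) to the postsynaptic
// membrane potential within the same time step, matching the current moments
// mu_bar = W mu and Sigma_bar = W Sigma W^T used by the moment network.
// Input drive is either a set of inhomogeneous Poisson sources (per-bin
// Bernoulli thinning with p = rate * dt) or a correlated Gaussian current
// with per-step increments mean mu*dt and covariance Sigma*dt.
// Randomness comes from R's RNG so set.seed() in R controls every draw.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct LayerState {
  std::vector<double> V;
  std::vector<int> ref;        // remaining refractory steps
  std::vector<int> spiked;     // 0/1 this step
};

inline void step_layer(LayerState &st, const std::vector<double> &drift,
                       const std::vector<double> &jump, double dt, double L,
                       double V_th, double V_res, int ref_steps) {
  const int n = st.V.size();
  for (int i = 0; i < n; ++i) {
    st.spiked[i] = 0;
    if (st.ref[i] > 0) {
      st.ref[i] -= 1;
      st.V[i] = V_res;
      continue;
    }
    double v = st.V[i] + (-L * st.V[i]) * dt + drift[i] + jump[i];
    if (v >= V_th) {
      st.spiked[i] = 1;
      v = V_res;
      st.ref[i] = ref_steps;
    }
    st.V[i] = v;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_snn_sim(List Ws, List mu_exts, int input_mode,
                 NumericMatrix rates, NumericVector gauss_mu,
                 NumericMatrix gauss_chol, int nsteps, double dt,
                 int bin_steps, int n_trials, double L, double V_th,
                 double V_res, double T_ref, bool record_v,
                 bool init_uniform) {
  const int n_layers = Ws.size();
  const int ref_steps = (int)std::lround(T_ref / dt);
  const int nbins = nsteps / bin_steps;
  const int n_in = (input_mode == 0) ? rates.nrow() : gauss_mu.size();

  std::vector<NumericMatrix> W(n_layers);
  std::vector<std::vector<double>> mu_ext(n_layers);
  std::vector<int> nsz(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    W[l] = as<NumericMatrix>(Ws[l]);
    NumericVector me = mu_exts[l];
    mu_ext[l] = std::vector<double>(me.begin(), me.end());
    nsz[l] = W[l].nrow();
  }

  List trials(n_trials);
  for (int tr = 0; tr < n_trials; ++tr) {
    std::vector<LayerState> st(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      st[l].V.assign(nsz[l], V_res);
      st[l].ref.assign(nsz[l], 0);
      st[l].spiked.assign(nsz[l], 0);
      if (init_uniform)
        for (int i = 0; i < nsz[l]; ++i)
          st[l].V[i] = V_res + unif_rand() * (V_th - V_res);
    }
    std::vector<IntegerMatrix> counts(n_layers);
    std::vector<NumericMatrix> vtr(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      counts[l] = IntegerMatrix(nsz[l], nbins);
      if (record_v) vtr[l] = NumericMatrix(nsz[l], nbins);
    }
    NumericVector input_pop(nbins);
    std::vector<int> in_spk(n_in, 0);
    std::vector<double> gz(n_in), gcur(n_in);
    std::vector<double> drift, jump;

    for (int t = 0; t < nsteps; ++t) {
      const int b = t / bin_steps;
      // external drive
      if (input_mode == 0) {
        int tot = 0;
        for (int i = 0; i < n_in; ++i) {
          const double p = rates(i, t) * dt;
          in_spk[i] = (unif_rand() < p) ? 1 : 0;
          tot += in_spk[i];
        }
        input_pop[b] += tot;
      } else {
        for (int i = 0; i < n_in; ++i) gz[i] = norm_rand();
        const double sdt = std::sqrt(dt);
        for (int i = 0; i < n_in; ++i) {
          double acc = gauss_mu[i] * dt;
          for (int j = 0; j <= i; ++j) acc += gauss_chol(i, j) * gz[j] * sdt;
          gcur[i] = acc;
        }
      }
      for (int l = 0; l < n_layers; ++l) {
        const int n = nsz[l];
        const int npre = W[l].ncol();
        drift.assign(n, 0.0);
        jump.assign(n, 0.0);
        for (int i = 0; i < n; ++i) drift[i] = mu_ext[l][i] * dt;
        if (l == 0 && input_mode == 1) {
          for (int i = 0; i < n; ++i) jump[i] = gcur[i];
        } else {
          const std::vector<int> &pre =
              (l == 0) ? in_spk : st[l - 1].spiked;
          for (int j = 0; j < npre; ++j) {
            if (!pre[j]) continue;
            for (int i = 0; i < n; ++i) jump[i] += W[l](i, j);
          }
        }
        step_layer(st[l], drift, jump, dt, L, V_th, V_res, ref_steps);
        for (int i = 0; i < n; ++i)
          if (st[l].spiked[i]) counts[l](i, b) += 1;
        if (record_v && (t + 1) % bin_steps == 0)
          for (int i = 0; i < n; ++i) vtr[l](i, b) = st[l].V[i];
      }
    }
    List lc(n_layers), lv(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      lc[l] = counts[l];
      if (record_v) lv[l] = vtr[l];
    }
    trials[tr] = List::create(_["counts"] = lc,
                              _["input_pop"] = input_pop,
                              _["vtraces"] = record_v ? (SEXP)lv
                                                      : R_NilValue);
  }
  return trials;
}

// Single LIF neuron driven by Gaussian white-noise current with mean mu and
// std sigma (mV/sqrt(ms)); returns spike counts per bin. Used as the
// Monte-Carlo oracle for the moment activation.
// [[Rcpp::export]]
IntegerVector cpp_lif_single(double mu, double sigma, int nsteps, double dt,
                             int bin_steps, double L, double V_th,
                             double V_res, double T_ref) {
  const int ref_steps = (int)std::lround(T_ref / dt);
  const int nbins = nsteps / bin_steps;
  IntegerVector counts(nbins);
  double V = V_res;
  int ref = 0;
  const double sdt = sigma * std::sqrt(dt);
  for (int t = 0; t < nsteps; ++t) {
    if (ref > 0) {
      --ref;
      V = V_res;
      continue;
    }
    V += (-L * V + mu) * dt + sdt * norm_rand();
    if (V >= V_th) {
      counts[t / bin_steps] += 1;
      V = V_res;
      ref = ref_steps;
    }
  }
  return counts;
}
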