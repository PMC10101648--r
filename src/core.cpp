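// Numerical engines for the motor-loop model: CPG integration, the
// basal-ganglia rate loop, and the cerebellar reservoir trial.
// All stochastic draws go through R's RNG so that set.seed() at the R
// level makes every simulation reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Integrate the two rhythm-generator cells of one CPG.
// params: tau_m, sigma_f, sigma_s, i_inj, alpha_0, theta_0
// Returns the V trace of the extensor cell (for oracle tests) when
// trace = true, otherwise the mean joint angle over the readout window.
// [[Rcpp::export]]
NumericVector cpp_cpg_joint(NumericVector params, List fixed, double duration,
                            double dt, double readout_ms, bool trace,
                            double v_init_e, double v_init_f, double guard) {
  const double tau_m = params[0], sigma_f = params[1], sigma_s = params[2];
  const double i_inj = params[3], alpha_0 = params[4], theta_0 = params[5];
  const double A_f = as<double>(fixed["A_f"]);
  const double tau_s = as<double>(fixed["tau_s_factor"]) * tau_m;
  const double alpha_PF = as<double>(fixed["alpha_PF"]);
  const double theta_PF = as<double>(fixed["theta_PF"]);
  const double W_rg = as<double>(fixed["W_rg"]);
  const double W_pf = as<double>(fixed["W_pf"]);
  const double Amp = as<double>(fixed["Amp"]);
  const double E_s = as<double>(fixed["E_s"]);
  const double U_ref = as<double>(fixed["U_ref_joint"]);

  const int n = (int)std::lround(duration / dt);
  const int n_read = (int)std::lround(readout_ms / dt);
  double Ve = v_init_e, qe = 0.0, Vf = v_init_f, qf = 0.0;
  double u_acc = 0.0;
  int n_acc = 0;
  NumericVector vtrace(trace ? n : 0);
  for (int i = 0; i < n; ++i) {
    const double dVe = -(Ve - A_f * std::tanh((sigma_f / A_f) * Ve) + qe - i_inj) / tau_m;
    const double dqe = (-qe + sigma_s * (Ve - E_s)) / tau_s;
    const double dVf = -(Vf - A_f * std::tanh((sigma_f / A_f) * Vf) + qf + i_inj) / tau_m;
    const double dqf = (-qf + sigma_s * (Vf - E_s)) / tau_s;
    Ve += dt * dVe; qe += dt * dqe;
    Vf += dt * dVf; qf += dt * dqf;
    if (std::abs(Ve) > guard || std::abs(Vf) > guard)
      stop("CPG integration failure: |V| exceeded guard value %f", guard);
    if (trace) vtrace[i] = Ve;
    if (i >= n - n_read) {
      const double PFe = logistic(-alpha_0 * alpha_PF * ((theta_0 + theta_PF) - W_rg * Ve));
      const double PFf = logistic(-alpha_0 * alpha_PF * ((theta_0 + theta_PF) - W_rg * Vf));
      const double MNe = logistic(-5.0 * (0.5 - W_pf * PFe));
      const double MNf = logistic(-5.0 * (0.5 - W_pf * PFf));
      u_acc += Amp * (MNe - MNf) + U_ref;
      ++n_acc;
    }
  }
  if (trace) return vtrace;
  return NumericVector::create(u_acc / n_acc);
}

// One cerebellar trial: random initial state, goal input on for in_steps,
// off for free_steps; output = mean rate of the first n_out units over the
// free phase. Eligibility accumulates the cubed pre-rate x post-deviation
// product (a rank-one structure, assembled as one matrix product).
// [[Rcpp::export]]
List cpp_reservoir_trial(const arma::mat& J, const arma::mat& B, int gid,
                         int n_out, int in_steps, int free_steps, double dt,
                         double tau, double f, double A, double xbar_tau,
                         double x_init_range) {
  const int N = J.n_rows;
  const int T = in_steps + free_steps;
  const double p_pert = f * dt / 1000.0;
  arma::vec x(N), xb(N), r(N);
  for (int i = 0; i < N; ++i) x[i] = R::runif(-x_init_range, x_init_range);
  xb = x;
  r = arma::tanh(x);
  arma::mat Dc(N, T), Rc(N, T);
  arma::vec out_acc(n_out, arma::fill::zeros);
  const double leak = dt / tau, xbk = dt / xbar_tau;
  for (int t = 0; t < T; ++t) {
    arma::vec drive = J * r;
    if (t < in_steps && gid >= 0) drive += B.col(gid);
    Rc.col(t) = arma::pow(r, 3);            // r(t-1)^3
    x += leak * (drive - x);
    if (p_pert > 0.0 && A > 0.0) {
      for (int i = 0; i < N; ++i)
        if (R::unif_rand() < p_pert) x[i] += R::runif(-A, A);
    }
    Dc.col(t) = arma::pow(x - xb, 3);        // (x(t) - xbar)^3
    xb += xbk * (x - xb);
    r = arma::tanh(x);
    if (t >= in_steps)
      out_acc += r.subvec(0, n_out - 1);
  }
  arma::mat elig = Dc * Rc.t();
  return List::create(_["output"] = NumericVector(out_acc.begin(), out_acc.end()) / (double)free_steps,
                      _["elig"] = elig,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["mean_abs_r"] = arma::mean(arma::abs(r)));
}

// Run the basal-ganglia rate loop for n_steps of dt ms.
// state: mp_pre, mp_str, mp_snr, mp_thal, mp_ctx, mp_par, da (membrane potentials)
// wts:   W (n_pre x n_act premotor->striatum, plastic), WDA (n_act, plastic),
//        WLIB (n_act x n_parcells, fixed random action->parameter weights)
// clamp: 0-based motor-cortex channel forced to rate 1 (-1 = none)
// P:     movement-gate input to the dopamine cell (0 or 1)
// learn: apply Eqs for corticostriatal and striatum->DA plasticity each step
// [[Rcpp::export]]
List cpp_bg_run(List state, List wts, const arma::vec& pre_base, int clamp,
                int n_steps, double P, bool learn, List par) {
  arma::vec mp_pre = as<arma::vec>(state["mp_pre"]);
  arma::vec mp_str = as<arma::vec>(state["mp_str"]);
  arma::vec mp_snr = as<arma::vec>(state["mp_snr"]);
  arma::vec mp_thal = as<arma::vec>(state["mp_thal"]);
  arma::vec mp_ctx = as<arma::vec>(state["mp_ctx"]);
  arma::vec mp_par = as<arma::vec>(state["mp_par"]);
  double da = as<double>(state["da"]);
  arma::mat W = as<arma::mat>(wts["W"]);
  arma::vec WDA = as<arma::vec>(wts["WDA"]);
  const arma::mat& WLIB = as<arma::mat>(wts["WLIB"]);

  const double tau = as<double>(par["tau"]), dt = as<double>(par["dt"]);
  const double tau_da = as<double>(par["tau_da"]), tau_w = as<double>(par["tau_w"]);
  const double w_str_snr = as<double>(par["w_str_snr"]);
  const double w_snr_thal = as<double>(par["w_snr_thal"]);
  const double w_thal_ctx = as<double>(par["w_thal_ctx"]);
  const double w_ctx_str = as<double>(par["w_ctx_str"]);
  const double B_str = as<double>(par["B_striatum"]), B_snr = as<double>(par["B_snr"]);
  const double B_thal = as<double>(par["B_thalamus"]), B_ctx = as<double>(par["B_cortex"]);
  const double B_da = as<double>(par["B_DA"]);
  const double K_b = as<double>(par["K_b"]), K_d = as<double>(par["K_d"]);
  const double alpha_j = as<double>(par["alpha_j"]);
  const double g_pre = as<double>(par["gamma_pre"]), g_post = as<double>(par["gamma_post"]);
  const double eps = as<double>(par["noise_amplitude"]);

  const int n_act = mp_str.n_elem;
  const double k = dt / tau, kda = dt / tau_da, kw = dt / tau_w;
  double peak_da = da;
  const int n_avg = std::min(n_steps, 50);   // cortex readout window, steps
  arma::vec ctx_acc(n_act, arma::fill::zeros);

  for (int t = 0; t < n_steps; ++t) {
    arma::vec r_pre = arma::clamp(mp_pre, 0.0, arma::datum::inf);
    arma::vec r_str = arma::clamp(mp_str, 0.0, arma::datum::inf);
    arma::vec r_snr = arma::clamp(mp_snr, 0.0, arma::datum::inf);
    arma::vec r_thal = arma::clamp(mp_thal, 0.0, arma::datum::inf);
    arma::vec r_ctx = arma::clamp(mp_ctx, 0.0, arma::datum::inf);
    if (clamp >= 0) { r_ctx.zeros(); r_ctx[clamp] = 1.0; }  // exclusive selection

    arma::vec nz(n_act);
    auto noise = [&](arma::vec& v) {
      if (eps > 0) for (int i = 0; i < n_act; ++i) v[i] = R::runif(-eps, eps);
      else v.zeros();
      return v;
    };
    mp_pre += k * (-mp_pre + pre_base);
    mp_str += k * (-mp_str + W.t() * r_pre + w_ctx_str * r_ctx + B_str + noise(nz));
    mp_snr += k * (-mp_snr + B_snr - w_str_snr * r_str + noise(nz));
    mp_thal += k * (-mp_thal + B_thal - w_snr_thal * r_snr + noise(nz));
    mp_ctx += k * (-mp_ctx + B_ctx + w_thal_ctx * r_thal + noise(nz));
    if (clamp >= 0) mp_ctx[clamp] = 1.0;
    mp_par += k * (-mp_par + WLIB.t() * r_ctx);
    if (t >= n_steps - n_avg) ctx_acc += arma::clamp(mp_ctx, 0.0, arma::datum::inf);
    const double pred = 1.0 - arma::dot(WDA, r_str);
    da += kda * (-da + P * std::max(0.0, pred) + B_da);
    if (da > peak_da) peak_da = da;

    if (learn) {
      arma::vec r_str2 = arma::clamp(mp_str, 0.0, arma::datum::inf);
      arma::vec r_pre2 = arma::clamp(mp_pre, 0.0, arma::datum::inf);
      const double mean_pre = arma::mean(r_pre2), mean_post = arma::mean(r_str2);
      const double x = da - B_da;
      const double fda = (x > 0 ? K_b : K_d) * x;
      arma::vec ci = r_pre2 - mean_pre - g_pre;     // pre factor
      arma::vec cj = r_str2 - mean_post - g_post;   // post factor
      arma::mat C = ci * cj.t();
      C.clamp(0.0, arma::datum::inf);
      arma::rowvec norm = alpha_j * arma::square(r_str2.t() - mean_post);
      W += kw * (fda * C - arma::repmat(norm, W.n_rows, 1));
      W.clamp(0.0, arma::datum::inf);
      WDA += kw * (3.0 * x * arma::clamp(r_str2 - mean_pre, 0.0, arma::datum::inf));
      WDA.clamp(0.0, arma::datum::inf);
    }
  }
  List st = List::create(_["mp_pre"] = mp_pre, _["mp_str"] = mp_str,
                         _["mp_snr"] = mp_snr, _["mp_thal"] = mp_thal,
                         _["mp_ctx"] = mp_ctx, _["mp_par"] = mp_par, _["da"] = da);
  arma::vec r_ctx_out = ctx_acc / (double)n_avg;  // time-averaged rates
  if (clamp >= 0) { r_ctx_out.zeros(); r_ctx_out[clamp] = 1.0; }
  return List::create(_["state"] = st,
                      _["W"] = W, _["WDA"] = WDA,
                      _["peak_da"] = peak_da,
                      _["r_ctx"] = NumericVector(r_ctx_out.begin(), r_ctx_out.end()),
                      _["r_par"] = NumericVector(mp_par.begin(), mp_par.end()));
}
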