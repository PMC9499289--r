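// Trial-level simulation engine. Composes exactly the single-step updates
// defined in R/dynamics.R (reservoir Euler step, winner-take-all MD,
// eligibility trace, Hebbian corticothalamic update with clipping, leaky
// readout with node perturbation) over the steps of one trial.
//
// RNG: draws come from R's RNG stream, in a fixed order per step (reservoir
// noise first, one draw per neuron, then one uniform perturbation draw per
// output neuron), so a pure-R composition of the step primitives reproduces
// the trajectories under the same seed.
//
// The recurrent matrix-vector product dominates the cost; with
// single_precision = true it is carried out in float (the rest of the state
// stays double). Trajectories then agree with the double path to ~1e-4 over
// a trial; results remain bit-reproducible for a given seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Standard normals from consecutive uniform draws via Box-Muller, consumed
// in pairs (an odd count draws a full pair and discards the second value).
// Using the uniform stream directly keeps the draws cheap and exactly
// reproducible from the R side.
static inline void fill_normals(double* z, int k) {
  for (int i = 0; i < k; i += 2) {
    double u1 = unif_rand(), u2 = unif_rand();
    double rad = std::sqrt(-2.0 * std::log(u1)), ang = 2.0 * M_PI * u2;
    z[i] = rad * std::cos(ang);
    if (i + 1 < k) z[i + 1] = rad * std::sin(ang);
  }
}

// [[Rcpp::export]]
List run_trial_cpp(const arma::mat& W_rec, const arma::mat& W_inp,
                   const arma::mat& W_md, arma::mat W_ct,
                   const arma::mat& W_out,
                   arma::vec I, arma::vec I_out, arma::vec rho,
                   arma::vec rho_bar,
                   arma::vec md_act, arma::vec I_md, arma::vec u_bar,
                   const arma::vec& inp4,
                   const arma::vec& route_md, const arma::vec& route_pfc,
                   int route_steps,
                   int n_steps, int input_steps,
                   double dt_over_tau, double noise_sd, double md_noise_sd,
                   double g_add, double g_mult, bool lesioned,
                   int forced_md,
                   bool learn_ct, double alpha_ct, double clip_bound,
                   double tau_pre_steps, double tau_adapt_steps,
                   double wta_hysteresis,
                   bool perturb,
                   int aw0, int aw1, int dw0, int dw1,
                   bool record, bool single_precision = true) {
  const int n = W_rec.n_rows;
  const int n_md = W_ct.n_rows;
  const int n_out = W_out.n_rows;
  const double k = dt_over_tau;

  arma::vec r = arma::clamp(arma::tanh(I), 0.0, arma::datum::inf);

  arma::vec r_sum(n, arma::fill::zeros), rdec_sum(n, arma::fill::zeros);
  arma::vec md_sum(n_md, arma::fill::zeros);
  arma::vec zeta_sum(n_out, arma::fill::zeros), out_sum(n_out, arma::fill::zeros);
  arma::mat zr_acc(n_out, n, arma::fill::zeros);

  arma::mat r_trace, md_trace, out_trace;
  if (record) {
    r_trace.set_size(n_steps, n);
    md_trace.set_size(n_steps, n_md);
    out_trace.set_size(n_steps, n_out);
  }

  // feedforward drives are constant within their windows: precompute
  arma::vec drive_inp = W_inp * inp4;           // while t <= input_steps
  arma::vec drive_both = drive_inp + route_pfc; // while also t <= route_steps

  // MD modulation changes only when the winner changes
  arma::vec m(n, arma::fill::zeros);
  bool m_stale = !lesioned;

  arma::fmat W_rec_f;
  arma::fvec r_f(n), rec_f(n);
  if (single_precision) W_rec_f = arma::conv_to<arma::fmat>::from(W_rec);

  arma::vec noise(n, arma::fill::zeros), zeta(n_out, arma::fill::zeros);
  arma::vec noise_md(n_md, arma::fill::zeros);
  arma::vec rec(n), u(n_md), out_drive(n_out);

  for (int t = 1; t <= n_steps; ++t) {
    // reservoir step (uses MD activations from the previous step)
    if (m_stale) { m = W_md * md_act; m_stale = false; }
    if (single_precision) {
      r_f = arma::conv_to<arma::fvec>::from(r);
      rec_f = W_rec_f * r_f;
      rec = arma::conv_to<arma::vec>::from(rec_f);
    } else {
      rec = W_rec * r;
    }
    const double* dr;
    if (t <= route_steps && t <= input_steps) dr = drive_both.memptr();
    else if (t <= input_steps) dr = drive_inp.memptr();
    else if (t <= route_steps) dr = route_pfc.memptr();
    else dr = nullptr;
    const bool zero_drive = (dr == nullptr);
    if (noise_sd > 0.0) fill_normals(noise.memptr(), n);
    double bad = 0.0;
    for (int i = 0; i < n; ++i) {
      double ni = (noise_sd > 0.0) ? noise[i] * noise_sd : 0.0;
      double di = -I[i] + (1.0 + g_mult * m[i]) * rec[i] + g_add * m[i] + ni;
      if (!zero_drive) di += dr[i];
      I[i] += k * di;
      bad += I[i];
      double ri = std::tanh(I[i]);
      r[i] = ri > 0.0 ? ri : 0.0;
    }
    if (!std::isfinite(bad)) stop("non-finite reservoir state");

    // MD winner-take-all. Corticothalamic drive is integrated with the same
    // membrane time constant as dlPFC, and the competition is referenced to
    // each MD neuron's slow running-average input (adaptive baseline), so it
    // is driven by input deviations rather than absolute levels and no
    // neuron can monopolize the winner-take-all. Independent noise on the
    // comparison lets the competition explore while the learned margins are
    // still small; trained margins dwarf it.
    if (forced_md >= 0) {
      if (noise_sd > 0.0) fill_normals(noise_md.memptr(), n_md);  // keep stream
      md_act.zeros();
      md_act[forced_md] = 1.0;
    } else {
      u = W_ct * r;
      if (t <= route_steps) u += route_md;
      I_md += k * (-I_md + u);
      if (noise_sd > 0.0) fill_normals(noise_md.memptr(), n_md);
      arma::vec uc = I_md - u_bar + md_noise_sd * noise_md;
      u_bar += (I_md - u_bar) / tau_adapt_steps;
      int w = uc.index_max();  // first maximum: ties go to the lowest index
      // switching hysteresis: a challenger must beat the incumbent by a
      // fixed margin, so near-tied inputs cannot make the winner flicker
      int cur = md_act.index_max();
      if (w != cur && uc[w] <= uc[cur] + wta_hysteresis) w = cur;
      if (md_act[w] != 1.0) { md_act.zeros(); md_act[w] = 1.0; m_stale = !lesioned; }
    }

    // eligibility trace and Hebbian corticothalamic update; the presynaptic
    // factor is the trace's deviation from its own slow running mean
    // (centering timescale tau_adapt), the postsynaptic factor the MD
    // activation centered on the population mean
    rho += (r - rho) / tau_pre_steps;
    rho_bar += (rho - rho_bar) / tau_adapt_steps;
    if (learn_ct) {
      double md_mean = arma::mean(md_act);
      for (int j = 0; j < n_md; ++j) {
        double post = alpha_ct * (md_act[j] - md_mean);
        for (int i = 0; i < n; ++i) {
          double w = W_ct(j, i) + post * (rho[i] - rho_bar[i]);
          W_ct(j, i) = w > clip_bound ? clip_bound
                       : (w < -clip_bound ? -clip_bound : w);
        }
      }
    }

    // readout step with node perturbation (linear output units)
    out_drive = W_out * r;
    for (int i = 0; i < n_out; ++i) {
      double z = perturb ? (unif_rand() * 2.0 - 1.0) : 0.0;
      zeta[i] = z;
      I_out[i] += k * (-I_out[i] + out_drive[i] + z);
    }

    if (perturb) zr_acc += zeta * r.t();
    if (t >= aw0 && t <= aw1) { r_sum += r; md_sum += md_act; }
    if (t >= dw0 && t <= dw1) {
      rdec_sum += r; zeta_sum += zeta; out_sum += I_out;
    }
    if (record) {
      r_trace.row(t - 1) = r.t();
      md_trace.row(t - 1) = md_act.t();
      out_trace.row(t - 1) = I_out.t();
    }
  }

  const double n_aw = aw1 - aw0 + 1, n_dw = dw1 - dw0 + 1;
  // return vectors as plain numeric vectors, not n x 1 matrices
  auto nv = [](const arma::vec& v) {
    return NumericVector(v.begin(), v.end());
  };
  List res = List::create(
      Named("I") = nv(I), Named("I_out") = nv(I_out), Named("rho") = nv(rho),
      Named("rho_bar") = nv(rho_bar),
      Named("md_act") = nv(md_act), Named("I_md") = nv(I_md),
      Named("u_bar") = nv(u_bar),
      Named("W_ct") = W_ct,
      Named("r_avg") = nv(r_sum / n_aw), Named("md_avg") = nv(md_sum / n_aw),
      Named("r_dec") = nv(rdec_sum / n_dw),
      Named("zeta_mean") = nv(zeta_sum / n_dw),
      Named("out_mean") = nv(out_sum / n_dw), Named("zr_acc") = zr_acc);
  if (record) {
    res["r_trace"] = r_trace;
    res["md_trace"] = md_trace;
    res["out_trace"] = out_trace;
  }
  return res;
}
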