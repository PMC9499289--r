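# Shared helpers: small network instances and a pure-R trial reference that
# composes the exported single-step primitives in the same order (and with
# the same RNG draw order) as the C++ engine.

# Box-Muller normals from the uniform stream, consumed in pairs exactly as
# the engine consumes them (odd counts draw a full pair, discard the sine).
rnorm_bm <- function(k) {
  z <- numeric(k)
  for (i in seq(1, k, by = 2)) {
    u <- stats::runif(2)
    rad <- sqrt(-2 * log(u[1])); ang <- 2 * pi * u[2]
    z[i] <- rad * cos(ang)
    if (i + 1 <= k) z[i + 1] <- rad * sin(ang)
  }
  z
}

small_params <- function(n_neurons = 20L, n_sub = 8L, n_steps = 30L,
                         input_steps = 15L, noise_var = 1e-3) {
  reservoir_params(n_neurons = n_neurons, n_sub = n_sub, n_steps = n_steps,
                   input_steps = input_steps, noise_var = noise_var,
                   analysis_window = c(5L, 20L),
                   decision_window = c(16L, n_steps))
}

small_network <- function(seed = 1, params = small_params()) {
  set.seed(seed)
  build_network(params, n_md = 2L)
}

# Pure-R reference for one trial: must reproduce run_trial_cpp (double
# precision path) exactly under the same RNG state.
run_trial_reference <- function(net, I, I_out, rho, md_act, inp4,
                                params, g_add = 1, g_mult = 1,
                                lesioned = FALSE, learn_ct = TRUE,
                                alpha_ct = 5e-5, clip_bound = 0.1,
                                tau_pre_steps = 2000,
                                tau_adapt_steps = 120000, u_bar = NULL,
                                I_md = NULL, rho_bar = NULL,
                                md_noise_sd = 0.05, wta_hysteresis = 0.1,
                                perturb = TRUE) {
  n <- params$n_neurons
  k_dt <- params$dt; k_tau <- params$tau
  noise_sd <- sqrt(params$noise_var)
  r <- pmax(tanh(I), 0)
  if (is.null(u_bar)) u_bar <- numeric(nrow(net$W_ct))
  if (is.null(I_md)) I_md <- numeric(nrow(net$W_ct))
  if (is.null(rho_bar)) rho_bar <- numeric(n)
  zr_acc <- matrix(0, 2, n)
  aw <- params$analysis_window; dw <- params$decision_window
  r_sum <- numeric(n); md_sum <- numeric(2)
  rdec_sum <- numeric(n); zeta_sum <- numeric(2); out_sum <- numeric(2)
  for (t in seq_len(params$n_steps)) {
    noise <- if (noise_sd > 0) rnorm_bm(n) * noise_sd else numeric(n)
    u_in <- if (t <= params$input_steps) inp4 else numeric(4)
    mod <- thalamic_modulation(md_act, net$W_md, g_add, g_mult, lesioned)
    st <- step_dynamics(I, r, as.vector(net$W_inp %*% u_in),
                        mod$additive, mod$gain, net$W_rec,
                        k_dt, k_tau, noise)
    I <- st$I; r <- st$r
    u <- as.vector(net$W_ct %*% r)
    I_md <- I_md + (k_dt / k_tau) * (-I_md + u)
    nmd <- if (noise_sd > 0) rnorm_bm(2) else numeric(2)
    # winner from the integrated input referenced to the adaptive baseline,
    # with exploration noise and incumbent hysteresis on the comparison
    uc <- I_md - u_bar + md_noise_sd * nmd
    w <- which.max(uc)
    cur <- which.max(md_act)
    if (w != cur && uc[w] <= uc[cur] + wta_hysteresis) w <- cur
    md_act <- as.numeric(tabulate(w, 2))
    u_bar <- u_bar + (I_md - u_bar) / tau_adapt_steps
    rho <- update_eligibility(rho, r, tau_pre_steps)
    rho_bar <- rho_bar + (rho - rho_bar) / tau_adapt_steps
    if (learn_ct)
      net$W_ct <- hebbian_ct_update(net$W_ct, rho, md_act, alpha_ct,
                                    clip_bound, center = rho_bar)
    zeta <- if (perturb) stats::runif(2, -1, 1) else numeric(2)
    I_out <- readout_step(I_out, r, net$W_out, zeta, k_dt, k_tau)$I_out
    zr_acc <- zr_acc + outer(zeta, r)
    if (t >= aw[1] && t <= aw[2]) { r_sum <- r_sum + r; md_sum <- md_sum + md_act }
    if (t >= dw[1] && t <= dw[2]) {
      rdec_sum <- rdec_sum + r; zeta_sum <- zeta_sum + zeta
      out_sum <- out_sum + I_out
    }
  }
  n_aw <- diff(aw) + 1; n_dw <- diff(dw) + 1
  list(I = I, I_out = I_out, rho = rho, rho_bar = rho_bar,
       md_act = md_act, I_md = I_md,
       u_bar = u_bar, W_ct = net$W_ct,
       r_avg = r_sum / n_aw, md_avg = md_sum / n_aw, r_dec = rdec_sum / n_dw,
       zeta_mean = zeta_sum / n_dw, out_mean = out_sum / n_dw,
       zr_acc = zr_acc)
}

call_engine <- function(net, I, I_out, rho, md_act, inp4, params,
                        g_add = 1, g_mult = 1, lesioned = FALSE,
                        learn_ct = TRUE, alpha_ct = 5e-5, clip_bound = 0.1,
                        tau_pre_steps = 2000, tau_adapt_steps = 120000,
                        u_bar = NULL, I_md = NULL, rho_bar = NULL,
                        md_noise_sd = 0.05, wta_hysteresis = 0.1,
                        perturb = TRUE,
                        record = FALSE, single_precision = FALSE,
                        forced_md = -1L, route_md = NULL, route_pfc = NULL,
                        route_steps = 0L) {
  n <- params$n_neurons
  if (is.null(u_bar)) u_bar <- numeric(nrow(net$W_ct))
  if (is.null(I_md)) I_md <- numeric(nrow(net$W_ct))
  if (is.null(rho_bar)) rho_bar <- numeric(n)
  thalamoflex:::run_trial_cpp(
    net$W_rec, net$W_inp, net$W_md, net$W_ct, net$W_out,
    I, I_out, rho, rho_bar, md_act, I_md, u_bar, inp4,
    if (is.null(route_md)) numeric(nrow(net$W_ct)) else route_md,
    if (is.null(route_pfc)) numeric(n) else route_pfc,
    route_steps, params$n_steps, params$input_steps,
    params$dt / params$tau, sqrt(params$noise_var), md_noise_sd,
    g_add, g_mult, lesioned, forced_md, learn_ct, alpha_ct, clip_bound,
    tau_pre_steps, tau_adapt_steps, wta_hysteresis, perturb,
    params$analysis_window[1], params$analysis_window[2],
    params$decision_window[1], params$decision_window[2],
    record, single_precision)
}

# Independent oracle: explicit log-space enumeration of the switch posterior.
brute_switch_probability <- function(consistent, prior, cl) {
  L <- length(consistent)
  lik <- function(idx_post) {
    ll <- 0
    for (i in seq_len(L)) {
      p_c <- if (consistent[i]) cl else 1 - cl
      p <- if (i %in% idx_post) 1 - p_c else p_c
      ll <- ll + log(p)
    }
    exp(ll)
  }
  ev_s <- 0
  for (i in seq_len(L)) ev_s <- ev_s + prior * lik(i:L)
  ev_ns <- max(1 - L * prior, 0) * lik(integer(0))
  ev_s / (ev_s + ev_ns)
}

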