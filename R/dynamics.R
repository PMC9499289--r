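# Single-step dynamics primitives. These are the reference definitions of the
# model equations; the trial-level C++ engine composes exactly these updates
# (a test asserts step-for-step agreement on a shared RNG stream).

#' One Euler step of the reservoir dynamics
#'
#' The membrane input of neuron i evolves as
#' \deqn{\tau \frac{dI_i}{dt} = -I_i + [W_{inp} u]_i + (1 + g_{mult} m_i)\,
#'   [W_{rec} r]_i + g_{add} m_i + \rho_i}
#' where `m = W_md %*% md_rates` is the per-neuron MD modulation (shared by
#' the additive and multiplicative pathways), and `rho` is i.i.d. Gaussian
#' noise of variance `noise_var` entering the rate-of-change. Rates are
#' `r = max(tanh(I), 0)` after every step, so all rates lie in [0, 1).
#'
#' @param I membrane input vector.
#' @param r rate vector from the previous step.
#' @param drive_inp feedforward drive `W_inp %*% u` (n-vector), already
#'   including any OFC routing current targeted at dlPFC.
#' @param md_add,md_gain additive and multiplicative MD modulation vectors
#'   (see [thalamic_modulation()]); zero vectors when MD is lesioned.
#' @param W_rec recurrent weight matrix.
#' @param dt,tau integration step and membrane time constant (same units).
#' @param noise per-neuron noise draws for this step (vector, typically
#'   `rnorm(n, 0, sqrt(noise_var))`); pass 0 to disable.
#' @param activation `"rectified_tanh"` (model) or `"identity"` (used by the
#'   linear-regime test harness).
#' @return list with updated `I` and `r`.
#' @export
step_dynamics <- function(I, r, drive_inp, md_add, md_gain, W_rec, dt, tau,
                          noise = 0, activation = c("rectified_tanh", "identity")) {
  activation <- match.arg(activation)
  rec <- as.vector(W_rec %*% r)
  dI <- -I + drive_inp + (1 + md_gain) * rec + md_add + noise
  I <- I + (dt / tau) * dI
  if (!all(is.finite(I))) stop("non-finite reservoir state")
  r <- if (activation == "identity") I else pmax(tanh(I), 0)
  list(I = I, r = r)
}

#' Update the Hebbian eligibility trace
#'
#' Low-pass filter of the presynaptic dlPFC rates:
#' `rho' = rho + (r - rho)/tau_pre`, with `tau_pre` in steps.
#'
#' @param rho current trace vector.
#' @param r current rate vector.
#' @param tau_pre_steps trace time constant in integration steps (> 0).
#' @export
update_eligibility <- function(rho, r, tau_pre_steps) {
  if (tau_pre_steps <= 0) stop("tau_pre_steps must be > 0")
  rho + (r - rho) / tau_pre_steps
}

#' Winner-take-all MD step
#'
#' MD inputs are `u = W_ct %*% r` plus any OFC routing current; the neuron
#' with the larger input has its activation set to 1 and the other(s) to 0.
#' Ties are broken toward the lowest index.
#'
#' When a `baseline` is supplied the comparison uses each neuron's input
#' deviation `u - baseline` instead of the absolute input. The simulator
#' maintains this baseline as a slow running average of each MD neuron's
#' input (time constant `tau_adapt_ms`, about 100 trials), which keeps the
#' competition sensitive to input *changes*: without it, whichever neuron
#' starts with the larger summed weights monopolizes the winner-take-all
#' forever and no context structure can form.
#'
#' @param W_ct corticothalamic weights (n_md x n).
#' @param r dlPFC rate vector.
#' @param route optional routing current (n_md-vector).
#' @param baseline optional per-neuron adaptive input baseline.
#' @return one-hot activation vector of length n_md.
#' @export
md_step <- function(W_ct, r, route = NULL, baseline = NULL) {
  u <- as.vector(W_ct %*% r)
  if (!is.null(route)) u <- u + route
  if (!is.null(baseline)) u <- u - baseline
  act <- numeric(length(u))
  act[which.max(u)] <- 1  # which.max takes the first maximum: lowest index
  act
}

#' Hebbian corticothalamic update
#'
#' `dW = alpha * (md - mean(md)) %o% (rho - center)`: both factors are
#' centered — the MD activations on their population mean, the presynaptic
#' trace on `center` — so uniform activity contributes nothing; entries are
#' then clipped to `[-clip_bound, clip_bound]`. By default `center` is the
#' trace's population mean at the current step; the simulator instead passes
#' each neuron's slow running trace average (timescale `tau_adapt_ms`), so
#' that learning is driven by each neuron's deviation from its own recent
#' activity rather than from the population's.
#'
#' @param W_ct corticothalamic weights (n_md x n).
#' @param rho presynaptic eligibility trace (n-vector).
#' @param md_act postsynaptic MD activations (n_md-vector).
#' @param alpha learning rate (default 5e-5).
#' @param clip_bound clipping bound (default 0.1).
#' @param center presynaptic centering term: scalar or n-vector; NULL for
#'   the population mean of `rho`.
#' @export
hebbian_ct_update <- function(W_ct, rho, md_act, alpha = 5e-5,
                              clip_bound = 0.1, center = NULL) {
  if (is.null(center)) center <- mean(rho)
  dW <- alpha * outer(md_act - mean(md_act), rho - center)
  W <- W_ct + dW
  pmin(pmax(W, -clip_bound), clip_bound)
}

#' Rescale corticothalamic weights to a fixed norm
#'
#' Applied once per trial end: `W' = W * target_norm / ||W||_F`.
#'
#' @param W_ct weight matrix.
#' @param target_norm the Frobenius norm recorded at initialization.
#' @export
rescale_ct_norm <- function(W_ct, target_norm) {
  nrm <- frobenius_norm(W_ct)
  if (nrm == 0) stop("cannot rescale a zero weight matrix")
  W_ct * (target_norm / nrm)
}

#' Thalamic modulation of the reservoir
#'
#' The additive and multiplicative MD outputs use the same fixed weights:
#' `m = W_md %*% md_act`; the additive term is `g_add * m` and the recurrent
#' gain term `g_mult * m`. When lesioned both are zero vectors (the caller is
#' responsible for the compensatory 1.3 scaling of the recurrent weights).
#'
#' @param md_act MD activation vector.
#' @param W_md fixed MD-to-dlPFC weights (n x n_md).
#' @param g_add,g_mult sweep factors scaling the additive and multiplicative
#'   pathways (default 1).
#' @param lesioned if TRUE both outputs are zero.
#' @return list with `additive` and `gain` n-vectors.
#' @export
thalamic_modulation <- function(md_act, W_md, g_add = 1, g_mult = 1,
                                lesioned = FALSE) {
  if (lesioned) {
    z <- numeric(nrow(W_md))
    return(list(additive = z, gain = z))
  }
  m <- as.vector(W_md %*% md_act)
  list(additive = g_add * m, gain = g_mult * m)
}

#' One Euler step of the output neurons
#'
#' `tau dI/dt = -I + W_out %*% r + zeta`, with the perturbation `zeta` drawn
#' fresh each step from U(-1, 1) per output neuron. The two output units are
#' linear: their activity is the membrane input itself.
#'
#' @param I_out output membrane inputs (2-vector).
#' @param r dlPFC rate vector.
#' @param W_out readout weights (2 x n).
#' @param zeta perturbation vector for this step (0 to disable).
#' @param dt,tau integration constants.
#' @return list with the updated `I_out`.
#' @export
readout_step <- function(I_out, r, W_out, zeta, dt, tau) {
  dI <- -I_out + as.vector(W_out %*% r) + zeta
  list(I_out = I_out + (dt / tau) * dI)
}

#' Decide a response from the output trace
#'
#' Response is `"up"` if the mean activity of the up output over the decision
#' window is at least that of the down output (ties go to up), else `"down"`.
#'
#' @param out_trace n_steps x 2 matrix of output activities (column 1 = up).
#' @param window inclusive 1-based step range, default steps 101-200.
#' @export
decide <- function(out_trace, window = c(101L, 200L)) {
  if (window[1] > window[2] || window[2] > nrow(out_trace))
    stop("decision window outside trial")
  m <- colMeans(out_trace[window[1]:window[2], , drop = FALSE])
  if (m[1] >= m[2]) "up" else "down"
}

#' Node-perturbation readout update
#'
#' `W'_ij = W_ij + mu * zeta_i * r_j * delta_e` where `delta_e` is the trial's
#' reward minus the running reward baseline. In the default per-step mode
#' `zeta_i * r_j` is the sum over trial steps of `zeta_i(t) r_j(t)` (the
#' per-time-step update applied at every step once the reward is known); in
#' trial-mean mode it is the product of the two window means.
#'
#' @param W_out readout weights (2 x n).
#' @param zr either the accumulated `sum_t zeta_i(t) r_j(t)` matrix (2 x n,
#'   per-step mode) or `outer(zeta_mean, r_mean)` (trial-mean mode).
#' @param delta_e reward minus baseline.
#' @param mu learning rate (default 5e-5).
#' @export
node_perturbation_update <- function(W_out, zr, delta_e, mu = 5e-5) {
  W_out + mu * delta_e * zr
}

#' Update the reward baseline
#'
#' Exponential moving average: `b' = (1 - decay) b + decay * reward`. The
#' reward-prediction error used by the learning rule is `reward - b` with the
#' baseline *before* the update; `decay = 1` reduces to a one-trial memory.
#'
#' @param baseline current baseline in [0, 1].
#' @param reward trial reward (0 or 1).
#' @param decay smoothing factor in (0, 1].
#' @return list with `baseline` (updated) and `delta_e`.
#' @export
update_reward_baseline <- function(baseline, reward, decay = 0.1) {
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  list(baseline = (1 - decay) * baseline + decay * reward,
       delta_e = reward - baseline)
}
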