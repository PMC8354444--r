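#' Plasticity rule configuration
#'
#' Constants of the dopamine-gated KC-to-MBON plasticity rule: eligibility
#' trace time constants for the Kenyon-cell and dopamine-neuron low-pass
#' filters, the relaxation constant of the effective weights, the weight
#' bound, and whether updates are clipped to the bounded range.
#'
#' The trace constants set the width of the biphasic pairing window; 1 s
#' (with tau_w = 5 s) gives a window spanning several seconds.
#'
#' @param tau_elig_kc,tau_elig_dan eligibility-trace time constants, seconds.
#' @param tau_w relaxation time constant of the effective weights toward the
#'   latent plastic variables, seconds (LTD/LTP induction timescale).
#' @param w_max maximum plastic weight.
#' @param clip clip the latent variables to \code{[0, w_max]} after each
#'   update (default TRUE).
#' @return an object of class \code{plasticity_config}.
#' @export
plasticity_config <- function(tau_elig_kc = 1, tau_elig_dan = 1,
                              tau_w = 5, w_max = 0.05, clip = TRUE) {
  stopifnot(tau_elig_kc > 0, tau_elig_dan > 0, tau_w > 0, w_max > 0)
  structure(list(tau_elig_kc = tau_elig_kc, tau_elig_dan = tau_elig_dan,
                 tau_w = tau_w, w_max = w_max, clip = isTRUE(clip)),
            class = "plasticity_config")
}

#' Advance the synaptic eligibility traces
#'
#' First-order exponential low-pass filters of the Kenyon-cell and
#' dopamine-neuron rates: \code{trace <- trace + dt/tau * (rate - trace)}.
#'
#' @param config a \code{plasticity_config}.
#' @param state an \code{mb_state}.
#' @param kc_rates Kenyon-cell rates, length n_kc, nonnegative.
#' @param dan_rates dopamine-neuron rates, length n_dan, nonnegative.
#' @param dt timestep in seconds.
#' @return the state with updated \code{trace_kc} and \code{trace_dan}.
#' @export
update_traces <- function(config, state, kc_rates, dan_rates, dt) {
  if (any(kc_rates < 0) || any(dan_rates < 0))
    stop("rates must be nonnegative")
  state$trace_kc <- state$trace_kc +
    (dt / config$tau_elig_kc) * (kc_rates - state$trace_kc)
  state$trace_dan <- state$trace_dan +
    (dt / config$tau_elig_dan) * (dan_rates - state$trace_dan)
  state
}

#' One Euler step of the dopamine-gated plasticity rule
#'
#' Updates the latent plastic variables by
#' \code{dw_ij/dt = rbar_DAN_i r_KC_j - rbar_KC_j r_DAN_i (+ beta_i
#' rbar_DAN_i)}, where the DAN rate and trace seen by MBON i are the
#' compartment-gated combinations \code{(G r_DAN)_i}, then clips \code{w} to
#' \code{[0, w_max]} (when clipping is on) and relaxes the effective weights
#' \code{W_kc_mbon} toward \code{w} with time constant \code{tau_w}.
#'
#' The product terms use the traces from the previous timestep (pre-update
#' values, the strictly causal reading of the low-pass filters); call
#' \code{\link{update_traces}} after this function, not before.
#'
#' @param config a \code{plasticity_config}.
#' @param params an \code{mb_params} (supplies the gating matrix and
#'   optional \code{beta}).
#' @param state an \code{mb_state} whose traces are the pre-update values.
#' @param kc_rates Kenyon-cell rates at this step.
#' @param dan_rates dopamine-neuron rates at this step.
#' @param dt timestep in seconds.
#' @return the state with updated \code{w} and \code{W_kc_mbon}.
#' @export
plasticity_step <- function(config, params, state, kc_rates, dan_rates, dt) {
  G <- params$G
  dd <- as.numeric(G %*% dan_rates)           # gated DAN rate per MBON
  ddbar <- as.numeric(G %*% state$trace_dan)  # gated DAN trace per MBON
  dw <- outer(ddbar, kc_rates) - outer(dd, state$trace_kc)
  if (!is.null(params$beta)) dw <- dw + params$beta * ddbar  # column-recycled
  u <- state$w + dt * dw
  state$w <- if (config$clip) pmin(pmax(u, 0), config$w_max) else u
  state$W_kc_mbon <- state$W_kc_mbon +
    (dt / config$tau_w) * (state$w - state$W_kc_mbon)
  state
}

#' Timing-dependence of the plasticity rule for isolated pulse pairs
#'
#' Presents a single square Kenyon-cell pulse and a single square
#' dopamine-neuron pulse separated by a lag \code{delta_t} (positive lag =
#' KC first, "forward" pairing) to a fresh single-synapse state with
#' \code{beta = 0} and no clipping, and integrates the rule. The resulting
#' curve of total weight change versus lag is biphasic: depression for
#' forward pairings, potentiation for backward pairings, vanishing for lags
#' much longer than the trace time constants.
#'
#' @param config a \code{plasticity_config}.
#' @param delta_t_grid numeric vector of lags in seconds (DAN onset minus KC
#'   onset).
#' @param pulse_amp pulse amplitude (rate units).
#' @param pulse_dur pulse duration in seconds.
#' @param dt integration step in seconds (finer than the circuit step for a
#'   smooth curve).
#' @return data frame with columns \code{delta_t_s} and \code{delta_w}.
#' @export
pairing_curve <- function(config, delta_t_grid = seq(-10, 10, by = 0.25),
                          pulse_amp = 1, pulse_dur = 2, dt = 0.1) {
  arch1 <- mb_arch(n_mbon = 1L, n_dan = 1L, n_fbn = 1L, n_kc = 1L,
                   n_compartments = 1L, dt = min(dt, 0.5))
  cfg <- config
  cfg$clip <- FALSE
  par1 <- mb_params(arch1, W = matrix(0, 3, 3), b = rep(0, 3),
                    W_ext = matrix(0, 1, 2), W_readout = matrix(0, 1, 1),
                    plasticity = cfg)
  dw <- vapply(delta_t_grid, function(lag) {
    t0 <- max(0, -lag)            # KC onset
    t1 <- max(0, lag)             # DAN onset
    t_end <- max(t0, t1) + pulse_dur + 8 * max(cfg$tau_elig_kc,
                                               cfg$tau_elig_dan)
    st <- initial_state(par1)
    st$w[] <- 0; st$W_kc_mbon[] <- 0
    tt <- 0
    while (tt < t_end) {
      kc <- if (tt >= t0 && tt < t0 + pulse_dur) pulse_amp else 0
      dan <- if (tt >= t1 && tt < t1 + pulse_dur) pulse_amp else 0
      st <- plasticity_step(cfg, par1, st, kc, dan, dt)
      st <- update_traces(cfg, st, kc, dan, dt)
      tt <- tt + dt
    }
    st$w[1, 1]
  }, numeric(1))
  data.frame(delta_t_s = delta_t_grid, delta_w = dw)
}
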