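#' Circuit parameter container
#'
#' Bundles the meta-learned quantities of the output-circuit model: the
#' recurrent weight matrix \code{W} over all MBONs, DANs and FBNs (with the
#' DAN-to-MBON block structurally zero, since dopamine acts on KC-to-MBON
#' plasticity rather than on MBON firing), biases \code{b}, external-input
#' weights \code{W_ext} (onto FBNs only), the MBON readout \code{W_readout},
#' and optional task-specific readouts and plasticity constants.
#'
#' Use \code{\link{initialize_parameters}} to draw a fresh random parameter
#' set; \code{mb_params} validates and assembles an explicit one.
#'
#' @param arch an \code{\link{mb_arch}}.
#' @param W recurrent weight matrix, \code{n x n} (n = n_mbon+n_dan+n_fbn).
#' @param b bias vector, length n.
#' @param W_ext FBN input weights, \code{n_fbn x d_ext}.
#' @param W_readout MBON readout, \code{d_readout x n_mbon}.
#' @param W_state optional DAN state readout, \code{3 x n_dan}.
#' @param beta optional per-compartment non-specific potentiation rates
#'   (length \code{n_mbon}, expanded per MBON), all \code{>= 0}.
#' @param velocity optional list with \code{W_u}, \code{b_u}, \code{W_omega},
#'   \code{b_omega}; velocity weights act on FBN rates (length n_fbn).
#' @param plasticity a \code{\link{plasticity_config}}.
#' @param W_km optional fixed KC-to-MBON weight matrix (\code{n_mbon x n_kc});
#'   used by non-plastic variants where these weights are themselves
#'   optimized parameters.
#' @return an object of class \code{mb_params}.
#' @export
mb_params <- function(arch, W, b, W_ext, W_readout, W_state = NULL,
                      beta = NULL, velocity = NULL,
                      plasticity = plasticity_config(w_max = arch$w_max),
                      W_km = NULL) {
  stopifnot(inherits(arch, "mb_arch"))
  W <- as.matrix(W); b <- as.numeric(b)
  if (!all(dim(W) == c(arch$n, arch$n))) stop("W must be n x n")
  if (length(b) != arch$n) stop("b must have length n")
  blk <- W[arch$idx_mbon, arch$idx_dan, drop = FALSE]
  if (any(blk != 0)) stop("DAN->MBON block of W must be exactly zero")
  W_ext <- as.matrix(W_ext)
  if (!all(dim(W_ext) == c(arch$n_fbn, arch$d_ext)))
    stop("W_ext must be n_fbn x d_ext")
  W_readout <- matrix(as.numeric(W_readout), nrow = arch$d_readout)
  if (ncol(W_readout) != arch$n_mbon)
    stop("W_readout must be d_readout x n_mbon")
  if (!is.null(W_state)) {
    W_state <- as.matrix(W_state)
    if (!all(dim(W_state) == c(3L, arch$n_dan)))
      stop("W_state must be 3 x n_dan")
  }
  if (!is.null(beta)) {
    beta <- as.numeric(beta)
    if (length(beta) != arch$n_mbon) stop("beta must have length n_mbon")
    if (any(beta < 0)) stop("beta entries must be >= 0")
  }
  if (!is.null(velocity)) {
    stopifnot(length(velocity$W_u) == arch$n_fbn,
              length(velocity$W_omega) == arch$n_fbn,
              length(velocity$b_u) == 1, length(velocity$b_omega) == 1)
  }
  if (!is.null(W_km)) {
    W_km <- as.matrix(W_km)
    if (!all(dim(W_km) == c(arch$n_mbon, arch$n_kc)))
      stop("W_km must be n_mbon x n_kc")
  }
  p <- list(arch = arch, W = W, b = b, W_ext = W_ext,
            W_readout = W_readout, W_state = W_state, beta = beta,
            velocity = velocity, plasticity = plasticity, W_km = W_km,
            G = compartment_gating(arch))
  class(p) <- "mb_params"
  p
}

#' Initial circuit state
#'
#' Firing rates start at 0 for MBONs and 0.1 for DANs and FBNs (a low
#' baseline), the latent plastic variables \code{w} and the effective
#' KC-to-MBON weights start at their maximum value \code{w_max}, and the
#' eligibility traces start at zero.
#'
#' @param params an \code{mb_params}.
#' @return an object of class \code{mb_state} with fields \code{r} (rates),
#'   \code{w} (latent plastic variables), \code{W_kc_mbon} (effective
#'   weights), \code{trace_kc} and \code{trace_dan}.
#' @export
initial_state <- function(params) {
  arch <- params$arch
  r <- c(rep(0, arch$n_mbon), rep(0.1, arch$n_dan + arch$n_fbn))
  s <- list(
    r = r,
    w = matrix(arch$w_max, arch$n_mbon, arch$n_kc),
    W_kc_mbon = matrix(arch$w_max, arch$n_mbon, arch$n_kc),
    trace_kc = rep(0, arch$n_kc),
    trace_dan = rep(0, arch$n_dan))
  class(s) <- "mb_state"
  s
}

#' Reset firing rates without touching plastic variables
#'
#' Applied at the start of each trial interval; prevents the network from
#' carrying associations in persistent activity while leaving \code{w},
#' \code{W_kc_mbon} and the eligibility traces intact.
#'
#' @param params an \code{mb_params}.
#' @param state an \code{mb_state}.
#' @return the state with rates restored to their initial values.
#' @export
reset_rates <- function(params, state) {
  arch <- params$arch
  state$r <- c(rep(0, arch$n_mbon), rep(0.1, arch$n_dan + arch$n_fbn))
  state
}

#' One forward-Euler step of the rate dynamics
#'
#' Integrates \code{tau dr/dt = -r + [W r + b + I]_+} for one step of length
#' \code{dt}. Input routing: MBONs receive Kenyon-cell input through the
#' current effective weights \code{W_kc_mbon}, FBNs receive external input
#' through \code{W_ext}, and DANs receive no direct input (everything
#' reaching them is relayed through the recurrent circuit). Rectification
#' applies inside the bracket only; the leak is linear. Plastic variables and
#' traces are not touched (see \code{\link{plasticity_step}}).
#'
#' @param params an \code{mb_params}.
#' @param state an \code{mb_state}.
#' @param kc_rates nonnegative Kenyon-cell rate vector, length n_kc.
#' @param ext_input external input vector, length d_ext.
#' @return the updated \code{mb_state}.
#' @export
circuit_step <- function(params, state, kc_rates, ext_input) {
  arch <- params$arch
  if (length(kc_rates) != arch$n_kc) stop("kc_rates must have length n_kc")
  if (length(ext_input) != arch$d_ext) stop("ext_input must have length d_ext")
  if (any(kc_rates < 0)) stop("kc_rates must be nonnegative")
  Wkm <- if (!is.null(params$W_km)) params$W_km else state$W_kc_mbon
  I <- numeric(arch$n)
  I[arch$idx_mbon] <- as.numeric(Wkm %*% kc_rates)
  I[arch$idx_fbn] <- as.numeric(params$W_ext %*% ext_input)
  a <- as.numeric(params$W %*% state$r) + params$b + I
  alpha <- arch$dt / arch$tau
  state$r <- (1 - alpha) * state$r + alpha * relu(a)
  state
}

#' Linear behavioral readout of MBON rates
#'
#' \code{v(t) = W_readout r_MBON(t)}: the valence (and, when a second readout
#' row is present, novelty) decoded from output-neuron activity.
#'
#' @param params an \code{mb_params}.
#' @param state an \code{mb_state}.
#' @return numeric vector of length \code{d_readout}.
#' @export
readout <- function(params, state) {
  as.numeric(params$W_readout %*% state$r[params$arch$idx_mbon])
}

#' Softmax state readout of DAN rates
#'
#' \code{s = Softmax(W_state r_DAN)}: decoded probabilities of occupying each
#' of the three internal states.
#'
#' @param params an \code{mb_params} with \code{W_state} present.
#' @param state an \code{mb_state}.
#' @return a 3-vector of positive entries summing to 1.
#' @export
state_readout <- function(params, state) {
  if (is.null(params$W_state)) stop("W_state is not present in params")
  softmax(as.numeric(params$W_state %*% state$r[params$arch$idx_dan]))
}
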