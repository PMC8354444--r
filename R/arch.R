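#' Mushroom-body circuit architecture
#'
#' Fixed structural constants of the output-circuit model: population sizes,
#' membrane time constant, integration step, the compartment map pairing
#' dopamine neurons (DANs) with output neurons (MBONs), and the dimensions of
#' the external-input and readout pathways.
#'
#' Neuron ordering is MBONs first (indices \code{1:n_mbon}), then DANs, then
#' feedback neurons (FBNs). The compartment map defaults to the identity
#' pairing (DAN k gates plasticity onto MBON k, \code{n_compartments =
#' n_mbon}); with fewer compartments the DAN-to-compartment gating matrix is
#' block-diagonal with within-block weights \code{1/n_compartments}.
#'
#' @param n_mbon,n_dan,n_fbn,n_kc population sizes. Defaults 20/20/60 circuit
#'   neurons and 200 Kenyon cells.
#' @param n_compartments number of compartments (at most \code{min(n_mbon,
#'   n_dan)}, dividing both).
#' @param tau membrane time constant in seconds.
#' @param dt integration step in seconds; must satisfy \code{dt <= tau} for
#'   stability of the forward-Euler rectified-linear dynamics.
#' @param w_max maximum KC-to-MBON weight.
#' @param d_ext dimension of the external-input vector (2 for conditioning
#'   and continual learning: positive/negative US channels; 5 for the state
#'   task: 3 state pulses + 2 US; 6 for navigation: 2 US + 4 wind).
#' @param d_readout number of MBON readout dimensions (1 = valence; 2 adds a
#'   novelty readout).
#' @return an object of class \code{mb_arch}.
#' @export
mb_arch <- function(n_mbon = 20L, n_dan = 20L, n_fbn = 60L, n_kc = 200L,
                    n_compartments = n_mbon, tau = 1, dt = 0.5,
                    w_max = 0.05, d_ext = 2L, d_readout = 1L) {
  n_mbon <- as.integer(n_mbon); n_dan <- as.integer(n_dan)
  n_fbn <- as.integer(n_fbn); n_kc <- as.integer(n_kc)
  n_compartments <- as.integer(n_compartments)
  stopifnot(n_mbon > 0, n_dan > 0, n_fbn > 0, n_kc > 0,
            tau > 0, dt > 0, w_max > 0, d_ext >= 1, d_readout >= 1)
  if (dt > tau) stop("dt must not exceed tau (forward-Euler stability)")
  if (n_compartments > min(n_mbon, n_dan))
    stop("n_compartments cannot exceed min(n_mbon, n_dan)")
  if (n_mbon %% n_compartments != 0 || n_dan %% n_compartments != 0)
    stop("n_compartments must divide n_mbon and n_dan")
  a <- list(n_mbon = n_mbon, n_dan = n_dan, n_fbn = n_fbn, n_kc = n_kc,
            n = n_mbon + n_dan + n_fbn, n_compartments = n_compartments,
            tau = tau, dt = dt, w_max = w_max,
            d_ext = as.integer(d_ext), d_readout = as.integer(d_readout))
  a$idx_mbon <- seq_len(n_mbon)
  a$idx_dan <- n_mbon + seq_len(n_dan)
  a$idx_fbn <- n_mbon + n_dan + seq_len(n_fbn)
  class(a) <- "mb_arch"
  a
}

#' DAN-to-MBON compartment gating matrix
#'
#' Returns the \code{n_mbon x n_dan} matrix G mapping DAN rates to the
#' dopamine drive experienced by each MBON's plastic inputs. With
#' \code{n_compartments == n_mbon == n_dan} this is the identity (one DAN per
#' compartment). With fewer compartments, G is block-diagonal over equal-size
#' blocks of MBONs and DANs, with within-block entries
#' \code{1/n_compartments}.
#'
#' @param arch an \code{mb_arch}.
#' @return a numeric matrix used only by the plasticity rule.
#' @export
compartment_gating <- function(arch) {
  nc <- arch$n_compartments
  if (nc == arch$n_mbon && nc == arch$n_dan) return(diag(arch$n_mbon))
  bm <- arch$n_mbon / nc
  bd <- arch$n_dan / nc
  G <- matrix(0, arch$n_mbon, arch$n_dan)
  for (k in seq_len(nc)) {
    rows <- (k - 1) * bm + seq_len(bm)
    cols <- (k - 1) * bd + seq_len(bd)
    G[rows, cols] <- 1 / nc
  }
  G
}

#' Compartment membership of MBONs and DANs
#'
#' @param arch an \code{mb_arch}.
#' @return list with integer vectors \code{mbon} and \code{dan} assigning
#'   each neuron to exactly one compartment.
#' @export
compartment_map <- function(arch) {
  nc <- arch$n_compartments
  list(mbon = rep(seq_len(nc), each = arch$n_mbon / nc),
       dan = rep(seq_len(nc), each = arch$n_dan / nc))
}

#' @export
print.mb_arch <- function(x, ...) {
  cat(sprintf(
    "mushroom-body architecture: %d MBON / %d DAN / %d FBN, %d KC\n",
    x$n_mbon, x$n_dan, x$n_fbn, x$n_kc))
  cat(sprintf("  %d compartment(s); tau = %g s, dt = %g s, w_max = %g\n",
              x$n_compartments, x$tau, x$dt, x$w_max))
  cat(sprintf("  external input dim %d, readout dim %d\n",
              x$d_ext, x$d_readout))
  invisible(x)
}
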