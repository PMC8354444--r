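#' Render a trial to per-timestep input and target traces
#'
#' Deterministically expands an \code{mb_trial} into the arrays consumed by
#' the simulator: Kenyon-cell rates, external input, readout targets, the
#' optional one-hot state target, interval-reset flags, a per-step loss
#' mask and the scored test window, all on the simulation time grid (step n
#' covers \code{[(n-1) dt, n dt)}; an event is active at every step whose
#' start time falls inside it).
#'
#' Readout targets respect the one-step integration lag of the rate
#' dynamics: a CS-presentation target applies from one timestep after
#' stimulus onset through stimulus offset, and the onset step itself is
#' excluded from the readout loss (mask 0) so the unavoidable single-step
#' rise of the readout is neither penalized nor scored.
#'
#' External-input channel conventions: with \code{d_ext = 2}, channels are
#' (positive US, negative US); with \code{d_ext = 5}, channels 1-3 are the
#' state pulses and 4-5 the US channels.
#'
#' @param trial an \code{mb_trial}.
#' @param arch an \code{\link{mb_arch}}.
#' @param us_amplitude amplitude of the US input (1 for conditioning tasks).
#' @return a list with elements \code{kc} (n_kc x T), \code{ext}
#'   (d_ext x T), \code{target} (d_readout x T), \code{state_target}
#'   (3 x T or NULL), \code{reset}, \code{score} (logical T),
#'   \code{loss_mask} (numeric T), \code{times} (step start times) and
#'   \code{T}.
#' @export
render_trial <- function(trial, arch, us_amplitude = 1) {
  dt <- arch$dt
  durs <- vapply(trial$intervals, function(iv) iv$duration, numeric(1))
  offs <- cumsum(c(0, durs))[seq_along(durs)]
  total <- sum(durs)
  Tn <- as.integer(round(total / dt))
  times <- (seq_len(Tn) - 1) * dt

  kc <- matrix(0, arch$n_kc, Tn)
  ext <- matrix(0, arch$d_ext, Tn)
  target <- matrix(0, arch$d_readout, Tn)
  reset <- rep(FALSE, Tn)
  score <- rep(FALSE, Tn)
  loss_mask <- rep(1, Tn)
  dt_lag <- dt   # targets apply one integration step after stimulus onset

  steps_of <- function(interval, onset, duration) {
    t0 <- offs[interval] + onset
    which(times >= t0 - 1e-9 & times < t0 + duration - 1e-9)
  }
  us_channel <- function(valence) {
    base <- if (arch$d_ext == 5) 3L else 0L
    base + if (valence > 0) 1L else 2L
  }

  cs_seen <- integer(0)  # odors already presented (for the novelty target)
  for (i in seq_along(trial$intervals)) {
    iv <- trial$intervals[[i]]
    reset[which.min(abs(times - offs[i]))] <- TRUE
    evs <- iv$events
    if (length(evs) == 0) next
    ord <- order(vapply(evs, function(e) e$onset, numeric(1)))
    for (e in evs[ord]) {
      idx <- steps_of(i, e$onset, e$duration)
      if (length(idx) == 0) next
      if (e$kind == "CS") {
        kc[, idx] <- kc[, idx] +
          e$amplitude * trial$patterns[e$odor_id, ]
        loss_mask[steps_of(i, e$onset, dt_lag)] <- 0
        if (arch$d_readout >= 2) {
          idx_t <- steps_of(i, e$onset + dt_lag, e$duration - dt_lag)
          if (!(e$odor_id %in% cs_seen)) target[2, idx_t] <- 1
          cs_seen <- union(cs_seen, e$odor_id)
        }
      } else if (e$kind == "US") {
        ext[us_channel(e$valence), idx] <- e$amplitude * us_amplitude
      } else if (e$kind == "state_pulse") {
        ext[e$state_id, idx] <- e$amplitude
      }
    }
  }

  tw <- trial$target_windows
  if (!is.null(tw) && nrow(tw) > 0)
    for (i in seq_len(nrow(tw))) {
      target[1, steps_of(tw$interval[i], tw$onset[i] + dt_lag,
                         tw$duration[i] - dt_lag)] <- tw$value[i]
      loss_mask[steps_of(tw$interval[i], tw$onset[i], dt_lag)] <- 0
    }
  sw <- trial$score_windows
  if (!is.null(sw) && nrow(sw) > 0)
    for (i in seq_len(nrow(sw)))
      score[steps_of(sw$interval[i], sw$onset[i] + dt_lag,
                     sw$duration[i] - dt_lag)] <- TRUE

  state_target <- NULL
  if (!is.null(trial$state_track)) {
    st <- trial$state_track
    state_target <- matrix(0, 3, Tn)
    cur <- vapply(times, function(t)
      st$states[1 + sum(st$times <= t + 1e-9)], numeric(1))
    state_target[cbind(cur, seq_len(Tn))] <- 1
  }

  list(kc = kc, ext = ext, target = target, state_target = state_target,
       reset = reset, score = score, loss_mask = loss_mask, times = times,
       T = Tn)
}
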