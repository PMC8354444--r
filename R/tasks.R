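#' Sparse Kenyon-cell odor code
#'
#' Encodes an odor as a random binary Kenyon-cell pattern with exactly
#' \code{round(sparsity * n_kc)} active cells (10% by default).
#'
#' @param n_kc number of Kenyon cells.
#' @param sparsity fraction of active cells, in (0, 1).
#' @return a binary vector of length \code{n_kc}.
#' @export
encode_odor <- function(n_kc, sparsity = 0.1) {
  stopifnot(sparsity > 0, sparsity < 1)
  k <- round(sparsity * n_kc)
  if (k < 1) stop("sparsity * n_kc must be at least 1")
  v <- numeric(n_kc)
  v[sample.int(n_kc, k)] <- 1
  v
}

#' A bank of fixed odors
#'
#' @param n number of odors.
#' @param n_kc number of Kenyon cells.
#' @param sparsity fraction of active cells per odor.
#' @return an \code{n x n_kc} binary matrix, one odor per row.
#' @export
odor_bank <- function(n, n_kc, sparsity = 0.1) {
  t(vapply(seq_len(n), function(i) encode_odor(n_kc, sparsity),
           numeric(n_kc)))
}

new_trial <- function(paradigm, intervals, patterns, target_windows,
                      score_windows, novelty_windows = NULL,
                      state_track = NULL, meta = list()) {
  structure(list(paradigm = paradigm, intervals = intervals,
                 patterns = patterns, target_windows = target_windows,
                 score_windows = score_windows,
                 novelty_windows = novelty_windows,
                 state_track = state_track, meta = meta),
            class = "mb_trial")
}

## fast data-frame builders for the per-trial hot path (plain data.frame()
## construction dominates trial-generation time otherwise)
tw_frame <- function(interval, onset, duration, value)
  structure(list(interval = interval, onset = onset, duration = duration,
                 value = value), class = "data.frame",
            row.names = seq_along(onset))

sw_frame <- function(interval, onset, duration)
  structure(list(interval = interval, onset = onset, duration = duration),
            class = "data.frame", row.names = seq_along(onset))

cs_event <- function(onset, odor, duration = 2, amplitude = 1)
  list(kind = "CS", onset = onset, duration = duration, odor_id = odor,
       amplitude = amplitude)

us_event <- function(onset, valence, duration = 2, amplitude = 1)
  list(kind = "US", onset = onset, duration = duration, valence = valence,
       amplitude = amplitude)

pulse_event <- function(onset, state_id, duration = 2, amplitude = 1)
  list(kind = "state_pulse", onset = onset, duration = duration,
       state_id = state_id, amplitude = amplitude)

#' Conditioning-style trial generator
#'
#' Builds the interval/event schedule, Kenyon-cell patterns and target
#' valence trace for the classical-conditioning paradigms. Trials are split
#' into 30-s intervals with firing rates reset at each interval start;
#' stimulus onsets are drawn uniformly between 5 and 15 s within their
#' interval; CS and US last 2 s, with the US beginning at CS offset.
#'
#' Paradigms: \code{first_order} (pairing interval then test interval),
#' \code{cs_minus} (unpaired CS), \code{extinction} (pairing, unreinforced
#' exposure, test; the exposure partially extinguishes the association so the
#' test target has magnitude \code{extinction_residual}), \code{second_order}
#' (CS1-US pairing, CS2-CS1 pairing, CS2 test) and \code{reversal}
#' (evaluation-only: CS1 paired, then CS2 paired, then both presented).
#'
#' The target valence equals the current learned association during every
#' post-pairing CS presentation: full magnitude at intact-association
#' presentations (the extinction exposure, the CS1 re-presentation in
#' second-order trials, and the tests), reduced to
#' \code{extinction_residual} at the post-extinction test, and zero
#' elsewhere. With probability \code{omission_prob} one scheduled stimulus
#' (CS or US) is omitted and the targets updated accordingly: omitting an
#' event that breaks the predictive chain zeroes the downstream targets,
#' while omitting the extinction exposure leaves an intact first-order
#' association (full-magnitude test target). The scored test window is the
#' final CS presentation.
#'
#' @param paradigm one of the paradigm names above.
#' @param arch an \code{\link{mb_arch}} (supplies \code{n_kc}).
#' @param options list of overrides: \code{omission_prob} (default 0.5),
#'   \code{valence} (US sign, default random in \{-1, +1\}),
#'   \code{valence_scale} (target magnitude, default 1),
#'   \code{extinction_residual} (default 0.5), \code{interval} (default 30),
#'   \code{cs_dur}, \code{us_dur} (default 2), \code{us_gap} (default 0),
#'   \code{sparsity} (default 0.1).
#' @return an \code{mb_trial}.
#' @export
make_conditioning_trial <- function(paradigm = c("first_order", "cs_minus",
                                                 "extinction", "second_order",
                                                 "reversal"),
                                    arch, options = list()) {
  paradigm <- match.arg(paradigm)
  o <- modifyList(list(omission_prob = 0.5, valence = NULL,
                       valence_scale = 1, extinction_residual = 0.5,
                       interval = 30, cs_dur = 2, us_dur = 2, us_gap = 0,
                       sparsity = 0.1), options)
  sgn <- o$valence %||% sample(c(-1, 1), 1)
  on <- function() runif(1, 5, 15)
  omit <- if (runif(1) < o$omission_prob) TRUE else FALSE

  mk_pat <- function(n) t(vapply(seq_len(n), function(i)
    encode_odor(arch$n_kc, o$sparsity), numeric(arch$n_kc)))

  if (paradigm %in% c("first_order", "cs_minus")) {
    pat <- mk_pat(1)
    a1 <- on(); a2 <- on()
    pair_us <- paradigm == "first_order"
    victim <- if (omit && pair_us) sample(c("cs1", "us"), 1)
              else if (omit) "cs1" else "none"
    ev1 <- list()
    if (victim != "cs1") ev1 <- c(ev1, list(cs_event(a1, 1, o$cs_dur)))
    if (pair_us && victim != "us")
      ev1 <- c(ev1, list(us_event(a1 + o$cs_dur + o$us_gap, sgn, o$us_dur)))
    ev2 <- list(cs_event(a2, 1, o$cs_dur))
    tgt <- if (pair_us && victim == "none") sgn * o$valence_scale else 0
    return(new_trial(paradigm,
      intervals = list(list(duration = o$interval, reset = TRUE, events = ev1),
                       list(duration = o$interval, reset = TRUE, events = ev2)),
      patterns = pat,
      target_windows = tw_frame(2, a2, o$cs_dur, tgt),
      score_windows = sw_frame(2, a2, o$cs_dur),
      meta = list(us_sign = sgn, omitted = victim)))
  }

  if (paradigm == "extinction") {
    pat <- mk_pat(1)
    a1 <- on(); a2 <- on(); a3 <- on()
    victim <- if (omit) sample(c("cs1", "us", "cs2"), 1) else "none"
    ev1 <- list()
    if (victim != "cs1") ev1 <- c(ev1, list(cs_event(a1, 1, o$cs_dur)))
    if (victim != "us")
      ev1 <- c(ev1, list(us_event(a1 + o$cs_dur + o$us_gap, sgn, o$us_dur)))
    ev2 <- if (victim == "cs2") list() else list(cs_event(a2, 1, o$cs_dur))
    ev3 <- list(cs_event(a3, 1, o$cs_dur))
    # the association is intact at the exposure presentation and partially
    # extinguished by the unreinforced exposure at the final test
    paired <- !victim %in% c("cs1", "us")
    tgt2 <- if (paired) sgn * o$valence_scale else 0
    tgt3 <- if (!paired) 0
    else if (victim == "cs2") sgn * o$valence_scale   # no exposure
    else sgn * o$valence_scale * o$extinction_residual
    tw <- if (victim != "cs2")
      tw_frame(c(2, 3), c(a2, a3), rep(o$cs_dur, 2), c(tgt2, tgt3))
    else tw_frame(3, a3, o$cs_dur, tgt3)
    return(new_trial(paradigm,
      intervals = list(list(duration = o$interval, reset = TRUE, events = ev1),
                       list(duration = o$interval, reset = TRUE, events = ev2),
                       list(duration = o$interval, reset = TRUE, events = ev3)),
      patterns = pat,
      target_windows = tw,
      score_windows = sw_frame(3, a3, o$cs_dur),
      meta = list(us_sign = sgn, omitted = victim)))
  }

  if (paradigm == "second_order") {
    pat <- mk_pat(2)
    a1 <- on(); a2 <- on(); a3 <- on()
    victim <- if (omit) sample(c("cs1_i1", "us", "cs1_i2"), 1) else "none"
    ev1 <- list()
    if (victim != "cs1_i1") ev1 <- c(ev1, list(cs_event(a1, 1, o$cs_dur)))
    if (victim != "us")
      ev1 <- c(ev1, list(us_event(a1 + o$cs_dur + o$us_gap, sgn, o$us_dur)))
    ev2 <- list(cs_event(a2, 2, o$cs_dur))
    if (victim != "cs1_i2")
      ev2 <- c(ev2, list(cs_event(a2 + o$cs_dur + o$us_gap, 1, o$cs_dur)))
    ev3 <- list(cs_event(a3, 2, o$cs_dur))
    cs1_paired <- !victim %in% c("cs1_i1", "us")
    tgt3 <- if (victim == "none") sgn * o$valence_scale else 0
    # CS1 carries its learned valence when re-presented in interval 2
    tw <- if (victim != "cs1_i2")
      tw_frame(c(2, 3), c(a2 + o$cs_dur + o$us_gap, a3),
               rep(o$cs_dur, 2),
               c(if (cs1_paired) sgn * o$valence_scale else 0, tgt3))
    else tw_frame(3, a3, o$cs_dur, tgt3)
    return(new_trial(paradigm,
      intervals = list(list(duration = o$interval, reset = TRUE, events = ev1),
                       list(duration = o$interval, reset = TRUE, events = ev2),
                       list(duration = o$interval, reset = TRUE, events = ev3)),
      patterns = pat,
      target_windows = tw,
      score_windows = sw_frame(3, a3, o$cs_dur),
      meta = list(us_sign = sgn, omitted = victim)))
  }

  # reversal: evaluation-only generalization probe. Phase 1 pairs CS1 (CS2
  # presented unreinforced); phase 2 reverses the contingencies; the test
  # phase presents both and compares the reported valences.
  pat <- mk_pat(2)
  a1 <- runif(1, 5, 9); a2 <- runif(1, 5, 9)
  u1 <- runif(1, 5, 9); u2 <- u1 + 10
  ev1 <- list(cs_event(a1, 1, o$cs_dur),
              us_event(a1 + o$cs_dur + o$us_gap, sgn, o$us_dur),
              cs_event(a1 + 6, 2, o$cs_dur))
  ev2 <- list(cs_event(a2, 2, o$cs_dur),
              us_event(a2 + o$cs_dur + o$us_gap, sgn, o$us_dur),
              cs_event(a2 + 6, 1, o$cs_dur))
  ev3 <- list(cs_event(u1, 1, o$cs_dur), cs_event(u2, 2, o$cs_dur))
  new_trial("reversal",
    intervals = list(list(duration = o$interval, reset = TRUE, events = ev1),
                     list(duration = o$interval, reset = TRUE, events = ev2),
                     list(duration = o$interval, reset = TRUE, events = ev3)),
    patterns = pat,
    target_windows = data.frame(interval = c(3, 3), onset = c(u1, u2),
                                duration = o$cs_dur,
                                value = c(0, sgn * o$valence_scale)),
    score_windows = data.frame(interval = 3, onset = u2, duration = o$cs_dur),
    meta = list(us_sign = sgn, omitted = "none",
                cs1_window = c(u1, u1 + o$cs_dur),
                cs2_window = c(u2, u2 + o$cs_dur)))
}

#' Continual-learning trial: a long random sequence of associations
#'
#' One 200-s interval in which two reinforced odors (CS+) and two neutral
#' odors (CS-) are presented in random order; the number of presentations of
#' each odor is Poisson with mean 2. Every CS+ presentation is immediately
#' followed by a US whose random sign redefines that odor's association; the
#' target valence during a CS+ presentation is the sign of its most recent
#' previous pairing (zero before the first), and zero throughout for CS-.
#' Onsets are uniform over the interval conditioned on stimulus windows not
#' overlapping (the order is shuffled and the slack distributed uniformly).
#'
#' Plastic weights are not reset between consecutive continual trials; the
#' carryover is handled by the optimizer (see \code{\link{mb_fit}}).
#'
#' @param arch an \code{\link{mb_arch}}.
#' @param options overrides: \code{duration} (200), \code{mean_pres} (2),
#'   \code{cs_dur}, \code{us_dur} (2), \code{valence_scale} (1),
#'   \code{sparsity} (0.1).
#' @return an \code{mb_trial}.
#' @export
make_continual_sequence <- function(arch, options = list()) {
  o <- modifyList(list(duration = 200, mean_pres = 2, cs_dur = 2, us_dur = 2,
                       valence_scale = 1, sparsity = 0.1), options)
  pat <- t(vapply(1:4, function(i) encode_odor(arch$n_kc, o$sparsity),
                  numeric(arch$n_kc)))
  n_pres <- rpois(4, o$mean_pres)
  block <- function(odor) if (odor <= 2) o$cs_dur + o$us_dur else o$cs_dur
  # uniform placement conditioned on non-overlap: shuffle the presentation
  # order, then distribute the slack uniformly between consecutive blocks
  odors <- sample(rep(1:4, n_pres))
  sched <- NULL
  if (length(odors) > 0) {
    blocks <- vapply(odors, block, numeric(1))
    slack <- o$duration - 4 - sum(blocks)
    if (slack <= 0) stop("continual schedule does not fit the interval")
    u <- sort(runif(length(odors), 0, slack))
    onsets <- 2 + u + c(0, cumsum(blocks))[seq_along(odors)]
    sched <- data.frame(odor = odors, onset = onsets)
  }
  events <- list()
  assoc <- c(0, 0)  # current association of the two CS+
  vals <- numeric(0); onsets <- numeric(0)
  if (!is.null(sched) && nrow(sched) > 0) {
    for (i in seq_len(nrow(sched))) {
      odor <- sched$odor[i]; t0 <- sched$onset[i]
      events <- c(events, list(cs_event(t0, odor, o$cs_dur)))
      onsets <- c(onsets, t0)
      vals <- c(vals, if (odor <= 2) assoc[odor] * o$valence_scale else 0)
      if (odor <= 2) {
        sgn <- sample(c(-1, 1), 1)
        events <- c(events, list(us_event(t0 + o$cs_dur, sgn, o$us_dur)))
        assoc[odor] <- sgn
      }
    }
  }
  tw <- tw_frame(rep(1, length(onsets)), onsets,
                 rep(o$cs_dur, length(onsets)), vals)
  sw <- sw_frame(rep(1, length(onsets)), onsets,
                 rep(o$cs_dur, length(onsets)))
  new_trial("continual",
            intervals = list(list(duration = o$duration, reset = TRUE,
                                  events = events)),
            patterns = pat, target_windows = tw, score_windows = sw,
            meta = list(n_pres = n_pres))
}

#' Internal-state tracking trial
#'
#' A single 300-s interval during which the network transitions between
#' three discrete internal states. Each transition is announced by a 2-s
#' pulse on the external channel of the next state; inter-pulse gaps are
#' distributed as 10 s * (1 + Exp(1)) (mean 20 s, minimum 10 s). The state
#' target is the one-hot current state at every timestep. External input is
#' 5-dimensional: 3 state-pulse channels followed by 2 US channels.
#'
#' By default a conditioning episode is embedded (a CS+ paired with a US,
#' re-presented later with the learned valence as target). With
#' \code{probe = TRUE} a neutral probe CS is instead presented for 2 s
#' beginning 8 s before the second state transition and re-presented for 5 s
#' afterwards (used by the stimulus/state-imprinting analysis).
#'
#' @param arch an \code{\link{mb_arch}} with \code{d_ext = 5}.
#' @param options overrides: \code{duration} (300), \code{pulse_dur} (2),
#'   \code{conditioning} (TRUE), \code{probe} (FALSE), \code{valence},
#'   \code{valence_scale} (1), \code{sparsity} (0.1),
#'   \code{probe_regap} (10, s between second transition pulse and the 5-s
#'   re-presentation).
#' @return an \code{mb_trial} with a \code{state_track} component.
#' @export
make_state_trial <- function(arch, options = list()) {
  o <- modifyList(list(duration = 300, pulse_dur = 2, conditioning = TRUE,
                       probe = FALSE, valence = NULL, valence_scale = 1,
                       sparsity = 0.1, probe_regap = 10), options)
  if (arch$d_ext != 5) stop("state trials need an architecture with d_ext = 5")
  # transition times
  tt <- c(); t_cur <- 10 * (1 + rexp(1))
  while (t_cur < o$duration - o$pulse_dur) {
    tt <- c(tt, t_cur)
    t_cur <- t_cur + 10 * (1 + rexp(1))
  }
  states <- integer(length(tt) + 1)
  states[1] <- sample(3, 1)
  for (i in seq_along(tt))
    states[i + 1] <- sample(setdiff(1:3, states[i]), 1)
  events <- lapply(seq_along(tt), function(i)
    pulse_event(tt[i], states[i + 1], o$pulse_dur))
  state_track <- list(times = tt, states = states)

  patterns <- matrix(numeric(0), 0, arch$n_kc)
  tw <- data.frame(interval = numeric(0), onset = numeric(0),
                   duration = numeric(0), value = numeric(0))
  sw <- tw[c("interval", "onset", "duration")]
  meta <- list(states = states, transition_times = tt)

  if (o$probe && length(tt) >= 2) {
    patterns <- matrix(encode_odor(arch$n_kc, o$sparsity), 1)
    p1 <- tt[2] - 8
    p2 <- tt[2] + o$pulse_dur + o$probe_regap
    events <- c(events, list(cs_event(p1, 1, 2), cs_event(p2, 1, 5)))
    sw <- data.frame(interval = 1, onset = p2, duration = 5)
    meta$probe_windows <- list(first = c(p1, p1 + 2), second = c(p2, p2 + 5))
    meta$probe_next_state <- states[3]
  } else if (o$conditioning) {
    patterns <- matrix(encode_odor(arch$n_kc, o$sparsity), 1)
    sgn <- o$valence %||% sample(c(-1, 1), 1)
    for (try in 1:100) {
      u1 <- runif(1, 0.1 * o$duration, 0.45 * o$duration)
      if (!any(tt < u1 + 4 & tt + o$pulse_dur > u1 - 0.5)) break
    }
    for (try in 1:100) {
      u2 <- runif(1, 0.55 * o$duration, 0.9 * o$duration)
      if (!any(tt < u2 + 2 & tt + o$pulse_dur > u2 - 0.5)) break
    }
    events <- c(events, list(cs_event(u1, 1, 2), us_event(u1 + 2, sgn, 2),
                             cs_event(u2, 1, 2)))
    tw <- data.frame(interval = 1, onset = u2, duration = 2,
                     value = sgn * o$valence_scale)
    sw <- tw[c("interval", "onset", "duration")]
    meta$us_sign <- sgn
  }

  new_trial("state",
            intervals = list(list(duration = o$duration, reset = TRUE,
                                  events = events)),
            patterns = patterns, target_windows = tw, score_windows = sw,
            state_track = state_track, meta = meta)
}

#' Fixed-odor-bank trial for networks without plasticity
#'
#' A single 30-s interval with deterministic timing: a CS+ drawn from a
#' fixed odor bank is presented at 5 s, followed by a US at CS offset; at
#' 15 s a probe is presented which is the same CS+ with probability 1/2 and
#' a different bank odor otherwise. The target valence is the US sign during
#' the probe when the probe is the CS+, and zero otherwise. The interval is
#' not subdivided, so the association must be held in persistent activity by
#' non-plastic networks.
#'
#' @param bank odor-bank matrix from \code{\link{odor_bank}} (>= 2 odors).
#' @param arch an \code{\link{mb_arch}}.
#' @param options overrides: \code{valence}, \code{valence_scale} (1),
#'   \code{cs_dur}, \code{us_dur} (2), \code{interval} (30).
#' @return an \code{mb_trial}.
#' @export
make_nonplastic_env_trial <- function(bank, arch, options = list()) {
  o <- modifyList(list(valence = NULL, valence_scale = 1, cs_dur = 2,
                       us_dur = 2, interval = 30), options)
  if (nrow(bank) < 2) stop("odor bank must contain at least 2 odors")
  sgn <- o$valence %||% sample(c(-1, 1), 1)
  csp <- sample(nrow(bank), 1)
  same <- runif(1) < 0.5
  probe <- if (same) csp else sample(setdiff(seq_len(nrow(bank)), csp), 1)
  events <- list(cs_event(5, csp, o$cs_dur),
                 us_event(5 + o$cs_dur, sgn, o$us_dur),
                 cs_event(15, probe, o$cs_dur))
  new_trial("nonplastic_env",
            intervals = list(list(duration = o$interval, reset = TRUE,
                                  events = events)),
            patterns = bank,
            target_windows = data.frame(interval = 1, onset = 15,
                                        duration = o$cs_dur,
                                        value = if (same)
                                          sgn * o$valence_scale else 0),
            score_windows = data.frame(interval = 1, onset = 15,
                                       duration = o$cs_dur),
            meta = list(us_sign = sgn, probe_same = same, cs_id = csp,
                        probe_id = probe))
}
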