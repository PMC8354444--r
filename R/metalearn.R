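## --- bridging to the compiled engine -------------------------------------

par_to_cpp <- function(params) {
  a <- params$arch
  pc <- params$plasticity
  list(n_mbon = a$n_mbon, n_dan = a$n_dan, n_fbn = a$n_fbn, n_kc = a$n_kc,
       W = params$W, b = params$b, W_ext = params$W_ext,
       W_readout = params$W_readout, W_state = params$W_state,
       beta = params$beta, W_km = params$W_km, G = params$G,
       tau = a$tau, dt = a$dt, tau_w = pc$tau_w,
       tau_elig_kc = pc$tau_elig_kc, tau_elig_dan = pc$tau_elig_dan,
       w_max = pc$w_max, clip = pc$clip,
       W_u = params$velocity$W_u, W_omega = params$velocity$W_omega,
       b_u = params$velocity$b_u, b_omega = params$velocity$b_omega)
}

## --- loss configuration ----------------------------------------------------

#' Trial-loss configuration
#'
#' @param lambda weight of the DAN activity penalty (0.1 by default).
#' @param dan_baseline DAN rate above which the penalty applies (0.1).
#' @param include_dan_penalty whether the penalty term is active (off for
#'   the internal-state task, whose fluctuating DAN activity is the point).
#' @param loss_kind one of \code{"valence"}, \code{"valence+novelty"},
#'   \code{"valence+state"}, \code{"navigation"}.
#' @return an object of class \code{loss_config}.
#' @export
loss_config <- function(lambda = 0.1, dan_baseline = 0.1,
                        include_dan_penalty = TRUE,
                        loss_kind = c("valence", "valence+novelty",
                                      "valence+state", "navigation")) {
  stopifnot(lambda >= 0)
  structure(list(lambda = lambda, dan_baseline = dan_baseline,
                 include_dan_penalty = isTRUE(include_dan_penalty),
                 loss_kind = match.arg(loss_kind)), class = "loss_config")
}

#' Trial loss
#'
#' Mean squared readout error over timesteps (valence, plus novelty or
#' decoded-state probabilities when present), plus the DAN penalty
#' \code{lambda/T * sum_t sum_i [r_DAN - baseline]_+^2} when enabled. For
#' navigation the loss is the squared final distance to the rewarded source.
#'
#' @param config a \code{\link{loss_config}}.
#' @param outputs list with \code{readout} (d_readout x T), \code{dan_rates}
#'   (n_dan x T), optional \code{state_probs} (3 x T); for navigation,
#'   \code{final_position}.
#' @param targets list with \code{target} (d_readout x T), optional
#'   \code{state_target} and per-step \code{loss_mask} (stimulus-onset
#'   steps are excluded from the readout error); for navigation,
#'   \code{goal} (length-2 position).
#' @return scalar loss.
#' @export
trial_loss <- function(config, outputs, targets) {
  if (config$loss_kind == "navigation")
    return(sum((outputs$final_position - targets$goal)^2))
  Tn <- ncol(outputs$readout)
  if (ncol(targets$target) != Tn) stop("outputs and targets misaligned")
  mask <- targets$loss_mask %||% rep(1, Tn)
  loss <- sum(t((outputs$readout - targets$target)^2) * mask) / Tn
  if (config$include_dan_penalty)
    loss <- loss + config$lambda / Tn *
      sum(relu(outputs$dan_rates - config$dan_baseline)^2)
  if (config$loss_kind == "valence+state") {
    if (is.null(outputs$state_probs) || is.null(targets$state_target))
      stop("state loss requires state_probs and state_target")
    loss <- loss + sum((outputs$state_probs - targets$state_target)^2) / Tn
  }
  loss
}

## --- parameter initialization ---------------------------------------------

#' Draw a fresh random parameter set
#'
#' Recurrent weights are zero-mean Gaussians whose variance is keyed to the
#' presynaptic neuron type, \code{1/(2 N_X)} for type X; the DAN-to-MBON
#' block is then zeroed. The readout variance is \code{1/N_MBON} and the
#' external-input variance 1. All biases start at 0.1. Optional components:
#' the DAN state readout (variance \code{1/N_DAN}), per-compartment
#' non-specific potentiation rates (each 0.01), FBN velocity readouts
#' (variance \code{1/N_FBN}, biases 0.1) and, for non-plastic variants,
#' directly optimized KC-to-MBON weights (presynaptic rule,
#' \code{1/(2 N_KC)}).
#'
#' @param arch an \code{\link{mb_arch}}.
#' @param state_readout include \code{W_state}.
#' @param beta include non-specific potentiation rates (init 0.01).
#' @param velocity include forward/angular velocity readouts.
#' @param fixed_kc_mbon include an optimized, non-plastic KC-to-MBON weight
#'   matrix \code{W_km}.
#' @param recurrent if FALSE, only the feedforward FBN-to-DAN block of the
#'   recurrent matrix is retained (non-recurrent ablation).
#' @param plasticity a \code{\link{plasticity_config}}.
#' @return an \code{mb_params}.
#' @export
initialize_parameters <- function(arch, state_readout = FALSE, beta = FALSE,
                                  velocity = FALSE, fixed_kc_mbon = FALSE,
                                  recurrent = TRUE,
                                  plasticity =
                                    plasticity_config(w_max = arch$w_max)) {
  n <- arch$n
  sd_by_type <- rep(c(sqrt(1 / (2 * arch$n_mbon)),
                      sqrt(1 / (2 * arch$n_dan)),
                      sqrt(1 / (2 * arch$n_fbn))),
                    c(arch$n_mbon, arch$n_dan, arch$n_fbn))
  W0 <- matrix(rnorm(n * n), n, n) *
    matrix(sd_by_type, n, n, byrow = TRUE)  # columns = presynaptic
  W0[arch$idx_mbon, arch$idx_dan] <- 0
  if (!recurrent) {
    # non-recurrent variant: keep only the feedforward FBN -> DAN relay
    # (the US pathway to the dopamine neurons); remove every loop
    ff <- matrix(0, n, n)
    ff[arch$idx_dan, arch$idx_fbn] <- W0[arch$idx_dan, arch$idx_fbn]
    W0 <- ff
  }
  mb_params(
    arch,
    W = W0,
    b = rep(0.1, n),
    W_ext = matrix(rnorm(arch$n_fbn * arch$d_ext), arch$n_fbn, arch$d_ext),
    W_readout = matrix(rnorm(arch$d_readout * arch$n_mbon,
                             sd = sqrt(1 / arch$n_mbon)),
                       arch$d_readout, arch$n_mbon),
    W_state = if (state_readout)
      matrix(rnorm(3 * arch$n_dan, sd = sqrt(1 / arch$n_dan)), 3,
             arch$n_dan),
    beta = if (beta) rep(0.01, arch$n_mbon),
    velocity = if (velocity)
      list(W_u = rnorm(arch$n_fbn, sd = sqrt(1 / arch$n_fbn)), b_u = 0.1,
           W_omega = rnorm(arch$n_fbn, sd = sqrt(1 / arch$n_fbn)),
           b_omega = 0.1),
    plasticity = plasticity,
    W_km = if (fixed_kc_mbon)
      matrix(rnorm(arch$n_mbon * arch$n_kc, sd = sqrt(1 / (2 * arch$n_kc))),
             arch$n_mbon, arch$n_kc))
}

## --- unrolling --------------------------------------------------------------

#' Unroll the plastic circuit through a trial
#'
#' Interleaves, at every timestep: one forward-Euler step of the rate
#' dynamics, one step of the dopamine-gated plasticity rule (using the
#' pre-update eligibility traces), and the trace update; firing rates are
#' reset to their initial values at the start of each interval while
#' plastic variables persist. The default engine is the compiled core (used
#' by the optimizer, with exact hand-derived gradients); \code{engine =
#' "r"} runs the same loop through the plain R module functions and is
#' intended for cross-checking on short trials.
#'
#' @param params an \code{mb_params}.
#' @param trial an \code{mb_trial} or a pre-rendered trial (from
#'   \code{\link{render_trial}}).
#' @param plasticity_on logical; freeze KC-to-MBON weights when FALSE.
#' @param loss a \code{\link{loss_config}}.
#' @param us_amplitude US input amplitude used at rendering.
#' @param w_init,weff_init optional initial plastic weights (defaults:
#'   \code{w_max} everywhere).
#' @param want_grad also return parameter gradients of the trial loss.
#' @param want_rates return the full rate trajectory (TRUE by default;
#'   turned off in the optimizer's inner loop).
#' @param want_final return the final plastic state (weights and traces).
#' @param engine \code{"cpp"} or \code{"r"}.
#' @return list with \code{rates} (n x T), \code{readout}, optional
#'   \code{state_probs}, loss components, \code{w_final},
#'   \code{weff_final}, the rendered trial, and optionally \code{grads}.
#' @export
unroll <- function(params, trial, plasticity_on = TRUE,
                   loss = loss_config(), us_amplitude = 1,
                   w_init = NULL, weff_init = NULL,
                   want_grad = FALSE, want_rates = TRUE, want_final = TRUE,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  arch <- params$arch
  rt <- if (inherits(trial, "mb_trial"))
    render_trial(trial, arch, us_amplitude) else trial
  w0 <- w_init %||% matrix(params$plasticity$w_max, arch$n_mbon, arch$n_kc)
  we0 <- weff_init %||% w0
  if (engine == "r") {
    if (want_grad) stop("gradients require the compiled engine")
    return(unroll_r(params, rt, plasticity_on, loss))
  }
  res <- cpp_run_trial(
    par_to_cpp(params), rt$kc, rt$ext, rt$target,
    if (!is.null(params$W_state) && !is.null(rt$state_target))
      rt$state_target else NULL,
    rt$reset, rt$loss_mask %||% rep(1, rt$T), w0, we0,
    rep(0, arch$n_kc), rep(0, arch$n_dan),
    plastic = plasticity_on && is.null(params$W_km),
    use_penalty = loss$include_dan_penalty,
    lambda = loss$lambda, dan_base = loss$dan_baseline,
    want_grad = want_grad, want_rates = want_rates,
    want_final = want_final)
  res$rendered <- rt
  res
}

# plain-R reference unroll (small problems; mirrors the compiled loop)
unroll_r <- function(params, rt, plasticity_on, loss) {
  arch <- params$arch
  pc <- params$plasticity
  st <- initial_state(params)
  Tn <- rt$T
  rates <- matrix(0, arch$n, Tn)
  V <- matrix(0, arch$d_readout, Tn)
  S <- if (!is.null(params$W_state) && !is.null(rt$state_target))
    matrix(0, 3, Tn)
  for (t in seq_len(Tn)) {
    if (rt$reset[t]) st <- reset_rates(params, st)
    st <- circuit_step(params, st, rt$kc[, t], rt$ext[, t])
    dan <- st$r[arch$idx_dan]
    if (plasticity_on && is.null(params$W_km))
      st <- plasticity_step(pc, params, st, rt$kc[, t], dan, arch$dt)
    st <- update_traces(pc, st, rt$kc[, t], dan, arch$dt)
    rates[, t] <- st$r
    V[, t] <- readout(params, st)
    if (!is.null(S)) S[, t] <- state_readout(params, st)
  }
  outputs <- list(readout = V, dan_rates = rates[arch$idx_dan, , drop = FALSE],
                  state_probs = S)
  list(rates = rates, readout = V, state_probs = S,
       loss = trial_loss(loss, outputs,
                         list(target = rt$target,
                              state_target = rt$state_target,
                              loss_mask = rt$loss_mask)),
       w_final = st$w, weff_final = st$W_kc_mbon, rendered = rt)
}

## --- optimizer ---------------------------------------------------------------

rmsprop_init <- function(leaves) lapply(leaves, function(x) x * 0)

rmsprop_step <- function(value, grad, cache, lr, alpha, eps) {
  cache <- alpha * cache + (1 - alpha) * grad^2
  list(value = value - lr * grad / (sqrt(cache) + eps), cache = cache)
}

## pull a trainable leaf out of params / push it back
get_leaf <- function(params, name) {
  switch(name,
         W_u = params$velocity$W_u, b_u = params$velocity$b_u,
         W_omega = params$velocity$W_omega,
         b_omega = params$velocity$b_omega,
         params[[name]])
}

set_leaf <- function(params, name, value) {
  if (name %in% c("W_u", "b_u", "W_omega", "b_omega"))
    params$velocity[[name]] <- value
  else params[[name]] <- value
  params
}

project_constraints <- function(params) {
  arch <- params$arch
  params$W[arch$idx_mbon, arch$idx_dan] <- 0
  if (!is.null(params$beta)) params$beta <- pmax(params$beta, 0)
  params
}

## --- the fitting entry point -------------------------------------------------

#' Meta-learn mushroom-body output circuitry for a task family
#'
#' Two-phase meta-learning: the connections of the output circuitry (and any
#' task readouts) are optimized by gradient descent through the unrolled
#' plastic dynamics (RMSprop, backpropagation through time); afterwards they
#' are frozen, and learning during evaluation happens only through the
#' dopamine-gated KC-to-MBON plasticity. Each epoch draws a batch of fresh
#' random trials and takes one optimizer step on the mean trial loss.
#'
#' Task families: \code{"mixture"} (extinction and second-order conditioning
#' trials with random stimulus omissions), \code{"first_order"},
#' \code{"novelty"} (first-order with an added novelty readout),
#' \code{"continual"} (long association sequences with meta-learned
#' non-specific potentiation and annealed trial-to-trial weight carryover),
#' \code{"state"} (three internal states decoded from DAN activity, plus
#' embedded conditioning; no DAN penalty), \code{"navigation"} (plume
#' following; loss is the squared final distance) and \code{"nonplastic"}
#' (plasticity disabled, KC-to-MBON weights optimized directly, fixed odor
#' bank).
#'
#' @param task task family (above).
#' @param arch an \code{\link{mb_arch}}; defaults to the standard 20/20/60
#'   circuit with 200 KCs and the task-appropriate input/readout dimensions.
#' @param n_epochs optimization epochs; defaults per task (2000 first-order
#'   and novelty, 5000 mixture and continual, 500 state and navigation).
#' @param batch_size trials per epoch (30).
#' @param learning_rate RMSprop learning rate (0.001).
#' @param recurrent if FALSE, the ablated non-recurrent variant: every loop
#'   in the output circuitry is removed, leaving only the feedforward
#'   FBN-to-DAN relay of external input (the US pathway that first-order
#'   conditioning requires).
#' @param lambda,dan_baseline DAN penalty configuration.
#' @param omission_prob probability that a conditioning trial has one
#'   stimulus omitted (0.5).
#' @param carryover_anneal_epochs epochs over which the continual-learning
#'   weight carryover anneals from fresh weights to full carryover (2500).
#' @param gamma_final final heading-randomization half-width for navigation
#'   (0.5, annealed linearly from 0).
#' @param bank_size odor-bank size for \code{task = "nonplastic"}.
#' @param potentiation meta-learn per-compartment non-specific potentiation
#'   rates (default: on for the continual task, off otherwise; set FALSE
#'   there for the ablated comparison).
#' @param clip_grad_norm clip the batch gradient to this global norm before
#'   the optimizer step. Default NULL (no clipping) except for navigation
#'   (1), whose closed-loop unrolls produce occasional exploding gradients
#'   that otherwise derail the optimization.
#' @param rmsprop_alpha,rmsprop_eps RMSprop smoothing constant and epsilon
#'   (canonical defaults 0.99 and 1e-8).
#' @param seed master seed; fans out to named streams for initialization and
#'   trial generation.
#' @param trial_options overrides passed to the trial generators.
#' @param verbose print progress every 100 epochs.
#' @return an object of class \code{mb_model}: trained parameters, the
#'   initialization, per-epoch loss history, resolved configuration and
#'   convergence flags.
#' @export
mb_fit <- function(task = c("mixture", "first_order", "novelty", "continual",
                            "state", "navigation", "nonplastic"),
                   arch = NULL, n_epochs = NULL, batch_size = 30,
                   learning_rate = 0.001, recurrent = TRUE,
                   lambda = 0.1, dan_baseline = 0.1,
                   omission_prob = 0.5, carryover_anneal_epochs = 2500,
                   gamma_final = 0.5, bank_size = 10,
                   potentiation = NULL, clip_grad_norm = NULL,
                   rmsprop_alpha = 0.99, rmsprop_eps = 1e-8,
                   seed = 1, trial_options = list(), verbose = FALSE) {
  task <- match.arg(task)
  potentiation <- potentiation %||% (task == "continual")
  if (is.null(clip_grad_norm) && task == "navigation") clip_grad_norm <- 1
  if (is.null(arch)) {
    arch <- switch(task,
      state = mb_arch(d_ext = 5L),
      navigation = mb_arch(d_ext = 6L),
      novelty = mb_arch(d_readout = 2L),
      mb_arch())
  }
  n_epochs <- n_epochs %||% switch(task,
    first_order = 2000L, novelty = 2000L, mixture = 5000L,
    continual = 5000L, state = 500L, navigation = 500L, nonplastic = 2000L)

  set.seed(derive_seed(seed, "init"))
  params <- initialize_parameters(
    arch,
    state_readout = task == "state",
    beta = potentiation,
    velocity = task == "navigation",
    fixed_kc_mbon = task == "nonplastic",
    recurrent = recurrent)

  trainable <- c("W", "b", "W_ext", "W_readout",
                 if (task == "state") "W_state",
                 if (potentiation) "beta",
                 if (task == "navigation") c("W_u", "b_u", "W_omega",
                                             "b_omega"),
                 if (task == "nonplastic") "W_km")
  cache <- rmsprop_init(lapply(stats::setNames(trainable, trainable),
                               function(nm) get_leaf(params, nm)))

  lcfg <- loss_config(lambda = lambda, dan_baseline = dan_baseline,
                      include_dan_penalty = task != "state" &&
                        task != "navigation",
                      loss_kind = switch(task,
                        novelty = "valence+novelty",
                        state = "valence+state",
                        navigation = "navigation",
                        "valence"))

  w_mask <- NULL
  if (!recurrent) {
    w_mask <- matrix(0, arch$n, arch$n)
    w_mask[arch$idx_dan, arch$idx_fbn] <- 1
  }

  bank <- NULL
  if (task == "nonplastic") {
    set.seed(derive_seed(seed, "bank"))
    bank <- odor_bank(bank_size, arch$n_kc)
  }

  w0 <- matrix(params$plasticity$w_max, arch$n_mbon, arch$n_kc)
  w_carry <- w0; weff_carry <- w0

  history <- matrix(NA_real_, n_epochs, 4,
                    dimnames = list(NULL, c("loss", "readout", "penalty",
                                            "state")))
  diverged <- FALSE
  set.seed(derive_seed(seed, "trials"))

  for (epoch in seq_len(n_epochs)) {
    gsum <- lapply(stats::setNames(trainable, trainable),
                   function(nm) get_leaf(params, nm) * 0)
    lsum <- c(0, 0, 0, 0)
    chi <- if (task == "continual")
      min(1, (epoch - 1) / carryover_anneal_epochs) else 0
    gamma <- if (task == "navigation")
      gamma_final * (epoch - 1) / max(1, n_epochs - 1) else 0

    for (bb in seq_len(batch_size)) {
      if (task == "navigation") {
        env <- nav_environment()
        res <- run_navigation_trial(params, env, "both", gamma,
                                    options = c(trial_options,
                                                list(want_grad = TRUE,
                                                     want_traj = FALSE)))
        lsum <- lsum + c(res$loss, res$loss, 0, 0)
      } else {
        trial <- switch(task,
          mixture = make_conditioning_trial(
            sample(c("extinction", "second_order"), 1), arch,
            c(trial_options, list(omission_prob = omission_prob))),
          first_order = , novelty = make_conditioning_trial(
            "first_order", arch,
            c(trial_options, list(omission_prob = omission_prob))),
          continual = make_continual_sequence(arch, trial_options),
          state = make_state_trial(arch, trial_options),
          nonplastic = make_nonplastic_env_trial(bank, arch, trial_options))
        wi <- if (task == "continual")
          (1 - chi) * w0 + chi * w_carry else w0
        wei <- if (task == "continual")
          (1 - chi) * w0 + chi * weff_carry else w0
        res <- unroll(params, trial, plasticity_on = task != "nonplastic",
                      loss = lcfg, w_init = wi, weff_init = wei,
                      want_grad = TRUE, want_rates = FALSE,
                      want_final = task == "continual")
        if (task == "continual") {
          w_carry <- res$w_final
          weff_carry <- res$weff_final
        }
        lsum <- lsum + c(res$loss, res$loss_readout, res$loss_penalty,
                         res$loss_state)
      }
      gtrial <- res$grads[trainable]
      if (!is.null(clip_grad_norm)) {
        # bound each trial's contribution: occasional divergent closed-loop
        # trajectories otherwise dominate the batch gradient
        gn1 <- sqrt(sum(vapply(gtrial, function(g) sum(g^2), numeric(1))))
        if (is.finite(gn1) && gn1 > clip_grad_norm)
          gtrial <- lapply(gtrial, function(g) g * clip_grad_norm / gn1)
      }
      for (nm in trainable)
        gsum[[nm]] <- gsum[[nm]] + gtrial[[nm]]
    }

    lsum <- lsum / batch_size
    history[epoch, ] <- lsum
    if (!all(is.finite(lsum)) ||
        !all(vapply(gsum, function(g) all(is.finite(g)), logical(1)))) {
      diverged <- TRUE
      warning(sprintf("divergent loss or gradient at epoch %d; stopping",
                      epoch))
      break
    }
    if (!is.null(clip_grad_norm)) {
      gn <- sqrt(sum(vapply(gsum, function(g) sum(g^2), numeric(1)))) /
        batch_size
      if (is.finite(gn) && gn > clip_grad_norm)
        gsum <- lapply(gsum, function(g) g * clip_grad_norm / gn)
    }
    for (nm in trainable) {
      g <- gsum[[nm]] / batch_size
      if (nm == "W" && !is.null(w_mask)) g <- g * w_mask
      upd <- rmsprop_step(get_leaf(params, nm), g,
                          cache[[nm]], learning_rate, rmsprop_alpha,
                          rmsprop_eps)
      params <- set_leaf(params, nm, upd$value)
      cache[[nm]] <- upd$cache
    }
    params <- project_constraints(params)
    if (verbose && epoch %% 100 == 0)
      message(sprintf("epoch %d: loss %.4f", epoch, lsum[1]))
  }

  model <- structure(list(
    params = params, arch = arch, task = task,
    loss_history = as.data.frame(history),
    config = list(n_epochs = n_epochs, batch_size = batch_size,
                  learning_rate = learning_rate, recurrent = recurrent,
                  lambda = lambda, dan_baseline = dan_baseline,
                  omission_prob = omission_prob,
                  carryover_anneal_epochs = carryover_anneal_epochs,
                  gamma_final = gamma_final, bank_size = bank_size,
                  potentiation = potentiation,
                  clip_grad_norm = clip_grad_norm,
                  rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
                  tau_elig_kc = params$plasticity$tau_elig_kc,
                  tau_elig_dan = params$plasticity$tau_elig_dan),
    seed = seed, diverged = diverged,
    w_carry = if (task == "continual") w_carry,
    bank = bank), class = "mb_model")
  if (task == "navigation") {
    # the study's convergence criterion: realizations whose mean final
    # position error exceeds 0.4 m are flagged for discarding
    ev <- evaluate_navigation(model, n_trials = 20, gamma = gamma_final,
                              seed = derive_seed(seed, "convergence"))
    model$nav_mean_distance <- ev$mean_distance
    model$converged <- ev$mean_distance <= 0.4
  }
  model
}

## --- evaluation --------------------------------------------------------------

#' Test-phase error rate
#'
#' Freezes the circuit parameters and evaluates fresh test trials: a trial
#' counts as an error when the reported valence deviates from the target by
#' more than \code{threshold} anywhere in the scored test window (the final
#' CS presentation for conditioning paradigms; every CS presentation for
#' continual sequences, with the higher default threshold of 0.5).
#'
#' @param object an \code{mb_model} or \code{mb_params}.
#' @param paradigm trial family to test on.
#' @param n_trials number of test trials (50).
#' @param threshold error threshold (0.2; 0.5 for continual).
#' @param seed seed for the test-trial stream.
#' @param trial_options generator overrides (omissions are off by default
#'   during testing).
#' @return list with \code{error_rate}, per-trial logical \code{errors},
#'   \code{threshold} and \code{paradigm}.
#' @export
evaluate_error_rate <- function(object, paradigm = "first_order",
                                n_trials = 50,
                                threshold = if (paradigm == "continual")
                                  0.5 else 0.2,
                                seed = 1, trial_options = list()) {
  params <- if (inherits(object, "mb_model")) object$params else object
  arch <- params$arch
  set.seed(derive_seed(seed, paste0("eval-", paradigm)))
  w0 <- matrix(params$plasticity$w_max, arch$n_mbon, arch$n_kc)
  w_carry <- w0; weff_carry <- w0
  errors <- logical(n_trials)
  if (n_trials == 0)
    return(list(error_rate = NaN, errors = errors, threshold = threshold,
                paradigm = paradigm))
  for (i in seq_len(n_trials)) {
    if (paradigm == "continual") {
      trial <- make_continual_sequence(arch, trial_options)
      res <- unroll(params, trial, w_init = w_carry,
                    weff_init = weff_carry)
      w_carry <- res$w_final; weff_carry <- res$weff_final
    } else {
      trial <- make_conditioning_trial(
        paradigm, arch, c(trial_options, list(omission_prob = 0)))
      res <- unroll(params, trial,
                    plasticity_on = is.null(params$W_km))
    }
    sc <- res$rendered$score
    dev <- abs(res$readout[1, sc] - res$rendered$target[1, sc])
    errors[i] <- any(dev > threshold)
  }
  list(error_rate = mean(errors), errors = errors, threshold = threshold,
       paradigm = paradigm)
}

#' Navigation performance of a trained model
#'
#' @param object an \code{mb_model} or \code{mb_params} with velocity
#'   readouts.
#' @param n_trials number of test trials.
#' @param plasticity plasticity condition passed to
#'   \code{\link{run_navigation_trial}}.
#' @param gamma heading-randomization half-width (0.5 at test).
#' @param seed test-trial stream seed.
#' @return list with \code{mean_distance}, per-trial \code{distances} and
#'   the condition.
#' @export
evaluate_navigation <- function(object, n_trials = 50,
                                plasticity = "both", gamma = 0.5,
                                seed = 1) {
  params <- if (inherits(object, "mb_model")) object$params else object
  set.seed(derive_seed(seed, "nav-eval"))
  d <- vapply(seq_len(n_trials), function(i) {
    env <- nav_environment()
    run_navigation_trial(params, env, plasticity, gamma,
                         options = list(want_traj = FALSE))$final_distance
  }, numeric(1))
  list(mean_distance = mean(d), distances = d, plasticity = plasticity)
}

#' CS+ versus neutral-probe response difference
#'
#' Runs fixed-bank probe trials (CS+ pairing at 5 s, probe at 15 s) and
#' returns the mean signed readout during the probe window, separately for
#' probes that repeat the CS+ and probes that present a different bank
#' odor, along with their difference. Networks that store the association
#' respond to the CS+ probe but not to neutral probes, so the difference is
#' near the trained valence magnitude; overgeneralizing networks shrink it
#' toward zero.
#'
#' @param object an \code{mb_model} or \code{mb_params}.
#' @param bank odor bank (defaults to the bank stored in the model).
#' @param n_trials number of probe trials.
#' @param seed test-trial stream seed.
#' @return list with \code{difference}, \code{mean_same}, \code{mean_diff}.
#' @export
evaluate_response_difference <- function(object, bank = NULL, n_trials = 50,
                                         seed = 1) {
  params <- if (inherits(object, "mb_model")) object$params else object
  if (is.null(bank) && inherits(object, "mb_model")) bank <- object$bank
  if (is.null(bank)) stop("an odor bank is required")
  set.seed(derive_seed(seed, "respdiff"))
  vals <- vapply(seq_len(n_trials), function(i) {
    trial <- make_nonplastic_env_trial(bank, params$arch)
    res <- unroll(params, trial, plasticity_on = is.null(params$W_km))
    sc <- res$rendered$score
    c(mean(res$readout[1, sc]) * trial$meta$us_sign,
      as.numeric(trial$meta$probe_same))
  }, numeric(2))
  same <- vals[2, ] == 1
  m_same <- mean(vals[1, same])
  m_diff <- mean(vals[1, !same])
  list(difference = m_same - m_diff, mean_same = m_same,
       mean_diff = m_diff, n_same = sum(same))
}
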