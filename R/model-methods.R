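## S3 methods for fitted mb_model objects

#' @export
print.mb_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("meta-learned mushroom-body model (task: %s)\n", x$task))
  cat(sprintf("  circuit: %d MBON / %d DAN / %d FBN, %d KC, %d compartments\n",
              a$n_mbon, a$n_dan, a$n_fbn, a$n_kc, a$n_compartments))
  ne <- sum(!is.na(x$loss_history$loss))
  cat(sprintf("  optimized %d epochs (batch %d, RMSprop lr %g)\n",
              ne, x$config$batch_size, x$config$learning_rate))
  if (ne > 0)
    cat(sprintf("  final loss %.4f (first epoch %.4f)\n",
                x$loss_history$loss[ne], x$loss_history$loss[1]))
  if (!x$config$recurrent) cat("  recurrence ablated (W fixed at 0)\n")
  if (x$diverged) cat("  NOTE: optimization diverged before completion\n")
  invisible(x)
}

#' @export
summary.mb_model <- function(object, n_test = 0, seed = 1, ...) {
  ne <- sum(!is.na(object$loss_history$loss))
  out <- list(task = object$task, epochs = ne,
              final_loss = object$loss_history$loss[ne],
              loss_components = object$loss_history[ne, ],
              config = object$config, diverged = object$diverged)
  if (n_test > 0 && object$task %in% c("mixture", "first_order", "novelty"))
    out$first_order_error <- evaluate_error_rate(
      object, "first_order", n_trials = n_test, seed = seed)$error_rate
  class(out) <- "summary.mb_model"
  out
}

#' @export
print.summary.mb_model <- function(x, ...) {
  cat(sprintf("task %s: %d epochs, final loss %.4f\n", x$task, x$epochs,
              x$final_loss))
  print(x$loss_components, row.names = FALSE)
  if (!is.null(x$first_order_error))
    cat(sprintf("first-order test error rate: %.3f\n", x$first_order_error))
  invisible(x)
}

#' @export
coef.mb_model <- function(object, ...) {
  p <- object$params
  c(list(W_recur = p$W, b = p$b, W_ext = p$W_ext, W_readout = p$W_readout),
    if (!is.null(p$W_state)) list(W_state = p$W_state),
    if (!is.null(p$beta)) list(beta = p$beta),
    if (!is.null(p$W_km)) list(W_kc_mbon = p$W_km),
    if (!is.null(p$velocity)) object$params["velocity"])
}

#' @export
plot.mb_model <- function(x, smooth = 25, ...) {
  lh <- x$loss_history$loss
  lh <- lh[!is.na(lh)]
  plot(seq_along(lh), lh, type = "l", col = "grey70",
       xlab = "epoch", ylab = "batch loss",
       main = sprintf("optimization (%s)", x$task), ...)
  if (length(lh) > smooth) {
    sm <- stats::filter(lh, rep(1 / smooth, smooth), sides = 1)
    lines(seq_along(lh), sm, lwd = 2)
  }
  invisible(x)
}

#' Run a fitted model on test trials
#'
#' Simulates fresh frozen-parameter test trials and returns the readout,
#' target and scored-window flags per timestep in long format.
#'
#' @param object an \code{mb_model}.
#' @param paradigm test-trial family.
#' @param n number of trials.
#' @param seed test-stream seed.
#' @param ... unused.
#' @return data frame with columns \code{trial}, \code{time},
#'   \code{readout}, \code{target}, \code{scored}.
#' @export
predict.mb_model <- function(object, paradigm = "first_order", n = 5,
                             seed = 1, ...) {
  params <- object$params
  set.seed(derive_seed(seed, paste0("predict-", paradigm)))
  do.call(rbind, lapply(seq_len(n), function(i) {
    trial <- make_conditioning_trial(paradigm, params$arch,
                                     list(omission_prob = 0))
    res <- unroll(params, trial, plasticity_on = is.null(params$W_km))
    data.frame(trial = i, time = res$rendered$times,
               readout = res$readout[1, ],
               target = res$rendered$target[1, ],
               scored = res$rendered$score)
  }))
}

#' Simulate full trial dynamics from a fitted model
#'
#' @param object an \code{mb_model}.
#' @param nsim number of trials.
#' @param seed optional seed.
#' @param paradigm trial family.
#' @param ... unused.
#' @return list of unroll results (rates, readouts, final weights).
#' @export
simulate.mb_model <- function(object, nsim = 1, seed = NULL,
                              paradigm = "first_order", ...) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "simulate"))
  lapply(seq_len(nsim), function(i) {
    trial <- make_conditioning_trial(paradigm, object$arch,
                                     list(omission_prob = 0))
    unroll(object$params, trial,
           plasticity_on = is.null(object$params$W_km))
  })
}

#' Readout residuals over scored test windows
#'
#' @param object an \code{mb_model}.
#' @param paradigm test-trial family.
#' @param n number of trials.
#' @param seed test-stream seed.
#' @param ... unused.
#' @return numeric vector of readout-minus-target residuals at scored
#'   timesteps.
#' @export
residuals.mb_model <- function(object, paradigm = "first_order", n = 10,
                               seed = 1, ...) {
  pr <- predict(object, paradigm = paradigm, n = n, seed = seed)
  pr$readout[pr$scored] - pr$target[pr$scored]
}
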