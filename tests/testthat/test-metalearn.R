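test_that("trial loss reproduces hand-computed values", {
  lc <- loss_config()
  Tn <- 10
  outputs <- list(readout = matrix(0, 1, Tn),
                  dan_rates = matrix(0.1, 20, Tn))
  targets <- list(target = matrix(0, 1, Tn))
  expect_equal(trial_loss(lc, outputs, targets), 0)

  # perfect valence, constant DAN rate 0.2, 20 DANs, lambda = 0.1:
  # penalty = 0.1 * 20 * 0.1^2 = 0.02
  outputs$dan_rates <- matrix(0.2, 20, Tn)
  expect_equal(trial_loss(lc, outputs, targets), 0.02)

  # navigation: at the goal the loss is zero
  lcn <- loss_config(loss_kind = "navigation")
  expect_equal(trial_loss(lcn, list(final_position = c(1, 0.3)),
                          list(goal = c(1, 0.3))), 0)
  expect_equal(trial_loss(lcn, list(final_position = c(0, 0)),
                          list(goal = c(0.6, 0.8))), 1)
})

test_that("initialization matches the stated presynaptic-type variances", {
  arch <- mb_arch()
  set.seed(42)
  draws <- replicate(30, {
    p <- initialize_parameters(arch)
    c(var(as.numeric(p$W[-arch$idx_dan, arch$idx_mbon])),
      var(as.numeric(p$W[, arch$idx_fbn])),
      var(as.numeric(p$W_readout)),
      var(as.numeric(p$W_ext)))
  })
  mv <- rowMeans(draws)
  expect_equal(mv[1], 1 / 40, tolerance = 0.05)    # MBON presynaptic columns
  expect_equal(mv[2], 1 / 120, tolerance = 0.05)   # FBN presynaptic columns
  expect_equal(mv[3], 1 / 20, tolerance = 0.05)    # readout
  expect_equal(mv[4], 1, tolerance = 0.05)         # external input

  p <- initialize_parameters(arch, beta = TRUE)
  expect_true(all(p$W[arch$idx_mbon, arch$idx_dan] == 0))
  expect_equal(p$b, rep(0.1, arch$n))
  expect_equal(p$beta, rep(0.01, arch$n_mbon))
})

test_that("unrolled gradients match central finite differences within 1%", {
  arch <- tiny_arch()
  p <- random_params(arch, seed = 3)
  set.seed(4)
  trial <- make_conditioning_trial("first_order", arch,
                                   list(omission_prob = 0,
                                        interval = 12))
  rt <- render_trial(trial, arch)
  g <- unroll(p, rt, want_grad = TRUE)$grads
  eps <- 1e-4
  worst <- 0; checked <- 0
  set.seed(5)
  for (nm in c("W", "b", "W_ext", "W_readout")) {
    x <- mbplast:::get_leaf(p, nm)
    for (i in sample(length(x), min(5, length(x)))) {
      fd <- local({
        lp <- unroll(mbplast:::set_leaf(p, nm, replace(x, i, x[i] + eps)),
                     rt)$loss
        lm <- unroll(mbplast:::set_leaf(p, nm, replace(x, i, x[i] - eps)),
                     rt)$loss
        (lp - lm) / (2 * eps)
      })
      an <- g[[nm]][i]
      if (abs(fd) > 1e-6) {
        worst <- max(worst, abs(an - fd) / abs(fd))
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 10)
  expect_lt(worst, 0.01)
})

test_that("unroll is deterministic and plasticity-off freezes weights", {
  arch <- tiny_arch()
  p <- random_params(arch, seed = 6)
  set.seed(7)
  trial <- make_conditioning_trial("first_order", arch,
                                   list(omission_prob = 0))
  r1 <- unroll(p, trial)
  r2 <- unroll(p, trial)
  expect_identical(r1$rates, r2$rates)

  r3 <- unroll(p, trial, plasticity_on = FALSE)
  expect_equal(r3$weff_final, matrix(0.05, arch$n_mbon, arch$n_kc))
  expect_false(isTRUE(all.equal(r1$weff_final, r3$weff_final)))
})

test_that("zero learning rate leaves parameters unchanged", {
  m <- mb_fit("first_order", arch = tiny_arch(), n_epochs = 3,
              batch_size = 2, learning_rate = 0, seed = 11)
  set.seed(mbplast::derive_seed(11, "init"))
  p0 <- initialize_parameters(tiny_arch())
  expect_equal(m$params$W, p0$W)
  expect_equal(m$params$W_ext, p0$W_ext)
})

test_that("fitting reduces the loss and keeps the structural constraints", {
  m <- small_mixture_model()
  lh <- m$loss_history$loss
  sm <- function(idx) mean(lh[idx])
  expect_lt(sm(451:500), sm(1:50))     # smoothed loss decreases overall
  a <- m$arch
  expect_true(all(m$params$W[a$idx_mbon, a$idx_dan] == 0))
  expect_false(m$diverged)
})

test_that("non-recurrent ablation keeps only the FBN-to-DAN relay", {
  m <- mb_fit("mixture", arch = small_arch(), n_epochs = 30,
              recurrent = FALSE, seed = 8)
  a <- m$arch
  W <- m$params$W
  relay <- W[a$idx_dan, a$idx_fbn]
  W[a$idx_dan, a$idx_fbn] <- 0
  expect_true(all(W == 0))          # no loops anywhere else
  expect_gt(max(abs(relay)), 0)     # the US pathway to DANs remains
})

test_that("error-rate counting matches a synthetic deviation pattern", {
  arch <- tiny_arch()
  p <- random_params(arch, seed = 12)
  # construct readouts directly: k of n trials deviating by 2*threshold
  errs <- vapply(1:10, function(i) {
    readout <- matrix(0, 1, 8)
    target <- matrix(0, 1, 8)
    if (i <= 3) readout[1, 5] <- 0.4      # deviate by 2 * 0.2
    any(abs(readout - target)[1, ] > 0.2)
  }, logical(1))
  expect_equal(mean(errs), 0.3)

  # untrained networks fail first-order conditioning badly
  ev <- evaluate_error_rate(p, "first_order", n_trials = 20, seed = 13)
  expect_gt(ev$error_rate, 0.5)
  expect_length(ev$errors, 20)
  # n_trials = 0 flags an undefined rate
  expect_true(is.nan(evaluate_error_rate(p, n_trials = 0)$error_rate))
})

test_that("continual weight carryover changes the chained dynamics exactly", {
  arch <- tiny_arch()
  p <- random_params(arch, seed = 14, beta = TRUE)
  set.seed(15)
  tr <- make_continual_sequence(arch, list(duration = 100))
  w_dep <- matrix(0.01, arch$n_mbon, arch$n_kc)   # strongly depressed chain
  r_carry <- unroll(p, tr, w_init = w_dep, weff_init = w_dep)
  r_fresh <- unroll(p, tr)
  expect_gt(max(abs(r_carry$rates - r_fresh$rates)), 1e-4)
  # the chain is deterministic: same carried weights, same dynamics
  r_again <- unroll(p, tr, w_init = w_dep, weff_init = w_dep)
  expect_identical(r_carry$rates, r_again$rates)
  # mixing rule at full annealing: initial weights are exactly the carryover
  expect_identical((1 - 1) * 0.05 + 1 * w_dep, w_dep)
})

test_that("trained mixture networks generalize to reversal probes", {
  m <- full_mixture_model()
  set.seed(16)
  diffs <- vapply(1:12, function(i) {
    tr <- make_conditioning_trial("reversal", m$arch,
                                  list(omission_prob = 0, valence = 1))
    res <- unroll(m$params, tr)
    tt <- res$rendered$times
    w1 <- tr$meta$cs1_window; w2 <- tr$meta$cs2_window
    off1 <- sum(vapply(tr$intervals[1:2], `[[`, numeric(1), "duration"))
    mean(res$readout[1, tt >= off1 + w2[1] & tt < off1 + w2[2]]) -
      mean(res$readout[1, tt >= off1 + w1[1] & tt < off1 + w1[2]])
  }, numeric(1))
  # positive US: the recently reinforced CS2 is preferred over CS1
  expect_gt(mean(diffs), 0)
})
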