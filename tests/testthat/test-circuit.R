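test_that("initial state follows the reset convention and shape contracts", {
  p <- random_params(tiny_arch())
  st <- initial_state(p)
  a <- p$arch
  expect_equal(st$r[a$idx_mbon], rep(0, a$n_mbon))
  expect_equal(st$r[a$idx_dan], rep(0.1, a$n_dan))
  expect_equal(st$r[a$idx_fbn], rep(0.1, a$n_fbn))
  expect_true(all(st$w == 0.05) && all(st$W_kc_mbon == 0.05))
  expect_true(all(st$trace_kc == 0) && all(st$trace_dan == 0))

  arch1 <- mb_arch(n_mbon = 1, n_dan = 1, n_fbn = 1, n_kc = 3,
                   n_compartments = 1)
  p1 <- random_params(arch1, seed = 2)
  st1 <- initial_state(p1)
  expect_equal(dim(st1$w), c(1L, 3L))
  expect_true(all(st1$w == 0.05))
})

test_that("rates converge to the rectified fixed point without recurrence", {
  a <- tiny_arch()
  p <- mb_params(a, W = matrix(0, a$n, a$n), b = rep(0.1, a$n),
                 W_ext = matrix(0, a$n_fbn, a$d_ext),
                 W_readout = matrix(0, 1, a$n_mbon))
  st <- initial_state(p)
  for (i in 1:100)
    st <- circuit_step(p, st, rep(0, a$n_kc), rep(0, a$d_ext))
  expect_equal(st$r, rep(0.1, a$n), tolerance = 1e-10)

  # one Euler decay step from r = 1 with b = 0
  p0 <- mb_params(a, W = matrix(0, a$n, a$n), b = rep(0, a$n),
                  W_ext = matrix(0, a$n_fbn, a$d_ext),
                  W_readout = matrix(0, 1, a$n_mbon))
  st0 <- initial_state(p0)
  st0$r <- rep(1, a$n)
  st0 <- circuit_step(p0, st0, rep(0, a$n_kc), rep(0, a$d_ext))
  expect_equal(st0$r, rep(0.5, a$n))
})

test_that("coarse Euler trajectory tracks a fine-step reference integrator", {
  # 10-neuron circuit, constant input, compare r(10 s) at dt = 0.5 vs 0.005
  arch <- mb_arch(n_mbon = 2, n_dan = 2, n_fbn = 6, n_kc = 10,
                  n_compartments = 2)
  set.seed(31)
  p <- initialize_parameters(arch)
  p$W <- p$W * 0.5                     # keep dynamics well within stability
  p <- mbplast:::project_constraints(p)
  kc <- rep(0, 10); ext <- c(0.5, 0.2)
  Wkm <- matrix(0.05, 2, 10)

  euler <- function(dt, t_end) {
    r <- c(0, 0, rep(0.1, 8))
    I <- numeric(10)
    I[1:2] <- Wkm %*% kc
    I[5:10] <- p$W_ext %*% ext
    for (i in seq_len(round(t_end / dt)))
      r <- r + dt / arch$tau * (-r + pmax(as.numeric(p$W %*% r) + p$b + I, 0))
    r
  }
  r_fine <- euler(0.005, 10)
  trial <- mbplast:::new_trial("const",
    intervals = list(list(duration = 10, reset = TRUE, events = list())),
    patterns = matrix(0, 0, 10),
    target_windows = data.frame(interval = numeric(0), onset = numeric(0),
                                duration = numeric(0), value = numeric(0)),
    score_windows = data.frame(interval = numeric(0), onset = numeric(0),
                               duration = numeric(0)))
  rt <- render_trial(trial, arch)
  rt$ext[] <- ext
  res <- unroll(p, rt, plasticity_on = FALSE)
  r_coarse <- res$rates[, ncol(res$rates)]
  expect_lt(sqrt(sum((r_coarse - r_fine)^2)) / sqrt(sum(r_fine^2)), 0.05)
})

test_that("rates stay nonnegative and steps are deterministic", {
  p <- random_params(tiny_arch(), seed = 5)
  a <- p$arch
  set.seed(9)
  st1 <- initial_state(p); st2 <- initial_state(p)
  for (i in 1:50) {
    kc <- rbinom(a$n_kc, 1, 0.1)
    ext <- runif(a$d_ext)
    st1 <- circuit_step(p, st1, kc, ext)
    st2 <- circuit_step(p, st2, kc, ext)
    expect_true(all(st1$r >= 0))
  }
  expect_identical(st1$r, st2$r)
})

test_that("DAN rates ignore external input when their afferent rows are zero", {
  p <- random_params(tiny_arch(), seed = 6)
  a <- p$arch
  # cut both routes by which external input can reach the DANs: the direct
  # FBN relay and the indirect FBN -> MBON -> DAN path
  p$W[a$idx_dan, a$idx_fbn] <- 0
  p$W[a$idx_dan, a$idx_mbon] <- 0
  run <- function(ext) {
    st <- initial_state(p)
    out <- matrix(0, a$n_dan, 30)
    for (i in 1:30) {
      st <- circuit_step(p, st, rep(0, a$n_kc), ext)
      out[, i] <- st$r[a$idx_dan]
    }
    out
  }
  expect_equal(run(c(0, 0)), run(c(3, 1)))
})

test_that("readouts are linear maps and the state readout is a softmax", {
  a <- mb_arch(n_mbon = 2, n_dan = 4, n_fbn = 4, n_kc = 10,
               n_compartments = 2)
  set.seed(3)
  p <- initialize_parameters(a, state_readout = TRUE)
  st <- initial_state(p)
  st$r[a$idx_mbon] <- c(0.3, 0.1)
  p$W_readout <- matrix(c(1, -1), 1, 2)
  expect_equal(readout(p, st), 0.2)

  # dual route: matrix readout vs naive multiply-accumulate loop
  set.seed(4)
  p$W_readout <- matrix(rnorm(2), 1, 2)
  st$r[a$idx_mbon] <- runif(2)
  manual <- sum(vapply(1:2, function(j)
    p$W_readout[1, j] * st$r[j], numeric(1)))
  expect_equal(readout(p, st), manual)

  p$W_state <- matrix(0, 3, a$n_dan)
  expect_equal(state_readout(p, st), rep(1 / 3, 3))
  st$r[a$idx_dan] <- runif(a$n_dan)
  p$W_state <- matrix(rnorm(3 * a$n_dan), 3, a$n_dan)
  expect_equal(sum(state_readout(p, st)), 1, tolerance = 1e-12)
  p$W_state <- matrix(0, 3, a$n_dan)
  p$W_state[1, ] <- 10 / sum(st$r[a$idx_dan] > 0) /
    mean(st$r[a$idx_dan])  # logits ~ (10, 0, 0)
  expect_gt(state_readout(p, st)[1], 0.99)
})

test_that("parameter validation enforces the DAN-to-MBON zero block", {
  a <- tiny_arch()
  W <- matrix(0, a$n, a$n)
  W[a$idx_mbon[1], a$idx_dan[1]] <- 0.2
  expect_error(
    mb_params(a, W = W, b = rep(0, a$n),
              W_ext = matrix(0, a$n_fbn, a$d_ext),
              W_readout = matrix(0, 1, a$n_mbon)),
    "DAN->MBON")
  expect_error(mb_arch(dt = 2, tau = 1), "dt")
})

test_that("compartment gating supports reduced compartment counts", {
  a <- mb_arch(n_mbon = 8, n_dan = 8, n_fbn = 8, n_kc = 20,
               n_compartments = 4)
  G <- compartment_gating(a)
  expect_equal(dim(G), c(8L, 8L))
  expect_equal(sort(unique(as.numeric(G))), c(0, 1 / 4))
  cm <- compartment_map(a)
  expect_equal(cm$mbon, rep(1:4, each = 2))
  # every neuron in exactly one compartment
  expect_true(all(table(cm$dan) == 2))
  # identity when n_compartments equals the population sizes
  expect_equal(compartment_gating(tiny_arch()), diag(4))
})
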