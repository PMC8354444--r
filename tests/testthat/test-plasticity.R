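pulse_sim <- function(cfg, par1, t_kc, t_dan, dur = 2, amp = 1, dt = 0.01,
                      t_end = NULL) {
  # integrate the rule for one KC/DAN pulse pair; returns total weight change
  t_end <- t_end %||% (max(t_kc, t_dan) + dur + 10 * cfg$tau_elig_kc)
  st <- initial_state(par1)
  st$w[] <- 0; st$W_kc_mbon[] <- 0
  tt <- 0
  while (tt < t_end) {
    kc <- as.numeric(tt >= t_kc && tt < t_kc + dur) * amp
    dan <- as.numeric(tt >= t_dan && tt < t_dan + dur) * amp
    st <- plasticity_step(cfg, par1, st, kc, dan, dt)
    st <- update_traces(cfg, st, kc, dan, dt)
    tt <- tt + dt
  }
  st$w[1, 1]
}

one_syn_params <- function(cfg) {
  a <- mb_arch(n_mbon = 1, n_dan = 1, n_fbn = 1, n_kc = 1,
               n_compartments = 1)
  mb_params(a, W = matrix(0, 3, 3), b = rep(0, 3),
            W_ext = matrix(0, 1, 2), W_readout = matrix(0, 1, 1),
            plasticity = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("eligibility traces are first-order low-pass filters", {
  cfg <- plasticity_config(tau_elig_kc = 1.5, tau_elig_dan = 0.8)
  p <- one_syn_params(cfg)
  st <- initial_state(p)
  dt <- 0.01
  prev <- 0
  for (i in seq_len(200)) {          # constant rate 1 for 2 s
    st <- update_traces(cfg, st, 1, 0, dt)
    expect_gte(st$trace_kc, prev)    # monotone approach
    prev <- st$trace_kc
  }
  # peak after a 2-s pulse matches the closed-form step response
  expect_equal(st$trace_kc, 1 - exp(-2 / 1.5), tolerance = 0.01)
  expect_equal(st$trace_dan, 0)      # silent input leaves the trace at 0
})

test_that("pairing sign convention: forward depresses, backward potentiates", {
  cfg <- plasticity_config(clip = FALSE)
  p <- one_syn_params(cfg)
  fwd <- pulse_sim(cfg, p, t_kc = 0, t_dan = 3)   # KC ends 1 s before DAN
  bwd <- pulse_sim(cfg, p, t_kc = 3, t_dan = 0)   # DAN ends 1 s before KC
  expect_lt(fwd, 0)
  expect_gt(bwd, 0)
  # rule-level antisymmetry for matched trace constants
  expect_equal(fwd, -bwd, tolerance = 1e-10)
})

test_that("non-overlapping pulse pairing matches the closed-form integral", {
  # KC pulse on [0, D], DAN pulse on [s, s+D], s >= D, equal trace constants:
  # dw = -Ak Ad tau (1 - exp(-D/tau))^2 exp(-(s - D)/tau)
  tau <- 1; D <- 2; s <- 3; A <- 1
  expected <- -A * A * tau * (1 - exp(-D / tau))^2 * exp(-(s - D) / tau)
  cfg <- plasticity_config(tau_elig_kc = tau, tau_elig_dan = tau,
                           clip = FALSE)
  p <- one_syn_params(cfg)
  got <- pulse_sim(cfg, p, t_kc = 0, t_dan = s, dur = D, dt = 0.01)
  expect_lt(abs(got - expected) / abs(expected), 0.02)
})

test_that("pairing curve is biphasic and vanishes at long lags", {
  cfg <- plasticity_config()
  pc <- pairing_curve(cfg, delta_t_grid = seq(-10, 10, by = 1), dt = 0.1)
  pos_lag <- pc$delta_w[pc$delta_t_s > 0 & pc$delta_t_s <= 4]
  neg_lag <- pc$delta_w[pc$delta_t_s < 0 & pc$delta_t_s >= -4]
  expect_true(all(pos_lag < 0))       # KC first -> depression
  expect_true(all(neg_lag > 0))       # DAN first -> potentiation
  peak <- max(abs(pc$delta_w))
  far <- abs(pc$delta_w[abs(pc$delta_t_s) >= 10])
  expect_true(all(far < 0.01 * peak))
})

test_that("pairing-window width scales with the trace time constant", {
  # the depression lobe decays as exp(-(lag - peak)/tau) beyond its peak, so
  # the peak-to-1/e span doubles when both trace constants double
  efold_span <- function(tau) {
    pc <- pairing_curve(plasticity_config(tau_elig_kc = tau,
                                          tau_elig_dan = tau),
                        delta_t_grid = seq(0.5, 6 * tau, by = 0.1),
                        pulse_dur = 0.5, dt = 0.05)
    aw <- abs(pc$delta_w)
    ipk <- which.max(aw)
    ie <- ipk + which(aw[-seq_len(ipk)] < aw[ipk] / exp(1))[1]
    pc$delta_t_s[ie] - pc$delta_t_s[ipk]
  }
  expect_equal(efold_span(2) / efold_span(1), 2, tolerance = 0.15)
})

test_that("weights stay inside [0, w_max] under arbitrary drive", {
  cfg <- plasticity_config()
  a <- mb_arch(n_mbon = 4, n_dan = 4, n_kc = 20, n_fbn = 4,
               n_compartments = 4)
  p <- random_params(a, seed = 11)
  st <- initial_state(p)
  set.seed(12)
  for (i in 1:200) {
    kc <- runif(a$n_kc, 0, 5)
    dan <- runif(a$n_dan, 0, 5)
    st <- plasticity_step(cfg, p, st, kc, dan, a$dt)
    st <- update_traces(cfg, st, kc, dan, a$dt)
    expect_true(all(st$w >= 0 & st$w <= cfg$w_max))
    expect_true(all(st$W_kc_mbon >= 0 & st$W_kc_mbon <= cfg$w_max + 1e-12))
  }
})

test_that("effective weights relax toward w with a 5-s time constant", {
  cfg <- plasticity_config()
  p <- one_syn_params(cfg)
  st <- initial_state(p)
  st$w[] <- 0                        # step change of the latent variable
  n <- round(5 / 0.5)                # integrate one time constant
  for (i in seq_len(n))
    st <- plasticity_step(cfg, p, st, 0, 0, 0.5)
  # discrete-time decay (1 - dt/tau_w)^n vs continuous exp(-1)
  expect_equal(st$W_kc_mbon[1, 1] / 0.05, (1 - 0.5 / 5)^n)
  expect_equal(st$W_kc_mbon[1, 1] / 0.05, exp(-1), tolerance = 0.06)
})

test_that("DAN activity without KC input potentiates only via beta, locally", {
  a <- mb_arch(n_mbon = 4, n_dan = 4, n_kc = 10, n_fbn = 4,
               n_compartments = 4)
  cfg <- plasticity_config()
  p <- random_params(a, seed = 13)
  p$beta <- rep(0.05, 4)
  st <- initial_state(p)
  st$w[] <- 0.02; st$W_kc_mbon[] <- 0.02
  dan <- c(0, 1, 0, 0)               # only compartment 2 active
  for (i in 1:20) {
    st <- plasticity_step(cfg, p, st, rep(0, 10), dan, 0.5)
    st <- update_traces(cfg, st, rep(0, 10), dan, 0.5)
  }
  expect_true(all(st$w[2, ] > 0.02))
  expect_true(all(st$w[-2, ] == 0.02))

  # with beta = 0, DAN-only drive leaves weights unchanged (traces are 0 for
  # silent KCs, so both product terms vanish)
  p$beta <- NULL
  st2 <- initial_state(p)
  st2$w[] <- 0.02
  for (i in 1:20) {
    st2 <- plasticity_step(cfg, p, st2, rep(0, 10), dan, 0.5)
    st2 <- update_traces(cfg, st2, rep(0, 10), dan, 0.5)
  }
  expect_equal(st2$w, matrix(0.02, 4, 10))
})
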