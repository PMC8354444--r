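test_that("odor codes have exact sparsity and reproducible support", {
  set.seed(1)
  v <- encode_odor(200, 0.1)
  expect_equal(sum(v), 20)
  expect_true(all(v %in% c(0, 1)))
  set.seed(99); a <- encode_odor(200, 0.1)
  set.seed(99); b <- encode_odor(200, 0.1)
  expect_identical(a, b)
  expect_error(encode_odor(5, 0.05), "at least 1")
})

test_that("mean overlap of independent codes matches the hypergeometric value", {
  set.seed(2)
  ov <- replicate(2000, sum(encode_odor(200, 0.1) * encode_odor(200, 0.1)))
  # E[overlap] = 200 * 0.1 * 0.1 = 2; se ~ sqrt(1.8/2000) ~ 0.03
  expect_equal(mean(ov), 2, tolerance = 0.1)
})

test_that("conditioning onsets fall in [5, 15] s within their intervals", {
  a <- tiny_arch()
  set.seed(3)
  onsets <- unlist(replicate(300, {
    tr <- make_conditioning_trial(
      sample(c("first_order", "extinction", "second_order"), 1), a)
    lapply(tr$intervals, function(iv)
      vapply(iv$events, function(e)
        if (e$kind == "CS" && e$onset <= 15) e$onset else NA_real_,
        numeric(1)))
  }))
  onsets <- onsets[!is.na(onsets)]
  expect_true(all(onsets >= 5 & onsets <= 15))
})

test_that("omissions zero the target except the intact-memory extinction case", {
  a <- tiny_arch()
  set.seed(4)
  seen <- character(0)
  for (i in 1:200) {
    tr <- make_conditioning_trial("extinction", a,
                                  list(omission_prob = 1, valence = 1))
    v <- tr$meta$omitted
    seen <- union(seen, v)
    if (v %in% c("cs1", "us"))
      expect_true(all(tr$target_windows$value == 0))
    if (v == "cs2") expect_equal(tr$target_windows$value, 1)
  }
  expect_setequal(seen, c("cs1", "us", "cs2"))

  # first-order with omitted US: target identically zero after rendering
  repeat {
    tr <- make_conditioning_trial("first_order", a,
                                  list(omission_prob = 1))
    if (tr$meta$omitted == "us") break
  }
  rt <- render_trial(tr, a)
  expect_true(all(rt$target == 0))

  # full extinction: intact association at the exposure, reduced at test
  tr_ext <- make_conditioning_trial("extinction", a,
                                    list(omission_prob = 0, valence = 1))
  tr_fo <- make_conditioning_trial("first_order", a,
                                   list(omission_prob = 0, valence = 1))
  expect_equal(tr_ext$target_windows$value, c(1, 0.5))
  expect_equal(tr_fo$target_windows$value, 1)
})

test_that("continual sequences follow the Poisson schedule and flip targets", {
  a <- tiny_arch()
  set.seed(5)
  n_pres <- unlist(replicate(500, make_continual_sequence(a)$meta$n_pres))
  expect_equal(mean(n_pres), 2, tolerance = 0.15)

  found_flip <- FALSE
  for (i in 1:300) {
    tr <- make_continual_sequence(a)
    ev <- tr$intervals[[1]]$events
    cs <- Filter(function(e) e$kind == "CS", ev)
    us <- Filter(function(e) e$kind == "US", ev)
    # CS- presentations carry target 0
    tw <- tr$target_windows
    for (e in cs) {
      if (e$odor_id > 2) {
        j <- which(abs(tw$onset - e$onset) < 1e-9)
        expect_equal(tw$value[j], 0)
      }
    }
    # target during a CS+ equals the sign of its most recent previous pairing
    for (odor in 1:2) {
      pres <- Filter(function(e) e$odor_id == odor, cs)
      if (length(pres) < 2) next
      ons <- sort(vapply(pres, `[[`, numeric(1), "onset"))
      for (k in 2:length(ons)) {
        prev_us <- Filter(function(e) abs(e$onset - (ons[k - 1] + 2)) < 1e-6,
                          us)
        j <- which(abs(tw$onset - ons[k]) < 1e-9)
        expect_equal(tw$value[j], prev_us[[1]]$valence)
        if (k > 2) found_flip <- TRUE
      }
      first <- which(abs(tw$onset - ons[1]) < 1e-9)
      expect_equal(tw$value[first], 0)   # no association before first pairing
    }
  }
  expect_true(found_flip)
})

test_that("state trials have Exp-shifted gaps, one-hot targets, 2-s pulses", {
  a <- tiny_arch(d_ext = 5)
  set.seed(6)
  gaps <- unlist(replicate(150, {
    tr <- make_state_trial(a, list(conditioning = FALSE))
    diff(tr$meta$transition_times)
  }))
  expect_gt(length(gaps), 500)
  expect_gte(min(gaps), 10)                 # support of 10 (1 + Exp)
  expect_equal(mean(gaps), 20, tolerance = 1.5)

  tr <- make_state_trial(a)
  rt <- render_trial(tr, a)
  expect_true(all(colSums(rt$state_target) == 1))
  expect_true(all(rt$state_target %in% c(0, 1)))
  # pulse channels are silent outside 2-s pulses
  pulse_steps <- colSums(rt$ext[1:3, , drop = FALSE] > 0)
  n_trans <- length(tr$meta$transition_times)
  expect_equal(sum(pulse_steps), n_trans * 4)  # 2 s / 0.5 s = 4 steps each
})

test_that("fixed-bank probe trials split probes evenly with correct targets", {
  a <- tiny_arch()
  set.seed(7)
  bank <- odor_bank(5, a$n_kc)
  same <- logical(400)
  for (i in seq_along(same)) {
    tr <- make_nonplastic_env_trial(bank, a, list(valence = 1))
    same[i] <- tr$meta$probe_same
    expect_equal(tr$target_windows$value,
                 if (tr$meta$probe_same) 1 else 0)
    ons <- vapply(tr$intervals[[1]]$events, `[[`, numeric(1), "onset")
    expect_equal(ons, c(5, 7, 15))
  }
  expect_equal(mean(same), 0.5, tolerance = 0.08)
})

test_that("rendering is deterministic and resets restore rates mid-trial", {
  a <- tiny_arch()
  set.seed(8)
  tr <- make_conditioning_trial("first_order", a, list(omission_prob = 0))
  r1 <- render_trial(tr, a)
  r2 <- render_trial(tr, a)
  expect_identical(r1, r2)
  expect_equal(sum(r1$reset), length(tr$intervals))

  # splice check: running interval 2 from a fresh rate state with carried
  # plastic weights/traces reproduces the full-trial rates
  p <- random_params(a, seed = 9)
  full <- unroll(p, r1)
  Tn <- r1$T; T1 <- Tn / 2
  cut <- function(x, idx) x[, idx, drop = FALSE]
  part1 <- mbplast:::cpp_run_trial(
    mbplast:::par_to_cpp(p), cut(r1$kc, 1:T1), cut(r1$ext, 1:T1),
    cut(r1$target, 1:T1), NULL, r1$reset[1:T1], rep(1, T1),
    matrix(0.05, a$n_mbon, a$n_kc), matrix(0.05, a$n_mbon, a$n_kc),
    rep(0, a$n_kc), rep(0, a$n_dan), TRUE, TRUE, 0.1, 0.1, FALSE, TRUE, TRUE)
  part2 <- mbplast:::cpp_run_trial(
    mbplast:::par_to_cpp(p), cut(r1$kc, (T1 + 1):Tn),
    cut(r1$ext, (T1 + 1):Tn), cut(r1$target, (T1 + 1):Tn), NULL,
    r1$reset[(T1 + 1):Tn], rep(1, Tn - T1), part1$w_final,
    part1$weff_final, part1$trace_kc_final, part1$trace_dan_final,
    TRUE, TRUE, 0.1, 0.1, FALSE, TRUE, TRUE)
  expect_equal(part2$rates, full$rates[, (T1 + 1):Tn], tolerance = 1e-12)
})
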