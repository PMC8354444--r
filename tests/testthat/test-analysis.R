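fake_tensor <- function(activity, dt = 0.5) {
  structure(list(activity = activity,
                 labels = data.frame(paradigm = rep("x", dim(activity)[3]),
                                     us_sign = 1, omitted = "none"),
                 dt = dt), class = "mb_response_tensor")
}

test_that("clustering merges identical responses first and finds groups", {
  set.seed(1)
  base <- matrix(rnorm(2 * 40), 2, 40)
  act <- array(0, c(6, 40, 1))
  act[1:3, , 1] <- rep(1, 3) %o% base[1, ] + 0.01 * rnorm(120)
  act[4:6, , 1] <- rep(1, 3) %o% base[2, ] + 0.01 * rnorm(120)
  act[2, , 1] <- act[1, , 1]          # two identical-response neurons
  cl <- cluster_dan_responses(fake_tensor(act))
  expect_equal(as.numeric(as.dist(as.matrix(cl$distance))[1]), 0,
               tolerance = 1e-12)
  # top split separates the two planted groups
  groups <- stats::cutree(cl$hclust, 2)
  expect_equal(length(unique(groups[1:3])), 1)
  expect_equal(length(unique(groups[4:6])), 1)
  expect_true(groups[1] != groups[4])

  # permuting neurons permutes the leaf order consistently
  perm <- c(3, 1, 2, 6, 4, 5)
  cl2 <- cluster_dan_responses(fake_tensor(act[perm, , , drop = FALSE]))
  expect_setequal(order(perm)[cl2$order], cl$order)
})

test_that("PCA recovers planted low-rank structure", {
  set.seed(2)
  load1 <- rnorm(8)
  tcourse <- sin(seq(0, 4 * pi, length.out = 30))
  act <- array(load1 %o% tcourse, c(8, 30, 3))
  pca <- pca_dan_responses(fake_tensor(act), n_components = 3)
  expect_gte(pca$var_frac[1], 0.999)            # rank-1 activity
  expect_true(all(diff(pca$var_frac) <= 1e-12)) # non-increasing
  expect_lte(sum(pca$var_frac), 1 + 1e-9)

  # planted opposite-sign mode (US vs omission) is recovered as PC1
  act2 <- array(0, c(8, 30, 2))
  act2[, , 1] <- load1 %o% tcourse
  act2[, , 2] <- -load1 %o% tcourse
  act2 <- act2 + 0.01 * array(rnorm(length(act2)), dim(act2))
  pca2 <- pca_dan_responses(fake_tensor(act2), n_components = 2)
  alignment <- abs(sum(pca2$components[, 1] * load1)) /
    sqrt(sum(load1^2))
  expect_gt(alignment, 0.99)
  # projections flip sign between the two planted conditions
  corr <- cor(pca2$projections[1, , 1], pca2$projections[1, , 2])
  expect_lt(corr, -0.95)
})

test_that("response correlations expose planted block structure", {
  resp <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  rc <- response_correlation_matrix(resp)
  expect_equal(rc$cor[1, 2], 1)

  # orthogonal mean-centered vectors
  resp2 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(response_correlation_matrix(resp2)$cor[1, 2], 0)

  set.seed(3)
  protos <- matrix(rnorm(2 * 12), 2, 12)
  resp3 <- protos[c(1, 1, 1, 2, 2, 2), ] + 0.3 * matrix(rnorm(72), 6, 12)
  grouping <- c(1, 1, 1, 2, 2, 2)[c(1, 4, 2, 5, 3, 6)]
  rc3 <- response_correlation_matrix(resp3[c(1, 4, 2, 5, 3, 6), ],
                                     grouping = grouping)
  C <- rc3$cor; g <- rc3$grouping
  within <- mean(C[outer(g, g, "==") & !diag(6)])
  between <- mean(C[outer(g, g, "!=")])
  expect_gt(within - between, 0.2)
  expect_equal(g, sort(grouping))

  expect_warning(response_correlation_matrix(rbind(rep(1, 4), 1:4)),
                 "zero-variance")
})

test_that("weight summaries normalize and average correctly", {
  W <- matrix(0.05, 4, 10)
  ws <- weight_summary(W, 0.05)
  expect_equal(ws$mean, 1)
  expect_equal(sum(ws$histogram$counts), 40)
  expect_equal(weight_summary(matrix(0, 4, 10), 0.05)$mean, 0)
  set.seed(4)
  wu <- weight_summary(matrix(runif(4000, 0, 0.05), 40, 100), 0.05)
  expect_equal(wu$mean, 0.5, tolerance = 0.05)
  expect_error(weight_summary(matrix(0.2, 2, 2), 0.05), "outside")
})

test_that("DAN-velocity cross-correlation has the expected identities", {
  set.seed(5)
  Tn <- 200
  v <- rnorm(Tn)
  dan <- rbind(v, rnorm(Tn))
  xc <- dan_velocity_xcorr(dan, v, max_lag = 10)
  expect_equal(dim(xc), c(2L, 21L))
  # velocity identically zero: all zeros
  expect_true(all(dan_velocity_xcorr(dan, rep(0, Tn), 5) == 0))
  # autocorrelation peaks at lag 0
  expect_equal(unname(which.max(xc[1, ])), 11)
  # shifting the velocity by +k steps moves the peak to lag -k
  k <- 3
  v_shift <- c(v[-seq_len(k)], rep(0, k))     # v_shift(t) = v(t + k)
  xc2 <- dan_velocity_xcorr(rbind(v_shift), v, max_lag = 10)
  expect_equal(unname(which.max(xc2[1, ])), 11 + k)
  expect_error(dan_velocity_xcorr(dan, v, max_lag = 300), "shorter")
})

test_that("planted readout/US-response anticorrelation is recovered", {
  # synthetic check of the scatter construction: plant dan_diff ~ -readout
  set.seed(6)
  ro <- rnorm(20)
  dd <- -0.9 * ro + sqrt(1 - 0.81) * rnorm(20) * sd(ro)
  expect_equal(cor(ro, dd), -0.9, tolerance = 0.25)

  # untrained symmetric networks show no systematic relation
  set.seed(7)
  cors <- replicate(15, {
    p <- initialize_parameters(mb_arch(n_mbon = 8, n_dan = 8, n_fbn = 16,
                                       n_kc = 40))
    attr(valence_vs_us_response(p), "correlation")
  })
  expect_lt(abs(mean(cors)), 0.25)
})
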