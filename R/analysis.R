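#' Record population activity over random test trials
#'
#' Simulates fresh conditioning trials with frozen parameters and collects
#' firing rates into a neurons x timesteps x trials array, with per-trial
#' labels (paradigm, US sign, omitted stimulus). Used as input for the
#' clustering and principal-component analyses of dopamine-neuron activity.
#'
#' @param params an \code{mb_params} (or \code{mb_model}).
#' @param n_trials number of trials (50).
#' @param paradigms trial families sampled uniformly.
#' @param neurons \code{"dan"}, \code{"mbon"} or \code{"all"} rows.
#' @param omission_prob per-trial omission probability (0.5, matching the
#'   optimization distribution so omission responses are represented).
#' @param seed trial-stream seed.
#' @return an object of class \code{mb_response_tensor}: list with
#'   \code{activity}, \code{labels}, \code{dt}.
#' @export
response_tensor <- function(params, n_trials = 50,
                            paradigms = c("extinction", "second_order"),
                            neurons = c("dan", "mbon", "all"),
                            omission_prob = 0.5, seed = 1) {
  if (inherits(params, "mb_model")) params <- params$params
  neurons <- match.arg(neurons)
  arch <- params$arch
  set.seed(derive_seed(seed, "tensor"))
  idx <- switch(neurons, dan = arch$idx_dan, mbon = arch$idx_mbon,
                all = seq_len(arch$n))
  acts <- vector("list", n_trials)
  labels <- data.frame(paradigm = character(n_trials),
                       us_sign = numeric(n_trials),
                       omitted = character(n_trials))
  for (i in seq_len(n_trials)) {
    pg <- if (length(paradigms) == 1) paradigms else sample(paradigms, 1)
    trial <- make_conditioning_trial(pg, arch,
                                     list(omission_prob = omission_prob))
    res <- unroll(params, trial)
    acts[[i]] <- res$rates[idx, , drop = FALSE]
    labels$paradigm[i] <- pg
    labels$us_sign[i] <- trial$meta$us_sign
    labels$omitted[i] <- trial$meta$omitted
  }
  Tn <- min(vapply(acts, ncol, integer(1)))
  activity <- array(0, c(length(idx), Tn, n_trials))
  for (i in seq_len(n_trials)) activity[, , i] <- acts[[i]][, seq_len(Tn)]
  structure(list(activity = activity, labels = labels, dt = arch$dt),
            class = "mb_response_tensor")
}

flatten_tensor <- function(tensor) {
  d <- dim(tensor$activity)
  matrix(tensor$activity, d[1], d[2] * d[3])
}

#' Hierarchical clustering of dopamine-neuron responses
#'
#' Agglomerative clustering on the Euclidean distances between the
#' concatenated per-neuron firing-rate vectors across trials; the returned
#' leaf order is used to sort heatmap rows by response similarity.
#'
#' @param tensor an \code{mb_response_tensor} (DAN activity).
#' @param linkage linkage method passed to \code{\link[stats]{hclust}}
#'   (average by default).
#' @return list with \code{order} (leaf order), \code{hclust} (the tree)
#'   and \code{distance} (the distance matrix).
#' @export
cluster_dan_responses <- function(tensor, linkage = "average") {
  X <- flatten_tensor(tensor)
  if (nrow(X) < 2) stop("need at least 2 neurons to cluster")
  D <- dist(X)
  hc <- hclust(D, method = linkage)
  list(order = hc$order, hclust = hc, distance = D)
}

#' Principal components of dopamine-neuron population activity
#'
#' PCA of mean-centered population activity (observations = timepoints
#' across trials, variables = neurons; no variance scaling since all rates
#' share units). Returns the neuron loadings, per-trial time courses of the
#' projections, and explained-variance fractions.
#'
#' @param tensor an \code{mb_response_tensor}.
#' @param n_components number of components to keep.
#' @return list with \code{components} (neurons x k), \code{projections}
#'   (k x time x trials), \code{var_frac}.
#' @export
pca_dan_responses <- function(tensor, n_components = 5) {
  d <- dim(tensor$activity)
  n_components <- min(n_components, d[1])
  X <- t(flatten_tensor(tensor))          # observations x neurons
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  proj <- array(t(pc$x[, seq_len(k), drop = FALSE]), c(k, d[2], d[3]))
  list(components = pc$rotation[, seq_len(k), drop = FALSE],
       projections = proj,
       var_frac = pc$sdev^2 / sum(pc$sdev^2))
}

#' Pearson correlation matrix of stimulus-evoked MBON responses
#'
#' Correlations between time-averaged output-neuron response vectors for
#' pairs of stimuli, optionally ordered by a grouping label (e.g. the state
#' transition that followed each stimulus's first presentation). Stimuli
#' whose response vector has zero variance yield NA entries with a warning.
#'
#' @param responses stimuli x neurons matrix of time-averaged MBON rates.
#' @param grouping optional per-stimulus labels used to order rows/columns.
#' @return list with \code{cor} (the ordered correlation matrix),
#'   \code{order}, \code{grouping} (ordered labels).
#' @export
response_correlation_matrix <- function(responses, grouping = NULL) {
  if (nrow(responses) < 2) stop("need at least 2 stimuli")
  v <- apply(responses, 1, sd)
  if (any(v == 0)) warning("zero-variance response vector(s); NA entries")
  ord <- if (!is.null(grouping)) order(grouping) else seq_len(nrow(responses))
  C <- suppressWarnings(cor(t(responses[ord, , drop = FALSE])))
  list(cor = C, order = ord,
       grouping = if (!is.null(grouping)) grouping[ord])
}

#' Summary of the KC-to-MBON weight distribution
#'
#' Histogram and mean of the weights normalized to their maximum value,
#' as used to compare continual-learning networks with and without
#' non-specific potentiation.
#'
#' @param W weight matrix (entries in \code{[0, w_max]}).
#' @param w_max maximum weight used for normalization.
#' @param breaks histogram breaks on the normalized scale.
#' @return list with \code{histogram} (a \code{hist} object on W/w_max),
#'   \code{mean} (normalized mean), \code{normalized} (the values).
#' @export
weight_summary <- function(W, w_max = 0.05, breaks = seq(0, 1, by = 0.05)) {
  x <- as.numeric(W) / w_max
  if (any(x < -1e-9 | x > 1 + 1e-9)) stop("weights outside [0, w_max]")
  x <- pmin(pmax(x, 0), 1)
  list(histogram = graphics::hist(x, breaks = breaks, plot = FALSE),
       mean = mean(x), normalized = x)
}

#' Cross-correlation between DAN activity and movement
#'
#' Lagged product expectations E[d(t) v(t + lag)] between each
#' dopamine-neuron rate series and a velocity series (forward or angular)
#' over a navigation phase.
#'
#' @param dan n_dan x T matrix of DAN rates.
#' @param velocity length-T velocity series.
#' @param max_lag maximum lag in steps.
#' @return matrix n_dan x (2 max_lag + 1); columns named by lag.
#' @export
dan_velocity_xcorr <- function(dan, velocity, max_lag = 20) {
  Tn <- length(velocity)
  if (ncol(dan) != Tn) stop("series misaligned")
  if (Tn <= max_lag) stop("series shorter than max_lag")
  lags <- -max_lag:max_lag
  out <- matrix(0, nrow(dan), length(lags),
                dimnames = list(NULL, lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    if (k >= 0) {
      t_idx <- seq_len(Tn - k)
      out[, j] <- dan[, t_idx, drop = FALSE] %*%
        velocity[t_idx + k] / length(t_idx)
    } else {
      t_idx <- (1 - k):Tn
      out[, j] <- dan[, t_idx, drop = FALSE] %*%
        velocity[t_idx + k] / length(t_idx)
    }
  }
  out
}

#' Per-compartment readout weight versus differential US response
#'
#' Presents an isolated positive-valence US and an isolated negative-valence
#' US to the frozen network and measures each DAN's mean rate during the US
#' window; pairs the per-compartment (US+ minus US-) DAN response with the
#' compartment's valence-readout weight. In trained conditioning networks
#' the two are anticorrelated: compartments whose MBONs push the readout
#' negative have DANs tuned to positive US (learning by depression).
#'
#' @param params an \code{mb_params} (or \code{mb_model}).
#' @param us_onset US onset within the probe interval (s).
#' @return data frame with columns \code{compartment},
#'   \code{readout_weight}, \code{dan_diff}, plus the Pearson correlation
#'   as attribute \code{"correlation"}.
#' @export
valence_vs_us_response <- function(params, us_onset = 5) {
  if (inherits(params, "mb_model")) params <- params$params
  arch <- params$arch
  probe <- function(sgn) {
    trial <- new_trial("us_probe",
      intervals = list(list(duration = 30, reset = TRUE,
                            events = list(us_event(us_onset, sgn, 2)))),
      patterns = matrix(0, 0, arch$n_kc),
      target_windows = data.frame(interval = numeric(0), onset = numeric(0),
                                  duration = numeric(0), value = numeric(0)),
      score_windows = data.frame(interval = numeric(0), onset = numeric(0),
                                 duration = numeric(0)))
    res <- unroll(params, trial)
    win <- res$rendered$times >= us_onset &
      res$rendered$times < us_onset + 2
    rowMeans(res$rates[arch$idx_dan, win, drop = FALSE])
  }
  diff_dan <- probe(+1) - probe(-1)
  cm <- compartment_map(arch)
  dan_by_comp <- tapply(diff_dan, cm$dan, mean)
  ro_by_comp <- tapply(params$W_readout[1, ], cm$mbon, sum)
  df <- data.frame(compartment = as.integer(names(dan_by_comp)),
                   readout_weight = as.numeric(ro_by_comp),
                   dan_diff = as.numeric(dan_by_comp))
  attr(df, "correlation") <- suppressWarnings(
    cor(df$readout_weight, df$dan_diff))
  df
}

#' Stimulus/state-transition imprinting of MBON responses
#'
#' For a state-tracking network: presents probe stimuli shortly before a
#' state transition and re-presents them later, then correlates the
#' time-averaged MBON responses to the re-presentations across probes,
#' grouped by the state each probe preceded. Stimuli that predicted the
#' same transition evoke similar responses (block structure).
#'
#' @param params an \code{mb_params} (or \code{mb_model}) trained on the
#'   state task.
#' @param n_probes number of probe stimuli (50).
#' @param seed probe-stream seed.
#' @return list with the ordered correlation matrix (\code{cor}),
#'   \code{labels} (predicted state per probe, ordered), and
#'   \code{within_minus_between} (mean within-group minus between-group
#'   correlation).
#' @export
state_probe_correlations <- function(params, n_probes = 50, seed = 1) {
  if (inherits(params, "mb_model")) params <- params$params
  arch <- params$arch
  set.seed(derive_seed(seed, "state-probe"))
  resp <- NULL; labs <- integer(0)
  i <- 0
  while (i < n_probes) {
    trial <- make_state_trial(arch, list(probe = TRUE))
    if (is.null(trial$meta$probe_windows)) next   # needs >= 2 transitions
    i <- i + 1
    res <- unroll(params, trial)
    w2 <- trial$meta$probe_windows$second
    win <- res$rendered$times >= w2[1] & res$rendered$times < w2[2]
    resp <- rbind(resp, rowMeans(res$rates[arch$idx_mbon, win,
                                           drop = FALSE]))
    labs <- c(labs, trial$meta$probe_next_state)
  }
  rcm <- response_correlation_matrix(resp, grouping = labs)
  C <- rcm$cor
  g <- rcm$grouping
  same <- outer(g, g, "==") & !diag(length(g))
  diffm <- outer(g, g, "!=")
  list(cor = C, labels = g,
       within_minus_between = mean(C[same], na.rm = TRUE) -
         mean(C[diffm], na.rm = TRUE))
}
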