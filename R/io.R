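## serialization and command-line glue

FORMAT_VERSION <- "1.0"

#' Serialize circuit parameters to JSON
#'
#' Writes all parameter arrays (with shapes), the architecture scalars, the
#' plasticity constants and a format version to a single JSON document at
#' full precision, so parameters round-trip exactly.
#'
#' @param params an \code{mb_params}.
#' @param path output file path (.json).
#' @return the path, invisibly.
#' @export
write_mb_params <- function(params, path) {
  a <- params$arch
  doc <- list(
    format_version = FORMAT_VERSION,
    arch = list(n_mbon = a$n_mbon, n_dan = a$n_dan, n_fbn = a$n_fbn,
                n_kc = a$n_kc, n_compartments = a$n_compartments,
                tau = a$tau, dt = a$dt, w_max = a$w_max,
                d_ext = a$d_ext, d_readout = a$d_readout),
    plasticity = unclass(params$plasticity),
    arrays = list(W = params$W, b = params$b, W_ext = params$W_ext,
                  W_readout = params$W_readout,
                  W_state = params$W_state, beta = params$beta,
                  W_km = params$W_km),
    velocity = params$velocity)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read circuit parameters from JSON
#'
#' @param path a file written by \code{\link{write_mb_params}}.
#' @return an \code{mb_params}.
#' @export
read_mb_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format_version, FORMAT_VERSION))
    stop("unsupported parameter-file version: ", doc$format_version)
  a <- doc$arch
  arch <- mb_arch(a$n_mbon, a$n_dan, a$n_fbn, a$n_kc, a$n_compartments,
                  a$tau, a$dt, a$w_max, a$d_ext, a$d_readout)
  pc <- do.call(plasticity_config, doc$plasticity)
  ar <- doc$arrays
  vel <- doc$velocity
  if (!is.null(vel))
    vel <- list(W_u = as.numeric(vel$W_u), b_u = vel$b_u,
                W_omega = as.numeric(vel$W_omega), b_omega = vel$b_omega)
  mb_params(arch, W = ar$W, b = ar$b, W_ext = ar$W_ext,
            W_readout = ar$W_readout, W_state = ar$W_state,
            beta = ar$beta, velocity = vel, plasticity = pc,
            W_km = ar$W_km)
}

#' Serialize a trial for exact replay
#'
#' Writes the full trial specification (intervals and events, odor
#' patterns, target and score windows, state track and metadata) to JSON;
#' \code{read_mb_trial} reconstructs a trial that renders identically.
#'
#' @param trial an \code{mb_trial}.
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
write_mb_trial <- function(trial, path) {
  doc <- unclass(trial)
  doc$n_kc <- ncol(trial$patterns)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mb_trial
#' @export
read_mb_trial <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  col <- function(rows, field)
    vapply(rows, function(r) as.numeric(r[[field]]), numeric(1))
  n_kc <- as.integer(doc$n_kc)
  patterns <- if (length(doc$patterns) == 0) matrix(0, 0, n_kc)
  else do.call(rbind, lapply(doc$patterns, function(r)
    as.numeric(unlist(r))))
  tw <- tw_frame(col(doc$target_windows, "interval"),
                 col(doc$target_windows, "onset"),
                 col(doc$target_windows, "duration"),
                 col(doc$target_windows, "value"))
  sw <- sw_frame(col(doc$score_windows, "interval"),
                 col(doc$score_windows, "onset"),
                 col(doc$score_windows, "duration"))
  st <- doc$state_track
  if (!is.null(st))
    st <- list(times = as.numeric(unlist(st$times)),
               states = as.integer(unlist(st$states)))
  structure(list(
    paradigm = doc$paradigm,
    intervals = lapply(doc$intervals, function(iv)
      list(duration = as.numeric(iv$duration), reset = isTRUE(iv$reset),
           events = lapply(iv$events, function(e) e))),
    patterns = patterns,
    target_windows = tw, score_windows = sw,
    novelty_windows = doc$novelty_windows,
    state_track = st, meta = doc$meta), class = "mb_trial")
}

#' Export rendered trial traces to CSV
#'
#' One row per timestep: time, summed Kenyon-cell drive, each external
#' input channel, each target row, the reset flag and the scored-window
#' flag.
#'
#' @param trial an \code{mb_trial}.
#' @param arch an \code{\link{mb_arch}}.
#' @param path output .csv path.
#' @return the path, invisibly.
#' @export
write_trial_traces_csv <- function(trial, arch, path) {
  rt <- render_trial(trial, arch)
  df <- data.frame(t = rt$times, kc_drive = colSums(rt$kc))
  for (i in seq_len(nrow(rt$ext)))
    df[[paste0("ext", i)]] <- rt$ext[i, ]
  for (i in seq_len(nrow(rt$target)))
    df[[paste0("target", i)]] <- rt$target[i, ]
  df$reset <- rt$reset
  df$scored <- rt$score
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## --- run configuration -------------------------------------------------------

run_config_keys <- c("task", "seed", "arch", "training", "plasticity",
                     "trial_options", "output_dir")

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON with top-level blocks \code{task},
#' \code{seed}, and optional \code{arch}, \code{training},
#' \code{plasticity}, \code{trial_options} and \code{output_dir}. Unknown
#' top-level keys are rejected.
#'
#' @param path configuration file (.yaml/.yml or .json).
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in c("task", "seed"))
    if (is.null(cfg[[key]]))
      stop("missing required configuration key: ", key)
  cfg
}

config_hash <- function(cfg) {
  # FNV-1a over the canonical JSON serialization
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (byte in utf8ToInt(as.character(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(byte))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## --- CLI entry points --------------------------------------------------------

#' Train a model from a configuration file
#'
#' Reads a run configuration, fits the model and writes artifacts into the
#' output directory: trained parameters (\code{params.json}), the per-epoch
#' loss curve (\code{loss.csv}) and the resolved configuration with its
#' hash and seed (\code{run_meta.json}).
#'
#' @param config_path configuration file.
#' @param output_dir output directory (defaults to the configuration's
#'   \code{output_dir} or the current directory).
#' @return the fitted \code{mb_model}, invisibly.
#' @export
cli_train <- function(config_path, output_dir = NULL) {
  cfg <- read_run_config(config_path)
  output_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  arch <- if (!is.null(cfg$arch)) do.call(mb_arch, cfg$arch)
  args <- c(list(task = cfg$task, arch = arch, seed = cfg$seed),
            cfg$training %||% list())
  if (!is.null(cfg$trial_options)) args$trial_options <- cfg$trial_options
  model <- do.call(mb_fit, args)
  write_mb_params(model$params, file.path(output_dir, "params.json"))
  lh <- model$loss_history
  lh$epoch <- seq_len(nrow(lh))
  write.csv(lh, file.path(output_dir, "loss.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg, config_hash = config_hash(cfg), seed = cfg$seed,
         resolved = model$config, task = model$task,
         diverged = model$diverged),
    file.path(output_dir, "run_meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(model)
}

#' Evaluate stored parameters on a test paradigm
#'
#' Writes a per-trial error table and a one-row summary CSV.
#'
#' @param params_path parameters file from \code{\link{write_mb_params}}.
#' @param paradigm test paradigm.
#' @param n_trials number of test trials.
#' @param seed test-stream seed.
#' @param output_csv output CSV path.
#' @param threshold error threshold (paradigm default when NULL).
#' @return the summary data frame, invisibly.
#' @export
cli_evaluate <- function(params_path, paradigm = "first_order",
                         n_trials = 50, seed = 1,
                         output_csv = "evaluation.csv", threshold = NULL) {
  params <- read_mb_params(params_path)
  threshold <- threshold %||% (if (paradigm == "continual") 0.5 else 0.2)
  ev <- evaluate_error_rate(params, paradigm, n_trials, threshold, seed)
  per_trial <- data.frame(trial = seq_len(n_trials),
                          error = if (n_trials) ev$errors else logical(0))
  write.csv(per_trial, sub("\\.csv$", "_trials.csv", output_csv),
            row.names = FALSE)
  summary <- data.frame(paradigm = paradigm, n_trials = n_trials,
                        threshold = threshold,
                        error_rate = ev$error_rate, seed = seed,
                        config_hash = config_hash(list(
                          params = params_path, paradigm = paradigm,
                          n_trials = n_trials, seed = seed)))
  write.csv(summary, output_csv, row.names = FALSE)
  invisible(summary)
}

#' Run a named analysis and write its outputs
#'
#' Analyses: \code{"pairing_curve"} (timing-dependence of the plasticity
#' rule), \code{"pca"} and \code{"cluster"} (dopamine-neuron population
#' analyses over fresh test trials of stored parameters),
#' \code{"weights"} (weight-distribution summary after a continual
#' sequence). Matrices go to CSV; a PNG figure is written alongside.
#'
#' @param params_path parameters file (ignored by \code{pairing_curve}).
#' @param analysis analysis name.
#' @param output_dir output directory.
#' @param n_trials trials used by the population analyses.
#' @param seed trial-stream seed.
#' @return invisibly, the analysis result object.
#' @export
cli_analyze <- function(params_path, analysis = c("pairing_curve", "pca",
                                                  "cluster", "weights"),
                        output_dir = ".", n_trials = 50, seed = 1) {
  analysis <- match.arg(analysis)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  if (analysis == "pairing_curve") {
    pc <- pairing_curve(plasticity_config())
    write.csv(pc, out("pairing_curve.csv"), row.names = FALSE)
    grDevices::png(out("pairing_curve.png"), 600, 400)
    plot(pc$delta_t_s, pc$delta_w, type = "l",
         xlab = "lag (s, DAN onset - KC onset)",
         ylab = expression(Delta * w))
    abline(h = 0, lty = 2)
    grDevices::dev.off()
    return(invisible(pc))
  }
  params <- read_mb_params(params_path)
  if (analysis == "weights") {
    set.seed(derive_seed(seed, "weights"))
    trial <- make_continual_sequence(params$arch)
    res <- unroll(params, trial)
    ws <- weight_summary(res$w_final, params$plasticity$w_max)
    write.csv(data.frame(mid = ws$histogram$mids,
                         density = ws$histogram$density),
              out("weight_histogram.csv"), row.names = FALSE)
    return(invisible(ws))
  }
  tensor <- response_tensor(params, n_trials = n_trials, seed = seed)
  if (analysis == "pca") {
    pca <- pca_dan_responses(tensor)
    write.csv(as.data.frame(pca$components), out("pca_components.csv"),
              row.names = FALSE)
    write.csv(data.frame(component = seq_along(pca$var_frac),
                         var_frac = pca$var_frac),
              out("pca_variance.csv"), row.names = FALSE)
    return(invisible(pca))
  }
  cl <- cluster_dan_responses(tensor)
  write.csv(data.frame(leaf = seq_along(cl$order), neuron = cl$order),
            out("cluster_order.csv"), row.names = FALSE)
  invisible(cl)
}
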