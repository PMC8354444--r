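#' Two-source odor-plume environment
#'
#' Two odor sources, one rewarded and one neutral, placed at horizontal
#' positions x1 = -1 m and +1 m (random side assignment) with vertical
#' positions drawn uniformly on [0, 2] m subject to a minimum spacing of
#' 0.5 m. Each source carries a unit wind vector parallel to the x1 axis and
#' oriented so its plume extends from the source toward the origin; plumes
#' occupy a band of total height 0.5 m centered on the source.
#'
#' @param min_spacing minimum vertical spacing between the sources (m).
#' @return an object of class \code{nav_environment} with fields
#'   \code{sources} (2 x 2 matrix, one column per source), \code{rewarded}
#'   (index of the rewarded source), \code{wind_x1} (per-source wind x1
#'   component) and \code{half_height}.
#' @export
nav_environment <- function(min_spacing = 0.5) {
  side <- sample(c(-1, 1), 2)          # random side assignment
  repeat {
    x2 <- runif(2, 0, 2)
    if (abs(diff(x2)) >= min_spacing) break
  }
  structure(list(
    sources = rbind(side, x2),
    rewarded = sample(2, 1),
    wind_x1 = -side,                   # plume extends toward the origin
    half_height = 0.25), class = "nav_environment")
}

#' Odor concentration at a position
#'
#' For each source, positions downwind of the source and within its 0.5-m
#' plume band have concentration
#' \code{c = 1/(1 + 0.5 dx1) * exp(-dx2^2 / (0.1 dx1))}, where \code{dx1}
#' is the downwind and \code{dx2} the vertical displacement from the source;
#' elsewhere the concentration is 0. The \code{dx1 = 0} limit is 1 exactly
#' at the source and 0 off-axis.
#'
#' @param env a \code{nav_environment}.
#' @param position numeric length-2 position (m).
#' @return numeric vector of per-source concentrations (rewarded source
#'   first is \emph{not} implied; order follows \code{env$sources}).
#' @export
concentration <- function(env, position) {
  stopifnot(all(is.finite(position)))
  vapply(1:2, function(s) {
    dx1 <- (position[1] - env$sources[1, s]) * env$wind_x1[s]
    dx2 <- position[2] - env$sources[2, s]
    if (dx1 < 0 || abs(dx2) > env$half_height) return(0)
    if (dx1 == 0) return(if (dx2 == 0) 1 else 0)
    1 / (1 + 0.5 * dx1) * exp(-dx2^2 / (0.1 * dx1))
  }, numeric(1))
}

#' Agent state
#'
#' @param position length-2 position (m).
#' @param heading heading angle in radians, wrapped to (-pi, pi].
#' @param u forward velocity (m/s).
#' @param omega angular velocity (rad/s).
#' @return an object of class \code{agent_state}.
#' @export
agent_state <- function(position = c(0, 0), heading = pi / 2, u = 0,
                        omega = 0) {
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading), u = u, omega = omega),
            class = "agent_state")
}

wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

#' Egocentric wind input
#'
#' Four rectified projections of the active wind vector onto the agent-frame
#' unit vectors (anterior, posterior, left, right); at most two entries are
#' nonzero. The active wind is that of the plume with the highest local
#' concentration; when the agent is outside both plumes the input is zero.
#'
#' @param env a \code{nav_environment}.
#' @param agent an \code{agent_state}.
#' @return numeric 4-vector (anterior, posterior, left, right).
#' @export
wind_input <- function(env, agent) {
  cc <- concentration(env, agent$position)
  if (all(cc == 0)) return(numeric(4))
  s <- which.max(cc)
  w <- c(env$wind_x1[s], 0)
  th <- agent$heading
  h <- list(c(cos(th), sin(th)), c(-cos(th), -sin(th)),
            c(-sin(th), cos(th)), c(sin(th), -cos(th)))
  vapply(h, function(hi) max(sum(w * hi), 0), numeric(1))
}

#' Euler step of the agent kinematics
#'
#' Heading first (\code{theta <- theta + dt * omega}), then position along
#' the new heading (\code{x <- x + dt * u (cos theta, sin theta)}).
#'
#' @param agent an \code{agent_state}.
#' @param u forward velocity (m/s).
#' @param omega angular velocity (rad/s).
#' @param dt timestep (s).
#' @return the updated \code{agent_state}.
#' @export
step_agent <- function(agent, u, omega, dt) {
  stopifnot(dt > 0)
  th <- agent$heading + dt * omega
  agent$position <- agent$position + dt * u * c(cos(th), sin(th))
  agent$heading <- wrap_angle(th)
  agent$u <- u
  agent$omega <- omega
  agent
}

#' Run one conditioned-navigation trial
#'
#' A 20-s conditioning interval in which the rewarded odor is paired with a
#' weak US (amplitude 0.1) at t = 2 s, followed by a 200-s navigation
#' interval during which Kenyon-cell drive equals the odor patterns scaled
#' by the local plume concentrations, external input carries the egocentric
#' wind direction (US channels silent), and forward/angular velocities are
#' read out from the feedback neurons (forward velocity through a Softplus).
#' The agent starts at the origin with heading drawn uniformly on
#' \code{[pi/2 (1-gamma), pi/2 (1+gamma)]}.
#'
#' @param params an \code{mb_params} with \code{d_ext = 6} and velocity
#'   readouts.
#' @param env a \code{nav_environment}.
#' @param plasticity one of \code{"both"} (dopamine-gated plasticity active
#'   in both phases), \code{"conditioning_only"} (blocked during
#'   navigation), \code{"none"} (blocked throughout).
#' @param gamma heading-randomization half-width (0 to 1).
#' @param options overrides: \code{t_train} (20), \code{t_nav} (200),
#'   \code{us_amplitude} (0.1), \code{cs_onset} (2), \code{theta0}
#'   (explicit initial heading, overrides \code{gamma}), \code{want_grad}.
#' @return list with \code{positions} (T+1 x 2), \code{theta}, \code{u},
#'   \code{omega}, \code{concentration}, \code{rates},
#'   \code{final_distance}, \code{loss} and the environment/patterns used.
#' @export
run_navigation_trial <- function(params, env,
                                 plasticity = c("both", "conditioning_only",
                                                "none"),
                                 gamma = 0.5, options = list()) {
  plasticity <- match.arg(plasticity)
  o <- modifyList(list(t_train = 20, t_nav = 200, us_amplitude = 0.1,
                       cs_onset = 2, theta0 = NULL, want_grad = FALSE,
                       sparsity = 0.1), options)
  arch <- params$arch
  if (arch$d_ext != 6) stop("navigation needs an architecture with d_ext = 6")
  if (is.null(params$velocity)) stop("params lack velocity readouts")
  pat_r <- encode_odor(arch$n_kc, o$sparsity)
  pat_n <- encode_odor(arch$n_kc, o$sparsity)
  theta0 <- o$theta0 %||% runif(1, pi / 2 * (1 - gamma),
                                pi / 2 * (1 + gamma))
  T1 <- as.integer(round(o$t_train / arch$dt))
  times <- (seq_len(T1) - 1) * arch$dt
  kc_train <- matrix(0, arch$n_kc, T1)
  ext_train <- matrix(0, 6, T1)
  cs_idx <- which(times >= o$cs_onset - 1e-9 & times < o$cs_onset + 2 - 1e-9)
  us_idx <- which(times >= o$cs_onset + 2 - 1e-9 &
                    times < o$cs_onset + 4 - 1e-9)
  kc_train[, cs_idx] <- pat_r
  ext_train[1, us_idx] <- o$us_amplitude   # positive-valence US channel
  res <- cpp_run_nav(par_to_cpp(params),
                     kc_train, ext_train,
                     env$sources, env$wind_x1, env$rewarded,
                     pat_r, pat_n, theta0,
                     as.integer(round(o$t_nav / arch$dt)),
                     plastic_train = plasticity != "none",
                     plastic_nav = plasticity == "both",
                     want_grad = isTRUE(o$want_grad), want_traj = TRUE)
  res$env <- env
  res$patterns <- list(rewarded = pat_r, neutral = pat_n)
  res$theta0 <- theta0
  res
}

#' Write a navigation trajectory to CSV
#'
#' @param trial result of \code{\link{run_navigation_trial}}.
#' @param path output CSV path.
#' @param dt timestep used (s).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(trial, path, dt = 0.5) {
  n <- length(trial$u)
  df <- data.frame(
    t = seq_len(n) * dt,
    x1 = trial$positions[-1, 1], x2 = trial$positions[-1, 2],
    theta = trial$theta[-1], u = trial$u, omega = trial$omega,
    c_rewarded = trial$concentration[, trial$env$rewarded],
    c_neutral = trial$concentration[, 3 - trial$env$rewarded])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
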