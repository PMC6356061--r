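#' Specification of a multi-state Brownian trajectory simulation
#'
#' Bundles the generative parameters for [simulate_trajectories()]: a set of
#' diffusive states with diffusion coefficients `D_states` (um^2/s), a
#' per-frame state transition matrix, the frame interval (default 20 ms,
#' i.e. 50 Hz acquisition), isotropic Gaussian localization noise (default
#' 20 nm per coordinate) and a trajectory length law.
#'
#' @param n_traj number of trajectories to simulate.
#' @param frame_interval time between frames in seconds (default 0.02).
#' @param length_law list describing the number of positions per trajectory:
#'   either `list(type = "fixed", length = L)` or
#'   `list(type = "geometric", mean = M, min = m)` (a shifted geometric
#'   distribution with the given mean, truncated below at `min`).
#' @param D_states numeric vector of diffusion coefficients, um^2/s, one per
#'   state.
#' @param transition_matrix row-stochastic K x K matrix of per-frame
#'   state-switch probabilities; defaults to identity (no switching).
#' @param loc_noise_sigma localization noise SD per coordinate, um
#'   (default 0.02).
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `"traj_sim_spec"`.
#' @seealso [simulate_trajectories()]
#' @export
traj_sim_spec <- function(n_traj,
                          frame_interval = 0.02,
                          length_law = list(type = "geometric", mean = 30, min = 5),
                          D_states = 0.1,
                          transition_matrix = NULL,
                          loc_noise_sigma = 0.02,
                          seed = NULL) {
  if (!.is_count(n_traj) || n_traj < 1) stop("n_traj must be a positive count")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (any(D_states < 0)) stop("diffusion coefficients must be >= 0")
  if (loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  K <- length(D_states)
  if (is.null(transition_matrix)) transition_matrix <- diag(K)
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != K)
    stop("transition_matrix dimension must match length(D_states)")
  .check_row_stochastic(transition_matrix)
  if (!length_law$type %in% c("fixed", "geometric"))
    stop("length_law$type must be 'fixed' or 'geometric'")
  if (length_law$type == "fixed" && length_law$length < 2)
    stop("fixed trajectory length must be >= 2")
  if (length_law$type == "geometric") {
    if (is.null(length_law$min)) length_law$min <- 2
    if (length_law$min < 2) stop("minimum trajectory length must be >= 2")
    if (length_law$mean < length_law$min)
      stop("mean trajectory length must be >= the minimum")
  }
  structure(list(n_traj = as.integer(n_traj),
                 frame_interval = frame_interval,
                 length_law = length_law,
                 D_states = D_states,
                 transition_matrix = transition_matrix,
                 loc_noise_sigma = loc_noise_sigma,
                 seed = seed),
            class = "traj_sim_spec")
}

.draw_lengths <- function(law, n) {
  if (law$type == "fixed") return(rep(as.integer(law$length), n))
  # shifted geometric: length = min + G, E[G] = mean - min
  p <- 1 / (law$mean - law$min + 1)
  law$min + stats::rgeom(n, p)
}

#' Simulate multi-state Brownian trajectories with localization noise
#'
#' Positions follow `x[t+1] = x[t] + sqrt(2 * D_s * dt) * eta` independently
#' per axis, where `s` is the hidden diffusive state during the interval
#' starting at position `t`, drawn from the Markov chain of the spec's
#' transition matrix (initial state from its stationary distribution).
#' Observed positions add i.i.d. Gaussian localization noise per coordinate
#' and frame, so the expected single-frame squared displacement is
#' `4*D*dt + 4*sigma^2`.
#'
#' @param spec a [traj_sim_spec()].
#' @return a list with components `tracks` (an object of class `"sm_tracks"`:
#'   a data frame with columns `traj_id`, `frame`, `x`, `y`, `state` and a
#'   `frame_interval` attribute; coordinates in um) and `state_sequences`
#'   (list of per-position integer state vectors; the state at position `t`
#'   governs the step to `t+1`).
#' @examples
#' sim <- simulate_trajectories(traj_sim_spec(3, D_states = 0.1, seed = 1))
#' head(sim$tracks)
#' @export
simulate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "traj_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  K <- length(spec$D_states)
  dt <- spec$frame_interval
  pi0 <- .stationary_distribution(spec$transition_matrix)
  lens <- .draw_lengths(spec$length_law, spec$n_traj)
  total <- sum(lens)
  out <- vector("list", spec$n_traj)
  states_list <- vector("list", spec$n_traj)
  for (i in seq_len(spec$n_traj)) {
    n <- lens[i]
    s <- integer(n)
    s[1L] <- sample.int(K, 1L, prob = pi0)
    if (n > 1L) for (t in 2:n)
      s[t] <- sample.int(K, 1L, prob = spec$transition_matrix[s[t - 1L], ])
    step_sd <- sqrt(2 * spec$D_states[s[-n]] * dt)
    x <- cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd)))
    y <- cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd)))
    if (spec$loc_noise_sigma > 0) {
      x <- x + stats::rnorm(n, 0, spec$loc_noise_sigma)
      y <- y + stats::rnorm(n, 0, spec$loc_noise_sigma)
    }
    out[[i]] <- data.frame(traj_id = i, frame = seq_len(n) - 1L,
                           x = x, y = y, state = s)
    states_list[[i]] <- s
  }
  tracks <- do.call(rbind, out)
  tracks <- sm_tracks(tracks, frame_interval = dt)
  list(tracks = tracks, state_sequences = states_list)
}

#' Trajectory container
#'
#' A thin classed data frame holding one or many trajectories in long format
#' (columns `traj_id`, `frame`, `x`, `y`, optionally `state`), coordinates in
#' um, with the frame interval (s) stored as an attribute. Frames within a
#' trajectory must be strictly increasing.
#'
#' @param df data frame with at least `traj_id`, `frame`, `x`, `y`.
#' @param frame_interval time between consecutive frames, seconds.
#' @return an object of class `"sm_tracks"`.
#' @export
sm_tracks <- function(df, frame_interval) {
  req <- c("traj_id", "frame", "x", "y")
  if (!all(req %in% names(df))) stop("tracks need columns traj_id, frame, x, y")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  df <- df[order(df$traj_id, df$frame), , drop = FALSE]
  bad <- tapply(df$frame, df$traj_id, function(f) any(diff(f) <= 0))
  if (any(unlist(bad))) stop("frames must be strictly increasing within a trajectory")
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("sm_tracks", "data.frame"))
}

#' @export
print.sm_tracks <- function(x, ...) {
  ids <- unique(x$traj_id)
  cat(sprintf("<sm_tracks> %d trajectories, %d localizations, dt = %g s\n",
              length(ids), nrow(x), attr(x, "frame_interval")))
  invisible(x)
}

#' @export
plot.sm_tracks <- function(x, max_traj = 50, ...) {
  ids <- unique(x$traj_id)
  ids <- ids[seq_len(min(length(ids), max_traj))]
  sub <- x[x$traj_id %in% ids, ]
  graphics::plot(sub$x, sub$y, type = "n", xlab = "x (um)", ylab = "y (um)", ...)
  for (id in ids) {
    tr <- sub[sub$traj_id == id, ]
    graphics::lines(tr$x, tr$y, col = grDevices::hcl.colors(length(ids))[match(id, ids)])
  }
  invisible(x)
}

#' Split a track container into per-trajectory data frames
#' @param tracks an `"sm_tracks"` object.
#' @return named list of data frames, one per trajectory.
#' @export
split_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "sm_tracks"))
  split(as.data.frame(tracks), tracks$traj_id)
}
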