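#' Mean squared displacement of a trajectory
#'
#' Time-averaged MSD:
#' `MSD(n*dt) = (1/count_n) * sum_i [(x[i+n]-x[i])^2 + (y[i+n]-y[i])^2]`,
#' over all pairs of localizations separated by `n` frames whose both
#' endpoints exist (`count_n = N - n` for a gapless trajectory of `N`
#' points). Lags with no available pair (inside gaps) are omitted.
#'
#' @param traj a single-trajectory data frame with columns `frame`, `x`, `y`
#'   (um), or an `"sm_tracks"` object (then a list of curves is returned,
#'   one per trajectory).
#' @param frame_interval frame interval in seconds; defaults to the
#'   `frame_interval` attribute for `"sm_tracks"` input.
#' @return an object of class `"msd_curve"`: data frame with columns
#'   `lag` (seconds), `msd` (um^2) and `count` (averaged pairs), with the
#'   frame interval as attribute. For `"sm_tracks"` input, a named list of
#'   such objects.
#' @export
compute_msd <- function(traj, frame_interval = attr(traj, "frame_interval")) {
  if (inherits(traj, "sm_tracks")) {
    return(lapply(split_tracks(traj), compute_msd,
                  frame_interval = frame_interval))
  }
  if (is.null(frame_interval)) stop("frame_interval is required")
  if (nrow(traj) < 2) stop("a trajectory needs at least 2 points")
  f <- as.integer(traj$frame - min(traj$frame))
  n_span <- max(f)
  pos_x <- rep(NA_real_, n_span + 1L); pos_y <- rep(NA_real_, n_span + 1L)
  pos_x[f + 1L] <- traj$x; pos_y[f + 1L] <- traj$y
  lags <- seq_len(n_span)
  msd <- numeric(n_span); cnt <- integer(n_span)
  for (n in lags) {
    i <- seq_len(n_span + 1L - n)
    d2 <- (pos_x[i + n] - pos_x[i])^2 + (pos_y[i + n] - pos_y[i])^2
    ok <- !is.na(d2)
    cnt[n] <- sum(ok)
    msd[n] <- if (cnt[n] > 0) sum(d2[ok]) / cnt[n] else NA_real_
  }
  keep <- cnt > 0
  out <- data.frame(lag = lags[keep] * frame_interval,
                    msd = msd[keep], count = cnt[keep])
  structure(out, frame_interval = frame_interval,
            class = c("msd_curve", "data.frame"))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, dt = %g s, MSD(dt) = %.4g um^2\n",
              nrow(x), attr(x, "frame_interval"), x$msd[1]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag, x$msd, xlab = "lag (s)", ylab = "MSD (um²)",
                 type = "b", ...)
  invisible(x)
}

#' Fit a diffusion coefficient to the initial MSD slope
#'
#' Ordinary least squares of `MSD` against lag time over the first
#' `fit_points` lags (2 to 5), with a free intercept:
#' `MSD(t) = 4 D t + 4 sigma_x^2`, so `D = slope / 4` and
#' `sigma_x = sqrt(max(intercept, 0) / 4)` estimates the one-direction
#' localization accuracy. If `sigma_known` is supplied the intercept is
#' fixed at `4 * sigma_known^2` and only the slope is estimated. A negative
#' fitted slope yields `D = 0` with `immobile = TRUE` rather than an error.
#'
#' @param msd an `"msd_curve"`.
#' @param fit_points number of initial lags used, between 2 and 5
#'   (default 4).
#' @param sigma_known optional known localization accuracy (um) fixing the
#'   intercept.
#' @return an object of class `"diffusion_fit"` with fields `D` (um^2/s),
#'   `sigma_x` (um), `fit_lags`, `immobile`, and the fitted intercept/slope.
#' @export
fit_diffusion_coefficient <- function(msd, fit_points = 4, sigma_known = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  if (fit_points < 2 || fit_points > 5)
    stop("fit_points must be between 2 and 5")
  if (nrow(msd) < fit_points)
    stop("MSD curve has fewer lags than fit_points")
  t <- msd$lag[seq_len(fit_points)]
  y <- msd$msd[seq_len(fit_points)]
  if (is.null(sigma_known)) {
    fit <- stats::lm.fit(cbind(1, t), y)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  } else {
    intercept <- 4 * sigma_known^2
    slope <- sum(t * (y - intercept)) / sum(t^2)
  }
  immobile <- slope < 0
  D <- max(slope, 0) / 4
  sigma_x <- if (is.null(sigma_known)) sqrt(max(intercept, 0) / 4) else sigma_known
  structure(list(D = unname(D), sigma_x = unname(sigma_x),
                 fit_lags = seq_len(fit_points), immobile = immobile,
                 slope = unname(slope), intercept = unname(intercept)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um²/s, sigma_x = %.4g um%s\n",
              x$D, x$sigma_x, if (x$immobile) " (immobile)" else ""))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$D, sigma_x = object$sigma_x)
}

#' Explored-area statistic of an MSD curve
#'
#' Trapezoidal integral of the MSD curve over the lag window (default 0.6 to
#' 0.9 s), by default normalized by the window length so a constant MSD
#' returns that constant (units um^2); small explored areas indicate
#' confinement. Window endpoints falling between lag grid points are linearly
#' interpolated. If the curve does not cover the window, `NA` is returned
#' with attribute `missing_reason`.
#'
#' @param msd an `"msd_curve"`.
#' @param window lag window in seconds, `c(lo, hi)`.
#' @param normalize divide the raw integral by the window length
#'   (default TRUE); the raw integral (um^2 s) is attached as attribute
#'   `raw_integral` either way.
#' @return numeric scalar (um^2), or `NA` when the window is not covered.
#' @export
explored_area <- function(msd, window = c(0.6, 0.9), normalize = TRUE) {
  stopifnot(inherits(msd, "msd_curve"))
  lo <- window[1]; hi <- window[2]
  if (hi <= lo) stop("window must be increasing")
  if (min(msd$lag) > lo + 1e-12 || max(msd$lag) < hi - 1e-12) {
    out <- NA_real_
    attr(out, "missing_reason") <- "msd curve does not cover the window"
    return(out)
  }
  inner <- msd$lag > lo + 1e-12 & msd$lag < hi - 1e-12
  t <- c(lo, msd$lag[inner], hi)
  y <- stats::approx(msd$lag, msd$msd, xout = t)$y
  raw <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  out <- if (normalize) raw / (hi - lo) else raw
  attr(out, "raw_integral") <- raw
  out
}

#' Aggregate per-trajectory estimates by group
#'
#' Arithmetic mean per group (e.g. per movie or per cell) plus the pooled
#' empirical cumulative distribution across all trajectories, the two
#' summaries used for population comparison of diffusion parameters.
#'
#' @param values numeric vector of per-trajectory estimates.
#' @param groups grouping factor/vector of the same length.
#' @return list with `means` (named numeric vector) and `ecdf`
#'   (a [stats::ecdf()] of the pooled values). Groups with no finite values
#'   are dropped with a warning.
#' @export
aggregate_estimates <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  ok <- is.finite(values)
  g <- split(values[ok], droplevels(factor(groups[ok])))
  empty <- setdiff(unique(as.character(groups)), names(g))
  if (length(empty))
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  if (length(g) == 0) stop("no non-empty groups")
  list(means = vapply(g, mean, numeric(1)),
       ecdf = stats::ecdf(values[ok]))
}
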