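#' Detect sub-diffraction spots by local maxima and Gaussian fitting
#'
#' Candidate pixels are strict 8-neighborhood local maxima exceeding the
#' image median by `threshold` counts. Each candidate is refined by
#' least-squares fitting of a pixel-integrated isotropic 2D Gaussian
#' (center, amplitude, constant offset, width) on a window of
#' `+/- ceiling(3 * psf_sigma / pixel_size)` pixels, giving subpixel
#' coordinates. Fits whose center leaves the window are dropped with a
#' warning. Coordinates follow the pixel-center convention of
#' [render_synthetic_image()] and are returned in um.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param pixel_size_nm pixel pitch in nm (taken from the image attribute if
#'   present).
#' @param psf_sigma_nm expected PSF SD in nm; initializes the width and sets
#'   the fit window. Must be positive.
#' @param threshold detection threshold in counts above the image median.
#' @return data frame of class `"sm_localizations"` with columns `frame`
#'   (all 0; set by the caller for stacks), `x`, `y` (um), `intensity`
#'   (fitted integrated counts) and `sigma_fit` (um).
#' @export
detect_spots <- function(image, pixel_size_nm = attr(image, "pixel_size_nm"),
                         psf_sigma_nm, threshold) {
  if (is.null(pixel_size_nm)) stop("pixel_size_nm is required")
  if (psf_sigma_nm <= 0) stop("psf_sigma_nm must be positive")
  nr <- nrow(image); nc <- ncol(image)
  med <- stats::median(image)
  cand <- image
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (cand > .shift_mat(cand, dr, dc, fill = -Inf))
  }
  is_max <- is_max & (image - med >= threshold)
  idx <- which(is_max, arr.ind = TRUE)
  out <- list()
  if (nrow(idx) > 0) {
    w <- as.integer(ceiling(3 * psf_sigma_nm / pixel_size_nm))
    sig_px <- psf_sigma_nm / pixel_size_nm
    for (i in seq_len(nrow(idx))) {
      r0 <- idx[i, 1]; c0 <- idx[i, 2]
      rs <- max(1, r0 - w):min(nr, r0 + w)
      cs <- max(1, c0 - w):min(nc, c0 + w)
      patch <- image[rs, cs, drop = FALSE]
      fit <- .fit_gauss2d(patch, r0 - rs[1] + 1, c0 - cs[1] + 1, sig_px)
      if (is.null(fit)) {
        warning("spot fit diverged; detection dropped")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        frame = 0L,
        x = (cs[1] - 1 + fit$c0 - 1) * pixel_size_nm / 1000,
        y = (rs[1] - 1 + fit$r0 - 1) * pixel_size_nm / 1000,
        intensity = fit$A,
        sigma_fit = fit$sigma * pixel_size_nm / 1000)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric(), sigma_fit = numeric())
  class(res) <- c("sm_localizations", "data.frame")
  res
}

# Least-squares pixel-integrated Gaussian fit on a patch. Returns NULL on
# divergence (center outside the patch).
.fit_gauss2d <- function(patch, r_init, c_init, sig_init) {
  nr <- nrow(patch); nc <- ncol(patch)
  b0 <- min(patch)
  A0 <- max(sum(patch - b0), .Machine$double.eps)
  obj <- function(p) {
    sig <- exp(p[5])
    gx <- .pixel_gauss_1d(seq_len(nc), p[2], sig)
    gy <- .pixel_gauss_1d(seq_len(nr), p[1], sig)
    model <- p[4] + p[3] * outer(gy, gx)
    sum((patch - model)^2)
  }
  fit <- try(stats::optim(c(r_init, c_init, A0, b0, log(sig_init)), obj,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  p <- fit$par
  if (p[1] < 0.5 || p[1] > nr + 0.5 || p[2] < 0.5 || p[2] > nc + 0.5)
    return(NULL)
  list(r0 = p[1], c0 = p[2], A = p[3], b = p[4], sigma = exp(p[5]))
}

#' Link localizations into trajectories by per-frame optimal assignment
#'
#' Frame-to-frame association minimizes the total squared displacement over
#' candidate pairs within `max_disp` of an active track (optimal bipartite
#' assignment per frame pair; not linking costs `max_disp^2`, so links are
#' made whenever cheaper than the alternative). Tracks left unmatched for
#' more than `max_gap` frames are closed; unmatched detections open new
#' tracks. Ties resolve deterministically by frame, then lowest joint cost,
#' then localization order.
#'
#' @param localizations data frame with columns `frame`, `x`, `y` (um),
#'   sorted by frame (any extra columns are carried along).
#' @param frame_interval frame interval in seconds, stored on the result.
#' @param max_disp maximum displacement (um) between linked detections.
#'   The default `4 * sqrt(4 * D_max * dt)` with `D_max = 0.5` um^2/s covers
#'   essentially all Brownian steps at that mobility.
#' @param max_gap maximum number of consecutive missed frames before a track
#'   is closed (default 2).
#' @param D_max mobility bound used for the default search radius, um^2/s.
#' @return an `"sm_tracks"` object.
#' @export
link_trajectories <- function(localizations, frame_interval,
                              max_disp = NULL, max_gap = 2, D_max = 0.5) {
  if (is.null(max_disp))
    max_disp <- 4 * sqrt(4 * D_max * frame_interval)
  if (nrow(localizations) == 0)
    return(sm_tracks(data.frame(traj_id = integer(), frame = integer(),
                                x = numeric(), y = numeric()),
                     frame_interval))
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  frames <- sort(unique(loc$frame))
  # active track state
  last_x <- numeric(); last_y <- numeric(); last_f <- integer()
  track_of <- integer(0)      # active slot -> track id
  next_id <- 1L
  rows_of <- list()           # track id -> row indices into loc
  for (f in frames) {
    det_rows <- which(loc$frame == f)
    dx <- loc$x[det_rows]; dy <- loc$y[det_rows]
    # retire tracks with too large a gap
    keep <- last_f >= f - max_gap - 1L
    last_x <- last_x[keep]; last_y <- last_y[keep]
    last_f <- last_f[keep]; track_of <- track_of[keep]
    nt <- length(track_of); nd <- length(det_rows)
    match <- integer(nt)
    if (nt > 0 && nd > 0) {
      cost <- outer(last_x, dx, "-")^2 + outer(last_y, dy, "-")^2
      cost[cost > max_disp^2] <- Inf
      match <- .assign_min_cost(cost, miss_cost = max_disp^2)
    }
    used <- rep(FALSE, nd)
    for (k in seq_len(nt)) {
      if (match[k] > 0L) {
        j <- match[k]; used[j] <- TRUE
        id <- track_of[k]
        rows_of[[id]] <- c(rows_of[[id]], det_rows[j])
        last_x[k] <- dx[j]; last_y[k] <- dy[j]; last_f[k] <- f
      }
    }
    for (j in which(!used)) {
      id <- next_id; next_id <- next_id + 1L
      rows_of[[id]] <- det_rows[j]
      last_x <- c(last_x, dx[j]); last_y <- c(last_y, dy[j])
      last_f <- c(last_f, f); track_of <- c(track_of, id)
    }
  }
  pieces <- lapply(seq_along(rows_of), function(id) {
    rows <- rows_of[[id]]
    cbind(data.frame(traj_id = id), loc[rows, , drop = FALSE])
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  sm_tracks(res, frame_interval)
}

#' Filter trajectories by minimum number of localizations
#'
#' @param tracks an `"sm_tracks"` object.
#' @param min_points minimum localizations per kept trajectory; must be
#'   >= 2. The study conventions are 15 for quantum-dot tracking, 5-6 for
#'   PALM MSD analysis, and 2 for the diffusive-state HMM.
#' @return the kept `"sm_tracks"`; attributes `n_kept` and `n_discarded`
#'   record the split (kept + discarded = input trajectory count).
#' @export
filter_trajectories <- function(tracks, min_points) {
  stopifnot(inherits(tracks, "sm_tracks"))
  if (min_points < 2) stop("min_points must be >= 2")
  counts <- table(tracks$traj_id)
  keep_ids <- names(counts)[counts >= min_points]
  out <- tracks[tracks$traj_id %in% keep_ids, , drop = FALSE]
  out <- sm_tracks(as.data.frame(out), attr(tracks, "frame_interval"))
  attr(out, "n_kept") <- length(keep_ids)
  attr(out, "n_discarded") <- length(counts) - length(keep_ids)
  out
}
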