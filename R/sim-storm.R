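#' Specification of a synthetic STORM localization cloud
#'
#' Parameters for [simulate_storm_cloud()]: `n_clusters` isotropic Gaussian
#' clusters (SD `cluster_radius` nm) at uniform random centers inside a
#' rectangular ROI, a uniform background of single molecules, and blinking
#' re-detections: each molecule reappears in the next frame with probability
#' `redetect_prob` (a geometric chain of consecutive-frame detections),
#' jittered by `redetect_jitter` nm so re-detections stay within a merge
#' radius.
#'
#' @param roi_um ROI width and height in um, `c(w, h)`.
#' @param n_clusters number of planted clusters.
#' @param cluster_radius cluster SD in nm.
#' @param events_per_cluster either a fixed count or
#'   `list(type = "poisson", mean = m)` molecules per cluster.
#' @param background_density background molecules per um^2.
#' @param redetect_prob probability that a molecule is re-detected in the
#'   next camera frame.
#' @param redetect_jitter SD (nm) of the positional jitter between
#'   consecutive re-detections of one molecule.
#' @param n_frames number of camera frames over which first detections are
#'   spread uniformly.
#' @param seed integer seed.
#' @return an object of class `"storm_sim_spec"`.
#' @export
storm_sim_spec <- function(roi_um = c(5, 5),
                           n_clusters = 10,
                           cluster_radius = 20,
                           events_per_cluster = 40,
                           background_density = 5,
                           redetect_prob = 0,
                           redetect_jitter = 10,
                           n_frames = 20000,
                           seed = NULL) {
  if (any(roi_um <= 0)) stop("roi must have positive width and height")
  if (!.is_count(n_clusters)) stop("n_clusters must be a count")
  if (cluster_radius < 0) stop("cluster_radius must be >= 0")
  if (background_density < 0) stop("background_density must be >= 0")
  if (redetect_prob < 0 || redetect_prob >= 1)
    stop("redetect_prob must be in [0, 1)")
  structure(list(roi_um = roi_um, n_clusters = as.integer(n_clusters),
                 cluster_radius = cluster_radius,
                 events_per_cluster = events_per_cluster,
                 background_density = background_density,
                 redetect_prob = redetect_prob,
                 redetect_jitter = redetect_jitter,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "storm_sim_spec")
}

#' STORM localization cloud container
#'
#' Point pattern of single-molecule detections: coordinates in nm, a frame
#' index per detection, and the ROI area in um^2. Ground-truth columns
#' (`cluster`, `molecule`) are carried when the cloud was simulated.
#'
#' @param df data frame with columns `x_nm`, `y_nm`, `frame` (optionally
#'   `cluster`, `molecule`).
#' @param roi_area_um2 ROI area in um^2.
#' @return an object of class `"storm_cloud"`.
#' @export
storm_cloud <- function(df, roi_area_um2) {
  req <- c("x_nm", "y_nm", "frame")
  if (!all(req %in% names(df))) stop("cloud needs columns x_nm, y_nm, frame")
  if (roi_area_um2 <= 0) stop("roi_area_um2 must be positive")
  rownames(df) <- NULL
  structure(df, roi_area_um2 = roi_area_um2,
            class = c("storm_cloud", "data.frame"))
}

#' @export
print.storm_cloud <- function(x, ...) {
  cat(sprintf("<storm_cloud> %d detections over %g um^2\n",
              nrow(x), attr(x, "roi_area_um2")))
  invisible(x)
}

#' Simulate a STORM localization cloud with ground truth
#'
#' Cluster members are drawn isotropically (Gaussian, SD = `cluster_radius`)
#' around uniform random centers placed inside the ROI (kept `3*SD` clear of
#' the edge so clusters stay inside); background molecules are uniform on the
#' ROI. Every molecule gets a uniform first-detection frame; with probability
#' `redetect_prob` it is detected again in the following frame (geometric
#' chain), each re-detection jittered by `redetect_jitter` nm.
#'
#' @param spec a [storm_sim_spec()].
#' @return a `"storm_cloud"` whose data frame carries ground-truth columns
#'   `cluster` (0 = background) and `molecule` (unique molecule id).
#' @export
simulate_storm_cloud <- function(spec) {
  stopifnot(inherits(spec, "storm_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$roi_um[1] * 1000; h <- spec$roi_um[2] * 1000  # nm
  area <- spec$roi_um[1] * spec$roi_um[2]
  margin <- min(3 * spec$cluster_radius, w / 2, h / 2)
  mols <- list(); mid <- 0L
  if (spec$n_clusters > 0) {
    cx <- stats::runif(spec$n_clusters, margin, w - margin)
    cy <- stats::runif(spec$n_clusters, margin, h - margin)
    for (k in seq_len(spec$n_clusters)) {
      epc <- spec$events_per_cluster
      m <- if (is.list(epc)) stats::rpois(1, epc$mean) else epc
      if (m == 0) next
      mx <- stats::rnorm(m, cx[k], spec$cluster_radius)
      my <- stats::rnorm(m, cy[k], spec$cluster_radius)
      mols[[length(mols) + 1L]] <-
        data.frame(x = mx, y = my, cluster = k,
                   molecule = mid + seq_len(m))
      mid <- mid + m
    }
  }
  n_bg <- stats::rpois(1, spec$background_density * area)
  if (n_bg > 0) {
    mols[[length(mols) + 1L]] <-
      data.frame(x = stats::runif(n_bg, 0, w), y = stats::runif(n_bg, 0, h),
                 cluster = 0L, molecule = mid + seq_len(n_bg))
  }
  if (length(mols) == 0L)
    return(storm_cloud(data.frame(x_nm = numeric(), y_nm = numeric(),
                                  frame = integer(), cluster = integer(),
                                  molecule = integer()), area))
  mol <- do.call(rbind, mols)
  n_mol <- nrow(mol)
  first <- sample.int(spec$n_frames, n_mol, replace = TRUE)
  reps <- 1L + stats::rgeom(n_mol, 1 - spec$redetect_prob)
  idx <- rep(seq_len(n_mol), reps)
  offs <- sequence(reps) - 1L
  jit_x <- stats::rnorm(length(idx), 0, spec$redetect_jitter)
  jit_y <- stats::rnorm(length(idx), 0, spec$redetect_jitter)
  jit_x[offs == 0L] <- 0; jit_y[offs == 0L] <- 0
  det <- data.frame(x_nm = mol$x[idx] + jit_x,
                    y_nm = mol$y[idx] + jit_y,
                    frame = first[idx] + offs,
                    cluster = mol$cluster[idx],
                    molecule = mol$molecule[idx])
  det <- det[order(det$frame, det$molecule), ]
  storm_cloud(det, area)
}
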