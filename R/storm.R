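#' Collapse multiple detections of one molecule in consecutive frames
#'
#' A fluorophore that stays on across camera frames produces a chain of
#' detections at nearly the same position in consecutive frames. Chains of
#' detections within `merge_radius` of the chain's last member, separated by
#' at most `max_frame_gap` frames, are collapsed to a single point at their
#' mean position (first frame kept). Detections are scanned in frame order;
#' within a frame, each detection joins the nearest open chain in range.
#'
#' @param cloud a `"storm_cloud"`.
#' @param merge_radius merge distance in nm (default 50).
#' @param max_frame_gap maximum frame gap inside a chain (default 1:
#'   strictly consecutive frames).
#' @return deduplicated `"storm_cloud"`; attributes `n_merged` and
#'   `n_survivors` record the split (merged + survivors = input count).
#' @export
merge_consecutive_detections <- function(cloud, merge_radius = 50,
                                         max_frame_gap = 1) {
  stopifnot(inherits(cloud, "storm_cloud"))
  n <- nrow(cloud)
  if (n == 0) return(cloud)
  ord <- order(cloud$frame)
  x <- cloud$x_nm[ord]; y <- cloud$y_nm[ord]; f <- cloud$frame[ord]
  chain <- integer(n)            # chain id per detection
  open_id <- integer(0)          # open chains
  open_x <- numeric(0); open_y <- numeric(0); open_f <- numeric(0)
  next_chain <- 0L
  for (i in seq_len(n)) {
    # drop chains whose last detection is too old to ever match again
    keep <- open_f >= f[i] - max_frame_gap
    open_id <- open_id[keep]; open_x <- open_x[keep]
    open_y <- open_y[keep]; open_f <- open_f[keep]
    # chains already touched in the current frame are retained but not
    # eligible (one detection per chain per frame)
    d2 <- (open_x - x[i])^2 + (open_y - y[i])^2
    j <- which(d2 <= merge_radius^2 & open_f < f[i])
    if (length(j)) {
      j <- j[which.min(d2[j])]
      chain[i] <- open_id[j]
      open_x[j] <- x[i]; open_y[j] <- y[i]; open_f[j] <- f[i]
    } else {
      next_chain <- next_chain + 1L
      chain[i] <- next_chain
      open_id <- c(open_id, next_chain)
      open_x <- c(open_x, x[i]); open_y <- c(open_y, y[i])
      open_f <- c(open_f, f[i])
    }
  }
  keep_cols <- as.data.frame(cloud)[ord, , drop = FALSE]
  agg_x <- rowsum(x, chain) / as.numeric(table(chain))
  agg_y <- rowsum(y, chain) / as.numeric(table(chain))
  first_row <- !duplicated(chain)
  out <- keep_cols[first_row, , drop = FALSE]
  ids <- chain[first_row]
  out$x_nm <- agg_x[as.character(ids), 1]
  out$y_nm <- agg_y[as.character(ids), 1]
  res <- storm_cloud(out, attr(cloud, "roi_area_um2"))
  attr(res, "n_survivors") <- nrow(res)
  attr(res, "n_merged") <- n - nrow(res)
  res
}

#' DBSCAN clustering of a localization cloud
#'
#' Standard DBSCAN with the inclusive neighborhood convention: a core point
#' has at least `min_pts` detections (itself included) within radial
#' distance `eps`; clusters are maximal sets of density-connected core
#' points plus their border points. The defaults implement a density
#' threshold of minimum 20 detections within 20 nm. Border points reachable
#' from several clusters are assigned to the cluster of their
#' lowest-indexed core neighbor, making labels independent of point order.
#'
#' @param cloud a `"storm_cloud"` (or data frame with `x_nm`, `y_nm`).
#' @param eps neighborhood radius, nm (default 20).
#' @param min_pts minimum detections within `eps`, self included
#'   (default 20).
#' @return an object of class `"cluster_set"`: list with `labels`
#'   (integer per point, 0 = noise), `clusters` (per-cluster data frame:
#'   `size`, `x_nm`, `y_nm` centroid, `radius_nm` radius of gyration),
#'   `eps`, `min_pts`, `n_points`, and the ROI area when known.
#' @export
dbscan_clusters <- function(cloud, eps = 20, min_pts = 20) {
  if (eps <= 0) stop("eps must be positive")
  if (min_pts < 1) stop("min_pts must be >= 1")
  x <- cloud$x_nm; y <- cloud$y_nm
  n <- length(x)
  if (n == 0) stop("cloud has no points")
  nb <- .eps_neighbors(x, y, eps)
  n_nb <- lengths(nb)                 # self included
  core <- n_nb >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (core[q] && labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  # border points: lowest-indexed core neighbor decides
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  clusters <- if (cl > 0) {
    do.call(rbind, lapply(seq_len(cl), function(k) {
      idx <- which(labels == k)
      data.frame(cluster = k, size = length(idx),
                 x_nm = mean(x[idx]), y_nm = mean(y[idx]),
                 radius_nm = .radius_gyration(x[idx], y[idx]))
    }))
  } else {
    data.frame(cluster = integer(), size = integer(), x_nm = numeric(),
               y_nm = numeric(), radius_nm = numeric())
  }
  structure(list(labels = labels, clusters = clusters, eps = eps,
                 min_pts = min_pts, n_points = n,
                 roi_area_um2 = attr(cloud, "roi_area_um2")),
            class = "cluster_set")
}

# eps-neighbor lists (self included) via grid bucketing.
.eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cellx <- floor(x / eps); celly <- floor(y / eps)
  key <- paste(cellx, celly)
  buckets <- split(seq_len(n), key)
  nb <- vector("list", n)
  e2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cellx[i] + dx, celly[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb[[i]] <- sort(cand[d2 <= e2])
  }
  nb
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d points, %d cluster(s), %d noise (eps = %g nm, min_pts = %d)\n",
              x$n_points, nrow(x$clusters), sum(x$labels == 0L),
              x$eps, x$min_pts))
  invisible(x)
}

#' Summary metrics of a clustered localization cloud
#'
#' Detections per um^2, clusters per um^2, per-cluster size (events) and
#' radius of gyration, and the fraction of detections lying in clusters
#' (clustered detections over total detections).
#'
#' @param cluster_set a `"cluster_set"` from [dbscan_clusters()].
#' @param roi_area_um2 ROI area in um^2; defaults to the area stored on the
#'   clustered cloud.
#' @return list with `detections_per_um2`, `clusters_per_um2`,
#'   `fraction_in_clusters`, `mean_events_per_cluster`,
#'   `mean_radius_nm`, `n_clusters`, `n_points`.
#' @export
cluster_metrics <- function(cluster_set, roi_area_um2 = cluster_set$roi_area_um2) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  if (is.null(roi_area_um2) || roi_area_um2 <= 0)
    stop("a positive roi_area_um2 is required")
  n <- cluster_set$n_points
  ncl <- nrow(cluster_set$clusters)
  in_cl <- sum(cluster_set$labels > 0L)
  list(detections_per_um2 = n / roi_area_um2,
       clusters_per_um2 = ncl / roi_area_um2,
       fraction_in_clusters = in_cl / n,
       mean_events_per_cluster = if (ncl) mean(cluster_set$clusters$size) else NA_real_,
       mean_radius_nm = if (ncl) mean(cluster_set$clusters$radius_nm) else NA_real_,
       n_clusters = ncl, n_points = n)
}

#' Render a localization cloud as a super-resolution image
#'
#' Each localization contributes a unit-integral pixel-integrated Gaussian
#' of SD `gaussian_radius` on a grid of `pixel_size` (defaults: 10 nm
#' pointing accuracy rendered on a 5 nm grid), so the integrated image
#' equals the localization count up to the mass falling outside the frame.
#'
#' @param cloud a `"storm_cloud"`.
#' @param pixel_size rendering pixel size, nm (default 5).
#' @param gaussian_radius Gaussian SD, nm (default 10).
#' @param extent optional `c(xmax, ymax)` nm; default spans the points plus
#'   a 5-SD margin.
#' @return numeric matrix (rows = y, cols = x) with attribute
#'   `pixel_size_nm`.
#' @export
render_storm <- function(cloud, pixel_size = 5, gaussian_radius = 10,
                         extent = NULL) {
  x <- cloud$x_nm; y <- cloud$y_nm
  if (length(x) == 0) {
    img <- matrix(0, 1, 1)
    attr(img, "pixel_size_nm") <- pixel_size
    return(img)
  }
  pad <- 5 * gaussian_radius
  if (is.null(extent)) extent <- c(max(x) + pad, max(y) + pad)
  nc <- ceiling(extent[1] / pixel_size)
  nr <- ceiling(extent[2] / pixel_size)
  img <- matrix(0, nr, nc)
  col_centers <- (seq_len(nc) - 0.5) * pixel_size
  row_centers <- (seq_len(nr) - 0.5) * pixel_size
  half_w <- ceiling(6 * gaussian_radius / pixel_size)
  for (i in seq_along(x)) {
    ci <- round(x[i] / pixel_size)
    ri <- round(y[i] / pixel_size)
    cs <- max(1, ci - half_w):min(nc, ci + half_w)
    rs <- max(1, ri - half_w):min(nr, ri + half_w)
    gx <- .pixel_gauss_1d(col_centers[cs], x[i], gaussian_radius, pixel_size)
    gy <- .pixel_gauss_1d(row_centers[rs], y[i], gaussian_radius, pixel_size)
    img[rs, cs] <- img[rs, cs] + outer(gy, gx)
  }
  attr(img, "pixel_size_nm") <- pixel_size
  img
}
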