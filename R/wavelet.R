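#' A-trous wavelet decomposition of an image
#'
#' Undecimated ("with holes") multiscale transform: the image is repeatedly
#' smoothed with a separable B3-spline kernel `[1, 4, 6, 4, 1] / 16` whose
#' taps are dilated by a factor 2 at each level (mirrored borders), and the
#' detail plane at level k is the difference of consecutive smooths:
#' `plane_k = smooth_{k-1} - smooth_k`. The planes plus the final smooth
#' (residual) reconstruct the input exactly, and plane 2 isolates
#' diffraction-limited spot-sized structure from larger background.
#'
#' @param image numeric matrix.
#' @param n_levels number of detail planes (default 3); the dilated kernel
#'   at the deepest level must fit the image.
#' @return an object of class `"wavelet_decomp"`: list with `planes` (list
#'   of matrices) and `residual`.
#' @export
atrous_decompose <- function(image, n_levels = 3) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (n_levels < 1) stop("n_levels must be >= 1")
  reach <- 2 * 2^(n_levels - 1)
  if (min(dim(image)) <= reach)
    stop("image smaller than the dilated kernel at the deepest level")
  planes <- vector("list", n_levels)
  smooth <- image
  for (k in seq_len(n_levels)) {
    nxt <- .b3_smooth(smooth, step = 2^(k - 1))
    planes[[k]] <- smooth - nxt
    smooth <- nxt
  }
  structure(list(planes = planes, residual = smooth),
            class = "wavelet_decomp")
}

#' @export
print.wavelet_decomp <- function(x, ...) {
  cat(sprintf("<wavelet_decomp> %d detail plane(s) + residual, %d x %d\n",
              length(x$planes), nrow(x$residual), ncol(x$residual)))
  invisible(x)
}

# Separable B3-spline smoothing with taps at +/- {0, step, 2*step},
# whole-sample mirrored borders.
.b3_smooth <- function(m, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2L, -1L, 0L, 1L, 2L) * step
  m <- .conv_rows(m, w, offs)        # along rows (vertical)
  t(.conv_rows(t(m), w, offs))       # along columns
}

.mirror_index <- function(i, n) {
  # whole-sample reflection: ..3 2 | 1 2 3 .. n-1 n | n-1 n-2..
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  # a second pass covers offsets beyond one reflection on tiny images
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

.conv_rows <- function(m, w, offs) {
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  base <- seq_len(nr)
  for (k in seq_along(w)) {
    idx <- .mirror_index(base + offs[k], nr)
    out <- out + w[k] * m[idx, , drop = FALSE]
  }
  out
}

#' Reconstruct the image from a wavelet decomposition
#' @param decomp a `"wavelet_decomp"`.
#' @return the reconstructed matrix (sum of planes plus residual).
#' @export
atrous_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomp"))
  Reduce(`+`, decomp$planes) + decomp$residual
}

#' Segment fluorescence clusters by thresholding a wavelet detail plane
#'
#' The detail plane at `level` (default 2, the spot scale) is thresholded at
#' `k_sigma` times its robust SD (1.4826 x median absolute deviation), the
#' result binarized, 8-connected components extracted and components below
#' `min_area` pixels discarded. Because only a band-pass plane is
#' thresholded, the mask is insensitive to constant or slowly varying
#' background ("background-free").
#'
#' @param image numeric matrix with a `pixel_size_nm` attribute (or supply
#'   `pixel_size_nm`).
#' @param level detail plane to threshold (default 2).
#' @param k_sigma threshold in robust SDs of the plane (default 2).
#' @param min_area minimum component area in pixels (default 4).
#' @param pixel_size_nm pixel size in nm.
#' @return an object of class `"segmentation_mask"`: list with `labels`
#'   (integer matrix, 0 = background), `n_components`, `mask` (logical),
#'   `threshold`, `pixel_size_nm`, and a per-component table `components`
#'   (`id`, `area_px`, centroid `row`/`col`).
#' @export
segment_clusters <- function(image, level = 2, k_sigma = 2, min_area = 4,
                             pixel_size_nm = attr(image, "pixel_size_nm")) {
  dec <- atrous_decompose(image, n_levels = level)
  plane <- dec$planes[[level]]
  thr <- k_sigma * stats::mad(plane)
  # floor guards against an all-flat plane passing everywhere at thr = 0
  thr <- max(thr, 1e-12 * max(abs(plane), 1e-300))
  mask <- plane > thr
  labels <- .label_components_8(mask)
  if (max(labels) > 0 && min_area > 1) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_area)
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      ids <- sort(unique(labels[labels > 0L]))
      labels[labels > 0L] <- match(labels[labels > 0L], ids)
    }
  }
  ncomp <- max(labels)
  comps <- if (ncomp > 0) {
    do.call(rbind, lapply(seq_len(ncomp), function(k) {
      idx <- which(labels == k, arr.ind = TRUE)
      data.frame(id = k, area_px = nrow(idx),
                 row = mean(idx[, 1]), col = mean(idx[, 2]))
    }))
  } else {
    data.frame(id = integer(), area_px = integer(), row = numeric(),
               col = numeric())
  }
  structure(list(labels = labels, n_components = ncomp,
                 mask = labels > 0L, threshold = thr,
                 pixel_size_nm = pixel_size_nm, components = comps),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d component(s), %d x %d px\n",
              x$n_components, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Cluster density and intensity statistics within a region of interest
#'
#' Cluster density is the number of segmented components whose pixels
#' intersect the ROI, divided by the ROI area in um^2. Per-cluster intensity
#' is the summed fluorescence of the component's pixels in the original
#' image; the image-level value is the mean over clusters in the ROI.
#'
#' @param seg a `"segmentation_mask"`.
#' @param image the original intensity image (same shape).
#' @param roi optional ROI polygon: two-column matrix of (col, row) pixel
#'   vertices. Default is the full frame. Storing the polygon keeps
#'   manually drawn regions reproducible.
#' @param pixel_size_nm pixel size in nm; defaults to the mask's.
#' @return list with `clusters_per_um2`, `mean_intensity`,
#'   `per_cluster` (data frame: `id`, `area_px`, `intensity`),
#'   `roi_area_um2`, `n_clusters`.
#' @export
cluster_stats <- function(seg, image, roi = NULL,
                          pixel_size_nm = seg$pixel_size_nm) {
  stopifnot(inherits(seg, "segmentation_mask"))
  if (!all(dim(seg$labels) == dim(image)))
    stop("mask and image shapes differ")
  if (is.null(pixel_size_nm)) stop("pixel_size_nm is required")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(roi)) {
    in_roi <- matrix(TRUE, nr, nc)
    roi_area_px <- nr * nc
  } else {
    grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    inside <- .points_in_polygon(grid$col, grid$row, roi)
    in_roi <- matrix(inside, nr, nc)
    roi_area_px <- .polygon_area(roi)
    if (roi_area_px <= 0) stop("ROI has zero area")
  }
  roi_area_um2 <- roi_area_px * (pixel_size_nm / 1000)^2
  ids <- sort(unique(seg$labels[seg$labels > 0L & in_roi]))
  per <- if (length(ids)) {
    do.call(rbind, lapply(ids, function(k) {
      idx <- seg$labels == k
      data.frame(id = k, area_px = sum(idx),
                 intensity = sum(image[idx]))
    }))
  } else {
    data.frame(id = integer(), area_px = integer(), intensity = numeric())
  }
  list(clusters_per_um2 = length(ids) / roi_area_um2,
       mean_intensity = if (length(ids)) mean(per$intensity) else NA_real_,
       per_cluster = per, roi_area_um2 = roi_area_um2,
       n_clusters = length(ids))
}

#' Co-localization of two segmentation masks
#'
#' In `"overlap"` mode a cluster of A co-localizes when it shares at least
#' one pixel with any cluster of B. In `"apposition"` mode it also counts
#' when its boundary lies within `max_dist_nm` (default 150 nm) of a B
#' cluster boundary, distances measured between boundary pixel centers,
#' so overlapping clusters are apposed at distance zero and the apposition
#' fraction can never fall below the overlap fraction.
#'
#' @param seg_A,seg_B `"segmentation_mask"` objects on registered images
#'   with identical pixel size.
#' @param mode `"overlap"` or `"apposition"`.
#' @param max_dist_nm apposition distance, nm (default 150).
#' @return list with `fraction_A` (fraction of A clusters co-localized with
#'   B), `fraction_B` (the symmetric fraction), and the per-cluster logical
#'   vectors `hit_A`, `hit_B`.
#' @export
colocalize <- function(seg_A, seg_B, mode = c("overlap", "apposition"),
                       max_dist_nm = 150) {
  mode <- match.arg(mode)
  stopifnot(inherits(seg_A, "segmentation_mask"),
            inherits(seg_B, "segmentation_mask"))
  if (!all(dim(seg_A$labels) == dim(seg_B$labels)))
    stop("masks have different shapes")
  psA <- seg_A$pixel_size_nm; psB <- seg_B$pixel_size_nm
  if (!is.null(psA) && !is.null(psB) && abs(psA - psB) > 1e-9)
    stop("masks have different pixel sizes")
  ps <- if (!is.null(psA)) psA else psB
  if (mode == "apposition" && is.null(ps))
    stop("apposition mode needs a pixel size")
  hit_A <- .coloc_hits(seg_A, seg_B, mode, max_dist_nm, ps)
  hit_B <- .coloc_hits(seg_B, seg_A, mode, max_dist_nm, ps)
  frac <- function(h) if (length(h)) mean(h) else NA_real_
  list(fraction_A = frac(hit_A), fraction_B = frac(hit_B),
       hit_A = hit_A, hit_B = hit_B, mode = mode)
}

.coloc_hits <- function(seg_from, seg_to, mode, max_dist_nm, ps) {
  nA <- seg_from$n_components
  if (nA == 0) return(logical(0))
  other <- seg_to$mask
  hits <- logical(nA)
  for (k in seq_len(nA)) {
    idx <- seg_from$labels == k
    hits[k] <- any(other & idx)
  }
  if (mode == "overlap" || all(hits) || seg_to$n_components == 0)
    return(hits)
  bA <- .boundary_pixels(seg_from$labels)
  bB_idx <- which(.boundary_mask(seg_to$mask), arr.ind = TRUE)
  if (nrow(bB_idx) == 0) return(hits)
  max_px <- max_dist_nm / ps
  for (k in which(!hits)) {
    pa <- bA[[k]]
    # bounding-box prefilter
    near <- bB_idx[, 1] >= min(pa[, 1]) - max_px - 1 &
      bB_idx[, 1] <= max(pa[, 1]) + max_px + 1 &
      bB_idx[, 2] >= min(pa[, 2]) - max_px - 1 &
      bB_idx[, 2] <= max(pa[, 2]) + max_px + 1
    pb <- bB_idx[near, , drop = FALSE]
    if (nrow(pb) == 0) next
    for (i in seq_len(nrow(pa))) {
      d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2
      if (min(d2) <= max_px^2) { hits[k] <- TRUE; break }
    }
  }
  hits
}

.boundary_mask <- function(mask) {
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & .shift_mat(mask, dr, dc, fill = FALSE)
  }
  mask & !interior
}

.boundary_pixels <- function(labels) {
  bmask <- .boundary_mask(labels > 0L)
  ncomp <- max(labels)
  lapply(seq_len(ncomp), function(k)
    which(bmask & labels == k, arr.ind = TRUE))
}
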