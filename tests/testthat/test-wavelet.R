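test_that("a-trous decomposition reconstructs exactly and kills flat images", {
  # constant image: all detail planes are zero
  const <- matrix(3.7, 32, 32)
  d <- atrous_decompose(const, 3)
  for (p in d$planes) expect_equal(max(abs(p)), 0)
  expect_equal(d$residual, const)
  # reconstruction identity on random images (fuzz)
  for (seed in 1:20) {
    set.seed(seed)
    img <- matrix(rnorm(48 * 40, 100, 25), 48, 40)
    dec <- atrous_decompose(img, 3)
    rel <- max(abs(atrous_reconstruct(dec) - img)) / max(abs(img))
    expect_lt(rel, 1e-10)
  }
  expect_error(atrous_decompose(matrix(0, 4, 4), 3), "smaller")
})

test_that("impulse response equals direct convolution of dilated kernels", {
  img <- matrix(0, 33, 33)
  img[17, 17] <- 1
  dec <- atrous_decompose(img, 3)
  s0 <- img
  for (k in 1:3) {
    s1 <- atrous_smooth_ref(s0, step = 2^(k - 1))
    expect_equal(dec$planes[[k]], s0 - s1, tolerance = 1e-14)
    s0 <- s1
  }
  expect_equal(dec$residual, s0, tolerance = 1e-14)
})

test_that("segmentation finds bright structure and ignores background offsets", {
  # zero image: empty mask
  zero <- matrix(0, 32, 32)
  expect_equal(segment_clusters(zero, pixel_size_nm = 100)$n_components, 0L)
  # single clean Gaussian spot: one component containing the peak pixel
  img <- render_synthetic_image(image_sim_spec(
    c(32, 32), 160, 200, data.frame(x_nm = 2400, y_nm = 2080,
                                    amplitude = 1000), background = 10))
  seg <- segment_clusters(img)
  expect_equal(seg$n_components, 1L)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_true(seg$mask[peak])
  # adding a constant offset leaves the mask unchanged (background-free)
  seg_off <- segment_clusters(img + 500, pixel_size_nm = 160)
  expect_equal(seg_off$labels, seg$labels)
})

test_that("planted spots are each recovered as one component near the truth", {
  spots <- spaced_spots(10, extent_nm = 10000, spacing_nm = 2400,
                        amplitude = 3000, seed = 81)
  img <- render_synthetic_image(image_sim_spec(
    c(64, 64), 160, 200, spots, background = 20, noise = "poisson",
    seed = 81))
  seg <- segment_clusters(img)
  expect_equal(seg$n_components, 10L)
  # centroids within one PSF sigma of the planted positions
  for (i in seq_len(10)) {
    d <- sqrt(((seg$components$col - 1) * 160 - spots$x_nm[i])^2 +
                ((seg$components$row - 1) * 160 - spots$y_nm[i])^2)
    expect_lt(min(d), 200)
  }
})

test_that("cluster statistics count densities and summed intensities", {
  labels <- matrix(0L, 10, 10)
  labels[2, 2] <- 1L; labels[2, 3] <- 1L; labels[8, 8] <- 2L
  seg <- structure(list(labels = labels, n_components = 2L,
                        mask = labels > 0L, threshold = 0,
                        pixel_size_nm = 1000,
                        components = data.frame(id = 1:2,
                                                area_px = c(2L, 1L),
                                                row = c(2, 8),
                                                col = c(2.5, 8))),
                   class = "segmentation_mask")
  img <- matrix(1, 10, 10)
  img[2, 2] <- 2; img[2, 3] <- 3; img[8, 8] <- 5
  st <- cluster_stats(seg, img)  # full frame: 100 px = 100 um^2 at 1 um/px
  expect_equal(st$clusters_per_um2, 0.02)
  expect_equal(sort(st$per_cluster$intensity), c(5, 5))
  # component of pixels {2, 3, 5}: intensity 10
  labels2 <- matrix(0L, 8, 8); labels2[3, 3:5] <- 1L
  seg2 <- structure(list(labels = labels2, n_components = 1L,
                         mask = labels2 > 0L, threshold = 0,
                         pixel_size_nm = 1000,
                         components = data.frame(id = 1L, area_px = 3L,
                                                 row = 3, col = 4)),
                    class = "segmentation_mask")
  img2 <- matrix(0, 8, 8); img2[3, 3:5] <- c(2, 3, 5)
  expect_equal(cluster_stats(seg2, img2)$mean_intensity, 10)
  # 4 clusters inside a 20 um^2 polygonal ROI: 0.2 clusters per um^2
  labels3 <- matrix(0L, 30, 30)
  labels3[cbind(rep(5, 4), c(5, 10, 15, 20))] <- 1:4
  seg3 <- structure(list(labels = labels3, n_components = 4L,
                         mask = labels3 > 0L, threshold = 0,
                         pixel_size_nm = 1000,
                         components = data.frame(id = 1:4, area_px = 1L,
                                                 row = 5,
                                                 col = c(5, 10, 15, 20))),
                    class = "segmentation_mask")
  roi <- cbind(c(3, 23, 23, 3), c(4.5, 4.5, 5.5, 5.5))  # 20 x 1 px strip
  st3 <- cluster_stats(seg3, matrix(1, 30, 30), roi = roi)
  expect_equal(st3$roi_area_um2, 20)
  expect_equal(st3$clusters_per_um2, 0.2)
  # planted amplitudes recovered within 5%; sampling near the pixel scale
  # keeps the thresholded component wide enough (in PSF units) to capture
  # essentially all of each spot's integrated intensity
  spots4 <- data.frame(x_nm = rep(c(2000, 6000, 10000), 2),
                       y_nm = rep(c(3000, 9000), each = 3),
                       amplitude = 4000)
  img4 <- render_synthetic_image(image_sim_spec(
    c(56, 56), 250, 200, spots4, background = 0))
  seg4 <- segment_clusters(img4, k_sigma = 0.5, min_area = 4)
  expect_equal(seg4$n_components, 6L)
  st4 <- cluster_stats(seg4, img4)
  expect_lt(abs(st4$mean_intensity - 4000) / 4000, 0.05)
})

test_that("co-localization fractions behave at the identities and extremes", {
  spots <- spaced_spots(8, extent_nm = 9000, spacing_nm = 3000,
                        amplitude = 3000, seed = 84)
  img <- render_synthetic_image(image_sim_spec(
    c(64, 64), 160, 200, spots, background = 10))
  seg <- segment_clusters(img)
  expect_gt(seg$n_components, 0)
  # A vs A: fraction 1 in both modes
  expect_equal(colocalize(seg, seg, "overlap")$fraction_A, 1)
  expect_equal(colocalize(seg, seg, "apposition")$fraction_A, 1)
  # A vs empty: 0
  empty <- segment_clusters(matrix(0, 64, 64), pixel_size_nm = 160)
  expect_equal(colocalize(seg, empty)$fraction_A, 0)
  # masks far apart: 0 in both modes; nearby but disjoint: apposition only
  mk_seg <- function(col_shift) {
    labels <- matrix(0L, 40, 40)
    labels[18:20, (10:12) + col_shift] <- 1L
    structure(list(labels = labels, n_components = 1L, mask = labels > 0L,
                   threshold = 0, pixel_size_nm = 100,
                   components = data.frame(id = 1L, area_px = 9L,
                                           row = 19, col = 11 + col_shift)),
              class = "segmentation_mask")
  }
  A <- mk_seg(0)
  far <- mk_seg(25)   # 2500 nm away
  expect_equal(colocalize(A, far, "overlap")$fraction_A, 0)
  expect_equal(colocalize(A, far, "apposition")$fraction_A, 0)
  near <- mk_seg(3)   # adjacent but disjoint: boundary centers 100 nm apart
  expect_equal(colocalize(A, near, "overlap")$fraction_A, 0)
  expect_equal(colocalize(A, near, "apposition")$fraction_A, 1)
})

test_that("overlap fraction never exceeds the apposition fraction", {
  pm <- planted_coloc_masks(60, frac_overlap = 0.5, seed = 85)
  ov <- colocalize(pm$A, pm$B, "overlap")
  ap <- colocalize(pm$A, pm$B, "apposition")
  expect_lte(ov$fraction_A, ap$fraction_A)
  expect_lte(ov$fraction_B, ap$fraction_B)
})
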