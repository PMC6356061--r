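test_that("consecutive-frame deduplication collapses blink chains", {
  mk <- function(frames, x = 100, y = 100) {
    storm_cloud(data.frame(x_nm = x, y_nm = y, frame = frames), 1)
  }
  # same position across frames 1-5 collapses to one point
  one <- merge_consecutive_detections(mk(1:5), merge_radius = 50)
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "n_merged"), 4L)
  # frames 1 and 10 with max_frame_gap 1 stay apart
  two <- merge_consecutive_detections(mk(c(1, 10)), merge_radius = 50,
                                      max_frame_gap = 1)
  expect_equal(nrow(two), 2L)
  # distant detections in consecutive frames stay apart
  far <- storm_cloud(data.frame(x_nm = c(0, 500), y_nm = 0, frame = 1:2), 1)
  expect_equal(nrow(merge_consecutive_detections(far, 50)), 2L)
  # merged position is the chain mean
  chain <- storm_cloud(data.frame(x_nm = c(100, 110, 120), y_nm = 0,
                                  frame = 1:3), 1)
  m <- merge_consecutive_detections(chain, 50)
  expect_equal(m$x_nm, 110)
})

test_that("deduplication recovers the ground-truth molecule count", {
  cl <- simulate_storm_cloud(storm_sim_spec(
    roi_um = c(5, 5), n_clusters = 8, cluster_radius = 20,
    events_per_cluster = 50, background_density = 3,
    redetect_prob = 0.5, seed = 71))
  n_mol <- length(unique(cl$molecule))
  dd <- merge_consecutive_detections(cl, merge_radius = 50, max_frame_gap = 1)
  expect_lt(abs(attr(dd, "n_survivors") - n_mol) / n_mol, 0.01)
  expect_equal(attr(dd, "n_merged") + attr(dd, "n_survivors"), nrow(cl))
})

test_that("DBSCAN honors the inclusive min_pts threshold exactly", {
  co <- function(n) storm_cloud(data.frame(x_nm = rep(100, n),
                                           y_nm = rep(100, n),
                                           frame = seq_len(n)), 1)
  cs20 <- dbscan_clusters(co(20))   # defaults eps 20, min_pts 20
  expect_equal(nrow(cs20$clusters), 1L)
  expect_equal(cs20$clusters$size, 20L)
  cs19 <- dbscan_clusters(co(19))
  expect_equal(nrow(cs19$clusters), 0L)
  expect_equal(sum(cs19$labels == 0L), 19L)
  expect_error(dbscan_clusters(co(5), eps = 0), "eps")
})

test_that("DBSCAN labels match the quadratic reference on planted clusters", {
  spec <- storm_sim_spec(roi_um = c(2, 2), n_clusters = 5, cluster_radius = 15,
                         events_per_cluster = 300, background_density = 125,
                         seed = 72)
  cl <- simulate_storm_cloud(spec)
  expect_gte(nrow(cl), 1500)
  cs <- dbscan_clusters(cl, eps = 20, min_pts = 20)
  ref <- dbscan_ref(cl$x_nm, cl$y_nm, eps = 20, min_pts = 20)
  expect_equal(cs$labels, ref)
  # point-order invariance: permuting the input permutes the labels
  set.seed(1)
  perm <- sample(nrow(cl))
  cl2 <- storm_cloud(as.data.frame(cl)[perm, ], attr(cl, "roi_area_um2"))
  cs2 <- dbscan_clusters(cl2, eps = 20, min_pts = 20)
  # same partition: compare label co-membership via cluster sizes per point
  relab <- function(l) match(l, unique(l[l > 0]))
  expect_true(all((cs2$labels > 0) == (cs$labels[perm] > 0)))
  tab <- table(cs2$labels[cs2$labels > 0], cs$labels[perm][cs$labels[perm] > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("fraction in clusters shrinks as min_pts grows and metrics check out", {
  cl <- simulate_storm_cloud(storm_sim_spec(
    roi_um = c(3, 3), n_clusters = 6, cluster_radius = 15,
    events_per_cluster = 40, background_density = 10, seed = 73))
  fr <- vapply(c(10, 20, 30, 40), function(mp) {
    cluster_metrics(dbscan_clusters(cl, eps = 20, min_pts = mp),
                    attr(cl, "roi_area_um2"))$fraction_in_clusters
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  # translation commutes with dedup + clustering
  sh <- as.data.frame(cl)
  sh$x_nm <- sh$x_nm + 5000; sh$y_nm <- sh$y_nm + 2000
  cs0 <- dbscan_clusters(merge_consecutive_detections(cl, 50), 20, 20)
  cs1 <- dbscan_clusters(merge_consecutive_detections(
    storm_cloud(sh, attr(cl, "roi_area_um2")), 50), 20, 20)
  expect_equal(cs1$labels, cs0$labels)
})

test_that("cluster metrics use area, gyration radius and counts as defined", {
  # 3 clusters of coincident points in 10 um^2
  df <- data.frame(x_nm = rep(c(100, 5000, 9000), each = 25) +
                     rep(rnorm(25, 0, 2), 3),
                   y_nm = rep(c(100, 5000, 9000), each = 25),
                   frame = 1:75)
  cs <- dbscan_clusters(storm_cloud(df, 10), eps = 20, min_pts = 20)
  met <- cluster_metrics(cs, 10)
  expect_equal(met$clusters_per_um2, 0.3)
  expect_equal(met$fraction_in_clusters, 1)
  expect_equal(met$detections_per_um2, 7.5)
  # points uniformly on a circle of radius r: radius of gyration = r
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- 12
  circ <- storm_cloud(data.frame(x_nm = 500 + r * cos(th),
                                 y_nm = 500 + r * sin(th),
                                 frame = seq_along(th)), 1)
  csc <- dbscan_clusters(circ, eps = 100, min_pts = 20)
  expect_equal(csc$clusters$radius_nm, r, tolerance = 1e-9)
  # planted ~50% background recovers the clustered fraction within 0.05
  cl2 <- simulate_storm_cloud(storm_sim_spec(
    roi_um = c(4, 4), n_clusters = 8, cluster_radius = 12,
    events_per_cluster = 50, background_density = 25, seed = 74))
  planted <- mean(cl2$cluster > 0)
  met2 <- cluster_metrics(dbscan_clusters(cl2, 20, 20),
                          attr(cl2, "roi_area_um2"))
  expect_lt(abs(met2$fraction_in_clusters - planted), 0.05)
  expect_error(cluster_metrics(cs, 0), "positive")
})

test_that("super-resolution rendering conserves localization counts", {
  one <- storm_cloud(data.frame(x_nm = 200, y_nm = 150, frame = 1), 1)
  expect_equal(sum(render_storm(one)), 1, tolerance = 1e-6)
  empty <- storm_cloud(data.frame(x_nm = numeric(), y_nm = numeric(),
                                  frame = integer()), 1)
  expect_equal(sum(render_storm(empty)), 0)
  set.seed(2)
  many <- storm_cloud(data.frame(x_nm = runif(100, 100, 900),
                                 y_nm = runif(100, 100, 900),
                                 frame = 1:100), 1)
  img <- render_storm(many, pixel_size = 5, gaussian_radius = 10)
  expect_equal(sum(img), 100, tolerance = 1e-4)
  expect_equal(attr(img, "pixel_size_nm"), 5)
})
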