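test_that("transition prior encodes the dwell time and survives a zero-count update", {
  W0 <- smquant:::.dirichlet_transition_prior(3, dwell_prior = 50, strength = 1)
  mean0 <- W0 / rowSums(W0)
  expect_equal(diag(mean0), rep(1 - 1 / 50, 3))
  expect_equal(rowSums(mean0), rep(1, 3))
  # conjugacy: posterior with zero expected transition counts is the prior
  post <- W0 + matrix(0, 3, 3)
  expect_equal(post / rowSums(post), mean0)
})

test_that("single-state data select K = 1 with accurate D", {
  sim <- simulate_trajectories(traj_sim_spec(
    500, D_states = 0.1, loc_noise_sigma = 0,
    length_law = list(type = "geometric", mean = 30, min = 5), seed = 51))
  fit <- infer_diffusive_states(sim$tracks, seed = 2)
  expect_equal(fit$K, 1L)
  expect_lt(abs(fit$D - 0.1) / 0.1, 0.10)
  # never K = 3 when the margin is clear
  expect_gt(fit$evidence[1] - max(fit$evidence[-1]), 0)
  # lower bound is monotone over iterations
  expect_gte(min(diff(fit$elbo_trace)), -1e-8)
  # invariants on the returned model
  expect_equal(sum(fit$occupancy), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$transition), rep(1, fit$K), tolerance = 1e-9)
  expect_equal(fit$dwell_s, fit$dt / (1 - diag(fit$transition)),
               tolerance = 1e-9)
})

test_that("all-zero displacements give a degenerate one-state model", {
  df <- data.frame(traj_id = rep(1:3, each = 5), frame = rep(0:4, 3),
                   x = 1, y = 2)
  fit <- infer_diffusive_states(sm_tracks(df, 0.02), seed = 1)
  expect_true(fit$degenerate)
  expect_equal(fit$K, 1L)
  expect_equal(fit$D, 0)
  expect_error(infer_diffusive_states(sm_tracks(df[1, , drop = FALSE], 0.02)),
               "usable")
})

test_that("two-state dynamics are recovered with ordered labels", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  sim <- simulate_trajectories(traj_sim_spec(
    500, D_states = c(0.01, 0.2), transition_matrix = P, loc_noise_sigma = 0,
    length_law = list(type = "geometric", mean = 30, min = 5), seed = 42))
  fit <- infer_diffusive_states(sim$tracks, seed = 7)
  expect_equal(fit$K, 2L)
  expect_false(is.unsorted(fit$D))  # bound state first
  expect_lt(abs(fit$D[1] - 0.01) / 0.01, 0.2)
  expect_lt(abs(fit$D[2] - 0.2) / 0.2, 0.2)
  truth_occ <- mean(unlist(lapply(sim$state_sequences,
                                  function(s) s[-length(s)])) == 1)
  expect_lt(abs(fit$occupancy[1] - truth_occ), 0.10)
  expect_gte(min(diff(fit$elbo_trace)), -1e-8)
  # state metrics are consistent with the model
  sm <- state_metrics(fit)
  expect_equal(sm$occupancy_pct / 100, fit$occupancy)
  expect_equal(sm$dwell_ms / 1000, fit$dwell_s)
  pi_ <- fit$occupancy
  expect_equal(sm$entry_prob[1],
               pi_[2] * fit$transition[2, 1] / pi_[2])
  # simulate() round-trips the fitted parameters into a valid spec
  rt <- simulate(fit, nsim = 5, seed = 3)
  expect_s3_class(rt$tracks, "sm_tracks")
})

test_that("hard-path metrics count occupancy, dwells and entries directly", {
  pm <- state_path_metrics(c(1, 1, 2, 2, 2), dt = 0.02)
  expect_equal(pm$occupancy_pct, c(40, 60))
  expect_equal(pm$dwell_ms, c(40, 60))
  single <- state_path_metrics(rep(1, 10), dt = 0.02, n_states = 2)
  expect_equal(single$occupancy_pct, c(100, 0))
  expect_equal(single$entry_prob[2], 0)
  # empirical entry probabilities of a long chain match the closed form
  P <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2, byrow = TRUE)
  sim <- simulate_trajectories(traj_sim_spec(
    1, D_states = c(0.01, 0.2), transition_matrix = P, loc_noise_sigma = 0,
    length_law = list(type = "fixed", length = 5e4), seed = 53))
  path <- sim$state_sequences[[1]]
  pm2 <- state_path_metrics(path, dt = 0.02)
  pi_ <- smquant:::.stationary_distribution(P)
  for (j in 1:2) {
    i <- 3 - j
    p_entry <- P[i, j]           # only one other state
    n_risk <- sum(path[-length(path)] == i)
    se <- sqrt(p_entry * (1 - p_entry) / n_risk)
    expect_lt(abs(pm2$entry_prob[j] - p_entry), 3 * se)
  }
})

test_that("condition comparison reports zero deltas on identical fits and recovers planted occupancy shifts", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  sim <- simulate_trajectories(traj_sim_spec(
    200, D_states = c(0.01, 0.2), transition_matrix = P, loc_noise_sigma = 0,
    length_law = list(type = "geometric", mean = 25, min = 5), seed = 61))
  fit <- infer_diffusive_states(sim$tracks, seed = 3)
  self <- compare_conditions(fit, fit, n_boot = 1)
  expect_equal(self$delta_D, rep(0, fit$K))
  expect_equal(self$delta_occupancy, rep(0, fit$K))
  # one resample: interval degenerate at the point estimate
  expect_equal(self$delta_D_lo, self$delta_D)
  expect_equal(self$delta_D_hi, self$delta_D)
  # occupancy 0.7 vs 0.55 in the bound state; detailed balance fixes T21
  mkP <- function(occ1) {
    t21 <- occ1 * 0.1 / (1 - occ1)
    matrix(c(0.9, 0.1, t21, 1 - t21), 2, 2, byrow = TRUE)
  }
  sa <- simulate_trajectories(traj_sim_spec(
    400, D_states = c(0.01, 0.2), transition_matrix = mkP(0.70),
    loc_noise_sigma = 0, length_law = list(type = "geometric", mean = 25,
                                           min = 5), seed = 62))
  sb <- simulate_trajectories(traj_sim_spec(
    400, D_states = c(0.01, 0.2), transition_matrix = mkP(0.55),
    loc_noise_sigma = 0, length_law = list(type = "geometric", mean = 25,
                                           min = 5), seed = 63))
  fa <- infer_diffusive_states(sa$tracks, seed = 4)
  fb <- infer_diffusive_states(sb$tracks, seed = 5)
  expect_equal(fa$K, 2L)
  expect_equal(fb$K, 2L)
  cmp <- compare_conditions(fa, fb, n_boot = 50, seed = 9)
  expect_lt(abs(cmp$delta_occupancy[1] - (-0.15)), 0.1)
  expect_lt(cmp$delta_occupancy_lo[1], cmp$delta_occupancy_hi[1] + 1e-12)
})

test_that("parameter recovery holds across repeated two-state simulations", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  errD <- c(); errO <- c()
  for (seed in 1:6) {
    sim <- simulate_trajectories(traj_sim_spec(
      300, D_states = c(0.01, 0.2), transition_matrix = P,
      loc_noise_sigma = 0,
      length_law = list(type = "geometric", mean = 30, min = 5),
      seed = 70 + seed))
    fit <- infer_diffusive_states(sim$tracks, seed = seed, n_restarts = 3)
    if (fit$K == 2L) {
      errD <- c(errD, abs(fit$D - c(0.01, 0.2)) / c(0.01, 0.2))
      truth <- mean(unlist(lapply(sim$state_sequences,
                                  function(s) s[-length(s)])) == 1)
      errO <- c(errO, abs(fit$occupancy[1] - truth))
    } else {
      errD <- c(errD, Inf); errO <- c(errO, Inf)
    }
  }
  expect_lte(stats::median(errD), 0.2)
  expect_lte(stats::median(errO), 0.1)
})
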