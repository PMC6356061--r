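#' Prior settings for diffusive-state inference
#'
#' Conjugate prior for the variational-Bayes hidden-Markov model of
#' [infer_diffusive_states()]: an inverse-gamma prior on each state's
#' per-axis step variance centered on `2 * D_prior * dt`, and Dirichlet
#' priors on the transition-matrix rows whose mean encodes a self-transition
#' probability of `1 - 1/dwell_prior`. Prior strengths default to one
#' observation-equivalent.
#'
#' @param D_prior prior mean diffusion coefficient, um^2/s (default 0.1).
#' @param dwell_prior prior mean dwell time in frames (default 50, i.e.
#'   1000 ms at a 20 ms frame interval).
#' @param max_states maximum number of candidate states (default 3).
#' @param min_traj_points minimum localizations per trajectory used
#'   (default 2, i.e. one displacement).
#' @param strength_D,strength_T prior strengths (pseudo-observations) of the
#'   variance and transition priors.
#' @return an object of class `"hmm_prior"`.
#' @export
hmm_prior <- function(D_prior = 0.1, dwell_prior = 50, max_states = 3,
                      min_traj_points = 2, strength_D = 1, strength_T = 1) {
  if (D_prior <= 0 || dwell_prior <= 0) stop("priors must be positive")
  if (max_states < 1) stop("max_states must be >= 1")
  if (min_traj_points < 2) stop("min_traj_points must be >= 2")
  structure(list(D_prior = D_prior, dwell_prior = dwell_prior,
                 max_states = as.integer(max_states),
                 min_traj_points = as.integer(min_traj_points),
                 strength_D = strength_D, strength_T = strength_T),
            class = "hmm_prior")
}

# Dirichlet transition prior: mean has self-transition 1 - 1/dwell, the rest
# shared equally; `strength` pseudo-counts per row.
.dirichlet_transition_prior <- function(K, dwell_prior, strength = 1) {
  if (K == 1L) return(matrix(strength, 1, 1))
  p_stay <- 1 - 1 / dwell_prior
  M <- matrix((1 - p_stay) / (K - 1), K, K)
  diag(M) <- p_stay
  M * strength
}

# Extract squared step displacements from tracks: one numeric vector per
# contiguous (gap-free) trajectory segment, with the owning trajectory id.
.traj_steps <- function(tracks, min_points = 2) {
  stopifnot(inherits(tracks, "sm_tracks"))
  segs <- list(); owner <- integer()
  for (tr in split_tracks(tracks)) {
    if (nrow(tr) < min_points) next
    brk <- cumsum(c(0L, as.integer(diff(tr$frame) != 1L)))
    for (piece in split(seq_len(nrow(tr)), brk)) {
      if (length(piece) < 2) next
      dx <- diff(tr$x[piece]); dy <- diff(tr$y[piece])
      segs[[length(segs) + 1L]] <- dx^2 + dy^2
      owner <- c(owner, tr$traj_id[1])
    }
  }
  list(r2 = segs, owner = owner)
}

.kl_dirichlet <- function(a, a0) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * (digamma(a) - digamma(sum(a))))
}

.kl_invgamma <- function(a, b, a0, b0) {
  a0 * (log(b) - log(b0)) - lgamma(a) + lgamma(a0) +
    (a - a0) * digamma(a) - (b - b0) * a / b
}

# One VB fit for fixed K from initial responsibilities.
# segs: list of r^2 step vectors. Returns posterior parameters, per-segment
# statistics and the ELBO trace.
.vb_fit <- function(segs, K, dt, prior, gamma_init, max_iter = 300,
                    tol = 1e-6) {
  lens <- lengths(segs)
  ord <- order(lens, decreasing = TRUE)
  segs <- segs[ord]; lens <- lens[ord]
  N <- length(segs); Tmax <- max(lens)
  r2 <- matrix(NA_real_, N, Tmax)
  for (n in seq_len(N)) r2[n, seq_len(lens[n])] <- segs[[n]]
  n_active <- vapply(seq_len(Tmax), function(t) sum(lens >= t), integer(1))
  # priors
  v0 <- 2 * prior$D_prior * dt
  a0 <- prior$strength_D / 2 + 1
  b0 <- v0 * (a0 - 1)
  W0 <- .dirichlet_transition_prior(K, prior$dwell_prior, prior$strength_T)
  u0 <- rep(1, K)
  # initial M-step for the emission posteriors from the step
  # responsibilities (steps treated i.i.d.); transition/initial posteriors
  # start at their priors
  flat_r2 <- unlist(segs)
  stopifnot(nrow(gamma_init) == length(flat_r2))
  Ngam <- colSums(gamma_init)
  S <- colSums(gamma_init * flat_r2) / 2
  u <- u0
  W <- W0
  a_ig <- a0 + Ngam
  b_ig <- b0 + S
  elbo_trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    # expected log parameters
    Elnpi <- digamma(u) - digamma(sum(u))
    ElnA <- digamma(W) - digamma(rowSums(W))
    ElnV <- log(b_ig) - digamma(a_ig)
    EinvV <- a_ig / b_ig
    Atil <- exp(ElnA); pitil <- exp(Elnpi)
    # forward pass (scaled), storing alpha and scaled emissions
    Alist <- vector("list", Tmax); Elist <- vector("list", Tmax)
    Clist <- vector("list", Tmax)
    lnZ <- numeric(N)
    alpha <- matrix(0, N, K)
    for (t in seq_len(Tmax)) {
      na <- n_active[t]
      rows <- seq_len(na)
      L <- -log(2 * pi) - matrix(ElnV, na, K, byrow = TRUE) -
        outer(r2[rows, t], EinvV / 2)
      m <- apply(L, 1, max)
      e <- exp(L - m)
      pred <- if (t == 1L) matrix(pitil, na, K, byrow = TRUE) else
        alpha[rows, , drop = FALSE] %*% Atil
      an <- pred * e
      cn <- rowSums(an)
      alpha[rows, ] <- an / cn
      lnZ[rows] <- lnZ[rows] + log(cn) + m
      Alist[[t]] <- alpha[rows, , drop = FALSE]
      Elist[[t]] <- e; Clist[[t]] <- cn
    }
    # ELBO with current posteriors
    elbo <- sum(lnZ) - .kl_dirichlet(u, u0) - .kl_invgamma_sum(a_ig, b_ig, a0, b0)
    for (i in seq_len(K)) elbo <- elbo - .kl_dirichlet(W[i, ], W0[i, ])
    elbo_trace <- c(elbo_trace, elbo)
    converged <- is.finite(prev) && abs(elbo - prev) <
      max(tol, 1e-10 * abs(elbo))
    prev <- elbo
    # backward pass and accumulation
    beta <- matrix(1, N, K)
    Ngam <- numeric(K); S <- numeric(K)
    Gseg <- matrix(0, N, K); Sseg <- matrix(0, N, K)
    Xi <- matrix(0, K, K); Xseg <- array(0, c(N, K, K))
    gam1 <- matrix(0, N, K)
    for (t in seq(Tmax, 1L)) {
      na <- n_active[t]; rows <- seq_len(na)
      g <- Alist[[t]] * beta[rows, , drop = FALSE]
      g <- g / rowSums(g)
      Ngam <- Ngam + colSums(g)
      S <- S + colSums(g * r2[rows, t]) / 2
      Gseg[rows, ] <- Gseg[rows, ] + g
      Sseg[rows, ] <- Sseg[rows, ] + g * r2[rows, t] / 2
      if (t == 1L) gam1[rows, ] <- g
      if (t > 1L) {
        # xi between t-1 and t for rows active at t
        eb <- Elist[[t]] * beta[rows, , drop = FALSE] / Clist[[t]]
        ap <- Alist[[t - 1L]][rows, , drop = FALSE]
        for (i in seq_len(K)) {
          contrib <- (ap[, i] * eb) * matrix(Atil[i, ], na, K, byrow = TRUE)
          Xi[i, ] <- Xi[i, ] + colSums(contrib)
          Xseg[rows, i, ] <- Xseg[rows, i, ] + contrib
        }
        beta[rows, ] <- eb %*% t(Atil)
      }
    }
    # M-step
    u <- u0 + colSums(gam1)
    W <- W0 + Xi
    a_ig <- a0 + Ngam
    b_ig <- b0 + S
    if (converged) break
  }
  list(K = K, elbo = prev, elbo_trace = elbo_trace,
       u = u, W = W, a_ig = a_ig, b_ig = b_ig,
       Ngam = Ngam, S = S, Gseg = Gseg, Sseg = Sseg, Xseg = Xseg,
       order = ord, prior_params = list(u0 = u0, W0 = W0, a0 = a0, b0 = b0))
}

.kl_invgamma_sum <- function(a, b, a0, b0) {
  sum(mapply(.kl_invgamma, a, b, MoreArgs = list(a0 = a0, b0 = b0)))
}

# quantile-bin initial responsibilities with seeded jitter, in the
# length-sorted flat step layout used by .vb_fit
.init_responsibilities <- function(segs, K, jitter_seed) {
  lens <- lengths(segs)
  ord <- order(lens, decreasing = TRUE)
  flat <- unlist(segs[ord])
  n <- length(flat)
  if (K == 1L) return(matrix(1, n, 1))
  set.seed(jitter_seed)
  qs <- stats::quantile(flat, probs = seq(0, 1, length.out = K + 1))
  bin <- pmin(pmax(findInterval(flat, qs[-c(1, K + 1)]) + 1L, 1L), K)
  g <- matrix(0.15 / K, n, K)
  g[cbind(seq_len(n), bin)] <- g[cbind(seq_len(n), bin)] + 0.85
  g <- g * matrix(stats::runif(n * K, 0.5, 1.5), n, K)
  g / rowSums(g)
}

#' Infer diffusive states from short trajectories (variational-Bayes HMM)
#'
#' Treats per-frame displacements as emissions of a hidden Markov chain over
#' K diffusive states: each displacement component is Gaussian with variance
#' `2 * D_k * dt` per axis. Inference is variational EM with conjugate
#' priors (inverse-gamma on the per-state step variance, Dirichlet on
#' transition-matrix rows; see [hmm_prior()]); hidden paths are integrated
#' by forward-backward. Candidate models K = 1..`max_states` are fitted,
#' each from `n_restarts` seeded initializations, and the K maximizing the
#' variational lower bound is returned. Localization noise is not part of
#' the likelihood, so estimated D carries a `sigma^2/dt` floor; displacement
#' across gap frames is excluded (gaps split a trajectory into independent
#' segments).
#'
#' States are reported in ascending order of D (state 1 = bound/slow,
#' state K = free/fast).
#'
#' @param tracks an `"sm_tracks"` object.
#' @param prior an [hmm_prior()].
#' @param dt frame interval in seconds; defaults to the tracks attribute.
#' @param n_restarts restarts per candidate K (default 5).
#' @param seed master seed; restart seeds derive from it by a fixed counter.
#' @param max_iter,tol variational EM iteration cap and absolute ELBO
#'   convergence tolerance.
#' @return an object of class `"diffusive_state_model"`: fields `K`, `D`
#'   (um^2/s, ascending), `transition` (per-frame probabilities, rows
#'   summing to 1), `occupancy`, `dwell_s` (`dt / (1 - transition[k, k])`),
#'   `evidence` (best lower bound per candidate K), `elbo_trace`,
#'   `degenerate` flag, and the data/prior bookkeeping used by
#'   [state_metrics()] and [compare_conditions()].
#' @export
infer_diffusive_states <- function(tracks, prior = hmm_prior(),
                                   dt = attr(tracks, "frame_interval"),
                                   n_restarts = 5, seed = 1,
                                   max_iter = 300, tol = 1e-6) {
  stopifnot(inherits(prior, "hmm_prior"))
  if (is.null(dt) || dt <= 0) stop("dt must be positive")
  st <- .traj_steps(tracks, prior$min_traj_points)
  if (length(st$r2) == 0) stop("no usable trajectories (need >= min_traj_points)")
  if (all(unlist(st$r2) == 0)) {
    return(structure(list(K = 1L, D = 0, transition = matrix(1, 1, 1),
                          occupancy = 1, dwell_s = Inf, evidence = NA_real_,
                          elbo_trace = numeric(0), degenerate = TRUE,
                          dt = dt, prior = prior, n_segments = length(st$r2),
                          n_steps = sum(lengths(st$r2))),
                     class = "diffusive_state_model"))
  }
  best_per_K <- vector("list", prior$max_states)
  counter <- 0L
  for (K in seq_len(prior$max_states)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      counter <- counter + 1L
      g0 <- .init_responsibilities(st$r2, K, jitter_seed = seed + counter)
      fit <- .vb_fit(st$r2, K, dt, prior, g0, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$elbo > best$elbo) best <- fit
      if (K == 1L) break  # restarts are redundant for one state
    }
    best_per_K[[K]] <- best
  }
  evidence <- vapply(best_per_K, function(f) f$elbo, numeric(1))
  K_sel <- which.max(evidence)
  fit <- best_per_K[[K_sel]]
  # posterior means
  v <- fit$b_ig / (fit$a_ig - 1)
  D <- v / (2 * dt)
  Tm <- fit$W / rowSums(fit$W)
  occupancy <- fit$Ngam / sum(fit$Ngam)
  ordD <- order(D)
  D <- D[ordD]; occupancy <- occupancy[ordD]
  Tm <- Tm[ordD, ordD, drop = FALSE]
  dwell <- dt / (1 - diag(Tm))
  structure(list(K = K_sel, D = unname(D), transition = unname(Tm),
                 occupancy = unname(occupancy), dwell_s = unname(dwell),
                 evidence = evidence, elbo_trace = fit$elbo_trace,
                 degenerate = FALSE, dt = dt, prior = prior,
                 n_segments = length(st$r2), n_steps = sum(lengths(st$r2)),
                 state_order = ordD,
                 seg_owner = st$owner[fit$order],
                 Gseg = fit$Gseg[, ordD, drop = FALSE],
                 Sseg = fit$Sseg[, ordD, drop = FALSE],
                 Xseg = fit$Xseg[, ordD, ordD, drop = FALSE],
                 posterior = list(u = fit$u[ordD],
                                  W = fit$W[ordD, ordD, drop = FALSE],
                                  a_ig = fit$a_ig[ordD], b_ig = fit$b_ig[ordD]),
                 prior_params = fit$prior_params),
            class = "diffusive_state_model")
}

#' @export
print.diffusive_state_model <- function(x, ...) {
  cat(sprintf("<diffusive_state_model> K = %d state(s)%s, dt = %g s\n",
              x$K, if (x$degenerate) " (degenerate)" else "", x$dt))
  for (k in seq_len(x$K))
    cat(sprintf("  state %d: D = %.4g um²/s, occupancy = %.1f%%, dwell = %.0f ms\n",
                k, x$D[k], 100 * x$occupancy[k], 1000 * x$dwell_s[k]))
  invisible(x)
}

#' @export
summary.diffusive_state_model <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat("evidence (lower bound) per K:",
        paste(sprintf("%.1f", object$evidence), collapse = ", "), "\n")
    cat("transition matrix (per frame):\n")
    print(round(object$transition, 4))
  }
  invisible(object)
}

#' @export
coef.diffusive_state_model <- function(object, ...) {
  cbind(D = object$D, occupancy = object$occupancy, dwell_s = object$dwell_s)
}

#' Simulate trajectories from a fitted diffusive-state model
#'
#' @param object a `"diffusive_state_model"`.
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param length_law trajectory length law (see [traj_sim_spec()]).
#' @param loc_noise_sigma localization noise, um (default 0: the model does
#'   not carry a noise term).
#' @param ... unused.
#' @return as [simulate_trajectories()].
#' @export
simulate.diffusive_state_model <- function(object, nsim = 100, seed = NULL,
                                           length_law = list(type = "geometric",
                                                             mean = 30, min = 5),
                                           loc_noise_sigma = 0, ...) {
  spec <- traj_sim_spec(nsim, frame_interval = object$dt,
                        length_law = length_law, D_states = object$D,
                        transition_matrix = object$transition,
                        loc_noise_sigma = loc_noise_sigma, seed = seed)
  simulate_trajectories(spec)
}

#' Per-state occupancy, dwell time and entry probability of a fitted model
#'
#' Occupancy is the posterior-expected fraction of steps in each state;
#' dwell time is `dt / (1 - T[k, k])`; the per-step entry probability into
#' state j is `sum_{i != j} pi_i T[i, j] / sum_{i != j} pi_i` (the
#' probability that a molecule not currently in j enters it on the next
#' step). The fraction of trajectories whose posterior path (marginal
#' probability > 0.5 at any step) visits each state is also reported, the
#' alternative reading of "proportion of molecules transitioning" into a
#' state.
#'
#' @param model a `"diffusive_state_model"`.
#' @return data frame with one row per state: `D`, `occupancy_pct`,
#'   `dwell_ms`, `entry_prob`, `frac_traj_visiting`.
#' @export
state_metrics <- function(model) {
  stopifnot(inherits(model, "diffusive_state_model"))
  K <- model$K
  pi_ <- model$occupancy
  Tm <- model$transition
  entry <- vapply(seq_len(K), function(j) {
    if (K == 1L) return(0)
    i <- setdiff(seq_len(K), j)
    sum(pi_[i] * Tm[i, j]) / sum(pi_[i])
  }, numeric(1))
  if (model$degenerate || is.null(model$Gseg)) {
    visit <- rep(NA_real_, K)
  } else {
    # a trajectory "visits" a state when its posterior-expected number of
    # steps in that state exceeds 0.5 in any of its segments
    per_traj <- rowsum((model$Gseg > 0.5) * 1, model$seg_owner) > 0
    visit <- colSums(per_traj) / nrow(per_traj)
  }
  data.frame(state = seq_len(K), D = model$D,
             occupancy_pct = 100 * model$occupancy,
             dwell_ms = 1000 * model$dwell_s,
             entry_prob = entry,
             frac_traj_visiting = visit)
}

#' Occupancy, dwell times and entry probabilities of a known state path
#'
#' Direct counting on a hard state sequence: occupancy is the fraction of
#' steps per state, dwell the mean length of continuous runs (in seconds),
#' and entry probability the empirical per-step probability of entering each
#' state from another.
#'
#' @param path integer state sequence (one state per step).
#' @param dt frame interval, seconds.
#' @param n_states number of states (default `max(path)`).
#' @return data frame with columns `state`, `occupancy_pct`, `dwell_ms`,
#'   `entry_prob`.
#' @export
state_path_metrics <- function(path, dt, n_states = max(path)) {
  stopifnot(length(path) >= 1, all(path >= 1))
  runs <- rle(path)
  occ <- vapply(seq_len(n_states), function(k) mean(path == k), numeric(1))
  dwell <- vapply(seq_len(n_states), function(k) {
    mean(runs$lengths[runs$values == k]) * dt
  }, numeric(1))
  trans_from <- path[-length(path)]; trans_to <- path[-1]
  entry <- vapply(seq_len(n_states), function(k) {
    at_risk <- trans_from != k
    if (!any(at_risk)) return(0)
    sum(at_risk & trans_to == k) / sum(at_risk)
  }, numeric(1))
  data.frame(state = seq_len(n_states), occupancy_pct = 100 * occ,
             dwell_ms = 1000 * dwell, entry_prob = entry)
}

#' Compare two fitted diffusive-state models
#'
#' Per-state differences (B minus A) in D, occupancy and dwell time, states
#' matched by D rank, with bootstrap percentile intervals obtained by
#' resampling trajectories and recombining their stored posterior
#' sufficient statistics (no refit per replicate). The first replicate is
#' the identity resample, so `n_boot = 1` yields an interval degenerate at
#' the point estimate.
#'
#' @param model_A,model_B fitted `"diffusive_state_model"` objects sharing
#'   `dt`. If their K differ, states are matched by D rank over the smaller
#'   K with a warning.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return data frame with one row per matched state and columns
#'   `delta_D`, `delta_occupancy`, `delta_dwell_s` plus their `lo`/`hi`
#'   interval bounds.
#' @export
compare_conditions <- function(model_A, model_B, n_boot = 200, conf = 0.95,
                               seed = 1) {
  stopifnot(inherits(model_A, "diffusive_state_model"),
            inherits(model_B, "diffusive_state_model"))
  if (abs(model_A$dt - model_B$dt) > 1e-12)
    stop("models have different frame intervals")
  K <- min(model_A$K, model_B$K)
  if (model_A$K != model_B$K)
    warning("models have different K; matching the ", K,
            " slowest states by D rank")
  bootfun <- function(model, idx_traj) {
    # weight each segment by how often its trajectory was drawn
    tab <- table(idx_traj)
    wt <- as.numeric(tab[as.character(model$seg_owner)])
    wt[is.na(wt)] <- 0
    G <- colSums(model$Gseg * wt)
    S <- colSums(model$Sseg * wt)
    pp <- model$prior_params
    a <- pp$a0 + G; b <- pp$b0 + S
    D <- (b / (a - 1)) / (2 * model$dt)
    occ <- G / sum(G)
    Xi <- apply(model$Xseg * wt, c(2, 3), sum)
    W <- pp$W0[model$state_order, model$state_order, drop = FALSE] + Xi
    Tm <- W / rowSums(W)
    dwell <- model$dt / (1 - diag(Tm))
    list(D = D[seq_len(K)], occ = occ[seq_len(K)], dwell = dwell[seq_len(K)])
  }
  traj_A <- unique(model_A$seg_owner); traj_B <- unique(model_B$seg_owner)
  point_A <- bootfun(model_A, traj_A); point_B <- bootfun(model_B, traj_B)
  delta <- function(a, b) list(D = b$D - a$D, occ = b$occ - a$occ,
                               dwell = b$dwell - a$dwell)
  pt <- delta(point_A, point_B)
  set.seed(seed)
  reps <- vector("list", n_boot)
  for (r in seq_len(n_boot)) {
    if (r == 1L) {
      reps[[r]] <- pt
    } else {
      sa <- sample(traj_A, replace = TRUE)
      sb <- sample(traj_B, replace = TRUE)
      reps[[r]] <- delta(bootfun(model_A, sa), bootfun(model_B, sb))
    }
  }
  alpha <- (1 - conf) / 2
  qs <- function(field, k) {
    v <- vapply(reps, function(x) x[[field]][k], numeric(1))
    stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
  }
  out <- data.frame(state = seq_len(K),
                    delta_D = pt$D, delta_occupancy = pt$occ,
                    delta_dwell_s = pt$dwell)
  for (field in c("D", "occ", "dwell")) {
    ci <- t(vapply(seq_len(K), function(k) qs(field, k), numeric(2)))
    nm <- c(D = "delta_D", occ = "delta_occupancy", dwell = "delta_dwell_s")[field]
    out[[paste0(nm, "_lo")]] <- ci[, 1]
    out[[paste0(nm, "_hi")]] <- ci[, 2]
  }
  out
}
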