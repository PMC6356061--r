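# Internal helpers shared across modules. Nothing here is exported.

# Stationary distribution of a row-stochastic matrix (left eigenvector of
# eigenvalue 1, renormalized to sum to 1).
.stationary_distribution <- function(P) {
  K <- nrow(P)
  if (K == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

.check_row_stochastic <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square")
  if (any(P < -tol))
    stop("transition matrix entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > max(tol, 1e-12)))
    stop("transition matrix rows must sum to 1")
  invisible(P)
}

# Shift a matrix by (dr, dc), filling vacated cells.
.shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-connected component labeling of a logical matrix by iterative minimum-label
# propagation. Returns an integer matrix with labels 1..n (0 = background).
.label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  # dense init: use linear indices so labels are unique
  lab[mask] <- which(mask)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      s <- .shift_mat(lab, offs[k, 1L], offs[k, 2L], fill = 0L)
      upd <- mask & s > 0L & (new == 0L | s < new)
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
# poly: two-column matrix of vertices (closed implicitly).
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Minimum-cost frame-to-frame assignment with an opt-out. cost is an
# n_track x n_det matrix with Inf where the candidate pair is disallowed;
# leaving a track unmatched costs `miss_cost` (the squared search radius,
# the usual gap-cost convention), so a link is made whenever it is cheaper
# than not linking. Exact branch-and-bound per connected component of the
# candidate graph; components at tracking densities hold a handful of spots.
# Ties between equal-cost assignments resolve to the lexicographically
# smallest match vector (rows in order, columns ascending, opt-out last).
.assign_min_cost <- function(cost, miss_cost, exact_limit = 14L) {
  nr <- nrow(cost); nc <- ncol(cost)
  match_out <- integer(nr)
  if (nr == 0L || nc == 0L) return(match_out)
  finite <- is.finite(cost)
  # connected components of the bipartite candidate graph
  comp_r <- integer(nr); comp_c <- integer(nc); ncomp <- 0L
  for (r0 in seq_len(nr)) {
    if (comp_r[r0] > 0L) next
    if (!any(finite[r0, ])) { comp_r[r0] <- -1L; next }
    ncomp <- ncomp + 1L
    qr <- r0
    while (length(qr)) {
      r <- qr[1L]; qr <- qr[-1L]
      if (comp_r[r] > 0L) next
      comp_r[r] <- ncomp
      for (cc in which(finite[r, ])) {
        if (comp_c[cc] == 0L) {
          comp_c[cc] <- ncomp
          more <- which(finite[, cc] & comp_r == 0L)
          qr <- c(qr, more)
        }
      }
    }
  }
  if (ncomp == 0L) return(match_out)
  for (cm in seq_len(ncomp)) {
    rows <- which(comp_r == cm)
    cols <- which(comp_c == cm)
    sub <- cost[rows, cols, drop = FALSE]
    if (length(rows) <= exact_limit) {
      sol <- .assign_exact(sub, miss_cost)
    } else {
      sol <- .assign_greedy(sub, miss_cost)
    }
    match_out[rows] <- ifelse(sol > 0L, cols[pmax(sol, 1L)], 0L)
    match_out[rows][sol == 0L] <- 0L
  }
  match_out
}

.assign_exact <- function(cost, miss_cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- list(cost = Inf, match = integer(nr))
  cur <- integer(nr)
  used <- rep(FALSE, nc)
  tol <- 1e-12
  rec <- function(r, acc) {
    if (acc >= best$cost - tol) return()
    if (r > nr) {
      if (acc < best$cost - tol) best <<- list(cost = acc, match = cur)
      return()
    }
    cand <- which(is.finite(cost[r, ]) & !used)
    for (cc in cand[order(cand)]) {
      cur[r] <<- cc; used[cc] <<- TRUE
      rec(r + 1L, acc + cost[r, cc])
      used[cc] <<- FALSE
    }
    cur[r] <<- 0L
    rec(r + 1L, acc + miss_cost)
  }
  rec(1L, 0)
  best$match
}

.assign_greedy <- function(cost, miss_cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  match <- integer(nr)
  used <- rep(FALSE, nc)
  ord <- order(cost)  # ascending over all entries
  for (k in ord) {
    if (!is.finite(cost[k])) break
    r <- (k - 1L) %% nr + 1L
    cc <- (k - 1L) %/% nr + 1L
    if (match[r] == 0L && !used[cc] && cost[k] < miss_cost) {
      match[r] <- cc; used[cc] <- TRUE
    }
  }
  match
}

# Radius of gyration of a 2D point set about its centroid.
.radius_gyration <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  sqrt(mean((x - cx)^2 + (y - cy)^2))
}

# Pixel-integrated isotropic Gaussian: fraction of unit mass falling in each
# pixel of a grid with centers `centers` (vector) for a 1D Gaussian at mu, sd.
.pixel_gauss_1d <- function(centers, mu, sd, pixel = 1) {
  stats::pnorm(centers + pixel / 2, mu, sd) -
    stats::pnorm(centers - pixel / 2, mu, sd)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
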