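# Independent reference implementations used as oracles. These are written
# with naive data structures (linear scans, dense linear algebra) so they
# share no code path with the package's implementations.

# Brute-force variable-window local-maximum scan.
seeds_oracle <- function(chm, params, window_scale = 1, res = 0.5) {
  z <- chm
  nr <- nrow(z); nc <- ncol(z)
  out <- NULL
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    h <- z[rr, cc]
    if (is.na(h) || h < params$min_tree_height_m) next
    diam <- window_scale * (params$seed_window_c * h^params$seed_window_d +
                              params$seed_window_floor_m)
    rad <- max(diam / 2 / res, 1)
    R <- floor(rad)
    ok <- TRUE
    for (dc in -R:R) for (dr in -R:R) {
      if (dr == 0 && dc == 0) next
      if (dr^2 + dc^2 > rad^2) next
      r2 <- rr + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      q <- z[r2, c2]
      if (is.na(q)) next
      if (q > h || (q == h && ((c2 - 1) * nr + r2) < ((cc - 1) * nr + rr))) {
        ok <- FALSE; break
      }
    }
    if (ok) out <- rbind(out, c(rr, cc, h))
  }
  if (is.null(out)) return(data.frame(row = integer(), col = integer(),
                                      height = numeric()))
  data.frame(row = out[, 1], col = out[, 2], height = out[, 3])
}

# Reference region grower: same documented rule (height-descending queue,
# ties by pixel index then region id; join iff unclaimed, > th_seed * seed,
# > th_cr * running region mean, within max radius of the seed), realised
# with a flat candidate list re-scanned at every step.
grow_oracle <- function(chm, seeds, th_seed, th_cr, max_rad, res) {
  nr <- nrow(chm); nc <- ncol(chm)
  lab <- matrix(0L, nr, nc)
  sumh <- seeds$height
  cnt <- rep(1L, nrow(seeds))
  cand_h <- numeric(0); cand_p <- integer(0); cand_r <- integer(0)
  push_nb <- function(r, c, k) {
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (lab[rr, cc] > 0) next
      h <- chm[rr, cc]
      if (is.na(h)) next
      cand_h <<- c(cand_h, h)
      cand_p <<- c(cand_p, (cc - 1L) * nr + rr)
      cand_r <<- c(cand_r, k)
    }
  }
  for (k in seq_len(nrow(seeds))) lab[seeds$row[k], seeds$col[k]] <- k
  for (k in seq_len(nrow(seeds))) push_nb(seeds$row[k], seeds$col[k], k)
  while (length(cand_h)) {
    best <- order(-cand_h, cand_p, cand_r)[1]
    h <- cand_h[best]; p <- cand_p[best]; k <- cand_r[best]
    cand_h <- cand_h[-best]; cand_p <- cand_p[-best]; cand_r <- cand_r[-best]
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    if (lab[r, c] > 0) next
    if (!(h > th_seed * seeds$height[k])) next
    if (!(h > th_cr * sumh[k] / cnt[k])) next
    if (sqrt((r - seeds$row[k])^2 + (c - seeds$col[k])^2) * res > max_rad[k])
      next
    lab[r, c] <- k
    sumh[k] <- sumh[k] + h; cnt[k] <- cnt[k] + 1L
    push_nb(r, c, k)
  }
  lab
}

# Flow-accumulation oracle: accumulation solves acc = 1 + W' acc where
# W[i, j] is the fraction of cell i's flow routed to cell j, i.e.
# acc = (I - W')^{-1} 1 by dense linear algebra.
accumulation_oracle <- function(z, res, routing = c("mfd", "d8")) {
  routing <- match.arg(routing)
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  off <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
               dc = c(0, 0, -1, 1, -1, 1, -1, 1))
  dist <- sqrt(off[, 1]^2 + off[, 2]^2) * res
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    sl <- rep(-Inf, 8); tgt <- rep(NA_integer_, 8)
    for (k in 1:8) {
      rr <- r + off[k, 1]; cc <- c + off[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      j <- (cc - 1) * nr + rr
      sl[k] <- (z[i] - z[j]) / dist[k]
      tgt[k] <- j
    }
    down <- which(sl > 0)
    if (length(down) == 0) next
    if (routing == "d8") {
      k <- down[which.max(sl[down])]
      W[i, tgt[k]] <- 1
    } else {
      W[i, tgt[down]] <- sl[down] / sum(sl[down])
    }
  }
  acc <- solve(diag(n) - t(W), rep(1, n))
  matrix(acc, nr, nc)
}

# Paraboloid-disc truth labels: reference crown set for benchmarking, built
# directly from the ground-truth tree list.
truth_labels <- function(truth, config, survey = "t1") {
  res <- config$chm_res_m
  nc <- round(config$extent_m[1] / res)
  nr <- round(config$extent_m[2] / res)
  lab <- matrix(0L, nr, nc)
  R <- if (survey == "t1") truth$crown_radius_t1 else truth$crown_radius_t2
  for (i in seq_len(nrow(truth))) {
    if (!is.finite(R[i]) || R[i] <= 0) next
    c0 <- max(1, floor((truth$x[i] - R[i]) / res) + 1)
    c1 <- min(nc, ceiling((truth$x[i] + R[i]) / res))
    r0 <- max(1, floor((config$extent_m[2] - truth$y[i] - R[i]) / res) + 1)
    r1 <- min(nr, ceiling((config$extent_m[2] - truth$y[i] + R[i]) / res))
    px <- (seq(c0, c1) - 0.5) * res
    py <- config$extent_m[2] - (seq(r0, r1) - 0.5) * res
    d2 <- outer(py, px, function(yy, xx)
      (xx - truth$x[i])^2 + (yy - truth$y[i])^2)
    blk <- lab[r0:r1, c0:c1]
    blk[d2 <= R[i]^2] <- truth$id[i]
    lab[r0:r1, c0:c1] <- blk
  }
  lab
}

# Small random CHM of a few paraboloid crowns plus optional noise, for
# oracle-equivalence sweeps.
random_chm <- function(seed, nr = NULL, nc = NULL, noise = 0.05) {
  set.seed(seed)
  if (is.null(nr)) nr <- sample(15:100, 1)
  if (is.null(nc)) nc <- sample(15:100, 1)
  res <- 0.5
  z <- matrix(0, nr, nc)
  n_tree <- sample(1:6, 1)
  for (i in seq_len(n_tree)) {
    H <- runif(1, 5, 18)
    R <- runif(1, 1.5, 4)
    x <- runif(1, 0, nc * res); y <- runif(1, 0, nr * res)
    px <- (seq_len(nc) - 0.5) * res
    py <- nr * res - (seq_len(nr) - 0.5) * res
    d2 <- outer(py, px, function(yy, xx) (xx - x)^2 + (yy - y)^2)
    crown <- H - (H - 0.4 * H) * d2 / R^2
    crown[d2 > R^2] <- 0
    z <- pmax(z, crown)
  }
  if (noise > 0) z <- pmax(z + matrix(rnorm(length(z), 0, noise), nr, nc), 0)
  height_raster(z, res = res)
}
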