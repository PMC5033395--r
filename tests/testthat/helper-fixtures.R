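# Shared fixtures, memoised for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# a small deterministic landscape (60 x 60 @ 250 m) shared across files
shared_landscape <- function() {
  if (is.null(.fixture_env$stack)) {
    .fixture_env$config <- sim_config(seed = 99, n_rows = 60, n_cols = 60,
                                      n_animals = 6)
    .fixture_env$stack <- generate_landscape(.fixture_env$config)
    .fixture_env$std_stack <- standardize_stack(.fixture_env$stack)
  }
  list(config = .fixture_env$config, stack = .fixture_env$stack,
       std_stack = .fixture_env$std_stack)
}

# small telemetry set on the shared landscape
shared_telemetry <- function() {
  if (is.null(.fixture_env$telemetry)) {
    fx <- shared_landscape()
    .fixture_env$telemetry <- simulate_telemetry(fx$stack, fx$config)
  }
  .fixture_env$telemetry
}

# brute-force TRI: loop over cells and existing neighbours
brute_tri <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) next
    s <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(m[ii, jj]))
        s <- s + (m[i, j] - m[ii, jj])^2
    }
    out[i, j] <- sqrt(s)
  }
  out
}

# O(n^3) convex hull: an edge (i, j) is on the hull iff all other points lie
# on one side
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
      on_hull[i] <- TRUE; on_hull[j] <- TRUE
    }
  }
  which(on_hull)
}

# brute-force single-source shortest path over the explicit 8-connected
# move graph (Bellman-Ford style relaxation until fixpoint)
brute_cwd <- function(f, cs, src_mask) {
  nr <- nrow(f); nc <- ncol(f)
  d <- matrix(Inf, nr, nc)
  d[src_mask & !is.na(f)] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(f[i, j]) || is.infinite(d[i, j])) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(f[ii, jj])) next
        w <- (f[i, j] + f[ii, jj]) / 2 * cs *
          (if (di != 0 && dj != 0) sqrt(2) else 1)
        if (d[i, j] + w < d[ii, jj] - 1e-12) {
          d[ii, jj] <- d[i, j] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d[is.na(f)] <- NA_real_
  d[is.infinite(d)] <- NA_real_
  d
}

# independent conditional-logit log-likelihood (loop form)
brute_ssf_loglik <- function(beta, X, used, stratum) {
  ll <- 0
  for (s in unique(stratum)) {
    ix <- which(stratum == s)
    eta <- as.vector(X[ix, , drop = FALSE] %*% beta)
    ll <- ll + eta[used[ix] == 1] - log(sum(exp(eta)))
  }
  ll
}

# two-regime speed mixture (exponential means in m/min)
speed_mixture <- function(n, p_slow = 0.8, mean_slow = 3, mean_fast = 40) {
  slow <- rbinom(n, 1, p_slow) == 1
  ifelse(slow, rexp(n, 1 / mean_slow), rexp(n, 1 / mean_fast))
}

# independent exhaustive two-segment least-squares over candidate
# breakpoints of the binned log-frequencies (QR solve, no lm.fit reuse)
oracle_broken_stick <- function(speeds, n_bins = 50) {
  qr_ <- quantile(speeds, c(0.001, 0.999), names = FALSE)
  breaks <- seq(qr_[1], qr_[2], length.out = n_bins + 1)
  inr <- speeds[speeds >= breaks[1] & speeds <= breaks[length(breaks)]]
  counts <- hist(inr, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- counts > 0
  x <- mids[keep]; y <- log(counts[keep])
  cand <- breaks[-c(1, length(breaks))]
  cand <- cand[vapply(cand, function(cc)
    sum(x < cc) >= 3 && sum(x >= cc) >= 3, TRUE)]
  rss <- vapply(cand, function(cc) {
    X <- cbind(1, x, pmax(x - cc, 0))
    sum(qr.resid(qr(X), y)^2)
  }, 0)
  cand[which.min(rss)]
}
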