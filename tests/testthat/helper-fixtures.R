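# Shared fixtures, built in code.

# A 1-min rainfall series from a vector of depths starting 2019-04-01 UTC.
rain_series <- function(depths, start = as.POSIXct("2019-04-01", tz = "UTC")) {
  data.frame(time = start + (seq_along(depths) - 1) * 60, depth_mm = depths)
}

# n dry minutes.
dry <- function(hours) rep(0, round(hours * 60))

# A small catchment config for fast tests.
small_catchment_config <- function(nrow = 40, ncol = 40, n_inlets = 8,
                                   n_plots = 6, ...) {
  catchment_config(nrow = nrow, ncol = ncol, n_inlets = n_inlets,
                   n_plots = n_plots, ...)
}

# Short rainfall window for fast end-to-end tests.
short_rainfall_config <- function(days = 30, ...) {
  rainfall_config(start = as.POSIXct("2019-04-01", tz = "UTC"),
                  end = as.POSIXct("2019-04-01", tz = "UTC") + days * 86400,
                  ...)
}

# Exhaustive-fractional-routing oracle for D-infinity accumulation: pushes
# every cell's unit mass down the receiver graph step by step until all
# mass is absorbed. Independent of the package's single-sweep propagation.
oracle_accumulation <- function(fd) {
  n <- length(fd$z)
  cur <- rep(1, n)
  total <- rep(1, n)
  for (it in seq_len(n + 2)) {
    nxt <- rep(0, n)
    for (i in seq_len(n)) {
      if (cur[i] == 0) next
      a <- fd$rec1[i]; b <- fd$rec2[i]
      if (!is.na(a)) nxt[a] <- nxt[a] + fd$p1[i] * cur[i]
      if (!is.na(b)) nxt[b] <- nxt[b] + fd$p2[i] * cur[i]
    }
    total <- total + nxt
    if (all(nxt == 0)) break
    cur <- nxt
  }
  matrix(total, nrow(fd$z), ncol(fd$z))
}

# Oracle destination shares: same stepwise mass pushing, but tracks where
# mass is absorbed (per destination index of the ca-map convention).
oracle_destination_shares <- function(fd, dest_of_cell, n_dest) {
  n <- length(fd$z)
  shares <- matrix(0, n, n_dest)
  for (src in seq_len(n)) {
    cur <- rep(0, n); cur[src] <- 1
    for (it in seq_len(n + 2)) {
      nxt <- rep(0, n)
      for (i in which(cur > 0)) {
        if (dest_of_cell[i] > 0) {
          shares[src, dest_of_cell[i]] <- shares[src, dest_of_cell[i]] + cur[i]
          next
        }
        a <- fd$rec1[i]; b <- fd$rec2[i]
        if (!is.na(a)) nxt[a] <- nxt[a] + fd$p1[i] * cur[i]
        if (!is.na(b)) nxt[b] <- nxt[b] + fd$p2[i] * cur[i]
      }
      if (all(nxt == 0)) break
      cur <- nxt
    }
  }
  shares
}

# Naive single-loop Lyne-Hollick reference (one pass), written separately
# from the package implementation.
naive_lh_pass <- function(x, alpha) {
  f <- numeric(length(x))
  for (i in seq_along(x)) {
    if (i == 1) { f[i] <- 0; next }
    cand <- alpha * f[i - 1] + (1 + alpha) / 2 * (x[i] - x[i - 1])
    f[i] <- min(max(cand, 0), x[i])
  }
  f
}

naive_lh_three_pass <- function(q, alpha) {
  b <- q
  f1 <- naive_lh_pass(b, alpha); b <- b - f1
  f2 <- naive_lh_pass(rev(b), alpha); b <- rev(rev(b) - f2)
  f3 <- naive_lh_pass(b, alpha); b <- b - f3
  q - b
}

# Storm-shaped synthetic hydrograph.
storm_hydrograph <- function(n = 600, base = 4, peak = 60, centre = 200,
                             width = 40) {
  base + peak * exp(-((seq_len(n) - centre)^2) / (2 * width^2))
}
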