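# Independent brute-force oracles: naive loop implementations kept
# deliberately separate from the package's vectorised code paths.

# frame-by-frame relative displacement by explicit loops
oracle_rd <- function(beak_x, beak_y, body_height_mean) {
  n <- length(beak_x)
  out <- rep(NA_real_, n)
  for (t in 2:n) {
    out[t] <- sqrt((beak_x[t] - beak_x[t - 1])^2 +
                     (beak_y[t] - beak_y[t - 1])^2) / body_height_mean
  }
  out
}

# delta statistics for an event starting at 0-based frame s; rd is the
# per-frame vector indexed from frame 0; returns NULL when the strict
# policy would skip the event
oracle_delta <- function(rd, s, b, w) {
  i <- s + 1
  base_idx <- (i - b + 1):i
  post_idx <- i:(i + w - 1)
  if (base_idx[1] < 1 || post_idx[w] > length(rd)) return(NULL)
  base <- rd[base_idx]
  post <- rd[post_idx]
  if (any(is.na(base)) || any(is.na(post))) return(NULL)
  list(delta_mean = mean(post) - mean(base),
       delta_max = max(post) - max(base))
}

# 0-based frames eligible as pseudo-event starts, by checking every frame
oracle_eligible <- function(rd, b, w) {
  out <- integer(0)
  for (s in 0:(length(rd) - 1)) {
    if (!is.null(oracle_delta(rd, s, b, w))) out <- c(out, s)
  }
  out
}

# exact null for one individual drawing k frames iid from vals:
# enumerate all ordered tuples (supported for k <= 3), returning every
# tuple's mean with equal weight 1/n^k
oracle_ordered_null <- function(vals, k) {
  n <- length(vals)
  if (k == 1) {
    vals
  } else if (k == 2) {
    means <- numeric(n * n)
    m <- 0
    for (i in 1:n) for (j in 1:n) {
      m <- m + 1
      means[m] <- (vals[i] + vals[j]) / 2
    }
    means
  } else if (k == 3) {
    means <- numeric(n^3)
    m <- 0
    for (i in 1:n) for (j in 1:n) for (l in 1:n) {
      m <- m + 1
      means[m] <- (vals[i] + vals[j] + vals[l]) / 3
    }
    means
  } else {
    stop("oracle supports k <= 3")
  }
}

# unordered pairs (multisets of size 2) and their means, by double loop
oracle_pair_means <- function(vals) {
  n <- length(vals)
  out <- numeric(0)
  for (i in 1:n) for (j in i:n) {
    out <- c(out, (vals[i] + vals[j]) / 2)
  }
  out
}

# Expected per-event delta_mean for the generator's startle pulse.
# The pulse moves the beak along a closed polygon: `dur` consecutive
# frames each with displacement M body heights, starting `latency`
# frames after the element onset.  Baseline frames carry jitter-only
# displacement whose magnitude is Rayleigh with scale s = jitter*sqrt(2)
# (difference of two iid jitters per axis), mean s*sqrt(pi/2).  Pulse
# frames have magnitude |M + noise| ~ M + s^2/(2M) to second order.
oracle_expected_delta <- function(M, jitter, dur, latencies, w) {
  s <- jitter * sqrt(2)
  mu_j <- s * sqrt(pi / 2)
  e_pulse <- if (M > 0) M + s^2 / (2 * M) else mu_j
  overlaps <- vapply(latencies, function(L) {
    max(0, min(dur, w - L))
  }, numeric(1))
  mean(overlaps) * (e_pulse - mu_j) / w
}

# two-sided tail probability of an enumerated null, robust to last-ulp
# differences between independently computed tied values
oracle_tail_p <- function(values, obs, eps = 1e-12) {
  p_up <- mean(values >= obs - eps)
  p_lo <- mean(values <= obs + eps)
  min(1, 2 * min(p_up, p_lo))
}

# two-group permutation p-value by full enumeration of label
# assignments, using independent combinatorics (recursive index walk)
oracle_permutation_p <- function(props, is_owner) {
  n <- length(props)
  k <- sum(is_owner)
  obs <- mean(props[is_owner]) - mean(props[!is_owner])
  stats <- numeric(0)
  rec <- function(start, chosen) {
    if (length(chosen) == k) {
      sel <- logical(n)
      sel[chosen] <- TRUE
      stats <<- c(stats, mean(props[sel]) - mean(props[!sel]))
      return()
    }
    if (start > n) return()
    for (i in start:n) rec(i + 1, c(chosen, i))
  }
  rec(1, integer(0))
  p_up <- mean(stats >= obs)
  p_lo <- mean(stats <= obs)
  list(observed = obs, n_assignments = length(stats),
       p_value = min(1, 2 * min(p_up, p_lo)))
}
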