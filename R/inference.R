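# Individual-balanced bootstrap null for the group delta statistic.
#
# Null construction mirrors the observed statistic exactly: a random
# frame is treated as a pseudo-event start (occurrence frame shared by
# baseline and post), each individual contributes as many random frames
# as it contributed display elements, frame draws are with replacement
# and pooled across the individual's bouts, per-individual means are
# averaged unweighted into the group replicate.

#' Inference configuration
#'
#' @param reps Bootstrap replicates B (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param tail `"two_sided"` (default), `"upper"` or `"lower"`.
#' @param post_sizes Post-window sizes for [window_sweep()] (default
#'   4:50).
#' @param baseline_sizes Baseline sizes for the robustness sweep
#'   (default 5, 10, 15, 20).
#' @param default_baseline Baseline held fixed while post size varies
#'   (default 10).
#' @param seed Seed for the bootstrap RNG (NULL: leave RNG state alone).
#' @param exhaustive If TRUE, enumerate the null exactly (all
#'   per-individual frame multisets with their sampling weights) instead
#'   of Monte-Carlo resampling; only feasible on tiny datasets.
#' @param max_exhaustive Cap on the enumeration size.
#' @param statistic `"delta_mean"` (default) or `"delta_max"`.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(reps = 1000L, alpha = 0.05,
                             tail = c("two_sided", "upper", "lower"),
                             post_sizes = 4:50,
                             baseline_sizes = c(5L, 10L, 15L, 20L),
                             default_baseline = 10L,
                             seed = NULL,
                             exhaustive = FALSE,
                             max_exhaustive = 2e5,
                             statistic = c("delta_mean", "delta_max")) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) {
    .stop_io("reps must be >= 1", class = "peristartle_config_error")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    .stop_io("alpha must lie in (0, 1)", class = "peristartle_config_error")
  }
  structure(list(reps = reps, alpha = alpha, tail = tail,
                 post_sizes = as.integer(post_sizes),
                 baseline_sizes = as.integer(baseline_sizes),
                 default_baseline = as.integer(default_baseline),
                 seed = seed, exhaustive = exhaustive,
                 max_exhaustive = max_exhaustive, statistic = statistic),
            class = "inference_config")
}

#' Empirical p-value from a bootstrap/permutation null
#'
#' Add-one-corrected empirical p:
#' `p_upper = (1 + #\{null >= observed\}) / (B + 1)`,
#' `p_lower = (1 + #\{null <= observed\}) / (B + 1)`,
#' `two_sided = min(1, 2 * min(p_upper, p_lower))`, so p always lies in
#' (0, 1].
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null replicates.
#' @param tail `"two_sided"` (default), `"upper"` or `"lower"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, null,
                        tail = c("two_sided", "upper", "lower")) {
  tail <- match.arg(tail)
  if (length(null) == 0) {
    .stop_io("null distribution is empty",
             class = "peristartle_parameter_error")
  }
  B <- length(null)
  p_upper <- (1 + sum(null >= observed)) / (B + 1)
  p_lower <- (1 + sum(null <= observed)) / (B + 1)
  switch(tail,
         upper = p_upper,
         lower = p_lower,
         two_sided = min(1, 2 * min(p_upper, p_lower)))
}

# exact (weighted-enumeration) p-value; no add-one needed because the
# enumeration is the complete distribution
.weighted_p <- function(observed, values, weights, tail) {
  p_upper <- sum(weights[values >= observed])
  p_lower <- sum(weights[values <= observed])
  switch(tail,
         upper = p_upper,
         lower = p_lower,
         two_sided = min(1, 2 * min(p_upper, p_lower)))
}

.weighted_quantile <- function(values, weights, probs) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(probs, function(p) v[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Per-individual eligible frame sets
#'
#' A frame is eligible as a pseudo-event start iff its full baseline and
#' post segments lie inside one bout with every RD value defined (the
#' strict policy).  Individuals with zero eligible frames are dropped
#' with a warning.
#'
#' @param rd An `rd_series` tibble.
#' @param window A [window_spec()].
#' @param metadata Bout metadata (maps bouts to males).
#' @return A tibble with columns `male_id`, `bout_id`, `frame`.
#' @export
eligible_frames <- function(rd, window, metadata) {
  rvecs <- .rd_vectors(rd)
  male_of <- setNames(metadata$male_id, metadata$bout_id)
  rows <- lapply(names(rvecs), function(bout) {
    dall <- .delta_mean_all(rvecs[[bout]], window$baseline, window$post)
    fr <- which(!is.na(dall)) - 1L
    if (length(fr) == 0) return(NULL)
    tibble(male_id = unname(male_of[bout]), bout_id = bout, frame = fr)
  })
  out <- bind_rows(c(
    list(tibble(male_id = character(), bout_id = character(),
                frame = integer())),
    rows
  ))
  empty <- setdiff(unique(male_of[names(rvecs)]), unique(out$male_id))
  if (length(empty) > 0) {
    warning("Individual(s) with zero eligible frames excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  arrange(out, .data$male_id, .data$bout_id, .data$frame)
}

# Assemble per-male inputs for the bootstrap: the observed per-male mean
# delta at real element onsets and the pool of delta values at eligible
# frames.  Returns NULL-male-free structure; warns about exclusions.
.group_inputs <- function(rvecs, events, metadata, status_group,
                          element_class, window, statistic) {
  males <- unique(metadata$male_id[metadata$status == status_group])
  if (length(males) == 0) {
    .stop_io("No males with status '", status_group, "'",
             class = "peristartle_empty_group_error")
  }
  male_of <- setNames(metadata$male_id, metadata$bout_id)
  bouts_of <- split(metadata$bout_id, metadata$male_id)

  fn_all <- if (statistic == "delta_mean") .delta_mean_all else .delta_max_all
  dall <- lapply(rvecs, fn_all, b = window$baseline, w = window$post)

  ev <- events[events$intensity_class == element_class &
                 male_of[events$bout_id] %in% males, , drop = FALSE]

  per_male <- list()
  dropped <- character()
  for (m in males) {
    bouts <- intersect(bouts_of[[m]], names(dall))
    pool <- unlist(lapply(dall[bouts], function(v) v[!is.na(v)]),
                   use.names = FALSE)
    evm <- ev[ev$bout_id %in% bouts, , drop = FALSE]
    obs_vals <- rep(NA_real_, nrow(evm))
    if (nrow(evm) > 0) {
      obs_vals <- vapply(seq_len(nrow(evm)), function(k) {
        dall[[evm$bout_id[k]]][evm$start_frame[k] + 1L]
      }, numeric(1))
    }
    obs_vals <- obs_vals[!is.na(obs_vals)]
    if (length(obs_vals) == 0 || length(pool) == 0) {
      dropped <- c(dropped, m)
      next
    }
    per_male[[m]] <- list(obs = obs_vals, pool = pool,
                          n_events = length(obs_vals),
                          n_eligible = length(pool))
  }
  if (length(dropped) > 0) {
    warning("Individual(s) excluded (no usable '", element_class,
            "' elements or no eligible frames): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(per_male) == 0) {
    .stop_io("No usable individuals in status group '", status_group, "'",
             class = "peristartle_empty_group_error")
  }
  per_male
}

# Monte-Carlo replicate grand means
.mc_replicates <- function(per_male, B) {
  K <- length(per_male)
  acc <- numeric(B)
  for (pm in per_male) {
    n_i <- pm$n_events
    idx <- sample.int(pm$n_eligible, B * n_i, replace = TRUE)
    acc <- acc + rowMeans(matrix(pm$pool[idx], nrow = B, ncol = n_i))
  }
  acc / K
}

# multisets of size k from n items, stars-and-bars over combn;
# returns values (mean of sampled deltas) and iid sampling weights
.enumerate_male <- function(vals, k, cap) {
  n <- length(vals)
  if (choose(n + k - 1, k) > cap) {
    .stop_io("Exhaustive enumeration size exceeds max_exhaustive",
             class = "peristartle_config_error")
  }
  combos <- utils::combn(n + k - 1L, k)
  idx <- combos - (seq_len(k) - 1L)  # column-wise non-decreasing indices
  means <- colMeans(matrix(vals[idx], nrow = k))
  logw <- apply(idx, 2, function(ii) {
    mult <- table(ii)
    lgamma(k + 1) - sum(lgamma(mult + 1)) - k * log(n)
  })
  list(values = means, weights = exp(logw))
}

.exhaustive_replicates <- function(per_male, cap) {
  K <- length(per_male)
  dists <- lapply(per_male, function(pm) {
    .enumerate_male(pm$pool, pm$n_events, cap)
  })
  comb <- dists[[1]]
  comb$values <- comb$values / K
  if (K > 1) {
    for (j in 2:K) {
      v <- outer(comb$values, dists[[j]]$values / K, `+`)
      w <- outer(comb$weights, dists[[j]]$weights)
      if (length(v) > cap) {
        .stop_io("Exhaustive enumeration size exceeds max_exhaustive",
                 class = "peristartle_config_error")
      }
      comb <- list(values = as.numeric(v), weights = as.numeric(w))
    }
  }
  comb
}

#' Bootstrap null distribution for the group delta
#'
#' Builds the sampling distribution of the group-level delta under the
#' null hypothesis that display elements of the given class are no more
#' startling than random moments of courtship: per replicate, each
#' individual contributes the mean delta at as many random eligible
#' frames (drawn with replacement, pooled across its bouts) as it
#' contributed elements, and individual means are averaged unweighted.
#'
#' @param dataset A `startle_dataset` (tracks assumed cleaned).
#' @param status_group `"owner"` or `"subordinate"`.
#' @param element_class `"high"` (default) or `"low"`.
#' @param window A [window_spec()].
#' @param config An [inference_config()].
#' @param rd Optional precomputed `rd_series` (computed from the tracks
#'   when NULL).
#' @return An object of class `null_distribution`: observed statistic,
#'   replicate vector (with weights in exhaustive mode), 2.5/97.5%
#'   quantile limits, empirical p-value and per-male bookkeeping.
#' @export
bootstrap_null <- function(dataset, status_group,
                           element_class = c("high", "low"),
                           window = window_spec(),
                           config = inference_config(),
                           rd = NULL) {
  element_class <- match.arg(element_class)
  if (is.null(rd)) {
    metrics <- compute_body_metrics(dataset$tracks)
    rd <- relative_displacement(dataset$tracks, metrics)
  }
  per_male <- .group_inputs(.rd_vectors(rd), dataset$events,
                            dataset$metadata, status_group, element_class,
                            window, config$statistic)
  .bootstrap_core(per_male, status_group, element_class, window, config)
}

.bootstrap_core <- function(per_male, status_group, element_class, window,
                            config) {
  observed <- mean(vapply(per_male, function(pm) mean(pm$obs), numeric(1)))
  probs <- c(config$alpha / 2, 1 - config$alpha / 2)

  if (isTRUE(config$exhaustive)) {
    en <- .exhaustive_replicates(per_male, config$max_exhaustive)
    q <- .weighted_quantile(en$values, en$weights, probs)
    p <- .weighted_p(observed, en$values, en$weights, config$tail)
    reps <- en$values
    weights <- en$weights
    mode <- "exhaustive"
  } else {
    if (!is.null(config$seed)) withr::local_seed(as.integer(config$seed))
    reps <- .mc_replicates(per_male, config$reps)
    q <- unname(quantile(reps, probs))
    p <- empirical_p(observed, reps, config$tail)
    weights <- NULL
    mode <- "monte_carlo"
  }

  males <- tibble(
    male_id = names(per_male),
    n_events = vapply(per_male, function(pm) pm$n_events, integer(1)),
    n_eligible = vapply(per_male, function(pm) pm$n_eligible, integer(1)),
    mean_delta = vapply(per_male, function(pm) mean(pm$obs), numeric(1))
  )
  structure(
    list(status = status_group, element_class = element_class,
         window = window, B = length(reps), replicates = reps,
         weights = weights, q_lower = q[1], q_upper = q[2],
         observed = observed, p_value = p, tail = config$tail,
         seed = config$seed, males = males, mode = mode,
         statistic = config$statistic),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$mode, "\n")
  cat(sprintf("  group: %s, class: %s, baseline %d + post %d\n",
              x$status, x$element_class, x$window$baseline, x$window$post))
  cat(sprintf("  observed %s = %.5f, null [%.5f, %.5f], p = %.4g (%s)\n",
              x$statistic, x$observed, x$q_lower, x$q_upper,
              x$p_value, x$tail))
  cat(sprintf("  %d replicates over %d individual(s)\n",
              x$B, nrow(x$males)))
  invisible(x)
}

.derive_cell_seed <- function(seed, idx) {
  if (is.null(seed)) return(NULL)
  (abs(as.integer(seed)) %% 100000L) * 20011L + as.integer(idx)
}

#' Window and baseline robustness sweep
#'
#' Re-runs the bootstrap test over a grid of post-window sizes (default
#' 4:50) crossed with baseline sizes (default 5, 10, 15, 20), per status
#' group and intensity class.  Each cell's null is resampled with a seed
#' derived deterministically from `config$seed` and the cell's position,
#' so any single cell can be reproduced in isolation.
#'
#' @param dataset A `startle_dataset`.
#' @param config An [inference_config()].
#' @param statuses Status groups to include.
#' @param classes Intensity classes to include.
#' @return A tibble of class `sweep_result`, one row per
#'   status x class x post x baseline cell, with the observed delta, null
#'   mean, quantile limits, p-value and significance flag
#'   (observed outside the `[q_lower, q_upper]` band).
#' @export
window_sweep <- function(dataset, config = inference_config(),
                         statuses = c("owner", "subordinate"),
                         classes = c("high", "low")) {
  metrics <- compute_body_metrics(dataset$tracks)
  rd <- relative_displacement(dataset$tracks, metrics)
  rvecs <- .rd_vectors(rd)

  grid <- expand.grid(post = config$post_sizes,
                      baseline = config$baseline_sizes,
                      intensity_class = classes,
                      status = statuses,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$status, grid$intensity_class, grid$baseline,
                     grid$post), , drop = FALSE]

  rows <- vector("list", nrow(grid))
  for (idx in seq_len(nrow(grid))) {
    g <- grid[idx, ]
    window <- window_spec(g$baseline, g$post)
    cell_cfg <- config
    cell_cfg$seed <- .derive_cell_seed(config$seed, idx)
    cell_cfg$exhaustive <- FALSE
    res <- tryCatch(
      {
        per_male <- .group_inputs(rvecs, dataset$events, dataset$metadata,
                                  g$status, g$intensity_class, window,
                                  config$statistic)
        .bootstrap_core(per_male, g$status, g$intensity_class, window,
                        cell_cfg)
      },
      peristartle_empty_group_error = function(e) NULL
    )
    if (is.null(res)) next
    rows[[idx]] <- tibble(
      status = g$status, intensity_class = g$intensity_class,
      post = g$post, baseline = g$baseline,
      observed = res$observed, null_mean = mean(res$replicates),
      q_lower = res$q_lower, q_upper = res$q_upper,
      p_value = res$p_value,
      significant = res$observed < res$q_lower | res$observed > res$q_upper,
      n_males = nrow(res$males),
      n_events = sum(res$males$n_events),
      seed = if (is.null(cell_cfg$seed)) NA_integer_ else cell_cfg$seed
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Leave-one-out stability of the group delta
#'
#' Omits one male at a time from a status group and recomputes the
#' observed delta and its bootstrap p-value, flagging sign changes of
#' the statistic and changes of the significance call relative to the
#' full group.
#'
#' @inheritParams bootstrap_null
#' @return A tibble with one row per omitted male; the full-group result
#'   is attached as attribute `"full"`.
#' @export
leave_one_out <- function(dataset, status_group,
                          element_class = c("high", "low"),
                          window = window_spec(),
                          config = inference_config()) {
  element_class <- match.arg(element_class)
  metrics <- compute_body_metrics(dataset$tracks)
  rd <- relative_displacement(dataset$tracks, metrics)
  rvecs <- .rd_vectors(rd)
  per_male <- .group_inputs(rvecs, dataset$events, dataset$metadata,
                            status_group, element_class, window,
                            config$statistic)
  if (length(per_male) < 2) {
    .stop_io("Leave-one-out stability is undefined for a group of ",
             length(per_male), class = "peristartle_parameter_error")
  }
  full <- .bootstrap_core(per_male, status_group, element_class, window,
                          config)
  males <- names(per_male)
  rows <- vector("list", length(males))
  for (i in seq_along(males)) {
    # same seed for every omission so identical remaining data give
    # identical rows
    res <- .bootstrap_core(per_male[males != males[i]], status_group,
                           element_class, window, config)
    rows[[i]] <- tibble(
      omitted_male = males[i],
      observed = res$observed,
      p_value = res$p_value,
      significant = res$observed < res$q_lower | res$observed > res$q_upper,
      sign_change = sign(res$observed) != sign(full$observed),
      significance_change =
        (res$observed < res$q_lower | res$observed > res$q_upper) !=
        (full$observed < full$q_lower | full$observed > full$q_upper)
    )
  }
  out <- bind_rows(rows)
  attr(out, "full") <- full
  out
}
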