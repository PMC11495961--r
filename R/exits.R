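# Bower-exit scoring, the courter-status contrast, and automatic-vs-
# manual annotation agreement.

#' Score bower-exit outcomes after display elements
#'
#' Each exit is attributed to the most recent display element (of any
#' class) whose start frame precedes it within the same bout, optionally
#' within `max_lag` frames.  An element's outcome is 1 iff at least one
#' exit is attributed to it.  Outcomes are then restricted to
#' `class_filter` (and optionally to specific element types, e.g. the
#' mock-attack-only analysis).
#'
#' @param events Display-event tibble (sorted per bout by start frame).
#' @param exits Exit tibble (`bout_id`, `frame`).
#' @param class_filter Intensity class(es) whose elements are scored
#'   (default `"high"`).
#' @param element_types Optional element-type filter applied after
#'   attribution.
#' @param max_lag Maximum frames between element start and exit for
#'   attribution (default `Inf`).
#' @return A tibble with one row per scored element (`bout_id`,
#'   `element_type`, `intensity_class`, `start_frame`, `outcome`);
#'   unattributed exits are listed in attribute `"unattributed"` with a
#'   warning.
#' @export
score_exits <- function(events, exits, class_filter = "high",
                        element_types = NULL, max_lag = Inf) {
  events <- arrange(events, .data$bout_id, .data$start_frame)
  hit <- rep(FALSE, nrow(events))
  unattributed <- list()
  for (bout in unique(exits$bout_id)) {
    ex_fr <- sort(exits$frame[exits$bout_id == bout])
    ev_idx <- which(events$bout_id == bout)
    starts <- events$start_frame[ev_idx]
    for (f in ex_fr) {
      j <- findInterval(f, starts)  # last element with start <= f
      if (j >= 1 && f - starts[j] <= max_lag) {
        hit[ev_idx[j]] <- TRUE
      } else {
        unattributed[[length(unattributed) + 1L]] <-
          tibble(bout_id = bout, frame = f)
      }
    }
  }
  unattributed <- if (length(unattributed) > 0) {
    bind_rows(unattributed)
  } else {
    tibble(bout_id = character(), frame = integer())
  }
  if (nrow(unattributed) > 0) {
    warning(nrow(unattributed),
            " exit(s) could not be attributed to any preceding element",
            call. = FALSE)
  }
  keep <- events$intensity_class %in% class_filter
  if (!is.null(element_types)) {
    keep <- keep & events$element_type %in% element_types
  }
  out <- tibble(
    bout_id = events$bout_id[keep],
    element_type = events$element_type[keep],
    intensity_class = events$intensity_class[keep],
    start_frame = events$start_frame[keep],
    outcome = as.integer(hit[keep])
  )
  attr(out, "unattributed") <- unattributed
  out
}

#' Test the courter-status effect on bower-exit probability
#'
#' Default method `cluster_permutation`: the statistic is the difference
#' between status groups in the unweighted mean of per-male exit
#' proportions; the null is built by permuting status labels across
#' males (males are the exchangeable units, each keeping its whole
#' outcome vector).  When the number of label assignments is small
#' (<= `max_enumeration`) the permutation distribution is enumerated
#' exhaustively and the p-value is exact; otherwise assignments are
#' sampled and the add-one empirical p-value of [empirical_p()] is used.
#'
#' Method `mixed_model` fits a binomial GLMM of the element-level
#' outcome with status as fixed effect and random intercepts for male
#' and date, and compares it against the null model without status via a
#' likelihood-ratio test.
#'
#' @param outcomes Outcome tibble from [score_exits()].
#' @param metadata Bout metadata tibble (male, status, date per bout).
#' @param method `"cluster_permutation"` (default) or `"mixed_model"`.
#' @param reps Monte-Carlo permutations when not enumerating (default
#'   10000).
#' @param seed Optional RNG seed for Monte-Carlo permutations.
#' @param max_enumeration Enumerate exhaustively when the number of
#'   assignments does not exceed this (default 20000).
#' @return A list of class `exit_test` with the statistic, p-value,
#'   per-male proportions and method details.
#' @export
test_exit_status_effect <- function(outcomes, metadata,
                                    method = c("cluster_permutation",
                                               "mixed_model"),
                                    reps = 10000L, seed = NULL,
                                    max_enumeration = 20000) {
  method <- match.arg(method)
  joined <- left_join(outcomes,
                      metadata[c("bout_id", "male_id", "status", "date")],
                      by = "bout_id")
  if (anyNA(joined$male_id)) {
    .stop_io("Outcome(s) reference bouts missing from metadata",
             class = "peristartle_referential_error")
  }
  if (length(unique(joined$status)) < 2) {
    .stop_io("Both status groups must be non-empty",
             class = "peristartle_empty_group_error")
  }

  if (method == "mixed_model") {
    joined$date <- as.factor(joined$date)
    full <- lme4::glmer(outcome ~ status + (1 | male_id) + (1 | date),
                        data = joined, family = stats::binomial)
    null <- lme4::glmer(outcome ~ (1 | male_id) + (1 | date),
                        data = joined, family = stats::binomial)
    lrt <- stats::anova(null, full)
    return(structure(list(
      method = method,
      chisq = lrt$Chisq[2], df = lrt$Df[2], p_value = lrt$`Pr(>Chisq)`[2],
      full_model = full, null_model = null
    ), class = "exit_test"))
  }

  per_male <- joined |>
    group_by(.data$male_id, .data$status) |>
    summarise(prop = mean(.data$outcome), n_elements = dplyr::n(),
              .groups = "drop")
  n_by_status <- table(per_male$status)
  if (any(n_by_status < 2)) {
    .stop_io("cluster permutation needs >= 2 males per status group",
             class = "peristartle_insufficient_clusters_error")
  }
  props <- per_male$prop
  is_owner <- per_male$status == "owner"
  n <- length(props)
  n_owner <- sum(is_owner)
  stat_for <- function(owner_idx) {
    mean(props[owner_idx]) - mean(props[-owner_idx])
  }
  observed <- stat_for(which(is_owner))

  n_assign <- choose(n, n_owner)
  if (n_assign <= max_enumeration) {
    combos <- utils::combn(n, n_owner)
    null_stats <- apply(combos, 2, stat_for)
    p_upper <- mean(null_stats >= observed)
    p_lower <- mean(null_stats <= observed)
    p <- min(1, 2 * min(p_upper, p_lower))
    mode <- "exhaustive"
  } else {
    if (!is.null(seed)) withr::local_seed(as.integer(seed))
    null_stats <- vapply(seq_len(reps), function(i) {
      stat_for(sample.int(n, n_owner))
    }, numeric(1))
    p <- empirical_p(observed, null_stats, "two_sided")
    mode <- "monte_carlo"
  }
  structure(list(
    method = method, mode = mode, statistic = observed, p_value = p,
    null = null_stats, n_assignments = n_assign, per_male = per_male,
    seed = seed
  ), class = "exit_test")
}

#' @export
print.exit_test <- function(x, ...) {
  cat("<exit_test>", x$method, "\n")
  if (x$method == "mixed_model") {
    cat(sprintf("  LRT chisq = %.3f, df = %d, p = %.4g\n",
                x$chisq, x$df, x$p_value))
  } else {
    cat(sprintf("  %s, %d assignments\n", x$mode, x$n_assignments))
    cat(sprintf("  statistic (owner - subordinate) = %.4f, p = %.4g\n",
                x$statistic, x$p_value))
  }
  invisible(x)
}

#' Agreement between automatic and manual keypoint annotations
#'
#' Compares two tracks sharing (bout, frame, keypoint) keys: per
#' keypoint, the Euclidean error per shared frame summarised as
#' mean +/- sd in pixels and in body-height fractions (pixel error
#' divided by the bout's mean body height), plus per-axis Pearson
#' correlations.
#'
#' @param auto,manual Keypoint track tibbles.
#' @param metrics `body_metrics` for the bouts compared (computed from
#'   `auto` when NULL).
#' @return A tibble of class `agreement_stats`, one row per keypoint.
#' @export
annotation_agreement <- function(auto, manual, metrics = NULL) {
  if (is.null(metrics)) metrics <- compute_body_metrics(auto)
  bout_mean <- setNames(metrics$bouts$body_height_mean, metrics$bouts$bout_id)
  shared <- inner_join(
    auto[auto$valid, c("bout_id", "frame", "keypoint", "x", "y")],
    manual[manual$valid, c("bout_id", "frame", "keypoint", "x", "y")],
    by = c("bout_id", "frame", "keypoint"), suffix = c("_auto", "_manual")
  )
  if (nrow(shared) == 0) {
    .stop_io("No shared (bout, frame, keypoint) records to compare",
             class = "peristartle_empty_comparison_error")
  }
  shared$err_px <- sqrt((shared$x_auto - shared$x_manual)^2 +
                          (shared$y_auto - shared$y_manual)^2)
  shared$err_bh <- shared$err_px / bout_mean[shared$bout_id]
  out <- shared |>
    group_by(.data$keypoint) |>
    summarise(
      n_frames = dplyr::n(),
      mean_err_px = mean(.data$err_px),
      sd_err_px = sd(.data$err_px),
      mean_err_bh = mean(.data$err_bh),
      sd_err_bh = sd(.data$err_bh),
      cor_x = if (dplyr::n() > 1 && sd(.data$x_auto) > 0 &&
                    sd(.data$x_manual) > 0) {
        cor(.data$x_auto, .data$x_manual)
      } else {
        NA_real_
      },
      cor_y = if (dplyr::n() > 1 && sd(.data$y_auto) > 0 &&
                    sd(.data$y_manual) > 0) {
        cor(.data$y_auto, .data$y_manual)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  class(out) <- c("agreement_stats", class(out))
  out
}
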