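# Relative displacement and peri-event delta statistics.
#
# RD normalises the beak tip's frame-to-frame Euclidean displacement by
# the bout's mean body height, so RD = 0.15 means a head movement of 15%
# of body size in one frame (33 ms at 30 fps).

#' Convert a frame count to milliseconds
#'
#' @param frames Number of frames.
#' @param fps Frames per second (default 30).
#' @return Duration in milliseconds.
#' @examples
#' frames_to_ms(4, 30) # ~133 ms, the shortest post window considered
#' @export
frames_to_ms <- function(frames, fps = 30) {
  stopifnot(fps > 0)
  1000 * frames / fps
}

#' Relative displacement series
#'
#' For each frame t >= 1, RD(t) is the Euclidean distance between the
#' beak-tip position at t and at t - 1, divided by the bout's mean body
#' height.  RD is undefined at frame 0 and wherever the beak record is
#' invalid in the frame or its predecessor.
#'
#' @param tracks Keypoint track tibble.
#' @param metrics `body_metrics` for the same tracks (computed if NULL).
#' @return A tibble with columns `bout_id`, `frame`, `rd`, `defined`,
#'   of class `rd_series`.
#' @export
relative_displacement <- function(tracks, metrics = NULL) {
  if (is.null(metrics)) metrics <- compute_body_metrics(tracks)
  bout_mean <- setNames(metrics$bouts$body_height_mean, metrics$bouts$bout_id)
  per_bout <- split(seq_len(nrow(tracks)), tracks$bout_id)
  out <- vector("list", length(per_bout))
  for (i in seq_along(per_bout)) {
    bout <- names(per_bout)[i]
    sub <- tracks[per_bout[[i]], ]
    L <- max(sub$frame) + 1L
    H <- bout_mean[[bout]]
    if (!is.finite(H) || H <= 0) {
      .stop_io("Bout '", bout, "' has non-positive mean body height",
               class = "peristartle_degenerate_geometry_error")
    }
    bx <- .kp_vector(sub, "beak_tip", "x", L)
    by <- .kp_vector(sub, "beak_tip", "y", L)
    rd <- c(NA_real_, sqrt(diff(bx)^2 + diff(by)^2)) / H
    out[[i]] <- tibble(bout_id = bout, frame = seq_len(L) - 1L,
                       rd = rd, defined = !is.na(rd))
  }
  res <- bind_rows(out)
  class(res) <- c("rd_series", class(res))
  res
}

#' Peri-event window specification
#'
#' The baseline segment spans the `baseline` frames up to and including
#' the element's start frame; the post segment spans the `post` frames
#' from the start frame onward.  The occurrence frame is deliberately
#' shared by both segments.
#'
#' @param baseline Baseline length in frames (default 10).
#' @param post Post length in frames.
#' @return A `window_spec` list with elements `baseline` and `post`.
#' @export
window_spec <- function(baseline = 10L, post = 10L) {
  baseline <- as.integer(baseline)
  post <- as.integer(post)
  if (is.na(baseline) || is.na(post) || baseline < 1L || post < 1L) {
    .stop_io("baseline and post must be integers >= 1",
             class = "peristartle_parameter_error")
  }
  structure(list(baseline = baseline, post = post), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> baseline %d + post %d frames (start frame shared)\n",
              x$baseline, x$post))
  invisible(x)
}

# rd vector for one bout, 1-based position i <-> frame i - 1
.rd_vectors <- function(rd) {
  lapply(split(rd$rd, rd$bout_id), as.numeric)
}

# delta_mean at every frame of one rd vector: position i carries the
# statistic for a (pseudo-)event starting at frame i - 1; NA where either
# segment leaves the bout or touches an undefined rd value.
.delta_mean_all <- function(r, b, w) {
  L <- length(r)
  out <- rep(NA_real_, L)
  if (L < max(b, w)) return(out)
  S <- c(0, cumsum(ifelse(is.na(r), 0, r)))
  Nna <- c(0, cumsum(is.na(r)))
  i <- seq.int(b, L - w + 1L)
  base_sum <- S[i + 1L] - S[i - b + 1L]
  base_na <- Nna[i + 1L] - Nna[i - b + 1L]
  post_sum <- S[i + w] - S[i]
  post_na <- Nna[i + w] - Nna[i]
  val <- post_sum / w - base_sum / b
  val[base_na > 0 | post_na > 0] <- NA_real_
  out[i] <- val
  out
}

# delta_max analogue (rolling maxima; NAs propagate, matching strict policy)
.delta_max_all <- function(r, b, w) {
  L <- length(r)
  out <- rep(NA_real_, L)
  if (L < max(b, w)) return(out)
  post_max <- zoo::rollapply(r, width = w, FUN = max, align = "left",
                             fill = NA_real_)
  base_max <- zoo::rollapply(r, width = b, FUN = max, align = "right",
                             fill = NA_real_)
  i <- seq.int(b, L - w + 1L)
  out[i] <- post_max[i] - base_max[i]
  out
}

#' Baseline-corrected peri-event delta statistics
#'
#' For each display element, isolates the RD values in the baseline
#' segment (frames `s - b + 1 ... s`) and the post segment (frames
#' `s ... s + w - 1`), where `s` is the element's start frame, and
#' computes `delta_mean = mean(post) - mean(baseline)` and
#' `delta_max = max(post) - max(baseline)`.  Under the default `strict`
#' policy a record is produced only when every frame of both segments
#' lies inside the bout and has a defined RD; otherwise the element is
#' skipped with a logged reason (attribute `"skipped"`).  The `tolerant`
#' policy averages over defined frames provided each segment retains at
#' least `min_coverage` of its frames.
#'
#' @param rd An `rd_series` tibble.
#' @param events Display-event tibble.
#' @param window A [window_spec()].
#' @param policy `"strict"` (default) or `"tolerant"`.
#' @param min_coverage Minimum defined fraction per segment under the
#'   tolerant policy (default 0.8).
#' @return A tibble of delta records (one per evaluable element) with a
#'   `"skipped"` attribute tibble listing skipped elements and reasons.
#' @export
peri_event_deltas <- function(rd, events, window = window_spec(),
                              policy = c("strict", "tolerant"),
                              min_coverage = 0.8) {
  policy <- match.arg(policy)
  b <- window$baseline
  w <- window$post
  rvecs <- .rd_vectors(rd)

  n <- nrow(events)
  delta_mean <- delta_max <- rep(NA_real_, n)
  n_base <- n_post <- rep(NA_integer_, n)
  skip_reason <- rep(NA_character_, n)

  for (k in seq_len(n)) {
    bout <- events$bout_id[k]
    r <- rvecs[[bout]]
    if (is.null(r)) {
      skip_reason[k] <- "bout without rd series"
      next
    }
    s <- events$start_frame[k]
    i <- s + 1L  # 1-based position of the start frame
    L <- length(r)
    base_idx <- (i - b + 1L):i
    post_idx <- i:(i + w - 1L)
    if (base_idx[1] < 1L) {
      skip_reason[k] <- "incomplete baseline"
      next
    }
    if (post_idx[w] > L) {
      skip_reason[k] <- "incomplete post"
      next
    }
    base <- r[base_idx]
    post <- r[post_idx]
    nb <- sum(!is.na(base))
    np <- sum(!is.na(post))
    if (policy == "strict") {
      if (nb < b) {
        skip_reason[k] <- "incomplete baseline"
        next
      }
      if (np < w) {
        skip_reason[k] <- "incomplete post"
        next
      }
    } else {
      if (nb < min_coverage * b || nb == 0L) {
        skip_reason[k] <- "insufficient baseline coverage"
        next
      }
      if (np < min_coverage * w || np == 0L) {
        skip_reason[k] <- "insufficient post coverage"
        next
      }
    }
    delta_mean[k] <- mean(post, na.rm = TRUE) - mean(base, na.rm = TRUE)
    delta_max[k] <- max(post, na.rm = TRUE) - max(base, na.rm = TRUE)
    n_base[k] <- nb
    n_post[k] <- np
  }

  kept <- is.na(skip_reason)
  out <- tibble(
    bout_id = events$bout_id[kept],
    element_type = events$element_type[kept],
    intensity_class = events$intensity_class[kept],
    start_frame = events$start_frame[kept],
    baseline_frames = b,
    post_frames = w,
    delta_mean = delta_mean[kept],
    delta_max = delta_max[kept],
    n_baseline_defined = n_base[kept],
    n_post_defined = n_post[kept]
  )
  skipped <- tibble(
    bout_id = events$bout_id[!kept],
    element_type = events$element_type[!kept],
    start_frame = events$start_frame[!kept],
    reason = skip_reason[!kept]
  )
  attr(out, "skipped") <- skipped
  out
}

#' Group-level delta statistic (average of individual averages)
#'
#' The test statistic is the unweighted mean, within each status group,
#' of the per-male mean delta.  Because males contribute very unequal
#' element counts, the unweighted mean of individual means prevents a
#' few well-sampled males from dominating the group value.
#'
#' @param deltas Delta-record tibble from [peri_event_deltas()].
#' @param metadata Bout metadata tibble (maps bouts to males/status).
#' @param statistic `"delta_mean"` (default) or `"delta_max"`.
#' @return A list of class `group_statistic` with tibbles `individual`
#'   (per-male mean and element count) and `group` (per-status grand
#'   mean and male count).
#' @export
group_statistic <- function(deltas, metadata,
                            statistic = c("delta_mean", "delta_max")) {
  statistic <- match.arg(statistic)
  if (nrow(deltas) == 0) {
    .stop_io("No delta records to summarise",
             class = "peristartle_empty_group_error")
  }
  joined <- left_join(deltas,
                      metadata[c("bout_id", "male_id", "status")],
                      by = "bout_id")
  if (anyNA(joined$male_id)) {
    .stop_io("Delta record(s) reference bouts missing from metadata",
             class = "peristartle_referential_error")
  }
  individual <- joined |>
    group_by(.data$male_id, .data$status) |>
    summarise(mean_delta = mean(.data[[statistic]]),
              n_elements = dplyr::n(), .groups = "drop") |>
    arrange(.data$status, .data$male_id)
  group <- individual |>
    group_by(.data$status) |>
    summarise(grand_mean = mean(.data$mean_delta),
              n_males = dplyr::n(), .groups = "drop")
  structure(list(individual = individual, group = group,
                 statistic = statistic),
            class = "group_statistic")
}

#' @export
print.group_statistic <- function(x, ...) {
  cat("<group_statistic> statistic:", x$statistic, "\n")
  print(x$group)
  invisible(x)
}
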