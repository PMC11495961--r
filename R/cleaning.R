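# Velocity-based track cleaning.
#
# "Body size" is identified with body height (vertical beak-to-ITJ
# extent), the only size measure the RD normalisation defines, so the
# same per-bout scale drives both cleaning thresholds and RD.

#' Per-bout body height metrics
#'
#' Body height is computed in each frame as the absolute difference
#' between the beak-tip y coordinate and the mean y coordinate of the
#' available inter-tarsal joints (both sides when valid, otherwise the
#' valid one), then averaged across frames within the bout.
#'
#' @param tracks Keypoint track tibble.
#' @return An object of class `body_metrics`: list with `frames`
#'   (tibble `bout_id`, `frame`, `body_height`) and `bouts` (tibble
#'   `bout_id`, `body_height_mean`, `n_frames_used`).
#' @export
compute_body_metrics <- function(tracks) {
  per_bout <- split(seq_len(nrow(tracks)), tracks$bout_id)
  frames_list <- vector("list", length(per_bout))
  bouts_list <- vector("list", length(per_bout))
  for (i in seq_along(per_bout)) {
    idx <- per_bout[[i]]
    bout <- names(per_bout)[i]
    sub <- tracks[idx, ]
    L <- max(sub$frame) + 1L
    beak_y <- .kp_vector(sub, "beak_tip", "y", L)
    li <- .kp_vector(sub, "left_itj", "y", L)
    ri <- .kp_vector(sub, "right_itj", "y", L)
    if (all(is.na(beak_y))) {
      .stop_io("Bout '", bout, "' has no valid beak_tip keypoint",
               class = "peristartle_missing_keypoint_error")
    }
    if (all(is.na(li)) && all(is.na(ri))) {
      .stop_io("Bout '", bout, "' has no ITJ keypoint",
               class = "peristartle_missing_keypoint_error")
    }
    itj_y <- rowMeans(cbind(li, ri), na.rm = TRUE)
    itj_y[is.nan(itj_y)] <- NA_real_
    height <- abs(itj_y - beak_y)
    frames_list[[i]] <- tibble(bout_id = bout, frame = seq_len(L) - 1L,
                               body_height = height)
    bouts_list[[i]] <- tibble(
      bout_id = bout,
      body_height_mean = mean(height, na.rm = TRUE),
      n_frames_used = sum(!is.na(height))
    )
  }
  structure(
    list(frames = bind_rows(frames_list), bouts = bind_rows(bouts_list)),
    class = "body_metrics"
  )
}

#' @export
print.body_metrics <- function(x, ...) {
  cat("<body_metrics> for", nrow(x$bouts), "bout(s)\n")
  print(x$bouts, n = 5)
  invisible(x)
}

# Extract one keypoint coordinate as a frame-aligned vector (NA where the
# record is absent or invalid).
.kp_vector <- function(sub, keypoint, coord, L) {
  rows <- sub[sub$keypoint == keypoint & sub$valid, , drop = FALSE]
  out <- rep(NA_real_, L)
  out[rows$frame + 1L] <- rows[[coord]]
  out
}

# Raw (validity-ignoring) coordinate vector, used for the single-pass
# jump filter which operates on the series as exported.
.kp_vector_raw <- function(sub, keypoint, coord, L) {
  rows <- sub[sub$keypoint == keypoint, , drop = FALSE]
  out <- rep(NA_real_, L)
  out[rows$frame + 1L] <- rows[[coord]]
  out
}

#' Filter implausible keypoint jumps
#'
#' Computes, per keypoint, the frame-to-frame Euclidean displacement on
#' the raw coordinate series (a single pass: removing a record does not
#' create new candidate jumps between its neighbours).  Records whose
#' displacement exceeds `hard` body heights are invalidated ("removed");
#' records in `(soft, hard]` body heights are retained but listed as
#' "flagged" for inspection.  A removal invalidates only the offending
#' keypoint, not the whole frame.
#'
#' @param tracks Keypoint track tibble.
#' @param metrics `body_metrics` for the same tracks (computed if NULL).
#' @param hard Removal threshold in body heights (default 0.5).
#' @param soft Flagging threshold in body heights (default 0.25).
#' @param iterate If TRUE, re-run the filter on the surviving records
#'   until no further removals (displacements then bridge removed
#'   neighbours).  Default FALSE: one pass on the raw series.
#' @return A list with `tracks` (valid flags updated) and `report`
#'   (class `cleaning_report`).
#' @export
filter_jumps <- function(tracks, metrics = NULL, hard = 0.5, soft = 0.25,
                         iterate = FALSE) {
  if (hard <= soft) {
    .stop_io("hard threshold (", hard, ") must exceed soft threshold (",
             soft, ")", class = "peristartle_parameter_error")
  }
  if (is.null(metrics)) metrics <- compute_body_metrics(tracks)
  bout_mean <- setNames(metrics$bouts$body_height_mean, metrics$bouts$bout_id)
  if (any(!is.finite(bout_mean)) || any(bout_mean <= 0)) {
    .stop_io("body_height_mean must be positive for every bout",
             class = "peristartle_degenerate_geometry_error")
  }

  out <- tracks
  records <- list()
  per_bout <- split(seq_len(nrow(tracks)), tracks$bout_id)
  for (bout in names(per_bout)) {
    idx <- per_bout[[bout]]
    sub <- tracks[idx, ]
    L <- max(sub$frame) + 1L
    H <- bout_mean[[bout]]
    for (kp in intersect(keypoint_vocabulary(), unique(sub$keypoint))) {
      xs <- .kp_vector_raw(sub, kp, "x", L)
      ys <- .kp_vector_raw(sub, kp, "y", L)
      disp <- c(NA_real_, sqrt(diff(xs)^2 + diff(ys)^2)) / H
      hit <- which(!is.na(disp) & disp > soft)
      for (f1 in hit) {
        action <- if (disp[f1] > hard) "removed" else "flagged"
        records[[length(records) + 1L]] <- tibble(
          bout_id = bout, frame = f1 - 1L, keypoint = kp,
          displacement_bh = disp[f1], action = action
        )
        if (action == "removed") {
          row <- idx[sub$keypoint == kp & sub$frame == f1 - 1L]
          out$valid[row] <- FALSE
        }
      }
    }
  }
  records <- if (length(records) > 0) bind_rows(records) else {
    tibble(bout_id = character(), frame = integer(), keypoint = character(),
           displacement_bh = numeric(), action = character())
  }

  if (iterate) {
    repeat {
      removed_more <- FALSE
      per_bout <- split(seq_len(nrow(out)), out$bout_id)
      for (bout in names(per_bout)) {
        idx <- per_bout[[bout]]
        sub <- out[idx, ]
        H <- bout_mean[[bout]]
        for (kp in intersect(keypoint_vocabulary(), unique(sub$keypoint))) {
          rows <- which(sub$keypoint == kp & sub$valid)
          if (length(rows) < 2) next
          rows <- rows[order(sub$frame[rows])]
          disp <- sqrt(diff(sub$x[rows])^2 + diff(sub$y[rows])^2) / H
          bad <- which(disp > hard)
          for (j in bad) {
            row <- idx[rows[j + 1L]]
            if (out$valid[row]) {
              out$valid[row] <- FALSE
              removed_more <- TRUE
              records <- bind_rows(records, tibble(
                bout_id = bout, frame = out$frame[row], keypoint = kp,
                displacement_bh = disp[j], action = "removed"
              ))
            }
          }
        }
      }
      if (!removed_more) break
    }
  }

  n_frames <- sum(vapply(split(tracks$frame, tracks$bout_id),
                         function(f) max(f) + 1L, integer(1)))
  report <- structure(
    list(
      hard_threshold = hard,
      soft_threshold = soft,
      removed = sum(records$action == "removed"),
      flagged = sum(records$action == "flagged"),
      records = arrange(records, .data$bout_id, .data$frame, .data$keypoint),
      n_frames = n_frames,
      n_records = nrow(tracks),
      iterate = iterate
    ),
    class = "cleaning_report"
  )
  list(tracks = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  thresholds: hard > %.3g, soft > %.3g body heights\n",
              x$hard_threshold, x$soft_threshold))
  cat(sprintf("  removed: %d   flagged: %d\n", x$removed, x$flagged))
  # data-loss share under both plausible denominators
  cat(sprintf("  data loss: %.4g%% of %d frames | %.4g%% of %d keypoint records\n",
              100 * x$removed / x$n_frames, x$n_frames,
              100 * x$removed / x$n_records, x$n_records))
  invisible(x)
}

#' Convert a cleaning report to a tibble
#'
#' @param x A `cleaning_report`.
#' @param ... Unused.
#' @return The per-record tibble of removed/flagged keypoints.
#' @export
as_tibble.cleaning_report <- function(x, ...) x$records

#' Clean a whole dataset in place
#'
#' Convenience wrapper: computes body metrics and applies
#' [filter_jumps()] to the dataset's tracks.
#'
#' @param dataset A `startle_dataset`.
#' @inheritParams filter_jumps
#' @return A list with the updated `dataset`, the `metrics` and the
#'   cleaning `report`.
#' @export
clean_dataset <- function(dataset, hard = 0.5, soft = 0.25, iterate = FALSE) {
  metrics <- compute_body_metrics(dataset$tracks)
  res <- filter_jumps(dataset$tracks, metrics, hard = hard, soft = soft,
                      iterate = iterate)
  dataset$tracks <- res$tracks
  list(dataset = dataset, metrics = metrics, report = res$report)
}
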