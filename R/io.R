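# CSV interchange for keypoint tracks, behavioural annotations and exits.
#
# All files are comma-separated, dot-decimal, UTF-8, with a header row.
# Frames are 0-based and contiguous within a bout at load time; image
# coordinates (y increases downward) match standard video/pose exports.

#' Keypoint vocabulary
#'
#' The five tracked morphological landmarks: beak tip, left/right foot and
#' left/right inter-tarsal joint (ITJ).
#'
#' @return Character vector of valid keypoint labels.
#' @export
keypoint_vocabulary <- function() {
  c("beak_tip", "left_foot", "right_foot", "left_itj", "right_itj")
}

#' Default element-type to intensity-class mapping
#'
#' Returns the shipped mapping from display-element labels to intensity
#' class.  The two high-intensity elements (`body_ripple`, `mock_attack`)
#' are the vigorous close-range moves known to precede bower exits; the
#' remaining seventeen low-intensity labels are a synthetic stand-in
#' vocabulary (the field repertoire is consumed as input, not re-derived),
#' shipped in `extdata/element_intensity_synthetic.csv`.
#'
#' @return A tibble with columns `element_type` and `intensity_class`.
#' @export
default_intensity_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "element_intensity_synthetic.csv",
                          package = "peristartle", mustWork = TRUE)
      cache <<- readr::read_csv(path, col_types = readr::cols(
        element_type = readr::col_character(),
        intensity_class = readr::col_character()
      ))
    }
    cache
  }
})

#' High-intensity element labels
#'
#' @return Character vector of element types classed as high intensity in
#'   the default mapping.
#' @export
high_intensity_elements <- function() {
  m <- default_intensity_map()
  m$element_type[m$intensity_class == "high"]
}

.stop_io <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "peristartle_error"))
}

.check_columns <- function(header, required, path) {
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    .stop_io("File '", path, "' is missing required column(s): ",
             paste(missing, collapse = ", "),
             class = "peristartle_format_error")
  }
}

#' Read a keypoint track CSV
#'
#' Reads pose-tracking output with columns `bout_id,frame,keypoint,x,y`
#' (an optional `confidence` column is accepted and ignored; an optional
#' logical `valid` column is honoured, e.g. when re-reading cleaned
#' tracks).  Frames must be consecutive integers starting at 0 within
#' each bout.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `bout_id`, `frame`, `keypoint`, `x`,
#'   `y`, `valid`, sorted by (bout_id, frame, keypoint).
#' @export
read_keypoint_csv <- function(path) {
  if (!file.exists(path)) {
    .stop_io("File not found: ", path, class = "peristartle_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  .check_columns(header, c("bout_id", "frame", "keypoint", "x", "y"), path)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in c("frame", "x", "y")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad) > 0) {
      .stop_io("Non-numeric value in column '", col, "' of '", path,
               "' at line ", bad[1] + 1L, " ('", raw[[col]][bad[1]], "')",
               class = "peristartle_parse_error")
    }
  }

  unknown <- setdiff(unique(raw$keypoint), keypoint_vocabulary())
  if (length(unknown) > 0) {
    .stop_io("Unknown keypoint label(s) in '", path, "': ",
             paste(unknown, collapse = ", "),
             "; expected one of ", paste(keypoint_vocabulary(), collapse = ", "),
             class = "peristartle_vocabulary_error")
  }

  tracks <- tibble(
    bout_id = raw$bout_id,
    frame = as.integer(raw$frame),
    keypoint = raw$keypoint,
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    valid = if ("valid" %in% names(raw)) {
      as.logical(raw$valid)
    } else {
      rep(TRUE, nrow(raw))
    }
  )
  validate_tracks(tracks)
  arrange(tracks, .data$bout_id, .data$frame, .data$keypoint)
}

#' Validate a keypoint track table
#'
#' Checks column presence/types, frame contiguity per bout (0-based
#' consecutive integers), coordinate finiteness for valid records and
#' uniqueness of (bout, frame, keypoint) keys.
#'
#' @param tracks A keypoint track tibble.
#' @return `tracks`, invisibly, if valid; otherwise an error.
#' @export
validate_tracks <- function(tracks) {
  need <- c("bout_id", "frame", "keypoint", "x", "y", "valid")
  .check_columns(names(tracks), need, "<tracks>")
  kp_idx <- match(tracks$keypoint, unique(tracks$keypoint))
  bout_idx <- match(tracks$bout_id, unique(tracks$bout_id))
  nk <- max(kp_idx)
  nf <- max(tracks$frame) + 1
  key <- ((bout_idx - 1) * nf + tracks$frame) * nk + (kp_idx - 1)
  if (anyDuplicated(key) > 0) {
    .stop_io("Duplicate (bout_id, frame, keypoint) records",
             class = "peristartle_format_error")
  }
  ok <- tracks$valid
  if (any(!is.finite(tracks$x[ok])) || any(!is.finite(tracks$y[ok]))) {
    .stop_io("Non-finite coordinates on valid records",
             class = "peristartle_format_error")
  }
  by_bout <- split(tracks$frame, tracks$bout_id)
  for (b in names(by_bout)) {
    fr <- sort(unique(by_bout[[b]]))
    if (!identical(fr, seq(0L, length(fr) - 1L))) {
      .stop_io("Frames of bout '", b,
               "' are not consecutive integers starting at 0",
               class = "peristartle_format_error")
    }
  }
  invisible(tracks)
}

#' Write a keypoint track CSV
#'
#' Inverse of [read_keypoint_csv()].  The `valid` column is written only
#' when some records are invalid, so freshly exported tracks keep the
#' minimal five-column interchange format.
#'
#' @param tracks A keypoint track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(tracks, path) {
  out <- arrange(tracks, .data$bout_id, .data$frame, .data$keypoint)
  cols <- c("bout_id", "frame", "keypoint", "x", "y")
  if (!all(out$valid)) cols <- c(cols, "valid")
  readr::write_csv(out[cols], path, progress = FALSE)
  invisible(path)
}

#' Read behavioural annotations (bout metadata + display elements)
#'
#' The annotations CSV has one row per display element with columns
#' `bout_id,male_id,status,date,element_type,intensity_class,kind,
#' start_frame,duration_frames`; rows with an empty `element_type`
#' contribute bout metadata only (bouts without coded elements).  A
#' missing/empty `intensity_class` is filled from the default
#' element-to-class mapping ([default_intensity_map()]).  An optional
#' `fps` column defaults to 30 frames per second.
#'
#' @param path Path to the annotations CSV.
#' @param exits_path Optional path to an exits CSV (`bout_id,frame`).
#' @param bout_lengths Optional named integer vector (frames per bout)
#'   used to bounds-check events; [assemble_dataset()] always re-checks
#'   against the tracks.
#' @return A list with tibbles `metadata` (one row per bout), `events`
#'   (sorted by bout and start frame) and `exits` (possibly empty).
#' @export
read_annotations <- function(path, exits_path = NULL, bout_lengths = NULL) {
  if (!file.exists(path)) {
    .stop_io("File not found: ", path, class = "peristartle_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  .check_columns(names(raw),
                 c("bout_id", "male_id", "status", "date", "element_type",
                   "kind", "start_frame", "duration_frames"),
                 path)

  bad_status <- setdiff(unique(raw$status), c("owner", "subordinate"))
  if (length(bad_status) > 0) {
    .stop_io("Unknown status value(s): ", paste(bad_status, collapse = ", "),
             class = "peristartle_vocabulary_error")
  }

  metadata <- raw |>
    distinct(.data$bout_id, .data$male_id, .data$status, .data$date,
             .keep_all = FALSE)
  if (anyDuplicated(metadata$bout_id) > 0) {
    dup <- metadata$bout_id[duplicated(metadata$bout_id)]
    .stop_io("Conflicting metadata for bout(s): ",
             paste(unique(dup), collapse = ", "),
             class = "peristartle_referential_error")
  }
  metadata <- mutate(
    metadata,
    date = as.Date(.data$date),
    receiver_id = if ("receiver_id" %in% names(raw)) {
      raw$receiver_id[match(metadata$bout_id, raw$bout_id)]
    } else {
      NA_character_
    },
    fps = if ("fps" %in% names(raw)) {
      as.numeric(raw$fps[match(metadata$bout_id, raw$bout_id)])
    } else {
      30
    }
  )
  if (any(!is.finite(metadata$fps)) || any(metadata$fps <= 0)) {
    .stop_io("fps must be a positive number",
             class = "peristartle_format_error")
  }

  is_event_row <- !is.na(raw$element_type) & raw$element_type != ""
  ev <- raw[is_event_row, , drop = FALSE]
  if (nrow(ev) == 0) {
    events <- tibble(bout_id = character(), element_type = character(),
                     intensity_class = character(), kind = character(),
                     start_frame = integer(), duration_frames = integer())
  } else {
    events <- tibble(
      bout_id = ev$bout_id,
      element_type = ev$element_type,
      intensity_class = if ("intensity_class" %in% names(ev)) {
        ifelse(is.na(ev$intensity_class) | ev$intensity_class == "",
               NA_character_, ev$intensity_class)
      } else {
        NA_character_
      },
      kind = ev$kind,
      start_frame = as.integer(ev$start_frame),
      duration_frames = as.integer(ev$duration_frames)
    )
    map <- default_intensity_map()
    fill <- is.na(events$intensity_class)
    events$intensity_class[fill] <-
      map$intensity_class[match(events$element_type[fill], map$element_type)]
    if (anyNA(events$intensity_class)) {
      missing_types <- unique(events$element_type[is.na(events$intensity_class)])
      .stop_io("No intensity class given or mappable for element type(s): ",
               paste(missing_types, collapse = ", "),
               class = "peristartle_vocabulary_error")
    }
    bad_class <- setdiff(unique(events$intensity_class), c("high", "low"))
    if (length(bad_class) > 0) {
      .stop_io("intensity_class must be 'high' or 'low', got: ",
               paste(bad_class, collapse = ", "),
               class = "peristartle_vocabulary_error")
    }
    bad_kind <- setdiff(unique(events$kind), c("event", "duration"))
    if (length(bad_kind) > 0) {
      .stop_io("kind must be 'event' or 'duration', got: ",
               paste(bad_kind, collapse = ", "),
               class = "peristartle_vocabulary_error")
    }
    if (any(events$kind == "event" & events$duration_frames != 1L)) {
      .stop_io("'event' kind elements must have duration_frames = 1",
               class = "peristartle_format_error")
    }
    if (any(events$duration_frames < 1L)) {
      .stop_io("duration_frames must be >= 1",
               class = "peristartle_format_error")
    }
    events <- arrange(events, .data$bout_id, .data$start_frame)
  }

  if (!is.null(bout_lengths)) {
    .check_event_bounds(events, bout_lengths)
  }

  exits <- if (is.null(exits_path)) {
    tibble(bout_id = character(), frame = integer())
  } else {
    read_exits(exits_path)
  }

  list(metadata = metadata, events = events, exits = exits)
}

.check_event_bounds <- function(events, bout_lengths) {
  len <- bout_lengths[events$bout_id]
  over <- which(!is.na(len) & events$start_frame + events$duration_frames > len)
  if (length(over) > 0) {
    .stop_io("Event(s) extend past bout length, e.g. bout '",
             events$bout_id[over[1]], "' start ", events$start_frame[over[1]],
             " duration ", events$duration_frames[over[1]],
             " in a ", len[over[1]], "-frame bout",
             class = "peristartle_bounds_error")
  }
  invisible(events)
}

#' Read a bower-exit CSV (`bout_id,frame`)
#'
#' @param path Path to the exits CSV.
#' @return A tibble with columns `bout_id` and `frame`.
#' @export
read_exits <- function(path) {
  if (!file.exists(path)) {
    .stop_io("File not found: ", path, class = "peristartle_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  .check_columns(names(raw), c("bout_id", "frame"), path)
  arrange(tibble(bout_id = raw$bout_id, frame = as.integer(raw$frame)),
          .data$bout_id, .data$frame)
}

#' Write annotations / exits CSVs
#'
#' @param metadata,events Tibbles as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(metadata, events, path) {
  meta_cols <- metadata[c("bout_id", "male_id", "status", "date", "fps")]
  joined <- left_join(events, meta_cols, by = "bout_id")
  out <- joined[c("bout_id", "male_id", "status", "date", "element_type",
                  "intensity_class", "kind", "start_frame",
                  "duration_frames", "fps")]
  # carry bouts that have no coded elements as metadata-only rows
  orphan <- metadata[!metadata$bout_id %in% events$bout_id, , drop = FALSE]
  if (nrow(orphan) > 0) {
    blank <- tibble(
      bout_id = orphan$bout_id, male_id = orphan$male_id,
      status = orphan$status, date = orphan$date,
      element_type = NA_character_, intensity_class = NA_character_,
      kind = NA_character_, start_frame = NA_integer_,
      duration_frames = NA_integer_, fps = orphan$fps
    )
    out <- bind_rows(out, blank)
  }
  readr::write_csv(arrange(out, .data$bout_id, .data$start_frame), path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @param exits Exits tibble (`bout_id`, `frame`).
#' @export
write_exits <- function(exits, path) {
  readr::write_csv(arrange(exits, .data$bout_id, .data$frame), path,
                   progress = FALSE)
  invisible(path)
}

#' Assemble a joined startle dataset
#'
#' Joins tracks, bout metadata, display events and exits into one
#' structure addressable by bout and by male, after referential and
#' bounds checks.  Inputs may arrive in any row order; the assembled
#' dataset is canonically sorted, so permuting input rows yields an
#' identical object.
#'
#' @param tracks Keypoint track tibble (see [read_keypoint_csv()]).
#' @param metadata Bout metadata tibble.
#' @param events Display-event tibble.
#' @param exits Exit tibble (may be empty).
#' @return An object of class `startle_dataset`: a list with elements
#'   `tracks`, `metadata`, `events`, `exits` and `bout_lengths`.
#' @export
assemble_dataset <- function(tracks, metadata, events,
                             exits = tibble(bout_id = character(),
                                            frame = integer())) {
  validate_tracks(tracks)
  track_bouts <- unique(tracks$bout_id)
  known <- intersect(track_bouts, metadata$bout_id)

  orphan <- unique(c(
    setdiff(events$bout_id, known),
    setdiff(exits$bout_id, known),
    setdiff(track_bouts, metadata$bout_id)
  ))
  if (length(orphan) > 0) {
    .stop_io("bout_id(s) without matching tracks and metadata: ",
             paste(orphan, collapse = ", "),
             class = "peristartle_referential_error")
  }
  if (anyDuplicated(metadata$bout_id) > 0) {
    .stop_io("Duplicate bout_id in metadata",
             class = "peristartle_referential_error")
  }
  # each male must carry a single status
  ms <- distinct(metadata, .data$male_id, .data$status)
  if (anyDuplicated(ms$male_id) > 0) {
    .stop_io("male_id mapped to more than one status",
             class = "peristartle_referential_error")
  }

  bout_lengths <- vapply(split(tracks$frame, tracks$bout_id),
                         function(f) max(f) + 1L, integer(1))
  .check_event_bounds(events, bout_lengths)
  if (nrow(exits) > 0) {
    bad <- which(exits$frame < 0L | exits$frame >= bout_lengths[exits$bout_id])
    if (length(bad) > 0) {
      .stop_io("Exit frame outside bout range in bout '",
               exits$bout_id[bad[1]], "' (frame ", exits$frame[bad[1]], ")",
               class = "peristartle_bounds_error")
    }
  }

  structure(
    list(
      tracks = arrange(tracks, .data$bout_id, .data$frame, .data$keypoint),
      metadata = arrange(as_tibble(metadata), .data$bout_id),
      events = arrange(as_tibble(events), .data$bout_id, .data$start_frame,
                       .data$element_type),
      exits = arrange(as_tibble(exits), .data$bout_id, .data$frame),
      bout_lengths = bout_lengths[sort(names(bout_lengths))]
    ),
    class = "startle_dataset"
  )
}

#' Per-male summary of a startle dataset
#'
#' @param object A `startle_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per male: status, bout count, high/low
#'   element counts and exit count.
#' @export
summary.startle_dataset <- function(object, ...) {
  meta <- object$metadata
  ev <- left_join(object$events,
                  meta[c("bout_id", "male_id")], by = "bout_id")
  ex <- left_join(object$exits,
                  meta[c("bout_id", "male_id")], by = "bout_id")
  per_male <- meta |>
    group_by(.data$male_id, .data$status) |>
    summarise(n_bouts = dplyr::n_distinct(.data$bout_id), .groups = "drop")
  cnt <- function(d) {
    if (nrow(d) == 0) return(integer(0))
    table(d$male_id)
  }
  hi <- cnt(ev[ev$intensity_class == "high", ])
  lo <- cnt(ev[ev$intensity_class == "low", ])
  xx <- cnt(ex)
  per_male$n_high <- as.integer(hi[per_male$male_id])
  per_male$n_low <- as.integer(lo[per_male$male_id])
  per_male$n_exits <- as.integer(xx[per_male$male_id])
  per_male$n_high[is.na(per_male$n_high)] <- 0L
  per_male$n_low[is.na(per_male$n_low)] <- 0L
  per_male$n_exits[is.na(per_male$n_exits)] <- 0L
  arrange(per_male, .data$status, .data$male_id)
}

#' @export
print.startle_dataset <- function(x, ...) {
  cat("<startle_dataset>\n")
  cat("  bouts:   ", length(x$bout_lengths), "\n")
  cat("  frames:  ", sum(x$bout_lengths), "\n")
  cat("  males:   ", length(unique(x$metadata$male_id)), "\n")
  cat("  events:  ", nrow(x$events),
      sprintf("(%d high / %d low)\n",
              sum(x$events$intensity_class == "high"),
              sum(x$events$intensity_class == "low")))
  cat("  exits:   ", nrow(x$exits), "\n")
  invisible(x)
}

#' Write all component tables of a dataset to a directory
#'
#' @param dataset A `startle_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_keypoint_csv(dataset$tracks, file.path(dir, "tracks.csv"))
  write_annotations(dataset$metadata, dataset$events,
                    file.path(dir, "annotations.csv"))
  write_exits(dataset$exits, file.path(dir, "exits.csv"))
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir Directory containing `tracks.csv`, `annotations.csv` and
#'   `exits.csv`.
#' @return A `startle_dataset`.
#' @export
read_dataset <- function(dir) {
  tracks <- read_keypoint_csv(file.path(dir, "tracks.csv"))
  ann <- read_annotations(file.path(dir, "annotations.csv"),
                          exits_path = file.path(dir, "exits.csv"))
  assemble_dataset(tracks, ann$metadata, ann$events, ann$exits)
}
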