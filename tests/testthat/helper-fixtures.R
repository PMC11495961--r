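# Fixture builders used across the suite.  All fixtures are constructed
# in code; nothing is read from disk except through the package's own io.

# A minimal track: beak plus both ITJs (constant ITJ geometry), beak
# coordinates given per frame.  Body height is |itj_y - beak_y| per
# frame; pass a vector itj_y to control it frame by frame.
make_track <- function(bout_id, beak_x, beak_y, itj_y = beak_y + 100) {
  n <- length(beak_x)
  stopifnot(length(beak_y) == n)
  itj_y <- rep_len(itj_y, n)
  dplyr::bind_rows(
    tibble::tibble(bout_id = bout_id, frame = 0:(n - 1),
                   keypoint = "beak_tip", x = beak_x, y = beak_y,
                   valid = TRUE),
    tibble::tibble(bout_id = bout_id, frame = 0:(n - 1),
                   keypoint = "left_itj", x = beak_x[1] - 10, y = itj_y,
                   valid = TRUE),
    tibble::tibble(bout_id = bout_id, frame = 0:(n - 1),
                   keypoint = "right_itj", x = beak_x[1] + 10, y = itj_y,
                   valid = TRUE)
  )
}

# Hand-built rd series (class rd_series) from a named list of per-bout
# rd vectors indexed by frame 0..L-1 (frame 0 must be NA).
make_rd <- function(rd_list) {
  out <- dplyr::bind_rows(lapply(names(rd_list), function(b) {
    r <- rd_list[[b]]
    tibble::tibble(bout_id = b, frame = seq_along(r) - 1L, rd = r,
                   defined = !is.na(r))
  }))
  class(out) <- c("rd_series", class(out))
  out
}

make_metadata <- function(bout_ids, male_ids, status = "owner",
                          date = as.Date("2018-09-01")) {
  tibble::tibble(bout_id = bout_ids, male_id = male_ids,
                 status = rep_len(status, length(bout_ids)),
                 date = rep_len(date, length(bout_ids)),
                 receiver_id = NA_character_, fps = 30)
}

make_events <- function(bout_ids, start_frames, intensity = "high",
                        type = "mock_attack", duration = 2L) {
  tibble::tibble(bout_id = bout_ids,
                 element_type = rep_len(type, length(bout_ids)),
                 intensity_class = rep_len(intensity, length(bout_ids)),
                 kind = "duration",
                 start_frame = as.integer(start_frames),
                 duration_frames = rep_len(as.integer(duration),
                                           length(bout_ids)))
}
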