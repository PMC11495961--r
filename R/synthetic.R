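# Synthetic keypoint-track generator.
#
# Emulates the statistical structure the analysis assumes: a receiver
# standing still inside the bower (one static pose per bout), per-frame
# Gaussian keypoint jitter, rare single-frame mis-detections, a stream
# of non-overlapping display elements, transient beak-displacement
# pulses (startles) time-locked to high-intensity element onsets, and
# occasional bower exits after high-intensity elements.

#' Simulation configuration
#'
#' Defaults mirror the recording design the analysis targets: 30 fps
#' video, 9 bower owners and 8 subordinate males, 4-32 bouts per male of
#' a few hundred to ~1000 frames, high-intensity element durations of
#' 36.69 +/- 35.92 frames, and a startle pulse added to the beak only
#' (RD is beak-based) for high-intensity elements.
#'
#' @param n_owners,n_subordinates Number of males per status group.
#' @param bouts_per_male Integer range (min, max) of bouts per male.
#' @param bout_length_frames Integer range of bout lengths.
#' @param fps Frames per second.
#' @param body_height_px Mean and sd of per-bout body height in pixels.
#' @param jitter_sd Per-frame, per-axis keypoint jitter sd as a fraction
#'   of body height.
#' @param misdetect_rate Per-frame, per-keypoint probability of a large
#'   single-frame jump (a spurious detection).
#' @param misdetect_magnitude Range of mis-detection jump sizes in body
#'   heights (straddles the 0.25 flagging and 0.5 removal thresholds).
#' @param element_rate Display elements per 100 frames of inter-element
#'   gap (exponential gaps on top of `min_element_gap` and element
#'   durations, so the realised per-frame rate is lower).
#' @param high_fraction Share of elements that are high-intensity.
#' @param high_duration_frames Mean and sd of high-intensity element
#'   durations (frames, truncated at 2).
#' @param low_event_fraction Share of low-intensity elements that are
#'   1-frame "event" kind.
#' @param low_duration_frames Range of low-intensity "duration" element
#'   lengths.
#' @param min_element_gap Minimum gap (frames) between an element's end
#'   and the next element's onset, so peri-event windows rarely overlap.
#' @param startle_magnitude Named per-status beak displacement per pulse
#'   frame, in body heights.  The default gives owners a startle effect
#'   and subordinates none, matching the contrast the pipeline is built
#'   to detect.
#' @param startle_latency_frames Integer range of pulse onset latency
#'   after the element start (frames, >= 1 so the shared occurrence
#'   frame stays pulse-free).
#' @param startle_duration_frames Pulse length in frames (>= 2; the beak
#'   traverses a closed polygon, one side per frame, so each pulse frame
#'   contributes one displacement of `startle_magnitude` body heights).
#' @param startle_probability Probability that a high-intensity element
#'   elicits a pulse.
#' @param exit_probability Named per-status probability that a
#'   high-intensity element is followed by a bower exit.
#' @param seed RNG seed used by [simulate_dataset()] (NULL: leave the
#'   RNG state alone).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_owners = 9L,
                       n_subordinates = 8L,
                       bouts_per_male = c(4L, 32L),
                       bout_length_frames = c(300L, 1000L),
                       fps = 30,
                       body_height_px = c(mean = 100, sd = 10),
                       jitter_sd = 0.01,
                       misdetect_rate = 0.001,
                       misdetect_magnitude = c(0.2, 0.8),
                       element_rate = 2.5,
                       high_fraction = 0.4,
                       high_duration_frames = c(mean = 36.69, sd = 35.92),
                       low_event_fraction = 0.5,
                       low_duration_frames = c(2L, 10L),
                       min_element_gap = 25L,
                       startle_magnitude = c(owner = 0.3, subordinate = 0),
                       startle_latency_frames = c(2L, 3L),
                       startle_duration_frames = 3L,
                       startle_probability = 1,
                       exit_probability = c(owner = 0.2, subordinate = 0.2),
                       seed = NULL) {
  cfg <- list(
    n_owners = as.integer(n_owners),
    n_subordinates = as.integer(n_subordinates),
    bouts_per_male = as.integer(bouts_per_male),
    bout_length_frames = as.integer(bout_length_frames),
    fps = fps,
    body_height_px = body_height_px,
    jitter_sd = jitter_sd,
    misdetect_rate = misdetect_rate,
    misdetect_magnitude = misdetect_magnitude,
    element_rate = element_rate,
    high_fraction = high_fraction,
    high_duration_frames = high_duration_frames,
    low_event_fraction = low_event_fraction,
    low_duration_frames = as.integer(low_duration_frames),
    min_element_gap = as.integer(min_element_gap),
    startle_magnitude = startle_magnitude,
    startle_latency_frames = as.integer(startle_latency_frames),
    startle_duration_frames = as.integer(startle_duration_frames),
    startle_probability = startle_probability,
    exit_probability = exit_probability,
    seed = seed
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  chk_range <- function(r, name) {
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2]) {
      .stop_io(name, " must be a non-empty (min, max) range",
               class = "peristartle_config_error")
    }
  }
  chk_prob <- function(p, name) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      .stop_io(name, " must lie in [0, 1]",
               class = "peristartle_config_error")
    }
  }
  chk_range(cfg$bouts_per_male, "bouts_per_male")
  chk_range(cfg$bout_length_frames, "bout_length_frames")
  chk_range(cfg$misdetect_magnitude, "misdetect_magnitude")
  chk_range(cfg$low_duration_frames, "low_duration_frames")
  chk_range(cfg$startle_latency_frames, "startle_latency_frames")
  chk_prob(cfg$misdetect_rate, "misdetect_rate")
  chk_prob(cfg$high_fraction, "high_fraction")
  chk_prob(cfg$low_event_fraction, "low_event_fraction")
  chk_prob(cfg$startle_probability, "startle_probability")
  chk_prob(cfg$exit_probability, "exit_probability")
  if (cfg$fps <= 0) {
    .stop_io("fps must be positive", class = "peristartle_config_error")
  }
  if (any(cfg$startle_magnitude < 0) || cfg$jitter_sd < 0) {
    .stop_io("magnitudes must be >= 0", class = "peristartle_config_error")
  }
  if (!all(c("owner", "subordinate") %in% names(cfg$startle_magnitude)) ||
      !all(c("owner", "subordinate") %in% names(cfg$exit_probability))) {
    .stop_io("startle_magnitude and exit_probability need named ",
             "'owner' and 'subordinate' entries",
             class = "peristartle_config_error")
  }
  if (cfg$startle_latency_frames[1] < 1L) {
    .stop_io("startle_latency_frames must be >= 1",
             class = "peristartle_config_error")
  }
  if (cfg$startle_duration_frames < 2L) {
    .stop_io("startle_duration_frames must be >= 2 (closed pulse path)",
             class = "peristartle_config_error")
  }
  if (cfg$bouts_per_male[1] < 1L || cfg$n_owners < 0L ||
      cfg$n_subordinates < 0L) {
    .stop_io("counts must be non-negative and bouts_per_male >= 1",
             class = "peristartle_config_error")
  }
  # a bout must fit at least one element plus placement margins
  min_needed <- .sim_margin() + 2L + cfg$min_element_gap + .sim_end_margin()
  if (cfg$bout_length_frames[1] < min_needed) {
    .stop_io("bout_length_frames minimum (", cfg$bout_length_frames[1],
             ") too short to place any full element (need >= ", min_needed,
             ")", class = "peristartle_config_error")
  }
  invisible(cfg)
}

.sim_margin <- function() 15L      # earliest element onset

# uniform integer draw from an inclusive range (safe for collapsed
# ranges, where sample(n, 1) would draw from 1..n)
.sample_range <- function(r) {
  if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1L)
}
.sim_end_margin <- function() 5L   # frames kept free at bout end

.low_intensity_labels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- default_intensity_map()
      cache <<- m$element_type[m$intensity_class == "low"]
    }
    cache
  }
})

#' Simulate a single courtship bout
#'
#' Uses the current RNG state (seed once, e.g. in [simulate_dataset()],
#' for reproducibility).  The receiver keeps one static pose; each
#' startle is a closed polygonal excursion of the beak with one side of
#' `startle_magnitude` body heights traversed per frame, starting
#' `startle_latency` frames after a high-intensity element onset.
#'
#' @param config A [sim_config()].
#' @param bout_id,male_id Identifiers for the generated bout.
#' @param status `"owner"` or `"subordinate"` (selects startle magnitude
#'   and exit probability).
#' @return A list with `tracks`, `events` and `exits` tibbles for one
#'   bout.
#' @export
simulate_bout <- function(config, bout_id, male_id,
                          status = c("owner", "subordinate")) {
  status <- match.arg(status)
  L <- .sample_range(config$bout_length_frames)
  H <- max(30, rnorm(1, config$body_height_px[["mean"]],
                     config$body_height_px[["sd"]]))
  x0 <- runif(1, 300, 900)
  y0 <- runif(1, 100, 300)
  base <- list(
    beak_tip = c(x0, y0),
    left_itj = c(x0 - 0.15 * H, y0 + H),
    right_itj = c(x0 + 0.15 * H, y0 + H),
    left_foot = c(x0 - 0.2 * H, y0 + 1.35 * H),
    right_foot = c(x0 + 0.2 * H, y0 + 1.35 * H)
  )

  events <- .place_elements(config, L)
  n_ev <- nrow(events)

  # startle pulses: beak offset vectors, one closed polygon per pulse
  beak_off_x <- numeric(L)
  beak_off_y <- numeric(L)
  M <- config$startle_magnitude[[status]]
  d <- config$startle_duration_frames
  if (M > 0 && n_ev > 0) {
    high_idx <- which(events$intensity_class == "high")
    for (k in high_idx) {
      if (runif(1) > config$startle_probability) next
      lat <- .sample_range(config$startle_latency_frames)
      p0 <- events$start_frame[k] + lat  # first elevated-RD frame
      ang <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(d) - 1L) / d
      vx <- cumsum(M * H * cos(ang))
      vy <- cumsum(M * H * sin(ang))
      vx[d] <- 0  # closed path: the polygon returns exactly to the pose
      vy[d] <- 0
      fr <- p0 + seq_len(d) - 1L
      keep <- fr <= L - 1L
      beak_off_x[fr[keep] + 1L] <- beak_off_x[fr[keep] + 1L] + vx[keep]
      beak_off_y[fr[keep] + 1L] <- beak_off_y[fr[keep] + 1L] + vy[keep]
    }
  }

  kp_names <- keypoint_vocabulary()
  xs_all <- vector("list", length(kp_names))
  ys_all <- vector("list", length(kp_names))
  for (j in seq_along(kp_names)) {
    kp <- kp_names[j]
    xs <- rep(base[[kp]][1], L)
    ys <- rep(base[[kp]][2], L)
    if (kp == "beak_tip") {
      xs <- xs + beak_off_x
      ys <- ys + beak_off_y
    }
    if (config$jitter_sd > 0) {
      xs <- xs + rnorm(L, 0, config$jitter_sd * H)
      ys <- ys + rnorm(L, 0, config$jitter_sd * H)
    }
    if (config$misdetect_rate > 0) {
      hit <- which(runif(L) < config$misdetect_rate)
      if (length(hit) > 0) {
        mag <- runif(length(hit), config$misdetect_magnitude[1],
                     config$misdetect_magnitude[2]) * H
        th <- runif(length(hit), 0, 2 * pi)
        xs[hit] <- xs[hit] + mag * cos(th)
        ys[hit] <- ys[hit] + mag * sin(th)
      }
    }
    xs_all[[j]] <- xs
    ys_all[[j]] <- ys
  }
  tracks <- tibble(
    bout_id = bout_id,
    frame = rep(seq_len(L) - 1L, times = length(kp_names)),
    keypoint = rep(kp_names, each = L),
    x = unlist(xs_all, use.names = FALSE),
    y = unlist(ys_all, use.names = FALSE),
    valid = TRUE
  )

  if (n_ev > 0) events$bout_id <- bout_id

  # exits after high-intensity elements
  exits <- tibble(bout_id = character(), frame = integer())
  p_exit <- config$exit_probability[[status]]
  if (n_ev > 0 && p_exit > 0) {
    high <- events[events$intensity_class == "high", , drop = FALSE]
    if (nrow(high) > 0) {
      go <- runif(nrow(high)) < p_exit
      if (any(go)) {
        fr <- pmin(L - 1L,
                   high$start_frame[go] + high$duration_frames[go] +
                     sample(1:10, sum(go), replace = TRUE))
        exits <- tibble(bout_id = bout_id, frame = as.integer(fr))
      }
    }
  }

  list(tracks = tracks, events = events, exits = exits)
}

# Renewal placement of non-overlapping display elements within L frames.
.place_elements <- function(config, L) {
  margin <- .sim_margin()
  end_margin <- .sim_end_margin()
  mean_gap <- 100 / config$element_rate
  onset <- margin + as.integer(round(rexp(1, 1 / mean_gap)))
  type <- cls <- kind <- character()
  start <- dur_all <- integer()
  repeat {
    is_high <- runif(1) < config$high_fraction
    if (is_high) {
      ty <- sample(high_intensity_elements(), 1L)
      dur <- max(2L, as.integer(round(
        rnorm(1, config$high_duration_frames[["mean"]],
              config$high_duration_frames[["sd"]]))))
      kd <- "duration"
      cl <- "high"
    } else {
      ty <- sample(.low_intensity_labels(), 1L)
      if (runif(1) < config$low_event_fraction) {
        dur <- 1L
        kd <- "event"
      } else {
        dur <- .sample_range(config$low_duration_frames)
        kd <- "duration"
      }
      cl <- "low"
    }
    if (onset + dur > L - end_margin) break
    type <- c(type, ty)
    cls <- c(cls, cl)
    kind <- c(kind, kd)
    start <- c(start, as.integer(onset))
    dur_all <- c(dur_all, dur)
    onset <- onset + dur + config$min_element_gap +
      as.integer(round(rexp(1, 1 / mean_gap)))
  }
  tibble(bout_id = rep(NA_character_, length(type)), element_type = type,
         intensity_class = cls, kind = kind, start_frame = start,
         duration_frames = dur_all)
}

#' Simulate a full multi-male dataset
#'
#' Draws per-male bout counts, simulates every bout and assembles the
#' result into a [assemble_dataset()] structure.  With a non-NULL
#' `config$seed` (or the `seed` argument) the output is bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `startle_dataset` with a `"sim_summary"` attribute (realised
#'   per-male counts, as from [summary.startle_dataset()]).
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  .validate_sim_config(config)
  if (config$n_owners + config$n_subordinates < 1L) {
    .stop_io("At least one male is required",
             class = "peristartle_config_error")
  }
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  males <- tibble(
    male_id = c(sprintf("O%02d", seq_len(config$n_owners)),
                sprintf("S%02d", seq_len(config$n_subordinates))),
    status = c(rep("owner", config$n_owners),
               rep("subordinate", config$n_subordinates))
  )
  season <- c(seq(as.Date("2018-08-01"), as.Date("2018-12-31"), by = "day"),
              seq(as.Date("2019-08-01"), as.Date("2019-12-31"), by = "day"))

  tracks <- list()
  events <- list()
  exits <- list()
  meta_bout <- meta_male <- meta_status <- character()
  meta_date <- as.Date(character())
  for (m in seq_len(nrow(males))) {
    n_bouts <- .sample_range(config$bouts_per_male)
    for (j in seq_len(n_bouts)) {
      bout_id <- sprintf("%s_b%02d", males$male_id[m], j)
      sim <- simulate_bout(config, bout_id, males$male_id[m],
                           males$status[m])
      tracks[[bout_id]] <- sim$tracks
      events[[bout_id]] <- sim$events
      exits[[bout_id]] <- sim$exits
      meta_bout <- c(meta_bout, bout_id)
      meta_male <- c(meta_male, males$male_id[m])
      meta_status <- c(meta_status, males$status[m])
      meta_date <- c(meta_date, sample(season, 1L))
    }
  }
  metadata <- tibble(bout_id = meta_bout, male_id = meta_male,
                     status = meta_status, date = meta_date,
                     receiver_id = NA_character_, fps = config$fps)
  dataset <- assemble_dataset(
    bind_rows(tracks), metadata, bind_rows(events), bind_rows(exits)
  )
  attr(dataset, "sim_summary") <- summary(dataset)
  attr(dataset, "sim_seed") <- seed
  dataset
}
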