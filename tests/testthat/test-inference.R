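test_that("eligibility matches boundary enumeration and brute force", {
  # 30 fully defined frames, b = 10, w = 10: starts 10..20 are eligible
  r <- c(NA, rep(0.1, 29))
  rd <- make_rd(list(b1 = r))
  meta <- make_metadata("b1", "m1")
  el <- eligible_frames(rd, window_spec(10, 10), meta)
  expect_equal(el$frame, 10:20)
  expect_equal(el$frame, oracle_eligible(r, 10, 10))

  # deleting one mid-bout rd value removes exactly the windows covering it
  r2 <- r
  r2[16] <- NA  # frame 15 undefined: it sits inside every window 10..20
  el2 <- suppressWarnings(
    eligible_frames(make_rd(list(b1 = r2)), window_spec(10, 10), meta)
  )
  expect_equal(el2$frame, oracle_eligible(r2, 10, 10))
  gone <- setdiff(el$frame, el2$frame)
  covers <- vapply(el$frame, function(s) {
    15 >= s - 9 && 15 <= s + 9  # frame 15 inside baseline or post
  }, logical(1))
  expect_equal(gone, el$frame[covers])

  # window larger than the bout: empty with a warning
  expect_warning(
    el3 <- eligible_frames(rd, window_spec(10, 40), meta),
    "zero eligible"
  )
  expect_equal(nrow(el3), 0)
})

test_that("empirical p-values follow the add-one formulas", {
  null <- 1:999 / 1000
  expect_equal(empirical_p(2, null, "two_sided"), 2 / 1000)
  expect_equal(empirical_p(2, null, "upper"), 1 / 1000)
  expect_equal(empirical_p(-1, null, "upper"), 1)  # capped at (1+B)/(B+1)
  expect_equal(empirical_p(median(null), null, "two_sided"), 1)
  expect_error(empirical_p(0, numeric(0)),
               class = "peristartle_parameter_error")
})

# A tiny one-male dataset with a constant-geometry track whose rd values
# we control exactly through beak x steps (body height 100).
tiny_dataset <- function(rd_vals, starts, L = length(rd_vals) + 1L) {
  beak_x <- cumsum(c(0, rd_vals * 100))
  tracks <- make_track("b1", beak_x = beak_x, beak_y = rep(0, L))
  meta <- make_metadata("b1", "m1")
  events <- make_events(rep("b1", length(starts)), starts)
  assemble_dataset(tracks, meta, events)
}

test_that("rd of zero everywhere gives a degenerate null with p = 1", {
  d <- tiny_dataset(rep(0, 40), starts = c(15, 25))
  res <- bootstrap_null(d, "owner", "high", window_spec(10, 10),
                        inference_config(reps = 100, seed = 1))
  expect_equal(res$observed, 0)
  expect_true(all(res$replicates == 0))
  expect_equal(res$p_value, 1)
})

test_that("exhaustive null equals full multiset enumeration exactly", {
  set.seed(31)
  # 1 individual, b = w = 5 so a 21-frame bout leaves 12 eligible starts,
  # and 2 high-intensity elements
  rd_vals <- abs(rnorm(20, 0.05, 0.02))
  d <- tiny_dataset(rd_vals, starts = c(6, 12))
  w <- window_spec(5, 5)

  rd <- relative_displacement(d$tracks)
  meta <- d$metadata
  el <- eligible_frames(rd, w, meta)
  expect_equal(nrow(el), 12)

  res <- bootstrap_null(d, "owner", "high", w,
                        inference_config(exhaustive = TRUE))
  expect_equal(res$B, choose(12 + 1, 2))  # 78 unordered frame pairs

  # oracle: per-start delta by naive loops, then all unordered pairs
  r <- rd$rd
  dstar <- vapply(el$frame, function(s) {
    oracle_delta(r, s, 5, 5)$delta_mean
  }, numeric(1))
  expect_equal(sort(res$replicates), sort(oracle_pair_means(dstar)))

  # weights reproduce the iid sampling law (144 ordered pairs)
  ordered <- oracle_ordered_null(dstar, 2)
  expect_equal(sum(res$weights), 1)
  expect_lt(abs(sum(res$weights[res$replicates >= res$observed]) -
                  mean(ordered >= res$observed - 1e-12)), 1e-9)

  # p-value equals the exact ordered-enumeration p
  expect_equal(res$p_value, oracle_tail_p(ordered, res$observed))
})

test_that("Monte-Carlo null converges to the exhaustive null", {
  set.seed(77)
  rd_vals <- abs(rnorm(20, 0.05, 0.02))
  d <- tiny_dataset(rd_vals, starts = c(6, 12))
  w <- window_spec(5, 5)
  ex <- bootstrap_null(d, "owner", "high", w,
                       inference_config(exhaustive = TRUE))
  B <- 20 * ex$B  # 20x the enumeration size
  mc <- bootstrap_null(d, "owner", "high", w,
                       inference_config(reps = B, seed = 2))
  for (p in c(0.1, 0.5, 0.9)) {
    q_ex <- peristartle:::.weighted_quantile(ex$replicates, ex$weights, p)
    q_mc <- quantile(mc$replicates, p, names = FALSE)
    expect_lt(abs(q_ex - q_mc), 1 / sqrt(B) + 1e-3)
  }
})

test_that("bootstrap nulls are bit-reproducible from the seed", {
  d <- simulate_dataset(sim_config(n_owners = 2L, n_subordinates = 0L,
                                   bouts_per_male = c(3L, 3L),
                                   bout_length_frames = c(250L, 300L)),
                        seed = 9)
  cfg <- inference_config(reps = 150, seed = 123)
  r1 <- bootstrap_null(d, "owner", "high", window_spec(10, 10), cfg)
  r2 <- bootstrap_null(d, "owner", "high", window_spec(10, 10), cfg)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("window sweep covers the full grid with per-cell seeds", {
  d <- simulate_dataset(sim_config(n_owners = 2L, n_subordinates = 2L,
                                   bouts_per_male = c(3L, 3L),
                                   bout_length_frames = c(300L, 400L)),
                        seed = 14)
  cfg <- inference_config(reps = 30, post_sizes = 4:50,
                          baseline_sizes = c(5L, 10L), seed = 99)
  sw <- suppressWarnings(window_sweep(d, cfg))
  # 47 post sizes per baseline per status x class
  counts <- dplyr::count(dplyr::as_tibble(sw), status, intensity_class,
                         baseline)
  expect_true(all(counts$n == 47))
  expect_equal(nrow(sw), 47 * 2 * 2 * 2)
  expect_false(any(duplicated(sw$seed)))
  # significance flag is exactly the quantile-band rule
  expect_equal(sw$significant,
               sw$observed < sw$q_lower | sw$observed > sw$q_upper)

  # single cells are reproducible in isolation from their stored seed
  row <- sw[17, ]
  cell <- bootstrap_null(d, row$status, row$intensity_class,
                         window_spec(row$baseline, row$post),
                         inference_config(reps = 30, seed = NULL))
  cell2 <- suppressWarnings(bootstrap_null(
    d, row$status, row$intensity_class,
    window_spec(row$baseline, row$post),
    inference_config(reps = 30, seed = row$seed)
  ))
  expect_equal(cell2$p_value, row$p_value)
  expect_equal(cell2$observed, row$observed)
})

test_that("leave-one-out is symmetric, exhaustive in rows, and flags
           influential males", {
  base <- simulate_dataset(sim_config(n_owners = 1L, n_subordinates = 0L,
                                      bouts_per_male = c(3L, 3L),
                                      bout_length_frames = c(300L, 350L)),
                           seed = 21)
  # duplicate the male's bouts under new identities -> 3 identical males
  clone <- function(d, male, suffix) {
    tr <- d$tracks
    tr$bout_id <- paste0(tr$bout_id, suffix)
    ev <- d$events
    ev$bout_id <- paste0(ev$bout_id, suffix)
    meta <- d$metadata
    meta$bout_id <- paste0(meta$bout_id, suffix)
    meta$male_id <- male
    list(tracks = tr, events = ev, meta = meta)
  }
  parts <- lapply(1:3, function(i) clone(base, sprintf("M%d", i), i))
  d <- assemble_dataset(
    dplyr::bind_rows(lapply(parts, `[[`, "tracks")),
    dplyr::bind_rows(lapply(parts, `[[`, "meta")),
    dplyr::bind_rows(lapply(parts, `[[`, "events"))
  )
  loo <- leave_one_out(d, "owner", "high", window_spec(10, 10),
                       inference_config(reps = 100, seed = 5))
  expect_equal(nrow(loo), 3)  # one row per male
  expect_equal(length(unique(loo$observed)), 1)
  expect_equal(length(unique(loo$p_value)), 1)
  expect_false(any(loo$sign_change))

  # give one male a huge injected effect: omitting it drops the delta most
  boost <- simulate_dataset(sim_config(n_owners = 1L, n_subordinates = 0L,
                                       bouts_per_male = c(3L, 3L),
                                       bout_length_frames = c(300L, 350L),
                                       startle_magnitude = c(owner = 0.5,
                                                             subordinate = 0)),
                            seed = 22)
  pb <- clone(boost, "M4", 9)
  d2 <- assemble_dataset(
    dplyr::bind_rows(dplyr::bind_rows(lapply(parts, `[[`, "tracks")),
                     pb$tracks),
    dplyr::bind_rows(dplyr::bind_rows(lapply(parts, `[[`, "meta")),
                     pb$meta),
    dplyr::bind_rows(dplyr::bind_rows(lapply(parts, `[[`, "events")),
                     pb$events)
  )
  loo2 <- leave_one_out(d2, "owner", "high", window_spec(10, 10),
                        inference_config(reps = 100, seed = 5))
  expect_equal(loo2$omitted_male[which.min(loo2$observed)], "M4")

  expect_error(
    leave_one_out(base, "owner", "high", window_spec(10, 10),
                  inference_config(reps = 50)),
    class = "peristartle_parameter_error"
  )
})
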