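test_that("relative displacement matches hand-computed Euclidean steps", {
  # stationary beak: rd = 0 for every frame >= 1, undefined at frame 0
  t <- make_track("b1", beak_x = rep(5, 20), beak_y = rep(10, 20))
  rd <- relative_displacement(t)
  expect_false(rd$defined[rd$frame == 0])
  expect_equal(rd$rd[rd$frame > 0], rep(0, 19))

  # a (3, 4) pixel step with body height 10 gives rd = 5/10 = 0.5
  t2 <- make_track("b1", beak_x = c(0, 3), beak_y = c(0, 4), itj_y = 10)
  # itj_y fixed at 10 while beak y moves 0 -> 4: heights 10 and 6, so
  # pin the mean height to 10 by moving the ITJ with the beak
  t2$y[t2$keypoint %in% c("left_itj", "right_itj")] <- c(10, 14)
  rd2 <- relative_displacement(t2)
  expect_equal(rd2$rd[rd2$frame == 1], 0.5)
})

test_that("rd agrees with a brute-force loop on random walks", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 150
    bx <- cumsum(rnorm(n, 0, 3))
    by <- cumsum(rnorm(n, 0, 3))
    t <- make_track("b1", beak_x = bx, beak_y = by, itj_y = by + 80)
    m <- compute_body_metrics(t)
    rd <- relative_displacement(t, m)
    expect_equal(rd$rd, oracle_rd(bx, by, m$bouts$body_height_mean))
  }
})

test_that("rd is invariant to translation and to joint scaling", {
  set.seed(7)
  bx <- cumsum(rnorm(100, 0, 2))
  by <- cumsum(rnorm(100, 0, 2))
  t0 <- make_track("b1", beak_x = bx, beak_y = by, itj_y = by + 50)
  rd0 <- relative_displacement(t0)

  t_shift <- t0
  t_shift$x <- t_shift$x + 123
  t_shift$y <- t_shift$y - 77
  expect_equal(relative_displacement(t_shift)$rd, rd0$rd)

  t_scale <- t0
  t_scale$x <- t_scale$x * 3.5
  t_scale$y <- t_scale$y * 3.5
  expect_equal(relative_displacement(t_scale)$rd, rd0$rd)
})

test_that("peri-event deltas reproduce hand arithmetic and skip rules", {
  # frames:      0   1    2    3    4    5    6    7
  # rd:         NA  0.1  0.1  0.1  0.5  0.3  0.1  0.1
  # event at s = 3, b = 3, w = 4: baseline (0.1,0.1,0.1),
  # post (0.1,0.5,0.3,0.1) sharing the occurrence frame
  rd <- make_rd(list(b1 = c(NA, 0.1, 0.1, 0.1, 0.5, 0.3, 0.1, 0.1)))
  ev <- make_events("b1", 3)
  out <- peri_event_deltas(rd, ev, window_spec(baseline = 3, post = 4))
  expect_equal(out$delta_mean, 0.25 - 0.1)
  expect_equal(out$delta_max, 0.5 - 0.1)
  expect_equal(out$n_baseline_defined, 3)
  expect_equal(out$n_post_defined, 4)

  # constant rd: both deltas exactly zero
  rdc <- make_rd(list(b1 = c(NA, rep(0.2, 30))))
  outc <- peri_event_deltas(rdc, make_events("b1", 15),
                            window_spec(10, 10))
  expect_equal(outc$delta_mean, 0, tolerance = 1e-12)
  expect_equal(outc$delta_max, 0, tolerance = 1e-12)

  # early event: incomplete baseline, skipped not fatal
  early <- peri_event_deltas(rdc, make_events("b1", 2), window_spec(10, 10))
  expect_equal(nrow(early), 0)
  expect_equal(attr(early, "skipped")$reason, "incomplete baseline")

  # event whose post window leaves the bout
  late <- peri_event_deltas(rdc, make_events("b1", 28), window_spec(10, 10))
  expect_equal(attr(late, "skipped")$reason, "incomplete post")
})

test_that("strict deltas match the brute-force oracle on noisy fixtures", {
  set.seed(99)
  r <- c(NA, abs(rnorm(199, 0.05, 0.03)))
  r[sample(50:150, 5)] <- NA  # undefined patches
  rd <- make_rd(list(b1 = r))
  starts <- 0:198
  ev <- make_events(rep("b1", length(starts)), starts)
  for (w in list(window_spec(5, 7), window_spec(10, 10))) {
    got <- peri_event_deltas(rd, ev, w)
    for (s in starts) {
      want <- oracle_delta(r, s, w$baseline, w$post)
      row <- got[got$start_frame == s, ]
      if (is.null(want)) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(row$delta_mean, want$delta_mean)
        expect_equal(row$delta_max, want$delta_max)
      }
    }
  }
})

test_that("tolerant policy admits partial windows above the coverage floor", {
  r <- c(NA, rep(0.1, 40))
  r[25] <- NA  # one undefined post frame for an event at s = 20
  rd <- make_rd(list(b1 = r))
  ev <- make_events("b1", 20)
  strict <- peri_event_deltas(rd, ev, window_spec(10, 10))
  expect_equal(nrow(strict), 0)
  tol <- peri_event_deltas(rd, ev, window_spec(10, 10),
                           policy = "tolerant", min_coverage = 0.8)
  expect_equal(nrow(tol), 1)
  expect_equal(tol$n_post_defined, 9)
  expect_equal(tol$delta_mean, 0)
})

test_that("group statistic is the unweighted mean of individual means", {
  # male A: 100 elements with mean 0.1; male B: 2 elements with mean 0.3
  deltas <- tibble::tibble(
    bout_id = c(rep("bA", 100), rep("bB", 2)),
    element_type = "mock_attack", intensity_class = "high",
    start_frame = 1L, baseline_frames = 10L, post_frames = 10L,
    delta_mean = c(rep(0.1, 100), rep(0.3, 2)),
    delta_max = c(rep(0.1, 100), rep(0.3, 2)),
    n_baseline_defined = 10L, n_post_defined = 10L
  )
  meta <- make_metadata(c("bA", "bB"), c("A", "B"))
  gs <- group_statistic(deltas, meta)
  expect_equal(gs$group$grand_mean, 0.2)  # not the pooled mean ~0.104

  # single individual: grand mean equals its own mean
  gs1 <- group_statistic(deltas[deltas$bout_id == "bA", ], meta)
  expect_equal(gs1$group$grand_mean, 0.1)

  # inflating one male's element count without changing its mean
  # leaves the grand mean unchanged
  inflated <- dplyr::bind_rows(deltas, deltas[deltas$bout_id == "bB", ])
  expect_equal(group_statistic(inflated, meta)$group$grand_mean, 0.2)
})
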