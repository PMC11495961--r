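test_that("exit attribution follows the most-recent-preceding rule", {
  ev <- make_events(c("b1", "b1"), c(100, 300))
  no_exits <- tibble::tibble(bout_id = character(), frame = integer())
  out0 <- score_exits(ev, no_exits)
  expect_equal(out0$outcome, c(0, 0))

  exits <- tibble::tibble(bout_id = "b1", frame = 150L)
  out1 <- score_exits(ev, exits)
  expect_equal(out1$outcome, c(1, 0))

  # an exit before any element is unattributed and warned about
  early <- tibble::tibble(bout_id = "b1", frame = 50L)
  expect_warning(out2 <- score_exits(ev, early), "not be attributed")
  expect_equal(out2$outcome, c(0, 0))
  expect_equal(attr(out2, "unattributed")$frame, 50L)

  # max_lag bounds the attribution window
  out3 <- score_exits(ev, exits, max_lag = 20) |> suppressWarnings()
  expect_equal(out3$outcome, c(0, 0))

  # each exit goes to at most one element
  many <- make_events(rep("b1", 4), c(10, 40, 70, 100))
  ex <- tibble::tibble(bout_id = "b1", frame = c(45L, 46L, 101L))
  out4 <- score_exits(many, ex)
  expect_equal(sum(out4$outcome), 2)  # elements at 40 and 100
})

test_that("attribution considers all elements but reports the class filter", {
  ev <- dplyr::bind_rows(
    make_events("b1", 100, intensity = "high"),
    make_events("b1", 200, intensity = "low", type = "head_bob")
  )
  exits <- tibble::tibble(bout_id = "b1", frame = 250L)
  out <- score_exits(ev, exits, class_filter = "high")
  # the exit belongs to the low element at 200, so the high element at
  # 100 keeps outcome 0
  expect_equal(out$outcome, 0)
  expect_equal(nrow(out), 1)
})

make_outcomes <- function(props, n_each, statuses) {
  males <- sprintf("m%02d", seq_along(props))
  rows <- lapply(seq_along(props), function(i) {
    k <- round(props[i] * n_each)
    tibble::tibble(
      bout_id = sprintf("%s_b", males[i]),
      element_type = "mock_attack", intensity_class = "high",
      start_frame = seq_len(n_each),
      outcome = c(rep(1L, k), rep(0L, n_each - k))
    )
  })
  meta <- tibble::tibble(
    bout_id = sprintf("%s_b", males), male_id = males,
    status = statuses, date = as.Date("2018-09-01"),
    receiver_id = NA_character_, fps = 30
  )
  list(outcomes = dplyr::bind_rows(rows), metadata = meta)
}

test_that("identical outcome vectors give statistic 0 and p = 1", {
  f <- make_outcomes(rep(0.3, 10), 10, rep(c("owner", "subordinate"), 5))
  res <- test_exit_status_effect(f$outcomes, f$metadata)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the permutation test is invariant to male relabeling", {
  set.seed(5)
  props <- runif(8)
  f1 <- make_outcomes(props, 10, rep(c("owner", "subordinate"), 4))
  r1 <- test_exit_status_effect(f1$outcomes, f1$metadata)
  # relabel male ids (and bout ids consistently)
  f2 <- f1
  shuffle <- setNames(sprintf("z%02d", sample(8)), unique(f1$metadata$male_id))
  f2$metadata$male_id <- unname(shuffle[f2$metadata$male_id])
  expect_equal(test_exit_status_effect(f2$outcomes, f2$metadata)$p_value,
               r1$p_value)
})

test_that("permutation needs two males per group", {
  f <- make_outcomes(c(0, 0.5, 0.6), 10,
                     c("owner", "subordinate", "subordinate"))
  expect_error(test_exit_status_effect(f$outcomes, f$metadata),
               class = "peristartle_insufficient_clusters_error")
})

test_that("type-I error of the exit test is controlled at alpha", {
  n_sim <- 120
  rejections <- 0
  cfg <- sim_config(n_owners = 4L, n_subordinates = 4L,
                    bouts_per_male = c(3L, 4L),
                    bout_length_frames = c(150L, 220L),
                    jitter_sd = 0.005, misdetect_rate = 0,
                    startle_magnitude = c(owner = 0, subordinate = 0),
                    exit_probability = c(owner = 0.3, subordinate = 0.3))
  for (i in seq_len(n_sim)) {
    d <- simulate_dataset(cfg, seed = 5000 + i)
    out <- suppressWarnings(score_exits(d$events, d$exits))
    if (nrow(out) == 0) next
    res <- tryCatch(
      test_exit_status_effect(out, d$metadata),
      peristartle_insufficient_clusters_error = function(e) NULL
    )
    if (!is.null(res) && res$p_value <= 0.05) rejections <- rejections + 1
  }
  # permutation tests on discrete proportions are valid, if conservative
  expect_lte(rejections / n_sim, 0.10)
})

test_that("the GLMM contrast runs and reports a likelihood-ratio p", {
  d <- simulate_dataset(sim_config(n_owners = 4L, n_subordinates = 4L,
                                   bouts_per_male = c(4L, 6L),
                                   bout_length_frames = c(300L, 400L),
                                   exit_probability = c(owner = 0.4,
                                                        subordinate = 0.4)),
                        seed = 33)
  out <- suppressWarnings(score_exits(d$events, d$exits))
  res <- suppressWarnings(suppressMessages(
    test_exit_status_effect(out, d$metadata, method = "mixed_model")
  ))
  expect_true(is.finite(res$chisq))
  expect_equal(res$df, 1)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("annotation agreement recovers exact and destroyed structure", {
  set.seed(12)
  n <- 200
  bx <- cumsum(rnorm(n, 0, 2))
  by <- cumsum(rnorm(n, 0, 2))
  auto <- make_track("b1", beak_x = bx, beak_y = by, itj_y = by + 100)

  perfect <- annotation_agreement(auto, auto)
  expect_equal(perfect$mean_err_px, rep(0, nrow(perfect)))
  expect_equal(perfect$cor_y, rep(1, nrow(perfect)))
  expect_equal(perfect$cor_x[perfect$keypoint == "beak_tip"], 1)

  offset <- auto
  offset$x <- offset$x + 3
  offset$y <- offset$y + 4
  off <- annotation_agreement(auto, offset)
  expect_equal(off$mean_err_px, rep(5, nrow(off)))
  # body-height fractions are exactly pixel error over mean body height
  m <- compute_body_metrics(auto)
  expect_equal(off$mean_err_bh,
               off$mean_err_px / m$bouts$body_height_mean)

  shuffled <- auto
  ridx <- shuffled$keypoint == "beak_tip"
  shuffled$y[ridx] <- sample(shuffled$y[ridx])
  sh <- annotation_agreement(auto, shuffled)
  expect_lt(abs(sh$cor_y[sh$keypoint == "beak_tip"]), 0.2)
  expect_equal(sh$cor_x[sh$keypoint == "beak_tip"], 1)

  empty <- auto
  empty$bout_id <- "other"
  expect_error(annotation_agreement(auto, empty),
               class = "peristartle_empty_comparison_error")
})
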