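# End-to-end orchestration: clean -> rd -> delta -> bootstrap -> sweep
# -> exits -> report, from a single YAML/list configuration with one
# master seed.  Stage-tagged log lines go to standard error (message());
# results only ever go to files and the returned object.

#' Default pipeline configuration
#'
#' Returns the configuration template accepted by [run_pipeline()]
#' (either as a list or written as YAML).  A pipeline run either
#' simulates a dataset (`simulate:` section, see [sim_config()]) or
#' loads one from `input: dir:` (a directory as written by
#' [write_dataset()]).
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return A nested list.
#' @export
pipeline_config_template <- function(seed = 1L, out_dir = "peristartle_out") {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(n_owners = 3L, n_subordinates = 3L,
                    bouts_per_male = c(4L, 8L),
                    bout_length_frames = c(300L, 600L)),
    input = NULL,
    cleaning = list(hard = 0.5, soft = 0.25),
    delta = list(baseline = 10L, post = 10L, policy = "strict",
                 classes = c("high", "low")),
    bootstrap = list(reps = 1000L, alpha = 0.05, statistic = "delta_mean",
                     statuses = c("owner", "subordinate")),
    sweep = list(enabled = FALSE, post = c(4L, 50L),
                 baselines = c(5L, 10L, 15L, 20L), reps = 1000L),
    exits = list(enabled = TRUE, method = "cluster_permutation",
                 reps = 10000L)
  )
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.stage <- function(name, expr) {
  message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full peri-startle pipeline
#'
#' Executes clean -> relative displacement -> peri-event deltas ->
#' bootstrap null -> (optional) window sweep -> exit test, writing all
#' stage outputs as CSV/JSON into the configured output directory along
#' with a run manifest (config echo, seeds, input digests, per-stage
#' record counts, warnings).
#'
#' @param config A configuration list (see
#'   [pipeline_config_template()]) or the path to a YAML file with the
#'   same structure.
#' @param out_dir Optional override of `config$out_dir`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config_template(),
                         out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(pipeline_config_template(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  warnings_log <- character()
  counts <- list()
  withCallingHandlers({

    input_digests <- NULL
    if (!is.null(cfg$input) && !is.null(cfg$input$dir)) {
      dataset <- .stage("load", read_dataset(cfg$input$dir))
      files <- file.path(cfg$input$dir,
                         c("tracks.csv", "annotations.csv", "exits.csv"))
      input_digests <- as.list(tools::md5sum(files[file.exists(files)]))
    } else {
      sim_cfg <- do.call(sim_config, c(cfg$simulate,
                                       list(seed = .derive_cell_seed(seed, 1L))))
      dataset <- .stage("simulate", simulate_dataset(sim_cfg))
    }
    counts$bouts <- length(dataset$bout_lengths)
    counts$frames <- sum(dataset$bout_lengths)
    counts$events <- nrow(dataset$events)
    counts$exits <- nrow(dataset$exits)

    cleaned <- .stage("clean", clean_dataset(dataset,
                                             hard = cfg$cleaning$hard,
                                             soft = cfg$cleaning$soft))
    dataset <- cleaned$dataset
    counts$removed <- cleaned$report$removed
    counts$flagged <- cleaned$report$flagged
    write_keypoint_csv(dataset$tracks,
                       file.path(cfg$out_dir, "cleaned_tracks.csv"))
    readr::write_csv(cleaned$report$records,
                     file.path(cfg$out_dir, "cleaning_report.csv"),
                     progress = FALSE)

    rd <- .stage("rd", relative_displacement(dataset$tracks,
                                             cleaned$metrics))
    readr::write_csv(rd, file.path(cfg$out_dir, "rd_series.csv"),
                     progress = FALSE)

    window <- window_spec(cfg$delta$baseline, cfg$delta$post)
    deltas <- .stage("delta", {
      ev <- dataset$events[dataset$events$intensity_class %in%
                             cfg$delta$classes, , drop = FALSE]
      peri_event_deltas(rd, ev, window, policy = cfg$delta$policy)
    })
    counts$delta_records <- nrow(deltas)
    counts$delta_skipped <- nrow(attr(deltas, "skipped"))
    readr::write_csv(deltas, file.path(cfg$out_dir, "delta_records.csv"),
                     progress = FALSE)

    gs <- .stage("group_statistic",
                 group_statistic(deltas, dataset$metadata,
                                 statistic = cfg$bootstrap$statistic))
    readr::write_csv(gs$individual,
                     file.path(cfg$out_dir, "individual_means.csv"),
                     progress = FALSE)
    readr::write_csv(gs$group, file.path(cfg$out_dir, "group_stats.csv"),
                     progress = FALSE)

    nulls <- .stage("bootstrap", {
      res <- list()
      i <- 0L
      for (st in cfg$bootstrap$statuses) {
        for (cl in cfg$delta$classes) {
          i <- i + 1L
          icfg <- inference_config(
            reps = cfg$bootstrap$reps, alpha = cfg$bootstrap$alpha,
            seed = .derive_cell_seed(seed, 100L + i),
            statistic = cfg$bootstrap$statistic
          )
          res[[paste(st, cl, sep = "_")]] <-
            bootstrap_null(dataset, st, cl, window, icfg, rd = rd)
        }
      }
      res
    })
    # report stage data: null histogram + observed-line data
    null_long <- bind_rows(lapply(nulls, function(x) {
      tibble(status = x$status, intensity_class = x$element_class,
             replicate = seq_along(x$replicates), value = x$replicates)
    }))
    null_summary <- bind_rows(lapply(nulls, function(x) {
      tibble(status = x$status, intensity_class = x$element_class,
             baseline = x$window$baseline, post = x$window$post,
             observed = x$observed, q_lower = x$q_lower,
             q_upper = x$q_upper, p_value = x$p_value)
    }))
    readr::write_csv(null_long,
                     file.path(cfg$out_dir, "null_distribution.csv"),
                     progress = FALSE)
    readr::write_csv(null_summary,
                     file.path(cfg$out_dir, "null_summary.csv"),
                     progress = FALSE)

    sweep <- NULL
    if (isTRUE(cfg$sweep$enabled)) {
      sweep <- .stage("sweep", {
        post_range <- unlist(cfg$sweep$post)
        scfg <- inference_config(
          reps = cfg$sweep$reps, alpha = cfg$bootstrap$alpha,
          post_sizes = seq(post_range[1], post_range[2]),
          baseline_sizes = unlist(cfg$sweep$baselines),
          seed = .derive_cell_seed(seed, 3L),
          statistic = cfg$bootstrap$statistic
        )
        window_sweep(dataset, scfg,
                     statuses = cfg$bootstrap$statuses,
                     classes = cfg$delta$classes)
      })
      readr::write_csv(sweep, file.path(cfg$out_dir, "sweep.csv"),
                       progress = FALSE)
      counts$sweep_rows <- nrow(sweep)
    }

    exit_test <- NULL
    if (isTRUE(cfg$exits$enabled) && nrow(dataset$events) > 0 &&
        length(unique(dataset$metadata$status)) == 2) {
      exit_test <- .stage("exits", {
        outcomes <- score_exits(dataset$events, dataset$exits,
                                class_filter = "high")
        test_exit_status_effect(outcomes, dataset$metadata,
                                method = cfg$exits$method,
                                reps = cfg$exits$reps,
                                seed = .derive_cell_seed(seed, 4L))
      })
      et <- list(method = exit_test$method,
                 statistic = exit_test$statistic,
                 p_value = exit_test$p_value,
                 mode = exit_test$mode,
                 n_assignments = exit_test$n_assignments)
      jsonlite::write_json(et, file.path(cfg$out_dir, "exit_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    manifest <- list(
      package = "peristartle",
      version = as.character(utils::packageVersion("peristartle")),
      created = format(Sys.time(), tz = "UTC"),
      seed = seed,
      config = cfg,
      input_digests = input_digests,
      counts = counts,
      warnings = warnings_log
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    message("[done] outputs in ", cfg$out_dir)

    invisible(list(dataset = dataset, cleaning = cleaned$report, rd = rd,
                   deltas = deltas, group_statistic = gs, nulls = nulls,
                   sweep = sweep, exit_test = exit_test,
                   manifest = manifest))
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}
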