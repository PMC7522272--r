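## Pipeline plumbing: stage functions over files, a manifest with content
## hashes, and a small CLI dispatcher (subcommands: simulate, segment,
## analyze, score-nba, stats, run).

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> segment -> analyze -> score-nba -> stats on one
#' configuration and writes every artifact under `config$out`. The stages
#' are file-coupled (CSV/TIFF/JSON), so each can also be run alone through
#' [pwf_cli()]. Identical config and seed reproduce identical manifest
#' hashes.
#'
#' @param config Pipeline configuration: a list as returned by
#'   [read_pipeline_config()], or a path to a YAML/JSON config file.
#' @return Invisibly, the artifact manifest: data frame `stage`, `file`,
#'   `md5`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out %||% stop("config error: no output directory set",
                                  call. = FALSE)
  if (!is.null(config$`in`) && !file.exists(config$`in`)) {
    stop("config error: input path does not exist: ", config$`in`,
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    files <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] %d file(s) in %.2fs", stage, length(files),
                    as.numeric(Sys.time() - t0, units = "secs")))
    note(stage, files)
    files
  }

  run_stage("simulate", stage_simulate(config, out_dir))
  run_stage("segment", stage_segment(config, out_dir))
  run_stage("analyze", stage_analyze(config, out_dir))
  run_stage("score-nba", stage_score_nba(config, out_dir))
  run_stage("stats", stage_stats(config, out_dir))
  manifest <- do.call(rbind, manifest)
  write_dataset(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

stage_simulate <- function(config, out_dir) {
  sc <- config$study
  ds <- simulate_longitudinal_study(sc, level = "timeseries")
  f_ds <- file.path(out_dir, "dataset.csv")
  write_dataset(ds, f_ds)
  nba <- attr(ds, "nba")
  items <- nba_items_from_totals(nba)
  f_nba <- file.path(out_dir, "nba_items.csv")
  write_dataset(items, f_nba)
  acq <- simulate_frame_sequence(sc, seed = sc$seed + 1L)
  f_tif <- file.path(out_dir, "frames.tif")
  paths <- write_mbr_tiff(acq$frames, f_tif)
  f_truth <- file.path(out_dir, "masks_truth.tif")
  write_masks_tiff(acq$masks, f_truth)
  c(f_ds, f_nba, paths, f_truth)
}

stage_segment <- function(config, out_dir) {
  seq <- read_mbr_tiff(file.path(out_dir, "frames.tif"))
  roi <- config$analysis$roi
  if (!is.null(roi)) {
    seq <- crop_roi(seq, roi_rect(roi[1], roi[2], roi[3], roi[4]))
  }
  mean_map <- apply(seq$frames, c(1, 2), mean)
  masks <- segment_vessel_tissue(mean_map, method = config$analysis$segmentation,
                                 quantile_q = config$analysis$quantile_q)
  f_masks <- file.path(out_dir, "masks.tif")
  write_masks_tiff(masks, f_masks)
  series <- extract_region_waveforms(seq, masks)
  f_series <- file.path(out_dir, "roi_series.csv")
  write_dataset(series, f_series)
  c(f_masks, f_series)
}

stage_analyze <- function(config, out_dir) {
  ds <- read_dataset(file.path(out_dir, "dataset.csv"), "timeseries")
  if (!"session" %in% names(ds)) ds$session <- ds$day
  key <- interaction(ds$rabbit_id, ds$session, ds$region, drop = TRUE)
  rows <- lapply(split(ds, key), function(g) {
    g <- g[order(g$frame_index), ]
    fs <- 1 / stats::median(diff(g$time_s))
    pwf <- tryCatch({
      cyc <- synchronize_cycles(g$mbr, fs, n_out = config$analysis$n_frames)
      as.data.frame(compute_pwf(cyc))
    }, error = function(e) NULL)
    if (is.null(pwf)) return(NULL)
    cbind(data.frame(rabbit_id = g$rabbit_id[1L], day = g$day[1L],
                     is_baseline = g$is_baseline[1L], region = g$region[1L],
                     session = g$session[1L]), pwf)
  })
  pwf <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  pwf <- pwf[order(pwf$rabbit_id, pwf$session, pwf$region), ]
  f <- file.path(out_dir, "pwf.csv")
  write_dataset(pwf, f)
  f
}

stage_score_nba <- function(config, out_dir) {
  items <- read_dataset(file.path(out_dir, "nba_items.csv"), "nba_items")
  totals <- vapply(seq_len(nrow(items)), function(i) {
    rec <- as.list(items[i, c(names(NBA_ITEM_MAX), "is_dead")])
    score_nba(structure(rec, class = "nba_record"))
  }, integer(1))
  out <- data.frame(rabbit_id = items$rabbit_id, day = items$day,
                    session = items$session, nba_total = totals)
  f <- file.path(out_dir, "nba_scores.csv")
  write_dataset(out, f)
  f
}

stage_stats <- function(config, out_dir) {
  pwf <- read_dataset(file.path(out_dir, "pwf.csv"), "pwf")
  nba <- utils::read.csv(file.path(out_dir, "nba_scores.csv"))
  pwf <- merge(pwf, nba[c("rabbit_id", "session", "nba_total")],
               by = c("rabbit_id", "session"), all.x = TRUE)
  res <- run_stats(pwf, phase_windows = config$analysis$phase_windows,
                   alpha = config$analysis$alpha)
  f_tests <- file.path(out_dir, "stats_results.csv")
  write_dataset(rbind(res$tests, res$correlations), f_tests)
  f_phase <- file.path(out_dir, "phase_report.json")
  jsonlite::write_json(
    lapply(res$phases, function(ph) {
      list(window = ph$window, label = ph$label,
           directions = as.list(ph$directions))
    }),
    f_phase, auto_unbox = TRUE, digits = NA)
  c(f_tests, f_phase)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Usage:
#' `lsfgpwf <simulate|segment|analyze|score-nba|stats|run> --config <yaml>
#' [--out <dir>] [--seed <int>]`. The installed launcher lives at
#' `system.file("cli", "lsfgpwf.R", package = "lsfgpwf")`.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Invisibly, the stage's file list or manifest.
#' @export
pwf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: lsfgpwf <simulate|segment|analyze|score-nba|stats|run> ",
         "--config <yaml|json> [--out <dir>] [--seed <int>]", call. = FALSE)
  }
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  if (is.null(opts$config)) {
    stop("config error: --config is required", call. = FALSE)
  }
  config <- read_pipeline_config(opts$config)
  if (!is.null(opts$out)) config$out <- opts$out
  if (!is.null(opts$seed)) {
    config$study$seed <- as.integer(opts$seed)
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    simulate = invisible(stage_simulate(config, out_dir)),
    segment = invisible(stage_segment(config, out_dir)),
    analyze = invisible(stage_analyze(config, out_dir)),
    `score-nba` = invisible(stage_score_nba(config, out_dir)),
    stats = invisible(stage_stats(config, out_dir)),
    run = run_pipeline(config),
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
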