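## CSV interchange. CSV is the canonical format (no open LSFG format
## exists); numeric columns are serialized with 17 significant digits so a
## write/read round trip reproduces doubles exactly.

DATASET_SCHEMAS <- list(
  timeseries = c("rabbit_id", "day", "is_baseline", "region", "frame_index",
                 "time_s", "mbr"),
  pwf = c("rabbit_id", "day", "region", "mbr", "mbr_max", "mbr_min", "ac",
          "bos", "bot", "rr", "fr", "fai", "ati", "ri", "s1_area", "s2_area",
          "w", "f", "n_frames"),
  nba_items = c("rabbit_id", "day", "session", names(NBA_ITEM_MAX), "is_dead")
)
REGION_LEVELS <- c("MA", "MV", "MT")

#' Write a dataset table to CSV at full precision
#'
#' @param dataset A data frame (any of the package's table schemas).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  out <- dataset
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset table, validating its schema
#'
#' Recognizes the per-frame time-series schema, the per-cycle PWF schema,
#' and the item-level NBA schema; `schema = "auto"` infers from the
#' columns. Unknown region labels and missing required columns are parse
#' errors naming the offender.
#'
#' @param path CSV path.
#' @param schema `"auto"`, `"timeseries"`, `"pwf"`, or `"nba_items"`.
#' @return Data frame with attribute `schema`.
#' @export
read_dataset <- function(path, schema = c("auto", "timeseries", "pwf",
                                          "nba_items")) {
  schema <- match.arg(schema)
  if (!file.exists(path) || file.info(path)$size == 0) {
    stop("parse error: empty or missing file ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop("parse error: no records in ", path, call. = FALSE)
  }
  if (schema == "auto") {
    schema <- if (all(DATASET_SCHEMAS$pwf %in% names(df))) "pwf"
      else if (all(DATASET_SCHEMAS$timeseries %in% names(df))) "timeseries"
      else if (all(DATASET_SCHEMAS$nba_items %in% names(df))) "nba_items"
      else stop("parse error: columns match no known schema: ",
                paste(names(df), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(DATASET_SCHEMAS[[schema]], names(df))
  if (length(miss)) {
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("region" %in% names(df)) {
    bad <- setdiff(unique(df$region), REGION_LEVELS)
    if (length(bad)) {
      stop("parse error: unknown region label(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if ("is_baseline" %in% names(df)) {
    df$is_baseline <- as.logical(df$is_baseline)
  }
  attr(df, "schema") <- schema
  df
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' The file may carry `out`, `seed`, a `study` block ([study_config()]
#' fields), and an `analysis` block (`n_frames`, `segmentation`,
#' `quantile_q`, `alpha`, `phase_windows`, `roi`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list with a fully built `study_config` in `$study`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: no such file ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config error: unsupported config format .", ext, call. = FALSE)
  }
  cfg$analysis <- utils::modifyList(
    list(n_frames = 30L, segmentation = "otsu", quantile_q = 0.2,
         alpha = 0.05, phase_windows = list(c(1, 19), c(20, 28)),
         roi = NULL),
    cfg$analysis %||% list())
  if (cfg$analysis$alpha <= 0 || cfg$analysis$alpha >= 1) {
    stop("config error: alpha must lie in (0, 1)", call. = FALSE)
  }
  study_args <- cfg$study %||% list()
  if (!is.null(cfg$seed)) study_args$seed <- cfg$seed
  cfg$study <- do.call(study_config, study_args)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
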