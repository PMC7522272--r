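#' Neurological and behavioural assessment record
#'
#' One scoring session of the combined rubric: five neurological-assessment
#' items (neck twist 0-1; righting reflex, forepaw extension, hind-limb
#' extension, postural reflex each 0-2) and six wellness items (facial
#' grimace, ears, exploration, grooming each 0-2; eating, drinking each
#' 0-1). 0 is normal; higher is worse. A living animal scores 0-19; death
#' is recorded as 20 regardless of item values.
#'
#' @param neck_twist,righting_reflex,forepaws_extension,hind_limbs_extension,postural_reflex
#'   Neurological items.
#' @param facial_grimace,ears,exploration,eating,drinking,grooming Wellness
#'   items.
#' @param is_dead Logical death flag.
#' @return Object of class `nba_record`.
#' @export
nba_record <- function(neck_twist = 0, righting_reflex = 0,
                       forepaws_extension = 0, hind_limbs_extension = 0,
                       postural_reflex = 0, facial_grimace = 0, ears = 0,
                       exploration = 0, eating = 0, drinking = 0,
                       grooming = 0, is_dead = FALSE) {
  structure(
    list(neck_twist = neck_twist, righting_reflex = righting_reflex,
         forepaws_extension = forepaws_extension,
         hind_limbs_extension = hind_limbs_extension,
         postural_reflex = postural_reflex, facial_grimace = facial_grimace,
         ears = ears, exploration = exploration, eating = eating,
         drinking = drinking, grooming = grooming,
         is_dead = isTRUE(is_dead)),
    class = "nba_record"
  )
}

#' Validate an NBA record
#'
#' @param record An [nba_record()] (or a compatible named list).
#' @return Character vector of violations, one per offending item, naming
#'   the item and its allowed range; empty when the record is valid.
#' @export
validate_nba <- function(record) {
  violations <- character(0)
  for (item in names(NBA_ITEM_MAX)) {
    v <- record[[item]]
    mx <- NBA_ITEM_MAX[[item]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      v == round(v) && v >= 0 && v <= mx
    if (!ok) {
      violations <- c(violations,
                      sprintf("%s must be an integer in {0..%d}", item, mx))
    }
  }
  violations
}

#' Score an NBA record
#'
#' Sums the 11 item scores; the maximum achievable total for a living
#' animal is 19. Death overrides the items and scores 20.
#'
#' @param record An [nba_record()].
#' @return Integer total in 0-19 (alive) or 20 (death).
#' @export
score_nba <- function(record) {
  if (isTRUE(record$is_dead)) return(20L)
  bad <- validate_nba(record)
  if (length(bad)) {
    stop("invalid NBA record: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  as.integer(sum(vapply(names(NBA_ITEM_MAX),
                        function(i) as.integer(record[[i]]), integer(1))))
}

#' Score a table of NBA sessions
#'
#' Scores item-level session rows and aggregates the (up to) three daily
#' wellness observations into one value per rabbit and day by the mean
#' rounded half-up.
#'
#' @param df Data frame with columns `rabbit_id`, `day`, `session`, the 11
#'   item columns, and `is_dead`.
#' @return Data frame `rabbit_id`, `day`, `nba_total` (one row per rabbit
#'   and day).
#' @export
score_nba_table <- function(df) {
  need <- c("rabbit_id", "day", names(NBA_ITEM_MAX), "is_dead")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("NBA table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  totals <- vapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, c(names(NBA_ITEM_MAX), "is_dead")])
    score_nba(structure(rec, class = "nba_record"))
  }, integer(1))
  agg <- stats::aggregate(totals,
                          by = list(rabbit_id = df$rabbit_id, day = df$day),
                          FUN = function(x) floor(mean(x) + 0.5))
  names(agg)[3L] <- "nba_total"
  agg[order(agg$rabbit_id, agg$day), ]
}
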