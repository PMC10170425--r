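#' Item schema for an ordinal symptom battery
#'
#' An item schema records, for every item of the battery, its ordinal scale
#' bounds and whether the raw survey coding has to be reflected
#' (reverse-coded) so that higher values indicate poorer mental health.
#'
#' @param item_id character vector of short item labels (unique).
#' @param scale_min,scale_max integer vectors of per-item scale bounds,
#'   `scale_min < scale_max` elementwise.
#' @param reverse_coded logical vector; `TRUE` for items whose raw coding has
#'   higher values = better health and must be reflected by
#'   [recode_items()].
#' @param label optional long item descriptions.
#'
#' @return A data frame of class `item_schema` with one row per item.
#' @seealso [default_item_schema()]
#' @export
item_schema <- function(item_id, scale_min, scale_max,
                        reverse_coded = FALSE, label = item_id) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) stop("item_id values must be unique")
  schema <- data.frame(
    item_id = item_id,
    scale_min = as.integer(scale_min),
    scale_max = as.integer(scale_max),
    reverse_coded = rep_len(as.logical(reverse_coded), length(item_id)),
    label = rep_len(as.character(label), length(item_id)),
    stringsAsFactors = FALSE
  )
  if (any(schema$scale_min >= schema$scale_max))
    stop("scale_min must be strictly below scale_max for every item")
  class(schema) <- c("item_schema", "data.frame")
  schema
}

#' Default 13-item distress battery schema
#'
#' Twelve GHQ-12 items on a 0-3 Likert scale plus a single loneliness item on
#' a 1-3 scale ("hardly ever or never" / "some of the time" / "often").
#'
#' @param recoded if `TRUE` (default) the schema describes data already
#'   oriented so that higher = more distress (no reverse-coded items), the
#'   orientation produced by [recode_items()] and by [simulate_panel()].
#'   If `FALSE`, the six positively worded GHQ items carry
#'   `reverse_coded = TRUE`, matching the raw instrument coding.
#'
#' @return An [item_schema] with 13 rows; the loneliness item is last.
#' @export
default_item_schema <- function(recoded = TRUE) {
  items <- c("concentrate", "sleep", "useful", "decisions", "stress",
             "difficulties", "activities", "face_problems", "depressed",
             "confidence", "worthless", "happy", "loneliness")
  labels <- c("Able to concentrate", "Lost much sleep",
              "Playing a useful part", "Capable of making decisions",
              "Under stress", "Could not overcome difficulties",
              "Enjoy normal activities", "Can face up to problems",
              "Feeling unhappy and depressed", "Losing confidence",
              "Thinking of self as worthless", "Feeling reasonably happy",
              "How often do you feel lonely")
  positive <- c("concentrate", "useful", "decisions", "activities",
                "face_problems", "happy")
  item_schema(
    item_id = items,
    scale_min = c(rep(0L, 12), 1L),
    scale_max = c(rep(3L, 12), 3L),
    reverse_coded = if (recoded) FALSE else items %in% positive,
    label = labels
  )
}

#' GHQ-12 item identifiers of a schema
#'
#' All items except the loneliness item, i.e. the items entering the GHQ sum
#' score.
#' @param schema an [item_schema].
#' @return character vector of item ids.
#' @export
ghq_items <- function(schema) {
  setdiff(schema$item_id, "loneliness")
}
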