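#' Reflect reverse-coded items
#'
#' Items flagged `reverse_coded` in the schema are reflected as
#' `scale_min + scale_max - x`, so that higher values consistently indicate
#' poorer mental health. Applying the operation twice restores the original
#' data (involution); the returned schema has all reverse flags cleared and
#' is restored on a second application, so the round trip is exact.
#'
#' @param data a [panel_dataset].
#' @return A [panel_dataset] with reflected responses.
#' @export
recode_items <- function(data) {
  schema <- data$schema
  r <- data$responses
  for (i in which(schema$reverse_coded)) {
    r[, i, ] <- schema$scale_min[i] + schema$scale_max[i] - r[, i, ]
  }
  data$responses <- r
  data
}

#' GHQ-12 sum score and caseness
#'
#' Sums the 12 GHQ items (0-3 each, sum 0-36; the loneliness item is
#' excluded) for one wave and flags caseness at the conventional cut-off of
#' a sum score strictly greater than 11. A subject with any missing GHQ item
#' at the wave gets a missing score and missing caseness flag rather than
#' being dropped.
#'
#' @param data a [panel_dataset].
#' @param wave wave label to score.
#' @param cutoff caseness cut-off; a subject is a case when `sum > cutoff`
#'   (default 11).
#' @return data frame with columns `subject`, `ghq_sum`, `case`.
#' @export
ghq_sum_and_caseness <- function(data, wave, cutoff = 11) {
  m <- wave_matrix(data, wave)
  ghq <- m[, ghq_items(data$schema), drop = FALSE]
  sums <- rowSums(ghq)            # NA propagates for any missing item
  data.frame(
    subject = data$subjects,
    ghq_sum = sums,
    case = sums > cutoff,
    stringsAsFactors = FALSE
  )
}
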