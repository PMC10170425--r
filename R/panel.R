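#' Panel dataset of ordinal item responses
#'
#' Container for subjects x items x waves ordinal responses with an explicit
#' missingness mask (`NA`), per-subject auxiliary covariates, and the item
#' schema. All downstream stages (imputation, network estimation, bootstrap)
#' consume this class.
#'
#' @param responses numeric array `[n_subjects, n_items, n_waves]`; `NA`
#'   marks a missing response. Dimnames are set from the other arguments.
#' @param subjects character vector of unique subject identifiers.
#' @param waves character vector of wave labels in temporal order.
#' @param schema an [item_schema]; its `item_id` order defines item order.
#' @param aux data frame of per-subject auxiliary covariates with columns
#'   `subject`, `sex` (1 = male, 0 = female), `ethnicity` (1 = non-white,
#'   0 = white), `age` (years), or `NULL` if unavailable.
#' @param latent optional latent continuous values of the same shape as
#'   `responses`; attached by [simulate_panel()] for recovery testing.
#'
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(responses, subjects, waves, schema, aux = NULL,
                          latent = NULL) {
  subjects <- as.character(subjects)
  waves <- as.character(waves)
  stopifnot(is.array(responses), length(dim(responses)) == 3)
  if (anyDuplicated(subjects)) stop("subject identifiers must be unique")
  if (anyDuplicated(waves)) stop("wave labels must be unique")
  dimnames(responses) <- list(subjects, schema$item_id, waves)
  if (!is.null(aux)) {
    aux <- as.data.frame(aux)
    if (!"subject" %in% names(aux)) stop("aux must have a 'subject' column")
    aux$subject <- as.character(aux$subject)
    aux <- aux[match(subjects, aux$subject), , drop = FALSE]
    rownames(aux) <- NULL
  }
  obj <- structure(
    list(responses = responses, subjects = subjects, waves = waves,
         schema = schema, aux = aux, latent = latent),
    class = "panel_dataset"
  )
  validate_panel(obj)
  obj
}

#' Validate a panel dataset against its schema
#'
#' Checks that every non-missing response lies within its item's scale bounds
#' and that dimensions are consistent.
#'
#' @param data a [panel_dataset].
#' @return `data`, invisibly; signals an error naming the offending
#'   subject/wave/item otherwise.
#' @export
validate_panel <- function(data) {
  r <- data$responses
  if (dim(r)[1] != length(data$subjects) ||
      dim(r)[2] != nrow(data$schema) ||
      dim(r)[3] != length(data$waves))
    stop("response array dimensions do not match subjects/schema/waves")
  for (i in seq_len(nrow(data$schema))) {
    v <- r[, i, , drop = FALSE]
    bad <- which(!is.na(v) & (v < data$schema$scale_min[i] |
                                v > data$schema$scale_max[i] |
                                v != round(v)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "response out of range for item '%s': subject '%s', wave '%s', value %g",
        data$schema$item_id[i],
        data$subjects[bad[1, 1]],
        data$waves[bad[1, 3]],
        v[bad[1, 1], 1, bad[1, 3]]))
    }
  }
  invisible(data)
}

#' @export
print.panel_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$responses))
  cat(sprintf(
    "panel_dataset: %d subjects, %d items, %d waves (%s), %d missing cells (%.1f%%)\n",
    length(x$subjects), nrow(x$schema), length(x$waves),
    paste(x$waves, collapse = ", "), n_miss,
    100 * n_miss / length(x$responses)))
  invisible(x)
}

#' Extract the item-response matrix of one wave
#'
#' @param data a [panel_dataset].
#' @param wave a wave label.
#' @return numeric matrix subjects x items (with `NA` for missing).
#' @export
wave_matrix <- function(data, wave) {
  wave <- as.character(wave)
  if (!wave %in% data$waves) stop(sprintf("unknown wave '%s'", wave))
  m <- data$responses[, , wave, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  dimnames(m) <- list(data$subjects, data$schema$item_id)
  m
}

#' Read a panel dataset from a delimited text file
#'
#' Supports a long layout (one row per subject/wave/item) and a wide layout
#' (one row per subject, one column per item-wave combination). Declared
#' sentinel codes (e.g. negative survey codes) become missing; any other
#' unparseable or out-of-range cell is an error.
#'
#' @param path path to a CSV/TSV file with a header row (UTF-8).
#' @param schema an [item_schema].
#' @param format_config list describing the layout:
#'   \describe{
#'     \item{format}{`"long"` or `"wide"`.}
#'     \item{subject, wave, item, value}{column names for the long layout
#'       (defaults `"subject"`, `"wave"`, `"item"`, `"value"`).}
#'     \item{waves}{for the wide layout, the ordered wave labels; columns are
#'       expected as `<item><sep><wave>`.}
#'     \item{sep}{item/wave separator of wide column names (default `"_"`).}
#'     \item{na_codes}{numeric sentinel codes to treat as missing.}
#'     \item{aux}{named character vector mapping `sex`/`ethnicity`/`age` to
#'       column names, if auxiliary covariates are present.}
#'     \item{delim}{field delimiter (default `","`).}
#'   }
#'
#' @return A validated [panel_dataset].
#' @export
read_panel <- function(path, schema = default_item_schema(),
                       format_config = list(format = "long")) {
  fc <- format_config
  delim <- fc$delim %||% ","
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  check.names = FALSE)
  format <- fc$format %||% "long"
  na_codes <- fc$na_codes %||% numeric(0)

  parse_value <- function(x, where) {
    v <- suppressWarnings(as.numeric(x))
    is_na_in <- is.na(x) | trimws(as.character(x)) %in% c("", "NA")
    v[!is.na(v) & v %in% na_codes] <- NA_real_
    bad <- is.na(v) & !is_na_in & !(as.character(x) %in% as.character(na_codes))
    if (any(bad))
      stop(sprintf("unparseable cell '%s' in %s (not a declared sentinel)",
                   x[which(bad)[1]], where))
    v
  }

  if (format == "long") {
    cols <- c(subject = fc[["subject"]] %||% "subject",
              wave = fc[["wave"]] %||% "wave",
              item = fc[["item"]] %||% "item",
              value = fc[["value"]] %||% "value")
    missing_cols <- setdiff(unname(cols), names(raw))
    if (length(missing_cols) > 0)
      stop(sprintf("declared column(s) not found: %s",
                   paste(missing_cols, collapse = ", ")))
    subj <- as.character(raw[[cols["subject"]]])
    wv <- as.character(raw[[cols["wave"]]])
    it <- as.character(raw[[cols["item"]]])
    unknown <- setdiff(unique(it), schema$item_id)
    if (length(unknown) > 0)
      stop(sprintf("item(s) not in schema: %s", paste(unknown, collapse = ", ")))
    val <- parse_value(raw[[cols["value"]]], "value column")
    subjects <- unique(subj)
    waves <- fc$waves %||% unique(wv)
    arr <- array(NA_real_, c(length(subjects), nrow(schema), length(waves)))
    i <- match(subj, subjects)
    j <- match(it, schema$item_id)
    k <- match(wv, waves)
    idx <- cbind(i, j, k)
    if (anyDuplicated(idx))
      stop("duplicate (subject, wave, item) rows in input")
    arr[idx] <- val
    aux <- NULL
    if (!is.null(fc$aux)) {
      aux_cols <- fc$aux
      missing_aux <- setdiff(unname(aux_cols), names(raw))
      if (length(missing_aux) > 0)
        stop(sprintf("declared auxiliary column(s) not found: %s",
                     paste(missing_aux, collapse = ", ")))
      first <- !duplicated(subj)
      aux <- data.frame(subject = subj[first], stringsAsFactors = FALSE)
      for (nm in names(aux_cols)) aux[[nm]] <- raw[[aux_cols[nm]]][first]
    }
    return(panel_dataset(arr, subjects, waves, schema, aux))
  }

  if (format == "wide") {
    subject_col <- fc$subject %||% "subject"
    if (!subject_col %in% names(raw))
      stop(sprintf("declared column(s) not found: %s", subject_col))
    waves <- fc$waves
    if (is.null(waves)) stop("wide format requires format_config$waves")
    sep <- fc$sep %||% "_"
    subjects <- as.character(raw[[subject_col]])
    arr <- array(NA_real_, c(length(subjects), nrow(schema), length(waves)))
    for (j in seq_len(nrow(schema))) {
      for (k in seq_along(waves)) {
        col <- paste0(schema$item_id[j], sep, waves[k])
        if (!col %in% names(raw))
          stop(sprintf("declared column(s) not found: %s", col))
        arr[, j, k] <- parse_value(raw[[col]], sprintf("column '%s'", col))
      }
    }
    aux <- NULL
    if (!is.null(fc$aux)) {
      aux_cols <- fc$aux
      missing_aux <- setdiff(unname(aux_cols), names(raw))
      if (length(missing_aux) > 0)
        stop(sprintf("declared auxiliary column(s) not found: %s",
                     paste(missing_aux, collapse = ", ")))
      aux <- data.frame(subject = subjects, stringsAsFactors = FALSE)
      for (nm in names(aux_cols)) aux[[nm]] <- raw[[aux_cols[nm]]]
    }
    return(panel_dataset(arr, subjects, waves, schema, aux))
  }

  stop(sprintf("unknown format '%s'", format))
}

#' Write a panel dataset to CSV (long layout)
#'
#' @param data a [panel_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  long <- as.data.frame(data)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) {
  d <- dim(x$responses)
  out <- data.frame(
    subject = rep(x$subjects, times = d[2] * d[3]),
    wave = rep(x$waves, each = d[1] * d[2]),
    item = rep(rep(x$schema$item_id, each = d[1]), times = d[3]),
    value = as.vector(x$responses),
    stringsAsFactors = FALSE
  )
  if (!is.null(x$aux)) {
    for (nm in setdiff(names(x$aux), "subject"))
      out[[nm]] <- x$aux[[nm]][match(out$subject, x$aux$subject)]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
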