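#' Encode QoL-AD response labels as ordinal levels
#'
#' The QoL-AD rates each of its 13 items on a four-point scale: poor, fair,
#' good, excellent, scored 1 to 4. This helper accepts the verbal labels
#' (case-insensitively), integers 1--4, or strings of those integers, and
#' returns integer levels. Anything else is an error naming the offending
#' value; use `quiet_na = TRUE` to convert unrecognised values to `NA`
#' (counting them) instead, as the CSV reader does.
#'
#' @param x character, factor or numeric vector of responses.
#' @param quiet_na if `TRUE`, unrecognised values become `NA` with an
#'   attribute `n_unparseable` on the result instead of an error.
#' @return integer vector of levels in 1--4 (with `NA` where input was `NA`).
#' @examples
#' encode_qolad_response(c("Fair", "poor", "EXCELLENT"))
#' encode_qolad_response(c(1, 4))
#' @export
encode_qolad_response <- function(x, quiet_na = FALSE) {
  if (is.factor(x)) x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  if (is.numeric(x)) {
    ok <- !is.na(x) & x %in% 1:4
    out[ok] <- as.integer(x[ok])
    bad <- !is.na(x) & !ok
  } else {
    x_chr <- trimws(tolower(as.character(x)))
    x_chr[x_chr == ""] <- NA_character_
    lab <- match(x_chr, QOLAD_LABELS)
    num <- suppressWarnings(as.numeric(x_chr))
    num[!num %in% 1:4] <- NA
    out <- as.integer(ifelse(!is.na(lab), lab, num))
    bad <- !is.na(x_chr) & is.na(out)
  }
  if (any(bad)) {
    if (!quiet_na) {
      abort(sprintf(
        "Unrecognised QoL-AD response value(s): %s. Expected poor/fair/good/excellent or 1-4.",
        paste(unique(utils::head(x[bad], 5)), collapse = ", ")
      ), class = "qoladmap_encoding_error")
    }
    out[bad] <- NA_integer_
  }
  attr(out, "n_unparseable") <- sum(bad)
  out
}

#' Score the QoL-AD composite
#'
#' Sums the 13 item responses into the composite score (range 13--52; higher is
#' better quality of life). Item 7 asks about the respondent's marriage and is
#' frequently unavailable, so the conventional usage -- and the default here --
#' drops it and standardises the 12-item sum back onto the 13-item range:
#'
#' \deqn{score = 13 + (sum_{12} - 12) \times 39/36}
#'
#' the unique affine map sending the 12-item extremes (12, 48) to the 13-item
#' extremes (13, 52). Full precision is kept; round only for display.
#'
#' @param data a data frame holding one QoL-AD item per column, or `NULL` when
#'   `items` is given directly.
#' @param items either a tidy-select vector of 13 column names in item order
#'   (defaults to `qolad_1` ... `qolad_13` or, when absent, the rater-suffixed
#'   names `qolad_<rater>_1` ...), or -- when `data` is `NULL` -- a numeric
#'   vector/matrix of 13 item responses.
#' @param rater which rater's items to score when columns are rater-suffixed.
#' @param include_item7 keep item 7 and return the raw 13-item sum (13--52
#'   integers) instead of the standardised 12-item score.
#' @return for data-frame input, the input tibble with a `qolad_score` column
#'   appended; for vector/matrix input, a numeric vector of scores.
#' @examples
#' # participant with items (1-6, 8-13) = 2,2,3,1,1,1,3,2,1,2,3,2 (sum 23)
#' x <- c(2, 2, 3, 1, 1, 1, NA, 3, 2, 1, 2, 3, 2)
#' score_qolad(items = x)              # 24.9166...
#' round(score_qolad(items = x), 1)    # 24.9
#' @export
score_qolad <- function(data = NULL, items = NULL, rater = c("self", "proxy"),
                        include_item7 = FALSE) {
  rater <- match.arg(rater)
  if (is.null(data)) {
    m <- if (is.matrix(items)) items else matrix(items, nrow = 1)
    if (ncol(m) != 13) {
      abort("`items` must supply exactly 13 item slots (item 7 may be NA).",
            class = "qoladmap_items_error")
    }
    return(qolad_composite(m, include_item7 = include_item7))
  }
  cols <- qolad_item_columns(data, rater)
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  dplyr::mutate(tibble::as_tibble(data),
                qolad_score = qolad_composite(m, include_item7 = include_item7))
}

# items: n x 13 matrix of levels in 1..4 (NA allowed only where excluded)
qolad_composite <- function(items, include_item7 = FALSE) {
  stopifnot(ncol(items) == 13)
  used <- if (include_item7) 1:13 else setdiff(1:13, 7)
  sub <- items[, used, drop = FALSE]
  bad_values <- !is.na(sub) & !(sub %in% 1:4)
  if (any(bad_values)) {
    abort("QoL-AD item responses must be in 1-4.", class = "qoladmap_items_error")
  }
  missing_rows <- rowSums(is.na(sub)) > 0
  if (any(missing_rows)) {
    miss <- which(is.na(sub[which(missing_rows)[1], ]))
    abort(sprintf(
      "Missing QoL-AD item(s) %s required for scoring (include_item7 = %s); %d row(s) affected.",
      paste(used[miss], collapse = ", "), include_item7, sum(missing_rows)
    ), class = "qoladmap_missing_error")
  }
  raw <- rowSums(sub)
  if (include_item7) raw else 13 + (raw - 12) * 39 / 36
}

# Locate item columns `qolad_1..13` or `qolad_<rater>_1..13`; error if absent.
qolad_item_columns <- function(data, rater, required = TRUE) {
  plain <- paste0("qolad_", 1:13)
  suff <- paste0("qolad_", rater, "_", 1:13)
  if (all(plain %in% names(data))) return(plain)
  if (all(suff %in% names(data))) return(suff)
  if (!required) return(NULL)
  abort(sprintf(
    "Expected QoL-AD item columns %s... or %s... in `data`.",
    plain[1], suff[1]
  ), class = "qoladmap_format_error")
}
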