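#' Read a paired QoL-AD / EQ-5D dataset from CSV
#'
#' Reads one observation (a subject at a visit) per row. Recognised columns:
#'
#' * `subject_id` (required), `visit`, `age`, `sex` (`female`/`male`);
#' * `qolad_self_1` ... `qolad_self_13` and/or `qolad_proxy_1` ...
#'   `qolad_proxy_13` (or unsuffixed `qolad_1` ..., treated as self-rated):
#'   levels 1--4 or the labels poor/fair/good/excellent;
#' * `eq5d5l_self_mo`, `_sc`, `_ua`, `_pd`, `_ad` and the `proxy` variants
#'   (levels 1--5); `eq5d3l_self_mo` ... (levels 1--3);
#' * `utility_self`, `utility_proxy` (optional; computed from the EQ-5D
#'   states when absent -- 5L states through the crosswalk, 3L states
#'   through the tariff).
#'
#' Unparseable ordinal cells become missing; counts are logged per column in
#' the `parse_log` attribute and summarised in a message. Missing values are
#' written as empty cells by [write_qolad_dataset()].
#'
#' @param path CSV file path.
#' @param crosswalk crosswalk used to value 5L states; defaults to the
#'   package's synthetic crosswalk (see [synthetic_crosswalk()]).
#' @param tariff tariff used to value 3L states.
#' @return a tibble, one row per observation, with a `parse_log` attribute.
#' @export
read_qolad_dataset <- function(path, crosswalk = default_crosswalk(),
                               tariff = uk_tariff_3l()) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"))
  if (!"subject_id" %in% names(df)) {
    abort("Column `subject_id` is mandatory.", class = "qoladmap_format_error")
  }
  names(df)[names(df) %in% paste0("qolad_", 1:13)] <-
    sub("^qolad_", "qolad_self_", names(df)[names(df) %in% paste0("qolad_", 1:13)])
  has_rater <- function(r) {
    all(paste0("qolad_", r, "_", setdiff(1:13, 7)) %in% names(df))
  }
  if (!has_rater("self") && !has_rater("proxy")) {
    abort(paste0("Need the 12 non-item-7 QoL-AD item columns for at least one ",
                 "rater (qolad_self_* or qolad_proxy_*)."),
          class = "qoladmap_format_error")
  }

  log <- list()
  out <- tibble::as_tibble(df)
  out$subject_id <- as.character(out$subject_id)
  if ("visit" %in% names(out)) out$visit <- parse_num(out$visit)
  if ("age" %in% names(out)) {
    out$age <- parse_num(out$age)
    if (any(!is.na(out$age) & out$age <= 0)) {
      abort("`age` must be positive.", class = "qoladmap_format_error")
    }
  }
  if ("sex" %in% names(out)) {
    s <- trimws(tolower(out$sex))
    bad <- !is.na(s) & !s %in% c("female", "male")
    if (any(bad)) log[["sex"]] <- sum(bad)
    s[bad] <- NA
    out$sex <- s
  }
  for (col in grep("^qolad_(self|proxy)_\\d+$", names(out), value = TRUE)) {
    enc <- encode_qolad_response(out[[col]], quiet_na = TRUE)
    if (attr(enc, "n_unparseable") > 0) log[[col]] <- attr(enc, "n_unparseable")
    out[[col]] <- as.integer(enc)
  }
  for (col in grep("^eq5d(5|3)l_(self|proxy)_(mo|sc|ua|pd|ad)$", names(out),
                   value = TRUE)) {
    lim <- if (grepl("^eq5d5l", col)) 5L else 3L
    v <- parse_num(out[[col]])
    bad <- !is.na(v) & (!v %in% seq_len(lim))
    if (any(bad) || sum(is.na(v) & !is.na(out[[col]])) > 0) {
      log[[col]] <- sum(bad) + sum(is.na(v) & !is.na(out[[col]]))
    }
    v[bad] <- NA
    out[[col]] <- as.integer(v)
  }
  for (col in intersect(c("utility_self", "utility_proxy"), names(out))) {
    out[[col]] <- parse_num(out[[col]])
    if (any(out[[col]] > 1 + 1e-9, na.rm = TRUE)) {
      abort(sprintf("`%s` contains values above the utility ceiling of 1.", col),
            class = "qoladmap_format_error")
    }
  }
  out <- fill_utilities(out, crosswalk, tariff)
  n_bad <- sum(unlist(log))
  if (n_bad > 0) {
    inform(sprintf("read_qolad_dataset: %d unparseable ordinal cell(s) set to missing (%s).",
                   n_bad, paste(names(log), unlist(log), sep = "=", collapse = ", ")))
  }
  attr(out, "parse_log") <-
    tibble::tibble(column = names(log) %||% character(),
                   n_unparseable = as.integer(unlist(log)) %||% integer())
  out
}

# derive utility_self / utility_proxy from states where absent
fill_utilities <- function(out, crosswalk, tariff) {
  for (r in c("self", "proxy")) {
    ucol <- paste0("utility_", r)
    c5 <- paste0("eq5d5l_", r, "_", EQ5D_DIMS)
    c3 <- paste0("eq5d3l_", r, "_", EQ5D_DIMS)
    have_u <- if (ucol %in% names(out)) !is.na(out[[ucol]]) else rep(FALSE, nrow(out))
    u <- if (ucol %in% names(out)) out[[ucol]] else rep(NA_real_, nrow(out))
    if (all(c5 %in% names(out))) {
      m <- as.matrix(out[c5])
      ok <- !have_u & rowSums(is.na(m)) == 0
      if (any(ok)) u[ok] <- crosswalk_utility(m[ok, , drop = FALSE], crosswalk)
      have_u <- have_u | ok
    }
    if (all(c3 %in% names(out))) {
      m <- as.matrix(out[c3])
      ok <- !have_u & rowSums(is.na(m)) == 0
      if (any(ok)) u[ok] <- utility_3l(m[ok, , drop = FALSE], tariff)
    }
    if (any(!is.na(u))) out[[ucol]] <- u
  }
  out
}

#' @rdname read_qolad_dataset
#' @param data tibble in the layout produced by [read_qolad_dataset()] or
#'   [simulate_qolad_eq5d()].
#' @export
write_qolad_dataset <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

# synthetic crosswalk, built once per session
crosswalk_cache <- new.env(parent = emptyenv())

#' @rdname read_qolad_dataset
#' @export
default_crosswalk <- function() {
  if (is.null(crosswalk_cache$cw)) {
    crosswalk_cache$cw <- synthetic_crosswalk()
  }
  crosswalk_cache$cw
}
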