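#' EQ-5D-3L tariffs and the 5L-to-3L crosswalk
#'
#' An EQ-5D-3L value set (tariff) attaches a societal utility to each of the
#' 243 three-level health states by an additive decrement scheme: utility
#' starts at 1 for full health (state 11111), subtracts a constant for any
#' dysfunction, a per-dimension decrement for each level-2 or level-3
#' response, and a further constant if any dimension is at level 3. A
#' crosswalk maps each of the 3125 five-level states to a 3L-valued utility,
#' so 5L data can be valued with a 3L tariff.
#'
#' `eq5d_tariff()` builds a tariff object; `uk_tariff_3l()` returns the
#' published UK (Dolan) tariff, under which the worst state 33333 values
#' -0.594. `load_value_set()` / `load_crosswalk()` read the CSV formats
#' documented below and validate them.
#'
#' @section Tariff CSV format:
#' Columns `term,dimension,level,decrement`. Rows with `term = "constant"`
#' and `term = "level3_anywhere"` leave `dimension`/`level` blank; decrement
#' rows have `term = "decrement"`, `dimension` in `mo,sc,ua,pd,ad` and
#' `level` 2 or 3. Decrements are the positive amounts subtracted.
#'
#' @section Crosswalk CSV format:
#' Columns `state,utility`: exactly 3125 rows, `state` the 5-character
#' string of levels in dimension order mobility, self-care, usual
#' activities, pain/discomfort, anxiety/depression.
#'
#' @param constant decrement applied once if any dimension is above level 1.
#' @param decrements 5x2 numeric matrix (rows `mo,sc,ua,pd,ad`, columns
#'   level 2 and 3) of per-dimension decrements, all non-negative.
#' @param level3_anywhere decrement applied once if any dimension is at 3.
#' @param label free-text label carried through outputs.
#' @return an object of class `eq5d_tariff`.
#' @examples
#' uk_tariff_3l()
#' utility_3l(c(1, 1, 1, 1, 1), uk_tariff_3l())
#' @name value_sets
NULL

#' @rdname value_sets
#' @importFrom tools file_path_sans_ext
#' @export
eq5d_tariff <- function(constant, decrements, level3_anywhere, label = "custom") {
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5, 2))) {
    abort("`decrements` must be a 5 x 2 matrix (dimensions x levels 2:3).",
          class = "qoladmap_tariff_error")
  }
  dimnames(decrements) <- list(EQ5D_DIMS, c("2", "3"))
  vals <- c(constant, decrements, level3_anywhere)
  if (anyNA(vals) || any(vals < 0)) {
    abort("All tariff decrements must be non-negative and non-missing.",
          class = "qoladmap_tariff_error")
  }
  structure(
    list(constant = constant, decrements = decrements,
         level3_anywhere = level3_anywhere, label = label),
    class = "eq5d_tariff"
  )
}

#' @rdname value_sets
#' @export
uk_tariff_3l <- function() {
  eq5d_tariff(
    constant = 0.081,
    decrements = rbind(
      mo = c(0.069, 0.314),
      sc = c(0.104, 0.214),
      ua = c(0.036, 0.094),
      pd = c(0.123, 0.386),
      ad = c(0.071, 0.236)
    ),
    level3_anywhere = 0.269,
    label = "UK-Dolan"
  )
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("<eq5d_tariff>", x$label, "\n")
  cat("  constant:", x$constant, " level-3 anywhere:", x$level3_anywhere, "\n")
  print(round(x$decrements, 4))
  invisible(x)
}

#' Evaluate an EQ-5D-3L tariff on health states
#'
#' @param states a length-5 vector of levels in 1--3, an n x 5 matrix, or a
#'   data frame with columns in dimension order.
#' @param tariff an [eq5d_tariff] object.
#' @return numeric utility vector, one per state; full health is exactly 1.
#' @examples
#' utility_3l(c(3, 3, 3, 3, 3), uk_tariff_3l())  # -0.594
#' @export
utility_3l <- function(states, tariff = uk_tariff_3l()) {
  m <- as_state_matrix(states, n_levels = 3)
  any_dys <- rowSums(m > 1) > 0
  any_l3 <- rowSums(m == 3) > 0
  dec <- numeric(nrow(m))
  for (d in 1:5) {
    dec <- dec +
      (m[, d] == 2) * tariff$decrements[d, "2"] +
      (m[, d] == 3) * tariff$decrements[d, "3"]
  }
  1 - tariff$constant * any_dys - dec - tariff$level3_anywhere * any_l3
}

#' Crosswalk utilities for EQ-5D-5L states
#'
#' Looks up the utility of each 5L health state in a validated crosswalk
#' table. `synthetic_crosswalk()` constructs a complete 3125-state table by
#' splitting each 5L level over adjacent 3L levels (1 -> 3L level 1;
#' 2 -> half 1, half 2; 3 -> level 2; 4 -> half 2, half 3; 5 -> level 3)
#' and taking the exact expected tariff value over the five independent
#' dimensions. It is a synthetic stand-in with the qualitative properties of
#' a published crosswalk (full health maps to 1, monotone, worst state at the
#' tariff minimum), not the published table itself.
#'
#' @param states a length-5 vector of levels in 1--5, an n x 5 matrix, or a
#'   data frame in dimension order.
#' @param crosswalk an `eq5d_crosswalk` object from [load_crosswalk()] or
#'   [synthetic_crosswalk()].
#' @return numeric utility vector, one per state.
#' @examples
#' cw <- synthetic_crosswalk()
#' crosswalk_utility(c(1, 1, 1, 1, 1), cw)  # 1
#' @export
crosswalk_utility <- function(states, crosswalk) {
  check_crosswalk(crosswalk)
  m <- as_state_matrix(states, n_levels = 5)
  crosswalk$utilities[state_index(m)]
}

#' @rdname crosswalk_utility
#' @param tariff tariff used to value the implied 3L states.
#' @param label label stored on the crosswalk object.
#' @export
synthetic_crosswalk <- function(tariff = uk_tariff_3l(),
                                label = "synthetic-5L3L") {
  # P[l5, l3]: probability a 5L level l5 is read as 3L level l3
  P <- rbind(
    c(1, 0, 0),
    c(0.5, 0.5, 0),
    c(0, 1, 0),
    c(0, 0.5, 0.5),
    c(0, 0, 1)
  )
  states3 <- as.matrix(expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3))
  states3 <- states3[, 5:1, drop = FALSE]
  u3 <- utility_3l(states3, tariff)
  states5 <- all_5l_states()
  u5 <- numeric(nrow(states5))
  # weight of each 3L state under each 5L state: product over dimensions
  for (s in seq_len(nrow(states5))) {
    w <- rep(1, nrow(states3))
    for (d in 1:5) w <- w * P[states5[s, d], states3[, d]]
    u5[s] <- sum(w * u3)
  }
  new_crosswalk(u5, label = label)
}

# all 3125 5L states in lexicographic order, first dimension slowest,
# matching state_index()
all_5l_states <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5)
  m <- as.matrix(g[, 5:1, drop = FALSE])
  colnames(m) <- EQ5D_DIMS
  m
}

state_index <- function(m) {
  (m[, 1] - 1) * 625 + (m[, 2] - 1) * 125 + (m[, 3] - 1) * 25 +
    (m[, 4] - 1) * 5 + m[, 5]
}

state_string <- function(m) {
  apply(m, 1, paste0, collapse = "")
}

new_crosswalk <- function(utilities, label) {
  if (length(utilities) != 3125 || anyNA(utilities)) {
    abort("A crosswalk must provide exactly 3125 non-missing utilities.",
          class = "qoladmap_crosswalk_error")
  }
  if (any(utilities > 1 + 1e-12)) {
    abort("Crosswalk utilities must not exceed 1.",
          class = "qoladmap_crosswalk_error")
  }
  structure(
    list(utilities = as.numeric(utilities),
         states = state_string(all_5l_states()),
         label = label),
    class = "eq5d_crosswalk"
  )
}

check_crosswalk <- function(crosswalk) {
  if (!inherits(crosswalk, "eq5d_crosswalk")) {
    abort("`crosswalk` must be an eq5d_crosswalk object (see load_crosswalk()).",
          class = "qoladmap_crosswalk_error")
  }
  invisible(crosswalk)
}

#' @export
print.eq5d_crosswalk <- function(x, ...) {
  cat("<eq5d_crosswalk>", x$label, "\n")
  cat(sprintf("  3125 states; utility range [%.4f, %g]\n",
              min(x$utilities), max(x$utilities)))
  invisible(x)
}

#' Read value-set and crosswalk files
#'
#' @param path path to a CSV file in the formats documented at [value_sets].
#' @return `load_value_set()` an [eq5d_tariff]; `load_crosswalk()` an
#'   `eq5d_crosswalk`.
#' @export
load_value_set <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("term", "dimension", "level", "decrement")
  if (!all(need %in% names(df))) {
    abort(sprintf("Value-set file must have columns %s.", paste(need, collapse = ", ")),
          class = "qoladmap_tariff_error")
  }
  dec_num <- suppressWarnings(as.numeric(df$decrement))
  if (anyNA(dec_num)) {
    abort(sprintf("Non-numeric decrement in value-set row(s): %s",
                  paste(which(is.na(dec_num)), collapse = ", ")),
          class = "qoladmap_tariff_error")
  }
  constant <- dec_num[df$term == "constant"]
  n3 <- dec_num[df$term == "level3_anywhere"]
  if (length(constant) != 1 || length(n3) != 1) {
    abort("Value-set file needs exactly one 'constant' and one 'level3_anywhere' row.",
          class = "qoladmap_tariff_error")
  }
  dec <- matrix(NA_real_, 5, 2, dimnames = list(EQ5D_DIMS, c("2", "3")))
  rows <- which(df$term == "decrement")
  for (i in rows) {
    d <- df$dimension[i]; l <- df$level[i]
    if (!d %in% EQ5D_DIMS || !l %in% c("2", "3")) {
      abort(sprintf("Invalid decrement row %d: dimension '%s', level '%s'.", i, d, l),
            class = "qoladmap_tariff_error")
    }
    dec[d, l] <- dec_num[i]
  }
  if (anyNA(dec)) {
    abort("Value-set file must give a decrement for every dimension at levels 2 and 3.",
          class = "qoladmap_tariff_error")
  }
  lab <- attr(df, "label") %||% tools::file_path_sans_ext(basename(path))
  eq5d_tariff(constant, dec, n3, label = lab)
}

#' @rdname load_value_set
#' @export
load_crosswalk <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("state", "utility") %in% names(df))) {
    abort("Crosswalk file must have columns state,utility.",
          class = "qoladmap_crosswalk_error")
  }
  if (nrow(df) != 3125) {
    abort(sprintf("Crosswalk file must have 3125 rows (one per 5L state); found %d.",
                  nrow(df)), class = "qoladmap_crosswalk_error")
  }
  if (anyDuplicated(df$state)) {
    abort(sprintf("Duplicate crosswalk state(s): %s",
                  paste(unique(df$state[duplicated(df$state)]), collapse = ", ")),
          class = "qoladmap_crosswalk_error")
  }
  ok <- grepl("^[1-5]{5}$", df$state)
  if (!all(ok)) {
    abort(sprintf("Malformed crosswalk state(s) in row(s): %s",
                  paste(which(!ok), collapse = ", ")),
          class = "qoladmap_crosswalk_error")
  }
  u <- suppressWarnings(as.numeric(df$utility))
  if (anyNA(u)) {
    abort(sprintf("Non-numeric crosswalk utility in row(s): %s",
                  paste(which(is.na(u)), collapse = ", ")),
          class = "qoladmap_crosswalk_error")
  }
  idx <- match(state_string(all_5l_states()), df$state)
  if (anyNA(idx)) {
    abort("Crosswalk file does not cover all 3125 states.",
          class = "qoladmap_crosswalk_error")
  }
  new_crosswalk(u[idx], label = tools::file_path_sans_ext(basename(path)))
}

#' Write a crosswalk table to CSV
#'
#' @param crosswalk an `eq5d_crosswalk`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(crosswalk, path) {
  check_crosswalk(crosswalk)
  readr::write_csv(
    tibble::tibble(state = crosswalk$states,
                   utility = sprintf("%.17g", crosswalk$utilities)),
    path
  )
  invisible(path)
}

# coerce states to integer matrix and validate levels
as_state_matrix <- function(states, n_levels) {
  if (is.data.frame(states)) states <- as.matrix(states)
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  if (ncol(states) != 5) {
    abort("A health state has exactly 5 dimensions.", class = "qoladmap_state_error")
  }
  storage.mode(states) <- "integer"
  if (anyNA(states) || any(states < 1 | states > n_levels)) {
    abort(sprintf("All levels must be present and in 1-%d.", n_levels),
          class = "qoladmap_state_error")
  }
  states
}
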