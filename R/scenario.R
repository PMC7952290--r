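#' Assemble an estimation table for one mapping scenario
#'
#' A mapping scenario pairs a predictor rater (whose QoL-AD items feed the
#' model) with a target rater (whose EQ-5D utility is predicted), and fixes
#' whether item 7 and the age/sex covariates are used. Following the
#' complete-case rule, only observations with non-missing data for all
#' relevant QoL-AD items, the target EQ-5D items (when item columns are
#' present) or utility, and -- when requested -- age and sex, are retained.
#'
#' @param data tibble from [read_qolad_dataset()] or [simulate_qolad_eq5d()].
#' @param predictor_rater,target_rater `"self"` or `"proxy"`.
#' @param include_item7 include QoL-AD item 7 among predictors (stricter
#'   complete-case filter; the 13-item raw composite is then used).
#' @param include_age_sex include age and sex as covariates.
#' @return a tibble of class `qolad_scenario` with columns `subject_id`,
#'   `visit`, `age`, `sex`, `item_1` ... `item_13` (predictor rater's
#'   responses; `item_7` may be `NA` when excluded), `qolad_score`,
#'   the target rater's EQ-5D-5L items `eq_mo` ... `eq_ad` when available,
#'   and `utility`. Attributes `scenario` (the settings), `n_included` and
#'   `n_excluded` record the filter; a message reports the counts.
#' @export
assemble_scenario <- function(data,
                              predictor_rater = c("self", "proxy"),
                              target_rater = NULL,
                              include_item7 = FALSE,
                              include_age_sex = TRUE) {
  predictor_rater <- match.arg(predictor_rater)
  target_rater <- if (is.null(target_rater)) predictor_rater
                  else match.arg(target_rater, c("self", "proxy"))
  if (nrow(data) == 0) {
    abort("`data` is empty.", class = "qoladmap_empty_scenario_error")
  }

  icols <- paste0("qolad_", predictor_rater, "_", 1:13)
  if (all(paste0("qolad_", 1:13) %in% names(data)) && !all(icols %in% names(data))) {
    icols <- paste0("qolad_", 1:13)
  }
  need_items <- icols[if (include_item7) 1:13 else setdiff(1:13, 7)]
  if (!all(need_items %in% names(data))) {
    abort(sprintf("Missing QoL-AD item columns for rater '%s'.", predictor_rater),
          class = "qoladmap_format_error")
  }
  ucol <- paste0("utility_", target_rater)
  eqcols <- paste0("eq5d5l_", target_rater, "_", EQ5D_DIMS)
  have_eq <- all(eqcols %in% names(data))
  if (!ucol %in% names(data) && !have_eq) {
    abort(sprintf("No target utility: need column `%s` or the 5L state columns for rater '%s'.",
                  ucol, target_rater), class = "qoladmap_format_error")
  }

  keep <- rep(TRUE, nrow(data))
  for (col in need_items) keep <- keep & !is.na(data[[col]])
  if (have_eq) for (col in eqcols) keep <- keep & !is.na(data[[col]])
  if (ucol %in% names(data)) keep <- keep & !is.na(data[[ucol]])
  if (include_age_sex) {
    for (col in c("age", "sex")) {
      if (!col %in% names(data)) {
        abort(sprintf("`include_age_sex = TRUE` but column `%s` is absent.", col),
              class = "qoladmap_format_error")
      }
      keep <- keep & !is.na(data[[col]])
    }
  }
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    abort("Zero complete cases under this scenario.",
          class = "qoladmap_empty_scenario_error")
  }
  sub <- data[keep, , drop = FALSE]

  out <- tibble::tibble(
    subject_id = as.character(sub$subject_id),
    visit = if ("visit" %in% names(sub)) sub$visit else NA_real_,
    age = if ("age" %in% names(sub)) sub$age else NA_real_,
    sex = if ("sex" %in% names(sub)) sub$sex else NA_character_
  )
  for (j in 1:13) {
    col <- icols[j]
    out[[paste0("item_", j)]] <-
      if (col %in% names(sub)) as.integer(sub[[col]]) else NA_integer_
  }
  items <- as.matrix(out[paste0("item_", 1:13)])
  out$qolad_score <- qolad_composite(items, include_item7 = include_item7)
  if (have_eq) {
    for (d in EQ5D_DIMS) out[[paste0("eq_", d)]] <-
      as.integer(sub[[paste0("eq5d5l_", target_rater, "_", d)]])
  }
  out$utility <- sub[[ucol]]

  scenario <- list(predictor_rater = predictor_rater, target_rater = target_rater,
                   include_item7 = include_item7, include_age_sex = include_age_sex)
  inform(sprintf("Scenario %s->%s: %d observations included, %d excluded (complete cases).",
                 predictor_rater, target_rater, nrow(out), n_excluded))
  structure(out, scenario = scenario, n_included = nrow(out),
            n_excluded = n_excluded,
            class = c("qolad_scenario", class(out)))
}

scenario_of <- function(table) {
  attr(table, "scenario") %||%
    list(predictor_rater = "self", target_rater = "self",
         include_item7 = FALSE, include_age_sex = all(c("age", "sex") %in% names(table)) &&
           !anyNA(table$age) && !anyNA(table$sex))
}

# ---- covariate specification and design matrices -------------------------

# predictors: "items" (categorical indicators, reference level 1),
# "items_continuous" (items as 1-4 scores), "score" (composite only).
make_covariate_spec <- function(table, predictors, include_age_sex,
                                include_item7 = scenario_of(table)$include_item7) {
  items_used <- if (include_item7) 1:13 else setdiff(1:13, 7)
  item_levels <- NULL
  if (predictors == "items") {
    item_levels <- lapply(items_used, function(j) {
      obs <- sort(unique(table[[paste0("item_", j)]]))
      sort(intersect(2:4, obs))
    })
    names(item_levels) <- paste0("item_", items_used)
    dropped <- purrr::imap_chr(item_levels, function(lv, nm) {
      miss <- setdiff(2:4, lv)
      if (length(miss)) sprintf("%s level %s", nm, paste(miss, collapse = "/")) else NA_character_
    })
    dropped <- dropped[!is.na(dropped)]
    if (length(dropped)) {
      warn(sprintf("Unobserved factor levels dropped from the design: %s.",
                   paste(dropped, collapse = "; ")))
    }
  }
  structure(
    list(predictors = predictors, items = items_used, item_levels = item_levels,
         include_age_sex = include_age_sex, include_item7 = include_item7),
    class = "qolad_covariate_spec"
  )
}

spec_terms <- function(spec) {
  terms <- "(Intercept)"
  if (spec$predictors == "items") {
    for (nm in names(spec$item_levels)) {
      terms <- c(terms, paste0(nm, "_l", spec$item_levels[[nm]]))
    }
  } else if (spec$predictors == "items_continuous") {
    terms <- c(terms, paste0("item_", spec$items))
  } else {
    terms <- c(terms, "qolad_score")
  }
  if (spec$include_age_sex) terms <- c(terms, "age", "sex_male")
  terms
}

# Build the model matrix for `data` under `spec`. With strict = TRUE (the
# prediction path) a level absent from the fitted design raises an error
# rather than silently collapsing to the reference.
build_design <- function(spec, data, strict = FALSE) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  if (spec$predictors %in% c("items", "items_continuous")) {
    for (j in spec$items) {
      nm <- paste0("item_", j)
      v <- data[[nm]]
      if (is.null(v)) abort(sprintf("Column `%s` is required.", nm),
                            class = "qoladmap_prediction_error")
      if (anyNA(v)) abort(sprintf("Missing values in `%s`.", nm),
                          class = "qoladmap_prediction_error")
      if (any(!v %in% 1:4)) abort(sprintf("`%s` must be in 1-4.", nm),
                                  class = "qoladmap_items_error")
      if (spec$predictors == "items") {
        allowed <- c(1L, spec$item_levels[[nm]])
        if (strict && any(!v %in% allowed)) {
          abort(sprintf(
            "Level(s) %s of `%s` were not observed when the model was fitted.",
            paste(setdiff(unique(v), allowed), collapse = ", "), nm),
            class = "qoladmap_prediction_error")
        }
        for (l in spec$item_levels[[nm]]) {
          cols[[paste0(nm, "_l", l)]] <- as.numeric(v == l)
        }
      } else {
        cols[[nm]] <- as.numeric(v)
      }
    }
  } else {
    sc <- data[["qolad_score"]]
    if (is.null(sc)) {
      items <- as.matrix(data[paste0("item_", 1:13)])
      sc <- qolad_composite(items, include_item7 = spec$include_item7)
    }
    if (anyNA(sc)) abort("Missing composite score.", class = "qoladmap_prediction_error")
    cols[["qolad_score"]] <- as.numeric(sc)
  }
  if (spec$include_age_sex) {
    age <- data[["age"]]; sex <- data[["sex"]]
    if (is.null(age) || is.null(sex) || anyNA(age) || anyNA(sex)) {
      abort("Missing `age`/`sex` required by this model.",
            class = "qoladmap_prediction_error")
    }
    sex <- trimws(tolower(as.character(sex)))
    if (any(!sex %in% c("female", "male"))) {
      abort("`sex` must be 'female' or 'male'.", class = "qoladmap_prediction_error")
    }
    cols[["age"]] <- as.numeric(age)
    cols[["sex_male"]] <- as.numeric(sex == "male")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# serialize / restore specs for the JSON model documents
spec_to_list <- function(spec) {
  list(predictors = spec$predictors, items = spec$items,
       item_levels = spec$item_levels, include_age_sex = spec$include_age_sex,
       include_item7 = spec$include_item7)
}

spec_from_list <- function(x) {
  il <- x$item_levels
  if (!is.null(il)) il <- lapply(il, as.integer)
  structure(
    list(predictors = x$predictors, items = as.integer(unlist(x$items)),
         item_levels = il,
         include_age_sex = isTRUE(x$include_age_sex),
         include_item7 = isTRUE(x$include_item7)),
    class = "qolad_covariate_spec"
  )
}
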