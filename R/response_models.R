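#' Response mapping: per-item EQ-5D-5L models combined through the crosswalk
#'
#' Response mapping fits one model per EQ-5D-5L dimension (mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression),
#' predicting the five-level response from the QoL-AD predictors, then turns
#' the five predicted level distributions into a utility. Families:
#'
#' * `mlogit` -- multinomial logit, one coefficient vector per non-reference
#'   level (reference is level 1 when observed);
#' * `ologit` -- proportional-odds ordinal logit with four ordered cutpoints;
#' * `ols_categorical` / `ols_continuous` -- least squares on the level
#'   treated as a 1--5 score, with items entering as indicator contrasts or
#'   as continuous 1--4 scores respectively; predictions are rounded to the
#'   nearest level (halves toward the worse level) and give a degenerate
#'   one-level distribution.
#'
#' Levels never observed in the estimation data receive structural-zero
#' probability, with a note logged on the fitted object. Estimation caps at
#' 200 iterations; on the cap the last iterate is kept with a warning.
#'
#' @param table a `qolad_scenario` table containing the target rater's
#'   EQ-5D-5L item columns `eq_mo` ... `eq_ad`.
#' @param family one of `"mlogit"`, `"ologit"`, `"ols_categorical"`,
#'   `"ols_continuous"`.
#' @param ridge optional non-negative ridge (weight-decay) penalty applied to
#'   the mlogit coefficients, a guard against perfect-prediction cells when
#'   the algorithm will be applied to populations unlike the estimation
#'   data. Default 0 (no penalty).
#' @param include_age_sex override the scenario's age/sex setting.
#' @return an object of class `qolad_response_fit` holding five item models.
#' @examples
#' sim <- simulate_qolad_eq5d(sim_config(n_subjects = 150, seed = 1))
#' sc <- assemble_scenario(sim, "self", "self")
#' fit <- fit_response_mapper(sc, "mlogit")
#' head(predict(fit, sc))
#' @export
fit_response_mapper <- function(table,
                                family = c("mlogit", "ologit",
                                           "ols_categorical", "ols_continuous"),
                                ridge = 0, include_age_sex = NULL) {
  family <- match.arg(family)
  scen <- scenario_of(table)
  include_age_sex <- include_age_sex %||% scen$include_age_sex
  eqcols <- paste0("eq_", EQ5D_DIMS)
  if (!all(eqcols %in% names(table))) {
    abort("Response mapping needs the EQ-5D-5L item columns eq_mo ... eq_ad.",
          class = "qoladmap_format_error")
  }
  predictors <- if (family == "ols_continuous") "items_continuous" else "items"
  spec <- make_covariate_spec(table, predictors, include_age_sex)
  X <- build_design(spec, table)
  items <- purrr::map(EQ5D_DIMS, function(d) {
    y <- table[[paste0("eq_", d)]]
    tryCatch(
      fit_item_model(y, X, family = family, dimension = d, ridge = ridge),
      qoladmap_degenerate_error = function(e) {
        abort(sprintf("Dimension '%s' (%s): %s", d, EQ5D_DIM_LABELS[[d]],
                      conditionMessage(e)),
              class = "qoladmap_degenerate_error")
      }
    )
  })
  names(items) <- EQ5D_DIMS
  structure(
    list(family = family, spec = spec, scenario = scen, items = items,
         ridge = ridge, n = nrow(X),
         convergence = list(
           converged = all(purrr::map_lgl(items, ~ .x$convergence$converged)),
           iterations = max(purrr::map_int(items, ~ .x$convergence$iterations)))),
    class = "qolad_response_fit"
  )
}

#' Fit a single EQ-5D item model
#'
#' Lower-level interface used by [fit_response_mapper()]; useful with a
#' custom design matrix. Coefficients are stored explicitly so predictions
#' are computed by the package (softmax, cumulative-logistic differences,
#' rounding) independent of the estimation backend.
#'
#' @param y integer responses in 1--5.
#' @param X design matrix whose first column is the intercept.
#' @param dimension label for the dimension being modelled.
#' @inheritParams fit_response_mapper
#' @return an object of class `qolad_item_model`.
#' @export
fit_item_model <- function(y, X, family = c("mlogit", "ologit",
                                            "ols_categorical", "ols_continuous"),
                           dimension = "item", ridge = 0) {
  family <- match.arg(family)
  if (anyNA(y) || any(!y %in% 1:5)) {
    abort("Item responses must be non-missing and in 1-5.",
          class = "qoladmap_format_error")
  }
  observed <- sort(unique(y))
  if (length(observed) < 2) {
    abort(sprintf("only one observed response level (%d).", observed),
          class = "qoladmap_degenerate_error")
  }
  structural_zero <- setdiff(1:5, observed)
  terms <- colnames(X)
  fit <- switch(family,
    mlogit = fit_item_mlogit(y, X, observed, ridge),
    ologit = fit_item_ologit(y, X, observed),
    fit_item_ols(y, X)
  )
  if (length(structural_zero)) {
    inform(sprintf("Dimension '%s': level(s) %s never observed; structural-zero probability assigned.",
                   dimension, paste(structural_zero, collapse = ", ")))
  }
  structure(
    c(fit, list(dimension = dimension, family = family, terms = terms,
                levels_observed = observed, structural_zero = structural_zero)),
    class = "qolad_item_model"
  )
}

fit_item_mlogit <- function(y, X, observed, ridge) {
  df <- as.data.frame(X[, -1, drop = FALSE], check.names = FALSE)
  df$.y <- factor(y, levels = observed)
  fit <- nnet::multinom(.y ~ ., data = df, maxit = 200, decay = ridge,
                        trace = FALSE, MaxNWts = 10000)
  converged <- fit$convergence == 0
  if (!converged) {
    warn("mlogit did not converge within 200 iterations; last iterate kept.")
  }
  cm <- coef(fit)
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1, dimnames = list(NULL, names(cm)))
  # rows: non-reference observed levels; columns reordered to match X
  B <- matrix(0, nrow = length(observed), ncol = ncol(X),
              dimnames = list(as.character(observed), colnames(X)))
  cn <- colnames(cm)
  cn[cn == "(Intercept)"] <- "(Intercept)"
  B[-1, ] <- cm[, match(colnames(X), cn), drop = FALSE]
  list(coefficients = B, reference = observed[1],
       convergence = list(converged = converged, iterations = 200L * (!converged)))
}

fit_item_ologit <- function(y, X, observed) {
  df <- as.data.frame(X[, -1, drop = FALSE], check.names = FALSE)
  df$.y <- factor(y, levels = observed, ordered = TRUE)
  p <- ncol(X) - 1
  fit <- tryCatch(
    MASS::polr(.y ~ ., data = df, method = "logistic",
               control = list(maxit = 200)),
    error = function(e) {
      # retry from a neutral start: zero slopes, cutpoints at sample logits
      cum <- cumsum(prop.table(table(df$.y)))
      start <- c(rep(0, p), stats::qlogis(pmin(pmax(cum[-length(cum)], 1e-3), 1 - 1e-3)))
      MASS::polr(.y ~ ., data = df, method = "logistic", start = start,
                 control = list(maxit = 200))
    }
  )
  converged <- is.null(fit$convergence) || fit$convergence == 0
  if (!converged) {
    warn("ologit did not converge within 200 iterations; last iterate kept.")
  }
  beta <- coef(fit)
  beta <- setNames(beta[match(colnames(X)[-1], names(beta))], colnames(X)[-1])
  list(coefficients = beta, zeta = fit$zeta,
       convergence = list(converged = converged, iterations = 200L * (!converged)))
}

fit_item_ols <- function(y, X) {
  ls <- lm.fit(X, as.numeric(y))
  check_full_rank(ls, X)
  list(coefficients = setNames(ls$coefficients, colnames(X)),
       convergence = list(converged = TRUE, iterations = 0L))
}

#' Predicted level distribution for one item model
#'
#' @param model a `qolad_item_model`.
#' @param X design matrix rows (same columns as at fit time).
#' @return an n x 5 matrix of probabilities over levels 1--5; each row sums
#'   to 1. OLS families return a degenerate one-hot distribution at the
#'   fitted value rounded to the nearest level, halves toward the higher
#'   (worse) level, clamped to 1--5.
#' @export
predict_item_distribution <- function(model, X) {
  n <- nrow(X)
  P <- matrix(0, n, 5, dimnames = list(NULL, paste0("p", 1:5)))
  if (model$family == "mlogit") {
    eta <- X %*% t(model$coefficients)   # n x n_observed, reference column = 0
    eta <- eta - apply(eta, 1, max)
    w <- exp(eta)
    P[, model$levels_observed] <- w / rowSums(w)
  } else if (model$family == "ologit") {
    eta <- drop(X[, -1, drop = FALSE] %*% model$coefficients)
    cum <- vapply(model$zeta, function(z) stats::plogis(z - eta), numeric(n))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    cum <- cbind(cum, 1)
    probs <- cum - cbind(0, cum[, -ncol(cum), drop = FALSE])
    P[, model$levels_observed] <- probs
  } else {
    yhat <- drop(X %*% model$coefficients)
    lvl <- pmin(pmax(floor(yhat + 0.5), 1), 5)   # halves round toward worse
    P[cbind(seq_len(n), lvl)] <- 1
  }
  P
}

#' Predict from a response mapping model
#'
#' @param object a `qolad_response_fit`.
#' @param newdata data frame carrying the scenario columns.
#' @param type `"utility"` (default: exact expected utility over all 3125
#'   states), `"modal"` (per-dimension modal level, ties toward the lower
#'   level, then a single crosswalk lookup) or `"distribution"` (a tibble of
#'   per-row, per-dimension level probabilities).
#' @param crosswalk crosswalk used to value states.
#' @param ... unused.
#' @return numeric utilities, or a tibble when `type = "distribution"`.
#' @export
predict.qolad_response_fit <- function(object, newdata,
                                       type = c("utility", "modal", "distribution"),
                                       crosswalk = default_crosswalk(), ...) {
  type <- match.arg(type)
  X <- build_design(object$spec, newdata, strict = TRUE)
  dists <- purrr::map(object$items, predict_item_distribution, X = X)
  if (type == "distribution") {
    return(purrr::imap_dfr(dists, function(P, d) {
      tibble::as_tibble(P) |>
        dplyr::mutate(.row = dplyr::row_number(), dimension = d, .before = 1)
    }) |> dplyr::arrange(.data$.row))
  }
  if (type == "modal") {
    m <- vapply(dists, function(P) max.col(P, ties.method = "first"), integer(nrow(X)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    return(crosswalk_utility(m, crosswalk))
  }
  expected_utility_rows(dists, crosswalk)
}

#' Expected and modal utility of predicted response distributions
#'
#' `expected_utility()` computes the exact expectation of the crosswalk
#' utility over the joint distribution of the five dimensions -- assumed
#' independent, as each dimension is modelled separately -- by full
#' enumeration of the 3125 five-level states (no sampling).
#' `modal_state_utility()` instead takes the per-dimension modal level
#' (ties broken toward the lower, healthier level) and performs a single
#' lookup.
#'
#' @param dist the per-dimension level probabilities: a list of five
#'   probability vectors of length 5 (single observation) or five n x 5
#'   matrices, in dimension order mobility, self-care, usual activities,
#'   pain/discomfort, anxiety/depression.
#' @param crosswalk an `eq5d_crosswalk`.
#' @return numeric utility vector.
#' @examples
#' cw <- synthetic_crosswalk()
#' deg <- replicate(5, c(1, 0, 0, 0, 0), simplify = FALSE)
#' expected_utility(deg, cw)  # 1
#' @export
expected_utility <- function(dist, crosswalk) {
  dists <- as_dist_list(dist)
  expected_utility_rows(dists, crosswalk)
}

#' @rdname expected_utility
#' @export
modal_state_utility <- function(dist, crosswalk) {
  dists <- as_dist_list(dist)
  check_distributions(dists)
  m <- vapply(dists, function(P) max.col(P, ties.method = "first"),
              integer(nrow(dists[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  crosswalk_utility(m, crosswalk)
}

as_dist_list <- function(dist) {
  if (!is.list(dist) || length(dist) != 5) {
    abort("`dist` must be a list of five per-dimension probability vectors or matrices.",
          class = "qoladmap_distribution_error")
  }
  lapply(dist, function(p) {
    m <- if (is.matrix(p)) p else matrix(p, nrow = 1)
    if (ncol(m) != 5) {
      abort("Each dimension needs probabilities for 5 levels.",
            class = "qoladmap_distribution_error")
    }
    m
  })
}

check_distributions <- function(dists, tol = 1e-10) {
  for (P in dists) {
    if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol)) {
      abort("Probabilities must be non-negative and sum to 1 within 1e-10.",
            class = "qoladmap_distribution_error")
    }
  }
  invisible(dists)
}

# exact enumeration: E[u] = sum_s u(s) prod_d P_d(s_d), chunked over rows
expected_utility_rows <- function(dists, crosswalk) {
  check_crosswalk(crosswalk)
  check_distributions(dists)
  S <- all_5l_states()
  u <- crosswalk$utilities
  n <- nrow(dists[[1]])
  out <- numeric(n)
  chunk <- max(1, floor(2e6 / 3125))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    W <- dists[[1]][idx, S[, 1], drop = FALSE]
    for (d in 2:5) W <- W * dists[[d]][idx, S[, d], drop = FALSE]
    out[idx] <- drop(W %*% u)
  }
  out
}

#' @export
print.qolad_response_fit <- function(x, ...) {
  cat(sprintf("<qolad_response_fit> family=%s n=%d converged=%s\n",
              x$family, x$n, x$convergence$converged))
  invisible(x)
}

#' @export
print.qolad_item_model <- function(x, ...) {
  cat(sprintf("<qolad_item_model> %s family=%s levels=%s\n", x$dimension,
              x$family, paste(x$levels_observed, collapse = ",")))
  invisible(x)
}
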