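#' Evaluate predicted against observed utilities
#'
#' Computes the standard mapping-performance surface: root mean square error,
#' mean absolute error, the percentage of predictions within 0.1 utility
#' points of the observed value (boundary counted as accurate), the range of
#' predictions, and a calibration table over quartiles of the observed
#' utilities (mean observed per quartile; median, interquartile range and
#' 10th--90th centiles of the predictions). Quartile boundaries use type-7
#' sample quantiles with ties assigned to the lower quartile. Metrics are
#' computed on the final (post-clamping) predictions, pooled over all
#' observations.
#'
#' @param data a data frame, or a numeric vector of predictions (then
#'   `predicted` is interpreted as the observed vector).
#' @param predicted,observed columns of `data` (tidy-eval), or numeric
#'   vectors when `data` is a vector.
#' @return an object of class `mapping_evaluation`: list with `metrics`
#'   (one-row tibble: `rmse`, `mae`, `accuracy_within_0_1`, `min_predicted`,
#'   `max_predicted`, `n`) and `quartiles` (four-row calibration tibble).
#' @examples
#' evaluate_predictions(c(0.1, 0.3), c(0, 0))
#' @export
evaluate_predictions <- function(data, predicted = NULL, observed = NULL) {
  if (is.numeric(data)) {
    p <- data
    o <- predicted
  } else {
    p <- rlang::eval_tidy(rlang::enquo(predicted), data)
    o <- rlang::eval_tidy(rlang::enquo(observed), data)
  }
  if (length(p) == 0 || length(o) == 0) {
    abort("Empty input.", class = "qoladmap_evaluation_error")
  }
  if (length(p) != length(o)) {
    abort("`predicted` and `observed` must be paired (equal length).",
          class = "qoladmap_evaluation_error")
  }
  if (anyNA(p) || anyNA(o)) {
    abort("Missing values in predictions or observations.",
          class = "qoladmap_evaluation_error")
  }
  err <- p - o
  metrics <- tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    accuracy_within_0_1 = 100 * mean(abs(err) <= 0.1),
    min_predicted = min(p),
    max_predicted = max(p),
    n = length(p)
  )
  br <- unique(quantile(o, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  q <- cut(o, breaks = c(-Inf, br, Inf), labels = FALSE, right = TRUE)
  quartiles <- tibble::tibble(observed = o, predicted = p, quartile = q) |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(
      mean_observed = mean(.data$observed),
      median_predicted = median(.data$predicted),
      q25_predicted = quantile(.data$predicted, 0.25, type = 7, names = FALSE),
      q75_predicted = quantile(.data$predicted, 0.75, type = 7, names = FALSE),
      q10_predicted = quantile(.data$predicted, 0.10, type = 7, names = FALSE),
      q90_predicted = quantile(.data$predicted, 0.90, type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop"
    )
  structure(list(metrics = metrics, quartiles = quartiles),
            class = "mapping_evaluation")
}

#' @export
print.mapping_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<mapping_evaluation> n=%d\n", m$n))
  cat(sprintf("  RMSE %.4f  MAE %.4f  accuracy@0.1 %.0f%%  predicted range [%.3f, %.3f]\n",
              m$rmse, m$mae, m$accuracy_within_0_1, m$min_predicted, m$max_predicted))
  invisible(x)
}

#' Fit and compare the mapping families on one scenario
#'
#' Fits each requested family on the estimation table, predicts (on the same
#' table, or on `newdata` for external validation), and reports one
#' evaluation row per family in a fixed order, flagging the lowest RMSE and
#' lowest MAE.
#'
#' @param table a `qolad_scenario` estimation table.
#' @param families character vector of family names; the default
#'   [mapping_families()] is all nine.
#' @param newdata optional validation table (defaults to `table`).
#' @param crosswalk crosswalk for the response families.
#' @return a tibble of class `mapping_comparison` with columns `model`,
#'   `rmse`, `mae`, `accuracy_within_0_1`, `min_predicted`, `max_predicted`,
#'   `n`, `converged`, `best_rmse`, `best_mae`, and the fitted models in
#'   attribute `fits`.
#' @export
compare_models <- function(table, families = mapping_families(), newdata = NULL,
                           crosswalk = default_crosswalk()) {
  bad <- setdiff(families, mapping_families())
  if (length(bad)) {
    abort(sprintf("Unknown model famil%s: %s.",
                  if (length(bad) > 1) "ies" else "y",
                  paste(bad, collapse = ", ")),
          class = "qoladmap_usage_error")
  }
  families <- mapping_families()[mapping_families() %in% families]
  newdata <- newdata %||% table
  fits <- purrr::map(families, fit_mapper, table = table, crosswalk = crosswalk)
  names(fits) <- families
  rows <- purrr::map2_dfr(fits, families, function(fit, fam) {
    pred <- if (inherits(fit, "qolad_response_fit")) {
      predict(fit, newdata, crosswalk = crosswalk)
    } else {
      predict(fit, newdata)
    }
    ev <- evaluate_predictions(pred, newdata$utility)
    dplyr::mutate(ev$metrics, model = fam, converged = fit$convergence$converged,
                  .before = 1)
  })
  rows <- dplyr::mutate(rows,
                        best_rmse = .data$rmse == min(.data$rmse),
                        best_mae = .data$mae == min(.data$mae))
  structure(rows, fits = fits,
            class = c("mapping_comparison", class(rows)))
}

#' @rdname compare_models
#' @export
mapping_families <- function() {
  c("direct_ols_continuous", "direct_ols_categorical", "direct_tobit",
    "direct_clad", "direct_two_part", "response_ols_categorical",
    "response_ols_continuous", "response_ologit", "response_mlogit")
}

# dispatch a family name to its fitting function
fit_mapper <- function(family, table, crosswalk = default_crosswalk(), ...) {
  if (startsWith(family, "direct_")) {
    fit_direct(table, sub("^direct_", "", family), ...)
  } else {
    fit_response_mapper(table, sub("^response_", "", family), ...)
  }
}

#' Cluster-robust covariance for a fitted mapping model
#'
#' Sandwich covariance with per-observation score contributions summed
#' within clusters (observations of the same subject across visits), with
#' the small-sample factor G/(G-1), G the number of clusters. Clustering
#' affects the covariance only, never point estimates. Available for models
#' exposing per-observation scores: the OLS families, the logistic and OLS
#' parts of the two-part model, the Tobit, and plain `lm`/`glm` objects.
#' The CLAD deliberately gets no cluster adjustment.
#'
#' @param model a fitted model.
#' @param cluster vector of cluster identifiers, one per estimation row.
#' @param ... unused.
#' @return covariance matrix (for the two-part family, a list with elements
#'   `logit` and `ols`).
#' @export
cluster_robust_vcov <- function(model, cluster, ...) {
  UseMethod("cluster_robust_vcov")
}

#' @export
cluster_robust_vcov.default <- function(model, cluster, ...) {
  abort(sprintf("No cluster-robust covariance method for class '%s'.",
                class(model)[1]),
        class = "qoladmap_usage_error")
}

#' @export
cluster_robust_vcov.lm <- function(model, cluster, ...) {
  X <- stats::model.matrix(model)
  sandwich_cluster(X * stats::residuals(model), crossprod(X), cluster)
}

#' @export
cluster_robust_vcov.glm <- function(model, cluster, ...) {
  X <- stats::model.matrix(model)
  # working-residual score and the fit's own unscaled information, so the
  # singleton-cluster limit reproduces the HC-robust covariance exactly
  U <- X * stats::residuals(model, "working") * model$weights
  Ainv <- summary(model)$cov.unscaled
  sandwich_cluster_inv(U, Ainv, cluster)
}

#' @export
cluster_robust_vcov.qolad_direct_fit <- function(model, cluster, ...) {
  X <- model$X; y <- model$y
  switch(model$family,
    ols_continuous = ,
    ols_categorical = {
      r <- y - drop(X %*% model$coefficients)
      sandwich_cluster(X * r, crossprod(X), cluster)
    },
    tobit = {
      U <- tobit_scores(model)
      sandwich_cluster(U, model$hessian, cluster)
    },
    two_part = {
      pr <- stats::plogis(drop(X %*% model$coefficients$logit))
      Ul <- X * (as.numeric(y >= 1 - 1e-12) - pr)
      Al <- crossprod(X * sqrt(pr * (1 - pr)))
      below <- y < 1 - 1e-12
      Xb <- X[below, , drop = FALSE]
      rb <- y[below] - drop(Xb %*% model$coefficients$ols)
      list(logit = sandwich_cluster(Ul, Al, cluster),
           ols = sandwich_cluster(Xb * rb, crossprod(Xb), cluster[below]))
    },
    clad = abort("The CLAD is fitted without a cluster adjustment.",
                 class = "qoladmap_usage_error")
  )
}

# V = G/(G-1) * A^-1 (sum_g s_g s_g') A^-1, s_g the within-cluster score sum
sandwich_cluster <- function(U, A, cluster) {
  sandwich_cluster_inv(U, solve(A), cluster)
}

sandwich_cluster_inv <- function(U, Ainv, cluster) {
  if (nrow(U) != length(cluster)) {
    abort("`cluster` must have one id per estimation row.",
          class = "qoladmap_usage_error")
  }
  G <- length(unique(cluster))
  if (G < 2) {
    abort("Need at least 2 clusters.", class = "qoladmap_degenerate_error")
  }
  S <- rowsum(U, group = as.character(cluster))
  G / (G - 1) * Ainv %*% crossprod(S) %*% Ainv
}
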