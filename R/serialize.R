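#' Save and restore fitted mapping models as JSON
#'
#' Models serialize to a library-agnostic JSON document holding the family,
#' the covariate specification (including the observed factor levels, so
#' predictions are coding-invariant), the coefficient blocks at full
#' precision, and the convergence diagnostics. A round-trip reproduces
#' predictions exactly.
#'
#' @param model a `qolad_direct_fit` or `qolad_response_fit`.
#' @param path output (input) JSON path.
#' @return `write_mapping_model()` returns `path` invisibly;
#'   `read_mapping_model()` the restored model object (refittable data such
#'   as the design matrix is not stored, so covariance methods are
#'   unavailable on a loaded model).
#' @export
write_mapping_model <- function(model, path) {
  doc <- if (inherits(model, "qolad_direct_fit")) {
    list(
      format = "qoladmap-model/1", type = "direct", family = model$family,
      scenario = model$scenario, covariate_spec = spec_to_list(model$spec),
      coefficients = coef_block(model$coefficients),
      sigma = model$sigma, convergence = model$convergence, n = model$n
    )
  } else if (inherits(model, "qolad_response_fit")) {
    list(
      format = "qoladmap-model/1", type = "response", family = model$family,
      scenario = model$scenario, covariate_spec = spec_to_list(model$spec),
      ridge = model$ridge, convergence = model$convergence, n = model$n,
      items = purrr::map(model$items, item_block)
    )
  } else {
    abort("`model` must be a fitted mapping model.", class = "qoladmap_usage_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

coef_block <- function(cf) {
  if (is.list(cf)) purrr::map(cf, as.list) else as.list(cf)
}

item_block <- function(it) {
  out <- list(dimension = it$dimension, family = it$family,
              levels_observed = it$levels_observed,
              structural_zero = it$structural_zero,
              terms = it$terms, convergence = it$convergence)
  if (it$family == "mlogit") {
    out$coefficients <- apply(it$coefficients, 1, as.list, simplify = FALSE)
    out$reference <- it$reference
  } else if (it$family == "ologit") {
    out$coefficients <- as.list(it$coefficients)
    out$zeta <- as.list(it$zeta)
  } else {
    out$coefficients <- as.list(it$coefficients)
  }
  out
}

#' @rdname write_mapping_model
#' @export
read_mapping_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "qoladmap-model/1")) {
    abort("Not a qoladmap model document.", class = "qoladmap_format_error")
  }
  spec <- spec_from_list(doc$covariate_spec)
  scen <- doc$scenario
  conv <- list(converged = isTRUE(doc$convergence$converged),
               iterations = as.integer(doc$convergence$iterations %||% 0L))
  if (doc$type == "direct") {
    cf <- doc$coefficients
    cf <- if (doc$family == "two_part") {
      list(logit = unlist_named(cf$logit), ols = unlist_named(cf$ols))
    } else {
      unlist_named(cf)
    }
    structure(
      list(coefficients = cf, sigma = doc$sigma, convergence = conv,
           family = doc$family, spec = spec, scenario = scen,
           n = doc$n %||% NA_integer_),
      class = "qolad_direct_fit"
    )
  } else {
    items <- purrr::map(doc$items, function(it) {
      base <- list(dimension = it$dimension, family = it$family,
                   terms = unlist(it$terms),
                   levels_observed = as.integer(unlist(it$levels_observed)),
                   structural_zero = as.integer(unlist(it$structural_zero)),
                   convergence = list(
                     converged = isTRUE(it$convergence$converged),
                     iterations = as.integer(it$convergence$iterations %||% 0L)))
      if (it$family == "mlogit") {
        B <- do.call(rbind, purrr::map(it$coefficients, ~ unlist(.x)))
        dimnames(B) <- list(as.character(base$levels_observed), base$terms)
        base$coefficients <- B
        base$reference <- as.integer(it$reference)
      } else if (it$family == "ologit") {
        base$coefficients <- unlist_named(it$coefficients)
        base$zeta <- unlist_named(it$zeta)
      } else {
        base$coefficients <- unlist_named(it$coefficients)
      }
      structure(base, class = "qolad_item_model")
    })
    names(items) <- purrr::map_chr(items, "dimension")
    structure(
      list(family = doc$family, spec = spec, scenario = scen, items = items,
           ridge = doc$ridge %||% 0, n = doc$n %||% NA_integer_,
           convergence = conv),
      class = "qolad_response_fit"
    )
  }
}

unlist_named <- function(x) {
  v <- unlist(x)
  setNames(as.numeric(v), names(v))
}
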