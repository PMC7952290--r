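#' Tidy methods for fitted mapping models
#'
#' `tidy()` returns one row per coefficient; `glance()` a one-row model
#' summary.
#'
#' @param x a fitted mapping model.
#' @param ... unused.
#' @return a tibble.
#' @name qoladmap-tidiers
NULL

#' @rdname qoladmap-tidiers
#' @method tidy qolad_direct_fit
#' @export
tidy.qolad_direct_fit <- function(x, ...) {
  if (x$family == "two_part") {
    purrr::imap_dfr(x$coefficients, function(cf, block) {
      tibble::tibble(block = block, term = names(cf), estimate = unname(cf))
    })
  } else {
    tibble::tibble(block = x$family, term = names(x$coefficients),
                   estimate = unname(x$coefficients))
  }
}

#' @rdname qoladmap-tidiers
#' @method glance qolad_direct_fit
#' @export
glance.qolad_direct_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n %||% NA_integer_,
    sigma = x$sigma %||% NA_real_,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations
  )
}

#' @rdname qoladmap-tidiers
#' @method tidy qolad_response_fit
#' @export
tidy.qolad_response_fit <- function(x, ...) {
  purrr::imap_dfr(x$items, function(it, d) {
    if (it$family == "mlogit") {
      B <- it$coefficients
      tidyr::expand_grid(level = rownames(B), term = colnames(B)) |>
        dplyr::mutate(dimension = d,
                      estimate = as.vector(t(B)), .before = 1)
    } else if (it$family == "ologit") {
      dplyr::bind_rows(
        tibble::tibble(dimension = d, level = NA_character_,
                       term = names(it$coefficients),
                       estimate = unname(it$coefficients)),
        tibble::tibble(dimension = d, level = NA_character_,
                       term = paste0("cutpoint_", names(it$zeta)),
                       estimate = unname(it$zeta))
      )
    } else {
      tibble::tibble(dimension = d, level = NA_character_,
                     term = names(it$coefficients),
                     estimate = unname(it$coefficients))
    }
  })
}

#' @rdname qoladmap-tidiers
#' @method glance qolad_response_fit
#' @export
glance.qolad_response_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n %||% NA_integer_,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations,
    structural_zeros = sum(purrr::map_int(x$items, ~ length(.x$structural_zero)))
  )
}

#' @rdname qoladmap-tidiers
#' @method tidy mapping_evaluation
#' @export
tidy.mapping_evaluation <- function(x, ...) x$metrics

#' @rdname qoladmap-tidiers
#' @method glance mapping_evaluation
#' @export
glance.mapping_evaluation <- function(x, ...) x$metrics
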