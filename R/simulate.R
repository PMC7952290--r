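#' Configuration for the paired QoL-AD / EQ-5D simulator
#'
#' The simulator emulates the structure of a longitudinal dementia cohort
#' with both self- and proxy-rated questionnaires: a latent health trait per
#' subject with visit-level noise (within-subject clustering), QoL-AD items
#' obtained by thresholding the latent trait plus item noise, EQ-5D-5L items
#' drawn from known multinomial-logit models given the realised QoL-AD
#' composite, age and sex (so the mlogit response mapper is correctly
#' specified and recovery tests are well-posed), and utilities valued
#' through the crosswalk. Defaults reflect the estimation-cohort conditions:
#' three visits per subject, mean age 78 (SD 8), 55% female, a 13% missing
#' rate for item 7, a ceiling fraction of 0.15, and a composite-utility
#' Spearman correlation near 0.5.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject visits per subject (default 3: baseline, 6 and
#'   12 months).
#' @param latent_between_sd,latent_within_sd SDs of the subject effect and
#'   visit noise on the latent health trait (their ratio controls
#'   within-subject clustering).
#' @param item_noise_sd SD of the item-specific noise added to the latent
#'   trait before thresholding.
#' @param qolad_thresholds 13 x 3 matrix of increasing cutpoints per item on
#'   the latent scale.
#' @param eq5d_item_models ground-truth mlogit coefficients: a list of five
#'   4 x 4 matrices (rows levels 2--5, columns `(Intercept)`, `qol_z`,
#'   `age_z`, `male`), where `qol_z` is the standardised 12-item raw sum
#'   `(sum12 - 33)/6` and `age_z` is `(age - 78)/10`.
#' @param ceiling_target fraction of observations at utility 1; hit by
#'   calibrating a common intercept shift (see [simulate_qolad_eq5d()]).
#' @param item7_missing_rate missing rate for QoL-AD item 7.
#' @param item_missing_rate independent missing rate for the other items.
#' @param proxy_shift shift of the proxy rater's latent trait (proxies rate
#'   quality of life lower than the person themselves).
#' @param age_mean,age_sd,female_fraction demographics.
#' @param seed integer seed; one global stream drawn in documented order.
#' @return a `qolad_sim_config` list.
#' @export
sim_config <- function(n_subjects = 500,
                       visits_per_subject = 3,
                       latent_between_sd = 0.55,
                       latent_within_sd = 0.6,
                       item_noise_sd = 1.0,
                       qolad_thresholds = default_thresholds(),
                       eq5d_item_models = default_item_truth(),
                       ceiling_target = 0.15,
                       item7_missing_rate = 0.13,
                       item_missing_rate = 0.02,
                       proxy_shift = -0.8,
                       age_mean = 78, age_sd = 8,
                       female_fraction = 0.55,
                       seed = 1) {
  stopifnot(latent_between_sd > 0, latent_within_sd > 0, item_noise_sd > 0,
            age_sd > 0, n_subjects >= 1, visits_per_subject >= 1)
  rates <- c(ceiling_target, item7_missing_rate, item_missing_rate, female_fraction)
  if (any(rates < 0 | rates > 1)) {
    abort("Rates must lie in [0, 1].", class = "qoladmap_config_error")
  }
  qolad_thresholds <- as.matrix(qolad_thresholds)
  if (!all(dim(qolad_thresholds) == c(13, 3)) ||
      any(qolad_thresholds[, 1] >= qolad_thresholds[, 2]) ||
      any(qolad_thresholds[, 2] >= qolad_thresholds[, 3])) {
    abort("`qolad_thresholds` must be 13 x 3 with strictly increasing rows.",
          class = "qoladmap_config_error")
  }
  structure(
    list(n_subjects = n_subjects, visits_per_subject = visits_per_subject,
         latent_between_sd = latent_between_sd, latent_within_sd = latent_within_sd,
         item_noise_sd = item_noise_sd, qolad_thresholds = qolad_thresholds,
         eq5d_item_models = eq5d_item_models, ceiling_target = ceiling_target,
         item7_missing_rate = item7_missing_rate,
         item_missing_rate = item_missing_rate, proxy_shift = proxy_shift,
         age_mean = age_mean, age_sd = age_sd,
         female_fraction = female_fraction, seed = seed),
    class = "qolad_sim_config"
  )
}

default_thresholds <- function() {
  base <- c(-1.7, -0.4, 1.1)
  off <- seq(-0.3, 0.3, length.out = 13)
  t(vapply(off, function(o) base + o, numeric(3)))
}

default_item_truth <- function() {
  dim_off <- c(mo = 0, sc = 0.2, ua = 0.1, pd = 0.4, ad = 0.3)
  qol_scale <- c(mo = 1, sc = 0.9, ua = 1.1, pd = 1.0, ad = 0.8)
  age_slope <- c(mo = 0.20, sc = 0.15, ua = 0.15, pd = 0.10, ad = -0.05)
  male_eff <- c(mo = 0.10, sc = 0, ua = 0.05, pd = -0.10, ad = -0.20)
  purrr::map(EQ5D_DIMS, function(d) {
    k <- 1:4  # levels 2..5
    m <- cbind(
      "(Intercept)" = c(-0.3, -1.3, -2.8, -4.5) + dim_off[[d]],
      qol_z = -0.4 * k * qol_scale[[d]],
      age_z = age_slope[[d]] * k,
      male = rep(male_eff[[d]], 4)
    )
    rownames(m) <- as.character(2:5)
    m
  }) |> setNames(EQ5D_DIMS)
}

#' Simulate a paired QoL-AD / EQ-5D dataset
#'
#' Draws, in order from a single stream seeded by `config$seed`: subject
#' effects, ages and sexes; visit noise; self item noise; proxy item noise;
#' item-7 and general missingness masks; EQ-5D levels for the self then the
#' proxy rater. A common intercept shift, calibrated deterministically from
#' the realised covariates, pushes the probability of full health to
#' `ceiling_target` before the EQ-5D levels are drawn. Utilities are valued
#' with `crosswalk`; exact 1 occurs only for state 11111, giving the ceiling
#' mass the direct ceiling-aware models target.
#'
#' @param config a [sim_config()] object.
#' @param crosswalk crosswalk used to value the drawn 5L states.
#' @return a tibble in the [read_qolad_dataset()] column layout, with the
#'   ground truth (config, calibrated intercept shift, effective item-model
#'   coefficients) in attribute `truth`.
#' @export
simulate_qolad_eq5d <- function(config = sim_config(),
                                crosswalk = default_crosswalk()) {
  stopifnot(inherits(config, "qolad_sim_config"))
  set.seed(config$seed)
  ns <- config$n_subjects; nv <- config$visits_per_subject
  n <- ns * nv

  b <- rnorm(ns, 0, config$latent_between_sd)
  age_s <- pmin(pmax(rnorm(ns, config$age_mean, config$age_sd), 40), 100)
  sex_s <- ifelse(runif(ns) < config$female_fraction, "female", "male")
  subj <- rep(seq_len(ns), each = nv)
  h <- b[subj] + rnorm(n, 0, config$latent_within_sd)

  draw_items <- function(latent) {
    m <- matrix(NA_integer_, n, 13)
    for (j in 1:13) {
      x <- latent + rnorm(n, 0, config$item_noise_sd)
      m[, j] <- 1L + findInterval(x, config$qolad_thresholds[j, ])
    }
    m
  }
  items_self <- draw_items(h)
  items_proxy <- draw_items(h + config$proxy_shift)

  mask <- function(m, j, rate) {
    if (rate > 0) m[runif(n) < rate, j] <- NA_integer_
    m
  }
  items_self <- mask(items_self, 7, config$item7_missing_rate)
  items_proxy <- mask(items_proxy, 7, config$item7_missing_rate)
  for (j in setdiff(1:13, 7)) {
    items_self <- mask(items_self, j, config$item_missing_rate)
    items_proxy <- mask(items_proxy, j, config$item_missing_rate)
  }

  age <- age_s[subj]; sex <- sex_s[subj]
  covars <- function(items) {
    sum12 <- rowSums(items[, setdiff(1:13, 7)])
    cbind("(Intercept)" = 1, qol_z = (sum12 - 33) / 6,
          age_z = (age - 78) / 10, male = as.numeric(sex == "male"))
  }
  # calibrate the common intercept shift on rows with complete self items
  Zs <- covars(items_self)
  ok <- !is.na(Zs[, "qol_z"])
  delta <- calibrate_ceiling(Zs[ok, , drop = FALSE], config$eq5d_item_models,
                             config$ceiling_target)
  truth_models <- purrr::map(config$eq5d_item_models, function(m) {
    m[, "(Intercept)"] <- m[, "(Intercept)"] + delta
    m
  })

  draw_eq5d <- function(Z) {
    ok <- !is.na(Z[, "qol_z"])
    out <- matrix(NA_integer_, n, 5, dimnames = list(NULL, EQ5D_DIMS))
    for (d in EQ5D_DIMS) {
      P <- mlogit_probs(Z[ok, , drop = FALSE], truth_models[[d]])
      u <- runif(sum(ok))
      cum <- t(apply(P, 1, cumsum))
      out[ok, d] <- 1L + rowSums(u > cum[, 1:4, drop = FALSE])
    }
    out
  }
  eq_self <- draw_eq5d(Zs)
  eq_proxy <- draw_eq5d(covars(items_proxy))

  to_utility <- function(m) {
    ok <- rowSums(is.na(m)) == 0
    u <- rep(NA_real_, n)
    if (any(ok)) u[ok] <- crosswalk_utility(m[ok, , drop = FALSE], crosswalk)
    u
  }

  out <- tibble::tibble(
    subject_id = sprintf("S%04d", subj),
    visit = rep(seq_len(nv), times = ns),
    age = round(age, 1), sex = sex
  )
  for (j in 1:13) out[[paste0("qolad_self_", j)]] <- items_self[, j]
  for (j in 1:13) out[[paste0("qolad_proxy_", j)]] <- items_proxy[, j]
  for (d in EQ5D_DIMS) out[[paste0("eq5d5l_self_", d)]] <- eq_self[, d]
  for (d in EQ5D_DIMS) out[[paste0("eq5d5l_proxy_", d)]] <- eq_proxy[, d]
  out$utility_self <- to_utility(eq_self)
  out$utility_proxy <- to_utility(eq_proxy)

  check_degenerate_items(out, n)
  attr(out, "truth") <- list(config = config, delta = delta,
                             item_models = truth_models)
  out
}

# level probabilities of a ground-truth mlogit block (rows = levels 2..5)
mlogit_probs <- function(Z, m) {
  eta <- cbind(0, Z %*% t(m))
  eta <- eta - apply(eta, 1, max)
  w <- exp(eta)
  w / rowSums(w)
}

# common intercept shift so that mean P(all five dimensions at level 1)
# equals the ceiling target; monotone in the shift, solved by uniroot
calibrate_ceiling <- function(Z, models, target) {
  p_ceiling <- function(delta) {
    p <- rep(1, nrow(Z))
    for (m in models) {
      md <- m; md[, "(Intercept)"] <- md[, "(Intercept)"] + delta
      p <- p * mlogit_probs(Z, md)[, 1]
    }
    mean(p) - target
  }
  uniroot(p_ceiling, c(-20, 20), tol = 1e-10)$root
}

check_degenerate_items <- function(out, n) {
  if (n < 500) return(invisible())
  for (col in grep("^(qolad|eq5d5l)_", names(out), value = TRUE)) {
    v <- out[[col]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(sprintf("Simulated column `%s` has a single observed level.", col))
    }
  }
  invisible()
}

#' Draw EQ-5D responses from a fitted response mapping model
#'
#' Closes the recovery loop: given any response mapping model (fitted or
#' loaded from JSON), draws item levels from the model's predicted level
#' distributions for the rows of `data`.
#'
#' @param model a `qolad_response_fit` or a path to a model JSON.
#' @param data data frame carrying the model's predictor columns.
#' @param seed integer seed.
#' @param crosswalk if not `NULL`, a `utility` column valued from the drawn
#'   states is appended.
#' @return tibble with columns `eq_mo` ... `eq_ad` (and optionally `utility`).
#' @export
simulate_from_model <- function(model, data, seed = 1, crosswalk = NULL) {
  if (is.character(model)) model <- read_mapping_model(model)
  if (!inherits(model, "qolad_response_fit")) {
    abort("`model` must be a response mapping model.", class = "qoladmap_usage_error")
  }
  set.seed(seed)
  X <- build_design(model$spec, data, strict = TRUE)
  out <- tibble::tibble(.rows = nrow(X))
  states <- matrix(NA_integer_, nrow(X), 5)
  for (i in seq_along(EQ5D_DIMS)) {
    P <- predict_item_distribution(model$items[[EQ5D_DIMS[i]]], X)
    u <- runif(nrow(X))
    cum <- t(apply(P, 1, cumsum))
    states[, i] <- 1L + rowSums(u > cum[, 1:4, drop = FALSE])
    out[[paste0("eq_", EQ5D_DIMS[i])]] <- states[, i]
  }
  if (!is.null(crosswalk)) out$utility <- crosswalk_utility(states, crosswalk)
  out
}
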