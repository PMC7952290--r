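# scenario-shaped table built from vectors, for controlled regression tests
toy_table <- function(score, utility, age = NULL, sex = NULL) {
  n <- length(score)
  out <- tibble::tibble(
    subject_id = as.character(seq_len(n)), visit = 1L,
    age = age %||% rep(70, n), sex = sex %||% rep("female", n),
    qolad_score = score, utility = utility
  )
  for (j in 1:13) out[[paste0("item_", j)]] <- 2L
  structure(out, scenario = list(predictor_rater = "self", target_rater = "self",
                                 include_item7 = FALSE, include_age_sex = FALSE),
            class = c("qolad_scenario", class(out)))
}

test_that("continuous OLS interpolates an exactly linear relationship", {
  score <- seq(13, 52, length.out = 30)
  tab <- toy_table(score, 0.01 * score - 0.2)
  fit <- fit_direct(tab, "ols_continuous")
  expect_equal(unname(fit$coefficients), c(-0.2, 0.01), tolerance = 1e-12)
  expect_equal(predict(fit, tab), 0.01 * score - 0.2, tolerance = 1e-12)
})

test_that("categorical OLS recovers known coefficients within 3 SEs", {
  set.seed(42)
  n <- 2000
  sim <- simulate_qolad_eq5d(sim_config(n_subjects = ceiling(n / 3), seed = 42,
                                        item_missing_rate = 0, item7_missing_rate = 0))
  sc <- suppressMessages(assemble_scenario(sim, "self", "self",
                                           include_age_sex = FALSE))
  spec <- qoladmap:::make_covariate_spec(sc, "items", include_age_sex = FALSE)
  X <- qoladmap:::build_design(spec, sc)
  beta0 <- setNames(c(0.5, rep(-0.01, ncol(X) - 1)), colnames(X))
  y <- drop(X %*% beta0) + rnorm(nrow(X), 0, 0.05)
  tab <- sc
  tab$utility <- y
  fit <- fit_direct(tab, "ols_categorical", include_age_sex = FALSE)
  se <- sqrt(diag(solve(crossprod(X))) * 0.05^2)
  expect_true(all(abs(fit$coefficients - beta0) < 3 * se))
})

test_that("rank-deficient designs raise a singularity error naming columns", {
  tab <- toy_table(rep(30, 20), runif(20))  # constant score, with intercept
  tab$utility <- runif(20, 0, 0.9)
  expect_error(fit_direct(tab, "ols_continuous"), "qolad_score",
               class = "qoladmap_singular_error")
})

test_that("predictions above the ceiling are clamped to 1", {
  score <- seq(13, 52, length.out = 40)
  tab <- toy_table(score, pmin(0.02 * score, 1))
  fit <- fit_direct(tab, "ols_continuous")
  # make the linear predictor exceed 1 deliberately
  fit$coefficients[] <- c(0.05, 0.03)  # 1.25 at score 40
  newrow <- toy_table(40, 0.5)
  expect_equal(predict(fit, newrow, type = "linear"), 1.25)
  expect_equal(predict(fit, newrow), 1)
})

test_that("Tobit censored expectation matches a Monte-Carlo oracle and stays below 1", {
  mu <- 0.8; s <- 0.2
  closed <- qoladmap:::tobit_censored_expectation(mu, s)
  set.seed(42)
  draws <- pmin(rnorm(1e6, mu, s), 1)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(closed - mean(draws)), 3 * mc_se)
  # strictly below 1 for any finite inputs
  for (m in c(-1, 0.5, 1, 1.2)) {
    expect_lt(qoladmap:::tobit_censored_expectation(m, 0.2), 1)
  }
})

test_that("Tobit collapses to OLS without censoring and recovers truth with it", {
  set.seed(42)
  n <- 1500
  score <- runif(n, 13, 52)
  y_unc <- 0.3 + 0.008 * score + rnorm(n, 0, 0.12)   # well below 1
  tab <- toy_table(score, pmin(y_unc - 0.3, 1))      # shift: no censoring
  fit_t <- fit_direct(tab, "tobit", predictors = "score")
  fit_o <- fit_direct(tab, "ols_continuous")
  expect_equal(unname(fit_t$coefficients), unname(fit_o$coefficients),
               tolerance = 1e-4)
  expect_true(fit_t$convergence$converged)

  # ~25% censored at 1
  beta0 <- c(0.55, 0.009)
  y_star <- beta0[1] + beta0[2] * score + rnorm(n, 0, 0.12)
  tab2 <- toy_table(score, pmin(y_star, 1))
  expect_gt(mean(tab2$utility == 1), 0.1)
  fit2 <- fit_direct(tab2, "tobit", predictors = "score")
  se <- sqrt(diag(solve(fit2$hessian)))[1:2]
  expect_true(all(abs(fit2$coefficients - beta0) < 3 * se))
  expect_true(abs(fit2$sigma - 0.12) < 0.02)
  # optimality: log-likelihood at the optimum beats the null (beta = 0, sigma = 1)
  cens <- tab2$utility >= 1 - 1e-12
  ll_null <- sum(dnorm(tab2$utility[!cens], 0, 1, log = TRUE)) +
    sum(pnorm(1, 0, 1, lower.tail = FALSE, log.p = TRUE)) * sum(cens)
  expect_gte(fit2$loglik, ll_null)
  # every prediction strictly below 1
  expect_true(all(predict(fit2, tab2) < 1))
})

test_that("Tobit with everything censored is degenerate", {
  tab <- toy_table(runif(30, 13, 52), rep(1, 30))
  expect_error(fit_direct(tab, "tobit", predictors = "score"), class = "qoladmap_degenerate_error")
})

test_that("CLAD equals plain median regression when trimming never triggers", {
  set.seed(42)
  n <- 200
  score <- runif(n, 13, 52)
  y <- 0.1 + 0.005 * score + (runif(n) - 0.5) * 0.2   # max ~0.5: no trimming
  tab <- toy_table(score, y)
  fit <- fit_direct(tab, "clad", predictors = "score")
  spec <- fit$spec
  X <- qoladmap:::build_design(spec, tab)
  lad <- quantreg::rq.fit.br(X, y, tau = 0.5)$coefficients
  expect_equal(unname(fit$coefficients), unname(lad), tolerance = 1e-10)
  expect_true(fit$convergence$converged)
  expect_lte(fit$convergence$iterations, 400)
})

test_that("CLAD beats a dense grid oracle on a tiny censored instance", {
  # n = 8, one predictor, integer-ish data, some censoring at 1
  score <- c(14, 18, 22, 28, 34, 40, 46, 50)
  y <- c(0.2, 0.35, 0.45, 0.6, 0.8, 1, 1, 1)
  tab <- toy_table(score, y)
  fit <- fit_direct(tab, "clad", predictors = "score")
  obj <- function(b0, b1) sum(abs(y - pmin(b0 + b1 * score, 1)))
  got <- obj(fit$coefficients[1], fit$coefficients[2])
  grid0 <- seq(-0.5, 0.5, by = 0.01)
  grid1 <- seq(0, 0.05, by = 0.0005)
  best <- min(outer(grid0, grid1, Vectorize(obj)))
  expect_lte(got, best + 1e-8)
})

test_that("the two-part model combines its blocks as Pr + (1 - Pr) * Y", {
  set.seed(42)
  n <- 600
  score <- runif(n, 13, 52)
  pr <- stats::plogis(-6 + 0.15 * score)
  at_ceiling <- runif(n) < pr
  y <- ifelse(at_ceiling, 1, pmin(0.2 + 0.01 * score + rnorm(n, 0, 0.1), 0.999))
  tab <- toy_table(score, y)
  fit <- fit_direct(tab, "two_part", predictors = "score")
  X <- qoladmap:::build_design(fit$spec, tab)
  pr_hat <- stats::plogis(drop(X %*% fit$coefficients$logit))
  y_hat <- drop(X %*% fit$coefficients$ols)
  expect_equal(predict(fit, tab), pmin(pr_hat + (1 - pr_hat) * y_hat, 1),
               tolerance = 1e-12)
  # formula endpoints
  fit2 <- fit
  fit2$coefficients$logit[] <- c(50, 0)   # Pr ~ 1
  expect_equal(predict(fit2, tab), rep(1, n), tolerance = 1e-9)
})

test_that("two-part blocks recover known coefficients within 3 SEs", {
  set.seed(42)
  n <- 5000
  z <- rnorm(n)
  b_logit <- c(-0.8, 1.1)
  b_ols <- c(0.6, 0.12)
  pr <- stats::plogis(b_logit[1] + b_logit[2] * z)
  ceiling_draw <- runif(n) < pr
  y <- ifelse(ceiling_draw, 1, b_ols[1] + b_ols[2] * z + rnorm(n, 0, 0.1))
  y <- pmin(y, 1)
  tab <- toy_table(13 + (z - min(z)) * 3, y)   # carrier; score unused below
  tab$qolad_score <- NULL
  tab$z <- z
  # fit via the low-level blocks on an explicit design
  X <- cbind("(Intercept)" = 1, z = z)
  fit <- qoladmap:::fit_two_part_blocks(X, y)
  g <- glm(I(y == 1) ~ z, family = binomial())
  se_logit <- sqrt(diag(vcov(g)))
  expect_true(all(abs(fit$coefficients$logit - b_logit) < 3 * se_logit))
  o <- lm(y[y < 1] ~ z[y < 1])
  se_ols <- sqrt(diag(vcov(o)))
  expect_true(all(abs(fit$coefficients$ols - b_ols) < 3 * se_ols))
})

test_that("two-part needs both ceiling and non-ceiling observations", {
  tab <- toy_table(runif(20, 13, 52), runif(20, 0, 0.9))
  expect_error(fit_direct(tab, "two_part", predictors = "score"), class = "qoladmap_degenerate_error")
})

test_that("refitting on permuted rows yields identical coefficients", {
  sc <- scenario_fixture()
  set.seed(42)
  perm <- sample(nrow(sc))
  scp <- sc[perm, ]
  attr(scp, "scenario") <- attr(sc, "scenario")
  for (fam in c("ols_categorical", "tobit", "two_part")) {
    f1 <- suppressWarnings(fit_direct(sc, fam))
    f2 <- suppressWarnings(fit_direct(scp, fam))
    expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8, info = fam)
  }
})

test_that("direct fits serialize to JSON and reproduce predictions exactly", {
  sc <- scenario_fixture()
  for (fam in c("ols_continuous", "tobit", "two_part")) {
    fit <- suppressWarnings(fit_direct(sc, fam))
    path <- withr::local_tempfile(fileext = ".json")
    write_mapping_model(fit, path)
    back <- read_mapping_model(path)
    expect_identical(predict(back, sc), predict(fit, sc), info = fam)
  }
})
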