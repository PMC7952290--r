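# hand-made item models for prediction-rule tests
manual_mlogit <- function(B, levels = 1:5) {
  structure(list(dimension = "mo", family = "mlogit", coefficients = B,
                 reference = levels[1], terms = colnames(B),
                 levels_observed = levels, structural_zero = setdiff(1:5, levels),
                 convergence = list(converged = TRUE, iterations = 0L)),
            class = "qolad_item_model")
}

manual_ols <- function(beta, terms = c("(Intercept)", "z")) {
  structure(list(dimension = "mo", family = "ols_categorical",
                 coefficients = setNames(beta, terms), terms = terms,
                 levels_observed = 1:5, structural_zero = integer(),
                 convergence = list(converged = TRUE, iterations = 0L)),
            class = "qolad_item_model")
}

test_that("a 2-level mlogit equals binary logistic regression", {
  set.seed(42)
  X <- compact_design(800, 42)
  B <- matrix(c(-0.5, 0.8, -0.3, 0.4), nrow = 1,
              dimnames = list("2", colnames(X)))
  y <- draw_mlogit(X, B)
  fit <- suppressMessages(fit_item_model(y, X, "mlogit"))
  ref <- glm(I(y == 2) ~ X[, -1], family = binomial())
  expect_equal(unname(fit$coefficients["2", ]), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("mlogit recovers known coefficients within 3 SEs (n = 5000)", {
  set.seed(42)
  X <- compact_design(5000, 42)
  B0 <- rbind("2" = c(-0.2, 0.5, 0.2, -0.1),
              "3" = c(-1.0, 1.0, 0.3, 0.2),
              "4" = c(-1.8, 1.4, 0.1, -0.3))
  colnames(B0) <- colnames(X)
  y <- draw_mlogit(X, B0)
  fit <- suppressMessages(fit_item_model(y, X, "mlogit"))
  # SEs from the estimation backend's information matrix
  df <- as.data.frame(X[, -1]); df$.y <- factor(y)
  ref <- nnet::multinom(.y ~ ., df, trace = FALSE, Hess = TRUE)
  se <- matrix(sqrt(diag(solve(ref$Hessian))), nrow = 3, byrow = TRUE)
  est <- fit$coefficients[c("2", "3", "4"), ]
  expect_true(all(abs(est - B0) < 3 * se))
})

test_that("ologit fits have strictly increasing cutpoints", {
  set.seed(42)
  for (rep in 1:5) {
    X <- compact_design(400, rep)
    B <- rbind("2" = c(-0.2, 0.6, 0, 0), "3" = c(-1, 1.2, 0, 0),
               "4" = c(-2, 1.8, 0, 0), "5" = c(-3, 2.4, 0, 0))
    colnames(B) <- colnames(X)
    y <- draw_mlogit(X, B)
    fit <- suppressMessages(fit_item_model(y, X, "ologit"))
    expect_true(all(diff(fit$zeta) > 0))
  }
})

test_that("mlogit with zero coefficients predicts a uniform distribution", {
  B <- matrix(0, 5, 3, dimnames = list(as.character(1:5),
                                       c("(Intercept)", "a", "b")))
  m <- manual_mlogit(B)
  P <- predict_item_distribution(m, cbind("(Intercept)" = 1, a = 2, b = -1))
  expect_equal(unname(P[1, ]), rep(0.2, 5))
})

test_that("OLS response prediction rounds halves toward the worse level", {
  X <- cbind("(Intercept)" = 1, z = c(0, 1, 2, 6))
  m <- manual_ols(c(3.5, -0.5))   # fitted: 3.5, 3.0, 2.5, 0.5
  P <- predict_item_distribution(m, X)
  expect_equal(max.col(P), c(4, 3, 3, 1))  # 3.5 -> 4; 2.5 -> 3; clamp at 1
  expect_true(all(rowSums(P) == 1))
  m2 <- manual_ols(c(5.6, 0))     # above the scale: clamp to 5
  expect_equal(max.col(predict_item_distribution(m2, X)), rep(5, 4))
})

test_that("mlogit and ologit probabilities match the library predictions", {
  set.seed(42)
  X <- compact_design(300, 7)
  B <- rbind("2" = c(-0.2, 0.5, 0.2, -0.1), "3" = c(-1, 1, 0.3, 0.2),
             "4" = c(-1.6, 1.3, 0, 0.1), "5" = c(-2.5, 1.7, -0.1, 0))
  colnames(B) <- colnames(X)
  y <- draw_mlogit(X, B)
  idx <- sample(nrow(X), 20)
  df <- as.data.frame(X[, -1]); df$.y <- factor(y)

  fit_m <- suppressMessages(fit_item_model(y, X, "mlogit"))
  ref_m <- nnet::multinom(.y ~ ., df, trace = FALSE)
  P <- predict_item_distribution(fit_m, X[idx, , drop = FALSE])
  Q <- predict(ref_m, df[idx, ], type = "probs")
  expect_equal(unname(P[, sort(unique(y))]), unname(Q), tolerance = 1e-5)

  fit_o <- suppressMessages(fit_item_model(y, X, "ologit"))
  ref_o <- MASS::polr(ordered(.y) ~ ., df, method = "logistic")
  Po <- predict_item_distribution(fit_o, X[idx, , drop = FALSE])
  Qo <- predict(ref_o, df[idx, ], type = "probs")
  expect_equal(unname(Po[, sort(unique(y))]), unname(Qo), tolerance = 1e-4)
})

test_that("unobserved levels get structural-zero probability", {
  set.seed(42)
  X <- compact_design(300, 3)
  y <- 1L + (X[, "z"] > 0)   # only levels 1 and 2
  suppressWarnings(  # deterministic outcome: separation warning expected
    expect_message(fit <- fit_item_model(y, X, "mlogit", dimension = "pd"),
                   "structural-zero"))
  P <- predict_item_distribution(fit, X[1:5, , drop = FALSE])
  expect_true(all(P[, 3:5] == 0))
  expect_equal(rowSums(P), rep(1, 5))
})

test_that("a single observed level is a degenerate outcome", {
  X <- compact_design(50, 1)
  expect_error(fit_item_model(rep(2L, 50), X, "mlogit"),
               class = "qoladmap_degenerate_error")
  sc <- scenario_fixture()
  sc$eq_ad <- 1L
  expect_error(suppressMessages(fit_response_mapper(sc, "mlogit")), "ad")
})

test_that("expected utility: degenerate, linear and Monte-Carlo cases", {
  cw <- toy_crosswalk()
  deg <- replicate(5, c(1, 0, 0, 0, 0), simplify = FALSE)
  expect_equal(expected_utility(deg, cw), crosswalk_utility(c(1, 1, 1, 1, 1), cw))
  syn <- synthetic_crosswalk()
  expect_equal(expected_utility(deg, syn), 1)
  # linearity: mass split over two states averages their entries
  half <- deg
  half[[1]] <- c(0.5, 0, 0, 0, 0.5)
  expect_equal(expected_utility(half, cw),
               mean(crosswalk_utility(rbind(c(1, 1, 1, 1, 1), c(5, 1, 1, 1, 1)), cw)))
  # exhaustive enumeration vs 10^6-draw sampling oracle
  set.seed(42)
  dist <- replicate(5, {
    p <- runif(5); p / sum(p)
  }, simplify = FALSE)
  exact <- expected_utility(dist, syn)
  draws <- vapply(dist, function(p) sample.int(5, 1e6, replace = TRUE, prob = p),
                  integer(1e6))
  u <- crosswalk_utility(draws, syn)
  expect_lt(abs(exact - mean(u)), 3 * sd(u) / sqrt(length(u)))
  expect_true(exact >= min(syn$utilities) && exact <= max(syn$utilities))
})

test_that("invalid distributions are rejected", {
  cw <- toy_crosswalk()
  bad <- replicate(5, c(0.5, 0.2, 0, 0, 0), simplify = FALSE)
  expect_error(expected_utility(bad, cw), class = "qoladmap_distribution_error")
  neg <- replicate(5, c(1.2, -0.2, 0, 0, 0), simplify = FALSE)
  expect_error(expected_utility(neg, cw), class = "qoladmap_distribution_error")
})

test_that("modal-state utility: ties go to the lower level; degenerate equals expected", {
  cw <- toy_crosswalk()
  deg <- replicate(5, c(0, 0, 1, 0, 0), simplify = FALSE)
  expect_equal(modal_state_utility(deg, cw), expected_utility(deg, cw))
  tied <- replicate(5, c(0.4, 0.4, 0.2, 0, 0), simplify = FALSE)
  expect_equal(modal_state_utility(tied, cw), crosswalk_utility(c(1, 1, 1, 1, 1), cw))
  # comparison harness over random distributions: both bounded by the table
  set.seed(42)
  gaps <- replicate(100, {
    d <- replicate(5, { p <- runif(5); p / sum(p) }, simplify = FALSE)
    abs(modal_state_utility(d, cw) - expected_utility(d, cw))
  })
  expect_true(all(is.finite(gaps)))
  expect_lte(max(gaps), diff(range(cw$utilities)))
})

test_that("the response mapper fits five dimensions with the shared design", {
  sc <- scenario_fixture()
  fit <- suppressMessages(suppressWarnings(fit_response_mapper(sc, "mlogit")))
  expect_named(fit$items, c("mo", "sc", "ua", "pd", "ad"))
  u <- predict(fit, sc)
  expect_true(all(u <= 1 + 1e-12))
  expect_true(all(u >= min(synthetic_crosswalk()$utilities)))
  # continuous-items family switches the design encoding
  fit_c <- suppressMessages(fit_response_mapper(sc, "ols_continuous"))
  expect_equal(fit_c$spec$predictors, "items_continuous")
  expect_true(all(paste0("item_", setdiff(1:13, 7)) %in%
                    fit_c$items$mo$terms))
  # order invariance
  set.seed(42)
  perm <- sample(nrow(sc))
  scp <- sc[perm, ]
  attr(scp, "scenario") <- attr(sc, "scenario")
  fit2 <- suppressMessages(suppressWarnings(fit_response_mapper(scp, "mlogit")))
  expect_equal(fit$items$mo$coefficients, fit2$items$mo$coefficients,
               tolerance = 1e-6)
})

test_that("response fits serialize and reproduce predictions bit-for-bit", {
  sc <- scenario_fixture()
  for (fam in c("mlogit", "ologit", "ols_categorical")) {
    fit <- suppressMessages(suppressWarnings(fit_response_mapper(sc, fam)))
    path <- withr::local_tempfile(fileext = ".json")
    write_mapping_model(fit, path)
    back <- read_mapping_model(path)
    expect_identical(predict(back, sc), predict(fit, sc), info = fam)
    expect_identical(predict(back, sc, type = "modal"),
                     predict(fit, sc, type = "modal"), info = fam)
  }
})
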