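# Shared fixtures, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# toy tariff: constant 0.1, every level-2 decrement 0.05, level-3 0.2, N3 0.3
toy_tariff <- function() {
  eq5d_tariff(constant = 0.1,
              decrements = cbind(rep(0.05, 5), rep(0.2, 5)),
              level3_anywhere = 0.3, label = "toy")
}

# build a crosswalk through the CSV loader from a function of the 5 levels
make_crosswalk <- function(u_fun, label = "toy-cw") {
  g <- expand.grid(l5 = 1:5, l4 = 1:5, l3 = 1:5, l2 = 1:5, l1 = 1:5)
  m <- as.matrix(g[, 5:1])
  states <- apply(m, 1, paste0, collapse = "")
  u <- apply(m, 1, u_fun)
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(tibble::tibble(state = states,
                                  utility = sprintf("%.17g", u)), path)
  load_crosswalk(path)
}

# linear toy crosswalk: u = 1 - sum(levels)/25; 11111 -> 0.8, 55555 -> 0
toy_crosswalk <- function() make_crosswalk(function(l) 1 - sum(l) / 25)

# Printed worked examples: item responses (items 1-6, 8-13) for three
# participants whose 12-item sums are 23, 32 and 42.
table3_items <- function() {
  list(
    p1 = c(2, 2, 3, 1, 1, 1, NA, 3, 2, 1, 2, 3, 2),   # sum 23 -> 24.9
    p4 = c(2, 1, 3, 4, 2, 4, NA, 3, 3, 1, 3, 3, 3),   # sum 32 -> 34.7
    p9 = c(3, 4, 3, 4, 4, 4, NA, 4, 3, 3, 4, 3, 3)    # sum 42 -> 45.5
  )
}

# small deterministic dataset in the reader's column layout
tiny_dataset <- function(n = 6, seed = 42) {
  sim <- simulate_qolad_eq5d(sim_config(n_subjects = max(2, ceiling(n / 3)),
                                        item_missing_rate = 0,
                                        item7_missing_rate = 0, seed = seed))
  head(sim, n)
}

# cached moderate simulated dataset + scenario shared across test files
.fixture_cache <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_qolad_eq5d(sim_config(n_subjects = 150, seed = 42))
  }
  .fixture_cache$sim
}

scenario_fixture <- function() {
  if (is.null(.fixture_cache$sc)) {
    .fixture_cache$sc <- suppressMessages(
      assemble_scenario(sim_fixture(), "self", "self"))
  }
  .fixture_cache$sc
}

# random-but-reproducible scenario-shaped design for low-level model tests:
# intercept + z + age_z + male
compact_design <- function(n, seed) {
  set.seed(seed)
  cbind("(Intercept)" = 1, z = rnorm(n), age_z = rnorm(n),
        male = rbinom(n, 1, 0.45))
}

# draw ordinal responses from a ground-truth mlogit block (rows levels 2..k)
draw_mlogit <- function(X, B) {
  eta <- cbind(0, X %*% t(B))
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  u <- runif(nrow(X))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}
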