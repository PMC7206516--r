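mk_data <- function(m, lv) {
  new_discrete_dataset(m, lv)
}

test_that("family BIC matches the closed form on counted fixtures", {
  d <- mk_data(cbind(A = rep(1:2, each = 5)), list(A = c("a", "b")))
  expect_equal(family_bic("A", character(0), d),
               10 * log(0.5) - log(10) / 2, tolerance = 1e-12)
  # parent that is a copy of the node: deterministic family
  d2 <- mk_data(cbind(A = rep(1:2, 10), B = rep(1:2, 10)),
                list(A = c("a", "b"), B = c("a", "b")))
  got <- family_bic("A", "B", d2)
  expect_equal(got, 0 - (log(20) / 2) * 2 * (2 - 1), tolerance = 1e-12)
  expect_error(family_bic("A", "A", d2), "own parent")
})

test_that("family BIC equals an independent multinomial oracle", {
  oracle <- function(node, parents, d) {
    x <- as.data.frame(d$data)
    x <- x[stats::complete.cases(x[, c(node, parents)]), , drop = FALSE]
    n <- nrow(x)
    cfg <- if (length(parents))
      interaction(x[, parents, drop = FALSE], drop = TRUE)
    else factor(rep(1, n))
    tab <- table(cfg, x[[node]])
    ll <- sum(ifelse(tab > 0, tab * log(tab / rowSums(tab)[row(tab)]), 0))
    ll - (log(n) / 2) * nlevels(cfg) * (d$cards[[node]] - 1)
  }
  set.seed(13)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    m <- cbind(A = sample(1:3, n, TRUE), B = sample(1:2, n, TRUE),
               C = sample(1:2, n, TRUE))
    m[sample(length(m), 5)] <- NA
    d <- mk_data(m, list(A = paste0("a", 1:3), B = c("x", "y"),
                         C = c("u", "v")))
    pa <- list(character(0), "B", c("B", "C"))[[sample(3, 1)]]
    expect_equal(family_bic("A", pa, d), oracle("A", pa, d),
                 tolerance = 1e-9)
  }
})

test_that("network score decomposes over families and ignores column order", {
  set.seed(4)
  mod <- rand_model(c("A", "B", "C"), p = 0.8)
  d <- logic_sample(mod, 500, seed = 2)
  empty <- empty_dag(c("A", "B", "C"))
  expect_equal(bic_score(empty, d),
               sum(vapply(c("A", "B", "C"), function(v)
                 family_bic(v, character(0), d), numeric(1))))
  g <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  d_perm <- new_discrete_dataset(d$data[, c("C", "A", "B")],
                                 d$levels[c("C", "A", "B")])
  expect_equal(bic_score(g, d), bic_score(g, d_perm))
  cyc <- structure(list(nodes = c("A", "B"),
                        parents = list(A = "B", B = "A")), class = "bn_dag")
  expect_error(bic_score(cyc, d), "cyclic")
})

test_that("dependence raises the score of the true chain over the empty graph", {
  chain <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  cpts <- list(A = matrix(c(0.5, 0.5), 1),
               B = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
               C = matrix(c(0.85, 0.15, 0.15, 0.85), 2, byrow = TRUE))
  lv <- list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"))
  mod <- new_bn_model(chain, cpts, lv)
  d <- logic_sample(mod, 2000, seed = 3)
  expect_gt(bic_score(chain, d), bic_score(empty_dag(c("A", "B", "C")), d))
})

test_that("hill climbing leaves independent variables unconnected", {
  set.seed(6)
  m <- cbind(A = sample(1:2, 5000, TRUE), B = sample(1:2, 5000, TRUE),
             C = sample(1:2, 5000, TRUE))
  d <- mk_data(m, list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")))
  g <- hill_climb(d, restarts = 1, seed = 1)
  expect_lte(nrow(dag_edges(g)), 1)
})

test_that("search attains the enumeration optimum on identifiable 3-node data", {
  set.seed(17)
  mod <- rand_model(c("A", "B", "C"), p = 0.9, shape = 0.5)
  d <- logic_sample(mod, 2000, seed = 9)
  best <- max(vapply(all_dags_3(), function(g) bic_score(g, d), numeric(1)))
  hc <- hill_climb(d, restarts = 2, seed = 1)
  tb <- tabu_search(d, seed = 1)
  expect_equal(attr(hc, "score"), best, tolerance = 1e-9)
  expect_equal(attr(tb, "score"), best, tolerance = 1e-9)
  # a local optimum is a fixed point
  again <- hill_climb(d, init = hc, restarts = 0)
  expect_equal(dag_edges(again), dag_edges(hc))
  # tabu with an empty list reduces to plain hill climbing
  tb0 <- tabu_search(d, tabu_len = 0, seed = 1)
  expect_equal(attr(tb0, "score"),
               attr(hill_climb(d, restarts = 0), "score"))
})

test_that("bootstrap support is well-formed and thresholds behave", {
  set.seed(19)
  mod <- rand_model(c("A", "B", "C"), p = 0.9, shape = 0.5)
  d <- logic_sample(mod, 800, seed = 10)
  ba1 <- bootstrap_average(d, B = 1, seed = 1)
  expect_true(all(ba1$support$strength %in% c(0, 1)))
  # direction fractions of the two orientations sum to one
  if (nrow(ba1$support)) {
    agg <- tapply(ba1$support$direction,
                  paste(pmin(ba1$support$from, ba1$support$to),
                        pmax(ba1$support$from, ba1$support$to)), sum)
    expect_true(all(abs(agg - 1) < 1e-12))
  }
  ba <- bootstrap_average(d, B = 10, seed = 2, strength_threshold = 1.01)
  expect_equal(nrow(dag_edges(ba$dag)), 0)
  ba2 <- bootstrap_average(d, B = 10, seed = 3, strength_threshold = 0.5)
  expect_true(dag_is_acyclic(ba2$dag))
  expect_true(all(ba2$support$strength >= 0 & ba2$support$strength <= 1))
})
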