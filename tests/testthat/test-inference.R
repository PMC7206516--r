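det_chain <- function() {
  # A -> B, both forced: every sample is the same configuration
  new_bn_model(new_dag(c("A", "B"), rbind(c("A", "B"))),
               list(A = matrix(c(1, 0), 1),
                    B = matrix(c(0, 1, 1, 0), 2, byrow = TRUE)),
               list(A = c("a1", "a2"), B = c("b1", "b2")))
}

test_that("forward sampling respects deterministic CPTs and marginals", {
  d <- logic_sample(det_chain(), 50, seed = 1)
  expect_true(all(d$data[, "A"] == 1L & d$data[, "B"] == 2L))
  set.seed(31)
  mod <- rand_model(c("A", "B", "C", "D"), p = 0.5)
  d2 <- logic_sample(mod, 100000, seed = 2)
  for (v in mod$dag$nodes) {
    exact <- exact_posterior(mod, list(), target = v)
    emp <- tabulate(d2$data[, v], mod$cards[[v]]) / 100000
    expect_lt(max(abs(emp - unclass(exact))), 0.01)
  }
})

test_that("exact inference agrees with brute-force enumeration", {
  set.seed(37)
  for (i in 1:10) {
    mod <- rand_model(c("A", "B", "C", "D", "E"), p = 0.5)
    ev_vars <- sample(mod$dag$nodes, 2)
    target <- sample(setdiff(mod$dag$nodes, ev_vars), 1)
    ev <- lapply(stats::setNames(ev_vars, ev_vars), function(v)
      sample(mod$cards[[v]], 1))
    got <- exact_posterior(mod, ev, target)
    want <- brute_posterior(mod, ev, target)
    expect_equal(as.numeric(got), want, tolerance = 1e-9)
  }
  # independence: posterior equals prior
  ind <- new_bn_model(empty_dag(c("A", "B")),
                      list(A = matrix(c(0.3, 0.7), 1),
                           B = matrix(c(0.6, 0.4), 1)),
                      list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(as.numeric(exact_posterior(ind, list(B = 1), "A")),
               c(0.3, 0.7))
  # textbook Bayes inversion on a 2-node chain
  chain <- new_bn_model(new_dag(c("A", "B"), rbind(c("A", "B"))),
                        list(A = matrix(c(0.2, 0.8), 1),
                             B = matrix(c(0.9, 0.1, 0.3, 0.7), 2,
                                        byrow = TRUE)),
                        list(A = c("a1", "a2"), B = c("b1", "b2")))
  post <- exact_posterior(chain, list(B = 1), "A")
  expect_equal(as.numeric(post),
               c(0.2 * 0.9, 0.8 * 0.3) / (0.2 * 0.9 + 0.8 * 0.3),
               tolerance = 1e-12)
})

test_that("observed mediators block upstream evidence (d-separation)", {
  gt <- default_ground_truth()
  base <- exact_posterior(gt$model, list(VRd = 2))
  plus <- exact_posterior(gt$model, list(VRd = 2, SIM = 1, BNT30 = 4))
  expect_lt(max(abs(unclass(base) - unclass(plus))), 1e-12)
})

test_that("likelihood weighting converges to the exact posterior", {
  chain <- new_bn_model(new_dag(c("A", "Status"), rbind(c("A", "Status"))),
                        list(A = matrix(c(0.3, 0.7), 1),
                             Status = matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                             byrow = TRUE)),
                        list(A = c("a1", "a2"), Status = c("HC", "AD")))
  lw <- likelihood_weighting(chain, list(A = 2), "Status",
                             n_samples = 50000, seed = 3)
  expect_equal(as.numeric(lw), c(0.2, 0.8), tolerance = 0.01)
  # evidence on the full test battery of a planted 12-node model
  gt <- default_ground_truth()
  set.seed(41)
  tvs <- vapply(1:3, function(i) {
    row <- logic_sample(gt$model, 1, seed = 100 + i)$data[1, ]
    ev <- as.list(row[np_test_names()])
    exact <- exact_posterior(gt$model, ev)
    approx <- likelihood_weighting(gt$model, ev, n_samples = 50000,
                                   seed = 200 + i)
    tv_dist(exact, approx)
  }, numeric(1))
  expect_lt(max(tvs), 0.02)
  expect_error(likelihood_weighting(det_chain(), list(B = 1), "A",
                                    n_samples = 100, seed = 1),
               "impossible evidence")
})

test_that("empty evidence reproduces the marginal and repeats average", {
  gt <- default_ground_truth()
  lw <- averaged_inference(gt$model, list(), repeats = 10,
                           n_samples = 5000, seed = 5)
  expect_lt(tv_dist(lw, gt$group_proportions), 0.02)
  one_a <- averaged_inference(gt$model, list(LMi = 1), repeats = 1,
                              n_samples = 2000, seed = 9)
  one_b <- likelihood_weighting(gt$model, list(LMi = 1),
                                n_samples = 2000, seed = 9)
  expect_equal(unclass(one_a), unclass(one_b), tolerance = 1e-12,
               ignore_attr = TRUE)
  # averaging reduces the spread of the estimate across master seeds
  ev <- list(VRd = 1, LMi = 1)
  single <- vapply(1:15, function(s)
    unclass(likelihood_weighting(gt$model, ev, n_samples = 500,
                                 seed = s))[["AD"]], numeric(1))
  avg <- vapply(1:15, function(s)
    unclass(averaged_inference(gt$model, ev, repeats = 20, n_samples = 500,
                               seed = s))[["AD"]], numeric(1))
  expect_lt(stats::sd(avg), stats::sd(single))
})

test_that("sampling error halves when the sample count quadruples", {
  gt <- default_ground_truth()
  ev <- list(LMi = 2, VRr = 1)
  exact <- exact_posterior(gt$model, ev)
  tv_at <- function(n) mean(vapply(1:20, function(s)
    tv_dist(likelihood_weighting(gt$model, ev, n_samples = n, seed = s),
            exact), numeric(1)))
  ratio <- tv_at(2000) / tv_at(500)
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.75)
})

test_that("status prediction takes the posterior argmax with HC-first ties", {
  gt <- default_ground_truth()
  set.seed(43)
  d <- logic_sample(gt$model, 30, seed = 11)
  agree <- vapply(1:30, function(i) {
    ev <- as.list(d$data[i, np_test_names()])
    pred <- predict_status(gt$model, ev, settings = list(method = "exact"))
    exact <- exact_posterior(gt$model, ev)
    as.character(pred) == names(exact)[which.max(unclass(exact))]
  }, logical(1))
  expect_true(all(agree))
  # uniform posterior: tie resolved to HC and flagged
  unif <- new_bn_model(empty_dag("Status"),
                       list(Status = matrix(rep(1 / 3, 3), 1)),
                       list(Status = status_levels()))
  pred <- predict_status(unif, list(), settings = list(method = "exact"))
  expect_equal(as.character(pred), "HC")
  expect_true(attr(pred, "tie"))
})

test_that("round trip: sampling then MLE recovers the planted parameters", {
  set.seed(47)
  mod <- rand_model(c("A", "B", "C"), p = 0.7)
  d <- logic_sample(mod, 100000, seed = 13)
  fit <- fit_mle(mod$dag, d)
  err <- max(vapply(mod$dag$nodes, function(v)
    max(abs(fit$cpts[[v]] - mod$cpts[[v]])), numeric(1)))
  expect_lt(err, 0.02)
})
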