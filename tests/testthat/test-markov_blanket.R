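test_that("stratified chi-square matches hand computation and collapses df", {
  # 2x2 table 50/0/0/50: X^2 = 100, df = 1
  d <- new_discrete_dataset(cbind(x = rep(1:2, each = 50),
                                  y = rep(1:2, each = 50)),
                            list(x = c("x1", "x2"), y = c("y1", "y2")))
  res <- chi2_ci_test("x", "y", character(0), d)
  expect_equal(unname(res["statistic"]), 100)
  expect_equal(unname(res["df"]), 1)
  expect_lt(unname(res["p"]), 1e-20)
  # y deterministic copy of z: conditioning on z empties every stratum
  set.seed(3)
  z <- sample.int(3, 2000, replace = TRUE)
  d2 <- new_discrete_dataset(cbind(x = sample.int(3, 2000, TRUE), y = z,
                                   z = z),
                             list(x = paste0("x", 1:3),
                                  y = paste0("y", 1:3),
                                  z = paste0("z", 1:3)))
  res2 <- chi2_ci_test("x", "y", "z", d2)
  expect_equal(unname(res2["df"]), 0)
  expect_equal(unname(res2["p"]), 1)
  expect_error(chi2_ci_test("x", "x", character(0), d2), "degenerate")
})

test_that("df adjustment never exceeds the unadjusted degrees of freedom", {
  set.seed(5)
  for (i in 1:10) {
    n <- 200
    m <- cbind(x = sample.int(4, n, TRUE), y = sample.int(3, n, TRUE),
               z = sample.int(3, n, TRUE))
    d <- new_discrete_dataset(m, list(x = paste0("x", 1:4),
                                      y = paste0("y", 1:3),
                                      z = paste0("z", 1:3)))
    res <- chi2_ci_test("x", "y", "z", d)
    expect_lte(unname(res["df"]), (4 - 1) * (3 - 1) * 3)
  }
})

test_that("chi-square test holds its nominal size on independent pairs", {
  set.seed(7)
  rej <- 0
  for (i in 1:100) {
    d <- new_discrete_dataset(
      cbind(x = sample.int(4, 4000, TRUE), y = sample.int(3, 4000, TRUE)),
      list(x = paste0("x", 1:4), y = paste0("y", 1:3)))
    if (chi2_ci_test("x", "y", character(0), d)["p"] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 100, 0.005)
  expect_lte(rej / 100, 0.12)
})

test_that("the blanket is sufficient for the status posterior", {
  gt <- default_ground_truth()
  suff <- blanket_sufficiency(gt$model, n_rows = 40, seed = 11)
  expect_lt(suff$max_tv, 1e-9)
  # a model whose blanket is everything: distance identically 0
  nodes <- c("Status", "LMi", "VRd", "SIM")
  star <- new_dag(nodes, cbind("Status", c("LMi", "VRd", "SIM")))
  cpts <- list(Status = matrix(c(0.7, 0.2, 0.1), 1),
               LMi = matrix(c(0.8, 0.2, 0.5, 0.2, 0.8, 0.5), 3, 2),
               VRd = matrix(c(0.9, 0.5, 0.2, 0.1, 0.5, 0.8), 3, 2),
               SIM = matrix(c(0.6, 0.4, 0.3, 0.4, 0.6, 0.7), 3, 2))
  lv <- list(Status = status_levels(), LMi = c("lo", "hi"),
             VRd = c("lo", "hi"), SIM = c("lo", "hi"))
  m <- new_bn_model(star, cpts, lv)
  suff2 <- blanket_sufficiency(m, n_rows = 25, seed = 13)
  expect_lt(suff2$max_tv, 1e-12)
  # a truncated non-blanket subset loses information
  trunc <- blanket_sufficiency(m, n_rows = 25, subset = "SIM", seed = 13)
  expect_gt(trunc$max_tv, suff2$max_tv)
})

test_that("blanket report combines structure with the independence screen", {
  gt <- default_ground_truth(missing_rate = 0)
  co <- sample_cohort(gt, 1500, seed = 17)
  disc <- apply_discretization(co[, c(np_test_names(), "Status")], gt$bins)
  rep <- blanket_report(gt$model$dag, disc)
  expect_setequal(rep$blanket$blanket, c("VRd", "LMi", "PASi", "VRr"))
  marg <- rep$ci_tests[rep$ci_tests$condition == "none", ]
  # unconditionally, every test associates with status
  expect_lt(max(marg$p[marg$test %in% c("LMi", "VRd", "PASi")]), 1e-6)
})
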