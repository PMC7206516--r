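test_that("PAM recovers exact medoids on separable fixtures", {
  res <- pam_1d(rep(0:4, each = 2), k = 5)
  expect_equal(res$medoids, 0:4)
  expect_equal(res$cost, 0)
  res2 <- pam_1d(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(res2$medoids, c(2, 11))
  expect_error(pam_1d(c(1, 1, 2), k = 3), "infeasible k")
  expect_error(pam_1d(c(1, NA), k = 1), "missing")
})

test_that("PAM matches exhaustive search on clusterable small fixtures", {
  # fixtures with separated modes, where the swap neighbourhood reaches the
  # global optimum; arbitrary fixtures are covered by the local-optimality
  # property below
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:3, 1)
    centers <- cumsum(c(sample(0:4, 1), stats::runif(k - 1, 10, 15)))
    vals <- unlist(lapply(centers, function(cc)
      cc + (if (stats::runif(1) < 0.4) 0 else c(0, 0.5, 1))))
    got <- pam_1d(vals, k)
    want <- brute_pam(vals, k)
    expect_equal(got$cost, want$cost, tolerance = 1e-9)
    expect_equal(got$medoids, want$medoids)
  }
})

test_that("PAM results are locally optimal under single swaps", {
  set.seed(3)
  vals <- sample(0:30, 40, replace = TRUE)
  res <- pam_1d(vals, 4)
  u <- sort(unique(vals))
  cost_of <- function(med) sum(vapply(vals, function(x)
    min(abs(x - med)), numeric(1)))
  for (m in res$medoids) {
    for (j in setdiff(u, res$medoids)) {
      expect_gte(cost_of(c(setdiff(res$medoids, m), j)) + 1e-9, res$cost)
    }
  }
})

test_that("silhouette matches the direct formula and its bounds", {
  # hand-enumerable case {1,2} vs {3,4}
  s <- silhouette_width(c(1, 2, 3, 4), c(1, 1, 2, 2))
  expect_equal(s, ((2.5 - 1) / 2.5 + (1.5 - 1) / 1.5) / 2, tolerance = 1e-12)
  expect_gt(silhouette_width(c(0, 0.1, 100, 100.1), c(1, 1, 2, 2)), 0.99)
  set.seed(21)
  for (i in 1:10) {
    vals <- stats::rnorm(30)
    cl <- sample(1:3, 30, replace = TRUE)
    if (length(unique(cl)) < 2) next
    sw <- silhouette_width(vals, cl)
    expect_equal(sw, brute_silhouette(vals, cl), tolerance = 1e-9)
    expect_true(sw >= -1 && sw <= 1)
  }
  expect_error(silhouette_width(1:5, rep(1, 5)), "single cluster")
})

test_that("interval fitting picks silhouette-optimal k and tight intervals", {
  x <- data.frame(VRr = rep(0:4, times = c(50, 40, 60, 45, 55)))
  m <- fit_discretization(x, k_max = 10)
  expect_equal(unname(m$k["VRr"]), 5L)
  expect_equal(m$intervals$VRr, cbind(lo = as.numeric(0:4),
                                      hi = as.numeric(0:4)))
  m2 <- fit_discretization(data.frame(VRd = rep(c(0, 10), each = 15)))
  expect_equal(unname(m2$k["VRd"]), 2L)
  expect_equal(m2$intervals$VRd, cbind(lo = c(0, 10), hi = c(0, 10)))
  expect_error(fit_discretization(data.frame(SIM = rep(3, 10))),
               "degenerate variable SIM")
})

test_that("chosen k matches a brute-force silhouette scan and shift invariance", {
  set.seed(9)
  x <- c(round(stats::rnorm(80, 5, 1)), round(stats::rnorm(80, 15, 1)))
  x <- pmax(x, 0)
  m <- fit_discretization(data.frame(SIM = x), k_max = 8)
  ks <- 2:8
  sw <- vapply(ks, function(k)
    brute_silhouette(x, pam_1d(x, k)$assignment), numeric(1))
  expect_equal(unname(m$k["SIM"]), ks[which.max(sw)])
  m_shift <- fit_discretization(data.frame(SIM = x + 4), k_max = 8)
  expect_equal(unname(m_shift$k["SIM"]), unname(m$k["SIM"]))
})

test_that("score-to-bin mapping is total on the grid and strict off it", {
  ref <- reference_discretization()
  tab <- data.frame(LMr = c(11, 0, NA, 5), Status = c("HC", "AD", "NAD", "HC"))
  d <- apply_discretization(tab, ref)
  expect_equal(unname(d$data[, "LMr"]), c(10L, 1L, NA, 4L))
  expect_equal(unname(d$data[, "Status"]), c(1L, 2L, 3L, 1L))
  # every in-range grid value lands in exactly one bin
  for (v in names(ref$intervals)) {
    iv <- ref$intervals[[v]]
    g <- seq(min(iv[, "lo"]), max(iv[, "hi"]), by = ref$step[[v]])
    hits <- vapply(g, function(x)
      sum(x >= iv[, "lo"] & x <= iv[, "hi"]), numeric(1))
    expect_true(all(hits == 1))
  }
  expect_error(apply_discretization(data.frame(LMr = 99), ref),
               "out of range for LMr")
  # clamp mode sends off-grid values to the nearest interval
  gap <- structure(list(intervals = list(VRd = cbind(lo = c(0, 10),
                                                     hi = c(0, 10))),
                        k = c(VRd = 2L), silhouette = c(VRd = NA_real_),
                        step = c(VRd = 1)), class = "np_discretization")
  d2 <- apply_discretization(data.frame(VRd = c(2, 9)), gap,
                             out_of_range = "clamp")
  expect_equal(unname(d2$data[, "VRd"]), c(1L, 2L))
})
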