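test_that("confusion metrics match hand arithmetic on a fixed matrix", {
  # truth HC: 3259 predicted HC, 255 predicted dementia;
  # truth dementia: 361 predicted HC, 637 predicted dementia
  truths <- c(rep("HC", 3514), rep("AD", 998))
  preds <- c(rep("HC", 3259), rep("AD", 255), rep("HC", 361), rep("AD", 637))
  m <- confusion_metrics(preds, truths)
  expect_equal(m$sensitivity, 637 / 998, tolerance = 1e-12)
  expect_equal(m$specificity, 3259 / 3514, tolerance = 1e-12)
  expect_equal(m$accuracy, (3259 + 637) / 4512, tolerance = 1e-12)
  # metrics invariant to permuting the (prediction, truth) pairs
  set.seed(3)
  ord <- sample(length(truths))
  m2 <- confusion_metrics(preds[ord], truths[ord])
  expect_equal(m2$sensitivity, m$sensitivity)
  expect_equal(m2$accuracy, m$accuracy)
})

test_that("degenerate confusion cases are reported, not crashed", {
  m <- confusion_metrics(rep("HC", 5), rep("HC", 5))
  expect_equal(m$accuracy, 1)
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$sensitivity))
  expect_error(confusion_metrics("XX", "HC"), "labels")
  # perfect prediction
  p <- c("HC", "AD", "NAD", "AD")
  mp <- confusion_metrics(p, p)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$specificity, 1)
  # AD-positive binarization counts NAD as negative
  m_ad <- confusion_metrics(c("AD", "AD", "HC"), c("AD", "NAD", "NAD"),
                            binarization = "ad")
  expect_equal(m_ad$sensitivity, 1)
  expect_equal(m_ad$specificity, 0.5)
})

test_that("cross-validation predicts every row once and beats the base rate", {
  gt <- default_ground_truth()
  co <- sample_cohort(gt, 900, seed = 21)
  cfg <- pipeline_config(B = 5, folds = 5, repeats = 5, n_samples = 300)
  cv <- cross_validate(co, cfg, seed = 22)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(length(cv$predictions), nrow(co))
  expect_true(all(cv$predictions %in% status_levels()))
  expect_equal(sum(cv$confusion), nrow(co))
  expect_gt(cv$accuracy, max(table(co$Status)) / nrow(co))
  expect_error(cross_validate(co[1:30, ], cfg),
               "at least")
})

test_that("participant grouping keeps exams of one person in one fold", {
  gt <- default_ground_truth()
  co <- sample_cohort(gt, 700, seed = 23)
  cfg <- pipeline_config(B = 3, folds = 4, repeats = 3, n_samples = 200,
                         group_by_participant = TRUE)
  cv <- cross_validate(co, cfg, seed = 24)
  folds_per_pid <- tapply(cv$fold, co$participant_id,
                          function(f) length(unique(f)))
  expect_true(all(folds_per_pid == 1))
})

test_that("stratified analysis partitions rows and reports exclusions", {
  gt <- default_ground_truth()
  co <- sample_cohort(gt, 1600, seed = 25)
  cfg <- pipeline_config(B = 5, folds = 5, repeats = 3, n_samples = 200)
  res <- stratified_networks(co, "sex", cfg, seed = 26)
  expect_setequal(names(res$results), c("F", "M"))
  ns <- vapply(res$results, `[[`, numeric(1), "n")
  expect_equal(sum(ns) + res$excluded, nrow(co))
  for (r in res$results) {
    expect_false(r$skipped)
    expect_true(dag_is_acyclic(r$dag))
    # both strata share the generative model: skeletons should broadly agree
  }
  skel <- function(g) {
    e <- dag_edges(g)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  s1 <- skel(res$results$F$dag); s2 <- skel(res$results$M$dag)
  expect_gt(length(intersect(s1, s2)) / max(length(s1), length(s2)), 0.5)
  # fully missing stratifier: everything excluded
  co2 <- co
  co2$education <- NA
  res2 <- stratified_networks(co2, "education", cfg, seed = 27)
  expect_equal(res2$excluded, nrow(co))
  expect_length(res2$results, 0)
})
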