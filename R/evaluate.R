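#' Diagnostic classification metrics
#'
#' Builds the 3x3 confusion matrix over `{HC, AD, NAD}`, the 3-class
#' accuracy (trace over total), and the binary dementia-vs-healthy
#' collapse: positives are the dementia states (`AD` and `NAD` by default,
#' `AD` alone under `binarization = "ad"`), negatives the rest, giving
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`. An empty positive
#' (or negative) class yields `NA` for the corresponding rate.
#'
#' @param predictions,truths equal-length vectors of status labels.
#' @param binarization `"dementia"` (AD or NAD positive) or `"ad"` (AD
#'   positive, HC and NAD negative).
#' @return list with `confusion`, `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predictions, truths,
                              binarization = c("dementia", "ad")) {
  binarization <- match.arg(binarization)
  lv <- status_levels()
  if (length(predictions) != length(truths)) stop("length mismatch")
  if (!all(predictions %in% lv) || !all(truths %in% lv)) {
    stop("labels must be one of ", paste(lv, collapse = ", "))
  }
  conf <- table(truth = factor(truths, lv), prediction = factor(predictions, lv))
  pos <- if (binarization == "dementia") c("AD", "NAD") else "AD"
  tp <- sum(conf[pos, pos]); fn <- sum(conf[pos, setdiff(lv, pos)])
  tn <- sum(conf[setdiff(lv, pos), setdiff(lv, pos)])
  fp <- sum(conf[setdiff(lv, pos), pos])
  list(confusion = conf,
       accuracy = sum(diag(conf)) / sum(conf),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Pipeline configuration
#'
#' Bundles the tunable settings of the discretization / structure /
#' parameter / inference / cross-validation stages with defaults sized for
#' a cohort of a few thousand examinations.
#'
#' @param k_max maximum intervals per test.
#' @param disc_scope `"fold"` refits the discretization inside every
#'   training fold (leakage-safe default); `"global"` fits once on all rows
#'   before splitting.
#' @param score,iss network score and BDeu/Bayes imaginary sample size.
#' @param B,strength_threshold bootstrap replicates and edge-strength
#'   cutoff for model averaging.
#' @param restarts hill-climbing restarts inside the bootstrap.
#' @param estimator `"bayes"` (default; strictly positive CPTs) or `"mle"`.
#' @param n_samples,repeats likelihood-weighting samples per repeat and
#'   repeat count used per prediction.
#' @param folds CV folds.
#' @param binarization see [confusion_metrics()].
#' @param group_by_participant keep all of a participant's exams in one
#'   fold.
#' @return list of class `np_config`.
#' @export
pipeline_config <- function(k_max = 10, disc_scope = c("fold", "global"),
                            score = "bic", iss = 1, B = 25,
                            strength_threshold = 0.5, restarts = 0,
                            estimator = c("bayes", "mle"),
                            n_samples = 1000, repeats = 20, folds = 10,
                            binarization = c("dementia", "ad"),
                            group_by_participant = FALSE) {
  structure(list(
    k_max = k_max, disc_scope = match.arg(disc_scope), score = score,
    iss = iss, B = B, strength_threshold = strength_threshold,
    restarts = restarts, estimator = match.arg(estimator),
    n_samples = n_samples, repeats = repeats, folds = folds,
    binarization = match.arg(binarization),
    group_by_participant = group_by_participant
  ), class = "np_config")
}

fit_estimator <- function(dag, dataset, config) {
  if (config$estimator == "mle") fit_mle(dag, dataset)
  else fit_bayes(dag, dataset, iss = config$iss)
}

# learn an averaged structure + parameters on (already discretized) data
learn_stage <- function(disc, config, seed) {
  ba <- bootstrap_average(disc, learner = hill_climb, B = config$B,
                          strength_threshold = config$strength_threshold,
                          seed = seed, restarts = config$restarts,
                          score = config$score)
  model <- fit_estimator(ba$dag, disc, config)
  list(support = ba$support, dag = ba$dag, model = model)
}

#' Cross-validated diagnostic performance
#'
#' Stratified-by-status k-fold cross-validation of the full pipeline:
#' within each training fold the discretization is (optionally) refitted,
#' an averaged structure is learned by bootstrapped hill-climbing, CPTs are
#' estimated, and every held-out examination's status is predicted by
#' averaged likelihood weighting from its observed (non-missing) test
#' scores. Folds partition the examination rows; every row is predicted
#' exactly once.
#'
#' @param table an `np_cohort` data.frame (or any cohort table with the
#'   test columns and `Status`).
#' @param config an [pipeline_config()] list.
#' @param seed integer master seed; fold assignment, per-fold learning and
#'   per-row inference seeds all derive from it.
#' @return object of class `np_cv_report`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `folds` (per-fold details), `config`.
#' @export
cross_validate <- function(table, config = pipeline_config(), seed = 1) {
  st <- factor(table$Status, levels = status_levels())
  if (any(base::table(st) < config$folds)) {
    stop("every status class needs at least ", config$folds, " rows")
  }
  set.seed(seed)
  n <- nrow(table)
  fold <- integer(n)
  if (config$group_by_participant && "participant_id" %in% colnames(table)) {
    pid <- table$participant_id
    u <- unique(pid)
    pf <- sample(rep_len(seq_len(config$folds), length(u)))
    fold <- pf[match(pid, u)]
  } else {
    for (s in levels(st)) {
      idx <- which(st == s)
      fold[idx] <- sample(rep_len(seq_len(config$folds), length(idx)))
    }
  }
  global_map <- if (config$disc_scope == "global") {
    fit_discretization(table, k_max = config$k_max)
  }
  preds <- character(n)
  fold_info <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    map <- global_map %||% fit_discretization(train, k_max = config$k_max)
    disc_train <- apply_discretization(train, map)
    stage <- learn_stage(disc_train, config, seed = seed * 1000 + f)
    disc_test <- apply_discretization(test, map, out_of_range = "clamp")
    tests <- setdiff(colnames(disc_test$data), "Status")
    set.seed(seed * 1000 + 500 + f)
    p <- vapply(seq_len(nrow(test)), function(i) {
      row <- disc_test$data[i, tests]
      ev <- as.list(row[!is.na(row)])
      as.character(predict_status(stage$model, ev, settings = list(
        repeats = config$repeats, n_samples = config$n_samples)))
    }, character(1))
    preds[fold == f] <- p
    fold_info[[f]] <- list(dag = stage$dag, seed = seed * 1000 + f,
                           n_train = nrow(train), n_test = nrow(test))
  }
  metrics <- confusion_metrics(preds, as.character(st),
                               binarization = config$binarization)
  structure(c(metrics,
              list(predictions = preds, fold = fold, folds = fold_info,
                   config = config, seed = seed)),
            class = "np_cv_report")
}

#' @export
print.np_cv_report <- function(x, ...) {
  cat("Cross-validated diagnosis (", length(x$folds), " folds)\n", sep = "")
  print(x$confusion)
  cat(sprintf("accuracy %.4f | sensitivity %.4f | specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Stratified network analyses
#'
#' Splits the cohort by a covariate (`sex`, `apoe4` or `education`), drops
#' rows with a missing stratifier (counts reported), and runs the full
#' discretize / learn / blanket / cross-validate pipeline inside each
#' stratum, enabling side-by-side comparison of the learned hierarchies and
#' of the status node's most upstream ancestors (first precursors).
#'
#' @param table cohort data.frame.
#' @param strata one of `"sex"`, `"apoe4"`, `"education"`.
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param run_cv also cross-validate within each stratum (slower).
#' @return list of class `np_stratified`: per-stratum results (`dag`,
#'   `support`, `blanket`, optional `cv`, `n`), plus `excluded` (rows
#'   dropped for missing stratifier) and skipped strata with reasons.
#' @export
stratified_networks <- function(table, strata = c("sex", "apoe4", "education"),
                                config = pipeline_config(), seed = 1,
                                run_cv = FALSE) {
  strata <- match.arg(strata)
  if (!strata %in% colnames(table)) stop("stratifier column missing")
  miss <- is.na(table[[strata]])
  kept <- table[!miss, , drop = FALSE]
  out <- list()
  for (lv in sort(unique(as.character(kept[[strata]])))) {
    sub <- kept[kept[[strata]] == lv, , drop = FALSE]
    counts <- base::table(factor(sub$Status, status_levels()))
    if (any(counts < config$folds) || nrow(sub) < 50) {
      out[[lv]] <- list(skipped = TRUE,
                        reason = "insufficient rows in stratum",
                        n = nrow(sub))
      next
    }
    map <- fit_discretization(sub, k_max = config$k_max)
    disc <- apply_discretization(sub, map)
    stage <- learn_stage(disc, config, seed = seed * 100 + nchar(lv))
    res <- list(skipped = FALSE, n = nrow(sub), map = map,
                dag = stage$dag, support = stage$support,
                blanket = blanket_report(stage$dag, disc),
                first_precursors = first_precursors(stage$dag, "Status"))
    if (run_cv) res$cv <- cross_validate(sub, config, seed = seed)
    out[[lv]] <- res
  }
  structure(list(strata = strata, results = out, excluded = sum(miss)),
            class = "np_stratified")
}

# most upstream ancestors of the target: ancestors with no parents
first_precursors <- function(dag, target) {
  adj <- dag_adjacency(dag)
  reach <- transitive_closure(adj)
  anc <- dag$nodes[reach[, target] > 0]
  anc[vapply(anc, function(v) length(dag$parents[[v]]) == 0, logical(1))]
}

#' @export
print.np_stratified <- function(x, ...) {
  cat("Stratified analysis by", x$strata, "(", x$excluded,
      "rows excluded for missing stratifier )\n")
  for (lv in names(x$results)) {
    r <- x$results[[lv]]
    if (isTRUE(r$skipped)) {
      cat("  ", lv, ": skipped (", r$reason, ")\n")
    } else {
      cat("  ", lv, ": n =", r$n, "| first precursors:",
          paste(r$first_precursors, collapse = ", "), "\n")
    }
  }
  invisible(x)
}
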