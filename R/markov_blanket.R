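#' Conditional-independence test with adjusted degrees of freedom
#'
#' Pearson chi-square test of `x` against `y` stratified by the joint
#' states of `z_set`: the statistic is the sum over strata of each
#' stratum's `x` by `y` Pearson X^2, and the degrees of freedom are
#' adjusted for sparse tables by counting, within each stratum, only the
#' non-empty rows and columns: `df = sum over strata of
#' (r_x* - 1)(r_y* - 1)` (empty strata contribute nothing). When
#' conditioning collapses every stratum to a single occupied row or column
#' the df reach 0 and the p-value is reported as 1 -- the behaviour that
#' makes near-deterministic mediators show p ~ 1.
#'
#' @param x,y column names of a `bn_discrete` (distinct).
#' @param z_set character vector of conditioning columns (may be empty).
#' @param dataset a `bn_discrete`; rows incomplete on `{x, y} U z_set` are
#'   dropped.
#' @return named numeric vector `c(statistic, df, p)`.
#' @export
chi2_ci_test <- function(x, y, z_set = character(0), dataset) {
  if (identical(x, y)) stop("degenerate test: x and y are identical")
  vars <- c(x, y, z_set)
  cn <- colnames(dataset$data)
  if (!all(vars %in% cn)) stop("unknown test variables")
  keep <- complete_rows(dataset, vars)
  if (!any(keep)) stop("no complete cases on the test variables")
  d <- dataset$data[keep, , drop = FALSE]
  strata <- if (length(z_set)) {
    parent_config_code(d[, z_set, drop = FALSE], dataset$cards[z_set])
  } else rep(1L, nrow(d))
  stat <- 0; df <- 0
  for (s in unique(strata)) {
    sel <- strata == s
    tab <- table(d[sel, x], d[sel, y])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    rx <- nrow(tab); ry <- ncol(tab)
    if (rx < 2 || ry < 2) next
    ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- stat + sum((tab - ex)^2 / ex)
    df <- df + (rx - 1) * (ry - 1)
  }
  p <- if (df <= 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  c(statistic = stat, df = df, p = p)
}

#' Markov-blanket report for the status node
#'
#' Combines the structural blanket (parents, children, spouses of the
#' target in a DAG) with a conditional-independence screen: for each test
#' outside the condition set, the adjusted-df chi-square association of the
#' test with the target conditional on each condition set.
#'
#' @param dag a `bn_dag` (typically a learned or averaged structure).
#' @param dataset a `bn_discrete` with the target and test columns.
#' @param target target node (default `"Status"`).
#' @param condition_sets list of character vectors of conditioning
#'   variables; the default menu is the empty set, each of the target's
#'   canonical first-level correlates `VRd` and `LMi`, and both together.
#' @return object of class `bn_blanket_report`: the `bn_blanket`, plus a
#'   data.frame `ci_tests` (`test`, `condition`, `statistic`, `df`, `p`).
#' @export
blanket_report <- function(dag, dataset, target = "Status",
                           condition_sets = list(character(0), "VRd", "LMi",
                                                 c("VRd", "LMi"))) {
  bl <- markov_blanket(dag, target)
  tests <- setdiff(colnames(dataset$data), target)
  rows <- list()
  for (zs in condition_sets) {
    for (te in setdiff(tests, zs)) {
      res <- chi2_ci_test(te, target, zs, dataset)
      rows[[length(rows) + 1]] <- data.frame(
        test = te,
        condition = if (length(zs)) paste(zs, collapse = "+") else "none",
        statistic = res[["statistic"]], df = res[["df"]], p = res[["p"]],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(blanket = bl, ci_tests = do.call(rbind, rows)),
            class = "bn_blanket_report")
}

#' @export
print.bn_blanket_report <- function(x, ...) {
  print(x$blanket)
  cat("\nConditional-independence screen:\n")
  print(x$ci_tests, digits = 3)
  invisible(x)
}

#' Does the blanket carry all diagnostic information?
#'
#' Compares, over sampled evidence configurations, the exact posterior of
#' the target given all other variables against the exact posterior given
#' only the target's Markov blanket. Under the model's own structure the
#' two are equal by d-separation, so the distance is a numerical check; for
#' a deliberately truncated non-blanket subset it quantifies the
#' information lost.
#'
#' @param model a `bn_model`.
#' @param dataset optional `bn_discrete` supplying evidence rows; when
#'   `NULL`, `n_rows` configurations are forward-sampled from the model.
#' @param n_rows number of evidence configurations evaluated.
#' @param target target node.
#' @param subset optional character vector overriding the blanket (to probe
#'   non-blanket subsets).
#' @param seed integer seed for the sampled evidence rows.
#' @return list with `max_tv` (maximum total-variation distance), `mean_tv`
#'   and the `blanket` used.
#' @export
blanket_sufficiency <- function(model, dataset = NULL, n_rows = 200,
                                target = "Status", subset = NULL,
                                seed = NULL) {
  blanket <- subset %||% markov_blanket(model$dag, target)$blanket
  if (is.null(dataset)) {
    dataset <- logic_sample(model, n_rows, seed = seed)
  }
  keep <- which(complete_rows(dataset))
  keep <- keep[seq_len(min(n_rows, length(keep)))]
  others <- setdiff(model$dag$nodes, target)
  tv <- vapply(keep, function(i) {
    row <- dataset$data[i, ]
    ev_all <- as.list(row[others])
    ev_blk <- as.list(row[blanket])
    p_all <- exact_posterior(model, ev_all, target)
    p_blk <- exact_posterior(model, ev_blk, target)
    0.5 * sum(abs(unclass(p_all) - unclass(p_blk)))
  }, numeric(1))
  list(max_tv = max(tv), mean_tv = mean(tv), blanket = blanket,
       n_rows = length(keep))
}
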