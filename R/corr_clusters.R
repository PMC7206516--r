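#' Pairwise correlations between NP tests
#'
#' Pearson product-moment correlations on raw scores, pairwise-complete
#' observations, with the per-pair sample size. An optional chi-square
#' independence test on the discretized pair is reported alongside when a
#' discretization map is supplied.
#'
#' @param table a cohort data.frame with the NP test columns.
#' @param variables which test columns to correlate.
#' @param map optional `np_discretization`; when given, a Pearson chi-square
#'   independence test of each binned pair is added to the report.
#' @return an object of class `np_correlation`: `r` (correlation matrix),
#'   `n` (pairwise-complete counts), optional `chisq_p`.
#' @export
correlation_matrix <- function(table,
                               variables = intersect(np_test_names(),
                                                     colnames(table)),
                               map = NULL) {
  x <- as.matrix(table[, variables, drop = FALSE])
  n <- crossprod(!is.na(x))
  if (any(n[upper.tri(n)] < 3)) {
    bad <- which(n < 3 & upper.tri(n), arr.ind = TRUE)[1, ]
    stop("insufficient pairwise-complete data for ",
         variables[bad[1]], " vs ", variables[bad[2]])
  }
  r <- stats::cor(x, use = "pairwise.complete.obs", method = "pearson")
  chisq_p <- NULL
  if (!is.null(map)) {
    disc <- apply_discretization(table, map, out_of_range = "clamp")
    chisq_p <- matrix(NA_real_, length(variables), length(variables),
                      dimnames = list(variables, variables))
    for (i in seq_along(variables)) for (j in seq_along(variables)) {
      if (i < j) {
        res <- chi2_ci_test(variables[i], variables[j], character(0), disc)
        chisq_p[i, j] <- chisq_p[j, i] <- res["p"]
      }
    }
  }
  structure(list(r = r, n = n, chisq_p = chisq_p),
            class = "np_correlation")
}

#' @export
print.np_correlation <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (", ncol(x$r), " tests)\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Cognitive-function clusters from a correlation matrix
#'
#' Thresholds the correlation matrix at `cutoff` and returns the connected
#' components of the resulting graph: two tests share a cluster exactly when
#' a chain of pairwise correlations at or above the cutoff links them.
#' Raising the cutoff can only refine the partition. Singleton clusters are
#' allowed.
#'
#' @param corr an `np_correlation` or a plain correlation matrix.
#' @param cutoff correlation threshold (default 0.6).
#' @param use_abs threshold `|r|` instead of `r` (default `FALSE`; the
#'   battery's inter-test correlations are positive).
#' @return list of character vectors, one per cluster, ordered by first
#'   member.
#' @export
extract_clusters <- function(corr, cutoff = 0.6, use_abs = FALSE) {
  r <- if (inherits(corr, "np_correlation")) corr$r else as.matrix(corr)
  if (use_abs) r <- abs(r)
  adj <- r >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(colnames(r), comp))
}

#' Association of each NP test with cognitive status
#'
#' One-way analysis of variance of each raw score across the three status
#' groups, with Bonferroni adjustment over the tests analysed, plus
#' Tukey-Kramer studentized-range pairwise comparisons (valid under unequal
#' group sizes).
#'
#' @param table cohort data.frame with test columns and `Status`.
#' @param variables test columns to analyse; the Bonferroni factor equals
#'   their number.
#' @return an object of class `np_status_association`: data.frame `anova`
#'   (`test`, `F`, `p`, `p_bonferroni`) and list `tukey` of pairwise
#'   comparison tables.
#' @export
status_association <- function(table,
                               variables = intersect(np_test_names(),
                                                     colnames(table))) {
  st <- factor(table$Status, levels = status_levels())
  res <- lapply(variables, function(v) {
    ok <- !is.na(table[[v]]) & !is.na(st)
    g <- droplevels(st[ok])
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      stop("grouping error for ", v,
           ": need >= 2 groups with >= 2 observations")
    }
    fit <- stats::aov(x ~ g, data = data.frame(x = table[[v]][ok], g = g))
    s <- summary(fit)[[1]]
    list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
         tukey = stats::TukeyHSD(fit)$g)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(
    test = variables,
    F = vapply(res, `[[`, numeric(1), "F"),
    p = p,
    p_bonferroni = pmin(1, p * length(variables)),
    stringsAsFactors = FALSE
  )
  structure(list(anova = out,
                 tukey = stats::setNames(lapply(res, `[[`, "tukey"),
                                         variables)),
            class = "np_status_association")
}

#' @export
print.np_status_association <- function(x, ...) {
  print(x$anova)
  invisible(x)
}
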