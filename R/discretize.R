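#' One-dimensional k-medoids (PAM)
#'
#' Exact PAM on a univariate sample: the BUILD phase greedily adds the
#' medoid that most reduces the total absolute deviation, then the SWAP
#' phase repeatedly applies the single best medoid/non-medoid exchange while
#' the objective strictly decreases. Medoids are data values; duplicated
#' values are collapsed to weighted distinct values, which leaves the
#' objective unchanged and makes the run time depend on the number of
#' distinct scores rather than the sample size.
#'
#' Determinism: assignment ties go to the lower medoid; cost ties during
#' BUILD/SWAP prefer the lexicographically smaller (sorted) medoid set.
#'
#' @param values numeric vector without missing values.
#' @param k number of medoids; must not exceed the number of distinct
#'   values.
#' @return list with `medoids` (sorted ascending), `assignment` (cluster
#'   index per input value, clusters numbered by ascending medoid), `cost`
#'   (total absolute deviation).
#' @export
pam_1d <- function(values, k) {
  if (anyNA(values)) stop("values must not contain missing entries")
  u <- sort(unique(values))
  if (k > length(u)) {
    stop("infeasible k: ", k, " clusters but only ", length(u),
         " distinct values")
  }
  w <- as.numeric(table(factor(values, levels = u)))
  D <- abs(outer(u, u, `-`)) # distinct x distinct

  cost_of <- function(med_idx) {
    sum(w * apply(D[, med_idx, drop = FALSE], 1, min))
  }

  # BUILD
  med <- integer(0)
  nearest <- rep(Inf, length(u))
  for (step in seq_len(k)) {
    cand <- setdiff(seq_along(u), med)
    costs <- vapply(cand, function(j) sum(w * pmin(nearest, D[, j])),
                    numeric(1))
    best <- cand[which(costs <= min(costs) + 1e-12)]
    j <- min(best) # lexicographically smallest extension
    med <- c(med, j)
    nearest <- pmin(nearest, D[, j])
  }
  med <- sort(med)
  cur_cost <- cost_of(med)

  # SWAP
  repeat {
    best_cost <- cur_cost
    best_set <- NULL
    for (m in med) {
      for (j in setdiff(seq_along(u), med)) {
        cand_set <- sort(c(setdiff(med, m), j))
        cc <- cost_of(cand_set)
        if (cc < best_cost - 1e-12 ||
            (!is.null(best_set) && abs(cc - best_cost) <= 1e-12 &&
             lex_less(cand_set, best_set))) {
          best_cost <- cc
          best_set <- cand_set
        }
      }
    }
    if (is.null(best_set)) break
    med <- best_set
    cur_cost <- best_cost
  }

  medoids <- u[med]
  dist <- abs(outer(values, medoids, `-`))
  assignment <- max.col(-dist, ties.method = "first")
  list(medoids = medoids, assignment = assignment, cost = cur_cost)
}

lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Mean silhouette width of a univariate clustering
#'
#' For each point, `a` is the mean absolute distance to the other members of
#' its own cluster and `b` the smallest mean distance to any other cluster;
#' the silhouette is `(b - a) / max(a, b)`. Points in singleton clusters
#' score 0, as do points with `a = b = 0`. Returns the mean over all points.
#'
#' @param values numeric vector without missing values.
#' @param assignment integer cluster labels, one per value; at least two
#'   distinct clusters, each nonempty.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(values, assignment) {
  if (anyNA(values) || anyNA(assignment)) stop("missing values not allowed")
  cl <- unique(assignment)
  if (length(cl) < 2) stop("silhouette undefined for a single cluster")
  # collapse to weighted (value, cluster) cells
  key <- paste(values, assignment, sep = "\r")
  first <- !duplicated(key)
  v <- values[first]
  a_cl <- assignment[first]
  w <- as.numeric(table(key)[key[first]])
  sizes <- tapply(w, a_cl, sum)
  s_tot <- 0
  for (i in seq_along(v)) {
    own <- a_cl == a_cl[i]
    n_own <- sizes[[as.character(a_cl[i])]]
    if (n_own <= 1) next # singleton: s = 0
    a_i <- sum(w[own] * abs(v[own] - v[i])) / (n_own - 1)
    b_i <- min(vapply(setdiff(cl, a_cl[i]), function(cc) {
      oth <- a_cl == cc
      sum(w[oth] * abs(v[oth] - v[i])) / sizes[[as.character(cc)]]
    }, numeric(1)))
    s_i <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
    s_tot <- s_tot + w[i] * s_i
  }
  s_tot / length(values)
}

#' Fit a score-interval discretization
#'
#' For every NP test column, runs [pam_1d()] for each candidate number of
#' clusters `k` in `2..min(k_max, #distinct values)`, keeps the `k` with the
#' largest mean silhouette width (ties go to the smaller `k`), and converts
#' the clusters to closed score intervals spanning each cluster's observed
#' extremes. Gaps between intervals can occur when scores are absent from
#' the sample; [apply_discretization()] handles them.
#'
#' @param table a cohort data.frame containing (some of) the NP test
#'   columns; missing scores are ignored during fitting.
#' @param k_max maximum number of intervals per test (default 10).
#' @param variables which columns to discretize (default: all NP test
#'   columns present).
#' @return an object of class `np_discretization`: per-variable interval
#'   matrices (`lo`, `hi`), chosen `k`, mean silhouette at the chosen `k`,
#'   and the score step.
#' @export
fit_discretization <- function(table, k_max = 10,
                               variables = intersect(np_test_names(),
                                                     colnames(table))) {
  stopifnot(k_max >= 2, length(variables) >= 1)
  vars <- np_variables()
  steps <- stats::setNames(vars$step, vars$name)
  intervals <- list(); ks <- integer(0); sil <- numeric(0)
  for (v in variables) {
    x <- table[[v]]
    x <- x[!is.na(x)]
    nd <- length(unique(x))
    if (nd < 2) {
      stop("degenerate variable ", v, ": fewer than 2 distinct values")
    }
    kk <- 2:min(k_max, nd)
    fits <- lapply(kk, function(k) pam_1d(x, k))
    sw <- vapply(seq_along(kk), function(i)
      silhouette_width(x, fits[[i]]$assignment), numeric(1))
    pick <- which.max(sw) # first max: smaller k on ties
    fit <- fits[[pick]]
    lo <- tapply(x, fit$assignment, min)
    hi <- tapply(x, fit$assignment, max)
    ord <- order(as.numeric(lo))
    intervals[[v]] <- cbind(lo = as.numeric(lo)[ord], hi = as.numeric(hi)[ord])
    ks[v] <- kk[pick]
    sil[v] <- sw[pick]
  }
  structure(list(intervals = intervals, k = ks, silhouette = sil,
                 step = steps[variables]),
            class = "np_discretization")
}

#' @export
print.np_discretization <- function(x, ...) {
  cat("Score-interval discretization (", length(x$intervals),
      " variables)\n", sep = "")
  for (v in names(x$intervals)) {
    iv <- x$intervals[[v]]
    cat(sprintf("  %-8s %s\n", v,
                paste0("(", iv[, "lo"], ",", iv[, "hi"], ")",
                       collapse = ", ")))
  }
  invisible(x)
}

#' Map raw scores to interval indices
#'
#' Replaces every non-missing NP score with the 1-based index of its
#' interval; missing scores stay missing; `Status` is coded over its three
#' levels, and any remaining columns (ids, covariates) are carried through
#' unchanged in the result's `covariates` slot.
#'
#' @param table a cohort data.frame.
#' @param map an `np_discretization` covering the table's test columns.
#' @param out_of_range `"error"` (default) fails on scores outside every
#'   interval, naming the variable, value and interval table; `"clamp"`
#'   assigns such scores to the nearest interval (ties to the lower one),
#'   which is the leakage-safe choice when applying a training-fold map to
#'   held-out rows.
#' @return a `bn_discrete` over the mapped tests (plus `Status` when
#'   present).
#' @export
apply_discretization <- function(table, map,
                                 out_of_range = c("error", "clamp")) {
  out_of_range <- match.arg(out_of_range)
  tests <- intersect(names(map$intervals), colnames(table))
  if (!length(tests)) stop("no mapped test columns present")
  n <- nrow(table)
  cols <- list(); levels <- list()
  for (v in tests) {
    iv <- map$intervals[[v]]
    x <- table[[v]]
    idx <- rep(NA_integer_, n)
    obs <- which(!is.na(x))
    if (length(obs)) {
      pos <- findInterval(x[obs], iv[, "lo"])
      inside <- pos >= 1 & pos <= nrow(iv) & x[obs] <= iv[pmax(pos, 1), "hi"]
      idx[obs[inside]] <- pos[inside]
      off <- obs[!inside]
      if (length(off)) {
        if (out_of_range == "error") {
          stop("score out of range for ", v, ": value ", x[off[1]],
               " not covered by intervals ",
               paste0("(", iv[, "lo"], ",", iv[, "hi"], ")", collapse = ", "))
        }
        for (i in off) {
          d_lo <- abs(iv[, "lo"] - x[i]); d_hi <- abs(iv[, "hi"] - x[i])
          idx[i] <- which.min(pmin(d_lo, d_hi))
        }
      }
    }
    cols[[v]] <- idx
    levels[[v]] <- paste0("(", iv[, "lo"], ",", iv[, "hi"], ")")
  }
  if ("Status" %in% colnames(table)) {
    st <- match(as.character(table$Status), status_levels())
    if (anyNA(st)) stop("invalid or missing Status labels")
    cols$Status <- st
    levels$Status <- status_levels()
  }
  extra <- setdiff(colnames(table), c(tests, "Status"))
  new_discrete_dataset(do.call(cbind, cols), levels,
                       covariates = if (length(extra))
                         table[, extra, drop = FALSE])
}
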