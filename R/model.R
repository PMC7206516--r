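#' Discrete datasets
#'
#' A `bn_discrete` wraps an integer-coded data matrix (one column per model
#' variable, states coded 1..r, `NA` for missing) together with the state
#' labels of every variable. It is the working representation handed to
#' structure learning, parameter estimation and the conditional-independence
#' tests.
#'
#' @param data integer matrix or data.frame of 1-based state codes.
#' @param levels named list of character state labels, one entry per column.
#' @param covariates optional data.frame carried alongside (same row count).
#' @return an object of class `bn_discrete`.
#' @export
new_discrete_dataset <- function(data, levels, covariates = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(colnames(data))) colnames(data) <- names(levels)
  stopifnot(identical(sort(colnames(data)), sort(names(levels))))
  data <- data[, names(levels), drop = FALSE]
  cards <- vapply(levels, length, integer(1))
  for (v in names(levels)) {
    bad <- !is.na(data[, v]) & (data[, v] < 1L | data[, v] > cards[[v]])
    if (any(bad)) stop("state code out of range for variable ", v)
  }
  if (!is.null(covariates) && nrow(covariates) != nrow(data)) {
    stop("covariates row count mismatch")
  }
  structure(list(data = data, levels = levels, cards = cards,
                 covariates = covariates),
            class = "bn_discrete")
}

#' @export
print.bn_discrete <- function(x, ...) {
  cat("Discrete dataset:", nrow(x$data), "rows,", ncol(x$data),
      "variables\n")
  invisible(x)
}

#' @export
dim.bn_discrete <- function(x) dim(x$data)

complete_rows <- function(dataset, vars = colnames(dataset$data)) {
  stats::complete.cases(dataset$data[, vars, drop = FALSE])
}

subset_rows <- function(dataset, idx) {
  new_discrete_dataset(dataset$data[idx, , drop = FALSE], dataset$levels,
                       if (!is.null(dataset$covariates))
                         dataset$covariates[idx, , drop = FALSE])
}

# mixed-radix code of parent states, first parent fastest; 1-based
parent_config_code <- function(states, cards) {
  if (!NCOL(states) || !length(cards)) return(rep(1L, NROW(states)))
  states <- as.matrix(states)
  code <- rep(0, nrow(states))
  stride <- 1
  for (m in seq_along(cards)) {
    code <- code + (states[, m] - 1) * stride
    stride <- stride * cards[m]
  }
  as.integer(code + 1L)
}

#' Fitted Bayesian-network models
#'
#' A `bn_model` couples a DAG with one conditional probability table (CPT)
#' per node. Each CPT is a `q x r` matrix: one row per parent configuration
#' (full Cartesian product, first parent varying fastest) and one column per
#' node state.
#'
#' @param dag a `bn_dag`.
#' @param cpts named list of CPT matrices.
#' @param levels named list of state labels per node.
#' @param fit_report optional list of fitting diagnostics.
#' @return object of class `bn_model`.
#' @export
new_bn_model <- function(dag, cpts, levels, fit_report = NULL) {
  stopifnot(setequal(dag$nodes, names(cpts)), setequal(dag$nodes, names(levels)))
  cards <- vapply(levels, length, integer(1))
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    q <- prod(cards[pa])
    if (!all(dim(cpts[[v]]) == c(q, cards[[v]]))) {
      stop("CPT dimension mismatch for node ", v)
    }
    if (any(abs(rowSums(cpts[[v]]) - 1) > 1e-9)) {
      stop("CPT rows of ", v, " do not sum to 1")
    }
    if (any(cpts[[v]] < 0)) stop("negative probability in CPT of ", v)
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes], levels = levels[dag$nodes],
                 cards = cards[dag$nodes], fit_report = fit_report),
            class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(dag_edges(x$dag)), "edges\n")
  invisible(x)
}

# flatten a model into the index form consumed by the C++ samplers
compile_model <- function(model) {
  nodes <- model$dag$nodes
  ord <- match(topological_order(model$dag), nodes)
  parents <- lapply(nodes, function(v) match(model$dag$parents[[v]], nodes))
  list(order = as.integer(ord),
       parents = lapply(parents, as.integer),
       cards = as.integer(model$cards),
       cpts = model$cpts,
       nodes = nodes)
}

family_counts <- function(node, parents, dataset) {
  cards <- dataset$cards
  fam <- c(parents, node)
  keep <- complete_rows(dataset, fam)
  x <- dataset$data[keep, , drop = FALSE]
  r <- cards[[node]]
  q <- prod(cards[parents])
  counts <- matrix(0L, nrow = q, ncol = r)
  if (nrow(x)) {
    code <- parent_config_code(x[, parents, drop = FALSE], cards[parents])
    tab <- tabulate((code - 1L) * r + x[, node], nbins = q * r)
    counts <- matrix(tab, nrow = q, ncol = r, byrow = TRUE)
  }
  counts
}

#' Parameter estimation for a fixed DAG
#'
#' `fit_mle()` estimates every CPT row by relative frequency
#' `n_jk / n_j`; parent configurations never observed get a uniform row and
#' are flagged in the model's `fit_report`. `fit_bayes()` returns the
#' posterior mean under a uniform Dirichlet prior with total imaginary
#' sample size `iss` spread evenly over the CPT's `q * r` cells:
#' `(n_jk + iss/(r q)) / (n_j + iss/q)`. Bayesian rows are strictly
#' positive, which keeps downstream likelihood weighting well-defined; it is
#' therefore the default estimator for inference.
#'
#' @param dag a `bn_dag`.
#' @param dataset a `bn_discrete`; rows incomplete on a family are dropped
#'   for that family only.
#' @param iss total imaginary sample size of the Dirichlet prior (> 0).
#' @return a `bn_model`.
#' @export
fit_mle <- function(dag, dataset) {
  if (!all(dag$nodes %in% colnames(dataset$data))) {
    stop("DAG nodes missing from data")
  }
  if (!any(complete_rows(dataset, dag$nodes))) stop("no complete rows to fit")
  uniform_rows <- list()
  cpts <- lapply(dag$nodes, function(v) {
    counts <- family_counts(v, dag$parents[[v]], dataset)
    nj <- rowSums(counts)
    cpt <- counts / ifelse(nj > 0, nj, 1)
    if (any(nj == 0)) {
      cpt[nj == 0, ] <- 1 / ncol(counts)
      uniform_rows[[v]] <<- which(nj == 0)
    }
    cpt
  })
  names(cpts) <- dag$nodes
  new_bn_model(dag, cpts, dataset$levels[dag$nodes],
               fit_report = list(estimator = "mle", uniform_rows = uniform_rows))
}

#' @rdname fit_mle
#' @export
fit_bayes <- function(dag, dataset, iss = 1) {
  if (!is.numeric(iss) || iss <= 0) stop("iss must be a positive number")
  if (!all(dag$nodes %in% colnames(dataset$data))) {
    stop("DAG nodes missing from data")
  }
  if (!any(complete_rows(dataset, dag$nodes))) stop("no complete rows to fit")
  cpts <- lapply(dag$nodes, function(v) {
    counts <- family_counts(v, dag$parents[[v]], dataset)
    r <- ncol(counts); q <- nrow(counts)
    (counts + iss / (r * q)) / (rowSums(counts) + iss / q)
  })
  names(cpts) <- dag$nodes
  new_bn_model(dag, cpts, dataset$levels[dag$nodes],
               fit_report = list(estimator = "bayes", iss = iss))
}
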