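#' Decomposable network scores
#'
#' `family_bic()` returns one node-family's contribution to the BIC/MDL
#' network score (higher is better): the multinomial log-likelihood of the
#' node given its parents minus the MDL penalty `(log N / 2) * q * (r - 1)`,
#' where `r` is the node's cardinality, `q` the number of parent
#' configurations with observed support and `N` the number of
#' family-complete rows. `bic_score()` sums the family contributions over a
#' DAG (score decomposability). `family_score()` additionally exposes the
#' AIC and BDeu alternatives used for sensitivity checks.
#'
#' @param node node name.
#' @param parents character vector of parent names (may be empty).
#' @param dataset a `bn_discrete`; rows incomplete on the family are
#'   dropped.
#' @param dag a `bn_dag` whose nodes are data columns.
#' @param score one of `"bic"`, `"aic"`, `"bdeu"`.
#' @param iss imaginary sample size for the BDeu score.
#' @return numeric score contribution (log scale, higher is better).
#' @export
family_bic <- function(node, parents = character(0), dataset) {
  family_score(node, parents, dataset, score = "bic")
}

#' @rdname family_bic
#' @export
family_score <- function(node, parents = character(0), dataset,
                         score = c("bic", "aic", "bdeu"), iss = 1) {
  score <- match.arg(score)
  if (node %in% parents) stop("node cannot be its own parent: ", node)
  cn <- colnames(dataset$data)
  if (!all(c(node, parents) %in% cn)) stop("unknown family variables")
  r <- dataset$cards[[node]]
  if (score == "bdeu") {
    counts <- family_counts(node, parents, dataset)
    q <- nrow(counts)
    a_jk <- iss / (r * q); a_j <- iss / q
    nj <- rowSums(counts)
    return(sum(lgamma(a_j) - lgamma(a_j + nj)) +
             sum(lgamma(a_jk + counts) - lgamma(a_jk)))
  }
  st <- cpp_family_stats(dataset$data, as.integer(dataset$cards),
                         match(node, cn), as.integer(match(parents, cn)))
  loglik <- st[1]; q <- st[2]; N <- st[3]
  if (N == 0) stop("no complete rows for family of ", node)
  pen <- if (score == "bic") (log(N) / 2) * q * (r - 1) else q * (r - 1)
  loglik - pen
}

#' @rdname family_bic
#' @export
bic_score <- function(dag, dataset, score = "bic", iss = 1) {
  if (!dag_is_acyclic(dag)) stop("graph is cyclic")
  if (!all(dag$nodes %in% colnames(dataset$data))) {
    stop("DAG nodes missing from data columns")
  }
  sum(vapply(dag$nodes, function(v)
    family_score(v, dag$parents[[v]], dataset, score = score, iss = iss),
    numeric(1)))
}

# memoized family scorer: key = node | sorted parents
make_scorer <- function(dataset, score = "bic", iss = 1) {
  cache <- new.env(parent = emptyenv())
  function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score(node, parents, dataset, score = score, iss = iss)
      cache[[key]] <- val
    }
    val
  }
}

transitive_closure <- function(adj) {
  reach <- adj
  repeat {
    nxt <- (reach + reach %*% adj) > 0
    storage.mode(nxt) <- "numeric"
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

dag_adjacency <- function(dag) {
  n <- length(dag$nodes)
  adj <- matrix(0, n, n, dimnames = list(dag$nodes, dag$nodes))
  e <- dag_edges(dag)
  if (nrow(e)) adj[e] <- 1
  adj
}

# enumerate scored single-edge moves in deterministic (from, to, type) order
hc_moves <- function(dag, scorer, blacklist, whitelist) {
  nodes <- dag$nodes
  moves <- vector("list", length(nodes)^2)
  nm <- 0
  bl_key <- if (NROW(blacklist)) paste(blacklist[, 1], blacklist[, 2]) else
    character(0)
  wl_key <- if (NROW(whitelist)) paste(whitelist[, 1], whitelist[, 2]) else
    character(0)
  adj <- dag_adjacency(dag)
  reach <- transitive_closure(adj)
  base <- vapply(nodes, function(v) scorer(v, dag$parents[[v]]), numeric(1))
  for (from in nodes) for (to in nodes) {
    if (from == to) next
    key <- paste(from, to)
    if (adj[from, to] > 0) {
      if (!key %in% wl_key) {
        nm <- nm + 1
        moves[[nm]] <- list(
          type = "delete", from = from, to = to,
          delta = scorer(to, setdiff(dag$parents[[to]], from)) - base[to])
      }
      if (!paste(to, from) %in% bl_key && !key %in% wl_key) {
        adj2 <- adj; adj2[from, to] <- 0
        if (transitive_closure(adj2)[from, to] == 0) {
          nm <- nm + 1
          moves[[nm]] <- list(
            type = "reverse", from = from, to = to,
            delta = (scorer(to, setdiff(dag$parents[[to]], from)) -
                       base[to]) +
              (scorer(from, c(dag$parents[[from]], to)) - base[from]))
        }
      }
    } else if (!key %in% bl_key && reach[to, from] == 0) {
      nm <- nm + 1
      moves[[nm]] <- list(
        type = "add", from = from, to = to,
        delta = scorer(to, c(dag$parents[[to]], from)) - base[to])
    }
  }
  moves[seq_len(nm)]
}

apply_move <- function(dag, mv) {
  switch(mv$type,
         add = dag_add_edge(dag, mv$from, mv$to),
         delete = dag_remove_edge(dag, mv$from, mv$to),
         reverse = dag_reverse_edge(dag, mv$from, mv$to))
}

move_key <- function(mv) paste(mv$type, mv$from, mv$to)

inverse_key <- function(mv) {
  switch(mv$type,
         add = paste("delete", mv$from, mv$to),
         delete = paste("add", mv$from, mv$to),
         reverse = paste("reverse", mv$to, mv$from))
}

hc_core <- function(dataset, init, scorer, max_iter, blacklist, whitelist) {
  dag <- init
  total <- sum(vapply(dag$nodes, function(v) scorer(v, dag$parents[[v]]),
                      numeric(1)))
  for (iter in seq_len(max_iter)) {
    moves <- hc_moves(dag, scorer, blacklist, whitelist)
    if (!length(moves)) break
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    best <- which.max(deltas) # first best: (from, to, type) enumeration order
    if (deltas[best] <= 1e-9) break
    dag <- apply_move(dag, moves[[best]])
    total <- total + deltas[best]
  }
  attr(dag, "score") <- total
  dag
}

#' Score-based structure search
#'
#' `hill_climb()` greedily applies the best acyclicity-preserving
#' single-edge move (add, delete or reverse) while the network score
#' strictly increases, with memoized family scores so only affected
#' families are re-scored. With `restarts > 0` the search is repeated from
#' randomly perturbed copies of the incumbent and the best-scoring local
#' optimum is returned. `tabu_search()` additionally escapes local optima:
#' at an optimum it takes the least-worsening move not on a FIFO tabu list
#' (each applied move's inverse becomes tabu), and returns the best DAG
#' ever visited; with `tabu_len = 0` it reduces to plain hill-climbing.
#'
#' @param dataset a `bn_discrete`.
#' @param nodes variables to model (default: all data columns).
#' @param init starting DAG (default empty).
#' @param max_iter maximum number of accepted moves.
#' @param restarts number of random-restart rounds after the first climb.
#' @param perturb number of random moves used to perturb a restart's start.
#' @param seed integer seed (used for restart perturbations).
#' @param score,iss scoring function, see [family_score()].
#' @param blacklist,whitelist optional two-column matrices of forbidden /
#'   forced edges.
#' @param tabu_len length of the FIFO tabu list.
#' @param stagnation stop after this many consecutive moves without a new
#'   best score.
#' @return a `bn_dag` with the attained score in `attr(, "score")`.
#' @export
hill_climb <- function(dataset, nodes = colnames(dataset$data), init = NULL,
                       max_iter = 10000, restarts = 5, perturb = 3,
                       seed = NULL, score = "bic", iss = 1,
                       blacklist = NULL, whitelist = NULL) {
  if (!any(complete_rows(dataset, nodes))) stop("no complete rows")
  scorer <- make_scorer(dataset, score = score, iss = iss)
  if (is.null(init)) init <- empty_dag(nodes)
  if (!is.null(whitelist)) {
    for (i in seq_len(nrow(whitelist))) {
      if (!dag_has_edge(init, whitelist[i, 1], whitelist[i, 2])) {
        init <- dag_add_edge(init, whitelist[i, 1], whitelist[i, 2])
      }
    }
  }
  if (!is.null(seed)) set.seed(seed)
  best <- hc_core(dataset, init, scorer, max_iter, blacklist, whitelist)
  for (r in seq_len(restarts)) {
    start <- best
    for (p in seq_len(perturb)) {
      moves <- hc_moves(start, scorer, blacklist, whitelist)
      if (!length(moves)) break
      start <- apply_move(start, moves[[sample.int(length(moves), 1)]])
    }
    cand <- hc_core(dataset, start, scorer, max_iter, blacklist, whitelist)
    if (attr(cand, "score") > attr(best, "score") + 1e-9) best <- cand
  }
  best
}

#' @rdname hill_climb
#' @export
tabu_search <- function(dataset, nodes = colnames(dataset$data),
                        tabu_len = 10, max_iter = 10000, stagnation = 15,
                        seed = NULL, score = "bic", iss = 1,
                        blacklist = NULL, whitelist = NULL) {
  if (!any(complete_rows(dataset, nodes))) stop("no complete rows")
  if (!is.null(seed)) set.seed(seed)
  scorer <- make_scorer(dataset, score = score, iss = iss)
  dag <- hc_core(dataset, empty_dag(nodes), scorer, max_iter,
                 blacklist, whitelist)
  best <- dag
  if (tabu_len == 0) return(best)
  total <- attr(dag, "score")
  tabu <- character(0)
  since_best <- 0
  for (iter in seq_len(max_iter)) {
    moves <- hc_moves(dag, scorer, blacklist, whitelist)
    moves <- moves[!vapply(moves, move_key, character(1)) %in% tabu]
    if (!length(moves)) break
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    pick <- which.max(deltas) # best admissible, worsening if need be
    mv <- moves[[pick]]
    dag <- apply_move(dag, mv)
    total <- total + deltas[pick]
    attr(dag, "score") <- total
    tabu <- c(tabu, inverse_key(mv))
    if (length(tabu) > tabu_len) tabu <- tabu[-1]
    if (total > attr(best, "score") + 1e-9) {
      best <- dag
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= stagnation) break
    }
  }
  best
}

#' Bootstrap model averaging of learned structures
#'
#' Learns a DAG on each of `B` row resamples (complete cases, drawn with
#' replacement) and tabulates, for every ordered node pair, the `strength`
#' (fraction of replicates containing the edge in either direction) and
#' `direction` (fraction of those orienting it this way). The averaged DAG
#' keeps edges with strength at or above `strength_threshold`, oriented by
#' majority direction; edges are committed in decreasing strength and an
#' edge whose majority orientation would close a directed cycle is resolved
#' by dropping that weakest edge of the cycle.
#'
#' @param dataset a `bn_discrete`.
#' @param nodes variables to model.
#' @param learner structure learner, [hill_climb()] (default) or
#'   [tabu_search()].
#' @param B number of bootstrap replicates.
#' @param strength_threshold minimum edge strength retained.
#' @param seed integer seed for the resampling.
#' @param ... further arguments passed to `learner` (by default the
#'   bootstrap learner runs single climbs, `restarts = 0`).
#' @return list with `support` (a `bn_edge_support` data.frame: `from`,
#'   `to`, `strength`, `direction`, `B`) and `dag` (the averaged `bn_dag`).
#' @export
bootstrap_average <- function(dataset, nodes = colnames(dataset$data),
                              learner = hill_climb, B = 500,
                              strength_threshold = 0.5, seed = NULL, ...) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- which(complete_rows(dataset, nodes))
  if (!length(keep)) stop("no complete rows")
  args <- list(...)
  if (is.null(args$restarts) && identical(learner, hill_climb)) {
    args$restarts <- 0
  }
  und <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes)) # directed presence counts
  for (b in seq_len(B)) {
    idx <- keep[sample.int(length(keep), length(keep), replace = TRUE)]
    d_b <- subset_rows(dataset, idx)
    g <- do.call(learner, c(list(dataset = d_b, nodes = nodes), args))
    e <- dag_edges(g)
    for (i in seq_len(nrow(e))) und[e[i, 1], e[i, 2]] <-
        und[e[i, 1], e[i, 2]] + 1
  }
  pairs <- which(upper.tri(und), arr.ind = TRUE)
  sup <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    u <- nodes[pairs[i, 1]]; v <- nodes[pairs[i, 2]]
    both <- und[u, v] + und[v, u]
    if (both == 0) return(NULL)
    data.frame(from = c(u, v), to = c(v, u),
               strength = both / B,
               direction = c(und[u, v], und[v, u]) / both,
               B = B, stringsAsFactors = FALSE)
  }))
  if (is.null(sup)) {
    sup <- data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction = numeric(0),
                      B = integer(0))
  }
  class(sup) <- c("bn_edge_support", "data.frame")

  kept <- sup[sup$strength >= strength_threshold & sup$direction >= 0.5, ]
  # on an exact direction tie keep the lexicographically first orientation
  ties <- kept$direction == 0.5
  if (any(ties)) {
    drop <- ties & (kept$from > kept$to)
    kept <- kept[!drop, ]
  }
  kept <- kept[order(-kept$strength, kept$from, kept$to), ]
  avg <- empty_dag(nodes)
  for (i in seq_len(nrow(kept))) {
    cand <- try(dag_add_edge(avg, kept$from[i], kept$to[i]), silent = TRUE)
    if (!inherits(cand, "try-error")) avg <- cand
    # else: this is the lowest-strength edge of the cycle it would close
  }
  list(support = sup, dag = avg)
}
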