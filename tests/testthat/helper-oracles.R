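# Independent oracles used to check the package implementations on small
# instances: brute-force enumeration of joints and posteriors, a graphical
# d-separation routine, exhaustive k-medoids, a direct silhouette formula,
# and exhaustive DAG enumeration for 3 nodes.

# random DAG over `nodes` (edge prob p along a random order)
rand_dag <- function(nodes, p = 0.4) {
  ord <- sample(nodes)
  g <- empty_dag(nodes)
  n <- length(ord)
  if (n >= 2) {
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (stats::runif(1) < p) g <- dag_add_edge(g, ord[j], ord[i])
      }
    }
  }
  g
}

# random discrete model on a random DAG, Dirichlet-style CPT rows
rand_model <- function(nodes, p = 0.4, cards = 2:3, shape = 1) {
  g <- rand_dag(nodes, p)
  card <- stats::setNames(sample(cards, length(nodes), replace = TRUE), nodes)
  lv <- lapply(card, function(r) paste0("s", seq_len(r)))
  cpts <- lapply(nodes, function(v) {
    q <- prod(card[g$parents[[v]]])
    r <- card[[v]]
    m <- matrix(stats::rgamma(q * r, shape) + 1e-4, nrow = q)
    m / rowSums(m)
  })
  names(cpts) <- nodes
  new_bn_model(g, cpts, lv)
}

# brute-force joint distribution: data.frame of configs + probability
enum_joint <- function(model) {
  nodes <- model$dag$nodes
  grid <- expand.grid(lapply(model$cards[nodes], seq_len))
  colnames(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- model$dag$parents[[v]]
    row <- npbnet:::parent_config_code(as.matrix(grid[, pa, drop = FALSE]),
                                       model$cards[pa])
    p <- p * model$cpts[[v]][cbind(row, grid[[v]])]
  }
  cbind(grid, prob = p)
}

# brute-force posterior of target given evidence (named integer states)
brute_posterior <- function(model, evidence, target) {
  j <- enum_joint(model)
  for (v in names(evidence)) j <- j[j[[v]] == evidence[[v]], , drop = FALSE]
  p <- tapply(j$prob, factor(j[[target]], seq_len(model$cards[[target]])),
              sum)
  p[is.na(p)] <- 0
  as.numeric(p / sum(p))
}

# graphical d-separation: x _||_ y | z in dag?
d_separated <- function(dag, x, y, z) {
  # ancestral subgraph of {x, y} U z
  anc <- unique(c(x, y, z))
  repeat {
    more <- unique(unlist(lapply(anc, dag_parents, dag = dag)))
    if (all(more %in% anc)) break
    anc <- unique(c(anc, more))
  }
  # moralize: undirected adjacency among ancestors
  n <- length(anc)
  adj <- matrix(FALSE, n, n, dimnames = list(anc, anc))
  for (v in anc) {
    pa <- intersect(dag_parents(dag, v), anc)
    for (p1 in pa) {
      adj[p1, v] <- adj[v, p1] <- TRUE
      for (p2 in pa) if (p1 != p2) adj[p1, p2] <- adj[p2, p1] <- TRUE
    }
  }
  # remove z, test connectivity x -- y
  keep <- setdiff(anc, z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  adj <- adj[keep, keep, drop = FALSE]
  frontier <- x
  seen <- character(0)
  while (length(frontier)) {
    if (y %in% frontier) return(FALSE)
    seen <- c(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, function(v)
      keep[adj[v, ]])))
    frontier <- setdiff(nxt, seen)
  }
  TRUE
}

# Markov blanket via the d-separation characterization:
# u is in MB(t) iff t and u are NOT d-separated given all other nodes
blanket_by_dsep <- function(dag, target) {
  others <- setdiff(dag$nodes, target)
  sort(others[!vapply(others, function(u)
    d_separated(dag, target, u, setdiff(others, u)), logical(1))])
}

# exhaustive k-medoids: best medoid set by total absolute deviation,
# ties to the lexicographically smallest set of values
brute_pam <- function(values, k) {
  u <- sort(unique(values))
  sets <- utils::combn(u, k, simplify = FALSE)
  costs <- vapply(sets, function(m)
    sum(vapply(values, function(x) min(abs(x - m)), numeric(1))),
    numeric(1))
  best <- which(costs <= min(costs) + 1e-12)
  # lexicographic tie-break over sorted sets
  cand <- sets[best]
  ord <- order(vapply(cand, function(s)
    paste(sprintf("%09.3f", s), collapse = ","), character(1)))
  list(medoids = cand[[ord[1]]], cost = min(costs))
}

# direct silhouette formula, O(n^2)
brute_silhouette <- function(values, assignment) {
  n <- length(values)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(abs(values[setdiff(own, i)] - values[i]))
    b <- min(vapply(setdiff(unique(assignment), assignment[i]), function(cc)
      mean(abs(values[assignment == cc] - values[i])), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# all 25 DAGs over three labeled nodes
all_dags_3 <- function(nodes = c("A", "B", "C")) {
  pairs <- t(utils::combn(nodes, 2))
  combos <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    e <- NULL
    for (j in seq_len(nrow(pairs))) {
      v <- combos[i, j]
      if (v == 1) e <- rbind(e, pairs[j, , drop = FALSE])
      if (v == 2) e <- rbind(e, rev(pairs[j, ]))
    }
    g <- try(new_dag(nodes, e), silent = TRUE)
    if (!inherits(g, "try-error")) out[[length(out) + 1]] <- g
  }
  out
}

# small helper: total-variation distance between two probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(as.numeric(p) - as.numeric(q)))
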