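#' Cohort CSV input and output
#'
#' The cohort interchange format is a plain comma-separated file, UTF-8,
#' `.` decimal, one header row, empty fields for missing values: columns
#' `participant_id`, `exam_id`, the 11 test scores, `Status`, `sex`,
#' `apoe4`, `education`. `read_cohort_csv()` validates every score against
#' the variable roster (range and score-step grid) and reports offending
#' line numbers; `Status` must never be missing.
#'
#' @param path file path.
#' @param table an `np_cohort` data.frame.
#' @param roster variable roster as returned by [np_variables()].
#' @return `read_cohort_csv()` returns an `np_cohort` data.frame.
#' @export
read_cohort_csv <- function(path, roster = np_variables()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  if (!nrow(tab)) stop("empty cohort file: ", path)
  tests <- roster$name[roster$kind == "np_test"]
  needed <- c(tests, "Status")
  missing_cols <- setdiff(needed, colnames(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(colnames(tab),
                     c("participant_id", "exam_id", roster$name))
  if (length(unknown)) {
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  }
  for (v in tests) {
    spec <- roster[roster$name == v, ]
    x <- suppressWarnings(as.numeric(tab[[v]]))
    bad_parse <- which(!is.na(tab[[v]]) & is.na(x))
    if (length(bad_parse)) {
      stop("malformed value for ", v, " at line ", bad_parse[1] + 1)
    }
    off <- which(!is.na(x) & (x < spec$min | x > spec$max |
                                abs(x / spec$step - round(x / spec$step)) > 1e-9))
    if (length(off)) {
      stop("out-of-range value for ", v, " at line ", off[1] + 1,
           ": ", x[off[1]], " (allowed ", spec$min, "..", spec$max,
           " step ", spec$step, ")")
    }
    tab[[v]] <- x
  }
  if (anyNA(tab$Status) || !all(tab$Status %in% status_levels())) {
    stop("Status must be one of ", paste(status_levels(), collapse = ", "))
  }
  class(tab) <- c("np_cohort", "data.frame")
  tab
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize analysis artifacts
#'
#' JSON writers/readers for the discretization map, DAGs (edge-list JSON
#' and Graphviz DOT), edge-support tables and CPTs. Every writer's output
#' is re-readable by the matching reader.
#'
#' @param map an `np_discretization`.
#' @param dag a `bn_dag`.
#' @param support a `bn_edge_support` data.frame.
#' @param model a `bn_model`.
#' @param path output file path.
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_discretization_json <- function(map, path) {
  obj <- list(
    variables = lapply(names(map$intervals), function(v) list(
      name = v,
      k = map$k[[v]],
      silhouette = map$silhouette[[v]],
      step = map$step[[v]],
      lo = map$intervals[[v]][, "lo"],
      hi = map$intervals[[v]][, "hi"]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname serialization
#' @export
read_discretization_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$variables
  intervals <- lapply(seq_len(nrow(v)), function(i)
    cbind(lo = unlist(v$lo[i]), hi = unlist(v$hi[i])))
  names(intervals) <- v$name
  structure(list(intervals = intervals,
                 k = stats::setNames(as.integer(v$k), v$name),
                 silhouette = stats::setNames(as.numeric(v$silhouette), v$name),
                 step = stats::setNames(as.numeric(v$step), v$name)),
            class = "np_discretization")
}

#' @rdname serialization
#' @export
write_dag_json <- function(dag, path) {
  e <- dag_edges(dag)
  jsonlite::write_json(list(nodes = dag$nodes,
                            edges = lapply(seq_len(nrow(e)), function(i)
                              list(from = e[i, 1], to = e[i, 2]))),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_dag_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) {
    cbind(obj$edges$from, obj$edges$to)
  }
  new_dag(obj$nodes, edges)
}

#' @rdname serialization
#' @export
write_dag_dot <- function(dag, path) {
  e <- dag_edges(dag)
  lines <- c("digraph G {",
             paste0("  \"", dag$nodes, "\";"),
             if (nrow(e)) paste0("  \"", e[, 1], "\" -> \"", e[, 2], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname serialization
#' @export
write_edge_support_csv <- function(support, path) {
  utils::write.csv(as.data.frame(support), path, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
write_cpts_csv <- function(model, path) {
  rows <- list()
  for (v in model$dag$nodes) {
    pa <- model$dag$parents[[v]]
    cpt <- model$cpts[[v]]
    q <- nrow(cpt)
    cfg <- if (length(pa)) {
      grid <- expand.grid(lapply(pa, function(p) model$levels[[p]]),
                          stringsAsFactors = FALSE)
      apply(grid, 1, function(g) paste(pa, g, sep = "=", collapse = ";"))
    } else rep("", q)
    for (j in seq_len(q)) {
      rows[[length(rows) + 1]] <- data.frame(
        node = v, parents = cfg[j], state = model$levels[[v]],
        probability = cpt[j, ], stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
write_cpts_json <- function(model, path) {
  obj <- lapply(model$dag$nodes, function(v) list(
    node = v,
    parents = model$dag$parents[[v]],
    states = model$levels[[v]],
    table = unclass(model$cpts[[v]])
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname serialization
#' @export
read_cpts_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  nodes <- obj$node
  parents <- stats::setNames(lapply(obj$parents, function(p)
    if (length(p)) as.character(p) else character(0)), nodes)
  levels <- stats::setNames(lapply(obj$states, as.character), nodes)
  cpts <- stats::setNames(lapply(obj$table, function(tb) {
    m <- matrix(as.numeric(tb), nrow = NROW(tb))
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      stop("CPT import failed validation: rows do not sum to 1")
    }
    m
  }), nodes)
  edges <- do.call(rbind, lapply(nodes, function(v)
    if (length(parents[[v]])) cbind(parents[[v]], v)))
  new_bn_model(new_dag(nodes, edges), cpts, levels)
}

#' Run the full analysis pipeline
#'
#' Executes the pipeline end to end on a cohort table: fit (or reuse) the
#' discretization, correlation clusters and status associations, learn the
#' averaged structure by bootstrapped hill-climbing, estimate CPTs, extract
#' the status node's Markov blanket with the conditional-independence
#' screen, and cross-validate the diagnosis. All artifacts are written to
#' `out_dir` together with a `manifest.json` recording the seeds, settings
#' and MD5 content hashes, so a run can be reproduced and verified exactly.
#'
#' @param table an `np_cohort` data.frame (e.g. from [sample_cohort()] or
#'   [read_cohort_csv()]).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param seed master seed; stage seeds derive from it as documented in the
#'   manifest.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(table, out_dir, config = pipeline_config(),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  map <- fit_discretization(table, k_max = config$k_max)
  write_discretization_json(map, p("discretization.json"))

  corr <- correlation_matrix(table)
  utils::write.csv(corr$r, p("correlation_matrix.csv"))
  clusters <- extract_clusters(corr, cutoff = 0.6)
  jsonlite::write_json(clusters, p("clusters.json"))
  assoc <- status_association(table)
  utils::write.csv(assoc$anova, p("status_association.csv"),
                   row.names = FALSE)

  disc <- apply_discretization(table, map)
  stage <- learn_stage(disc, config, seed = seed * 1000 + 1)
  write_dag_json(stage$dag, p("network.json"))
  write_dag_dot(stage$dag, p("network.dot"))
  write_edge_support_csv(stage$support, p("edge_support.csv"))
  write_cpts_csv(stage$model, p("cpts.csv"))

  blanket <- blanket_report(stage$dag, disc)
  jsonlite::write_json(list(
    target = blanket$blanket$target,
    parents = blanket$blanket$parents,
    children = blanket$blanket$children,
    spouses = blanket$blanket$spouses,
    ci_tests = blanket$ci_tests
  ), p("blanket.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cv <- cross_validate(table, config, seed = seed * 1000 + 2)
  utils::write.csv(as.data.frame.matrix(cv$confusion),
                   p("cv_confusion.csv"))
  jsonlite::write_json(list(accuracy = cv$accuracy,
                            sensitivity = cv$sensitivity,
                            specificity = cv$specificity),
                       p("cv_report.json"), auto_unbox = TRUE, digits = NA)

  files <- c("discretization.json", "correlation_matrix.csv",
             "clusters.json", "status_association.csv", "network.json",
             "network.dot", "edge_support.csv", "cpts.csv", "blanket.json",
             "cv_confusion.csv", "cv_report.json")
  manifest <- list(
    seed = seed,
    stage_seeds = list(learn = seed * 1000 + 1, cv = seed * 1000 + 2),
    config = unclass(config),
    n_rows = nrow(table),
    hashes = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(map = map, correlation = corr, clusters = clusters,
                 association = assoc, stage = stage, blanket = blanket,
                 cv = cv, manifest = manifest))
}
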