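#' Probabilistic inference of cognitive status
#'
#' Inference over a fitted discrete Bayesian network. `logic_sample()`
#' performs ancestral (forward) sampling of complete joint configurations.
#' `likelihood_weighting()` estimates the posterior of a target variable
#' under partial evidence by clamping evidence nodes and weighting each
#' sample by the likelihood of the clamped states given their sampled
#' parents. `averaged_inference()` repeats likelihood weighting and averages
#' the repeat posteriors, the form used for clinical decisions so that
#' individual sampling runs do not sway the call. `exact_posterior()`
#' computes the posterior exactly by sum-product variable elimination and
#' serves as the deterministic reference. `predict_status()` reports the
#' maximum-posterior state.
#'
#' Missing test scores are handled by simply omitting those variables from
#' the evidence: the network marginalizes over them, so every available
#' score contributes and none is imputed.
#'
#' @param model a `bn_model`.
#' @param n,n_samples number of joint draws / samples per repeat.
#' @param seed integer seed; all randomness derives from it.
#' @param evidence named list or vector mapping variable names to observed
#'   states (state labels or 1-based indices). Must not contain `target`.
#' @param target variable whose posterior is sought (default `"Status"`).
#' @param repeats number of independent likelihood-weighting repeats.
#' @return `logic_sample()` a `bn_discrete`; the inference functions an
#'   object of class `bn_posterior` (named probability vector with
#'   diagnostics in attributes).
#' @export
logic_sample <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cm <- compile_model(model)
  x <- cpp_logic_sample(cm, as.integer(n))
  colnames(x) <- cm$nodes
  new_discrete_dataset(x, model$levels)
}

validate_evidence <- function(model, evidence, target) {
  if (!target %in% model$dag$nodes) stop("unknown target: ", target)
  evidence <- as.list(evidence)
  if (!length(evidence)) return(integer(0))
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    stop("evidence must be named")
  }
  bad <- setdiff(names(evidence), model$dag$nodes)
  if (length(bad)) stop("evidence on unknown variables: ",
                        paste(bad, collapse = ", "))
  if (target %in% names(evidence)) stop("target cannot carry evidence")
  out <- vapply(names(evidence), function(v) {
    s <- evidence[[v]]
    if (is.character(s)) s <- match(s, model$levels[[v]])
    s <- as.integer(s)
    if (is.na(s) || s < 1L || s > model$cards[[v]]) {
      stop("invalid state for evidence variable ", v)
    }
    s
  }, integer(1))
  out
}

evidence_vector <- function(model, ev_idx) {
  e <- rep(NA_integer_, length(model$dag$nodes))
  names(e) <- model$dag$nodes
  if (length(ev_idx)) e[names(ev_idx)] <- ev_idx
  e
}

new_posterior <- function(p, levels, ...) {
  structure(stats::setNames(as.numeric(p), levels),
            class = "bn_posterior", ...)
}

#' @export
print.bn_posterior <- function(x, digits = 4, ...) {
  cat("Posterior:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @rdname logic_sample
#' @export
likelihood_weighting <- function(model, evidence, target = "Status",
                                 n_samples = 5000, seed = NULL) {
  stopifnot(n_samples >= 1)
  ev <- validate_evidence(model, evidence, target)
  if (!is.null(seed)) set.seed(seed)
  cm <- compile_model(model)
  res <- cpp_likelihood_weighting(cm, evidence_vector(model, ev),
                                  match(target, cm$nodes),
                                  as.integer(n_samples), 1L)
  if (res$total_weight[1] <= 0) {
    stop("impossible evidence: all sample weights are zero")
  }
  p <- res$posterior[1, ] / res$total_weight[1]
  new_posterior(p, model$levels[[target]],
                n_samples = n_samples, repeats = 1L,
                total_weight = res$total_weight[1])
}

#' @rdname logic_sample
#' @export
averaged_inference <- function(model, evidence, target = "Status",
                               repeats = 100, n_samples = 5000, seed = NULL) {
  stopifnot(repeats >= 1, n_samples >= 1)
  ev <- validate_evidence(model, evidence, target)
  if (!is.null(seed)) set.seed(seed)
  cm <- compile_model(model)
  res <- cpp_likelihood_weighting(cm, evidence_vector(model, ev),
                                  match(target, cm$nodes),
                                  as.integer(n_samples), as.integer(repeats))
  ok <- res$total_weight > 0
  if (!any(ok)) stop("impossible evidence: all sample weights are zero")
  post <- res$posterior[ok, , drop = FALSE] / res$total_weight[ok]
  p <- colMeans(post)
  p <- p / sum(p)
  new_posterior(p, model$levels[[target]],
                n_samples = n_samples, repeats = as.integer(repeats),
                repeats_used = sum(ok),
                repeat_sd = apply(post, 2, stats::sd))
}

#' @rdname logic_sample
#' @export
exact_posterior <- function(model, evidence, target = "Status") {
  ev <- validate_evidence(model, evidence, target)
  space <- prod(as.numeric(model$cards[setdiff(model$dag$nodes,
                                               names(ev))]))
  if (space > 1e9) {
    stop("state space too large for exact inference; use sampling")
  }
  factors <- lapply(model$dag$nodes, function(v) {
    pa <- model$dag$parents[[v]]
    f <- f_make(c(pa, v), c(model$cards[pa], model$cards[[v]]),
                as.vector(model$cpts[[v]]))
    for (e in intersect(names(ev), f$vars)) f <- f_reduce(f, e, ev[[e]])
    f
  })
  res <- ve_eliminate(factors, keep = target)
  for (v in setdiff(res$vars, target)) res <- f_marginalize(res, v)
  tot <- sum(res$val)
  if (tot <= 0) stop("impossible evidence: zero probability under the model")
  new_posterior(res$val / tot, model$levels[[target]], exact = TRUE)
}

#' @rdname logic_sample
#' @param settings list of inference settings for `predict_status()`:
#'   `method` (`"averaged"` or `"exact"`), `repeats`, `n_samples`, `seed`.
#' @export
predict_status <- function(model, evidence, settings = list()) {
  target <- settings$target %||% "Status"
  method <- settings$method %||% "averaged"
  post <- if (identical(method, "exact")) {
    exact_posterior(model, evidence, target)
  } else {
    averaged_inference(model, evidence, target,
                       repeats = settings$repeats %||% 100,
                       n_samples = settings$n_samples %||% 5000,
                       seed = settings$seed)
  }
  states <- names(post)
  # tie preference: HC first, then NAD, then AD; other targets keep order
  pref <- if (all(c("HC", "AD", "NAD") %in% states)) {
    c("HC", "NAD", "AD")
  } else states
  p <- unclass(post)[pref]
  best <- pref[which.max(p)]
  tie <- sum(abs(p - max(p)) < 1e-12) > 1
  structure(best, posterior = post, tie = tie)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact marginal of a single variable (no evidence)
exact_marginal <- function(model, var) {
  exact_posterior(model, evidence = list(), target = var)
}
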