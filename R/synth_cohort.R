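#' Planted ground-truth configuration for synthetic cohorts
#'
#' Builds the default generative model behind the synthetic cohort: a
#' 12-node discrete Bayesian network over the 11 NP tests and cognitive
#' status, with the reasoning-to-visual chain
#' `SIM -> BNT30 -> VRi -> VRd -> Status` feeding status, and status
#' emitting a verbal-memory chain (`Status -> LMi -> LMd -> LMr`), a
#' new-learning chain (`Status -> PASi -> PASi_h -> PASd_h`) and visual
#' recognition (`Status -> VRr`).
#'
#' CPTs are derived from the status-conditional score means and SDs of
#' [cohort_calibration()]: each test's score distribution given status is a
#' grid-discretized normal, aggregated onto the planted score intervals.
#' Chain CPTs are the conditionals implied by mixing those distributions
#' over status. The `Status | VRd` table is calibrated by iterative
#' proportional fitting so that the exact marginal of status under the
#' network equals the cohort's group proportions (0.779, 0.123, 0.098).
#'
#' Planted intervals are near-equal-mass bins of each test's marginal
#' (`n_bins` of them; short-range tests get one singleton interval per
#' score), which keeps every CPT row well-populated in finite samples.
#'
#' @param sd_scale multiplier on the within-status score SDs. `1` keeps the
#'   calibration values; values below 1 sharpen all dependencies (useful
#'   when a strongly identifiable structure is wanted).
#' @param n_bins target number of planted score intervals per wide-range
#'   test.
#' @param missing_rate fraction of test scores masked completely at random.
#' @param exam_mean mean number of examinations per participant (exam
#'   counts are 1 + geometric).
#' @return an object of class `bn_ground_truth`: list with the planted
#'   `model` (a [new_bn_model()] over the 12 variables), `bins` (an
#'   `np_discretization` holding the planted intervals), `group_proportions`,
#'   `covariates`, `covariate_missing`, `missing_rate`, `exam_mean`.
#' @export
default_ground_truth <- function(sd_scale = 1, n_bins = 5,
                                 missing_rate = 0.05, exam_mean = 2.2) {
  stopifnot(sd_scale > 0, n_bins >= 2, missing_rate >= 0, missing_rate < 1,
            exam_mean >= 1)
  cal <- cohort_calibration()
  vars <- np_variables()
  tests <- np_test_names()
  props <- cal$proportions

  # per-test grid pmf given status (discretized normal, tails absorbed)
  grid_pmf <- function(test, status) {
    v <- vars[vars$name == test, ]
    g <- seq(v$min, v$max, by = v$step)
    mu <- cal$means[test, status]
    sd <- cal$sds[test, status] * sd_scale
    up <- stats::pnorm(c(g[-length(g)] + v$step / 2, Inf), mu, sd)
    lo <- stats::pnorm(c(-Inf, g[-length(g)] + v$step / 2), mu, sd)
    p <- up - lo
    stats::setNames(p / sum(p), g)
  }
  pmfs <- lapply(stats::setNames(tests, tests), function(te)
    vapply(status_levels(), function(s) grid_pmf(te, s),
           numeric(length(grid_pmf(te, "HC")))))

  # planted intervals: near-equal-mass cuts of the marginal grid pmf
  intervals <- lapply(stats::setNames(tests, tests), function(te) {
    v <- vars[vars$name == te, ]
    g <- seq(v$min, v$max, by = v$step)
    if (length(g) <= n_bins) {
      m <- cbind(lo = g, hi = g)
      return(m)
    }
    marg <- as.numeric(pmfs[[te]] %*% props)
    cum <- cumsum(marg)
    cuts <- vapply(seq_len(n_bins - 1) / n_bins,
                   function(qq) which(cum >= qq - 1e-12)[1], integer(1))
    cuts <- unique(pmin(cuts, length(g) - 1))
    lo <- g[c(1, cuts + 1)]
    hi <- g[c(cuts, length(g))]
    cbind(lo = lo, hi = hi)
  })
  steps <- stats::setNames(vars$step, vars$name)[tests]
  bins <- structure(list(
    intervals = intervals,
    k = vapply(intervals, nrow, integer(1)),
    silhouette = stats::setNames(rep(NA_real_, length(tests)), tests),
    step = steps
  ), class = "np_discretization")

  # aggregate grid pmfs onto the planted bins: B[[test]] is k x 3
  bin_pmf <- lapply(stats::setNames(tests, tests), function(te) {
    v <- vars[vars$name == te, ]
    g <- seq(v$min, v$max, by = v$step)
    iv <- intervals[[te]]
    idx <- findInterval(g, iv[, "lo"])
    rowsum(pmfs[[te]], idx)
  })

  nodes <- c(tests, "Status")
  levels <- c(lapply(intervals, function(iv)
    paste0("(", iv[, "lo"], ",", iv[, "hi"], ")")), list(status_levels()))
  names(levels) <- nodes

  cond_on <- function(parent_te, child_te) {
    # R(child | parent) under status-mixture: rows = parent bins
    bp <- bin_pmf[[parent_te]]; bc <- bin_pmf[[child_te]]
    joint <- bp %*% diag(props) %*% t(bc) # parent x child
    joint / rowSums(joint)
  }
  status_given <- function(parent_te) {
    bp <- bin_pmf[[parent_te]]
    num <- sweep(bp, 2, props, `*`) # parent x status
    num / rowSums(num)
  }

  cpts <- list(
    SIM = matrix(as.numeric(bin_pmf$SIM %*% props), nrow = 1),
    BNT30 = cond_on("SIM", "BNT30"),
    VRi = cond_on("BNT30", "VRi"),
    VRd = cond_on("VRi", "VRd"),
    LMi = t(bin_pmf$LMi),
    LMd = cond_on("LMi", "LMd"),
    LMr = cond_on("LMd", "LMr"),
    PASi = t(bin_pmf$PASi),
    PASi_h = cond_on("PASi", "PASi_h"),
    PASd_h = cond_on("PASi_h", "PASd_h"),
    VRr = t(bin_pmf$VRr)
  )

  # Status | VRd, IPF-calibrated so the exact status marginal equals props.
  # The chain preserves single-variable marginals, so P(VRd) is the mixture
  # marginal.
  p_vrd <- as.numeric(bin_pmf$VRd %*% props)
  st <- status_given("VRd")
  for (i in 1:200) {
    m <- as.numeric(p_vrd %*% st)
    st <- sweep(st, 2, props / m, `*`)
    st <- st / rowSums(st)
  }
  cpts$Status <- st

  edges <- rbind(
    c("SIM", "BNT30"), c("BNT30", "VRi"), c("VRi", "VRd"),
    c("VRd", "Status"),
    c("Status", "LMi"), c("LMi", "LMd"), c("LMd", "LMr"),
    c("Status", "PASi"), c("PASi", "PASi_h"), c("PASi_h", "PASd_h"),
    c("Status", "VRr")
  )
  dag <- new_dag(nodes, edges)
  model <- new_bn_model(dag, cpts[nodes], levels)

  structure(list(
    model = model,
    bins = bins,
    group_proportions = props,
    covariates = cal$covariates,
    covariate_missing = cal$covariate_missing,
    missing_rate = missing_rate,
    exam_mean = exam_mean,
    sd_scale = sd_scale
  ), class = "bn_ground_truth")
}

#' @export
print.bn_ground_truth <- function(x, ...) {
  cat("Planted ground truth:", length(x$model$dag$nodes), "nodes,",
      nrow(dag_edges(x$model$dag)), "edges; missing rate", x$missing_rate,
      "\n")
  invisible(x)
}

validate_ground_truth <- function(config) {
  if (!inherits(config, "bn_ground_truth")) {
    stop("config must be a bn_ground_truth")
  }
  if (abs(sum(config$group_proportions) - 1) > 1e-9) {
    stop("group proportions must sum to 1")
  }
  if (config$missing_rate < 0 || config$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  invisible(config)
}

#' Expected raw score of a test given status under a planted configuration
#'
#' Computes the exact bin distribution of `test` conditional on
#' `Status = status` by variable elimination, then maps bins to scores by
#' the mean of the grid values inside each planted interval (the value a
#' bin contributes under the generator's uniform-within-interval score
#' draw).
#'
#' @param config a `bn_ground_truth`.
#' @param test an NP test name.
#' @param status one of `"HC"`, `"AD"`, `"NAD"`.
#' @return expected raw score (numeric scalar).
#' @export
planted_conditional_mean <- function(config, test, status) {
  validate_ground_truth(config)
  post <- exact_posterior(config$model, list(Status = status), target = test)
  iv <- config$bins$intervals[[test]]
  step <- config$bins$step[[test]]
  mids <- vapply(seq_len(nrow(iv)), function(j)
    mean(seq(iv[j, "lo"], iv[j, "hi"], by = step)), numeric(1))
  sum(unclass(post) * mids)
}

#' Sample a synthetic cohort of NP examinations
#'
#' Draws examination rows from a planted ground truth. Participants receive
#' `1 + Geometric` examination counts with the configured mean; a
#' participant's cognitive status is constant across their examinations and
#' all their exam rows are drawn independently from the planted network
#' conditional on that status. Discrete test bins are mapped to raw scores
#' uniformly over the grid points of the bin's interval; covariates are
#' drawn from status-conditional prevalences; test scores are then masked
#' completely at random at the configured missing rate.
#'
#' @param config a `bn_ground_truth` (see [default_ground_truth()]).
#' @param n_exams number of examination rows to generate (>= 1).
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(config, n_exams, seed)`.
#' @return a data.frame of class `np_cohort`: `participant_id`, `exam_id`,
#'   the 11 test scores, `Status`, `sex`, `apoe4`, `education`.
#' @export
sample_cohort <- function(config, n_exams, seed = 1) {
  validate_ground_truth(config)
  stopifnot(n_exams >= 1)
  n_exams <- as.integer(n_exams)
  set.seed(seed)
  model <- config$model
  tests <- np_test_names()

  # participant exam counts, truncated to exactly n_exams rows
  counts <- integer(0)
  while (sum(counts) < n_exams) {
    k <- 1L + stats::rgeom(max(64, ceiling(n_exams / config$exam_mean)),
                           prob = 1 / config$exam_mean)
    counts <- c(counts, k)
  }
  over <- which(cumsum(counts) >= n_exams)[1]
  counts <- counts[seq_len(over)]
  counts[over] <- counts[over] - (sum(counts) - n_exams)
  counts <- counts[counts > 0]
  n_part <- length(counts)

  part_status <- sample.int(3, n_part, replace = TRUE,
                            prob = config$group_proportions)

  # pool of ancestral draws, partitioned by status and topped up on demand
  cm <- compile_model(model)
  s_col <- match("Status", cm$nodes)
  pool <- cpp_logic_sample(cm, as.integer(ceiling(n_exams * 1.8) + 100))
  queues <- lapply(1:3, function(s) pool[pool[, s_col] == s, , drop = FALSE])
  used <- c(0L, 0L, 0L)
  need <- vapply(1:3, function(s) sum(counts[part_status == s]), integer(1))
  for (s in 1:3) {
    while (nrow(queues[[s]]) < need[s]) {
      extra <- cpp_logic_sample(cm, as.integer(2 * n_exams + 100))
      queues[[s]] <- rbind(queues[[s]],
                           extra[extra[, s_col] == s, , drop = FALSE])
    }
  }
  rows <- matrix(NA_integer_, nrow = n_exams, ncol = length(cm$nodes))
  colnames(rows) <- cm$nodes
  pid <- rep(seq_len(n_part), counts)
  for (i in seq_len(n_exams)) {
    s <- part_status[pid[i]]
    used[s] <- used[s] + 1L
    rows[i, ] <- queues[[s]][used[s], ]
  }

  # bins -> raw scores, uniform over the grid points of the interval
  scores <- matrix(NA_real_, nrow = n_exams, ncol = length(tests),
                   dimnames = list(NULL, tests))
  for (te in tests) {
    iv <- config$bins$intervals[[te]]
    step <- config$bins$step[[te]]
    b <- rows[, te]
    for (j in seq_len(nrow(iv))) {
      g <- seq(iv[j, "lo"], iv[j, "hi"], by = step)
      sel <- which(b == j)
      if (length(sel)) {
        scores[sel, te] <- g[sample.int(length(g), length(sel),
                                        replace = TRUE)]
      }
    }
  }

  status <- status_levels()[rows[, "Status"]]
  draw_cov <- function(prev, miss = 0, levels_yes_no) {
    p <- prev[status]
    out <- ifelse(stats::runif(n_exams) < p, levels_yes_no[1],
                  levels_yes_no[2])
    if (miss > 0) out[stats::runif(n_exams) < miss] <- NA
    out
  }
  sex <- draw_cov(config$covariates$male, 0, c("M", "F"))
  apoe4 <- draw_cov(config$covariates$apoe4,
                    config$covariate_missing[["apoe4"]], c("+", "-"))
  education <- draw_cov(config$covariates$education_high,
                        config$covariate_missing[["education"]],
                        c("high", "low"))

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_exams * length(tests)) < config$missing_rate,
                   nrow = n_exams)
    scores[mask] <- NA_real_
  }

  exam_id <- stats::ave(pid, pid, FUN = seq_along)
  out <- data.frame(participant_id = pid, exam_id = exam_id,
                    scores, Status = status, sex = sex, apoe4 = apoe4,
                    education = education, stringsAsFactors = FALSE)
  class(out) <- c("np_cohort", "data.frame")
  out
}
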