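# Minimal discrete-factor algebra backing exact inference. A factor is a
# list(vars, card, val) with val a vector over the joint configurations of
# vars, first variable varying fastest (column-major).

f_make <- function(vars, card, val) {
  stopifnot(length(val) == prod(card))
  list(vars = vars, card = as.integer(card), val = as.numeric(val))
}

# linear indices of a sub-factor within a joint scope
f_index_into <- function(joint_vars, joint_card, sub) {
  total <- prod(joint_card)
  idx <- rep(1, total)
  pos <- match(sub$vars, joint_vars)
  joint_stride <- cumprod(c(1, joint_card))[seq_along(joint_card)]
  sub_stride <- cumprod(c(1, sub$card))[seq_along(sub$card)]
  conf <- 0:(total - 1)
  for (m in seq_along(sub$vars)) {
    j <- pos[m]
    state <- (conf %/% joint_stride[j]) %% joint_card[j]
    idx <- idx + state * sub_stride[m]
  }
  idx
}

f_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  v1 <- f1$val[f_index_into(vars, card, f1)]
  v2 <- f2$val[f_index_into(vars, card, f2)]
  f_make(vars, card, v1 * v2)
}

f_marginalize <- function(f, var) {
  m <- match(var, f$vars)
  if (is.na(m)) return(f)
  arr <- array(f$val, dim = f$card)
  keep <- setdiff(seq_along(f$card), m)
  if (!length(keep)) {
    return(f_make(character(0), integer(0), sum(f$val)))
  }
  val <- apply(arr, keep, sum)
  f_make(f$vars[keep], f$card[keep], as.vector(val))
}

f_reduce <- function(f, var, state) {
  m <- match(var, f$vars)
  if (is.na(m)) return(f)
  stride <- cumprod(c(1, f$card))[seq_along(f$card)]
  conf <- 0:(length(f$val) - 1)
  sel <- ((conf %/% stride[m]) %% f$card[m]) == (state - 1)
  keep <- setdiff(seq_along(f$card), m)
  if (!length(keep)) return(f_make(character(0), integer(0), f$val[sel]))
  f_make(f$vars[keep], f$card[keep], f$val[sel])
}

# sum-product variable elimination over a set of factors, retaining `keep`
ve_eliminate <- function(factors, keep) {
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), keep)
  while (length(elim)) {
    # greedy: eliminate the variable whose combined factor is smallest
    sizes <- vapply(elim, function(v) {
      touch <- factors[vapply(factors, function(f) v %in% f$vars, logical(1))]
      vars <- unique(unlist(lapply(touch, `[[`, "vars")))
      cards <- unlist(lapply(touch, function(f) stats::setNames(f$card, f$vars)))
      prod(cards[match(vars, names(cards))])
    }, numeric(1))
    v <- elim[which.min(sizes)]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prodf <- Reduce(f_product, factors[hit])
    factors <- c(factors[!hit], list(f_marginalize(prodf, v)))
    elim <- setdiff(elim, v)
  }
  Reduce(f_product, factors)
}
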