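# Factor workspace for exact inference. A factor is a non-negative table
# over the state grid of its scope, stored column-major with the first
# variable fastest (the layout of a CPT array).

new_factor <- function(vars, card, values) {
  stopifnot(length(values) == prod(card) || length(vars) == 0)
  list(vars = vars, card = as.integer(card), values = as.numeric(values))
}

factor_lin_index <- function(coords, vars, f) {
  if (length(f$vars) == 0L) return(rep(1L, nrow(coords)))
  m <- coords[, match(f$vars, vars), drop = FALSE]
  strides <- cumprod(c(1, f$card[-length(f$card)]))
  as.vector((m - 1) %*% strides) + 1
}

factor_product <- function(a, b) {
  vars <- union(a$vars, b$vars)
  card <- c(a$card, b$card)[match(vars, c(a$vars, b$vars))]
  n <- prod(card)
  if (length(vars) == 0L)
    return(new_factor(character(0), integer(0), a$values * b$values))
  coords <- arrayInd(seq_len(n), card)
  vals <- a$values[factor_lin_index(coords, vars, a)] *
    b$values[factor_lin_index(coords, vars, b)]
  new_factor(vars, card, vals)
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  stopifnot(!is.na(i))
  if (length(f$vars) == 1L)
    return(new_factor(character(0), integer(0), sum(f$values)))
  arr <- array(f$values, dim = f$card)
  vals <- apply(arr, seq_along(f$card)[-i], sum)
  new_factor(f$vars[-i], f$card[-i], as.vector(vals))
}

factor_reduce <- function(f, var, state_idx) {
  i <- match(var, f$vars)
  stopifnot(!is.na(i))
  keep <- arrayInd(seq_along(f$values), f$card)[, i] == state_idx
  new_factor(f$vars[-i], f$card[-i], f$values[keep])
}

factor_from_cpt <- function(bn, node) {
  pa <- bn$parents[[node]]
  vars <- c(node, pa)
  card <- vapply(vars, function(v) length(bn$levels[[v]]), 1L)
  new_factor(vars, card, as.vector(bn$cpts[[node]]))
}

# Greedy min-degree elimination order over the current factor scopes.
min_degree_order <- function(scopes, elim) {
  order <- character(0)
  scopes <- scopes
  while (length(elim)) {
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
      length(setdiff(nb, v))
    }, 1L)
    v <- elim[which.min(deg)]
    involved <- vapply(scopes, function(s) v %in% s, TRUE)
    merged <- setdiff(unique(unlist(scopes[involved])), v)
    scopes <- c(scopes[!involved], list(merged))
    order <- c(order, v)
    elim <- setdiff(elim, v)
  }
  order
}

#' Exact posterior query by variable elimination
#'
#' Computes the exact posterior distribution of one node given evidence, by
#' sum-product variable elimination. The elimination order is chosen by a
#' greedy min-degree heuristic (exactness does not depend on the order; an
#' explicit order can be supplied to verify this).
#'
#' @param bn a `dbn`.
#' @param target node to query.
#' @param evidence named character vector or list mapping observed nodes to
#'   their states; may be empty.
#' @param elim_order optional explicit elimination order (permutation of the
#'   non-target, non-evidence nodes).
#' @return Named numeric vector of posterior probabilities over the target's
#'   states (sums to 1).
#' @export
bn_query <- function(bn, target, evidence = NULL, elim_order = NULL) {
  nodes <- bn$dag$nodes
  if (!target %in% nodes) stop("unknown node '", target, "'", call. = FALSE)
  evidence <- unlist(evidence)
  if (length(evidence)) {
    unknown <- setdiff(names(evidence), nodes)
    if (length(unknown))
      stop("unknown evidence node(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (target %in% names(evidence))
      stop("target must not appear in the evidence", call. = FALSE)
    for (v in names(evidence))
      if (!evidence[[v]] %in% bn$levels[[v]])
        stop("'", evidence[[v]], "' is not a state of '", v, "'",
             call. = FALSE)
  }
  facs <- lapply(nodes, factor_from_cpt, bn = bn)
  for (v in names(evidence)) {
    si <- match(evidence[[v]], bn$levels[[v]])
    facs <- lapply(facs, function(f)
      if (v %in% f$vars) factor_reduce(f, v, si) else f)
  }
  elim <- setdiff(nodes, c(target, names(evidence)))
  if (is.null(elim_order)) {
    elim_order <- min_degree_order(lapply(facs, `[[`, "vars"), elim)
  } else {
    if (!setequal(elim_order, elim))
      stop("elim_order must be a permutation of the non-target, ",
           "non-evidence nodes", call. = FALSE)
  }
  for (v in elim_order) {
    involved <- vapply(facs, function(f) v %in% f$vars, TRUE)
    if (!any(involved)) next
    psi <- Reduce(factor_product, facs[involved])
    facs <- c(facs[!involved], list(factor_marginalize(psi, v)))
  }
  res <- Reduce(factor_product, facs)
  if (length(res$vars) && !identical(res$vars, target)) {
    for (v in setdiff(res$vars, target)) res <- factor_marginalize(res, v)
  }
  tot <- sum(res$values)
  if (tot <= 0)
    stop("evidence has zero probability under the network", call. = FALSE)
  p <- res$values / tot
  if (!length(res$vars)) stop("target was eliminated", call. = FALSE)
  stats::setNames(p, bn$levels[[target]])
}

#' Conditional-probability report for pairs of risk factors
#'
#' For each pair of variables, instantiates both to their designated risk
#' states (e.g. smoking = past-or-current, hypertension = yes, BMI =
#' obesity, lipids at their adverse level) and reports the exact posterior
#' of the target outcome, as percentages. HDL-C's adverse level is "low"
#' (low HDL-C carries the higher cardiovascular risk).
#'
#' @param bn a `dbn`.
#' @param pairs two-column character matrix (or data frame) of variable
#'   pairs; defaults to the twelve standard report pairs.
#' @param target outcome node (default "ascvd").
#' @param schema cohort schema supplying each variable's risk state.
#' @return Data frame with columns `var1`, `var2`, `state1`, `state2`,
#'   `cp_no`, `cp_yes` (percentages; each row sums to 100).
#' @export
cp_report <- function(bn, pairs = cp_report_pairs(), target = "ascvd",
                      schema = cohort_schema()) {
  pairs <- as.matrix(pairs)
  out <- data.frame(var1 = pairs[, 1], var2 = pairs[, 2],
                    state1 = NA_character_, state2 = NA_character_,
                    cp_no = NA_real_, cp_yes = NA_real_, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs[i, 1]; v2 <- pairs[i, 2]
    if (v1 == target || v2 == target || v1 == v2)
      stop("pair variables must be distinct from the target", call. = FALSE)
    s1 <- schema[[v1]]$risk; s2 <- schema[[v2]]$risk
    out$state1[i] <- s1; out$state2[i] <- s2
    ev <- stats::setNames(c(s1, s2), c(v1, v2))
    post <- tryCatch(bn_query(bn, target, ev), error = function(e) e)
    if (inherits(post, "error")) {
      out$note[i] <- conditionMessage(post)
    } else {
      out$cp_no[i] <- 100 * post[["no"]]
      out$cp_yes[i] <- 100 * post[["yes"]]
    }
  }
  out
}

#' The twelve standard risk-factor pairs of the conditional-probability report
#' @return Two-column character matrix of variable pairs.
#' @export
cp_report_pairs <- function() {
  rbind(
    c("smoking", "hypertension"), c("smoking", "bmi"), c("smoking", "ldl"),
    c("smoking", "hdl"), c("bmi", "hdl"), c("bmi", "diabetes"),
    c("age", "diabetes"), c("age", "hypertension"), c("age", "fbs"),
    c("hdl", "tc"), c("fbs", "hypertension"), c("fbs", "hdl")
  )
}

dist_between <- function(p, q, metric) {
  switch(metric,
         euclidean = sqrt(sum((p - q)^2)),
         hellinger = sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2),
         tv = 0.5 * sum(abs(p - q)),
         stop("unknown metric '", metric, "'", call. = FALSE))
}

#' Strength of influence of one arc
#'
#' Measures how strongly a parent sways its child's conditional
#' distribution: for every configuration of the child's other parents, the
#' chosen distance is computed between the child's conditionals for each
#' unordered pair of the parent's states, and the unweighted mean over
#' configurations and pairs is returned. Zero iff the child's CPT ignores
#' the parent.
#'
#' @param bn a `dbn`.
#' @param from,to the arc (must exist in the network).
#' @param metric "euclidean" (default), "hellinger" or "tv" (total
#'   variation).
#' @return Single non-negative number.
#' @export
strength_of_influence <- function(bn, from, to, metric = "euclidean") {
  g <- bn$dag
  if (!any(g$edges[, 1] == from & g$edges[, 2] == to))
    stop("no arc ", from, " -> ", to, " in the network", call. = FALSE)
  pa <- bn$parents[[to]]
  j <- match(from, pa)
  arr <- bn$cpts[[to]]
  r <- length(bn$levels[[to]])
  s <- length(bn$levels[[from]])
  card <- c(r, vapply(pa, function(p) length(bn$levels[[p]]), 1L))
  perm <- c(1L, 1L + j, setdiff(seq_along(pa), j) + 1L)
  m <- aperm(array(as.vector(arr), dim = card), perm)
  q_other <- prod(card[-c(1L, 1L + j)])
  dim(m) <- c(r, s, q_other)
  prs <- utils::combn(s, 2)
  d <- 0; cnt <- 0L
  for (q in seq_len(q_other)) {
    for (k in seq_len(ncol(prs))) {
      d <- d + dist_between(m[, prs[1, k], q], m[, prs[2, k], q], metric)
      cnt <- cnt + 1L
    }
  }
  d / cnt
}

#' Strength-of-influence table for every arc of a network
#'
#' @param bn a `dbn`.
#' @param metric distance metric, see [strength_of_influence()].
#' @return Data frame with columns `from`, `to`, `strength`, one row per
#'   arc in edge-list order.
#' @export
strength_table <- function(bn, metric = "euclidean") {
  e <- bn$dag$edges
  data.frame(
    from = e[, 1], to = e[, 2],
    strength = vapply(seq_len(nrow(e)), function(i)
      strength_of_influence(bn, e[i, 1], e[i, 2], metric), 1),
    stringsAsFactors = FALSE)
}
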