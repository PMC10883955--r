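# Independent brute-force oracles used to verify the package's algorithms.
# These deliberately avoid the code paths they check: full-joint enumeration
# instead of variable elimination, undirected-path enumeration instead of
# moralization, all-pairs counting instead of the rank statistic, and direct
# hypergeometric summation instead of fisher.test.

# Full joint table of a small discrete network, as a data frame of states
# plus a probability column.
oracle_joint <- function(bn) {
  nodes <- bn$dag$nodes
  grid <- expand.grid(bn$levels[nodes], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- bn$parents[[v]]
    fam <- c(v, pa)
    card <- vapply(fam, function(u) length(bn$levels[[u]]), 1L)
    codes <- vapply(fam, function(u) match(grid[[u]], bn$levels[[u]]),
                    integer(nrow(grid)))
    strides <- cumprod(c(1, card[-length(card)]))
    idx <- as.vector((codes - 1) %*% strides) + 1
    p <- p * as.vector(bn$cpts[[v]])[idx]
  }
  grid$prob <- p
  grid
}

# Posterior of `target` given evidence by summing the full joint.
oracle_posterior <- function(bn, target, evidence = NULL) {
  joint <- oracle_joint(bn)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  p <- vapply(bn$levels[[target]],
              function(s) sum(joint$prob[keep & joint[[target]] == s]), 1)
  p / sum(p)
}

oracle_descendants <- function(g, node) {
  desc <- character(0)
  frontier <- node
  repeat {
    ch <- unique(g$edges[g$edges[, 1] %in% frontier, 2])
    new <- setdiff(ch, desc)
    if (!length(new)) break
    desc <- c(desc, new)
    frontier <- new
  }
  desc
}

# d-separation by enumerating every simple undirected path and applying the
# chain/fork/collider blocking rules path by path.
oracle_dsep <- function(g, x, y, z = character(0)) {
  E <- g$edges
  nbrs <- function(v) unique(c(E[E[, 1] == v, 2], E[E[, 2] == v, 1]))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v %in% y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  for (s in x) walk(s)
  blocked <- function(path) {
    if (length(path) < 3) return(FALSE)
    for (i in 2:(length(path) - 1)) {
      a <- path[i - 1]; m <- path[i]; b <- path[i + 1]
      collider <- any(E[, 1] == a & E[, 2] == m) &&
        any(E[, 1] == b & E[, 2] == m)
      if (collider) {
        if (!any(c(m, oracle_descendants(g, m)) %in% z)) return(TRUE)
      } else if (m %in% z) return(TRUE)
    }
    FALSE
  }
  all(vapply(paths, blocked, TRUE))
}

# AUC by counting all positive/negative pairs, ties worth one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration.
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  a_all <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(a_all, c1, c2, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random discrete network with Dirichlet-ish random CPTs (for oracle
# equivalence checks). Deterministic given `seed`.
random_net <- function(n_nodes, seed, p_edge = 0.4, max_card = 3) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  cards <- sample(2:max_card, n_nodes, replace = TRUE)
  names(cards) <- nodes
  ord <- sample(nodes)
  edges <- NULL
  for (j in seq_len(n_nodes)[-1]) {
    for (i in seq_len(j - 1)) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(ord[i], ord[j]))
    }
  }
  g <- dag(nodes, edges)
  lv <- lapply(cards, function(k) letters[seq_len(k)])
  cpts <- lapply(nodes, function(v) {
    pa <- dag_parents(g, v)
    card <- c(cards[[v]], vapply(pa, function(p) cards[[p]], 1L))
    m <- matrix(stats::rgamma(prod(card), 1) + 0.05, nrow = card[1])
    m <- sweep(m, 2, colSums(m), "/")
    arr <- array(as.vector(m), dim = card, dimnames = c(lv[v], lv[pa]))
    attr(arr, "parents") <- pa
    arr
  })
  names(cpts) <- nodes
  bayes_net(g, cpts, lv)
}

# Convenience: small hand-specified nets.
two_node_net <- function() {
  g <- dag(c("X", "Y"), rbind(c("X", "Y")))
  cx <- array(c(0.6, 0.4), 2, dimnames = list(c("x1", "x2")))
  attr(cx, "parents") <- character(0)
  cy <- array(c(0.9, 0.1, 0.2, 0.8), c(2, 2),
              dimnames = list(c("y1", "y2"), c("x1", "x2")))
  attr(cy, "parents") <- "X"
  bayes_net(g, list(X = cx, Y = cy))
}

collider_net <- function() {
  g <- dag(c("X", "Y", "Z"), rbind(c("X", "Z"), c("Y", "Z")))
  cu <- array(c(0.5, 0.5), 2, dimnames = list(c("a", "b")))
  attr(cu, "parents") <- character(0)
  cz <- array(c(0.9, 0.1, 0.5, 0.5, 0.5, 0.5, 0.1, 0.9), c(2, 2, 2),
              dimnames = list(c("a", "b"), c("a", "b"), c("a", "b")))
  attr(cz, "parents") <- c("X", "Y")
  bayes_net(g, list(X = cu, Y = cu, Z = cz))
}

# Standard synthetic cohort used across tests (cached per session).
test_cohort <- local({
  cache <- new.env()
  function(n = 491, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) cache[[key]] <- sample_cohort(n, seed = seed)
    cache[[key]]
  }
})
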