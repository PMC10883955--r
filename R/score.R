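#' Learning hyper-parameters
#'
#' Bundles the knobs of parametric and structural learning: the Dirichlet
#' pseudo-count used when CPTs are fitted for prediction, the structure
#' search's parent-set bound, number of random restarts, iteration cap,
#' BDeu equivalent sample size, and RNG seed.
#'
#' @param prior_alpha Dirichlet pseudo-count per CPT cell (>= 0).
#' @param max_parents maximum in-degree during structure search (>= 1).
#' @param restarts number of hill-climbing restarts (>= 1; the first starts
#'   from the empty graph, later ones from random DAGs).
#' @param max_iterations cap on arc changes within one restart.
#' @param ess BDeu equivalent sample size.
#' @param seed integer RNG seed for the random restarts.
#' @return A `learning_config` list.
#' @export
learning_config <- function(prior_alpha = 1, max_parents = 8, restarts = 20,
                            max_iterations = 200, ess = 1, seed = 1) {
  stopifnot(prior_alpha >= 0, max_parents >= 1, restarts >= 1, ess > 0)
  structure(list(prior_alpha = prior_alpha, max_parents = max_parents,
                 restarts = restarts, max_iterations = max_iterations,
                 ess = ess, seed = as.integer(seed)),
            class = "learning_config")
}

# BDeu family score of `child` given `parents` from an integer code matrix.
bdeu_family <- function(codes, card, child, parents, ess = 1) {
  r <- card[[child]]
  q <- if (length(parents)) prod(unlist(card[parents])) else 1L
  a_ijk <- ess / (r * q)
  a_ij <- ess / q
  fam_card <- c(r, unlist(card[parents], use.names = FALSE))
  idx <- linear_index(codes[, c(child, parents), drop = FALSE], fam_card)
  n_ijk <- tabulate(idx, nbins = r * q)
  n_ij <- colSums(matrix(n_ijk, nrow = r))
  sum(lgamma(a_ij) - lgamma(a_ij + n_ij)) +
    sum(lgamma(a_ijk + n_ijk) - lgamma(a_ijk))
}

#' BDeu network score
#'
#' Decomposable Bayesian Dirichlet equivalent uniform log marginal
#' likelihood of a structure given data (uniform structure prior).
#'
#' @param structure a `bn_dag`.
#' @param data data frame of factors covering the structure's nodes.
#' @param ess equivalent sample size.
#' @return List with `total` and `per_family` (named numeric vector).
#' @export
bdeu_score <- function(structure, data, ess = 1) {
  codes <- vapply(structure$nodes, function(v) as.integer(as.factor(data[[v]])),
                  integer(nrow(data)))
  if (nrow(data) == 1L) codes <- matrix(codes, nrow = 1L,
                                        dimnames = list(NULL, structure$nodes))
  card <- lapply(structure$nodes, function(v) nlevels(as.factor(data[[v]])))
  names(card) <- structure$nodes
  per <- vapply(structure$nodes, function(v)
    bdeu_family(codes, card, v, dag_parents(structure, v), ess), 1)
  list(total = sum(per), per_family = per)
}

# --- hill-climbing machinery over adjacency matrices -----------------------

amat_from_dag <- function(g) {
  n <- length(g$nodes)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) a[g$edges] <- 1L
  a
}

dag_from_amat <- function(a) {
  idx <- which(a == 1L, arr.ind = TRUE)
  dag(rownames(a), cbind(rownames(a)[idx[, 1]], colnames(a)[idx[, 2]]))
}

# would adding from->to create a cycle? (is `from` reachable from `to`?)
amat_path <- function(a, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(a))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (any(nxt == to)) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

random_dag_amat <- function(nodes, max_parents, p = 0.15) {
  n <- length(nodes)
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  ord <- sample.int(n)
  for (j in 2:n) {
    cand <- ord[seq_len(j - 1)]
    pick <- cand[stats::runif(length(cand)) < p]
    if (length(pick) > max_parents) pick <- pick[seq_len(max_parents)]
    a[pick, ord[j]] <- 1L
  }
  a
}

#' Score-based structure learning by hill climbing
#'
#' Greedy search over single-arc moves (add, delete, reverse) maximizing
#' the BDeu score, with random restarts. Decomposability makes move
#' evaluation incremental: only the affected families are re-scored, and
#' family scores are cached across the whole search. The first restart
#' starts from the empty graph; subsequent restarts from random DAGs drawn
#' under the given seed, so the result is deterministic given data, config
#' and seed. The best-scoring DAG over all restarts is returned.
#'
#' @param data data frame of factors.
#' @param config a [learning_config()].
#' @param nodes variables to include (default: all columns of `data`).
#' @param trace logical; keep a per-move log.
#' @return A `bn_dag`; attributes `score` (BDeu total) and, when
#'   `trace = TRUE`, `trace` (data frame: restart, iteration, move, from,
#'   to, score).
#' @export
bayesian_search <- function(data, config = learning_config(),
                            nodes = names(data), trace = FALSE) {
  stopifnot(nrow(data) >= 1)
  n <- length(nodes)
  codes <- vapply(nodes, function(v) as.integer(as.factor(data[[v]])),
                  integer(nrow(data)))
  if (nrow(data) == 1L) codes <- matrix(codes, nrow = 1L,
                                        dimnames = list(NULL, nodes))
  card <- lapply(nodes, function(v) nlevels(as.factor(data[[v]])))
  names(card) <- nodes
  cache <- new.env(parent = emptyenv())
  fam_score <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bdeu_family(codes, card, child, parents, config$ess)
      cache[[key]] <- val
    }
    val
  }
  parents_of <- function(a, j) nodes[a[, j] == 1L]

  climb <- function(a) {
    fams <- vapply(seq_len(n), function(j) fam_score(nodes[j], parents_of(a, j)), 1)
    total <- sum(fams)
    log <- list()
    for (iter in seq_len(config$max_iterations)) {
      best <- NULL
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        if (a[i, j] == 1L) {
          # delete i -> j
          d <- fam_score(nodes[j], setdiff(parents_of(a, j), nodes[i])) - fams[j]
          if (is.null(best) || d > best$delta + 1e-9)
            best <- list(delta = d, move = "delete", i = i, j = j)
          # reverse i -> j  (j -> i must stay acyclic and respect max_parents)
          if (sum(a[, i]) < config$max_parents) {
            a2 <- a; a2[i, j] <- 0L
            if (!amat_path(a2, i, j)) {
              d2 <- d + fam_score(nodes[i], c(parents_of(a, i), nodes[j])) - fams[i]
              if (is.null(best) || d2 > best$delta + 1e-9)
                best <- list(delta = d2, move = "reverse", i = i, j = j)
            }
          }
        } else if (a[j, i] == 0L) {
          # add i -> j
          if (sum(a[, j]) >= config$max_parents) next
          if (amat_path(a, j, i)) next
          d <- fam_score(nodes[j], c(parents_of(a, j), nodes[i])) - fams[j]
          if (is.null(best) || d > best$delta + 1e-9)
            best <- list(delta = d, move = "add", i = i, j = j)
        }
      }
      if (is.null(best) || best$delta <= 1e-9) break
      i <- best$i; j <- best$j
      if (best$move == "add") a[i, j] <- 1L
      if (best$move == "delete") a[i, j] <- 0L
      if (best$move == "reverse") { a[i, j] <- 0L; a[j, i] <- 1L }
      fams[j] <- fam_score(nodes[j], parents_of(a, j))
      if (best$move == "reverse") fams[i] <- fam_score(nodes[i], parents_of(a, i))
      total <- total + best$delta
      log[[length(log) + 1L]] <- data.frame(
        iteration = iter, move = best$move, from = nodes[i], to = nodes[j],
        score = total)
    }
    list(a = a, score = total,
         log = if (length(log)) do.call(rbind, log) else NULL)
  }

  runs <- with_seed(config$seed, {
    lapply(seq_len(config$restarts), function(r) {
      a0 <- if (r == 1L) matrix(0L, n, n, dimnames = list(nodes, nodes))
            else random_dag_amat(nodes, config$max_parents)
      res <- climb(a0)
      res$restart <- r
      res
    })
  })
  scores <- vapply(runs, `[[`, 1, "score")
  best <- runs[[which.max(scores)]]
  out <- dag_from_amat(best$a)
  attr(out, "score") <- best$score
  if (trace) {
    logs <- lapply(runs, function(r)
      if (!is.null(r$log)) cbind(restart = r$restart, r$log) else NULL)
    attr(out, "trace") <- do.call(rbind, logs)
  }
  out
}

# skeleton + v-structures; two DAGs are Markov equivalent iff these agree.
cpdag_signature <- function(g) {
  und <- unique(t(apply(g$edges, 1, sort)))
  vs <- list()
  for (v in g$nodes) {
    pa <- dag_parents(g, v)
    if (length(pa) > 1) {
      prs <- utils::combn(sort(pa), 2)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        adjacent <- any((g$edges[, 1] == a & g$edges[, 2] == b) |
                        (g$edges[, 1] == b & g$edges[, 2] == a))
        if (!adjacent) vs[[length(vs) + 1L]] <- c(a, v, b)
      }
    }
  }
  list(skeleton = und[order(und[, 1], und[, 2]), , drop = FALSE],
       vstructures = vs[order(vapply(vs, paste, "", collapse = "|"))])
}

#' Are two DAGs Markov equivalent?
#'
#' True when the graphs share the same skeleton and the same v-structures
#' (immoralities), i.e. encode identical conditional-independence models.
#'
#' @param g1,g2 `bn_dag` objects over the same node set.
#' @return Logical.
#' @export
markov_equivalent <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) return(FALSE)
  s1 <- cpdag_signature(g1); s2 <- cpdag_signature(g2)
  identical(unname(s1$skeleton), unname(s2$skeleton)) &&
    identical(s1$vstructures, s2$vstructures)
}

#' Enumerate every DAG on a small node set
#'
#' Exhaustive enumeration used as an oracle for the structure search (25
#' DAGs exist on 3 nodes). Intended for <= 4 nodes.
#'
#' @param nodes character vector of node names.
#' @return List of `bn_dag` objects.
#' @export
all_dags <- function(nodes) {
  n <- length(nodes)
  prs <- utils::combn(n, 2)
  m <- ncol(prs)
  out <- list()
  states <- as.matrix(expand.grid(rep(list(0:2), m)))
  for (s in seq_len(nrow(states))) {
    a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    for (k in seq_len(m)) {
      st <- states[s, k]
      if (st == 1) a[prs[1, k], prs[2, k]] <- 1L
      if (st == 2) a[prs[2, k], prs[1, k]] <- 1L
    }
    g <- tryCatch(dag_from_amat(a), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}
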