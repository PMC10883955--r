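#' Construct a discrete Bayesian network
#'
#' Couples a DAG with one conditional probability table (CPT) per node. Each
#' CPT is a numeric array whose first dimension indexes the child's states
#' and whose remaining dimensions index the parents' states, in the order
#' given by `parents`; columns (child distributions per parent
#' configuration) must sum to one.
#'
#' @param structure a `bn_dag`.
#' @param cpts named list of CPT arrays, one per node. Arrays must carry
#'   `dimnames` naming the states; parent order is taken from the array's
#'   dimension names attribute `vars` or, when absent, from the DAG's edge
#'   list order.
#' @param levels named list of state labels per node; defaults to the state
#'   names found in the CPTs.
#' @param check validate the network on construction.
#' @return Object of class `dbn` with elements `dag`, `cpts`, `levels`,
#'   `parents` (named list, parent order used by each CPT).
#' @export
bayes_net <- function(structure, cpts, levels = NULL, check = TRUE) {
  stopifnot(inherits(structure, "bn_dag"))
  parents <- lapply(structure$nodes, function(v) {
    p <- attr(cpts[[v]], "parents")
    if (is.null(p)) dag_parents(structure, v) else p
  })
  names(parents) <- structure$nodes
  if (is.null(levels)) {
    levels <- lapply(structure$nodes, function(v) dimnames(cpts[[v]])[[1]])
    names(levels) <- structure$nodes
  }
  bn <- list(dag = structure, cpts = cpts, levels = levels,
             parents = parents)
  class(bn) <- "dbn"
  if (check) {
    rep <- validate_network(bn)
    if (!rep$valid)
      stop("invalid network:\n  ", paste(rep$failures, collapse = "\n  "),
           call. = FALSE)
  }
  bn
}

#' Validate a discrete Bayesian network
#'
#' Checks structural acyclicity, agreement between CPT parents and
#' structural parents, state-space consistency, probability bounds, and
#' per-configuration normalization (columns sum to one within 1e-9).
#'
#' @param bn a `dbn`.
#' @return List with `valid` (logical) and `failures` (character vector of
#'   itemized problems; empty when valid).
#' @export
validate_network <- function(bn) {
  f <- character(0)
  g <- bn$dag
  if (is.null(topo_sort(g))) f <- c(f, "structure contains a directed cycle")
  for (v in g$nodes) {
    cpt <- bn$cpts[[v]]
    if (is.null(cpt)) { f <- c(f, paste0(v, ": missing CPT")); next }
    pa <- bn$parents[[v]]
    if (!setequal(pa, dag_parents(g, v)))
      f <- c(f, paste0(v, ": CPT parents (", paste(pa, collapse = ","),
                       ") differ from structural parents (",
                       paste(dag_parents(g, v), collapse = ","), ")"))
    card <- c(length(bn$levels[[v]]),
              vapply(pa, function(p) length(bn$levels[[p]]), 1L))
    if (!identical(as.integer(dim(cpt) %||% length(cpt)),
                   as.integer(card)))
      f <- c(f, paste0(v, ": CPT dimensions inconsistent with state spaces"))
    vals <- as.vector(cpt)
    if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
      f <- c(f, paste0(v, ": probabilities outside [0, 1]"))
    m <- matrix(vals, nrow = length(bn$levels[[v]]))
    tot <- colSums(m)
    bad <- which(abs(tot - 1) > 1e-9)
    if (length(bad))
      f <- c(f, paste0(v, ": distribution for parent configuration ",
                       bad[1], " sums to ", format(tot[bad[1]]),
                       " (not 1)"))
  }
  list(valid = length(f) == 0, failures = f)
}

#' @export
print.dbn <- function(x, ...) {
  k <- sum(vapply(x$dag$nodes, function(v) {
    q <- prod(vapply(x$parents[[v]], function(p) length(x$levels[[p]]), 1L))
    (length(x$levels[[v]]) - 1L) * q
  }, 1))
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "arcs,", k, "free parameters\n")
  for (v in x$dag$nodes) {
    pa <- x$parents[[v]]
    cat("  ", v, " (", paste(x$levels[[v]], collapse = "/"), ")",
        if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.dbn <- function(object, ...) {
  print(object)
  cat("\nMarginal distributions (exact, by variable elimination):\n")
  for (v in object$dag$nodes) {
    m <- bn_query(object, v)
    cat(sprintf("  %-13s %s\n", v,
                paste(sprintf("%s %.3f", names(m), m), collapse = "  ")))
  }
  invisible(object)
}

#' @export
coef.dbn <- function(object, ...) object$cpts

#' Plot the network structure
#'
#' @param x a `dbn` or `bn_dag`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.dbn <- function(x, ...) plot(x$dag, ...)

#' @export
plot.bn_dag <- function(x, ...) {
  g <- igraph::graph_from_data_frame(as.data.frame(x$edges), directed = TRUE,
                                     vertices = x$nodes)
  igraph::plot.igraph(g, vertex.size = 24, vertex.color = "lightsteelblue",
                      edge.arrow.size = 0.4, ...)
}

n_free_parameters <- function(bn) {
  sum(vapply(bn$dag$nodes, function(v) {
    q <- prod(vapply(bn$parents[[v]], function(p) length(bn$levels[[p]]), 1L))
    (length(bn$levels[[v]]) - 1L) * q
  }, 1))
}

#' Serialize a network to structured text, and read it back
#'
#' Writes a YAML document listing, per node, its states, parents and
#' flattened CPT values (column-major: child states fastest, then parents in
#' listed order). Probabilities are printed with 17 significant digits so a
#' write/read/write round trip is byte-identical.
#'
#' @param bn a `dbn`.
#' @param path output (input) file path.
#' @return `path` invisibly; for [read_bayes_net()], the reconstructed `dbn`.
#' @export
write_bayes_net <- function(bn, path) {
  q <- function(x) if (length(x)) paste0("'", x, "'", collapse = ", ") else ""
  lines <- c("nodes:")
  for (v in bn$dag$nodes) {
    lines <- c(lines,
      paste0("  ", v, ":"),
      paste0("    states: [", q(bn$levels[[v]]), "]"),
      paste0("    parents: [", q(bn$parents[[v]]), "]"),
      paste0("    cpt: [", paste(fmt_num(as.vector(bn$cpts[[v]])),
                                 collapse = ", "), "]"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bayes_net
#' @export
read_bayes_net <- function(path) {
  doc <- yaml::read_yaml(path)
  nodes <- names(doc$nodes)
  edges <- do.call(rbind, lapply(nodes, function(v) {
    pa <- doc$nodes[[v]]$parents
    if (length(pa)) cbind(pa, v) else NULL
  }))
  g <- dag(nodes, edges)
  levels <- lapply(doc$nodes, function(nd) as.character(nd$states))
  cpts <- list()
  for (v in nodes) {
    nd <- doc$nodes[[v]]
    pa <- as.character(nd$parents %||% character(0))
    card <- c(length(levels[[v]]),
              vapply(pa, function(p) length(levels[[p]]), 1L))
    arr <- array(as.numeric(nd$cpt), dim = card,
                 dimnames = c(list(levels[[v]]), levels[pa]))
    attr(arr, "parents") <- pa
    cpts[[v]] <- arr
  }
  bayes_net(g, cpts, levels)
}
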