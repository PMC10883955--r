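#' Directed acyclic graph over named nodes
#'
#' Lightweight structure holding node names and an edge list. Construction
#' validates that edge endpoints are nodes, that there are no self-loops, and
#' that the graph is acyclic (by topological sort).
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix (or data frame) of from/to pairs;
#'   may have zero rows.
#' @return An object of class `bn_dag` with elements `nodes` and `edges`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(character(0), ncol = 2)
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  rownames(edges) <- NULL
  bad <- !(edges %in% nodes)
  if (any(bad))
    stop("edge endpoint(s) not in node set: ",
         paste(unique(edges[bad]), collapse = ", "), call. = FALSE)
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed", call. = FALSE)
  if (anyDuplicated(paste(edges[, 1], edges[, 2])))
    stop("duplicate edges", call. = FALSE)
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  ord <- topo_sort(g)
  if (is.null(ord)) {
    cyc <- find_cycle(g)
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Directed acyclic graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "arcs\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges))
    cat("  arcs: ", paste(x$edges[, 1], "->", x$edges[, 2], collapse = "; "),
        "\n")
  invisible(x)
}

#' Parents / children of a node
#' @param g a `bn_dag`.
#' @param node node name.
#' @return Character vector of parent (child) node names, in edge-list order.
#' @export
dag_parents <- function(g, node) {
  stopifnot(node %in% g$nodes)
  g$edges[g$edges[, 2] == node, 1]
}

#' @rdname dag_parents
#' @export
dag_children <- function(g, node) {
  stopifnot(node %in% g$nodes)
  g$edges[g$edges[, 1] == node, 2]
}

# Kahn topological sort; NULL if cyclic.
topo_sort <- function(g) {
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(g$edges)) {
    t <- table(g$edges[, 2])
    indeg[names(t)] <- as.integer(t)
  }
  out <- character(0)
  avail <- nodes[indeg == 0]
  indeg <- indeg
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    ch <- g$edges[g$edges[, 1] == v, 2]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(out) != length(nodes)) return(NULL)
  out
}

# Locate one directed cycle by DFS (used for error messages).
find_cycle <- function(g) {
  adj <- split(g$edges[, 2], factor(g$edges[, 1], levels = g$nodes))
  state <- stats::setNames(integer(length(g$nodes)), g$nodes)  # 0 new 1 open 2 done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (!is.null(found)) return()
      if (state[w] == 1L) {
        found <<- c(path[which(path == w)[1]:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in g$nodes) if (state[v] == 0L) visit(v)
  found
}

dag_ancestors <- function(g, nodes) {
  anc <- unique(nodes)
  repeat {
    pa <- unique(g$edges[g$edges[, 2] %in% anc, 1])
    new <- setdiff(pa, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  anc
}

dag_descendants <- function(g, node) {
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

#' The literature-derived 13-node ASCVD network structure
#'
#' Returns the knowledge-based DAG over the 13 cohort variables: age and sex
#' are roots; ASCVD receives nine arcs (from age, BMI, T-C, diabetes, FBS,
#' HDL-C, hypertension, LDL-C and smoking) and has no children; metabolic
#' syndrome is determined by its component factors (BMI, FBS, TG). The 39
#' arcs encode established epidemiological dependence among demographic,
#' metabolic and lipid variables.
#'
#' @return A `bn_dag` with 13 nodes and 39 arcs.
#' @export
knowledge_dag <- function() {
  e <- rbind(
    c("age", "fbs"), c("age", "ascvd"), c("age", "diabetes"),
    c("age", "bmi"), c("age", "hypertension"), c("age", "smoking"),
    c("bmi", "fbs"), c("bmi", "mets"), c("bmi", "ascvd"),
    c("bmi", "diabetes"), c("bmi", "tg"), c("bmi", "hypertension"),
    c("bmi", "hdl"),
    c("tc", "ldl"), c("tc", "ascvd"),
    c("diabetes", "ascvd"),
    c("fbs", "tg"), c("fbs", "hypertension"), c("fbs", "mets"),
    c("fbs", "hdl"), c("fbs", "ascvd"),
    c("hdl", "tc"), c("hdl", "ascvd"),
    c("hypertension", "ascvd"),
    c("ldl", "ascvd"),
    c("sex", "hdl"), c("sex", "smoking"), c("sex", "diabetes"),
    c("sex", "hypertension"), c("sex", "tg"),
    c("smoking", "ldl"), c("smoking", "ascvd"), c("smoking", "bmi"),
    c("smoking", "hypertension"), c("smoking", "tg"), c("smoking", "hdl"),
    c("tg", "diabetes"), c("tg", "mets"), c("tg", "hdl")
  )
  dag(cohort_variables(), e)
}

#' Test d-separation of two node sets given a conditioning set
#'
#' Implements the standard graphical criterion: `x` and `y` are d-separated
#' by `z` when every path between them is blocked — a chain or fork is
#' blocked when its middle node is in `z`, a collider is blocked when
#' neither it nor any of its descendants is in `z`. The test is carried out
#' on the moralized ancestral graph of `x`, `y`, `z` (an equivalent
#' formulation): the sets are d-separated iff `z` separates them in that
#' undirected graph.
#'
#' @param g a `bn_dag`.
#' @param x,y,z character vectors of node names; `z` may be empty. The three
#'   sets must be disjoint.
#' @return TRUE if `x` and `y` are d-separated given `z`.
#' @export
is_dseparated <- function(g, x, y, z = character(0)) {
  all_nodes <- c(x, y, z)
  unknown <- setdiff(all_nodes, g$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(all_nodes))
    stop("x, y and z must be disjoint", call. = FALSE)
  if (!length(x) || !length(y)) stop("x and y must be non-empty", call. = FALSE)

  keep <- dag_ancestors(g, c(x, y, z))
  sub <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, , drop = FALSE]
  # moralize: undirected skeleton + marry co-parents
  und <- rbind(sub, sub[, 2:1, drop = FALSE])
  for (v in keep) {
    pa <- sub[sub[, 2] == v, 1]
    if (length(pa) > 1) {
      prs <- t(utils::combn(pa, 2))
      und <- rbind(und, prs, prs[, 2:1, drop = FALSE])
    }
  }
  # remove z, then check connectivity from x to y
  und <- und[!(und[, 1] %in% z) & !(und[, 2] %in% z), , drop = FALSE]
  reach <- intersect(x, keep)
  repeat {
    nb <- unique(und[und[, 1] %in% reach, 2])
    new <- setdiff(nb, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  !any(y %in% reach)
}

#' Export a DAG as Graphviz DOT text or an edge-list CSV
#'
#' @param g a `bn_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dag_dot <- function(g, path) {
  lines <- c("digraph bn {",
             paste0("  \"", g$nodes, "\";"),
             if (nrow(g$edges))
               paste0("  \"", g$edges[, 1], "\" -> \"", g$edges[, 2], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dag_dot
#' @export
write_dag_csv <- function(g, path) {
  utils::write.csv(as.data.frame(g$edges), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
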