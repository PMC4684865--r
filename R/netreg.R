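#' Construct a regulator-to-target network over a gene universe
#'
#' Validates and stores a directed edge list restricted to a gene
#' universe. Duplicate edges are collapsed; self-edges are retained in the
#' list but never count toward coverage.
#'
#' @param edges `data.frame` with character columns `regulator` and
#'   `target`; endpoints must belong to the universe.
#' @param universe Character vector of gene ids (the network's gene
#'   universe, e.g. the costimulation-upregulated set).
#' @return List of class `reg_network` with elements `universe` and
#'   `edges`.
#' @export
as_regnetwork <- function(edges, universe) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "target") %in% names(edges)))
  universe <- unique(as.character(universe))
  if (length(universe) < 2) stop("the gene universe needs at least 2 genes")
  edges <- unique(edges[, c("regulator", "target")])
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  out <- c(edges$regulator, edges$target)
  if (!all(out %in% universe)) {
    stop("edge endpoints outside the gene universe: ",
         paste(utils::head(setdiff(out, universe), 5), collapse = ", "))
  }
  structure(list(universe = universe, edges = edges), class = "reg_network")
}

# Directed out-reachability (excluding the start node) via igraph.
reachable_set <- function(net, node) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$universe)
  reach <- igraph::subcomponent(g, node, mode = "out")
  setdiff(names(reach), node)
}

#' Coverage of the network by one regulator
#'
#' The fraction of the gene universe (excluding the node itself) that the
#' node regulates: its direct targets by default, or every gene reachable
#' along directed edges in `"reachable"` mode (regulatory cascades).
#'
#' @param net A `reg_network`.
#' @param node Gene id; must be in the universe.
#' @param mode `"direct"` (out-neighbours) or `"reachable"` (directed
#'   closure).
#' @return Fraction in `[0, 1]`.
#' @examples
#' net <- as_regnetwork(data.frame(regulator = "g1", target = c("g2", "g3")),
#'                      paste0("g", 1:11))
#' node_coverage(net, "g1")  # 2/10
#' @export
node_coverage <- function(net, node, mode = c("direct", "reachable")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "reg_network"))
  if (!node %in% net$universe) stop("node not in network: ", node)
  targets <- if (mode == "direct") {
    unique(net$edges$target[net$edges$regulator == node])
  } else {
    reachable_set(net, node)
  }
  covered <- setdiff(intersect(targets, net$universe), node)
  length(covered) / (length(net$universe) - 1)
}

#' Classify every node as a major or minor regulator
#'
#' Applies the coverage-based definitions: a *major* regulator triggers
#' strictly more than 30% of the network, a *minor* regulator 10% up to
#' (and including) 30%; anything below 10% is unclassified. Boundaries:
#' coverage exactly 0.30 is minor (major requires strictly more), coverage
#' exactly 0.10 is minor.
#'
#' @param net A `reg_network`.
#' @param mode Coverage mode, see [node_coverage()].
#' @param major_threshold,minor_threshold Class boundaries (defaults 0.30
#'   and 0.10).
#' @return `data.frame` with columns `node`, `coverage`, `klass`
#'   (major/minor/none), one row per universe gene, sorted by decreasing
#'   coverage.
#' @export
classify_nodes <- function(net, mode = c("direct", "reachable"),
                           major_threshold = 0.30, minor_threshold = 0.10) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "reg_network"),
            minor_threshold < major_threshold)
  if (mode == "direct") {
    # one pass over the edge list instead of per-node subsetting
    e <- net$edges[net$edges$regulator != net$edges$target, , drop = FALSE]
    deg <- table(e$regulator[!duplicated(e[c("regulator", "target")])])
    cov <- stats::setNames(rep(0, length(net$universe)), net$universe)
    cov[names(deg)] <- as.numeric(deg) / (length(net$universe) - 1)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$universe)
    cov <- vapply(net$universe, function(v) {
      length(setdiff(names(igraph::subcomponent(g, v, mode = "out")), v)) /
        (length(net$universe) - 1)
    }, numeric(1))
  }
  klass <- ifelse(cov > major_threshold, "major",
                  ifelse(cov >= minor_threshold, "minor", "none"))
  out <- data.frame(node = names(cov), coverage = as.numeric(cov),
                    klass = klass, stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$coverage, out$node), , drop = FALSE]
}

#' Joint coverage of a set of regulators
#'
#' The fraction of the residual universe (universe minus the regulators
#' themselves) covered by the union of the per-node regulated sets under
#' the chosen mode. Used to ask how much of a costimulation network a
#' handful of major regulators impacts jointly.
#'
#' @param net A `reg_network`.
#' @param nodes Character vector of regulator gene ids (subset of the
#'   universe); empty gives 0.
#' @param mode Coverage mode, see [node_coverage()].
#' @return Fraction in `[0, 1]`.
#' @export
set_coverage <- function(net, nodes, mode = c("direct", "reachable")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "reg_network"))
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0) return(0)
  if (!all(nodes %in% net$universe)) {
    stop("nodes outside the network: ",
         paste(setdiff(nodes, net$universe), collapse = ", "))
  }
  targets <- if (mode == "direct") {
    unique(net$edges$target[net$edges$regulator %in% nodes])
  } else {
    unique(unlist(lapply(nodes, function(v) reachable_set(net, v))))
  }
  residual <- setdiff(net$universe, nodes)
  if (length(residual) == 0) return(0)
  length(intersect(targets, residual)) / length(residual)
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("reg_network: %d genes, %d unique directed edges\n",
              length(x$universe), nrow(x$edges)))
  invisible(x)
}
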