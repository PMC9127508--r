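## Per-gene graph statistics on the filtered interaction network.  The
## graph is unweighted: interaction scores gate edge existence at read
## time and play no further role.

#' Degree, closeness and betweenness centrality per gene
#'
#' Computes, on the unweighted undirected graph:
#'
#' * `degree`: incident edge count;
#' * `closeness`: Wasserman--Faust closeness, `(r - 1) / sum(d)` over
#'   the `r` reachable nodes, scaled by `(r - 1) / (N - 1)` so that the
#'   statistic is comparable across components of a disconnected graph;
#'   isolated nodes get 0;
#' * `betweenness`: exact shortest-path betweenness with the standard
#'   unordered-pair normalization `B / ((N - 1)(N - 2) / 2)`.
#'
#' @param graph an [igraph::igraph], e.g. from [readNetwork()].
#' @return data.frame with columns `gene`, `degree`, `closeness`,
#'   `betweenness`; empty for an empty graph.
#' @export
nodeCentralities <- function(graph) {
    n <- igraph::vcount(graph)
    if (n == 0L)
        return(data.frame(gene = character(), degree = integer(),
                          closeness = numeric(), betweenness = numeric()))
    genes <- igraph::V(graph)$name
    deg <- igraph::degree(graph)
    d <- igraph::distances(graph)
    clo <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        r <- length(reach) + 1L
        if (r == 1L || n == 1L) return(0)
        ((r - 1) / sum(reach)) * ((r - 1) / (n - 1))
    }, numeric(1))
    btw <- if (n > 2L) {
        igraph::betweenness(graph, directed = FALSE) / ((n - 1) * (n - 2) / 2)
    } else rep(0, n)
    data.frame(gene = genes, degree = as.integer(deg),
               closeness = clo, betweenness = btw,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Hop-limited neighborhoods
#'
#' For every gene, the set of genes reachable in at most `n` hops (BFS
#' ball of radius `n` minus the gene itself).
#'
#' @param graph an [igraph::igraph].
#' @param n integer >= 1, neighborhood radius in hops.
#' @return named list of character vectors.
#' @export
neighborsWithinHops <- function(graph, n = 1L) {
    stopifnot(n >= 1L)
    if (igraph::vcount(graph) == 0L) return(stats::setNames(list(), character()))
    nb <- igraph::ego(graph, order = n, mindist = 1)
    stats::setNames(lapply(nb, function(v) v$name), igraph::V(graph)$name)
}

#' Network randomization controls
#'
#' Two negative-control randomizations of the interaction network:
#' `"node_label"` permutes the gene identities on the fixed topology
#' (the degree multiset is preserved but per-gene degrees are not);
#' `"degree_preserving"` performs double-edge swaps (at least
#' `swapFactor * |E|` attempted swaps), preserving every gene's degree
#' exactly while rewiring the neighborhoods.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param graph an [igraph::igraph].
#' @param mode `"node_label"` or `"degree_preserving"`.
#' @param swapFactor attempted swaps per edge for degree-preserving
#'   rewiring.
#' @return a randomized [igraph::igraph].
#' @export
randomizeNetwork <- function(graph, mode = c("node_label",
                                             "degree_preserving"),
                             swapFactor = 10) {
    mode <- match.arg(mode)
    if (mode == "node_label") {
        g <- graph
        igraph::V(g)$name <- sample(igraph::V(graph)$name)
        g
    } else {
        igraph::rewire(graph, igraph::keeping_degseq(
            niter = max(1L, ceiling(swapFactor * igraph::ecount(graph)))))
    }
}
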