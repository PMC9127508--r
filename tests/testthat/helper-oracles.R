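# Brute-force oracles, written independently of the package internals:
# plain adjacency-matrix BFS, explicit shortest-path counting, and
# direct loops over the feature definitions.

# Erdos-Renyi graph as an adjacency matrix plus the matching igraph
randomTestGraph <- function(nNodes, p = 0.25) {
  nodes <- sprintf("N%02d", seq_len(nNodes))
  adj <- matrix(0L, nNodes, nNodes, dimnames = list(nodes, nodes))
  for (i in seq_len(nNodes - 1)) {
    for (j in seq(i + 1, nNodes)) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g, nodes = nodes)
}

# all-pairs hop distances by BFS on the adjacency matrix
bruteDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    hop <- 0L
    while (length(frontier)) {
      hop <- hop + 1L
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1L))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- hop
      frontier <- nxt
    }
  }
  d
}

# shortest-path counts sigma[s, t] from the distance matrix by dynamic
# programming over BFS levels
brutePathCounts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(adj[, v] == 1L & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# degree / Wasserman-Faust closeness / pair-normalized betweenness by
# direct enumeration over ordered triples
bruteCentralities <- function(adj) {
  n <- nrow(adj)
  d <- bruteDistances(adj)
  sigma <- brutePathCounts(adj, d)
  degree <- rowSums(adj)
  closeness <- numeric(n)
  betweenness <- numeric(n)
  for (v in seq_len(n)) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    r <- length(reach) + 1
    closeness[v] <- if (r > 1 && n > 1)
      ((r - 1) / sum(reach)) * ((r - 1) / (n - 1)) else 0
    if (n > 2) {
      b <- 0
      for (s in seq_len(n)) {
        for (t in seq_len(n)) {
          if (s >= t || s == v || t == v) next
          if (!is.finite(d[s, t])) next
          if (d[s, v] + d[v, t] == d[s, t])
            b <- b + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
      betweenness[v] <- b / ((n - 1) * (n - 2) / 2)
    }
  }
  data.frame(gene = rownames(adj), degree = as.integer(degree),
             closeness = closeness, betweenness = betweenness,
             stringsAsFactors = FALSE)
}

bruteNeighborhood <- function(adj, hops) {
  d <- bruteDistances(adj)
  out <- lapply(seq_len(nrow(adj)), function(v) {
    rownames(adj)[d[v, ] >= 1 & d[v, ] <= hops]
  })
  names(out) <- rownames(adj)
  out
}

# feature definitions written out longhand
bruteNeighFC <- function(logfc, neighbors, tau) {
  total <- 0; k <- 0
  for (v in neighbors) {
    if (!v %in% names(logfc)) next
    if (abs(logfc[[v]]) > tau) { total <- total + logfc[[v]]; k <- k + 1 }
  }
  c(total, if (k > 0) total / k else 0)
}

bruteNeighCnvFC <- function(logfc, cnvCol, neighbors, tau) {
  total <- 0; k <- 0
  for (v in neighbors) {
    if (!v %in% names(logfc) || !v %in% names(cnvCol)) next
    if (cnvCol[[v]] != 0 && abs(logfc[[v]]) > tau) {
      total <- total + logfc[[v]]; k <- k + 1
    }
  }
  c(total, if (k > 0) total / k else 0)
}

# classification metrics recomputed longhand from raw labels
bruteMetrics <- function(truth, pred, classes) {
  out <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else if (!is.na(rec)) 0 else NA_real_
    c(precision = prec, recall = rec, f1 = f1)
  })
  list(accuracy = mean(truth == pred),
       perClass = do.call(rbind, out))
}
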