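# Hub-gene ranking: five node centralities on the thresholded, simple,
# undirected PPI graph, column-wise Z-scores, and a fixed-weight linear
# composite. Conventions (the composite depends on them, so they are
# pinned): normalized betweenness; closeness per connected component,
# (n_c - 1)/sum of intra-component distances; degree normalized by N-1;
# eigenvector centrality by power iteration (tol 1e-10, <= 1e4
# iterations) scaled to max 1; PageRank with damping 0.85. The graph is
# unweighted after thresholding - confidence scores only gate edges.

#' Default centrality weights of the composite hub score
#'
#' Betweenness and closeness carry the highest weights (0.25 each) as
#' the best captures of bottleneck and global-accessibility character;
#' degree 0.20; eigenvector and PageRank 0.15 each. Sums to 1.
#'
#' @return named numeric of length 5.
#' @export
centralityWeights <- function() {
  c(betweenness = 0.25, closeness = 0.25, degree = 0.20,
    eigenvector = 0.15, pagerank = 0.15)
}

#' Read a STRING-style edge list into a thresholded gene network
#'
#' Expects a TSV with header columns \code{geneA}, \code{geneB},
#' \code{combined_score}. Edges below the confidence threshold
#' (inclusive at the threshold) are dropped, self-loops removed, and
#' duplicate undirected edges collapsed keeping the maximum score.
#' Isolated genes are retained only if listed in \code{nodes}.
#'
#' @param path TSV path (or a data.frame with the same columns).
#' @param score_threshold minimum combined score kept (default 400).
#' @param nodes optional character vector (or one-column file) of gene
#'   symbols to retain even when isolated.
#' @return a [GeneNetwork-class].
#' @export
readEdgeList <- function(path, score_threshold = 400, nodes = NULL) {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    if (!file.exists(path)) stop("edge list not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("geneA", "geneB", "combined_score")
  if (!all(need %in% names(tab)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(score) | !nzchar(trimws(tab$geneA)) |
                 !nzchar(trimws(tab$geneB)))
  if (length(bad))
    stop("malformed edge-list row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  tab$combined_score <- score
  tab <- tab[score >= score_threshold, , drop = FALSE]
  tab <- tab[tab$geneA != tab$geneB, , drop = FALSE]
  if (nrow(tab)) {
    a <- pmin(tab$geneA, tab$geneB)
    b <- pmax(tab$geneA, tab$geneB)
    key <- paste(a, b, sep = "\r")
    best <- tapply(tab$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    edges <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                        score = as.numeric(best))
  } else {
    edges <- data.frame(geneA = character(), geneB = character(),
                        score = numeric())
  }
  verts <- sort(unique(c(edges$geneA, edges$geneB)))
  if (!is.null(nodes)) {
    if (length(nodes) == 1L && file.exists(nodes))
      nodes <- readLines(nodes, warn = FALSE)
    verts <- sort(unique(c(verts, trimws(nodes[nzchar(trimws(nodes))]))))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  new("GeneNetwork", graph = g, threshold = score_threshold)
}

.asGraph <- function(net) {
  if (is(net, "GeneNetwork")) networkGraph(net) else net
}

# Power-iteration eigenvector centrality, scaled so max(|x|) = 1.
# Iterates on A + I: same principal eigenvector as A, but the shift
# makes the dominant eigenvalue strictly largest in magnitude so the
# iteration cannot oscillate on bipartite graphs. The successive-change
# tolerance is kept well below the 1e-9 accuracy the composite is
# validated to, since the limit error exceeds the per-step change.
.eigenCentrality <- function(g, tol = 1e-13, max_iter = 1e5) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) + diag(n)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    xn <- as.numeric(A %*% x)
    nrm <- sqrt(sum(xn^2))
    if (nrm == 0) return(stats::setNames(rep(0, n), igraph::V(g)$name))
    xn <- xn / nrm
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x <- abs(x)
  stats::setNames(x / max(x), igraph::V(g)$name)
}

#' Compute the five raw node centralities
#'
#' Betweenness (normalized), closeness (per connected component),
#' degree (normalized by N-1), eigenvector (power iteration, max 1)
#' and PageRank (damping 0.85), all on the unweighted graph.
#'
#' @param net a [GeneNetwork-class] or igraph object.
#' @return data.frame with columns \code{gene}, \code{betweenness},
#'   \code{closeness}, \code{degree}, \code{eigenvector},
#'   \code{pagerank}, ordered by gene symbol.
#' @export
computeCentralities <- function(net) {
  g <- .asGraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  genes <- igraph::V(g)$name
  betw <- if (n > 2L)
    igraph::betweenness(g, directed = FALSE, normalized = TRUE,
                        weights = NA)
  else stats::setNames(rep(0, n), genes)
  dmat <- igraph::distances(g, weights = NA)
  close <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(dmat[i, ]) & seq_len(n) != i)
    if (!length(reach)) return(0)
    length(reach) / sum(dmat[i, reach])
  }, 0)
  deg <- if (n > 1L) igraph::degree(g) / (n - 1) else rep(0, n)
  eig <- .eigenCentrality(g)
  pr <- igraph::page_rank(g, damping = 0.85, weights = NA)$vector
  out <- data.frame(gene = genes, betweenness = as.numeric(betw),
                    closeness = close, degree = as.numeric(deg),
                    eigenvector = as.numeric(eig),
                    pagerank = as.numeric(pr))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Column-wise Z-scores of a centrality table
#'
#' Sample (n-1) standard deviation; a zero-variance column maps to all
#' zeros.
#'
#' @param raw data.frame from [computeCentralities()].
#' @return data.frame with the same shape, columns prefixed \code{z_}.
#' @export
zscoreTable <- function(raw) {
  idx_cols <- c("betweenness", "closeness", "degree", "eigenvector",
                "pagerank")
  stopifnot(all(idx_cols %in% names(raw)))
  if (nrow(raw) < 2L) stop("need at least 2 genes for Z-scores")
  out <- data.frame(gene = raw$gene)
  for (cn in idx_cols) {
    x <- raw[[cn]]
    s <- stats::sd(x)
    # a column that is constant up to floating noise carries no signal
    tol <- 1e-12 * max(1, max(abs(x)))
    out[[paste0("z_", cn)]] <- if (is.na(s) || s <= tol) rep(0, length(x))
      else (x - mean(x)) / s
  }
  out
}

#' Composite hub score and ranking
#'
#' Composite = 0.25 z_betweenness + 0.25 z_closeness + 0.20 z_degree +
#' 0.15 z_eigenvector + 0.15 z_pagerank (default weights), sorted
#' descending with lexicographic gene-symbol tie-break and a top-K flag.
#'
#' @param ztab data.frame from [zscoreTable()].
#' @param weights named centrality weights, see [centralityWeights()].
#' @param top size of the reported head set (default 30).
#' @return data.frame ordered by rank: \code{gene}, z columns,
#'   \code{composite}, \code{rank}, \code{top}.
#' @export
compositeRank <- function(ztab, weights = centralityWeights(), top = 30) {
  idx <- c("betweenness", "closeness", "degree", "eigenvector",
           "pagerank")
  stopifnot(all(idx %in% names(weights)))
  z <- as.matrix(ztab[, paste0("z_", idx)])
  comp <- as.numeric(z %*% weights[idx])
  out <- ztab
  out$composite <- comp
  ord <- order(-comp, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top
  rownames(out) <- NULL
  out
}

#' Rank genes by the Z-score-weighted centrality composite
#'
#' Composition: raw centralities, Z-scores, weighted composite, rank.
#' The returned table carries raw and Z columns side by side.
#'
#' @param net a [GeneNetwork-class] or igraph object.
#' @param weights centrality weights, see [centralityWeights()].
#' @param top top-K flag size (default 30).
#' @return data.frame ordered by rank with raw, z, composite, rank and
#'   top columns.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- paste0("G", 1:5)
#' rankGenes(g)
#' @export
rankGenes <- function(net, weights = centralityWeights(), top = 30) {
  raw <- computeCentralities(net)
  ranked <- compositeRank(zscoreTable(raw), weights = weights, top = top)
  merged <- merge(raw, ranked, by = "gene", sort = FALSE)
  merged <- merged[order(merged$rank), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Global topology statistics of a gene network
#'
#' Density 2E/(N(N-1)), mean shortest-path length on the largest
#' connected component, and the global clustering coefficient
#' (transitivity).
#'
#' @param net a [GeneNetwork-class] or igraph object (N >= 2).
#' @return list with \code{density}, \code{avg_path_length},
#'   \code{clustering}.
#' @export
topologyStats <- function(net) {
  g <- .asGraph(net)
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- if (igraph::vcount(sub) > 1L)
    igraph::mean_distance(sub, directed = FALSE) else NA_real_
  cl <- igraph::transitivity(sub, type = "global")
  list(density = igraph::edge_density(g),
       avg_path_length = apl,
       clustering = if (is.nan(cl)) 0 else cl)
}

#' Write a ranked centrality table and topology stats
#'
#' @param ranked data.frame from [rankGenes()].
#' @param path output CSV path.
#' @param topology optional list from [topologyStats()]; written as
#'   JSON next to \code{path} when given.
#' @return invisibly, \code{path}.
#' @export
writeRanking <- function(ranked, path, topology = NULL) {
  utils::write.csv(ranked, path, row.names = FALSE)
  if (!is.null(topology))
    jsonlite::write_json(topology,
                         sub("\\.csv$", "_topology.json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
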