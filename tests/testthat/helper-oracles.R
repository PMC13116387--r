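# Independent brute-force oracles used across the suite. These are
# deliberately naive re-derivations (path enumeration, dense linear
# algebra, all-pairs scans) kept separate from the package's
# implementations.

# --- graph centralities ---------------------------------------------

# All simple paths from s to t in an adjacency matrix, as a list of
# integer vectors. Exponential; for oracle use on <= 8 nodes only.
allSimplePaths <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(adj[last, ] > 0))
      if (!(nxt %in% path)) walk(c(path, nxt))
  }
  walk(s)
  paths
}

# The five centralities by brute force, matching the package's stated
# conventions: normalized betweenness, per-component closeness, degree
# over N-1, principal eigenvector of A scaled to max 1 (dense eigen),
# PageRank by direct linear solve at damping 0.85.
bfCentralities <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 2)
  # geodesics by exhaustive simple-path enumeration
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  geo <- vector("list", n * n)
  betw <- rep(0, n)
  for (s in 1:n) for (t in 1:n) {
    if (s >= t) next
    paths <- allSimplePaths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, 0L)
    dist[s, t] <- dist[t, s] <- min(lens) - 1L
    shortest <- paths[lens == min(lens)]
    for (v in setdiff(1:n, c(s, t))) {
      through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
      betw[v] <- betw[v] + through / length(shortest)
    }
  }
  if (n > 2) betw <- betw * 2 / ((n - 1) * (n - 2))
  close <- vapply(1:n, function(i) {
    reach <- which(is.finite(dist[i, ]) & (1:n) != i)
    if (!length(reach)) return(0)
    length(reach) / sum(dist[i, reach])
  }, 0)
  deg <- rowSums(adj) / (n - 1)
  ev <- eigen(adj, symmetric = TRUE)
  v1 <- abs(ev$vectors[, which.max(ev$values)])
  eigv <- if (max(v1) > 0) v1 / max(v1) else rep(0, n)
  d <- 0.85
  degs <- rowSums(adj)
  M <- t(adj / pmax(degs, 1))       # column-stochastic for non-dangling
  dangling <- degs == 0
  if (any(dangling)) M[, dangling] <- 1 / n
  pr <- solve(diag(n) - d * M, rep((1 - d) / n, n))
  pr <- pr / sum(pr)
  data.frame(betweenness = betw, closeness = close, degree = deg,
             eigenvector = eigv, pagerank = pr)
}

adjToGraph <- function(adj, names = NULL) {
  if (is.null(names)) names <- sprintf("N%02d", seq_len(nrow(adj)))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- names
  g
}

# Every labeled connected graph on n nodes (n <= 4 is practical).
allConnectedGraphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    adj <- matrix(0, n, n)
    for (e in seq_len(m)) if (bitwAnd(mask, bitwShiftL(1, e - 1)) > 0) {
      adj[pairs[1, e], pairs[2, e]] <- 1
      adj[pairs[2, e], pairs[1, e]] <- 1
    }
    if (igraph::is_connected(adjToGraph(adj))) out[[length(out) + 1L]] <- adj
  }
  out
}

randomConnectedAdj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0, n, n)
    up <- upper.tri(adj)
    adj[up] <- as.numeric(stats::runif(sum(up)) < p)
    adj <- adj + t(adj)
    if (igraph::is_connected(adjToGraph(adj))) return(adj)
  }
}

# --- interaction contacts -------------------------------------------

# Brute-force all-pairs contact scan over typed atom sets: explicit
# double loops, re-deriving every distance from raw coordinates.
bfContacts <- function(lig, prot, cutoffs = defaultCutoffs()) {
  rows <- list()
  la <- lig$atoms; pa <- prot$atoms
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(pa))) {
    dd <- sqrt((la$x[i] - pa$x[j])^2 + (la$y[i] - pa$y[j])^2 +
                 (la$z[i] - pa$z[j])^2)
    if (dd <= 0) next
    if (dd <= cutoffs[["hbond"]] &&
        ((la$donor[i] && pa$acceptor[j]) ||
         (la$acceptor[i] && pa$donor[j])))
      rows[[length(rows) + 1L]] <- data.frame(kind = "hydrogen-bond",
        ligand_atom = la$idx[i], residue = pa$residue[j], distance = dd)
    if (dd <= cutoffs[["saltbridge"]] &&
        ((la$cation[i] && pa$anion[j]) || (la$anion[i] && pa$cation[j])))
      rows[[length(rows) + 1L]] <- data.frame(kind = "salt-bridge",
        ligand_atom = la$idx[i], residue = pa$residue[j], distance = dd)
    if (dd <= cutoffs[["hydrophobic"]] &&
        la$hydrophobic[i] && pa$hydrophobic[j] &&
        la$element[i] == "C" && pa$element[j] == "C")
      rows[[length(rows) + 1L]] <- data.frame(kind = "hydrophobic",
        ligand_atom = la$idx[i], residue = pa$residue[j], distance = dd)
  }
  lr <- lig$rings; pr <- prot$rings
  for (i in seq_len(nrow(lr))) {
    for (j in seq_len(nrow(pr))) {
      dd <- sqrt((lr$x[i] - pr$x[j])^2 + (lr$y[i] - pr$y[j])^2 +
                   (lr$z[i] - pr$z[j])^2)
      if (dd > 0 && dd <= cutoffs[["pi"]])
        rows[[length(rows) + 1L]] <- data.frame(kind = "pi",
          ligand_atom = lr$first_atom[i], residue = pr$residue[j],
          distance = dd)
    }
    for (j in which(pa$cation)) {
      dd <- sqrt((lr$x[i] - pa$x[j])^2 + (lr$y[i] - pa$y[j])^2 +
                   (lr$z[i] - pa$z[j])^2)
      if (dd > 0 && dd <= cutoffs[["pi"]])
        rows[[length(rows) + 1L]] <- data.frame(kind = "pi",
          ligand_atom = lr$first_atom[i], residue = pa$residue[j],
          distance = dd)
    }
  }
  for (i in which(la$cation)) for (j in seq_len(nrow(pr))) {
    dd <- sqrt((la$x[i] - pr$x[j])^2 + (la$y[i] - pr$y[j])^2 +
                 (la$z[i] - pr$z[j])^2)
    if (dd > 0 && dd <= cutoffs[["pi"]])
      rows[[length(rows) + 1L]] <- data.frame(kind = "pi",
        ligand_atom = la$idx[i], residue = pr$residue[j], distance = dd)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), ligand_atom = integer(),
               residue = character(), distance = numeric())
  tab[order(tab$kind, tab$ligand_atom, tab$residue), , drop = FALSE]
}

sortedContacts <- function(x) {
  tab <- if (methods::is(x, "ContactSet")) contacts(x) else x
  tab <- tab[order(tab$kind, tab$ligand_atom, tab$residue), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# --- small fixtures -------------------------------------------------

# Minimal PDB text: a 4-atom LIG ligand, 3 waters, one SER residue.
toyPDBText <- function() {
  line <- GradeScreen:::.pdbLine
  paste(c(
    "HEADER    TOY COMPLEX",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    2.10 ANGSTROMS.",
    "SOURCE   2 ORGANISM_SCIENTIFIC: HOMO SAPIENS;",
    line("ATOM", 1, "N", "SER", "A", 10, 0, 0, 0, "N"),
    line("ATOM", 2, "CA", "SER", "A", 10, 1.4, 0, 0, "C"),
    line("ATOM", 3, "OG", "SER", "A", 10, 2.1, 1.0, 0, "O"),
    line("HETATM", 4, "C1", "LIG", "L", 900, 10, 0, 0, "C"),
    line("HETATM", 5, "C2", "LIG", "L", 900, 11.4, 0, 0, "C"),
    line("HETATM", 6, "O1", "LIG", "L", 900, 12.1, 1.1, 0, "O"),
    line("HETATM", 7, "N1", "LIG", "L", 900, 10.0, -1.4, 0, "N"),
    line("HETATM", 8, "O", "HOH", "W", 801, 30, 30, 30, "O"),
    line("HETATM", 9, "O", "HOH", "W", 802, 31, 30, 30, "O"),
    line("HETATM", 10, "O", "HOH", "W", 803, 32, 30, 30, "O"),
    "END"), collapse = "\n")
}

olaparibSMILES <- function() {
  "C1CC1C(=O)N2CCN(CC2)C(=O)C3=C(C=CC(=C3)CC4=NNC(=O)C5=CC=CC=C54)F"
}
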