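# Edge-list ingestion, centralities, Z-scores, composite and topology.

test_that("edge lists are thresholded inclusively and deduplicated", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tcombined_score",
               "A\tB\t350", "A\tC\t400", "B\tC\t450", "C\tD\t900",
               "B\tD\t200"), f)
  net <- readEdgeList(f)
  expect_equal(igraph::ecount(networkGraph(net)), 3L)

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tcombined_score",
               "A\tA\t950", "A\tB\t500", "B\tA\t700"), f2)
  net2 <- readEdgeList(f2)
  g2 <- networkGraph(net2)
  expect_equal(igraph::ecount(g2), 1L)        # self-loop dropped, dup merged
  expect_equal(igraph::E(g2)$score, 700)      # max score kept

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tcombined_score",
               "A\tB\t500", "C\tD\tnotanumber"), f3)
  expect_error(readEdgeList(f3), "line")
})

test_that("centralities match hand results on the path graph and star", {
  path3 <- readEdgeList(data.frame(geneA = c("A", "B"),
                                   geneB = c("B", "C"),
                                   combined_score = 999))
  cen <- computeCentralities(path3)
  expect_equal(cen$betweenness[cen$gene == "B"], 1)
  expect_equal(cen$betweenness[cen$gene %in% c("A", "C")], c(0, 0))
  star <- readEdgeList(data.frame(geneA = "HUB",
                                  geneB = paste0("L", 1:4),
                                  combined_score = 999))
  cs <- computeCentralities(star)
  hub_row <- which(cs$gene == "HUB")
  for (cn in c("betweenness", "closeness", "degree", "eigenvector",
               "pagerank"))
    expect_equal(which.max(cs[[cn]]), hub_row)
})

test_that("all five centralities match brute force on small graphs", {
  for (adj in allConnectedGraphs(4)) {
    g <- adjToGraph(adj)
    got <- computeCentralities(g)
    want <- bfCentralities(adj)
    ord <- match(got$gene, igraph::V(g)$name)
    for (cn in names(want))
      expect_equal(got[[cn]], want[[cn]][ord], tolerance = 1e-9,
                   label = cn)
  }
  set.seed(99)
  for (i in 1:10) {
    adj <- randomConnectedAdj(sample(5:8, 1))
    g <- adjToGraph(adj)
    got <- computeCentralities(g)
    want <- bfCentralities(adj)
    ord <- match(got$gene, igraph::V(g)$name)
    for (cn in names(want))
      expect_equal(got[[cn]], want[[cn]][ord], tolerance = 1e-9,
                   label = cn)
  }
})

test_that("Z-scores use sample sd, center to zero and absorb constants", {
  raw <- data.frame(gene = c("A", "B"), betweenness = c(0, 1),
                    closeness = c(0.3, 0.3), degree = c(1, 1),
                    eigenvector = c(0.2, 0.9), pagerank = c(0.5, 0.5))
  z <- zscoreTable(raw)
  expect_equal(z$z_betweenness, c(-0.707, 0.707), tolerance = 1e-3)
  expect_equal(z$z_closeness, c(0, 0))
  expect_equal(mean(z$z_eigenvector), 0, tolerance = 1e-12)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  zz <- zscoreTable(computeCentralities(k4))
  expect_true(all(abs(as.matrix(zz[, -1])) < 1e-9))
})

test_that("composite ranking is symmetric on K4 and finds the star center", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("D", "B", "A", "C")
  r <- rankGenes(k4)
  expect_equal(r$composite, rep(0, 4))
  expect_equal(r$gene, c("A", "B", "C", "D"))  # lexicographic ties
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("CTR", paste0("L", 1:5))
  rs <- rankGenes(star)
  expect_equal(rs$gene[1], "CTR")
  expect_true(all(abs(rowSums(
    as.matrix(rs[, paste0("z_", c("betweenness", "closeness", "degree",
                                  "eigenvector", "pagerank"))]) *
      rep(centralityWeights(), each = 6)) - rs$composite) < 1e-9))
})

test_that("degenerate weight vector reduces the composite to degree order", {
  set.seed(5)
  adj <- randomConnectedAdj(8, 0.35)
  g <- adjToGraph(adj)
  w <- c(betweenness = 0, closeness = 0, degree = 1, eigenvector = 0,
         pagerank = 0)
  r <- rankGenes(g, weights = w)
  expect_true(all(diff(r$degree) <= 1e-12))
})

test_that("gene relabeling permutes records without changing composites", {
  set.seed(21)
  adj <- randomConnectedAdj(7, 0.4)
  g1 <- adjToGraph(adj, sprintf("A%02d", 1:7))
  perm <- sample(7)
  g2 <- adjToGraph(adj, sprintf("B%02d", perm))
  r1 <- rankGenes(g1); r2 <- rankGenes(g2)
  m1 <- r1$composite[match(sprintf("A%02d", 1:7), r1$gene)]
  m2 <- r2$composite[match(sprintf("B%02d", perm), r2$gene)]
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("topology statistics match hand enumeration", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- LETTERS[1:4]
  t1 <- topologyStats(k4)
  expect_equal(t1$density, 1); expect_equal(t1$avg_path_length, 1)
  expect_equal(t1$clustering, 1)
  p3 <- readEdgeList(data.frame(geneA = c("A", "B"),
                                geneB = c("B", "C"),
                                combined_score = 999))
  t2 <- topologyStats(p3)
  expect_equal(t2$density, 2 / 3)
  expect_equal(t2$avg_path_length, 4 / 3)
  expect_equal(t2$clustering, 0)
  s4 <- igraph::make_star(4, mode = "undirected")
  igraph::V(s4)$name <- LETTERS[1:4]
  t3 <- topologyStats(s4)
  expect_equal(t3$density, 0.5)
  expect_equal(t3$avg_path_length, 1.5)
  expect_equal(t3$clustering, 0)
})
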