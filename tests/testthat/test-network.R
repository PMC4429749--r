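test_that("MTI correlations are computed and missing expression is flagged", {
  conds <- paste0("s", 1:6)
  prof <- c(1, 3, 2, 5, 4, 6)
  mirnaExpr <- matrix(prof, 1, dimnames = list("mirX", conds))
  geneExpr <- rbind(gNeg = -prof, gOther = c(2, 2, 1, 3, 2, 4))
  colnames(geneExpr) <- conds
  mtis <- data.frame(mirna = "mirX", target = c("gNeg", "gAbsent"),
                     evidence = "verified", source = "db")
  out <- mtiCorrelation(mtis, mirnaExpr, geneExpr)
  expect_equal(out$correlation[1], -1.0)
  expect_false(out$corr_missing[1])
  expect_true(out$corr_missing[2])
  expect_equal(nrow(out), 2)  # the edge is kept
})

test_that("DFS expansion handles chains, cycles and self-loops", {
  edges <- data.frame(from = c("G1", "G2"), to = c("G2", "G3"))
  f <- expandIndirectTargets("G1", edges)
  expect_setequal(f$indirect, c("G2", "G3"))
  expect_equal(f$nodes$depth[match(c("G1", "G2", "G3"), f$nodes$node)],
               c(0L, 1L, 2L))

  # feedback loop plus self-control terminates
  edges2 <- data.frame(from = c("G1", "G2", "G2"), to = c("G2", "G1", "G2"))
  f2 <- expandIndirectTargets("G1", edges2)
  expect_setequal(f2$indirect, "G2")

  expect_warning(f3 <- expandIndirectTargets(c("G1", "nope"), edges),
                 "not in graph")
  expect_setequal(f3$indirect, c("G2", "G3"))

  # empty graph: empty indirect set
  f4 <- suppressWarnings(expandIndirectTargets(
    "G1", data.frame(from = character(), to = character())))
  expect_length(f4$indirect, 0)
})

test_that("DFS children are visited in lexicographic order deterministically", {
  edges <- data.frame(from = c("G1", "G1", "G1"), to = c("Gc", "Ga", "Gb"))
  f <- expandIndirectTargets("G1", edges)
  expect_equal(f$edges$to, c("Ga", "Gb", "Gc"))
  f2 <- expandIndirectTargets("G1", edges[c(3, 1, 2), ])
  expect_identical(f, f2)
})

test_that("DFS reachability equals the transitive-closure oracle", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    dens <- runif(1, 0.02, 0.3)
    A <- matrix(as.integer(runif(n * n) < dens), n, n,
                dimnames = list(nodes, nodes))
    edges <- data.frame(from = nodes[which(A > 0, arr.ind = TRUE)[, 1]],
                        to = nodes[which(A > 0, arr.ind = TRUE)[, 2]])
    direct <- sample(nodes, sample(1:3, 1))
    f <- suppressWarnings(expandIndirectTargets(direct, edges))
    inGraph <- intersect(direct, unique(c(edges$from, edges$to)))
    expected <- if (length(inGraph))
      setdiff(union(reachOracle(A, inGraph), inGraph), direct) else character(0)
    expect_setequal(f$indirect, expected)
    # the indirect set never intersects the direct set; forest is bounded
    expect_length(intersect(f$indirect, direct), 0)
    expect_lte(nrow(f$nodes), n)
  }
})

test_that("adjacency matrices are square 0/1 with self-edges on the diagonal", {
  edges <- data.frame(from = c("G1", "G2", "G2"), to = c("G2", "G3", "G2"))
  A <- geneGraphAdjacency(edges)
  expect_equal(dim(A), c(3, 3))
  expect_equal(A["G1", "G2"], 1L)
  expect_equal(A["G2", "G2"], 1L)
  expect_equal(sum(A), 3L)
})

test_that("GO enrichment ranks maximally enriched terms first", {
  ann <- rbind(
    data.frame(gene = paste0("g", 1:5), term = "GO:A"),
    data.frame(gene = paste0("g", 1:20), term = "GO:ALL"))
  enr <- goEnrichment(paste0("g", 1:5), ann)
  expect_equal(enr$term[1], "GO:A")
  # N=20 background, K=5, n=5, k=5 -> p = 1/C(20,5)
  expect_equal(enr$p_value[1], 1 / choose(20, 5), tolerance = 1e-12)
  # k = 0 under the upper tail gives p = 1
  enr0 <- goEnrichment(paste0("g", 6:10), ann)
  expect_equal(enr0$p_value[enr0$term == "GO:A"], 1.0)
  expect_error(goEnrichment("gNope", ann), "background")
  # BH adjustment is optional and order-preserving
  enrBH <- goEnrichment(paste0("g", 1:5), ann, adjust = "BH")
  expect_true(all(enrBH$p_adjusted >= enrBH$p_value - 1e-15))
})

test_that("GO enrichment p-values share the hypergeometric implementation", {
  ann <- rbind(
    data.frame(gene = paste0("g", 1:8), term = "GO:X"),
    data.frame(gene = paste0("g", 1:30), term = "GO:ALL"))
  enr <- goEnrichment(paste0("g", c(1:4, 25:30)), ann)
  row <- enr[enr$term == "GO:X", ]
  expect_equal(row$p_value,
               hypergeomPvalue(row$N, row$K, row$n, row$k, "upper"))
})

test_that("networks assemble with typed nodes, merged MTIs and full provenance", {
  tfm <- data.frame(tf = c("TF1", "TF2"), mirna = "miR-X",
                    frequency = c(0.8, 0.7), p_value = c(0.01, 0.02))
  mtis <- data.frame(mirna = "miR-X", target = c("G1", "G2"),
                     evidence = "verified", source = "db",
                     correlation = c(-0.9, -0.8))
  edges <- data.frame(from = c("G1", "G2", "G3"), to = c("G3", "G4", "G5"))
  forest <- expandIndirectTargets(c("G1", "G2"), edges)
  net <- buildNetwork(tfm, mtis, forest)
  expect_s4_class(net, "RegulatoryNetwork")
  expect_equal(nrow(netNodes(net)), 8)  # 2 TF + 1 miRNA + 2 direct + 3 indirect
  expect_equal(nrow(netEdges(net)), 7)  # 2 TF + 2 MTI + 3 tree edges
  expect_setequal(netNodes(net)$type[netNodes(net)$id %in% c("G3", "G4", "G5")],
                  "indirect_target")

  # duplicate MTI: single edge, verified dominates, sources merged
  dup <- rbind(mtis,
               data.frame(mirna = "miR-X", target = "G1",
                          evidence = "putative", source = "pred",
                          correlation = NA))
  net2 <- buildNetwork(NULL, dup, NULL)
  e <- netEdges(net2)
  expect_equal(sum(e$from == "miR-X" & e$to == "G1"), 1)
  expect_equal(e$evidence[e$to == "G1"], "verified")
  expect_match(e$source[e$to == "G1"], "db")
  expect_match(e$source[e$to == "G1"], "pred")

  # partial input: MTI layer only
  net3 <- buildNetwork(NULL, mtis, NULL)
  expect_equal(nrow(netNodes(net3)), 3)
})

test_that("network export covers SIF, GraphML round-trip and bad formats", {
  tfm <- data.frame(tf = "TF1", mirna = "miR-X", frequency = 0.8,
                    p_value = 0.01)
  net <- buildNetwork(tfm, NULL, NULL)
  sif <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(net, sif, "sif")
  expect_equal(readLines(sif), "TF1 regulates miR-X")

  mtis <- data.frame(mirna = "miR-X", target = c("G1", "G2"),
                     evidence = "verified", source = "db",
                     correlation = c(-0.9, -0.8))
  full <- buildNetwork(tfm, mtis,
                       expandIndirectTargets("G1",
                         data.frame(from = "G1", to = "G3")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(full, gml, "graphml")
  back <- importNetworkGraphML(gml)
  expect_equal(netNodes(back), netNodes(full))
  expect_equal(netEdges(back)[, c("from", "to", "type", "evidence")],
               netEdges(full)[, c("from", "to", "type", "evidence")])
  expect_equal(netEdges(back)$correlation, netEdges(full)$correlation)

  expect_error(exportNetwork(full, sif, "dot"), "supported.*sif")
  empty <- buildNetwork(NULL, NULL, NULL)
  expect_warning(exportNetwork(empty, sif, "sif"), "empty")
  expect_identical(readLines(sif), character(0))

  cy <- withr::local_tempfile(fileext = ".json")
  exportNetwork(full, cy, "cyjson")
  parsed <- jsonlite::read_json(cy)
  expect_length(parsed$elements$nodes, nrow(netNodes(full)))
  expect_length(parsed$elements$edges, nrow(netEdges(full)))
})

test_that("dangling edge endpoints are rejected at network construction", {
  expect_error(
    new("RegulatoryNetwork",
        nodes = data.frame(id = "a", type = "TF"),
        edges = data.frame(from = "a", to = "b", type = "regulates")),
    "missing from nodes")
})
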