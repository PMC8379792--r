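pcit_pair <- function(sig_ref, sig_alt, ids) {
  mk <- function(sig) {
    dimnames(sig) <- list(ids, ids)
    w <- matrix(0.5, length(ids), length(ids), dimnames = dimnames(sig))
    diag(w) <- 1
    structure(list(significant = sig, weights = w, node_ids = ids,
                   skipped_trios = 0, eq7_variant = "corrected"),
              class = "pcit_result")
  }
  list(mk(sig_ref), mk(sig_alt))
}

full_sig <- function(n) { s <- matrix(TRUE, n, n); diag(s) <- FALSE; s }
empty_sig <- function(n) matrix(FALSE, n, n)

test_that("build_networks turns significant pairs into undirected edges", {
  ids <- c("a", "b", "c", "d")
  p <- pcit_pair(full_sig(4), empty_sig(4), ids)
  nets <- build_networks(p[[1]], p[[2]], tfs = "a",
                         conditions = c("ref", "alt"))
  expect_equal(nrow(nets$ref$edges), 6)       # complete graph on 4 nodes
  expect_equal(nrow(nets$alt$edges), 0)
  expect_identical(nets$ref$nodes$role, c("TF", "gene", "gene", "gene"))
  expect_false(any(nets$ref$edges$node_a == nets$ref$edges$node_b))
  expect_equal(anyDuplicated(nets$ref$edges[c("node_a", "node_b")]), 0L)

  q <- pcit_pair(full_sig(3), empty_sig(3), c("x", "y", "z"))
  expect_error(build_networks(p[[1]], q[[2]]), "mismatched")
})

test_that("networks from symmetric PCIT results are clean on random inputs", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    pa <- pcit(rand_cor(n)); pb <- pcit(rand_cor(n))
    nets <- build_networks(pa, pb)
    for (net in nets) {
      expect_false(any(net$edges$node_a == net$edges$node_b))
      expect_equal(anyDuplicated(net$edges[c("node_a", "node_b")]), 0L)
      expect_true(all(c(net$edges$node_a, net$edges$node_b) %in% net$nodes$id))
    }
  }
})

test_that("hri_table joins RIF scores with per-condition degrees", {
  ids <- c("t1", "t2", "g1", "g2", "g3")
  # reference: t1-g1, t1-g2, t1-g3, t2-g1; alternate: t1-g1
  sref <- empty_sig(5); dimnames(sref) <- list(ids, ids)
  for (pr in list(c("t1", "g1"), c("t1", "g2"), c("t1", "g3"), c("t2", "g1"))) {
    sref[pr[1], pr[2]] <- sref[pr[2], pr[1]] <- TRUE
  }
  salt <- empty_sig(5); dimnames(salt) <- list(ids, ids)
  salt["t1", "g1"] <- salt["g1", "t1"] <- TRUE
  p <- pcit_pair(sref, salt, ids)
  nets <- build_networks(p[[1]], p[[2]], tfs = c("t1", "t2"))
  rt <- make_rif_table(c("t1", "t2", "t3"), RIF1 = c(2.5, -2.1, 0.3),
                       RIF2 = c(0.1, 0.2, 2.2))
  hri <- hri_table(nets[[1]], nets[[2]], rt, significant_only = FALSE)
  expect_identical(hri$freq_diff, hri$freq_ref - hri$freq_alt)
  expect_equal(hri$freq_ref[hri$TF == "t1"], 3)
  expect_equal(hri$freq_alt[hri$TF == "t1"], 1)
  expect_equal(hri$freq_diff[hri$TF == "t1"], 2)
  # TF absent from both networks gets zero frequencies
  expect_equal(unlist(hri[hri$TF == "t3", c("freq_ref", "freq_alt",
                                            "freq_diff")]),
               c(freq_ref = 0, freq_alt = 0, freq_diff = 0))
  expect_true(!is.unsorted(rev(hri$freq_diff)))

  # significant-only filtering drops the non-significant rows
  rt2 <- make_rif_table(c("t1", "t2"), RIF1 = c(2.5, 0.3), RIF2 = c(0, 0.2))
  expect_identical(hri_table(nets[[1]], nets[[2]], rt2)$TF, "t1")
})

test_that("hri frequencies equal igraph-computed degrees on random networks", {
  set.seed(47)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    pa <- pcit(rand_cor(n)); pb <- pcit(rand_cor(n))
    nref <- build_networks(pa, pb, tfs = sprintf("n%02d", 1:2))
    rt <- make_rif_table(sprintf("n%02d", 1:2), RIF1 = c(3, -3),
                         RIF2 = c(0, 0))
    hri <- hri_table(nref[[1]], nref[[2]], rt)
    g <- as_igraph(nref[[1]])
    want <- igraph::degree(g)[hri$TF]
    expect_equal(hri$freq_ref, unname(want))
  }
})

test_that("tf_targets lists sorted neighbors", {
  star <- toy_net(edge_df(rep("hub", 4), c("l3", "l1", "l4", "l2")),
                  nodes = c("hub", "l1", "l2", "l3", "l4", "lonely"))
  expect_identical(tf_targets(star, "hub"), c("l1", "l2", "l3", "l4"))
  expect_identical(tf_targets(star, "lonely"), character(0))
  expect_error(tf_targets(star, "nope"), "unknown node")
})

test_that("clustering coefficient matches hand counts", {
  k4 <- toy_net(edge_df(c("a", "a", "a", "b", "b", "c"),
                        c("b", "c", "d", "c", "d", "d")))
  expect_equal(clustering_coefficient(k4), 1)
  star <- toy_net(edge_df(rep("h", 4), c("a", "b", "c", "d")))
  expect_equal(clustering_coefficient(star), 0)
  # triangle a-b-c plus pendant d on a: locals 1/1 (b), 1/1 (c), 1/3 (a), 0 (d)
  tri <- toy_net(edge_df(c("a", "a", "b", "a"), c("b", "c", "c", "d")))
  expect_equal(clustering_coefficient(tri), 7 / 12)
  expect_equal(clustering_coefficient_pct(tri), 700 / 12)
})

test_that("clustering coefficient agrees with igraph on random graphs", {
  set.seed(59)
  for (i in 1:10) {
    p <- pcit(rand_cor(sample(5:12, 1)))
    net <- build_networks(p, p)[[1]]
    want <- igraph::transitivity(as_igraph(net), type = "localaverage",
                                 isolates = "zero")
    expect_equal(clustering_coefficient(net), want)
  }
})

test_that("degree histogram counts nodes and satisfies the handshake lemma", {
  empty <- toy_net(edge_df(), nodes = sprintf("n%d", 1:5))
  expect_identical(degree_histogram(empty), c("0" = 5L))
  path3 <- toy_net(edge_df(c("a", "b"), c("b", "c")))
  expect_identical(degree_histogram(path3), c("1" = 2L, "2" = 1L))

  set.seed(61)
  for (i in 1:10) {
    p <- pcit(rand_cor(sample(4:12, 1)))
    net <- build_networks(p, p)[[1]]
    h <- degree_histogram(net)
    expect_equal(sum(h), nrow(net$nodes))
    expect_equal(sum(as.integer(names(h)) * h), 2 * nrow(net$edges))
  }
})

test_that("SIF/TSV/GraphML exports carry the full network", {
  net <- toy_net(edge_df(c("a", "b"), c("b", "c"), w = c(0.9, -0.4)),
                 nodes = c("a", "b", "c", "iso"), tfs = "a",
                 condition = "ref")
  dir <- withr::local_tempdir()
  write_sif(net, file.path(dir, "n.sif"))
  sif <- readLines(file.path(dir, "n.sif"))
  expect_identical(sif, c("a\tcor\tb", "b\tcor\tc", "iso"))

  write_edges_tsv(net, file.path(dir, "n.tsv"))
  tsv <- read.delim(file.path(dir, "n.tsv"))
  expect_identical(names(tsv),
                   c("node_a", "interaction", "node_b", "weight", "condition"))
  expect_identical(unique(tsv$condition), "ref")

  write_graphml(net, file.path(dir, "n.graphml"))
  g <- igraph::read_graph(file.path(dir, "n.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
})
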