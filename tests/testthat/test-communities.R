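test_that("Girvan-Newman resolves canonical toy graphs", {
  # two triangles joined by a bridge edge
  em <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  g <- toy_graph(em)
  part <- girvan_newman(g)
  expect_equal(part$n_communities, 2)
  mem <- part$node_to_community
  expect_equal(length(unique(mem[c("n01", "n02", "n03")])), 1)
  expect_equal(length(unique(mem[c("n04", "n05", "n06")])), 1)
  expect_false(mem[["n01"]] == mem[["n04"]])
  # a single triangle stays one community
  tri <- toy_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(girvan_newman(tri)$n_communities, 1)
  # edgeless graph: all singletons
  iso <- toy_graph(matrix(integer(0), 0, 2), n = 3)
  expect_equal(girvan_newman(iso)$n_communities, 3)
})

test_that("modularity matches igraph on arbitrary partitions", {
  set.seed(5)
  for (rep in 1:5) {
    em <- unique(t(replicate(12, sort(sample(7, 2)))))
    g <- toy_graph(em, n = 7)
    mem <- sample(1:3, 7, replace = TRUE)
    names(mem) <- names(g$nodes)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = names(g$nodes))
    expect_equal(modularity_q(g, mem),
                 igraph::modularity(ig, mem[names(g$nodes)]),
                 tolerance = 1e-12)
  }
})

test_that("GN equals the independent brute-force oracle on small graphs", {
  # all connected labeled graphs on 4 nodes, plus random 6/7-node graphs
  graphs <- all_connected_graphs(4)
  set.seed(2)
  for (rep in 1:15) {
    k <- sample(6:7, 1)
    em <- unique(t(replicate(sample(6:12, 1), sort(sample(k, 2)))))
    graphs[[length(graphs) + 1]] <- em
  }
  for (em in graphs) {
    n <- max(em)
    g <- toy_graph(em, n = n)
    mine <- girvan_newman(g)
    oracle <- bf_girvan_newman(n, em)
    expect_equal(mine$modularity, oracle$modularity, tolerance = 1e-9)
    expect_equal(adjusted_rand_index(unname(mine$node_to_community), oracle$membership), 1)
    # modularity of the returned partition cross-checked against igraph
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = names(g$nodes))
    expect_equal(mine$modularity,
                 igraph::modularity(ig, mine$node_to_community[names(g$nodes)]),
                 tolerance = 1e-12)
  }
})

test_that("samples are assigned by membership count with documented tie-breaks", {
  # fixed partition: nodes a* form community 1, nodes b* community 2
  nodes <- list(a1 = c("x", "u1", "u2"), a2 = c("x", "u1", "u3"),
                b1 = c("x", "v1"), b2 = c("v1", "v2", "v3", "v4", "v5"))
  g <- build_graph(nodes)
  part <- structure(list(node_to_community = c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L),
                         modularity = 0, n_communities = 2L),
                    class = "gn_partition")
  cp <- assign_samples(part, g)
  # x is in 2 nodes of the a-community and 1 of the b-community
  expect_equal(cp$sample_to_cluster[["x"]], cp$sample_to_cluster[["u1"]])
  expect_false(cp$sample_to_cluster[["x"]] == cp$sample_to_cluster[["v1"]])
  # a sample in exactly one node takes that node's community
  expect_equal(cp$sample_to_cluster[["v2"]], cp$sample_to_cluster[["v1"]])
  # every sample gets exactly one label
  expect_setequal(names(cp$sample_to_cluster), unique(unlist(nodes)))
  # cluster ids ordered by size: cl 1 is the larger v-side (5 samples vs 4)
  sizes <- table(cp$sample_to_cluster)
  expect_equal(as.integer(names(which.max(sizes))), 1L)
  expect_equal(cp$sample_to_cluster[["v1"]], 1L)
  expect_equal(cp$sample_to_cluster[["x"]], 2L)
})

test_that("an engineered membership tie resolves to the larger community", {
  # t sits in one node of each community with equal summed Jaccard weight;
  # community 1 has more nodes, so t goes there
  nodes <- list(a1 = c("t", "u1"), a2 = c("u1", "u2"), a3 = c("u2", "u3"),
                b1 = c("t", "v1"), b2 = c("v1", "v2"))
  g <- build_graph(nodes)
  g$edges$weight <- rep(0.5, nrow(g$edges))  # equalize the Jaccard tie-break
  part <- structure(list(node_to_community = c(a1 = 1L, a2 = 1L, a3 = 1L,
                                               b1 = 2L, b2 = 2L),
                         modularity = 0, n_communities = 2L),
                    class = "gn_partition")
  cp <- assign_samples(part, g)
  expect_equal(cp$sample_to_cluster[["t"]], cp$sample_to_cluster[["u1"]])
})

test_that("an identity resample gives gamma exactly 1", {
  x <- make_blobs(n1 = 20, n2 = 20, sep = 50, sd = 0.1, seed = 3)
  st <- bootstrap_stability(x, nb = 3, bo = 0.2, B = 1, seed = 11,
                            resample_fn = function(n) seq_len(n))
  expect_equal(st$gamma, rep(1, nrow(st)))
  expect_false(any(st$dissolved))
  expect_error(bootstrap_stability(x, 3, 0.2, B = 0), "B must be")
})

test_that("separated blob clusters are stable, noise clusters are not", {
  x <- make_blobs(n1 = 60, n2 = 60, sep = 10, sd = 1, seed = 12)
  st <- bootstrap_stability(x, nb = 3, bo = 0.2, B = 50, seed = 13)
  big <- st[order(-st$n_replicates_used, -st$gamma), ][1:2, ]
  expect_true(all(big$gamma >= 0.95))
  # i.i.d. noise: forced fine binning produces unstable clusters
  set.seed(14)
  noise <- matrix(rnorm(40 * 5), 40, 5,
                  dimnames = list(sprintf("n%02d", 1:40), sprintf("v%d", 1:5)))
  stn <- bootstrap_stability(noise, nb = 4, bo = 0.1, B = 20, seed = 15)
  if (nrow(stn) >= 4) expect_lt(min(stn$gamma), 0.6)
})

test_that("composition tables give row percentages over glycemic classes", {
  cl <- stats::setNames(c(rep(1L, 12), rep(2L, 5)), sprintf("s%02d", 1:17))
  clinical <- data.frame(
    sample_id = sprintf("s%02d", 1:17),
    glycemic_class = c(rep("noDM", 1), rep("PreDM", 4), rep("T2DM", 7),
                       rep("noDM", 5)))
  comp <- cluster_composition(cl, clinical)
  expect_equal(unname(comp$counts["1", ]), c(1, 4, 7))
  expect_equal(unname(comp$percent["1", ]), c(8.3, 33.3, 58.3), tolerance = 0.05)
  expect_equal(unname(rowSums(comp$percent)), c(100, 100))
  expect_equal(sum(comp$counts), 17)
})

test_that("the community pipeline is deterministic under a fixed seed", {
  co <- generate_cohort(small_spec(seed = 8))
  pp <- preprocess_cohort(co)
  a <- detect_communities(pp$imputed, 4, 0.2)
  b <- detect_communities(pp$imputed, 4, 0.2)
  expect_identical(a$sample_to_cluster, b$sample_to_cluster)
  expect_identical(a$modularity, b$modularity)
})
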