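test_that("lens contracts: duplicated samples, variance ordering, sign fix", {
  x <- make_blobs(n1 = 15, n2 = 15, seed = 2)
  lens <- compute_lens(x)
  expect_equal(nrow(lens$coords), 30)
  expect_gte(lens$explained[1], lens$explained[2])
  # duplicated sample row -> identical lens rows
  x2 <- rbind(x, dup = x[1, ])
  rownames(x2)[31] <- "dup"
  lens2 <- compute_lens(x2)
  expect_equal(unname(lens2$coords["dup", ]), unname(lens2$coords[1, ]))
  # deterministic sign: largest-|loading| protein has positive loading,
  # so flipping the data sign flips the scores back deterministically
  lens3 <- compute_lens(-x)
  expect_equal(abs(lens3$coords[, 1]), abs(lens$coords[, 1]), tolerance = 1e-8)
  expect_error(compute_lens(matrix(1:4, 2, 2)), "3 samples")
})

test_that("cover intervals follow the overlap formula and cover all points", {
  coords <- cbind(seq(0, 10, length.out = 21), seq(0, 1, length.out = 21))
  rownames(coords) <- sprintf("s%d", 1:21)
  cov0 <- build_cover(coords, nb = 5, bo = 0)
  expect_equal(cov0$intervals[[1]]$lo, c(0, 2, 4, 6, 8))
  expect_equal(cov0$intervals[[1]]$hi, c(2, 4, 6, 8, 10))
  cov2 <- build_cover(coords, nb = 2, bo = 0.2)
  expect_equal(cov2$intervals[[2]]$lo, c(0, 0.45))
  expect_equal(cov2$intervals[[2]]$hi, c(0.55, 1))
  # every point lies in at least one interval per dimension
  for (d in 1:2) {
    iv <- build_cover(coords, 4, 0.15)$intervals[[d]]
    hit <- vapply(coords[, d], function(v) any(v >= iv$lo & v <= iv$hi), logical(1))
    expect_true(all(hit))
  }
  expect_error(build_cover(coords, 0, 0.2), "nb")
  expect_error(build_cover(coords, 3, 1), "bo")
  expect_warning(build_cover(cbind(coords[, 1], 0), 3, 0.1), "degenerate")
})

test_that("bin clustering matches single-linkage oracles on small instances", {
  x <- make_blobs(n1 = 6, n2 = 6, d = 3, sep = 10, sd = 0.1, seed = 4)
  dmat <- as.matrix(dist(x))
  nodes <- cluster_bin(rownames(x), dmat)
  expect_length(nodes, 2)
  expect_setequal(nodes[[which(lengths(nodes) == 6)[1]]], rownames(x)[1:6])
  # a single sample is a singleton node
  expect_equal(cluster_bin("b001", dmat), list("b001"))
  # all pairwise distances equal: no histogram gap, one node
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(deq) <- 0
  expect_length(cluster_bin(letters[1:4], deq), 1)
  # two distant samples split only when a global scale says so
  dp <- matrix(c(0, 9, 9, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_length(cluster_bin(c("a", "b"), dp), 1)
  expect_length(cluster_bin(c("a", "b"), dp, global_cutoff = 5), 2)
})

test_that("graph edges carry Jaccard weights over intersecting nodes", {
  nodes <- list(n1 = c("1", "2", "3"), n2 = c("2", "3", "4"), n3 = c("9"))
  g <- build_graph(nodes)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 0.5)  # 2/4
  g2 <- build_graph(list(a = c("1", "2"), b = c("1", "2")))
  expect_equal(g2$edges$weight, 1)
  expect_equal(jaccard_index(1:3, 2:4), 0.5)
  expect_equal(jaccard_index(1:2, 4:5), 0)
})

test_that("scale-free fit matches an independent least-squares oracle", {
  # degree frequencies 8,4,2,1 at degrees 1,2,4,8: exactly log-linear
  deg <- rep(c(1, 2, 4, 8), times = c(8, 4, 2, 1))
  tab <- table(deg)
  fit <- suppressWarnings(lm(log(as.numeric(tab)) ~ log(as.numeric(names(tab)))))
  expect_equal(unname(suppressWarnings(summary(fit))$r.squared), 1,
               tolerance = 1e-12)
  # uniform degrees -> undefined
  tri <- toy_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_true(is.na(scale_free_fit(tri)))
  # random graph: package value equals brute-force regression on same points
  set.seed(8)
  em <- unique(t(replicate(25, sort(sample(12, 2)))))
  gr <- toy_graph(em, n = 12)
  degs <- table(c(em[, 1], em[, 2]))
  freq <- table(as.integer(degs))
  oracle <- summary(lm(log(as.numeric(freq)) ~ log(as.numeric(names(freq)))))$r.squared
  expect_equal(scale_free_fit(gr), oracle, tolerance = 1e-12)
})

test_that("every sample is covered and membership grows with overlap", {
  co <- generate_cohort(small_spec(seed = 6))
  pp <- preprocess_cohort(co)
  g <- mapper(pp$imputed, 4, 0.15)
  expect_setequal(unique(unlist(g$nodes)), rownames(pp$imputed))
  multiplicity <- function(bo) {
    gg <- mapper(pp$imputed, 4, bo)
    sum(lengths(gg$nodes))
  }
  m1 <- multiplicity(0.10); m2 <- multiplicity(0.20); m3 <- multiplicity(0.30)
  expect_lte(m1, m2); expect_lte(m2, m3)
})

test_that("the graph is invariant to sample and protein order", {
  co <- generate_cohort(small_spec(seed = 7))
  pp <- preprocess_cohort(co)
  x <- pp$imputed
  g <- mapper(x, 4, 0.2)
  set.seed(1)
  x2 <- x[sample(nrow(x)), sample(ncol(x))]
  g2 <- mapper(x2, 4, 0.2)
  canon <- function(g) {
    sets <- sort(vapply(g$nodes, function(s) paste(sort(s), collapse = "|"), ""))
    unname(sets)
  }
  expect_identical(canon(g), canon(g2))
  edge_canon <- function(g) {
    key <- function(nd) paste(sort(g$nodes[[nd]]), collapse = "|")
    e <- data.frame(a = vapply(g$edges$from, key, ""), b = vapply(g$edges$to, key, ""),
                    w = g$edges$weight)
    swap <- e$a > e$b
    tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
    e <- e[order(e$a, e$b), ]; rownames(e) <- NULL; e
  }
  expect_equal(edge_canon(g), edge_canon(g2), tolerance = 1e-12)
})

test_that("two well-separated blobs give exactly two components", {
  x <- make_blobs(n1 = 60, n2 = 60, sep = 10, sd = 1, seed = 9)
  g <- mapper(x, 3, 0.2)
  comp <- inflamapper:::graph_components(g)
  # components by sample content
  blob_of <- function(ids) unique(substr(ids, 1, 1))
  samp_comp <- lapply(split(names(g$nodes), comp), function(nds) unique(unlist(g$nodes[nds])))
  expect_equal(length(samp_comp), 2)
})

test_that("grid search selects admissible maxima with deterministic ties", {
  x <- make_blobs(n1 = 40, n2 = 40, sep = 3, sd = 1, seed = 10)
  gs <- grid_search(x, nb_values = 4, bo_values = 0.2,
                    min_component_coverage = 0.5)
  expect_equal(nrow(gs$table), 1)
  if (gs$table$admissible[1]) {
    expect_equal(gs$selected$nb, 4)
    expect_equal(gs$selected$bo, 0.2)
  } else {
    expect_null(gs$selected)
    expect_match(gs$diagnostic, "no admissible")
  }
  expect_error(grid_search(x, integer(0), 0.2), "empty")
})
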