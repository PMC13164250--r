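# Shared fixtures and independent oracles used across the test files.

# A reduced synthetic cohort spec for fast unit tests (full panel, smaller n).
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_per_group = c(noDM = 24, PreDM = 12, T2DM = 18),
         n_bridge = 12, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over ranks j >= rank(i)
# of p_(j) * n / j, capped at 1. O(n^2), written from the definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ranks <- match(seq_len(n), o)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- Inf
    for (j in seq_len(n)) {
      if (j >= ranks[i]) cand <- min(cand, p[o[j]] * n / j)
    }
    q[i] <- min(1, cand)
  }
  q
}

# Enumerate every connected labeled graph on n nodes as edge-list matrices.
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  out <- list()
  for (mask in 1:(2^nrow(pairs) - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)))
    em <- pairs[sel, , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(em))) {
        m <- min(comp[em[e, 1]], comp[em[e, 2]])
        if (comp[em[e, 1]] != m || comp[em[e, 2]] != m) {
          comp[comp == comp[em[e, 1]] | comp == comp[em[e, 2]]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) == 1) out[[length(out) + 1]] <- em
  }
  out
}

# Wrap an edge matrix (integer endpoints) as a mapper_graph with singleton
# sample sets, so graph algorithms can run on arbitrary abstract graphs.
toy_graph <- function(edge_mat, n = max(edge_mat, 1)) {
  nodes <- stats::setNames(lapply(seq_len(n), function(i) sprintf("s%02d", i)),
                           sprintf("n%02d", seq_len(n)))
  g <- list(nodes = nodes, samples = unlist(nodes))
  if (nrow(edge_mat)) {
    g$edges <- data.frame(from = sprintf("n%02d", edge_mat[, 1]),
                          to = sprintf("n%02d", edge_mat[, 2]),
                          weight = rep(1, nrow(edge_mat)),
                          stringsAsFactors = FALSE)
  } else {
    g$edges <- data.frame(from = character(0), to = character(0),
                          weight = numeric(0), stringsAsFactors = FALSE)
  }
  class(g) <- "mapper_graph"
  g
}

# Two well-separated Gaussian blobs in `d` dimensions, `sep` units apart.
make_blobs <- function(n1 = 30, n2 = 30, d = 10, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * d, 0, sd), n1, d),
             matrix(rnorm(n2 * d, sep, sd), n2, d))
  rownames(x) <- sprintf("b%03d", seq_len(n1 + n2))
  colnames(x) <- sprintf("v%02d", seq_len(d))
  x
}

# Run QC + bridge normalization on a generated cohort, returning the
# collapsed matrix and friends (the standard preprocessing chain).
preprocess_cohort <- function(cohort, threshold = 0.20, reference = "P1") {
  qc <- filter_missingness(cohort$npx, threshold)
  norm <- bridge_normalize(qc$npx, reference)
  list(npx = norm$npx, qc = qc$report, adjustment = norm$adjustment,
       imputed = impute_for_projection(norm$npx))
}

# ---- independent brute-force Girvan-Newman oracle -------------------------
# Edge betweenness by explicit enumeration of all shortest paths (recursive
# backtracking over predecessor links), modularity from the definitional
# double sum, components by BFS. Same lexicographic tie rule as specified
# for the algorithm, but none of the package's code paths.

bf_components <- function(n, em) {
  comp <- rep(NA_integer_, n); k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

bf_edge_betweenness <- function(n, em) {
  eb <- numeric(nrow(em))
  edge_id <- function(u, v) which((em[, 1] == min(u, v)) & (em[, 2] == max(u, v)))
  for (s in seq_len(n - 1)) {
    # BFS distances and predecessors from s
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    preds <- vector("list", n)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
      for (w in nb) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1; preds[[w]] <- v; queue <- c(queue, w)
        } else if (dist[w] == dist[v] + 1) {
          preds[[w]] <- union(preds[[w]], v)
        }
      }
    }
    for (t_ in (s + 1):n) {
      if (!is.finite(dist[t_])) next
      # enumerate every shortest s-t path explicitly
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) { paths[[length(paths) + 1]] <<- acc; return(invisible()) }
        for (u in preds[[v]]) walk(u, c(list(c(u, v)), acc))
      }
      walk(t_, list())
      for (pth in paths) {
        for (e in pth) eb[edge_id(e[1], e[2])] <- eb[edge_id(e[1], e[2])] + 1 / length(paths)
      }
    }
  }
  eb
}

bf_modularity <- function(n, em, membership) {
  m <- nrow(em)
  if (m == 0) return(0)
  A <- matrix(0, n, n)
  for (e in seq_len(m)) { A[em[e, 1], em[e, 2]] <- A[em[e, 1], em[e, 2]] + 1
                          A[em[e, 2], em[e, 1]] <- A[em[e, 2], em[e, 1]] + 1 }
  deg <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
  }
  q / (2 * m)
}

bf_girvan_newman <- function(n, em) {
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  partitions <- list(bf_components(n, em))
  active <- em
  while (nrow(active)) {
    eb <- bf_edge_betweenness(n, active)
    mx <- max(eb)
    drop_idx <- which(eb >= mx - 1e-9 * max(1, mx))[1]  # lexicographically first
    active <- active[-drop_idx, , drop = FALSE]
    comp <- bf_components(n, active)
    if (max(comp) > max(partitions[[length(partitions)]])) {
      partitions[[length(partitions) + 1]] <- comp
    }
  }
  qs <- vapply(partitions, function(p) bf_modularity(n, em, p), numeric(1))
  list(membership = partitions[[which.max(qs)]], modularity = max(qs))
}
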