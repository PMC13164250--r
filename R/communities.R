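#' @name communities
#' @title Girvan-Newman community detection and bootstrap stability
#' @description
#' Divisive community detection on the Mapper graph: edges with the highest
#' (unweighted) edge betweenness are removed iteratively; every
#' fragmentation of the graph is recorded as a candidate partition, and the
#' partition maximizing Newman modularity on the original graph is
#' returned. Jaccard edge weights are not used during removal (only for
#' sample-assignment tie-breaks). Per-sample cluster labels are derived by
#' majority node membership, and cluster robustness is scored by bootstrap
#' resampling of samples.
NULL

# Brandes accumulation of unweighted edge betweenness.
# adj: list of integer neighbor vectors; eid: n x n matrix of edge indices.
edge_betweenness_all <- function(adj, eid, n_edges) {
  n <- length(adj)
  eb <- numeric(n_edges)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        c_ <- sigma[v] / sigma[w] * (1 + delta[w])
        eb[eid[v, w]] <- eb[eid[v, w]] + c_
        delta[v] <- delta[v] + c_
      }
    }
  }
  eb / 2  # each unordered pair contributes from both endpoints
}

# connected components over an active edge subset; returns membership 1..k
components_from_edges <- function(n, edge_mat, active) {
  comp <- seq_len(n)
  for (e in which(active)) {
    a <- edge_mat[e, 1]; b <- edge_mat[e, 2]
    ca <- comp[a]; cb <- comp[b]
    if (ca != cb) comp[comp == cb] <- ca
  }
  match(comp, unique(comp))
}

#' Newman modularity of a node partition
#'
#' Unweighted modularity Q = sum_c (L_c/m - (d_c / 2m)^2) computed on the
#' graph's original edge set; Q = 0 for an edgeless graph.
#'
#' @param graph a `mapper_graph` (or list with `nodes` and `edges`).
#' @param membership integer community id per node, named by node id or
#'   aligned with `names(graph$nodes)`.
#' @return modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  ids <- names(graph$nodes)
  if (!is.null(names(membership))) membership <- membership[ids]
  m <- nrow(graph$edges)
  if (m == 0) return(0)
  deg <- graph_degrees(graph)
  q <- 0
  for (c_ in unique(membership)) {
    in_c <- ids[membership == c_]
    l_c <- sum(graph$edges$from %in% in_c & graph$edges$to %in% in_c)
    d_c <- sum(deg[in_c])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest unweighted edge
#' betweenness (ties broken lexicographically by the sorted endpoint id
#' pair), records the node partition at every fragmentation, and returns
#' the recorded partition (including the initial connected components)
#' that maximizes modularity on the original graph. Isolated nodes form
#' singleton communities.
#'
#' @param graph a `mapper_graph`.
#' @return object of class `gn_partition`: `node_to_community` (named
#'   integer), `modularity`, `n_communities`.
#' @export
girvan_newman <- function(graph) {
  ids <- names(graph$nodes)
  n <- length(ids)
  if (n == 0) stop("graph has no nodes")
  edges <- graph$edges
  if (nrow(edges)) {
    # canonical lexicographic edge order for deterministic tie-breaking
    a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
    o <- order(a, b)
    edge_mat <- cbind(match(a, ids), match(b, ids))[o, , drop = FALSE]
  } else {
    edge_mat <- matrix(integer(0), 0, 2)
  }
  n_edges <- nrow(edge_mat)
  active <- rep(TRUE, n_edges)

  partitions <- list(components_from_edges(n, edge_mat, active))
  while (any(active)) {
    adj <- vector("list", n)
    eid <- matrix(0L, n, n)
    for (e in which(active)) {
      u <- edge_mat[e, 1]; v <- edge_mat[e, 2]
      adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
      eid[u, v] <- e; eid[v, u] <- e
    }
    eb_active <- edge_betweenness_all(adj, eid, n_edges)[active]
    idx_active <- which(active)
    mx <- max(eb_active)
    cand <- idx_active[eb_active >= mx - 1e-9 * max(1, mx)]
    remove <- cand[1]  # lexicographically first among tied edges
    n_before <- max(partitions[[length(partitions)]])
    active[remove] <- FALSE
    comp <- components_from_edges(n, edge_mat, active)
    if (max(comp) > n_before || length(partitions) == 1) {
      if (max(comp) > max(partitions[[length(partitions)]])) {
        partitions[[length(partitions) + 1]] <- comp
      }
    }
  }
  qs <- vapply(partitions, function(p) modularity_q(graph, stats::setNames(p, ids)),
               numeric(1))
  best <- which.max(qs)  # ties: earliest recorded (fewest communities)
  membership <- stats::setNames(partitions[[best]], ids)
  structure(list(node_to_community = membership,
                 modularity = qs[best],
                 n_communities = max(membership)),
            class = "gn_partition")
}

#' Assign samples to communities
#'
#' A sample occupying several overlapping nodes is assigned to the
#' community containing the largest number of its node memberships; ties
#' are broken by the larger summed Jaccard edge weight between the sample's
#' nodes and the community's nodes, then by the larger community. Cluster
#' ids are relabelled by size (descending, cl 1 = largest).
#'
#' @param partition a `gn_partition`.
#' @param graph the `mapper_graph` the partition was computed on.
#' @return object of class `cluster_partition`: `sample_to_cluster` (named
#'   integer), `node_to_community` (relabelled), `modularity`,
#'   `n_communities`, `sizes`.
#' @export
assign_samples <- function(partition, graph) {
  membership <- partition$node_to_community
  ids <- names(graph$nodes)
  stopifnot(all(ids %in% names(membership)))
  samples <- sort(unique(unlist(graph$nodes)))
  ncomm <- max(membership)
  # per-sample membership counts per community
  counts <- matrix(0L, length(samples), ncomm, dimnames = list(samples, NULL))
  for (nd in ids) {
    counts[graph$nodes[[nd]], membership[nd]] <-
      counts[graph$nodes[[nd]], membership[nd]] + 1L
  }
  if (any(rowSums(counts) == 0)) stop("sample in no node: cover invariant violated")
  # summed Jaccard weight from each node to each community (for tie-breaks)
  node_comm_w <- matrix(0, length(ids), ncomm, dimnames = list(ids, NULL))
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      f <- graph$edges$from[e]; t_ <- graph$edges$to[e]; w <- graph$edges$weight[e]
      node_comm_w[f, membership[t_]] <- node_comm_w[f, membership[t_]] + w
      node_comm_w[t_, membership[f]] <- node_comm_w[t_, membership[f]] + w
    }
  }
  comm_node_count <- tabulate(membership[ids], ncomm)
  assigned <- integer(length(samples))
  for (si in seq_along(samples)) {
    cnt <- counts[si, ]
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1) {
      in_nodes <- ids[vapply(graph$nodes, function(nn) samples[si] %in% nn, logical(1))]
      wsum <- colSums(node_comm_w[in_nodes, cand, drop = FALSE])
      cand <- cand[wsum == max(wsum)]
    }
    if (length(cand) > 1) {
      # remaining ties: larger community (node count), then smaller id
      cand <- cand[order(-comm_node_count[cand], cand)]
    }
    assigned[si] <- cand[1]
  }
  # relabel by sample count, descending (stable on ties by old id)
  sizes <- tabulate(assigned, ncomm)
  new_of_old <- integer(ncomm)
  new_of_old[order(-sizes, seq_len(ncomm))] <- seq_len(ncomm)
  sample_to_cluster <- stats::setNames(new_of_old[assigned], samples)
  node_to_community <- stats::setNames(new_of_old[membership[ids]], ids)
  structure(list(sample_to_cluster = sample_to_cluster,
                 node_to_community = node_to_community,
                 modularity = partition$modularity,
                 n_communities = partition$n_communities,
                 sizes = sort(sizes, decreasing = TRUE)),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d communities (Q = %.3f); cluster sizes: %s\n",
              x$n_communities, x$modularity, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Mapper + Girvan-Newman in one call
#'
#' @param x complete numeric matrix (samples x proteins).
#' @param nb,bo Mapper resolution parameters.
#' @return a `cluster_partition` (with the `mapper_graph` attached as
#'   attribute `graph`).
#' @export
detect_communities <- function(x, nb, bo) {
  g <- mapper(x, nb, bo)
  part <- assign_samples(girvan_newman(g), g)
  attr(part, "graph") <- g
  part
}

#' Bootstrap stability of the sample clusters
#'
#' For each of B bootstrap replicates, samples are resampled with
#' replacement, the Mapper + Girvan-Newman pipeline is rerun at fixed
#' (nb, bo), and each baseline cluster is scored by its maximum Jaccard
#' similarity to any bootstrap cluster, computed on sets of original
#' sample ids (with-replacement duplicates collapsed; the baseline cluster
#' is restricted to samples drawn in the replicate). The per-cluster mean
#' over replicates is gamma; gamma < 0.5 flags a dissolved cluster.
#'
#' @param x complete numeric matrix (samples x proteins).
#' @param nb,bo Mapper resolution parameters.
#' @param B bootstrap iterations (default 100).
#' @param seed RNG seed for the resampling.
#' @param baseline optional precomputed `cluster_partition` on `x`.
#' @param resample_fn function(n) returning the row indices of one
#'   replicate; the default draws n samples with replacement. Exposed so
#'   the Jaccard bookkeeping can be verified exactly (an identity
#'   permutation must give gamma = 1).
#' @return object of class `stability_report`: data.frame (`cluster`,
#'   `gamma`, `dissolved`, `n_replicates_used`), plus attributes `B` and
#'   `n_failed`.
#' @export
bootstrap_stability <- function(x, nb, bo, B = 100, seed = 1, baseline = NULL,
                                resample_fn = function(n) sample.int(n, replace = TRUE)) {
  if (B < 1) stop("B must be >= 1")
  x <- as.matrix(x)
  baseline <- baseline %||% detect_communities(x, nb, bo)
  base_clusters <- split(names(baseline$sample_to_cluster), baseline$sample_to_cluster)
  K <- length(base_clusters)
  jac <- matrix(NA_real_, B, K)
  n_failed <- 0
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- resample_fn(nrow(x))
      drawn <- rownames(x)[idx]
      xb <- x[idx, , drop = FALSE]
      rownames(xb) <- sprintf("r%04d", seq_len(nrow(xb)))
      part_b <- tryCatch(detect_communities(xb, nb, bo), error = function(e) NULL)
      if (is.null(part_b)) { n_failed <- n_failed + 1; next }
      boot_sets <- lapply(split(names(part_b$sample_to_cluster), part_b$sample_to_cluster),
                          function(rs) unique(drawn[match(rs, rownames(xb))]))
      drawn_u <- unique(drawn)
      for (k in seq_len(K)) {
        base_k <- intersect(base_clusters[[k]], drawn_u)
        if (length(base_k) == 0) next
        jac[b, k] <- max(vapply(boot_sets, jaccard_index, numeric(1), b = base_k))
      }
    }
  })
  gamma <- colMeans(jac, na.rm = TRUE)
  report <- data.frame(cluster = as.integer(names(base_clusters)),
                       gamma = gamma,
                       dissolved = gamma < 0.5,
                       n_replicates_used = colSums(!is.na(jac)))
  structure(report, class = c("stability_report", "data.frame"),
            B = B, n_failed = n_failed)
}

#' Cluster x glycemic-class composition table
#'
#' @param sample_to_cluster named integer cluster labels.
#' @param clinical a clinical table with `sample_id` and `glycemic_class`.
#' @return list with `counts` (cluster x class matrix) and `percent`
#'   (row percentages).
#' @export
cluster_composition <- function(sample_to_cluster, clinical) {
  cls <- clinical$glycemic_class[match(names(sample_to_cluster), clinical$sample_id)]
  if (anyNA(cls)) stop("clustered samples missing a glycemic label")
  if (!is.factor(cls)) {
    canonical <- c("noDM", "PreDM", "T2DM")
    cls <- if (all(cls %in% canonical)) factor(cls, levels = canonical) else factor(cls)
  }
  counts <- table(cluster = sample_to_cluster, class = droplevels(cls))
  percent <- 100 * sweep(counts, 1, rowSums(counts), "/")
  list(counts = unclass(counts), percent = unclass(percent))
}
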