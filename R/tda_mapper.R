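#' PCA lens for Mapper
#'
#' Projects samples onto the first two principal components of the
#' per-protein mean-centred (not variance-scaled: NPX is already log2 and
#' cross-protein comparable) matrix. A deterministic sign convention is
#' applied per component: the protein with the largest absolute loading
#' gets a positive loading.
#'
#' @param x complete (imputed) numeric matrix, samples x proteins, with
#'   sample row names.
#' @return object of class `mapper_lens`: `coords` (samples x 2),
#'   `explained` (variance fractions of PC1/PC2), `sign_flip` record.
#' @export
compute_lens <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least 3 samples required for a PCA lens")
  if (anyNA(x)) stop("lens requires a complete matrix; impute first")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < 2 || pc$sdev[2] <= sqrt(.Machine$double.eps)) {
    stop("data rank < 2: cannot build a 2D lens")
  }
  flip <- logical(2)
  for (k in 1:2) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
      flip[k] <- TRUE
    }
  }
  coords <- pc$x[, 1:2, drop = FALSE]
  rownames(coords) <- rownames(x)
  structure(list(coords = coords,
                 explained = (pc$sdev[1:2]^2) / sum(pc$sdev^2),
                 sign_flip = flip),
            class = "mapper_lens")
}

#' Overlapping interval cover of the 2D lens
#'
#' Per lens dimension the data range is split into `nb` base intervals of
#' width w = range/nb; interval i is extended symmetrically by g*w/2 per
#' side (g = `bo`, the overlap ratio) and clipped to the data range, so
#' adjacent intervals overlap by g*w. The 2D cover is the product of the
#' two interval lists.
#'
#' @param lens a `mapper_lens` (or a samples x 2 coordinate matrix).
#' @param nb bins per dimension (>= 1).
#' @param bo overlap ratio in \[0, 1).
#' @return object of class `mapper_cover`: `intervals` (list of two
#'   data.frames with lo/hi), `nb`, `bo`.
#' @export
build_cover <- function(lens, nb, bo) {
  coords <- if (inherits(lens, "mapper_lens")) lens$coords else as.matrix(lens)
  if (nb < 1) stop("nb must be >= 1")
  if (bo < 0 || bo >= 1) stop("bo must lie in [0, 1)")
  intervals <- vector("list", 2)
  for (d in 1:2) {
    rng <- range(coords[, d])
    if (diff(rng) == 0) {
      if (nb > 1) warning("degenerate lens dimension ", d, ": falling back to a single interval")
      intervals[[d]] <- data.frame(lo = rng[1], hi = rng[2])
      next
    }
    w <- diff(rng) / nb
    i <- seq_len(nb) - 1
    lo <- pmax(rng[1], rng[1] + i * w - bo * w / 2)
    hi <- pmin(rng[2], rng[1] + (i + 1) * w + bo * w / 2)
    intervals[[d]] <- data.frame(lo = lo, hi = hi)
  }
  structure(list(intervals = intervals, nb = nb, bo = bo), class = "mapper_cover")
}

# sample ids falling in each 2D bin (closed intervals); empty bins dropped
cover_bins <- function(cover, coords) {
  iv1 <- cover$intervals[[1]]; iv2 <- cover$intervals[[2]]
  bins <- list()
  for (i in seq_len(nrow(iv1))) {
    in1 <- coords[, 1] >= iv1$lo[i] & coords[, 1] <= iv1$hi[i]
    for (j in seq_len(nrow(iv2))) {
      members <- rownames(coords)[in1 & coords[, 2] >= iv2$lo[j] & coords[, 2] <= iv2$hi[j]]
      if (length(members)) bins[[sprintf("bin_%d_%d", i, j)]] <- members
    }
  }
  bins
}

#' Cluster the samples of one cover bin into Mapper nodes
#'
#' Single-linkage agglomerative clustering on Euclidean distances in the
#' full (imputed) protein space, cut by the classic first-gap heuristic: a
#' 10-bin histogram of the merge heights is scanned for its first empty
#' bin, and the dendrogram is cut at that bin's lower edge; no empty bin
#' (or a single merge height value) means one cluster. A gap is meant to
#' separate the bulk of within-cluster merges from the few between-cluster
#' merges, so an empty bin only counts as a gap when at least half of the
#' merge heights lie below it (guarding against a spurious gap created by
#' a single unusually small first merge, which would otherwise shatter a
#' homogeneous bin into singletons).
#'
#' When [mapper()] finds a gap in the merge-height distribution of the
#' whole dataset it passes that height as `global_cutoff`, and every bin is
#' cut at this one scale: a bin-local histogram of few merge heights is too
#' jumpy (a sparse right tail fakes a gap and shaves samples off a
#' homogeneous bin; two-sample bins have no histogram at all yet may span
#' two communities). The local first-gap rule is used when the dataset
#' shows no global gap (default `Inf`).
#'
#' @param members sample ids in the bin.
#' @param dmat full symmetric distance matrix with sample dimnames.
#' @param n_hist_bins histogram resolution of the gap heuristic.
#' @param global_cutoff dataset-level cut height taking precedence over the
#'   bin-local gap search.
#' @return list of character vectors, one per node.
#' @export
cluster_bin <- function(members, dmat, n_hist_bins = 10, global_cutoff = Inf) {
  if (length(members) == 0) stop("empty bin")
  if (length(members) == 1) return(list(members))
  d <- stats::as.dist(dmat[members, members])
  hc <- stats::hclust(d, method = "single")
  h <- hc$height
  cut_h <- if (is.finite(global_cutoff)) global_cutoff
           else local_gap_cutoff(h, n_hist_bins)
  if (!is.finite(cut_h) || cut_h >= max(h)) return(list(members))
  grp <- stats::cutree(hc, h = cut_h * (1 + 1e-12))
  unname(split(members, grp))
}

# Guarded first-gap rule on a vector of merge heights: the first empty bin
# of an n_hist_bins histogram over [min, max] having at least half of the
# heights below it (a gap is meant to separate the bulk of within-cluster
# merges from the few between-cluster merges). Inf when no such gap.
local_gap_cutoff <- function(h, n_hist_bins = 10) {
  if (length(h) < 2 || diff(range(h)) <= .Machine$double.eps^0.5) return(Inf)
  breaks <- seq(min(h), max(h), length.out = n_hist_bins + 1)
  counts <- graphics::hist(h, breaks = breaks, plot = FALSE, right = FALSE)$counts
  counts[n_hist_bins] <- counts[n_hist_bins] + sum(h == max(h))  # right-open top bin
  below <- cumsum(counts) - counts  # heights strictly below each bin
  empty <- which(counts == 0 & below >= length(h) / 2)
  if (length(empty) == 0) return(Inf)
  breaks[empty[1]]
}

# Dataset-level cut scale from the merge heights of the full single-linkage
# dendrogram: locate the guarded first gap, then place the cut just below
# the smallest height ABOVE the gap. Cutting at the top of the gap (rather
# than its lower edge) keeps loose outlier merges attached to their bulk
# while still severing the clearly separated top merges. Inf when the
# height distribution shows no gap.
global_gap_cutoff <- function(dmat, n_hist_bins = 10) {
  if (nrow(dmat) < 3) return(Inf)
  h <- stats::hclust(stats::as.dist(dmat), method = "single")$height
  gap <- local_gap_cutoff(h, n_hist_bins)
  if (!is.finite(gap)) return(Inf)
  min(h[h >= gap]) * (1 - 1e-9)
}

#' Build the Jaccard-weighted Mapper graph from nodes
#'
#' Nodes are sample sets; an edge joins every pair of nodes whose sets
#' intersect, weighted by the Jaccard index of the two sets. No self-loops.
#'
#' @param nodes named list of character sample-id vectors.
#' @param samples optional character vector of all sample ids (for coverage
#'   accounting); defaults to the union of node members.
#' @return object of class `mapper_graph`: `nodes`, `edges`
#'   (data.frame from/to/weight), `samples`.
#' @export
build_graph <- function(nodes, samples = NULL) {
  if (length(nodes) == 0) stop("at least one node required")
  if (is.null(names(nodes))) names(nodes) <- sprintf("n%03d", seq_along(nodes))
  if (any(lengths(nodes) == 0)) stop("nodes must be non-empty")
  ids <- names(nodes)
  from <- character(0); to <- character(0); w <- numeric(0)
  if (length(nodes) > 1) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        inter <- length(intersect(nodes[[i]], nodes[[j]]))
        if (inter > 0) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
          w <- c(w, inter / length(union(nodes[[i]], nodes[[j]])))
        }
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 samples = samples %||% sort(unique(unlist(nodes)))),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges, %d samples covered\n",
              length(x$nodes), nrow(x$edges), length(unique(unlist(x$nodes)))))
  invisible(x)
}

# node degrees (0 for isolated nodes)
graph_degrees <- function(graph) {
  deg <- stats::setNames(rep(0L, length(graph$nodes)), names(graph$nodes))
  if (nrow(graph$edges)) {
    tab <- table(c(graph$edges$from, graph$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# connected components of a mapper graph -> named membership vector
graph_components <- function(graph) {
  ids <- names(graph$nodes)
  comp <- stats::setNames(seq_along(ids), ids)
  if (nrow(graph$edges)) {
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(graph$edges))) {
        a <- graph$edges$from[e]; b <- graph$edges$to[e]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  stats::setNames(match(comp, sort(unique(comp))), ids)
}

#' Goodness of a scale-free degree distribution
#'
#' Least-squares fit of log(frequency) against log(degree) over the
#' observed positive degrees; returns the coefficient of determination.
#' Fewer than three distinct positive degrees make the fit undefined (NA).
#'
#' @param graph a `mapper_graph`.
#' @return R-squared of the log-log fit, or NA.
#' @export
scale_free_fit <- function(graph) {
  deg <- graph_degrees(graph)
  deg <- deg[deg >= 1]
  if (length(deg) == 0) return(NA_real_)
  tab <- table(deg)
  if (length(tab) < 3) return(NA_real_)
  fit <- stats::lm(log(as.numeric(tab)) ~ log(as.numeric(names(tab))))
  summary(fit)$r.squared
}

#' Run the full Mapper construction at fixed resolution
#'
#' lens -> cover -> per-bin single-linkage clustering -> Jaccard graph.
#'
#' @param x complete numeric matrix (samples x proteins, sample row names).
#' @param nb bins per lens dimension.
#' @param bo bin overlap ratio.
#' @param lens optionally a precomputed `mapper_lens`.
#' @param dmat optionally a precomputed full distance matrix.
#' @return a `mapper_graph` with attributes `lens` and `cover`.
#' @export
mapper <- function(x, nb, bo, lens = NULL, dmat = NULL) {
  x <- as.matrix(x)
  lens <- lens %||% compute_lens(x)
  dmat <- dmat %||% as.matrix(stats::dist(x))
  cover <- build_cover(lens, nb, bo)
  bins <- cover_bins(cover, lens$coords)
  # dataset-level merge-height gap: one cut scale shared by all bins
  cutoff <- global_gap_cutoff(dmat)
  nodes <- list()
  node_bin <- character(0)
  for (b in names(bins)) {
    cl <- cluster_bin(bins[[b]], dmat, global_cutoff = cutoff)
    for (k in seq_along(cl)) {
      nodes[[sprintf("%s_c%d", b, k)]] <- cl[[k]]
      node_bin <- c(node_bin, b)
    }
  }
  g <- build_graph(nodes, samples = rownames(x))
  g$node_bin <- stats::setNames(node_bin, names(nodes))
  attr(g, "lens") <- lens
  attr(g, "cover") <- cover
  g
}

#' Grid search over Mapper resolution parameters
#'
#' Runs the full Mapper construction for every (nb, bo) pair, records node
#' and edge counts, sample coverage of the largest connected component,
#' component count and the scale-free fit, and selects — among pairs whose
#' largest component covers at least `min_component_coverage` of the
#' samples and that yield at least `min_nodes` nodes — the pair maximizing
#' the scale-free R-squared (ties: smaller nb, then smaller bo).
#'
#' @param x complete numeric matrix (samples x proteins).
#' @param nb_values,bo_values grids; defaults nb 4..10, bo 0.10-0.30.
#' @param min_component_coverage admissibility threshold on the fraction of
#'   samples inside the largest connected component.
#' @param min_nodes minimum node count for admissibility.
#' @return object of class `grid_search_result`: `table` (one row per
#'   pair), `selected` (list with nb/bo, or NULL with a diagnostic).
#' @export
grid_search <- function(x, nb_values = 4:10,
                        bo_values = c(0.10, 0.15, 0.20, 0.25, 0.30),
                        min_component_coverage = 0.95, min_nodes = 2) {
  if (length(nb_values) == 0 || length(bo_values) == 0) stop("empty parameter grid")
  x <- as.matrix(x)
  lens <- compute_lens(x)
  dmat <- as.matrix(stats::dist(x))
  rows <- list()
  for (nb in sort(nb_values)) {
    for (bo in sort(bo_values)) {
      g <- mapper(x, nb, bo, lens = lens, dmat = dmat)
      comp <- graph_components(g)
      comp_cover <- vapply(seq_len(max(comp)), function(k) {
        length(unique(unlist(g$nodes[comp == k])))
      }, integer(1))
      rows[[length(rows) + 1]] <- data.frame(
        nb = nb, bo = bo,
        n_nodes = length(g$nodes), n_edges = nrow(g$edges),
        coverage = length(unique(unlist(g$nodes))) / nrow(x),
        largest_component_coverage = max(comp_cover) / nrow(x),
        n_components = max(comp),
        scale_free_r2 = scale_free_fit(g))
    }
  }
  tab <- do.call(rbind, rows)
  admissible <- tab$largest_component_coverage >= min_component_coverage &
    tab$n_nodes >= min_nodes & !is.na(tab$scale_free_r2)
  tab$admissible <- admissible
  selected <- NULL
  diagnostic <- NULL
  if (any(admissible)) {
    cand <- tab[admissible, ]
    cand <- cand[order(-cand$scale_free_r2, cand$nb, cand$bo), ]
    selected <- list(nb = cand$nb[1], bo = cand$bo[1],
                     scale_free_r2 = cand$scale_free_r2[1])
  } else {
    diagnostic <- "no admissible (nb, bo) pair: no parameterization reached the coverage/size thresholds with a defined scale-free fit"
  }
  structure(list(table = tab, selected = selected, diagnostic = diagnostic),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  if (is.null(x$selected)) {
    cat("<grid_search_result> no admissible pair selected\n  ", x$diagnostic, "\n")
  } else {
    cat(sprintf("<grid_search_result> selected nb = %d, bo = %.2f (scale-free R2 = %.3f) of %d pairs\n",
                x$selected$nb, x$selected$bo, x$selected$scale_free_r2, nrow(x$table)))
  }
  invisible(x)
}
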