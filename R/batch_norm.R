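#' Estimate per-protein bridge adjustments between plates
#'
#' Standard bridge normalization: for each non-reference plate and each
#' protein, the adjustment is the median over bridge samples of the paired
#' difference (value on that plate minus value on the reference plate),
#' computed on pairwise-complete bridge pairs. The median is robust to a
#' single aberrant bridge sample.
#'
#' @param m an `npx_matrix` containing bridge samples measured on the
#'   reference plate and on every other plate.
#' @param reference_plate plate label left unchanged by the adjustment.
#' @return an object of class `bridge_adjustment`: `reference_plate`,
#'   `adjustments` (named list: plate -> per-protein delta), `n_bridge_used`
#'   (named list: plate -> per-protein count of complete bridge pairs).
#' @export
estimate_bridge_adjustment <- function(m, reference_plate) {
  stopifnot(inherits(m, "npx_matrix"))
  plates <- unique(m$plate)
  if (!reference_plate %in% plates) stop("reference plate not present: ", reference_plate)
  others <- setdiff(plates, reference_plate)
  adjustments <- list()
  n_used <- list()
  for (p in others) {
    ref_rows <- which(m$plate == reference_plate & m$is_bridge)
    oth_rows <- which(m$plate == p & m$is_bridge)
    common <- intersect(m$sample_id[ref_rows], m$sample_id[oth_rows])
    if (length(common) == 0) stop("no bridge samples shared between plates ",
                                  reference_plate, " and ", p)
    ref_v <- m$values[ref_rows[match(common, m$sample_id[ref_rows])], , drop = FALSE]
    oth_v <- m$values[oth_rows[match(common, m$sample_id[oth_rows])], , drop = FALSE]
    diffs <- oth_v - ref_v  # NA where either measurement missing
    n_pairs <- colSums(!is.na(diffs))
    if (any(n_pairs == 0)) {
      stop("no complete bridge pairs for plate ", p, ", proteins: ",
           paste(colnames(diffs)[n_pairs == 0], collapse = ", "))
    }
    adjustments[[p]] <- apply(diffs, 2, stats::median, na.rm = TRUE)
    n_used[[p]] <- n_pairs
  }
  structure(list(reference_plate = reference_plate,
                 adjustments = adjustments,
                 n_bridge_used = n_used),
            class = "bridge_adjustment")
}

#' @export
print.bridge_adjustment <- function(x, ...) {
  cat(sprintf("<bridge_adjustment> reference plate %s; adjusted plates: %s\n",
              x$reference_plate, paste(names(x$adjustments), collapse = ", ")))
  for (p in names(x$adjustments)) {
    d <- x$adjustments[[p]]
    cat(sprintf("  %s: median |delta| = %.3f NPX over %d proteins\n",
                p, stats::median(abs(d)), length(d)))
  }
  invisible(x)
}

#' Apply bridge adjustments and collapse replicate measurements
#'
#' Subtracts the per-protein adjustment from every non-reference-plate
#' measurement, then collapses samples measured on more than one plate to
#' the mean of their post-adjustment replicates (NA-aware: a cell missing in
#' one replicate takes the observed value of the other), yielding one row
#' per individual.
#'
#' @param m an `npx_matrix`.
#' @param adj a `bridge_adjustment` covering every non-reference plate in `m`.
#' @return an `npx_matrix` with one row per sample; collapsed bridge rows
#'   carry the reference plate label.
#' @export
apply_bridge_adjustment <- function(m, adj) {
  stopifnot(inherits(m, "npx_matrix"), inherits(adj, "bridge_adjustment"))
  plates <- unique(m$plate)
  uncovered <- setdiff(plates, c(adj$reference_plate, names(adj$adjustments)))
  if (length(uncovered)) stop("plates missing from adjustment: ",
                              paste(uncovered, collapse = ", "))
  vals <- m$values
  for (p in names(adj$adjustments)) {
    delta <- adj$adjustments[[p]]
    if (!all(colnames(vals) %in% names(delta))) {
      stop("adjustment does not cover proteins: ",
           paste(setdiff(colnames(vals), names(delta)), collapse = ", "))
    }
    rows <- m$plate == p
    vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2, delta[colnames(vals)], "-")
  }
  ids <- unique(m$sample_id)
  out <- matrix(NA_real_, length(ids), ncol(vals), dimnames = list(NULL, colnames(vals)))
  out_plate <- character(length(ids))
  out_bridge <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(m$sample_id == ids[i])
    if (length(rows) == 1) {
      out[i, ] <- vals[rows, ]
      out_plate[i] <- m$plate[rows]
    } else {
      out[i, ] <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
      out[i, is.nan(out[i, ])] <- NA_real_
      out_plate[i] <- adj$reference_plate
    }
    out_bridge[i] <- any(m$is_bridge[rows])
  }
  npx_matrix(out, ids, out_plate, out_bridge)
}

#' One-shot bridge normalization
#'
#' Convenience wrapper: estimate adjustments against `reference_plate` and
#' apply them. Exposed separately so alternative adjusters (e.g. two-step
#' refinements) can be slotted in via the `adjuster` hook.
#'
#' @param m an `npx_matrix`.
#' @param reference_plate plate label used as reference.
#' @param adjuster function `(m, reference_plate) -> bridge_adjustment`;
#'   defaults to [estimate_bridge_adjustment()].
#' @return list with `npx` (normalized, collapsed matrix) and `adjustment`.
#' @export
bridge_normalize <- function(m, reference_plate,
                             adjuster = estimate_bridge_adjustment) {
  adj <- adjuster(m, reference_plate)
  list(npx = apply_bridge_adjustment(m, adj), adjustment = adj)
}
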