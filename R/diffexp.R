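#' Two-group differential expression on NPX values
#'
#' Per-protein Welch (unequal-variance) t-test between two groups. Because
#' NPX is a log2-scale unit, the difference of group means is directly a
#' log2 fold change. Missing cells are dropped per protein (complete-case);
#' a protein with fewer than two observed values in either group is flagged
#' untested rather than producing a spurious statistic. P-values are
#' Benjamini-Hochberg adjusted across the tested proteins.
#'
#' @param m an `npx_matrix` with one row per sample, or a numeric matrix with
#'   sample row names.
#' @param labels group label per sample: a vector named by sample id, or
#'   aligned with the rows of `m`.
#' @param groupA,groupB labels of the test and reference groups; `log2FC`
#'   is mean(A) - mean(B).
#' @return a data.frame of class `diffexp_result` with columns `protein`,
#'   `log2FC`, `mean_A`, `mean_B`, `n_A`, `n_B`, `t`, `df`, `p`, `q`,
#'   `tested`.
#' @export
ttest_two_group <- function(m, labels, groupA, groupB) {
  x <- if (inherits(m, "npx_matrix")) {
    if (anyDuplicated(m$sample_id)) stop("one row per sample required; collapse bridges first")
    v <- m$values; rownames(v) <- m$sample_id; v
  } else as.matrix(m)
  if (!is.null(names(labels))) {
    if (!all(rownames(x) %in% names(labels))) stop("labels missing for some samples")
    labels <- labels[rownames(x)]
  } else if (length(labels) != nrow(x)) {
    stop("labels must align with samples")
  }
  labels <- as.character(labels)
  for (g in c(groupA, groupB)) {
    if (!g %in% labels) stop("unknown or empty group label: ", g)
  }
  inA <- labels == groupA
  inB <- labels == groupB
  res <- data.frame(
    protein = colnames(x), log2FC = NA_real_, mean_A = NA_real_, mean_B = NA_real_,
    n_A = NA_integer_, n_B = NA_integer_, t = NA_real_, df = NA_real_,
    p = NA_real_, q = NA_real_, tested = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(x))) {
    a <- x[inA, j]; a <- a[!is.na(a)]
    b <- x[inB, j]; b <- b[!is.na(b)]
    res$n_A[j] <- length(a); res$n_B[j] <- length(b)
    if (length(a) >= 1 && length(b) >= 1) {
      res$mean_A[j] <- mean(a); res$mean_B[j] <- mean(b)
      res$log2FC[j] <- mean(a) - mean(b)
    }
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      res$t[j] <- unname(tt$statistic)
      res$df[j] <- unname(tt$parameter)
      res$p[j] <- tt$p.value
      res$tested[j] <- TRUE
    } else if (length(a) >= 2 && length(b) >= 2) {
      # zero variance in both groups: the t statistic is 0 when means are
      # equal and undefined otherwise; report t = 0 / p = 1 only when equal
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        res$t[j] <- 0; res$df[j] <- length(a) + length(b) - 2; res$p[j] <- 1
        res$tested[j] <- TRUE
      }
    }
  }
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  attr(res, "groups") <- c(A = groupA, B = groupB)
  class(res) <- c("diffexp_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`: q_i is the
#' running minimum over ranks >= rank(i) of p_(j) * n / j, capped at 1, with
#' the original input order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Annotate differential-expression results for a volcano display
#'
#' Labels each protein `fdr_significant` (q < alpha), `nominal_only`
#' (p < alpha but q >= alpha), or `ns`.
#'
#' @param results a `diffexp_result`.
#' @param alpha significance level, default 0.05.
#' @return the input with an added `class` column and `neg_log10_p`.
#' @export
volcano_table <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "diffexp_result"))
  cls <- rep("ns", nrow(results))
  cls[!is.na(results$p) & results$p < alpha] <- "nominal_only"
  cls[!is.na(results$q) & results$q < alpha] <- "fdr_significant"
  cls[!results$tested] <- NA_character_
  results$class <- cls
  results$neg_log10_p <- -log10(results$p)
  results
}

#' Run all pairwise glycemic contrasts
#'
#' Runs [ttest_two_group()] independently for each contrast, each BH-adjusted
#' within contrast.
#'
#' @param m NPX matrix (one row per sample).
#' @param labels glycemic class per sample (named by sample id).
#' @param contrasts list of c(test, reference) pairs; default the three
#'   pairwise glycemic contrasts.
#' @return named list of `diffexp_result` tables ("A_vs_B").
#' @export
diffexp_all_contrasts <- function(m, labels,
                                  contrasts = list(c("T2DM", "noDM"),
                                                   c("PreDM", "noDM"),
                                                   c("T2DM", "PreDM"))) {
  out <- list()
  for (ct in contrasts) {
    out[[paste0(ct[1], "_vs_", ct[2])]] <- ttest_two_group(m, labels, ct[1], ct[2])
  }
  out
}
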