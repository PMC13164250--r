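#' NPX measurement matrix
#'
#' Container for plate-based targeted proteomics measurements on the NPX
#' scale (log2 arbitrary units). One row per *measurement*: a bridge sample
#' measured on both plates contributes two rows with the same `sample_id`
#' and different `plate`. Missing values are encoded as `NA` in `values`.
#'
#' @param values numeric matrix, measurements x proteins; column names are
#'   assay (protein) identifiers.
#' @param sample_id character vector, one per row of `values`.
#' @param plate character vector of plate labels, one per row.
#' @param is_bridge logical vector; `TRUE` for samples measured on more than
#'   one plate. Derived from duplicated `sample_id` when omitted.
#' @return an object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, sample_id, plate, is_bridge = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("protein ids (column names) are required")
  if (anyDuplicated(colnames(values))) stop("duplicate protein ids")
  sample_id <- as.character(sample_id)
  plate <- as.character(plate)
  if (length(sample_id) != nrow(values) || length(plate) != nrow(values)) {
    stop("sample_id and plate must have one entry per measurement row")
  }
  key <- paste(sample_id, plate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(sample_id[duplicated(key)])
    stop("duplicate (sample, plate) measurements for: ", paste(dup, collapse = ", "))
  }
  derived_bridge <- sample_id %in% sample_id[duplicated(sample_id)]
  if (is.null(is_bridge)) {
    is_bridge <- derived_bridge
  } else {
    is_bridge <- as.logical(is_bridge)
    if (length(is_bridge) != nrow(values)) stop("is_bridge must have one entry per row")
    if (any(derived_bridge & !is_bridge)) {
      stop("samples measured on multiple plates must be flagged as bridges")
    }
  }
  rownames(values) <- NULL
  structure(
    list(values = values, sample_id = sample_id, plate = plate,
         is_bridge = is_bridge, protein_ids = colnames(values)),
    class = "npx_matrix"
  )
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d measurements (%d samples, %d bridge) x %d proteins; plates: %s\n",
              nrow(x$values), length(unique(x$sample_id)), sum(x$is_bridge & !duplicated(x$sample_id)),
              ncol(x$values), paste(sort(unique(x$plate)), collapse = ", ")))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Number of distinct individuals in an NPX matrix
#' @param m an `npx_matrix`.
#' @export
n_samples <- function(m) length(unique(m$sample_id))

.npx_na_strings <- c("", "NA")

#' Read a wide-format NPX table
#'
#' Expected CSV layout: columns `sample_id`, `plate`, optionally `is_bridge`,
#' followed by one numeric column per assay. Missing values may be empty
#' fields or `NA`.
#'
#' @param path CSV file path.
#' @return an [npx_matrix()].
#' @export
read_npx_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = .npx_na_strings,
                        colClasses = NA, stringsAsFactors = FALSE)
  need <- c("sample_id", "plate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  meta_cols <- intersect(c("sample_id", "plate", "is_bridge"), names(df))
  prot_cols <- setdiff(names(df), meta_cols)
  if (length(prot_cols) == 0) stop("no protein columns found")
  vals <- df[prot_cols]
  bad <- names(vals)[!vapply(vals, function(x) is.numeric(x) || all(is.na(x)), logical(1))]
  if (length(bad)) stop("non-numeric NPX values in columns: ", paste(bad, collapse = ", "))
  values <- as.matrix(data.matrix(vals))
  colnames(values) <- prot_cols
  npx_matrix(values, df$sample_id, df$plate,
             is_bridge = if ("is_bridge" %in% names(df)) as.logical(df$is_bridge) else NULL)
}

#' Write a wide-format NPX table
#' @param m an `npx_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_npx_wide <- function(m, path) {
  df <- data.frame(sample_id = m$sample_id, plate = m$plate,
                   is_bridge = m$is_bridge, check.names = FALSE)
  # 17 significant digits so the read-back double is bit-identical
  vals <- as.data.frame(apply(m$values, 2, .fmt_full), check.names = FALSE)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

.fmt_full <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))

#' Read a long-format (vendor-export style) NPX table
#'
#' Columns: `sample_id`, `protein_id`, `NPX`, `plate`. A duplicated
#' (sample, protein, plate) triple is an error.
#'
#' @param path CSV file path.
#' @return an [npx_matrix()].
#' @export
read_npx_long <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = .npx_na_strings,
                        stringsAsFactors = FALSE)
  need <- c("sample_id", "protein_id", "NPX", "plate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$NPX) && !all(is.na(df$NPX))) stop("non-numeric NPX values")
  key <- paste(df$sample_id, df$protein_id, df$plate, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated (sample, protein, plate) rows")
  proteins <- unique(df$protein_id)
  rows <- unique(data.frame(sample_id = df$sample_id, plate = df$plate,
                            stringsAsFactors = FALSE))
  values <- matrix(NA_real_, nrow(rows), length(proteins),
                   dimnames = list(NULL, proteins))
  ri <- match(paste(df$sample_id, df$plate, sep = "\r"),
              paste(rows$sample_id, rows$plate, sep = "\r"))
  ci <- match(df$protein_id, proteins)
  values[cbind(ri, ci)] <- df$NPX
  npx_matrix(values, rows$sample_id, rows$plate)
}

#' Write a long-format NPX table
#' @param m an `npx_matrix`.
#' @param path output CSV path.
#' @param keep_missing write rows for missing cells (as `NA`)? Default TRUE so
#'   that round-trips preserve the missingness mask exactly.
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(m, path, keep_missing = TRUE) {
  long <- data.frame(
    sample_id = rep(m$sample_id, times = ncol(m$values)),
    protein_id = rep(m$protein_ids, each = nrow(m$values)),
    NPX = as.vector(m$values),
    plate = rep(m$plate, times = ncol(m$values)),
    stringsAsFactors = FALSE
  )
  if (!keep_missing) long <- long[!is.na(long$NPX), ]
  long$NPX <- .fmt_full(long$NPX)
  utils::write.csv(long, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a clinical metadata table
#'
#' Validates the categorical levels used downstream (glycemic class, sex,
#' MASLD stage, medication burden) and coerces them to factors with the
#' reference level first.
#'
#' @param path CSV file path with one row per sample.
#' @return a data.frame with class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = .npx_na_strings,
                        stringsAsFactors = FALSE)
  as_clinical_table(df)
}

#' Validate and type a clinical data.frame
#' @param df data.frame with at least `sample_id` and `glycemic_class`.
#' @return the validated data.frame (factors with fixed reference levels).
#' @export
as_clinical_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  lvls <- list(
    glycemic_class = c("noDM", "PreDM", "T2DM"),
    sex = c("F", "M"),
    MASLD_stage = c("No MASL", "MASL", "MASH"),
    med_burden = c("0", "1", "2+")
  )
  for (col in names(lvls)) {
    if (col %in% names(df)) {
      vals <- as.character(df[[col]])
      bad <- setdiff(stats::na.omit(unique(vals)), lvls[[col]])
      if (length(bad)) stop(sprintf("invalid %s levels: %s", col, paste(bad, collapse = ", ")))
      df[[col]] <- factor(vals, levels = lvls[[col]])
    }
  }
  for (col in intersect(c("age", "BMI", "FPG", "HbA1c", "WBC", "neutrophils",
                          "monocytes", "lymphocytes"), names(df))) {
    if (!is.numeric(df[[col]])) stop(sprintf("column %s must be numeric", col))
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(sprintf("column %s has negative values", col))
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Protein-level missingness filter
#'
#' Removes proteins whose fraction of missing measurements exceeds the
#' threshold (strictly greater than; a protein at exactly the threshold is
#' retained). The returned QC report lists both sets and the per-protein
#' missingness fractions.
#'
#' @param m an `npx_matrix`.
#' @param threshold maximum tolerated missingness fraction, default 0.20.
#' @return list with elements `npx` (filtered matrix) and `report`
#'   (class `qc_report`: `missingness`, `retained`, `excluded`, `threshold`).
#' @export
filter_missingness <- function(m, threshold = 0.20) {
  stopifnot(inherits(m, "npx_matrix"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  if (nrow(m$values) == 0 || ncol(m$values) == 0) stop("empty NPX matrix")
  miss <- colMeans(is.na(m$values))
  keep <- miss <= threshold
  report <- structure(
    list(missingness = miss,
         retained = names(miss)[keep],
         excluded = names(miss)[!keep],
         threshold = threshold,
         n_proteins_in = length(miss),
         n_proteins_retained = sum(keep)),
    class = "qc_report"
  )
  filtered <- npx_matrix(m$values[, keep, drop = FALSE], m$sample_id, m$plate, m$is_bridge)
  list(npx = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d proteins retained at missingness threshold %.2f\n",
              x$n_proteins_retained, x$n_proteins_in, x$threshold))
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Median-impute missing cells for geometric stages
#'
#' Replaces each missing cell by the per-protein median of observed values.
#' The completed matrix is used only for the PCA lens and Mapper distances;
#' all inferential statistics operate on observed values. The input object
#' is not modified and observed cells are returned bit-identical.
#'
#' @param m an `npx_matrix` with at most one row per sample (run after
#'   bridge collapsing), or a plain numeric matrix with sample row names.
#' @return numeric matrix, samples x proteins, with sample_id row names.
#' @export
impute_for_projection <- function(m) {
  if (inherits(m, "npx_matrix")) {
    if (anyDuplicated(m$sample_id)) {
      stop("impute_for_projection expects one row per sample; collapse bridges first")
    }
    x <- m$values
    rownames(x) <- m$sample_id
  } else {
    x <- as.matrix(m)
    if (is.null(rownames(x))) stop("matrix input needs sample row names")
  }
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("proteins with no observed values: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[!nas, j])
  }
  x
}
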