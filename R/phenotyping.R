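#' Cluster inflammatory signatures
#'
#' For every protein p and cluster c the raw signature is the log2
#' fold-change Delta_pc = mean NPX over cluster members minus mean over the
#' remainder of the cohort (observed values only; NPX is log2 so the mean
#' difference is a log2FC). The scaled signature s_pc is the per-protein
#' z-score of Delta_pc across clusters (sd 0 gives s = 0).
#'
#' @param m an `npx_matrix` with one row per sample, or a numeric matrix
#'   with sample row names.
#' @param sample_to_cluster named integer cluster labels.
#' @return object of class `signature_matrix`: `log2fc` and `scaled`
#'   (proteins x clusters matrices), `cluster_sizes`.
#' @export
cluster_signature <- function(m, sample_to_cluster) {
  x <- if (inherits(m, "npx_matrix")) {
    v <- m$values; rownames(v) <- m$sample_id; v
  } else as.matrix(m)
  x <- x[names(sample_to_cluster), , drop = FALSE]
  clusters <- sort(unique(sample_to_cluster))
  if (length(clusters) < 2) stop("at least 2 clusters required")
  sizes <- table(factor(sample_to_cluster, levels = clusters))
  if (any(sizes == 0)) stop("cluster of size 0")
  delta <- matrix(NA_real_, ncol(x), length(clusters),
                  dimnames = list(colnames(x), paste0("cl", clusters)))
  for (k in seq_along(clusters)) {
    inc <- sample_to_cluster == clusters[k]
    delta[, k] <- colMeans(x[inc, , drop = FALSE], na.rm = TRUE) -
      colMeans(x[!inc, , drop = FALSE], na.rm = TRUE)
  }
  # a cluster with no observed value for a protein has no defined contrast
  delta[is.nan(delta)] <- NA_real_
  mu <- rowMeans(delta, na.rm = TRUE)
  sdv <- apply(delta, 1, stats::sd, na.rm = TRUE)
  scaled <- (delta - mu) / ifelse(!is.na(sdv) & sdv > 0, sdv, Inf)  # sd 0 -> 0
  structure(list(log2fc = delta, scaled = scaled,
                 cluster_sizes = as.integer(sizes)),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d proteins x %d clusters\n",
              nrow(x$log2fc), ncol(x$log2fc)))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness Z and the Anscombe-Glynn kurtosis Z
#' into K2 = Zs^2 + Zk^2, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param x numeric vector (n >= 8; NAs dropped).
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("constant sample")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1_b2 * (2 / sqrt_b1_b2 + sqrt(1 + 4 / sqrt_b1_b2^2))
  cube_root <- function(v) sign(v) * abs(v)^(1 / 3)  # negative base allowed
  z_kurt <- ((1 - 2 / (9 * a)) -
               cube_root((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the
#' standard tie correction; two-sided p-values, Benjamini-Hochberg adjusted
#' across the pairs.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame: `group1`, `group2`, `z`, `p`, `p.adj`.
#' @export
dunn_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- sort(unique(groups))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z[k] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p.adj = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Cluster-wise clinical association tests
#'
#' Continuous variables are tested across clusters with Kruskal-Wallis
#' followed by Dunn pairwise comparisons (BH-adjusted); categorical
#' variables with a chi-squared test on the cluster x level contingency
#' table. Missing values are dropped per variable and counted. Variables
#' constant over all samples are reported untested.
#'
#' @param clinical a clinical table (`sample_id` plus variables).
#' @param sample_to_cluster named integer cluster labels.
#' @param variables columns to test; defaults to every column except
#'   `sample_id`.
#' @return list with `overall` (data.frame: variable, type, statistic, df,
#'   p, n_missing, tested) and `posthoc` (named list of Dunn tables).
#' @export
cluster_clinical_tests <- function(clinical, sample_to_cluster, variables = NULL) {
  cl <- sample_to_cluster[match(clinical$sample_id, names(sample_to_cluster))]
  keep <- !is.na(cl)
  clinical <- clinical[keep, , drop = FALSE]
  cl <- factor(cl[keep])
  if (nlevels(cl) < 2) stop("at least 2 clusters required")
  variables <- variables %||% setdiff(names(clinical), "sample_id")
  rows <- list(); posthoc <- list()
  for (v in variables) {
    x <- clinical[[v]]
    n_missing <- sum(is.na(x))
    ok <- !is.na(x)
    row <- data.frame(variable = v, type = NA_character_, statistic = NA_real_,
                      df = NA_real_, p = NA_real_, n_missing = n_missing,
                      tested = FALSE, stringsAsFactors = FALSE)
    if (length(unique(x[ok])) < 2) {
      row$type <- "constant"
    } else if (is.numeric(x)) {
      row$type <- "continuous"
      kw <- stats::kruskal.test(x[ok], cl[ok])
      row$statistic <- unname(kw$statistic); row$df <- unname(kw$parameter)
      row$p <- kw$p.value; row$tested <- TRUE
      posthoc[[v]] <- dunn_test(x[ok], cl[ok])
    } else {
      row$type <- "categorical"
      tab <- table(cl[ok], x[ok])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      row$statistic <- unname(ct$statistic); row$df <- unname(ct$parameter)
      row$p <- ct$p.value; row$tested <- TRUE
    }
    rows[[v]] <- row
  }
  overall <- do.call(rbind, rows)
  rownames(overall) <- NULL
  overall$p.adj <- NA_real_
  overall$p.adj[overall$tested] <- bh_adjust(overall$p[overall$tested])
  list(overall = overall, posthoc = posthoc)
}

#' Cohort summary by glycemic group
#'
#' For each variable: continuous variables are gated by the
#' D'Agostino-Pearson omnibus test (pooled, alpha 0.05) into mean +/- SD
#' with ANOVA + Tukey HSD pairwise contrasts, or median \[IQR\] with
#' Kruskal-Wallis + Dunn (BH) pairwise contrasts; categorical variables get
#' counts (%) with an overall chi-squared test and BH-adjusted pairwise
#' chi-squared contrasts.
#'
#' @param clinical a clinical table.
#' @param group grouping column, default `glycemic_class`.
#' @param variables columns to summarize (default: all but sample_id/group).
#' @return data.frame with one row per variable: per-group summary strings,
#'   overall p, and one adjusted p per pairwise contrast.
#' @export
cohort_summary <- function(clinical, group = "glycemic_class", variables = NULL) {
  g <- droplevels(factor(clinical[[group]]))
  if (any(table(g) == 0) || nlevels(g) < 2) stop("groups must be non-empty")
  variables <- variables %||% setdiff(names(clinical), c("sample_id", group))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  pair_names <- apply(pairs, 2, paste, collapse = " vs ")
  rows <- list()
  for (v in variables) {
    x <- clinical[[v]]
    ok <- !is.na(x)
    row <- stats::setNames(
      as.list(rep(NA_character_, length(lev))), paste0("summary_", lev))
    row$variable <- v
    row$p_overall <- NA_real_
    pp <- stats::setNames(rep(NA_real_, length(pair_names)), pair_names)
    if (is.numeric(x) && length(unique(x[ok])) > 2) {
      normal <- isTRUE(tryCatch(dagostino_pearson(x[ok])$p.value > 0.05,
                                error = function(e) FALSE))
      if (normal) {
        row$summary_type <- "mean_sd"
        for (l in lev) {
          row[[paste0("summary_", l)]] <- sprintf(
            "%.2f ± %.2f", mean(x[ok & g == l]), stats::sd(x[ok & g == l]))
        }
        fit <- stats::aov(x[ok] ~ g[ok])
        row$p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
        tk <- stats::TukeyHSD(fit)[[1]]
        for (k in seq_along(pair_names)) {
          nm1 <- paste(pairs[2, k], pairs[1, k], sep = "-")
          nm2 <- paste(pairs[1, k], pairs[2, k], sep = "-")
          hit <- rownames(tk) %in% c(nm1, nm2)
          if (any(hit)) pp[k] <- tk[hit, "p adj"][1]
        }
      } else {
        row$summary_type <- "median_iqr"
        for (l in lev) {
          q <- stats::quantile(x[ok & g == l], c(0.25, 0.5, 0.75))
          row[[paste0("summary_", l)]] <- sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
        }
        row$p_overall <- stats::kruskal.test(x[ok], g[ok])$p.value
        dn <- dunn_test(x[ok], as.character(g[ok]))
        for (k in seq_along(pair_names)) {
          hit <- (dn$group1 == pairs[1, k] & dn$group2 == pairs[2, k]) |
            (dn$group1 == pairs[2, k] & dn$group2 == pairs[1, k])
          if (any(hit)) pp[k] <- dn$p.adj[hit][1]
        }
      }
    } else {
      row$summary_type <- "count_pct"
      xf <- factor(x[ok])
      for (l in lev) {
        tab <- table(xf[g[ok] == l])
        row[[paste0("summary_", l)]] <- paste(
          sprintf("%s: %d (%.0f%%)", names(tab), tab, 100 * tab / max(1, sum(tab))),
          collapse = "; ")
      }
      if (nlevels(xf) >= 2) {
        row$p_overall <- suppressWarnings(
          stats::chisq.test(table(g[ok], xf), correct = FALSE)$p.value)
        praw <- numeric(length(pair_names))
        for (k in seq_along(pair_names)) {
          sel <- ok & g %in% pairs[, k]
          tab <- table(droplevels(g[sel]), factor(x[sel]))
          tab <- tab[, colSums(tab) > 0, drop = FALSE]
          praw[k] <- if (ncol(tab) >= 2)
            suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value) else NA
        }
        pp[] <- bh_adjust(praw)
      }
    }
    for (k in seq_along(pair_names)) row[[paste0("p_", pair_names[k])]] <- pp[k]
    rows[[v]] <- as.data.frame(row, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shared builder for the regression data/design
.regression_frame <- function(protein_values, clinical, predictor,
                              covariates = c("age", "sex", "BMI", "MASLD_stage",
                                             "antidiabetic", "med_burden")) {
  df <- data.frame(.y = protein_values[clinical$sample_id], clinical,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vars <- c(predictor, covariates)
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars)) stop("clinical table lacks: ", paste(missing_vars, collapse = ", "))
  df <- df[, c(".y", vars)]
  n_total <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  # fixed reference levels: noDM, female, No MASL, med burden 0
  for (col in intersect(c("glycemic_class", "sex", "MASLD_stage", "med_burden"), names(df))) {
    df[[col]] <- droplevels(factor(df[[col]]))
  }
  if ("antidiabetic" %in% names(df)) df$antidiabetic <- as.logical(df$antidiabetic)
  list(df = df, n_dropped = n_total - nrow(df),
       formula = stats::as.formula(paste(".y ~", paste(vars, collapse = " + "))))
}

#' Multivariable regression of a protein on glycemic status
#'
#' Ordinary least squares of one protein's NPX values on glycemic class
#' (treatment-coded, reference noDM) adjusted for age, sex (reference F),
#' BMI, MASLD stage (reference No MASL), antidiabetic therapy and
#' medication burden (reference 0; tested at the model level with an
#' F-test). Reports coefficients with 95% CIs, variance inflation factors
#' computed by the auxiliary-R2 method on the model matrix, and residual
#' normality by D'Agostino-Pearson, Shapiro-Wilk and Lilliefors-corrected
#' Kolmogorov-Smirnov tests. Complete cases only; dropped rows are counted.
#'
#' @param m an `npx_matrix` (one row per sample) or numeric matrix with
#'   sample row names.
#' @param protein assay id of the response.
#' @param clinical a clinical table covering the model variables.
#' @param predictor `"glycemic_class"` (default) or `"FPG"` for the
#'   continuous sensitivity analysis.
#' @param covariates adjustment set.
#' @return object of class `regression_result`: `coefficients` (term,
#'   estimate, ci_lo, ci_hi, p), `term_tests` (model-level F for
#'   multi-level factors), `vif`, `normality`, `n_used`, `n_dropped`,
#'   `model` (the `lm` fit).
#' @export
fit_protein_regression <- function(m, protein, clinical,
                                   predictor = "glycemic_class",
                                   covariates = c("age", "sex", "BMI",
                                                  "MASLD_stage", "antidiabetic",
                                                  "med_burden")) {
  x <- if (inherits(m, "npx_matrix")) {
    v <- m$values; rownames(v) <- m$sample_id; v
  } else as.matrix(m)
  if (!protein %in% colnames(x)) stop("unknown protein: ", protein)
  pv <- stats::setNames(x[, protein], rownames(x))
  fr <- .regression_frame(pv, clinical, predictor, covariates)
  mm <- stats::model.matrix(fr$formula, fr$df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fr$formula, data = fr$df)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  coefficients <- data.frame(term = rownames(cf), estimate = cf[, 1],
                             se = cf[, 2], ci_lo = ci[, 1], ci_hi = ci[, 2],
                             p = cf[, 4], row.names = NULL,
                             stringsAsFactors = FALSE)
  # model-level F per term (relevant for multi-level factors like med_burden)
  d1 <- stats::drop1(fit, test = "F")
  term_tests <- data.frame(term = rownames(d1)[-1],
                           F = d1$`F value`[-1], p = d1$`Pr(>F)`[-1],
                           row.names = NULL, stringsAsFactors = FALSE)
  # auxiliary-R2 VIF per non-intercept model-matrix column
  pred_cols <- setdiff(colnames(mm), "(Intercept)")
  vif <- stats::setNames(numeric(length(pred_cols)), pred_cols)
  for (j in pred_cols) {
    others <- mm[, setdiff(colnames(mm), j), drop = FALSE]
    y <- mm[, j]
    rss <- sum(stats::lm.fit(others, y)$residuals^2)
    tss <- sum((y - mean(y))^2)  # centred R2: the intercept column is in `others`
    vif[j] <- tss / rss
  }
  res <- stats::residuals(fit)
  normality <- data.frame(
    test = c("dagostino_pearson", "shapiro_wilk", "kolmogorov_smirnov"),
    p = c(dagostino_pearson(res)$p.value,
          stats::shapiro.test(res)$p.value,
          nortest::lillie.test(res)$p.value),
    stringsAsFactors = FALSE)
  structure(list(protein = protein, predictor = predictor,
                 coefficients = coefficients, term_tests = term_tests,
                 vif = vif, normality = normality,
                 n_used = nrow(fr$df), n_dropped = fr$n_dropped, model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s + covariates (n = %d, %d dropped)\n",
              x$protein, x$predictor, x$n_used, x$n_dropped))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' FPG sensitivity regression
#'
#' Identical to [fit_protein_regression()] with fasting plasma glucose as a
#' continuous predictor in place of categorical glycemic status.
#'
#' @inheritParams fit_protein_regression
#' @return a `regression_result`.
#' @export
fpg_sensitivity <- function(m, protein, clinical,
                            covariates = c("age", "sex", "BMI", "MASLD_stage",
                                           "antidiabetic", "med_burden")) {
  fit_protein_regression(m, protein, clinical, predictor = "FPG",
                         covariates = covariates)
}
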