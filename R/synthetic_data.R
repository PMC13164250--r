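#' @name synthetic_data
#' @title Synthetic NPX cohort generator
#' @description
#' Generates inflammation-panel NPX cohorts with fully known ground truth:
#' planted inflammatory phenotype clusters (additive shifts on disjoint
#' protein blocks), per-group mean shifts on selected proteins, clinical
#' covariate effects, per-plate batch offsets with bridge replicates, and
#' MCAR missingness. The default spec emulates a 142-subject severe-obesity
#' cohort (69 normoglycemic / 25 prediabetic / 48 T2DM) measured on a
#' 92-assay inflammation panel across two plates with 35 bridge samples.
NULL

# 92 inflammation-panel assay identifiers (standard targeted inflammation
# panel naming; leading-digit assay renamed EIF4EBP1 for syntactic safety).
inflammation_panel_92 <- c(
  "IL8", "VEGFA", "CD8A", "MCP3", "GDNF", "CDCP1", "CD244", "IL7", "OPG",
  "LAPTGFB1", "uPA", "IL6", "IL17C", "MCP1", "IL17A", "CXCL11", "AXIN1",
  "TRAIL", "IL20RA", "CXCL9", "CST5", "IL2RB", "IL1A", "OSM", "IL2",
  "CXCL1", "TSLP", "CCL4", "CD6", "SCF", "IL18", "SLAMF1", "TGFA", "MCP4",
  "CCL11", "TNFSF14", "FGF23", "IL10RA", "FGF5", "MMP1", "LIFR", "FGF21",
  "CCL19", "IL15RA", "IL10RB", "IL22RA1", "IL18R1", "PDL1", "BNGF",
  "CXCL5", "TRANCE", "HGF", "IL12B", "IL24", "IL13", "ARTN", "MMP10",
  "IL10", "TNF", "CCL23", "CD5", "CCL3", "FLT3L", "CXCL6", "CXCL10",
  "EIF4EBP1", "IL20", "SIRT2", "CCL28", "DNER", "ENRAGE", "CD40", "IL33",
  "IFNG", "FGF19", "IL4", "LIF", "NRTN", "MCP2", "CASP8", "CCL25",
  "CX3CL1", "TNFRSF9", "NT3", "TWEAK", "CCL20", "ST1A1", "STAMBP", "IL5",
  "ADA", "TNFB", "CSF1"
)

# Low-detectability assays planted with high (> 20%) missingness by default;
# chosen among cytokines that are commonly below detection in plasma panels.
default_high_missing <- c(
  "IL2", "IL4", "IL5", "IL13", "IL20", "IL24", "IL33", "TSLP", "IFNG",
  "ARTN", "NRTN", "BNGF", "IL22RA1", "FGF5", "LIF", "TNFB", "IL2RB", "NT3"
)

# Disjoint signature blocks defining the seven planted inflammatory
# phenotypes. Block 7 carries the cytokine/regulatory axis of the
# T2DM-enriched phenotype; IL8/FLT3L/CDCP1 are deliberately left out of all
# blocks so their class contrasts are governed solely by the planted group
# shifts (their elevation in the T2DM-enriched cluster then emerges from
# cluster composition).
default_cluster_blocks <- list(
  c("CD5", "CD6", "CD244", "IL7", "IL15RA", "IL18R1"),
  c("CCL3", "CCL4", "CCL23", "MCP1", "MCP2", "MCP4"),
  c("CASP8", "STAMBP", "SIRT2", "AXIN1", "ST1A1", "EIF4EBP1"),
  c("TRAIL", "TWEAK", "TNFSF14", "TNFRSF9", "CD40", "TRANCE"),
  c("CXCL1", "CXCL5", "CXCL6", "CXCL10", "CXCL11", "CCL11"),
  c("MMP1", "MMP10", "uPA", "HGF", "OPG", "SCF"),
  c("IL6", "IL10", "CSF1", "FGF23", "CD8A", "IL10RA")
)

# Class-conditional cluster membership probabilities (rows noDM/PreDM/T2DM,
# columns planted clusters 1..7), patterned so cluster 7 is T2DM-enriched
# and clusters 1-2 are predominantly normoglycemic.
default_cluster_probs <- rbind(
  noDM  = c(27, 5, 6, 11, 8, 11, 1) / 69,
  PreDM = c(3, 2, 7, 2, 4, 3, 4) / 25,
  T2DM  = c(18, 1, 9, 5, 3, 5, 7) / 48
)

default_group_shifts <- function() {
  data.frame(protein = c("IL8", "FLT3L", "CDCP1"),
             PreDM = c(0.28, 0.24, 0.18),
             T2DM = c(0.62, 0.47, 0.49),
             stringsAsFactors = FALSE)
}

default_covariate_effects <- function() {
  data.frame(protein = c("FLT3L", "IL8", "CDCP1"),
             covariate = c("age", "FPG", "FPG"),
             slope = c(0.033, 0.008, 0.010),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Bundles and validates every knob of the generator. Defaults reproduce
#' the study design: group sizes 69/25/48, a 92-assay panel of which 18
#' assays carry > 20% missingness, two plates with 35 bridge-replicated
#' samples, seven planted inflammatory phenotypes with class-dependent
#' membership, planted T2DM-vs-noDM shifts of 0.62/0.47/0.49 NPX on
#' IL8/FLT3L/CDCP1, an age slope of 0.033 NPX/yr on FLT3L, and FPG slopes
#' of 0.008 and 0.010 NPX per mg/dL on IL8 and CDCP1.
#'
#' @param n_per_group named counts for (noDM, PreDM, T2DM).
#' @param n_proteins panel size; 92 uses the named inflammation panel,
#'   other sizes generate generic assay ids.
#' @param n_clusters number of planted phenotypes.
#' @param cluster_shift NPX units added to each phenotype's signature block.
#' @param cluster_blocks list of protein-id vectors (disjoint), one per
#'   cluster; `NULL` uses the panel defaults (or auto-blocks for non-default
#'   panels).
#' @param cluster_probs class x cluster membership probability matrix.
#' @param group_shift_table data.frame(protein, PreDM, T2DM) of per-group
#'   mean NPX offsets relative to noDM.
#' @param covariate_effects data.frame(protein, covariate, slope); slopes
#'   act on group-mean-centred covariates so group contrasts stay governed
#'   by `group_shift_table`.
#' @param batch_offsets per-protein additive plate-2 offsets (NPX); `NULL`
#'   draws them from N(0.2, 0.1) under the cohort seed; a scalar is
#'   recycled.
#' @param n_bridge number of bridge-replicated samples (split as evenly as
#'   possible across glycemic groups).
#' @param missing_high_proteins assay ids planted with high missingness.
#' @param missing_high_range MCAR rate range for high-missing assays.
#' @param missing_low_rate MCAR rate for the remaining assays.
#' @param noise_sd residual NPX standard deviation per individual.
#' @param bridge_noise_sd technical replicate noise between the two plate
#'   measurements of a bridge sample (0 = noiseless bridges).
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(noDM = 69, PreDM = 25, T2DM = 48),
                        n_proteins = 92,
                        n_clusters = 7,
                        cluster_shift = 3.0,
                        cluster_blocks = NULL,
                        cluster_probs = NULL,
                        group_shift_table = default_group_shifts(),
                        covariate_effects = default_covariate_effects(),
                        batch_offsets = NULL,
                        n_bridge = 35,
                        missing_high_proteins = NULL,
                        missing_high_range = c(0.35, 0.60),
                        missing_low_rate = 0.02,
                        noise_sd = 0.5,
                        bridge_noise_sd = 0,
                        seed = 42) {
  if (length(n_per_group) != 3) stop("n_per_group must give counts for (noDM, PreDM, T2DM)")
  if (is.null(names(n_per_group))) names(n_per_group) <- c("noDM", "PreDM", "T2DM")
  if (any(n_per_group <= 0)) stop("all group counts must be positive")
  n_total <- sum(n_per_group)
  if (n_proteins < 1) stop("n_proteins must be positive")
  if (n_clusters < 1) stop("n_clusters must be positive")
  if (n_clusters > n_total) stop("cluster count exceeds sample count")
  if (noise_sd < 0 || bridge_noise_sd < 0) stop("negative standard deviation")
  if (missing_low_rate < 0 || missing_low_rate > 1 ||
      any(missing_high_range < 0) || any(missing_high_range > 1)) {
    stop("missingness rates must lie in [0, 1]")
  }
  if (n_bridge < 0 || n_bridge > n_total) stop("n_bridge must be in [0, n]")

  proteins <- if (n_proteins == 92) inflammation_panel_92 else
    sprintf("ASSAY%03d", seq_len(n_proteins))

  if (is.null(missing_high_proteins)) {
    missing_high_proteins <- if (n_proteins == 92) default_high_missing else character(0)
  }
  if (!all(missing_high_proteins %in% proteins)) stop("unknown high-missing protein ids")

  if (is.null(cluster_blocks)) {
    if (n_proteins == 92 && n_clusters == 7) {
      cluster_blocks <- default_cluster_blocks
    } else {
      pool <- setdiff(proteins,
                      c(missing_high_proteins, group_shift_table$protein,
                        covariate_effects$protein))
      per <- max(1, min(6, floor(length(pool) / n_clusters)))
      cluster_blocks <- split(pool[seq_len(per * n_clusters)],
                              rep(seq_len(n_clusters), each = per))
    }
  }
  if (length(cluster_blocks) != n_clusters) stop("one signature block per cluster required")
  if (anyDuplicated(unlist(cluster_blocks))) stop("cluster blocks must be disjoint")
  if (!all(unlist(cluster_blocks) %in% proteins)) stop("unknown proteins in cluster blocks")
  if (any(unlist(cluster_blocks) %in% missing_high_proteins)) {
    stop("signature proteins cannot be planted with high missingness")
  }

  if (is.null(cluster_probs)) {
    if (n_clusters == 7) {
      cluster_probs <- default_cluster_probs
    } else {
      cluster_probs <- matrix(1 / n_clusters, 3, n_clusters,
                              dimnames = list(c("noDM", "PreDM", "T2DM"), NULL))
    }
  }
  if (ncol(cluster_probs) != n_clusters || nrow(cluster_probs) != 3) {
    stop("cluster_probs must be 3 x n_clusters")
  }
  if (!all(group_shift_table$protein %in% proteins)) stop("unknown proteins in group_shift_table")
  if (!all(covariate_effects$protein %in% proteins)) stop("unknown proteins in covariate_effects")
  if (!all(covariate_effects$covariate %in% c("age", "BMI", "FPG", "HbA1c"))) {
    stop("covariate effects supported for age, BMI, FPG, HbA1c")
  }
  if (!is.null(batch_offsets)) {
    if (length(batch_offsets) == 1) batch_offsets <- rep(batch_offsets, n_proteins)
    if (length(batch_offsets) != n_proteins) stop("batch_offsets must cover every protein")
    batch_offsets <- stats::setNames(as.numeric(batch_offsets), proteins)
  }

  structure(list(
    n_per_group = n_per_group, n_proteins = n_proteins, proteins = proteins,
    n_clusters = n_clusters, cluster_shift = cluster_shift,
    cluster_blocks = cluster_blocks, cluster_probs = cluster_probs,
    group_shift_table = group_shift_table, covariate_effects = covariate_effects,
    batch_offsets = batch_offsets, n_bridge = n_bridge,
    missing_high_proteins = missing_high_proteins,
    missing_high_range = missing_high_range, missing_low_rate = missing_low_rate,
    noise_sd = noise_sd, bridge_noise_sd = bridge_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# truncated normal by resampling (ranges are wide, so acceptance is high)
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Per-group clinical sampling parameterized from published-scale summary
# statistics (means/SDs), truncated to physiologically plausible ranges.
# FPG truncation respects the glycemic definitions (PreDM 110-125 mg/dL,
# noDM < 110; treated T2DM may present below 126).
sample_clinical <- function(n_per_group) {
  grp <- rep(names(n_per_group), times = n_per_group)
  n <- length(grp)
  par <- list(
    age  = list(noDM = c(44.1, 8.2), PreDM = c(53.0, 9.4), T2DM = c(58.1, 9.3),
                lo = 25, hi = 80),
    BMI  = list(noDM = c(43.2, 4.8), PreDM = c(44.6, 6.4), T2DM = c(43.9, 5.3),
                lo = 35, hi = 65),
    HbA1c = list(noDM = c(5.7, 0.5), PreDM = c(5.98, 0.4), T2DM = c(6.5, 0.9),
                 lo = 4.5, hi = 12),
    WBC = list(noDM = c(8.7, 2.8), PreDM = c(8.8, 2.2), T2DM = c(8.3, 2.6),
               lo = 3, hi = 25),
    neutrophils = list(noDM = c(4.4, 1.5), PreDM = c(4.4, 1.4), T2DM = c(6.3, 2.5),
                       lo = 1, hi = 20),
    monocytes = list(noDM = c(0.6, 0.2), PreDM = c(0.5, 0.2), T2DM = c(0.5, 0.2),
                     lo = 0.1, hi = 2),
    lymphocytes = list(noDM = c(2.2, 0.6), PreDM = c(1.9, 0.5), T2DM = c(2.1, 0.6),
                       lo = 0.5, hi = 6)
  )
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                   glycemic_class = grp, stringsAsFactors = FALSE)
  for (v in names(par)) {
    x <- numeric(n)
    for (g in c("noDM", "PreDM", "T2DM")) {
      idx <- grp == g
      p <- par[[v]][[g]]
      x[idx] <- rtnorm(sum(idx), p[1], p[2], par[[v]]$lo, par[[v]]$hi)
    }
    df[[v]] <- round(x, 2)
  }
  fpg_par <- list(noDM = c(98.9, 14.8, 70, 109.9), PreDM = c(115.2, 7.0, 110, 125.9),
                  T2DM = c(125.1, 38.0, 80, 300))
  fpg <- numeric(n)
  for (g in names(fpg_par)) {
    idx <- grp == g
    p <- fpg_par[[g]]
    fpg[idx] <- rtnorm(sum(idx), p[1], p[2], p[3], p[4])
  }
  df$FPG <- round(fpg, 1)
  sex_pF <- c(noDM = 0.88, PreDM = 0.68, T2DM = 0.54)
  df$sex <- ifelse(stats::runif(n) < sex_pF[grp], "F", "M")
  masld_p <- rbind(noDM = c(0.27, 0.43, 0.30), PreDM = c(0.16, 0.40, 0.44),
                   T2DM = c(0.12, 0.46, 0.42))
  masld_lvl <- c("No MASL", "MASL", "MASH")
  df$MASLD_stage <- vapply(grp, function(g)
    sample(masld_lvl, 1, prob = masld_p[g, ]), character(1))
  fib_p <- c(noDM = 0.46, PreDM = 0.68, T2DM = 0.54)
  df$fibrosis <- as.integer(stats::runif(n) < fib_p[grp])
  ad_p <- c(noDM = 0.05, PreDM = 0.10, T2DM = 0.80)
  df$antidiabetic <- stats::runif(n) < ad_p[grp]
  mb_p <- rbind(noDM = c(0.55, 0.25, 0.20), PreDM = c(0.35, 0.30, 0.35),
                T2DM = c(0.10, 0.25, 0.65))
  df$med_burden <- vapply(grp, function(g)
    sample(c("0", "1", "2+"), 1, prob = mb_p[g, ]), character(1))
  # antidiabetic therapy implies at least one medication
  df$med_burden[df$antidiabetic & df$med_burden == "0"] <- "1"
  com_p <- c(noDM = 0.45, PreDM = 0.65, T2DM = 0.90)
  df$comorbidity <- stats::runif(n) < com_p[grp]
  # blood counts carry real-world missingness
  for (v in c("WBC", "neutrophils", "monocytes", "lymphocytes")) {
    df[[v]][stats::runif(n) < 0.20] <- NA_real_
  }
  as_clinical_table(df)
}

#' Generate a synthetic NPX cohort with ground truth
#'
#' The generated NPX value for sample i, protein j is
#' baseline_j + cluster_shift x \[j in block of i's planted cluster\]
#' + group shift(j, class_i) + covariate effects on group-centred covariates
#' + N(0, noise_sd), measured on the sample's home plate (plus the plate-2
#' batch offset when applicable). Bridge samples receive a second
#' measurement on the other plate differing by the batch offset plus
#' N(0, bridge_noise_sd). MCAR masking is applied per measurement cell.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `npx_cohort` with elements `npx` ([npx_matrix()]
#'   including bridge replicate rows), `clinical` (one row per individual),
#'   and `truth` (planted cluster labels, batch offsets, effect tables,
#'   signature blocks, baseline means, bridge ids, home plates).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    P <- spec$n_proteins
    proteins <- spec$proteins
    n <- sum(spec$n_per_group)

    baseline <- stats::setNames(round(stats::rnorm(P, 4, 1.5), 4), proteins)
    delta <- spec$batch_offsets %||%
      stats::setNames(stats::rnorm(P, 0.2, 0.1), proteins)

    clinical <- sample_clinical(spec$n_per_group)
    grp <- as.character(clinical$glycemic_class)

    cluster <- integer(n)
    for (g in c("noDM", "PreDM", "T2DM")) {
      idx <- which(grp == g)
      cluster[idx] <- sample.int(spec$n_clusters, length(idx), replace = TRUE,
                                 prob = spec$cluster_probs[g, ])
    }

    # bridge samples: as even a split across groups as sizes allow
    n_bridge_g <- rep(floor(spec$n_bridge / 3), 3)
    extra <- spec$n_bridge - sum(n_bridge_g)
    if (extra > 0) n_bridge_g[seq_len(extra)] <- n_bridge_g[seq_len(extra)] + 1
    names(n_bridge_g) <- c("noDM", "PreDM", "T2DM")
    bridge_ids <- character(0)
    for (g in names(n_bridge_g)) {
      idx <- which(grp == g)
      k <- min(n_bridge_g[[g]], length(idx))
      if (k > 0) bridge_ids <- c(bridge_ids, sample(clinical$sample_id[idx], k))
    }
    home_plate <- sample(c("P1", "P2"), n, replace = TRUE)

    # deterministic mean structure
    signal <- matrix(rep(baseline, each = n), n, P, dimnames = list(clinical$sample_id, proteins))
    for (k in seq_len(spec$n_clusters)) {
      block <- spec$cluster_blocks[[k]]
      if (length(block)) {
        signal[cluster == k, block] <- signal[cluster == k, block, drop = FALSE] +
          spec$cluster_shift
      }
    }
    gst <- spec$group_shift_table
    for (r in seq_len(nrow(gst))) {
      for (g in c("PreDM", "T2DM")) {
        signal[grp == g, gst$protein[r]] <- signal[grp == g, gst$protein[r]] + gst[[g]][r]
      }
    }
    eff <- spec$covariate_effects
    for (r in seq_len(nrow(eff))) {
      cov <- clinical[[eff$covariate[r]]]
      centred <- cov - stats::ave(cov, grp, FUN = function(z) mean(z, na.rm = TRUE))
      centred[is.na(centred)] <- 0
      signal[, eff$protein[r]] <- signal[, eff$protein[r]] + eff$slope[r] * centred
    }
    signal <- signal + matrix(stats::rnorm(n * P, 0, spec$noise_sd), n, P)

    # measurement rows: home plate for everyone, second plate for bridges
    is_b <- clinical$sample_id %in% bridge_ids
    other_plate <- ifelse(home_plate == "P1", "P2", "P1")
    row_sample <- c(clinical$sample_id, clinical$sample_id[is_b])
    row_plate <- c(home_plate, other_plate[is_b])
    vals <- rbind(signal, signal[is_b, , drop = FALSE])
    if (spec$bridge_noise_sd > 0) {
      nb <- sum(is_b)
      vals[(n + 1):(n + nb), ] <- vals[(n + 1):(n + nb), , drop = FALSE] +
        matrix(stats::rnorm(nb * P, 0, spec$bridge_noise_sd), nb, P)
    }
    vals <- vals + outer(row_plate == "P2", delta)

    # MCAR masking per measurement cell
    rate <- stats::setNames(rep(spec$missing_low_rate, P), proteins)
    if (length(spec$missing_high_proteins)) {
      rate[spec$missing_high_proteins] <- stats::runif(
        length(spec$missing_high_proteins),
        spec$missing_high_range[1], spec$missing_high_range[2])
    }
    mask <- matrix(stats::runif(nrow(vals) * P), nrow(vals), P) <
      matrix(rep(rate, each = nrow(vals)), nrow(vals), P)
    vals[mask] <- NA_real_
    rownames(vals) <- NULL

    npx <- npx_matrix(vals, row_sample, row_plate,
                      is_bridge = row_sample %in% bridge_ids)
    truth <- list(
      cluster_label = stats::setNames(cluster, clinical$sample_id),
      batch_offsets = delta,
      effect_table = eff,
      group_shift_table = gst,
      cluster_blocks = spec$cluster_blocks,
      cluster_shift = spec$cluster_shift,
      baseline = baseline,
      bridge_ids = sort(bridge_ids),
      home_plate = stats::setNames(home_plate, clinical$sample_id),
      missing_rates = rate
    )
    structure(list(npx = npx, clinical = clinical, truth = truth, spec = spec),
              class = "npx_cohort")
  })
}

#' @export
print.npx_cohort <- function(x, ...) {
  cat(sprintf("<npx_cohort> %d individuals (%s), %d proteins, %d planted clusters\n",
              nrow(x$clinical),
              paste(sprintf("%s=%d", names(table(x$clinical$glycemic_class)),
                            table(x$clinical$glycemic_class)), collapse = "/"),
              x$spec$n_proteins, x$spec$n_clusters))
  invisible(x)
}

#' Serialize a synthetic cohort to CSV fixtures
#'
#' Writes `npx_wide.csv`, `clinical.csv`, `truth_clusters.csv` and
#' `truth_effects.csv` into `dir`. The NPX file round-trips losslessly
#' through [read_npx_wide()].
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  cohort <- generate_cohort(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    npx = file.path(dir, "npx_wide.csv"),
    clinical = file.path(dir, "clinical.csv"),
    clusters = file.path(dir, "truth_clusters.csv"),
    effects = file.path(dir, "truth_effects.csv")
  )
  write_npx_wide(cohort$npx, paths["npx"])
  utils::write.csv(cohort$clinical, paths["clinical"], row.names = FALSE, na = "NA")
  utils::write.csv(
    data.frame(sample_id = names(cohort$truth$cluster_label),
               cluster = unname(cohort$truth$cluster_label)),
    paths["clusters"], row.names = FALSE)
  gst <- cohort$truth$group_shift_table
  effects <- rbind(
    data.frame(type = "group_shift", protein = rep(gst$protein, 2),
               term = rep(c("PreDM", "T2DM"), each = nrow(gst)),
               value = c(gst$PreDM, gst$T2DM)),
    data.frame(type = "covariate", protein = cohort$truth$effect_table$protein,
               term = cohort$truth$effect_table$covariate,
               value = cohort$truth$effect_table$slope),
    data.frame(type = "batch_offset", protein = names(cohort$truth$batch_offsets),
               term = "P2", value = unname(cohort$truth$batch_offsets))
  )
  utils::write.csv(effects, paths["effects"], row.names = FALSE)
  invisible(paths)
}
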