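#' Default pipeline configuration
#'
#' Settings reproducing the study design: a synthetic 142-subject cohort,
#' 20% missingness threshold, plate P1 as bridge-normalization reference,
#' the three pairwise glycemic contrasts, Mapper at NB = 5 / BO = 0.20,
#' 100 bootstrap iterations, and the six pre-specified regression proteins
#' (IL8, FLT3L, CDCP1, IL6, IL10, CSF1).
#'
#' @param seed integer seed driving the synthetic cohort and the bootstrap.
#' @return a named list (see [run_pipeline()] for the schema).
#' @export
default_config <- function(seed = 42) {
  list(
    seed = seed,
    cohort = list(),  # overrides passed to cohort_spec()
    missingness_threshold = 0.20,
    reference_plate = "P1",
    contrasts = list(c("T2DM", "noDM"), c("PreDM", "noDM"), c("T2DM", "PreDM")),
    mapper = list(nb = 5, bo = 0.20),  # or list(grid = TRUE) for a grid search
    bootstrap_B = 100,
    regression_proteins = c("IL8", "FLT3L", "CDCP1", "IL6", "IL10", "CSF1")
  )
}

validate_config <- function(config) {
  if (!is.list(config)) stage_stop("config", "config must be a list")
  defaults <- default_config()
  unknown <- setdiff(names(config), c(names(defaults), "npx_path", "clinical_path", "out_dir"))
  if (length(unknown)) stage_stop("config", paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  for (f in names(defaults)) config[[f]] <- config[[f]] %||% defaults[[f]]
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stage_stop("config", "field 'seed' must be a single number")
  }
  th <- config$missingness_threshold
  if (!is.numeric(th) || th < 0 || th > 1) {
    stage_stop("config", "field 'missingness_threshold' must lie in [0, 1]")
  }
  if (!is.list(config$mapper) ||
      (is.null(config$mapper$grid) && (is.null(config$mapper$nb) || is.null(config$mapper$bo)))) {
    stage_stop("config", "field 'mapper' must give nb and bo, or grid = TRUE")
  }
  if (!is.numeric(config$bootstrap_B) || config$bootstrap_B < 0) {
    stage_stop("config", "field 'bootstrap_B' must be a non-negative count")
  }
  if (!is.character(config$regression_proteins)) {
    stage_stop("config", "field 'regression_proteins' must be a character vector")
  }
  config
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields as in [default_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$contrasts)) cfg$contrasts <- lapply(cfg$contrasts, unlist)
  validate_config(cfg)
}

#' Run the full phenotyping pipeline
#'
#' simulate (or load) -> missingness QC -> bridge normalization ->
#' differential expression -> Mapper -> Girvan-Newman communities (+
#' bootstrap stability) -> signatures, cluster clinical tests, cohort
#' summary, regressions. Any stage failure aborts with a stage-named
#' diagnostic. The result bundle carries a manifest (package version, seed,
#' config hash, per-stage dimensions); the same config and seed reproduce
#' the bundle bit-identically.
#'
#' @param config list as in [default_config()], or a YAML path. Supply
#'   `npx_path`/`clinical_path` to run on files instead of a synthetic
#'   cohort; `out_dir` to write CSV/JSON outputs.
#' @return object of class `pipeline_result`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  res <- list(config = config)

  # --- data ---
  if (!is.null(config$npx_path)) {
    npx_raw <- tryCatch(read_npx_wide(config$npx_path),
                        error = function(e) stage_stop("load", conditionMessage(e)))
    clinical <- tryCatch(read_clinical(config$clinical_path),
                         error = function(e) stage_stop("load", conditionMessage(e)))
    truth <- NULL
  } else {
    cohort <- tryCatch(
      generate_cohort(do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))),
      error = function(e) stage_stop("simulate", conditionMessage(e)))
    npx_raw <- cohort$npx; clinical <- cohort$clinical; truth <- cohort$truth
  }

  # --- QC ---
  qc <- tryCatch(filter_missingness(npx_raw, config$missingness_threshold),
                 error = function(e) stage_stop("qc", conditionMessage(e)))

  # --- bridge normalization ---
  norm <- tryCatch(bridge_normalize(qc$npx, config$reference_plate),
                   error = function(e) stage_stop("normalize", conditionMessage(e)))
  npx <- norm$npx

  # --- differential expression ---
  labels <- stats::setNames(as.character(clinical$glycemic_class), clinical$sample_id)
  diffexp <- tryCatch(
    lapply(diffexp_all_contrasts(npx, labels, config$contrasts), volcano_table),
    error = function(e) stage_stop("diffexp", conditionMessage(e)))

  # --- Mapper ---
  imputed <- tryCatch(impute_for_projection(npx),
                      error = function(e) stage_stop("impute", conditionMessage(e)))
  gs <- NULL
  if (isTRUE(config$mapper$grid)) {
    gs <- tryCatch(grid_search(imputed),
                   error = function(e) stage_stop("mapper", conditionMessage(e)))
    if (is.null(gs$selected)) stage_stop("mapper", gs$diagnostic)
    nb <- gs$selected$nb; bo <- gs$selected$bo
  } else {
    nb <- config$mapper$nb; bo <- config$mapper$bo
  }
  graph <- tryCatch(mapper(imputed, nb, bo),
                    error = function(e) stage_stop("mapper", conditionMessage(e)))

  # --- communities ---
  partition <- tryCatch(assign_samples(girvan_newman(graph), graph),
                        error = function(e) stage_stop("communities", conditionMessage(e)))
  stability <- NULL
  if (config$bootstrap_B >= 1) {
    stability <- tryCatch(
      bootstrap_stability(imputed, nb, bo, B = config$bootstrap_B,
                          seed = config$seed + 1L, baseline = partition),
      error = function(e) stage_stop("bootstrap", conditionMessage(e)))
  }
  composition <- tryCatch(cluster_composition(partition$sample_to_cluster, clinical),
                          error = function(e) stage_stop("communities", conditionMessage(e)))

  # --- phenotyping ---
  signatures <- tryCatch(cluster_signature(npx, partition$sample_to_cluster),
                         error = function(e) stage_stop("phenotype", conditionMessage(e)))
  clinical_tests <- tryCatch(
    cluster_clinical_tests(clinical, partition$sample_to_cluster,
                           variables = intersect(
                             c("glycemic_class", "MASLD_stage", "sex", "age", "BMI",
                               "FPG", "HbA1c", "comorbidity", "antidiabetic",
                               "WBC", "neutrophils", "monocytes", "lymphocytes"),
                             names(clinical))),
    error = function(e) stage_stop("phenotype", conditionMessage(e)))
  summary_tab <- tryCatch(
    cohort_summary(clinical, variables = intersect(
      c("age", "sex", "BMI", "FPG", "HbA1c", "MASLD_stage", "WBC",
        "neutrophils", "monocytes", "lymphocytes"), names(clinical))),
    error = function(e) stage_stop("phenotype", conditionMessage(e)))
  regressions <- list()
  for (p in intersect(config$regression_proteins, npx$protein_ids)) {
    regressions[[p]] <- tryCatch(
      list(categorical = fit_protein_regression(npx, p, clinical),
           fpg = fpg_sensitivity(npx, p, clinical)),
      error = function(e) stage_stop("regression", paste0(p, ": ", conditionMessage(e))))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("inflamapper")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    nb = nb, bo = bo,
    stages = list(
      input = dim(npx_raw$values),
      qc = c(dim(qc$npx$values), retained = qc$report$n_proteins_retained),
      normalized = dim(npx$values),
      n_nodes = length(graph$nodes), n_edges = nrow(graph$edges),
      n_communities = partition$n_communities
    )
  )
  manifest$manifest_hash <- rlang::hash(manifest)

  res <- structure(list(
    config = config, qc_report = qc$report, adjustment = norm$adjustment,
    npx = npx, clinical = clinical, truth = truth, diffexp = diffexp,
    grid_search = gs, graph = graph, partition = partition,
    stability = stability, composition = composition, signatures = signatures,
    clinical_tests = clinical_tests, cohort_summary = summary_tab,
    regressions = regressions, manifest = manifest
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d samples, %d proteins after QC (threshold %.2f)\n",
              n_samples(x$npx), ncol(x$npx$values), x$qc_report$threshold))
  cat(sprintf("  mapper nb = %d, bo = %.2f -> %d nodes, %d communities (Q = %.3f)\n",
              x$manifest$nb, x$manifest$bo, length(x$graph$nodes),
              x$partition$n_communities, x$partition$modularity))
  invisible(x)
}

#' Write the pipeline result bundle as CSV/JSON files
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @return vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "NA")
    paths <<- c(paths, p)
  }
  w(data.frame(protein = names(res$qc_report$missingness),
               missingness = unname(res$qc_report$missingness),
               retained = names(res$qc_report$missingness) %in% res$qc_report$retained),
    "qc_report.csv")
  for (ct in names(res$diffexp)) w(res$diffexp[[ct]], paste0("diffexp_", ct, ".csv"))
  w(data.frame(sample_id = names(res$partition$sample_to_cluster),
               cluster = unname(res$partition$sample_to_cluster)), "clusters.csv")
  if (!is.null(res$stability)) w(as.data.frame(res$stability), "stability.csv")
  sig <- res$signatures
  w(data.frame(protein = rownames(sig$scaled), sig$scaled, check.names = FALSE),
    "signatures_scaled.csv")
  w(res$clinical_tests$overall, "cluster_clinical_tests.csv")
  w(res$cohort_summary, "cohort_summary.csv")
  coefs <- do.call(rbind, lapply(names(res$regressions), function(p) {
    rbind(cbind(protein = p, model = "glycemic_class",
                res$regressions[[p]]$categorical$coefficients),
          cbind(protein = p, model = "FPG", res$regressions[[p]]$fpg$coefficients))
  }))
  if (!is.null(coefs)) w(coefs, "regressions.csv")
  gp <- file.path(dir, "graph.json")
  jsonlite::write_json(
    list(nodes = lapply(names(res$graph$nodes), function(nd) {
           list(id = nd, bin = unname(res$graph$node_bin[nd]),
                members = res$graph$nodes[[nd]])
         }),
         edges = res$graph$edges),
    gp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jp <- file.path(dir, "manifest.json")
  jsonlite::write_json(res$manifest, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, gp, jp)
  invisible(paths)
}
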