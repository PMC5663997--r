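#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits expression.tsv, clinical.tsv, signature.tsv, mutations.maf
#' (MAF-style rows, one per mutated gene/sample call), cna.tsv (discrete
#' region x sample calls), region_map.tsv, edges.tsv, sets.gmt,
#' proliferation.txt and ground_truth.tsv.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expr = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    signature = file.path(dir, "signature.tsv"),
    maf = file.path(dir, "mutations.maf"),
    cna = file.path(dir, "cna.tsv"),
    region_map = file.path(dir, "region_map.tsv"),
    edges = file.path(dir, "edges.tsv"),
    gmt = file.path(dir, "sets.gmt"),
    proliferation = file.path(dir, "proliferation.txt"),
    ground_truth = file.path(dir, "ground_truth.tsv"))
  write_expression(cohort$expr, paths$expr)
  write_clinical(cohort$clinical, paths$clinical)
  write_signature(cohort$signature, paths$signature)
  hit <- which(cohort$mutations == 1L, arr.ind = TRUE)
  maf <- data.frame(
    Hugo_Symbol = rownames(cohort$mutations)[hit[, 1L]],
    Tumor_Sample_Barcode = colnames(cohort$mutations)[hit[, 2L]],
    Variant_Classification = "Missense_Mutation")
  # keep every sample visible in the MAF even if it has no qualifying row
  silent <- setdiff(colnames(cohort$mutations), maf$Tumor_Sample_Barcode)
  if (length(silent))
    maf <- rbind(maf, data.frame(Hugo_Symbol = rownames(cohort$mutations)[1L],
                                 Tumor_Sample_Barcode = silent,
                                 Variant_Classification = "Silent"))
  utils::write.table(maf, paths$maf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(cohort$cna, paths$cna, id_name = "region")
  utils::write.table(cohort$region_map, paths$region_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(cohort$edges, paths$edges)
  write_gmt(cohort$gene_sets, paths$gmt)
  writeLines(cohort$proliferation_set, paths$proliferation)
  gt <- data.frame(sample_id = names(cohort$ground_truth$latent),
                   latent_met = cohort$ground_truth$latent,
                   occult = as.integer(cohort$ground_truth$occult))
  utils::write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Pipeline configuration
#'
#' @param expr,clinical,signature,maf,cna,region_map,edges,gmt Input file
#'   paths (see the readers in this package for the dialects).
#' @param out_dir Output directory.
#' @param k,n Voting rule; `k = NULL` requests calibration of k on the
#'   stage I samples against `target_interval`.
#' @param candidate_ks,target_interval Calibration settings.
#' @param cv_threshold,fdr,min_prevalence,horizon,min_evaluable Analysis
#'   thresholds.
#' @param endpoint `"os"` or `"rfs"`.
#' @param seed Seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr, clinical, signature, maf = NULL,
                            cna = NULL, region_map = NULL, edges = NULL,
                            gmt = NULL, out_dir = ".",
                            k = 7L, n = 9L, candidate_ks = NULL,
                            target_interval = c(0.35, 0.50),
                            cv_threshold = 0.10, fdr = 0.05,
                            min_prevalence = 0.05, horizon = 60,
                            min_evaluable = 6L, endpoint = "os",
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(fdr > 0, fdr < 1, min_prevalence >= 0, horizon > 0)
  structure(cfg, class = "pipeline_config")
}

# tiny FNV-1a over a string; enough to fingerprint a config in the manifest
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs, classify (or calibrate then classify), associate
#' risk with clinical metastasis, survival comparison, reclassify
#' metastasis states, differential expression under clinical and
#' reclassified labels with direction concordance, proliferation scoring,
#' subtype association, lesion tests and burden, expression-copy number
#' correlation, driver selection and network construction, per-driver
#' enrichment. Outputs are plain TSV/JSON in `out_dir` plus a
#' `manifest.json` recording every threshold; identical configs produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  expr <- stage("read_expression", function() read_expression(cfg$expr))
  clinical <- stage("read_clinical", function() read_clinical(cfg$clinical))
  sig <- stage("read_signature", function() read_signature(cfg$signature))

  calibration <- NULL
  k <- cfg$k
  if (is.null(k)) {
    stage1 <- clinical$sample_id[clinical$stage %in% c("IA", "IB")]
    calibration <- stage("calibrate", function()
      calibrate_threshold(expr[, intersect(colnames(expr), stage1)], sig,
                          candidate_ks = cfg$candidate_ks,
                          target_interval = cfg$target_interval,
                          min_evaluable = cfg$min_evaluable))
    k <- calibration$selected_k
  }
  rule <- voting_rule(k, cfg$n)
  calls <- stage("classify", function()
    classify_samples(expr, sig, rule, cfg$min_evaluable))
  assoc <- stage("associate", function()
    fisher_association(risk_met_table(calls, clinical)))
  surv <- stage("survival", function()
    survival_comparison(
      build_survival_data(clinical, calls, cfg$endpoint), cfg$horizon))
  relab <- stage("reclassify", function() reclassify(clinical, calls))
  status <- stats::setNames(relab$status, relab$sample_id)

  tested <- stage("cv_filter", function()
    cv_filter(expr, cfg$cv_threshold))
  clin_status <- stats::setNames(
    ifelse(clinical$metastasis_clinical == "yes", "metastatic",
           "nonmetastatic"), clinical$sample_id)
  expr_f <- expr[tested, , drop = FALSE]
  de_clin <- stage("de_clinical", function()
    de_test(expr_f, clin_status, alpha_fdr = cfg$fdr))
  de_re <- stage("de_reclassified", function()
    de_test(expr_f, status[colnames(expr_f)], alpha_fdr = cfg$fdr))
  conc <- stage("concordance", function()
    direction_concordance(de_clin[de_clin$significant, ],
                          de_re[de_re$significant, ]))

  results <- list(rule = rule, calibration = calibration, calls = calls,
                  association = assoc, survival = surv,
                  reclassified = relab, tested_genes = tested,
                  de_clinical = de_clin, de_reclassified = de_re,
                  concordance = conc)

  if (!is.null(cfg$gmt)) {
    sets <- stage("read_gmt", function() read_gmt(cfg$gmt))
    results$enrichment <- stage("enrich", function()
      enrich(de_re$gene[de_re$significant], sets, tested, cfg$fdr))
  }

  lesion_all <- NULL
  if (!is.null(cfg$maf)) {
    muts <- stage("read_maf", function() read_maf(cfg$maf))
    muts <- muts[, intersect(colnames(muts), names(status)), drop = FALSE]
    mut_f <- prevalence_filter(muts, cfg$min_prevalence)
    results$mutation_tests <- stage("mutation_tests", function()
      lesion_tests(mut_f, status, "mutation", cfg$fdr))
    results$mutation_burden <- stage("mutation_burden", function()
      burden_compare(mut_f, status))
    lesion_all <- results$mutation_tests
  }
  if (!is.null(cfg$cna)) {
    cna <- stage("read_gistic", function() read_gistic(cfg$cna))
    cna <- cna[, intersect(colnames(cna), names(status)), drop = FALSE]
    lesions <- prevalence_filter(cna_to_lesions(cna), cfg$min_prevalence)
    results$cna_tests <- stage("cna_tests", function()
      lesion_tests(lesions, status, "cna", cfg$fdr))
    results$cna_burden <- stage("cna_burden", function()
      burden_compare(lesions, status))
    lesion_all <- rbind(lesion_all, results$cna_tests)
    if (!is.null(cfg$region_map)) {
      rmap <- stage("read_region_map", function()
        read_region_map(cfg$region_map))
      results$expr_cna_corr <- stage("expr_cna_correlation", function()
        expr_cna_correlation(expr, cna, rmap, cfg$fdr))
    }
  }
  if (!is.null(cfg$edges) && !is.null(lesion_all)) {
    edges <- stage("read_network", function() read_network(cfg$edges))
    rmap <- if (!is.null(cfg$region_map)) read_region_map(cfg$region_map)
            else data.frame(region = character(), gene = character())
    corr <- results$expr_cna_corr
    if (is.null(corr))
      corr <- data.frame(gene = character(), region = character(),
                         rho = numeric(), p = numeric(), fdr = numeric(),
                         positive_significant = logical())
    drivers <- stage("select_drivers", function()
      select_drivers(lesion_all, rmap, corr, unique(edges$regulator)))
    results$drivers <- drivers
    results$network <- stage("build_network", function()
      build_network(drivers, de_re$gene[de_re$significant], edges))
    results$two_hop <- stage("two_hop", function()
      two_hop_targets(drivers, de_re$gene[de_re$significant], edges))
    if (!is.null(cfg$gmt))
      results$driver_enrichment <- stage("driver_enrichment", function()
        per_driver_enrichment(results$network, read_gmt(cfg$gmt), tested,
                              cfg$fdr))
  }

  .write_pipeline_outputs(results, cfg)
  invisible(results)
}

.write_pipeline_outputs <- function(results, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  wt <- function(df, name)
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(results$calls, "risk_calls.tsv")
  wt(results$reclassified, "reclassified_labels.tsv")
  wt(results$de_clinical, "de_clinical.tsv")
  wt(results$de_reclassified, "de_reclassified.tsv")
  if (!is.null(results$mutation_tests))
    wt(results$mutation_tests, "mutation_tests.tsv")
  if (!is.null(results$cna_tests)) wt(results$cna_tests, "cna_tests.tsv")
  if (!is.null(results$expr_cna_corr))
    wt(results$expr_cna_corr, "expr_cna_correlation.tsv")
  if (!is.null(results$network)) {
    wt(results$network$edges, "driver_network.tsv")
    wt(results$drivers, "drivers.tsv")
  }
  summary <- list(
    rule = results$rule[c("k", "n", "name")],
    selected_k = if (!is.null(results$calibration))
      results$calibration$selected_k else results$rule$k,
    n_high = sum(results$calls$label == "high", na.rm = TRUE),
    n_low = sum(results$calls$label == "low", na.rm = TRUE),
    association_p = results$association$p,
    logrank_p = results$survival$logrank$p,
    hr = results$survival$hr,
    c_index = results$survival$c_index,
    n_de_clinical = sum(results$de_clinical$significant),
    n_de_reclassified = sum(results$de_reclassified$significant),
    concordance = results$concordance[c("overlap", "same_direction",
                                        "fraction")])
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg_plain <- unclass(cfg)
  manifest <- list(
    package = "reometa",
    version = as.character(utils::packageVersion("reometa")),
    config = cfg_plain,
    config_hash = .fnv1a(paste(deparse(cfg_plain), collapse = "")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(NULL)
}
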