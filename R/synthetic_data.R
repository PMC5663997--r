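#' Parameters for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a latent metastasis state, clinical labels contaminated by occult
#' false-negatives, signature-pair orderings informative about the latent
#' state, planted differentially expressed genes, risk-dependent survival,
#' planted mutation / copy-number lesions with dosage-coupled expression,
#' and a regulator network with a planted driver.
#'
#' @param n_samples Cohort size (default 400, the scale of a TCGA-like
#'   tumor cohort).
#' @param n_genes Number of genes (default 2000).
#' @param n_pairs Signature pairs (default 9).
#' @param pi_met Latent metastasis prevalence (default 0.37; 157/423 in a
#'   typical stage I-IV adenocarcinoma cohort).
#' @param phi_occult P(clinical label nonmetastatic | latent metastatic),
#'   the occult false-negative rate (default 0.2).
#' @param theta1,theta0 Marginal P(gene_high > gene_low) per signature
#'   pair given latent metastasis / no metastasis (defaults 0.85 / 0.35).
#' @param tau Sd of the per-sample heterogeneity shared across the pair
#'   differences of one sample (default 1); induces the within-sample vote
#'   correlation real tumors show while preserving the marginal thetas.
#' @param n_de,delta_de Number of planted DE genes (default 150) and their
#'   mean absolute log2 effect (default 1; per-gene effects are
#'   Uniform(0.2, 2*delta_de - 0.2)).
#' @param hr_true Hazard ratio of latent metastatic samples (default 2.5).
#' @param baseline_hazard Events per month for latent nonmetastatic
#'   samples (default 0.01, median survival ~69 months).
#' @param censor_window Independent uniform censoring on [0, window]
#'   months (default 120).
#' @param n_mut_genes,n_planted_mut Mutation lesions and how many are
#'   planted differential (defaults 60 / 6).
#' @param n_cna_regions,n_planted_cna Copy-number regions (half amplified,
#'   half deleted; defaults 30 / 6 planted).
#' @param genes_per_region Member genes per region (default 4).
#' @param f1,f0 Planted lesion frequency in latent metastatic /
#'   nonmetastatic samples (defaults 0.4 / 0.1).
#' @param cna_coupling Log2 expression shift per copy-number call unit for
#'   region member genes (default 0.5).
#' @param n_regulators,out_degree Background regulators and their
#'   out-degree (defaults 100 / 5).
#' @param driver_targets Planted DE genes wired to the planted driver
#'   (default 30).
#' @param low_var_fraction Fraction of background genes given small
#'   variance so the CV filter has work to do (default 0.2).
#' @param seed Master seed; every layer derives its own sub-stream.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_samples = 400L, n_genes = 2000L, n_pairs = 9L,
                          pi_met = 0.37, phi_occult = 0.2,
                          theta1 = 0.85, theta0 = 0.35, tau = 1,
                          n_de = 150L, delta_de = 1,
                          hr_true = 2.5, baseline_hazard = 0.01,
                          censor_window = 120,
                          n_mut_genes = 60L, n_planted_mut = 6L,
                          n_cna_regions = 30L, n_planted_cna = 6L,
                          genes_per_region = 4L,
                          f1 = 0.4, f0 = 0.1, cna_coupling = 0.5,
                          n_regulators = 100L, out_degree = 5L,
                          driver_targets = 30L,
                          low_var_fraction = 0.2, seed = 1L) {
  p <- as.list(environment())
  probs <- c(pi_met = pi_met, phi_occult = phi_occult, theta1 = theta1,
             theta0 = theta0, f1 = f1, f0 = f0)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]")
  if (!(theta1 > theta0)) stop("need theta1 > theta0")
  if (any(c(theta1, theta0) %in% c(0, 1)))
    stop("infeasible theta: no finite mean offset achieves 0 or 1")
  if (hr_true <= 0) stop("hr_true must be > 0")
  if (delta_de <= 0.2) stop("delta_de must exceed 0.2")
  structure(p, class = "cohort_params")
}

# offset such that P(N(offset, 2 + tau^2) > 0) = theta
.pair_offset <- function(theta, tau) stats::qnorm(theta) * sqrt(2 + tau^2)

#' Generate a synthetic cohort with known ground truth
#'
#' All randomness flows from `params$seed` through independent per-layer
#' sub-streams, so the same parameters always yield a bit-identical
#' cohort. See [cohort_params()] for the generative model.
#'
#' @param params A [cohort_params()] list.
#' @return A `synthetic_cohort` list: `expr`, `clinical`, `signature`,
#'   `mutations`, `cna`, `region_map`, `edges`, `gene_sets`,
#'   `proliferation_set`, `ground_truth`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  p <- params
  set.seed(p$seed)
  layer_seed <- sample.int(2147483646L, 8L)

  n <- p$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("g%04d", seq_len(p$n_genes))

  ## --- latent state and clinical labels -------------------------------
  set.seed(layer_seed[1L])
  latent <- stats::rbinom(n, 1L, p$pi_met)
  if (length(unique(latent)) < 2L)
    latent[1:2] <- c(0L, 1L)  # degenerate draw guard at tiny n
  occult <- latent == 1L & stats::runif(n) < p$phi_occult
  met_clin <- ifelse(latent == 1L & !occult, "yes", "no")

  ## --- gene roles ------------------------------------------------------
  n_pair_genes <- 2L * p$n_pairs
  pair_genes <- genes[seq_len(n_pair_genes)]
  de_genes <- genes[n_pair_genes + seq_len(p$n_de)]
  n_member <- p$n_cna_regions * p$genes_per_region
  member_genes <- genes[n_pair_genes + p$n_de + seq_len(n_member)]
  free_genes <- setdiff(genes, c(pair_genes, de_genes, member_genes))

  ## --- expression ------------------------------------------------------
  set.seed(layer_seed[2L])
  mu <- stats::runif(p$n_genes, 4, 9)
  # pair partners share a baseline so the vote probability is governed by
  # the state-conditional offset alone
  mu[seq_len(p$n_pairs) * 2L] <- mu[seq_len(p$n_pairs) * 2L - 1L]
  sd_g <- rep(1, p$n_genes)
  n_low <- round(p$low_var_fraction * length(free_genes))
  low_var <- sample(free_genes, n_low)
  sd_g[match(low_var, genes)] <- 0.3
  expr <- matrix(stats::rnorm(p$n_genes * n, 0, 1), p$n_genes, n) * sd_g + mu
  dimnames(expr) <- list(genes, samples)

  # signature pairs: per-sample offset shared across pairs
  d1 <- .pair_offset(p$theta1, p$tau)
  d0 <- .pair_offset(p$theta0, p$tau)
  b <- stats::rnorm(n, 0, p$tau)
  d_sample <- ifelse(latent == 1L, d1, d0) + b
  gene_high <- pair_genes[seq_len(p$n_pairs) * 2L - 1L]
  gene_low <- pair_genes[seq_len(p$n_pairs) * 2L]
  expr[gene_high, ] <- expr[gene_high, ] +
    matrix(d_sample / 2, p$n_pairs, n, byrow = TRUE)
  expr[gene_low, ] <- expr[gene_low, ] -
    matrix(d_sample / 2, p$n_pairs, n, byrow = TRUE)
  signature <- gene_pair_signature(gene_high, gene_low)

  # planted DE genes; the first 44 form the proliferation axis (up in met)
  effects <- stats::runif(p$n_de, 0.2, 2 * p$delta_de - 0.2)
  sign_de <- sample(c(-1, 1), p$n_de, replace = TRUE)
  n_prolif <- min(44L, p$n_de)
  sign_de[seq_len(n_prolif)] <- 1
  shift <- effects * sign_de
  expr[de_genes, latent == 1L] <- expr[de_genes, latent == 1L] + shift

  ## --- mutations -------------------------------------------------------
  set.seed(layer_seed[3L])
  mut_genes <- sample(free_genes, p$n_mut_genes)
  planted_mut <- mut_genes[seq_len(p$n_planted_mut)]
  bg_freq_mut <- stats::runif(p$n_mut_genes, 0.05, 0.25)
  prob <- matrix(bg_freq_mut, p$n_mut_genes, n)
  prob[seq_len(p$n_planted_mut), ] <-
    matrix(ifelse(latent == 1L, p$f1, p$f0), p$n_planted_mut, n, byrow = TRUE)
  mutations <- matrix(stats::rbinom(length(prob), 1L, prob),
                      p$n_mut_genes, n, dimnames = list(mut_genes, samples))

  ## --- copy number -----------------------------------------------------
  set.seed(layer_seed[4L])
  regions <- sprintf("r%02d", seq_len(p$n_cna_regions))
  half <- ceiling(p$n_cna_regions / 2)
  region_type <- rep(c("amp", "del"), c(half, p$n_cna_regions - half))
  planted_idx <- c(seq_len(ceiling(p$n_planted_cna / 2)),
                   half + seq_len(floor(p$n_planted_cna / 2)))
  bg_freq_cna <- stats::runif(p$n_cna_regions, 0.05, 0.25)
  prob <- matrix(bg_freq_cna, p$n_cna_regions, n)
  prob[planted_idx, ] <-
    matrix(ifelse(latent == 1L, p$f1, p$f0), length(planted_idx), n,
           byrow = TRUE)
  altered <- matrix(stats::rbinom(length(prob), 1L, prob),
                    p$n_cna_regions, n)
  cna <- altered * ifelse(region_type == "amp", 1L, -1L)
  dimnames(cna) <- list(regions, samples)
  storage.mode(cna) <- "integer"
  region_map <- data.frame(
    region = rep(regions, each = p$genes_per_region),
    gene = member_genes, stringsAsFactors = FALSE)
  # dosage coupling: member expression follows the region's call
  for (i in seq_len(p$n_cna_regions)) {
    g <- region_map$gene[region_map$region == regions[i]]
    expr[g, ] <- expr[g, ] +
      p$cna_coupling * matrix(cna[i, ], length(g), n, byrow = TRUE)
  }

  ## --- survival --------------------------------------------------------
  set.seed(layer_seed[5L])
  haz <- p$baseline_hazard * p$hr_true^latent
  os_t <- stats::rexp(n, haz)
  os_c <- stats::runif(n, 0, p$censor_window)
  rfs_t <- stats::rexp(n, 1.5 * haz)
  rfs_c <- stats::runif(n, 0, p$censor_window)

  ## --- clinical table --------------------------------------------------
  set.seed(layer_seed[6L])
  stage <- ifelse(latent == 1L,
    sample(c("IA", "IB", "II", "III", "IV"), n, TRUE,
           prob = c(0.10, 0.15, 0.20, 0.30, 0.25)),
    sample(c("IA", "IB", "II", "III", "IV"), n, TRUE,
           prob = c(0.35, 0.30, 0.20, 0.10, 0.05)))
  subtype <- ifelse(latent == 1L,
    sample(c("bronchioid", "squamoid", "magnoid"), n, TRUE,
           prob = c(0.2, 0.4, 0.4)),
    sample(c("bronchioid", "squamoid", "magnoid"), n, TRUE,
           prob = c(0.6, 0.2, 0.2)))
  clinical <- data.frame(
    sample_id = samples,
    stage = stage,
    age = pmin(pmax(round(stats::rnorm(n, 65, 10)), 30), 90),
    gender = sample(c("male", "female"), n, TRUE),
    os_time = round(pmin(os_t, os_c), 2),
    os_event = as.integer(os_t <= os_c),
    rfs_time = round(pmin(rfs_t, rfs_c), 2),
    rfs_event = as.integer(rfs_t <= rfs_c),
    metastasis_clinical = met_clin,
    adjuvant = sample(c("unknown", "none", "yes"), n, TRUE,
                      prob = c(0.8, 0.1, 0.1)),
    subtype = subtype,
    stringsAsFactors = FALSE)

  ## --- regulatory network ---------------------------------------------
  set.seed(layer_seed[7L])
  driver <- planted_mut[1L]
  # one member of each planted region is a regulator wired to DE genes
  planted_regions <- regions[planted_idx]
  region_regs <- region_map$gene[match(planted_regions, region_map$region)]
  reg_pool <- setdiff(free_genes, c(mut_genes, low_var))
  bg_regs <- sample(reg_pool, min(p$n_regulators, length(reg_pool)))
  reg_nodes <- unique(c(driver, region_regs, bg_regs))
  driver_edge_targets <- sample(de_genes, min(p$driver_targets, p$n_de))
  edges <- data.frame(
    regulator = driver, target = driver_edge_targets,
    stringsAsFactors = FALSE)
  for (r in region_regs) {
    edges <- rbind(edges, data.frame(
      regulator = r,
      target = sample(de_genes, min(8L, p$n_de)),
      stringsAsFactors = FALSE))
  }
  bg_edges <- data.frame(
    regulator = rep(bg_regs, each = p$out_degree),
    target = sample(genes, length(bg_regs) * p$out_degree, replace = TRUE),
    stringsAsFactors = FALSE)
  edges <- unique(rbind(edges, bg_edges))
  edges <- edges[edges$regulator != edges$target, ]

  ## --- gene sets -------------------------------------------------------
  set.seed(layer_seed[8L])
  prolif_set <- de_genes[seq_len(n_prolif)]
  gene_sets <- c(
    list(proliferation = prolif_set,
         driver_response = sort(driver_edge_targets)),
    stats::setNames(lapply(1:8, function(i) sample(genes, 40L)),
                    sprintf("random_set_%02d", 1:8)))

  structure(list(
    expr = expr, clinical = clinical, signature = signature,
    mutations = mutations, cna = cna, region_map = region_map,
    edges = edges, gene_sets = gene_sets, proliferation_set = prolif_set,
    ground_truth = list(
      latent = stats::setNames(latent, samples),
      occult = stats::setNames(occult, samples),
      de = data.frame(gene = de_genes, effect = effects, sign = sign_de,
                      stringsAsFactors = FALSE),
      planted_mut = planted_mut,
      planted_cna = paste0(region_type[planted_idx], ":",
                           regions[planted_idx]),
      driver = driver,
      regulators = reg_nodes,
      params = p)), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples, %d genes, %d latent metastatic\n",
    ncol(x$expr), nrow(x$expr), sum(x$ground_truth$latent)))
  invisible(x)
}

#' Score pipeline outputs against a cohort's ground truth
#'
#' Each argument beyond the cohort is optional; only the metrics whose
#' inputs are supplied appear in the report.
#'
#' @param cohort A [generate_cohort()] result.
#' @param calls Risk calls ([classify_samples()]): yields sensitivity and
#'   specificity against the latent state.
#' @param cox [cox_fit()] row for the risk term: yields the log hazard
#'   ratio error against `hr_true`.
#' @param de [de_test()] output: yields the fraction of planted DE genes
#'   recovered at FDR.
#' @param lesions [lesion_tests()] output (both families bound together):
#'   yields the fraction of planted lesions recovered.
#' @param network [build_network()] output: yields the planted driver's
#'   rank by direct-target count (1 = most targets).
#' @return Named list of recovery metrics.
#' @export
evaluate_recovery <- function(cohort, calls = NULL, cox = NULL, de = NULL,
                              lesions = NULL, network = NULL) {
  gt <- cohort$ground_truth
  out <- list()
  if (!is.null(calls)) {
    lab <- stats::setNames(calls$label, calls$sample_id)[names(gt$latent)]
    out$sensitivity <- mean(lab[gt$latent == 1L] == "high", na.rm = TRUE)
    out$specificity <- mean(lab[gt$latent == 0L] == "low", na.rm = TRUE)
  }
  if (!is.null(cox))
    out$log_hr_error <- log(cox$hr[1L]) - log(gt$params$hr_true)
  if (!is.null(de)) {
    sig <- de$gene[de$significant]
    out$de_recovery <- mean(gt$de$gene %in% sig)
  }
  if (!is.null(lesions)) {
    planted <- c(gt$planted_mut, gt$planted_cna)
    sig <- lesions$lesion_id[lesions$significant &
                             lesions$direction == "higher_in_met"]
    out$lesion_recovery <- mean(planted %in% sig)
  }
  if (!is.null(network)) {
    cnt <- sort(network$counts, decreasing = TRUE)
    out$driver_rank <- if (gt$driver %in% names(cnt))
      which(names(cnt) == gt$driver) else NA_integer_
  }
  out
}
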