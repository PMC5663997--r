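#' Coefficient-of-variation gene filter
#'
#' Keeps genes whose sample coefficient of variation (sd / mean, computed
#' on the log2 scale the matrix carries) exceeds the threshold. Genes with
#' non-positive mean have no meaningful CV on this scale and are excluded
#' with a warning count.
#'
#' @param expr Expression matrix (genes x samples).
#' @param threshold CV cutoff, default 0.10 (strict `>`).
#' @return Character vector of retained gene ids.
#' @export
cv_filter <- function(expr, threshold = 0.10) {
  if (ncol(expr) < 2L) stop("need >= 2 samples")
  mu <- rowMeans(expr)
  nonpos <- mu <= 0
  if (any(nonpos))
    warning(sum(nonpos), " gene(s) with non-positive mean excluded from CV filter")
  sds <- apply(expr, 1L, stats::sd)
  keep <- !nonpos & (sds / mu > threshold)
  rownames(expr)[keep]
}

# Vectorized two-sample t-test across rows of a matrix.
# var_equal = TRUE gives the classical pooled ("Student") test.
.row_t_test <- function(x_a, x_b, var_equal = TRUE) {
  na <- ncol(x_a); nb <- ncol(x_b)
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  va <- rowSums((x_a - ma)^2) / (na - 1L)
  vb <- rowSums((x_b - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows: zero variance in both groups
  degen <- se == 0 | !is.finite(se)
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  tstat[degen] <- ifelse(ma[degen] == mb[degen], 0, Inf * sign((ma - mb)[degen]))
  list(mean_a = ma, mean_b = mb, t = tstat, p = p)
}

#' Two-group differential expression with BH-FDR control
#'
#' Per-gene two-sided Student's t-test (pooled variance by default; Welch
#' by flag) between the case and control groups, with Benjamini-Hochberg
#' adjustment over the tested genes. Genes should be pre-filtered with
#' [cv_filter()].
#'
#' @param expr Expression matrix (genes x samples).
#' @param groups Character vector aligned with `colnames(expr)` (or named
#'   by sample) giving each sample's group.
#' @param case,control Group levels to contrast; direction is the sign of
#'   `mean(case) - mean(control)`.
#' @param var_equal Pooled-variance test if TRUE (default).
#' @param alpha_fdr Significance threshold on the FDR, default 0.05.
#' @return data.frame: gene, mean_case, mean_control, t, p, fdr,
#'   direction in {"up_in_case","down_in_case"}, significant.
#' @export
de_test <- function(expr, groups, case = "metastatic",
                    control = "nonmetastatic", var_equal = TRUE,
                    alpha_fdr = 0.05) {
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  stopifnot(length(groups) == ncol(expr))
  ia <- which(groups == case); ib <- which(groups == control)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per group")
  tt <- .row_t_test(expr[, ia, drop = FALSE], expr[, ib, drop = FALSE],
                    var_equal = var_equal)
  fdr <- stats::p.adjust(tt$p, method = "BH")
  data.frame(gene = rownames(expr),
             mean_case = tt$mean_a, mean_control = tt$mean_b,
             t = tt$t, p = tt$p, fdr = fdr,
             direction = ifelse(tt$mean_a >= tt$mean_b,
                                "up_in_case", "down_in_case"),
             significant = fdr < alpha_fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction concordance between two differential-expression lists
#'
#' Overlaps the two gene lists by id and tests whether the shared genes'
#' dysregulation directions agree more often than chance (exact binomial
#' test against 1/2, two-sided by default).
#'
#' @param list_a,list_b data.frames with columns `gene` and `direction`
#'   (e.g. significant rows of [de_test()] output).
#' @param alternative Passed to [stats::binom.test()], default
#'   `"two.sided"`.
#' @return list(overlap, same_direction, fraction, binomial_p).
#' @export
direction_concordance <- function(list_a, list_b,
                                  alternative = "two.sided") {
  shared <- intersect(list_a$gene, list_b$gene)
  if (!length(shared)) {
    warning("empty overlap: concordance undefined")
    return(list(overlap = 0L, same_direction = 0L, fraction = NA_real_,
                binomial_p = NA_real_))
  }
  da <- list_a$direction[match(shared, list_a$gene)]
  db <- list_b$direction[match(shared, list_b$gene)]
  same <- sum(da == db)
  list(overlap = length(shared), same_direction = same,
       fraction = same / length(shared),
       binomial_p = stats::binom.test(same, length(shared), p = 0.5,
                                      alternative = alternative)$p.value)
}

#' Per-sample proliferation scores
#'
#' The score of a sample is its mean log2 expression over the proliferation
#' gene set (44 genes in typical use); missing set genes are dropped with a
#' count. If `groups` is supplied the two groups' scores are compared with
#' a two-sided Student's t-test.
#'
#' @param expr Expression matrix.
#' @param gene_set Character vector of proliferation genes.
#' @param groups Optional two-level group vector aligned with samples.
#' @return list(scores = data.frame(sample_id, score), n_missing,
#'   comparison = htest or NULL).
#' @export
proliferation_scores <- function(expr, gene_set, groups = NULL) {
  present <- intersect(gene_set, rownames(expr))
  if (!length(present)) stop("no proliferation-set gene present in matrix")
  n_missing <- length(setdiff(gene_set, present))
  if (n_missing)
    warning(n_missing, " proliferation gene(s) absent; scoring over ",
            length(present))
  score <- colMeans(expr[present, , drop = FALSE])
  comparison <- NULL
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[colnames(expr)]
    g <- factor(groups)
    if (nlevels(droplevels(g)) != 2L) stop("groups must have 2 levels")
    comparison <- stats::t.test(score ~ g, var.equal = TRUE)
  }
  list(scores = data.frame(sample_id = colnames(expr), score = score,
                           row.names = NULL, stringsAsFactors = FALSE),
       n_missing = n_missing, comparison = comparison)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each set's overlap with the query,
#' within the stated universe (by default the tested-gene universe should
#' be supplied, e.g. the CV-filtered list). Sets are intersected with the
#' universe; BH adjustment across sets.
#'
#' @param query Character vector of genes of interest (subset of universe).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param alpha_fdr Significance cutoff, default 0.05.
#' @return data.frame: set_id, overlap, set_size, query_size,
#'   universe_size, p, fdr, significant.
#' @export
enrich <- function(query, sets, universe, alpha_fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(query), universe)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(sets[[id]], universe)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1L, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = length(s),
               query_size = length(query),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < alpha_fdr
  out[order(out$p), , drop = FALSE]
}

#' Association between reclassified status and transcriptional subtype
#'
#' Pearson chi-square test (no continuity correction) on the status x
#' subtype contingency table. A warning recommends an exact test when any
#' expected cell count falls below 1.
#'
#' @param status Character vector of reclassified labels.
#' @param subtype Character vector of subtype labels, aligned.
#' @return list(table, stat, p).
#' @export
subtype_association <- function(status, subtype) {
  keep <- !is.na(status) & !is.na(subtype)
  tab <- table(status[keep], subtype[keep])
  if (ncol(tab) < 2L) stop("need >= 2 subtype levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected cell count < 1; consider an exact test")
  list(table = tab, stat = unname(ct$statistic), p = ct$p.value)
}
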