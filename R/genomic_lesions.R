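#' Split a {-1,0,+1} copy-number matrix into binary lesion matrices
#'
#' Amplification and deletion of the same region are distinct lesions: the
#' +1 calls become an `amp:<region>` binary lesion and the -1 calls a
#' `del:<region>` lesion.
#'
#' @param cna Integer matrix with entries in {-1,0,1}, regions x samples.
#' @return Binary integer matrix with lesion ids `amp:*` / `del:*`.
#' @export
cna_to_lesions <- function(cna) {
  if (!all(cna %in% c(-1L, 0L, 1L))) stop("CNA calls must be in {-1,0,1}")
  amp <- (cna == 1L) * 1L
  del <- (cna == -1L) * 1L
  rownames(amp) <- paste0("amp:", rownames(cna))
  rownames(del) <- paste0("del:", rownames(cna))
  out <- rbind(amp, del)
  storage.mode(out) <- "integer"
  out
}

#' Prevalence filter for lesion matrices
#'
#' Keeps lesions altered (nonzero) in strictly more than `min_fraction` of
#' all samples (a lesion in exactly 5% of samples is removed at the
#' default).
#'
#' @param mat Binary lesion matrix (lesions x samples).
#' @param min_fraction Default 0.05.
#' @return Row-subset of `mat`.
#' @export
prevalence_filter <- function(mat, min_fraction = 0.05) {
  keep <- rowMeans(mat != 0L) > min_fraction
  mat[keep, , drop = FALSE]
}

#' Per-lesion Fisher tests between reclassified groups
#'
#' For each (prevalence-filtered) lesion, a two-sided Fisher's exact test
#' of altered status against group membership, with BH adjustment across
#' the lesions supplied (call separately per lesion family - mutations and
#' copy-number lesions - to adjust the families separately, or bind the
#' matrices first for joint adjustment).
#'
#' @param mat Binary lesion matrix (lesions x samples).
#' @param status Named or aligned vector of labels in
#'   {"metastatic","nonmetastatic"}.
#' @param lesion_type Label recorded in the output (e.g. "mutation").
#' @param alpha_fdr Default 0.05.
#' @return data.frame: lesion_id, lesion_type, freq_met, freq_nonmet, p,
#'   fdr, direction, significant.
#' @export
lesion_tests <- function(mat, status, lesion_type = "mutation",
                         alpha_fdr = 0.05) {
  if (!is.null(names(status))) status <- status[colnames(mat)]
  stopifnot(length(status) == ncol(mat))
  im <- which(status == "metastatic"); inm <- which(status == "nonmetastatic")
  if (!length(im) || !length(inm)) stop("a group has zero samples")
  a <- rowSums(mat[, im, drop = FALSE] != 0L)   # altered in met
  b <- rowSums(mat[, inm, drop = FALSE] != 0L)  # altered in nonmet
  nm <- length(im); nn <- length(inm)
  p <- vapply(seq_len(nrow(mat)), function(i)
    stats::fisher.test(matrix(c(a[i], nm - a[i], b[i], nn - b[i]), 2L))$p.value,
    0)
  fm <- a / nm; fn <- b / nn
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(lesion_id = rownames(mat), lesion_type = lesion_type,
             freq_met = fm, freq_nonmet = fn, p = p, fdr = fdr,
             direction = ifelse(fm >= fn, "higher_in_met", "higher_in_nonmet"),
             significant = fdr < alpha_fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-sample lesion burden between groups
#'
#' The burden of a sample is its total number of altered lesions. Group
#' medians are reported (the usual summary for such skewed counts); the
#' comparison is a two-sided pooled-variance Student's t-test on the raw
#' counts.
#'
#' @param mat Binary lesion matrix.
#' @param status Group labels as in [lesion_tests()].
#' @return list(median_met, median_nonmet, t, p,
#'   counts = data.frame(sample_id, group, count)).
#' @export
burden_compare <- function(mat, status) {
  if (!is.null(names(status))) status <- status[colnames(mat)]
  stopifnot(length(status) == ncol(mat))
  count <- colSums(mat != 0L)
  im <- status == "metastatic"; inm <- status == "nonmetastatic"
  if (sum(im) < 2L || sum(inm) < 2L) stop("need >= 2 samples per group")
  if (stats::var(count[im]) == 0 && stats::var(count[inm]) == 0) {
    # degenerate: constant counts in both groups
    equal <- stats::median(count[im]) == stats::median(count[inm])
    tt <- list(statistic = if (equal) 0 else Inf,
               p.value = if (equal) 1 else 0)
  } else {
    tt <- stats::t.test(count[im], count[inm], var.equal = TRUE)
  }
  list(median_met = stats::median(count[im]),
       median_nonmet = stats::median(count[inm]),
       t = unname(tt$statistic), p = tt$p.value,
       counts = data.frame(sample_id = colnames(mat),
                           group = ifelse(im, "metastatic",
                                   ifelse(inm, "nonmetastatic", NA)),
                           count = count, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Spearman correlation of expression with copy-number calls
#'
#' For each gene mapped to a copy-number lesion (via the region map, or
#' directly when the matrix is gene-level), the Spearman rank correlation
#' of its expression with the region's calls across the shared samples.
#' BH adjustment across genes; `positive_significant` flags rho > 0 with
#' FDR below the cutoff. Genes whose CNA vector is constant are skipped
#' (count in attribute `n_skipped`).
#'
#' @param expr Expression matrix.
#' @param cna {-1,0,+1} matrix, regions (or genes) x samples.
#' @param region_map Optional data.frame (region, gene); when NULL the CNA
#'   rownames are taken as gene ids directly.
#' @param alpha_fdr Default 0.05.
#' @return data.frame: gene, region, rho, p, fdr, positive_significant.
#' @export
expr_cna_correlation <- function(expr, cna, region_map = NULL,
                                 alpha_fdr = 0.05) {
  shared <- intersect(colnames(expr), colnames(cna))
  if (length(shared) < 10L) stop("need >= 10 shared samples")
  if (is.null(region_map))
    region_map <- data.frame(region = rownames(cna), gene = rownames(cna),
                             stringsAsFactors = FALSE)
  map <- region_map[region_map$gene %in% rownames(expr) &
                    region_map$region %in% rownames(cna), , drop = FALSE]
  n_skipped <- 0L
  rows <- lapply(seq_len(nrow(map)), function(i) {
    g <- map$gene[i]; r <- map$region[i]
    calls <- cna[r, shared]
    if (length(unique(calls)) < 2L) return(NULL)
    ct <- suppressWarnings(
      stats::cor.test(expr[g, shared], calls, method = "spearman",
                      exact = FALSE))
    data.frame(gene = g, region = r, rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  n_skipped <- sum(vapply(rows, is.null, TRUE))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(gene = character(), region = character(),
                      rho = numeric(), p = numeric(), fdr = numeric(),
                      positive_significant = logical())
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out$positive_significant <- out$rho > 0 & out$fdr < alpha_fdr
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
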