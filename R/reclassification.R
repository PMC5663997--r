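#' Reclassify metastasis states using strict-rule risk calls
#'
#' A sample is kept nonmetastatic only when it is clinically nonmetastatic
#' AND called low risk; every sample that is clinically metastatic or
#' called high risk is (re)labeled metastatic. The rule is one-directional:
#' no clinically metastatic sample can become nonmetastatic. Samples with a
#' risk call but no clinical metastasis status are excluded with a warning.
#'
#' @param clinical Clinical data.frame with `sample_id` and
#'   `metastasis_clinical` in {"yes","no"}.
#' @param calls Risk calls from [classify_samples()].
#' @return data.frame: sample_id, status in
#'   {"metastatic","nonmetastatic"}, and provenance in
#'   {"clinical_met","signature_high","both","neither"}.
#' @export
reclassify <- function(clinical, calls) {
  miss <- setdiff(calls$sample_id, clinical$sample_id)
  if (length(miss))
    stop("calls for sample(s) absent from clinical table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  df <- merge(calls[, c("sample_id", "label")],
              clinical[, c("sample_id", "metastasis_clinical")],
              by = "sample_id")
  drop <- is.na(df$metastasis_clinical) | is.na(df$label)
  if (any(drop)) {
    warning(sum(drop), " sample(s) excluded: missing metastasis status",
            " or risk label")
    df <- df[!drop, , drop = FALSE]
  }
  met_clin <- df$metastasis_clinical == "yes"
  high <- df$label == "high"
  data.frame(
    sample_id = df$sample_id,
    status = ifelse(met_clin | high, "metastatic", "nonmetastatic"),
    provenance = ifelse(met_clin & high, "both",
                 ifelse(met_clin, "clinical_met",
                 ifelse(high, "signature_high", "neither"))),
    stringsAsFactors = FALSE)
}

#' 2x2 risk-by-metastasis contingency table
#'
#' Rows are clinical metastasis status (metastatic, nonmetastatic), columns
#' the risk call (high, low).
#'
#' @param calls Risk calls from [classify_samples()].
#' @param clinical Clinical data.frame.
#' @return 2x2 integer matrix.
#' @export
risk_met_table <- function(calls, clinical) {
  df <- merge(calls[, c("sample_id", "label")],
              clinical[, c("sample_id", "metastasis_clinical")],
              by = "sample_id")
  df <- df[!is.na(df$metastasis_clinical) & !is.na(df$label), ]
  tab <- matrix(c(
    sum(df$metastasis_clinical == "yes" & df$label == "high"),
    sum(df$metastasis_clinical == "yes" & df$label == "low"),
    sum(df$metastasis_clinical == "no" & df$label == "high"),
    sum(df$metastasis_clinical == "no" & df$label == "low")),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("metastatic", "nonmetastatic"), c("high", "low")))
  tab
}

#' Fisher's exact test on a 2x2 association table
#'
#' Two-sided p-values sum the probabilities of all tables (with the
#' observed margins) at most as probable as the observed one; the
#' one-sided alternative tests enrichment of high-risk calls among the
#' metastatic group (first row). Degenerate margins return p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts,
#'   `[[high&met, low&met], [high&nonmet, low&nonmet]]`.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return list(table, p, sidedness, odds_ratio).
#' @export
fisher_association <- function(tab, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(table = tab, p = 1, sidedness = sidedness,
                odds_ratio = NA_real_))
  }
  alt <- if (sidedness == "two") "two.sided" else "greater"
  ft <- stats::fisher.test(tab, alternative = alt)
  list(table = tab, p = ft$p.value, sidedness = sidedness,
       odds_ratio = unname(ft$estimate))
}

#' Reconstruct a 2x2 table from printed percentages and group sizes
#'
#' Utility for turning published "x% of n" statements into integer counts
#' (`round(pct * n)` per group); intended for documented test fixtures.
#'
#' @param pct_high Fraction called high per group (length 2: met, nonmet).
#' @param n Group sizes (length 2).
#' @return 2x2 integer matrix as in [risk_met_table()].
#' @export
table_from_percentages <- function(pct_high, n) {
  stopifnot(length(pct_high) == 2L, length(n) == 2L)
  high <- round(pct_high * n)
  matrix(c(high[1L], n[1L] - high[1L], high[2L], n[2L] - high[2L]),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("metastatic", "nonmetastatic"), c("high", "low")))
}
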