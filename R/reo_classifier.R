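#' Voting rules for gene-pair classifiers
#'
#' A sample is called low risk iff at least `k` of the `n` signature pairs
#' vote low; otherwise high risk. The majority rule for odd `n` is
#' `k = ceiling((n + 1) / 2)` (k = 5 for n = 9); the strict rule raises
#' `k` (k = 7 of 9 labels a sample low risk only when at least seven pairs
#' vote low).
#'
#' @param k Minimum number of low votes required for a low-risk call.
#' @param n Signature size.
#' @param name Optional rule label.
#' @return A `voting_rule` list with fields `k`, `n`, `name`.
#' @export
voting_rule <- function(k, n = 9L, name = sprintf("strict-%d/%d", k, n)) {
  k <- as.integer(k); n <- as.integer(n)
  if (k < 1L || k > n) stop("need 1 <= k <= n")
  structure(list(k = k, n = n, name = name), class = "voting_rule")
}

#' @rdname voting_rule
#' @export
majority_rule <- function(n = 9L) {
  voting_rule(ceiling((n + 1) / 2), n, name = "majority")
}

#' @export
print.voting_rule <- function(x, ...) {
  cat(sprintf("voting rule '%s': low risk iff low votes >= %d of %d\n",
              x$name, x$k, x$n))
  invisible(x)
}

#' Per-pair REO votes for one sample
#'
#' For each signature pair, compares the sample's expression of the two
#' genes: `gene_high > gene_low` is a high-risk vote, `<` a low-risk vote,
#' equality a tie (neither). Pairs with either gene absent from the matrix
#' are non-evaluable (`NA`).
#'
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param sig A [gene_pair_signature()].
#' @param sample_id Column to evaluate.
#' @return data.frame with columns gene_high, gene_low, vote in
#'   {"high","low","tie",NA}.
#' @export
pair_votes <- function(expr, sig, sample_id) {
  if (!sample_id %in% colnames(expr))
    stop("sample '", sample_id, "' not in expression matrix")
  j <- match(sample_id, colnames(expr))
  ia <- match(sig$gene_high, rownames(expr))
  ib <- match(sig$gene_low, rownames(expr))
  a <- ifelse(is.na(ia), NA_real_, expr[cbind(ia, j)])
  b <- ifelse(is.na(ib), NA_real_, expr[cbind(ib, j)])
  vote <- ifelse(is.na(a) | is.na(b), NA_character_,
          ifelse(a > b, "high", ifelse(a < b, "low", "tie")))
  data.frame(gene_high = sig$gene_high, gene_low = sig$gene_low,
             vote = vote, stringsAsFactors = FALSE)
}

#' Classify samples by k-of-n voting over gene-pair orderings
#'
#' Counts, per sample, the signature pairs voting high
#' (`expr[gene_high] > expr[gene_low]`), low (`<`) and tie (`=`). A sample
#' is labeled `"low"` iff its low votes reach the rule's threshold,
#' otherwise `"high"`. Pairs whose genes are absent are non-evaluable;
#' samples with fewer than `min_evaluable` evaluable pairs are refused
#' (label `NA`, with a warning). When pairs are lost to missing genes or
#' ties the threshold is rescaled proportionally:
#' `effective_k = ceiling(k * decisive / n)` where `decisive` is the number
#' of strict (high or low) votes.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sig A [gene_pair_signature()].
#' @param rule A [voting_rule()]; its `n` must equal the signature size.
#' @param min_evaluable Minimum pairs with both genes present (default 6).
#' @return data.frame with one row per sample: vote counts, `effective_k`,
#'   and `label` in {"high","low"}.
#' @export
classify_samples <- function(expr, sig, rule = majority_rule(nrow(sig)),
                             min_evaluable = 6L) {
  if (rule$n != nrow(sig))
    stop("rule is for n = ", rule$n, " but signature has ", nrow(sig), " pairs")
  a <- expr[match(sig$gene_high, rownames(expr)), , drop = FALSE]
  b <- expr[match(sig$gene_low, rownames(expr)), , drop = FALSE]
  ok <- !(is.na(a) | is.na(b))
  high <- colSums(a > b & ok, na.rm = TRUE)
  low <- colSums(a < b & ok, na.rm = TRUE)
  tie <- colSums(a == b & ok, na.rm = TRUE)
  evaluable <- colSums(ok)
  decisive <- high + low
  effective_k <- as.integer(ceiling(rule$k * decisive / rule$n))
  label <- ifelse(low >= effective_k & decisive > 0L, "low", "high")
  refused <- evaluable < min_evaluable
  if (any(refused)) {
    warning(sprintf("%d sample(s) refused: fewer than %d evaluable pairs",
                    sum(refused), min_evaluable))
    label[refused] <- NA_character_
  }
  data.frame(sample_id = colnames(expr),
             evaluable_pairs = as.integer(evaluable),
             high_votes = as.integer(high),
             low_votes = as.integer(low),
             tie_votes = as.integer(tie),
             effective_k = effective_k,
             label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Calibrate the low-risk vote threshold against a relapse interval
#'
#' For each candidate `k`, classifies the calibration cohort (typically the
#' stage I samples) and records the high-risk fraction. The selected `k` is
#' the one whose fraction is closest to the target interval: distance 0
#' inside the interval, otherwise distance to the nearer endpoint; ties are
#' broken toward the larger (stricter) `k`.
#'
#' @param expr Calibration expression matrix (>= 10 samples).
#' @param sig A [gene_pair_signature()].
#' @param candidate_ks Candidate thresholds, default `6:9` style strict
#'   rules (defaults to `(majority k + 1) : n`).
#' @param target_interval Expected high-risk (relapse) fraction interval,
#'   default `c(0.35, 0.50)`.
#' @param min_evaluable Passed to [classify_samples()].
#' @return A `calibration_report` list: `table` (k, frac_high, distance),
#'   `selected_k`, `target_interval`.
#' @export
calibrate_threshold <- function(expr, sig, candidate_ks = NULL,
                                target_interval = c(0.35, 0.50),
                                min_evaluable = 6L) {
  n <- nrow(sig)
  if (is.null(candidate_ks))
    candidate_ks <- seq.int(ceiling((n + 1) / 2) + 1L, n)
  if (!length(candidate_ks)) stop("empty candidate set")
  if (ncol(expr) < 10L) stop("need >= 10 calibration samples")
  fracs <- vapply(candidate_ks, function(k) {
    calls <- classify_samples(expr, sig, voting_rule(k, n), min_evaluable)
    mean(calls$label == "high", na.rm = TRUE)
  }, 0)
  sel <- .select_k(candidate_ks, fracs, target_interval)
  structure(list(
    table = data.frame(k = as.integer(candidate_ks), frac_high = fracs,
                       distance = sel$distance),
    selected_k = sel$selected_k,
    target_interval = target_interval), class = "calibration_report")
}

# selection function: distance 0 inside the interval, else distance to the
# nearer endpoint; ties broken toward the larger (stricter) k
.select_k <- function(ks, fracs, interval) {
  dist <- ifelse(fracs < interval[1L], interval[1L] - fracs,
          ifelse(fracs > interval[2L], fracs - interval[2L], 0))
  best <- which(dist == min(dist))
  list(selected_k = as.integer(max(ks[best])), distance = dist)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration against high-risk interval [%.2f, %.2f]\n",
              x$target_interval[1L], x$target_interval[2L]))
  print(x$table, row.names = FALSE)
  cat("selected k =", x$selected_k, "\n")
  invisible(x)
}
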