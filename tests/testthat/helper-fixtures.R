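# Small in-code fixtures and independent oracles shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_signature <- function(n = 3L) {
  gene_pair_signature(sprintf("a%d", seq_len(n)), sprintf("b%d", seq_len(n)))
}

# expression matrix realizing a given vote pattern for tiny_signature:
# votes is a list per sample of per-pair codes "h", "l", "t"
expr_from_votes <- function(votes, n_pairs = 3L) {
  n <- length(votes)
  m <- matrix(0, 2L * n_pairs, n,
              dimnames = list(c(sprintf("a%d", seq_len(n_pairs)),
                                sprintf("b%d", seq_len(n_pairs))),
                              sprintf("s%02d", seq_len(n))))
  for (j in seq_len(n)) {
    for (i in seq_len(n_pairs)) {
      v <- votes[[j]][i]
      base <- 5 + i
      m[sprintf("a%d", i), j] <- base + switch(v, h = 1, l = -1, t = 0)
      m[sprintf("b%d", i), j] <- base
    }
  }
  m
}

## ---- independent oracles -------------------------------------------------

# step-up Benjamini-Hochberg, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank downward
  for (i in (m - 1L):1L) if (m > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  pmin(adj, 1)[order(o)]
}

# exact Fisher p by enumeration over all tables with the observed margins
fisher_oracle <- function(tab, sided = c("two", "one")) {
  sided <- match.arg(sided)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  if (sided == "one") sum(probs[xs >= a])
  else sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Harrell's C by explicit double loop
cindex_oracle <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# log-rank O-E and variance tally from the definition (2 groups)
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Spearman rho from the rank definition (Pearson on ranks)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  stats::cor(rx, ry)
}

# clinical table for n samples with given metastasis labels
make_clinical <- function(sample_id, metastasis = "no", stage = "IA",
                          os_time = 24, os_event = 0, adjuvant = "unknown") {
  n <- length(sample_id)
  data.frame(sample_id = sample_id,
             stage = rep_len(stage, n),
             age = 65, gender = "female",
             os_time = rep_len(os_time, n),
             os_event = rep_len(os_event, n),
             metastasis_clinical = rep_len(metastasis, n),
             adjuvant = rep_len(adjuvant, n),
             stringsAsFactors = FALSE)
}

# small default cohort used when a test just needs coherent layers
small_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_params(n_samples = 200L, n_genes = 600L,
                                n_de = 60L, seed = seed, ...))
}
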