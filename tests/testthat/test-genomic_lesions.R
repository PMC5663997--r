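test_that("prevalence_filter uses a strict fraction cutoff", {
  m <- matrix(0L, 3, 100, dimnames = list(c("l6", "l5", "l0"), NULL))
  colnames(m) <- sprintf("s%03d", 1:100)
  m["l6", 1:6] <- 1L   # 6% > 5% -> kept
  m["l5", 1:5] <- 1L   # exactly 5% -> removed
  out <- prevalence_filter(m, 0.05)
  expect_identical(rownames(out), "l6")
})

test_that("cna_to_lesions splits gains and losses into distinct lesions", {
  cna <- matrix(c(1L, -1L, 0L, 1L), 2, 2,
                dimnames = list(c("7p11.2", "3p21.31"), c("s1", "s2")))
  les <- cna_to_lesions(cna)
  expect_setequal(rownames(les),
                  c("amp:7p11.2", "amp:3p21.31", "del:7p11.2",
                    "del:3p21.31"))
  expect_equal(les["amp:7p11.2", "s1"], 1L)
  expect_equal(les["del:3p21.31", "s1"], 1L)
  expect_equal(les["amp:3p21.31", "s1"], 0L)
  expect_error(cna_to_lesions(matrix(2L, 1, 2)), "calls")
})

test_that("lesion_tests flags frequency differences with direction", {
  # TP53-scale fixture: 201/315 metastatic vs 22/108 nonmetastatic
  n_m <- 315L; n_n <- 108L
  mat <- matrix(0L, 2, n_m + n_n)
  colnames(mat) <- sprintf("s%03d", seq_len(n_m + n_n))
  rownames(mat) <- c("TP53", "flat")
  status <- setNames(rep(c("metastatic", "nonmetastatic"), c(n_m, n_n)),
                     colnames(mat))
  mat["TP53", 1:201] <- 1L
  mat["TP53", n_m + (1:22)] <- 1L
  mat["flat", c(1:100, n_m + (1:34))] <- 1L  # ~0.32 both groups
  res <- lesion_tests(mat, status)
  tp <- res[res$lesion_id == "TP53", ]
  expect_identical(tp$direction, "higher_in_met")
  expect_lt(tp$p, 1e-10)
  expect_equal(tp$freq_met, 201 / 315)
  fl <- res[res$lesion_id == "flat", ]
  expect_gt(fl$p, 0.05)

  # identical frequencies -> p = 1
  same <- matrix(rep(c(1L, 0L), 10), 1, 20,
                 dimnames = list("x", sprintf("s%02d", 1:20)))
  st <- setNames(rep(c("metastatic", "nonmetastatic"), each = 10),
                 colnames(same))
  expect_equal(lesion_tests(same, st)$p, 1)
  expect_error(lesion_tests(same, setNames(rep("metastatic", 20),
                                           colnames(same))), "zero samples")
})

test_that("lesion_tests are invariant to sample and lesion order", {
  set.seed(5)
  mat <- matrix(rbinom(30 * 80, 1, 0.2), 30, 80,
                dimnames = list(sprintf("l%02d", 1:30),
                                sprintf("s%02d", 1:80)))
  status <- setNames(rep(c("metastatic", "nonmetastatic"), each = 40),
                     colnames(mat))
  a <- lesion_tests(mat, status)
  perm <- mat[sample(30), sample(80)]
  b <- lesion_tests(perm, status[colnames(perm)])
  b <- b[match(a$lesion_id, b$lesion_id), ]
  expect_equal(a$p, b$p)
  expect_equal(a$freq_met, b$freq_met)
})

test_that("burden_compare reports medians and a pooled t-test", {
  mat <- matrix(0L, 100, 6)
  colnames(mat) <- sprintf("s%d", 1:6)
  mat[1:80, 1:3] <- 1L; mat[1:44, 4:6] <- 1L
  status <- setNames(rep(c("metastatic", "nonmetastatic"), each = 3),
                     colnames(mat))
  res <- burden_compare(mat, status)
  expect_equal(res$median_met, 80)
  expect_equal(res$median_nonmet, 44)

  # identical groups -> p ~ 1
  same <- cbind(mat[, 1:3], mat[, 1:3])
  colnames(same) <- sprintf("s%d", 1:6)
  expect_gt(burden_compare(same, status)$p, 0.99)

  # Poisson(80) vs Poisson(44) burdens are detected across seeds
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    counts <- c(rpois(100, 80), rpois(100, 44))
    m <- matrix(0L, max(counts), 200)
    for (j in seq_len(200)) if (counts[j] > 0) m[seq_len(counts[j]), j] <- 1L
    colnames(m) <- sprintf("s%03d", 1:200)
    st <- setNames(rep(c("metastatic", "nonmetastatic"), each = 100),
                   colnames(m))
    burden_compare(m, st)$p < 0.001
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("expr_cna_correlation matches the rank-based oracle", {
  # expression a strictly increasing function of the call -> rho = 1
  calls <- matrix(rep(c(-1L, 0L, 1L), each = 4), 1, 12,
                  dimnames = list("r1", sprintf("s%02d", 1:12)))
  expr <- make_expr(matrix(5 + rep(c(-1, 0, 1), each = 4), 1, 12),
                    genes = "gA", samples = sprintf("s%02d", 1:12))
  res <- expr_cna_correlation(expr, calls,
                              data.frame(region = "r1", gene = "gA"))
  expect_equal(res$rho, 1)

  # fixture vs direct rank computation
  set.seed(31)
  e2 <- make_expr(matrix(rnorm(12, 7), 1, 12), genes = "gB",
                  samples = sprintf("s%02d", 1:12))
  c2 <- matrix(sample(c(-1L, 0L, 1L), 12, replace = TRUE), 1, 12,
               dimnames = list("r2", sprintf("s%02d", 1:12)))
  res2 <- expr_cna_correlation(e2, c2,
                               data.frame(region = "r2", gene = "gB"))
  expect_equal(res2$rho, spearman_oracle(e2["gB", ], c2["r2", ]),
               tolerance = 1e-12)

  # constant CNA vector skipped with a count
  c3 <- matrix(0L, 1, 12, dimnames = list("r3", sprintf("s%02d", 1:12)))
  res3 <- expr_cna_correlation(e2, c3,
                               data.frame(region = "r3", gene = "gB"))
  expect_equal(nrow(res3), 0L)
  expect_equal(attr(res3, "n_skipped"), 1L)
  expect_error(expr_cna_correlation(e2[, 1:5, drop = FALSE],
                                    c2[, 1:5, drop = FALSE]), ">= 10")
})

test_that("planted lesions all come out higher_in_met on synthetic data", {
  co <- small_cohort(seed = 3)
  calls <- classify_samples(co$expr, co$signature, voting_rule(7, 9))
  relab <- reclassify(co$clinical, calls)
  status <- setNames(relab$status, relab$sample_id)
  muts <- prevalence_filter(co$mutations)
  cnas <- prevalence_filter(cna_to_lesions(co$cna))
  res <- rbind(lesion_tests(muts, status, "mutation"),
               lesion_tests(cnas, status, "cna"))
  planted <- c(co$ground_truth$planted_mut, co$ground_truth$planted_cna)
  sig <- res[res$significant & res$lesion_id %in% planted, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$direction == "higher_in_met"))
})
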