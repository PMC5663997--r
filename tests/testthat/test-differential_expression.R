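test_that("cv_filter keeps genes with CV above the threshold", {
  x <- make_expr(rbind(c(10, 10, 10),     # constant -> CV 0
                       c(9, 11, 10),      # sd 1, mean 10 -> CV 0.1 (not >)
                       c(9, 11, 13)))     # CV 0.18
  expect_identical(cv_filter(x, 0.10), "g03")
  # sample sd: {9,11} has sd sqrt(2), mean 10 -> CV 0.1414 > 0.10
  x2 <- make_expr(rbind(c(9, 11), c(10, 10)))
  expect_identical(cv_filter(x2, 0.10), "g01")
  # threshold 0 keeps every non-constant positive-mean gene
  expect_setequal(cv_filter(x, 0), c("g02", "g03"))
  # non-positive mean genes excluded with a warning
  x3 <- make_expr(rbind(c(-5, 5), c(1, 3)))
  expect_warning(kept <- cv_filter(x3, 0.1), "non-positive")
  expect_identical(kept, "g02")
})

test_that("de_test is a pooled t-test with BH control", {
  set.seed(4)
  x <- make_expr(matrix(rnorm(50 * 20, 8), 50, 20))
  g <- rep(c("metastatic", "nonmetastatic"), each = 10)
  same <- de_test(make_expr(cbind(x[, 1:10], x[, 1:10])), g)
  expect_equal(sum(same$significant), 0L)
  expect_true(all(same$p > 0.999))

  # agreement with t.test(var.equal = TRUE) per gene
  de <- de_test(x, g)
  ref <- apply(x, 1L, function(v)
    t.test(v[1:10], v[11:20], var.equal = TRUE)$p.value)
  expect_equal(de$p, unname(ref), tolerance = 1e-12)
  expect_true(all(de$fdr >= de$p))

  # label swap flips directions, preserves p-values
  sw <- de_test(x, g, case = "nonmetastatic", control = "metastatic")
  expect_equal(sw$p, de$p)
  flip <- ifelse(de$direction == "up_in_case", "down_in_case", "up_in_case")
  nonzero <- de$mean_case != de$mean_control
  expect_identical(sw$direction[nonzero], flip[nonzero])

  # zero variance in both groups with equal means -> p = 1
  flat <- make_expr(matrix(5, 2, 8))
  def <- de_test(flat, rep(c("metastatic", "nonmetastatic"), each = 4))
  expect_equal(def$p, c(1, 1))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("de_test recovers planted shifts (delta = 2 sd, 100 of 1000)", {
  recovered <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(1000 * 100, 8, 1), 1000, 100)
    x[1:100, 1:50] <- x[1:100, 1:50] + 2
    dimnames(x) <- list(sprintf("g%04d", 1:1000), sprintf("s%03d", 1:100))
    g <- rep(c("metastatic", "nonmetastatic"), each = 50)
    de <- de_test(x, g)
    sum(de$significant[1:100])
  }, 0)
  expect_gte(stats::median(recovered), 90)
})

test_that("direction_concordance runs the exact binomial test", {
  mk <- function(genes, dirs) data.frame(gene = genes, direction = dirs)
  a <- mk(sprintf("g%d", 1:48), rep("up_in_case", 48))
  b24 <- mk(sprintf("g%d", 1:48),
            rep(c("up_in_case", "down_in_case"), each = 24))
  expect_equal(direction_concordance(a, b24)$binomial_p, 1)
  b46 <- mk(sprintf("g%d", 1:48),
            c(rep("up_in_case", 46), rep("down_in_case", 2)))
  res <- direction_concordance(a, b46)
  expect_equal(res$same_direction, 46L)
  expect_lt(res$binomial_p, 1e-4)
  expect_warning(none <- direction_concordance(a, mk("zz", "up_in_case")),
                 "empty overlap")
  expect_equal(none$overlap, 0L)
})

test_that("proliferation scores average the set and detect group shifts", {
  flat <- make_expr(matrix(5, 10, 4))
  ps <- proliferation_scores(flat, rownames(flat))
  expect_true(all(ps$scores$score == 5))

  set.seed(12)
  x <- make_expr(matrix(rnorm(60 * 100, 7), 60, 100))
  set_genes <- rownames(x)[1:20]
  grp <- rep(c("A", "B"), each = 50)
  x[set_genes, grp == "A"] <- x[set_genes, grp == "A"] + 1
  res <- proliferation_scores(x, set_genes, groups = grp)
  expect_equal(unname(diff(rev(res$comparison$estimate))), 1,
               tolerance = 0.25)
  expect_lt(res$comparison$p.value, 0.01)

  expect_warning(m <- proliferation_scores(x, c(set_genes, "absent")),
                 "absent")
  expect_equal(m$n_missing, 1L)
  expect_error(proliferation_scores(x, "nope"), "no proliferation-set gene")
})

test_that("enrich computes hypergeometric upper tails over the universe", {
  universe <- sprintf("u%02d", 1:10)
  sets <- list(hit = universe[1:5])
  res <- enrich(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(10, 5))
  # disjoint query -> upper tail including 0 is 1
  res0 <- enrich(universe[6:10], sets, universe)
  expect_equal(res0$p, 1)
  # overlap at the null expectation: p stays large
  set.seed(2)
  big_u <- sprintf("u%03d", 1:500)
  res1 <- enrich(sample(big_u, 100), list(s = sample(big_u, 50)), big_u)
  expect_gt(res1$p, 0.2)
  expect_error(enrich("a", sets, character()), "empty universe")
})

test_that("subtype_association is a Pearson chi-square without correction", {
  status <- rep(c("metastatic", "nonmetastatic"), each = 50)
  sep <- rep(c("squamoid", "bronchioid"), each = 50)
  expect_lt(subtype_association(status, sep)$p, 1e-10)
  # identical rows -> no association
  flat <- subtype_association(rep(c("metastatic", "nonmetastatic"), 50),
                              rep(c("x", "y"), each = 50))
  expect_equal(flat$stat, 0)
  expect_equal(flat$p, 1)
  expect_error(subtype_association(status, rep("only", 100)), "2 subtype")

  # null p-values approximately uniform across seeds
  set.seed(77)
  ps <- replicate(200, {
    s <- sample(c("metastatic", "nonmetastatic"), 120, replace = TRUE)
    b <- sample(c("bronchioid", "squamoid", "magnoid"), 120, replace = TRUE)
    suppressWarnings(subtype_association(s, b)$p)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
})
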