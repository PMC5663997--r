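make_lesion_row <- function(id, type, sig = TRUE, dir = "higher_in_met") {
  data.frame(lesion_id = id, lesion_type = type, freq_met = 0.4,
             freq_nonmet = 0.1, p = 0.001, fdr = 0.01, direction = dir,
             significant = sig, stringsAsFactors = FALSE)
}

test_that("select_drivers follows the provenance filter chain", {
  lesions <- rbind(
    make_lesion_row("TP53", "mutation"),
    make_lesion_row("del:3p21.31", "cna"),
    make_lesion_row("amp:7p11.2", "cna", dir = "higher_in_nonmet"),
    make_lesion_row("KRAS", "mutation", sig = FALSE))
  rmap <- data.frame(region = c("3p21.31", "3p21.31", "7p11.2"),
                     gene = c("IRF1", "OTHER", "EGFR"))
  corr <- data.frame(gene = c("IRF1", "OTHER", "EGFR"),
                     region = c("3p21.31", "3p21.31", "7p11.2"),
                     rho = c(0.6, 0.5, 0.7), p = 0.001, fdr = 0.01,
                     positive_significant = c(TRUE, TRUE, TRUE))
  drv <- select_drivers(lesions, rmap, corr,
                        network_regulators = c("TP53", "IRF1", "EGFR"))
  # mutated lesion contributes the gene itself
  expect_true("TP53" %in% drv$driver_gene)
  expect_identical(drv$provenance[drv$driver_gene == "TP53"], "mutated")
  # region member must be regulator AND positively coupled: IRF1 yes,
  # OTHER is not a regulator
  expect_true("IRF1" %in% drv$driver_gene)
  expect_identical(drv$provenance[drv$driver_gene == "IRF1"], "deleted")
  expect_false("OTHER" %in% drv$driver_gene)
  # wrong direction and non-significant lesions excluded
  expect_false("EGFR" %in% drv$driver_gene)
  expect_false("KRAS" %in% drv$driver_gene)
})

test_that("build_network keeps only driver -> DE edges from the input", {
  edges <- data.frame(regulator = c("A", "A", "B"),
                      target = c("B", "C", "C"))
  net <- build_network(data.frame(driver_gene = "A"), "B", edges)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$target, "B")
  expect_identical(net$targets$A, "B")
  # driver with no DE targets retained in the report with count 0
  net0 <- build_network(data.frame(driver_gene = c("A", "Z")), "B", edges)
  expect_equal(unname(net0$counts["Z"]), 0L)

  # random bipartite fixture vs brute-force filter
  set.seed(17)
  for (i in 1:5) {
    e <- unique(data.frame(
      regulator = sample(LETTERS[1:10], 60, replace = TRUE),
      target = sample(letters[1:15], 60, replace = TRUE)))
    drv <- data.frame(driver_gene = sample(LETTERS[1:10], 3))
    de <- sample(letters[1:15], 6)
    got <- build_network(drv, de, e)$edges
    ref <- e[e$regulator %in% drv$driver_gene & e$target %in% de, ]
    expect_setequal(paste(got$regulator, got$target),
                    paste(ref$regulator, ref$target))
  }
})

test_that("two_hop_targets finds exactly-2-step targets with exclusions", {
  edges <- data.frame(regulator = c("A", "X", "A", "B", "X"),
                      target = c("X", "B", "C", "C", "A"))
  drv <- data.frame(driver_gene = "A")
  th <- two_hop_targets(drv, c("B", "C"), edges)
  expect_true("B" %in% th$A)        # A -> X -> B
  expect_false("C" %in% th$A)       # C is a direct target: excluded
  expect_false("A" %in% th$A)       # cycle A -> X -> A: self excluded

  # restricted intermediates: only driver nodes may relay
  th2 <- two_hop_targets(drv, c("B", "C"), edges, intermediates = "drivers")
  expect_equal(length(th2$A), 0L)
})

test_that("per_driver_enrichment delegates per target set", {
  universe <- sprintf("u%02d", 1:10)
  edges <- data.frame(regulator = rep("D", 5), target = universe[1:5])
  net <- build_network(data.frame(driver_gene = c("D", "E")),
                       universe[1:5], edges)
  expect_message(
    res <- per_driver_enrichment(net, list(hit = universe[1:5]), universe),
    "skipping")
  expect_named(res, "D")
  expect_equal(res$D$p[1], 1 / choose(10, 5))
})

test_that("the planted driver ranks first by direct-target count", {
  co <- small_cohort(seed = 2)
  # latent-state labels isolate the network machinery from classifier noise
  status <- setNames(ifelse(co$ground_truth$latent == 1L, "metastatic",
                            "nonmetastatic"),
                     names(co$ground_truth$latent))
  tested <- suppressWarnings(cv_filter(co$expr))
  de <- de_test(co$expr[tested, ], status[colnames(co$expr)])
  muts <- prevalence_filter(co$mutations)
  lt <- lesion_tests(muts, status, "mutation")
  drv <- select_drivers(lt, co$region_map,
                        data.frame(gene = character(), region = character(),
                                   rho = numeric(), p = numeric(),
                                   fdr = numeric(),
                                   positive_significant = logical()),
                        unique(co$edges$regulator))
  expect_true(co$ground_truth$driver %in% drv$driver_gene)
  net <- build_network(drv, de$gene[de$significant], co$edges)
  rec <- evaluate_recovery(co, network = net)
  expect_equal(rec$driver_rank, 1L)
  # every reported edge exists in the input edge list
  expect_true(all(paste(net$edges$regulator, net$edges$target) %in%
                  paste(co$edges$regulator, co$edges$target)))
  # two-hop and direct sets are disjoint
  th <- two_hop_targets(drv, de$gene[de$significant], co$edges)
  for (d in names(net$targets))
    expect_length(intersect(net$targets[[d]], th[[d]]), 0)
})
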