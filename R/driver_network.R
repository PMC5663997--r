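#' Select candidate driver genes from significant lesions
#'
#' Driver lesions are the tested lesions that are significant at FDR and
#' enriched in the metastatic group (`direction == "higher_in_met"`).
#' A mutated-gene lesion contributes the gene itself. A copy-number lesion
#' contributes those member genes (via the region map) that both act as
#' regulators in the supplied network and show a significant positive
#' expression-copy number correlation - i.e. genes whose dosage change is
#' actually transmitted to expression and that can regulate downstream
#' targets.
#'
#' @param lesions [lesion_tests()] output (mutations and copy-number
#'   lesions may be row-bound; `lesion_type` distinguishes them, and
#'   copy-number lesion ids carry the `amp:`/`del:` prefix).
#' @param region_map data.frame (region, gene) for copy-number lesions.
#' @param corr [expr_cna_correlation()] output.
#' @param network_regulators Character vector of genes appearing as
#'   regulators in the edge list.
#' @return data.frame: driver_gene, provenance in
#'   {"mutated","amplified","deleted"}, source_lesion.
#' @export
select_drivers <- function(lesions, region_map, corr, network_regulators) {
  qual <- lesions[lesions$significant &
                  lesions$direction == "higher_in_met", , drop = FALSE]
  rows <- lapply(seq_len(nrow(qual)), function(i) {
    id <- qual$lesion_id[i]
    if (qual$lesion_type[i] == "mutation") {
      return(data.frame(driver_gene = id, provenance = "mutated",
                        source_lesion = id, stringsAsFactors = FALSE))
    }
    kind <- if (startsWith(id, "amp:")) "amplified" else "deleted"
    region <- sub("^(amp|del):", "", id)
    members <- region_map$gene[region_map$region == region]
    if (!length(members)) {
      warning("region '", region, "' has no mapped genes")
      return(NULL)
    }
    pos <- corr$gene[corr$positive_significant & corr$region == region]
    g <- intersect(intersect(members, network_regulators), pos)
    if (!length(g)) return(NULL)
    data.frame(driver_gene = g, provenance = kind, source_lesion = id,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(driver_gene = character(), provenance = character(),
                      source_lesion = character()))
  unique(do.call(rbind, rows))
}

#' Build the driver-to-DE-gene regulatory subnetwork
#'
#' Keeps the input edges whose source is a driver gene and whose target is
#' a differentially expressed gene. No edges are inferred; drivers absent
#' from the network simply have zero targets.
#'
#' @param drivers [select_drivers()] output (or a data.frame with a
#'   `driver_gene` column).
#' @param de_genes Character vector of significant DE gene ids.
#' @param edges data.frame (regulator, target).
#' @return list(edges = filtered edge data.frame, targets = named list of
#'   per-driver direct target sets, counts = named integer vector).
#' @export
build_network <- function(drivers, de_genes, edges) {
  dg <- unique(drivers$driver_gene)
  keep <- edges$regulator %in% dg & edges$target %in% de_genes
  sub <- unique(edges[keep, c("regulator", "target"), drop = FALSE])
  targets <- lapply(stats::setNames(dg, dg), function(d)
    sort(unique(sub$target[sub$regulator == d])))
  list(edges = sub, targets = targets,
       counts = vapply(targets, length, 0L))
}

#' Two-hop indirect targets of each driver
#'
#' Targets reachable in exactly two directed steps through any intermediate
#' node (or only through other drivers, with `intermediates = "drivers"`),
#' excluding the driver's direct targets and the driver itself.
#'
#' @param drivers As in [build_network()].
#' @param de_genes Significant DE gene ids.
#' @param edges Edge data.frame (regulator, target).
#' @param intermediates `"any"` (default) or `"drivers"`.
#' @return Named list of per-driver indirect DE-target sets.
#' @export
two_hop_targets <- function(drivers, de_genes, edges,
                            intermediates = c("any", "drivers")) {
  intermediates <- match.arg(intermediates)
  dg <- unique(drivers$driver_gene)
  lapply(stats::setNames(dg, dg), function(d) {
    mid <- edges$target[edges$regulator == d]
    if (intermediates == "drivers") mid <- intersect(mid, dg)
    hop2 <- edges$target[edges$regulator %in% mid]
    direct <- edges$target[edges$regulator == d]
    sort(setdiff(intersect(unique(hop2), de_genes), c(direct, d)))
  })
}

#' Gene-set enrichment of each driver's direct target set
#'
#' Delegates to [enrich()] for every driver with at least one direct
#' target; drivers with empty target sets are skipped with a notice.
#'
#' @param network [build_network()] output.
#' @param sets Gene-set list (see [read_gmt()]).
#' @param universe Background gene ids.
#' @param alpha_fdr Default 0.05.
#' @return Named list of enrichment data.frames.
#' @export
per_driver_enrichment <- function(network, sets, universe,
                                  alpha_fdr = 0.05) {
  nonempty <- names(network$targets)[network$counts > 0L]
  skipped <- setdiff(names(network$targets), nonempty)
  if (length(skipped))
    message("skipping driver(s) with no direct targets: ",
            paste(skipped, collapse = ", "))
  lapply(stats::setNames(nonempty, nonempty), function(d)
    enrich(network$targets[[d]], sets, universe, alpha_fdr))
}
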