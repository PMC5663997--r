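#' Read a log2 expression matrix from TSV
#'
#' Expects genes as rows and samples as columns: a header row of sample
#' identifiers and a first column of gene identifiers. Values are assumed to
#' already be on the log2 scale; the reader performs no transformation.
#'
#' @param path Path to a tab-separated file.
#' @param missing_policy What to do with rows containing missing or
#'   non-numeric cells: `"error"` (default) aborts naming the offending
#'   coordinates, `"drop_gene"` removes the row with a warning.
#' @return A numeric matrix (genes x samples) with unique dimnames.
#' @export
read_expression <- function(path, missing_policy = c("error", "drop_gene")) {
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 3L)
    stop("expression table needs a gene-id column and at least 2 samples")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(gene_ids, sample_ids)
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (missing_policy == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite value at gene '%s', sample '%s'",
                   gene_ids[idx[1L]], sample_ids[idx[2L]]))
    }
    drop_rows <- rowSums(bad) > 0L
    warning(sprintf("dropping %d gene(s) with missing values", sum(drop_rows)))
    vals <- vals[!drop_rows, , drop = FALSE]
  }
  validate_expression(vals)
}

#' Validate an expression matrix
#'
#' Enforces the container invariants: unique dimnames, all values finite,
#' at least one gene and two samples.
#'
#' @param x Numeric matrix, genes x samples.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids")
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("need at least 1 gene and 2 samples")
  if (!all(is.finite(x)))
    stop("expression values must all be finite")
  x
}

#' Write an expression matrix to TSV
#' @param x Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to no gene or to more than one gene are discarded; the
#' remaining probes of each gene are averaged per sample.
#'
#' @param probe_matrix Numeric matrix, probes x samples.
#' @param probe_to_gene data.frame with columns `probe`, `gene` (a probe may
#'   appear on several rows when it maps to several genes).
#' @return Gene-level expression matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(all(c("probe", "gene") %in% colnames(probe_to_gene)))
  map <- unique(probe_to_gene[, c("probe", "gene")])
  n_genes <- table(map$probe)
  uniq_probes <- names(n_genes)[n_genes == 1L]
  map <- map[map$probe %in% uniq_probes & map$probe %in% rownames(probe_matrix), ]
  if (nrow(map) == 0L)
    stop("no probe maps uniquely to a gene")
  sub <- probe_matrix[map$probe, , drop = FALSE]
  sums <- rowsum(sub, group = map$gene)
  counts <- as.vector(table(map$gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

.default_nonsyn_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
  "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del", "Splice_Site",
  "Nonstop_Mutation", "Translation_Start_Site")

#' Read a MAF-style mutation file into a binary gene x sample matrix
#'
#' A cell is 1 iff the gene carries at least one variant of a nonsynonymous
#' class in that sample. Samples present in the file whose variants are all
#' filtered out remain as all-zero columns.
#'
#' @param path Tab-separated MAF with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode` and `Variant_Classification` columns.
#' @param nonsyn_classes Variant classes counted as nonsynonymous. The
#'   default covers missense, nonsense, frameshift and in-frame indels,
#'   splice site, nonstop and translation start site.
#' @param allow_empty If `TRUE` (default) an empty MAF body yields a
#'   0-gene matrix; otherwise it is an error.
#' @return Binary integer matrix, genes x samples.
#' @export
read_maf <- function(path, nonsyn_classes = .default_nonsyn_classes,
                     allow_empty = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(required, colnames(raw))
  if (length(miss))
    stop("MAF is missing required column(s): ", paste(miss, collapse = ", "))
  all_samples <- unique(raw$Tumor_Sample_Barcode)
  keep <- raw$Variant_Classification %in% nonsyn_classes
  raw <- raw[keep, , drop = FALSE]
  if (length(all_samples) == 0L) {
    if (!allow_empty) stop("empty MAF body")
    return(matrix(0L, 0L, 0L, dimnames = list(character(), character())))
  }
  genes <- sort(unique(raw$Hugo_Symbol))
  out <- matrix(0L, length(genes), length(all_samples),
                dimnames = list(genes, all_samples))
  if (nrow(raw))
    out[cbind(match(raw$Hugo_Symbol, genes),
              match(raw$Tumor_Sample_Barcode, all_samples))] <- 1L
  out
}

#' Threshold continuous copy-number values into {-1, 0, +1} calls
#'
#' Strict inequalities: values above `amp_threshold` become +1, values
#' below `del_threshold` become -1, everything else (including the
#' thresholds themselves) is 0.
#'
#' @param x Numeric vector or matrix of GISTIC-style scores.
#' @param amp_threshold Amplification threshold (default +0.3).
#' @param del_threshold Deletion threshold (default -0.3).
#' @export
threshold_cna <- function(x, amp_threshold = 0.3, del_threshold = -0.3) {
  if (!(del_threshold < 0 && 0 < amp_threshold))
    stop("need del_threshold < 0 < amp_threshold")
  out <- x
  out[] <- ifelse(x > amp_threshold, 1L, ifelse(x < del_threshold, -1L, 0L))
  out
}

#' Read a GISTIC-style copy-number table
#'
#' Accepts either continuous scores (thresholded at strict +/- cutoffs) or
#' already-discrete calls in {-2,-1,0,1,2} (collapsed to sign). With
#' `dialect = "auto"` the input is treated as discrete when every value is
#' one of -2,-1,0,1,2.
#'
#' @param path TSV, lesions x samples, first column lesion ids.
#' @param amp_threshold,del_threshold Thresholds for continuous input.
#' @param dialect One of `"auto"`, `"continuous"`, `"discrete"`.
#' @return Integer matrix with entries in {-1,0,1}; thresholds attached as
#'   attributes `amp_threshold` / `del_threshold`.
#' @export
read_gistic <- function(path, amp_threshold = 0.3, del_threshold = -0.3,
                        dialect = c("auto", "continuous", "discrete")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           row.names = 1L)
  x <- as.matrix(raw)
  if (!is.numeric(x)) stop("non-numeric copy-number values")
  discrete <- all(x %in% c(-2, -1, 0, 1, 2))
  if (dialect == "discrete" && !discrete)
    stop("discrete dialect requested but values outside {-2,...,2} found")
  if (dialect == "auto") dialect <- if (discrete) "discrete" else "continuous"
  out <- if (dialect == "discrete") sign(x) else
    threshold_cna(x, amp_threshold, del_threshold)
  storage.mode(out) <- "integer"
  attr(out, "amp_threshold") <- amp_threshold
  attr(out, "del_threshold") <- del_threshold
  out
}

#' Gene-pair signature constructor
#'
#' Each row is an ordered pair (gene_high, gene_low); within a sample,
#' expression(gene_high) > expression(gene_low) is a high-risk vote.
#'
#' @param gene_high,gene_low Character vectors of equal length.
#' @return A `gene_pair_signature` data.frame with attribute `n_pairs`.
#' @export
gene_pair_signature <- function(gene_high, gene_low) {
  if (length(gene_high) != length(gene_low) || length(gene_high) < 1L)
    stop("need >= 1 pair with both members")
  if (any(gene_high == gene_low))
    stop("a pair may not contain the same gene twice")
  key <- paste(gene_high, gene_low, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate gene pairs")
  sig <- data.frame(gene_high = as.character(gene_high),
                    gene_low = as.character(gene_low),
                    stringsAsFactors = FALSE)
  class(sig) <- c("gene_pair_signature", "data.frame")
  sig
}

#' @export
print.gene_pair_signature <- function(x, ...) {
  cat(sprintf("gene-pair signature with %d pairs\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a gene-pair signature from TSV (columns gene_high, gene_low)
#' @param path Path to TSV.
#' @export
read_signature <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("gene_high", "gene_low") %in% colnames(raw)))
    stop("signature file needs columns gene_high, gene_low")
  gene_pair_signature(raw$gene_high, raw$gene_low)
}

#' Write a gene-pair signature to TSV
#' @param sig A `gene_pair_signature`.
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed regulator-target edge list
#'
#' Accepts a 2-column TSV (regulator, target) with or without a header, or
#' SIF lines (source, relation, target).
#'
#' @param path Path to edge list.
#' @return data.frame with columns `regulator`, `target`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1L]))
    stop("malformed edge list at line ", which(nf != nf[1L])[1L])
  if (!nf[1L] %in% c(2L, 3L))
    stop("edge list must have 2 (TSV) or 3 (SIF) columns")
  tgt_col <- nf[1L]
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", tgt_col)
  if (tolower(reg[1L]) %in% c("regulator", "source") ) {
    reg <- reg[-1L]; tgt <- tgt[-1L]
  }
  unique(data.frame(regulator = reg, target = tgt, stringsAsFactors = FALSE))
}

#' Write an edge list as 2-column TSV
#' @param edges data.frame with columns regulator, target.
#' @param path Output path.
#' @export
write_network <- function(edges, path) {
  utils::write.table(edges[, c("regulator", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set id, description, then member genes, tab-separated.
#' Members are deduplicated within a set; empty sets are an error.
#'
#' @param path Path to GMT file.
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": need id, description, >=1 gene")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene-set ids")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

.major_stage <- function(stage) {
  s <- toupper(trimws(stage))
  s <- sub("^STAGE\\s*", "", s)
  out <- ifelse(grepl("^IA", s), "IA",
         ifelse(grepl("^IB", s), "IB",
         ifelse(grepl("^IV", s), "IV",
         ifelse(grepl("^III", s), "III",
         ifelse(grepl("^II", s), "II",
         ifelse(s == "I", "IA", NA_character_))))))
  if (anyNA(out) && !anyNA(stage))
    stop("unknown stage label(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Read a clinical annotation table
#'
#' Required columns: `sample_id`, `stage`, `os_time`, `os_event`,
#' `metastasis_clinical`. Recognized optional columns: `age`, `gender`,
#' `rfs_time`, `rfs_event`, `adjuvant`, `subtype`, `smoking`. Sub-stages
#' (e.g. IIIA) are mapped to their major stage; stage I keeps its IA/IB
#' split. Survival times are stored in months; pass `time_unit = "days"`
#' to convert (x 1/30.44).
#'
#' @param path Path to TSV.
#' @param time_unit `"months"` (default) or `"days"`.
#' @return data.frame, one row per sample.
#' @export
read_clinical <- function(path, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "stage", "os_time", "os_event",
                "metastasis_clinical")
  miss <- setdiff(required, colnames(raw))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  validate_clinical(raw, time_unit = time_unit)
}

#' Validate (and normalize) a clinical table
#' @param x data.frame of clinical annotations.
#' @param time_unit Unit of the supplied survival times.
#' @return Normalized data.frame (times in months, major stages).
#' @export
validate_clinical <- function(x, time_unit = "months") {
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample ids in clinical table")
  x$stage <- .major_stage(x$stage)
  scale <- if (time_unit == "days") 1 / 30.44 else 1
  for (col in intersect(c("os_time", "rfs_time"), colnames(x))) {
    x[[col]] <- as.numeric(x[[col]]) * scale
    if (any(x[[col]] < 0, na.rm = TRUE)) stop(col, " must be >= 0")
  }
  for (col in intersect(c("os_event", "rfs_event"), colnames(x))) {
    x[[col]] <- as.integer(x[[col]])
    if (!all(x[[col]] %in% c(0L, 1L, NA))) stop(col, " must be 0/1")
  }
  mc <- tolower(as.character(x$metastasis_clinical))
  if (!all(mc %in% c("yes", "no", NA)))
    stop("metastasis_clinical must be yes/no")
  x$metastasis_clinical <- mc
  if (!"adjuvant" %in% colnames(x)) x$adjuvant <- "unknown"
  adj <- tolower(as.character(x$adjuvant))
  adj[is.na(adj) | adj %in% c("not available", "na")] <- "unknown"
  if (!all(adj %in% c("none", "unknown", "yes")))
    stop("adjuvant must be none/unknown/yes")
  x$adjuvant <- adj
  x
}

#' Write a clinical table to TSV
#' @param x Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a region-to-gene membership map
#'
#' TSV with columns `region` and `gene`; a region may span many genes and a
#' gene may belong to several regions.
#'
#' @param path Path to TSV.
#' @return data.frame with columns region, gene.
#' @export
read_region_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("region", "gene") %in% colnames(raw)))
    stop("region map needs columns region, gene")
  raw <- unique(raw[, c("region", "gene")])
  if (any(!nzchar(raw$gene)))
    stop("region map contains empty gene ids")
  raw
}

#' Write a generic lesion/call matrix to TSV (first column = lesion id)
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param id_name Name of the id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
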