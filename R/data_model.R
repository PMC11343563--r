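# Readers, writers and validators for the package's tabular inputs:
# count matrices, sample metadata, and allele-resolved F1 counts.
# Dialect: tab-separated, UTF-8, no quoting, gene ids in a first column
# named "gene_id".

#' Validate a count matrix
#'
#' Checks that `counts` is a nonnegative integer-valued matrix with unique,
#' non-missing row (gene) and column (sample) names.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix (in storage mode double, integral values).
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid)) stop("counts must have gene and sample names")
  dup_g <- gid[duplicated(gid)]
  if (length(dup_g)) stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "counts must be nonnegative integers; first offending entry at gene '%s', sample '%s'",
      gid[bad[1, 1]], sid[bad[1, 2]]
    ))
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a gene-by-sample count matrix
#'
#' Reads a tab-separated count table whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are one sample each. Input ordering
#' of genes and samples is preserved.
#'
#' @param path Path to a TSV file.
#' @return A validated numeric matrix with gene rownames and sample colnames.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a gene_id column plus >=1 sample column")
  gid <- as.character(df[[1]])
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table body")
  rownames(m) <- gid
  validate_counts(m)
}

#' Write a count matrix
#'
#' @param counts Validated count matrix.
#' @param path Output TSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonicalize stage labels; aliases map onto the closed vocabulary
normalize_stage <- function(stage) {
  s <- tolower(trimws(as.character(stage)))
  s <- gsub("[ _]+", "-", s)
  s[s %in% c("16cell", "16-cells", "sixteen-cell", "sixteencell")] <- "16-cell"
  s[s %in% c("1week", "one-week", "week-1", "7-dpf")] <- "1-week"
  s
}

#' Read and validate a sample metadata table
#'
#' Requires columns `sample_id`, `genotype`, `stage`, `replicate`; an optional
#' `cross_id` and `total_reads` are carried through. Genotypes must come from
#' the closed vocabulary [GENOTYPES]; stages are normalized (e.g. "1 week" to
#' "1-week") and must come from [STAGES]. The stage column is returned as a
#' factor ordered by developmental time.
#'
#' @param path Path to a TSV file, or a data.frame to validate in place.
#' @return A validated data.frame.
#' @export
read_sample_table <- function(path) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "genotype", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  bad_g <- setdiff(unique(df$genotype), GENOTYPES)
  if (length(bad_g)) {
    stop("unknown genotype(s): ", paste(bad_g, collapse = ", "),
         "; valid genotypes are ", paste(GENOTYPES, collapse = ", "))
  }
  df$stage <- normalize_stage(df$stage)
  bad_s <- setdiff(unique(df$stage), STAGES)
  if (length(bad_s)) {
    stop("unknown stage(s): ", paste(bad_s, collapse = ", "),
         "; valid stages are ", paste(STAGES, collapse = ", "))
  }
  df$stage <- factor(df$stage, levels = STAGES, ordered = TRUE)
  if (any(!is.finite(df$replicate) | df$replicate < 1 | df$replicate != round(df$replicate))) {
    stop("replicate must be a positive integer")
  }
  if (is.null(df$cross_id)) df$cross_id <- NA_character_
  df
}

#' Write a sample table
#' @param samples Sample metadata data.frame.
#' @param path Output TSV path.
#' @export
write_sample_table <- function(samples, path) {
  out <- samples
  out$stage <- as.character(out$stage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join a count matrix with its sample table
#'
#' Verifies that every sample column of `counts` has exactly one metadata row
#' and returns the table reordered to match the matrix columns.
#'
#' @param counts Count matrix.
#' @param samples Sample table (see [read_sample_table()]).
#' @return The sample table, one row per count column, in column order.
#' @export
align_samples <- function(counts, samples) {
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss)) {
    stop("sample(s) in counts but not in sample table: ", paste(miss, collapse = ", "))
  }
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}

#' Read an allele-resolved F1 count table
#'
#' Long-format table with columns `gene_id`, `sample_id`, `p_count`, `l_count`
#' giving, for each gene in each F1 sample, the reads assignable to the P and
#' L parental alleles. Only F1 (PL/LP) samples may appear, and per gene the
#' assignable total may not exceed the gene's total count in that sample.
#'
#' @param path Path to TSV, or a data.frame to validate.
#' @param counts Optional count matrix for the total-count consistency check.
#' @param samples Optional sample table for the genotype check.
#' @return Validated data.frame.
#' @export
read_allele_counts <- function(path, counts = NULL, samples = NULL) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "sample_id", "p_count", "l_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele count table missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("p_count", "l_count")) {
    v <- df[[cc]]
    if (any(!is.finite(v) | v < 0 | v != round(v))) stop(cc, " must be nonnegative integers")
  }
  if (!is.null(samples)) {
    geno <- samples$genotype[match(df$sample_id, samples$sample_id)]
    if (anyNA(geno)) stop("allele counts reference unknown sample id(s)")
    if (any(!geno %in% c("PL", "LP"))) stop("allele counts must come from F1 (PL/LP) samples only")
  }
  if (!is.null(counts)) {
    idx <- cbind(match(df$gene_id, rownames(counts)), match(df$sample_id, colnames(counts)))
    ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
    tot <- rep(Inf, nrow(df))
    tot[ok] <- counts[idx[ok, , drop = FALSE]]
    if (any(df$p_count + df$l_count > tot)) {
      stop("assignable allele counts exceed the gene's total count in some sample")
    }
  }
  df
}

#' Write an allele count table
#' @param allele_counts Allele count data.frame.
#' @param path Output TSV path.
#' @export
write_allele_counts <- function(allele_counts, path) {
  utils::write.table(allele_counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop low-depth samples
#'
#' Removes samples whose sequencing depth falls below `min_reads` (default two
#' million). Depth is the `total_reads` metadata column when present, else the
#' sample's column sum of counts. Retained counts are never altered.
#'
#' @param counts Count matrix.
#' @param samples Sample table aligned to `counts`.
#' @param min_reads Minimum depth; samples strictly below are dropped.
#' @return List with elements `counts`, `samples`, and `dropped` (ids removed).
#' @export
qc_filter_samples <- function(counts, samples, min_reads = 2e6) {
  stopifnot(min_reads >= 0)
  samples <- align_samples(counts, samples)
  depth <- if (!is.null(samples$total_reads) && all(is.finite(samples$total_reads))) {
    samples$total_reads
  } else {
    colSums(counts)
  }
  drop <- depth < min_reads
  dropped <- colnames(counts)[drop]
  for (s in dropped) {
    message(sprintf("qc_filter_samples: dropping '%s' (depth %.3g < %.3g)", s,
                    depth[match(s, colnames(counts))], min_reads))
  }
  kept_samples <- samples[!drop, , drop = FALSE]
  cells_before <- unique(paste(samples$genotype, samples$stage))
  cells_after <- unique(paste(kept_samples$genotype, kept_samples$stage))
  lost <- setdiff(cells_before, cells_after)
  if (length(lost)) {
    warning("all samples dropped for genotype x stage cell(s): ",
            paste(lost, collapse = "; "))
  }
  list(counts = counts[, !drop, drop = FALSE], samples = kept_samples, dropped = dropped)
}
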