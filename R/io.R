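# Readers and writers for expression tables, gene annotations, eQTL tables,
# partitions and statistics tables. Downstream modules consume only the
# in-memory objects constructed here.

#' Expression layer constructor
#'
#' Holds one tissue's genes-by-samples TPM matrix together with a sample-to-
#' donor mapping, so that samples can be matched across tissues when computing
#' interlayer couplings.
#'
#' @param tissue_label tissue name.
#' @param values numeric N x S matrix of non-negative TPM values with gene IDs
#'   as rownames and sample IDs as colnames.
#' @param donor_ids named character vector mapping every sample ID to a donor
#'   identifier.
#' @return An object of class `expression_layer`.
#' @export
expression_layer <- function(tissue_label, values, donor_ids) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_mlc("expression values need gene rownames and sample colnames")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (anyDuplicated(gene_ids))
    stop_mlc("duplicate gene ID: %s", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(sample_ids))
    stop_mlc("duplicate sample ID: %s", sample_ids[duplicated(sample_ids)][1])
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_mlc("negative expression value %.4g for gene '%s' (sample '%s')",
             values[neg[1, 1], neg[1, 2]], gene_ids[neg[1, 1]],
             sample_ids[neg[1, 2]])
  missing <- setdiff(sample_ids, names(donor_ids))
  if (length(missing) > 0)
    stop_mlc("no donor mapping for sample '%s'", missing[1])
  structure(
    list(tissue_label = tissue_label, gene_ids = gene_ids,
         sample_ids = sample_ids,
         donor_ids = donor_ids[sample_ids],
         values = values),
    class = "expression_layer"
  )
}

#' @export
print.expression_layer <- function(x, ...) {
  cat(sprintf("Expression layer '%s': %d genes x %d samples (%d donors)\n",
              x$tissue_label, length(x$gene_ids), length(x$sample_ids),
              length(unique(x$donor_ids))))
  invisible(x)
}

# Default GTEx-style donor rule: first two dash/dot-delimited tokens of the
# sample ID ("GTEX-1117F-0226-SM-5GZZ7" -> "GTEX-1117F").
default_donor_rule <- function(sample_ids) {
  vapply(strsplit(sample_ids, "[-.]"), function(tok) {
    paste(tok[seq_len(min(2L, length(tok)))], collapse = "-")
  }, character(1))
}

resolve_donors <- function(sample_ids, donor_rule) {
  if (is.null(donor_rule)) {
    d <- default_donor_rule(sample_ids)
  } else if (is.function(donor_rule)) {
    d <- donor_rule(sample_ids)
  } else if (is.character(donor_rule) && length(donor_rule) == 1L &&
             file.exists(donor_rule)) {
    map <- utils::read.delim(donor_rule, header = TRUE,
                             stringsAsFactors = FALSE)
    if (ncol(map) < 2) stop_mlc("donor mapping file needs two columns")
    d <- map[[2]][match(sample_ids, map[[1]])]
    if (anyNA(d)) stop_mlc("donor mapping file misses sample '%s'",
                           sample_ids[which(is.na(d))[1]])
  } else if (!is.null(names(donor_rule))) {
    d <- unname(donor_rule[sample_ids])
    if (anyNA(d)) stop_mlc("donor vector misses sample '%s'",
                           sample_ids[which(is.na(d))[1]])
  } else {
    stop_mlc("donor_rule must be NULL, a function, a named vector, or a file")
  }
  names(d) <- sample_ids
  d
}

#' Read an expression table
#'
#' Reads a genes-by-samples TPM table in TSV (header row of sample IDs, gene
#' IDs in the first column) or GCT 1.2 format and returns an
#' [expression_layer()].
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param donor_rule `NULL` for the default GTEx-style rule (first two
#'   dash/dot-delimited tokens of the sample ID), or a function on sample IDs,
#'   a named sample-to-donor vector, or the path of a two-column TSV.
#' @param tissue_label layer label; defaults to the file name stem.
#' @return An `expression_layer`.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), donor_rule = NULL,
                            tissue_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mlc("file not found: %s", path)
  if (is.null(tissue_label))
    tissue_label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      stop_mlc("not a GCT 1.2 file (missing '#1.2' version line): %s", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || anyNA(dims[1:2]))
      stop_mlc("malformed GCT dimension line in %s", path)
    tab <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                             header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    # GCT carries Name and Description columns before the samples.
    if (ncol(tab) < 3) stop_mlc("GCT table needs Name, Description, samples")
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(vals) <- tab[[1]]
    if (nrow(vals) != dims[1] || ncol(vals) != dims[2])
      stop_mlc(
        "GCT dimension mismatch in %s: header says %d x %d, data are %d x %d",
        path, dims[1], dims[2], nrow(vals), ncol(vals))
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- tab[[1]]
  }
  if (!is.numeric(vals))
    stop_mlc("non-numeric expression values in %s", path)
  donors <- resolve_donors(colnames(vals), donor_rule)
  expression_layer(tissue_label, vals, donors)
}

ALLOWED_CHROMS <- c(as.character(1:22), "X", "Y", "M")

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), or BED-like `chrom`, `start`, `end`, `gene_id`
#'   (0-based half-open, no header) when `format = "bed"`.
#' @param format `"tsv"` or `"bed"`.
#' @param allowed_chroms declared chromosome label set; `"chr"` prefixes and
#'   `"MT"` are normalized.
#' @return A `gene_annotation` data frame with columns gene_id, chrom, start,
#'   end (1-based inclusive).
#' @export
read_annotation <- function(path, format = c("tsv", "bed"),
                            allowed_chroms = ALLOWED_CHROMS) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mlc("file not found: %s", path)
  if (format == "bed") {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop_mlc("BED-like annotation needs 4 columns")
    ann <- data.frame(gene_id = tab[[4]], chrom = as.character(tab[[1]]),
                      start = tab[[2]] + 1L, end = tab[[3]],
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(tab)))
      stop_mlc("annotation is missing column(s): %s",
               paste(setdiff(need, names(tab)), collapse = ", "))
    ann <- tab[, need]
    ann$chrom <- as.character(ann$chrom)
  }
  gene_annotation(ann, allowed_chroms = allowed_chroms)
}

#' Gene annotation constructor
#'
#' @param df data frame with columns gene_id, chrom, start, end (1-based
#'   inclusive coordinates).
#' @param allowed_chroms declared chromosome label set.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(df, allowed_chroms = ALLOWED_CHROMS) {
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$chrom[df$chrom == "MT"] <- "M"
  bad <- setdiff(unique(df$chrom), allowed_chroms)
  if (length(bad) > 0)
    stop_mlc("chromosome label(s) outside the declared set: %s",
             paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop_mlc("duplicate gene ID in annotation: %s",
             df$gene_id[duplicated(df$gene_id)][1])
  rev <- which(df$start > df$end)
  if (length(rev) > 0)
    stop_mlc("start > end for gene '%s'", df$gene_id[rev[1]])
  rownames(df) <- df$gene_id
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read an eQTL association table
#'
#' @param path TSV with header columns `snp_id`, `gene_id`, `p_value`.
#'   Duplicate (snp_id, gene_id) rows are collapsed to one record with a
#'   warning.
#' @return An `eqtl_table` data frame.
#' @export
read_eqtl <- function(path) {
  if (!file.exists(path)) stop_mlc("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "p_value")
  if (!all(need %in% names(tab)))
    stop_mlc("eQTL table is missing column(s): %s",
             paste(setdiff(need, names(tab)), collapse = ", "))
  tab <- tab[, need]
  if (any(tab$p_value <= 0 | tab$p_value > 1))
    stop_mlc("eQTL p-values must lie in (0, 1]")
  key <- paste(tab$snp_id, tab$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warn_mlc("%d duplicate (snp, gene) record(s) dropped",
             sum(duplicated(key)))
    tab <- tab[!duplicated(key), ]
  }
  rownames(tab) <- NULL
  class(tab) <- c("eqtl_table", "data.frame")
  tab
}

#' Write / read a supra partition as TSV
#'
#' Columns gene_id, layer_label, community_label; community labels are 1-based
#' integers renumbered consecutively by decreasing community size, so output is
#' deterministic and diffable.
#'
#' @param partition a [supra_partition()].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "supra_partition"))
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "layer_label", "community_label")
  if (!all(need %in% names(tab)))
    stop_mlc("partition file is missing column(s): %s",
             paste(setdiff(need, names(tab)), collapse = ", "))
  gene_ids <- unique(tab$gene_id)
  layer_labels <- unique(tab$layer_label)
  N <- length(gene_ids); L <- length(layer_labels)
  if (nrow(tab) != N * L)
    stop_mlc("partition file does not cover every (gene, layer) node exactly once")
  idx <- (match(tab$layer_label, layer_labels) - 1L) * N +
    match(tab$gene_id, gene_ids)
  labels <- integer(N * L)
  labels[idx] <- tab$community_label
  supra_partition(labels, gene_ids, layer_labels, renumber = FALSE)
}

#' Write a statistics table as TSV
#'
#' @param table a data frame.
#' @param path output path.
#' @export
write_stats <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "N/A")
  invisible(path)
}

#' Write an expression layer as TSV (gene IDs in the first column)
#' @param layer an [expression_layer()].
#' @param path output path.
#' @export
write_expression <- function(layer, path) {
  stopifnot(inherits(layer, "expression_layer"))
  df <- data.frame(gene_id = layer$gene_ids, layer$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
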