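#' Read gene models from a GFF3 file
#'
#' Imports features of the requested type(s) via rtracklayer and returns a
#' plain data.frame of gene models: one row per feature with its contig,
#' 1-based inclusive coordinates, strand, gene ID and the protein ID used
#' to link genes to the quantification matrix. The protein link is taken
#' from a configurable attribute key (default `"ID"`, i.e. protein IDs are
#' assumed to be locus tags).
#'
#' A light pre-scan rejects malformed lines (wrong field count,
#' non-numeric or inverted coordinates) with the offending line number.
#'
#' @param path GFF3 file.
#' @param feature_type feature types to keep (default CDS and gene).
#' @param protein_attr attribute key holding the protein ID.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `protein_id` (NA when the attribute is absent). Genome
#'   order is not assigned here; see [order_genes()].
#' @export
read_gff <- function(path, feature_type = c("CDS", "gene"),
                     protein_attr = "ID") {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) break  # appended FASTA: ignore the rest
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("unparseable GFF3 line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    st <- suppressWarnings(as.numeric(f[4])); en <- suppressWarnings(as.numeric(f[5]))
    if (is.na(st) || is.na(en))
      stop("unparseable GFF3 line ", i, ": non-numeric coordinates")
    if (st > en)
      stop("invalid feature at line ", i, " (", f[1], ":", f[4], "-", f[5],
           "): start > end")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (!length(gr))
    stop("no features of type ", paste(feature_type, collapse = "/"),
         " in ", path)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    rep(NA_character_, length(gr))
  bad <- which(is.na(ids) | ids == "")
  if (length(bad)) {
    b <- bad[1]
    stop("feature without ID attribute on contig ",
         as.character(GenomicRanges::seqnames(gr))[b], " at ",
         GenomicRanges::start(gr)[b], "-", GenomicRanges::end(gr)[b])
  }
  prot <- if (protein_attr %in% names(mc))
    as.character(mc[[protein_attr]]) else rep(NA_character_, length(gr))
  data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = prot,
    stringsAsFactors = FALSE)
}

#' Assign genome-order ordinals to gene models
#'
#' Sorts genes by (contig, start, end) — contig names lexicographically,
#' then start ascending, ties broken by end ascending — and assigns each a
#' dense 0-based `ordinal`. The ordering is total and deterministic, so
#' the ordinal sequence is a permutation of 0..n-1 regardless of input
#' order. "Consecutive genes" in the window screen means consecutive
#' ordinals on the same contig; windows never span contigs.
#'
#' @param genes data.frame as from [read_gff()].
#' @return the same data.frame, sorted, with an `ordinal` column.
#' @export
order_genes <- function(genes) {
  if (!nrow(genes)) stop("no genes to order")
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         genes$gene_id[which(genes$start > genes$end)[1]])
  o <- order(genes$contig, genes$start, genes$end, method = "radix")
  genes <- genes[o, , drop = FALSE]
  genes$ordinal <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  genes
}

#' Write gene models as GFF3
#'
#' @param genes data.frame as from [read_gff()] (an `ordinal` column, if
#'   present, is not written; it is reconstructed by [order_genes()]).
#' @param path output path.
#' @param feature_type feature type to write (default `"CDS"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature_type = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- feature_type
  S4Vectors::mcols(gr)$source <- "proteoscreen"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a term annotation map
#'
#' Two-column TSV `term_id<TAB>gene_id` (no header required; a header line
#' whose first field is `term_id` is skipped), plus an optional names file
#' `term_id<TAB>term_name`.
#'
#' @param path annotation TSV.
#' @param names_path optional term-name TSV.
#' @return data.frame with columns `term_id`, `gene_id`, `term_name`.
#' @export
read_term_map <- function(path, names_path = NULL) {
  tm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("term_id", "gene_id"),
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(tm) && tm$term_id[1] == "term_id") tm <- tm[-1, , drop = FALSE]
  tm$term_name <- tm$term_id
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, header = FALSE, sep = "\t",
                            col.names = c("term_id", "term_name"),
                            stringsAsFactors = FALSE, quote = "")
    idx <- match(tm$term_id, nm$term_id)
    tm$term_name[!is.na(idx)] <- nm$term_name[idx[!is.na(idx)]]
  }
  rownames(tm) <- NULL
  tm
}

#' Read a qPCR CT table
#'
#' TSV with columns `sample`, `gene`, `ct`; one row per technical CT
#' replicate.
#'
#' @param path CT table path.
#' @return data.frame with columns `sample`, `gene`, `ct`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample", "gene", "ct")
  if (!all(req %in% names(ct)))
    stop("CT table must have columns sample, gene, ct")
  if (any(!is.finite(ct$ct)) || any(ct$ct < 0))
    stop("CT values must be finite and >= 0")
  ct[, req]
}
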