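#' Relative expression by the 2^-ddCt method
#'
#' Technical CT replicates are averaged (arithmetic mean) per
#' (sample, gene); then, per sample, dCt = mean CT(gene) - mean
#' CT(reference gene); ddCt = dCt - dCt(calibrator sample); relative
#' expression ratio = 2^(-ddCt). Amplification efficiency is fixed at 2
#' (no efficiency correction). The calibrator sample's ratio is 1 for
#' every gene, and ratios are exactly invariant to adding a constant to
#' all CTs of a sample (reference normalization).
#'
#' Statistics, if wanted, belong on the dCt scale (approximately normal);
#' ratios are reported on the linear scale.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (one row per
#'   technical CT replicate; see [read_ct_table()]).
#' @param reference_gene normalizer gene (e.g. the 16S rRNA gene),
#'   required in every sample.
#' @param calibrator_sample sample whose dCt anchors ddCt (typically an
#'   uninduced control).
#' @return data.frame with columns `sample`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `ratio` (the reference gene itself is not
#'   reported).
#' @examples
#' ct <- data.frame(sample = rep(c("ctl", "trt"), each = 2),
#'                  gene = rep(c("ref", "g"), 2),
#'                  ct = c(15, 25, 15, 23))
#' delta_delta_ct(ct, "ref", "ctl")  # trt/g ratio = 4
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator_sample) {
  req <- c("sample", "gene", "ct")
  if (!all(req %in% names(ct)))
    stop("CT table must have columns sample, gene, ct")
  if (!calibrator_sample %in% ct$sample)
    stop("calibrator sample '", calibrator_sample, "' absent from CT table")
  mct <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  samples <- unique(ct$sample)
  ref <- mct[mct$gene == reference_gene, , drop = FALSE]
  no_ref <- setdiff(samples, ref$sample)
  if (length(no_ref))
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(no_ref, collapse = ", "))
  tgt <- mct[mct$gene != reference_gene, , drop = FALSE]
  if (!nrow(tgt)) stop("no target genes in CT table")
  tgt$delta_ct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
  cal <- tgt[tgt$sample == calibrator_sample, , drop = FALSE]
  no_cal <- setdiff(unique(tgt$gene), cal$gene)
  if (length(no_cal))
    stop("gene(s) not measured in the calibrator sample: ",
         paste(no_cal, collapse = ", "))
  tgt$delta_delta_ct <- tgt$delta_ct - cal$delta_ct[match(tgt$gene, cal$gene)]
  tgt$ratio <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample),
             c("sample", "gene", "delta_ct", "delta_delta_ct", "ratio")]
  rownames(out) <- NULL
  out
}
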