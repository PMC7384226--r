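#' Count uniquely mapped fragments per gene (union mode)
#'
#' HTSeq-style union-mode counting at gene level. Only fragments flagged
#' unique are considered. A fragment is assigned to a gene iff the set of
#' genes overlapped (by >= 1 bp of any of its blocks, under the strand
#' rule) contains exactly that one gene; fragments touching exons of more
#' than one gene are ambiguous and uncounted, fragments touching nothing
#' are uncounted. The default strand rule `reverse` matches dUTP-type
#' stranded mRNA libraries: a fragment counts against a transcript on the
#' opposite strand.
#'
#' @param fragments Block-level alignment tibble (see
#'   [read_alignments()]), optionally with a `sample` column.
#' @param transcripts Exon-level annotation tibble.
#' @param strandedness `"reverse"`, `"forward"` or `"unstranded"`.
#' @return A count-matrix tibble: `feature_id` (gene id), `length_bp`
#'   (merged exonic bp of the gene), one integer column per sample.
#' @export
count_reads <- function(fragments, transcripts,
                        strandedness = c("reverse", "forward", "unstranded")) {
  strandedness <- match.arg(strandedness)
  if (!"sample" %in% names(fragments)) fragments$sample <- "sample1"
  genes <- gene_lengths(transcripts)
  samples <- unique(fragments$sample)
  counts <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$feature_id, samples))
  frags <- dplyr::filter(fragments, .data$unique)
  if (nrow(frags)) {
    strand_mode <- switch(strandedness, reverse = "opposite",
                          forward = "same", unstranded = "ignore")
    ov <- query_overlaps(
      dplyr::select(frags, "sample", "qname", "chrom", "start", "end",
                    "strand"),
      dplyr::select(transcripts, "gene_id", "chrom", "start", "end",
                    "strand"),
      strand_mode = strand_mode)
    if (nrow(ov)) {
      tally <- ov |>
        dplyr::distinct(.data$sample, .data$qname, .data$gene_id) |>
        dplyr::group_by(.data$sample, .data$qname) |>
        dplyr::filter(dplyr::n() == 1) |>
        dplyr::ungroup() |>
        dplyr::count(.data$sample, .data$gene_id)
      counts[cbind(match(tally$gene_id, genes$feature_id),
                   match(tally$sample, samples))] <- tally$n
    }
  }
  out <- tibble::tibble(feature_id = genes$feature_id,
                        length_bp = genes$length_bp)
  for (s in samples) out[[s]] <- unname(counts[, s])
  out
}

# Merged exonic length per gene.
gene_lengths <- function(transcripts) {
  transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(~ tibble::tibble(length_bp = merged_bp(.x))) |>
    dplyr::ungroup() |>
    dplyr::rename(feature_id = "gene_id") |>
    dplyr::arrange(.data$feature_id)
}

# Sample columns of a count-matrix tibble.
count_samples <- function(counts) {
  setdiff(names(counts), c("feature_id", "length_bp"))
}

count_mat <- function(counts) {
  m <- as.matrix(counts[count_samples(counts)])
  rownames(m) <- counts$feature_id
  m
}
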