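#' Derive strand-aware promoter windows
#'
#' The promoter is the region from `up` bp upstream through `down` bp
#' downstream of the TSS (default 2000/500). On the plus strand this is
#' `[tss - up, tss + down)`; on the minus strand the mirrored window
#' `[tss - down + 1, tss + up + 1)`, with `tss` the 0-based first
#' transcribed base. Windows are clamped to the chromosome.
#'
#' @param transcripts Exon-level tibble (see [read_gtf()]) or a
#'   transcript-level tibble with a `tss` column (see
#'   [transcript_summary()]).
#' @param up,down Bp upstream/downstream of the TSS.
#' @param layout Optional genome layout used for clamping.
#' @return A tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `tss`, `start`, `end` (the promoter interval).
#' @export
derive_promoter <- function(transcripts, up = 2000, down = 500,
                            layout = NULL) {
  tx <- if ("tss" %in% names(transcripts)) transcripts
        else transcript_summary(transcripts)
  if (any(!tx$strand %in% c("+", "-"))) {
    stop("promoter derivation requires stranded transcripts")
  }
  p_start <- ifelse(tx$strand == "+", tx$tss - up, tx$tss - down + 1)
  p_end <- ifelse(tx$strand == "+", tx$tss + down, tx$tss + up + 1)
  p_start <- pmax(0, p_start)
  if (!is.null(layout)) {
    len <- layout$length[match(tx$chrom, layout$chrom)]
    p_end <- pmin(p_end, len)
  }
  tibble::tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                 chrom = tx$chrom, strand = tx$strand, tss = tx$tss,
                 start = p_start, end = p_end)
}

#' Classify merged-assembly transcripts into cryptic transcripts
#'
#' A cryptic transcript is a noncoding transcript (not flagged coding and
#' not overlapping any annotated coding gene) at least one exon of which
#' overlaps a retrotransposon (LTR, LINE or SINE) annotation. When several
#' elements overlap, the element with the largest total exonic overlap is
#' assigned; ties break by lower element start, then lexicographic
#' subfamily.
#'
#' Two coding-overlap exclusion modes are provided because the plain
#' reading ("not overlapping annotated coding genes") also discards
#' antisense transcripts: `span_any_strand` (default) excludes a candidate
#' when its genomic span intersects any coding gene span on either strand;
#' `exon_same_strand` only excludes on same-strand exonic overlap.
#'
#' @param transcripts Exon-level tibble of the merged assembly.
#' @param coding_genes Exon-level tibble of the reference coding genes
#'   (rows with `coding = TRUE` are used; all rows if the flag is absent).
#' @param repeats Repeat annotation tibble (see
#'   [read_repeat_annotation()]).
#' @param overlap_mode `"span_any_strand"` or `"exon_same_strand"`.
#' @return A tibble with one row per cryptic transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `exonic_bp`, `tss`, and
#'   the assignment columns `subfamily`, `family`, `repeat_class`,
#'   `repeat_start`, `repeat_end`, `repeat_strand`, `overlap_bp`.
#' @export
classify_cryptic <- function(transcripts, coding_genes, repeats,
                             overlap_mode = c("span_any_strand",
                                              "exon_same_strand")) {
  overlap_mode <- match.arg(overlap_mode)
  tx <- transcript_summary(transcripts)
  cand <- dplyr::filter(tx, !.data$coding)
  if ("coding" %in% names(coding_genes)) {
    coding_genes <- dplyr::filter(coding_genes, .data$coding)
  }
  if (nrow(cand) && nrow(coding_genes)) {
    if (overlap_mode == "span_any_strand") {
      gene_spans <- coding_genes |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                         end = max(.data$end), .groups = "drop")
      hit <- query_overlaps(dplyr::select(cand, "chrom", "start", "end"),
                            gene_spans)
      cand <- cand[setdiff(seq_len(nrow(cand)), unique(hit$x_idx)), ,
                   drop = FALSE]
    } else {
      cand_ex <- dplyr::semi_join(transcripts, cand, by = "transcript_id")
      hit <- query_overlaps(cand_ex, coding_genes, strand_mode = "same")
      excl <- unique(cand_ex$transcript_id[hit$x_idx])
      cand <- dplyr::filter(cand, !.data$transcript_id %in% excl)
    }
  }
  empty <- tibble::tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = numeric(), end = numeric(),
    exonic_bp = numeric(), tss = numeric(), subfamily = character(),
    family = character(), repeat_class = character(),
    repeat_start = numeric(), repeat_end = numeric(),
    repeat_strand = character(), overlap_bp = numeric())
  if (nrow(cand) == 0) return(empty)
  retro <- dplyr::filter(repeats, .data$repeat_class %in% retro_classes)
  if (nrow(retro) == 0) return(empty)
  cand_ex <- dplyr::semi_join(transcripts, cand, by = "transcript_id")
  ov <- query_overlaps(
    dplyr::select(cand_ex, "transcript_id", "chrom", "start", "end"),
    dplyr::mutate(retro, elem = dplyr::row_number()))
  if (nrow(ov) == 0) return(empty)
  assigned <- ov |>
    dplyr::group_by(.data$transcript_id, .data$elem) |>
    dplyr::summarise(overlap_bp = sum(.data$overlap_bp),
                     subfamily = .data$subfamily[1],
                     family = .data$family[1],
                     repeat_class = .data$repeat_class[1],
                     repeat_start = .data$start.y[1],
                     repeat_end = .data$end.y[1],
                     repeat_strand = .data$strand[1],
                     .groups = "drop") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(dplyr::desc(.data$overlap_bp), .data$repeat_start,
                   .data$subfamily, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  cand |>
    dplyr::inner_join(dplyr::select(assigned, -"elem"),
                      by = "transcript_id") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "start",
                  "end", "exonic_bp", "tss", "subfamily", "family",
                  "repeat_class", "repeat_start", "repeat_end",
                  "repeat_strand", "overlap_bp") |>
    dplyr::arrange(.data$transcript_id)
}

#' Flag HIF-associated cryptic transcripts
#'
#' A cryptic transcript is HIF-associated iff at least one peak summit
#' position falls within its promoter interval (half-open: the promoter
#' start is included, the end coordinate is not). A peak merely overlapping
#' the promoter with its summit outside does not qualify.
#'
#' @param cryptics Cryptic transcript tibble from [classify_cryptic()].
#' @param peaks Peak tibble with a `summit` column.
#' @param up,down,layout Promoter parameters, see [derive_promoter()].
#' @return `cryptics` plus logical `hif_bound` and the promoter interval
#'   (`promoter_start`, `promoter_end`).
#' @export
annotate_hif_bound <- function(cryptics, peaks, up = 2000, down = 500,
                               layout = NULL) {
  if (nrow(cryptics) == 0) {
    return(dplyr::mutate(cryptics, promoter_start = numeric(),
                         promoter_end = numeric(), hif_bound = logical()))
  }
  prom <- derive_promoter(cryptics, up = up, down = down, layout = layout)
  bound <- rep(FALSE, nrow(cryptics))
  if (nrow(peaks)) {
    summits <- tibble::tibble(chrom = peaks$chrom, start = peaks$summit,
                              end = peaks$summit + 1)
    hit <- query_overlaps(dplyr::select(prom, "chrom", "start", "end"),
                          summits)
    bound[unique(hit$x_idx)] <- TRUE
  }
  dplyr::mutate(cryptics, promoter_start = prom$start,
                promoter_end = prom$end, hif_bound = bound)
}
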