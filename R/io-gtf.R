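#' Read transcript models from a GTF file
#'
#' Parses exon features of a GTF (1-based, closed coordinates) into an
#' exon-level tibble in the package's internal convention (0-based,
#' half-open). Book-ended or overlapping exons of the same transcript are
#' merged. A transcript is flagged coding when its biotype is in
#' `coding_biotypes`; transcripts without a biotype attribute (typical for
#' de-novo assembled models) are noncoding.
#'
#' @param path Path to a GTF file.
#' @param coding_biotypes Character set of biotypes treated as coding.
#' @return A tibble with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `coding`.
#' @export
read_gtf <- function(path, coding_biotypes = "protein_coding") {
  empty <- tibble::tibble(transcript_id = character(), gene_id = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          coding = logical())
  first <- readLines(path, n = 100)
  if (!any(nzchar(first) & !startsWith(first, "#"))) return(empty)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", path, "': ",
                                          conditionMessage(e)))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) return(empty)
  m <- S4Vectors::mcols(gr)
  if (is.null(m$transcript_id) || anyNA(m$transcript_id)) {
    bad <- if (is.null(m$transcript_id)) seq_along(gr) else which(is.na(m$transcript_id))
    stop("GTF parse error: exon feature(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " lack a transcript_id attribute")
  }
  biotype <- m$transcript_biotype
  if (is.null(biotype)) biotype <- m$gene_biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))
  gene_id <- if (is.null(m$gene_id)) m$transcript_id else m$gene_id
  ex <- tibble::tibble(
    transcript_id = as.character(m$transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    coding = !is.na(biotype) & biotype %in% coding_biotypes
  )
  ex$strand[ex$strand == "*"] <- "."
  merge_bookended_exons(ex)
}

# Merge book-ended/overlapping exons within each transcript and sort.
merge_bookended_exons <- function(ex) {
  ex <- dplyr::arrange(ex, .data$transcript_id, .data$start)
  ex |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom,
                    .data$strand, .data$coding) |>
    dplyr::group_modify(function(d, key) {
      d$grp <- cumsum(c(TRUE, d$start[-1] > cummax(d$end)[-nrow(d)]))
      d |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         .groups = "drop") |>
        dplyr::select(-"grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand", "coding") |>
    dplyr::arrange(.data$transcript_id, .data$start)
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` row and one `exon` row per exon, converting the
#' internal 0-based half-open coordinates back to GTF's 1-based closed
#' convention. Reading the file back with [read_gtf()] reproduces the input.
#'
#' @param exons Exon-level tibble as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "credentor") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  if (nrow(exons) == 0) return(invisible(path))
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  per_tx <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
                     start = min(.data$start), end = max(.data$end),
                     strand = .data$strand[1], coding = .data$coding[1],
                     .groups = "drop")
  fmt_attr <- function(gene_id, transcript_id, coding) {
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            gene_id, transcript_id,
            ifelse(coding, "protein_coding", "noncoding"))
  }
  tx_lines <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      per_tx$chrom, source, per_tx$start + 1, per_tx$end,
                      ifelse(per_tx$strand %in% c("+", "-"), per_tx$strand, "."),
                      fmt_attr(per_tx$gene_id, per_tx$transcript_id, per_tx$coding))
  ex_lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                      exons$chrom, source, exons$start + 1, exons$end,
                      ifelse(exons$strand %in% c("+", "-"), exons$strand, "."),
                      fmt_attr(exons$gene_id, exons$transcript_id, exons$coding))
  ord <- order(match(c(per_tx$transcript_id, exons$transcript_id),
                     per_tx$transcript_id),
               c(rep(0L, nrow(per_tx)), seq_len(nrow(exons))))
  writeLines(c(tx_lines, ex_lines)[ord], con)
  invisible(path)
}

#' Summarise an exon table at transcript level
#'
#' Derives, per transcript, its genomic span, total exonic length and the
#' transcription start site (TSS): the 0-based first transcribed base, i.e.
#' the lowest start on the plus strand and the highest `end - 1` on the
#' minus strand.
#'
#' @param exons Exon-level tibble (see [read_gtf()]).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `coding`, `exonic_bp`, `n_exons`,
#'   `tss`. `tss` is `NA` for unstranded transcripts.
#' @export
transcript_summary <- function(exons) {
  exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      coding = .data$coding[1],
      exonic_bp = sum(.data$end - .data$start),
      n_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(tss = dplyr::case_when(
      .data$strand == "+" ~ .data$start,
      .data$strand == "-" ~ .data$end - 1,
      TRUE ~ NA_real_
    ))
}
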