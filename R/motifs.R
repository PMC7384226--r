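#' Scan a genome for HRE (RCGTG) motifs
#'
#' Finds every occurrence of the hypoxia response element consensus RCGTG
#' (R = A or G) on both strands. Minus-strand hits appear on the forward
#' genome as CACGY (Y = C or T). Overlapping hits are all reported, scanning
#' is case-insensitive, and N bases never match. The position of the C of
#' the core CpG dinucleotide is reported per hit (`cpg_pos`): offset +1
#' within plus-strand hits and +2 within minus-strand hits.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`,
#'   one entry per chromosome.
#' @return A tibble of motif hits: `chrom`, `start`, `end` (0-based
#'   half-open, always width 5), `strand`, `match` (forward-genome text),
#'   `cpg_pos`.
#' @examples
#' scan_rcgtg(c(chr = "AACGTGA")) # one plus-strand hit at [1, 6)
#' @export
scan_rcgtg <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences))) {
    stop("sequences must be named by chromosome")
  }
  purrr::imap_dfr(sequences, function(seq, chrom) {
    seq <- toupper(seq)
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", seq)
    if (bad > 0) {
      stop("non-IUPAC character '", substr(seq, bad, bad),
           "' at position ", bad, " of ", chrom)
    }
    hit_tbl <- function(pattern, strand) {
      m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      start <- as.numeric(m) - 1
      tibble::tibble(chrom = chrom, start = start, end = start + 5,
                     strand = strand,
                     match = substring(seq, start + 1, start + 5))
    }
    dplyr::bind_rows(hit_tbl("[AG]CGTG", "+"), hit_tbl("CACG[CT]", "-"))
  }) -> hits
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          match = character(), cpg_pos = numeric()))
  }
  hits |>
    dplyr::mutate(cpg_pos = .data$start + ifelse(.data$strand == "+", 1, 2)) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

#' Per-bp motif enrichment inside peaks
#'
#' Compares the per-bp frequency of motif hits inside peaks with the rate in
#' the rest of the genome. A hit counts as inside a peak iff the midpoint of
#' its interval lies within a (merged) peak.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param motifs Motif hit tibble from [scan_rcgtg()].
#' @param layout Genome layout giving total genome size.
#' @return A one-row tibble: `hits_in`, `bp_in`, `hits_out`, `bp_out`,
#'   `rate_in`, `rate_out`, `fold_enrichment` (`NA` with a warning when the
#'   outside rate is zero).
#' @export
motif_enrichment <- function(peaks, motifs, layout) {
  bp_in <- merged_bp(peaks)
  bp_total <- sum(layout$length)
  bp_out <- bp_total - bp_in
  mid <- tibble::tibble(chrom = motifs$chrom,
                        start = floor((motifs$start + motifs$end) / 2))
  mid$end <- mid$start + 1
  hits_in <- if (nrow(motifs)) {
    length(unique(query_overlaps(mid, peaks)$x_idx))
  } else 0L
  hits_out <- nrow(motifs) - hits_in
  rate_in <- if (bp_in > 0) hits_in / bp_in else NA_real_
  rate_out <- if (bp_out > 0) hits_out / bp_out else NA_real_
  fold <- if (!is.na(rate_out) && rate_out > 0) rate_in / rate_out else {
    warning("outside motif rate is zero; fold enrichment undefined")
    NA_real_
  }
  tibble::tibble(hits_in = hits_in, bp_in = bp_in, hits_out = hits_out,
                 bp_out = bp_out, rate_in = rate_in, rate_out = rate_out,
                 fold_enrichment = fold)
}

#' Stratify motif signal by CpG methylation
#'
#' Looks up, for every motif hit, the methylation beta at the C of its core
#' CpG (requiring bisulfite coverage above `min_coverage`), bins motifs by
#' beta, and reports the mean signal depth over the motif plus a flank for
#' each hit. This reproduces the inverse methylation/occupancy comparison:
#' with methylation repelling binding, bin mean signal decreases with beta.
#'
#' @param motifs Motif hits from [scan_rcgtg()].
#' @param methylation Methylation records (`chrom`, `pos`, `beta`,
#'   `coverage`); multiple samples are averaged per position.
#' @param coverage Signal coverage track (`chrom`, `start`, `end`, `depth`),
#'   e.g. ChIP read depth.
#' @param bins Numeric vector of beta bin edges.
#' @param flank Bp added on both sides of the motif when averaging signal.
#' @param min_coverage Minimum bisulfite coverage (exclusive) for a CpG
#'   record to be used; `NULL` disables the filter.
#' @return A tibble with one row per retained motif: the motif columns plus
#'   `beta`, `bin` (factor over `bins`), `signal`. Motifs without a
#'   qualifying CpG record are excluded.
#' @export
stratify_motifs_by_methylation <- function(motifs, methylation, coverage,
                                           bins = c(0, .2, .4, .6, .8, 1),
                                           flank = 100, min_coverage = 10) {
  meth <- methylation
  if (!is.null(min_coverage)) {
    meth <- dplyr::filter(meth, !is.na(.data$coverage),
                          .data$coverage > min_coverage)
  }
  meth <- meth |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop")
  keyed <- dplyr::left_join(
    dplyr::mutate(motifs, .row = dplyr::row_number()),
    meth, by = c(chrom = "chrom", cpg_pos = "pos"))
  keyed <- dplyr::filter(keyed, !is.na(.data$beta))
  if (nrow(keyed) == 0) {
    return(dplyr::mutate(keyed, bin = factor(character()), signal = numeric()))
  }
  win <- dplyr::transmute(keyed, chrom = .data$chrom,
                          start = pmax(0, .data$start - flank),
                          end = .data$end + flank)
  keyed$signal <- region_mean_depth(win, coverage)
  keyed$bin <- cut(keyed$beta, breaks = bins, include.lowest = TRUE)
  dplyr::select(keyed, -".row")
}
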