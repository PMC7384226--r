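# Small fixture builders shared across test files.

exon_tbl <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(transcript_id = r$id,
                   gene_id = sub("\\.T\\d+$", "", r$id),
                   chrom = r$chrom %||% "chr1",
                   start = r$starts, end = r$ends,
                   strand = r$strand %||% "+",
                   coding = r$coding %||% FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

repeat_tbl <- function(chrom, start, end, subfamily = "AluY",
                       family = "Alu", repeat_class = "SINE",
                       strand = "+", consensus_start = NA,
                       consensus_end = NA) {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 subfamily = subfamily, family = family,
                 repeat_class = repeat_class,
                 consensus_start = consensus_start,
                 consensus_end = consensus_end)
}

peak_tbl <- function(chrom, summit, width = 400) {
  tibble::tibble(chrom = chrom, start = summit - width / 2,
                 end = summit + width / 2, summit = summit)
}

# Coverage track with a constant background and per-peak summit windows at
# the depth giving the requested effective ratio (eps = 0.5, bg = 7.5 so
# the denominator is exactly 8).
ratio_coverage <- function(chrom_len, summits, ratios, bg = 7.5,
                           chrom = "chr1") {
  o <- order(summits)
  summits <- summits[o]; ratios <- ratios[o]
  w <- ratios * (bg + 0.5) - 0.5
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(chrom = chrom, start = c(0, summits + 100),
                   end = c(summits - 100, chrom_len), depth = bg),
    tibble::tibble(chrom = chrom, start = summits - 100,
                   end = summits + 100, depth = w)
  ), start)
}

# dense repeat/peak fixture used by the permutation calibration checks:
# per-class hit probability for a 400-bp peak is ~0.1 so the overlap
# fraction statistic has enough resolution
enrichment_fixture <- function(n_per_class = 120, seed = 1) {
  set.seed(seed)
  layout <- credentor::genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
  reps <- purrr::map_dfr(c("LTR", "LINE", "SINE"), function(cl) {
    ch <- sample(seq_len(2), n_per_class, replace = TRUE)
    st <- floor(stats::runif(n_per_class) * (layout$length[ch] - 450))
    repeat_tbl(layout$chrom[ch], st, st + 450, subfamily = cl, family = cl,
               repeat_class = cl, consensus_start = 0, consensus_end = 450)
  })
  list(layout = layout, repeats = reps)
}
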