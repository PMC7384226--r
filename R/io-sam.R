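#' Read aligned fragments from a SAM file
#'
#' Loads primary alignments and splits each into its aligned blocks
#' (CIGAR N gaps start a new block). Uniqueness is decided by
#' `unique_rule`: `"nh_tag"` flags a fragment unique when its NH tag is 1
#' (alignments without an NH tag are taken as unique); `"mapq_threshold"`
#' requires MAPQ >= `mapq` (default 255, the common "uniquely mapped"
#' sentinel). Unmapped, secondary and supplementary records are never
#' unique and are dropped.
#'
#' @param path Path to a SAM text file with a header (an `@SQ` line per
#'   reference is required).
#' @param unique_rule `"nh_tag"` or `"mapq_threshold"`.
#' @param mapq MAPQ threshold for `unique_rule = "mapq_threshold"`.
#' @return A tibble with one row per aligned block: `qname`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (of the originating
#'   fragment), `unique`.
#' @export
read_alignments <- function(path, unique_rule = c("nh_tag", "mapq_threshold"),
                            mapq = 255) {
  unique_rule <- match.arg(unique_rule)
  hdr <- readLines(path, n = 1000)
  if (!any(grepl("^@SQ", hdr))) {
    stop("SAM header lacks @SQ reference lines in '", path, "'")
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, tag = "NH",
                                   what = c("qname", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0) {
    return(tibble::tibble(qname = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character(), unique = logical()))
  }
  nh <- S4Vectors::mcols(ga)$NH
  uni <- if (unique_rule == "nh_tag") {
    is.na(nh) | nh == 1
  } else {
    mq <- S4Vectors::mcols(ga)$mapq
    !is.na(mq) & mq >= mapq
  }
  blocks <- GenomicAlignments::grglist(ga) # CIGAR N splits ranges
  nb <- S4Vectors::elementNROWS(blocks)
  fb <- unlist(blocks, use.names = FALSE)
  tibble::tibble(
    qname = rep(S4Vectors::mcols(ga)$qname, nb),
    chrom = as.character(GenomicRanges::seqnames(fb)),
    start = GenomicRanges::start(fb) - 1,
    end = as.numeric(GenomicRanges::end(fb)),
    strand = rep(as.character(GenomicAlignments::strand(ga)), nb),
    unique = rep(uni, nb)
  )
}

#' Write aligned fragments as SAM text
#'
#' Inverse convenience for [read_alignments()], used mainly by the
#' synthetic-data generator. Blocks of a fragment are joined with N gaps in
#' the CIGAR; each fragment becomes a single-end primary alignment with an
#' NH tag.
#'
#' @param fragments Block-level tibble (`qname`, `chrom`, `start`, `end`,
#'   `strand`, `unique`); non-unique fragments are written with `NH:i:2`.
#' @param layout Genome layout for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(fragments, layout, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                       as.integer(layout$length))), con)
  if (nrow(fragments) == 0) return(invisible(path))
  recs <- fragments |>
    dplyr::arrange(.data$qname, .data$start) |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      pos = min(.data$start) + 1,
      flag = ifelse(.data$strand[1] == "-", 16L, 0L),
      cigar = {
        w <- .data$end - .data$start
        gap <- .data$start[-1] - .data$end[-length(.data$end)]
        parts <- sprintf("%dM", w)
        if (length(gap)) {
          parts <- c(rbind(parts[-length(parts)], sprintf("%dN", gap)),
                     parts[length(parts)])
        }
        paste(parts, collapse = "")
      },
      seqlen = sum(.data$end - .data$start),
      nh = ifelse(.data$unique[1], 1L, 2L),
      .groups = "drop"
    )
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d",
                     recs$qname, recs$flag, recs$chrom, as.integer(recs$pos),
                     ifelse(recs$nh == 1L, 255L, 1L), recs$cigar,
                     strrep("A", recs$seqlen), recs$nh), con)
  invisible(path)
}
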