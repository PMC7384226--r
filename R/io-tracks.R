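narrowpeak_extra <- c(signal_value = "numeric", p_value = "numeric",
                      q_value = "numeric", peak = "integer")

#' Read ENCODE narrowPeak files
#'
#' Parses the 10-column narrowPeak dialect of BED. The summit is derived
#' from the column-10 offset relative to the peak start; an offset of -1
#' (summit not called) falls back to the interval midpoint. Records whose
#' summit falls outside the peak interval are rejected with a warning.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`, `summit` (0-based
#'   genomic position).
#' @export
read_narrowpeak <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED", extraCols = narrowpeak_extra),
    error = function(e) stop("narrowPeak format error in '", path, "': ",
                             conditionMessage(e))
  )
  m <- S4Vectors::mcols(gr)
  pk <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    name = if (is.null(m$name)) "." else as.character(m$name),
    score = if (is.null(m$score)) 0 else as.numeric(m$score),
    strand = as.character(GenomicRanges::strand(gr)),
    signal_value = as.numeric(m$signal_value),
    p_value = as.numeric(m$p_value),
    q_value = as.numeric(m$q_value),
    peak_offset = as.integer(m$peak)
  )
  pk$strand[pk$strand == "*"] <- "."
  pk$name[is.na(pk$name)] <- "."
  pk$summit <- ifelse(pk$peak_offset < 0,
                      floor((pk$start + pk$end) / 2),
                      pk$start + pk$peak_offset)
  bad <- pk$summit < pk$start | pk$summit >= pk$end
  if (any(bad)) {
    warning(sum(bad), " narrowPeak record(s) rejected: summit outside interval")
    pk <- pk[!bad, , drop = FALSE]
  }
  dplyr::select(pk, -"peak_offset")
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param peaks Peak tibble (see [read_narrowpeak()]); only `chrom`, `start`,
#'   `end` and `summit` are required, remaining columns default.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  col <- function(nm, default) if (nm %in% names(peaks)) peaks[[nm]] else rep(default, n)
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%g\t%g\t%g\t%d",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   col("name", "."), col("score", 0),
                   col("strand", "."), col("signal_value", 0),
                   col("p_value", -1), col("q_value", -1),
                   as.integer(peaks$summit - peaks$start))
  writeLines(lines, path)
  invisible(path)
}

#' Read plain BED regions
#'
#' BED3+ reader for exclusion sets, open-chromatin regions and similar
#' carriers. Overlapping rows are preserved as-is (no merging).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name`, `score`, `strand`.
#' @export
read_bed_regions <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("BED parse error in '", path, "': ",
                                          conditionMessage(e)))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
  m <- S4Vectors::mcols(gr)
  if (!is.null(m$name) && !all(is.na(m$name))) out$name <- as.character(m$name)
  if (!is.null(m$score) && !all(is.na(m$score))) out$score <- as.numeric(m$score)
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) { s[s == "*"] <- "."; out$strand <- s }
  out
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (`chrom start end depth`, 0-based
#'   half-open).
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("bedGraph parse error in '", path,
                                          "': ", conditionMessage(e)))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    depth = as.numeric(S4Vectors::mcols(gr)$score)
  )
}

#' Write a bedGraph coverage track
#'
#' @param coverage Tibble with columns `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", coverage$chrom,
                     as.integer(coverage$start), as.integer(coverage$end),
                     coverage$depth), path)
  invisible(path)
}
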