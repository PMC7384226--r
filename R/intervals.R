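#' Define a genome layout
#'
#' A genome layout is the minimal description of the coordinate space all
#' interval operations live in: an ordered set of chromosome names and their
#' lengths in bp. It is the substrate for whole-genome quantities such as the
#' per-bp motif rate and the placeable space of the peak shuffler.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' Read a chrom.sizes file as a genome layout
#'
#' @param path Path to a two-column `<chrom>\\t<length>` file.
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

# Internal: convert an interval tibble (chrom/start/end[/strand], 0-based
# half-open) into a GRanges. Strand "." or missing maps to "*".
as_gr <- function(x, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  strand <- if ("strand" %in% names(x)) x$strand else rep("*", nrow(x))
  strand[is.na(strand) | strand == "."] <- "*"
  seqinfo <- NULL
  if (!is.null(layout)) {
    seqinfo <- GenomicRanges::Seqinfo(seqnames = layout$chrom,
                                      seqlengths = as.integer(layout$length))
  }
  if (nrow(x) == 0) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(seqinfo)) GenomicRanges::seqinfo(gr) <- seqinfo
    return(gr)
  }
  validate_intervals(x, layout)
  suppressWarnings(GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand,
    seqinfo = seqinfo
  ))
}

validate_intervals <- function(x, layout = NULL) {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if (!is.null(layout)) {
    len <- layout$length[match(x$chrom, layout$chrom)]
    bad <- which(!is.na(len) & x$end > len)
    if (length(bad)) {
      stop("interval(s) beyond chromosome end at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(x)
}

#' Find overlapping intervals between two sets
#'
#' Reports every pair of intervals with at least one bp of overlap under
#' half-open semantics (touching intervals do not overlap), together with the
#' width of the intersection. Strand can be ignored, required equal, or
#' required opposite.
#'
#' @param x,y Data frames with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param strand_mode One of `"ignore"`, `"same"`, `"opposite"`.
#' @param suffix Length-2 character suffixes for disambiguating shared column
#'   names of `x` and `y` in the output.
#' @return A tibble with one row per overlapping pair: all columns of the two
#'   inputs (suffixed where they clash), the row indices `x_idx`, `y_idx`,
#'   and `overlap_bp`. A query chromosome absent from `y` simply yields no
#'   rows.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = c(150, 200), end = c(250, 300))
#' query_overlaps(a, b) # one pair, 50 bp; the touching interval is not hit
#' @export
query_overlaps <- function(x, y, strand_mode = c("ignore", "same", "opposite"),
                           suffix = c(".x", ".y")) {
  strand_mode <- match.arg(strand_mode)
  gx <- as_gr(x)
  gy <- as_gr(y)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gx, gy, ignore.strand = TRUE))
  xi <- S4Vectors::queryHits(hits)
  yi <- S4Vectors::subjectHits(hits)
  if (strand_mode != "ignore" && length(xi)) {
    sx <- as.character(GenomicRanges::strand(gx))[xi]
    sy <- as.character(GenomicRanges::strand(gy))[yi]
    keep <- if (strand_mode == "same") sx == sy else
      (sx == "+" & sy == "-") | (sx == "-" & sy == "+")
    xi <- xi[keep]; yi <- yi[keep]
  }
  ov <- pmin(x$end[xi], y$end[yi]) - pmax(x$start[xi], y$start[yi])
  shared <- intersect(names(x), names(y))
  xs <- x; ys <- y
  names(xs)[match(shared, names(xs))] <- paste0(shared, suffix[1])
  names(ys)[match(shared, names(ys))] <- paste0(shared, suffix[2])
  out <- dplyr::bind_cols(
    xs[xi, , drop = FALSE],
    ys[yi, , drop = FALSE],
    tibble::tibble(x_idx = xi, y_idx = yi, overlap_bp = as.numeric(ov))
  )
  tibble::as_tibble(out)
}

#' Distance from query points to the nearest feature
#'
#' For each query point, finds the nearest feature interval on the same
#' chromosome and the distance in bp (0 when the point lies inside a
#' feature). Ties are broken toward the feature with the lower start
#' coordinate, so results are deterministic.
#'
#' @param points Data frame with columns `chrom` and `pos` (0-based bp).
#' @param features Data frame with columns `chrom`, `start`, `end`.
#' @return A tibble with one row per point: `chrom`, `pos`, `feature_idx`
#'   (row index into `features`, `NA` when the chromosome holds no feature)
#'   and `distance`.
#' @export
nearest_feature_distance <- function(points, features) {
  n <- nrow(points)
  out <- tibble::tibble(chrom = points$chrom, pos = points$pos,
                        feature_idx = rep(NA_integer_, n),
                        distance = rep(NA_real_, n))
  if (n == 0 || nrow(features) == 0) return(out)
  gp <- GenomicRanges::GRanges(points$chrom,
                               IRanges::IRanges(points$pos + 1L, width = 1L))
  gf <- as_gr(features)
  hits <- GenomicRanges::distanceToNearest(gp, gf, select = "all",
                                           ignore.strand = TRUE)
  if (!length(hits)) return(out)
  h <- tibble::tibble(p = S4Vectors::queryHits(hits),
                      f = S4Vectors::subjectHits(hits),
                      d = S4Vectors::mcols(hits)$distance)
  # distanceToNearest() counts one intervening bp between abutting ranges as
  # distance 0; recompute the plain bp gap so a point one base past an end
  # has distance 1, and break ties by lower feature start.
  h$d <- pmax(0, pmax(features$start[h$f] - points$pos[h$p],
                      points$pos[h$p] - (features$end[h$f] - 1)))
  h <- h[order(h$p, h$d, features$start[h$f]), ]
  h <- h[!duplicated(h$p), ]
  out$feature_idx[h$p] <- h$f
  out$distance[h$p] <- h$d
  out
}

# Internal: total bp covered by a set of intervals after merging overlaps.
merged_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(as_gr(x), ignore.strand = TRUE)))
}
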