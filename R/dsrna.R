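#' Flag transcripts with sense-antisense dsRNA potential
#'
#' A transcript is flagged when its transcription overlaps a transcript
#' expressed from the complementary strand: at least `min_overlap` bp of
#' exonic (default) or span overlap with any partner transcript on the
#' opposite strand. The partner set defaults to the transcripts themselves
#' (coding partners included); the relation is symmetric.
#'
#' @param transcripts Exon-level tibble of the transcripts to flag.
#' @param partners Exon-level tibble of potential antisense partners;
#'   default `transcripts`.
#' @param min_overlap Minimum overlap in bp.
#' @param overlap_basis `"exonic"` or `"span"`.
#' @return A tibble `transcript_id`, `sense_antisense` (logical).
#' @export
flag_sense_antisense <- function(transcripts, partners = NULL,
                                 min_overlap = 1,
                                 overlap_basis = c("exonic", "span")) {
  overlap_basis <- match.arg(overlap_basis)
  if (is.null(partners)) partners <- transcripts
  if (any(!transcripts$strand %in% c("+", "-")) ||
      any(!partners$strand %in% c("+", "-"))) {
    stop("sense-antisense flagging requires stranded transcripts")
  }
  pick <- function(ex) {
    if (overlap_basis == "exonic") {
      dplyr::select(ex, "transcript_id", "chrom", "start", "end", "strand")
    } else {
      ex |>
        dplyr::group_by(.data$transcript_id) |>
        dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                         end = max(.data$end), strand = .data$strand[1],
                         .groups = "drop")
    }
  }
  a <- pick(transcripts)
  b <- pick(partners)
  ov <- query_overlaps(a, b, strand_mode = "opposite")
  flagged <- if (nrow(ov)) {
    ov |>
      dplyr::filter(.data$transcript_id.x != .data$transcript_id.y) |>
      dplyr::group_by(.data$transcript_id.x, .data$transcript_id.y) |>
      dplyr::summarise(bp = sum(.data$overlap_bp), .groups = "drop") |>
      dplyr::filter(.data$bp >= min_overlap) |>
      dplyr::pull(.data$transcript_id.x) |>
      unique()
  } else character()
  ids <- unique(transcripts$transcript_id)
  tibble::tibble(transcript_id = ids,
                 sense_antisense = ids %in% flagged)
}

#' Flag transcripts containing palindromic repeat pairs
#'
#' A transcript is flagged when its exons overlap at least two elements of
#' the same repeat subfamily in opposite orientations (i.e. with differing
#' repeat strands) -- the inverted-repeat configuration from which an
#' intramolecular RNA duplex can fold.
#'
#' @param transcripts Exon-level tibble.
#' @param repeats Repeat annotation with element strands.
#' @return A tibble `transcript_id`, `palindromic` (logical).
#' @export
flag_palindromic <- function(transcripts, repeats) {
  ids <- unique(transcripts$transcript_id)
  ov <- query_overlaps(
    dplyr::select(transcripts, "transcript_id", "chrom", "start", "end"),
    dplyr::mutate(dplyr::select(repeats, "chrom", "start", "end", "strand",
                                "subfamily"),
                  elem = dplyr::row_number()))
  flagged <- if (nrow(ov)) {
    ov |>
      dplyr::distinct(.data$transcript_id, .data$subfamily, .data$elem,
                      .data$strand) |>
      dplyr::group_by(.data$transcript_id, .data$subfamily) |>
      dplyr::summarise(both = dplyr::n_distinct(.data$strand) >= 2,
                       .groups = "drop") |>
      dplyr::filter(.data$both) |>
      dplyr::pull(.data$transcript_id) |>
      unique()
  } else character()
  tibble::tibble(transcript_id = ids, palindromic = ids %in% flagged)
}

# Pearson chi-square on a 2x2 table, no continuity correction.
chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e < 1)) warning("expected cell count < 1; chi-square unreliable")
  stat <- sum((tab - e)^2 / e)
  c(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare dsRNA-potential fractions between two transcript groups
#'
#' For each flag category (sense-antisense, palindromic) builds the 2x2
#' table of flagged/unflagged counts in the two groups and computes the
#' Pearson chi-square statistic (df = 1, no continuity correction).
#'
#' @param flags_a,flags_b Flag tibbles for the two groups, each holding
#'   logical columns among `sense_antisense` and `palindromic` (e.g. the
#'   joined outputs of [flag_sense_antisense()] and [flag_palindromic()]).
#' @return A tibble with one row per category: `category`, `frac_a`,
#'   `frac_b`, `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
compare_dsrna_fractions <- function(flags_a, flags_b) {
  if (nrow(flags_a) == 0 || nrow(flags_b) == 0) {
    stop("both groups must be non-empty")
  }
  cats <- intersect(c("sense_antisense", "palindromic"),
                    intersect(names(flags_a), names(flags_b)))
  purrr::map_dfr(cats, function(cat) {
    a <- flags_a[[cat]]; b <- flags_b[[cat]]
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    cs <- chisq_2x2(tab)
    tibble::tibble(category = cat, frac_a = mean(a), frac_b = mean(b),
                   n_a = length(a), n_b = length(b),
                   statistic = unname(cs["statistic"]),
                   p_value = unname(cs["p"]))
  })
}
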