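#' Filter transcripts on expression support
#'
#' Keeps a row iff its count exceeds 10 in at least one sample and its RPKM
#' exceeds 1 in at least one sample (not necessarily the same one). Both
#' thresholds are strict.
#'
#' @param counts Count-matrix tibble (`feature_id`, `length_bp`, one column
#'   per sample).
#' @param lib_sizes Optional named numeric of library sizes per sample;
#'   defaults to column totals (total assigned reads).
#' @param min_count,min_rpkm Strict thresholds.
#' @return A tibble `feature_id`, `max_count`, `max_rpkm`, `kept`.
#' @export
filter_expressed <- function(counts, lib_sizes = NULL, min_count = 10,
                             min_rpkm = 1) {
  m <- count_mat(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes == 0)) stop("zero library size")
  lib_sizes <- lib_sizes[colnames(m)]
  rpkm <- sweep(m / (counts$length_bp / 1000), 2, lib_sizes / 1e6, "/")
  max_count <- unname(apply(m, 1, max))
  max_rpkm <- unname(apply(rpkm, 1, max))
  tibble::tibble(
    feature_id = counts$feature_id,
    max_count = max_count,
    max_rpkm = max_rpkm,
    kept = max_count > min_count & max_rpkm > min_rpkm
  )
}

#' Normalise a count matrix
#'
#' Three conventions: `tpm_offset` length-normalises to transcripts per
#' million and adds a 0.01 offset (columns sum to 1e6 before the offset);
#' `rpkm` is reads per kb per million; `cpm_log` is
#' `log2(1e6 * count / library + offset)` with offset 1.
#'
#' @param counts Count-matrix tibble.
#' @param mode `"tpm_offset"`, `"rpkm"` or `"cpm_log"`.
#' @param lib_sizes Optional named library sizes; default column totals.
#' @param offset Offset added after (tpm) or inside the log (cpm_log).
#' @return A tibble of the same shape with normalised values.
#' @export
normalize_expression <- function(counts,
                                 mode = c("tpm_offset", "rpkm", "cpm_log"),
                                 lib_sizes = NULL, offset = NULL) {
  mode <- match.arg(mode)
  m <- count_mat(counts)
  if (mode %in% c("tpm_offset", "rpkm")) {
    if (any(counts$length_bp <= 0)) stop("zero-length feature")
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  lib_sizes <- lib_sizes[colnames(m)]
  v <- switch(mode,
    tpm_offset = {
      if (is.null(offset)) offset <- 0.01
      rate <- m / counts$length_bp
      sweep(rate, 2, colSums(rate), "/") * 1e6 + offset
    },
    rpkm = sweep(m / (counts$length_bp / 1000), 2, lib_sizes / 1e6, "/"),
    cpm_log = {
      if (is.null(offset)) offset <- 1
      log2(sweep(m, 2, lib_sizes / 1e6, "/") + offset)
    })
  out <- tibble::tibble(feature_id = counts$feature_id,
                        length_bp = counts$length_bp)
  for (s in colnames(v)) out[[s]] <- unname(v[, s])
  out
}

#' Cryptic transcription load per sample
#'
#' The total cryptic transcript read count divided by the total coding gene
#' read count of each sample.
#'
#' @param counts Count-matrix tibble.
#' @param cryptic_ids,coding_ids Disjoint feature id sets.
#' @return A tibble `sample`, `cryptic_total`, `coding_total`, `load`
#'   (`NA` with a warning when the coding total is zero).
#' @export
cryptic_load <- function(counts, cryptic_ids, coding_ids) {
  if (length(intersect(cryptic_ids, coding_ids))) {
    stop("cryptic and coding id sets must be disjoint")
  }
  m <- count_mat(counts)
  cry <- colSums(m[rownames(m) %in% cryptic_ids, , drop = FALSE])
  cod <- colSums(m[rownames(m) %in% coding_ids, , drop = FALSE])
  if (any(cod == 0)) warning("coding total is zero for some sample(s); load undefined")
  tibble::tibble(sample = colnames(m), cryptic_total = unname(cry),
                 coding_total = unname(cod),
                 load = unname(ifelse(cod > 0, cry / cod, NA_real_)))
}

#' Aggregate cryptic counts into retrotransposon subfamilies
#'
#' Sums cryptic transcript counts by their assigned repeat subfamily;
#' column totals over the aggregated rows equal the totals over the member
#' rows.
#'
#' @param counts Count-matrix tibble.
#' @param assignments Tibble mapping `transcript_id` (matched against
#'   `feature_id`) to `subfamily`, e.g. the output of
#'   [classify_cryptic()].
#' @return A count-matrix tibble with `feature_id` = subfamily and
#'   `length_bp` = NA.
#' @export
aggregate_by_subfamily <- function(counts, assignments) {
  sub <- assignments$subfamily[match(counts$feature_id,
                                     assignments$transcript_id)]
  keep <- !is.na(sub)
  m <- count_mat(counts)[keep, , drop = FALSE]
  agg <- rowsum(m, group = sub[keep])
  out <- tibble::tibble(feature_id = rownames(agg), length_bp = NA_real_)
  for (s in colnames(agg)) out[[s]] <- unname(agg[, s])
  dplyr::arrange(out, .data$feature_id)
}
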