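# Mean depth of a coverage track over query regions; bases without coverage
# rows count as depth 0. Vectorised over regions via run-length encodings.
region_mean_depth <- function(regions, coverage) {
  n <- nrow(regions)
  out <- numeric(n)
  if (n == 0) return(out)
  width <- regions$end - regions$start
  if (any(width <= 0)) stop("regions must have positive width")
  cov_by_chrom <- split(coverage, coverage$chrom)
  idx_by_chrom <- split(seq_len(n), regions$chrom)
  for (chrom in names(idx_by_chrom)) {
    idx <- idx_by_chrom[[chrom]]
    cv <- cov_by_chrom[[chrom]]
    if (is.null(cv) || nrow(cv) == 0) next
    rle <- IRanges::coverage(IRanges::IRanges(cv$start + 1, cv$end),
                             weight = cv$depth)
    s1 <- pmax(1, regions$start[idx] + 1)
    e1 <- pmin(length(rle), regions$end[idx])
    ok <- which(s1 <= e1)
    if (!length(ok)) next
    sums <- sum(IRanges::Views(rle, start = s1[ok], end = e1[ok]))
    out[idx[ok]] <- sums / width[idx][ok]
  }
  out
}

#' Call per-sample peak presence against local background
#'
#' Implements the presence/absence rule for cross-sample ChIP comparisons:
#' the mean coverage over a `window`-bp window centred on the summit is
#' compared with the local background, defined as the mean read depth over
#' the regions `bg_flank[1]`–`bg_flank[2]` bp up- and downstream of the peak
#' interval (both sides pooled). With
#' `ratio = (window_mean + eps) / (background_mean + eps)`, a peak is
#' `present` when ratio > `fold_present`, `absent` when ratio <
#' `fold_absent`, and `unclassified` in between (boundary values included).
#'
#' @param peaks Peak tibble with a `summit` column (see
#'   [read_narrowpeak()]).
#' @param coverage Coverage track tibble (`chrom`, `start`, `end`, `depth`).
#' @param window Width in bp of the summit-centred window.
#' @param bg_flank Length-2 numeric, inner and outer background flank
#'   distances in bp.
#' @param eps Pseudodepth guarding zero background.
#' @param fold_present,fold_absent Strict thresholds on the ratio.
#' @param layout Optional genome layout used to clamp windows at chromosome
#'   edges (a truncated window raises a warning and is computed on the
#'   available bases).
#' @return The peak tibble plus `window_mean`, `background_mean`, `ratio`
#'   and `status` (`present`/`absent`/`unclassified`).
#' @export
classify_peak_presence <- function(peaks, coverage, window = 200,
                                   bg_flank = c(1500, 5000), eps = 0.5,
                                   fold_present = 4, fold_absent = 2.5,
                                   layout = NULL) {
  half <- window / 2
  chrom_len <- if (is.null(layout)) {
    stats::setNames(rep(Inf, length(unique(peaks$chrom))), unique(peaks$chrom))
  } else stats::setNames(layout$length, layout$chrom)
  len <- unname(chrom_len[peaks$chrom])
  win <- tibble::tibble(chrom = peaks$chrom,
                        start = pmax(0, peaks$summit - half),
                        end = pmin(len, peaks$summit + half))
  truncated <- win$end - win$start < window
  if (any(truncated)) {
    warning("summit window truncated at chromosome edge for ",
            sum(truncated), " peak(s)")
  }
  window_mean <- region_mean_depth(win, coverage)

  bg_regions <- dplyr::bind_rows(
    tibble::tibble(peak = seq_len(nrow(peaks)), chrom = peaks$chrom,
                   start = pmax(0, peaks$start - bg_flank[2]),
                   end = pmax(0, peaks$start - bg_flank[1])),
    tibble::tibble(peak = seq_len(nrow(peaks)), chrom = peaks$chrom,
                   start = pmin(len, peaks$end + bg_flank[1]),
                   end = pmin(len, peaks$end + bg_flank[2]))
  ) |>
    dplyr::filter(.data$end > .data$start)
  bg_regions$depth_sum <- region_mean_depth(bg_regions, coverage) *
    (bg_regions$end - bg_regions$start)
  bg <- bg_regions |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(background_mean = sum(.data$depth_sum) /
                       sum(.data$end - .data$start), .groups = "drop")
  background_mean <- rep(0, nrow(peaks))
  background_mean[bg$peak] <- bg$background_mean

  ratio <- (window_mean + eps) / (background_mean + eps)
  status <- dplyr::case_when(
    ratio > fold_present ~ "present",
    ratio < fold_absent ~ "absent",
    TRUE ~ "unclassified"
  )
  dplyr::mutate(peaks, window_mean = window_mean,
                background_mean = background_mean,
                ratio = ratio, status = status)
}

#' Compare peak presence across samples
#'
#' Calls presence per sample over a union peak list and categorises each
#' peak: `shared` when present in every sample, `unique(<sample>)` when
#' present in exactly one sample and absent in all others, otherwise
#' `unclassified`. The categories partition the union list.
#'
#' @param peaks Union peak tibble with `summit`.
#' @param coverage_by_sample Named list of coverage tibbles, one per sample
#'   (at least two).
#' @param ... Passed on to [classify_peak_presence()].
#' @return The peak tibble plus one `status_<sample>` column per sample and
#'   a `category` column.
#' @export
compare_peak_sets <- function(peaks, coverage_by_sample, ...) {
  if (length(coverage_by_sample) < 2) {
    stop("compare_peak_sets needs coverage for at least two samples")
  }
  samples <- names(coverage_by_sample)
  status <- purrr::map(coverage_by_sample, function(cv) {
    classify_peak_presence(peaks, cv, ...)$status
  })
  smat <- do.call(cbind, status)
  category <- apply(smat, 1, function(s) {
    if (all(s == "present")) return("shared")
    if (sum(s == "present") == 1 && all(s[s != "present"] == "absent")) {
      return(paste0("unique(", samples[s == "present"], ")"))
    }
    "unclassified"
  })
  out <- peaks
  for (s in samples) out[[paste0("status_", s)]] <- smat[, s]
  out$category <- category
  out
}

#' Mean methylation at peaks
#'
#' Averages CpG betas over each peak, either across the whole peak interval
#' or a summit +/- 100 bp window, after requiring bisulfite coverage above
#' `min_coverage`. Peaks without a qualifying CpG get `NA`.
#'
#' @param peaks Peak tibble (with `summit` for the windowed mode).
#' @param methylation Methylation records (`chrom`, `pos`, `beta`,
#'   `coverage`).
#' @param min_coverage Exclusive coverage threshold; `NULL` disables the
#'   filter (e.g. for array probes without a coverage field).
#' @param mode `"whole_peak"` or `"summit100"` (summit +/- 100 bp).
#' @return The peak tibble plus `n_cpgs` and `mean_beta`.
#' @export
methylation_at_peaks <- function(peaks, methylation, min_coverage = 40,
                                 mode = c("whole_peak", "summit100")) {
  mode <- match.arg(mode)
  meth <- methylation
  if (!is.null(min_coverage)) {
    meth <- dplyr::filter(meth, !is.na(.data$coverage),
                          .data$coverage > min_coverage)
  }
  regions <- if (mode == "whole_peak") {
    dplyr::select(peaks, "chrom", "start", "end")
  } else {
    tibble::tibble(chrom = peaks$chrom, start = pmax(0, peaks$summit - 100),
                   end = peaks$summit + 100)
  }
  cpgs <- tibble::tibble(chrom = meth$chrom, start = meth$pos,
                         end = meth$pos + 1, beta = meth$beta)
  ov <- query_overlaps(regions, cpgs)
  stat <- ov |>
    dplyr::group_by(.data$x_idx) |>
    dplyr::summarise(n_cpgs = dplyr::n(), mean_beta = mean(.data$beta),
                     .groups = "drop")
  out <- dplyr::mutate(peaks, n_cpgs = 0L, mean_beta = NA_real_)
  out$n_cpgs[stat$x_idx] <- stat$n_cpgs
  out$mean_beta[stat$x_idx] <- stat$mean_beta
  out
}
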