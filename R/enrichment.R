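#' Randomly shuffle peaks across the genome
#'
#' Generates `n_permutations` random placements of the observed peak set.
#' Each peak keeps its length and summit offset; the target chromosome is
#' drawn proportionally to its length and the position uniformly within
#' it. Draws overlapping an excluded ("poorly mapping") region are
#' discarded from that permutation, so permuted set sizes may shrink
#' (recorded in the `perm` column); a `redraw` policy re-samples instead.
#' In `distal_matched` mode only peaks whose observed summit is distal
#' (outside every promoter window) are shuffled, and shuffled draws whose
#' summit lands inside a promoter window are discarded or redrawn.
#'
#' @param peaks Peak tibble with `summit`.
#' @param layout Genome layout.
#' @param n_permutations Number of permuted sets.
#' @param excluded Optional tibble of regions whose overlap invalidates a
#'   draw.
#' @param mode `"genome_wide"` or `"distal_matched"`.
#' @param promoters Promoter windows (required for `distal_matched`), e.g.
#'   from [derive_promoter()].
#' @param discard_policy `"discard"` (shrink the permuted set, the default)
#'   or `"redraw"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of permuted peaks: `perm` (1..n), `peak` (index into
#'   the shuffled subset of `peaks`), `chrom`, `start`, `end`, `summit`.
#' @export
shuffle_peaks <- function(peaks, layout, n_permutations = 10000,
                          excluded = NULL,
                          mode = c("genome_wide", "distal_matched"),
                          promoters = NULL,
                          discard_policy = c("discard", "redraw"),
                          seed = NULL) {
  mode <- match.arg(mode)
  discard_policy <- match.arg(discard_policy)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "distal_matched") {
    if (is.null(promoters)) stop("distal_matched mode needs promoter windows")
    peaks <- peaks[peak_is_distal(peaks, promoters), , drop = FALSE]
  }
  n <- nrow(peaks)
  if (n == 0) stop("no peaks to shuffle")
  w <- peaks$end - peaks$start
  soff <- peaks$summit - peaks$start
  if (all(layout$length < min(w))) stop("no chromosome can host the peaks")

  # one batched draw for a set of (perm, peak) slots
  draw <- function(perm, idx) {
    k <- length(idx)
    ci <- sample.int(nrow(layout), k, replace = TRUE, prob = layout$length)
    space <- layout$length[ci] - w[idx]
    start <- floor(stats::runif(k) * (space + 1))
    d <- tibble::tibble(perm = perm, peak = idx, chrom = layout$chrom[ci],
                        start = start, end = start + w[idx],
                        summit = start + soff[idx])
    d[space >= 0, , drop = FALSE]
  }
  valid <- function(d) {
    bad <- rep(FALSE, nrow(d))
    if (!is.null(excluded) && nrow(excluded) && nrow(d)) {
      hit <- query_overlaps(dplyr::select(d, "chrom", "start", "end"),
                            excluded)
      bad[unique(hit$x_idx)] <- TRUE
    }
    if (mode == "distal_matched" && nrow(d)) {
      bad <- bad | !peak_is_distal(d, promoters)
    }
    !bad
  }

  d <- draw(rep(seq_len(n_permutations), each = n),
            rep.int(seq_len(n), n_permutations))
  keep <- valid(d)
  if (discard_policy == "discard") {
    d <- d[keep, , drop = FALSE]
  } else {
    for (it in 1:100) {
      if (all(keep)) break
      redo <- draw(d$perm[!keep], d$peak[!keep])
      d <- dplyr::bind_rows(d[keep, , drop = FALSE], redo)
      keep <- valid(d)
    }
    d <- d[keep, , drop = FALSE]
  }
  dplyr::arrange(d, .data$perm, .data$peak)
}

# TRUE for peaks whose summit lies outside every promoter window.
peak_is_distal <- function(peaks, promoters) {
  distal <- rep(TRUE, nrow(peaks))
  if (nrow(promoters) == 0 || nrow(peaks) == 0) return(distal)
  summits <- tibble::tibble(chrom = peaks$chrom, start = peaks$summit,
                            end = peaks$summit + 1)
  hit <- query_overlaps(summits,
                        dplyr::select(promoters, "chrom", "start", "end"))
  distal[unique(hit$x_idx)] <- FALSE
  distal
}

#' Permutation enrichment of peaks in repeat classes
#'
#' For each repeat class, compares the observed fraction of peaks
#' overlapping (>= 1 bp) at least one element of the class with the null
#' distribution of that fraction over permuted peak sets. The empirical
#' p-value uses the add-one estimator `(1 + #\{null >= obs\}) / (1 + N)`.
#' A two-sided Fisher exact test is additionally computed on the 2x2 table
#' of observed vs pooled-null in/out peak counts.
#'
#' @param peaks Observed peak tibble.
#' @param repeats Repeat annotation tibble.
#' @param shuffles Permuted peaks from [shuffle_peaks()].
#' @param classes Repeat classes to report.
#' @return A tibble with one row per class: `repeat_class`, `n_peaks`,
#'   `observed_fraction`, `null_mean`, `null_sd`, `p_empirical`,
#'   `fisher_p`, `odds_ratio`, `n_permutations`.
#' @export
repeat_class_enrichment <- function(peaks, repeats, shuffles,
                                    classes = c("LTR", "LINE", "SINE")) {
  if (nrow(peaks) == 0) stop("no observed peaks")
  n_perm <- max(shuffles$perm)
  perm_sizes <- dplyr::count(shuffles, .data$perm, name = "size")
  sizes <- rep(0L, n_perm)
  sizes[perm_sizes$perm] <- perm_sizes$size
  purrr::map_dfr(classes, function(cl) {
    elems <- dplyr::filter(repeats, .data$repeat_class == cl)
    overlap_count <- function(pk) {
      if (nrow(pk) == 0 || nrow(elems) == 0) return(integer(0))
      unique(query_overlaps(dplyr::select(pk, "chrom", "start", "end"),
                            dplyr::select(elems, "chrom", "start", "end"))$x_idx)
    }
    obs_in <- length(overlap_count(peaks))
    obs_frac <- obs_in / nrow(peaks)
    hit_rows <- if (nrow(shuffles) && nrow(elems)) {
      hits <- query_overlaps(
        dplyr::select(shuffles, "chrom", "start", "end"),
        dplyr::select(elems, "chrom", "start", "end"))
      unique(hits$x_idx)
    } else integer(0)
    in_per_perm <- rep(0L, n_perm)
    if (length(hit_rows)) {
      tab <- table(shuffles$perm[hit_rows])
      in_per_perm[as.integer(names(tab))] <- as.integer(tab)
    }
    null_frac <- ifelse(sizes > 0, in_per_perm / sizes, NA_real_)
    p_emp <- (1 + sum(null_frac >= obs_frac, na.rm = TRUE)) / (1 + n_perm)
    null_in <- sum(in_per_perm)
    null_tot <- sum(sizes)
    ft <- stats::fisher.test(matrix(c(obs_in, nrow(peaks) - obs_in,
                                      null_in, null_tot - null_in), 2,
                                    byrow = TRUE))
    tibble::tibble(repeat_class = cl, n_peaks = nrow(peaks),
                   observed_fraction = obs_frac,
                   null_mean = mean(null_frac, na.rm = TRUE),
                   null_sd = stats::sd(null_frac, na.rm = TRUE),
                   p_empirical = p_emp, fisher_p = ft$p.value,
                   odds_ratio = unname(ft$estimate),
                   n_permutations = n_perm)
  })
}

#' Positional profile of peak summits along repeat consensus sequences
#'
#' Maps every peak summit falling inside a repeat element onto the repeat
#' consensus and reports its relative position in [0, 1], with 0 the
#' repeat 5' end: minus-strand elements are mirrored. The consensus length
#' of a subfamily is taken as the largest consensus end observed among its
#' elements. Elements lacking consensus coordinates are skipped (count
#' recorded in the `n_skipped` attribute).
#'
#' @param peaks Peak tibble with `summit`.
#' @param repeats Repeat annotation with consensus coordinates.
#' @return A tibble with one row per (summit, element) pair: `chrom`,
#'   `summit`, `subfamily`, `family`, `repeat_class`, `rel_pos`.
#' @export
positional_profile <- function(peaks, repeats) {
  has_cons <- !is.na(repeats$consensus_start) & !is.na(repeats$consensus_end)
  n_skipped <- sum(!has_cons)
  reps <- dplyr::mutate(repeats[has_cons, , drop = FALSE],
                        elem = dplyr::row_number())
  summits <- tibble::tibble(chrom = peaks$chrom, start = peaks$summit,
                            end = peaks$summit + 1, summit = peaks$summit)
  out <- if (nrow(reps) && nrow(summits)) {
    cons_len <- reps |>
      dplyr::group_by(.data$subfamily) |>
      dplyr::summarise(cons_len = max(.data$consensus_end), .groups = "drop")
    ov <- query_overlaps(summits, reps)
    if (nrow(ov)) {
      ov <- dplyr::left_join(ov, cons_len, by = "subfamily")
      pos_c <- ifelse(ov$strand == "-",
                      ov$consensus_start + (ov$end.y - 1 - ov$summit),
                      ov$consensus_start + (ov$summit - ov$start.y))
      tibble::tibble(chrom = ov$chrom.x, summit = ov$summit,
                     subfamily = ov$subfamily, family = ov$family,
                     repeat_class = ov$repeat_class,
                     rel_pos = pmin(1, pmax(0, (pos_c + 0.5) / ov$cons_len)))
    } else NULL
  } else NULL
  if (is.null(out)) {
    out <- tibble::tibble(chrom = character(), summit = numeric(),
                          subfamily = character(), family = character(),
                          repeat_class = character(), rel_pos = numeric())
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
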