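#' Read CpG methylation tables
#'
#' Two layouts are supported. `cpg_counts` expects bisulfite-style counts
#' (`chrom`, `pos` 1-based, `methylated`, `total`, optional `sample`); beta
#' is computed as methylated/total and records with zero total coverage are
#' dropped with a warning. `probe_betas` expects array-style rows (`probe`,
#' `chrom`, `pos` 1-based, then one beta column per sample), which are
#' pivoted to one record per (position, sample). Betas outside [0, 1] are
#' rejected.
#'
#' @param path Path to a TSV file with a header line.
#' @param kind `"cpg_counts"` or `"probe_betas"`.
#' @return A tibble with columns `chrom`, `pos` (0-based), `sample`,
#'   `beta`, `coverage` (`NA` for array probes), and `probe` for
#'   `probe_betas`.
#' @export
read_methylation_table <- function(path, kind = c("cpg_counts", "probe_betas")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (kind == "cpg_counts") {
    need <- c("chrom", "pos", "methylated", "total")
    if (!all(need %in% names(df))) {
      stop("cpg_counts table needs columns: ", paste(need, collapse = ", "))
    }
    zero <- df$total == 0
    if (any(zero)) {
      warning(sum(zero), " CpG record(s) with zero coverage dropped")
      df <- df[!zero, , drop = FALSE]
    }
    out <- tibble::tibble(
      chrom = as.character(df$chrom),
      pos = df$pos - 1,
      sample = if ("sample" %in% names(df)) as.character(df$sample) else "sample1",
      beta = df$methylated / df$total,
      coverage = as.numeric(df$total)
    )
  } else {
    need <- c("probe", "chrom", "pos")
    if (!all(need %in% names(df))) {
      stop("probe_betas table needs columns: ", paste(need, collapse = ", "))
    }
    out <- df |>
      tibble::as_tibble() |>
      tidyr::pivot_longer(-dplyr::all_of(need), names_to = "sample",
                          values_to = "beta") |>
      dplyr::transmute(chrom = as.character(.data$chrom), pos = .data$pos - 1,
                       sample = .data$sample, beta = .data$beta,
                       coverage = NA_real_, probe = as.character(.data$probe))
  }
  bad <- !is.na(out$beta) & (out$beta < 0 | out$beta > 1)
  if (any(bad)) {
    warning(sum(bad), " record(s) with beta outside [0, 1] rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out
}
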