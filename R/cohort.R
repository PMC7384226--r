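#' Hypoxia metagene signature
#'
#' The 15-gene hypoxia metagene list used for tumor oxygenation
#' classification; one gene (CDKN3) appears twice in the published list,
#' leaving 14 unique symbols.
#'
#' @return Character vector of gene symbols.
#' @export
hypoxia_signature <- function() {
  unique(c("ALDOA", "MIF", "TUBB6", "P4HA1", "SLC2A1", "PGAM1", "ENO1",
           "LDHA", "CDKN3", "TPI1", "NDRG1", "VEGFA", "ACOT7", "CDKN3",
           "ADM"))
}

#' Ward error-sum-of-squares hierarchical clustering
#'
#' Agglomerative clustering with the classical Ward.D update on squared
#' Euclidean distances (Lance-Williams coefficients
#' `((n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) - n_k d(i,j)) /
#' (n_i + n_j + n_k)`). With squared input distances the merge height of
#' two singletons equals their squared distance, i.e. twice the increase
#' in within-cluster error sum of squares.
#'
#' @param x A numeric matrix (items in rows) or a `dist` object. Matrices
#'   are converted to squared Euclidean distances; `dist` inputs are used
#'   as-is and are assumed squared.
#' @return An object of class `hclust`.
#' @export
ward_linkage <- function(x) {
  d2 <- if (inherits(x, "dist")) {
    x
  } else if (is.matrix(x) || is.data.frame(x)) {
    if (nrow(x) < 2) stop("need at least two items to cluster")
    stats::dist(as.matrix(x))^2
  } else {
    stop("x must be a matrix, data frame, or dist object")
  }
  if (is.null(attr(d2, "Size")) || attr(d2, "Size") < 2) {
    stop("need at least two items to cluster")
  }
  stats::hclust(d2, method = "ward.D")
}

#' Cluster tumors into hypoxic and normoxic groups
#'
#' Ward clusters samples on normalised log-transformed expression (log2
#' counts per million, offset 1) of the hypoxia signature genes, cuts the
#' tree into its top two subclusters, and labels the subcluster with the
#' higher mean signature expression `hypoxic` (the signature genes are
#' hypoxia-induced), the other `normoxic`.
#'
#' @param counts Count-matrix tibble (gene symbols in `feature_id`).
#' @param signature Character vector of signature genes; those missing
#'   from the matrix are dropped with a warning.
#' @param normalization Only `"cpm_log"` is currently provided.
#' @return A tibble `sample`, `cluster` (1/2), `oxygenation`
#'   (`"hypoxic"`/`"normoxic"`), `oxy_code` (hypoxic = 0, normoxic = 1, the
#'   convention of the interaction model), `mean_signature`.
#' @export
hypoxia_cluster <- function(counts, signature = hypoxia_signature(),
                            normalization = "cpm_log") {
  normalization <- match.arg(normalization, "cpm_log")
  present <- intersect(signature, counts$feature_id)
  if (length(present) < length(unique(signature))) {
    warning("signature genes missing from matrix: ",
            paste(setdiff(signature, present), collapse = ", "))
  }
  if (length(present) < 2) stop("fewer than 2 signature genes present")
  expr <- normalize_expression(counts, mode = "cpm_log")
  sig <- count_mat(expr)[present, , drop = FALSE]
  if (ncol(sig) < 4) stop("need at least 4 tumors to cluster")
  hc <- ward_linkage(t(sig))
  cluster <- stats::cutree(hc, k = 2)
  mean_sig <- colMeans(sig)
  hyp_cluster <- which.max(tapply(mean_sig, cluster, mean))
  oxy <- ifelse(cluster == hyp_cluster, "hypoxic", "normoxic")
  tibble::tibble(sample = colnames(sig), cluster = unname(cluster),
                 oxygenation = unname(oxy),
                 oxy_code = unname(ifelse(oxy == "hypoxic", 0L, 1L)),
                 mean_signature = unname(mean_sig))
}

#' Stratify tumors by cryptic-promoter methylation
#'
#' Probes falling inside any cryptic transcript promoter are the cryptic
#' transcription-associated probes; each tumor's promoter methylation is
#' their unweighted mean beta, and tumors are split into high/low groups
#' at the cohort median (values equal to the median go low).
#'
#' @param probes Methylation records (`chrom`, `pos`, `sample`, `beta`).
#' @param promoters Promoter interval tibble (e.g. [derive_promoter()] on
#'   the cryptic catalogue).
#' @return A tibble `sample`, `n_probes`, `mean_beta`, `methylation`
#'   (`"high"`/`"low"`, `NA` when a tumor has no probe values),
#'   `meth_code` (low = 0, high = 1).
#' @export
promoter_methylation_stratify <- function(probes, promoters) {
  pr <- tibble::tibble(chrom = probes$chrom, start = probes$pos,
                       end = probes$pos + 1, sample = probes$sample,
                       beta = probes$beta)
  ov <- query_overlaps(pr, dplyr::select(promoters, "chrom", "start", "end"))
  if (nrow(ov) == 0) stop("no probe falls inside any promoter")
  per_tumor <- ov |>
    dplyr::distinct(.data$x_idx, .keep_all = TRUE) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_probes = dplyr::n(), mean_beta = mean(.data$beta),
                     .groups = "drop")
  all_samples <- unique(probes$sample)
  missing <- setdiff(all_samples, per_tumor$sample)
  if (length(missing)) {
    warning("tumor(s) without promoter probe values left unclassified: ",
            paste(missing, collapse = ", "))
  }
  med <- stats::median(per_tumor$mean_beta)
  out <- per_tumor |>
    dplyr::mutate(methylation = ifelse(.data$mean_beta > med, "high", "low"),
                  meth_code = ifelse(.data$mean_beta > med, 1L, 0L))
  dplyr::bind_rows(out,
                   tibble::tibble(sample = missing, n_probes = 0L,
                                  mean_beta = NA_real_,
                                  methylation = NA_character_,
                                  meth_code = NA_integer_))
}

#' Stratify values at a quantile threshold
#'
#' Splits values into low (<= the linear-interpolation quantile, default
#' the third decile) and high groups.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @param quantile Probability of the cutoff.
#' @return A tibble `value`, `stratum` (`"low"`/`"high"`), `cutoff`.
#' @export
threshold_stratify <- function(values, quantile = 0.3) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least two finite values")
  cutoff <- unname(stats::quantile(v, probs = quantile, type = 7))
  if (all(v == v[1])) warning("all values equal; everything stratified low")
  tibble::tibble(value = values,
                 stratum = ifelse(values <= cutoff, "low", "high"),
                 cutoff = cutoff)
}

#' Cytolytic activity from GZMA and PRF1 expression
#'
#' The geometric mean of granzyme A and perforin 1 expression in TPM
#' (offset expected upstream), plus its natural log.
#'
#' @param tpm Normalised expression tibble (e.g.
#'   `normalize_expression(counts, "tpm_offset")`).
#' @param genes The two cytolytic effector gene ids.
#' @return A tibble `sample`, `cytolytic_activity`, `log_cytolytic`.
#' @export
cytolytic_activity <- function(tpm, genes = c("GZMA", "PRF1")) {
  m <- count_mat(tpm)
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) stop("missing gene(s): ", paste(miss, collapse = ", "))
  sub <- m[genes, , drop = FALSE]
  log_cyt <- colMeans(log(sub))
  tibble::tibble(sample = colnames(m),
                 cytolytic_activity = unname(exp(log_cyt)),
                 log_cytolytic = unname(log_cyt))
}
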