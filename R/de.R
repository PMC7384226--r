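#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's median ratio of counts
#' to the row-wise geometric mean, taken over rows with a positive
#' geometric mean.
#'
#' @param counts Count-matrix tibble or plain integer matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors_mor <- function(counts) {
  m <- if (is.data.frame(counts)) count_mat(counts) else counts
  logm <- log(m)
  log_gm <- rowMeans(logm)
  ok <- is.finite(log_gm)
  if (!any(ok)) stop("no row with all-positive counts; cannot normalise")
  sf <- apply(logm[ok, , drop = FALSE], 2,
              function(col) exp(stats::median(col - log_gm[ok])))
  sf
}

# One NB Wald test of y ~ group with log size-factor offsets. The
# dispersion is estimated per row by Cox-Reid adjusted profile likelihood
# (the adjustment corrects the downward bias of plain profile ML when the
# mean parameters are estimated from the same few samples), started from a
# method-of-moments value and floored at 1e-8; the Wald statistic is
# referred to a t distribution on the residual degrees of freedom.
nb_wald_row <- function(y, design_mat, log_sf) {
  if (all(y == 0)) {
    return(c(log2fc = NA, dispersion = NA, stat = NA, p = NA,
             base_mean = 0))
  }
  base_mean <- mean(y / exp(log_sf))
  nb_glm <- function(alpha) {
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    suppressWarnings(stats::glm.fit(design_mat, y, offset = log_sf,
                                    family = fam))
  }
  apl <- function(log_alpha) {
    alpha <- exp(log_alpha)
    f <- nb_glm(alpha)
    mu <- f$fitted.values
    w <- mu / (1 + alpha * mu)
    ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    ll - 0.5 * determinant(crossprod(design_mat * sqrt(w)),
                           logarithm = TRUE)$modulus
  }
  res <- tryCatch({
    ybar <- mean(y / exp(log_sf))
    mom <- max((stats::var(y / exp(log_sf)) - ybar) / ybar^2, 1e-8)
    upper <- log(max(50, 10 * mom))
    opt <- stats::optimize(apl, c(log(1e-8), upper), maximum = TRUE,
                           tol = 1e-4)
    alpha <- max(exp(opt$maximum), 1e-8)
    f <- nb_glm(alpha)
    mu <- f$fitted.values
    w <- mu / (1 + alpha * mu)
    v <- solve(crossprod(design_mat * sqrt(w)))
    est <- unname(f$coefficients[2])
    se <- sqrt(v[2, 2])
    df <- length(y) - ncol(design_mat)
    tt <- est / se
    c(log2fc = est / log(2), dispersion = alpha, stat = tt,
      p = 2 * stats::pt(-abs(tt), df = df), base_mean = base_mean)
  }, error = function(e) {
    c(log2fc = NA, dispersion = NA, stat = NA, p = NA,
      base_mean = base_mean)
  })
  res
}

#' Negative-binomial differential expression between two conditions
#'
#' For each row, fits a negative-binomial log-linear model of counts on the
#' condition with median-of-ratios size factors as offsets. The dispersion
#' is estimated per row by Cox-Reid adjusted profile likelihood (method-of-
#' moments start, floor 1e-8) -- the adjustment removes the small-sample
#' downward bias of plain profile ML -- and the condition coefficient is
#' tested with a Wald t-test on the residual degrees of freedom. P-values
#' are Benjamini-Hochberg adjusted over the tested rows. All-zero rows are
#' reported untested (`NA`).
#'
#' @param counts Count-matrix tibble.
#' @param groups Named character/factor vector mapping sample names to one
#'   of two conditions; the log2 fold change is second level over first.
#' @param min_replicates Minimum samples per condition.
#' @param size_factors Optional named size factors; default
#'   [size_factors_mor()].
#' @return A tibble of class `credentor_de`: `feature_id`, `base_mean`,
#'   `log2fc`, `dispersion`, `stat`, `p_value`, `padj`.
#' @export
differential_expression <- function(counts, groups, min_replicates = 2,
                                    size_factors = NULL) {
  samples <- count_samples(counts)
  groups <- groups[samples]
  if (anyNA(groups)) stop("every sample column needs a group label")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two conditions are required")
  if (any(table(groups) < min_replicates)) {
    stop("each condition needs >= ", min_replicates, " replicates")
  }
  m <- count_mat(counts)
  if (is.null(size_factors)) size_factors <- size_factors_mor(m)
  log_sf <- log(size_factors[samples])
  design_mat <- stats::model.matrix(~groups)
  res <- t(apply(m, 1, nb_wald_row, design_mat = design_mat,
                 log_sf = log_sf))
  out <- tibble::tibble(
    feature_id = counts$feature_id,
    base_mean = res[, "base_mean"],
    log2fc = res[, "log2fc"],
    dispersion = res[, "dispersion"],
    stat = res[, "stat"],
    p_value = res[, "p"]
  )
  out$padj <- NA_real_
  tested <- !is.na(out$p_value)
  out$padj[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  class(out) <- c("credentor_de", class(out))
  attr(out, "groups") <- levels(groups)
  out
}

#' @export
glance.credentor_de <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_signif = sum(x$padj <= alpha, na.rm = TRUE),
    alpha = alpha,
    contrast = paste(attr(x, "groups"), collapse = " vs ")
  )
}

#' @export
tidy.credentor_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "credentor_de")
  out
}
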