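nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 1e-8) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# Fit one NB GLM; dispersion profiled by ML (glm.nb) unless fixed.
fit_nb <- function(formula, data, dispersion = NULL) {
  if (is.null(dispersion)) {
    warned <- FALSE
    fit <- withCallingHandlers(
      MASS::glm.nb(formula, data = data),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    alpha <- max(1 / fit$theta, 1e-8)
    if (!is.finite(alpha)) alpha <- 1e-8
    converged <- fit$converged && !warned
  } else {
    alpha <- max(dispersion, 1e-8)
    fit <- suppressWarnings(
      stats::glm(formula, data = data,
                 family = MASS::negative.binomial(theta = 1 / alpha)))
    converged <- fit$converged
  }
  ll <- nb_loglik(fit$y, stats::fitted(fit), alpha)
  list(fit = fit, alpha = alpha, loglik = ll, converged = converged)
}

#' Negative-binomial hypoxia-by-methylation interaction test
#'
#' Fits two NB log-linear models of per-tumor counts on oxygenation
#' (hypoxic = 0, normoxic = 1) and methylation (low = 0, high = 1), with
#' and without their interaction, each with its own ML dispersion, and
#' compares them with a likelihood-ratio test (df = 1). Under these
#' encodings a positive interaction coefficient means cooperative
#' enhancement of expression in hypoxic, low-methylation tumors: the
#' log-mean of the (0, 0) cell exceeds what the additive model predicts by
#' exactly the interaction coefficient.
#'
#' @param data Data frame with one row per tumor.
#' @param counts,oxygenation,methylation Bare column names of the integer
#'   counts and the 0/1 factor encodings.
#' @param offset Optional bare column name of a log offset (e.g. log
#'   coding-gene totals or log library size).
#' @param dispersion `NULL` to estimate the dispersion per model by
#'   maximum likelihood, or a fixed value of alpha (`Var = mu + alpha
#'   mu^2`); values at or below 1e-8 give the Poisson limit.
#' @return An object of class `nb_interaction_fit`: use [tidy()] for the
#'   full-model coefficient table and [glance()] for the LRT summary.
#'   Components include `coefficients`, `alpha_full`, `alpha_reduced`,
#'   `lrt`, `p_value`, `converged`.
#' @examples
#' df <- data.frame(y = rpois(40, 20), oxy = rep(0:1, 20),
#'                  meth = rep(0:1, each = 20))
#' fit <- nb_interaction_test(df, y, oxy, meth)
#' glance(fit)
#' @export
nb_interaction_test <- function(data, counts, oxygenation, methylation,
                                offset = NULL, dispersion = NULL) {
  y <- rlang::eval_tidy(rlang::enquo(counts), data)
  oxy <- rlang::eval_tidy(rlang::enquo(oxygenation), data)
  meth <- rlang::eval_tidy(rlang::enquo(methylation), data)
  off_quo <- rlang::enquo(offset)
  off <- if (rlang::quo_is_null(off_quo)) rep(0, length(y)) else
    rlang::eval_tidy(off_quo, data)
  # drop the argument bindings so the model formula below resolves
  # offset() to stats::offset rather than the promise captured here
  rm(counts, oxygenation, methylation, offset)
  if (any(table(oxy, meth) == 0) || length(unique(oxy)) < 2 ||
      length(unique(meth)) < 2) {
    stop("all four oxygenation x methylation design cells must be non-empty")
  }
  d <- data.frame(y = y, oxy = oxy, meth = meth, off = off)
  full <- fit_nb(y ~ oxy * meth + offset(off), d, dispersion)
  red <- fit_nb(y ~ oxy + meth + offset(off), d, dispersion)
  lrt <- max(0, 2 * (full$loglik - red$loglik))
  sm <- summary(full$fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = c("(Intercept)", "oxygenation", "methylation", "interaction"),
    estimate = sm[, 1], std.error = sm[, 2], statistic = sm[, 3],
    p.value = sm[, 4])
  structure(list(
    coefficients = coef_tbl,
    alpha_full = full$alpha, alpha_reduced = red$alpha,
    loglik_full = full$loglik, loglik_reduced = red$loglik,
    lrt = lrt, df = 1L,
    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    interaction = unname(sm[4, 1]),
    n = length(y),
    converged = full$converged && red$converged
  ), class = "nb_interaction_fit")
}

#' @export
print.nb_interaction_fit <- function(x, ...) {
  cat("Negative-binomial hypoxia x methylation interaction test\n")
  cat(sprintf("  interaction coefficient: %.4f\n", x$interaction))
  cat(sprintf("  LRT = %.3f (df = %d), p = %.4g\n", x$lrt, x$df, x$p_value))
  cat(sprintf("  dispersion alpha: full %.4g, reduced %.4g\n",
              x$alpha_full, x$alpha_reduced))
  if (!x$converged) cat("  (warning: fit flagged non-converged)\n")
  invisible(x)
}

#' @export
tidy.nb_interaction_fit <- function(x, ...) x$coefficients

#' @export
glance.nb_interaction_fit <- function(x, ...) {
  tibble::tibble(interaction = x$interaction, lrt = x$lrt, df = x$df,
                 p_value = x$p_value, alpha_full = x$alpha_full,
                 alpha_reduced = x$alpha_reduced, n = x$n,
                 converged = x$converged)
}

#' Per-transcript interaction screen
#'
#' Applies [nb_interaction_test()] to every row of a count matrix and
#' BH-adjusts the LRT p-values across transcripts.
#'
#' @param counts Count-matrix tibble.
#' @param labels Tibble with `sample`, `oxy_code`, `meth_code` and
#'   optionally `log_offset` columns.
#' @return A tibble `feature_id`, `interaction`, `lrt`, `p_value`, `padj`,
#'   `converged`.
#' @export
nb_interaction_screen <- function(counts, labels) {
  samples <- count_samples(counts)
  lab <- labels[match(samples, labels$sample), ]
  m <- count_mat(counts)
  has_off <- "log_offset" %in% names(lab)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    d <- data.frame(y = m[i, ], oxy = lab$oxy_code, meth = lab$meth_code,
                    off = if (has_off) lab$log_offset else 0)
    fit <- tryCatch(nb_interaction_test(d, y, oxy, meth, offset = off),
                    error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(feature_id = counts$feature_id[i],
                     interaction = NA_real_, lrt = NA_real_,
                     p_value = NA_real_, converged = FALSE)
    } else {
      tibble::tibble(feature_id = counts$feature_id[i],
                     interaction = fit$interaction, lrt = fit$lrt,
                     p_value = fit$p_value, converged = fit$converged)
    }
  })
  res$padj <- NA_real_
  ok <- !is.na(res$p_value)
  res$padj[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res
}

#' Methylation-by-hypoxia linear model for single-cell expression
#'
#' Ordinary least squares of per-cell log expression on promoter
#' methylation fraction, hypoxia status, and their interaction, with a
#' t-test on the interaction coefficient: a significant negative
#' interaction means the methylation-expression anticorrelation is
#' stronger in hypoxic cells.
#'
#' @param data Data frame with one row per cell.
#' @param expression,methylation,hypoxia Bare column names: numeric log
#'   expression, methylation fraction in [0, 1], and a 0/1 or logical
#'   hypoxia indicator.
#' @return An object of class `meth_glm` wrapping the `lm` fit;
#'   [tidy()] gives the coefficient table, [glance()] the interaction
#'   p-value and fit statistics.
#' @export
meth_expression_glm <- function(data, expression, methylation, hypoxia) {
  d <- data.frame(
    expr = rlang::eval_tidy(rlang::enquo(expression), data),
    meth = rlang::eval_tidy(rlang::enquo(methylation), data),
    hyp = as.numeric(rlang::eval_tidy(rlang::enquo(hypoxia), data)))
  if (min(table(d$hyp)) < 3 || length(unique(d$hyp)) != 2) {
    stop("need >= 3 observations in each hypoxia group")
  }
  fit <- stats::lm(expr ~ meth * hyp, data = d)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  structure(list(
    model = fit,
    coefficients = tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                                  std.error = sm[, 2], statistic = sm[, 3],
                                  p.value = sm[, 4]),
    interaction = unname(sm["meth:hyp", 1]),
    interaction_p = unname(sm["meth:hyp", 4]),
    n = nrow(d)
  ), class = "meth_glm")
}

#' @export
tidy.meth_glm <- function(x, ...) x$coefficients

#' @export
glance.meth_glm <- function(x, ...) {
  tibble::tibble(interaction = x$interaction,
                 interaction_p = x$interaction_p,
                 r_squared = summary(x$model)$r.squared, n = x$n)
}

#' @export
print.meth_glm <- function(x, ...) {
  cat("Methylation x hypoxia linear model (n =", x$n, ")\n")
  cat(sprintf("  interaction: %.4f (p = %.4g)\n", x$interaction,
              x$interaction_p))
  invisible(x)
}
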