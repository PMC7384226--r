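test_that("Ward merges reproduce error-sum-of-squares increments", {
  set.seed(81)
  # two points merge at their squared distance
  x2 <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  hc2 <- ward_linkage(x2)
  expect_equal(hc2$height, 25)
  # duplicate points merge first at height zero
  xd <- rbind(c(1, 1), c(5, 5), c(1, 1))
  hcd <- ward_linkage(xd)
  expect_equal(hcd$height[1], 0)
  expect_setequal(hcd$merge[1, ], c(-1, -3))
  # heights equal twice the ESS increase for all n <= 10
  for (n in 4:10) {
    x <- matrix(rnorm(n * 3), n)
    hc <- ward_linkage(x)
    expect_equal(hc$height, 2 * bf_ess_increments(x, hc$merge),
                 tolerance = 1e-10)
  }
  expect_error(ward_linkage(list()), "matrix")
  expect_error(ward_linkage(matrix(1, 1, 2)), "two items")
})

test_that("hypoxia clustering labels the high-signature subcluster hypoxic", {
  set.seed(82)
  sig <- hypoxia_signature()
  expect_equal(length(sig), 14) # the published list repeats one gene
  n <- 20
  mk_counts <- function(shift_group1) {
    counts <- tibble::tibble(feature_id = c(sig, "OTHER1", "OTHER2"),
                             length_bp = 1000)
    for (j in seq_len(n)) {
      hyp <- j <= n / 2
      base <- rpois(length(sig) + 2, 100)
      if (hyp) base[seq_along(sig)] <-
          rpois(length(sig), 100 * 2^shift_group1)
      counts[[sprintf("t%02d", j)]] <- base
    }
    counts
  }
  counts <- mk_counts(3)
  cl <- hypoxia_cluster(counts)
  expect_equal(cl$oxygenation, rep(c("hypoxic", "normoxic"), each = 10))
  expect_equal(cl$oxy_code, rep(c(0L, 1L), each = 10))
  # swapping the direction of the shift swaps the labels
  cl2 <- hypoxia_cluster(mk_counts(-3))
  expect_equal(cl2$oxygenation, rep(c("normoxic", "hypoxic"), each = 10))
  # two identical pairs co-cluster
  cp <- tibble::tibble(feature_id = sig, length_bp = 1000,
                       a1 = 1:14 * 10, a2 = 1:14 * 10,
                       b1 = 14:1 * 10, b2 = 14:1 * 10)
  cl3 <- hypoxia_cluster(cp)
  expect_equal(cl3$cluster[1], cl3$cluster[2])
  expect_equal(cl3$cluster[3], cl3$cluster[4])
  expect_true(cl3$cluster[1] != cl3$cluster[3])
  expect_warning(hypoxia_cluster(counts, signature = c(sig, "MISSING")),
                 "MISSING")
  expect_error(suppressWarnings(
    hypoxia_cluster(counts, signature = c("A", "B"))), "signature genes")
})

test_that("promoter methylation stratifies tumors at the cohort median", {
  prom <- tibble::tibble(chrom = "chr1", start = 1000, end = 3500)
  probes <- tidyr::expand_grid(sample = c("t1", "t2", "t3", "t4"),
                               pos = c(1500, 2500))
  probes$chrom <- "chr1"
  probes$beta <- rep(c(0.1, 0.2, 0.3, 0.4), each = 2)
  got <- promoter_methylation_stratify(probes, prom)
  expect_equal(got$mean_beta, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(got$methylation, c("low", "low", "high", "high"))
  expect_equal(got$meth_code, c(0L, 0L, 1L, 1L))
  # a probe outside every promoter is ignored
  out_probe <- dplyr::bind_rows(
    probes, tibble::tibble(sample = "t1", pos = 9000, chrom = "chr1",
                           beta = 1))
  expect_equal(promoter_methylation_stratify(out_probe, prom)$mean_beta,
               got$mean_beta)
  # betas {0.2, 0.4} average to 0.3
  one <- promoter_methylation_stratify(
    tibble::tibble(sample = "t", pos = c(1500, 2500), chrom = "chr1",
                   beta = c(0.2, 0.4)), prom)
  expect_equal(one$mean_beta, 0.3)
  expect_error(promoter_methylation_stratify(
    tibble::tibble(sample = "t", pos = 9000, chrom = "chr1", beta = 0.5),
    prom), "no probe")
})

test_that("quantile stratification splits at the interpolated third decile", {
  got <- threshold_stratify(1:10)
  expect_equal(got$stratum, rep(c("low", "high"), c(3, 7)))
  expect_equal(got$cutoff[1], 3.7)
  med <- threshold_stratify(1:10, quantile = 0.5)
  expect_equal(med$stratum, ifelse(1:10 <= median(1:10), "low", "high"))
  # monotone transforms preserve the labels
  expect_equal(threshold_stratify(exp(1:10))$stratum, got$stratum)
  expect_warning(all_low <- threshold_stratify(rep(2, 5)), "equal")
  expect_true(all(all_low$stratum == "low"))
  expect_error(threshold_stratify(3), "two finite")
})

test_that("cytolytic activity is the geometric mean of GZMA and PRF1", {
  tpm <- tibble::tibble(feature_id = c("GZMA", "PRF1", "X"),
                        length_bp = 1000,
                        s1 = c(4, 9, 100), s2 = c(5, 5, 1))
  got <- cytolytic_activity(tpm)
  expect_equal(got$cytolytic_activity, c(6, 5))
  expect_equal(got$log_cytolytic, log(c(6, 5)))
  scaled <- dplyr::mutate(tpm, s1 = s1 * 10, s2 = s2 * 10)
  expect_equal(cytolytic_activity(scaled)$cytolytic_activity,
               10 * got$cytolytic_activity)
  expect_error(cytolytic_activity(tpm[-1, ]), "GZMA")
})

test_that("the NB interaction test validates its design and nests its models", {
  set.seed(83)
  n <- 40
  d <- tibble::tibble(y = rpois(n, 30), oxy = rep(0:1, n / 2),
                      meth = rep(0:1, each = n / 2))
  fit <- nb_interaction_test(d, y, oxy, meth)
  expect_gte(fit$lrt, 0)
  expect_equal(fit$loglik_full >= fit$loglik_reduced, TRUE)
  expect_equal(nrow(tidy(fit)), 4)
  expect_error(nb_interaction_test(dplyr::mutate(d, meth = 0), y, oxy, meth),
               "design cells")
})

test_that("the interaction LRT is invariant under joint relabeling", {
  set.seed(84)
  n <- 30
  d <- tibble::tibble(y = rnbinom(4 * n, size = 5,
                                  mu = rep(c(40, 25, 30, 35), each = n)),
                      oxy = rep(c(0, 0, 1, 1), each = n),
                      meth = rep(c(0, 1, 0, 1), each = n))
  f1 <- nb_interaction_test(d, y, oxy, meth)
  d2 <- dplyr::mutate(d, oxy = 1 - oxy, meth = 1 - meth)
  f2 <- nb_interaction_test(d2, y, oxy, meth)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-6)
  # under double relabeling the interaction coefficient is unchanged
  expect_equal(f1$interaction, f2$interaction, tolerance = 1e-6)
})

test_that("fixed small dispersion reproduces the Poisson fit", {
  set.seed(85)
  n <- 50
  d <- tibble::tibble(y = rpois(4 * n, rep(c(50, 30, 35, 40), each = n)),
                      oxy = rep(c(0, 0, 1, 1), each = n),
                      meth = rep(c(0, 1, 0, 1), each = n))
  fnb <- nb_interaction_test(d, y, oxy, meth, dispersion = 0)
  fp <- stats::glm(y ~ oxy * meth, family = stats::poisson, data = d)
  expect_equal(unname(fnb$coefficients$estimate), unname(stats::coef(fp)),
               tolerance = 1e-4)
})

test_that("the per-transcript interaction screen BH-adjusts across rows", {
  set.seed(86)
  labels <- tibble::tibble(sample = sprintf("t%02d", 1:40),
                           oxy_code = rep(0:1, 20),
                           meth_code = rep(0:1, each = 20))
  counts <- tibble::tibble(feature_id = sprintf("c%d", 1:5),
                           length_bp = 1000)
  for (s in labels$sample) counts[[s]] <- rpois(5, 40)
  res <- nb_interaction_screen(counts, labels)
  expect_equal(nrow(res), 5)
  ok <- !is.na(res$p_value)
  expect_equal(res$padj[ok], bf_bh(res$p_value[ok]))
})

test_that("the single-cell methylation GLM recovers planted interactions", {
  set.seed(87)
  # n chosen so the analytic power puts the interaction t well past 5:
  # se ~ sd * sqrt(2 * 12 / (n/2)) = 0.14 at n = 400, sd = 0.4
  n <- 400
  meth <- runif(n)
  hyp <- rep(0:1, each = n / 2)
  # slope -1 in hypoxic (hyp = 0 is hypoxic per the cohort encoding);
  # here hyp is a plain indicator: slopes differ by 1 between groups
  expr <- 2 - 1 * meth * (hyp == 0) + rnorm(n, 0, 0.4)
  fit <- meth_expression_glm(tibble::tibble(e = expr, m = meth, h = hyp),
                             e, m, h)
  expect_lt(fit$interaction_p, 1e-6)
  # zero-noise data on an exact line gives exact coefficients
  expr2 <- 1 + 2 * meth + 3 * hyp + 4 * meth * hyp
  fit2 <- suppressWarnings(
    meth_expression_glm(tibble::tibble(e = expr2, m = meth, h = hyp),
                        e, m, h))
  expect_equal(unname(fit2$coefficients$estimate), c(1, 2, 3, 4),
               tolerance = 1e-10)
  expect_error(meth_expression_glm(
    tibble::tibble(e = expr, m = hyp, h = hyp), e, m, h), "collinear")
  expect_error(meth_expression_glm(
    tibble::tibble(e = expr[1:4], m = meth[1:4], h = c(0, 0, 0, 1)),
    e, m, h), ">= 3")
})

test_that("identical slopes give uniform interaction p-values", {
  set.seed(88)
  ps <- replicate(200, {
    n <- 60
    meth <- runif(n); hyp <- rep(0:1, each = n / 2)
    expr <- 1 - meth + rnorm(n, 0, 0.5)
    meth_expression_glm(tibble::tibble(e = expr, m = meth, h = hyp),
                        e, m, h)$interaction_p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
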