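test_that("promoters span 2 kb upstream to 500 bp downstream of the TSS", {
  plus <- tibble::tibble(transcript_id = "t", gene_id = "g", chrom = "chr1",
                         strand = "+", tss = 10000)
  p <- derive_promoter(plus)
  expect_equal(c(p$start, p$end), c(8000, 10500))
  minus <- dplyr::mutate(plus, strand = "-", tss = 10599)
  m <- derive_promoter(minus)
  expect_equal(c(m$start, m$end), c(10100, 12600))
  # clamped at the chromosome start
  near0 <- dplyr::mutate(plus, tss = 100)
  expect_equal(derive_promoter(near0)$start, 0)
  expect_error(derive_promoter(dplyr::mutate(plus, strand = ".")),
               "stranded")
})

test_that("promoter derivation is strand-symmetric under genome reversal", {
  set.seed(41)
  glen <- 50000
  for (i in 1:20) {
    tss <- sample(3000:47000, 1)
    fwd <- tibble::tibble(transcript_id = "t", gene_id = "g",
                          chrom = "chr1", strand = "+", tss = tss)
    rev <- dplyr::mutate(fwd, strand = "-", tss = glen - 1 - tss)
    pf <- derive_promoter(fwd)
    pr <- derive_promoter(rev)
    # mirroring the forward promoter maps it onto the reverse one
    expect_equal(glen - pf$end, pr$start)
    expect_equal(glen - pf$start, pr$end)
  }
})

test_that("cryptic classification keeps noncoding repeat-overlapping transcripts", {
  coding <- exon_tbl(list(id = "CG1.T1", starts = 10000, ends = 12000,
                          strand = "+", coding = TRUE))
  tx <- dplyr::bind_rows(
    coding,
    # overlaps an LTR by 300 bp and a LINE by 100 bp
    exon_tbl(list(id = "N1.T1", starts = 20000, ends = 21000, strand = "+")),
    # overlaps the coding gene span
    exon_tbl(list(id = "N2.T1", starts = 11500, ends = 13000, strand = "-")),
    # no repeat overlap
    exon_tbl(list(id = "N3.T1", starts = 30000, ends = 31000, strand = "+"))
  )
  reps <- dplyr::bind_rows(
    repeat_tbl("chr1", 20000, 20300, subfamily = "LTR5_Hs", family = "ERVK",
               repeat_class = "LTR"),
    repeat_tbl("chr1", 20900, 21200, subfamily = "L1HS", family = "L1",
               repeat_class = "LINE"))
  cry <- classify_cryptic(tx, coding, reps)
  expect_equal(cry$transcript_id, "N1.T1")
  expect_equal(cry$subfamily, "LTR5_Hs") # maximal overlap wins
  expect_equal(cry$overlap_bp, 300)
})

test_that("coding-overlap modes differ for antisense transcripts", {
  coding <- exon_tbl(list(id = "CG1.T1", starts = 10000, ends = 11000,
                          strand = "+", coding = TRUE))
  anti <- exon_tbl(list(id = "A1.T1", starts = 10200, ends = 10800,
                        strand = "-"))
  reps <- repeat_tbl("chr1", 10300, 10600)
  expect_equal(nrow(classify_cryptic(anti, coding, reps)), 0)
  sym <- classify_cryptic(anti, coding, reps,
                          overlap_mode = "exon_same_strand")
  expect_equal(sym$transcript_id, "A1.T1")
})

test_that("repeat assignment ties break by element start then subfamily", {
  tx <- exon_tbl(list(id = "T1.T1", starts = 1000, ends = 2000,
                      strand = "+"))
  reps <- dplyr::bind_rows(
    repeat_tbl("chr1", 1500, 1700, subfamily = "AluY"),
    repeat_tbl("chr1", 1200, 1400, subfamily = "AluSx"))
  got <- classify_cryptic(tx, tx[0, ], reps)
  expect_equal(got$subfamily, "AluSx") # equal overlap, lower start wins
})

test_that("classification equals a brute-force classifier on synthetic designs", {
  for (s in c(51, 52)) {
    ann <- simulate_annotation(simulation_design(seed = s))
    got <- classify_cryptic(ann$transcripts, ann$reference, ann$repeats)
    # brute force: span overlap vs coding spans, exon loops vs repeats
    tx <- transcript_summary(ann$transcripts)
    spans <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(ann$reference, coding), gene_id),
      chrom = chrom[1], start = min(start), end = max(end))
    keep <- character(); assigned <- character()
    for (i in seq_len(nrow(tx))) {
      if (tx$coding[i]) next
      cod_ov <- any(spans$chrom == tx$chrom[i] &
                      pmin(spans$end, tx$end[i]) -
                      pmax(spans$start, tx$start[i]) > 0)
      if (cod_ov) next
      ex <- ann$transcripts[ann$transcripts$transcript_id ==
                              tx$transcript_id[i], ]
      best_bp <- 0; best <- NA
      for (j in seq_len(nrow(ann$repeats))) {
        rj <- ann$repeats[j, ]
        if (!rj$repeat_class %in% c("LTR", "LINE", "SINE")) next
        bp <- sum(pmax(0, pmin(ex$end, rj$end) - pmax(ex$start, rj$start)) *
                    (ex$chrom == rj$chrom))
        if (bp > best_bp) { best_bp <- bp; best <- rj$subfamily }
      }
      if (best_bp > 0) {
        keep <- c(keep, tx$transcript_id[i])
        assigned <- c(assigned, best)
      }
    }
    expect_setequal(got$transcript_id, keep)
    expect_equal(got$subfamily, assigned[match(got$transcript_id, keep)])
  }
})

test_that("HIF association requires the summit inside the half-open promoter", {
  cry <- tibble::tibble(transcript_id = "t", gene_id = "g", chrom = "chr1",
                        strand = "+", start = 10000, end = 12000,
                        exonic_bp = 2000, tss = 10000)
  # promoter is [8000, 10500)
  at_start <- tibble::tibble(chrom = "chr1", start = 7900, end = 8300,
                             summit = 8000)
  expect_true(annotate_hif_bound(cry, at_start)$hif_bound)
  at_end <- dplyr::mutate(at_start, summit = 10500)
  expect_false(annotate_hif_bound(cry, at_end)$hif_bound)
  # peak overlapping the promoter but summit outside does not qualify
  overlap_only <- tibble::tibble(chrom = "chr1", start = 10300, end = 10700,
                                 summit = 10600)
  expect_false(annotate_hif_bound(cry, overlap_only)$hif_bound)
})

test_that("union-mode counting assigns unique single-gene fragments only", {
  tx <- dplyr::bind_rows(
    exon_tbl(list(id = "G1.T1", starts = 1000, ends = 2000, strand = "+")),
    exon_tbl(list(id = "G2.T1", starts = 1900, ends = 3000, strand = "+")))
  frag <- function(qname, start, end, strand = "-", unique = TRUE) {
    tibble::tibble(qname = qname, chrom = "chr1", start = start, end = end,
                   strand = strand, unique = unique, sample = "s1")
  }
  counts <- count_reads(dplyr::bind_rows(
    frag("a", 1100, 1180),            # inside G1 only
    frag("b", 1950, 1990),            # touches G1 and G2 -> ambiguous
    frag("c", 2500, 2580, unique = FALSE), # multimapper
    frag("d", 1100, 1180, strand = "+")    # wrong strand under reverse
  ), tx)
  m <- count_mat(counts)
  expect_equal(m["G1", "s1"], 1)
  expect_equal(m["G2", "s1"], 0)
  # unstranded mode counts the sense fragment too
  m2 <- count_mat(count_reads(frag("d", 1100, 1180, strand = "+"), tx,
                              strandedness = "unstranded"))
  expect_equal(m2["G1", "s1"], 1)
})

test_that("counting matches the enumeration oracle on random fixtures", {
  set.seed(42)
  tx <- dplyr::bind_rows(purrr::map(1:6, function(g) {
    st <- 5000 * g
    exon_tbl(list(id = sprintf("G%d.T1", g), starts = c(st, st + 1500),
                  ends = c(st + 800, st + 2300),
                  strand = sample(c("+", "-"), 1)))
  }))
  st <- floor(runif(300) * 33000)
  frags <- tibble::tibble(
    qname = sprintf("r%03d", 1:300), chrom = "chr1",
    start = st, end = st + 80,
    strand = sample(c("+", "-"), 300, replace = TRUE),
    unique = runif(300) > 0.1,
    sample = sample(c("s1", "s2"), 300, replace = TRUE))
  for (mode in c("reverse", "unstranded")) {
    got <- count_mat(count_reads(frags, tx, strandedness = mode))
    want <- bf_count_reads(frags, tx, strandedness = mode)
    expect_equal(got[rownames(want), colnames(want)], want)
  }
})

test_that("expression filtering needs count > 10 and RPKM > 1 somewhere", {
  counts <- tibble::tibble(
    feature_id = c("kept", "low_count", "low_rpkm"),
    length_bp = c(1000, 1000, 100000),
    s1 = c(12, 9, 11), s2 = c(0, 8, 0), s3 = c(0, 5, 0))
  got <- filter_expressed(counts, lib_sizes = c(s1 = 1e6, s2 = 1e6, s3 = 1e6))
  expect_equal(got$kept, c(TRUE, FALSE, FALSE))
  expect_equal(got$max_rpkm[1], 12)
  expect_error(filter_expressed(counts, lib_sizes = c(s1 = 0, s2 = 1, s3 = 1)),
               "library")
})

test_that("normalisation identities hold", {
  counts <- tibble::tibble(feature_id = c("a", "b"),
                           length_bp = c(1000, 2000),
                           s1 = c(100, 200))
  tpm <- normalize_expression(counts, "tpm_offset")
  expect_equal(tpm$s1, c(500000.01, 500000.01)) # equal per-bp rates
  expect_equal(sum(tpm$s1 - 0.01), 1e6)
  cpm <- normalize_expression(counts, "cpm_log", lib_sizes = c(s1 = 1e6))
  expect_equal(cpm$s1, log2(c(100, 200) + 1))
  rpkm <- normalize_expression(counts, "rpkm", lib_sizes = c(s1 = 1e6))
  expect_equal(rpkm$s1, c(100, 100))
  bad <- dplyr::mutate(counts, length_bp = c(0, 100))
  expect_error(normalize_expression(bad, "tpm_offset"), "length")
})

test_that("cryptic load is the cryptic/coding count ratio and scale-invariant", {
  counts <- tibble::tibble(feature_id = c("c1", "g1"), length_bp = 1000,
                           s1 = c(50, 10000), s2 = c(0, 5000))
  load <- cryptic_load(counts, "c1", "g1")
  expect_equal(load$load, c(0.005, 0))
  doubled <- dplyr::mutate(counts, s1 = s1 * 2, s2 = s2 * 2)
  expect_equal(cryptic_load(doubled, "c1", "g1")$load, load$load)
  expect_error(cryptic_load(counts, "c1", "c1"), "disjoint")
  counts0 <- dplyr::mutate(counts, s1 = c(50, 0), s2 = c(0, 0))
  expect_warning(l0 <- cryptic_load(counts0, "c1", "g1"), "zero")
  expect_true(all(is.na(l0$load)))
})

test_that("subfamily aggregation preserves totals and ignores row order", {
  counts <- tibble::tibble(feature_id = c("t1", "t2", "t3"),
                           length_bp = 1000,
                           s1 = c(5, 7, 2), s2 = c(1, 0, 4))
  asg <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                        subfamily = c("AluY", "AluY", "L1HS"))
  agg <- aggregate_by_subfamily(counts, asg)
  m <- count_mat(agg)
  expect_equal(m["AluY", ], c(s1 = 12, s2 = 1))
  expect_equal(colSums(m), colSums(count_mat(counts)))
  shuffled <- aggregate_by_subfamily(counts[c(3, 1, 2), ], asg)
  expect_equal(as.data.frame(shuffled), as.data.frame(agg))
})

test_that("size factors and BH adjustment match their definitions", {
  m <- matrix(c(10, 20, 100, 200, 30, 60), nrow = 3, byrow = TRUE)
  colnames(m) <- c("s1", "s2")
  sf <- size_factors_mor(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), bf_bh(p))
  }
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("differential expression flags planted effects and skips zero rows", {
  sim <- simulate_nb_matrix(60, 5, base_mean = 200,
                            log2fc = c(rep(0, 50), rep(3, 10)),
                            dispersion = 0.05, seed = 44)
  counts <- sim$counts
  counts[counts$feature_id == "gene00001",
         count_samples(counts)] <- as.list(rep(0, 10))
  de <- differential_expression(counts, sim$groups)
  expect_true(is.na(de$p_value[1]))
  expect_true(all(de$padj[51:60] < 0.01))
  expect_true(all(de$log2fc[51:60] > 1.5))
  expect_true(all(de$padj >= de$p_value, na.rm = TRUE))
  expect_equal(glance(de)$n_tested, 59)
  expect_error(differential_expression(counts, c(sim$groups[-1])),
               "group label")
  expect_error(
    differential_expression(counts,
                            stats::setNames(rep("g1", 10),
                                            count_samples(counts))),
    "two conditions")
})
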