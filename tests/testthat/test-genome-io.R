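test_that("GTF coordinates convert between 1-based closed and 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.T1"; transcript_biotype "protein_coding";',
    'chr1\tsrc\texon\t1001\t1200\t.\t-\t.\tgene_id "G2"; transcript_id "G2.T1";',
    'chr1\tsrc\texon\t1401\t1600\t.\t-\t.\tgene_id "G2"; transcript_id "G2.T1";'
  ), gtf)
  ex <- read_gtf(gtf)
  t1 <- ex[ex$transcript_id == "G1.T1", ]
  expect_equal(t1$start, 1000)
  expect_equal(t1$end, 1200)
  expect_true(t1$coding)
  tx <- transcript_summary(ex)
  expect_equal(tx$tss[tx$transcript_id == "G2.T1"], 1599)
  expect_false(tx$coding[tx$transcript_id == "G2.T1"])
})

test_that("GTF read/write round-trip is lossless and book-ended exons merge", {
  ex <- exon_tbl(
    list(id = "A.T1", starts = c(100, 300), ends = c(200, 500),
         strand = "-", coding = TRUE),
    list(id = "B.T1", starts = 1000, ends = 1600, strand = ".")
  )
  path <- tempfile(fileext = ".gtf")
  write_gtf(ex, path)
  back <- read_gtf(path)
  expect_equal(as.data.frame(dplyr::arrange(back, transcript_id, start)),
               as.data.frame(dplyr::arrange(ex, transcript_id, start)))
  # book-ended exons merge on read
  ex2 <- exon_tbl(list(id = "C.T1", starts = c(100, 200), ends = c(200, 300)))
  write_gtf(ex2, path)
  merged <- read_gtf(path)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 300))
  # empty set gives a header-only file that reads back empty
  write_gtf(ex[0, ], path)
  expect_equal(nrow(read_gtf(path)), 0)
})

test_that("exon features without transcript_id are a parse error", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t10\t20\t.\t+\t.\tgene_id "G1";', gtf)
  expect_error(read_gtf(gtf), "transcript_id")
})

test_that("narrowPeak summits follow the column-10 offset rules", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\t.\t0\t.\t5\t9\t7\t50",
               "chr1\t100\t300\t.\t0\t.\t5\t9\t7\t-1"), np)
  pk <- read_narrowpeak(np)
  expect_equal(pk$summit, c(150, 200))
  # summit outside the interval is rejected with a warning
  writeLines("chr1\t100\t300\tbad\t0\t.\t5\t9\t7\t900", np)
  expect_warning(pk2 <- read_narrowpeak(np), "summit")
  expect_equal(nrow(pk2), 0)
  # a 3-column BED is not narrowPeak
  writeLines("chr1\t100\t300", np)
  expect_error(read_narrowpeak(np), "format")
})

test_that("narrowPeak read/write round-trip preserves canonical fields", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\tp1\t10\t+\t5.5\t9\t7\t50",
               "chr2\t0\t900\tp2\t0\t.\t1\t2\t3\t450"), np)
  pk <- read_narrowpeak(np)
  out <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, out)
  expect_equal(as.data.frame(read_narrowpeak(out)), as.data.frame(pk))
})

test_that("BED regions keep overlapping rows and empty files give empty sets", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600", "chr1\t300\t700"), bed)
  r <- read_bed_regions(bed)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(100, 300))
  file.create(bed2 <- tempfile(fileext = ".bed"))
  expect_equal(nrow(read_bed_regions(bed2)), 0)
})

test_that("RepeatMasker .out dialect maps C strand and consensus columns", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)  ID",
    "",
    " 1500 10.0  0.1  0.2  chr1        101      600   (9400) +  AluY           SINE/Alu               1  500   (11)   1",
    " 1200 12.0  0.1  0.2  chr1       2001     2400   (7600) C  L1HS           LINE/L1             (200) 6000  5601    2",
    "  800  8.0  0.0  0.0  chr1       5001     5100   (4900) +  MER20          DNA/hAT-Charlie        1  100    (0)   3"
  ), out)
  r <- read_repeat_annotation(out, dialect = "repeatmasker_out")
  expect_equal(r$start, c(100, 2000, 5000))
  expect_equal(r$strand, c("+", "-", "+"))
  expect_equal(r$repeat_class, c("SINE", "LINE", "other"))
  expect_equal(r$family, c("Alu", "L1", "hAT-Charlie"))
  # consensus interval of the C-strand row comes from the swapped columns
  expect_equal(r$consensus_start[2], 5600)
  expect_equal(r$consensus_end[2], 6000)
})

test_that("BED repeat dialect resolves families and warns on unknown subfamilies", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tAluY\t0\t+",
               "chr1\t700\t900\tNOSUCH\t0\t-"), bed)
  expect_warning(r <- read_repeat_annotation(bed, dialect = "bed"), "NOSUCH")
  expect_equal(r$repeat_class, c("SINE", "other"))
  expect_equal(r$family[1], "Alu")
})

test_that("methylation tables compute betas from counts and reject bad records", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tmethylated\ttotal",
               "chr1\t101\t8\t10",
               "chr1\t201\t0\t0"), tsv)
  expect_warning(m <- read_methylation_table(tsv, "cpg_counts"), "zero coverage")
  expect_equal(nrow(m), 1)
  expect_equal(m$beta, 0.8)
  expect_equal(m$pos, 100) # 1-based input to 0-based
  # probe tables pivot one record per (position, sample)
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("probe\tchrom\tpos\ts1\ts2",
               "cg01\tchr1\t501\t0.1\t0.9"), tsv2)
  p <- read_methylation_table(tsv2, "probe_betas")
  expect_equal(nrow(p), 2)
  expect_setequal(p$sample, c("s1", "s2"))
  expect_setequal(p$beta, c(0.1, 0.9))
})

test_that("SAM alignments split on N gaps and honour uniqueness rules", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    sprintf("r1\t0\tchr1\t101\t255\t50M1000N50M\t*\t0\t0\t%s\t*\tNH:i:1",
            strrep("A", 100)),
    sprintf("r2\t16\tchr1\t201\t3\t60M\t*\t0\t0\t%s\t*\tNH:i:2",
            strrep("A", 60)),
    sprintf("r3\t256\tchr1\t301\t255\t40M\t*\t0\t0\t%s\t*\tNH:i:1",
            strrep("A", 40))
  ), sam)
  fr <- read_alignments(sam)
  r1 <- fr[fr$qname == "r1", ]
  expect_equal(nrow(r1), 2) # the N gap starts a second block
  expect_equal(r1$start, c(100, 1150))
  expect_equal(r1$end - r1$start, c(50, 50))
  expect_false(any(fr$unique[fr$qname == "r2"])) # NH=2
  expect_false("r3" %in% fr$qname) # secondary alignments dropped
  expect_equal(fr$strand[fr$qname == "r2"][1], "-")
  # mapq rule instead of the NH tag
  fr2 <- read_alignments(sam, unique_rule = "mapq_threshold")
  expect_true(all(fr2$unique[fr2$qname == "r1"]))
  expect_false(any(fr2$unique[fr2$qname == "r2"]))
  # a missing @SQ header is an error
  writeLines(c("@HD\tVN:1.6", "r1\t0\tchr1\t101\t255\t10M\t*\t0\t0\tAAAAAAAAAA\t*"),
             sam)
  expect_error(read_alignments(sam), "@SQ")
})

test_that("interval overlap queries respect half-open semantics", {
  a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  b <- tibble::tibble(chrom = "chr1", start = c(150, 200), end = c(250, 300))
  ov <- query_overlaps(a, b)
  expect_equal(nrow(ov), 1) # the touching interval never overlaps
  expect_equal(ov$overlap_bp, 50)
  # unknown query chromosome is an empty result, not an error
  expect_equal(nrow(query_overlaps(
    tibble::tibble(chrom = "chrZ", start = 0, end = 10), b)), 0)
})

test_that("overlap queries match the brute-force all-pairs oracle", {
  set.seed(11)
  for (mode in c("ignore", "same", "opposite")) {
    x <- random_intervals(60, stranded = TRUE)
    y <- random_intervals(60, stranded = TRUE)
    got <- query_overlaps(x, y, strand_mode = mode)
    want <- bf_overlaps(x, y, strand_mode = mode)
    got <- got[order(got$x_idx, got$y_idx), ]
    want <- want[order(want$x_idx, want$y_idx), ]
    expect_equal(got$x_idx, want$x_idx)
    expect_equal(got$y_idx, want$y_idx)
    expect_equal(got$overlap_bp, want$overlap_bp)
  }
})

test_that("nearest-feature distances match the oracle and break ties low", {
  feats <- tibble::tibble(chrom = "chr1", start = c(1500, 300),
                          end = c(1501, 301))
  got <- nearest_feature_distance(
    tibble::tibble(chrom = "chr1", pos = 1000), feats)
  expect_equal(got$distance, 500)
  inside <- nearest_feature_distance(
    tibble::tibble(chrom = "chr1", pos = 300), feats)
  expect_equal(inside$distance, 0)
  # equidistant features resolve to the lower start
  tie_feats <- tibble::tibble(chrom = "chr1", start = c(900, 1100),
                              end = c(950, 1150))
  tie <- nearest_feature_distance(
    tibble::tibble(chrom = "chr1", pos = 1024), tie_feats)
  expect_equal(tie$feature_idx, 1)
  set.seed(12)
  feats <- random_intervals(50)
  pts <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                        pos = floor(runif(50) * 11000))
  got <- nearest_feature_distance(pts, feats)
  want <- bf_nearest(pts, feats)
  expect_equal(got$distance, want[, 2])
  expect_equal(got$feature_idx, as.integer(want[, 1]))
})

test_that("genome layouts validate and read from chrom.sizes", {
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_layout("a", 0), "positive")
  path <- tempfile()
  writeLines("chr1\t1000\nchr2\t2000", path)
  lay <- read_chrom_sizes(path)
  expect_equal(lay$length, c(1000, 2000))
})
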