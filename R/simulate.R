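#' Build a simulation design
#'
#' Bundles all parameters of the synthetic fixtures: a toy two-chromosome
#' genome laid out in 10-kb feature slots holding coding genes, decoy
#' noncoding transcripts, cryptic transcripts planted on LTR/LINE/SINE
#' elements, background repeats, ChIP peaks with designed
#' presence/absence ratios, planted HRE motifs, an NB count model for the
#' tumor cohort, and a promoter methylation model. Every generator draws
#' its randomness from `seed`.
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named bp lengths of the toy chromosomes.
#' @param n_coding,n_noncoding_decoy,n_overlap_decoy Feature counts:
#'   coding genes, noncoding transcripts without repeat overlap, noncoding
#'   transcripts overlapping a coding gene (both decoy kinds must never be
#'   classified cryptic).
#' @param n_cryptic Named integer: planted cryptic transcripts per repeat
#'   class.
#' @param n_background_repeats Repeat elements outside any transcript.
#' @param n_background_peaks Peaks far from every promoter.
#' @param frac_hif_bound Fraction of cryptic transcripts given a peak
#'   summit inside their promoter.
#' @param n_motifs Planted RCGTG motifs (outside peaks by construction).
#' @param peak_width Width of generated peaks in bp.
#' @param background_depth Coverage depth outside summit windows; 7.5 so
#'   that with the pseudodepth 0.5 the denominator is exactly 8 and
#'   planted ratios are floating-point exact.
#' @param ratio_present,ratio_absent,ratio_unclassified Designed effective
#'   coverage ratios (the quantity the presence rule thresholds).
#' @param n_per_cell Tumors per oxygenation x methylation design cell.
#' @param base_mean NB mean of a cryptic transcript in the reference cell
#'   (hypoxic, low methylation).
#' @param b_oxy,b_meth,b_int Log-scale effects of normoxia (oxy = 1), high
#'   methylation (meth = 1) and their interaction; a positive `b_int`
#'   is cooperative enhancement in hypoxic low-methylation tumors.
#' @param dispersion NB dispersion alpha of the count model.
#' @param coding_base_mean NB mean of coding genes.
#' @param signature_shift Log2 shift of the hypoxia signature genes in
#'   hypoxic tumors.
#' @param beta_low,beta_high,beta_sd Promoter methylation stratum means
#'   and probe-level noise sd.
#' @param probes_per_promoter CpG probes simulated per cryptic promoter.
#' @param meth_coverage Range of simulated bisulfite coverages.
#' @param excluded_fraction Fraction of the genome marked as excluded
#'   ("poorly mapping") regions for the shuffle engine.
#' @return A list of class `credentor_design`.
#' @export
simulation_design <- function(seed = 1,
                              chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                              n_coding = 25,
                              n_noncoding_decoy = 8,
                              n_overlap_decoy = 4,
                              n_cryptic = c(LTR = 5, LINE = 5, SINE = 5),
                              n_background_repeats = 30,
                              n_background_peaks = 8,
                              frac_hif_bound = 0.5,
                              frac_sense_antisense = 0.25,
                              frac_palindromic = 0.25,
                              n_motifs = 40,
                              peak_width = 400,
                              background_depth = 7.5,
                              ratio_present = 6,
                              ratio_absent = 1.5,
                              ratio_unclassified = 3,
                              n_per_cell = 25,
                              base_mean = 60,
                              b_oxy = -0.7,
                              b_meth = -0.7,
                              b_int = log(2),
                              dispersion = 0.2,
                              coding_base_mean = 200,
                              signature_shift = 3,
                              beta_low = 0.3,
                              beta_high = 0.8,
                              beta_sd = 0.08,
                              probes_per_promoter = 3,
                              meth_coverage = c(45, 90),
                              excluded_fraction = 0) {
  design <- as.list(environment())
  class(design) <- "credentor_design"
  design
}

subfamilies_by_class <- list(
  LTR = c("LTR5_Hs", "IAPEz-int", "THE1B"),
  LINE = c("L1HS", "L1PA2", "L2a"),
  SINE = c("AluY", "AluSx", "MIR")
)

#' Generate the synthetic genome annotation
#'
#' Lays out coding genes, decoy noncoding transcripts, cryptic transcripts
#' (each with a retrotransposon element fully inside its first exon and a
#' smaller distractor element to exercise the maximal-overlap assignment),
#' background repeats, HIF peaks (summits planted inside the promoters of
#' the designated cryptic transcripts, plus background peaks far from any
#' promoter) and HRE motif positions, one feature per 10-kb slot, with
#' per-slot random jitter. The layout guarantees the classification truth
#' by construction.
#'
#' @param design A [simulation_design()].
#' @return A list: `layout`, `transcripts` (exon tibble of the merged
#'   assembly), `reference` (coding-gene exon tibble), `repeats`, `peaks`
#'   (narrowPeak-style tibble), `motifs` (planted motif tibble), `truth`
#'   (per-transcript truth table), `excluded` (excluded regions tibble).
#' @export
simulate_annotation <- function(design) {
  set.seed(design$seed)
  layout <- genome_layout(names(design$chrom_lengths),
                          unname(design$chrom_lengths))
  slot_w <- 10000
  slots <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    n <- floor(layout$length[i] / slot_w)
    tibble::tibble(chrom = layout$chrom[i],
                   slot_start = (seq_len(n) - 1) * slot_w)
  })
  n_cry <- sum(design$n_cryptic)
  need <- design$n_coding + design$n_noncoding_decoy + n_cry +
    design$n_background_repeats + design$n_background_peaks +
    ceiling(design$n_motifs / 8)
  if (need > nrow(slots)) stop("features exceed chromosome capacity")
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  take <- function(n) {
    if (n == 0) return(slots[0, , drop = FALSE])
    out <- slots[seq_len(n), , drop = FALSE]
    slots <<- slots[-seq_len(n), , drop = FALSE]
    out
  }

  exons <- list(); repeats <- list(); truth <- list()
  peaks <- list(); motifs <- list()

  # coding genes (the first n_overlap_decoy also host an overlapping decoy)
  cod <- take(design$n_coding)
  for (i in seq_len(design$n_coding)) {
    b <- cod$slot_start[i] + sample(0:1000, 1)
    chrom <- cod$chrom[i]
    strand <- sample(c("+", "-"), 1)
    e1 <- sample(300:800, 1); gap <- sample(300:800, 1)
    e2 <- sample(400:1000, 1)
    gid <- sprintf("GENE%03d", i)
    exons[[length(exons) + 1]] <- tibble::tibble(
      transcript_id = paste0(gid, ".T1"), gene_id = gid, chrom = chrom,
      start = c(b + 1000, b + 1000 + e1 + gap),
      end = c(b + 1000 + e1, b + 1000 + e1 + gap + e2),
      strand = strand, coding = TRUE)
    truth[[length(truth) + 1]] <- tibble::tibble(
      transcript_id = paste0(gid, ".T1"), role = "coding",
      is_cryptic = FALSE, subfamily = NA_character_,
      repeat_class = NA_character_, hif_bound = NA)
    if (i <= design$n_overlap_decoy) {
      tid <- sprintf("DECOY_OV%02d.T1", i)
      exons[[length(exons) + 1]] <- tibble::tibble(
        transcript_id = tid, gene_id = sprintf("DECOY_OV%02d", i),
        chrom = chrom, start = b + 1100, end = b + 1100 + 250,
        strand = strand, coding = FALSE)
      truth[[length(truth) + 1]] <- tibble::tibble(
        transcript_id = tid, role = "overlap_decoy", is_cryptic = FALSE,
        subfamily = NA_character_, repeat_class = NA_character_,
        hif_bound = NA)
    }
  }

  # cryptic transcripts
  classes <- rep(names(design$n_cryptic), design$n_cryptic)
  cry <- take(n_cry)
  bound_flags <- sample(seq_len(n_cry) <= round(design$frac_hif_bound * n_cry))
  # disjoint subsets get a planted antisense partner / inverted repeat pair
  n_sa <- round(design$frac_sense_antisense * n_cry)
  n_pal <- round(design$frac_palindromic * n_cry)
  if (n_sa + n_pal > n_cry) stop("dsRNA fractions exceed the cryptic set")
  ds_kind <- sample(rep(c("sense_antisense", "palindromic", "none"),
                        c(n_sa, n_pal, n_cry - n_sa - n_pal)))
  for (i in seq_len(n_cry)) {
    b <- cry$slot_start[i] + sample(0:1000, 1)
    chrom <- cry$chrom[i]
    strand <- sample(c("+", "-"), 1)
    cls <- classes[i]
    subf <- sample(subfamilies_by_class[[cls]], 1)
    rw <- sample(300:600, 1)
    rep_start <- b + 2200
    exon1 <- c(b + 2000, rep_start + rw + 200)
    gap <- sample(200:600, 1); e2 <- sample(200:500, 1)
    exon2 <- c(exon1[2] + gap, exon1[2] + gap + e2)
    tid <- sprintf("CRYPTIC%03d.T1", i)
    exons[[length(exons) + 1]] <- tibble::tibble(
      transcript_id = tid, gene_id = sprintf("CRYPTIC%03d", i),
      chrom = chrom, start = c(exon1[1], exon2[1]),
      end = c(exon1[2], exon2[2]), strand = strand, coding = FALSE)
    # main element fully inside exon 1; smaller distractor of another
    # subfamily straddling the exon start
    other <- sample(setdiff(unlist(subfamilies_by_class), subf), 1)
    other_cls <- names(subfamilies_by_class)[
      purrr::map_lgl(subfamilies_by_class, ~ other %in% .x)]
    repeats[[length(repeats) + 1]] <- tibble::tibble(
      chrom = chrom, start = c(rep_start, exon1[1] - 100),
      end = c(rep_start + rw, exon1[1] + 100),
      strand = sample(c("+", "-"), 2, replace = TRUE),
      subfamily = c(subf, other),
      family = c(cls, other_cls), repeat_class = c(cls, other_cls),
      consensus_start = c(0, 0), consensus_end = c(rw, 200))
    if (ds_kind[i] == "sense_antisense") {
      # partner transcript on the opposite strand overlapping exon 2
      pid <- sprintf("ANTISENSE%03d", i)
      exons[[length(exons) + 1]] <- tibble::tibble(
        transcript_id = paste0(pid, ".T1"), gene_id = pid, chrom = chrom,
        start = exon2[1] + 50, end = exon2[2] + 300,
        strand = if (strand == "+") "-" else "+", coding = FALSE)
      truth[[length(truth) + 1]] <- tibble::tibble(
        transcript_id = paste0(pid, ".T1"), role = "antisense_partner",
        is_cryptic = FALSE, subfamily = NA_character_,
        repeat_class = NA_character_, hif_bound = NA)
    } else if (ds_kind[i] == "palindromic") {
      # same subfamily, opposite orientation, inside exon 2 and smaller
      # than the main element so the assignment is unchanged
      main_strand <- repeats[[length(repeats)]]$strand[1]
      repeats[[length(repeats) + 1]] <- tibble::tibble(
        chrom = chrom, start = exon2[1] + 20, end = exon2[1] + 170,
        strand = if (main_strand == "+") "-" else "+",
        subfamily = subf, family = cls, repeat_class = cls,
        consensus_start = 0, consensus_end = 150)
    }
    tss <- if (strand == "+") exon1[1] else exon2[2] - 1
    if (bound_flags[i]) {
      summit <- if (strand == "+") tss + 250 else tss - 250
      peaks[[length(peaks) + 1]] <- tibble::tibble(
        chrom = chrom, start = summit - design$peak_width / 2,
        end = summit + design$peak_width / 2,
        name = sprintf("peak_prom_%03d", i), summit = summit)
    }
    truth[[length(truth) + 1]] <- tibble::tibble(
      transcript_id = tid, role = "cryptic", is_cryptic = TRUE,
      subfamily = subf, repeat_class = cls, hif_bound = bound_flags[i],
      sense_antisense = ds_kind[i] == "sense_antisense",
      palindromic = ds_kind[i] == "palindromic")
  }

  # noncoding decoys without any repeat overlap
  dec <- take(design$n_noncoding_decoy)
  for (i in seq_len(design$n_noncoding_decoy)) {
    b <- dec$slot_start[i] + sample(0:1000, 1)
    tid <- sprintf("DECOY_NC%02d.T1", i)
    exons[[length(exons) + 1]] <- tibble::tibble(
      transcript_id = tid, gene_id = sprintf("DECOY_NC%02d", i),
      chrom = dec$chrom[i],
      start = c(b + 2000, b + 3000), end = c(b + 2600, b + 3400),
      strand = sample(c("+", "-"), 1), coding = FALSE)
    truth[[length(truth) + 1]] <- tibble::tibble(
      transcript_id = tid, role = "noncoding_decoy", is_cryptic = FALSE,
      subfamily = NA_character_, repeat_class = NA_character_,
      hif_bound = NA)
  }

  # background repeats in their own slots
  bg <- take(design$n_background_repeats)
  for (i in seq_len(design$n_background_repeats)) {
    b <- bg$slot_start[i] + sample(0:1000, 1)
    cls <- sample(names(subfamilies_by_class), 1)
    w <- sample(300:600, 1)
    repeats[[length(repeats) + 1]] <- tibble::tibble(
      chrom = bg$chrom[i], start = b + 2000, end = b + 2000 + w,
      strand = sample(c("+", "-"), 1),
      subfamily = sample(subfamilies_by_class[[cls]], 1),
      family = cls, repeat_class = cls,
      consensus_start = 0, consensus_end = w)
  }

  # background peaks far from every promoter
  bgp <- take(design$n_background_peaks)
  for (i in seq_len(design$n_background_peaks)) {
    b <- bgp$slot_start[i] + sample(0:1000, 1)
    summit <- b + 5000
    peaks[[length(peaks) + 1]] <- tibble::tibble(
      chrom = bgp$chrom[i], start = summit - design$peak_width / 2,
      end = summit + design$peak_width / 2,
      name = sprintf("peak_bg_%03d", i), summit = summit)
  }

  # planted motifs, 8 per slot, >= 50 bp apart
  n_motif_slots <- ceiling(design$n_motifs / 8)
  ms <- take(n_motif_slots)
  left <- design$n_motifs
  for (i in seq_len(n_motif_slots)) {
    k <- min(8, left); left <- left - k
    b <- ms$slot_start[i] + sample(0:1000, 1)
    motifs[[length(motifs) + 1]] <- tibble::tibble(
      chrom = ms$chrom[i], start = b + 2000 + (seq_len(k) - 1) * 200,
      strand = sample(c("+", "-"), k, replace = TRUE))
  }

  excluded <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric())
  if (design$excluded_fraction > 0) {
    ex <- take(max(1, round(design$excluded_fraction * nrow(slots))))
    excluded <- tibble::tibble(chrom = ex$chrom, start = ex$slot_start,
                               end = ex$slot_start + slot_w)
  }

  transcripts <- dplyr::bind_rows(exons) |>
    dplyr::arrange(.data$transcript_id, .data$start)
  peaks <- if (length(peaks)) dplyr::bind_rows(peaks) else
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   name = character(), summit = numeric())
  peaks <- dplyr::mutate(peaks, score = 100, strand = ".",
                         signal_value = 10, p_value = -1, q_value = -1)
  motifs <- if (length(motifs)) dplyr::bind_rows(motifs) else
    tibble::tibble(chrom = character(), start = numeric(),
                   strand = character())
  motifs <- dplyr::mutate(motifs, end = .data$start + 5)
  list(layout = layout,
       transcripts = transcripts,
       reference = dplyr::filter(transcripts, .data$coding),
       repeats = dplyr::bind_rows(repeats),
       peaks = peaks,
       motifs = motifs,
       truth = dplyr::bind_rows(truth),
       excluded = excluded,
       design = design)
}

#' Generate the genome sequence with planted HRE motifs
#'
#' Draws a random sequence for each chromosome, removes every accidental
#' RCGTG occurrence (both strands) by iterative base patching, then writes
#' the planted motifs at their recorded positions, so a motif scan finds
#' exactly the planted set.
#'
#' @param annotation Output of [simulate_annotation()] (uses `layout`,
#'   `motifs` and the design seed).
#' @return Named character vector of chromosome sequences.
#' @export
simulate_genome_sequence <- function(annotation) {
  set.seed(annotation$design$seed + 1)
  motifs <- annotation$motifs
  seqs <- purrr::map_chr(seq_len(nrow(annotation$layout)), function(i) {
    chrom <- annotation$layout$chrom[i]
    len <- annotation$layout$length[i]
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    mine <- motifs[motifs$chrom == chrom, , drop = FALSE]
    planted_bases <- unlist(purrr::map(mine$start, ~ .x + 1:5))
    for (j in seq_len(nrow(mine))) {
      core <- if (mine$strand[j] == "+") {
        c(sample(c("A", "G"), 1), "C", "G", "T", "G")
      } else {
        c("C", "A", "C", "G", sample(c("C", "T"), 1))
      }
      s[mine$start[j] + 1:5] <- core
    }
    txt <- paste(s, collapse = "")
    for (iter in 1:50) {
      hits <- c(unlist(gregexpr("(?=[AG]CGTG)", txt, perl = TRUE)),
                unlist(gregexpr("(?=CACG[CT])", txt, perl = TRUE)))
      hits <- hits[hits > 0]
      extra <- setdiff(hits, mine$start + 1)
      if (!length(extra)) break
      for (h in extra) {
        cand <- setdiff(h + 0:4, planted_bases)
        p <- cand[ceiling(length(cand) / 2)]
        s[p] <- "A"
        # an A breaks the hit everywhere except the degenerate R slot;
        # fall back to T there
        if (grepl("^([AG]CGTG|CACG[CT])$",
                  paste(s[h:(h + 4)], collapse = ""))) {
          s[p] <- "T"
        }
      }
      txt <- paste(s, collapse = "")
    }
    txt
  })
  names(seqs) <- annotation$layout$chrom
  seqs
}

#' Generate peaks and coverage tracks realising designed presence ratios
#'
#' Builds, per sample, a bedGraph-style coverage track in which every
#' peak's effective ratio -- `(window mean + eps) / (background mean +
#' eps)` with `eps = 0.5` -- equals the designed value exactly: the
#' background depth is 7.5 genome-wide (so the denominator is exactly 8)
#' and the 200-bp summit window is raised to `8 * ratio - 0.5`.
#'
#' @param design A [simulation_design()].
#' @param ratio_matrix Optional numeric matrix (peaks x samples) of
#'   designed effective ratios; the default builds
#'   `n_background_peaks` peaks in three blocks: shared (present
#'   everywhere), unique to each sample (present in one, absent
#'   elsewhere), and intermediate (unclassified) in all.
#' @param samples Sample names (>= 2).
#' @return A list: `layout`, `peaks`, `ratio_matrix`,
#'   `coverage` (named list of per-sample coverage tibbles), `truth`
#'   (per-peak expected status per sample and comparison category).
#' @export
simulate_peaks_coverage <- function(design,
                                    ratio_matrix = NULL,
                                    samples = c("cellA", "cellB", "cellC")) {
  set.seed(design$seed + 2)
  layout <- genome_layout(names(design$chrom_lengths),
                          unname(design$chrom_lengths))
  n_s <- length(samples)
  if (is.null(ratio_matrix)) {
    blocks <- rbind(
      matrix(design$ratio_present, nrow = 3, ncol = n_s),
      t(sapply(seq_len(n_s), function(i) {
        r <- rep(design$ratio_absent, n_s); r[i] <- design$ratio_present; r
      })),
      matrix(design$ratio_unclassified, nrow = 2, ncol = n_s))
    ratio_matrix <- blocks
  }
  n_p <- nrow(ratio_matrix)
  colnames(ratio_matrix) <- samples
  spacing <- 15000
  per_chrom <- floor((layout$length - spacing) / spacing)
  slots <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    tibble::tibble(chrom = layout$chrom[i],
                   summit = spacing * seq_len(per_chrom[i]))
  })
  if (n_p > nrow(slots)) stop("too many peaks for the genome")
  slots <- slots[seq_len(n_p), , drop = FALSE]
  peaks <- tibble::tibble(
    chrom = slots$chrom, summit = slots$summit,
    start = slots$summit - design$peak_width / 2,
    end = slots$summit + design$peak_width / 2,
    name = sprintf("peak%03d", seq_len(n_p)),
    score = 0, strand = ".", signal_value = 0, p_value = -1, q_value = -1)
  bgd <- design$background_depth
  eps <- 0.5
  coverage <- purrr::map(samples, function(s) {
    purrr::map_dfr(layout$chrom, function(ch) {
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      r <- ratio_matrix[peaks$chrom == ch, s]
      len <- layout$length[layout$chrom == ch]
      if (nrow(pk) == 0) {
        return(tibble::tibble(chrom = ch, start = 0, end = len, depth = bgd))
      }
      w_depth <- r * (bgd + eps) - eps
      starts <- c(0, pk$summit + 100)
      ends <- c(pk$summit - 100, len)
      dplyr::arrange(dplyr::bind_rows(
        tibble::tibble(chrom = ch, start = starts, end = ends, depth = bgd),
        tibble::tibble(chrom = ch, start = pk$summit - 100,
                       end = pk$summit + 100, depth = w_depth)
      ), .data$start)
    })
  })
  names(coverage) <- samples
  rvec <- as.vector(ratio_matrix)
  status <- matrix(dplyr::case_when(rvec > 4 ~ "present",
                                    rvec < 2.5 ~ "absent",
                                    TRUE ~ "unclassified"),
                   nrow = n_p, dimnames = list(NULL, samples))
  category <- apply(status, 1, function(st) {
    if (all(st == "present")) "shared"
    else if (sum(st == "present") == 1 && all(st[st != "present"] == "absent"))
      paste0("unique(", samples[st == "present"], ")")
    else "unclassified"
  })
  truth <- tibble::as_tibble(as.data.frame(status)) |>
    dplyr::mutate(name = peaks$name, category = category)
  list(layout = layout, peaks = peaks, ratio_matrix = ratio_matrix,
       coverage = coverage, truth = truth)
}

#' Simulate the tumor cohort: counts, labels and methylation
#'
#' Draws a cohort with `n_per_cell` tumors in each oxygenation x
#' methylation cell. Cryptic transcript counts follow
#' `NB(mean = exp(log(base_mean) + b_oxy oxy + b_meth meth + b_int oxy
#' meth + log libfactor), alpha)`; coding genes are flat except the
#' hypoxia signature genes, which are shifted up in hypoxic tumors so the
#' clustering can recover the labels; GZMA/PRF1 are included for the
#' cytolytic readout. Promoter probe betas are drawn around the stratum
#' mean of each tumor.
#'
#' @param design A [simulation_design()].
#' @param cryptics Cryptic catalogue (with promoters) from
#'   [classify_cryptic()]/[annotate_hif_bound()]; when `NULL` a fresh
#'   annotation is generated.
#' @return A list: `counts` (count-matrix tibble over coding + cryptic
#'   rows), `labels` (per-tumor truth: `sample`, `oxy_code`, `meth_code`,
#'   `log_offset`), `probes` (methylation records), `cryptic_ids`,
#'   `coding_ids`, `annotation`.
#' @export
simulate_cohort <- function(design, cryptics = NULL) {
  ann <- simulate_annotation(design)
  set.seed(design$seed + 3)
  if (is.null(cryptics)) {
    cryptics <- classify_cryptic(ann$transcripts, ann$reference,
                                 ann$repeats)
    cryptics <- annotate_hif_bound(cryptics, ann$peaks, layout = ann$layout)
  }
  n <- design$n_per_cell * 4
  labels <- tibble::tibble(
    sample = sprintf("tumor%03d", seq_len(n)),
    oxy_code = rep(c(0L, 0L, 1L, 1L), each = design$n_per_cell),
    meth_code = rep(c(0L, 1L, 0L, 1L), each = design$n_per_cell))
  libf <- exp(stats::rnorm(n, 0, 0.15))
  coding_ids <- unique(ann$reference$gene_id)
  sig <- hypoxia_signature()
  extra <- c(sig, "GZMA", "PRF1")
  cry_ids <- cryptics$transcript_id
  mu_cry <- exp(log(design$base_mean) +
                  design$b_oxy * labels$oxy_code +
                  design$b_meth * labels$meth_code +
                  design$b_int * labels$oxy_code * labels$meth_code)
  rows <- list()
  draw_nb <- function(mu) {
    if (design$dispersion <= 1e-8) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / design$dispersion, mu = mu)
  }
  for (id in cry_ids) {
    len <- cryptics$exonic_bp[cryptics$transcript_id == id]
    rows[[id]] <- c(len, draw_nb(mu_cry * libf))
  }
  glen <- gene_lengths(ann$reference)
  for (id in coding_ids) {
    len <- glen$length_bp[glen$feature_id == id]
    rows[[id]] <- c(len, draw_nb(design$coding_base_mean * libf))
  }
  for (g in extra) {
    mu <- design$coding_base_mean *
      2^(if (g %in% sig) design$signature_shift * (labels$oxy_code == 0) else 0)
    rows[[g]] <- c(1000, draw_nb(mu * libf))
  }
  mat <- do.call(rbind, rows)
  counts <- tibble::tibble(feature_id = names(rows), length_bp = mat[, 1])
  for (j in seq_len(n)) counts[[labels$sample[j]]] <- mat[, j + 1]
  # promoter methylation probes per tumor, around the stratum mean
  prom <- tibble::tibble(chrom = cryptics$chrom,
                         start = cryptics$promoter_start,
                         end = cryptics$promoter_end)
  probes <- purrr::map_dfr(seq_len(nrow(prom)), function(i) {
    pos <- round(seq(prom$start[i] + 50, prom$end[i] - 50,
                     length.out = design$probes_per_promoter))
    purrr::map_dfr(seq_len(n), function(j) {
      mean_beta <- if (labels$meth_code[j] == 1) design$beta_high else
        design$beta_low
      tibble::tibble(
        chrom = prom$chrom[i], pos = pos, sample = labels$sample[j],
        beta = pmin(1, pmax(0, stats::rnorm(length(pos), mean_beta,
                                            design$beta_sd))),
        coverage = sample(design$meth_coverage[1]:design$meth_coverage[2],
                          length(pos), replace = TRUE))
    })
  })
  coding_totals <- colSums(mat[coding_ids, -1, drop = FALSE])
  labels$log_offset <- log(coding_totals)
  list(counts = counts, labels = labels, probes = probes,
       cryptic_ids = cry_ids,
       coding_ids = coding_ids, annotation = ann, cryptics = cryptics)
}

#' Simulate a two-group NB count matrix
#'
#' Convenience generator for differential-expression checks: a matrix of
#' NB counts with given per-group log2 fold changes.
#'
#' @param n_genes Number of rows.
#' @param n_per_group Samples per group (two groups).
#' @param base_mean NB mean in group 1.
#' @param log2fc Scalar or per-gene vector of log2 fold changes of group 2
#'   over group 1.
#' @param dispersion NB dispersion alpha.
#' @param lib_sizes Optional per-sample library scale factors.
#' @param seed Optional seed.
#' @return A list: `counts` (count-matrix tibble, `length_bp` 1000),
#'   `groups` (named vector).
#' @export
simulate_nb_matrix <- function(n_genes, n_per_group, base_mean = 100,
                               log2fc = 0, dispersion = 0.1,
                               lib_sizes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_group
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n)
  lfc <- rep_len(log2fc, n_genes)
  grp <- rep(c("g1", "g2"), each = n_per_group)
  mu <- outer(rep(base_mean, n_genes), lib_sizes) *
    2^outer(lfc, as.numeric(grp == "g2"))
  m <- matrix(stats::rnbinom(n_genes * n, size = 1 / max(dispersion, 1e-8),
                             mu = mu), nrow = n_genes)
  counts <- tibble::tibble(feature_id = sprintf("gene%05d", seq_len(n_genes)),
                           length_bp = 1000)
  samples <- sprintf("s%02d", seq_len(n))
  for (j in seq_len(n)) counts[[samples[j]]] <- m[, j]
  list(counts = counts, groups = stats::setNames(grp, samples),
       log2fc = lfc)
}

#' Simulate aligned fragments consistent with a count matrix
#'
#' Emits, per gene and sample, exactly the counted number of unique
#' fragments, each a single block inside the gene's first exon on the
#' strand implied by the library protocol, so [count_reads()] reproduces
#' the matrix exactly. Optionally adds non-unique decoy fragments that
#' must never be counted.
#'
#' @param counts Count-matrix tibble.
#' @param transcripts Exon-level annotation (genes must not overlap).
#' @param strandedness Library protocol the fragments should follow.
#' @param n_multimappers Non-unique decoy fragments to add.
#' @return Block-level fragment tibble for [count_reads()]/[write_sam()].
#' @export
simulate_fragments <- function(counts, transcripts,
                               strandedness = "reverse",
                               n_multimappers = 0) {
  first_exons <- transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  samples <- count_samples(counts)
  frag_strand <- function(tx_strand) {
    switch(strandedness,
           reverse = ifelse(tx_strand == "+", "-", "+"),
           forward = tx_strand,
           unstranded = tx_strand)
  }
  out <- purrr::map_dfr(samples, function(s) {
    k <- counts[[s]]
    idx <- rep(seq_len(nrow(counts)), k)
    if (!length(idx)) return(NULL)
    ex <- first_exons[match(counts$feature_id[idx], first_exons$gene_id), ]
    w <- pmin(80, ex$end - ex$start)
    tibble::tibble(
      qname = sprintf("%s_frag%06d", s, seq_along(idx)),
      chrom = ex$chrom, start = ex$start, end = ex$start + w,
      strand = frag_strand(ex$strand), unique = TRUE, sample = s)
  })
  if (n_multimappers > 0) {
    ex <- first_exons[sample.int(nrow(first_exons), n_multimappers,
                                 replace = TRUE), ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      qname = sprintf("multi_frag%06d", seq_len(n_multimappers)),
      chrom = ex$chrom, start = ex$start,
      end = ex$start + pmin(80, ex$end - ex$start),
      strand = frag_strand(ex$strand), unique = FALSE,
      sample = samples[1]))
  }
  out
}
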