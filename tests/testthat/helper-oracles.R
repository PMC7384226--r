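# Brute-force oracles, deliberately independent of the package's
# implementation paths: nested loops and direct enumeration only.

bf_overlaps <- function(x, y, strand_mode = "ignore") {
  out <- list()
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] != y$chrom[j]) next
      ov <- min(x$end[i], y$end[j]) - max(x$start[i], y$start[j])
      if (ov <= 0) next
      if (strand_mode == "same" && x$strand[i] != y$strand[j]) next
      if (strand_mode == "opposite" &&
          !((x$strand[i] == "+" && y$strand[j] == "-") ||
            (x$strand[i] == "-" && y$strand[j] == "+"))) next
      out[[length(out) + 1]] <- c(i, j, ov)
    }
  }
  if (!length(out)) {
    return(data.frame(x_idx = integer(), y_idx = integer(),
                      overlap_bp = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(x_idx = m[, 1], y_idx = m[, 2], overlap_bp = m[, 3])
}

bf_nearest <- function(points, features) {
  t(vapply(seq_len(nrow(points)), function(i) {
    best_d <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(features))) {
      if (features$chrom[j] != points$chrom[i]) next
      p <- points$pos[i]
      d <- if (p >= features$start[j] && p < features$end[j]) 0 else
        min(abs(features$start[j] - p), abs(p - (features$end[j] - 1)))
      if (d < best_d ||
          (d == best_d && !is.na(best_j) &&
           features$start[j] < features$start[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    c(best_j, best_d)
  }, numeric(2)))
}

# sliding 5-mer scan with explicit reverse complement
bf_scan_rcgtg <- function(seq) {
  seq <- toupper(seq)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hits <- list()
  for (i in seq_len(nchar(seq) - 4)) {
    w <- substr(seq, i, i + 4)
    if (grepl("^[AG]CGTG$", w)) {
      hits[[length(hits) + 1]] <- c(i - 1, "+")
    }
    if (grepl("^[AG]CGTG$", rc(w))) {
      hits[[length(hits) + 1]] <- c(i - 1, "-")
    }
  }
  if (!length(hits)) {
    return(data.frame(start = numeric(), strand = character()))
  }
  m <- do.call(rbind, hits)
  data.frame(start = as.numeric(m[, 1]), strand = m[, 2])
}

# union-mode counting by direct enumeration over fragments and exons
bf_count_reads <- function(fragments, transcripts, strandedness = "reverse") {
  genes <- sort(unique(transcripts$gene_id))
  samples <- unique(fragments$sample)
  counts <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  keys <- unique(fragments[, c("sample", "qname")])
  for (r in seq_len(nrow(keys))) {
    blocks <- fragments[fragments$sample == keys$sample[r] &
                          fragments$qname == keys$qname[r], ]
    if (!all(blocks$unique)) next
    touched <- character()
    for (b in seq_len(nrow(blocks))) {
      for (e in seq_len(nrow(transcripts))) {
        if (blocks$chrom[b] != transcripts$chrom[e]) next
        ok <- switch(strandedness,
                     reverse = blocks$strand[b] != transcripts$strand[e],
                     forward = blocks$strand[b] == transcripts$strand[e],
                     unstranded = TRUE)
        if (!ok) next
        if (min(blocks$end[b], transcripts$end[e]) -
            max(blocks$start[b], transcripts$start[e]) > 0) {
          touched <- union(touched, transcripts$gene_id[e])
        }
      }
    }
    if (length(touched) == 1) {
      counts[touched, keys$sample[r]] <- counts[touched, keys$sample[r]] + 1L
    }
  }
  counts
}

# two-sided Fisher p by hypergeometric enumeration
bf_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square on a 2x2 table by direct expected-count arithmetic
bf_chisq_2x2 <- function(tab) {
  tot <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / tot
  sum((tab - e)^2 / e)
}

# Benjamini-Hochberg step-up by hand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# replay an hclust merge tree, returning the within-cluster ESS increase
# of every merge
bf_ess_increments <- function(x, merge) {
  ess <- function(m) {
    if (nrow(m) < 2) return(0)
    sum(sweep(m, 2, colMeans(m))^2)
  }
  n <- nrow(x)
  clusters <- vector("list", n - 1)
  increments <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    get <- function(id) if (id < 0) x[-id, , drop = FALSE] else clusters[[id]]
    ga <- get(merge[k, 1]); gb <- get(merge[k, 2])
    m <- rbind(ga, gb)
    clusters[[k]] <- m
    increments[k] <- ess(m) - ess(ga) - ess(gb)
  }
  increments
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 300, stranded = FALSE) {
  start <- floor(stats::runif(n) * max_pos)
  len <- 1 + floor(stats::runif(n) * max_len)
  out <- tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                        start = start, end = start + len)
  if (stranded) out$strand <- sample(c("+", "-"), n, replace = TRUE)
  out
}
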