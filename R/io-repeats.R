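#' Built-in retrotransposon subfamily lookup table
#'
#' A small subfamily -> family/class table for the BED dialect of
#' [read_repeat_annotation()], covering common human and murine
#' retrotransposon subfamilies plus a few non-retrotransposon entries.
#' Users supplying their own annotations should pass a complete table.
#'
#' @return A tibble with columns `subfamily`, `family`, `repeat_class`.
#' @export
repeat_family_table <- function() {
  tibble::tribble(
    ~subfamily,   ~family,    ~repeat_class,
    "AluY",       "Alu",      "SINE",
    "AluSx",      "Alu",      "SINE",
    "AluJb",      "Alu",      "SINE",
    "MIR",        "MIR",      "SINE",
    "B1_Mus1",    "Alu",      "SINE",
    "L1HS",       "L1",       "LINE",
    "L1PA2",      "L1",       "LINE",
    "L1Md_T",     "L1",       "LINE",
    "L2a",        "L2",       "LINE",
    "HERVK-int",  "ERVK",     "LTR",
    "LTR5_Hs",    "ERVK",     "LTR",
    "IAPEz-int",  "ERVK",     "LTR",
    "RLTR10",     "ERVK",     "LTR",
    "MLT1A",      "ERVL-MaLR","LTR",
    "THE1B",      "ERVL-MaLR","LTR",
    "MER20",      "hAT-Charlie","DNA",
    "(GAATG)n",   "Satellite","Satellite"
  )
}

retro_classes <- c("LTR", "LINE", "SINE")

#' Read repeat annotations
#'
#' Two dialects are supported. `repeatmasker_out` parses the UCSC/
#' RepeatMasker `.out` format: the `C` strand code maps to `-`, the
#' class/family column is split into `repeat_class` and `family`, and the
#' consensus coordinates are taken from the match columns (for minus-strand
#' rows the parenthesised field order is handled). `bed` parses BED6 with
#' the subfamily in the name column, resolving family and class through
#' `family_table`; subfamilies absent from the table are tagged class
#' `"other"` with a warning. Non-retrotransposon classes are retained but
#' normalised to `"other"` unless they are LTR/LINE/SINE.
#'
#' @param path Path to the annotation file.
#' @param dialect `"repeatmasker_out"` or `"bed"`.
#' @param family_table Lookup tibble with `subfamily`, `family`,
#'   `repeat_class` columns, used by the BED dialect.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `subfamily`, `family`, `repeat_class` (`LTR`, `LINE`, `SINE` or
#'   `other`), `consensus_start`, `consensus_end` (0-based half-open in
#'   consensus coordinates, `NA` when unavailable).
#' @export
read_repeat_annotation <- function(path,
                                   dialect = c("repeatmasker_out", "bed"),
                                   family_table = repeat_family_table()) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    bed <- read_bed_regions(path)
    if (is.null(bed$name)) stop("BED repeat annotation needs a name column")
    hit <- match(bed$name, family_table$subfamily)
    if (anyNA(hit)) {
      warning("subfamilies absent from family table tagged 'other': ",
              paste(unique(bed$name[is.na(hit)]), collapse = ", "))
    }
    out <- tibble::tibble(
      chrom = bed$chrom, start = bed$start, end = bed$end,
      strand = if (is.null(bed$strand)) "." else bed$strand,
      subfamily = bed$name,
      family = ifelse(is.na(hit), "other", family_table$family[hit]),
      repeat_class = ifelse(is.na(hit), "other", family_table$repeat_class[hit]),
      consensus_start = NA_real_, consensus_end = NA_real_
    )
  } else {
    lines <- readLines(path)
    # skip the banner (two header lines + blank) if present
    is_data <- grepl("^\\s*\\d+", lines)
    lines <- lines[is_data]
    out <- purrr::map_dfr(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 14) {
        stop("RepeatMasker .out parse error at data line ", i,
             ": expected >= 14 columns, got ", length(f))
      }
      strand <- if (f[9] == "C") "-" else f[9]
      cf <- strsplit(f[11], "/")[[1]]
      cls <- cf[1]
      fam <- if (length(cf) > 1) cf[2] else cf[1]
      # consensus match columns: plus rows are repStart repEnd (repLeft),
      # C rows are (repLeft) repEnd repStart
      if (strand == "-") {
        cstart <- as.numeric(f[14]); cend <- as.numeric(f[13])
      } else {
        cstart <- as.numeric(f[12]); cend <- as.numeric(f[13])
      }
      tibble::tibble(
        chrom = f[5],
        start = as.numeric(f[6]) - 1,
        end = as.numeric(f[7]),
        strand = strand,
        subfamily = f[10],
        family = fam,
        repeat_class = if (cls %in% retro_classes) cls else "other",
        consensus_start = cstart - 1,
        consensus_end = cend
      )
    })
  }
  bad <- which(!is.na(out$consensus_start) &
                 out$consensus_start >= out$consensus_end)
  if (length(bad)) stop("invalid consensus coordinates at record(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  out
}
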