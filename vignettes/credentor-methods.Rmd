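---
title: "Methods: cryptic retrotransposon transcripts, HIF binding and the hypoxia-methylation interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic retrotransposon transcripts, HIF binding and the hypoxia-methylation interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credentor)
```

## The biological model

Hypoxia-inducible factors (HIFs) are heterodimers of an oxygen-labile
alpha subunit and the constitutive HIF1&beta; subunit. They bind the
RCGTG consensus (the hypoxia response element, HRE; R = A or G), and the
core CpG of that consensus is methylation-sensitive: methylated sites
repel the complex. Retrotransposons — LTR elements (including ERVK
endogenous retroviruses), LINEs and SINEs — carry many RCGTG copies that
are normally kept methylated. Where methylation is absent, HIF binding at
these elements can start transcription of *cryptic transcripts*:
assembled transcript models that do not overlap annotated coding genes
but whose exons overlap a retrotransposon. Because retrotransposon
sequences occur in both orientations, such transcripts are prone to
forming double-stranded RNA, the trigger of viral-mimicry interferon
responses.

`credentor` implements the analysis chain for this model: defining and
quantifying cryptic transcripts, linking them to HIF binding, measuring
motif/peak/methylation relationships, and testing at cohort scale whether
hypoxia and promoter hypomethylation act cooperatively on cryptic
transcription.

## Coordinates and interval logic

All internal coordinates are 0-based, half-open; conversion to and from
the 1-based closed conventions of GTF and the 0-based half-open
conventions of BED/narrowPeak/bedGraph happens only in the readers and
writers. Touching intervals never overlap. Nearest-feature queries return
distance 0 for points inside a feature and break ties toward the feature
with the lower start, so results are deterministic. Overlap and nearest
queries run on GenomicRanges/IRanges index structures internally but take
and return plain tibbles.

## Cryptic transcript definition

A transcript from the merged assembly is a cryptic-transcript candidate
when it is not flagged coding and does not overlap any annotated coding
gene. Two exclusion modes are provided because the plain phrase
"not overlapping coding genes" is ambiguous for antisense transcripts:

* `span_any_strand` (default): the candidate's genomic span may not
  intersect any coding gene span, on either strand. This is the literal
  reading; it also removes antisense-overlapping transcripts.
* `exon_same_strand`: exclusion only on same-strand exonic overlap,
  which retains antisense transcripts.

A candidate is cryptic iff at least one exonic bp overlaps an LTR, LINE
or SINE element. When several elements overlap, the element with the
largest *total exonic* overlap is assigned; ties break by lower element
start, then lexicographic subfamily — an arbitrary but deterministic
order.

The promoter is TSS − 2000 bp through TSS + 500 bp, strand-aware, clamped
to the chromosome, with the TSS as the 0-based first transcribed base. A
transcript is HIF-associated iff at least one peak *summit* position lies
in the half-open promoter interval; a peak overlapping the promoter with
its summit outside does not count. (Published single-cell work states the
mirrored window "2 kb downstream / 500 bp upstream"; we treat that as a
transcription of the same definition and keep one orientation, with `up`
and `down` exposed as arguments for users who want the mirror.)

## Counting and expression

`count_reads()` implements union-mode, gene-level counting of uniquely
mapping fragments: a fragment (all CIGAR M blocks, N gaps split blocks)
is assigned to a gene iff the set of genes its blocks touch, under the
library strand rule, is exactly that one gene; fragments touching two
genes are ambiguous and dropped, as are fragments touching nothing and
all non-unique fragments. Uniqueness defaults to `NH == 1` with a
`MAPQ >= 255` fallback rule, matching common aligner conventions without
assuming a specific aligner. The strandedness default is `reverse`
(dUTP-type stranded mRNA libraries).

Expression support requires a count above 10 in at least one sample *and*
an RPKM above 1 in at least one sample (strict inequalities; the two
conditions may be met in different samples). Normalisations are TPM with
a 0.01 offset (columns sum to 10^6 before the offset), RPKM, and
log2 CPM with offset 1. Library sizes default to total assigned counts
(configurable), since whether the original computation used total mapped
or total assigned reads is not recoverable. Cryptic load is the ratio of
total cryptic to total coding counts per sample. Cytolytic activity is
the geometric mean of GZMA and PRF1 TPM.

## Differential expression

Per-row negative-binomial log-linear models with median-of-ratios size
factors as offsets and a Wald test on the condition coefficient, BH
correction across tested rows. The dispersion is estimated per row by
**Cox–Reid adjusted profile likelihood** (method-of-moments start, floor
10^-8), and the Wald statistic is referred to a t distribution on the
residual degrees of freedom. These two small-sample choices are
deliberate: plain profile ML underestimates the dispersion when the group
means are estimated from the same few samples, and a normal reference
then rejects well above the nominal level at n = 10 per group. With the
adjustment the test holds its nominal size in the package's null
simulations (see `tests/testthat/test-acceptance.R`). No information is
shared across rows — dispersions are per-row, not shrunken — which keeps
the test self-contained at the cost of power relative to
empirical-Bayes moderation.

## Peak presence and comparison

For a peak with summit s, the ratio

    (mean depth over [s - 100, s + 100) + eps) / (background + eps)

is compared with strict thresholds: present if > 4, absent if < 2.5,
otherwise unclassified (boundary values are unclassified). The background
is the pooled mean depth over 1.5–5 kb on both sides of the *peak
interval*. `eps = 0.5` is a pseudodepth guarding zero background; the
published rule is silent there, and any small constant only matters for
near-empty tracks. Cross-sample categories over a union peak list:
`shared` (present everywhere), `unique(s)` (present only in s, absent
everywhere else), else `unclassified`; the three categories partition the
list.

Methylation at peaks averages CpG betas with bisulfite coverage above
40×, over the whole peak or summit ± 100 bp. Motif-level stratification
looks up the beta at the C of the core CpG (offset +1 in RCGTG hits,
+2 in CACGY minus-strand hits), requires > 10× coverage, and bins motifs
by beta; the bin edges are configurable (default 0.2 steps) since the
original binning is not stated.

## Permutation enrichment

Observed peaks are shuffled across the genome: the chromosome is drawn
proportionally to its length and the position uniformly; each permuted
peak keeps its length and summit offset. Draws overlapping an excluded
("poorly mapping") region are discarded from that permutation — the
permuted set shrinks, which mirrors the description "randomly assigned
... were discarded"; a redraw policy is available as an option. In
`distal_matched` mode only peaks whose observed summit is distal (outside
every promoter window, reusing the 2000/500 promoter) are shuffled, and
draws landing in promoter space are rejected; whether the original
distal matching was this constraint or a distance-histogram match is not
stated, and we make no claim of equivalence.

Per repeat class, the observed fraction of peaks overlapping ≥ 1 element
is compared with the permuted fractions; the empirical p-value uses the
add-one estimator (1 + #{null ≥ obs}) / (1 + N), which is never exactly
zero, and a two-sided Fisher test on observed vs pooled-null in/out
counts is reported alongside. The full-scale analysis uses N = 10,000
permutations; calibration tests in this package use N = 1,000.

Summit positions inside elements are mapped onto the repeat consensus
(minus-strand elements mirrored so 0 is the repeat 5' end). The consensus
length of a subfamily is taken as the largest consensus end seen among
its elements; elements without consensus coordinates are skipped and
counted.

## dsRNA potential

`flag_sense_antisense()` flags a transcript when ≥ 1 bp of exonic
(default) or span overlap exists with any transcript on the opposite
strand; the partner set defaults to all transcripts, coding included —
the published definition does not restrict it, and sense–antisense
duplexes do not care about partner biotype. `flag_palindromic()` flags a
transcript whose exons overlap two elements of the *same subfamily* in
opposite orientations; instance-level identity would make the flag
unsatisfiable, and the subfamily reading matches the inverted-repeat
mechanism of intramolecular duplex formation. Group comparisons use the
2×2 Pearson chi-square without continuity correction (df = 1), with a
warning when an expected cell is below 1.

## Cohort statistics

Tumors are clustered with the classical Ward.D agglomeration on squared
Euclidean distances over log2 CPM (offset 1, no per-gene scaling) of the
hypoxia metagene signature; the published 15-entry list contains one gene
twice, leaving 14 unique symbols, and we do not guess a replacement. The
tree is cut into its top two subclusters and the subcluster with the
higher mean signature expression is labelled hypoxic — the signature
genes are hypoxia-induced, so this orientation is forced. With squared
input distances the Ward.D merge height of two singletons equals their
squared distance, i.e. twice the within-cluster ESS increase; the test
suite checks all merge heights against a brute-force ESS replay under
that convention.

Promoter methylation per tumor is the unweighted mean beta over all
probes inside any cryptic promoter; the cohort splits at the median
(ties go low, so the groups differ in size by at most one for distinct
values). PDL1 and TMB strata split at the third decile using the
linear-interpolation quantile, low ⇐ value ≤ cutoff; the original
tie/direction handling is unstated, so we state ours.

The interaction test fits two NB GLMs of counts on oxygenation
(hypoxic = 0, normoxic = 1) and methylation (low = 0, high = 1), with and
without the product term, each with its own ML (profile) dispersion
(floor 10^-8; a fixed dispersion can be supplied, and values at the floor
reproduce a Poisson fit), and compares them by LRT on 1 df. Because the
reduced model's parameter space is contained in the full model's, the
statistic is non-negative (clamped against roundoff). Under the 0/1
encodings, the interaction coefficient equals the log-mean of the
(hypoxic, low) cell minus what the additive model implies, so a positive
coefficient is cooperative enhancement of cryptic transcription in
hypoxic, hypomethylated tumors. The exact aggregation behind the single
published cohort p-value is not recoverable, so the package exposes both
the pooled-load test (counts = per-tumor cryptic totals, offset = log
coding totals) and a per-transcript screen with BH correction
(`nb_interaction_screen()`).

The single-cell companion, `meth_expression_glm()`, is an OLS of log
expression on promoter methylation fraction, hypoxia and their
interaction, with a t-test on the interaction coefficient.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
package's study conditions. The toy genome is 2 chromosomes × 500 kb,
laid out in 10-kb slots with one feature per slot and per-slot random
jitter: 25 coding genes (4 hosting an overlapping noncoding decoy),
8 noncoding decoys without repeat overlap, 5 cryptic transcripts per
repeat class — each with its element fully inside exon 1 and a smaller
distractor element of another subfamily to exercise the maximal-overlap
rule — 30 background repeats, 8 background peaks, and 40 planted RCGTG
motifs. Half the cryptic transcripts get a peak summit planted inside
their promoter. Disjoint quarters of the cryptic set get a planted
antisense partner or an inverted same-subfamily repeat pair, so both
dsRNA flags have known truth. Genome sequence, when requested, is drawn
at random and then iteratively patched until the only RCGTG occurrences
(both strands) are the planted ones, so a motif scan has an exact
expected answer.

Coverage tracks plant *effective* presence ratios — the quantity the
classifier actually thresholds, (window + eps)/(background + eps) — with
a background depth of 7.5 so the denominator is exactly 8 (a power of
two) and designed ratios, including the boundary values 2.5 and 4.0, are
exact in floating point. Raw window/background ratios could not express
the boundary cases, because the pseudodepth strictly shrinks them.

Cohort counts are NB with mean
exp(log 60 − 0.7·oxy − 0.7·meth + ln 2·oxy·meth) for cryptic transcripts
(dispersion 0.2, 25 tumors per design cell, log-normal library factors),
flat coding genes, and signature genes shifted +3 log2 units in hypoxic
tumors so the clustering has a recoverable structure of realistic
magnitude. Promoter probes draw betas around stratum means 0.3 (low) and
0.8 (high) with sd 0.08, clipped to [0, 1], at 45–90× coverage — numbers
chosen once to resemble hypo/hypermethylated tumor promoters. Fragment
emission places exactly the counted number of unique fragments inside
each gene's first exon on the protocol-implied strand, so `count_reads()`
reproduces the matrix identically and a SAM round-trip is exact.

What the generator does **not** emulate: multimapping ambiguity within
repeat families (fragments are planted unambiguously), assembly errors in
the merged GTF, nested or fragmented RepeatMasker elements, covariation
between methylation and peak strength beyond the planted strata, GC or
mappability structure, and batch effects. Green tests therefore certify
the *rules* (classification logic, thresholds, calibration of the
statistics), not robustness to the noise sources of real sequencing data.

## Problem sizes and numerical choices in the test suite

Monte Carlo sizes were fixed from standard-error considerations: the
permutation calibration uses 400 null datasets of 150 peaks with
per-class hit probabilities near 0.1 and N = 1,000 permutations — with
few peaks the overlap fraction is so discrete that the add-one empirical
p is visibly conservative, so the fixture is sized to give the statistic
adequate resolution; the NB-interaction null uses 1,000 fits at 50 tumors
per cell; the DE null uses 2,000 rows at 10 samples per group; effect
recovery embeds 200 planted 4-fold rows among 1,000 null rows (global
normalisation would absorb a fold change planted in *every* row). The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
at slightly reduced sizes and reports the measured values as JSON.

Other numerical details: empirical p-values use the add-one estimator;
the LRT is clamped at zero; NB dispersions are floored at 10^-8 and a
fixed dispersion at the floor reproduces a Poisson GLM; quantile
stratification uses the linear-interpolation (type 7) quantile; the
nearest-feature tie-break and the repeat-assignment tie-break are
deterministic as described above.

## Pipeline orchestration

`run_credentor()` executes the stages in dependency order on in-memory
tibbles from a single design object, and the thin CLI at
`inst/scripts/credentor.R` wraps it for shell use. All stochastic stages
derive from the design seed, so two runs with the same configuration are
identical. No stage caching is implemented: on the scales this package
targets a full run is a single short call, and caching would only add
state to invalidate.

## Known limitations

* The DE test uses per-row dispersions without shrinkage; at very small
  n it is calibrated but less powerful than empirical-Bayes methods.
* The distal-matched shuffle is a distal-only constraint, not a
  distance-histogram match; both are plausible readings of the original
  procedure.
* `read_alignments()` targets single-end SAM text (BAM is converted on
  the fly); mate-aware fragment reconstruction is out of scope.
* The permutation engine models excluded regions by discard (optionally
  redraw) and has no GC- or chromatin-matched null.
* Consensus lengths for positional profiles are inferred from the
  annotation itself (max consensus end per subfamily), which
  underestimates lengths for subfamilies seen only as fragments.
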