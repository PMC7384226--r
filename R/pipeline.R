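#' Run the full synthetic-cohort pipeline
#'
#' End-to-end orchestration over a [simulation_design()]: generates the
#' annotation, classifies cryptic transcripts and compares them with the
#' planted truth, annotates HIF association, simulates the tumor cohort,
#' computes cryptic load and subfamily aggregates, stratifies tumors by
#' hypoxia clustering and promoter methylation, runs the NB interaction
#' test on the pooled cryptic load counts, scores dsRNA potential, and
#' tests repeat-class enrichment of the peaks by permutation. Stages run
#' in dependency order on in-memory tibbles; all randomness derives from
#' the design seed, so two runs of the same design are identical.
#'
#' @param design A [simulation_design()].
#' @param n_permutations Permutations for the enrichment stage (the
#'   full-scale analysis uses 10,000; the default here keeps the
#'   end-to-end run interactive).
#' @return A list of stage outputs: `annotation`, `cryptics`,
#'   `classification` (precision/recall vs truth), `cohort`, `load`,
#'   `subfamily_counts`, `oxygenation`, `methylation`, `interaction`,
#'   `dsrna`, `enrichment`, `cytolytic`, and a `manifest` recording
#'   parameters and versions.
#' @export
run_credentor <- function(design = simulation_design(),
                          n_permutations = 1000) {
  cohort <- simulate_cohort(design)
  ann <- cohort$annotation
  cryptics <- cohort$cryptics

  truth <- ann$truth
  called <- cryptics$transcript_id
  planted <- truth$transcript_id[truth$is_cryptic]
  tp <- length(intersect(called, planted))
  classification <- tibble::tibble(
    n_called = length(called), n_planted = length(planted),
    precision = ifelse(length(called) > 0, tp / length(called), NA),
    recall = ifelse(length(planted) > 0, tp / length(planted), NA))

  load <- cryptic_load(cohort$counts, cohort$cryptic_ids, cohort$coding_ids)
  sub_counts <- aggregate_by_subfamily(cohort$counts, cryptics)

  oxy <- hypoxia_cluster(cohort$counts)
  prom <- tibble::tibble(chrom = cryptics$chrom,
                         start = cryptics$promoter_start,
                         end = cryptics$promoter_end)
  meth <- promoter_methylation_stratify(cohort$probes, prom)

  fit_df <- dplyr::inner_join(oxy, meth, by = "sample") |>
    dplyr::inner_join(load, by = "sample") |>
    dplyr::mutate(log_offset = log(.data$coding_total))
  interaction <- nb_interaction_test(
    fit_df, .data$cryptic_total, .data$oxy_code, .data$meth_code,
    offset = .data$log_offset)

  cry_ex <- dplyr::semi_join(ann$transcripts, cryptics,
                             by = "transcript_id")
  sa <- flag_sense_antisense(cry_ex, partners = ann$transcripts)
  pal <- flag_palindromic(cry_ex, ann$repeats)
  flags <- dplyr::inner_join(sa, pal, by = "transcript_id") |>
    dplyr::left_join(dplyr::select(cryptics, "transcript_id", "hif_bound"),
                     by = "transcript_id")
  dsrna <- compare_dsrna_fractions(
    dplyr::filter(flags, .data$hif_bound),
    dplyr::filter(flags, !.data$hif_bound))

  shuffles <- shuffle_peaks(ann$peaks, ann$layout,
                            n_permutations = n_permutations,
                            excluded = ann$excluded,
                            seed = design$seed + 10)
  enrichment <- repeat_class_enrichment(ann$peaks, ann$repeats, shuffles)

  tpm <- normalize_expression(cohort$counts, "tpm_offset")
  cytolytic <- cytolytic_activity(tpm)

  manifest <- list(
    package_version = as.character(utils::packageVersion("credentor")),
    r_version = R.version.string,
    seed = design$seed,
    n_permutations = n_permutations,
    parameters = design[setdiff(names(design), "chrom_lengths")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  list(annotation = ann, cryptics = cryptics,
       classification = classification, cohort = cohort, load = load,
       subfamily_counts = sub_counts, oxygenation = oxy,
       methylation = meth, interaction = interaction, dsrna = dsrna,
       enrichment = enrichment, cytolytic = cytolytic,
       manifest = manifest)
}
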