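# End-to-end driver: simulate (or ingest) -> annotate -> DM + DE ->
# enrichment -> DM x DE integration -> classification -> candidate
# ranking, with a machine-readable JSON report.

#' Run the full paired methylome analysis pipeline
#'
#' Executes every stage on a synthetic dataset generated from `sim`
#' (or on a pre-built [simulate_dataset()] result passed as `dataset`)
#' and collects all summary tables in one report. All randomness is
#' governed by the configuration seed plus the explicit stage seeds, so a
#' repeated call reproduces the report exactly.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param dataset optional pre-generated `sim_dataset`; overrides `sim`.
#' @param alpha FDR significance threshold used on both platforms.
#' @param promoter_width,gb_start_offset,shore_width,shore_mode annotation
#'   parameters.
#' @param enrich_target compartment tested for over-representation.
#' @param enrich_iterations permutation iterations (default 1000).
#' @param k,classifier_iterations top-k panel size and number of
#'   train/test splits.
#' @param consistency_window bp window of the loco-regional ranking.
#' @param dedup integration dedup policy ("locus" or "pair").
#' @param outdir optional directory; when given, loci BED, annotation,
#'   matrices, sample sheet, truth, DM/DE/integration tables and the JSON
#'   report are written there.
#' @return list of class `helpdm_report` with elements `config`, `n`,
#'   `dm`, `de`, `compartment_summary`, `enrichment`, `integration`,
#'   `subcompartments`, `classifier`, `consistency`, `recovery`.
#' @export
run_pipeline <- function(sim = sim_config(), dataset = NULL, alpha = 0.05,
                         promoter_width = 2000, gb_start_offset = 0,
                         shore_width = 2000,
                         shore_mode = c("both-flanks", "upstream-only"),
                         enrich_target = "GB", enrich_iterations = 1000,
                         k = 25, classifier_iterations = 10,
                         consistency_window = 2000,
                         dedup = c("locus", "pair"), outdir = NULL) {
  shore_mode <- match.arg(shore_mode)
  dedup <- match.arg(dedup)
  ds <- dataset %||% simulate_dataset(sim, promoter_width = promoter_width,
                                      gb_start_offset = gb_start_offset,
                                      shore_width = shore_width,
                                      shore_mode = shore_mode)
  cfg <- ds$config

  dm <- run_dm(ds$meth, ds$design, annotation = ds$loci, alpha = alpha)
  de <- run_de(ds$expr, ds$design, alpha = alpha)
  dm_sig <- dm[!is.na(dm$q) & dm$q < alpha, , drop = FALSE]

  enr <- permutation_compartment_test(
    dm_sig$locus_id, ds$loci[, c("locus_id", "compartment")],
    target = enrich_target, B = enrich_iterations,
    seed = stage_seed(cfg, "methylome") + 7L)

  records <- link_loci_to_genes(
    dm, de, ds$loci, ds$annotation$genes, ds$annotation$cgis, alpha = alpha,
    promoter_width = promoter_width, gb_start_offset = gb_start_offset,
    shore_width = shore_width, shore_mode = shore_mode, dedup = dedup,
    chrom_lengths = ds$annotation$chrom_lengths)
  counts <- build_counts_table(records)
  subc <- subcompartment_breakdown(records)

  classifier <- iterate_classification(
    ds$meth, ds$design, k = min(k, nrow(ds$meth)),
    n_iterations = classifier_iterations,
    seed = stage_seed(cfg, "expression") + 11L, alpha = alpha)

  consistency <- consistency_rank(dm_sig, ds$loci,
                                  window = consistency_window)
  recovery <- evaluate_dm_recovery(dm, ds$truth$loci, alpha = alpha)

  report <- structure(list(
    config = unclass(cfg),
    n = list(loci = nrow(ds$loci), genes = nrow(ds$annotation$genes),
             subjects = cfg$n_subjects,
             dm_significant = nrow(dm_sig),
             de_significant = sum(!is.na(de$q) & de$q < alpha),
             integration_records = nrow(records)),
    dm = dm, de = de,
    compartment_summary = compartment_summary(dm, ds$loci, alpha),
    enrichment = enr,
    integration = list(records = records, counts = counts),
    subcompartments = subc,
    classifier = classifier,
    consistency = consistency,
    recovery = recovery), class = "helpdm_report")

  if (!is.null(outdir)) write_pipeline_outputs(ds, report, outdir)
  report
}

#' @export
print.helpdm_report <- function(x, ...) {
  cat(sprintf("helpdm pipeline report: %d loci x %d subjects, %d genes\n",
              x$n$loci, x$n$subjects, x$n$genes))
  cat(sprintf("  DM loci (q<alpha): %d; DE genes: %d\n",
              x$n$dm_significant, x$n$de_significant))
  print(x$compartment_summary, row.names = FALSE)
  print(x$enrichment)
  print(x$integration$counts)
  print(x$classifier)
  invisible(x)
}

write_pipeline_outputs <- function(ds, report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_bed(data.frame(chrom = ds$loci$chrom, start = ds$loci$start,
                       end = ds$loci$end, name = ds$loci$locus_id,
                       score = 0,
                       strand = "."), p("loci.bed"))
  write_tsv(ds$loci, p("loci_annotated.tsv"))
  write_tsv(ds$annotation$genes, p("genes.tsv"))
  write_bed(data.frame(chrom = ds$annotation$cgis$chrom,
                       start = ds$annotation$cgis$start,
                       end = ds$annotation$cgis$end,
                       name = ds$annotation$cgis$cgi_id), p("cgi.bed"))
  write_matrix_tsv(ds$meth, p("methylation.tsv"), id_col = "locus_id")
  write_matrix_tsv(ds$expr, p("expression.tsv"), id_col = "gene_id")
  write_tsv(ds$sample_sheet, p("sample_sheet.tsv"))
  write_tsv(ds$truth$loci, p("truth_loci.tsv"))
  write_tsv(ds$truth$genes, p("truth_genes.tsv"))
  write_tsv(report$dm, p("dm.tsv"))
  write_tsv(report$de, p("de.tsv"))
  write_tsv(report$integration$records, p("integration_records.tsv"))
  write_tsv(report$integration$counts$table, p("integration_counts.tsv"))
  write_tsv(report$compartment_summary, p("compartment_summary.tsv"))
  write_tsv(report$consistency, p("consistency_rank.tsv"))
  jsonlite::write_json(report_to_json(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

# JSON-serializable view of the report (tables kept, big matrices dropped)
report_to_json <- function(report) {
  enr <- report$enrichment
  list(
    config = report$config,
    n = report$n,
    compartment_summary = report$compartment_summary,
    enrichment = list(observed = enr$observed,
                      null_mean = enr$null_mean, null_sd = enr$null_sd,
                      empirical_p = enr$empirical_p,
                      gaussian_p = enr$gaussian_p, B = enr$B,
                      target = enr$target, mode = enr$mode),
    integration = list(
      counts = report$integration$counts$table,
      total = report$integration$counts$total,
      canonical_total = report$integration$counts$canonical_total,
      canonical_fraction = report$integration$counts$canonical_fraction),
    subcompartment_grid = as.data.frame.matrix(report$subcompartments$grid),
    subcompartment_chi2 = report$subcompartments$chi2[c("chi2", "df", "p")],
    classifier = list(
      mean_accuracy = report$classifier$mean_accuracy,
      pooled_accuracy = report$classifier$pooled_accuracy,
      mean_sensitivity = report$classifier$mean_sensitivity,
      mean_specificity = report$classifier$mean_specificity,
      k = report$classifier$k,
      n_iterations = report$classifier$n_iterations,
      stable_loci = report$classifier$stable_loci),
    recovery = report$recovery)
}
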