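# End-to-end reproduction pipeline for a deposited PMA spike-in study:
# taxonomy table + sample metadata + qPCR totals in, per-type efficacies and
# PERMANOVA variance fractions out. The deposited tables themselves are
# third-party supplementary data and are not shipped with the package; point
# the path arguments at local copies.

#' Expected on-disk locations of a deposited study's tables
#'
#' The reproduction pipeline looks for user-supplied copies of a study's
#' taxonomy, metadata and qPCR tables under `inst/extdata/study/` (TSV, in
#' the dialects of [read_abundance_table()], [read_sample_metadata()] and
#' [read_qpcr_table()]). The files are not distributed with the package.
#'
#' @return named list of three paths (which may not exist).
#' @export
study_data_paths <- function() {
  base <- system.file("extdata", "study", package = "viabench")
  if (base == "") base <- file.path("inst", "extdata", "study")
  list(taxonomy = file.path(base, "all_sample_taxonomy.tsv"),
       metadata = file.path(base, "all_sample_meta.tsv"),
       qpcr = file.path(base, "qpcr_totals.tsv"))
}

#' Reproduce a spike-in study's headline estimates from deposited tables
#'
#' Runs the full analysis on a deposited data set: collapse OTUs to genus,
#' apply the prevalence/abundance filter, compute per-sample-type spike-in
#' PMA efficacies, and the marginal PERMANOVA variance fraction for sample
#' type on Bray-Curtis distances — separately for the spike-in experiment
#' samples (`spiked` arms present) and any additional sample set given.
#'
#' @param taxonomy_path OTU table with lineage column
#'   ([read_abundance_table()] TSV dialect).
#' @param metadata_path sample metadata ([read_sample_metadata()]).
#' @param qpcr_path qPCR totals ([read_qpcr_table()]).
#' @param reference_taxon spiked reference lineage substring.
#' @param n_permutations,seed passed to [permanova()].
#' @return list with `efficacy` (named per-type values), `efficacy_set`,
#'   and `permanova` (data.frame from [permanova_factors()]).
#' @export
reproduce_study_estimates <- function(taxonomy_path, metadata_path, qpcr_path,
                                      reference_taxon = "Enterobacteriaceae",
                                      n_permutations = 9999, seed = 1) {
  table <- read_abundance_table(taxonomy_path)
  meta <- read_sample_metadata(metadata_path)
  qpcr <- read_qpcr_table(qpcr_path)
  prepped <- filter_taxa(collapse_to_genus(to_relative(table)))
  eff <- efficacy_by_type(prepped, meta, qpcr,
                          reference_taxon = reference_taxon)
  dm <- bray_curtis(prepped)
  perm <- permanova_factors(dm, meta,
                            factors = intersect(c("sample_type", "pma_treated",
                                                  "spiked"), names(meta)),
                            n_permutations = n_permutations, seed = seed)
  list(efficacy = vapply(eff, function(e) e$value, numeric(1)),
       efficacy_set = eff, permanova = perm)
}
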