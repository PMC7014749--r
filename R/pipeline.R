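#' Run the full prioritization pipeline
#'
#' Orchestrates the whole tertiary analysis: combine per-sample VCFs,
#' run the five-step filter cascade, assemble tiered candidates,
#' enumerate and phase biallelic pairs, compute segregation verdicts
#' for every non-cis pair, and build the family report. The pipeline is
#' deterministic: identical inputs and configuration produce identical
#' outputs.
#'
#' @param vcfs A [variant_table()], or a character vector of VCF paths
#'   combined with [combine_tables()] (per [filter_config()]'s
#'   `missing_call`).
#' @param ped A [pedigree()] or PED path.
#' @param panel A [gene_panel()] or BED path.
#' @param control_samples Sample ids forming the pseudo-control cohort;
#'   remaining table samples are the family.
#' @param scores Optional splice-score data frame or TSV path.
#' @param genotypes Optional Sanger genotype [variant_table()] or
#'   long-format TSV path used for pairing/segregation over the
#'   extended pedigree; defaults to the sequenced members' calls from
#'   the combined table.
#' @param config A [filter_config()] or YAML path.
#' @param out_dir Optional output directory; when given, writes
#'   `candidates.tsv`, `exclusions.json`, `trace.json`, `report.json`
#'   and `report.txt`.
#' @return A list of class `pipeline_result`: `cascade`, `candidates`,
#'   `pairs`, `segregation` (named list of verdicts), `report`.
#' @export
run_pipeline <- function(vcfs, ped, panel, control_samples = character(),
                         scores = NULL, genotypes = NULL,
                         config = filter_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_filter_config(config)
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(panel)) panel <- read_gene_panel(panel)
  if (is.character(scores)) scores <- read_splice_scores(scores)
  table <- if (is.character(vcfs)) {
    combine_tables(lapply(vcfs, read_vcf), missing_as = config$missing_call)
  } else vcfs
  family_samples <- setdiff(table$samples, control_samples)

  cascade <- run_cascade(table, ped, panel, family_samples, control_samples,
                         config)
  candidates <- assemble_candidates(cascade$table, panel, scores, config)

  geno_table <- if (is.null(genotypes)) table
    else if (is.character(genotypes))
      read_genotype_tsv(genotypes, records = table$records)
    else genotypes
  pairs <- enumerate_pairs(candidates, geno_table, ped)
  pairs <- infer_phases(pairs, geno_table, ped)

  segregation <- list()
  for (i in seq_len(nrow(pairs))) {
    if (pairs$phase[i] == "cis") next
    cfg_ids <- unique(c(pairs$variant_a[i], pairs$variant_b[i]))
    key <- paste(sort(cfg_ids), collapse = "+")
    if (is.null(segregation[[key]])) {
      segregation[[key]] <- segregate(cfg_ids, geno_table, ped)
    }
  }
  report <- family_report(pairs, candidates, geno_table, ped,
                          results = segregation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates(candidates, file.path(out_dir, "candidates.tsv"),
                     file.path(out_dir, "exclusions.json"))
    write_trace_json(cascade, file.path(out_dir, "trace.json"))
    write_family_report(report, file.path(out_dir, "report.json"),
                        file.path(out_dir, "report.txt"))
  }
  structure(list(cascade = cascade, candidates = candidates, pairs = pairs,
                 segregation = segregation, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$cascade)
  cat(sprintf("\ncandidates: %d (tier 1: %d, tier 2: %d)\n",
              nrow(x$candidates), sum(x$candidates$tier == 1),
              sum(x$candidates$tier == 2)))
  print(x$report)
  invisible(x)
}
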