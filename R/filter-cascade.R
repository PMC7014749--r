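#' ClinVar phenotype rescue
#'
#' Before any variant is discarded, records already linked to the
#' patient's phenotype in ClinVar are marked for rescue: a variant is
#' rescued when its clinical significance is pathogenic, likely
#' pathogenic or conflicting-between-pathogenic-and-VUS *and* its
#' ClinVar phenotype list matches any configured phenotype term
#' (case-insensitive substring). Rescued variants are exempt from the
#' recurrence and frequency filters downstream (but not from the
#' pedigree filter).
#'
#' @param table A [variant_table()].
#' @param config A [filter_config()].
#' @return Character vector of rescued `variant_id`s (possibly empty).
#' @export
clinvar_rescue <- function(table, config = filter_config()) {
  rec <- table$records
  if (!nrow(rec)) return(character())
  sig_ok <- rec$clinvar_significance %in% CLINVAR_RESCUE_LEVELS
  phen_ok <- vapply(rec$clinvar_phenotypes, function(phen) {
    if (!length(phen)) return(FALSE)
    phen <- tolower(phen)
    any(vapply(config$phenotype_terms,
               function(term) any(grepl(term, phen, fixed = TRUE)), TRUE))
  }, TRUE)
  rec$variant_id[sig_ok & phen_ok]
}

check_samples_known <- function(table, samples, what) {
  miss <- setdiff(samples, table$samples)
  if (length(miss)) stop("unknown ", what, " sample id: ", miss[1])
}

#' Recurrence filter against a pseudo-control cohort
#'
#' Removes sequencing artefacts and platform-shared polymorphisms by
#' keeping only variants exclusive of the family under study: a record
#' survives iff no pseudo-control sample is homozygous for the
#' alternate allele, at least one family sample carries it, and at most
#' `max_control_carriers` control samples carry it (default 0, i.e.
#' strictly family-exclusive). Rescued records survive regardless.
#'
#' @param table A [variant_table()].
#' @param family_samples,control_samples Disjoint sample-id sets, both
#'   present in the table.
#' @param rescued Character vector of rescued `variant_id`s
#'   ([clinvar_rescue()]).
#' @param max_control_carriers See [filter_config()].
#' @return The filtered [variant_table()].
#' @export
recurrence_filter <- function(table, family_samples, control_samples,
                              rescued = character(), max_control_carriers = 0) {
  check_samples_known(table, family_samples, "family")
  check_samples_known(table, control_samples, "control")
  if (length(intersect(family_samples, control_samples))) {
    stop("family and control sample sets overlap")
  }
  if (!nrow(table$records)) return(table)
  fam <- table$geno[, family_samples, drop = FALSE]
  ctl <- table$geno[, control_samples, drop = FALSE]
  ctl_hom <- rowSums(ctl == "hom_alt") > 0
  ctl_carriers <- rowSums(carries_alt(ctl))
  fam_carrier <- rowSums(carries_alt(fam)) > 0
  keep <- (!ctl_hom & fam_carrier & ctl_carriers <= max_control_carriers) |
    table$records$variant_id %in% rescued
  subset_variants(table, table$records$variant_id[keep])
}

#' Population frequency filter
#'
#' Discards variants with a population minor-allele frequency above
#' `maf_threshold` (default 0.01, gnomAD). Variants with no frequency
#' entry (novel variants) pass when `treat_missing_maf_as_pass` is set;
#' rescued variants always pass.
#'
#' @inheritParams recurrence_filter
#' @param config A [filter_config()].
#' @return The filtered [variant_table()].
#' @export
frequency_filter <- function(table, config = filter_config(), rescued = character()) {
  if (!nrow(table$records)) return(table)
  maf <- table$records$maf
  keep <- ifelse(is.na(maf), config$treat_missing_maf_as_pass,
                 maf <= config$maf_threshold) |
    table$records$variant_id %in% rescued
  subset_variants(table, table$records$variant_id[keep])
}

#' Gene-panel filter
#'
#' Keeps variants located in any panel gene: either the position falls
#' inside a gene span (the full gene body — exonic and intronic alike,
#' regardless of distance from splice sites) or the gene annotation
#' matches a panel gene symbol. Either criterion suffices.
#'
#' @inheritParams recurrence_filter
#' @param panel A [gene_panel()].
#' @return The filtered [variant_table()].
#' @export
gene_filter <- function(table, panel) {
  if (!nrow(table$records)) return(table)
  rec <- table$records
  by_symbol <- rec$gene %in% panel_genes(panel)
  lv <- union(rec$chrom, panel$spans$chrom)
  rec_gr <- GenomicRanges::GRanges(factor(rec$chrom, levels = lv),
                                   IRanges::IRanges(rec$pos, rec$pos))
  span_gr <- GenomicRanges::GRanges(factor(panel$spans$chrom, levels = lv),
                                    IRanges::IRanges(panel$spans$start,
                                                     panel$spans$end))
  by_span <- IRanges::overlapsAny(rec_gr, span_gr)
  subset_variants(table, rec$variant_id[by_symbol | by_span])
}

#' Pedigree filter
#'
#' The recessive-compatible zygosity/phenotype rule: a record survives
#' iff at least one sequenced affected member carries the alternate
#' allele (het or hom) — whether or not the other affected individuals
#' do — and no sequenced unaffected member is homozygous for it. Table
#' samples that are not sequenced pedigree members (e.g. pseudo-control
#' columns) are ignored.
#'
#' @inheritParams recurrence_filter
#' @param ped A [pedigree()].
#' @return The filtered [variant_table()].
#' @export
pedigree_filter <- function(table, ped) {
  aff <- intersect(intersect(affected_members(ped), sequenced_members(ped)),
                   table$samples)
  if (!length(aff)) stop("no sequenced affected member present in the table")
  una <- intersect(intersect(unaffected_members(ped), sequenced_members(ped)),
                   table$samples)
  if (!nrow(table$records)) return(table)
  aff_carrier <- rowSums(carries_alt(table$geno[, aff, drop = FALSE])) > 0
  una_hom <- rowSums(table$geno[, una, drop = FALSE] == "hom_alt") > 0
  subset_variants(table, table$records$variant_id[aff_carrier & !una_hom])
}

#' Run the full filtering cascade
#'
#' Applies the five prioritization steps in order: ClinVar phenotype
#' rescue (marking only), recurrence against the pseudo-control cohort,
#' population frequency, gene panel, and pedigree. Per-step counts are
#' traced, and every removed record is attributed to the step that
#' removed it.
#'
#' @param table Combined [variant_table()] holding family and control
#'   samples.
#' @param ped A [pedigree()]; table family samples must be sequenced
#'   members.
#' @param panel A [gene_panel()].
#' @param family_samples,control_samples Disjoint sample-id sets.
#' @param config A [filter_config()].
#' @return A list of class `cascade_result`:
#'   \describe{
#'     \item{table}{the surviving [variant_table()]}
#'     \item{trace}{data frame with `step`, `n_in`, `n_out`,
#'       `n_rescued` (survivors owing their survival to rescue)}
#'     \item{removed}{data frame attributing each removed `variant_id`
#'       to a step}
#'     \item{rescued}{the rescued id set}
#'   }
#' @export
run_cascade <- function(table, ped, panel, family_samples, control_samples,
                        config = filter_config()) {
  rescued <- clinvar_rescue(table, config)
  steps <- list(
    recurrence = function(t, r) recurrence_filter(
      t, family_samples, control_samples, rescued = r,
      max_control_carriers = config$max_control_carriers),
    frequency = function(t, r) frequency_filter(t, config, rescued = r),
    gene_panel = function(t, r) gene_filter(t, panel),
    pedigree = function(t, r) pedigree_filter(t, ped)
  )
  trace <- data.frame(step = character(), n_in = integer(), n_out = integer(),
                      n_rescued = integer(), stringsAsFactors = FALSE)
  removed <- data.frame(variant_id = character(), step = character(),
                        stringsAsFactors = FALSE)
  cur <- table
  for (nm in names(steps)) {
    before <- cur$records$variant_id
    cur <- steps[[nm]](cur, rescued)
    after <- cur$records$variant_id
    # survivors that the raw predicate would have removed
    raw_after <- steps[[nm]](subset_variants(table, before), character())$records$variant_id
    n_resc <- length(setdiff(after, raw_after))
    trace <- rbind(trace, data.frame(step = nm, n_in = length(before),
                                     n_out = length(after), n_rescued = n_resc))
    gone <- setdiff(before, after)
    if (length(gone)) {
      removed <- rbind(removed, data.frame(variant_id = gone, step = nm))
    }
  }
  structure(list(table = cur, trace = trace, removed = removed,
                 rescued = rescued),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("filter cascade:\n")
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("  %-11s %d -> %d%s\n", x$trace$step[i], x$trace$n_in[i],
                x$trace$n_out[i],
                if (x$trace$n_rescued[i] > 0)
                  sprintf(" (%d rescued)", x$trace$n_rescued[i]) else ""))
  }
  cat(sprintf("  rescued ids: %s\n",
              if (length(x$rescued)) paste(x$rescued, collapse = ", ") else "none"))
  invisible(x)
}

#' Write a cascade trace as JSON
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(result, path) {
  jsonlite::write_json(
    list(trace = result$trace, removed = result$removed,
         rescued = result$rescued),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
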