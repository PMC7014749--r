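REGION_CLASSES <- c("coding_exonic", "near_splice", "deep_intronic", "other")

#' Classify variant positions against a panel's exon model
#'
#' A position inside a panel gene span is `coding_exonic` when it falls
#' within an exon, `near_splice` when it lies within `flank_bp` bases of
#' an exon boundary without being exonic (inclusive bound: the position
#' exactly `flank_bp` away still qualifies), and `deep_intronic`
#' otherwise. Positions outside every gene span are `other`. Distances
#' are measured in 1-based inclusive coordinates from the first/last
#' exonic base.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param panel A [gene_panel()].
#' @param flank_bp Flank width in bases (default 10).
#' @param gene Optional vector of gene annotations used to resolve
#'   overlapping spans.
#' @return Character vector over
#'   `c("coding_exonic", "near_splice", "deep_intronic", "other")`.
#' @export
classify_region <- function(chrom, pos, panel, flank_bp = 10, gene = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n)
  if (is.null(gene)) gene <- rep("", n)
  out <- character(n)
  for (i in seq_len(n)) {
    hit <- span_hit(panel, chrom[i], pos[i], gene[i])
    if (is.na(hit)) { out[i] <- "other"; next }
    g <- panel$spans$gene[hit]
    ex <- panel$exons[panel$exons$gene == g & panel$exons$chrom == chrom[i], ,
                      drop = FALSE]
    if (!nrow(ex)) { out[i] <- "deep_intronic"; next }
    if (any(pos[i] >= ex$start & pos[i] <= ex$end)) {
      out[i] <- "coding_exonic"
    } else {
      dist <- pmin(abs(pos[i] - ex$start), abs(pos[i] - ex$end))
      out[i] <- if (min(dist) <= flank_bp) "near_splice" else "deep_intronic"
    }
  }
  out
}

#' Splice-impact decision for one predictor's score pair
#'
#' Applies the per-tool decision thresholds to a wild-type/mutant score
#' pair: the pair passes iff the stronger site score reaches the tool's
#' floor, `max(|wt|, |mut|) >= min_score`, and the relative score change
#' exceeds the tool's variation bound,
#' `|wt - mut| / max(|wt|, eps) * 100 > min_variation_pct`
#' (`eps = 1e-9` guards a zero wild-type score). Defaults: MaxEntScan
#' floor 2 and variation > 15%; HSF floor 70 and variation > 10%;
#' NNSPLICE floor 0.4 and variation > 10%.
#'
#' Both site-loss (strong wild-type score collapsing) and site-gain
#' (strong novel mutant site) events satisfy the floor.
#'
#' @param tool Vector over `c("maxent", "hsf", "nnsplice")`.
#' @param wt_score,mut_score Numeric vectors of wild-type and mutant
#'   site scores from the same tool.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where the pair passes.
#' @export
splice_impact <- function(tool, wt_score, mut_score, config = filter_config()) {
  tool <- tolower(tool)
  bad <- !tool %in% SPLICE_TOOLS
  if (any(bad)) stop("unknown splice tool: ", tool[bad][1])
  n <- max(length(tool), length(wt_score), length(mut_score))
  tool <- rep_len(tool, n)
  wt <- rep_len(as.numeric(wt_score), n)
  mut <- rep_len(as.numeric(mut_score), n)
  min_score <- vapply(tool, function(t) config$splice_thresholds[[t]]$min_score, 0)
  min_var <- vapply(tool, function(t) config$splice_thresholds[[t]]$min_variation_pct, 0)
  variation <- abs(wt - mut) / pmax(abs(wt), 1e-9) * 100
  unname(pmax(abs(wt), abs(mut)) >= min_score & variation > min_var)
}

#' Assemble the ranked candidate list from a cascade output
#'
#' The manual-prioritization step of the workflow, made explicit:
#' variants in coding exons or within the near-splice flank form tier 1;
#' deep-intronic variants are admitted to tier 2 only when at least
#' `splice_quorum` predictor score pairs pass [splice_impact()].
#' Remaining records are dropped with a recorded reason. Each candidate
#' carries a homozygote flag (`hom_flag`) raised when the population
#' reports any homozygote — the reported frequency alone does not
#' establish compatibility with a recessive disease, so the absence of
#' population homozygotes is surfaced for every candidate.
#'
#' @param table A [variant_table()], normally the cascade output.
#' @param panel A [gene_panel()].
#' @param scores Optional data frame of splice score pairs
#'   ([read_splice_scores()]); without it no tier-2 candidate exists.
#' @param config A [filter_config()].
#' @return Data frame of candidates (class `candidate_set`) sorted by
#'   tier, gene, chrom, pos, with an `excluded` attribute listing
#'   dropped records and reasons.
#' @export
assemble_candidates <- function(table, panel, scores = NULL,
                                config = filter_config()) {
  rec <- table$records
  region <- classify_region(rec$chrom, rec$pos, panel, config$flank_bp, rec$gene)
  n_pass <- integer(nrow(rec))
  tools_passed <- character(nrow(rec))
  if (!is.null(scores) && nrow(scores)) {
    pass <- splice_impact(scores$tool, scores$wt_score, scores$mut_score, config)
    for (i in seq_len(nrow(rec))) {
      hit <- scores$variant_id == rec$variant_id[i]
      n_pass[i] <- sum(pass[hit])
      tools_passed[i] <- paste(scores$tool[hit][pass[hit]], collapse = ",")
    }
  }
  tier <- ifelse(region %in% c("coding_exonic", "near_splice"), 1L,
                 ifelse(region == "deep_intronic" &
                          n_pass >= config$splice_quorum, 2L, NA_integer_))
  reason <- ifelse(region == "other", "outside gene model",
                   ifelse(region == "deep_intronic", "splice quorum not met", ""))
  excluded <- data.frame(variant_id = rec$variant_id[is.na(tier)],
                         reason = reason[is.na(tier)],
                         stringsAsFactors = FALSE)
  keep <- !is.na(tier)
  cand <- data.frame(
    variant_id = rec$variant_id[keep], gene = rec$gene[keep],
    chrom = rec$chrom[keep], pos = rec$pos[keep],
    region = region[keep], tier = tier[keep],
    hom_flag = !is.na(rec$hom_count[keep]) & rec$hom_count[keep] > 0,
    splice_tools_passed = tools_passed[keep],
    maf = rec$maf[keep], hom_count = rec$hom_count[keep],
    clinvar_significance = rec$clinvar_significance[keep],
    acmg_class = rec$acmg_class[keep], label = rec$label[keep],
    stringsAsFactors = FALSE
  )
  cand$predictor_calls <- rec$predictor_calls[keep]
  cand <- cand[order(cand$tier, cand$gene, cand$chrom, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  structure(cand, class = c("candidate_set", "data.frame"), excluded = excluded)
}

#' Write a candidate list as TSV (plus optional exclusion JSON)
#'
#' Columns mirror a clinical candidate-variant table: gene, variant
#' label, frequency, homozygote count/flag, ClinVar class, predictor
#' calls, ACMG class, tier.
#'
#' @param candidates A `candidate_set` from [assemble_candidates()].
#' @param path Output TSV path.
#' @param exclusions_path Optional path for a JSON of dropped records
#'   and reasons.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, exclusions_path = NULL) {
  out <- as.data.frame(candidates)
  out$predictor_calls <- vapply(out$predictor_calls, function(p) {
    if (!length(p)) "" else paste(paste0(names(p), ":", unname(p)), collapse = "|")
  }, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(exclusions_path)) {
    jsonlite::write_json(attr(candidates, "excluded"), exclusions_path,
                         pretty = TRUE)
  }
  invisible(path)
}
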