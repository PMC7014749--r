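#' Pipeline filter configuration
#'
#' Holds every tunable threshold of the prioritization cascade and the
#' splice-impact rules. Defaults reflect the diagnostic setting the
#' pipeline was designed for: rare-variant analysis of inherited retinal
#' dystrophy (IRD) families against gnomAD and a RetNet-derived gene
#' panel.
#'
#' @param maf_threshold Maximum population minor-allele frequency; the
#'   frequency filter discards variants with MAF above this (default
#'   0.01).
#' @param flank_bp Width of the near-splice flank around coding exons,
#'   in bases, inclusive (default 10).
#' @param phenotype_terms Lower-cased terms matched (case-insensitive
#'   substring) against the ClinVar phenotype list during the rescue
#'   step.
#' @param splice_thresholds Per-tool list of `min_score` (floor on the
#'   stronger of the wild-type/mutant site scores) and
#'   `min_variation_pct` (strict lower bound on the percent score
#'   change). Defaults: MaxEntScan 2 / 15%, HSF 70 / 10%, NNSPLICE
#'   0.4 / 10%.
#' @param splice_quorum Number of tools that must flag a deep-intronic
#'   variant for tier-2 admission (default 2 of 3).
#' @param treat_missing_maf_as_pass Keep variants with no population
#'   frequency entry (novel variants) in the frequency filter (default
#'   `TRUE`).
#' @param max_control_carriers Maximum number of pseudo-control samples
#'   allowed to carry the alternate allele in the recurrence filter
#'   (default 0: strictly family-exclusive). Homozygous control calls
#'   always fail the filter regardless of this knob.
#' @param missing_call Zygosity assumed when combining per-sample VCFs
#'   at sites absent from one sample: `"missing"` (default) or
#'   `"hom_ref"` for all-sites sources.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          flank_bp = 10,
                          phenotype_terms = c("retinitis pigmentosa",
                                              "retinal dystrophy", "usher"),
                          splice_thresholds = list(
                            maxent = list(min_score = 2, min_variation_pct = 15),
                            hsf = list(min_score = 70, min_variation_pct = 10),
                            nnsplice = list(min_score = 0.4, min_variation_pct = 10)
                          ),
                          splice_quorum = 2,
                          treat_missing_maf_as_pass = TRUE,
                          max_control_carriers = 0,
                          missing_call = c("missing", "hom_ref")) {
  missing_call <- match.arg(missing_call)
  stopifnot(
    is.numeric(maf_threshold), maf_threshold > 0, maf_threshold <= 1,
    flank_bp >= 0, max_control_carriers >= 0, splice_quorum >= 1
  )
  miss <- setdiff(SPLICE_TOOLS, names(splice_thresholds))
  if (length(miss)) stop("splice_thresholds missing tool(s): ", paste(miss, collapse = ", "))
  for (tool in SPLICE_TOOLS) {
    th <- splice_thresholds[[tool]]
    if (is.null(th$min_score) || is.null(th$min_variation_pct) ||
        th$min_score < 0 || th$min_variation_pct < 0) {
      stop("invalid splice thresholds for tool: ", tool)
    }
  }
  structure(list(
    maf_threshold = maf_threshold, flank_bp = as.integer(flank_bp),
    phenotype_terms = tolower(phenotype_terms),
    splice_thresholds = splice_thresholds,
    splice_quorum = as.integer(splice_quorum),
    treat_missing_maf_as_pass = isTRUE(treat_missing_maf_as_pass),
    max_control_carriers = as.integer(max_control_carriers),
    missing_call = missing_call
  ), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  cat(sprintf("  maf_threshold: %g   flank_bp: %d   max_control_carriers: %d\n",
              x$maf_threshold, x$flank_bp, x$max_control_carriers))
  cat("  phenotype_terms:", paste(x$phenotype_terms, collapse = "; "), "\n")
  for (tool in names(x$splice_thresholds)) {
    th <- x$splice_thresholds[[tool]]
    cat(sprintf("  %s: min_score %g, variation > %g%%\n",
                tool, th$min_score, th$min_variation_pct))
  }
  invisible(x)
}

#' Read a filter configuration from a YAML file
#'
#' Keys mirror the arguments of [filter_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [filter_config()].
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  defaults <- filter_config()
  if (!is.null(vals$splice_thresholds)) {
    merged <- defaults$splice_thresholds
    for (tool in names(vals$splice_thresholds)) {
      merged[[tool]] <- utils::modifyList(merged[[tool]], vals$splice_thresholds[[tool]])
    }
    vals$splice_thresholds <- merged
  }
  do.call(filter_config, vals)
}
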