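#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats setNames
#' @importFrom utils read.table write.table read.delim
NULL

## The four-valued zygosity code used throughout the package.
ZYGOSITY_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

## Recognised ClinVar clinical-significance categories (normalized).
CLINVAR_LEVELS <- c(
  "pathogenic", "likely_pathogenic", "conflicting_path_vus",
  "vus", "benign", "likely_benign", "not_reported"
)

## ClinVar significance that, combined with a phenotype match, triggers the
## rescue step ahead of the recurrence/frequency filters.
CLINVAR_RESCUE_LEVELS <- c("pathogenic", "likely_pathogenic", "conflicting_path_vus")

#' Build a stable variant identifier
#'
#' Identifiers have the form `chrom:pos:ref:alt` and are unique within a
#' [variant_table()] by construction (multiallelic sites must have been
#' split into biallelic records first).
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic variants
#'   (1-based VCF positions).
#' @return Character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

empty_records <- function() {
  data.frame(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    maf = numeric(), hom_count = integer(),
    clinvar_significance = character(),
    label = character(), acmg_class = integer(),
    stringsAsFactors = FALSE
  )
}

normalize_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  defaults <- list(
    gene = "", maf = NA_real_, hom_count = NA_integer_,
    clinvar_significance = "not_reported", label = "",
    acmg_class = NA_integer_
  )
  for (nm in names(defaults)) {
    if (is.null(records[[nm]])) records[[nm]] <- rep(defaults[[nm]], nrow(records))
  }
  if (is.null(records$clinvar_phenotypes)) {
    records$clinvar_phenotypes <- replicate(nrow(records), character(), simplify = FALSE)
  }
  if (is.null(records$predictor_calls)) {
    records$predictor_calls <- replicate(nrow(records), character(), simplify = FALSE)
  }
  if (is.null(records$variant_id)) {
    records$variant_id <- variant_id(records$chrom, records$pos, records$ref, records$alt)
  }
  records$pos <- as.integer(records$pos)
  records$gene[is.na(records$gene)] <- ""
  records$clinvar_significance[is.na(records$clinvar_significance)] <- "not_reported"
  rownames(records) <- NULL
  records
}

validate_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$pos < 1)) stop("variant positions must be >= 1 (VCF convention)")
  if (any(records$ref == records$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(records$variant_id)) {
    dup <- records$variant_id[duplicated(records$variant_id)][1]
    stop("duplicate variant_id after splitting: ", dup)
  }
  bad <- !records$clinvar_significance %in% CLINVAR_LEVELS
  if (any(bad)) {
    stop("unknown ClinVar significance value: ", records$clinvar_significance[bad][1])
  }
  invisible(records)
}

#' Construct a variant table
#'
#' The central container of the package: a set of normalized biallelic
#' variant records together with a zygosity call for every
#' (variant, sample) pair. Genotypes are held as a character matrix with
#' one row per variant (`variant_id` rownames) and one column per sample,
#' each cell one of `hom_ref`, `het`, `hom_alt`, `missing`.
#'
#' @param records Data frame of variant records. Required columns:
#'   `chrom`, `pos`, `ref`, `alt`. Optional annotation columns: `gene`,
#'   `maf`, `hom_count`, `clinvar_significance`, `clinvar_phenotypes`
#'   (list column), `predictor_calls` (list column of named character
#'   vectors), `acmg_class`, `label`, `variant_id`.
#' @param samples Character vector of sample identifiers (ordered).
#' @param geno Character matrix of zygosity calls (`variant x sample`),
#'   or `NULL` to initialise every call as `missing`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(records = empty_records(), samples = character(),
                          geno = NULL) {
  records <- normalize_records(records)
  validate_records(records)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids in variant table")
  if (is.null(geno)) {
    geno <- matrix("missing", nrow = nrow(records), ncol = length(samples),
                   dimnames = list(records$variant_id, samples))
  }
  geno <- as.matrix(geno)
  if (nrow(records) > 0 || length(samples) > 0) {
    if (!identical(dim(geno), c(nrow(records), length(samples)))) {
      stop("genotype matrix dimensions do not match records x samples")
    }
  }
  dimnames(geno) <- list(records$variant_id, samples)
  bad <- !geno %in% ZYGOSITY_LEVELS
  if (any(bad)) stop("invalid zygosity value: ", geno[bad][1])
  structure(list(records = records, samples = samples, geno = geno),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d record(s) x %d sample(s)\n",
              nrow(x$records), length(x$samples)))
  if (length(x$samples)) cat("samples:", paste(x$samples, collapse = ", "), "\n")
  if (nrow(x$records)) {
    show <- utils::head(x$records[, c("variant_id", "gene", "maf", "clinvar_significance")], 8)
    print(show)
    if (nrow(x$records) > 8) cat("...\n")
  }
  invisible(x)
}

#' Number of variant records in a table
#' @param table A [variant_table()].
#' @return Integer count.
#' @export
n_variants <- function(table) nrow(table$records)

#' Restrict a variant table to a subset of records
#'
#' @param table A [variant_table()].
#' @param ids Character vector of `variant_id`s to keep (order taken from
#'   the table, not from `ids`).
#' @return A [variant_table()] with the same samples.
#' @export
subset_variants <- function(table, ids) {
  keep <- table$records$variant_id %in% ids
  variant_table(table$records[keep, , drop = FALSE], table$samples,
                table$geno[keep, , drop = FALSE])
}

#' Zygosity call lookup
#'
#' @param table A [variant_table()].
#' @param ids Variant ids (rows); defaults to all.
#' @param samples Sample ids (columns); defaults to all.
#' @return Character matrix of zygosity calls.
#' @export
zygosity <- function(table, ids = NULL, samples = NULL) {
  g <- table$geno
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(g))
    if (length(miss)) stop("unknown variant_id: ", miss[1])
    g <- g[ids, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(g))
    if (length(miss)) stop("unknown sample id: ", miss[1])
    g <- g[, samples, drop = FALSE]
  }
  g
}

## TRUE where the sample carries >= 1 alternate allele.
carries_alt <- function(geno) geno == "het" | geno == "hom_alt"

#' Combine variant tables across samples
#'
#' Mirrors the joint-VCF step of the workflow: the union of variant
#' records over all input tables, with the samples concatenated. A sample
#' with no call at a union variant receives `missing` by default;
#' `missing_as = "hom_ref"` reflects all-sites source VCFs that assert
#' reference calls.
#'
#' Annotations for a variant seen in several tables are taken from the
#' first table that carries the record.
#'
#' @param tables List of [variant_table()] objects with disjoint samples.
#' @param missing_as Zygosity assigned where a table has no record for a
#'   union variant: `"missing"` (default) or `"hom_ref"`.
#' @return A single [variant_table()].
#' @export
combine_tables <- function(tables, missing_as = c("missing", "hom_ref")) {
  missing_as <- match.arg(missing_as)
  if (inherits(tables, "variant_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  all_samples <- unlist(lapply(tables, `[[`, "samples"))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample id across tables: ",
         all_samples[duplicated(all_samples)][1])
  }
  recs <- do.call(rbind, lapply(tables, function(t) t$records))
  recs <- recs[!duplicated(recs$variant_id), , drop = FALSE]
  geno <- matrix(missing_as, nrow = nrow(recs), ncol = length(all_samples),
                 dimnames = list(recs$variant_id, all_samples))
  for (t in tables) {
    if (nrow(t$records) == 0 || length(t$samples) == 0) next
    geno[t$records$variant_id, t$samples] <- t$geno
  }
  variant_table(recs, all_samples, geno)
}
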