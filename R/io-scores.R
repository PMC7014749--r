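SPLICE_TOOLS <- c("maxent", "hsf", "nnsplice")

#' Read a splice-predictor score table
#'
#' The pipeline does not compute splice-site scores itself; it consumes
#' pairs of wild-type and mutant scores produced externally by
#' MaxEntScan, Human Splicing Finder or NNSPLICE and applies the
#' decision thresholds (see [splice_impact()]). The table is
#' tab-separated with columns `variant_id`, `tool`, `wt_score`,
#' `mut_score`.
#'
#' @param path Path to a TSV file.
#' @return Data frame of score pairs.
#' @export
read_splice_scores <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "tool", "wt_score", "mut_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table missing columns: ", paste(miss, collapse = ", "))
  df$tool <- tolower(df$tool)
  bad <- !df$tool %in% SPLICE_TOOLS
  if (any(bad)) stop("unknown splice tool: ", df$tool[bad][1])
  df$wt_score <- as.numeric(df$wt_score)
  df$mut_score <- as.numeric(df$mut_score)
  df[need]
}

#' Write a splice-predictor score table
#' @param scores Data frame as returned by [read_splice_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls from a long-format TSV
#'
#' Sanger segregation results arrive as one call per line:
#' `member_id`, `variant_id`, `zygosity` (the four-valued code).
#' Members/variants absent from the file are `missing`. Variant ids of
#' the form `chrom:pos:ref:alt` are decomposed into minimal records;
#' alternatively supply annotated `records` (matched by `variant_id`).
#'
#' @param path Path to a TSV file.
#' @param records Optional data frame of variant records supplying
#'   annotations (e.g. the `records` of a cascade output table).
#' @param members Optional character vector fixing the sample set (and
#'   order); defaults to the members seen in the file.
#' @return A [variant_table()].
#' @export
read_genotype_tsv <- function(path, records = NULL, members = NULL) {
  if (!file.exists(path)) stop("genotype TSV not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("member_id", "variant_id", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("genotype TSV missing columns: ", paste(miss, collapse = ", "))
  bad <- !df$zygosity %in% ZYGOSITY_LEVELS
  if (any(bad)) stop("invalid zygosity in genotype TSV: ", df$zygosity[bad][1])
  genotype_table(df, records = records, members = members)
}

#' Build a variant table from long-format genotype calls
#'
#' @param calls Data frame with columns `member_id`, `variant_id`,
#'   `zygosity`.
#' @inheritParams read_genotype_tsv
#' @return A [variant_table()].
#' @export
genotype_table <- function(calls, records = NULL, members = NULL) {
  ids <- unique(calls$variant_id)
  if (is.null(records)) {
    parts <- strsplit(ids, ":", fixed = TRUE)
    ok <- lengths(parts) == 4
    if (!all(ok)) stop("variant_id not of the form chrom:pos:ref:alt: ", ids[!ok][1])
    records <- data.frame(
      chrom = vapply(parts, `[[`, "", 1),
      pos = as.integer(vapply(parts, `[[`, "", 2)),
      ref = vapply(parts, `[[`, "", 3),
      alt = vapply(parts, `[[`, "", 4),
      stringsAsFactors = FALSE
    )
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    unknown <- setdiff(ids, records$variant_id)
    if (length(unknown)) stop("genotype calls for unknown variant: ", unknown[1])
    records <- records[records$variant_id %in% ids, , drop = FALSE]
  }
  if (is.null(members)) members <- unique(calls$member_id)
  tab <- variant_table(records, members)
  known <- calls$member_id %in% members
  tab$geno[cbind(match(calls$variant_id[known], rownames(tab$geno)),
                 match(calls$member_id[known], members))] <- calls$zygosity[known]
  tab
}

#' Write genotype calls as a long-format TSV
#'
#' Emits one line per non-missing call (missing is the default on
#' re-read).
#'
#' @param table A [variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(table, path) {
  idx <- which(table$geno != "missing", arr.ind = TRUE)
  df <- data.frame(
    member_id = colnames(table$geno)[idx[, 2]],
    variant_id = rownames(table$geno)[idx[, 1]],
    zygosity = table$geno[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$member_id, df$variant_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
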