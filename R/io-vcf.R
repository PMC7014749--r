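#' Annotation key mapping for VCF INFO fields
#'
#' The pipeline consumes already-annotated VCFs; annotations travel in
#' INFO keys whose names are configurable here. Frequency and homozygote
#' counts are treated as per-alternate-allele (`Number=A`) fields.
#'
#' @param gene,maf,hom_count,clnsig,clndn,pred,acmg,label INFO key names.
#' @return Named list of key names.
#' @export
anno_keys <- function(gene = "GENE", maf = "GNOMAD_AF",
                      hom_count = "GNOMAD_NHOMALT", clnsig = "CLNSIG",
                      clndn = "CLNDN", pred = "PRED", acmg = "ACMG",
                      label = "LABEL") {
  list(gene = gene, maf = maf, hom_count = hom_count, clnsig = clnsig,
       clndn = clndn, pred = pred, acmg = acmg, label = label)
}

## Normalize ClinVar significance strings (ours or ClinVar's own notation)
## to the package's seven-valued code.
normalize_clnsig <- function(x) {
  if (is.na(x) || x == "" || x == ".") return("not_reported")
  key <- tolower(gsub("[ /,]+", "_", x))
  if (key %in% CLINVAR_LEVELS) return(key)
  map <- c(
    pathogenic = "pathogenic",
    likely_pathogenic = "likely_pathogenic",
    pathogenic_likely_pathogenic = "likely_pathogenic",
    conflicting_interpretations_of_pathogenicity = "conflicting_path_vus",
    conflicting_classifications_of_pathogenicity = "conflicting_path_vus",
    uncertain_significance = "vus",
    benign = "benign",
    likely_benign = "likely_benign",
    benign_likely_benign = "likely_benign",
    not_provided = "not_reported"
  )
  out <- unname(map[key])
  if (is.na(out)) stop("unknown ClinVar significance value in VCF: ", x)
  out
}

## Zygosity of allele `k` given a raw GT string like "0/1", "1|2", ".".
gt_to_zygosity <- function(gt, k) {
  if (is.na(gt) || gt == "" || gt == ".") return("missing")
  gt <- sub(":.*$", "", gt)
  tokens <- strsplit(gt, "[/|]")[[1]]
  if (any(tokens == "." | tokens == "")) return("missing")
  n_alt <- sum(tokens == as.character(k))
  if (length(tokens) == 1) {
    # haploid call (e.g. male X): treated as hom_alt / hom_ref
    return(if (n_alt >= 1) "hom_alt" else "hom_ref")
  }
  c("hom_ref", "het", "hom_alt")[pmin(n_alt, 2L) + 1L]
}

## Pick the k-th comma-separated value of a per-allele INFO field.
pick_allele_value <- function(x, k) {
  if (is.na(x) || x == "" || x == ".") return(NA_character_)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  v <- if (length(parts) >= k) parts[k] else parts[1]
  if (v == "." || v == "") NA_character_ else v
}

#' Read an annotated VCF into a variant table
#'
#' Parses a VCF v4.x file (plain or gzipped) with [vcfR::read.vcfR()],
#' splits multiallelic sites into biallelic records, maps genotypes to
#' the four-valued zygosity code, and lifts annotations out of the INFO
#' keys named in `keys`. Symbolic alternate alleles (`<DEL>`, `*`, ...)
#' are skipped with a warning; structural records are out of scope.
#'
#' @param path Path to a VCF file.
#' @param keys INFO key mapping, see [anno_keys()].
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, keys = anno_keys()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)),
    warning = function(w) stop("malformed VCF '", path, "': ", conditionMessage(w))
  )
  samples <- character()
  if (ncol(vcf@gt) > 1) samples <- colnames(vcf@gt)[-1]
  n_sites <- nrow(vcf@fix)
  if (n_sites == 0) return(variant_table(samples = samples))

  fix <- vcf@fix
  info_field <- function(key) {
    if (is.null(key)) return(rep(NA_character_, n_sites))
    suppressWarnings(vcfR::extract.info(vcf, element = key))
  }
  gene_raw <- info_field(keys$gene)
  maf_raw <- info_field(keys$maf)
  hom_raw <- info_field(keys$hom_count)
  sig_raw <- info_field(keys$clnsig)
  phen_raw <- info_field(keys$clndn)
  pred_raw <- info_field(keys$pred)
  acmg_raw <- info_field(keys$acmg)
  label_raw <- info_field(keys$label)

  gt_col <- if (length(samples)) vcf@gt[, -1, drop = FALSE] else
    matrix(character(), nrow = n_sites, ncol = 0)

  rows <- list()
  geno_rows <- list()
  for (i in seq_len(n_sites)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (grepl("^<", alt) || alt == "*" || alt == ".") {
        warning("skipping symbolic/overlapping ALT allele at ",
                fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
        next
      }
      phen <- pick_string_set(phen_raw[i])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alt,
        gene = if (is.na(gene_raw[i])) "" else gene_raw[i],
        maf = as.numeric(pick_allele_value(maf_raw[i], k)),
        hom_count = as.integer(pick_allele_value(hom_raw[i], k)),
        clinvar_significance = normalize_clnsig(sig_raw[i]),
        label = if (is.na(label_raw[i])) "" else info_unescape(label_raw[i]),
        acmg_class = suppressWarnings(as.integer(acmg_raw[i])),
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$clinvar_phenotypes <- list(phen)
      rows[[length(rows)]]$predictor_calls <- list(parse_pred(pred_raw[i]))
      geno_rows[[length(geno_rows) + 1L]] <-
        vapply(seq_along(samples), function(s) gt_to_zygosity(gt_col[i, s], k), "")
    }
  }
  if (!length(rows)) return(variant_table(samples = samples))
  records <- do.call(rbind, rows)
  geno <- do.call(rbind, geno_rows)
  if (length(samples) == 0) geno <- matrix("missing", nrow(records), 0)
  variant_table(records, samples, geno)
}

## Phenotype lists follow the ClinVar CLNDN convention of underscores
## for spaces; percent-escapes are decoded first.
pick_string_set <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(character())
  gsub("_", " ", info_unescape(strsplit(x, "|", fixed = TRUE)[[1]]))
}

parse_pred <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(character())
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(info_unescape(vapply(kv, function(p) if (length(p) > 1) p[2] else "", "")),
           vapply(kv, `[[`, "", 1))
}

## VCF INFO fields may not contain spaces, semicolons, equals signs or
## (here) the pipe used as a list separator; percent-encode them.
info_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(" ", "%20", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("|", "%7C", x, fixed = TRUE)
}

info_unescape <- function(x) vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)

#' Write a variant table to VCF
#'
#' Serializes a [variant_table()] as VCF v4.2, one biallelic record per
#' line, with annotations placed in the INFO keys named in `keys`. A
#' `.gz` extension produces a gzip-compressed file. The output
#' round-trips through [read_vcf()] to an equal table.
#'
#' @param table A [variant_table()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @param keys INFO key mapping, see [anno_keys()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, keys = anno_keys()) {
  rec <- table$records
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", keys$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population minor allele frequency\">", keys$maf),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Population homozygote count\">", keys$hom_count),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"ClinVar clinical significance\">", keys$clnsig),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"ClinVar phenotype list\">", keys$clndn),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Pathogenicity predictor calls\">", keys$pred),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"ACMG class (carried annotation)\">", keys$acmg),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Variant label\">", keys$label),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", table$samples), collapse = "\t")
  info_of <- function(i) {
    r <- rec[i, ]
    parts <- character()
    if (nzchar(r$gene)) parts <- c(parts, paste0(keys$gene, "=", info_escape(r$gene)))
    if (!is.na(r$maf)) parts <- c(parts, paste0(keys$maf, "=", format(r$maf, scientific = FALSE, trim = TRUE)))
    if (!is.na(r$hom_count)) parts <- c(parts, paste0(keys$hom_count, "=", r$hom_count))
    if (r$clinvar_significance != "not_reported") {
      parts <- c(parts, paste0(keys$clnsig, "=", r$clinvar_significance))
    }
    phen <- rec$clinvar_phenotypes[[i]]
    if (length(phen)) {
      parts <- c(parts, paste0(keys$clndn, "=", paste(info_escape(phen), collapse = "|")))
    }
    pred <- rec$predictor_calls[[i]]
    if (length(pred)) {
      parts <- c(parts, paste0(keys$pred, "=", paste(
        paste0(names(pred), ":", info_escape(unname(pred))), collapse = "|")))
    }
    if (!is.na(r$acmg_class)) parts <- c(parts, paste0(keys$acmg, "=", r$acmg_class))
    if (nzchar(r$label)) parts <- c(parts, paste0(keys$label, "=", info_escape(r$label)))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  body <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    body[i] <- paste(c(rec$chrom[i], rec$pos[i], ".", rec$ref[i], rec$alt[i],
                       ".", "PASS", info_of(i), "GT",
                       unname(gt_code[table$geno[i, , drop = TRUE]])),
                     collapse = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}
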