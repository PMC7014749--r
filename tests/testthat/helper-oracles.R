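# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain per-record loops, independent of the package's
# vectorized implementations.

# A 2-exon toy gene with span padding on both sides, so every region
# class is reachable on either flank of either exon.
two_exon_panel <- function() {
  gene_panel(
    exons = data.frame(chrom = "chrT", start = c(1100L, 1600L),
                       end = c(1200L, 1700L), gene = "TOY1"),
    spans = data.frame(chrom = "chrT", start = 1000L, end = 1900L,
                       gene = "TOY1"),
    name = "toy"
  )
}

# Quartet-plus pedigree over family samples A1..A6 (A1, A2 affected;
# all sequenced) used by the random-table cascade oracle tests.
oracle_pedigree <- function() {
  pedigree(data.frame(
    member_id = paste0("A", 1:6),
    father_id = c(NA, NA, "A1", "A1", "A1", "A1"),
    mother_id = c(NA, NA, "A2", "A2", "A2", "A2"),
    sex = rep(c("male", "female"), 3),
    affected = c("affected", "affected", "unaffected", "unaffected",
                 "unaffected", "unknown"),
    sequenced = TRUE, genotyped = TRUE, stringsAsFactors = FALSE
  ), family_id = "ORACLE")
}

# Random annotated table over the oracle pedigree + controls; records
# are scattered in and out of the toy simulator panel.
random_table <- function(n_records, n_family = 6, n_controls = 6,
                         panel = toy_oracle_panel()) {
  fam <- paste0("A", seq_len(n_family))
  ctl <- paste0("C", seq_len(n_controls))
  samples <- c(fam, ctl)
  in_panel <- runif(n_records) < 0.6
  gene_idx <- sample(seq_len(nrow(panel$spans)), n_records, replace = TRUE)
  pos <- ifelse(in_panel,
                panel$spans$start[gene_idx] +
                  sample.int(2500L, n_records, replace = TRUE),
                900000L + sample.int(50000L, n_records))
  chrom <- ifelse(in_panel, panel$spans$chrom[gene_idx], "chrA")
  ref <- sample(c("A", "C"), n_records, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "T")
  pos <- pos + seq_len(n_records) # avoid id collisions
  sig <- sample(c("pathogenic", "likely_pathogenic", "vus", "benign",
                  "not_reported"), n_records, replace = TRUE)
  phen <- lapply(seq_len(n_records), function(i) {
    if (runif(1) < 0.3) "Retinitis pigmentosa" else character()
  })
  records <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = ifelse(in_panel, panel$spans$gene[gene_idx], ""),
    maf = ifelse(runif(n_records) < 0.25, NA,
                 round(runif(n_records, 0, 0.05), 4)),
    clinvar_significance = sig, stringsAsFactors = FALSE
  )
  records$clinvar_phenotypes <- phen
  geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                        n_records * length(samples), replace = TRUE,
                        prob = c(0.55, 0.25, 0.1, 0.1)),
                 nrow = n_records,
                 dimnames = list(NULL, samples))
  list(table = variant_table(records, samples, geno),
       family = fam, controls = ctl)
}

toy_oracle_panel <- function() {
  gene_panel(
    exons = data.frame(
      chrom = rep(c("chrA", "chrB"), each = 3),
      start = c(10000L, 20000L, 30000L, 10000L, 20000L, 30000L),
      end = c(12999L, 22999L, 32999L, 12999L, 22999L, 32999L),
      gene = c("OG1", "OG2", "OG3", "OG4", "OG5", "OG6")),
    name = "oracle-panel")
}

# Brute-force evaluation of the whole cascade as one conjunctive
# predicate per record.
oracle_cascade_ids <- function(table, ped, panel, family, controls,
                               config = filter_config()) {
  keep <- character()
  aff <- intersect(ped$member_id[ped$affected == "affected" & ped$sequenced],
                   table$samples)
  una <- intersect(ped$member_id[ped$affected == "unaffected" & ped$sequenced],
                   table$samples)
  for (i in seq_len(nrow(table$records))) {
    r <- table$records[i, ]
    g <- table$geno[i, ]
    carrier <- function(s) g[s] %in% c("het", "hom_alt")
    rescued <- r$clinvar_significance %in%
      c("pathogenic", "likely_pathogenic", "conflicting_path_vus") &&
      any(vapply(config$phenotype_terms, function(term)
        any(grepl(term, tolower(unlist(r$clinvar_phenotypes)), fixed = TRUE)),
        TRUE))
    rec_ok <- rescued ||
      (!any(g[controls] == "hom_alt") &&
         any(vapply(family, carrier, TRUE)) &&
         sum(vapply(controls, carrier, TRUE)) <= config$max_control_carriers)
    freq_ok <- rescued ||
      (if (is.na(r$maf)) config$treat_missing_maf_as_pass
       else r$maf <= config$maf_threshold)
    gene_ok <- r$gene %in% panel$spans$gene ||
      any(panel$spans$chrom == r$chrom & panel$spans$start <= r$pos &
            panel$spans$end >= r$pos)
    ped_ok <- any(vapply(aff, carrier, TRUE)) &&
      !any(g[una] == "hom_alt")
    if (rec_ok && freq_ok && gene_ok && ped_ok) {
      keep <- c(keep, r$variant_id)
    }
  }
  keep
}

# Brute-force region classification by scanning exon distance directly.
oracle_region <- function(pos, panel, gene, flank) {
  s <- panel$spans[panel$spans$gene == gene, ]
  if (pos < s$start || pos > s$end) return("other")
  ex <- panel$exons[panel$exons$gene == gene, ]
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) return("coding_exonic")
  }
  d <- min(vapply(seq_len(nrow(ex)), function(i)
    min(abs(pos - ex$start[i]), abs(pos - ex$end[i])), 0))
  if (d <= flank) "near_splice" else "deep_intronic"
}

# Mendelian check: a child's allele count must be the sum of one gamete
# from each parent; missing parents can donate either allele.
mendelian_consistent <- function(table, ped) {
  gametes <- function(z) switch(z, hom_ref = 0L, het = c(0L, 1L),
                                hom_alt = 1L, missing = c(0L, 1L))
  count_of <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (i in seq_len(nrow(ped))) {
    ch <- ped$member_id[i]
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    if (is.na(fa) || is.na(mo)) next
    if (!all(c(ch, fa, mo) %in% table$samples)) next
    for (v in seq_len(nrow(table$records))) {
      zc <- table$geno[v, ch]
      if (zc == "missing") next
      possible <- outer(gametes(table$geno[v, fa]),
                        gametes(table$geno[v, mo]), `+`)
      if (!count_of[[zc]] %in% possible) return(FALSE)
    }
  }
  TRUE
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
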