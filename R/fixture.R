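#' Bundled case study: a pseudo-dominant retinitis pigmentosa family
#'
#' Reconstructs, entirely in code, the worked example the pipeline was
#' designed around: a large three-generation Spanish family with an
#' apparently dominant retinitis pigmentosa pedigree that resolves into
#' autosomal recessive inheritance through compound-heterozygous USH2A
#' variants, with possible oligogenic contributions from PDZD7 and
#' ADGRV1 in the index patient.
#'
#' The fixture contains: six clinically relevant heterozygous variants
#' (M1-M4 in *USH2A*, M5 in *PDZD7*, M6 in *ADGRV1*) with their
#' published gnomAD frequencies, homozygote counts, ClinVar classes and
#' predictor calls; a 28-member pedigree of which 19 are genotyped,
#' 5 affected (II:1, III:3, III:17, III:20, III:23) and 3 sequenced
#' (III:3, III:23, IV:1); whole-genome genotypes for the 3 sequenced
#' members plus 6 pseudo-control samples; and Sanger-style genotype
#' calls limited to the documented carrier statements — genotypes of
#' members not explicitly documented are left untyped rather than
#' guessed. Genomic coordinates and a 4-gene panel subset are synthetic
#' placeholders on toy contigs; annotations and carrier patterns are
#' the real ones.
#'
#' Up to four decoy variants exercise one cascade filter each: a common
#' polymorphism (frequency), a control-shared artefact (recurrence), a
#' variant homozygous in the unaffected sequenced son (pedigree), and an
#' off-panel variant (gene filter).
#'
#' @param n_decoys Number of decoy variants to include, 0-4 (default 4).
#' @return A list: `table` (combined family + pseudo-control
#'   [variant_table()]), `ped` ([pedigree()]), `panel` (4-gene
#'   [gene_panel()] subset), `sanger` (Sanger-call [variant_table()]
#'   over the 19 genotyped members), `family_samples`,
#'   `control_samples`, `variants` (named map M1..M6 to `variant_id`),
#'   `truth` (per-variant labels).
#' @export
rp_family_fixture <- function(n_decoys = 4) {
  stopifnot(n_decoys >= 0, n_decoys <= 4)
  panel <- rp_panel_fixture()

  m_pos <- c(M1 = 105050L, M2 = 110100L, M3 = 120150L, M4 = 170080L,
             M5 = 52060L, M6 = 250100L)
  records <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr10", "chr5"),
    pos = unname(m_pos),
    ref = c("C", "C", "G", "G", "C", "A"),
    alt = c("CGCCA", "T", "T", "A", "T", "ATGGAACTCCAGGAGGG"),
    gene = c("USH2A", "USH2A", "USH2A", "USH2A", "PDZD7", "ADGRV1"),
    maf = c(0.0000568, 0.0000531, 0.0009677, 0.0000213, 0.0000134, NA),
    hom_count = c(0L, 0L, 0L, 0L, 0L, NA),
    clinvar_significance = c("pathogenic", "likely_pathogenic",
                             "likely_pathogenic", "not_reported",
                             "not_reported", "not_reported"),
    label = c("M1 c.923_924dupGCCA p.(His308Glnfs*16)",
              "M2 c.1000C>T p.(Arg334Trp)",
              "M3 c.2276G>T p.(Cys759Phe)",
              "M4 c.12560G>A p.(Arg4187His)",
              "M5 c.1543C>T p.(Gln515*)",
              "M6 c.13165_13166insTGGAACTCCAGGAGGG p.(Gly4360Glufs*10)"),
    acmg_class = c(5L, 5L, 4L, 3L, 5L, 4L),
    stringsAsFactors = FALSE
  )
  usher_phen <- c("Retinitis pigmentosa", "Usher syndrome type 2A")
  records$clinvar_phenotypes <- list(usher_phen, usher_phen, usher_phen,
                                     character(), character(), character())
  records$predictor_calls <- list(
    character(), character(), character(),
    c(SIFT = "damaging", PolyPhen2 = "benign(0.066)", MutationTaster = "polymorphism"),
    c(SIFT = "damaging", MutationTaster = "disease_causing"),
    c(PolyPhen2 = "probably_damaging(0.999)", MutationTaster = "disease_causing")
  )

  decoys <- data.frame(
    chrom = c("chr1", "chr1", "chr10", "chr1"),
    pos = c(140050L, 160070L, 55080L, 500000L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    gene = c("USH2A", "USH2A", "PDZD7", ""),
    maf = c(0.2, 0.0001, NA, NA),
    hom_count = c(1200L, 0L, NA, NA),
    clinvar_significance = "not_reported",
    label = "", acmg_class = NA_integer_,
    stringsAsFactors = FALSE
  )
  decoys$clinvar_phenotypes <- replicate(4, character(), simplify = FALSE)
  decoys$predictor_calls <- replicate(4, character(), simplify = FALSE)
  decoy_class <- c("common_polymorphism", "control_shared_artifact",
                   "hom_in_unaffected", "off_panel")
  decoys <- decoys[seq_len(n_decoys), , drop = FALSE]
  decoy_class <- decoy_class[seq_len(n_decoys)]

  all_records <- rbind(records, decoys)
  family_samples <- c("III:3", "III:23", "IV:1")
  control_samples <- paste0("PC", 1:6)
  samples <- c(family_samples, control_samples)
  ids <- variant_id(all_records$chrom, all_records$pos,
                    all_records$ref, all_records$alt)
  geno <- matrix("hom_ref", nrow(all_records), length(samples),
                 dimnames = list(ids, samples))
  m_id <- setNames(ids[1:6], c("M1", "M2", "M3", "M4", "M5", "M6"))
  geno[m_id["M1"], "III:23"] <- "het"
  geno[m_id["M3"], "III:23"] <- "het"
  geno[m_id[c("M2", "M4", "M5", "M6")], "III:3"] <- "het"
  if (n_decoys >= 1) geno[ids[7], "III:3"] <- "het"            # common polymorphism
  if (n_decoys >= 2) { geno[ids[8], "III:23"] <- "het"         # control-shared
                       geno[ids[8], "PC2"] <- "hom_alt" }
  if (n_decoys >= 3) { geno[ids[9], "III:3"] <- "het"          # hom in unaffected
                       geno[ids[9], "IV:1"] <- "hom_alt" }
  if (n_decoys >= 4) geno[ids[10], "III:23"] <- "het"          # off panel
  table <- variant_table(all_records, samples, geno)

  ped <- rp_pedigree_fixture()

  sanger_calls <- data.frame(
    member_id = c("II:1",
                  "III:3", "III:3", "III:3", "III:3",
                  "III:4", "III:4",
                  "III:17", "III:17",
                  "III:20", "III:20",
                  "III:23", "III:23"),
    variant_id = unname(m_id[c("M2",
                               "M2", "M4", "M5", "M6",
                               "M2", "M4",
                               "M1", "M3",
                               "M2", "M3",
                               "M1", "M3")]),
    zygosity = "het", stringsAsFactors = FALSE
  )
  sanger <- genotype_table(sanger_calls, records = table$records,
                           members = genotyped_members(ped))

  truth <- data.frame(
    variant_id = ids,
    label = c(rep("causal_candidate", 6),
              if (n_decoys) paste0("decoy:", decoy_class)),
    stringsAsFactors = FALSE
  )
  list(table = table, ped = ped, panel = panel, sanger = sanger,
       family_samples = family_samples, control_samples = control_samples,
       variants = m_id, truth = truth)
}

## Synthetic-coordinate panel subset: the three genes of the case study
## plus one extra IRD gene so the panel filter has a non-trivial
## complement.
rp_panel_fixture <- function() {
  exons <- rbind(
    data.frame(chrom = "chr1", start = c(105001L, 110001L, 120001L, 140001L,
                                         160001L, 170001L),
               end = c(105200L, 110200L, 120200L, 140200L, 160200L, 170200L),
               gene = "USH2A"),
    data.frame(chrom = "chr1", start = c(305001L, 315001L),
               end = c(305200L, 315200L), gene = "CRB1"),
    data.frame(chrom = "chr10", start = c(52001L, 55001L, 58001L),
               end = c(52200L, 55200L, 58200L), gene = "PDZD7"),
    data.frame(chrom = "chr5", start = c(250001L, 270001L),
               end = c(250200L, 270200L), gene = "ADGRV1")
  )
  spans <- data.frame(
    chrom = c("chr1", "chr1", "chr10", "chr5"),
    start = c(100000L, 300000L, 50000L, 200000L),
    end = c(180000L, 320000L, 60000L, 290000L),
    gene = c("USH2A", "CRB1", "PDZD7", "ADGRV1")
  )
  gene_panel(exons, spans = spans, name = "ird-panel-subset")
}

## The 28-member pedigree: three generations, three gen-III sibships,
## 19 genotyped members (Sanger), 5 affected, 3 sequenced (WGS).
rp_pedigree_fixture <- function() {
  m <- function(id, fa, mo, sex, aff, seq = FALSE, gen = FALSE) {
    data.frame(member_id = id, father_id = fa, mother_id = mo, sex = sex,
               affected = aff, sequenced = seq, genotyped = gen,
               stringsAsFactors = FALSE)
  }
  members <- rbind(
    m("I:1", NA, NA, "male", "unknown"),
    m("I:2", NA, NA, "female", "unknown"),
    # generation II: three sibships' parents; II:1 is the affected father
    m("II:1", "I:1", "I:2", "male", "affected", gen = TRUE),
    m("II:2", NA, NA, "female", "unaffected"),
    m("II:3", "I:1", "I:2", "male", "unaffected"),
    m("II:4", NA, NA, "female", "unaffected"),
    m("II:5", "I:1", "I:2", "female", "unaffected"),
    m("II:6", NA, NA, "male", "unaffected"),
    # branch 1 (II:1 x II:2): index patient III:3 and sibs
    m("III:2", NA, NA, "male", "unaffected"),
    m("III:3", "II:1", "II:2", "female", "affected", seq = TRUE, gen = TRUE),
    m("III:4", "II:1", "II:2", "female", "unaffected", gen = TRUE),
    m("III:5", "II:1", "II:2", "male", "unaffected", gen = TRUE),
    m("III:7", "II:1", "II:2", "female", "unaffected", gen = TRUE),
    m("III:8", "II:1", "II:2", "male", "unaffected", gen = TRUE),
    # branch 2 (II:3 x II:4)
    m("III:10", "II:3", "II:4", "female", "unaffected", gen = TRUE),
    m("III:11", "II:3", "II:4", "male", "unaffected", gen = TRUE),
    m("III:15", "II:3", "II:4", "female", "unaffected", gen = TRUE),
    # branch 3 (II:5 x II:6): three affected sibs and two spouses
    m("III:17", "II:5", "II:6", "male", "affected", gen = TRUE),
    m("III:18", NA, NA, "female", "unaffected", gen = TRUE),
    m("III:20", "II:5", "II:6", "female", "affected", gen = TRUE),
    m("III:21", NA, NA, "male", "unaffected", gen = TRUE),
    m("III:23", "II:5", "II:6", "male", "affected", seq = TRUE, gen = TRUE),
    m("III:24", NA, NA, "female", "unaffected"),
    # generation IV
    m("IV:1", "III:2", "III:3", "male", "unaffected", seq = TRUE, gen = TRUE),
    m("IV:2", "III:2", "III:3", "female", "unaffected", gen = TRUE),
    m("IV:3", "III:2", "III:3", "male", "unaffected", gen = TRUE),
    m("IV:4", "III:2", "III:3", "female", "unaffected", gen = TRUE),
    m("IV:35", "III:21", "III:20", "male", "unaffected", gen = TRUE)
  )
  pedigree(members, family_id = "RP-FAM")
}

#' Write the bundled family fixture to a directory
#'
#' Emits `cohort.vcf` (family + pseudo-controls), `family.ped`,
#' `panel.bed`, `sanger_genotypes.tsv` and `truth.json`.
#'
#' @inheritParams rp_family_fixture
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_fixture <- function(dir, n_decoys = 4) {
  fx <- rp_family_fixture(n_decoys)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(fx$table, file.path(dir, "cohort.vcf"))
  write_pedigree(fx$ped, file.path(dir, "family.ped"))
  write_gene_panel(fx$panel, file.path(dir, "panel.bed"))
  write_genotype_tsv(fx$sanger, file.path(dir, "sanger_genotypes.tsv"))
  jsonlite::write_json(fx$truth, file.path(dir, "truth.json"), pretty = TRUE)
  invisible(dir)
}
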