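extdata <- function(f) system.file("extdata", f, package = "irdprio")

test_that("read_vcf splits multiallelic sites and maps zygosity", {
  tab <- read_vcf(extdata("mini.vcf"))
  # 3 site lines, one with two ALT alleles -> 4 biallelic records
  expect_equal(n_variants(tab), 4L)
  expect_equal(tab$samples, c("S1", "S2", "S3"))
  expect_setequal(
    tab$records$variant_id,
    c("chr1:1500:A:G", "chr1:1650:C:T", "chr1:1650:C:G", "chr1:9000:T:C"))
  # per-allele zygosity at the multiallelic site: S2 is 1/2
  expect_equal(unname(zygosity(tab, "chr1:1650:C:T", "S2")[1, 1]), "het")
  expect_equal(unname(zygosity(tab, "chr1:1650:C:G", "S2")[1, 1]), "het")
  expect_equal(unname(zygosity(tab, "chr1:1650:C:G", "S1")[1, 1]), "hom_ref")
  expect_equal(unname(zygosity(tab, "chr1:1500:A:G", "S3")[1, 1]), "missing")
  expect_equal(unname(zygosity(tab, "chr1:9000:T:C", "S1")[1, 1]), "hom_alt")
  # per-allele INFO (Number=A) is indexed by allele
  rec <- tab$records
  expect_equal(rec$maf[rec$variant_id == "chr1:1650:C:T"], 0.001)
  expect_equal(rec$maf[rec$variant_id == "chr1:1650:C:G"], 0.2)
  # annotation lifting and ClinVar normalization
  expect_equal(rec$clinvar_significance[rec$variant_id == "chr1:1500:A:G"],
               "pathogenic")
  expect_equal(rec$clinvar_phenotypes[rec$variant_id == "chr1:1500:A:G"][[1]],
               "Retinitis pigmentosa")
  expect_equal(rec$gene[rec$variant_id == "chr1:9000:T:C"], "")
})

test_that("read_vcf handles an empty-body VCF and missing files", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"), p)
  tab <- read_vcf(p)
  expect_equal(n_variants(tab), 0L)
  expect_equal(tab$samples, "S1")
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("VCF write/read round-trips the family fixture", {
  fx <- rp_family_fixture()
  for (ext in c(".vcf", ".vcf.gz")) {
    p <- tempfile(fileext = ext)
    write_vcf(fx$table, p)
    back <- read_vcf(p)
    expect_identical(back$geno, fx$table$geno)
    expect_identical(back$samples, fx$table$samples)
    for (cn in names(fx$table$records)) {
      expect_equal(back$records[[cn]], fx$table$records[[cn]],
                   info = paste("column", cn, ext))
    }
  }
})

test_that("variant_table enforces its invariants", {
  expect_error(variant_table(data.frame(chrom = "c", pos = 0L, ref = "A",
                                        alt = "G")), ">= 1")
  expect_error(variant_table(data.frame(chrom = "c", pos = 5L, ref = "A",
                                        alt = "A")), "differ")
  dup <- data.frame(chrom = "c", pos = c(5L, 5L), ref = "A", alt = "G")
  expect_error(variant_table(dup), "duplicate variant_id")
})

test_that("combine_tables unions records and defaults absent calls", {
  r1 <- data.frame(chrom = "c", pos = 10L, ref = "A", alt = "G")
  r2 <- data.frame(chrom = "c", pos = c(10L, 20L), ref = "A", alt = "G")
  ta <- variant_table(r1, "SA", matrix("het", 1, 1))
  tb <- variant_table(r2, "SB", matrix(c("het", "hom_alt"), 2, 1))
  comb <- combine_tables(list(ta, tb))
  expect_setequal(comb$records$variant_id, c("c:10:A:G", "c:20:A:G"))
  expect_equal(unname(zygosity(comb, "c:20:A:G", "SA")[1, 1]), "missing")
  all_sites <- combine_tables(list(ta, tb), missing_as = "hom_ref")
  expect_equal(unname(zygosity(all_sites, "c:20:A:G", "SA")[1, 1]), "hom_ref")
  # identity on a single table
  expect_identical(combine_tables(list(ta))$geno, ta$geno)
  # duplicate sample ids rejected
  expect_error(combine_tables(list(ta, ta)), "duplicate sample")
})

test_that("combine_tables is order-insensitive up to sample ordering", {
  withr::with_seed(11, {
    tabs <- lapply(1:3, function(i) {
      n <- sample(1:5, 1)
      recs <- data.frame(chrom = "c", pos = sample(1:30, n), ref = "A",
                         alt = "G")
      variant_table(recs, paste0("S", i),
                    matrix(sample(c("het", "hom_ref"), n, TRUE), n, 1))
    })
    for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
      comb <- combine_tables(tabs[perm])
      expect_setequal(comb$records$variant_id,
                      unique(unlist(lapply(tabs, function(t)
                        t$records$variant_id))))
    }
  })
})

test_that("read_pedigree resolves parents and rejects bad graphs", {
  ped <- read_pedigree(extdata("mini.ped"))
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$father_id[ped$member_id == "S1"], "S2")
  expect_equal(ped$affected[ped$member_id == "S1"], "affected")
  expect_true(all(ped$sequenced))

  p <- tempfile()
  writeLines("F1\tA\tA\t0\t1\t2", p) # own father
  expect_error(read_pedigree(p), "cyclic")
  writeLines("F1\tA\tB\t0\t1\t2", p) # unknown parent
  expect_error(read_pedigree(p), "parent id")
})

test_that("gene panels read from BED, merge overlaps, and round-trip", {
  panel <- read_gene_panel(extdata("mini_panel.bed"))
  expect_equal(panel_genes(panel), "TOY1")
  # BED is 0-based half-open; internal representation 1-based inclusive
  expect_equal(panel$exons$start, c(1100L, 1600L))
  expect_equal(panel$exons$end, c(1200L, 1700L))
  expect_equal(panel$spans$start, 1000L)

  # one-exon panel: span equals the exon
  p1 <- tempfile(fileext = ".bed")
  writeLines("chr2\t99\t200\tG1", p1)
  single <- read_gene_panel(p1)
  expect_equal(single$spans$start, 100L)
  expect_equal(single$spans$end, 200L)

  # overlapping exon lines merge into one interval
  p2 <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t99\t200\tG1", "chr2\t149\t300\tG1"), p2)
  merged <- read_gene_panel(p2)
  expect_equal(nrow(merged$exons), 1L)
  expect_equal(merged$exons$start, 100L)
  expect_equal(merged$exons$end, 300L)

  # BED <-> internal conversion is the identity on write/read
  out <- tempfile(fileext = ".bed")
  write_gene_panel(panel, out)
  back <- read_gene_panel(out)
  expect_equal(back$exons, panel$exons)
  expect_equal(back$spans, panel$spans)

  expect_error(gene_panel(data.frame(chrom = "c", start = 10L, end = 5L,
                                     gene = "G")), "end < start")
})

test_that("splice score tables validate tools and genotype TSVs round-trip", {
  sc <- read_splice_scores(extdata("mini_scores.tsv"))
  expect_equal(nrow(sc), 4L)
  expect_true(all(sc$tool %in% c("maxent", "hsf", "nnsplice")))
  bad <- tempfile()
  writeLines(c("variant_id\ttool\twt_score\tmut_score", "v1\tspliceai\t1\t2"), bad)
  expect_error(read_splice_scores(bad), "unknown splice tool")

  fx <- rp_family_fixture()
  p <- tempfile(fileext = ".tsv")
  write_genotype_tsv(fx$sanger, p)
  back <- read_genotype_tsv(p, records = fx$sanger$records,
                            members = fx$sanger$samples)
  expect_identical(back$geno, fx$sanger$geno)
})
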