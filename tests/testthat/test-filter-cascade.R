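fx <- rp_family_fixture()
cfg <- filter_config()

test_that("clinvar_rescue requires both significance and phenotype match", {
  rescued <- clinvar_rescue(fx$table, cfg)
  expect_setequal(rescued, unname(fx$variants[c("M1", "M2", "M3")]))

  # all not_reported -> empty set
  plain <- fx$table
  plain$records$clinvar_significance <- "not_reported"
  expect_length(clinvar_rescue(plain, cfg), 0L)

  # pathogenic but wrong phenotype -> not rescued
  rec <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G",
                    clinvar_significance = "pathogenic")
  rec$clinvar_phenotypes <- list("Hearing loss")
  t1 <- variant_table(rec, "S1", matrix("het", 1, 1))
  expect_length(clinvar_rescue(t1, cfg), 0L)
  # matching term is a case-insensitive substring
  rec$clinvar_phenotypes <- list("USHER SYNDROME TYPE 2A")
  t2 <- variant_table(rec, "S1", matrix("het", 1, 1))
  expect_equal(clinvar_rescue(t2, cfg), "c:1:A:G")
})

test_that("recurrence filter keeps family-exclusive variants only", {
  mk <- function(fam_z, ctl_z) {
    rec <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G")
    variant_table(rec, c("F1", "C1", "C2"),
                  matrix(c(fam_z, ctl_z[1], ctl_z[2]), 1, 3))
  }
  run <- function(t, rescued = character(), max_cc = 0) {
    n_variants(recurrence_filter(t, "F1", c("C1", "C2"), rescued, max_cc))
  }
  expect_equal(run(mk("het", c("hom_ref", "hom_ref"))), 1L)       # exclusive
  expect_equal(run(mk("het", c("hom_alt", "hom_ref"))), 0L)       # control hom
  expect_equal(run(mk("hom_ref", c("hom_ref", "hom_ref"))), 0L)   # not in family
  expect_equal(run(mk("het", c("het", "hom_ref"))), 0L)           # control carrier
  expect_equal(run(mk("het", c("het", "hom_ref")), max_cc = 1), 1L)
  # the hom_alt guard is independent of the carrier-count knob
  expect_equal(run(mk("het", c("hom_alt", "hom_ref")), max_cc = 2), 0L)
  # rescue overrides
  expect_equal(run(mk("het", c("hom_alt", "hom_ref")), rescued = "c:1:A:G"), 1L)
  expect_error(recurrence_filter(mk("het", c("hom_ref", "hom_ref")),
                                 "nope", "C1"), "unknown family sample")
  expect_error(recurrence_filter(mk("het", c("hom_ref", "hom_ref")),
                                 "F1", "F1"), "overlap")
})

test_that("frequency filter honours threshold, missing MAF and rescue", {
  out <- frequency_filter(fx$table, cfg)
  kept <- out$records$variant_id
  expect_true(fx$variants[["M3"]] %in% kept)   # MAF 0.0009677 <= 0.01
  expect_true(fx$variants[["M6"]] %in% kept)   # no gnomAD entry
  common <- fx$truth$variant_id[fx$truth$label == "decoy:common_polymorphism"]
  expect_false(common %in% kept)               # MAF 0.2

  strict <- filter_config(treat_missing_maf_as_pass = FALSE)
  expect_false(fx$variants[["M6"]] %in%
                 frequency_filter(fx$table, strict)$records$variant_id)
  expect_true(common %in%
                frequency_filter(fx$table, cfg, rescued = common)$records$variant_id)
})

test_that("gene filter keeps whole gene bodies and symbol matches", {
  rec <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    pos = c(130000L, 500000L, 165000L, 1L),
    ref = "A", alt = "G",
    gene = c("", "", "", "USH2A"), # last: symbol match, position elsewhere
    stringsAsFactors = FALSE)
  t <- variant_table(rec, "S1", matrix("het", 4, 1))
  kept <- gene_filter(t, fx$panel)$records$variant_id
  expect_true("chr1:130000:A:G" %in% kept)  # deep intronic, inside span
  expect_true("chr1:165000:A:G" %in% kept)  # intronic between exons
  expect_false("chr1:500000:A:G" %in% kept) # off panel
  expect_true("chr9:1:A:G" %in% kept)       # by symbol

  # a whole-genome panel is the identity
  wide <- gene_panel(data.frame(chrom = c("chr1", "chr9"), start = 1L,
                                end = 2e9, gene = c("ALL1", "ALL9")))
  expect_equal(gene_filter(t, wide)$records$variant_id, t$records$variant_id)
})

test_that("pedigree filter uses affected carriers and unaffected homozygotes", {
  ped <- fx$ped
  mk <- function(z3, z23, zIV) {
    rec <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G")
    variant_table(rec, c("III:3", "III:23", "IV:1"),
                  matrix(c(z3, z23, zIV), 1, 3))
  }
  keep1 <- pedigree_filter(mk("het", "hom_ref", "het"), ped)   # carrier child ok
  expect_equal(n_variants(keep1), 1L)
  expect_equal(n_variants(pedigree_filter(mk("het", "hom_ref", "hom_alt"), ped)), 0L)
  expect_equal(n_variants(pedigree_filter(mk("hom_ref", "hom_ref", "hom_ref"), ped)), 0L)
  expect_equal(n_variants(pedigree_filter(mk("hom_alt", "hom_ref", "hom_ref"), ped)), 1L)

  no_aff <- pedigree(data.frame(member_id = "X", father_id = NA,
                                mother_id = NA, sex = "male",
                                affected = "unaffected", sequenced = TRUE,
                                genotyped = TRUE))
  t <- mk("het", "hom_ref", "hom_ref")
  expect_error(pedigree_filter(t, no_aff), "no sequenced affected")
})

test_that("full cascade on the family fixture yields exactly M1-M6", {
  res <- run_cascade(fx$table, fx$ped, fx$panel, fx$family_samples,
                     fx$control_samples, cfg)
  expect_setequal(res$table$records$variant_id, unname(fx$variants))
  # each decoy is attributed to the step it was built to violate
  removed <- merge(res$removed, fx$truth, by = "variant_id")
  step_of <- c(`decoy:common_polymorphism` = "frequency",
               `decoy:control_shared_artifact` = "recurrence",
               `decoy:hom_in_unaffected` = "pedigree",
               `decoy:off_panel` = "gene_panel")
  expect_equal(removed$step, unname(step_of[removed$label]))
  # trace is a contraction at every step
  expect_true(all(res$trace$n_out <= res$trace$n_in))
  # rescue shows up in the trace only where it changed the outcome
  expect_true(all(res$trace$n_rescued >= 0))
})

test_that("filters are idempotent and the cascade is too", {
  res <- run_cascade(fx$table, fx$ped, fx$panel, fx$family_samples,
                     fx$control_samples, cfg)
  again <- run_cascade(res$table, fx$ped, fx$panel, fx$family_samples,
                       fx$control_samples, cfg)
  expect_identical(again$table$records$variant_id,
                   res$table$records$variant_id)
  f <- frequency_filter(fx$table, cfg)
  expect_identical(frequency_filter(f, cfg)$records, f$records)
  g <- gene_filter(fx$table, fx$panel)
  expect_identical(gene_filter(g, fx$panel)$records, g$records)
})

test_that("sample-independent filters commute", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      rt <- random_table(30)
      a <- gene_filter(frequency_filter(rt$table, cfg), toy_oracle_panel())
      b <- frequency_filter(gene_filter(rt$table, toy_oracle_panel()), cfg)
      expect_identical(a$records$variant_id, b$records$variant_id)
    }
  })
})

test_that("a rescued family variant survives recurrence and frequency", {
  rec <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G", maf = 0.3,
                    clinvar_significance = "pathogenic")
  rec$clinvar_phenotypes <- list("Retinitis pigmentosa")
  t <- variant_table(rec, c("F1", "C1"), matrix(c("het", "hom_alt"), 1, 2))
  rescued <- clinvar_rescue(t, cfg)
  expect_equal(rescued, "c:1:A:G")
  out <- frequency_filter(recurrence_filter(t, "F1", "C1", rescued), cfg,
                          rescued)
  expect_equal(n_variants(out), 1L)
})
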