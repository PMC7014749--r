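fx <- rp_family_fixture()

# small helper: a nuclear family genotype table for phase tests
phase_family <- function(calls, children = "C1") {
  members <- c("P", "O", children)
  ped <- pedigree(data.frame(
    member_id = members,
    father_id = c(NA, NA, rep("P", length(children))),
    mother_id = c(NA, NA, rep("O", length(children))),
    sex = c("male", "female", rep("unknown", length(children))),
    affected = c("unaffected", "unaffected", rep("affected", length(children))),
    sequenced = TRUE, genotyped = TRUE, stringsAsFactors = FALSE))
  rec <- data.frame(chrom = "c", pos = c(10L, 20L), ref = "A", alt = "G",
                    gene = "G1", stringsAsFactors = FALSE)
  rec$alt <- c("G", "T")
  tab <- variant_table(rec, members)
  for (nm in names(calls)) tab$geno[, nm] <- calls[[nm]]
  list(tab = tab, ped = ped,
       pair = data.frame(gene = "G1", variant_a = "c:10:A:G",
                         variant_b = "c:20:A:T", phase = "unknown",
                         evidence = "", stringsAsFactors = FALSE))
}

test_that("enumerate_pairs matches a brute-force double loop", {
  res <- run_cascade(fx$table, fx$ped, fx$panel, fx$family_samples,
                     fx$control_samples)
  cand <- assemble_candidates(res$table, fx$panel)
  pairs <- enumerate_pairs(cand, fx$sanger, fx$ped)
  m <- fx$variants
  expect_setequal(
    pair_key(pairs$variant_a, pairs$variant_b),
    c(pair_key(m[["M1"]], m[["M3"]]),   # III:17 / III:23
      pair_key(m[["M2"]], m[["M3"]]),   # III:20
      pair_key(m[["M2"]], m[["M4"]])))  # III:3

  # brute-force oracle over all candidate pairs per gene
  aff <- fx$ped$member_id[fx$ped$affected == "affected"]
  oracle <- character()
  for (g in unique(cand$gene)) {
    ids <- cand$variant_id[cand$gene == g]
    if (length(ids) < 2) next
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      for (a in aff) {
        za <- zygosity(fx$sanger, ids[i], a)[1, 1]
        zb <- zygosity(fx$sanger, ids[j], a)[1, 1]
        if (za == "het" && zb == "het") {
          oracle <- c(oracle, pair_key(ids[i], ids[j]))
        }
      }
    }
  }
  expect_setequal(pair_key(pairs$variant_a, pairs$variant_b), unique(oracle))

  # genes with a single candidate yield no pairs
  one <- cand[cand$gene == "PDZD7", , drop = FALSE]
  expect_equal(nrow(enumerate_pairs(one, fx$sanger, fx$ped)), 0L)
})

test_that("a homozygous affected member yields a self-pair phased trans", {
  rec <- data.frame(chrom = "c", pos = 10L, ref = "A", alt = "G", gene = "G1")
  tab <- variant_table(rec, "P", matrix("hom_alt", 1, 1))
  ped <- pedigree(data.frame(member_id = "P", father_id = NA, mother_id = NA,
                             sex = "male", affected = "affected",
                             sequenced = TRUE, genotyped = TRUE))
  cand <- data.frame(variant_id = "c:10:A:G", gene = "G1")
  pairs <- enumerate_pairs(cand, tab, ped)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$variant_a, pairs$variant_b)
  phased <- infer_phases(pairs, tab, ped)
  expect_equal(phased$phase, "trans")
})

test_that("trio meioses resolve trans and cis phases", {
  # child received exactly one variant -> trans
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("het", "hom_ref")))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "trans")
  # child received both -> cis
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("het", "het")))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "cis")
  # a single both-absent meiosis is uninformative
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("hom_ref", "hom_ref")))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "unknown")
  # ... but a second informative child disambiguates
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("hom_ref", "hom_ref"),
                         C2 = c("hom_ref", "het")),
                    children = c("C1", "C2"))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "trans")
  # confounded meiosis (other parent carries) is skipped
  f <- phase_family(list(P = c("het", "het"), O = c("het", "hom_ref"),
                         C1 = c("het", "het")))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "unknown")
})

test_that("parental origin phases a doubly heterozygous child", {
  # one variant from each parent -> trans
  f <- phase_family(list(P = c("het", "hom_ref"), O = c("hom_ref", "het"),
                         C1 = c("het", "het")))
  expect_equal(infer_phase(f$pair, f$tab, f$ped)$phase, "trans")
  # both from the same parent ride one transmitted haplotype -> cis
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("het", "het")))
  got <- infer_phase(f$pair, f$tab, f$ped)
  expect_equal(got$phase, "cis")
})

test_that("conflicting phase evidence warns and yields unknown", {
  f <- phase_family(list(P = c("het", "het"), O = c("hom_ref", "hom_ref"),
                         C1 = c("het", "het"),       # cis vote
                         C2 = c("het", "hom_ref")),  # trans vote
                    children = c("C1", "C2"))
  expect_warning(got <- infer_phase(f$pair, f$tab, f$ped), "conflicting")
  expect_equal(got$phase, "unknown")
})

test_that("no informative relatives leaves the phase unknown", {
  pairs <- data.frame(gene = "USH2A", variant_a = fx$variants[["M2"]],
                      variant_b = fx$variants[["M4"]], phase = "unknown",
                      evidence = "", stringsAsFactors = FALSE)
  got <- infer_phase(pairs, fx$sanger, fx$ped)
  expect_equal(got$phase, "unknown")
  expect_match(got$evidence, "no informative")
})

test_that("segregation verdicts reproduce the family narrative", {
  m <- fx$variants
  # M1+M3 segregates in the third branch's affected sibs
  s <- segregate(c(m[["M1"]], m[["M3"]]), fx$sanger, fx$ped,
                 members = c("III:17", "III:23"))
  expect_equal(s$verdict, "segregates")
  expect_true(all(s$per_member$status == "consistent"))
  # M2+M4: unaffected III:4 shares the full genotype with III:3 -> partial
  s <- segregate(c(m[["M2"]], m[["M4"]]), fx$sanger, fx$ped,
                 members = c("III:3", "III:4", "III:5", "III:7", "III:8"))
  expect_equal(s$verdict, "partial")
  expect_equal(s$per_member$status[s$per_member$member_id == "III:4"],
               "inconsistent")
  # M2+M3 segregates via III:20
  s <- segregate(c(m[["M2"]], m[["M3"]]), fx$sanger, fx$ped)
  expect_equal(s$verdict, "segregates")
  # a configuration carried by no member is excluded
  s <- segregate(c(m[["M1"]], m[["M4"]]), fx$sanger, fx$ped)
  expect_equal(s$verdict, "excluded")
  # a typed affected member lacking the configuration excludes it:
  # the WGS calls type III:3 as hom_ref at M1/M3
  s <- segregate(c(m[["M1"]], m[["M3"]]), fx$table, fx$ped,
                 members = c("III:3", "III:23"))
  expect_equal(s$verdict, "excluded")
  # Sanger calls leave III:20 untyped at M1, so the branch-wide verdict
  # over all three affected sibs rests on III:17/III:23 only
  s <- segregate(c(m[["M1"]], m[["M3"]]), fx$sanger, fx$ped,
                 members = c("III:17", "III:20", "III:23"))
  expect_equal(s$verdict, "segregates")
  expect_equal(s$per_member$status[s$per_member$member_id == "III:20"],
               "untyped")
  expect_error(segregate("nope:1:A:G", fx$sanger, fx$ped), "absent")
  expect_error(segregate(m[["M1"]], fx$sanger, fx$ped, members = "ghost"),
               "not in pedigree")
})

test_that("segregate ignores member order and added untyped members", {
  m <- fx$variants
  cfg_ids <- c(m[["M2"]], m[["M4"]])
  branch <- c("III:3", "III:4", "III:5")
  a <- segregate(cfg_ids, fx$sanger, fx$ped, members = branch)
  b <- segregate(cfg_ids, fx$sanger, fx$ped, members = rev(branch))
  expect_equal(a$verdict, b$verdict)
  # III:10 is untyped for these variants; adding it changes nothing
  c <- segregate(cfg_ids, fx$sanger, fx$ped, members = c(branch, "III:10"))
  expect_equal(c$verdict, a$verdict)
  expect_equal(c$per_member$status[c$per_member$member_id == "III:10"],
               "untyped")
})

test_that("the family report counts alleles and flags oligogenicity", {
  res <- run_cascade(fx$table, fx$ped, fx$panel, fx$family_samples,
                     fx$control_samples)
  cand <- assemble_candidates(res$table, fx$panel)
  pairs <- infer_phases(enumerate_pairs(cand, fx$sanger, fx$ped),
                        fx$sanger, fx$ped)
  rep <- family_report(pairs, cand, fx$sanger, fx$ped)

  idx <- rep$member_alleles[rep$member_alleles$member_id == "III:3", ]
  expect_equal(idx$n_alleles, 4L)
  expect_setequal(strsplit(idx$genes, ",")[[1]], c("USH2A", "PDZD7", "ADGRV1"))
  outside <- sum(!strsplit(idx$variants, ",")[[1]] %in%
                   cand$variant_id[cand$gene == "USH2A"])
  expect_equal(outside, 2L)
  expect_equal(rep$oligogenic$member_id, "III:3")
  expect_equal(rep$oligogenic$n_genes, 3L)

  # allele counts match brute-force counting over candidate variants
  counts <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = 0L)
  for (i in seq_len(nrow(rep$member_alleles))) {
    mbr <- rep$member_alleles$member_id[i]
    brute <- sum(counts[zygosity(fx$sanger, cand$variant_id, mbr)[, 1]])
    expect_equal(rep$member_alleles$n_alleles[i], unname(brute))
  }

  # cis pairs are excluded from causal reporting
  pairs2 <- pairs
  pairs2$phase[1] <- "cis"
  rep2 <- family_report(pairs2, cand, fx$sanger, fx$ped)
  expect_equal(rep2$pairs$verdict[1], "excluded_cis")
})

test_that("a single-pair family raises no oligogenic flag", {
  co <- simulate_cohort(simulation_params(n_decoy_variants = 0, seed = 3))
  res <- run_cascade(co$table, co$ped, co$panel, co$family_samples,
                     co$control_samples)
  cand <- assemble_candidates(res$table, co$panel)
  pairs <- infer_phases(enumerate_pairs(cand, co$table, co$ped),
                        co$table, co$ped)
  rep <- family_report(pairs, cand, co$table, co$ped)
  expect_equal(nrow(rep$oligogenic), 0L)
  expect_equal(rep$pairs$verdict, "segregates")
})
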