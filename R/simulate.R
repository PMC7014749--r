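DECOY_CLASSES <- c("common_polymorphism", "control_shared_artifact",
                   "hom_in_unaffected", "off_panel", "cis_pair")

#' Parameters for the cohort simulator
#'
#' Defines a seeded synthetic study: a nuclear family (two founders plus
#' children, the first child affected) and a pseudo-control cohort of
#' unrelated unaffected individuals, with one or more planted causal
#' compound-heterozygote pairs and a configurable mix of decoy variants,
#' each decoy class designed to be removed by exactly one pipeline
#' stage:
#' \describe{
#'   \item{common_polymorphism}{family-exclusive but MAF > 0.01 —
#'     frequency filter}
#'   \item{control_shared_artifact}{homozygous in a pseudo-control —
#'     recurrence filter}
#'   \item{hom_in_unaffected}{homozygous in an unaffected family member
#'     — pedigree filter}
#'   \item{off_panel}{outside every panel gene — gene filter}
#'   \item{cis_pair}{a co-transmitted same-haplotype pair that survives
#'     the cascade and is excluded at the phasing stage}
#' }
#'
#' Defaults mirror the study design the pipeline targets: six
#' pseudo-controls, a family quartet, and one planted trans pair.
#'
#' @param n_family_sequenced Family size (2 founders + children), >= 3.
#' @param n_controls Number of pseudo-control samples (default 6).
#' @param n_decoy_variants Total decoy variants (default 40).
#' @param decoy_mix Named proportions over the five decoy classes
#'   (must sum to 1).
#' @param planted List of planted causal configurations; each element a
#'   list with `gene` (panel gene symbol). Default: one pair in the
#'   first panel gene, carried in trans by the affected child.
#' @param n_genes Panel size of the toy genome (default 12).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_family_sequenced = 4, n_controls = 6,
                              n_decoy_variants = 40,
                              decoy_mix = c(common_polymorphism = 0.25,
                                            control_shared_artifact = 0.25,
                                            hom_in_unaffected = 0.2,
                                            off_panel = 0.2, cis_pair = 0.1),
                              planted = NULL, n_genes = 12, seed = 1) {
  stopifnot(n_family_sequenced >= 3, n_controls >= 1, n_decoy_variants >= 0,
            n_genes >= 2)
  miss <- setdiff(DECOY_CLASSES, names(decoy_mix))
  if (length(miss)) stop("decoy_mix missing class: ", miss[1])
  if (abs(sum(decoy_mix) - 1) > 1e-8) stop("decoy_mix proportions must sum to 1")
  if (any(decoy_mix < 0)) stop("decoy_mix proportions must be >= 0")
  if (is.null(planted)) planted <- list(list(gene = "GENE01"))
  structure(list(n_family_sequenced = as.integer(n_family_sequenced),
                 n_controls = as.integer(n_controls),
                 n_decoy_variants = as.integer(n_decoy_variants),
                 decoy_mix = decoy_mix[DECOY_CLASSES], planted = planted,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "simulation_params")
}

## Toy genome: two contigs, `n_genes` three-exon genes of 3 kb spaced
## 8 kb apart. Real genome scale is unnecessary for correctness tests.
toy_panel <- function(n_genes = 12) {
  contig <- ifelse(seq_len(n_genes) <= ceiling(n_genes / 2), "chrA", "chrB")
  idx <- stats::ave(seq_len(n_genes), contig, FUN = seq_along)
  span_start <- 5000L + (idx - 1L) * 8000L
  exon_off <- cbind(c(200L, 1200L, 2400L), c(500L, 1500L, 2700L))
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    data.frame(chrom = contig[g], start = span_start[g] + exon_off[, 1],
               end = span_start[g] + exon_off[, 2],
               gene = sprintf("GENE%02d", g), stringsAsFactors = FALSE)
  }))
  spans <- data.frame(chrom = contig, start = span_start,
                      end = span_start + 2999L,
                      gene = sprintf("GENE%02d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  gene_panel(exons, spans = spans, name = "toy-panel")
}

## Largest-remainder allocation of n decoys over the class proportions,
## with the cis class forced even (cis decoys come in pairs).
allocate_decoys <- function(n, mix) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_by_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_by_frac[seq_len(rem)]] <- counts[order_by_frac[seq_len(rem)]] + 1
  }
  if (counts["cis_pair"] %% 2 == 1) {
    counts["cis_pair"] <- counts["cis_pair"] - 1
    counts["off_panel"] <- counts["off_panel"] + 1
  }
  counts
}

#' Simulate a family + pseudo-control cohort with planted truth
#'
#' Generates a [variant_table()] over the family and control samples, a
#' [pedigree()], the toy [gene_panel()], and a truth table labelling
#' every variant (`causal` or `decoy:<class>`) and every constructed
#' pair (`trans_causal` or `cis_decoy`). Genotypes are
#' Mendelian-consistent: every child call is derivable from its
#' parents', and planted pairs are in trans by construction (one allele
#' per parent) while cis decoy pairs ride a single parental haplotype.
#' Unaffected children never carry a full planted configuration (the
#' planted model is fully penetrant).
#'
#' @param params A [simulation_params()].
#' @return A list of class `simulated_cohort`: `table`, `ped`, `panel`,
#'   `truth` (list with `variants` and `pairs` data frames),
#'   `family_samples`, `control_samples`, `params`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  panel <- toy_panel(params$n_genes)
  genes <- panel_genes(panel)
  for (p in params$planted) {
    if (!p$gene %in% genes) stop("planted gene not in panel: ", p$gene)
  }
  planted_genes <- vapply(params$planted, `[[`, "", "gene")

  n_children <- params$n_family_sequenced - 2L
  child_ids <- c("A1", if (n_children > 1) paste0("U", seq_len(n_children - 1)))
  family <- c("FA", "MO", child_ids)
  controls <- paste0("PC", seq_len(params$n_controls))
  samples <- c(family, controls)
  unaff_children <- setdiff(child_ids, "A1")

  ped <- pedigree(data.frame(
    member_id = family,
    father_id = c(NA, NA, rep("FA", n_children)),
    mother_id = c(NA, NA, rep("MO", n_children)),
    sex = c("male", "female", rep(c("female", "male"), length.out = n_children)),
    affected = c("unaffected", "unaffected", "affected",
                 rep("unaffected", n_children - 1)),
    sequenced = TRUE, genotyped = TRUE, stringsAsFactors = FALSE
  ), family_id = "SIM")

  used <- new.env(parent = emptyenv())
  draw_pos <- function(gene) {
    ex <- panel$exons[panel$exons$gene == gene, , drop = FALSE]
    pool <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE))
    key <- gene
    taken <- if (is.null(used[[key]])) integer() else used[[key]]
    pool <- setdiff(pool, taken)
    p <- pool[sample.int(length(pool), 1)]
    used[[key]] <- c(taken, p)
    list(chrom = ex$chrom[1], pos = p)
  }
  draw_alleles <- function() {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    c(ref, alt)
  }

  rows <- list(); geno_rows <- list()
  truth_var <- list(); truth_pair <- list()
  add_variant <- function(chrom, pos, gene, maf, label, pattern) {
    al <- draw_alleles()
    g <- setNames(rep("hom_ref", length(samples)), samples)
    g[names(pattern)] <- pattern
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = al[1], alt = al[2], gene = gene,
      maf = maf, stringsAsFactors = FALSE)
    geno_rows[[length(geno_rows) + 1L]] <<- g
    id <- variant_id(chrom, pos, al[1], al[2])
    truth_var[[length(truth_var) + 1L]] <<- data.frame(
      variant_id = id, label = label, stringsAsFactors = FALSE)
    id
  }

  # planted causal pairs: one allele per parent, affected child het at
  # both; unaffected children inherit at most one planted allele
  for (p in params$planted) {
    loc_a <- draw_pos(p$gene); loc_b <- draw_pos(p$gene)
    pat_a <- c(FA = "het", A1 = "het")
    pat_b <- c(MO = "het", A1 = "het")
    for (u in unaff_children) {
      which_one <- sample(c("a", "b", "none"), 1)
      if (which_one == "a") pat_a[u] <- "het"
      if (which_one == "b") pat_b[u] <- "het"
    }
    id_a <- add_variant(loc_a$chrom, loc_a$pos, p$gene,
                        stats::runif(1, 0, 0.005), "causal", pat_a)
    id_b <- add_variant(loc_b$chrom, loc_b$pos, p$gene,
                        stats::runif(1, 0, 0.005), "causal", pat_b)
    truth_pair[[length(truth_pair) + 1L]] <- data.frame(
      gene = p$gene, variant_a = min(id_a, id_b), variant_b = max(id_a, id_b),
      label = "trans_causal", stringsAsFactors = FALSE)
  }

  counts <- allocate_decoys(params$n_decoy_variants, params$decoy_mix)
  decoy_genes <- setdiff(genes, planted_genes)
  cis_genes <- decoy_genes
  offpanel_base <- max(panel$spans$end[panel$spans$chrom == "chrA"]) + 10000L

  rand_child_pattern <- function(pat, prob_het = 0.5) {
    for (u in unaff_children) if (stats::runif(1) < prob_het) pat[u] <- "het"
    pat
  }
  for (k in seq_len(counts[["common_polymorphism"]])) {
    loc <- draw_pos(sample(decoy_genes, 1))
    pat <- rand_child_pattern(c(FA = "het", A1 = "het"))
    add_variant(loc$chrom, loc$pos, panel_gene_at(panel, loc$chrom, loc$pos),
                stats::runif(1, 0.02, 0.5), "decoy:common_polymorphism", pat)
  }
  for (k in seq_len(counts[["control_shared_artifact"]])) {
    loc <- draw_pos(sample(decoy_genes, 1))
    pat <- rand_child_pattern(c(FA = "het", A1 = "het"))
    pat[sample(controls, 1)] <- "hom_alt"
    add_variant(loc$chrom, loc$pos, panel_gene_at(panel, loc$chrom, loc$pos),
                stats::runif(1, 0, 0.005), "decoy:control_shared_artifact", pat)
  }
  for (k in seq_len(counts[["hom_in_unaffected"]])) {
    loc <- draw_pos(sample(decoy_genes, 1))
    pat <- setNames(rep("het", length(child_ids)), child_ids)
    pat <- c(MO = "hom_alt", pat)
    add_variant(loc$chrom, loc$pos, panel_gene_at(panel, loc$chrom, loc$pos),
                stats::runif(1, 0, 0.005), "decoy:hom_in_unaffected", pat)
  }
  for (k in seq_len(counts[["off_panel"]])) {
    pos <- offpanel_base + k * 37L
    pat <- rand_child_pattern(c(FA = "het", A1 = "het"))
    add_variant("chrA", pos, "", stats::runif(1, 0, 0.005),
                "decoy:off_panel", pat)
  }
  n_cis_pairs <- counts[["cis_pair"]] %/% 2
  if (n_cis_pairs > length(cis_genes)) {
    stop("too many cis decoy pairs for the panel size (one pair per gene)")
  }
  cis_assigned <- if (n_cis_pairs > 0) sample(cis_genes, n_cis_pairs) else character()
  for (g in cis_assigned) {
    loc_a <- draw_pos(g); loc_b <- draw_pos(g)
    pat <- c(FA = "het", A1 = "het")
    for (u in unaff_children) if (stats::runif(1) < 0.5) pat[u] <- "het"
    id_a <- add_variant(loc_a$chrom, loc_a$pos, g, stats::runif(1, 0, 0.005),
                        "decoy:cis_pair", pat)
    id_b <- add_variant(loc_b$chrom, loc_b$pos, g, stats::runif(1, 0, 0.005),
                        "decoy:cis_pair", pat)
    truth_pair[[length(truth_pair) + 1L]] <- data.frame(
      gene = g, variant_a = min(id_a, id_b), variant_b = max(id_a, id_b),
      label = "cis_decoy", stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, rows)
  geno <- do.call(rbind, geno_rows)
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  table <- variant_table(records, samples, geno)
  truth <- list(variants = do.call(rbind, truth_var),
                pairs = if (length(truth_pair)) do.call(rbind, truth_pair)
                        else data.frame(gene = character(),
                                        variant_a = character(),
                                        variant_b = character(),
                                        label = character()))
  structure(list(table = table, ped = ped, panel = panel, truth = truth,
                 family_samples = family, control_samples = controls,
                 params = params),
            class = "simulated_cohort")
}

## Gene whose span contains chrom:pos ("" when off panel).
panel_gene_at <- function(panel, chrom, pos) {
  hit <- span_hit(panel, chrom, pos)
  if (is.na(hit)) "" else panel$spans$gene[hit]
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort (seed %d): %d variant(s), %d family + %d control sample(s)\n",
              x$params$seed, n_variants(x$table), length(x$family_samples),
              length(x$control_samples)))
  cat("truth:", sum(x$truth$variants$label == "causal"), "causal,",
      sum(grepl("^decoy", x$truth$variants$label)), "decoys\n")
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Emits `cohort.vcf`, `family.ped`, `panel.bed` and `truth.json`;
#' output is byte-identical for a fixed seed.
#'
#' @param cohort A `simulated_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$table, file.path(dir, "cohort.vcf"))
  write_pedigree(cohort$ped, file.path(dir, "family.ped"))
  write_gene_panel(cohort$panel, file.path(dir, "panel.bed"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"), pretty = TRUE)
  invisible(dir)
}
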