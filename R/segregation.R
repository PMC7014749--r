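## Does `member` carry the full biallelic configuration in `table`?
## A distinct pair needs an alt allele at both variants; a homozygous
## self-configuration (one id, or a == b) needs hom_alt.
carries_configuration <- function(table, member, config_ids) {
  config_ids <- unique(config_ids)
  g <- zygosity(table, config_ids, member)[, 1]
  if (any(g == "missing")) return(NA)
  if (length(config_ids) == 1) return(g[1] == "hom_alt")
  all(carries_alt(g))
}

#' Enumerate candidate biallelic pairs per gene
#'
#' For each gene with candidates, lists every unordered pair of
#' candidate variants for which at least one affected member is
#' heterozygous at both, plus homozygous self-pairs (`variant_a ==
#' variant_b`) where an affected member is hom-alt. Phase starts
#' `unknown`; see [infer_phase()].
#'
#' @param candidates A `candidate_set` ([assemble_candidates()]) or any
#'   data frame with `variant_id` and `gene`.
#' @param table A [variant_table()] holding genotypes for pedigree
#'   members (WGS or Sanger-derived).
#' @param ped A [pedigree()].
#' @return Data frame with columns `gene`, `variant_a`, `variant_b`,
#'   `phase`, `evidence`, `carriers` (comma-separated affected members
#'   supporting the pair).
#' @export
enumerate_pairs <- function(candidates, table, ped) {
  out <- data.frame(gene = character(), variant_a = character(),
                    variant_b = character(), phase = character(),
                    evidence = character(), carriers = character(),
                    stringsAsFactors = FALSE)
  aff <- intersect(affected_members(ped), table$samples)
  cand <- as.data.frame(candidates)
  cand <- cand[cand$variant_id %in% table$records$variant_id, , drop = FALSE]
  for (g in unique(cand$gene[nzchar(cand$gene)])) {
    ids <- cand$variant_id[cand$gene == g]
    geno <- zygosity(table, ids, aff)
    # homozygous self-pairs
    for (id in ids) {
      hom <- aff[geno[id, ] == "hom_alt"]
      if (length(hom)) {
        out <- rbind(out, data.frame(
          gene = g, variant_a = id, variant_b = id, phase = "unknown",
          evidence = "", carriers = paste(hom, collapse = ",")))
      }
    }
    if (length(ids) < 2) next
    pairs <- utils::combn(sort(ids), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      both_het <- aff[geno[a, ] == "het" & geno[b, ] == "het"]
      if (length(both_het)) {
        out <- rbind(out, data.frame(
          gene = g, variant_a = a, variant_b = b, phase = "unknown",
          evidence = "", carriers = paste(both_het, collapse = ",")))
      }
    }
  }
  rownames(out) <- NULL
  out
}

## Genotype of one member at one variant; "missing" when the member has
## no column in the table.
geno_of <- function(table, member, id) {
  if (!member %in% table$samples) return("missing")
  zygosity(table, id, member)[1, 1]
}

## Phase votes from one doubly-het parent's meioses: each genotyped
## child that received exactly one of the two variants implies trans;
## both implies cis; neither is uninformative on its own. A meiosis is
## skipped as confounded when the child's other parent is a known
## carrier of either variant.
meiosis_votes <- function(table, ped, a, b) {
  votes <- character(); who <- character()
  parents <- ped$member_id[vapply(ped$member_id, function(m)
    geno_of(table, m, a) == "het" && geno_of(table, m, b) == "het", TRUE)]
  for (p in parents) {
    children <- ped$member_id[!is.na(ped$father_id) & ped$father_id == p |
                              !is.na(ped$mother_id) & ped$mother_id == p]
    for (ch in children) {
      other <- setdiff(c(ped$father_id[ped$member_id == ch],
                         ped$mother_id[ped$member_id == ch]), p)
      other <- other[!is.na(other)]
      if (length(other) &&
          (carries_alt(geno_of(table, other, a)) ||
           carries_alt(geno_of(table, other, b)))) next
      ga <- geno_of(table, ch, a); gb <- geno_of(table, ch, b)
      if (ga == "missing" || gb == "missing") next
      n <- carries_alt(ga) + carries_alt(gb)
      if (n == 1) { votes <- c(votes, "trans"); who <- c(who, paste0(p, "->", ch)) }
      if (n == 2) { votes <- c(votes, "cis"); who <- c(who, paste0(p, "->", ch)) }
    }
  }
  list(votes = votes, who = who)
}

## Parental-origin votes: for a member het at both variants whose
## parents are genotyped, each variant whose origin is certain (one
## parent carries it, the other is genotyped hom_ref) is assigned a
## parent. Different parents => trans; the same parent transmitted one
## haplotype, so both variants ride it => cis (no intragenic
## recombination assumed).
origin_votes <- function(table, ped, a, b) {
  votes <- character(); who <- character()
  doubly <- ped$member_id[vapply(ped$member_id, function(m)
    geno_of(table, m, a) == "het" && geno_of(table, m, b) == "het", TRUE)]
  for (m in doubly) {
    fa <- ped$father_id[ped$member_id == m]
    mo <- ped$mother_id[ped$member_id == m]
    if (is.na(fa) || is.na(mo)) next
    origin <- function(v) {
      gf <- geno_of(table, fa, v); gm <- geno_of(table, mo, v)
      if (carries_alt(gf) && gm == "hom_ref") return("father")
      if (carries_alt(gm) && gf == "hom_ref") return("mother")
      NA_character_
    }
    oa <- origin(a); ob <- origin(b)
    if (is.na(oa) || is.na(ob)) next
    v <- if (oa == ob) "cis" else "trans"
    votes <- c(votes, v)
    who <- c(who, sprintf("%s(%s:%s,%s:%s)", m, a, oa, b, ob))
  }
  list(votes = votes, who = who)
}

#' Infer cis/trans phase for a biallelic pair
#'
#' Uses one informative meiosis at a time across the pedigree: for a
#' parent heterozygous at both variants, a genotyped child carrying
#' exactly one implies trans, carrying both implies cis, and carrying
#' neither is uninformative alone (consistent with transmission of the
#' wild-type haplotype of a cis pair). Parental origin is also used:
#' when each variant of a doubly heterozygous member is traced to a
#' different parent the pair is trans; both to the same parent, cis.
#' Conflicting observations (possible genotyping error) yield `unknown`
#' with a warning, never a silent resolution. Homozygous self-pairs are
#' trans by construction.
#'
#' @param pair One-row data frame (or list) with `variant_a`,
#'   `variant_b`.
#' @param table A [variant_table()] over pedigree members.
#' @param ped A [pedigree()].
#' @return The pair with `phase` set to `trans`, `cis` or `unknown` and
#'   an `evidence` string.
#' @export
infer_phase <- function(pair, table, ped) {
  a <- pair$variant_a; b <- pair$variant_b
  if (a == b) {
    pair$phase <- "trans"
    pair$evidence <- "homozygous configuration"
    return(pair)
  }
  mv <- meiosis_votes(table, ped, a, b)
  ov <- origin_votes(table, ped, a, b)
  votes <- c(mv$votes, ov$votes)
  who <- c(if (length(mv$votes)) paste0("meiosis ", mv$who),
           if (length(ov$votes)) paste0("origin ", ov$who))
  if (!length(votes)) {
    pair$phase <- "unknown"; pair$evidence <- "no informative relatives"
  } else if (all(votes == "trans")) {
    pair$phase <- "trans"; pair$evidence <- paste(who, collapse = "; ")
  } else if (all(votes == "cis")) {
    pair$phase <- "cis"; pair$evidence <- paste(who, collapse = "; ")
  } else {
    warning("conflicting phase evidence for (", a, ", ", b,
            "); possible genotyping error", call. = FALSE)
    pair$phase <- "unknown"
    pair$evidence <- paste("conflict:", paste(who, collapse = "; "))
  }
  pair
}

#' Infer phase for every enumerated pair
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @inheritParams infer_phase
#' @return `pairs` with `phase`/`evidence` filled in.
#' @export
infer_phases <- function(pairs, table, ped) {
  for (i in seq_len(nrow(pairs))) {
    pairs[i, ] <- infer_phase(pairs[i, , drop = FALSE], table, ped)
  }
  pairs
}

#' Segregation verdict for a candidate genotype configuration
#'
#' Checks, member by member, that the configuration (a biallelic pair,
#' or a homozygous single allele) tracks with affection status. An
#' affected member is consistent when it carries the full
#' configuration; an unaffected member is inconsistent when it does
#' (carrying a single allele of a pair is tolerated — the recessive
#' carrier state). Members with a missing call at any configuration
#' variant are `untyped` and excluded from the verdict.
#'
#' Verdicts, in order of precedence: `excluded` when any typed affected
#' member lacks the configuration (or no member carries it at all);
#' `partial` when the affected members are consistent but a typed
#' unaffected member shares the full configuration; `segregates`
#' otherwise.
#'
#' @param configuration Character vector of 1 or 2 `variant_id`s.
#' @param table A [variant_table()] of genotype calls (e.g. from
#'   [read_genotype_tsv()]).
#' @param ped A [pedigree()].
#' @param members Optional subset of members over which the verdict is
#'   computed (e.g. one family branch); defaults to all genotyped
#'   members present in the table.
#' @return A list of class `segregation_result` with `configuration`,
#'   `per_member` (member, affection, carries_full, status) and
#'   `verdict`.
#' @export
segregate <- function(configuration, table, ped, members = NULL) {
  configuration <- unique(as.character(configuration))
  missing_ids <- setdiff(configuration, table$records$variant_id)
  if (length(missing_ids)) {
    stop("configuration variant absent from genotype table: ", missing_ids[1])
  }
  if (is.null(members)) {
    members <- intersect(genotyped_members(ped), table$samples)
  } else {
    unknown <- setdiff(members, ped$member_id)
    if (length(unknown)) stop("member not in pedigree: ", unknown[1])
  }
  per <- data.frame(member_id = members, stringsAsFactors = FALSE)
  per$affected <- ped$affected[match(members, ped$member_id)]
  carries <- vapply(members, function(m) {
    if (!m %in% table$samples) return(NA)
    carries_configuration(table, m, configuration)
  }, TRUE)
  per$carries_full <- carries
  per$status <- ifelse(is.na(carries), "untyped",
    ifelse(per$affected == "affected",
           ifelse(carries, "consistent", "inconsistent"),
    ifelse(per$affected == "unaffected",
           ifelse(carries, "inconsistent", "consistent"),
           "consistent")))
  typed <- !is.na(carries)
  aff_typed <- typed & per$affected == "affected"
  una_typed <- typed & per$affected == "unaffected"
  verdict <- if (!any(carries[typed])) "excluded"
  else if (any(aff_typed & !per$carries_full)) "excluded"
  else if (any(una_typed & per$carries_full)) "partial"
  else "segregates"
  structure(list(configuration = configuration, per_member = per,
                 verdict = verdict),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("configuration:", paste(x$configuration, collapse = " + "), "\n")
  cat("verdict:", x$verdict, "\n")
  print(x$per_member, row.names = FALSE)
  invisible(x)
}

## Sibship key of a member: its parental couple, or its own id for
## founders/married-in members. Used to group segregating pairs by
## family branch.
sibship_of <- function(ped, member) {
  i <- match(member, ped$member_id)
  fa <- ped$father_id[i]; mo <- ped$mother_id[i]
  if (is.na(fa) && is.na(mo)) return(member)
  paste(ifelse(is.na(fa), "?", fa), ifelse(is.na(mo), "?", mo), sep = "x")
}

#' Family-level candidate report
#'
#' Assembles the per-family picture: every non-cis pair with its phase
#' and (when computable) segregation verdict grouped by the family
#' branch (sibship) of its affected carriers; per-member counts of
#' clinically relevant candidate alleles (het = 1, hom = 2); and an
#' oligogenic flag for each affected member carrying candidate alleles
#' in two or more genes. Oligogenic flagging is reporting-only — no
#' causality claim is attached.
#'
#' @param pairs Data frame from [infer_phases()].
#' @param candidates A `candidate_set` ([assemble_candidates()]).
#' @param table A [variant_table()] of genotype calls over pedigree
#'   members.
#' @param ped A [pedigree()].
#' @param results Optional named list of `segregation_result`s keyed by
#'   `"a+b"` configuration strings; computed when omitted.
#' @return A list of class `family_report` with `pairs` (incl. verdict
#'   and branch), `member_alleles`, `oligogenic`.
#' @export
family_report <- function(pairs, candidates, table, ped, results = NULL) {
  cand <- as.data.frame(candidates)
  cand_ids <- intersect(cand$variant_id, table$records$variant_id)
  config_key <- function(a, b) paste(sort(unique(c(a, b))), collapse = "+")

  pairs <- as.data.frame(pairs)
  pairs$verdict <- rep(NA_character_, nrow(pairs))
  pairs$branch <- rep("", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$phase[i] == "cis") { pairs$verdict[i] <- "excluded_cis"; next }
    key <- config_key(pairs$variant_a[i], pairs$variant_b[i])
    carriers <- strsplit(pairs$carriers[i], ",", fixed = TRUE)[[1]]
    branches <- unique(vapply(carriers, function(m) sibship_of(ped, m), ""))
    pairs$branch[i] <- paste(branches, collapse = ";")
    res <- if (!is.null(results) && !is.null(results[[key]])) results[[key]]
    else segregate(unique(c(pairs$variant_a[i], pairs$variant_b[i])), table, ped)
    pairs$verdict[i] <- res$verdict
  }

  members <- intersect(genotyped_members(ped), table$samples)
  allele_count <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = 0L)
  member_alleles <- do.call(rbind, lapply(members, function(m) {
    g <- zygosity(table, cand_ids, m)[, 1]
    carried <- cand_ids[carries_alt(g)]
    genes <- unique(cand$gene[match(carried, cand$variant_id)])
    data.frame(member_id = m,
               affected = ped$affected[match(m, ped$member_id)],
               n_alleles = sum(allele_count[g]),
               variants = paste(carried, collapse = ","),
               genes = paste(genes, collapse = ","),
               n_genes = length(genes), stringsAsFactors = FALSE)
  }))
  rownames(member_alleles) <- NULL

  olig <- member_alleles[member_alleles$affected == "affected" &
                           member_alleles$n_genes >= 2, , drop = FALSE]
  rownames(olig) <- NULL
  structure(list(pairs = pairs, member_alleles = member_alleles,
                 oligogenic = olig),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat("family report\n=============\n")
  if (nrow(x$pairs)) {
    cat("biallelic pairs:\n")
    print(x$pairs[, c("gene", "variant_a", "variant_b", "phase", "verdict",
                      "branch")], row.names = FALSE)
  } else cat("no biallelic pairs\n")
  cat("\ncandidate alleles per genotyped member:\n")
  print(x$member_alleles[, c("member_id", "affected", "n_alleles", "genes")],
        row.names = FALSE)
  if (nrow(x$oligogenic)) {
    cat("\npossible oligogenic configurations (candidate alleles in >= 2 genes):\n")
    print(x$oligogenic[, c("member_id", "n_alleles", "genes")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a family report as JSON and text
#'
#' @param report A `family_report`.
#' @param json_path Output JSON path.
#' @param text_path Optional human-readable text path.
#' @return `json_path`, invisibly.
#' @export
write_family_report <- function(report, json_path, text_path = NULL) {
  jsonlite::write_json(
    list(pairs = report$pairs, member_alleles = report$member_alleles,
         oligogenic = report$oligogenic),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(json_path)
}
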