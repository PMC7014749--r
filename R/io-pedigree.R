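#' Construct a pedigree
#'
#' A pedigree is a data frame (class `pedigree`) with one row per family
#' member: identifiers, parent links, sex, affection status and two
#' boolean flags recording whether the member underwent genome
#' sequencing (`sequenced`) and whether Sanger genotypes for candidate
#' variants are available (`genotyped`).
#'
#' @param members Data frame with columns `member_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`male`/`female`/`unknown`),
#'   `affected` (`affected`/`unaffected`/`unknown`), `sequenced`,
#'   `genotyped` (logical).
#' @param family_id Family identifier string.
#' @return A `pedigree` data frame.
#' @export
pedigree <- function(members, family_id = "FAM1") {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("member_id", "father_id", "mother_id", "sex", "affected")
  miss <- setdiff(need, names(members))
  if (length(miss)) stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(members$sequenced)) members$sequenced <- FALSE
  if (is.null(members$genotyped)) members$genotyped <- FALSE
  members$father_id[members$father_id %in% c("", "0")] <- NA_character_
  members$mother_id[members$mother_id %in% c("", "0")] <- NA_character_
  if (anyDuplicated(members$member_id)) {
    stop("duplicate member_id: ", members$member_id[duplicated(members$member_id)][1])
  }
  stopifnot(all(members$sex %in% c("male", "female", "unknown")),
            all(members$affected %in% c("affected", "unaffected", "unknown")))
  parents <- c(members$father_id, members$mother_id)
  unknown <- setdiff(parents[!is.na(parents)], members$member_id)
  if (length(unknown)) stop("parent id not in pedigree: ", unknown[1])
  check_acyclic(members)
  rownames(members) <- NULL
  structure(members, class = c("pedigree", "data.frame"), family_id = family_id)
}

## Topological check of the parent graph (a member may not be its own
## ancestor). Repeatedly peel founders; leftovers imply a cycle.
check_acyclic <- function(members) {
  remaining <- members$member_id
  repeat {
    parent_of <- members[members$member_id %in% remaining,
                         c("father_id", "mother_id")]
    founders <- remaining[!(parent_of$father_id %in% remaining |
                            parent_of$mother_id %in% remaining)]
    if (!length(founders)) break
    remaining <- setdiff(remaining, founders)
    if (!length(remaining)) return(invisible(TRUE))
  }
  stop("cyclic parentage involving: ", paste(remaining, collapse = ", "))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree '%s': %d member(s), %d affected, %d sequenced, %d genotyped\n",
              attr(x, "family_id"), nrow(x), sum(x$affected == "affected"),
              sum(x$sequenced), sum(x$genotyped)))
  NextMethod()
}

#' Read a PED-format pedigree file
#'
#' Standard 6-column whitespace-delimited PED (family, member, father,
#' mother, sex, phenotype) with `0` for unknown parents, sex `1`/`2` for
#' male/female, and phenotype `2` = affected, `1` = unaffected,
#' `0`/`-9` = unknown. Two optional trailing columns (`0`/`1`) carry the
#' `sequenced` and `genotyped` flags.
#'
#' @param path Path to a PED file.
#' @param family Family id to extract when the file holds several;
#'   defaults to the only family present.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path, family = NULL) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6) stop("PED file must have >= 6 columns, found ", ncol(raw))
  fams <- unique(raw[[1]])
  if (is.null(family)) {
    if (length(fams) > 1) stop("PED holds several families; pass `family`")
    family <- fams
  }
  raw <- raw[raw[[1]] == family, , drop = FALSE]
  if (!nrow(raw)) stop("family not found in PED: ", family)
  sex <- c("1" = "male", "2" = "female")[raw[[5]]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("2" = "affected", "1" = "unaffected")[raw[[6]]]
  aff[is.na(aff)] <- "unknown"
  members <- data.frame(
    member_id = raw[[2]], father_id = raw[[3]], mother_id = raw[[4]],
    sex = unname(sex), affected = unname(aff),
    sequenced = if (ncol(raw) >= 7) raw[[7]] == "1" else FALSE,
    genotyped = if (ncol(raw) >= 8) raw[[8]] == "1" else FALSE,
    stringsAsFactors = FALSE
  )
  pedigree(members, family_id = family)
}

#' Write a pedigree as a PED file
#'
#' Inverse of [read_pedigree()]; always writes the two extra flag
#' columns.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    fam = attr(ped, "family_id"), id = ped$member_id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[ped$sex],
    phen = c(affected = "2", unaffected = "1", unknown = "0")[ped$affected],
    seq = as.integer(ped$sequenced), gen = as.integer(ped$genotyped)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Convenience accessors used by the filters.
affected_members <- function(ped) ped$member_id[ped$affected == "affected"]
unaffected_members <- function(ped) ped$member_id[ped$affected == "unaffected"]
sequenced_members <- function(ped) ped$member_id[ped$sequenced]
genotyped_members <- function(ped) ped$member_id[ped$genotyped]
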