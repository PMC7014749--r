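---
title: "Prioritizing variants in inherited retinal dystrophy families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing variants in inherited retinal dystrophy families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdprio)
```

## The problem

Whole-genome sequencing of a family with inherited retinal dystrophy
(IRD) yields millions of variant calls per individual, of which at most
a handful are clinically relevant. `irdprio` implements the tertiary
half of a diagnostic WGS workflow: it takes already-called,
already-annotated VCFs and reduces them to a short, auditable candidate
list, then tests whether candidate genotype configurations actually
track with disease in the extended pedigree.

The package is aimed at the hard cases: pedigrees that look autosomal
dominant (affected members in consecutive generations) but are driven
by recessive alleles segregating in pairs — pseudo-dominance through
carrier-by-affected matings — and patients carrying relevant alleles in
more than one gene (possible oligogenic inheritance). In such families
a single compound-heterozygote explanation per family is the wrong unit
of analysis; the package therefore reports pairs per branch and alleles
per member rather than one verdict per family.

## The filter cascade

Five steps are applied in a fixed order, each a pure table-to-table
transformation with a per-step count trace and per-variant removal
attribution:

1. **ClinVar phenotype rescue** (marking only). A variant already
   described as pathogenic, likely pathogenic, or
   conflicting-between-pathogenic-and-VUS *and* linked to a matching
   phenotype term is marked before anything is discarded. Rescued
   variants are exempt from the two statistical filters that could
   plausibly discard a true known mutation (recurrence and frequency).
   They are *not* exempt from the pedigree filter: a known pathogenic
   allele homozygous in an unaffected relative is still incompatible
   with the family's disease model. Phenotype matching is
   case-insensitive substring containment (term `"usher"` matches
   `"Usher syndrome type 2A"`); the sensible terms are short and
   lower-case, e.g. `c("retinitis pigmentosa", "retinal dystrophy",
   "usher")`.
2. **Recurrence filter.** Against a pseudo-control cohort — unaffected
   individuals from unrelated families sequenced on the same platform —
   the filter keeps variants exclusive of the family: no control
   homozygote, at least one family carrier, and at most
   `max_control_carriers` control carriers. The default is 0 (strict
   exclusivity). The strict reading makes the no-control-homozygote
   clause redundant; we nevertheless keep that clause as a separate,
   always-on guard so that relaxing `max_control_carriers` (useful for
   platform-noisy sites that appear as scattered heterozygous calls)
   still never admits a variant homozygous in a control.
3. **Frequency filter.** Discards variants with population MAF above
   `maf_threshold` (default 0.01, the conventional recessive-disease
   bound against gnomAD). Variants with *no* frequency entry pass by
   default (`treat_missing_maf_as_pass`): novel variants are precisely
   the ones a WGS workflow must not lose.
4. **Gene filter.** Keeps variants inside any panel gene span — the
   full gene body, introns included, regardless of distance from splice
   sites, because deep-intronic splice-altering variants are a known
   blind spot of exon-centric workflows — or annotated with a panel
   gene symbol. Either criterion suffices, so span errors and
   annotation errors fail safe independently.
5. **Pedigree filter.** The recessive-compatible rule: an alternate
   allele in at least one sequenced affected member (whether or not the
   other affected members share it — different branches may carry
   different pairs), and no homozygous call in any sequenced unaffected
   member. Heterozygous unaffected members are tolerated: they are the
   expected carrier state.

Every filter is a contraction and idempotent, and the two
sample-independent filters (frequency, gene) commute; the test suite
asserts all three properties, plus equivalence of the whole cascade
with a brute-force per-record predicate on randomized tables.

## Region classification and splice thresholds

After the cascade, candidates are tiered by region against the panel's
exon model. Positions inside an exon are `coding_exonic`; within
`flank_bp` (default 10) of an exon boundary, `near_splice` — the bound
is inclusive, so a position exactly 10 bp from the exon still
qualifies; inside the gene span but farther away, `deep_intronic`;
outside every span, `other`. Distances are counted in 1-based inclusive
coordinates from the first/last exonic base. Tier 1 is
`coding_exonic` + `near_splice`. Deep-intronic variants reach tier 2
only on in-silico splice evidence.

The package does not compute splice scores; it consumes wild-type and
mutant score pairs from MaxEntScan, Human Splicing Finder and NNSPLICE
and applies decision thresholds: a floor on the site score (2, 70 and
0.4 respectively, on each tool's native scale — HSF's consensus scale
runs 0–100) and a strict lower bound on the relative change (15%, 10%,
10%). Three choices here were genuinely open:

* **Which score must clear the floor.** We require
  `max(|wt|, |mut|) >= min_score`, so both site-loss events (a strong
  wild-type site collapsing) and site-gain events (a strong novel site
  appearing) qualify; both event types are detectable by these tools.
* **The variation formula.** "Score variation" is computed as
  `|wt - mut| / max(|wt|, 1e-9) * 100`; the epsilon guards a zero
  wild-type score, in which case any gain is effectively an infinite
  relative change and passes the variation clause (the floor clause
  still applies).
* **Combining three tools.** A majority quorum (≥ 2 of 3, configurable
  via `splice_quorum`) admits a deep-intronic variant to tier 2. A
  single tool is too noisy; requiring all three penalizes sites where
  one tool has no model.

Predictor annotations (SIFT, PolyPhen-2, MutationTaster) and ACMG
classes are carried through and reported but never used as filters — a
candidate with a benign PolyPhen call can still be the second allele of
a causal pair. Likewise, every candidate carries a `hom_flag` raised
when the population reports homozygotes, surfacing the
manual-review question (can this allele be benign in homozygosis?)
without automating its answer.

## Pairing, phase, and segregation

Within each gene, every unordered pair of candidates for which some
affected member is heterozygous at both is a potential compound
heterozygote; a homozygous affected member yields a self-pair. Only
*trans* pairs (one allele per homologous chromosome) can explain
recessive disease, so phase is inferred from the pedigree, one
informative meiosis at a time:

* a parent heterozygous at both variants transmitting exactly one to a
  genotyped child implies **trans**; transmitting both implies **cis**;
  transmitting neither is uninformative on its own (it is consistent
  with transmission of the wild-type haplotype of a cis pair), so a
  lone both-absent observation leaves the phase `unknown`;
* parental origin: when the two variants of a doubly heterozygous
  member trace to different parents, the pair is trans; to the same
  parent, cis — the child received a single haplotype from that parent,
  and we assume no recombination within a gene at pedigree scale;
* a meiosis is skipped as confounded when the child's other parent is a
  known carrier of either variant, and conflicting observations across
  meioses (possible genotyping error) yield `unknown` with a warning,
  never a silent resolution.

Segregation is then checked per member over Sanger-genotyped relatives:
an affected member is consistent when it carries the full
configuration; an unaffected member is inconsistent only when it
carries the *full* configuration (single-allele carriers are expected).
Members missing any configuration call are `untyped` and excluded from
the verdict. Verdicts: `excluded` when a typed affected member lacks
the configuration or nobody carries it; `partial` when an unaffected
member shares the full genotype; `segregates` otherwise. Because
different branches of a large family may carry different pairs, the
`members` argument scopes a verdict to a branch; the family report
groups pairs by the sibship of their affected carriers and additionally
lists candidate-allele counts per member, flagging affected members
with alleles in two or more genes as possible oligogenic
configurations. The flag is reporting-only: no causality score is
attached.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the pipeline targets: a
nuclear family (two founders plus children, the first child affected;
default four members, matching a realistic sequencing budget) and six
pseudo-controls, the cohort size used throughout the package's
validation. The toy genome is two contigs carrying a 12-gene panel of
three-exon genes — correctness of interval logic does not depend on
genome scale. One compound-heterozygote pair is planted in trans (one
allele per parent) in a panel gene; decoys are generated per class so
that each violates exactly one pipeline stage (common polymorphism →
frequency; control-shared homozygote → recurrence; homozygote in an
unaffected member → pedigree; off-panel → gene filter; co-transmitted
cis pair → phase stage). Default decoy load is 40 variants per cohort,
enough for every class to appear while keeping a 100-seed validation
run under a minute.

Genotypes are Mendelian-consistent per variant (the suite validates
every trio exhaustively), and cis pairs ride a single parental
haplotype by construction — the two-haplotype founder model with
gene-scale linkage is what makes cis/trans well-defined. The generator
is deliberately idealized: no genotyping error, full penetrance of the
planted pair (unaffected children never receive both planted alleles),
no linkage disequilibrium or demography, and no read-level artefact
model beyond the control-shared class. Passing tests on simulated
cohorts therefore demonstrate the *logic* of the pipeline — that each
filter removes exactly its intended class and that trans pairs are
recovered and cis pairs excluded — not robustness to noisy real-world
calls, which depends on upstream calling quality.

The bundled family fixture (`rp_family_fixture()`) encodes the worked
case study: six heterozygous candidates in three recessive IRD genes,
with published frequencies, ClinVar classes and predictor calls. Its
genomic coordinates and 4-gene panel are synthetic placeholders on toy
contigs (the published record gives cDNA-level descriptions, carried in
the `label` field); carrier patterns, annotations and the 19-member
genotyped pedigree structure are the documented ones. Sanger genotypes
are emitted only for the documented carrier statements; all other
member-variant calls are left `missing` rather than invented, which is
why branch-scoped verdicts rest on the explicitly typed members.

## Numerical and degenerate-input choices

* VCF positions are 1-based; BED panels are 0-based half-open on disk
  and converted at the file boundary; all internal intervals are
  1-based inclusive.
* Multiallelic sites are split into biallelic records; per-allele
  annotations (`Number=A`) are indexed by allele. Symbolic alternate
  alleles are skipped with a warning (structural variation is out of
  scope).
* A sample with no record at a combined-VCF site defaults to `missing`,
  not `hom_ref` — single-sample VCFs do not assert reference calls; an
  all-sites flag (`missing_call = "hom_ref"`) is available for sources
  that do.
* Haploid genotype calls (male X) map to `hom_ref`/`hom_alt`; the
  filters have no heterozygous-male special case because all genes in
  the bundled analyses are autosomal.
* Empty tables flow through every stage: an empty VCF yields an empty
  candidate list and an empty report, exit status 0.
* Ties and ordering: candidates sort by (tier, gene, chrom, pos);
  pair enumeration sorts variant ids lexicographically so output is
  deterministic and byte-stable for fixed inputs.

## Problem sizes used in validation

The test suite and the acceptance script run the case-study fixture
(10 variants × 9 samples), randomized oracle tables up to 50 records ×
12 samples, and 100 seeded simulated cohorts of ~42 variants × 10
samples each — sizes chosen so the full logic (every filter class,
every phase rule) is exercised while a complete validation run stays in
the tens of seconds. Scaling to real cohorts is linear in records for
every filter; the pairing step is quadratic per gene in the number of
*surviving* candidates, which the cascade keeps small by design.

## Known limitations

* Phase inference uses pedigree transmission only; read-backed phasing
  from alignments is out of scope, so families without informative
  relatives keep `unknown` phase.
* No statistical linkage or penetrance model: verdicts are exact
  set-logic over genotypes, appropriate for the small pedigrees of
  diagnostic practice but not a substitute for LOD-score analysis.
* The ClinVar rescue inherits ClinVar's curation: a mis-annotated
  significance or phenotype propagates.
* CNV/SV handling, annotation itself (gene symbols, frequencies,
  ClinVar), and splice-score computation are upstream concerns; the
  package consumes their outputs.
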