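---
title: "Prioritizing exome variants in a quartet with an ungenotyped parent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing exome variants in a quartet with an ungenotyped parent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetvar)
library(dplyr)
```

## The problem

Hereditary hemolytic anemias of unknown molecular cause are a classic use
case for exome sequencing of a nuclear family: variants compatible with the
observed inheritance pattern are intersected with functional annotations,
population allele frequencies, clinically curated gene panels and
tissue-expression evidence until a short list of candidates remains. The
family structure this package targets is a *quartet with a missing parent*:
two affected brothers, an unaffected father and sister, and a mother whose
genetic material is unavailable. That missing parent is not a corner case —
it changes what the inheritance filters can and cannot conclude, most
visibly for compound heterozygotes, where "one allele per parent" can only
be *implied*, never observed.

The motivating phenotype is an erythrocyte enzymopathy: deficiency of the
cytosolic pyrimidine 5′-nucleotidase (P5N, gene *NT5C3A*), the enzyme that
dephosphorylates UMP and CMP so pyrimidine nucleosides can diffuse out of
the maturing reticulocyte. Loss of P5N activity causes pyrimidine
accumulation, a lowered purine/pyrimidine ratio and chronic hemolysis. The
package therefore pairs the genomic pipeline with the deterministic
arithmetic of the confirmatory functional assays (phosphate-release enzyme
activity, hemoglobin quantification, EMA binding, dual-luciferase
normalization), because candidate prioritization and functional validation
are two halves of one analysis.

## Data model

Every stage operates on a *variant table*: a tibble with one row per
(site, ALT allele), the positional identity key `(chrom, pos, ref, alt)`,
a parsed annotation bundle (gene, one consequence class, functional-domain
/ repeat / known-catalog flags, HGVS strings), a `pop_freqs` list-column of
per-population `allele_count` / `allele_number` pairs, and one `gt_<sample>`
genotype column per genotyped pedigree member. Annotations enter through a
single documented INFO-key convention (`GENE`, `CSQCLASS`, `AF_<pop>`,
`DOMAIN`, `REPEAT`, `KNOWN`) rather than any particular annotator's dialect:
the pipeline's contract is the parsed bundle, and adapters from specific
annotation tools can be layered on top without touching the filters.

Zygosity is derived, not stored: it is a pure function of the genotype
string, the sample's sex and the chromosome. On the X chromosome males are
hemizygous; a heterozygous male X call is a QC artifact and is coerced to
missing with a warning. Pseudo-autosomal regions are not modeled.

## Inheritance filters

Four genotype-pattern predicates drive the genetic logic, all evaluated per
record:

* **shared**: every affected member carries at least one ALT allele. A
  missing call in an affected member disqualifies the record from every
  model — every surviving candidate is expected to be validated by Sanger
  sequencing, and letting no-calls pass silently would fabricate
  candidates.
* **recessive homozygous**: all affected hom-alt, every genotyped
  unaffected member het or hom-ref. A missing call in an unaffected member
  also fails the predicate: the constraint cannot be verified, and the
  conservative reading is the one that does not admit unverifiable
  candidates.
* **X-linked hemizygous**: affected males hemi-alt, unaffected males
  hemi-ref, unaffected females may be carriers (het) — the carrier-sister
  allowance is this package's own reading of how an X-linked model should
  treat an unaffected sister, since a het sister is fully consistent with
  X-linked recessive transmission.
* **compound heterozygous**: two or more distinct records in one gene, het
  in every affected member, such that (i) no genotyped unaffected member
  carries the full combination and (ii) with exactly one genotyped parent,
  at least one record of the pair is absent from that parent. Clause (ii)
  is where the missing mother matters: a variant absent from the genotyped
  father but present in the children must have come from the mother — an
  inference the package labels `maternal_implied`, never an observation. A
  pair in which *neither* variant is in the father is cis-implied (both
  alleles would have to ride the single transmitted maternal homolog) and
  is reported as phase-unresolved rather than as a candidate. A pair fully
  carried by the unaffected father is already excluded by clause (i),
  because under the compound-het model he would be affected.

The ungenotyped mother is never assumed to be reference; her genotypes
simply contribute no evidence. All filters are monotone (each returns a
subset of its input), deterministic, and order-insensitive after canonical
`(chrom, pos, ref, alt)` sorting.

## Annotation filters and frequency arithmetic

The large-effect filter keeps missense, nonsense, splice-site and
frameshift classes, **plus in-frame indels**: this inclusion is a
deliberate extension, because a single-residue in-frame deletion can
abolish enzyme function — precisely the lesion class of the motivating
case — and a frameshift-only definition would discard it. It is
switchable (`include_inframe = FALSE`) for a stricter reading.

Population frequencies are kept as integer count/total pairs and converted
with `af_from_counts()`, which rounds *half-up* at a caller-chosen number
of decimals. Databases print frequencies at mixed precisions, and base R's
round-half-even would disagree with printed values at exact midpoints, so
the half-up helper exists to reproduce printed numbers bit-exactly. The
rarity filter takes the **maximum** frequency across the selected
populations (threshold default 0.5%); whether a multi-database filter
should use max-across or any-population logic is genuinely open, and
max-across is this package's contract because it is the stricter of the
two. Records with no frequency data pass the filter with
`max_frequency = 0` and a no-data marker — absence from population
controls is rarity evidence, the same logic the PM2 criterion uses.

## Gene-level integration

Candidate genes are intersected with clinical panels (membranopathy,
enzymopathy, hemoglobinopathy) and with two erythroid expression libraries
representing early (CD71-high) and late (glycophorin-A-positive)
reticulocyte maturation; a gene expressed in *both* is the strongest
expression evidence. Pathway over-representation is the upper-tail
hypergeometric probability P[X ≥ overlap] with Benjamini–Hochberg
adjustment across the tested pathways. This is an open, testable
substitute for proprietary gene-set scoring: the commercial tool used in
the original analysis is closed, but its statistical intent —
over-representation against a gene universe — is standard. The run report
notes the substitution.

The ACMG-style classifier auto-triggers the three moderate criteria that
the annotation bundle can support: PM1 (critical functional domain), PM2
(absent from controls or below 1% for a recessive phenotype), PM4
(in-frame length change outside a repeat). The full published combining
table is implemented in `acmg_combine()` — three moderates give *likely
pathogenic*, a single moderate is a VUS, conflicting evidence resolves to
VUS — so manually curated criteria at other strengths can be added
without re-deriving the rules.

Final ranking is deliberately mechanical: the score is the count of stages
passed plus fixed documented bonuses (panel hit +2, both-libraries
expression +2, ACMG class from +4 for pathogenic to −4 for benign), with
ties broken by genomic coordinate. The original workflow ranked by expert
judgment; a reusable pipeline must instead be deterministic, and the
weights are visible configuration rather than hidden heuristics.

## The synthetic quartet generator

`simulate_quartet()` exists so that every stage is testable without any
data download. It draws founder genotypes under Hardy–Weinberg equilibrium
at each site's simulated allele frequency (a 70/30 mixture of common sites,
Beta(2,2) scaled into 0.1–0.5, and rare sites log-uniform in 1e-5–0.005),
produces children by Mendelian transmission with sons hemizygous for a
maternal X allele (5% of sites are X-linked), and spikes one causal
variant: a heterozygous in-frame deletion in both brothers, transmitted
from the mother, absent from father and sister, in a functional domain
outside a repeat, with a population frequency below 1e-5. The latent
mother is simulated explicitly and then withheld from the output; her
genotypes survive only in the truth table, so maternal-transmission
inferences can be audited against ground truth.

Default problem sizes are 2,000 sites and 200 genes per run — large enough
that hundreds of variants survive the shared filter and the causal variant
must genuinely out-compete decoys, small enough that a hundred seeded
end-to-end runs complete in a few minutes. The erythroid libraries default
to 35% / 33% of the gene universe with a 10% overlap, mirroring the
relative sizes of real early/late reticulocyte libraries (701 and 654
genes sharing 201) against an exome-scale background. The assay generator
forward-computes plate absorbances from programmed specific activities
(controls at 130 pmol Pi/mg Hb/min — a mid-normal erythrocyte P5N
activity — patients at fold changes 0.21 and 0.07, hemolysate at
160 mg/mL hemoglobin, 2.5-fold diluted), so at zero noise the activity
pipeline inverts the construction exactly.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: sequencing error and genotype-quality
modeling, linkage disequilibrium between sites, population stratification
of allele frequencies, annotation error (the consequence class and domain
flags are taken as given), and multi-allelic complexity beyond the
splitter's contract. Recovery of the spiked variant demonstrates that the
predicates and ranking compose correctly, not that real exomes are this
clean.

Randomness follows one root seed with per-component substreams derived by
fixed text labels, so every generator is a pure function of its
configuration and the same seed reproduces byte-identical files.

## Assay arithmetic

The enzymatic assay chain is: fit an ordinary least-squares calibration
line through known phosphate amounts (absorbance at 750 nm), invert it for
each well after blank subtraction, convert well amounts back to
per-reaction amounts through explicit volume bookkeeping (150 µL
hemolysate + 150 µL substrate; 120 µL aliquot quenched in 1200 µL stop
solution; 120 µL of extract per detection well — a combined factor of
27.5), subtract the paired zero-time control, and normalize by hemoglobin
mass and the 120-minute incubation to pmol Pi per mg Hb per minute.
Hemoglobin itself comes from Beer–Lambert at 512 nm with a molar
extinction coefficient of 26,936.8 cm⁻¹ M⁻¹; the molar mass defaults to
the 64,458 g/mol tetramer and is a visible parameter because the mass
basis of the coefficient is a unit-chain choice the caller should be able
to audit. Negative baseline-subtracted activities clip to zero with a
warning rather than erroring — near-zero patient activities sit within
measurement noise of the baseline, and an error there would make exactly
the interesting samples unprocessable. An AMP-substrate control, when
present, reports the nonspecific nucleotidase fraction with a warning
above 15%.

Percent-of-reference for the EMA binding test uses the stated reference
mean when a single value is given and the midpoint when the laboratory
reports a range; reporting rounds half-up to an integer. The
purine/pyrimidine ratio operation takes pre-extracted purine and
pyrimidine signals as inputs — the deproteinization and wavelength
protocol is instrument-side and out of scope.

## Numerical choices and degenerate inputs

* Variant identity is positional, `(chrom, pos, ref, alt)`, with `chr`
  prefixes stripped and allele pairs trimmed to parsimony (shared suffix
  first, then shared prefix); rsIDs and HGVS strings are carried but never
  used as keys, because identifier-based joins are ambiguous across
  database versions.
* Multi-allelic sites split into one biallelic record per ALT; a genotype
  allele belonging to a *different* ALT counts as non-carriage (0) for the
  record at hand, and fully missing calls are canonicalized to `./.`.
* Hypergeometric p-values come from `stats::phyper`, BH adjustment from
  `stats::p.adjust`; tests verify both against exhaustive subset
  enumeration on small universes and against a closed-form point-mass sum.
* An empty pathway universe, a calibration with fewer than two distinct
  points or non-positive slope, a zero control mean, a zero Renilla value
  and an unknown population label are all fatal; they indicate a broken
  input, not a boundary case.
* Tie-breaks everywhere are lexicographic on the positional key, so equal
  scores produce a stable, reproducible order.

## Known limitations

The pipeline consumes annotated VCFs; it performs no alignment, variant
calling, liftover, or live database queries. No statistical phasing or
imputation of the missing parent is attempted — phase labels are logical
implications only. Deleteriousness scores from external annotators can be
carried through but are never computed. The ACMG layer auto-triggers only
PM1/PM2/PM4; other criteria require manual evidence counts. The test
problem sizes (100-site oracle quartets across 50 seeds, 2,000-site
end-to-end runs across 100 seeds) were chosen as the smallest sizes at
which the properties under test are non-trivial while a full suite run
stays comfortably interactive.
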