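---
title: "Allelic requirements, variant consequences, and zygosity-aware prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic requirements, variant consequences, and zygosity-aware prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AllelicReq)
```

## The problem

Clinical interpretation of a rare variant hinges on context that lives at
the *gene-disease pair* level, not the variant level: how many affected
alleles are needed to cause the disease (the allelic requirement), how the
phenotype is transmitted (the mode of inheritance), and which high-level
consequences of variation — loss of product, altered product, increased
product — have actually been associated with that disease. Groups curating
this information have historically used incompatible vocabularies, which
makes curations hard to pool and variant filters hard to standardize.

AllelicReq implements a harmonized machine-readable vocabulary for these
concepts, together with the machinery needed to *use* it in a
prioritization pipeline: a likelihood matrix linking SO variant classes to
six high-level disease-associated consequences, a first-principles variant
classifier with nonsense-mediated-decay (NMD) awareness, a validating
curation-record schema, and an engine that decides whether the variants
observed in one individual satisfy a curated allelic requirement.

## The vocabulary

`buildVocabulary()` assembles three fixed term tables.

*Mendelian requirement/inheritance pairs.* Eight allelic-requirement
tokens are paired one-to-one with eight mode-of-inheritance terms, and
each pair shares a single HPO identifier (the requirement token is an
allelic-requirement synonym of the inheritance term). The bijection is
load-bearing: `mapRequirementInheritance()` applied twice is the identity,
and every lookup route (token, label, curie) lands on the same entry.
Because one pair ("mitochondrial" / "Mitochondrial") differs only by
case, direction inference prefers exact matches before falling back to
case-insensitive ones.

*Inheritance qualifiers.* Seventeen cross-cutting qualifier terms
(penetrance bands, imprinting direction, anticipation, de novo tendency,
sex-limited expression, requires-heterozygosity, mosaicism, contiguous
gene syndrome) that can decorate any pair without changing it. Sibling
qualifiers that contradict each other (complete vs incomplete penetrance
and its children; maternal vs paternal imprinting; male- vs female-limited
expression) are mutually exclusive in validation.

*Consequence hierarchy.* Six high-level disease-associated consequence
terms with SO identifiers, where *decreased* and *increased gene product
level* are children of *altered gene product level* and *absent gene
product* is a child of *decreased*. Two further SO nodes
(function-uncertain, functionally-abnormal) are represented in the
hierarchy but are deliberately not matrix columns: the matrix is fixed at
six columns.

## The consequence matrix

The matrix maps variant classes (rows) to the six consequences (columns)
on a five-level ordinal likelihood scale — 1 almost never, 2 unlikely,
3 possible, 4 probable, 5 almost always. The scale is ordinal by
definition; no probabilistic calibration is implied, and none is
performed.

The row set starts from the 33 variant-class SO terms used by Ensembl
VEP. The published sources do not enumerate that set term-by-term, so the
package fixes a reconstruction (`vepConsequences()`): the current Ensembl
consequence table minus `start_retained_variant`, `feature_elongation`
and `feature_truncation`, which postdate the snapshot the vocabulary was
aligned to. Eight terms that are redundant for disease-gene curation
(`upstream_gene_variant`, `downstream_gene_variant`,
`NMD_transcript_variant`, the TFBS/regulatory ablation and amplification
terms, `intergenic_variant`) are culled from the matrix rows;
`transcript_ablation` is retained as the sole whole-gene-loss stand-in.
The two PTC-producing classes, `stop_gained` and `frameshift_variant`,
are split into `|NMD_triggering` and `|NMD_escaping` rows, because their
consequences differ qualitatively (degraded transcript vs truncated
product). Splice donor/acceptor classes are *not* split; they carry a
single row with both "decreased gene product level" and "altered gene
product sequence" at likelihood >= 3, reflecting that a splice-site
variant may do either.

Cell values: the handful of cells that the terminology's own text fixes
(NMD-competent stops score 5 for decreased and absent product; missense
scores 5 for altered sequence; synonymous scores 5 for functionally
normal; the splice-site dual consequences) are encoded exactly and tagged
with provenance `paper_text`. Every other cell is an expert default
(`expert_default`) filled from the term definitions, and the whole matrix
is overridable: `loadMatrix()` accepts a user TSV, re-validates it, and
tags user cells `user`. `validateMatrix()` enforces the scale range, row
uniqueness, and hierarchy monotonicity — for every class, altered level
>= max(decreased, increased) and decreased >= absent — so a parent
consequence can never be less likely than its child.

Two derived operations implement the intended inference workflow.
`inferConsequences()` returns, for a set of observed pathogenic classes,
the element-wise maximum of their rows (monotone: adding a class never
lowers the profile). `suggestClasses()` then admits novel classes whose
likelihood reaches the threshold (default 4, "probable") for a
consequence that the observed classes also reach at threshold; ties in the
output are broken by severity rank then lexicographically, so the result
is deterministic and order-independent. One consequence of hierarchy
monotonicity worth knowing: because *altered level* dominates its
children, a class that only increases product level (e.g.
`transcript_amplification`) can be suggested from observed
loss-of-function classes via the parent column; filter on the child
columns if directionality matters.

## Variant classification and the NMD rule

`classifyVariant()` works from first principles on a transcript model:
normalize the alleles (shared suffix/prefix trimming, then left alignment
of pure indels against the reference), verify the reference allele, map
the variant into transcript coordinates, and splice and translate the
edited CDS. Coordinate conventions are fixed once: VCF positions are
1-based genomic; transcript coordinates are 1-based from the
transcription start in transcript orientation; interval arithmetic is done
on IRanges. Canonical splice sites are intronic positions 1-2 on either
side of a junction; intronic positions 3-8 and the last three exonic
bases of each junction-flanking exon are splice region. A variant can
legitimately carry several terms (a missense in the last exonic codon of
an exon is also splice region); all applicable terms are retained in
`allTerms` and the reported class is the most severe under the VEP
severity order. Variants outside the transcript footprint return a
`no_overlap` result rather than an error; reference mismatches are
errors.

For PTC-producing outcomes the classifier reports the transcript
coordinate of the new stop and `assessNMD()` applies the canonical
junction rule: a PTC escapes NMD when the transcript has one exon, when
the PTC lies in the final exon, or when it lies within the last 50
nucleotides upstream of the final exon-exon junction — boundary
inclusive, so exactly 50 nt escapes. The vocabulary only distinguishes
triggering from escaping; the 50-nt last-junction rule is the package's
choice of concrete rule, being the standard operational criterion in
annotation practice. A start-proximal escape clause (translation
reinitiation within the first ~150 coding nucleotides) exists as an
option on `assessNMD()` and is off by default. A frameshift whose shifted
frame reaches the transcript end without a stop has no PTC; there is no
junction downstream to trigger degradation, so it is reported as
escaping.

For variants that arrive pre-annotated, `parseVepConsequences()` picks
the most severe recognized term from an ampersand-separated CSQ string.
Its default recognized set is the matrix-resolvable one, so culled terms
such as `downstream_gene_variant` map to `function_uncertain` with a
warning rather than silently entering the matrix.

## The requirement engine

`evaluateRequirement()` turns qualifying observations into one of three
verdicts — `satisfied`, `candidate_partial`, `unsatisfied` — with
rationale codes from a fixed set (`requirementRationaleCodes()`). The
rule table:

| requirement | rule |
|---|---|
| monoallelic_autosomal | any qualifying allele satisfies |
| biallelic_autosomal | homozygote satisfies; two heterozygotes are a trans-compound (satisfied) if phased trans, not satisfied if phased cis, a phase-unknown candidate otherwise; a lone heterozygote is a candidate ("second contributory variant or alternative cause should be sought") |
| monoallelic_X_heterozygous | any qualifying allele, either sex; an XX homozygote satisfies with a `HOMOZYGOUS_UNDER_DOMINANT` flag |
| monoallelic_X_hemizygous | XY hemizygote satisfies; XX homozygote or (possible) compound heterozygote satisfies; an XX lone heterozygote is a carrier (`X_CARRIER_HET`), not satisfied |
| monoallelic_Y_hemizygous | qualifying Y variant in XY; in XX the verdict is `KARYOTYPE_IMPOSSIBLE`, a rationale rather than an exception |
| mitochondrial | any qualifying MT variant; heteroplasmy fractions are surfaced, no threshold is applied |
| monoallelic_PAR / biallelic_PAR | observations are restricted to the pseudoautosomal intervals (`NOT_IN_PAR` otherwise), then counted autosomal-fashion across the X and Y copies |

Phase handling is deliberately conservative. Two phased heterozygotes
resolve cis/trans only within a shared phase set. In the PAR, a haploid
call is located on a chromosome copy, so two haploid calls on different
copies (X vs Y) are trans and two on the same copy are cis — but a
diploid het call carries no copy location, and phase-set haplotype labels
are not tied to chromosome copies, so mixed comparisons stay "unknown".
The test oracle formalizes exactly this by enumerating haplotype
assignments with the phase-frame/copy-frame mapping itself unknown.

With an unknown karyotype the engine refuses to guess: wherever the
verdict would differ between XX and XY (a lone X heterozygote under an
X-linked recessive requirement, any Y requirement) it returns
`candidate_partial` with `UNKNOWN_KARYOTYPE`; verdicts that are
sex-independent are returned normally. Two semantics points were open and
were decided as follows: XX homozygosity under a dominant X requirement
satisfies but is flagged, and non-Mendelian records are representable in
curations but skip engine logic entirely
(`NON_MENDELIAN_NOT_EVALUATED`), since no filtering semantics exist for
them.

`applyQualifiers()` decorates a decision. Only one qualifier can change a
status: requires-heterozygosity downgrades an XY hemizygous satisfaction
to a candidate (hemizygous males seldom manifest the full phenotype).
Imprinting direction is checked against parental origin — "with maternal
imprinting" silences the maternal copy, so disease needs a paternally
inherited variant, and vice versa; inconsistency, consistency and unknown
origin each get a flag. De novo and sex-limited qualifiers flag; the
penetrance, onset, anticipation, mosaicism and contiguous-gene qualifiers
are descriptors and only ever attach informational flags. Penetrance
bands (moderate 20-80%, high 80-100%) are recorded as terms, not checked
against a numeric field, because curations carry no numeric penetrance in
this schema.

`prioritize()` composes the pieces per (sample, gene-disease pair) and is
deterministic: identical inputs give identical reports. The same variant
set can satisfy one pair and not another — the bundled exemplars include
a toy X-linked gene curated as two disease entities (hemizygous-required
congenital disease vs heterozygous-sufficient later-onset disease)
exactly to exercise this.

Default PAR intervals ship for GRCh38 (from genome-build documentation,
0-based half-open BED) and are fully overridable through
`SampleContext()`.

## The synthetic-data generators

`synthTranscript()` builds a toy chromosome containing one transcript:
random sequence, ATG start, single terminal TAA, no internal in-frame
stops (codons are drawn from the 61 non-stop codons), GT..AG introns, on
either strand. It emulates exactly what the classifier needs — exon/CDS
geometry and a faithful regional reference — and nothing else: no codon
usage bias, no splice-strength realism, no repeats, no polymorphism
background. Passing tests therefore demonstrate correctness of the
coordinate/translation/NMD logic, not performance on real genomes, where
transcript-model disagreements, multi-transcript genes and messy indel
representations dominate the error budget.

`synthVariants()` places variants constructively by codon arithmetic
(which codon, which substitution, which intron offset), independently of
the classifier, so the round trip — generate, write VCF, read, classify —
is a genuine two-route check. NMD-suffixed recipe keys pin the PTC to a
triggering or escaping location. Generated positions are pairwise
disjoint with a 1-bp margin so indel normalization cannot make neighbors
interact. Default study conditions used across the tests: 3-exon
transcripts of 90/120/90 nt exons with 50 nt introns and 30 nt UTRs (and
a 4-exon and a single-exon variant), a 16-class recipe of 19 variants,
five seeds, both strands.

`exemplarCurations()` bundles 19 records: 13 assembled from named gene
examples in the published text (MYH7, KCNQ1 twice, FBN1, EFNB1, DMPK,
DHH, NF1, CYP1B1, IRF6, C9orf72, RYR1, CACNA1S) and 6 synthetic records
(marked `source = "synthetic"`) so that every requirement token,
including Y-linked, mitochondrial and both PAR forms, is exercised.

## Numerical and testing choices

Problem sizes were chosen to keep every check exhaustive at desk scale:
the requirement engine is compared against the brute-force oracle over
roughly 1,300 enumerated cases (<= 3 observations x zygosities x
{XX, XY, unknown} x 8 requirements x phase configurations); the NMD rule
is scanned at every CDS position of three transcripts (~1,450 positions)
including the 50-nt boundary; the recipe round trip covers 95 variants
over five seeds. All generators are pure functions of their arguments and
seed, and restore the RNG state they found.

Known limitations: one transcript per gene is used in prioritization (the
first model wins); indels spanning exon-intron boundaries are classed by
their splice-site footprint rather than translated; frameshift PTC
positions are mapped back to reference transcript coordinates by length
adjustment, which is exact for the single-edit case the classifier
handles; repeat-expansion and structural-variant classes are out of scope
(DMPK- and C9orf72-style records carry an `altered gene product level`
consequence with no class rows); and the engine performs no pedigree
analysis beyond the per-variant de novo and parental-origin fields.
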