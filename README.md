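# AllelicReq

Harmonized, machine-readable terminology for Mendelian disease-gene
relationships — and the machinery to use it for variant prioritization.

Gene-disease curation and variant annotation need three pieces of
gene-level context that have long been described with incompatible
vocabularies: the **allelic requirement** (how many affected alleles cause
disease — monoallelic for dominant, biallelic for recessive, with X/Y/MT
and pseudoautosomal refinements), the **mode of inheritance**, and the
**disease-associated variant consequence** (the predictable high-level
effect of a variant on gene product level or sequence). AllelicReq
implements a standardized vocabulary for all three and the downstream
logic a clinical-genomics pipeline needs:

- the 8 allelic-requirement ↔ inheritance term pairs with their shared
  HPO identifiers, plus 17 cross-cutting inheritance qualifiers
  (penetrance, imprinting, anticipation, requires-heterozygosity, ...),
- the 6-term SO consequence hierarchy (altered / decreased / absent /
  increased gene product level, altered gene product sequence,
  functionally normal) and a variant-class × consequence likelihood
  matrix on the ordinal 1–5 scale (1 almost never ... 5 almost always),
  with per-cell provenance and user override,
- a first-principles variant classifier on transcript models (SNVs and
  indels; splice-site conventions; CDS translation) with NMD-competence
  assessment of premature termination codons (last-exon + 50-nt junction
  rule),
- a zygosity-, phase-, karyotype- and PAR-aware engine that decides
  whether the variants observed in an individual **satisfy** a curated
  allelic requirement (compound-het phase resolution, carrier flags,
  qualifier application),
- a validating TSV/JSON curation-record schema, bundled exemplar
  curations, and deterministic generators for toy transcripts and
  recipe-driven variant VCFs so everything is testable offline.

## Worked example

A hemizygous nonsense variant in a toy X-linked gene, evaluated against
two curations of the same gene with different allelic requirements:

```r
library(AllelicReq)

v <- buildVocabulary()
mapRequirementInheritance(v, "monoallelic_X_hemizygous")$mapped
#> [1] "X-linked Recessive"

m <- defaultMatrix()
likelihood(m, "stop_gained|NMD_triggering", "absent gene product")
#> almost always
#>             5

# toy X-linked gene + one hemizygous NMD-competent stop in an XY sample
tx  <- synthTranscript(c(90, 120, 90), c(50, 50), chrom = "X",
                       gene = "GENEX", txId = "TXX", seed = 5)
vcf <- synthVariants(tx, c("stop_gained|NMD_triggering" = 1), seed = 2,
                     genotypes = "1", sampleId = "M1")
classifyVariant(readVariants(vcf)[[1]], tx, m)
#> AnnotatedVariant X:154 G>A -> stop_gained|NMD_triggering (NMD: triggering)

curs <- Filter(function(r) r@gene == "GENEX", exemplarCurations())
rep  <- prioritize(vcf, curs, list(tx), SampleContext("M1", "XY"))
rep[, c("allelic_requirement", "class", "matched_consequence", "score",
        "status")]
#>          allelic_requirement                      class          matched_consequence score    status
#> 1   monoallelic_X_hemizygous stop_gained|NMD_triggering decreased gene product level     5 satisfied
#> 2 monoallelic_X_heterozygous stop_gained|NMD_triggering decreased gene product level     5 satisfied
```

The variant is classified as an NMD-triggering stop (its profile row
scores 5 for both decreased and absent gene product), qualifies for both
curations at the default threshold of 4, and — being hemizygous in an XY
sample — satisfies both requirements. Rerun the last block with
`genotypes = "0/1"` and `SampleContext("F1", "XX")` and the single
heterozygote satisfies only the `monoallelic_X_heterozygous` pair; under
`monoallelic_X_hemizygous` it is an unsatisfied carrier
(`X_CARRIER_HET`).

The matrix also drives novel-class inference: if the known pathogenic
classes are NMD-competent stops,

```r
suggestClasses(m, "stop_gained|NMD_triggering")
#> [1] "transcript_ablation"               "splice_acceptor_variant"
#> [3] "splice_donor_variant"              "frameshift_variant|NMD_triggering"
#> [5] "start_lost"                        "transcript_amplification"
#> [7] "TF_binding_site_variant"           "regulatory_region_variant"
```

returns the other classes probable-or-better for the same consequences
(an NMD-competent frameshift chief among them; `transcript_amplification`
enters via the parent "altered level" column — see the vignette).

A thin command-line front end over the same functions lives at
`inst/scripts/gdr.R` (`validate`, `matrix lookup|suggest`, `annotate`,
`prioritize`).

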