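#' @import methods
#' @importFrom utils read.delim write.table head
NULL

#' Vocabulary of inheritance, allelic-requirement and qualifier terms
#'
#' Container built by [buildVocabulary()]. Holds the mode-of-inheritance
#' category hierarchy, the eight harmonized allelic-requirement /
#' Mendelian-inheritance term pairs (which share HPO identifiers), the
#' cross-cutting inheritance qualifiers, and the high-level
#' disease-associated consequence hierarchy.
#'
#' @slot categories data.frame of top-level mode-of-inheritance categories.
#' @slot requirements data.frame with one row per requirement/inheritance
#'   pair: token, inheritance label, HPO curie, chromosome context, copy
#'   requirement and X-zygosity context.
#' @slot qualifiers data.frame of inheritance qualifier terms (parents and
#'   children) with HPO curies.
#' @slot consequences data.frame of the SO disease-associated consequence
#'   hierarchy (matrix columns plus non-column hierarchy nodes).
#' @exportClass Vocabulary
setClass("Vocabulary", representation(
  categories   = "data.frame",
  requirements = "data.frame",
  qualifiers   = "data.frame",
  consequences = "data.frame"
))

#' Gene-disease curation record
#'
#' One gene-disease pair curated with an allelic requirement, optional
#' inheritance qualifiers, the high-level variant consequences associated
#' with disease, and the variant classes already reported pathogenic.
#' Qualifiers are stored canonicalized to HPO curies.
#'
#' @slot gene Gene symbol.
#' @slot geneId Optional gene identifier ("" if absent).
#' @slot disease Disease label.
#' @slot diseaseId Optional disease identifier.
#' @slot allelicRequirement One of the eight requirement tokens (or
#'   "non_mendelian", representable but skipped by the requirement engine).
#' @slot qualifiers Character vector of qualifier HPO curies.
#' @slot consequences Character vector of high-level consequence names.
#' @slot knownClasses Character vector of variant-class keys (base SO term,
#'   optionally suffixed "|NMD_triggering"/"|NMD_escaping").
#' @slot mechanismNote Free-text mechanism note.
#' @slot source Provenance (source and/or date).
#' @exportClass GeneDiseaseCuration
setClass("GeneDiseaseCuration", representation(
  gene               = "character",
  geneId             = "character",
  disease            = "character",
  diseaseId          = "character",
  allelicRequirement = "character",
  qualifiers         = "character",
  consequences       = "character",
  knownClasses       = "character",
  mechanismNote      = "character",
  source             = "character"
))

setValidity("GeneDiseaseCuration", function(object) {
  msg <- character()
  for (s in c("gene", "disease", "allelicRequirement"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single non-NA string", s))
  if (length(msg)) msg else TRUE
})

#' Validation report
#'
#' Ordered list of violations produced by [validateCuration()] or
#' [validateMatrix()]. A record is valid iff the report contains no
#' violations of severity "error"; an empty report means fully clean.
#'
#' @slot violations data.frame with columns severity ("error"/"warning"),
#'   code, message, field.
#' @exportClass ValidationReport
setClass("ValidationReport", representation(violations = "data.frame"))

#' Variant-class by consequence likelihood matrix
#'
#' Rows are SO variant classes (keys such as "missense_variant" or
#' "stop_gained|NMD_triggering"), columns the six high-level
#' disease-associated consequence terms. Cells carry an ordinal likelihood
#' on the 1-5 scale (1 almost never ... 5 almost always) plus a per-cell
#' provenance tag ("paper_text", "expert_default" or "user").
#'
#' @slot scores Integer matrix, rownames = class keys, colnames = the six
#'   consequence names.
#' @slot provenance Character matrix of identical shape.
#' @exportClass ConsequenceMatrix
setClass("ConsequenceMatrix", representation(
  scores     = "matrix",
  provenance = "matrix"
))

setValidity("ConsequenceMatrix", function(object) {
  s <- object@scores
  p <- object@provenance
  msg <- character()
  if (!identical(dim(s), dim(p)) || !identical(dimnames(s), dimnames(p)))
    msg <- c(msg, "scores and provenance must have identical dimnames")
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    msg <- c(msg, "row keys must be unique")
  if (length(msg)) msg else TRUE
})

#' Transcript model
#'
#' Minimal exon/CDS model used for first-principles variant classification
#' and NMD assessment. Exons are genomic 1-based inclusive intervals stored
#' in ascending genomic order; transcript order follows the strand. The
#' regional reference sequence covers [refOffset, refOffset + length - 1]
#' on the forward genomic strand so intronic and flanking bases are known.
#'
#' @slot txId Transcript identifier.
#' @slot gene Gene symbol.
#' @slot chrom Chromosome name.
#' @slot strand "+" or "-".
#' @slot exons IRanges of exons (genomic coordinates, ascending).
#' @slot cdsStart,cdsEnd Genomic CDS bounds (cdsStart <= cdsEnd regardless
#'   of strand).
#' @slot refSeq DNAString, forward-strand regional reference.
#' @slot refOffset Genomic coordinate of refSeq position 1.
#' @exportClass TranscriptModel
setClass("TranscriptModel", representation(
  txId      = "character",
  gene      = "character",
  chrom     = "character",
  strand    = "character",
  exons     = "IRanges",
  cdsStart  = "integer",
  cdsEnd    = "integer",
  refSeq    = "DNAString",
  refOffset = "integer"
))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex), strictly = TRUE))
      msg <- c(msg, "exons must be in ascending genomic order")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must not overlap or touch")
  }
  inExon <- function(p) any(p >= IRanges::start(ex) & p <= IRanges::end(ex))
  if (!is.na(object@cdsStart) && !inExon(object@cdsStart))
    msg <- c(msg, "cdsStart must fall inside an exon")
  if (!is.na(object@cdsEnd) && !inExon(object@cdsEnd))
    msg <- c(msg, "cdsEnd must fall inside an exon")
  if (!is.na(object@cdsStart) && !is.na(object@cdsEnd) &&
      object@cdsStart > object@cdsEnd)
    msg <- c(msg, "cdsStart must be <= cdsEnd (genomic)")
  span <- c(object@refOffset, object@refOffset + length(object@refSeq) - 1L)
  if (IRanges::start(ex)[1L] < span[1L] ||
      IRanges::end(ex)[length(ex)] > span[2L])
    msg <- c(msg, "refSeq must cover the exon span")
  if (length(msg)) msg else TRUE
})

#' A single observed variant
#'
#' VCF-convention representation (1-based position, explicit ref/alt
#' alleles) of one variant call in one sample, with its decoded genotype.
#'
#' @slot chrom Chromosome.
#' @slot pos 1-based position of the first ref base.
#' @slot ref,alt Reference and alternate alleles.
#' @slot gt Raw genotype string (e.g. "0/1", "1|0", "1").
#' @slot zygosity "heterozygous", "homozygous_alt" or "hemizygous".
#' @slot phaseSet Phase-set identifier (NA if unphased).
#' @slot parentalOrigin "maternal", "paternal" or "unknown".
#' @slot deNovo "confirmed", "inherited" or "unknown".
#' @slot hetFraction Heteroplasmy / allele fraction if recorded (NA else).
#' @exportClass Variant
setClass("Variant", representation(
  chrom          = "character",
  pos            = "integer",
  ref            = "character",
  alt            = "character",
  gt             = "character",
  zygosity       = "character",
  phaseSet       = "character",
  parentalOrigin = "character",
  deNovo         = "character",
  hetFraction    = "numeric"
))

#' Variant with assigned class and consequence profile
#'
#' @slot variant The underlying [Variant-class] call.
#' @slot variantClass Matrix row key ("frameshift_variant|NMD_triggering",
#'   "missense_variant", ... or "no_overlap" when the variant misses the
#'   transcript footprint).
#' @slot baseClass Base SO term without NMD suffix.
#' @slot nmd "triggering", "escaping" or "not_applicable".
#' @slot ptcTxPos Transcript coordinate (1-based from transcription start,
#'   reference frame) of the first base of a premature termination codon,
#'   NA when none.
#' @slot allTerms All SO terms that applied (most severe first).
#' @slot profile Named integer vector: the matrix row for variantClass
#'   (all NA for "no_overlap").
#' @exportClass AnnotatedVariant
setClass("AnnotatedVariant", representation(
  variant      = "Variant",
  variantClass = "character",
  baseClass    = "character",
  nmd          = "character",
  ptcTxPos     = "integer",
  allTerms     = "character",
  profile      = "integer"
))

#' Sample context for requirement evaluation
#'
#' @slot sampleId Sample identifier.
#' @slot karyotype "XX", "XY" or "unknown". Unknown karyotype forces
#'   conservative (candidate) verdicts wherever the decision would depend
#'   on sex chromosomes.
#' @slot par data.frame of pseudoautosomal intervals (chrom, start, end;
#'   0-based half-open), X and Y only.
#' @slot genomeBuild Label for the PAR interval provenance.
#' @exportClass SampleContext
setClass("SampleContext", representation(
  sampleId    = "character",
  karyotype   = "character",
  par         = "data.frame",
  genomeBuild = "character"
))

setValidity("SampleContext", function(object) {
  msg <- character()
  if (!object@karyotype %in% c("XX", "XY", "unknown"))
    msg <- c(msg, "karyotype must be XX, XY or unknown")
  p <- object@par
  if (nrow(p)) {
    if (!all(c("chrom", "start", "end") %in% names(p)))
      msg <- c(msg, "par needs chrom/start/end columns")
    else if (!all(.normChrom(p$chrom) %in% c("X", "Y")))
      msg <- c(msg, "PAR intervals must lie on X or Y")
  }
  if (length(msg)) msg else TRUE
})

#' Allelic-requirement decision
#'
#' Verdict of [evaluateRequirement()]: whether the qualifying variants
#' observed in a sample satisfy a curated allelic requirement.
#'
#' @slot status "satisfied", "candidate_partial" or "unsatisfied".
#' @slot rationale Codes from the fixed documented set (see
#'   [rationaleCodes()]).
#' @slot contributing Identifiers of contributing variants.
#' @slot qualifierFlags Flags attached by [applyQualifiers()].
#' @exportClass RequirementDecision
setClass("RequirementDecision", representation(
  status         = "character",
  rationale      = "character",
  contributing   = "character",
  qualifierFlags = "character"
))

setValidity("RequirementDecision", function(object) {
  msg <- character()
  if (!object@status %in% c("satisfied", "candidate_partial", "unsatisfied"))
    msg <- c(msg, "invalid status")
  if (object@status == "satisfied" && length(object@contributing) == 0L)
    msg <- c(msg, "satisfied requires at least one contributing variant")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary:", nrow(object@requirements),
      "requirement/inheritance pairs,",
      nrow(object@qualifiers), "qualifiers,",
      nrow(object@consequences), "consequence terms\n")
})

setMethod("show", "GeneDiseaseCuration", function(object) {
  cat(sprintf("GeneDiseaseCuration: %s - %s [%s]\n",
              object@gene, object@disease, object@allelicRequirement))
  if (length(object@qualifiers))
    cat("  qualifiers:", paste(object@qualifiers, collapse = "; "), "\n")
  if (length(object@consequences))
    cat("  consequences:", paste(object@consequences, collapse = "; "), "\n")
})

setMethod("show", "ValidationReport", function(object) {
  v <- object@violations
  cat("ValidationReport:", nrow(v), "violation(s)\n")
  if (nrow(v)) print(v, row.names = FALSE)
})

setMethod("show", "ConsequenceMatrix", function(object) {
  cat("ConsequenceMatrix:", nrow(object@scores), "variant classes x",
      ncol(object@scores), "consequences\n")
})

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              object@txId, object@gene, object@chrom,
              IRanges::start(object@exons)[1L],
              IRanges::end(object@exons)[length(object@exons)],
              object@strand, length(object@exons)))
})

setMethod("show", "AnnotatedVariant", function(object) {
  v <- object@variant
  cat(sprintf("AnnotatedVariant %s:%d %s>%s -> %s (NMD: %s)\n",
              v@chrom, v@pos, v@ref, v@alt,
              object@variantClass, object@nmd))
})

setMethod("show", "RequirementDecision", function(object) {
  cat("RequirementDecision:", object@status, "\n")
  if (length(object@rationale))
    cat("  rationale:", paste(object@rationale, collapse = "; "), "\n")
  if (length(object@qualifierFlags))
    cat("  flags:", paste(object@qualifierFlags, collapse = "; "), "\n")
})

## ---- accessors ----------------------------------------------------------

#' Accessors for AllelicReq objects
#'
#' Small accessor generics: `violations()` and `isValid()` for
#' [ValidationReport-class]; `scores()` and `cellProvenance()` for
#' [ConsequenceMatrix-class]; `decisionStatus()`, `rationaleCodes()`,
#' `contributingVariants()` and `qualifierFlags()` for
#' [RequirementDecision-class]; `variantClass()` and `nmdFlag()` for
#' [AnnotatedVariant-class].
#'
#' @param x The object.
#' @return The slot content; `isValid()` returns TRUE iff the report has no
#'   error-severity violation.
#' @name accessors
#' @aliases violations isValid scores cellProvenance decisionStatus
#'   rationaleCodes contributingVariants qualifierFlags variantClass nmdFlag
NULL

#' @rdname accessors
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))
#' @rdname accessors
#' @export
setMethod("violations", "ValidationReport", function(x) x@violations)

#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setMethod("isValid", "ValidationReport", function(x) {
  !any(x@violations$severity == "error")
})

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ConsequenceMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("cellProvenance", function(x) standardGeneric("cellProvenance"))
#' @rdname accessors
#' @export
setMethod("cellProvenance", "ConsequenceMatrix", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("decisionStatus", function(x) standardGeneric("decisionStatus"))
#' @rdname accessors
#' @export
setMethod("decisionStatus", "RequirementDecision", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("rationaleCodes", function(x) standardGeneric("rationaleCodes"))
#' @rdname accessors
#' @export
setMethod("rationaleCodes", "RequirementDecision", function(x) x@rationale)

#' @rdname accessors
#' @export
setGeneric("contributingVariants",
           function(x) standardGeneric("contributingVariants"))
#' @rdname accessors
#' @export
setMethod("contributingVariants", "RequirementDecision",
          function(x) x@contributing)

#' @rdname accessors
#' @export
setGeneric("qualifierFlags", function(x) standardGeneric("qualifierFlags"))
#' @rdname accessors
#' @export
setMethod("qualifierFlags", "RequirementDecision", function(x) x@qualifierFlags)

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))
#' @rdname accessors
#' @export
setMethod("variantClass", "AnnotatedVariant", function(x) x@variantClass)

#' @rdname accessors
#' @export
setGeneric("nmdFlag", function(x) standardGeneric("nmdFlag"))
#' @rdname accessors
#' @export
setMethod("nmdFlag", "AnnotatedVariant", function(x) x@nmd)

## internal helpers shared across modules

.normChrom <- function(x) sub("^chr", "", as.character(x))

.newReport <- function(severity = character(), code = character(),
                       message = character(), field = character()) {
  df <- data.frame(severity = severity, code = code, message = message,
                   field = field, stringsAsFactors = FALSE)
  ## deterministic, order-independent presentation
  if (nrow(df))
    df <- df[order(df$severity, df$code, df$field, df$message), , drop = FALSE]
  rownames(df) <- NULL
  new("ValidationReport", violations = df)
}
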