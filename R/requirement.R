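## Allelic-requirement engine: qualifying-variant filtering, zygosity/
## phase/karyotype-aware satisfaction rules, qualifier application, and the
## per-(sample, gene-disease pair) prioritization report.

## Fixed rationale code set (documented in the methods vignette):
.RATIONALE_CODES <- c(
  "NO_QUALIFYING_VARIANTS", "MONOALLELIC_SATISFIED",
  "SECOND_VARIANT_SOUGHT", "POSSIBLE_COMPHET_PHASE_UNKNOWN",
  "COMPHET_TRANS", "COMPHET_CIS", "HOMOZYGOUS_SATISFIED",
  "BIALLELIC_FEMALE_SATISFIED", "HEMIZYGOUS_SATISFIED", "X_CARRIER_HET",
  "HOMOZYGOUS_UNDER_DOMINANT", "KARYOTYPE_IMPOSSIBLE", "UNKNOWN_KARYOTYPE",
  "NOT_IN_PAR", "MT_SATISFIED", "MT_HETEROPLASMY_RECORDED",
  "NON_MENDELIAN_NOT_EVALUATED")

#' Rationale codes used by the requirement engine
#' @return Character vector of all codes [evaluateRequirement()] can emit.
#' @export
requirementRationaleCodes <- function() .RATIONALE_CODES

#' Construct a sample context
#'
#' @param sampleId Sample identifier.
#' @param karyotype "XX", "XY" or "unknown".
#' @param par PAR intervals (data.frame chrom/start/end, 0-based half-open);
#'   default the bundled GRCh38 intervals.
#' @param genomeBuild Build label for the PAR provenance.
#' @return A [SampleContext-class].
#' @export
SampleContext <- function(sampleId, karyotype = "unknown",
                          par = defaultPAR(), genomeBuild = "GRCh38") {
  new("SampleContext", sampleId = as.character(sampleId),
      karyotype = karyotype, par = par, genomeBuild = genomeBuild)
}

#' Bundled GRCh38 pseudoautosomal intervals
#'
#' PAR1 and PAR2 on X and Y in 0-based half-open coordinates (provenance:
#' genome-build documentation). Fully overridable: pass any BED-style
#' data.frame to [SampleContext()].
#'
#' @return data.frame with chrom, start, end, name.
#' @export
defaultPAR <- function() {
  path <- system.file("extdata", "par_GRCh38.bed", package = "AllelicReq",
                      mustWork = TRUE)
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name"))
  df$chrom <- as.character(df$chrom)
  df
}

.inPAR <- function(par, chrom, pos) {
  if (is.null(par) || nrow(par) == 0L) return(rep(FALSE, length(pos)))
  chrom <- .normChrom(chrom)
  vapply(seq_along(pos), function(i) {
    any(.normChrom(par$chrom) == chrom[i] &
        par$start <= pos[i] - 1L & pos[i] - 1L < par$end)
  }, logical(1L))
}

#' Turn annotated variants into requirement-engine observations
#'
#' @param annotated List of [AnnotatedVariant-class].
#' @return data.frame with one row per observation: id, chrom, pos,
#'   zygosity, gt, phase_set, parental_origin, de_novo, het_fraction.
#' @export
asObservations <- function(annotated) {
  if (length(annotated) == 0L)
    return(data.frame(id = character(), chrom = character(),
                      pos = integer(), zygosity = character(),
                      gt = character(), phase_set = character(),
                      parental_origin = character(), de_novo = character(),
                      het_fraction = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(annotated), function(i) {
    av <- annotated[[i]]
    v <- av@variant
    id <- names(annotated)[i]
    if (is.null(id) || !nzchar(id))
      id <- sprintf("%s:%d:%s>%s", v@chrom, v@pos, v@ref, v@alt)
    data.frame(id = id, chrom = .normChrom(v@chrom), pos = v@pos,
               zygosity = v@zygosity, gt = v@gt, phase_set = v@phaseSet,
               parental_origin = v@parentalOrigin, de_novo = v@deNovo,
               het_fraction = v@hetFraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter variants whose consequence profile matches a curation
#'
#' Keeps annotated variants whose likelihood for at least one of the
#' curation's disease-associated consequences reaches the threshold.
#'
#' @param annotated List of [AnnotatedVariant-class].
#' @param curation A [GeneDiseaseCuration-class] with a non-empty
#'   disease-associated consequence set.
#' @param matrix A [ConsequenceMatrix-class].
#' @param threshold Integer 1-5 (default 4, "probable").
#' @return The qualifying subset, with a per-variant rationale data.frame
#'   (id, matched_consequence, score) in `attr(, "rationale")`.
#' @export
qualifyingVariants <- function(annotated, curation,
                               matrix = defaultMatrix(), threshold = 4L) {
  if (!threshold %in% 1:5) stop("threshold must be in 1-5", call. = FALSE)
  if (length(curation@consequences) == 0L)
    stop("curation has no disease-associated consequences; derive them ",
         "from known pathogenic classes with inferConsequences()",
         call. = FALSE)
  cols <- vapply(curation@consequences, .resolveConsequence, character(1L))
  keep <- logical(length(annotated))
  rat <- list()
  for (i in seq_along(annotated)) {
    av <- annotated[[i]]
    if (av@variantClass == "no_overlap" || anyNA(av@profile)) next
    sub <- av@profile[cols]
    j <- which.max(sub)
    if (sub[j] >= threshold) {
      keep[i] <- TRUE
      v <- av@variant
      rat[[length(rat) + 1L]] <- data.frame(
        id = sprintf("%s:%d:%s>%s", v@chrom, v@pos, v@ref, v@alt),
        matched_consequence = cols[j], score = unname(sub[j]),
        stringsAsFactors = FALSE)
    }
  }
  out <- annotated[keep]
  attr(out, "rationale") <- if (length(rat)) do.call(rbind, rat) else
    data.frame(id = character(), matched_consequence = character(),
               score = integer(), stringsAsFactors = FALSE)
  out
}

## haplotype relation of two heterozygous observations:
## "trans", "cis" or "unknown"
.pairPhase <- function(o1, o2) {
  ## haploid calls are located on a chromosome copy: two on the same copy
  ## are cis, two on different copies (X vs Y in the PAR) are trans; a
  ## diploid het call carries no copy location, so its relation to a
  ## haploid call is unknown
  if (o1$zygosity == "hemizygous" && o2$zygosity == "hemizygous")
    return(if (o1$chrom != o2$chrom) "trans" else "cis")
  if (o1$zygosity == "hemizygous" || o2$zygosity == "hemizygous" ||
      o1$chrom != o2$chrom)
    return("unknown")
  if (is.na(o1$phase_set) || is.na(o2$phase_set) ||
      o1$phase_set != o2$phase_set) return("unknown")
  hap <- function(gt) {
    a <- strsplit(gt, "|", fixed = TRUE)[[1L]]
    if (length(a) != 2L) return(NA_integer_)
    which(a != "0")[1L]
  }
  h1 <- hap(o1$gt); h2 <- hap(o2$gt)
  if (is.na(h1) || is.na(h2)) return("unknown")
  if (h1 == h2) "cis" else "trans"
}

.decision <- function(status, rationale = character(),
                      contributing = character(), flags = character()) {
  new("RequirementDecision", status = status,
      rationale = unique(rationale), contributing = contributing,
      qualifierFlags = flags)
}

## biallelic counting over one diploid locus set; allele-contributing
## observations are hom (2 alleles), het and hemizygous (1 allele each,
## hemizygous arises for PAR loci called haploid per sex-chromosome copy)
.biallelicVerdict <- function(obs) {
  hom <- obs[obs$zygosity == "homozygous_alt", , drop = FALSE]
  single <- obs[obs$zygosity %in% c("heterozygous", "hemizygous"), ,
                drop = FALSE]
  if (nrow(hom))
    return(.decision("satisfied", "HOMOZYGOUS_SATISFIED", hom$id[1L]))
  if (nrow(single) >= 2L) {
    phases <- character()
    for (i in seq_len(nrow(single) - 1L))
      for (j in (i + 1L):nrow(single))
        phases <- c(phases,
                    .pairPhase(single[i, , drop = FALSE],
                               single[j, , drop = FALSE]))
    if (any(phases == "trans"))
      return(.decision("satisfied", "COMPHET_TRANS", single$id))
    if (all(phases == "cis"))
      return(.decision("unsatisfied", "COMPHET_CIS", character()))
    return(.decision("candidate_partial", "POSSIBLE_COMPHET_PHASE_UNKNOWN",
                     single$id))
  }
  if (nrow(single) == 1L)
    return(.decision("candidate_partial", "SECOND_VARIANT_SOUGHT",
                     single$id))
  .decision("unsatisfied", "NO_QUALIFYING_VARIANTS")
}

## are the heterozygous observations provably all on one haplotype?
.allCis <- function(hets) {
  if (nrow(hets) < 2L) return(FALSE)
  for (i in seq_len(nrow(hets) - 1L))
    for (j in (i + 1L):nrow(hets))
      if (.pairPhase(hets[i, , drop = FALSE],
                     hets[j, , drop = FALSE]) != "cis") return(FALSE)
  TRUE
}

#' Decide whether observations satisfy an allelic requirement
#'
#' Applies the rule table for the eight requirement tokens (see the methods
#' vignette for the full table): monoallelic requirements are satisfied by
#' a single qualifying allele; biallelic requirements need a homozygous
#' call or a trans compound heterozygote (phase-set-aware; an unphased pair
#' is a candidate, a proven cis pair is not satisfied, a lone heterozygote
#' directs the search to a second contributory variant or alternative
#' cause); X-linked recessive requirements are satisfied hemizygous in XY
#' or biallelic in XX, with an XX single heterozygote flagged as a carrier;
#' Y-linked requirements are karyotype-impossible in XX (a rationale, not
#' an exception); mitochondrial requirements are satisfied by any
#' qualifying MT variant, recording heteroplasmy when present; PAR
#' requirements restrict observations to the pseudoautosomal intervals and
#' then count autosomal-fashion across the X and Y copies. With an unknown
#' karyotype the engine returns a candidate verdict wherever the decision
#' would depend on the sex chromosomes.
#'
#' @param observations data.frame as produced by [asObservations()] (the
#'   qualifying variants for one gene-disease pair).
#' @param requirement A requirement token (see [requirementTokens()]).
#' @param context A [SampleContext-class].
#' @return A [RequirementDecision-class].
#' @examples
#' ctx <- SampleContext("S1", "XY")
#' obs <- data.frame(id = "v1", chrom = "X", pos = 500L,
#'                   zygosity = "hemizygous", gt = "1",
#'                   phase_set = NA_character_, parental_origin = "unknown",
#'                   de_novo = "unknown", het_fraction = NA_real_)
#' decisionStatus(evaluateRequirement(obs, "monoallelic_X_hemizygous", ctx))
#' @export
evaluateRequirement <- function(observations, requirement, context) {
  stopifnot(is(context, "SampleContext"))
  tokens <- .REQUIREMENTS$token
  if (identical(requirement, "non_mendelian"))
    return(.decision("unsatisfied", "NON_MENDELIAN_NOT_EVALUATED"))
  if (!requirement %in% tokens)
    stop("unknown allelic requirement '", requirement, "'; nearest: ",
         paste(.nearest(requirement, tokens), collapse = ", "),
         call. = FALSE)
  obs <- observations
  if (is.null(obs) || nrow(obs) == 0L)
    return(.decision("unsatisfied", "NO_QUALIFYING_VARIANTS"))
  kt <- context@karyotype
  hets <- obs[obs$zygosity == "heterozygous", , drop = FALSE]
  homs <- obs[obs$zygosity == "homozygous_alt", , drop = FALSE]
  hemi <- obs[obs$zygosity == "hemizygous", , drop = FALSE]

  switch(requirement,
    monoallelic_autosomal = {
      .decision("satisfied", "MONOALLELIC_SATISFIED", obs$id)
    },
    biallelic_autosomal = .biallelicVerdict(obs),
    monoallelic_X_heterozygous = {
      extra <- if (kt == "XX" && nrow(homs))
        "HOMOZYGOUS_UNDER_DOMINANT" else character()
      .decision("satisfied", c("MONOALLELIC_SATISFIED", extra), obs$id)
    },
    monoallelic_X_hemizygous = {
      if (kt == "XY") {
        .decision("satisfied", "HEMIZYGOUS_SATISFIED", obs$id)
      } else if (kt == "XX") {
        if (nrow(homs))
          .decision("satisfied", "HOMOZYGOUS_SATISFIED", homs$id[1L])
        else if (nrow(hets) >= 2L && !.allCis(hets))
          .decision("satisfied", "BIALLELIC_FEMALE_SATISFIED", hets$id)
        else
          .decision("unsatisfied", "X_CARRIER_HET")
      } else {
        if (nrow(homs))
          .decision("satisfied", "HOMOZYGOUS_SATISFIED", homs$id[1L])
        else if (nrow(hets) >= 2L && !.allCis(hets))
          .decision("satisfied", "BIALLELIC_FEMALE_SATISFIED", hets$id)
        else
          .decision("candidate_partial", "UNKNOWN_KARYOTYPE", obs$id)
      }
    },
    monoallelic_Y_hemizygous = {
      if (kt == "XY")
        .decision("satisfied", "HEMIZYGOUS_SATISFIED", obs$id)
      else if (kt == "XX")
        .decision("unsatisfied", "KARYOTYPE_IMPOSSIBLE")
      else
        .decision("candidate_partial", "UNKNOWN_KARYOTYPE", obs$id)
    },
    mitochondrial = {
      extra <- if (any(!is.na(obs$het_fraction)))
        "MT_HETEROPLASMY_RECORDED" else character()
      .decision("satisfied", c("MT_SATISFIED", extra), obs$id)
    },
    monoallelic_PAR = ,
    biallelic_PAR = {
      inside <- .inPAR(context@par, obs$chrom, obs$pos)
      codes <- if (any(!inside)) "NOT_IN_PAR" else character()
      obsP <- obs[inside, , drop = FALSE]
      d <- if (requirement == "monoallelic_PAR") {
        if (nrow(obsP))
          .decision("satisfied", "MONOALLELIC_SATISFIED", obsP$id)
        else .decision("unsatisfied", "NO_QUALIFYING_VARIANTS")
      } else .biallelicVerdict(obsP)
      .decision(d@status, c(d@rationale, codes), d@contributing)
    })
}

#' Apply inheritance qualifiers to a requirement decision
#'
#' Requires heterozygosity downgrades an XY hemizygous satisfaction to a
#' candidate (hemizygous males seldom manifest the full phenotype);
#' imprinting qualifiers check parental origin against the imprinting
#' direction ("with maternal imprinting" silences the maternal copy, so
#' disease needs a paternally inherited variant, and vice versa); typically
#' de novo adds a supportive flag for confirmed de novo variants and a
#' caution flag for confirmed inherited ones; sex-limited expression flags
#' a decision in the non-manifesting karyotype; penetrance, onset,
#' anticipation, mosaicism and contiguous-gene qualifiers attach
#' informational flags only and never change the satisfaction status.
#'
#' @param decision A [RequirementDecision-class] from
#'   [evaluateRequirement()].
#' @param qualifiers Character vector of qualifier HPO curies (labels are
#'   accepted and canonicalized).
#' @param observations The observations passed to [evaluateRequirement()].
#' @param context A [SampleContext-class].
#' @return The decision with `qualifierFlags` (and possibly a downgraded
#'   status).
#' @export
applyQualifiers <- function(decision, qualifiers, observations, context) {
  if (length(qualifiers) == 0L) return(decision)
  vocab <- buildVocabulary()
  qualifiers <- vapply(qualifiers, function(q) {
    if (grepl(.CURIE_RE, q)) return(q)
    i <- which(tolower(vocab@qualifiers$label) == tolower(trimws(q)))
    if (length(i)) vocab@qualifiers$curie[i[1L]] else q
  }, character(1L), USE.NAMES = FALSE)
  flags <- decision@qualifierFlags
  status <- decision@status
  obs <- observations
  contrib <- if (!is.null(obs) && nrow(obs))
    obs[obs$id %in% decision@contributing, , drop = FALSE] else obs

  if ("HP:0034343" %in% qualifiers && status == "satisfied" &&
      context@karyotype == "XY" && !is.null(contrib) && nrow(contrib) &&
      any(contrib$zygosity == "hemizygous")) {
    status <- "candidate_partial"
    flags <- c(flags, "REQUIRES_HET_HEMIZYGOUS_DOWNGRADE")
  }
  impDir <- if ("HP:0012275" %in% qualifiers) "paternal"      # maternal copy silenced
            else if ("HP:0012274" %in% qualifiers) "maternal" # paternal copy silenced
            else NA_character_
  if (any(c("HP:0034338", "HP:0012275", "HP:0012274") %in% qualifiers) &&
      !is.null(contrib) && nrow(contrib)) {
    origins <- contrib$parental_origin
    if (is.na(impDir)) {
      flags <- c(flags, "IMPRINTED_INFO")
    } else if (all(origins == "unknown")) {
      flags <- c(flags, "IMPRINTING_ORIGIN_UNKNOWN")
    } else if (any(origins != "unknown" & origins != impDir)) {
      flags <- c(flags, "ORIGIN_INCONSISTENT_WITH_IMPRINTING")
    } else {
      flags <- c(flags, "ORIGIN_CONSISTENT_WITH_IMPRINTING")
    }
  }
  if ("HP:0025352" %in% qualifiers && !is.null(contrib) && nrow(contrib)) {
    if (any(contrib$de_novo == "confirmed"))
      flags <- c(flags, "DE_NOVO_SUPPORTIVE")
    if (any(contrib$de_novo == "inherited"))
      flags <- c(flags, "INHERITED_DESPITE_TYPICALLY_DE_NOVO")
  }
  if ("HP:0001475" %in% qualifiers && context@karyotype == "XX")
    flags <- c(flags, "SEX_LIMITED_NOT_EXPECTED")
  if ("HP:0034344" %in% qualifiers && context@karyotype == "XY")
    flags <- c(flags, "SEX_LIMITED_NOT_EXPECTED")
  if ("HP:0001470" %in% qualifiers &&
      !any(c("HP:0001475", "HP:0034344") %in% qualifiers))
    flags <- c(flags, "SEX_LIMITED_INFO")
  info <- c("HP:0003829" = "INFO_PENETRANCE", "HP:4000159" = "INFO_PENETRANCE",
            "HP:4000158" = "INFO_PENETRANCE", "HP:0034950" = "INFO_PENETRANCE",
            "HP:0034857" = "INFO_ONSET", "HP:0003831" = "INFO_ONSET",
            "HP:0003743" = "INFO_ANTICIPATION",
            "HP:0001442" = "INFO_MOSAICISM",
            "HP:0001466" = "INFO_CONTIGUOUS_GENE")
  flags <- c(flags, unname(info[intersect(qualifiers, names(info))]))
  .decision(status, decision@rationale, decision@contributing,
            unique(flags))
}

#' Prioritize variants against a set of gene-disease curations
#'
#' For each gene-disease pair: classify the sample's variants on the
#' gene's transcript model, keep the qualifying subset, evaluate the
#' allelic requirement and apply the curation's qualifiers. The same
#' variant set may satisfy one pair and not another (e.g. a hemizygous X
#' variant under an X-linked recessive pair vs a heterozygous one under an
#' X-linked dominant pair for the same gene).
#'
#' @param vcfPath VCF for the sample.
#' @param curations List of [GeneDiseaseCuration-class].
#' @param transcripts List of [TranscriptModel-class].
#' @param context A [SampleContext-class].
#' @param matrix A [ConsequenceMatrix-class].
#' @param threshold Qualifying-likelihood threshold (default 4).
#' @return data.frame with one row per (pair, qualifying variant) - or a
#'   single summary row for pairs without qualifying variants - with
#'   columns sample, gene, disease, allelic_requirement, variant, class,
#'   nmd_flag, matched_consequence, score, status, rationale_codes,
#'   qualifier_flags.
#' @export
prioritize <- function(vcfPath, curations, transcripts, context,
                       matrix = defaultMatrix(), threshold = 4L) {
  variants <- readVariants(vcfPath, context@sampleId)
  txGenes <- vapply(transcripts, function(t) t@gene, character(1L))
  rows <- list()
  addRow <- function(cur, variant = "", class = "", nmdf = "",
                     matched = "", score = NA_integer_, status, rat, flags) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = context@sampleId, gene = cur@gene, disease = cur@disease,
      allelic_requirement = cur@allelicRequirement, variant = variant,
      class = class, nmd_flag = nmdf, matched_consequence = matched,
      score = score, status = status,
      rationale_codes = paste(rat, collapse = ";"),
      qualifier_flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (cur in curations) {
    i <- which(txGenes == cur@gene)
    if (!length(i)) {
      addRow(cur, status = "no transcript model", rat = character(),
             flags = character())
      next
    }
    tx <- transcripts[[i[1L]]]
    onTx <- Filter(function(v) .normChrom(v@chrom) == .normChrom(tx@chrom),
                   variants)
    annotated <- lapply(onTx, classifyVariant, tx = tx, matrix = matrix)
    names(annotated) <- names(onTx)
    annotated <- Filter(function(a) a@variantClass != "no_overlap",
                        annotated)
    consequences <- cur@consequences
    if (length(consequences) == 0L && length(cur@knownClasses))
      consequences <- names(which(
        inferConsequences(matrix, cur@knownClasses) >= threshold))
    curEff <- cur
    curEff@consequences <- consequences
    qual <- if (length(consequences))
      qualifyingVariants(annotated, curEff, matrix, threshold)
    else structure(list(), rationale = data.frame(
      id = character(), matched_consequence = character(),
      score = integer(), stringsAsFactors = FALSE))
    obs <- asObservations(qual)
    dec <- evaluateRequirement(obs, cur@allelicRequirement, context)
    dec <- applyQualifiers(dec, cur@qualifiers, obs, context)
    rat <- attr(qual, "rationale")
    if (length(qual) == 0L) {
      addRow(cur, status = dec@status, rat = dec@rationale,
             flags = dec@qualifierFlags)
    } else {
      for (k in seq_along(qual)) {
        av <- qual[[k]]
        v <- av@variant
        id <- sprintf("%s:%d:%s>%s", v@chrom, v@pos, v@ref, v@alt)
        r <- rat[rat$id == id, , drop = FALSE]
        addRow(cur, variant = id, class = av@variantClass, nmdf = av@nmd,
               matched = if (nrow(r)) r$matched_consequence[1L] else "",
               score = if (nrow(r)) r$score[1L] else NA_integer_,
               status = dec@status, rat = dec@rationale,
               flags = dec@qualifierFlags)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$disease, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
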