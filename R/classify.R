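## First-principles variant classification on transcript models, NMD
## assessment of premature termination codons, VEP CSQ parsing, VCF input.
##
## Conventions: VCF positions are 1-based; transcript coordinates are
## 1-based from the transcription start in transcript orientation; the
## canonical splice positions are intronic +/-1,2 (donor/acceptor), the
## splice region is intronic positions 3-8 plus the last 3 exonic bases
## flanking each junction.

#' Construct a variant call
#'
#' @param chrom,pos,ref,alt Site and alleles (VCF convention).
#' @param gt Genotype string ("0/1", "1|0", "1", ...).
#' @param phaseSet Phase-set identifier (NA when unphased).
#' @param parentalOrigin "maternal", "paternal" or "unknown".
#' @param deNovo "confirmed", "inherited" or "unknown".
#' @param hetFraction Optional allele / heteroplasmy fraction.
#' @return A [Variant-class].
#' @export
Variant <- function(chrom, pos, ref, alt, gt = "0/1",
                    phaseSet = NA_character_, parentalOrigin = "unknown",
                    deNovo = "unknown", hetFraction = NA_real_) {
  if (identical(ref, alt)) stop("ref and alt alleles must differ")
  new("Variant", chrom = as.character(chrom), pos = as.integer(pos),
      ref = toupper(ref), alt = toupper(alt), gt = as.character(gt),
      zygosity = .gtZygosity(gt), phaseSet = as.character(phaseSet),
      parentalOrigin = parentalOrigin, deNovo = deNovo,
      hetFraction = as.numeric(hetFraction))
}

.gtZygosity <- function(gt) {
  a <- strsplit(gt, "[/|]")[[1L]]
  if (length(a) == 1L) return(if (a == "0") "ref" else "hemizygous")
  if (all(a == "0")) return("ref")
  if (all(a != "0" & a == a[1L])) return("homozygous_alt")
  "heterozygous"
}

## minimal representation: trim shared suffix then prefix, then left-align
## pure indels against the regional reference
.normalizeAllele <- function(tx, pos, ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (xor(nchar(ref) == 0L, nchar(alt) == 0L)) {
    ins <- nchar(ref) == 0L
    seqv <- if (ins) alt else ref
    guard <- 0L
    while (guard < 200L && pos - 1L >= tx@refOffset) {
      lastb <- substr(seqv, nchar(seqv), nchar(seqv))
      prevb <- .refBases(tx, pos - 1L, 1L)
      if (lastb != prevb) break
      seqv <- paste0(prevb, substr(seqv, 1L, nchar(seqv) - 1L))
      pos <- pos - 1L
      guard <- guard + 1L
    }
    if (ins) alt <- seqv else ref <- seqv
  }
  list(pos = pos, ref = ref, alt = alt)
}

## intronic offsets of genomic position p in transcript orientation:
## NULL if exonic/outside; else list(donor = dist from donor side (1 = first
## intronic base), acceptor = dist from acceptor side)
.intronOffsets <- function(tx, p) {
  et <- .txExonTable(tx)
  n <- nrow(et)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    if (tx@strand == "+") {
      lo <- et$gend[i] + 1L; hi <- et$gstart[i + 1L] - 1L
      if (p >= lo && p <= hi)
        return(list(donor = p - lo + 1L, acceptor = hi - p + 1L))
    } else {
      hi <- et$gend[i + 1L] + 1L; lo2 <- et$gstart[i] - 1L
      if (p >= hi && p <= lo2)
        return(list(donor = lo2 - p + 1L, acceptor = p - hi + 1L))
    }
  }
  NULL
}

## distance (bases) from exonic transcript position t to its nearest
## junction-adjacent exon edge; Inf when the adjacent feature is a
## transcript end rather than an intron
.exonEdgeDist <- function(tx, t) {
  et <- .txExonTable(tx)
  n <- nrow(et)
  i <- which(t >= et$tstart & t <= et$tend)[1L]
  up <- if (i > 1L) t - et$tstart[i] + 1L else Inf
  dn <- if (i < n) et$tend[i] - t + 1L else Inf
  min(up, dn)
}

.mostSevere <- function(terms) {
  terms[which.min(match(terms, .VEP_CONSEQUENCES))]
}

#' Assess NMD competence of a premature termination codon
#'
#' A PTC escapes nonsense-mediated decay when (a) the transcript has a
#' single exon, (b) the PTC lies in the final exon, or (c) the PTC lies
#' within the last 50 nucleotides upstream of the final exon-exon junction
#' (boundary inclusive: exactly 50 nt escapes). It triggers NMD otherwise.
#' Optionally, a start-proximal escape clause (reinitiation near the start
#' codon) can be switched on; it is off by default.
#'
#' @param ptcTxPos Transcript coordinate (1-based from transcription start)
#'   of the first base of the termination codon.
#' @param tx A [TranscriptModel-class].
#' @param startProximalEscape If TRUE, a PTC within `startProximalNt` of
#'   the translation start also escapes. Default FALSE.
#' @param startProximalNt Width of the start-proximal window (coding
#'   nucleotides; default 150).
#' @return "triggering" or "escaping".
#' @examples
#' tx <- synthTranscript(exonLengths = c(90, 120, 90),
#'                       intronLengths = c(50, 50), seed = 1)
#' assessNMD(30L, tx)
#' @export
assessNMD <- function(ptcTxPos, tx, startProximalEscape = FALSE,
                      startProximalNt = 150L) {
  cds <- .cdsTxRange(tx)
  if (is.na(cds[1L])) stop("transcript has no CDS", call. = FALSE)
  if (is.na(ptcTxPos) || ptcTxPos < cds[1L] || ptcTxPos > .txLength(tx))
    stop("PTC position outside the CDS/transcript", call. = FALSE)
  if (startProximalEscape && ptcTxPos - cds[1L] < startProximalNt)
    return("escaping")
  if (length(tx@exons) == 1L) return("escaping")
  junction <- .finalJunctionTx(tx)
  if (ptcTxPos > junction) return("escaping")       # final exon
  if (junction - ptcTxPos <= 50L) return("escaping") # junction-proximal
  "triggering"
}

#' Classify a variant on a transcript from first principles
#'
#' Normalizes the alleles (shared-suffix/prefix trimming, left alignment of
#' pure indels), checks the reference allele against the model's regional
#' reference, then assigns one SO base class by splicing and translating
#' the edited CDS. PTC-producing classes (stop_gained, frameshift_variant)
#' carry the PTC transcript coordinate and are split by NMD competence into
#' matrix row keys such as "stop_gained|NMD_triggering". Variants outside
#' the transcript footprint yield class "no_overlap". All applicable terms
#' are retained in `allTerms`; `variantClass` is the most severe.
#'
#' @param variant A [Variant-class].
#' @param tx A [TranscriptModel-class].
#' @param matrix Optional [ConsequenceMatrix-class] used to attach the
#'   consequence profile (default: the bundled matrix).
#' @return An [AnnotatedVariant-class].
#' @export
classifyVariant <- function(variant, tx, matrix = defaultMatrix()) {
  stopifnot(is(variant, "Variant"), is(tx, "TranscriptModel"))
  if (.normChrom(variant@chrom) != .normChrom(tx@chrom))
    return(.annotate(variant, "no_overlap", "not_applicable", NA_integer_,
                     "no_overlap", matrix))
  nv <- .normalizeAllele(tx, variant@pos, variant@ref, variant@alt)
  pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
  isIns <- nchar(ref) == 0L
  if (!isIns && .refBases(tx, pos, nchar(ref)) != ref)
    stop(sprintf("reference mismatch at %s:%d: expected '%s', model has '%s'",
                 tx@chrom, pos, ref, .refBases(tx, pos, nchar(ref))),
         call. = FALSE)
  et <- .txExonTable(tx)
  span <- c(min(et$gstart), max(et$gend))
  gAff <- if (isIns) c(pos - 1L, pos) else pos:(pos + nchar(ref) - 1L)
  if (max(gAff) < span[1L] || min(gAff) > span[2L])
    return(.annotate(variant, "no_overlap", "not_applicable", NA_integer_,
                     "no_overlap", matrix))

  terms <- character()
  intronic <- logical(length(gAff))
  for (k in seq_along(gAff)) {
    off <- .intronOffsets(tx, gAff[k])
    if (is.null(off)) next
    intronic[k] <- TRUE
    if (off$donor <= 2L) terms <- c(terms, "splice_donor_variant")
    else if (off$acceptor <= 2L) terms <- c(terms, "splice_acceptor_variant")
    else if (off$donor <= 8L || off$acceptor <= 8L)
      terms <- c(terms, "splice_region_variant")
    else terms <- c(terms, "intron_variant")
  }
  tAff <- .genomicToTx(tx, gAff)
  exonic <- !is.na(tAff)
  allExonic <- all(exonic)
  cds <- .cdsTxRange(tx)
  ptc <- NA_integer_

  if (allExonic && !any(intronic)) {
    tA <- min(tAff); tB <- max(tAff)
    if (any(vapply(tAff, function(t) is.finite(.exonEdgeDist(tx, t)) &&
                     .exonEdgeDist(tx, t) <= 3L, logical(1L))))
      terms <- c(terms, "splice_region_variant")
    if (is.na(cds[1L])) {
      terms <- c(terms, "non_coding_transcript_exon_variant")
    } else if (!isIns && (tB < cds[1L] || tA > cds[2L])) {
      terms <- c(terms, if (tB < cds[1L]) "5_prime_UTR_variant"
                        else "3_prime_UTR_variant")
    } else if (isIns && (tB <= cds[1L] || tA >= cds[2L] + 1L) &&
               !(tA >= cds[1L] && tB <= cds[2L])) {
      terms <- c(terms, if (tB <= cds[1L]) "5_prime_UTR_variant"
                        else "3_prime_UTR_variant")
    } else {
      cod <- .codingEffect(tx, pos, ref, alt, tAff, cds)
      terms <- c(terms, cod$terms)
      ptc <- cod$ptc
    }
  } else if (any(exonic) && any(intronic)) {
    ## straddles an exon/intron boundary: splice terms above already apply;
    ## a disrupted junction without a canonical-site hit is splice region
    if (!length(intersect(terms, c("splice_donor_variant",
                                   "splice_acceptor_variant"))))
      terms <- c(terms, "splice_region_variant")
  }
  if (!length(terms)) terms <- "intron_variant"
  terms <- unique(terms)
  base <- .mostSevere(terms)

  nmd <- "not_applicable"
  key <- base
  if (base %in% .NMD_SPLIT && !is.na(ptc)) {
    nmd <- assessNMD(ptc, tx)
    key <- paste0(base, "|NMD_", nmd)
  } else if (base %in% .NMD_SPLIT) {
    ## PTC-producing class whose PTC falls beyond the transcript end:
    ## no degradable junction downstream, treat as escaping
    nmd <- "escaping"
    key <- paste0(base, "|NMD_", nmd)
  }
  .annotate(variant, key, nmd, ptc,
            terms[order(match(terms, .VEP_CONSEQUENCES))], matrix)
}

## coding-region effect of an entirely exonic edit; returns base terms + PTC
.codingEffect <- function(tx, pos, ref, alt, tAff, cds) {
  S <- as.character(.splicedSeq(tx))
  isIns <- nchar(ref) == 0L
  if (tx@strand == "-") {
    refT <- if (nchar(ref)) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref))) else ""
    altT <- if (nchar(alt)) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt))) else ""
  } else { refT <- ref; altT <- alt }
  if (isIns) {
    ## insertion between genomic pos-1 and pos; in transcript orientation it
    ## falls after min(tAff) (the two flanking transcript positions differ
    ## by strand)
    after <- min(tAff)
    edited <- paste0(substr(S, 1L, after), altT,
                     substr(S, after + 1L, nchar(S)))
    tEd <- after + 1L
    refLenT <- 0L
  } else {
    tEd <- min(tAff); tEnd <- max(tAff)
    edited <- paste0(substr(S, 1L, tEd - 1L), altT,
                     substr(S, tEnd + 1L, nchar(S)))
    refLenT <- nchar(refT)
  }
  dlen <- nchar(altT) - refLenT
  c1 <- cds[1L]; c2 <- cds[2L]
  terms <- character()
  ptc <- NA_integer_

  refCds <- substr(S, c1, c2)
  refProt <- as.character(Biostrings::translate(
    Biostrings::DNAString(refCds), no.init.codon = TRUE))

  if (dlen == 0L) {
    altCds <- substr(edited, c1, c2)
    altProt <- as.character(Biostrings::translate(
      Biostrings::DNAString(altCds), no.init.codon = TRUE))
    rp <- strsplit(refProt, "")[[1L]]; ap <- strsplit(altProt, "")[[1L]]
    diff <- which(rp != ap)
    if (!length(diff)) {
      codon <- ceiling((tEd - c1 + 1L) / 3)
      terms <- c(terms, if (codon >= length(rp) && rp[length(rp)] == "*")
        "stop_retained_variant" else "synonymous_variant")
    } else {
      i <- diff[1L]
      if (i == 1L && rp[1L] == "M") terms <- c(terms, "start_lost")
      else if (ap[i] == "*" && i < length(rp)) {
        terms <- c(terms, "stop_gained")
        ptc <- c1 + (i - 1L) * 3L
      } else if (rp[i] == "*") terms <- c(terms, "stop_lost")
      else terms <- c(terms, "missense_variant")
    }
  } else {
    editA <- tEd; editB <- if (isIns) tEd - 1L else tEd + refLenT - 1L
    if (editA <= c1 + 2L && (isIns || editB >= c1))
      terms <- c(terms, "start_lost")
    if (dlen %% 3L != 0L) {
      terms <- c(terms, "frameshift_variant")
      ptc <- .findPtc(edited, c1, tEd, nchar(altT), dlen)
    } else {
      terms <- c(terms, if (dlen > 0L) "inframe_insertion"
                        else "inframe_deletion")
      if (!isIns && editA <= c2 && editB >= c2 - 2L)
        terms <- c(terms, "stop_lost")
      p <- .findPtc(edited, c1, tEd, nchar(altT), dlen)
      refStop <- c2 - 2L
      if (!is.na(p) && p < refStop) {
        terms <- c(terms, "stop_gained")
        ptc <- p
      }
    }
  }
  list(terms = terms, ptc = ptc)
}

## first in-frame stop at/after the edit, in reference transcript
## coordinates (edited coordinates shifted back by dlen past the edit)
.findPtc <- function(edited, c1, tEd, altLen, dlen) {
  tail <- substr(edited, c1, nchar(edited))
  usable <- (nchar(tail) %/% 3L) * 3L
  if (usable < 3L) return(NA_integer_)
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(tail, 1L, usable)), no.init.codon = TRUE))
  stops <- which(strsplit(prot, "")[[1L]] == "*")
  if (!length(stops)) return(NA_integer_)
  starts <- c1 + (stops - 1L) * 3L            # edited coordinates
  varCodonStart <- c1 + ((tEd - c1) %/% 3L) * 3L
  starts <- starts[starts >= varCodonStart]
  if (!length(starts)) return(NA_integer_)
  e <- starts[1L]
  if (e >= tEd + altLen) e - dlen else e
}

.annotate <- function(variant, key, nmd, ptc, allTerms, matrix) {
  base <- sub("\\|.*$", "", key)
  profile <- if (!is.null(matrix) && key %in% rownames(matrix@scores)) {
    p <- matrix@scores[key, ]
    storage.mode(p) <- "integer"
    p
  } else {
    p <- rep(NA_integer_, length(.matrixColumns()))
    names(p) <- .matrixColumns()
    p
  }
  new("AnnotatedVariant", variant = variant, variantClass = key,
      baseClass = base, nmd = nmd, ptcTxPos = as.integer(ptc),
      allTerms = allTerms, profile = profile)
}

#' Pick the most severe SO term from a VEP-style CSQ annotation
#'
#' @param annotation Ampersand-separated SO terms
#'   (e.g. "splice_donor_variant&intron_variant").
#' @param severityOrder Recognized terms, most severe first. The default is
#'   the matrix-resolvable base set (the VEP consequence set minus the
#'   redundant terms culled from the matrix rows), so terms like
#'   "downstream_gene_variant" map to "function_uncertain".
#' @return The most severe recognized term; if no term is recognized,
#'   "function_uncertain" with a warning.
#' @export
parseVepConsequences <- function(annotation,
                                 severityOrder = setdiff(.VEP_CONSEQUENCES,
                                                         .CULLED)) {
  if (length(annotation) != 1L || is.na(annotation) ||
      !nzchar(trimws(annotation)))
    stop("empty consequence annotation", call. = FALSE)
  terms <- trimws(strsplit(annotation, "&", fixed = TRUE)[[1L]])
  known <- terms[terms %in% severityOrder]
  if (!length(known)) {
    warning("no recognized SO term in '", annotation,
            "'; mapping to function_uncertain", call. = FALSE)
    return("function_uncertain")
  }
  known[which.min(match(known, severityOrder))]
}

#' Read variant calls for one sample from a VCF
#'
#' Decodes genotypes: "0/1" heterozygous, "1/1" homozygous-alt, a single
#' haploid index "1" hemizygous; "./." and hom-ref calls are excluded with
#' a logged skip. Phased separators are preserved via the phase set (FORMAT
#' PS when present, else a file-level default). Optional INFO keys PO
#' (parental origin), DN (de novo status: confirmed/inherited/unknown) and
#' HF (heteroplasmy / allele fraction) are carried onto the variants.
#'
#' @param vcfPath VCF 4.x file (plain or bgzipped).
#' @param sample Sample name (default: the first sample).
#' @return List of [Variant-class].
#' @export
readVariants <- function(vcfPath, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  samples <- colnames(vcf)
  if (is.null(sample)) sample <- samples[1L]
  if (!sample %in% samples)
    stop("sample '", sample, "' not present in VCF (has: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, sample]
  ps <- if ("PS" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$PS[, sample] else rep(NA, length(gt))
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key, i) {
    if (!key %in% names(info)) return(NA_character_)
    v <- info[[key]][i]
    if (is.list(v)) v <- unlist(v)[1L]
    as.character(v)
  }
  out <- list()
  for (i in seq_along(rr)) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      message("skipping record ", i, ": missing genotype")
      next
    }
    zyg <- .gtZygosity(g)
    if (zyg == "ref") {
      message("skipping record ", i, ": homozygous reference call")
      next
    }
    alts <- as.character(unlist(rr$ALT[i]))
    idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1L]]))
    aidx <- unique(idx[!is.na(idx) & idx > 0L])
    if (length(aidx) > 1L) {
      message("skipping record ", i, ": multi-allelic genotype")
      next
    }
    phase <- if (grepl("|", g, fixed = TRUE)) {
      if (!is.na(ps[i])) as.character(ps[i]) else "PS0"
    } else NA_character_
    po <- getInfo("PO", i)
    dn <- getInfo("DN", i)
    hf <- suppressWarnings(as.numeric(getInfo("HF", i)))
    out[[length(out) + 1L]] <- Variant(
      chrom = .normChrom(as.character(GenomeInfoDb::seqnames(rr)[i])),
      pos = IRanges::start(IRanges::ranges(rr))[i],
      ref = as.character(rr$REF[i]), alt = alts[aidx],
      gt = g, phaseSet = phase,
      parentalOrigin = if (is.na(po)) "unknown" else po,
      deNovo = if (is.na(dn)) "unknown" else dn,
      hetFraction = hf)
  }
  names(out) <- vapply(out, function(v)
    sprintf("%s:%d:%s>%s", v@chrom, v@pos, v@ref, v@alt), character(1L))
  out
}
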