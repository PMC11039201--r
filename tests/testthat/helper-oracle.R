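## Independent brute-force oracles, written against the stated rules and
## kept separate from the package implementation.

## NMD oracle: scan the explicit list of exon-exon junction coordinates; a
## PTC escapes iff no junction lies more than 50 nt downstream of it, or
## the transcript has a single exon.
oracleNMD <- function(ptcTxPos, exonWidthsTxOrder) {
  n <- length(exonWidthsTxOrder)
  if (n == 1L) return("escaping")
  junctions <- cumsum(exonWidthsTxOrder)[seq_len(n - 1L)]
  for (j in junctions) {
    if (j - ptcTxPos > 50L) return("triggering")
  }
  "escaping"
}

## exon widths in transcript order for a TranscriptModel
txExonWidths <- function(tx) {
  w <- IRanges::width(tx@exons)
  if (tx@strand == "-") rev(w) else w
}

## ---- requirement oracle --------------------------------------------------
## Formulated by haplotype enumeration: each observation contributes
## pathogenic alleles to one or both of two haplotypes; phase constraints
## (shared phase sets, chromosome copy for haploid PAR calls) restrict the
## consistent assignments. A biallelic requirement is
##   satisfied          iff every consistent assignment hits both haplotypes
##   candidate_partial  iff some (not all) assignments hit both, or exactly
##                      one allele-carrying observation exists
##   unsatisfied        otherwise.

oracleBiallelic <- function(obs) {
  if (nrow(obs) == 0L) return("unsatisfied")
  if (any(obs$zygosity == "homozygous_alt")) return("satisfied")
  singles <- obs[obs$zygosity %in% c("heterozygous", "hemizygous"), ,
                 drop = FALSE]
  k <- nrow(singles)
  if (k == 0L) return("unsatisfied")
  if (k == 1L) return("candidate_partial")
  ## fixed haplotype for phased calls / haploid chromosome copies;
  ## NA = unconstrained
  refSet <- stats::na.omit(singles$phase_set)
  refSet <- if (length(refSet)) refSet[1L] else NA_character_
  ## two constraint frames: haploid calls are fixed on a chromosome copy
  ## (X = copy 1, Y = copy 2), phased het calls are fixed within their
  ## phase set; the mapping between phase-set haplotypes and chromosome
  ## copies is itself unknown and enumerated as a global flip
  hapCopy <- vapply(seq_len(k), function(i) {
    o <- singles[i, , drop = FALSE]
    if (o$zygosity == "hemizygous")
      (if (o$chrom == "Y") 2L else 1L) else NA_integer_
  }, integer(1L))
  hapPhase <- vapply(seq_len(k), function(i) {
    o <- singles[i, , drop = FALSE]
    if (o$zygosity == "heterozygous" && !is.na(o$phase_set) &&
        identical(o$phase_set, refSet) &&
        grepl("|", o$gt, fixed = TRUE)) {
      a <- strsplit(o$gt, "|", fixed = TRUE)[[1L]]
      h <- which(a != "0")[1L]
      if (!is.na(h)) return(h)
    }
    NA_integer_
  }, integer(1L))
  both <- logical(0)
  for (flip in c(FALSE, TRUE)) {
    hap <- ifelse(!is.na(hapCopy), hapCopy,
                  ifelse(!is.na(hapPhase),
                         if (flip) 3L - hapPhase else hapPhase,
                         NA_integer_))
    free <- which(is.na(hap))
    for (a in seq_len(2^length(free)) - 1L) {
      h <- hap
      if (length(free))
        h[free] <- 1L + as.integer(intToBits(a)[seq_along(free)])
      both <- c(both, all(c(1L, 2L) %in% h))
    }
  }
  if (all(both)) "satisfied"
  else if (any(both)) "candidate_partial"
  else "unsatisfied"
}

oracleRequirementKnownSex <- function(obs, token, karyotype, par) {
  n <- nrow(obs)
  inPar <- function(o)
    any(par$chrom == o$chrom & par$start <= o$pos - 1L & o$pos - 1L < par$end)
  switch(token,
    monoallelic_autosomal = if (n >= 1L) "satisfied" else "unsatisfied",
    biallelic_autosomal = oracleBiallelic(obs),
    monoallelic_X_heterozygous = if (n >= 1L) "satisfied" else "unsatisfied",
    monoallelic_X_hemizygous = {
      if (n == 0L) "unsatisfied"
      else if (karyotype == "XY") "satisfied"
      else {
        v <- oracleBiallelic(obs)
        ## in XX, "possibly biallelic" counts as satisfied; a lone or
        ## proven-cis heterozygote is a carrier
        if (v == "candidate_partial" &&
            sum(obs$zygosity == "heterozygous") >= 2L) "satisfied"
        else if (v == "satisfied") "satisfied"
        else "unsatisfied"
      }
    },
    monoallelic_Y_hemizygous = {
      if (n == 0L) "unsatisfied"
      else if (karyotype == "XY") "satisfied" else "unsatisfied"
    },
    mitochondrial = if (n >= 1L) "satisfied" else "unsatisfied",
    monoallelic_PAR = {
      keep <- if (n) vapply(seq_len(n), function(i)
        inPar(obs[i, , drop = FALSE]), logical(1L)) else logical(0)
      if (sum(keep) >= 1L) "satisfied" else "unsatisfied"
    },
    biallelic_PAR = {
      keep <- if (n) vapply(seq_len(n), function(i)
        inPar(obs[i, , drop = FALSE]), logical(1L)) else logical(0)
      oracleBiallelic(obs[keep, , drop = FALSE])
    })
}

## unknown karyotype: merge the XX and XY verdicts; if they disagree the
## conservative answer is a candidate
oracleRequirement <- function(obs, token, karyotype, par) {
  if (karyotype != "unknown")
    return(oracleRequirementKnownSex(obs, token, karyotype, par))
  vXX <- oracleRequirementKnownSex(obs, token, "XX", par)
  vXY <- oracleRequirementKnownSex(obs, token, "XY", par)
  if (identical(vXX, vXY)) vXX else "candidate_partial"
}
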