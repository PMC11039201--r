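## Deterministic generators: toy transcripts, recipe-driven variant sets
## (written as VCF), and the bundled exemplar curations. Every generator is
## a pure function of its arguments plus seed; the reference sequence is
## synthetic, not a real genome.

.withSeed <- function(seed, fn) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  fn()
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.STOPS <- c("TAA", "TAG", "TGA")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

.codonPool <- function() {
  all <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                         .BASES, paste0))
  setdiff(all, .STOPS)
}

#' Generate a toy transcript with a clean coding sequence
#'
#' Builds a random regional reference containing one transcript: the CDS
#' starts with ATG, ends with a TAA stop, contains no internal in-frame
#' stop codon, and introns carry canonical GT..AG dinucleotides. The
#' transcript sequence is split across the requested exon lengths.
#' Reproducible: the same arguments and seed give the same model.
#'
#' @param exonLengths Positive exon lengths (transcript order).
#' @param intronLengths Intron lengths (length = exons - 1; each >= 4).
#' @param utr5,utr3 UTR lengths inside the first/last exon; the CDS length
#'   `sum(exonLengths) - utr5 - utr3` must be >= 6 and divisible by 3.
#' @param strand "+" or "-".
#' @param chrom,txId,gene Identifiers.
#' @param seed Integer seed.
#' @param pad Flanking genomic padding on each side.
#' @return A [TranscriptModel-class] whose refSeq is the whole toy
#'   chromosome (refOffset 1).
#' @examples
#' tx <- synthTranscript(c(90, 120, 90), c(50, 50), seed = 7)
#' tx
#' @export
synthTranscript <- function(exonLengths, intronLengths = integer(0),
                            utr5 = 30L, utr3 = 30L, strand = "+",
                            chrom = "chr1", txId = "TX1", gene = "GENE1",
                            seed = 1L, pad = 100L) {
  exonLengths <- as.integer(exonLengths)
  intronLengths <- as.integer(intronLengths)
  if (any(exonLengths <= 0L) || any(intronLengths < 4L))
    stop("infeasible geometry: exon lengths must be positive and introns >= 4",
         call. = FALSE)
  if (length(intronLengths) != length(exonLengths) - 1L)
    stop("infeasible geometry: need one intron fewer than exons",
         call. = FALSE)
  cdsLen <- sum(exonLengths) - utr5 - utr3
  if (cdsLen < 6L || cdsLen %% 3L != 0L)
    stop("infeasible geometry: CDS length must be >= 6 and divisible by 3",
         call. = FALSE)
  if (utr5 >= exonLengths[1L] || utr3 >= exonLengths[length(exonLengths)])
    stop("infeasible geometry: UTRs must fit inside the terminal exons",
         call. = FALSE)
  .withSeed(seed, function() {
    nCodon <- cdsLen %/% 3L
    cdsSeq <- paste0("ATG",
                     paste(sample(.codonPool(), nCodon - 2L, replace = TRUE),
                           collapse = ""),
                     "TAA")
    txSeq <- paste0(.randSeq(utr5), cdsSeq, .randSeq(utr3))
    cumEx <- cumsum(exonLengths)
    exSeqs <- substring(txSeq, c(1L, head(cumEx, -1L) + 1L), cumEx)
    inSeqs <- vapply(intronLengths, function(l)
      paste0("GT", .randSeq(l - 4L), "AG"), character(1L))
    parts <- character(0)
    for (i in seq_along(exSeqs)) {
      parts <- c(parts, exSeqs[i])
      if (i <= length(inSeqs)) parts <- c(parts, inSeqs[i])
    }
    F <- paste(parts, collapse = "")
    nF <- nchar(F)
    ## F-index of each exon
    lens <- integer(0)
    for (i in seq_along(exSeqs)) {
      lens <- c(lens, exonLengths[i])
      if (i <= length(inSeqs)) lens <- c(lens, intronLengths[i])
    }
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    exIdx <- seq(1L, length(lens), by = 2L)
    fs <- starts[exIdx]; fe <- ends[exIdx]
    if (strand == "+") {
      chromSeq <- paste0(.randSeq(pad), F, .randSeq(pad))
      gs <- pad + fs; ge <- pad + fe
    } else {
      chromSeq <- paste0(
        .randSeq(pad),
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(F))),
        .randSeq(pad))
      gs <- pad + nF - fe + 1L; ge <- pad + nF - fs + 1L
      o <- order(gs); gs <- gs[o]; ge <- ge[o]
    }
    ## transcript position -> F index (add introns upstream)
    cumIn <- c(0L, cumsum(intronLengths))
    txToF <- function(t) {
      e <- findInterval(t, c(1L, cumEx + 1L))
      t + cumIn[e]
    }
    fToG <- function(f) if (strand == "+") pad + f else pad + nF - f + 1L
    ct <- c(utr5 + 1L, utr5 + cdsLen)
    gcds <- sort(fToG(txToF(ct)))
    TranscriptModel(txId = txId, gene = gene, chrom = chrom,
                    strand = strand, exons = cbind(gs, ge),
                    cdsStart = gcds[1L], cdsEnd = gcds[2L],
                    refSeq = chromSeq, refOffset = 1L)
  })
}

## intron-anchored genomic position: transcript-order intron j, offset from
## donor (d) or acceptor (a) side, 1-based
.intronPos <- function(tx, j, donor = NA_integer_, acceptor = NA_integer_) {
  et <- .txExonTable(tx)
  if (tx@strand == "+") {
    if (!is.na(donor)) et$gend[j] + donor else et$gstart[j + 1L] - acceptor
  } else {
    if (!is.na(donor)) et$gstart[j] - donor else et$gend[j + 1L] + acceptor
  }
}

.intronLen <- function(tx, j) {
  et <- .txExonTable(tx)
  if (tx@strand == "+") et$gstart[j + 1L] - et$gend[j] - 1L
  else et$gstart[j] - et$gend[j + 1L] - 1L
}

#' Generate a recipe-driven variant VCF on a toy transcript
#'
#' Constructs variants from first principles (codon arithmetic on the
#' transcript model, not the classifier) so that reclassification with
#' [classifyVariant()] recovers exactly the requested class counts. Recipe
#' names are matrix row keys; `stop_gained` / `frameshift_variant` may be
#' suffixed `|NMD_triggering` or `|NMD_escaping` to pin the PTC location
#' (unsuffixed means either). Positions differ between seeds but class
#' counts are honoured for any seed.
#'
#' @param tx A [TranscriptModel-class] from [synthTranscript()].
#' @param recipe Named integer vector of per-class counts.
#' @param seed Integer seed.
#' @param vcfPath Output VCF path.
#' @param sampleId Sample column name.
#' @param genotypes Genotype strings recycled across variants
#'   (default "0/1").
#' @param info INFO column strings recycled across variants (default ".";
#'   keys PO, DN, HF are declared in the header).
#' @return Invisibly, the VCF path with the record table as
#'   `attr(, "records")`.
#' @export
synthVariants <- function(tx, recipe, seed = 1L,
                          vcfPath = tempfile(fileext = ".vcf"),
                          sampleId = "S1", genotypes = "0/1", info = ".") {
  stopifnot(is(tx, "TranscriptModel"), length(recipe) > 0L,
            !is.null(names(recipe)))
  S <- as.character(.splicedSeq(tx))
  cds <- .cdsTxRange(tx)
  c1 <- cds[1L]; c2 <- cds[2L]
  nCodon <- (c2 - c1 + 1L) %/% 3L
  nEx <- length(tx@exons)
  J <- .finalJunctionTx(tx)
  codonStr <- function(k) substr(S, c1 + (k - 1L) * 3L, c1 + (k - 1L) * 3L + 2L)
  aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])
  edgeOK <- function(t, margin = 4L) {
    d <- .exonEdgeDist(tx, t)
    is.finite(d) && d > margin || is.infinite(d)
  }
  codonSafe <- function(k, margin = 4L) {
    ts <- c1 + (k - 1L) * 3L + 0:2
    all(vapply(ts, edgeOK, logical(1L), margin = margin))
  }
  nmdOf <- function(ptc) {
    if (nEx == 1L) "escaping"
    else if (ptc > J) "escaping"
    else if (J - ptc <= 50L) "escaping"
    else "triggering"
  }
  gOf <- function(t) .txToGenomic(tx, t)
  refG <- function(g, n = 1L) .refBases(tx, g, n)
  toG <- function(b) if (tx@strand == "-") unname(.COMP[b]) else b

  used <- matrix(numeric(0), ncol = 2L)
  reserve <- function(a, b) {
    if (nrow(used) &&
        any(a - 1L <= used[, 2L] & b + 1L >= used[, 1L])) return(FALSE)
    used <<- rbind(used, c(a, b))
    TRUE
  }
  snvRec <- function(t, newBaseT) {
    g <- gOf(t)
    list(pos = g, ref = refG(g), alt = toG(newBaseT), span = c(g, g))
  }

  candidatesFor <- function(base, nmdReq) {
    out <- list()
    add <- function(x) out[[length(out) + 1L]] <<- x
    if (base %in% c("stop_gained", "missense_variant",
                    "synonymous_variant")) {
      for (k in 2:(nCodon - 1L)) {
        if (!codonSafe(k)) next
        cod <- codonStr(k)
        if (aa(cod) == "*") next
        for (p in 1:3) for (b in setdiff(.BASES, substr(cod, p, p))) {
          newc <- cod
          substr(newc, p, p) <- b
          na <- aa(newc); oa <- aa(cod)
          t <- c1 + (k - 1L) * 3L + p - 1L
          if (base == "stop_gained" && na == "*") {
            ptc <- c1 + (k - 1L) * 3L
            if (is.na(nmdReq) || nmdOf(ptc) == nmdReq)
              add(snvRec(t, b))
          } else if (base == "missense_variant" && na != oa && na != "*") {
            add(snvRec(t, b))
          } else if (base == "synonymous_variant" && na == oa) {
            add(snvRec(t, b))
          }
        }
      }
    } else if (base == "stop_lost") {
      cod <- codonStr(nCodon)
      for (p in 1:3) for (b in setdiff(.BASES, substr(cod, p, p))) {
        newc <- cod; substr(newc, p, p) <- b
        if (aa(newc) != "*")
          add(snvRec(c1 + (nCodon - 1L) * 3L + p - 1L, b))
      }
    } else if (base == "start_lost") {
      cod <- codonStr(1L)
      for (p in 1:3) for (b in setdiff(.BASES, substr(cod, p, p))) {
        newc <- cod; substr(newc, p, p) <- b
        if (newc != "ATG") add(snvRec(c1 + p - 1L, b))
      }
    } else if (base == "inframe_deletion") {
      for (k in 3:(nCodon - 2L)) {
        ts <- c1 + (k - 1L) * 3L + 0:2
        if (!codonSafe(k, 5L)) next
        gs <- sort(vapply(c(ts[1L] - 1L, ts, ts[3L] + 1L), gOf, integer(1L)))
        if (any(diff(gs) != 1L)) next  # not one contiguous exon block
        d1 <- gs[2L]
        add(list(pos = d1 - 1L, ref = refG(d1 - 1L, 4L),
                 alt = refG(d1 - 1L, 1L), span = c(d1 - 1L, d1 + 2L)))
      }
    } else if (base == "inframe_insertion") {
      pool <- .codonPool()
      for (k in 3:(nCodon - 2L)) {
        t <- c1 + (k - 1L) * 3L + 2L   # codon boundary after codon k
        if (!edgeOK(t, 5L) || !edgeOK(t + 1L, 5L)) next
        g2 <- sort(c(gOf(t), gOf(t + 1L)))
        if (diff(g2) != 1L) next
        ins <- pool[1L + (k %% length(pool))]
        insG <- if (tx@strand == "-")
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(ins))) else ins
        add(list(pos = g2[1L], ref = refG(g2[1L], 1L),
                 alt = paste0(refG(g2[1L], 1L), insG),
                 span = c(g2[1L], g2[2L])))
      }
    } else if (base == "frameshift_variant") {
      for (k in 3:(nCodon - 3L)) {
        ts <- c1 + (k - 1L) * 3L + 0:2
        if (!codonSafe(k, 5L)) next
        for (t in ts) {
          ## generator's own frame arithmetic: delete base t, find PTC
          Sp <- paste0(substr(S, 1L, t - 1L), substr(S, t + 1L, nchar(S)))
          tailSeq <- substr(Sp, c1, nchar(Sp))
          usable <- (nchar(tailSeq) %/% 3L) * 3L
          prot <- strsplit(as.character(Biostrings::translate(
            Biostrings::DNAString(substr(tailSeq, 1L, usable)),
            no.init.codon = TRUE)), "")[[1L]]
          stops <- which(prot == "*")
          starts <- c1 + (stops - 1L) * 3L
          varCodonStart <- c1 + (k - 1L) * 3L
          starts <- starts[starts >= varCodonStart]
          if (!length(starts)) next
          ptcRef <- if (starts[1L] >= t) starts[1L] + 1L else starts[1L]
          if (!is.na(nmdReq) && nmdOf(ptcRef) != nmdReq) next
          gs <- sort(c(gOf(t - 1L), gOf(t), gOf(t + 1L)))
          if (any(diff(gs) != 1L)) next
          gd <- gOf(t)
          add(list(pos = gd - 1L, ref = refG(gd - 1L, 2L),
                   alt = refG(gd - 1L, 1L), span = c(gd - 1L, gd)))
        }
      }
    } else if (base %in% c("splice_donor_variant", "splice_acceptor_variant",
                           "splice_region_variant", "intron_variant")) {
      if (nEx < 2L)
        stop("cannot generate ", base, " on a single-exon transcript",
             call. = FALSE)
      for (j in seq_len(nEx - 1L)) {
        len <- .intronLen(tx, j)
        offs <- switch(base,
          splice_donor_variant = list(donor = 1:2),
          splice_acceptor_variant = list(acceptor = 1:2),
          splice_region_variant = list(donor = 3:8, acceptor = 3:8),
          intron_variant = list(donor = seq(9L, max(9L, len - 8L))))
        if (base == "intron_variant" && len < 17L) next
        for (side in names(offs)) for (o in offs[[side]]) {
          if (base == "intron_variant" && (o < 9L || o > len - 8L)) next
          g <- if (side == "donor") .intronPos(tx, j, donor = o)
               else .intronPos(tx, j, acceptor = o)
          rb <- refG(g)
          add(list(pos = g, ref = rb,
                   alt = sample(setdiff(.BASES, rb), 1L),
                   span = c(g, g)))
        }
      }
    } else if (base %in% c("5_prime_UTR_variant", "3_prime_UTR_variant")) {
      rng <- if (base == "5_prime_UTR_variant") seq_len(c1 - 1L)
             else seq(c2 + 1L, .txLength(tx))
      for (t in rng) {
        if (!edgeOK(t)) next
        g <- gOf(t); rb <- refG(g)
        add(list(pos = g, ref = rb,
                 alt = sample(setdiff(.BASES, rb), 1L), span = c(g, g)))
      }
    } else {
      stop("recipe class '", base, "' is not supported by the generator",
           call. = FALSE)
    }
    out
  }

  records <- .withSeed(seed, function() {
    recs <- list()
    for (key in names(recipe)) {
      n <- recipe[[key]]
      if (n == 0L) next
      base <- sub("\\|.*$", "", key)
      nmdReq <- if (grepl("\\|NMD_", key))
        sub("^.*\\|NMD_", "", key) else NA_character_
      cand <- candidatesFor(base, nmdReq)
      if (!length(cand))
        stop("cannot generate class '", key, "' on transcript ", tx@txId,
             call. = FALSE)
      cand <- cand[sample(length(cand))]
      got <- 0L
      for (cd in cand) {
        if (got == n) break
        if (!reserve(cd$span[1L], cd$span[2L])) next
        recs[[length(recs) + 1L]] <- data.frame(
          pos = cd$pos, ref = cd$ref, alt = cd$alt, class = key,
          stringsAsFactors = FALSE)
        got <- got + 1L
      }
      if (got < n)
        stop("could not place ", n, " non-overlapping '", key,
             "' variants on transcript ", tx@txId, call. = FALSE)
    }
    df <- do.call(rbind, recs)
    df[order(df$pos), , drop = FALSE]
  })
  records$id <- sprintf("v%d", seq_len(nrow(records)))
  records$gt <- rep_len(genotypes, nrow(records))
  records$info <- rep_len(info, nrow(records))
  .writeVCF(records, vcfPath, tx@chrom, length(tx@refSeq), sampleId)
  structure(invisible(vcfPath), records = records)
}

.writeVCF <- function(records, path, chrom, contigLen, sampleId) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contigLen),
    "##INFO=<ID=PO,Number=1,Type=String,Description=\"Parental origin\">",
    "##INFO=<ID=DN,Number=1,Type=String,Description=\"De novo status\">",
    "##INFO=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy or allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                  chrom, records$pos, records$id, records$ref, records$alt,
                  records$info, records$gt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Bundled exemplar gene-disease curations
#'
#' Reads the packaged curation set: records assembled from named gene
#' examples (MYH7, KCNQ1, FBN1, EFNB1, DMPK, DHH, NF1, CYP1B1, IRF6,
#' C9orf72, RYR1, CACNA1S) plus synthetic records (source "synthetic") so
#' that every allelic-requirement token, including Y-linked, mitochondrial
#' and PAR, is exercised. All records pass [validateCuration()] with no
#' error-severity violations.
#'
#' @return List of [GeneDiseaseCuration-class] (>= 10 records).
#' @export
exemplarCurations <- function() {
  path <- system.file("extdata", "exemplar_curations.tsv",
                      package = "AllelicReq", mustWork = TRUE)
  readCurations(path, format = "tsv")
}
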