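## Transcript models: construction, coordinate arithmetic, GFF3/JSON I/O.
## Conventions: genomic and transcript coordinates 1-based inclusive
## (transcript coordinates count from the transcription start in transcript
## orientation); internal interval arithmetic on IRanges.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   subseq readDNAStringSet writeXStringSet GENETIC_CODE
#' @importFrom IRanges IRanges start end width
NULL

#' Construct a transcript model
#'
#' @param txId,gene,chrom,strand Identifiers and orientation.
#' @param exons Two-column matrix/data.frame of genomic (start, end), or an
#'   IRanges; ascending genomic order.
#' @param cdsStart,cdsEnd Genomic CDS bounds (start <= end regardless of
#'   strand); NA for non-coding transcripts.
#' @param refSeq Forward-strand reference sequence (character or DNAString)
#'   covering at least the exon span.
#' @param refOffset Genomic coordinate of refSeq position 1.
#' @return A [TranscriptModel-class].
#' @export
TranscriptModel <- function(txId, gene, chrom, strand, exons,
                            cdsStart = NA_integer_, cdsEnd = NA_integer_,
                            refSeq, refOffset = 1L) {
  if (!is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[, 1L]),
                              end = as.integer(exons[, 2L]))
  }
  if (is.character(refSeq)) refSeq <- Biostrings::DNAString(refSeq)
  new("TranscriptModel", txId = as.character(txId), gene = as.character(gene),
      chrom = as.character(chrom), strand = as.character(strand),
      exons = exons, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd), refSeq = refSeq,
      refOffset = as.integer(refOffset))
}

## exons in transcript order with cumulative transcript coordinates
.txExonTable <- function(tx) {
  s <- IRanges::start(tx@exons); e <- IRanges::end(tx@exons)
  if (tx@strand == "-") { s <- rev(s); e <- rev(e) }
  w <- e - s + 1L
  cum <- cumsum(w)
  data.frame(gstart = s, gend = e, width = w,
             tstart = c(1L, head(cum, -1L) + 1L), tend = cum)
}

.txLength <- function(tx) sum(IRanges::width(tx@exons))

## genomic position -> transcript coordinate (NA if not exonic)
.genomicToTx <- function(tx, gpos) {
  et <- .txExonTable(tx)
  vapply(as.integer(gpos), function(p) {
    i <- which(p >= pmin(et$gstart, et$gend) & p <= pmax(et$gstart, et$gend))
    if (!length(i)) return(NA_integer_)
    i <- i[1L]
    if (tx@strand == "+") et$tstart[i] + (p - et$gstart[i])
    else et$tstart[i] + (et$gend[i] - p)
  }, integer(1L))
}

.txToGenomic <- function(tx, tpos) {
  et <- .txExonTable(tx)
  vapply(as.integer(tpos), function(p) {
    i <- which(p >= et$tstart & p <= et$tend)
    if (!length(i)) return(NA_integer_)
    i <- i[1L]
    if (tx@strand == "+") et$gstart[i] + (p - et$tstart[i])
    else et$gend[i] - (p - et$tstart[i])
  }, integer(1L))
}

## forward-strand reference bases at genomic [gpos, gpos+len-1]
.refBases <- function(tx, gpos, len = 1L) {
  i <- gpos - tx@refOffset + 1L
  if (i < 1L || i + len - 1L > length(tx@refSeq))
    stop("position outside the regional reference", call. = FALSE)
  as.character(Biostrings::subseq(tx@refSeq, i, i + len - 1L))
}

## spliced transcript sequence in transcript orientation
.splicedSeq <- function(tx) {
  s <- IRanges::start(tx@exons); w <- IRanges::width(tx@exons)
  parts <- vapply(seq_along(s), function(i)
    .refBases(tx, s[i], w[i]), character(1L))
  seq <- Biostrings::DNAString(paste(parts, collapse = ""))
  if (tx@strand == "-") Biostrings::reverseComplement(seq) else seq
}

## CDS bounds in transcript coordinates: c(start, end), start <= end
.cdsTxRange <- function(tx) {
  if (is.na(tx@cdsStart) || is.na(tx@cdsEnd)) return(c(NA_integer_, NA_integer_))
  a <- .genomicToTx(tx, tx@cdsStart)
  b <- .genomicToTx(tx, tx@cdsEnd)
  sort(c(a, b))
}

## transcript coordinates of the final exon-exon junction: the last base of
## the penultimate exon in transcript order (NA for single-exon models)
.finalJunctionTx <- function(tx) {
  et <- .txExonTable(tx)
  if (nrow(et) < 2L) return(NA_integer_)
  et$tend[nrow(et) - 1L]
}

#' Read transcript models from a minimal JSON file
#'
#' Format: a JSON list of objects with fields `id`, `gene`, `chrom`,
#' `strand`, `exons` (list of [start, end] genomic pairs), `cds_start`,
#' `cds_end`, `sequence` (forward-strand regional reference) and optional
#' `offset` (genomic coordinate of sequence position 1; default 1).
#'
#' @param path JSON file.
#' @return List of [TranscriptModel-class].
#' @export
readTranscriptsJSON <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(objs, function(o) {
    ex <- do.call(rbind, lapply(o$exons, function(p) as.integer(unlist(p))))
    TranscriptModel(txId = o$id, gene = o$gene %||% o$id, chrom = o$chrom,
                    strand = o$strand, exons = ex,
                    cdsStart = o$cds_start %||% NA_integer_,
                    cdsEnd = o$cds_end %||% NA_integer_,
                    refSeq = o$sequence,
                    refOffset = as.integer(o$offset %||% 1L))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write transcript models to minimal JSON
#'
#' @param transcripts List of [TranscriptModel-class].
#' @param path Destination file.
#' @export
writeTranscriptsJSON <- function(transcripts, path) {
  objs <- lapply(transcripts, function(tx) {
    ex <- lapply(seq_along(tx@exons), function(i)
      c(IRanges::start(tx@exons)[i], IRanges::end(tx@exons)[i]))
    list(id = tx@txId, gene = tx@gene, chrom = tx@chrom, strand = tx@strand,
         exons = ex, cds_start = tx@cdsStart, cds_end = tx@cdsEnd,
         sequence = as.character(tx@refSeq), offset = tx@refOffset)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read transcript models from GFF3 plus a reference FASTA
#'
#' Exon and CDS features are grouped by their Parent transcript; the
#' chromosome sequence from the FASTA becomes the regional reference.
#'
#' @param gffPath GFF3 file with exon and CDS features.
#' @param fastaPath FASTA with the chromosome sequences.
#' @return List of [TranscriptModel-class].
#' @export
readTranscriptsGFF3 <- function(gffPath, fastaPath) {
  gr <- rtracklayer::import(gffPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- S4Vectors::mcols(gr)
  parent <- vapply(seq_along(gr), function(i) {
    p <- meta$Parent[[i]]
    if (length(p)) as.character(p[1L]) else NA_character_
  }, character(1L))
  exonIdx <- which(meta$type == "exon")
  txIds <- unique(parent[exonIdx])
  mrna <- gr[meta$type %in% c("mRNA", "transcript")]
  lapply(txIds, function(id) {
    ex <- gr[exonIdx][parent[exonIdx] == id]
    ex <- ex[order(IRanges::start(IRanges::ranges(ex)))]
    cds <- gr[meta$type == "CDS" & !is.na(parent) & parent == id]
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[1L]
    strand <- as.character(BiocGenerics::strand(ex))[1L]
    gene <- id
    m <- mrna[S4Vectors::mcols(mrna)$ID == id]
    if (length(m) && !is.null(S4Vectors::mcols(m)$gene))
      gene <- as.character(S4Vectors::mcols(m)$gene)[1L]
    if (!chrom %in% names(seqs))
      stop("chromosome '", chrom, "' absent from FASTA", call. = FALSE)
    TranscriptModel(
      txId = id, gene = gene, chrom = chrom, strand = strand,
      exons = cbind(IRanges::start(IRanges::ranges(ex)),
                    IRanges::end(IRanges::ranges(ex))),
      cdsStart = if (length(cds)) min(IRanges::start(IRanges::ranges(cds)))
                 else NA_integer_,
      cdsEnd = if (length(cds)) max(IRanges::end(IRanges::ranges(cds)))
               else NA_integer_,
      refSeq = as.character(seqs[[chrom]]), refOffset = 1L)
  })
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features per transcript.
#'
#' @param transcripts List of [TranscriptModel-class].
#' @param path Destination GFF3 file.
#' @export
writeTranscriptsGFF3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    et <- data.frame(s = IRanges::start(tx@exons), e = IRanges::end(tx@exons))
    span <- c(min(et$s), max(et$e))
    lines <- c(lines,
      sprintf("%s\tAllelicReq\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              tx@chrom, span[1L], span[2L], tx@strand, tx@gene),
      sprintf("%s\tAllelicReq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;gene=%s",
              tx@chrom, span[1L], span[2L], tx@strand, tx@txId, tx@gene,
              tx@gene))
    for (i in seq_len(nrow(et)))
      lines <- c(lines,
        sprintf("%s\tAllelicReq\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                tx@chrom, et$s[i], et$e[i], tx@strand, tx@txId))
    if (!is.na(tx@cdsStart)) {
      for (i in seq_len(nrow(et))) {
        cs <- max(et$s[i], tx@cdsStart); ce <- min(et$e[i], tx@cdsEnd)
        if (cs <= ce)
          lines <- c(lines,
            sprintf("%s\tAllelicReq\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                    tx@chrom, cs, ce, tx@strand, tx@txId))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference FASTA for a set of transcript models
#'
#' One entry per distinct chromosome; each model's regional reference must
#' start at genomic position 1 (refOffset 1) for a faithful chromosome
#' record.
#'
#' @param transcripts List of [TranscriptModel-class].
#' @param path Destination FASTA.
#' @export
writeReferenceFASTA <- function(transcripts, path) {
  chroms <- unique(vapply(transcripts, function(t) t@chrom, character(1L)))
  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    tx <- transcripts[[which(vapply(transcripts, function(t) t@chrom,
                                    character(1L)) == ch)[1L]]]
    if (tx@refOffset != 1L)
      stop("refOffset must be 1 to emit a chromosome FASTA", call. = FALSE)
    as.character(tx@refSeq)
  }, character(1L)))
  names(seqs) <- chroms
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
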