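## Hand-built 3-exon transcript with a fully hand-translated CDS; every
## expected class below was derived by hand from the codon layout.
##
## layout (pad 10 'A's each side, chrom "chrT", forward strand):
##   exon1 g11-24  = GGGGG ATG CAG CAT            (5'UTR 5 nt; codons 1-3)
##   intron1 g25-48 (GT..AG)
##   exon2 g49-66  = TGG AAA CCC GAG TTT GCG      (codons 4-9)
##   intron2 g67-88 (GT..AG)
##   exon3 g89-102 = GAT TAC TAA TTTTT            (codons 10-12; 3'UTR 5 nt)
## protein: M Q H W K P E F A D Y *
handExon1 <- "GGGGGATGCAGCAT"
handIntron1 <- paste0("GT", strrep("T", 20), "AG")
handExon2 <- "TGGAAACCCGAGTTTGCG"
handIntron2 <- paste0("GT", strrep("C", 18), "AG")
handExon3 <- "GATTACTAATTTTT"
handChrom <- paste0(strrep("A", 10), handExon1, handIntron1, handExon2,
                    handIntron2, handExon3, strrep("A", 10))
handTx <- TranscriptModel(
  txId = "HT1", gene = "HGENE", chrom = "chrT", strand = "+",
  exons = rbind(c(11, 24), c(49, 66), c(89, 102)),
  cdsStart = 16L, cdsEnd = 97L, refSeq = handChrom, refOffset = 1L)

classify1 <- function(chrom, pos, ref, alt) {
  classifyVariant(Variant(chrom, pos, ref, alt), handTx, BUNDLED_MATRIX)
}

test_that("point mutations in the CDS are classified by translation", {
  ## CAG -> TAG at codon 2: premature stop 23 nt before the final junction
  av <- classify1("chrT", 19, "C", "T")
  expect_identical(variantClass(av), "stop_gained|NMD_escaping")
  expect_identical(av@ptcTxPos, 9L)
  ## CAT -> CGT (His -> Arg), also within 3 nt of the exon 1 donor edge
  av <- classify1("chrT", 23, "A", "G")
  expect_identical(variantClass(av), "missense_variant")
  expect_true("splice_region_variant" %in% av@allTerms)
  ## CCC -> CCT, both Pro
  av <- classify1("chrT", 57, "C", "T")
  expect_identical(variantClass(av), "synonymous_variant")
  ## ATG -> GTG start loss
  av <- classify1("chrT", 16, "A", "G")
  expect_identical(variantClass(av), "start_lost")
  ## TAA -> TCA stop loss
  av <- classify1("chrT", 96, "A", "C")
  expect_identical(variantClass(av), "stop_lost")
})

test_that("indels are classified by frame arithmetic", {
  ## deletion of codon 6 (CCC) with anchor base
  av <- classify1("chrT", 54, "ACCC", "A")
  expect_identical(variantClass(av), "inframe_deletion")
  ## codon-boundary insertion of AGG (Arg) after codon 6
  av <- classify1("chrT", 57, "C", "CAGG")
  expect_identical(variantClass(av), "inframe_insertion")
  ## single-base deletion in codon 8: frameshift; the shifted tail
  ## (TGC GGA TTA CTA ATT TTT) contains no stop before the transcript end
  av <- classify1("chrT", 60, "GT", "G")
  expect_identical(variantClass(av), "frameshift_variant|NMD_escaping")
  expect_true(is.na(av@ptcTxPos))
})

test_that("splice, intron and UTR positions follow the site conventions", {
  ## first intronic base 3' of an internal exon
  av <- classify1("chrT", 67, "G", "A")
  expect_identical(variantClass(av), "splice_donor_variant")
  ## last intronic base before exon 2
  av <- classify1("chrT", 48, "G", "T")
  expect_identical(variantClass(av), "splice_acceptor_variant")
  ## intronic position 13 from the donor: plain intron variant
  av <- classify1("chrT", 37, "T", "C")
  expect_identical(variantClass(av), "intron_variant")
  ## intronic position 4 from the donor: splice region
  av <- classify1("chrT", 28, "T", "C")
  expect_identical(variantClass(av), "splice_region_variant")
  ## UTRs
  expect_identical(variantClass(classify1("chrT", 13, "G", "T")),
                   "5_prime_UTR_variant")
  expect_identical(variantClass(classify1("chrT", 100, "T", "G")),
                   "3_prime_UTR_variant")
})

test_that("reference mismatches error and non-overlap is a result", {
  expect_error(classify1("chrT", 19, "G", "T"), "reference mismatch")
  av <- classify1("chrT", 5, "A", "T")
  expect_identical(variantClass(av), "no_overlap")
  expect_true(all(is.na(av@profile)))
  av2 <- classify1("chr9", 19, "C", "T")
  expect_identical(variantClass(av2), "no_overlap")
})

test_that("the attached profile equals the matrix row of the class", {
  av <- classify1("chrT", 19, "C", "T")
  expect_identical(av@profile,
                   {p <- scores(BUNDLED_MATRIX)["stop_gained|NMD_escaping", ]
                    storage.mode(p) <- "integer"; p})
})

test_that("reverse-strand transcripts classify like their mirror", {
  ## the recipe round trip on a minus-strand model recovers each class,
  ## i.e. classification is strand-symmetric
  rec <- c("stop_gained|NMD_triggering" = 1, missense_variant = 2,
           synonymous_variant = 1, splice_donor_variant = 1,
           splice_acceptor_variant = 1, inframe_deletion = 1,
           "frameshift_variant|NMD_triggering" = 1,
           "5_prime_UTR_variant" = 1, intron_variant = 1)
  for (tx in list(TX_FWD, TX_REV)) {
    path <- synthVariants(tx, rec, seed = 29)
    vs <- readVariants(path)
    cls <- vapply(vs, function(v)
      variantClass(classifyVariant(v, tx, BUNDLED_MATRIX)), character(1))
    expect_identical(sort(unname(cls)),
                     sort(attr(path, "records")$class),
                     label = tx@strand)
  }
})

test_that("VEP CSQ strings resolve to the most severe recognized term", {
  expect_identical(parseVepConsequences("missense_variant"),
                   "missense_variant")
  expect_identical(
    parseVepConsequences("splice_donor_variant&intron_variant"),
    "splice_donor_variant")
  expect_identical(
    parseVepConsequences("intron_variant&splice_donor_variant"),
    "splice_donor_variant")
  expect_warning(
    out <- parseVepConsequences("regulatory_region_amplification"),
    "function_uncertain")
  expect_identical(out, "function_uncertain")
  expect_error(parseVepConsequences(""), "empty")
})

test_that("VCF genotypes decode to zygosity, phase and skips", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=112>",
    "##INFO=<ID=PO,Number=1,Type=String,Description=\"Parental origin\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chrT\t13\tv1\tG\tT\t.\tPASS\t.\tGT:PS\t0/1:.",
    "chrT\t19\tv2\tC\tT\t.\tPASS\tPO=maternal\tGT:PS\t1|0:77",
    "chrT\t23\tv3\tA\tG\t.\tPASS\t.\tGT:PS\t1/1:.",
    "chrT\t57\tv4\tC\tT\t.\tPASS\t.\tGT:PS\t1:.",
    "chrT\t96\tv5\tA\tC\t.\tPASS\t.\tGT:PS\t./.:."), path)
  msgs <- capture_messages(vs <- readVariants(path, "S1"))
  expect_length(vs, 4L)
  expect_match(msgs, "skipping record 5", all = FALSE)
  zyg <- vapply(vs, function(v) v@zygosity, character(1))
  expect_identical(unname(zyg),
                   c("heterozygous", "heterozygous", "homozygous_alt",
                     "hemizygous"))
  expect_identical(vs[[2]]@phaseSet, "77")
  expect_true(is.na(vs[[1]]@phaseSet))
  expect_identical(vs[[2]]@parentalOrigin, "maternal")
  expect_error(readVariants(path, "S9"), "not present")
})
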