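## Shared fixtures: built once per test run, all generated in code.

BUNDLED_MATRIX <- defaultMatrix()

## standard toy transcripts
TX_FWD <- synthTranscript(c(90, 120, 90), c(50, 50), strand = "+",
                          chrom = "chr1", txId = "TXF", gene = "GENEF",
                          seed = 11)
TX_REV <- synthTranscript(c(90, 120, 90), c(50, 50), strand = "-",
                          chrom = "chr2", txId = "TXR", gene = "GENER",
                          seed = 12)
TX_SINGLE <- synthTranscript(c(240), integer(0), strand = "+",
                             chrom = "chr3", txId = "TXS", gene = "GENES",
                             seed = 13)
TX_LONG <- synthTranscript(c(120, 200, 160, 90), c(60, 60, 60),
                           strand = "+", chrom = "chr4", txId = "TXL",
                           gene = "GENEL", seed = 14)

## a full multi-class recipe producible on any of the 3-exon toys
FULL_RECIPE <- c("stop_gained|NMD_triggering" = 2,
                 "stop_gained|NMD_escaping" = 1,
                 missense_variant = 3, synonymous_variant = 1,
                 "frameshift_variant|NMD_triggering" = 1,
                 "frameshift_variant|NMD_escaping" = 1,
                 inframe_deletion = 1, inframe_insertion = 1,
                 splice_donor_variant = 1, splice_acceptor_variant = 1,
                 splice_region_variant = 1, intron_variant = 1,
                 "5_prime_UTR_variant" = 1, "3_prime_UTR_variant" = 1,
                 stop_lost = 1, start_lost = 1)

## one observation row for requirement-engine tests
obsRow <- function(id, chrom = "1", pos = 1000L, zygosity = "heterozygous",
                   gt = "0/1", phase_set = NA_character_,
                   parental_origin = "unknown", de_novo = "unknown",
                   het_fraction = NA_real_) {
  data.frame(id = id, chrom = chrom, pos = as.integer(pos),
             zygosity = zygosity, gt = gt, phase_set = phase_set,
             parental_origin = parental_origin, de_novo = de_novo,
             het_fraction = het_fraction, stringsAsFactors = FALSE)
}
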