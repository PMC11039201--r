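PAR <- defaultPAR()

test_that("hand-derived requirement verdicts match the stated rules", {
  ctxXX <- SampleContext("S", "XX")
  ctxXY <- SampleContext("S", "XY")
  h1 <- obsRow("v1")
  h2 <- obsRow("v2", pos = 2000L)
  ## dominant: one heterozygous qualifying variant is a diagnosis
  d <- evaluateRequirement(h1, "monoallelic_autosomal", ctxXX)
  expect_identical(decisionStatus(d), "satisfied")
  expect_true("MONOALLELIC_SATISFIED" %in% rationaleCodes(d))
  ## recessive: a lone heterozygote directs the search onwards
  d <- evaluateRequirement(h1, "biallelic_autosomal", ctxXX)
  expect_identical(decisionStatus(d), "candidate_partial")
  expect_true("SECOND_VARIANT_SOUGHT" %in% rationaleCodes(d))
  ## two unphased heterozygotes: possible compound het
  d <- evaluateRequirement(rbind(h1, h2), "biallelic_autosomal", ctxXX)
  expect_identical(decisionStatus(d), "candidate_partial")
  expect_true("POSSIBLE_COMPHET_PHASE_UNKNOWN" %in% rationaleCodes(d))
  ## phased trans resolves to satisfied, phased cis to unsatisfied
  t1 <- obsRow("v1", gt = "1|0", phase_set = "PS1")
  t2 <- obsRow("v2", pos = 2000L, gt = "0|1", phase_set = "PS1")
  c2 <- obsRow("v2", pos = 2000L, gt = "1|0", phase_set = "PS1")
  expect_identical(decisionStatus(
    evaluateRequirement(rbind(t1, t2), "biallelic_autosomal", ctxXX)),
    "satisfied")
  expect_identical(decisionStatus(
    evaluateRequirement(rbind(t1, c2), "biallelic_autosomal", ctxXX)),
    "unsatisfied")
  ## homozygote satisfies recessive
  hom <- obsRow("v1", zygosity = "homozygous_alt", gt = "1/1")
  expect_identical(decisionStatus(
    evaluateRequirement(hom, "biallelic_autosomal", ctxXX)), "satisfied")

  ## X-linked recessive: hemizygous XY satisfied; XX single het carrier
  xh <- obsRow("v1", chrom = "X", pos = 5000000L, zygosity = "hemizygous",
               gt = "1")
  d <- evaluateRequirement(xh, "monoallelic_X_hemizygous", ctxXY)
  expect_identical(decisionStatus(d), "satisfied")
  xhet <- obsRow("v1", chrom = "X", pos = 5000000L)
  d <- evaluateRequirement(xhet, "monoallelic_X_hemizygous", ctxXX)
  expect_identical(decisionStatus(d), "unsatisfied")
  expect_true("X_CARRIER_HET" %in% rationaleCodes(d))
  ## ... and X-linked dominant is satisfied by the same single het
  expect_identical(decisionStatus(
    evaluateRequirement(xhet, "monoallelic_X_heterozygous", ctxXX)),
    "satisfied")
  ## XX homozygous under a dominant requirement satisfies with a flag
  xhom <- obsRow("v1", chrom = "X", pos = 5000000L,
                 zygosity = "homozygous_alt", gt = "1/1")
  d <- evaluateRequirement(xhom, "monoallelic_X_heterozygous", ctxXX)
  expect_identical(decisionStatus(d), "satisfied")
  expect_true("HOMOZYGOUS_UNDER_DOMINANT" %in% rationaleCodes(d))

  ## Y requirement in XX: a rationale, not an exception
  yv <- obsRow("v1", chrom = "Y", pos = 5000000L, zygosity = "hemizygous",
               gt = "1")
  d <- evaluateRequirement(yv, "monoallelic_Y_hemizygous", ctxXX)
  expect_identical(decisionStatus(d), "unsatisfied")
  expect_true("KARYOTYPE_IMPOSSIBLE" %in% rationaleCodes(d))

  ## mitochondrial with heteroplasmy recorded
  mt <- obsRow("v1", chrom = "MT", pos = 100L, zygosity = "hemizygous",
               gt = "1", het_fraction = 0.7)
  d <- evaluateRequirement(mt, "mitochondrial", ctxXX)
  expect_identical(decisionStatus(d), "satisfied")
  expect_true("MT_HETEROPLASMY_RECORDED" %in% rationaleCodes(d))

  ## PAR: an X variant outside the PAR does not count
  outside <- obsRow("v1", chrom = "X", pos = 5000000L)
  d <- evaluateRequirement(outside, "monoallelic_PAR", ctxXX)
  expect_identical(decisionStatus(d), "unsatisfied")
  expect_true("NOT_IN_PAR" %in% rationaleCodes(d))
  inside <- obsRow("v1", chrom = "X", pos = 100000L)
  expect_identical(decisionStatus(
    evaluateRequirement(inside, "monoallelic_PAR", ctxXX)), "satisfied")
  ## biallelic PAR across the X and Y copies is trans by construction
  px <- obsRow("v1", chrom = "X", pos = 100000L, zygosity = "hemizygous",
               gt = "1")
  py <- obsRow("v2", chrom = "Y", pos = 100000L, zygosity = "hemizygous",
               gt = "1")
  expect_identical(decisionStatus(
    evaluateRequirement(rbind(px, py), "biallelic_PAR", ctxXY)),
    "satisfied")

  ## empty observations
  expect_identical(decisionStatus(
    evaluateRequirement(obsRow("x")[0, ], "biallelic_autosomal", ctxXX)),
    "unsatisfied")
  ## unknown requirement errors with suggestions
  expect_error(evaluateRequirement(h1, "monoallelic", ctxXX), "nearest")
  ## non-Mendelian records skip engine logic
  expect_identical(
    rationaleCodes(evaluateRequirement(h1, "non_mendelian", ctxXX)),
    "NON_MENDELIAN_NOT_EVALUATED")
})

test_that("evaluateRequirement matches the brute-force oracle on the grid", {
  tokens <- requirementTokens()
  ## per-token locus for the observations
  locus <- list(
    monoallelic_autosomal = list(chrom = "1", pos = 1000L),
    biallelic_autosomal = list(chrom = "1", pos = 1000L),
    monoallelic_X_heterozygous = list(chrom = "X", pos = 5000000L),
    monoallelic_X_hemizygous = list(chrom = "X", pos = 5000000L),
    monoallelic_Y_hemizygous = list(chrom = "Y", pos = 5000000L),
    mitochondrial = list(chrom = "MT", pos = 100L),
    monoallelic_PAR = list(chrom = "X", pos = 100000L),
    biallelic_PAR = list(chrom = "X", pos = 100000L))
  alphabetFor <- function(token, karyotype) {
    loc <- locus[[token]]
    het <- list(zyg = "heterozygous", gt = "0/1", chrom = loc$chrom)
    hom <- list(zyg = "homozygous_alt", gt = "1/1", chrom = loc$chrom)
    hemi <- list(zyg = "hemizygous", gt = "1", chrom = loc$chrom)
    hemiY <- list(zyg = "hemizygous", gt = "1", chrom = "Y")
    outX <- list(zyg = "heterozygous", gt = "0/1", chrom = "X",
                 pos = 5000000L)
    switch(token,
      monoallelic_autosomal = ,
      biallelic_autosomal = list(het = het, hom = hom),
      monoallelic_X_heterozygous = ,
      monoallelic_X_hemizygous =
        if (karyotype == "XY") list(hemi = hemi, het = het, hom = hom)
        else list(het = het, hom = hom),
      monoallelic_Y_hemizygous = list(hemi = hemiY),
      mitochondrial = list(hemi = hemi, het = het),
      monoallelic_PAR = ,
      biallelic_PAR =
        if (karyotype == "XY")
          list(het = het, hom = hom, hemiX = hemi, hemiY = hemiY,
               outX = outX)
        else list(het = het, hom = hom, outX = outX))
  }
  buildObs <- function(items, loc, phase) {
    if (length(items) == 0L)
      return(obsRow("none")[0, ])
    rows <- lapply(seq_along(items), function(i) {
      it <- items[[i]]
      obsRow(sprintf("v%d", i), chrom = it$chrom,
             pos = if (!is.null(it$pos)) it$pos else loc$pos + 10L * i,
             zygosity = it$zyg, gt = it$gt)
    })
    obs <- do.call(rbind, rows)
    hets <- which(obs$zygosity == "heterozygous")
    if (phase != "unphased" && length(hets) >= 2L) {
      i1 <- hets[1]; i2 <- hets[2]
      obs$phase_set[c(i1, i2)] <- "PS1"
      obs$gt[i1] <- "1|0"
      obs$gt[i2] <- if (phase == "cis") "1|0" else "0|1"
    }
    obs
  }
  tuples <- function(alphabet, n) {
    if (n == 0L) return(list(list()))
    idx <- expand.grid(rep(list(seq_along(alphabet)), n))
    lapply(seq_len(nrow(idx)), function(k)
      lapply(as.integer(idx[k, ]), function(j) alphabet[[j]]))
  }
  nCases <- 0L
  for (token in tokens) {
    for (karyotype in c("XX", "XY", "unknown")) {
      ctx <- SampleContext("S", karyotype, par = PAR)
      alphabet <- alphabetFor(token, karyotype)
      for (n in 0:3) {
        for (items in tuples(alphabet, n)) {
          nHet <- sum(vapply(items, function(i)
            i$zyg == "heterozygous", logical(1)))
          phases <- if (nHet >= 2L) c("unphased", "cis", "trans")
                    else "unphased"
          for (phase in phases) {
            obs <- buildObs(items, locus[[token]], phase)
            got <- decisionStatus(evaluateRequirement(obs, token, ctx))
            want <- oracleRequirement(obs, token, karyotype, PAR)
            nCases <- nCases + 1L
            if (!identical(got, want))
              fail(sprintf(
                "mismatch: %s %s n=%d phase=%s zyg=%s -> engine %s, oracle %s",
                token, karyotype, n, phase,
                paste(vapply(items, `[[`, "", "zyg"), collapse = ","),
                got, want))
          }
        }
      }
    }
  }
  expect_gt(nCases, 900L)
  succeed()
})

test_that("a satisfied decision stays satisfied when variants are added", {
  ctx <- SampleContext("S", "XX")
  set.seed(99)
  for (i in 1:40) {
    token <- sample(c("monoallelic_autosomal", "biallelic_autosomal",
                      "monoallelic_X_heterozygous"), 1)
    chrom <- if (grepl("_X_", token)) "X" else "1"
    n <- sample(1:3, 1)
    zyg <- sample(c("heterozygous", "homozygous_alt"), n, replace = TRUE)
    obs <- do.call(rbind, lapply(seq_len(n), function(k)
      obsRow(sprintf("v%d", k), chrom = chrom, pos = 1000L + 10L * k,
             zygosity = zyg[k], gt = if (zyg[k] == "heterozygous")
               "0/1" else "1/1")))
    before <- decisionStatus(evaluateRequirement(obs, token, ctx))
    extra <- obsRow("extra", chrom = chrom, pos = 5000L,
                    zygosity = sample(c("heterozygous", "homozygous_alt"), 1))
    after <- decisionStatus(
      evaluateRequirement(rbind(obs, extra), token, ctx))
    if (before == "satisfied") expect_identical(after, "satisfied")
    rank <- c(unsatisfied = 0L, candidate_partial = 1L, satisfied = 2L)
    if (before == "unsatisfied") expect_gte(rank[[after]], 0L)
  }
})

test_that("qualifying set shrinks (weakly) as the threshold rises", {
  tx <- TX_FWD
  path <- synthVariants(tx, FULL_RECIPE, seed = 31)
  annotated <- lapply(readVariants(path), classifyVariant, tx = tx,
                      matrix = BUNDLED_MATRIX)
  cur <- GeneDiseaseCuration("GENEF", "toy disease", "monoallelic_autosomal",
                             consequences = c("decreased gene product level",
                                              "absent gene product"))
  sizes <- vapply(1:5, function(t)
    length(qualifyingVariants(annotated, cur, BUNDLED_MATRIX, t)),
    integer(1))
  expect_true(all(diff(sizes) <= 0L))
  ## missense qualifies under a sequence-consequence curation, not a
  ## level-consequence one; synonymous qualifies under neither
  curSeq <- GeneDiseaseCuration("GENEF", "toy", "monoallelic_autosomal",
                                consequences = "altered gene product sequence")
  q <- qualifyingVariants(annotated, curSeq, BUNDLED_MATRIX, 4L)
  cls <- vapply(q, variantClass, character(1))
  expect_true("missense_variant" %in% cls)
  expect_false("synonymous_variant" %in% cls)
  expect_false(any(vapply(
    qualifyingVariants(annotated, cur, BUNDLED_MATRIX, 4L),
    variantClass, character(1)) == "missense_variant"))
  ## threshold 3 admits splice_region for a decreased-level curation
  q3 <- qualifyingVariants(annotated, cur, BUNDLED_MATRIX, 3L)
  expect_true("splice_region_variant" %in%
              vapply(q3, variantClass, character(1)))
  ## an empty consequence set is an error pointing at inferConsequences
  curEmpty <- GeneDiseaseCuration("GENEF", "toy", "monoallelic_autosomal")
  expect_error(qualifyingVariants(annotated, curEmpty, BUNDLED_MATRIX),
               "inferConsequences")
})

test_that("qualifiers flag decisions without changing them, except requires-het", {
  ctxXY <- SampleContext("S", "XY")
  ctxXX <- SampleContext("S", "XX")
  xh <- obsRow("v1", chrom = "X", pos = 5000000L, zygosity = "hemizygous",
               gt = "1")
  base <- evaluateRequirement(xh, "monoallelic_X_hemizygous", ctxXY)
  expect_identical(decisionStatus(base), "satisfied")
  ## requires heterozygosity downgrades the hemizygous male
  d <- applyQualifiers(base, "HP:0034343", xh, ctxXY)
  expect_identical(decisionStatus(d), "candidate_partial")
  expect_true("REQUIRES_HET_HEMIZYGOUS_DOWNGRADE" %in% qualifierFlags(d))
  ## male-limited expression in an XX proband
  h <- obsRow("v1")
  dd <- evaluateRequirement(h, "monoallelic_autosomal", ctxXX)
  d <- applyQualifiers(dd, "HP:0001475", h, ctxXX)
  expect_identical(decisionStatus(d), "satisfied")
  expect_true("SEX_LIMITED_NOT_EXPECTED" %in% qualifierFlags(d))
  ## no qualifiers: identity
  expect_identical(applyQualifiers(dd, character(0), h, ctxXX), dd)
  ## imprinting: maternal imprinting silences the maternal copy, so a
  ## maternally inherited variant is inconsistent
  hm <- obsRow("v1", parental_origin = "maternal")
  dm <- evaluateRequirement(hm, "monoallelic_autosomal", ctxXX)
  d <- applyQualifiers(dm, "HP:0012275", hm, ctxXX)
  expect_true("ORIGIN_INCONSISTENT_WITH_IMPRINTING" %in% qualifierFlags(d))
  hp <- obsRow("v1", parental_origin = "paternal")
  dp <- evaluateRequirement(hp, "monoallelic_autosomal", ctxXX)
  d <- applyQualifiers(dp, "HP:0012275", hp, ctxXX)
  expect_true("ORIGIN_CONSISTENT_WITH_IMPRINTING" %in% qualifierFlags(d))
  d <- applyQualifiers(dm, "HP:0034338", hm, ctxXX)
  expect_true("IMPRINTED_INFO" %in% qualifierFlags(d))
  ## typically de novo
  hd <- obsRow("v1", de_novo = "confirmed")
  d <- applyQualifiers(evaluateRequirement(hd, "monoallelic_autosomal",
                                           ctxXX),
                       "HP:0025352", hd, ctxXX)
  expect_true("DE_NOVO_SUPPORTIVE" %in% qualifierFlags(d))
  hi <- obsRow("v1", de_novo = "inherited")
  d <- applyQualifiers(evaluateRequirement(hi, "monoallelic_autosomal",
                                           ctxXX),
                       "HP:0025352", hi, ctxXX)
  expect_true("INHERITED_DESPITE_TYPICALLY_DE_NOVO" %in% qualifierFlags(d))
  ## penetrance/onset/anticipation annotate only
  d <- applyQualifiers(dd, c("HP:0003829", "HP:0003831", "HP:0003743"),
                       h, ctxXX)
  expect_identical(decisionStatus(d), decisionStatus(dd))
  expect_setequal(qualifierFlags(d),
                  c("INFO_PENETRANCE", "INFO_ONSET", "INFO_ANTICIPATION"))
})
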