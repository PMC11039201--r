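m <- BUNDLED_MATRIX

test_that("text-anchored cells are exact, with paper_text provenance", {
  expect_identical(unname(likelihood(m, "stop_gained|NMD_triggering",
                                     "decreased gene product level")), 5L)
  expect_identical(unname(likelihood(m, "stop_gained|NMD_triggering",
                                     "absent gene product")), 5L)
  expect_identical(unname(likelihood(m, "missense_variant",
                                     "altered gene product sequence")), 5L)
  expect_gte(likelihood(m, "splice_donor_variant",
                        "decreased gene product level"), 3L)
  expect_gte(likelihood(m, "splice_donor_variant",
                        "altered gene product sequence"), 3L)
  expect_identical(unname(likelihood(m, "synonymous_variant",
                                     "functionally normal")), 5L)
  expect_identical(unname(likelihood(m, "synonymous_variant",
                                     "altered gene product sequence")), 1L)
  p <- cellProvenance(m)
  expect_identical(p["stop_gained|NMD_triggering", "absent gene product"],
                   "paper_text")
  expect_identical(p["missense_variant", "altered gene product sequence"],
                   "paper_text")
  expect_true(all(p %in% c("paper_text", "expert_default")))
})

test_that("the ordinal likelihood scale has five labelled levels", {
  expect_identical(likelihoodLabel(1:5),
                   c("almost never", "unlikely", "possible", "probable",
                     "almost always"))
  expect_error(likelihoodLabel(0), "1-5")
  expect_error(likelihoodLabel(6), "1-5")
})

test_that("base class list is the 33-term VEP set; rows derive from it", {
  vep <- vepConsequences()
  expect_identical(length(vep), 33L)
  expect_true(all(c("transcript_ablation", "splice_acceptor_variant",
                    "stop_gained", "frameshift_variant", "missense_variant",
                    "synonymous_variant", "intron_variant",
                    "downstream_gene_variant", "intergenic_variant")
                  %in% vep))
  keys <- matrixClassKeys()
  expect_identical(rownames(scores(m)), keys)
  ## culled redundant terms are not rows
  expect_false(any(c("downstream_gene_variant", "upstream_gene_variant",
                     "intergenic_variant") %in% keys))
  ## NMD splits on the PTC-producing classes only
  split <- sub("\\|.*$", "", keys[grepl("\\|", keys)])
  expect_setequal(unique(split), c("stop_gained", "frameshift_variant"))
  ## severity ranks form a strict total order
  expect_identical(severityRank(keys), seq_along(keys))
})

test_that("serialize then load preserves every cell and provenance tag", {
  path <- tempfile(fileext = ".tsv")
  writeMatrix(m, path)
  back <- loadMatrix(path)
  expect_identical(scores(back), scores(m))
  expect_identical(cellProvenance(back), cellProvenance(m))
})

test_that("malformed matrix TSVs fail with informative errors", {
  path <- tempfile(fileext = ".tsv")
  writeMatrix(m, path)
  lines <- readLines(path)
  ## cell out of range, naming row and column
  bad <- sub("\t5\t5\t5\t", "\t5\t7\t5\t", lines[2], fixed = TRUE)
  writeLines(c(lines[1], bad, lines[-(1:2)]), path)
  expect_error(loadMatrix(path), "out of range 1-5.*transcript_ablation")
  ## missing consequence column
  df <- utils::read.delim({writeMatrix(m, path); path}, check.names = FALSE)
  df[["absent gene product"]] <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadMatrix(path), "absent gene product")
  ## unknown class name
  writeMatrix(m, path)
  lines <- readLines(path)
  lines[2] <- sub("^transcript_ablation", "made_up_variant", lines[2])
  writeLines(lines, path)
  expect_error(loadMatrix(path), "made_up_variant")
})

test_that("likelihood lookups resolve names and reject unknowns", {
  expect_identical(unname(likelihood(m, "inframe_deletion",
                                     "SO:0002318")), 5L)
  ## unambiguous base term resolves to its single row
  expect_identical(unname(likelihood(m, "missense_variant",
                                     "altered gene product sequence")),
                   unname(likelihood(m, resolveClass(m, "missense_variant"),
                                     "altered gene product sequence")))
  expect_error(likelihood(m, "made_up_variant", "absent gene product"),
               "unknown variant class")
  expect_error(resolveClass(m, "stop_gained"), "ambiguous")
  expect_error(likelihood(m, "missense_variant", "nonsense consequence"),
               "unknown consequence")
})

test_that("inferConsequences is the element-wise max over observed rows", {
  p <- inferConsequences(m, "stop_gained|NMD_triggering")
  expect_identical(unname(p["decreased gene product level"]), 5L)
  expect_identical(unname(p["absent gene product"]), 5L)
  expect_identical(inferConsequences(m, character(0)), integer(0))
  ## brute-force expectation for a two-class profile
  s <- scores(m)
  expected <- vapply(colnames(s), function(cn)
    max(s["missense_variant", cn], s["splice_donor_variant", cn]),
    integer(1))
  expect_identical(inferConsequences(m, c("missense_variant",
                                          "splice_donor_variant")),
                   expected)
  expect_error(inferConsequences(m, "made_up_variant"), "unknown")
})

test_that("inferConsequences is monotone under added classes", {
  keys <- matrixClassKeys()
  set.seed(42)
  for (i in 1:25) {
    base <- sample(keys, sample(1:4, 1))
    extra <- sample(setdiff(keys, base), 1)
    p1 <- inferConsequences(m, base)
    p2 <- inferConsequences(m, c(base, extra))
    expect_true(all(p2 >= p1))
  }
})

test_that("suggestClasses reproduces the pilot inference", {
  sug <- suggestClasses(m, "stop_gained|NMD_triggering", threshold = 4L)
  expect_true("frameshift_variant|NMD_triggering" %in% sug)
  expect_false("stop_gained|NMD_triggering" %in% sug)
  ## threshold 5 from a functionally-normal class: only classes with a 5
  ## in "functionally normal" (enumerated over the bundled matrix)
  sug5 <- suggestClasses(m, "synonymous_variant", threshold = 5L)
  s <- scores(m)
  expected <- setdiff(rownames(s)[s[, "functionally normal"] == 5L],
                      "synonymous_variant")
  expect_setequal(sug5, expected)
  expect_identical(suggestClasses(m, character(0)), character(0))
  expect_error(suggestClasses(m, "missense_variant", threshold = 0L),
               "1-5")
  expect_error(suggestClasses(m, "missense_variant", threshold = 6L),
               "1-5")
})

test_that("suggestClasses is input-order invariant and disjoint from input", {
  keys <- matrixClassKeys()
  set.seed(7)
  for (i in 1:20) {
    obs <- sample(keys, sample(1:4, 1))
    a <- suggestClasses(m, obs)
    b <- suggestClasses(m, rev(obs))
    expect_identical(a, b)
    expect_length(intersect(a, obs), 0L)
    ## sorted by severity rank
    expect_identical(a, a[order(severityRank(a), a)])
  }
})

test_that("every bundled class reaches 'possible' for some consequence", {
  expect_true(all(apply(scores(m), 1, max) >= 3L))
})

test_that("validateMatrix flags range and hierarchy violations", {
  expect_true(isValid(validateMatrix(m)))
  expect_identical(nrow(violations(validateMatrix(m))), 0L)
  bad <- m
  bad@scores["missense_variant", "altered gene product level"] <- 2L
  bad@scores["missense_variant", "decreased gene product level"] <- 5L
  rep <- validateMatrix(bad)
  expect_true("hierarchy_monotonicity" %in% violations(rep)$code)
  bad2 <- m
  bad2@scores["intron_variant", "functionally normal"] <- 0L
  expect_true("value_out_of_range" %in%
              violations(validateMatrix(bad2))$code)
})
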