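## SO variant classes, severity order, and the variant-class x high-level
## consequence likelihood matrix.

## The 33-term VEP consequence set, most to least severe. This is the base
## class list before redundant terms are culled for the matrix rows and
## before the NMD splits are applied to the PTC-producing classes.
.VEP_CONSEQUENCES <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "transcript_amplification", "inframe_insertion", "inframe_deletion",
  "missense_variant", "protein_altering_variant", "splice_region_variant",
  "incomplete_terminal_codon_variant", "stop_retained_variant",
  "synonymous_variant", "coding_sequence_variant", "mature_miRNA_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "NMD_transcript_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "TFBS_ablation",
  "TFBS_amplification", "TF_binding_site_variant",
  "regulatory_region_ablation", "regulatory_region_amplification",
  "regulatory_region_variant", "intergenic_variant")

## Terms dropped from the matrix as redundant for disease-gene curation
## (transcript_ablation is retained as the whole-gene-loss stand-in).
.CULLED <- c("upstream_gene_variant", "downstream_gene_variant",
             "NMD_transcript_variant", "TFBS_ablation", "TFBS_amplification",
             "regulatory_region_ablation", "regulatory_region_amplification",
             "intergenic_variant")

.NMD_SPLIT <- c("stop_gained", "frameshift_variant")
.NMD_SUFFIXES <- c("NMD_triggering", "NMD_escaping")

.LIKELIHOOD_LABELS <- c("almost never", "unlikely", "possible", "probable",
                        "almost always")

#' The VEP variant-class consequence set
#'
#' The 33 SO variant-class terms used by Ensembl VEP, in severity order
#' (most severe first). This is the base set from which the matrix rows are
#' derived by culling redundant terms and splitting the PTC-producing
#' classes by NMD competence.
#'
#' @return Character vector of 33 SO terms.
#' @export
vepConsequences <- function() .VEP_CONSEQUENCES

#' Matrix row keys in severity order
#'
#' Row keys are base SO terms, with `stop_gained` and `frameshift_variant`
#' split into `|NMD_triggering` / `|NMD_escaping` rows (triggering ranked
#' more severe than escaping).
#'
#' @return Character vector of row keys, most severe first.
#' @export
matrixClassKeys <- function() {
  base <- setdiff(.VEP_CONSEQUENCES, .CULLED)
  unlist(lapply(base, function(b) {
    if (b %in% .NMD_SPLIT) paste(b, .NMD_SUFFIXES, sep = "|") else b
  }), use.names = FALSE)
}

#' Severity rank of a variant-class key
#'
#' @param class Vector of row keys (or base terms resolvable to one row).
#' @return Integer rank(s); 1 is most severe.
#' @export
severityRank <- function(class) {
  keys <- matrixClassKeys()
  r <- match(class, keys)
  if (anyNA(r)) stop("unknown variant class: ",
                     paste(class[is.na(r)], collapse = ", "), call. = FALSE)
  r
}

#' Ordinal likelihood label
#'
#' @param value Integer score(s) in 1-5.
#' @return "almost never", "unlikely", "possible", "probable" or
#'   "almost always".
#' @export
likelihoodLabel <- function(value) {
  if (any(!value %in% 1:5)) stop("likelihood values must be in 1-5")
  .LIKELIHOOD_LABELS[value]
}

.matrixColumns <- function() {
  cs <- .CONSEQUENCES
  cs$name[cs$matrix_column]
}

.knownKey <- function(key) {
  base <- sub("\\|NMD_(triggering|escaping)$", "", key)
  suf <- grepl("\\|NMD_(triggering|escaping)$", key)
  base %in% .VEP_CONSEQUENCES & (!suf | base %in% .NMD_SPLIT)
}

#' Resolve a class name to a matrix row key
#'
#' Accepts an exact row key or a base SO term; a base term that maps to a
#' single row (no NMD split) resolves to it, an NMD-split base term without
#' suffix is ambiguous and errors listing the candidate rows.
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @param class Class key or base term.
#' @return The resolved row key.
#' @export
resolveClass <- function(matrix, class) {
  stopifnot(is(matrix, "ConsequenceMatrix"), length(class) == 1L)
  keys <- rownames(matrix@scores)
  if (class %in% keys) return(class)
  cand <- keys[sub("\\|.*$", "", keys) == class]
  if (length(cand) == 1L) return(cand)
  if (length(cand) > 1L)
    stop(sprintf("'%s' is ambiguous; specify one of: %s",
                 class, paste(cand, collapse = ", ")), call. = FALSE)
  stop(sprintf("unknown variant class '%s'; nearest matches: %s",
               class, paste(.nearest(class, keys), collapse = ", ")),
       call. = FALSE)
}

.resolveConsequence <- function(consequence) {
  cols <- .matrixColumns()
  q <- tolower(trimws(consequence))
  i <- which(tolower(cols) == q)
  if (!length(i)) {
    cs <- .CONSEQUENCES
    j <- which(cs$curie == consequence & cs$matrix_column)
    if (length(j)) return(cs$name[j])
    stop(sprintf("unknown consequence '%s'; nearest matches: %s", consequence,
                 paste(.nearest(consequence, cols), collapse = ", ")),
         call. = FALSE)
  }
  cols[i]
}

#' Load a consequence matrix from TSV
#'
#' Expects a first column `variant_class`, the six consequence columns by
#' exact name, and an optional `provenance` column
#' (`<consequence>=<tag>` pairs separated by ";"; unlisted cells default to
#' "user", or to "expert_default" for the bundled file).
#'
#' @param path TSV file.
#' @param defaultProvenance Tag for cells without an explicit override.
#' @return A [ConsequenceMatrix-class]; loading fails if the parsed matrix
#'   does not pass [validateMatrix()].
#' @export
loadMatrix <- function(path, defaultProvenance = "user") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cols <- .matrixColumns()
  if (!"variant_class" %in% names(df))
    stop("matrix TSV must have a 'variant_class' column", call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("matrix TSV missing consequence column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  keys <- df$variant_class
  bad <- keys[!.knownKey(keys)]
  if (length(bad))
    stop("unknown variant class in matrix TSV: ",
         paste(bad, collapse = ", "), call. = FALSE)
  s <- matrix(NA_integer_, nrow(df), length(cols),
              dimnames = list(keys, cols))
  for (cn in cols) {
    v <- suppressWarnings(as.integer(df[[cn]]))
    bad <- which(is.na(v) | v < 1L | v > 5L)
    if (length(bad))
      stop(sprintf("value '%s' out of range 1-5 at row '%s', column '%s'",
                   df[[cn]][bad[1L]], keys[bad[1L]], cn), call. = FALSE)
    s[, cn] <- v
  }
  p <- matrix(defaultProvenance, nrow(df), length(cols),
              dimnames = list(keys, cols))
  if ("provenance" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      spec <- trimws(df$provenance[i])
      if (is.na(spec) || !nzchar(spec)) next
      for (pair in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
        kv <- strsplit(pair, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
          stop("malformed provenance entry '", pair, "' at row ", keys[i],
               call. = FALSE)
        p[i, .resolveConsequence(trimws(kv[1L]))] <- trimws(kv[2L])
      }
    }
  }
  m <- new("ConsequenceMatrix", scores = s, provenance = p)
  rep <- validateMatrix(m)
  if (!isValid(rep))
    stop("matrix fails validation:\n",
         paste(utils::capture.output(show(rep)), collapse = "\n"),
         call. = FALSE)
  m
}

#' The bundled default consequence matrix
#'
#' Cells anchored in the terminology's own definitions and prose carry
#' provenance "paper_text"; the remaining cells are expert defaults
#' (provenance "expert_default") and can be overridden via a user matrix
#' loaded with [loadMatrix()].
#'
#' @return A [ConsequenceMatrix-class] with one row per class key of
#'   [matrixClassKeys()].
#' @examples
#' m <- defaultMatrix()
#' likelihood(m, "stop_gained|NMD_triggering", "absent gene product")
#' @export
defaultMatrix <- function() {
  path <- system.file("extdata", "consequence_matrix.tsv",
                      package = "AllelicReq", mustWork = TRUE)
  m <- loadMatrix(path, defaultProvenance = "expert_default")
  stopifnot(identical(rownames(m@scores), matrixClassKeys()))
  m
}

#' Serialize a consequence matrix to TSV
#'
#' Inverse of [loadMatrix()]: the round trip preserves every cell and
#' provenance tag.
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @param path Destination TSV.
#' @export
writeMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "ConsequenceMatrix"))
  s <- matrix@scores
  p <- matrix@provenance
  prov <- vapply(seq_len(nrow(s)), function(i) {
    paste(sprintf("%s=%s", colnames(p), p[i, ]), collapse = ";")
  }, character(1L))
  df <- data.frame(variant_class = rownames(s), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (cn in colnames(s)) df[[cn]] <- s[, cn]
  df$provenance <- prov
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Likelihood of a consequence for a variant class
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @param class Row key or unambiguous base term.
#' @param consequence Consequence name (case-insensitive) or SO curie.
#' @return Integer score 1-5 with its ordinal label as names.
#' @export
likelihood <- function(matrix, class, consequence) {
  key <- resolveClass(matrix, class)
  col <- .resolveConsequence(consequence)
  v <- matrix@scores[key, col]
  names(v) <- likelihoodLabel(v)
  v
}

#' Consequence profile implied by observed variant classes
#'
#' For each of the six high-level consequences, the maximum likelihood over
#' the observed classes' matrix rows. Adding a class never lowers any
#' profile value.
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @param classes Character vector of observed class keys.
#' @return Named integer vector over the six consequences; empty input
#'   gives an empty profile.
#' @export
inferConsequences <- function(matrix, classes) {
  if (length(classes) == 0L) {
    out <- integer(0)
    return(out)
  }
  keys <- vapply(classes, resolveClass, character(1L), matrix = matrix)
  sub <- matrix@scores[keys, , drop = FALSE]
  apply(sub, 2L, max)
}

#' Suggest additional variant classes consistent with observed pathogenic classes
#'
#' Reproduces the pilot inference: take the consequences that the observed
#' pathogenic classes reach with likelihood >= threshold, then admit any
#' novel class whose likelihood for one of those consequences is also
#' >= threshold (default 4, "probable").
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @param observed Observed pathogenic class keys.
#' @param threshold Integer in 1-5 (default 4).
#' @return Character vector of suggested class keys, disjoint from the
#'   observed set, ordered by severity rank.
#' @examples
#' suggestClasses(defaultMatrix(), "stop_gained|NMD_triggering")
#' @export
suggestClasses <- function(matrix, observed, threshold = 4L) {
  if (length(threshold) != 1L || is.na(threshold) || !threshold %in% 1:5)
    stop("threshold must be an integer in 1-5", call. = FALSE)
  if (length(observed) == 0L) return(character(0))
  keys <- unique(vapply(observed, resolveClass, character(1L),
                        matrix = matrix))
  profile <- inferConsequences(matrix, keys)
  target <- names(profile)[profile >= threshold]
  if (length(target) == 0L) return(character(0))
  s <- matrix@scores[, target, drop = FALSE]
  hit <- rownames(s)[apply(s >= threshold, 1L, any)]
  out <- setdiff(hit, keys)
  out[order(severityRank(out), out)]
}

#' Validate a consequence matrix
#'
#' Checks that all cells lie in 1-5, that the consequence hierarchy is
#' monotone for every class (altered level >= max(decreased, increased);
#' decreased >= absent), and that no row key is duplicated.
#'
#' @param matrix A [ConsequenceMatrix-class].
#' @return A [ValidationReport-class].
#' @export
validateMatrix <- function(matrix) {
  s <- matrix@scores
  sev <- code <- msg <- fld <- character()
  addV <- function(severity, vcode, vmsg, vfield) {
    sev <<- c(sev, severity); code <<- c(code, vcode)
    msg <<- c(msg, vmsg); fld <<- c(fld, vfield)
  }
  oob <- !(s >= 1L & s <= 5L)
  oob[is.na(oob)] <- TRUE
  bad <- which(oob, arr.ind = TRUE)
  if (nrow(bad))
    for (i in seq_len(nrow(bad)))
      addV("error", "value_out_of_range",
           sprintf("cell (%s, %s) = %s outside 1-5",
                   rownames(s)[bad[i, 1L]], colnames(s)[bad[i, 2L]],
                   s[bad[i, 1L], bad[i, 2L]]),
           rownames(s)[bad[i, 1L]])
  dup <- rownames(s)[duplicated(rownames(s))]
  for (d in unique(dup))
    addV("error", "duplicate_row", sprintf("duplicate row '%s'", d), d)
  al <- "altered gene product level"; dl <- "decreased gene product level"
  ab <- "absent gene product"; il <- "increased gene product level"
  for (k in rownames(s)) {
    if (s[k, al] < max(s[k, dl], s[k, il]))
      addV("error", "hierarchy_monotonicity",
           sprintf("'%s': altered level (%d) < max(decreased %d, increased %d)",
                   k, s[k, al], s[k, dl], s[k, il]), k)
    if (s[k, dl] < s[k, ab])
      addV("error", "hierarchy_monotonicity",
           sprintf("'%s': decreased level (%d) < absent (%d)",
                   k, s[k, dl], s[k, ab]), k)
  }
  .newReport(sev, code, msg, fld)
}
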