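## Gene-disease curation records: construction, validation, TSV/JSON I/O.

.CURATION_COLUMNS <- c("gene", "gene_id", "disease", "disease_id",
                       "allelic_requirement", "qualifiers",
                       "disease_associated_consequences",
                       "known_pathogenic_variant_classes",
                       "mechanism_note", "source")

## Mutually exclusive qualifier pairs (by curie). Complete penetrance
## excludes incomplete penetrance and both its children; moderate vs high
## penetrance, maternal vs paternal imprinting and male- vs female-limited
## expression are sibling-exclusive.
.EXCLUSIVE_QUALIFIERS <- list(
  c("HP:0034950", "HP:0003829"),  # complete vs incomplete penetrance
  c("HP:0034950", "HP:4000159"),  # complete vs moderate penetrance
  c("HP:0034950", "HP:4000158"),  # complete vs high penetrance
  c("HP:4000159", "HP:4000158"),  # moderate vs high penetrance
  c("HP:0012275", "HP:0012274"),  # maternal vs paternal imprinting
  c("HP:0001475", "HP:0034344")   # male- vs female-limited expression
)

#' Construct a gene-disease curation record
#'
#' Qualifiers may be given as HPO curies or labels (case-insensitive) and
#' are canonicalized to curies. Construction is permissive about vocabulary
#' membership; use [validateCuration()] for the full rule set.
#'
#' @param gene Gene symbol.
#' @param disease Disease label.
#' @param allelicRequirement Requirement token (see [requirementTokens()])
#'   or "non_mendelian".
#' @param qualifiers Character vector of qualifier curies or labels.
#' @param consequences Character vector of high-level consequence names.
#' @param knownClasses Character vector of variant-class keys.
#' @param geneId,diseaseId,mechanismNote,source Optional annotations.
#' @param vocabulary Vocabulary used to canonicalize qualifier labels.
#' @return A [GeneDiseaseCuration-class] object.
#' @export
GeneDiseaseCuration <- function(gene, disease, allelicRequirement,
                                qualifiers = character(),
                                consequences = character(),
                                knownClasses = character(),
                                geneId = "", diseaseId = "",
                                mechanismNote = "", source = "",
                                vocabulary = buildVocabulary()) {
  qualifiers <- vapply(qualifiers, function(q) {
    q <- trimws(q)
    if (grepl(.CURIE_RE, q)) return(q)
    i <- which(tolower(vocabulary@qualifiers$label) == tolower(q))
    if (length(i)) vocabulary@qualifiers$curie[i[1L]] else q
  }, character(1L), USE.NAMES = FALSE)
  new("GeneDiseaseCuration",
      gene = as.character(gene), geneId = as.character(geneId),
      disease = as.character(disease), diseaseId = as.character(diseaseId),
      allelicRequirement = as.character(allelicRequirement),
      qualifiers = unname(qualifiers),
      consequences = as.character(consequences),
      knownClasses = as.character(knownClasses),
      mechanismNote = as.character(mechanismNote),
      source = as.character(source))
}

#' Validate a curation record against the vocabulary
#'
#' Deterministic, order-independent rule set:
#' \itemize{
#'   \item errors: missing/unknown allelic requirement; unknown qualifier,
#'     consequence or variant-class names; empty gene or disease;
#'     co-asserted mutually exclusive qualifier children (complete vs
#'     incomplete penetrance and its children, maternal vs paternal
#'     imprinting, male- vs female-limited expression).
#'   \item warnings: "requires heterozygosity" together with a biallelic
#'     requirement (such disorders are currently all X-linked, but the
#'     mechanism is theoretically possible in autosomal genes);
#'     empty consequence set while known pathogenic classes are recorded.
#' }
#'
#' @param record A [GeneDiseaseCuration-class].
#' @param vocabulary A [Vocabulary-class].
#' @return A [ValidationReport-class]; an empty report means valid.
#' @examples
#' v <- buildVocabulary()
#' rec <- GeneDiseaseCuration("EFNB1", "Craniofrontonasal dysplasia",
#'                            "monoallelic_X_heterozygous",
#'                            qualifiers = "HP:0034343")
#' isValid(validateCuration(rec, v))
#' @export
validateCuration <- function(record, vocabulary = buildVocabulary()) {
  sev <- code <- msg <- fld <- character()
  addV <- function(severity, vcode, vmsg, vfield) {
    sev <<- c(sev, severity); code <<- c(code, vcode)
    msg <<- c(msg, vmsg); fld <<- c(fld, vfield)
  }
  if (!nzchar(record@gene))
    addV("error", "missing_field", "gene symbol is empty", "gene")
  if (!nzchar(record@disease))
    addV("error", "missing_field", "disease label is empty", "disease")
  req <- record@allelicRequirement
  tokens <- vocabulary@requirements$token
  if (!nzchar(req) || is.na(req)) {
    addV("error", "missing_field", "allelic_requirement is missing",
         "allelic_requirement")
  } else if (!req %in% c(tokens, "non_mendelian")) {
    addV("error", "unknown_term",
         sprintf("unknown allelic requirement '%s'; nearest matches: %s",
                 req, paste(.nearest(req, tokens), collapse = ", ")),
         "allelic_requirement")
  }
  known <- vocabulary@qualifiers$curie
  for (q in record@qualifiers)
    if (!q %in% known)
      addV("error", "unknown_term",
           sprintf("unknown qualifier '%s'", q), "qualifiers")
  cols <- vocabulary@consequences$name[vocabulary@consequences$matrix_column]
  for (cq in record@consequences)
    if (!tolower(cq) %in% tolower(cols))
      addV("error", "unknown_term",
           sprintf("unknown consequence '%s'; nearest matches: %s", cq,
                   paste(.nearest(cq, cols), collapse = ", ")),
           "disease_associated_consequences")
  for (k in record@knownClasses)
    if (!.knownKey(k))
      addV("error", "unknown_term",
           sprintf("unknown variant class '%s'", k),
           "known_pathogenic_variant_classes")
  qs <- record@qualifiers
  for (pair in .EXCLUSIVE_QUALIFIERS)
    if (all(pair %in% qs))
      addV("error", "mutually_exclusive_qualifiers",
           sprintf("qualifiers %s and %s are mutually exclusive",
                   pair[1L], pair[2L]), "qualifiers")
  if ("HP:0034343" %in% qs &&
      req %in% tokens[vocabulary@requirements$copy_requirement == "biallelic"])
    addV("warning", "requires_het_with_biallelic",
         "'Requires heterozygosity' with a biallelic requirement: known disorders of this kind are all X-linked",
         "qualifiers")
  if (length(record@consequences) == 0L && length(record@knownClasses) > 0L)
    addV("warning", "consequences_empty",
         "known pathogenic classes recorded but no disease-associated consequences; consider inferConsequences()",
         "disease_associated_consequences")
  .newReport(sev, code, msg, fld)
}

.splitMulti <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

.curationFromFields <- function(fields, index, vocabulary) {
  getf <- function(nm) {
    v <- fields[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) "" else as.character(v)
  }
  rec <- GeneDiseaseCuration(
    gene = getf("gene"), geneId = getf("gene_id"),
    disease = getf("disease"), diseaseId = getf("disease_id"),
    allelicRequirement = getf("allelic_requirement"),
    qualifiers = .splitMulti(getf("qualifiers")),
    consequences = .splitMulti(getf("disease_associated_consequences")),
    knownClasses = .splitMulti(getf("known_pathogenic_variant_classes")),
    mechanismNote = getf("mechanism_note"), source = getf("source"),
    vocabulary = vocabulary)
  rep <- validateCuration(rec, vocabulary)
  bad <- violations(rep)
  bad <- bad[bad$severity == "error" &
             bad$code %in% c("unknown_term", "missing_field"), , drop = FALSE]
  if (nrow(bad))
    stop(sprintf("record %d: parse error in field '%s': %s",
                 index, bad$field[1L], bad$message[1L]), call. = FALSE)
  rec
}

#' Read curation records
#'
#' TSV has one record per row with the toolkit's column set
#' (gene, gene_id, disease, disease_id, allelic_requirement, qualifiers,
#' disease_associated_consequences, known_pathogenic_variant_classes,
#' mechanism_note, source; multi-valued fields ";"-separated). JSON is a
#' list of objects with the same field names. Unresolvable terms raise an
#' error naming the record index and field.
#'
#' @param path Input file.
#' @param format "tsv" or "json" ("auto" infers from the extension).
#' @param vocabulary Vocabulary for term resolution.
#' @return List of [GeneDiseaseCuration-class] records.
#' @export
readCurations <- function(path, format = c("auto", "tsv", "json"),
                          vocabulary = buildVocabulary()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, colClasses = "character")
    missing <- setdiff(c("gene", "disease", "allelic_requirement"), names(df))
    if (length(missing))
      stop("curation TSV missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(rows)) stop("curation JSON must be a list of objects")
    rows <- lapply(rows, function(r) {
      lapply(r, function(v)
        if (length(v) > 1L) paste(unlist(v), collapse = ";") else v)
    })
  }
  lapply(seq_along(rows), function(i)
    .curationFromFields(rows[[i]], i, vocabulary))
}

.curationToFields <- function(rec) {
  list(gene = rec@gene, gene_id = rec@geneId, disease = rec@disease,
       disease_id = rec@diseaseId,
       allelic_requirement = rec@allelicRequirement,
       qualifiers = paste(rec@qualifiers, collapse = ";"),
       disease_associated_consequences =
         paste(rec@consequences, collapse = ";"),
       known_pathogenic_variant_classes =
         paste(rec@knownClasses, collapse = ";"),
       mechanism_note = rec@mechanismNote, source = rec@source)
}

#' Write curation records
#'
#' Inverse of [readCurations()]: write followed by read is the identity on
#' valid records.
#'
#' @param records List of [GeneDiseaseCuration-class].
#' @param path Destination file.
#' @param format "tsv" or "json" ("auto" infers from the extension).
#' @export
writeCurations <- function(records, path,
                           format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  rows <- lapply(records, .curationToFields)
  if (format == "tsv") {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
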