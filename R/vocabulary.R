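## Harmonized terminology: mode-of-inheritance categories, the eight
## allelic-requirement / Mendelian-inheritance pairs (shared HPO ids),
## cross-cutting inheritance qualifiers, and the SO disease-associated
## consequence hierarchy.

.MOI_CATEGORIES <- data.frame(
  label = c("Mode of inheritance", "Mendelian inheritance",
            "Inheritance qualifier", "Non-Mendelian inheritance"),
  curie = c("HP:0000005", "HP:0034345", "HP:0034335", "HP:0001426"),
  parent = c(NA, "HP:0000005", "HP:0000005", "HP:0000005"),
  stringsAsFactors = FALSE
)

.REQUIREMENTS <- data.frame(
  token = c("monoallelic_autosomal", "biallelic_autosomal",
            "monoallelic_X_heterozygous", "monoallelic_X_hemizygous",
            "monoallelic_Y_hemizygous", "mitochondrial",
            "monoallelic_PAR", "biallelic_PAR"),
  inheritance = c("Autosomal Dominant", "Autosomal Recessive",
                  "X-linked Dominant", "X-linked Recessive",
                  "Y-linked", "Mitochondrial",
                  "PAR dominant", "PAR recessive"),
  curie = c("HP:0000006", "HP:0000007", "HP:0001423", "HP:0001419",
            "HP:0001450", "HP:0001427", "HP:0034340", "HP:0034341"),
  chromosome_context = c("autosomal", "autosomal", "X", "X", "Y", "MT",
                         "PAR", "PAR"),
  copy_requirement = c("monoallelic", "biallelic", "monoallelic",
                       "monoallelic", "monoallelic", "not_applicable",
                       "monoallelic", "biallelic"),
  x_zygosity_context = c("not_applicable", "not_applicable", "heterozygous",
                         "hemizygous", "not_applicable", "not_applicable",
                         "not_applicable", "not_applicable"),
  stringsAsFactors = FALSE
)

.QUALIFIERS <- data.frame(
  label = c("Typified by somatic mosaicism", "Typically de novo",
            "Typified by incomplete penetrance",
            "Typified by moderate penetrance",
            "Typified by high penetrance",
            "Typified by complete penetrance",
            "Typified by highly variable age of onset",
            "Typified by age-related onset",
            "Imprinted", "With maternal imprinting",
            "With paternal imprinting",
            "Displays anticipation", "Requires heterozygosity",
            "Sex-limited expression", "Male-limited expression",
            "Female-limited expression", "Contiguous gene syndrome"),
  curie = c("HP:0001442", "HP:0025352", "HP:0003829", "HP:4000159",
            "HP:4000158", "HP:0034950", "HP:0034857", "HP:0003831",
            "HP:0034338", "HP:0012275", "HP:0012274", "HP:0003743",
            "HP:0034343", "HP:0001470", "HP:0001475", "HP:0034344",
            "HP:0001466"),
  parent = c(NA, NA, NA, "HP:0003829", "HP:0003829", NA, NA, NA,
             NA, "HP:0034338", "HP:0034338", NA, NA, NA, "HP:0001470",
             "HP:0001470", NA),
  stringsAsFactors = FALSE
)

## Six high-level consequence columns plus the two non-column hierarchy
## nodes; decreased and increased are children of altered level, absent is
## a child of decreased.
.CONSEQUENCES <- data.frame(
  name = c("altered gene product level", "decreased gene product level",
           "absent gene product", "increased gene product level",
           "altered gene product sequence", "functionally normal",
           "function uncertain", "functionally abnormal"),
  curie = c("SO:0002314", "SO:0002316", "SO:0002317", "SO:0002315",
            "SO:0002318", "SO:0002219", "SO:0002220", "SO:0002218"),
  parent = c(NA, "altered gene product level",
             "decreased gene product level", "altered gene product level",
             NA, NA, NA, NA),
  matrix_column = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.CURIE_RE <- "^(HP|SO):[0-9]{7}$"

#' Build the harmonized terminology vocabulary
#'
#' Assembles the built-in term tables: top-level mode-of-inheritance
#' categories, the eight allelic-requirement / Mendelian-inheritance pairs
#' (each pair shares one HPO identifier; the requirement token is an
#' allelic-requirement synonym of the inheritance term), the inheritance
#' qualifiers (parents and children), and the SO disease-associated
#' consequence hierarchy.
#'
#' @return A [Vocabulary-class] object.
#' @examples
#' v <- buildVocabulary()
#' vocabLookup(v, "monoallelic_autosomal")
#' @export
buildVocabulary <- function() {
  stopifnot(all(grepl(.CURIE_RE, .REQUIREMENTS$curie)),
            all(grepl(.CURIE_RE, .QUALIFIERS$curie)),
            all(grepl(.CURIE_RE, .CONSEQUENCES$curie)))
  new("Vocabulary",
      categories   = .MOI_CATEGORIES,
      requirements = .REQUIREMENTS,
      qualifiers   = .QUALIFIERS,
      consequences = .CONSEQUENCES)
}

.nearest <- function(query, candidates, n = 3L) {
  d <- utils::adist(tolower(query), tolower(candidates))
  candidates[order(d)][seq_len(min(n, length(candidates)))]
}

#' Look up a vocabulary term
#'
#' Resolves a requirement token, an inheritance label, a qualifier label or
#' an HP/SO curie to its vocabulary entry. Label and token matching is
#' case-insensitive; curie matching is exact. Because a requirement token
#' and its paired inheritance term share one HPO identifier, looking up a
#' shared curie resolves to the pair entry.
#'
#' @param vocabulary A [Vocabulary-class] object.
#' @param term Token, label or curie.
#' @return A one-row data.frame with an added `kind` column
#'   ("requirement_pair", "qualifier", "consequence" or "category").
#' @export
vocabLookup <- function(vocabulary, term) {
  stopifnot(is(vocabulary, "Vocabulary"), is.character(term),
            length(term) == 1L)
  q <- tolower(trimws(term))
  req <- vocabulary@requirements
  hit <- req[tolower(req$token) == q | tolower(req$inheritance) == q |
             tolower(req$curie) == tolower(term), , drop = FALSE]
  if (nrow(hit)) return(cbind(hit[1L, ], kind = "requirement_pair"))
  qu <- vocabulary@qualifiers
  hit <- qu[tolower(qu$label) == q | qu$curie == term, , drop = FALSE]
  if (nrow(hit)) return(cbind(hit[1L, ], kind = "qualifier"))
  cs <- vocabulary@consequences
  hit <- cs[tolower(cs$name) == q | cs$curie == term, , drop = FALSE]
  if (nrow(hit)) return(cbind(hit[1L, ], kind = "consequence"))
  ca <- vocabulary@categories
  hit <- ca[tolower(ca$label) == q | ca$curie == term, , drop = FALSE]
  if (nrow(hit)) return(cbind(hit[1L, ], kind = "category"))
  near <- .nearest(term, c(req$token, req$inheritance, qu$label, cs$name))
  stop(sprintf("unknown term '%s'; nearest matches: %s",
               term, paste(near, collapse = ", ")), call. = FALSE)
}

#' Map between allelic-requirement and inheritance terms
#'
#' The eight requirement tokens and the eight Mendelian inheritance terms
#' form a bijection; applying the map twice returns the input.
#'
#' @param vocabulary A [Vocabulary-class] object.
#' @param term A requirement token, inheritance label, or shared curie.
#' @param direction "auto" (infer from the input), "requirement_to_inheritance"
#'   or "inheritance_to_requirement".
#' @return Named list with `token`, `inheritance` and `curie` of the pair,
#'   plus `mapped`, the partner term in the requested direction.
#' @examples
#' v <- buildVocabulary()
#' mapRequirementInheritance(v, "monoallelic_X_hemizygous")$mapped
#' @export
mapRequirementInheritance <- function(vocabulary, term,
                                      direction = c("auto",
                                        "requirement_to_inheritance",
                                        "inheritance_to_requirement")) {
  direction <- match.arg(direction)
  req <- vocabulary@requirements
  q <- tolower(trimws(term))
  ## exact matches take precedence so that pairs whose token and label
  ## differ only by case (mitochondrial / Mitochondrial) stay directional
  i <- which(req$token == trimws(term))
  isToken <- length(i) > 0L
  if (!isToken) {
    i <- which(req$inheritance == trimws(term))
    if (!length(i)) {
      i <- which(tolower(req$token) == q)
      isToken <- length(i) > 0L
    }
    if (!length(i)) i <- which(tolower(req$inheritance) == q |
                               tolower(req$curie) == q)
  }
  if (!length(i)) {
    near <- .nearest(term, c(req$token, req$inheritance))
    stop(sprintf("unknown requirement/inheritance term '%s'; nearest matches: %s",
                 term, paste(near, collapse = ", ")), call. = FALSE)
  }
  i <- i[1L]
  if (direction == "auto")
    direction <- if (isToken) "requirement_to_inheritance" else
                              "inheritance_to_requirement"
  mapped <- if (direction == "requirement_to_inheritance")
    req$inheritance[i] else req$token[i]
  list(token = req$token[i], inheritance = req$inheritance[i],
       curie = req$curie[i], mapped = mapped)
}

#' Allelic-requirement tokens
#'
#' @param vocabulary A [Vocabulary-class] object (default: built fresh).
#' @return Character vector of the eight requirement tokens.
#' @export
requirementTokens <- function(vocabulary = buildVocabulary()) {
  vocabulary@requirements$token
}
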