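## Controlled vocabularies for panel entries.
##
## Each curated entry links a gene to a disease through a disease mechanism:
## an allelic requirement (the genotype configuration needed at the locus)
## and a mutation consequence (the mechanism class of pathogenic variants).
## A confidence level states how firmly the gene is implicated; confirmed and
## probable entries are reportable for diagnosis, possible entries are not,
## and "both RD and IF" entries are reportable but flag a potential
## incidental finding alongside the relevant disease.

#' Controlled vocabularies
#'
#' Canonical tokens for the panel-entry confidence levels, allelic
#' requirements and mutation-consequence mechanisms, and the derived subsets
#' the filter relies on.
#'
#' @name vocabularies
#' @aliases G2P_CONFIDENCE G2P_REPORTABLE_CONFIDENCE G2P_ALLELIC_REQUIREMENT
#'   G2P_MUTATION_CONSEQUENCE MONOALLELIC_LIKE_REQUIREMENTS
#'   UNSUPPORTED_REQUIREMENTS
#' @export
G2P_CONFIDENCE <- c("confirmed", "probable", "possible", "both_rd_and_if")

#' @rdname vocabularies
#' @export
G2P_REPORTABLE_CONFIDENCE <- c("confirmed", "probable", "both_rd_and_if")

#' @rdname vocabularies
#' @export
G2P_ALLELIC_REQUIREMENT <- c(
  "monoallelic", "biallelic", "hemizygous", "x_linked_dominant",
  "x_linked_over_dominance", "imprinted", "mosaic", "mitochondrial",
  "digenic", "uncertain"
)

#' @rdname vocabularies
#' @export
G2P_MUTATION_CONSEQUENCE <- c(
  "loss_of_function", "activating", "dominant_negative", "utr_mutation",
  "cis_regulatory", "increased_gene_dosage", "all_missense_in_frame",
  "uncertain"
)

## Requirements satisfiable by a single altered allele; these share the
## stringent (monoallelic) MAF cut-off in the filter.
#' @rdname vocabularies
#' @export
MONOALLELIC_LIKE_REQUIREMENTS <- c(
  "monoallelic", "hemizygous", "x_linked_dominant",
  "x_linked_over_dominance", "imprinted", "mosaic"
)

## Requirements the genotype-aggregation engine cannot establish from a
## single proband VCF (digenic needs a second locus, mitochondrial needs
## heteroplasmy handling, uncertain has no defined genotype model).
#' @rdname vocabularies
#' @export
UNSUPPORTED_REQUIREMENTS <- c("digenic", "mitochondrial", "uncertain")

## Common alternative spellings seen in public downloads, mapped onto the
## canonical tokens after lower-casing and squashing of non-alphanumerics.
.vocab_aliases <- c(
  "both_rd_and_if"            = "both_rd_and_if",
  "rd_and_if"                 = "both_rd_and_if",
  "both_rd_if"                = "both_rd_and_if",
  "loss_of_function"          = "loss_of_function",
  "all_missense_in_frame"     = "all_missense_in_frame",
  "all_missense_inframe"      = "all_missense_in_frame",
  "5_or_3_utr_mutation"       = "utr_mutation",
  "utr_mutation"              = "utr_mutation",
  "cis_regulatory_or_promotor_mutation" = "cis_regulatory",
  "cis_regulatory_or_promoter_mutation" = "cis_regulatory",
  "cis_regulatory"            = "cis_regulatory",
  "increased_gene_dosage"     = "increased_gene_dosage",
  "x_linked_dominant"         = "x_linked_dominant",
  "x_linked_over_dominance"   = "x_linked_over_dominance",
  "hemizygous"                = "hemizygous",
  "monoallelic"               = "monoallelic",
  "biallelic"                 = "biallelic",
  "imprinted"                 = "imprinted",
  "mosaic"                    = "mosaic",
  "mitochondrial"             = "mitochondrial",
  "digenic"                   = "digenic",
  "uncertain"                 = "uncertain",
  "unknown"                   = "uncertain",
  "confirmed"                 = "confirmed",
  "probable"                  = "probable",
  "possible"                  = "possible",
  "activating"                = "activating",
  "dominant_negative"         = "dominant_negative"
)

.squash_token <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

## Normalize a vector of raw vocabulary strings onto one of the canonical
## vocabularies; unknown values raise a validation error naming the offender.
normalize_vocab <- function(x, vocabulary, what, row_ids = NULL) {
  tok <- .squash_token(as.character(x))
  mapped <- unname(.vocab_aliases[tok])
  mapped[is.na(mapped) & tok %in% vocabulary] <- tok[is.na(mapped) & tok %in% vocabulary]
  bad <- which(is.na(mapped) | !(mapped %in% vocabulary))
  if (length(bad) > 0L) {
    where <- if (is.null(row_ids)) bad[1L] else row_ids[bad[1L]]
    stop(sprintf("unknown %s value '%s' (row %s)", what, x[bad[1L]], where),
         call. = FALSE)
  }
  mapped
}
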