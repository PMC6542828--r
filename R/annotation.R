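## Parsing and classification of VEP-style CSQ transcript consequences.
##
## VEP writes one INFO key (CSQ by default) per record holding one
## comma-separated block per (alternate allele x transcript), each block a
## pipe-delimited list of subfields whose order is declared once in the VCF
## header line ##INFO=<ID=CSQ,...Description="...Format: Allele|...">.

## Sequence Ontology terms treated as loss-of-function; config-overridable
## via the `lof_terms` argument of classify_consequence().
#' Consequence term sets
#'
#' The Sequence Ontology terms counted as loss-of-function, the in-frame
#' term set, and the ordered consequence classes (most severe first).
#' @name consequence-terms
#' @aliases LOF_SO_TERMS INFRAME_SO_TERMS CONSEQUENCE_CLASSES
#' @export
LOF_SO_TERMS <- c("stop_gained", "frameshift_variant",
                  "splice_acceptor_variant", "splice_donor_variant",
                  "start_lost", "transcript_ablation")

#' @rdname consequence-terms
#' @export
INFRAME_SO_TERMS <- c("inframe_insertion", "inframe_deletion", "stop_lost")

#' @rdname consequence-terms
#' @export
CONSEQUENCE_CLASSES <- c("lof", "missense", "inframe", "splice_region",
                         "other")

#' Extract the CSQ subfield order from a VCF header description
#'
#' @param description the Description string of the CSQ INFO header line,
#'   e.g. `"Consequence annotations from Ensembl VEP. Format: Allele|..."`.
#' @return Character vector of subfield names, in order.
#' @export
csq_field_order <- function(description) {
  m <- regmatches(description,
                  regexpr("Format:\\s*[^\"]+", description))
  if (length(m) == 0L || m == "") {
    stop("CSQ header description does not declare a 'Format:' field order",
         call. = FALSE)
  }
  fields <- sub("Format:\\s*", "", m)
  strsplit(trimws(fields), "|", fixed = TRUE)[[1]]
}

## Which CSQ subfields carry population allele frequencies. Anything whose
## name ends in "AF" (gnomAD_AF, TOPMed_AF, UK10K_AF, EA_AF, MAX_AF, AF...)
## is treated as a named frequency source; override with `af_fields`.
detect_af_fields <- function(fields) {
  fields[grepl("AF$", fields)]
}

#' Parse a CSQ INFO value into transcript consequence annotations
#'
#' The subfield order is taken from the header description, never assumed.
#' Each comma-separated block becomes one annotation row; empty subfields
#' become missing values.
#'
#' @param header_description Description string of the CSQ INFO header line.
#' @param csq_value the raw CSQ value of one record (may be `NA` or empty:
#'   returns a zero-row frame).
#' @param af_fields names of subfields holding population allele frequencies;
#'   autodetected from the header by default.
#' @param record_id optional record coordinate string used in error messages.
#' @return Data frame with one row per annotation: columns `allele`,
#'   `gene_symbol`, `transcript_id`, `is_canonical`, `so_terms` (ampersand
#'   joined), `sift_prediction`, `sift_score`, `polyphen_prediction`,
#'   `polyphen_score`, `cadd_phred`, one numeric column per AF source, and
#'   attribute `af_fields` naming those columns.
#' @export
parse_csq <- function(header_description, csq_value,
                      af_fields = NULL, record_id = NULL) {
  fields <- csq_field_order(header_description)
  if (is.null(af_fields)) af_fields <- detect_af_fields(fields)
  empty <- .csq_frame(character(0), fields, af_fields, record_id)
  if (length(csq_value) == 0L || is.na(csq_value) || csq_value == "") {
    return(empty)
  }
  blocks <- strsplit(csq_value, ",", fixed = TRUE)[[1]]
  .csq_frame(blocks, fields, af_fields, record_id)
}

.csq_frame <- function(blocks, fields, af_fields, record_id) {
  nf <- length(fields)
  if (length(blocks) > 0L) {
    parts <- strsplit(blocks, "|", fixed = TRUE)
    lens <- vapply(parts, length, integer(1))
    if (any(lens > nf)) {
      where <- if (is.null(record_id)) "" else paste0(" at ", record_id)
      stop(sprintf("CSQ block has %d subfields but header declares %d%s",
                   max(lens), nf, where), call. = FALSE)
    }
    ## VEP drops trailing empty subfields; right-pad
    mat <- t(vapply(parts, function(p) c(p, rep("", nf - length(p))),
                    character(nf)))
  } else {
    mat <- matrix(character(0), nrow = 0L, ncol = nf)
  }
  colnames(mat) <- fields
  grab <- function(nm) {
    if (nm %in% fields) as.character(mat[, nm]) else
      rep(NA_character_, nrow(mat))
  }
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  so <- blank_to_na(grab("Consequence"))
  sift <- .split_pred_score(blank_to_na(grab("SIFT")))
  poly <- .split_pred_score(blank_to_na(grab("PolyPhen")))
  cadd_raw <- blank_to_na(grab("CADD_PHRED"))
  out <- data.frame(
    allele = blank_to_na(grab("Allele")),
    gene_symbol = blank_to_na(grab("SYMBOL")),
    transcript_id = blank_to_na(grab("Feature")),
    is_canonical = !is.na(blank_to_na(grab("CANONICAL"))) &
      grab("CANONICAL") == "YES",
    so_terms = so,
    sift_prediction = sift$prediction,
    sift_score = sift$score,
    polyphen_prediction = poly$prediction,
    polyphen_score = poly$score,
    cadd_phred = suppressWarnings(as.numeric(cadd_raw)),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$cadd_phred) & out$cadd_phred < 0)) {
    stop("negative CADD score in CSQ annotation", call. = FALSE)
  }
  for (af in af_fields) {
    v <- suppressWarnings(as.numeric(blank_to_na(grab(af))))
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("allele frequency outside [0,1] in CSQ field %s", af),
           call. = FALSE)
    }
    out[[af]] <- v
  }
  attr(out, "af_fields") <- af_fields
  out
}

## "deleterious(0.01)" -> prediction "deleterious", score 0.01
.split_pred_score <- function(x) {
  pred <- sub("\\(.*\\)$", "", x)
  score <- suppressWarnings(as.numeric(sub("^.*\\(([^)]*)\\)$", "\\1", x)))
  score[!grepl("\\(", ifelse(is.na(x), "", x))] <- NA_real_
  list(prediction = ifelse(is.na(x), NA_character_, pred), score = score)
}

#' Classify Sequence Ontology consequence terms
#'
#' Most-severe-wins over the recognised classes: `lof` (stop gained,
#' frameshift, essential splice site, start lost, transcript ablation), then
#' `missense`, then `inframe` (inframe indel, stop lost), then
#' `splice_region`, else `other`. Order-independent in the input terms.
#'
#' @param so_terms character vector of SO terms, or a single
#'   ampersand-joined string as VEP writes it.
#' @param lof_terms the SO terms counted as loss-of-function.
#' @return One of `"lof"`, `"missense"`, `"inframe"`, `"splice_region"`,
#'   `"other"`.
#' @export
classify_consequence <- function(so_terms, lof_terms = LOF_SO_TERMS) {
  if (length(so_terms) == 1L && !is.na(so_terms) &&
      grepl("&", so_terms, fixed = TRUE)) {
    so_terms <- strsplit(so_terms, "&", fixed = TRUE)[[1]]
  }
  so_terms <- so_terms[!is.na(so_terms) & so_terms != ""]
  if (length(so_terms) == 0L) {
    stop("cannot classify an empty consequence term list", call. = FALSE)
  }
  if (any(so_terms %in% lof_terms)) return("lof")
  if ("missense_variant" %in% so_terms) return("missense")
  if (any(so_terms %in% INFRAME_SO_TERMS)) return("inframe")
  if ("splice_region_variant" %in% so_terms) return("splice_region")
  "other"
}

#' Consequence classes admissible for a mutation-consequence mechanism
#'
#' Loss-of-function genes admit LOF plus predicted-deleterious coding classes
#' (missense/in-frame/splice region); missense/in-frame mechanism genes and
#' gain-type mechanisms (activating, dominant negative) admit missense and
#' in-frame only; uncertain admits everything coding; UTR, cis-regulatory and
#' gene-dosage mechanisms are not detectable from coding consequences and
#' return an empty set (reported as unsupported upstream).
#'
#' @param mutation_consequence one vocabulary value.
#' @param overrides optional named list mapping mechanism values to class
#'   vectors, replacing the defaults.
#' @return Character vector of admissible classes (possibly empty).
#' @export
allowed_classes <- function(mutation_consequence, overrides = NULL) {
  mc <- normalize_vocab(mutation_consequence, G2P_MUTATION_CONSEQUENCE,
                        "mutation consequence")
  if (!is.null(overrides) && !is.null(overrides[[mc]])) {
    cls <- overrides[[mc]]
    stopifnot(all(cls %in% CONSEQUENCE_CLASSES))
    return(cls)
  }
  switch(mc,
    loss_of_function      = c("lof", "missense", "inframe", "splice_region"),
    all_missense_in_frame = c("missense", "inframe"),
    activating            = c("missense", "inframe"),
    dominant_negative     = c("missense", "inframe"),
    uncertain             = c("lof", "missense", "inframe", "splice_region"),
    utr_mutation          = character(0),
    cis_regulatory        = character(0),
    increased_gene_dosage = character(0)
  )
}

#' Maximum population allele frequency of an annotation
#'
#' The frequency filter compares each variant against its worst case: the
#' maximum frequency over all populated reference sources. An allele absent
#' from every source ("not seen in any control databases") has frequency 0.
#'
#' @param tc one-row data frame (or list) from [parse_csq()], or a data frame
#'   of several rows (vectorised).
#' @param af_fields frequency column names; taken from the `af_fields`
#'   attribute when present.
#' @return Numeric vector of maxima in \[0,1\], 0 where no source is populated.
#' @export
max_population_af <- function(tc, af_fields = NULL) {
  if (is.null(af_fields)) af_fields <- attr(tc, "af_fields")
  if (is.null(af_fields)) af_fields <- detect_af_fields(names(tc))
  if (length(af_fields) == 0L) {
    return(rep(0, if (is.data.frame(tc)) nrow(tc) else 1L))
  }
  m <- as.matrix(as.data.frame(tc)[, af_fields, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.na(m) & (m < 0 | m > 1))) {
    stop("allele frequency outside [0,1]", call. = FALSE)
  }
  out <- apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) 0 else max(r)
  })
  as.numeric(out)
}
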