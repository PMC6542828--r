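#' Construct a gene panel
#'
#' A panel is an ordered collection of curated entries, each linking one gene
#' to one disease through an allelic requirement and a mutation consequence,
#' together with a confidence level, HPO phenotype terms and supporting
#' publications. A gene may carry several entries (e.g. monoallelic/activating
#' and biallelic/loss-of-function), and lookups by gene must return all of
#' them.
#'
#' @param entries data frame with columns `gene_symbol`, `disease_name`,
#'   `confidence`, `allelic_requirement`, `mutation_consequence` and
#'   optionally `gene_ids`, `hpo_terms`, `organ_specificity`, `pmids`
#'   (multi-valued cells semicolon-delimited).
#' @param name panel name.
#' @return An object of class `g2p_panel`.
#' @export
g2p_panel <- function(entries, name = "panel") {
  required <- c("gene_symbol", "disease_name", "confidence",
                "allelic_requirement", "mutation_consequence")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("panel entries missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("gene_ids", "hpo_terms", "organ_specificity", "pmids")) {
    if (is.null(entries[[opt]])) entries[[opt]] <- ""
  }
  entries$gene_symbol <- trimws(as.character(entries$gene_symbol))
  if (any(is.na(entries$gene_symbol) | entries$gene_symbol == "")) {
    stop("gene_symbol must be non-empty for every panel entry", call. = FALSE)
  }
  entries$confidence <- normalize_vocab(
    entries$confidence, G2P_CONFIDENCE, "confidence", seq_len(nrow(entries)))
  entries$allelic_requirement <- normalize_vocab(
    entries$allelic_requirement, G2P_ALLELIC_REQUIREMENT,
    "allelic requirement", seq_len(nrow(entries)))
  entries$mutation_consequence <- normalize_vocab(
    entries$mutation_consequence, G2P_MUTATION_CONSEQUENCE,
    "mutation consequence", seq_len(nrow(entries)))
  entries <- entries[, c(required[1L], "gene_ids", required[2L:5L],
                         "hpo_terms", "organ_specificity", "pmids")]
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries), class = "g2p_panel")
}

#' @export
print.g2p_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s': %d entries, %d distinct genes\n",
              x$name, nrow(x$entries), length(unique(x$entries$gene_symbol))))
  tab <- table(x$entries$confidence)
  cat("  confidence:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of panel entries
#' @param x a `g2p_panel`.
#' @export
length.g2p_panel <- function(x) nrow(x$entries)

#' All entries for one gene
#'
#' Returns every entry carried by `gene` (a gene may have more than one
#' reportable entry).
#'
#' @param panel a `g2p_panel`.
#' @param gene gene symbol (case-sensitive after trimming).
#' @return Data frame of matching entries (possibly zero rows).
#' @export
panel_entries_for_gene <- function(panel, gene) {
  stopifnot(inherits(panel, "g2p_panel"))
  panel$entries[panel$entries$gene_symbol == trimws(gene), , drop = FALSE]
}

#' Distinct gene symbols in a panel
#' @param panel a `g2p_panel`.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "g2p_panel"))
  unique(panel$entries$gene_symbol)
}

## Default header-name candidates for the CSV reader; the public download
## format is not byte-specified, so each logical field accepts several
## header spellings (matched case-insensitively) and the whole map is
## caller-overridable.
default_panel_columns <- function() {
  list(
    gene_symbol          = c("gene symbol", "gene", "gene_symbol"),
    gene_ids             = c("hgnc id", "gene mim", "gene_ids", "gene ids"),
    disease_name         = c("disease name", "disease", "disease_name"),
    confidence           = c("ddd category", "g2p confidence", "confidence",
                             "confidence category", "category"),
    allelic_requirement  = c("allelic requirement", "allelic_requirement"),
    mutation_consequence = c("mutation consequence", "mutation_consequence"),
    hpo_terms            = c("phenotypes", "hpo terms", "hpo_terms"),
    organ_specificity    = c("organ specificity list", "organ specificity",
                             "organ_specificity"),
    pmids                = c("pmids", "publications")
  )
}

.match_column <- function(header, candidates) {
  hit <- match(tolower(candidates), tolower(trimws(header)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Read a G2P-style panel CSV
#'
#' Reads the comma-separated download format: one entry per row, one header
#' row, multi-valued cells (HPO terms, PMIDs) semicolon-delimited. Vocabulary
#' values are normalised case-insensitively; unknown values are rejected with
#' the offending row and value named.
#'
#' @param path CSV file path.
#' @param name panel name (defaults to the file name).
#' @param column_map named list mapping the logical fields to candidate
#'   header names; see [default_panel_columns()].
#' @param delim field delimiter, default comma.
#' @return A [g2p_panel()] with row order preserved.
#' @export
read_g2p_csv <- function(path, name = NULL,
                         column_map = default_panel_columns(),
                         delim = ",") {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  header <- names(raw)
  required <- c("gene_symbol", "disease_name", "confidence",
                "allelic_requirement", "mutation_consequence")
  cols <- lapply(column_map, .match_column, header = header)
  for (field in required) {
    if (is.na(cols[[field]])) {
      stop(sprintf("panel CSV is missing a '%s' column (accepted headers: %s)",
                   field, paste(column_map[[field]], collapse = ", ")),
           call. = FALSE)
    }
  }
  take <- function(field) {
    idx <- cols[[field]]
    if (is.null(idx) || is.na(idx)) rep("", nrow(raw)) else raw[[idx]]
  }
  entries <- data.frame(
    gene_symbol          = take("gene_symbol"),
    gene_ids             = take("gene_ids"),
    disease_name         = take("disease_name"),
    confidence           = take("confidence"),
    allelic_requirement  = take("allelic_requirement"),
    mutation_consequence = take("mutation_consequence"),
    hpo_terms            = take("hpo_terms"),
    organ_specificity    = take("organ_specificity"),
    pmids                = take("pmids"),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  g2p_panel(entries, name = name)
}

#' Write a panel back to CSV
#'
#' Inverse of [read_g2p_csv()]; a read/write/read round trip reproduces the
#' identical panel.
#'
#' @param panel a `g2p_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_g2p_csv <- function(panel, path) {
  stopifnot(inherits(panel, "g2p_panel"))
  out <- panel$entries
  names(out) <- c("gene symbol", "gene_ids", "disease name", "confidence",
                  "allelic requirement", "mutation consequence",
                  "hpo_terms", "organ_specificity", "pmids")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Restrict a panel to reportable entries
#'
#' Confirmed and probable entries are reportable for clinical diagnosis;
#' possible entries are not. Entries associated with both the relevant
#' disease and an incidental finding ("both RD and IF") are reportable and
#' keep their flag so downstream reports can mark the incidental-finding
#' context.
#'
#' @param panel a `g2p_panel`.
#' @return A new `g2p_panel` containing only reportable entries, in the
#'   original order; the input is unmodified. Idempotent.
#' @export
reportable_entries <- function(panel) {
  stopifnot(inherits(panel, "g2p_panel"))
  keep <- panel$entries$confidence %in% G2P_REPORTABLE_CONFIDENCE
  g2p_panel(panel$entries[keep, , drop = FALSE], name = panel$name)
}

#' Read a PanelApp-style gene panel export
#'
#' Converts the tab-separated PanelApp export into the internal panel model.
#' Ratings map onto confidence levels (default: green=confirmed,
#' amber=probable, red=possible); mode-of-inheritance strings map onto
#' allelic requirements, with unmappable strings becoming `uncertain` (with a
#' warning). The mutation consequence is not curated in PanelApp and defaults
#' to `uncertain`.
#'
#' @param path tab-separated export path.
#' @param confidence_map named character vector from rating to confidence.
#' @param name panel name.
#' @return A [g2p_panel()].
#' @export
read_panelapp <- function(path,
                          confidence_map = c(green = "confirmed",
                                             amber = "probable",
                                             red = "possible"),
                          name = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  header <- names(raw)
  gene_idx <- .match_column(header, c("entity name", "gene symbol", "gene",
                                      "gene_symbol", "symbol"))
  if (is.na(gene_idx)) {
    stop("PanelApp export is missing a gene symbol column", call. = FALSE)
  }
  rating_idx <- .match_column(header, c("gel status", "rating", "confidence",
                                        "level of confidence", "status",
                                        "colour", "color"))
  moi_idx <- .match_column(header, c("model_of_inheritance",
                                     "mode of inheritance", "moi",
                                     "inheritance"))
  disease_idx <- .match_column(header, c("phenotypes", "disease", "panel",
                                         "disease name", "level4"))
  rating <- if (is.na(rating_idx)) rep("green", nrow(raw)) else
    tolower(trimws(raw[[rating_idx]]))
  conf <- unname(confidence_map[rating])
  if (anyNA(conf)) {
    bad <- which(is.na(conf))[1L]
    stop(sprintf("unknown PanelApp rating '%s' (row %d)", rating[bad], bad),
         call. = FALSE)
  }
  moi <- if (is.na(moi_idx)) rep("", nrow(raw)) else raw[[moi_idx]]
  req <- map_panelapp_moi(moi)
  entries <- data.frame(
    gene_symbol          = raw[[gene_idx]],
    gene_ids             = "",
    disease_name         = if (is.na(disease_idx)) "unspecified" else
      ifelse(trimws(raw[[disease_idx]]) == "", "unspecified",
             raw[[disease_idx]]),
    confidence           = conf,
    allelic_requirement  = req,
    mutation_consequence = "uncertain",
    hpo_terms            = "",
    organ_specificity    = "",
    pmids                = "",
    stringsAsFactors = FALSE
  )
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  g2p_panel(entries, name = name)
}

#' Map PanelApp mode-of-inheritance strings to allelic requirements
#'
#' Recognises the common PanelApp phrasings (BIALLELIC/MONOALLELIC/
#' X-LINKED/MITOCHONDRIAL...); anything unrecognised maps to `uncertain`
#' with one warning listing the unmapped strings.
#'
#' @param moi character vector of inheritance strings.
#' @return Character vector of allelic requirement tokens.
#' @export
map_panelapp_moi <- function(moi) {
  m <- tolower(trimws(as.character(moi)))
  out <- rep(NA_character_, length(m))
  out[grepl("biallelic|recessive", m) & !grepl("x.?link", m)] <- "biallelic"
  out[grepl("monoallelic|dominant", m) & !grepl("x.?link", m)] <- "monoallelic"
  out[grepl("both monoallelic and biallelic", m)] <- "monoallelic"
  out[grepl("x.?link", m) & grepl("dominant", m)] <- "x_linked_dominant"
  out[grepl("x.?link", m) & !grepl("dominant", m)] <- "hemizygous"
  out[grepl("mitochondrial", m)] <- "mitochondrial"
  out[grepl("imprint", m)] <- "imprinted"
  out[grepl("mosaic|somatic", m)] <- "mosaic"
  out[grepl("digenic", m)] <- "digenic"
  unmapped <- is.na(out)
  if (any(unmapped)) {
    shown <- unique(m[unmapped])
    shown <- shown[shown != ""]
    if (length(shown) > 0L) {
      warning("unmappable mode(s) of inheritance set to 'uncertain': ",
              paste(utils::head(shown, 5L), collapse = "; "), call. = FALSE)
    }
    out[unmapped] <- "uncertain"
  }
  out
}

#' Tabulate a panel by confidence, allelic requirement and consequence
#'
#' Counts and percentages per facet. Percentages are computed over the
#' reportable entries only (confirmed, probable, both RD and IF); possible
#' entries are counted but carry no percentage, mirroring how public panel
#' summaries report them in brackets.
#'
#' @param panel a `g2p_panel`.
#' @return A list of class `g2p_panel_summary` with one data frame per facet
#'   (`confidence`, `allelic_requirement`, `mutation_consequence`), each with
#'   columns `level`, `n`, `percent`, plus `n_reportable` and
#'   `n_reportable_genes`.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "g2p_panel"))
  rep_panel <- reportable_entries(panel)
  n_rep <- nrow(rep_panel$entries)
  facet <- function(values, levels) {
    n <- as.integer(table(factor(values, levels = levels)))
    data.frame(level = levels, n = n,
               percent = if (n_rep > 0L) round(100 * n / n_rep, 1) else
                 rep(NA_real_, length(levels)),
               stringsAsFactors = FALSE)
  }
  conf <- facet(rep_panel$entries$confidence, G2P_CONFIDENCE)
  ## possible entries are never reportable: report their raw count, no pct
  n_possible <- sum(panel$entries$confidence == "possible")
  conf[conf$level == "possible", c("n", "percent")] <-
    list(n_possible, NA_real_)
  out <- list(
    n_reportable = n_rep,
    n_reportable_genes = length(unique(rep_panel$entries$gene_symbol)),
    confidence = conf,
    allelic_requirement = facet(rep_panel$entries$allelic_requirement,
                                G2P_ALLELIC_REQUIREMENT),
    mutation_consequence = facet(rep_panel$entries$mutation_consequence,
                                 G2P_MUTATION_CONSEQUENCE)
  )
  class(out) <- "g2p_panel_summary"
  out
}

#' @export
print.g2p_panel_summary <- function(x, ...) {
  cat(sprintf("Reportable entries: %d (%d distinct genes)\n",
              x$n_reportable, x$n_reportable_genes))
  for (facet in c("confidence", "allelic_requirement",
                  "mutation_consequence")) {
    cat(facet, ":\n", sep = "")
    df <- x[[facet]]
    df <- df[df$n > 0L, , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-26s %6d %s\n", df$level[i], df$n[i],
                  ifelse(is.na(df$percent[i]), "", sprintf("%5.1f%%",
                                                           df$percent[i]))))
    }
  }
  invisible(x)
}
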