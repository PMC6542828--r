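## The core panel filter: per-variant validity against each panel entry and
## genotype aggregation against the entry's allelic requirement.

#' Filtering configuration
#'
#' @param maf_monoallelic frequency cut-off for entries satisfiable by a
#'   single altered allele (monoallelic, hemizygous, X-linked, imprinted,
#'   mosaic); default 1e-4 (the 1-in-10,000 rule). Comparison is strict
#'   less-than; a cut-off of 0 admits only alleles unseen in every reference
#'   source.
#' @param maf_biallelic frequency cut-off for biallelic entries; default
#'   5e-3. Recessive alleles may segregate at higher frequencies, hence the
#'   looser cut-off.
#' @param canonical_only keep only annotations on the canonical transcript
#'   (default TRUE).
#' @param require_sift_polyphen_concordance for missense variants, require
#'   SIFT deleterious and PolyPhen damaging to agree (default FALSE; used by
#'   the stricter burden analyses).
#' @param allowed_class_overrides optional named list overriding
#'   [allowed_classes()] per mutation-consequence mechanism.
#' @return A list of class `g2p_filter_config`.
#' @export
filter_config <- function(maf_monoallelic = 1e-4, maf_biallelic = 5e-3,
                          canonical_only = TRUE,
                          require_sift_polyphen_concordance = FALSE,
                          allowed_class_overrides = NULL) {
  if (!(maf_monoallelic >= 0 && maf_monoallelic <= maf_biallelic &&
        maf_biallelic <= 1)) {
    stop("need 0 <= maf_monoallelic <= maf_biallelic <= 1", call. = FALSE)
  }
  structure(list(maf_monoallelic = maf_monoallelic,
                 maf_biallelic = maf_biallelic,
                 canonical_only = isTRUE(canonical_only),
                 require_sift_polyphen_concordance =
                   isTRUE(require_sift_polyphen_concordance),
                 allowed_class_overrides = allowed_class_overrides),
            class = "g2p_filter_config")
}

## MAF cut-off applicable to an allelic requirement.
maf_threshold_for <- function(allelic_requirement, cfg) {
  ifelse(allelic_requirement == "biallelic",
         cfg$maf_biallelic, cfg$maf_monoallelic)
}

## Strict less-than comparison; a cut-off of exactly 0 encodes "not seen in
## any control databases" and admits only AF == 0.
maf_passes <- function(af, cutoff) {
  pass_zero <- af == 0
  pass_lt <- af < cutoff
  ifelse(rep_len(cutoff == 0, length(pass_lt)), pass_zero, pass_lt)
}

.polyphen_damaging <- function(p) {
  !is.na(p) & p %in% c("probably_damaging", "possibly_damaging")
}

.sift_deleterious <- function(s) {
  !is.na(s) & startsWith(s, "deleterious")
}

#' Is a transcript consequence a valid candidate for a panel entry?
#'
#' Applies, in order: (a) canonical-transcript restriction; (b) consequence
#' class admissible for the entry's mutation-consequence mechanism (an
#' entry whose mechanism is not detectable from coding consequences fails
#' with reason `unsupported_mechanism`); (c) maximum population allele
#' frequency strictly below the cut-off for the entry's allelic requirement;
#' (d) optionally, SIFT/PolyPhen concordance for missense variants. The
#' reason names the first failing criterion.
#'
#' @param tc one annotation row from [parse_csq()] (one-row data frame or
#'   list), with its AF columns.
#' @param lgmdet one panel entry (one-row data frame or list).
#' @param cfg a [filter_config()].
#' @param max_af precomputed [max_population_af()] of `tc`; computed when
#'   missing.
#' @return list(valid = logical, reason = one of `"ok"`, `"not_canonical"`,
#'   `"consequence_class"`, `"unsupported_mechanism"`, `"maf"`,
#'   `"sift_polyphen_discordant"`, class = consequence class, max_af).
#' @export
variant_is_valid <- function(tc, lgmdet, cfg = filter_config(),
                             max_af = NULL) {
  tc <- as.list(tc)
  lgmdet <- as.list(lgmdet)
  if (!is.na(tc$gene_symbol) && tc$gene_symbol != lgmdet$gene_symbol) {
    stop(sprintf("annotation gene '%s' does not match panel entry gene '%s'",
                 tc$gene_symbol, lgmdet$gene_symbol), call. = FALSE)
  }
  cls <- classify_consequence(tc$so_terms)
  if (is.null(max_af)) {
    af_fields <- intersect(detect_af_fields(names(tc)), names(tc))
    vals <- unlist(tc[af_fields], use.names = FALSE)
    vals <- suppressWarnings(as.numeric(vals))
    vals <- vals[!is.na(vals)]
    if (any(vals < 0 | vals > 1)) {
      stop("allele frequency outside [0,1]", call. = FALSE)
    }
    max_af <- if (length(vals) == 0L) 0 else max(vals)
  }
  fail <- function(reason) list(valid = FALSE, reason = reason,
                                class = cls, max_af = max_af)
  if (cfg$canonical_only && !isTRUE(tc$is_canonical)) {
    return(fail("not_canonical"))
  }
  allowed <- allowed_classes(lgmdet$mutation_consequence,
                             cfg$allowed_class_overrides)
  if (length(allowed) == 0L) return(fail("unsupported_mechanism"))
  if (!(cls %in% allowed)) return(fail("consequence_class"))
  cutoff <- maf_threshold_for(lgmdet$allelic_requirement, cfg)
  if (!maf_passes(max_af, cutoff)) return(fail("maf"))
  if (cfg$require_sift_polyphen_concordance && cls == "missense" &&
      !(.sift_deleterious(tc$sift_prediction) &&
        .polyphen_damaging(tc$polyphen_prediction))) {
    return(fail("sift_polyphen_discordant"))
  }
  list(valid = TRUE, reason = "ok", class = cls, max_af = max_af)
}

#' Aggregate one sample's qualifying variants against an allelic requirement
#'
#' Decides whether the genotypes observed at the qualifying variant sites
#' satisfy the panel entry's allelic requirement. Monoallelic-type
#' requirements need one altered allele (het, hom-alt or hemizygous call).
#' Biallelic requirements need a homozygous-alternate call or two or more
#' distinct heterozygous sites — a possible compound heterozygote; phase is
#' not resolved, so cis configurations cannot be excluded. Hemizygous
#' requirements need a hemizygous or homozygous-alternate call, or a
#' heterozygous call when the sample's sex is female or unknown. Digenic,
#' mitochondrial and uncertain requirements are never satisfied by this
#' engine and yield a `not_satisfied` finding with a reason.
#'
#' @param sample_id sample identifier.
#' @param lgmdet one panel entry (list or one-row data frame).
#' @param variants data frame of this sample's qualifying variants for the
#'   entry: columns `chrom`, `pos`, `ref`, `alt`, `zygosity` (none of which
#'   may be `hom_ref`/`no_call`), plus any annotation columns.
#' @param sex sample sex, `"male"`, `"female"` or `"unknown"` (default).
#' @return One-row data frame: `sample_id`, `gene_symbol`, `disease_name`,
#'   `allelic_requirement`, `mutation_consequence`, `confidence`,
#'   `requirement_satisfied`, `genotype_pattern` (`single_het`, `hom_alt`,
#'   `two_or_more_hets`, `hemizygous_alt`, `not_satisfied`), `reason`,
#'   `incidental_flag`, `n_variants`.
#' @export
aggregate_gene_findings <- function(sample_id, lgmdet, variants,
                                    sex = "unknown") {
  lgmdet <- as.list(lgmdet)
  zy <- variants$zygosity
  if (any(zy %in% c("hom_ref", "no_call"))) {
    stop("qualifying variants must carry an alternate allele", call. = FALSE)
  }
  site_key <- paste(variants$chrom, variants$pos, variants$ref,
                    variants$alt, sep = ":")
  n_het_sites <- length(unique(site_key[zy == "het"]))
  any_hom <- any(zy == "hom_alt")
  any_hemi <- any(zy == "hemi")
  any_het <- n_het_sites > 0L
  req <- lgmdet$allelic_requirement
  satisfied <- FALSE
  pattern <- "not_satisfied"
  reason <- NA_character_
  if (req %in% UNSUPPORTED_REQUIREMENTS) {
    reason <- paste0("allelic requirement '", req,
                     "' not assessable from a single-sample VCF")
  } else if (req == "biallelic") {
    if (any_hom) {
      satisfied <- TRUE; pattern <- "hom_alt"
    } else if (n_het_sites >= 2L) {
      satisfied <- TRUE; pattern <- "two_or_more_hets"
    } else {
      reason <- "biallelic requirement needs a homozygote or two distinct heterozygous sites"
    }
  } else if (req == "hemizygous") {
    if (any_hemi) {
      satisfied <- TRUE; pattern <- "hemizygous_alt"
    } else if (any_hom) {
      satisfied <- TRUE; pattern <- "hom_alt"
    } else if (any_het && sex %in% c("female", "unknown")) {
      satisfied <- TRUE; pattern <- "single_het"
    } else {
      reason <- "hemizygous requirement needs a hemizygous or homozygous alternate call"
    }
  } else {
    ## monoallelic, x_linked_dominant, x_linked_over_dominance, imprinted,
    ## mosaic: a single altered allele suffices
    if (any_hemi) {
      satisfied <- TRUE; pattern <- "hemizygous_alt"
    } else if (any_hom) {
      satisfied <- TRUE; pattern <- "hom_alt"
    } else if (any_het) {
      satisfied <- TRUE; pattern <- "single_het"
    } else {
      reason <- "no altered allele observed"
    }
  }
  data.frame(sample_id = sample_id,
             gene_symbol = lgmdet$gene_symbol,
             disease_name = lgmdet$disease_name,
             allelic_requirement = req,
             mutation_consequence = lgmdet$mutation_consequence,
             confidence = lgmdet$confidence,
             requirement_satisfied = satisfied,
             genotype_pattern = pattern,
             reason = reason,
             incidental_flag = identical(lgmdet$confidence, "both_rd_and_if"),
             n_variants = nrow(variants),
             stringsAsFactors = FALSE)
}

## Pick the reporting annotation for a gene among a record's CSQ rows:
## canonical first, else most severe consequence class, ties broken by
## transcript identifier order for determinism.
.select_winning_annotation <- function(cand) {
  if (nrow(cand) == 1L) return(cand)
  sev <- match(vapply(cand$so_terms, classify_consequence, character(1)),
               CONSEQUENCE_CLASSES)
  ord <- order(!cand$is_canonical, sev,
               ifelse(is.na(cand$transcript_id), "~", cand$transcript_id))
  cand[ord[1L], , drop = FALSE]
}

#' Filter an annotated cohort VCF against a gene panel
#'
#' The full diagnostic filter: parse the CSQ annotations of each record,
#' reset low-quality genotype calls, test each variant against every
#' reportable panel entry for its gene ([variant_is_valid()]), and aggregate
#' each sample's qualifying variants per panel entry against the allelic
#' requirement ([aggregate_gene_findings()]). Variants in genes absent from
#' the reportable panel never appear in the output.
#'
#' @param vcf path to a decomposed, normalised, CSQ-annotated multi-sample
#'   VCF, or a [read_annotated_vcf()] result.
#' @param panel a [g2p_panel()]; restricted to reportable entries internally.
#' @param cfg a [filter_config()].
#' @param sex_table optional data frame `sample_id`, `sex` (see
#'   [read_ped()]); samples not listed default to unknown sex.
#' @param thresholds genotype quality thresholds, see
#'   [quality_thresholds()].
#' @return An object of class `g2p_findings`: `findings` (one row per sample
#'   x panel entry with at least one qualifying variant), `variants` (one
#'   row per sample x entry x qualifying variant), `sample_summary` (per
#'   sample: unique qualifying sites, SNVs and indels counted separately,
#'   satisfied findings), `dropped` (per variant x entry failures with
#'   reason codes), `samples`, `config`.
#' @export
filter_cohort <- function(vcf, panel, cfg = filter_config(),
                          sex_table = NULL,
                          thresholds = quality_thresholds()) {
  vd <- if (inherits(vcf, "g2p_vcf")) vcf else read_annotated_vcf(vcf)
  stopifnot(inherits(panel, "g2p_panel"))
  rep_panel <- reportable_entries(panel)
  entries <- rep_panel$entries
  entries$.lgmdet_id <- seq_len(nrow(entries))
  genes <- unique(entries$gene_symbol)
  samples <- vd$samples
  sex <- rep("unknown", length(samples))
  names(sex) <- samples
  if (!is.null(sex_table)) {
    hit <- match(samples, sex_table$sample_id)
    sex[!is.na(hit)] <- sex_table$sex[hit[!is.na(hit)]]
  }
  n_rec <- nrow(vd$fix)

  ## quality resets, vectorised across the whole genotype matrix
  zy <- vd$zygosity
  eligible <- zy %in% c("het", "hom_alt", "hemi")
  ratio <- ifelse(!is.na(vd$ad_alt) & !is.na(vd$dp) & vd$dp > 0,
                  vd$ad_alt / vd$dp, NA_real_)
  bad <- (!is.na(vd$gq) & vd$gq < thresholds$min_gq) |
    (!is.na(vd$dp) & vd$dp < thresholds$min_dp) |
    (!is.na(ratio) & ratio < thresholds$min_ad_ratio) |
    (!is.na(vd$mq) & vd$mq < thresholds$min_mq)
  zy[matrix(eligible & as.vector(bad), nrow = n_rec)] <- "no_call"

  variant_rows <- vector("list", n_rec)
  dropped_rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    rec_id <- sprintf("%s:%d", vd$fix$chrom[i], vd$fix$pos[i])
    csq <- parse_csq(vd$csq_description, vd$csq[i], record_id = rec_id)
    if (nrow(csq) == 0L) next
    hit_genes <- unique(csq$gene_symbol[!is.na(csq$gene_symbol)])
    hit_genes <- intersect(hit_genes, genes)
    if (length(hit_genes) == 0L) next
    carriers <- which(zy[i, ] %in% c("het", "hom_alt", "hemi"))
    drops <- list()
    vrows <- list()
    for (g in hit_genes) {
      cand <- csq[!is.na(csq$gene_symbol) & csq$gene_symbol == g, ,
                  drop = FALSE]
      attr(cand, "af_fields") <- attr(csq, "af_fields")
      winner <- .select_winning_annotation(cand)
      w_af <- max_population_af(winner, attr(csq, "af_fields"))
      lg_rows <- which(entries$gene_symbol == g)
      for (j in lg_rows) {
        verdict <- variant_is_valid(winner, entries[j, ], cfg, max_af = w_af)
        if (!verdict$valid) {
          drops[[length(drops) + 1L]] <- data.frame(
            chrom = vd$fix$chrom[i], pos = vd$fix$pos[i],
            ref = vd$fix$ref[i], alt = vd$fix$alt[i],
            gene_symbol = g, lgmdet_id = entries$.lgmdet_id[j],
            allelic_requirement = entries$allelic_requirement[j],
            reason = verdict$reason, stringsAsFactors = FALSE)
          next
        }
        if (length(carriers) == 0L) next
        vrows[[length(vrows) + 1L]] <- data.frame(
          sample_id = samples[carriers],
          lgmdet_id = entries$.lgmdet_id[j],
          gene_symbol = g,
          chrom = vd$fix$chrom[i], pos = vd$fix$pos[i],
          ref = vd$fix$ref[i], alt = vd$fix$alt[i],
          zygosity = zy[i, carriers],
          consequence_class = verdict$class,
          max_af = verdict$max_af,
          cadd_phred = winner$cadd_phred,
          allelic_requirement = entries$allelic_requirement[j],
          is_snv = nchar(vd$fix$ref[i]) == 1L & nchar(vd$fix$alt[i]) == 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (length(vrows) > 0L) {
      variant_rows[[i]] <- do.call(rbind, vrows)
    }
    if (length(drops) > 0L) dropped_rows[[i]] <- do.call(rbind, drops)
  }
  variants <- do.call(rbind, variant_rows[!vapply(variant_rows, is.null,
                                                  logical(1))])
  dropped <- do.call(rbind, dropped_rows[!vapply(dropped_rows, is.null,
                                                 logical(1))])
  if (is.null(variants)) variants <- .empty_variants_frame()
  if (is.null(dropped)) {
    dropped <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          gene_symbol = character(0), lgmdet_id = integer(0),
                          allelic_requirement = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  }
  findings <- .aggregate_all(variants, entries, sex)
  summary_df <- .sample_summary(variants, findings, samples)
  structure(list(findings = findings, variants = variants,
                 sample_summary = summary_df, dropped = dropped,
                 samples = samples, sex = sex, config = cfg,
                 thresholds = thresholds, panel_name = panel$name),
            class = "g2p_findings")
}

.empty_variants_frame <- function() {
  data.frame(sample_id = character(0), lgmdet_id = integer(0),
             gene_symbol = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             zygosity = character(0), consequence_class = character(0),
             max_af = numeric(0), cadd_phred = numeric(0),
             allelic_requirement = character(0), is_snv = logical(0),
             stringsAsFactors = FALSE)
}

.empty_findings_frame <- function() {
  data.frame(sample_id = character(0), gene_symbol = character(0),
             disease_name = character(0), allelic_requirement = character(0),
             mutation_consequence = character(0), confidence = character(0),
             requirement_satisfied = logical(0),
             genotype_pattern = character(0), reason = character(0),
             incidental_flag = logical(0), n_variants = integer(0),
             lgmdet_id = integer(0), stringsAsFactors = FALSE)
}

.aggregate_all <- function(variants, entries, sex) {
  if (nrow(variants) == 0L) return(.empty_findings_frame())
  key <- paste(variants$sample_id, variants$lgmdet_id, sep = "\r")
  groups <- split(seq_len(nrow(variants)), key)
  ## deterministic output order: sample, then panel entry
  ord <- order(vapply(groups, function(ix) variants$sample_id[ix[1L]],
                      character(1)),
               vapply(groups, function(ix) variants$lgmdet_id[ix[1L]],
                      integer(1)))
  groups <- groups[ord]
  rows <- lapply(groups, function(ix) {
    v <- variants[ix, , drop = FALSE]
    lg <- entries[entries$.lgmdet_id == v$lgmdet_id[1L], , drop = FALSE]
    f <- aggregate_gene_findings(v$sample_id[1L], lg, v,
                                 sex = sex[[v$sample_id[1L]]])
    f$lgmdet_id <- v$lgmdet_id[1L]
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.sample_summary <- function(variants, findings, samples) {
  uniq <- unique(variants[, c("sample_id", "chrom", "pos", "ref", "alt",
                              "is_snv")])
  count_for <- function(s, snv) {
    sum(uniq$sample_id == s & uniq$is_snv == snv)
  }
  data.frame(
    sample_id = samples,
    n_qualifying = vapply(samples, function(s) sum(uniq$sample_id == s),
                          integer(1)),
    n_snv = vapply(samples, count_for, integer(1), snv = TRUE),
    n_indel = vapply(samples, count_for, integer(1), snv = FALSE),
    n_satisfied = vapply(samples, function(s)
      sum(findings$sample_id == s & findings$requirement_satisfied),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.g2p_findings <- function(x, ...) {
  cat(sprintf("Panel filter result ('%s'): %d samples\n",
              x$panel_name, length(x$samples)))
  cat(sprintf("  findings: %d (%d requirement-satisfied)\n",
              nrow(x$findings), sum(x$findings$requirement_satisfied)))
  cat(sprintf("  qualifying variant observations: %d; dropped variant x entry tests: %d\n",
              nrow(x$variants), nrow(x$dropped)))
  cat(sprintf("  mean qualifying variants per sample: %.2f\n",
              mean(x$sample_summary$n_qualifying)))
  invisible(x)
}

#' @export
summary.g2p_findings <- function(object, ...) {
  object$sample_summary
}

#' Write filter findings to TSV
#'
#' One row per qualifying variant observation joined with its finding; the
#' cohort sample list is preserved in a `##samples=` header line so that
#' downstream statistics can count zero-finding samples.
#'
#' @param x a `g2p_findings` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(x, path) {
  stopifnot(inherits(x, "g2p_findings"))
  fcols <- x$findings[, c("sample_id", "lgmdet_id", "disease_name",
                          "mutation_consequence", "confidence",
                          "requirement_satisfied", "genotype_pattern",
                          "incidental_flag")]
  merged <- merge(x$variants, fcols, by = c("sample_id", "lgmdet_id"),
                  sort = FALSE)
  merged <- merged[order(merged$sample_id, merged$lgmdet_id, merged$chrom,
                         merged$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("##samples=", paste(x$samples, collapse = ",")), con)
  utils::write.table(merged, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read findings written by [write_findings()]
#'
#' @param path findings TSV path.
#' @return A `g2p_findings`-like object with `findings`, `variants`,
#'   `samples` and `sample_summary` components.
#' @export
read_findings <- function(path) {
  if (!file.exists(path)) stop("findings file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  samples <- character(0)
  skip <- 0L
  if (startsWith(first, "##samples=")) {
    samples <- strsplit(sub("^##samples=", "", first), ",", fixed = TRUE)[[1]]
    skip <- 1L
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           stringsAsFactors = FALSE)
  if (length(samples) == 0L) samples <- unique(tab$sample_id)
  vcols <- c("sample_id", "lgmdet_id", "gene_symbol", "chrom", "pos", "ref",
             "alt", "zygosity", "consequence_class", "max_af", "cadd_phred",
             "allelic_requirement", "is_snv")
  variants <- tab[, intersect(vcols, names(tab)), drop = FALSE]
  fkey <- !duplicated(tab[, c("sample_id", "lgmdet_id")])
  findings <- tab[fkey, intersect(
    c("sample_id", "lgmdet_id", "gene_symbol", "disease_name",
      "allelic_requirement", "mutation_consequence", "confidence",
      "requirement_satisfied", "genotype_pattern", "incidental_flag"),
    names(tab)), drop = FALSE]
  findings$n_variants <- as.integer(table(
    paste(tab$sample_id, tab$lgmdet_id))[
      paste(findings$sample_id, findings$lgmdet_id)])
  rownames(findings) <- NULL
  out <- list(findings = findings, variants = variants, samples = samples,
              sample_summary = .sample_summary(variants, findings, samples))
  class(out) <- "g2p_findings"
  out
}
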