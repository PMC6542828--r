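## Confusion-matrix evaluation of the filter against a truth set of known
## causative variants, MAF-sweep ROC/PR points, and causative-gene ranking.

#' Confusion counts and derived accuracy rates
#'
#' @param tp,fp,fn true positives, false positives, false negatives.
#' @param tn true negatives; `NA` unless a negative universe was supplied,
#'   in which case specificity and the classical false-positive rate are
#'   defined.
#' @return Object of class `g2p_confusion` with `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity` (= recall, tp/(tp+fn)), `precision` (tp/(tp+fp)),
#'   `false_positive_fraction` (fp/(tp+fp), the complement of precision),
#'   `specificity` (tn/(tn+fp)), `fpr` (fp/(fp+tn)) and `f1`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  spec <- if (!is.na(tn) && tn + fp > 0) tn / (tn + fp) else NA_real_
  fpr <- if (!is.na(tn) && fp + tn > 0) fp / (fp + tn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, precision = prec,
                 false_positive_fraction = if (is.na(prec)) NA_real_ else
                   1 - prec,
                 specificity = spec, fpr = fpr,
                 f1 = f1_score(prec, sens)),
            class = "g2p_confusion")
}

#' @export
print.g2p_confusion <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%s\n", x$tp, x$fp, x$fn,
              ifelse(is.na(x$tn), "-", as.character(x$tn))))
  cat(sprintf("sensitivity=%.3f precision=%.3f f1=%.3f",
              x$sensitivity, x$precision, x$f1))
  if (!is.na(x$specificity)) cat(sprintf(" specificity=%.3f", x$specificity))
  cat("\n")
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)`; `f1(p, p) = p`.
#'
#' @param precision,recall rates in \[0,1\].
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

.variant_key <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

## Predicted variant set: unique (sample, variant) among qualifying variants
## of requirement-satisfied findings; a plain data frame is taken as the
## predicted set directly.
.predicted_variants <- function(findings) {
  if (inherits(findings, "g2p_findings")) {
    sat <- findings$findings[findings$findings$requirement_satisfied,
                             c("sample_id", "lgmdet_id"), drop = FALSE]
    v <- merge(findings$variants, sat, by = c("sample_id", "lgmdet_id"),
               sort = FALSE)
  } else {
    v <- findings
  }
  v[!duplicated(.variant_key(v)), , drop = FALSE]
}

#' Score findings against a truth set
#'
#' Matching is at variant granularity (sample, chrom, pos, ref, alt). True
#' positives are truth variants found among the qualifying variants of
#' requirement-satisfied findings; false negatives are truth variants not
#' found; false positives are predicted variants not in the truth set. True
#' negatives are only defined when a negative universe is supplied.
#'
#' @param findings a `g2p_findings` object, or a data frame of predicted
#'   variants (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param truth data frame with the same columns; rows must be unique on
#'   (sample, variant).
#' @param universe optional negative universe: either its total size (number
#'   of candidate units, from which `tn = universe - tp - fp - fn`) or a data
#'   frame of all candidate units.
#' @return A [confusion_counts()] object.
#' @export
score_findings <- function(findings, truth, universe = NULL) {
  tkey <- .variant_key(truth)
  if (anyDuplicated(tkey) > 0L) {
    stop("truth set has duplicate (sample, variant) rows", call. = FALSE)
  }
  pred <- .predicted_variants(findings)
  pkey <- .variant_key(pred)
  tp <- sum(tkey %in% pkey)
  fn <- length(tkey) - tp
  fp <- length(pkey) - tp
  tn <- NA_real_
  if (!is.null(universe)) {
    n_universe <- if (is.data.frame(universe)) nrow(universe) else
      as.numeric(universe)
    tn <- max(n_universe - tp - fp - fn, 0)
  }
  confusion_counts(tp, fp, fn, tn)
}

#' Why were truth variants missed?
#'
#' Joins the false negatives of a filter run against the engine's dropped-
#' variant log and genotype information to name the first rule each missed
#' variant failed (e.g. `maf`, `not_canonical`, `consequence_class`), or
#' `genotype_absent_or_reset` when the variant never reached the rules.
#'
#' @param result a `g2p_findings` object from [filter_cohort()].
#' @param truth truth-set data frame.
#' @return Data frame of missed truth rows with a `reason` column.
#' @export
fn_reasons <- function(result, truth) {
  stopifnot(inherits(result, "g2p_findings"))
  pred <- .predicted_variants(result)
  missed <- truth[!(.variant_key(truth) %in% .variant_key(pred)), ,
                  drop = FALSE]
  if (nrow(missed) == 0L) {
    missed$reason <- character(0)
    return(missed)
  }
  dkey <- paste(result$dropped$chrom, result$dropped$pos,
                result$dropped$ref, result$dropped$alt, sep = ":")
  mkey <- paste(missed$chrom, missed$pos, missed$ref, missed$alt, sep = ":")
  missed$reason <- vapply(mkey, function(k) {
    hit <- which(dkey == k)
    if (length(hit) > 0L) result$dropped$reason[hit[1L]] else
      "genotype_absent_or_reset"
  }, character(1))
  rownames(missed) <- NULL
  missed
}

#' Sweep the MAF cut-off and score each point
#'
#' Runs the filter once with the loosest cut-off and re-thresholds the
#' qualifying variants post hoc (valid because the frequency rule is the
#' only criterion swept), re-aggregating genotypes per panel entry at each
#' point. A cut-off of 0 encodes "not seen in any control databases". The
#' swept cut-off is applied uniformly to every allelic requirement, so each
#' point equals a full run with both MAF parameters set to the cut-off.
#'
#' @param vcf annotated VCF path or [read_annotated_vcf()] result.
#' @param panel a [g2p_panel()].
#' @param cfg base [filter_config()] (its MAF parameters are overridden by
#'   the sweep).
#' @param truth truth-set data frame.
#' @param cutoffs frequencies to sweep; sorted internally. Default
#'   `c(0, 1e-5, 2e-5, 4e-5, 1e-4)`.
#' @param universe optional negative universe passed to [score_findings()].
#' @param sex_table,thresholds passed to [filter_cohort()].
#' @return Data frame: `cutoff`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `precision`, `specificity`, `fpr`, `f1`.
#' @export
maf_sweep <- function(vcf, panel, cfg = filter_config(), truth,
                      cutoffs = c(0, 1e-5, 2e-5, 4e-5, 1e-4),
                      universe = NULL, sex_table = NULL,
                      thresholds = quality_thresholds()) {
  cutoffs <- sort(unique(cutoffs))
  loosest <- max(cutoffs)
  base_cfg <- filter_config(
    maf_monoallelic = loosest, maf_biallelic = loosest,
    canonical_only = cfg$canonical_only,
    require_sift_polyphen_concordance =
      cfg$require_sift_polyphen_concordance,
    allowed_class_overrides = cfg$allowed_class_overrides)
  result <- filter_cohort(vcf, panel, base_cfg, sex_table = sex_table,
                          thresholds = thresholds)
  entries <- reportable_entries(panel)$entries
  entries$.lgmdet_id <- seq_len(nrow(entries))
  rows <- lapply(cutoffs, function(cut) {
    keep <- maf_passes(result$variants$max_af, cut)
    sub <- result$variants[keep, , drop = FALSE]
    findings <- .aggregate_all(sub, entries, result$sex)
    pseudo <- list(findings = findings, variants = sub,
                   samples = result$samples)
    class(pseudo) <- "g2p_findings"
    cc <- score_findings(pseudo, truth, universe = universe)
    data.frame(cutoff = cut, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               sensitivity = cc$sensitivity, precision = cc$precision,
               specificity = cc$specificity, fpr = cc$fpr, f1 = cc$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision-recall points per consequence stratum over the MAF sweep
#'
#' Restricts the predictions to a consequence stratum — all classes, LOF
#' only, or missense with CADD at or above 20/30 — and scores each MAF
#' cut-off against the full truth set, so recall reflects the truth variants
#' a stratum cannot reach.
#'
#' @inheritParams maf_sweep
#' @param strata subset of `c("all", "lof_only", "missense_cadd20",
#'   "missense_cadd30")`.
#' @return Data frame: `stratum`, `cutoff`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`; precision is NA (flagged by `undefined`) where the
#'   stratum makes no predictions.
#' @export
consequence_strata_pr <- function(vcf, panel, cfg = filter_config(), truth,
                                  strata = c("all", "lof_only",
                                             "missense_cadd20",
                                             "missense_cadd30"),
                                  cutoffs = c(0, 1e-5, 2e-5, 4e-5, 1e-4),
                                  sex_table = NULL,
                                  thresholds = quality_thresholds()) {
  strata <- match.arg(strata, several.ok = TRUE)
  cutoffs <- sort(unique(cutoffs))
  loosest <- max(cutoffs)
  base_cfg <- filter_config(maf_monoallelic = loosest,
                            maf_biallelic = loosest,
                            canonical_only = cfg$canonical_only,
                            require_sift_polyphen_concordance =
                              cfg$require_sift_polyphen_concordance,
                            allowed_class_overrides =
                              cfg$allowed_class_overrides)
  result <- filter_cohort(vcf, panel, base_cfg, sex_table = sex_table,
                          thresholds = thresholds)
  entries <- reportable_entries(panel)$entries
  entries$.lgmdet_id <- seq_len(nrow(entries))
  in_stratum <- function(v, stratum) {
    switch(stratum,
      all = rep(TRUE, nrow(v)),
      lof_only = v$consequence_class == "lof",
      missense_cadd20 = v$consequence_class == "missense" &
        !is.na(v$cadd_phred) & v$cadd_phred >= 20,
      missense_cadd30 = v$consequence_class == "missense" &
        !is.na(v$cadd_phred) & v$cadd_phred >= 30)
  }
  rows <- list()
  for (stratum in strata) {
    for (cut in cutoffs) {
      keep <- in_stratum(result$variants, stratum) &
        maf_passes(result$variants$max_af, cut)
      sub <- result$variants[keep, , drop = FALSE]
      findings <- .aggregate_all(sub, entries, result$sex)
      pseudo <- list(findings = findings, variants = sub,
                     samples = result$samples)
      class(pseudo) <- "g2p_findings"
      cc <- score_findings(pseudo, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, cutoff = cut, tp = cc$tp, fp = cc$fp, fn = cc$fn,
        precision = cc$precision, recall = cc$sensitivity, f1 = cc$f1,
        undefined = is.na(cc$precision))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lower bound for the area under the ROC curve of a binary test
#'
#' For a single operating point, `(sensitivity + specificity) / 2` bounds the
#' AUC from below.
#'
#' @param sensitivity,specificity rates in \[0,1\].
#' @export
auc_lower_bound <- function(sensitivity, specificity) {
  if (any(is.na(c(sensitivity, specificity))) ||
      any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1)) {
    stop("sensitivity and specificity must lie in [0,1]", call. = FALSE)
  }
  (sensitivity + specificity) / 2
}

#' Rank of the causative gene in one sample's report
#'
#' Findings are ordered deterministically: requirement-satisfied first, then
#' most severe consequence class among the finding's variants, then ascending
#' minimum population MAF, then gene symbol. The rank is the 1-based position
#' of the truth gene; `NA` (a miss) when the gene is not reported.
#'
#' @param result a `g2p_findings` object.
#' @param sample_id the sample whose report is ranked.
#' @param truth_gene causative gene symbol.
#' @return Integer rank, or `NA_integer_` when absent.
#' @export
rank_causative_gene <- function(result, sample_id, truth_gene) {
  stopifnot(inherits(result, "g2p_findings"))
  f <- result$findings[result$findings$sample_id == sample_id, ,
                       drop = FALSE]
  if (nrow(f) == 0L) return(NA_integer_)
  v <- result$variants[result$variants$sample_id == sample_id, ,
                       drop = FALSE]
  per_gene <- function(g) {
    vg <- v[v$gene_symbol == g, , drop = FALSE]
    list(severity = min(match(vg$consequence_class, CONSEQUENCE_CLASSES)),
         min_af = min(vg$max_af))
  }
  genes <- unique(f$gene_symbol)
  sat <- vapply(genes, function(g)
    any(f$requirement_satisfied[f$gene_symbol == g]), logical(1))
  info <- lapply(genes, per_gene)
  ord <- order(!sat,
               vapply(info, `[[`, numeric(1), "severity"),
               vapply(info, `[[`, numeric(1), "min_af"),
               genes)
  rank <- match(truth_gene, genes[ord])
  if (is.na(rank)) NA_integer_ else as.integer(rank)
}

#' Read / write a truth set TSV
#'
#' Columns: `sample_id`, `chrom`, `pos`, `ref`, `alt`, and optionally
#' `gene_symbol`, `expected_requirement`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_truth_tsv <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname read_truth_tsv
#' @param truth truth-set data frame.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
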