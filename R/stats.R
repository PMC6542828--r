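## Case:control background-noise statistics. A diagnostic panel applied to a
## population unselected for the disease yields the expected background of
## qualifying variants; comparing carrier burdens between a disease cohort
## and controls quantifies that noise and identifies discriminating features.

.variants_of <- function(x) {
  if (inherits(x, "g2p_findings")) x$variants else x
}

.samples_of <- function(x) {
  if (inherits(x, "g2p_findings")) x$samples else unique(x$sample_id)
}

#' Carrier burden tables per stratum
#'
#' For each stratum (by default allelic requirement x consequence class),
#' counts the samples carrying at least one qualifying variant in the
#' stratum, in each arm. A sample counts once per stratum regardless of how
#' many variants it carries (set semantics).
#'
#' @param case,control `g2p_findings` objects (or their variant tables)
#'   produced with the same panel and configuration.
#' @param stratify_by variant columns defining the strata.
#' @return Data frame with the stratum columns plus `case_carriers`,
#'   `case_total`, `control_carriers`, `control_total`.
#' @export
burden_tables <- function(case, control,
                          stratify_by = c("allelic_requirement",
                                          "consequence_class")) {
  cv <- .variants_of(case); kv <- .variants_of(control)
  cs <- .samples_of(case); ks <- .samples_of(control)
  overlap <- intersect(cs, ks)
  if (length(overlap) > 0L) {
    stop("case and control cohorts share sample ids: ",
         paste(utils::head(overlap, 3L), collapse = ", "), call. = FALSE)
  }
  strata <- unique(rbind(cv[, stratify_by, drop = FALSE],
                         kv[, stratify_by, drop = FALSE]))
  strata <- strata[do.call(order, strata), , drop = FALSE]
  rownames(strata) <- NULL
  carriers <- function(v, stratum) {
    keep <- rep(TRUE, nrow(v))
    for (col in stratify_by) keep <- keep & v[[col]] == stratum[[col]]
    length(unique(v$sample_id[keep]))
  }
  strata$case_carriers <- vapply(seq_len(nrow(strata)), function(i)
    carriers(cv, strata[i, , drop = FALSE]), integer(1))
  strata$case_total <- length(cs)
  strata$control_carriers <- vapply(seq_len(nrow(strata)), function(i)
    carriers(kv, strata[i, , drop = FALSE]), integer(1))
  strata$control_total <- length(ks)
  strata
}

#' Odds ratio with exact test for a 2x2 table
#'
#' Returns the sample (cross-product) odds ratio, the two-tailed Fisher
#' exact p-value (the sum of hypergeometric probabilities of tables at most
#' as probable as the observed one, at fixed margins), and an approximate
#' 95% confidence interval from the normal theory of the log odds ratio,
#' with the Haldane-Anscombe 0.5 correction applied when any cell is zero.
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise:
#'   rows are arms (case, control), columns carrier/non-carrier.
#' @return List of class `g2p_odds_ratio`: `odds_ratio` (may be `Inf`),
#'   `p_value`, `ci95` (lower, upper), `undefined` (TRUE when a margin is
#'   all zero).
#' @export
fisher_odds_ratio <- function(table) {
  m <- matrix(as.numeric(table), nrow = 2L, byrow = is.null(dim(table)))
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("2x2 table must hold non-negative counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    out <- list(odds_ratio = NA_real_, p_value = NA_real_,
                ci95 = c(NA_real_, NA_real_), undefined = TRUE)
    class(out) <- "g2p_odds_ratio"
    return(out)
  }
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c_)  # 0/0 margins excluded above; may be Inf or 0
  p <- stats::fisher.test(m)$p.value
  cc <- if (any(m == 0)) m + 0.5 else m
  log_or <- log((cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1]))
  se <- sqrt(sum(1 / cc))
  ci <- exp(log_or + c(-1, 1) * stats::qnorm(0.975) * se)
  out <- list(odds_ratio = or, p_value = p, ci95 = ci, undefined = FALSE)
  class(out) <- "g2p_odds_ratio"
  out
}

#' @export
print.g2p_odds_ratio <- function(x, ...) {
  if (x$undefined) {
    cat("odds ratio undefined (empty margin)\n")
  } else {
    cat(sprintf("OR = %.3g [95%% CI %.3g, %.3g], two-tailed exact p = %.3g\n",
                x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value))
  }
  invisible(x)
}

#' Per-gene carrier proportions in case and control arms
#'
#' For every gene reported in the case arm, the fraction of samples carrying
#' at least one qualifying variant in each arm, with summary counts of genes
#' whose carrier proportion is higher in controls and genes with no control
#' carriers at all.
#'
#' @param case,control `g2p_findings` objects or variant tables.
#' @return List: `per_gene` data frame (`gene_symbol`, `case_carriers`,
#'   `case_fraction`, `control_carriers`, `control_fraction`),
#'   `n_genes`, `n_higher_in_control`, `n_absent_in_control`.
#' @export
per_gene_proportions <- function(case, control) {
  cv <- .variants_of(case); kv <- .variants_of(control)
  n_case <- length(.samples_of(case))
  n_control <- length(.samples_of(control))
  genes <- sort(unique(cv$gene_symbol))
  carrier_count <- function(v, g)
    length(unique(v$sample_id[v$gene_symbol == g]))
  cc <- vapply(genes, carrier_count, integer(1), v = cv)
  kc <- vapply(genes, carrier_count, integer(1), v = kv)
  per_gene <- data.frame(
    gene_symbol = genes,
    case_carriers = cc,
    case_fraction = if (n_case > 0) cc / n_case else NA_real_,
    control_carriers = kc,
    control_fraction = if (n_control > 0) kc / n_control else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_gene = per_gene,
       n_genes = length(genes),
       n_higher_in_control = sum(per_gene$control_fraction >
                                   per_gene$case_fraction),
       n_absent_in_control = sum(per_gene$control_carriers == 0L))
}

#' Fraction of unique missense variants with high CADD
#'
#' Uniqueness is keyed on (chrom, pos, ref, alt) across the cohort; variants
#' lacking a CADD score are excluded from numerator and denominator.
#'
#' @param findings a `g2p_findings` object or variant table.
#' @param cadd_cutoff score above which a variant counts as high, default 30.
#' @return List: `fraction` (NA when no scored missense variant exists,
#'   flagged by `undefined`), `n_high`, `n_scored`, `n_unscored`.
#' @export
cadd_high_fraction <- function(findings, cadd_cutoff = 30) {
  v <- .variants_of(findings)
  mis <- v[v$consequence_class == "missense", , drop = FALSE]
  uniq <- mis[!duplicated(mis[, c("chrom", "pos", "ref", "alt")]), ,
              drop = FALSE]
  scored <- uniq[!is.na(uniq$cadd_phred), , drop = FALSE]
  n_unscored <- nrow(uniq) - nrow(scored)
  if (nrow(scored) == 0L) {
    return(list(fraction = NA_real_, n_high = 0L, n_scored = 0L,
                n_unscored = n_unscored, undefined = TRUE))
  }
  n_high <- sum(scored$cadd_phred > cadd_cutoff)
  list(fraction = n_high / nrow(scored), n_high = n_high,
       n_scored = nrow(scored), n_unscored = n_unscored, undefined = FALSE)
}

#' Distribution of qualifying variants per sample
#'
#' Histogram of per-sample unique qualifying variant counts over the whole
#' cohort (zero-finding samples included), with mean and standard deviation,
#' and SNV/indel counts reported separately.
#'
#' @param findings a `g2p_findings` object (needs the cohort sample list).
#' @return List: `histogram` (data frame `count`, `n_samples`, `proportion`),
#'   `mean`, `sd`, `mean_snv`, `sd_snv`, `mean_indel`, `sd_indel`.
#' @export
findings_per_sample_distribution <- function(findings) {
  stopifnot(inherits(findings, "g2p_findings"))
  s <- findings$sample_summary
  counts <- s$n_qualifying
  tab <- table(factor(counts, levels = 0:max(c(counts, 0L))))
  histogram <- data.frame(count = as.integer(names(tab)),
                          n_samples = as.integer(tab),
                          proportion = as.numeric(tab) / length(counts))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(histogram = histogram,
       mean = mean(counts), sd = sd0(counts),
       mean_snv = mean(s$n_snv), sd_snv = sd0(s$n_snv),
       mean_indel = mean(s$n_indel), sd_indel = sd0(s$n_indel))
}

#' Ratio of mean population MAF, control over case
#'
#' Mean of the per-variant maximum population allele frequency over the
#' qualifying variants in the stratum, control divided by case. A stratum
#' empty in either arm yields an undefined (NA) ratio, flagged.
#'
#' @param case,control `g2p_findings` objects or variant tables.
#' @param stratum optional named list of variant-column filters, e.g.
#'   `list(consequence_class = "missense", allelic_requirement =
#'   "monoallelic")`.
#' @return List: `ratio`, `mean_case`, `mean_control`, `undefined`.
#' @export
maf_ratio <- function(case, control, stratum = NULL) {
  pick <- function(v) {
    keep <- rep(TRUE, nrow(v))
    for (col in names(stratum)) keep <- keep & v[[col]] %in% stratum[[col]]
    v$max_af[keep]
  }
  a <- pick(.variants_of(case))
  b <- pick(.variants_of(control))
  if (length(a) == 0L || length(b) == 0L) {
    return(list(ratio = NA_real_, mean_case = NA_real_,
                mean_control = NA_real_, undefined = TRUE))
  }
  list(ratio = mean(b) / mean(a), mean_case = mean(a),
       mean_control = mean(b), undefined = FALSE)
}
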