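## Genotype-level quality resets and sample-level QC exclusions.

#' Default genotype quality thresholds
#'
#' Calls failing any threshold are reset to no-calls before filtering:
#' genotype quality (GQ) below 13 (under 95% confidence on the Phred scale),
#' read depth (DP) below 5, alternate-allele balance (AD/DP) below 0.2, or
#' mapping quality (MQ) below 13 where MQ is available.
#'
#' @param min_gq minimum genotype quality (Phred).
#' @param min_dp minimum read depth.
#' @param min_ad_ratio minimum alt-depth / total-depth.
#' @param min_mq minimum mapping quality (Phred); applied only when MQ is
#'   present (some joint-called cohorts carry no per-call MQ).
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function(min_gq = 13, min_dp = 5,
                               min_ad_ratio = 0.2, min_mq = 13) {
  stopifnot(min_gq >= 0, min_dp >= 0,
            min_ad_ratio >= 0, min_ad_ratio <= 1, min_mq >= 0)
  list(min_gq = min_gq, min_dp = min_dp,
       min_ad_ratio = min_ad_ratio, min_mq = min_mq)
}

#' Confidence implied by a Phred-scaled quality score
#'
#' A Phred score q encodes an error probability of 10^(-q/10); the implied
#' confidence is its complement. Phred 13 is just under 95% confidence, hence
#' the GQ/MQ cut-off of 13.
#'
#' @param q Phred score(s), >= 0.
#' @return `1 - 10^(-q/10)`, in \[0,1).
#' @export
phred_to_confidence <- function(q) {
  if (any(is.na(q)) || any(q < 0)) {
    stop("Phred scores must be non-negative", call. = FALSE)
  }
  1 - 10^(-q / 10)
}

#' Reset low-quality genotype calls to no-calls
#'
#' Applies the per-call quality screen: GQ below threshold, DP below
#' threshold, alt-allele balance (ad_alt/dp) below threshold, or MQ below
#' threshold. An absent (NA) quality field never triggers its reset, so
#' cohorts lacking a field (e.g. per-call MQ) are screened by the remaining
#' rules. Homozygous-reference calls pass through unchanged (their alt
#' balance is legitimately near zero), as do existing no-calls. The operation
#' never changes a genotype except to `no_call` and is idempotent.
#'
#' @param calls data frame with columns `gt` (one of `hom_ref`, `het`,
#'   `hom_alt`, `hemi`, `no_call`), and optional `gq`, `dp`, `ad_alt`, `mq`
#'   (NA where unavailable).
#' @param thresholds see [quality_thresholds()].
#' @return `calls` with `gt` reset to `"no_call"` where any rule fires, plus
#'   a `reset_reason` column naming the first firing rule (NA otherwise).
#' @export
reset_low_quality_calls <- function(calls, thresholds = quality_thresholds()) {
  stopifnot(is.data.frame(calls), "gt" %in% names(calls))
  n <- nrow(calls)
  get_num <- function(nm) {
    if (nm %in% names(calls)) suppressWarnings(as.numeric(calls[[nm]]))
    else rep(NA_real_, n)
  }
  gq <- get_num("gq"); dp <- get_num("dp")
  ad <- get_num("ad_alt"); mq <- get_num("mq")
  if (any(!is.na(ad) & !is.na(dp) & ad > dp)) {
    stop("ad_alt exceeds dp", call. = FALSE)
  }
  ratio <- ifelse(!is.na(ad) & !is.na(dp) & dp > 0, ad / dp, NA_real_)
  eligible <- calls$gt %in% c("het", "hom_alt", "hemi")
  reason <- rep(NA_character_, n)
  fire <- function(cond, code) {
    hit <- eligible & !is.na(cond) & cond & is.na(reason)
    reason[hit] <<- code
  }
  fire(gq < thresholds$min_gq, "low_gq")
  fire(dp < thresholds$min_dp, "low_dp")
  fire(ratio < thresholds$min_ad_ratio, "low_allele_balance")
  fire(mq < thresholds$min_mq, "low_mq")
  calls$gt[!is.na(reason)] <- "no_call"
  calls$reset_reason <- reason
  calls
}

#' Per-sample QC metrics
#'
#' For each sample, counts (i) extreme heterozygous calls, hets whose
#' alt-allele fraction falls outside \[0.15, 0.8\] — an excess indicates
#' possible contamination — and (ii) rare homozygous-alternate calls at sites
#' with reference-panel allele frequency below 0.01 — a deficit indicates
#' poor calling quality. Sites without a reference frequency are excluded
#' from the rare-homozygote count.
#'
#' @param calls data frame with columns `sample_id`, `gt`, `ad_alt`, `dp`,
#'   and `site_af` (reference-panel AF of the site, NA when unknown).
#' @param extreme_het_range alt-fraction band considered normal for hets.
#' @param rare_af_cutoff AF below which a homozygote counts as rare.
#' @return Data frame with one row per sample: `sample_id`, `n_extreme_het`,
#'   `n_rare_hom`.
#' @export
compute_sample_qc <- function(calls, extreme_het_range = c(0.15, 0.8),
                              rare_af_cutoff = 0.01) {
  stopifnot(all(c("sample_id", "gt") %in% names(calls)))
  samples <- unique(calls$sample_id)
  ratio <- ifelse(!is.na(calls$ad_alt) & !is.na(calls$dp) & calls$dp > 0,
                  calls$ad_alt / calls$dp, NA_real_)
  extreme <- calls$gt == "het" & !is.na(ratio) &
    (ratio < extreme_het_range[1] | ratio > extreme_het_range[2])
  site_af <- if ("site_af" %in% names(calls)) calls$site_af else
    rep(NA_real_, nrow(calls))
  rare_hom <- calls$gt == "hom_alt" & !is.na(site_af) &
    site_af < rare_af_cutoff
  data.frame(
    sample_id = samples,
    n_extreme_het = vapply(samples, function(s)
      sum(extreme[calls$sample_id == s]), integer(1)),
    n_rare_hom = vapply(samples, function(s)
      sum(rare_hom[calls$sample_id == s]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exclude outlier samples on QC metrics
#'
#' A sample is excluded when it has more extreme heterozygotes than the
#' cohort mean + 3 SD, or fewer rare homozygotes than the cohort mean - 3 SD.
#' Computed in a single pass (no iterative re-screening). A zero-variance
#' metric excludes nobody by that metric. The result is invariant to sample
#' order.
#'
#' @param metrics data frame from [compute_sample_qc()].
#' @param n_sd number of standard deviations, default 3.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1); at realistic cohort sizes the difference is negligible.
#' @return Data frame `sample_id`, `excluded`, `reason` (NA when kept).
#' @export
exclude_outlier_samples <- function(metrics, n_sd = 3,
                                    sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("sample_id", "n_extreme_het", "n_rare_hom") %in%
                  names(metrics)))
  n <- nrow(metrics)
  if (n < 2L) {
    stop("outlier exclusion needs at least 2 samples", call. = FALSE)
  }
  sdev <- function(x) {
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
  }
  het <- metrics$n_extreme_het
  hom <- metrics$n_rare_hom
  hi_het <- mean(het) + n_sd * sdev(het)
  lo_hom <- mean(hom) - n_sd * sdev(hom)
  too_het <- sdev(het) > 0 & het > hi_het
  too_hom <- sdev(hom) > 0 & hom < lo_hom
  reason <- rep(NA_character_, n)
  reason[too_hom] <- "few_rare_homozygotes"
  reason[too_het] <- "excess_extreme_heterozygotes"
  data.frame(sample_id = metrics$sample_id,
             excluded = too_het | too_hom,
             reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}
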