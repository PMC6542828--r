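# Independent brute-force oracles. These re-derive expected results from
# first principles (literal rule tables, exhaustive enumeration) and share no
# code path with the implementation they check.

# consequence classification by explicit per-term table + severity scan
oracle_classify <- function(terms) {
  term_class <- c(
    stop_gained = "lof", frameshift_variant = "lof",
    splice_acceptor_variant = "lof", splice_donor_variant = "lof",
    start_lost = "lof", transcript_ablation = "lof",
    missense_variant = "missense",
    inframe_insertion = "inframe", inframe_deletion = "inframe",
    stop_lost = "inframe",
    splice_region_variant = "splice_region")
  classes <- unname(term_class[terms])
  classes[is.na(classes)] <- "other"
  severity <- c(lof = 1, missense = 2, inframe = 3, splice_region = 4,
                other = 5)
  names(sort(severity[unique(classes)]))[1]
}

# two-tailed Fisher exact p by hypergeometric enumeration at fixed margins
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# genotype reset decided rule by rule
oracle_reset_gt <- function(gt, gq, dp, ad_alt, mq, thr) {
  if (!(gt %in% c("het", "hom_alt", "hemi"))) return(gt)
  if (!is.na(gq) && gq < thr$min_gq) return("no_call")
  if (!is.na(dp) && dp < thr$min_dp) return("no_call")
  if (!is.na(ad_alt) && !is.na(dp) && dp > 0 &&
      ad_alt / dp < thr$min_ad_ratio) return("no_call")
  if (!is.na(mq) && mq < thr$min_mq) return("no_call")
  gt
}

# literal allowed-class table (independent copy of the filtering contract)
oracle_allowed <- function(mc) {
  switch(mc,
         loss_of_function = c("lof", "missense", "inframe", "splice_region"),
         all_missense_in_frame = c("missense", "inframe"),
         activating = c("missense", "inframe"),
         dominant_negative = c("missense", "inframe"),
         uncertain = c("lof", "missense", "inframe", "splice_region"),
         character(0))
}

# requirement satisfaction decided by a literal truth table over zygosities
oracle_requirement <- function(req, zygosities, n_het_sites, sex) {
  has <- function(z) z %in% zygosities
  if (req %in% c("digenic", "mitochondrial", "uncertain")) return(FALSE)
  if (req == "biallelic") return(has("hom_alt") || n_het_sites >= 2)
  if (req == "hemizygous") {
    return(has("hemi") || has("hom_alt") ||
             (has("het") && sex %in% c("female", "unknown")))
  }
  has("het") || has("hom_alt") || has("hemi")
}

# full engine oracle: re-evaluates every (sample, panel entry, rule) triple
# from the generator's in-memory account of what was written to the VCF
oracle_engine_findings <- function(sim, cfg = filter_config(),
                                   thr = quality_thresholds()) {
  rec <- sim$records
  panel_entries <- reportable_entries(sim$panel)$entries
  panel_entries$.id <- seq_len(nrow(panel_entries))
  qualifying <- list()
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (r$low_quality) next  # generator builds these to fail one QC rule
    entries <- panel_entries[panel_entries$gene_symbol == r$gene_symbol, ,
                             drop = FALSE]
    for (j in seq_len(nrow(entries))) {
      e <- entries[j, ]
      cls <- oracle_classify(r$so_term)
      if (!(cls %in% oracle_allowed(e$mutation_consequence))) next
      cutoff <- if (e$allelic_requirement == "biallelic")
        cfg$maf_biallelic else cfg$maf_monoallelic
      passes <- if (cutoff == 0) r$af == 0 else r$af < cutoff
      if (!passes) next
      qualifying[[length(qualifying) + 1L]] <- data.frame(
        sample_id = r$sample_id, entry_id = e$.id,
        gene_symbol = r$gene_symbol,
        allelic_requirement = e$allelic_requirement,
        chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
        zygosity = r$zygosity, stringsAsFactors = FALSE)
    }
  }
  qual <- do.call(rbind, qualifying)
  keys <- unique(qual[, c("sample_id", "entry_id")])
  keys$satisfied <- vapply(seq_len(nrow(keys)), function(k) {
    sub <- qual[qual$sample_id == keys$sample_id[k] &
                  qual$entry_id == keys$entry_id[k], , drop = FALSE]
    oracle_requirement(sub$allelic_requirement[1L], sub$zygosity,
                       length(unique(paste(sub$chrom, sub$pos)[
                         sub$zygosity == "het"])),
                       sim$sex[[keys$sample_id[k]]])
  }, logical(1))
  list(qualifying = qual, findings = keys)
}
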