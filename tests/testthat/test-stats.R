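make_variants <- function(samples, gene = "AAA1", req = "monoallelic",
                          class = "missense", af = 1e-5, pos = 100,
                          cadd = NA_real_) {
  if (length(samples) == 0L) {
    return(make_variants("placeholder", gene, req, class, af, pos,
                         cadd)[0L, , drop = FALSE])
  }
  data.frame(sample_id = samples, lgmdet_id = 1L, gene_symbol = gene,
             chrom = "1", pos = pos, ref = "A", alt = "T",
             zygosity = "het", consequence_class = class, max_af = af,
             cadd_phred = cadd, allelic_requirement = req, is_snv = TRUE,
             stringsAsFactors = FALSE)
}

as_findings <- function(variants, samples) {
  structure(list(variants = variants, samples = samples,
                 findings = data.frame()), class = "g2p_findings")
}

test_that("burden tables count carriers once per stratum", {
  case <- as_findings(make_variants(c("A1", "A2", "A3", "A3")),
                      paste0("A", 1:10))
  control <- as_findings(make_variants("B1"), paste0("B", 1:10))
  tab <- burden_tables(case, control)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$case_carriers, 3L)   # A3 counted once
  expect_equal(tab$case_total, 10L)
  expect_equal(tab$control_carriers, 1L)
  expect_equal(tab$control_total, 10L)

  # duplicating a variant record never changes carrier counts (set semantics)
  case2 <- as_findings(rbind(case$variants, case$variants), case$samples)
  expect_equal(burden_tables(case2, control)$case_carriers, 3L)

  # empty control arm
  empty <- as_findings(make_variants(character(0)), paste0("B", 1:5))
  expect_equal(burden_tables(case, empty)$control_carriers, 0L)

  # overlapping sample ids rejected
  expect_error(burden_tables(case, as_findings(make_variants("A1"),
                                               c("A1", "B9"))), "share")
})

test_that("burden tables match a per-sample membership scan on random cohorts", {
  set.seed(43)
  genes <- c("AAA1", "BBB2")
  reqs <- c(AAA1 = "monoallelic", BBB2 = "biallelic")
  classes <- c("lof", "missense")
  rand_arm <- function(prefix, n_samp, n_var) {
    g <- sample(genes, n_var, replace = TRUE)
    make <- make_variants(sample(paste0(prefix, 1:n_samp), n_var,
                                 replace = TRUE))
    make$gene_symbol <- g
    make$allelic_requirement <- unname(reqs[g])
    make$consequence_class <- sample(classes, n_var, replace = TRUE)
    make$pos <- sample(1:20, n_var, replace = TRUE) * 10
    as_findings(make, paste0(prefix, 1:n_samp))
  }
  case <- rand_arm("A", 15, 40)
  control <- rand_arm("B", 12, 30)
  tab <- burden_tables(case, control)
  for (i in seq_len(nrow(tab))) {
    for (arm in list(c("case", "A"), c("control", "B"))) {
      v <- if (arm[1] == "case") case$variants else control$variants
      members <- unique(v$sample_id[
        v$allelic_requirement == tab$allelic_requirement[i] &
          v$consequence_class == tab$consequence_class[i]])
      expect_equal(tab[[paste0(arm[1], "_carriers")]][i], length(members))
    }
  }
})

test_that("odds ratio and exact p match enumeration", {
  r <- fisher_odds_ratio(c(10, 5, 2, 20))
  expect_equal(r$odds_ratio, 20.0)
  expect_equal(r$p_value, oracle_fisher_p(10, 5, 2, 20))
  expect_true(r$ci95[1] <= r$odds_ratio && r$odds_ratio <= r$ci95[2])

  sym <- fisher_odds_ratio(c(5, 5, 5, 5))
  expect_equal(sym$odds_ratio, 1.0)
  expect_equal(sym$p_value, 1.0)

  extreme <- fisher_odds_ratio(c(0, 10, 10, 0))
  expect_identical(extreme$odds_ratio, 0)  # no case carriers at all
  expect_true(all(is.finite(extreme$ci95)))
  inf <- fisher_odds_ratio(c(10, 0, 0, 10))
  expect_identical(inf$odds_ratio, Inf)
  expect_true(all(is.finite(inf$ci95)))

  undef <- fisher_odds_ratio(c(0, 0, 3, 4))
  expect_true(undef$undefined)
  expect_error(fisher_odds_ratio(c(-1, 2, 3, 4)), "non-negative")
})

test_that("exact p equals hypergeometric enumeration across tables with n <= 60", {
  # deterministic sweep of small tables plus a random sample of larger ones
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(fisher_odds_ratio(c(a, b, c_, d))$p_value,
                 oracle_fisher_p(a, b, c_, d), tolerance = 1e-12)
  }
  set.seed(47)
  for (i in 1:400) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4)))
    m <- matrix(cells, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_odds_ratio(cells)$p_value,
                 oracle_fisher_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("per-gene proportions flag higher-in-control and absent-in-control genes", {
  case <- as_findings({
    v <- make_variants(c("A1", "A2"))
    v2 <- make_variants("A1", gene = "BBB2")
    rbind(v, v2)
  }, paste0("A", 1:100))
  control <- as_findings(make_variants(c("B1", "B2"), gene = "BBB2"),
                         paste0("B", 1:10))
  pg <- per_gene_proportions(case, control)
  expect_equal(pg$n_genes, 2L)
  # BBB2: 1/100 cases vs 2/10 controls -> higher in control
  expect_equal(pg$n_higher_in_control, 1L)
  # AAA1 absent from controls
  expect_equal(pg$n_absent_in_control, 1L)

  # random cohorts against a direct per-gene loop
  set.seed(53)
  sim <- cached_sim()
  res <- filter_cohort(sim$vcf, sim$panel)
  case_ids <- grep("^CASE", res$samples, value = TRUE)
  ctrl_ids <- grep("^CTRL", res$samples, value = TRUE)
  split_arm <- function(ids) {
    as_findings(res$variants[res$variants$sample_id %in% ids, ], ids)
  }
  pg2 <- per_gene_proportions(split_arm(case_ids), split_arm(ctrl_ids))
  cv <- res$variants[res$variants$sample_id %in% case_ids, ]
  kv <- res$variants[res$variants$sample_id %in% ctrl_ids, ]
  higher <- 0L; absent <- 0L
  for (g in unique(cv$gene_symbol)) {
    cf <- length(unique(cv$sample_id[cv$gene_symbol == g])) / length(case_ids)
    kf <- length(unique(kv$sample_id[kv$gene_symbol == g])) / length(ctrl_ids)
    if (kf > cf) higher <- higher + 1L
    if (kf == 0) absent <- absent + 1L
  }
  expect_equal(pg2$n_higher_in_control, higher)
  expect_equal(pg2$n_absent_in_control, absent)
})

test_that("high-CADD fraction uses unique scored missense variants", {
  v <- rbind(
    make_variants(paste0("S", 1:7), pos = 1:7 * 10,
                  cadd = c(31, 35, 40, 10, 12, 15, 20)),
    make_variants(c("S8", "S9", "S10"), pos = 8:10 * 10,
                  cadd = c(25, 28, 29)))
  f <- cadd_high_fraction(as_findings(v, paste0("S", 1:10)))
  expect_equal(f$fraction, 0.30)
  # the same variant in several samples counts once
  dup <- rbind(v, make_variants("S99", pos = 10, cadd = 31))
  f2 <- cadd_high_fraction(as_findings(dup, c(paste0("S", 1:10), "S99")))
  expect_equal(f2$n_scored, 10L)
  expect_equal(f2$fraction, 0.30)
  # unscored variants are excluded, not counted as low
  na_only <- make_variants("S1", cadd = NA_real_)
  f3 <- cadd_high_fraction(as_findings(na_only, "S1"))
  expect_true(f3$undefined)
  expect_true(is.na(f3$fraction))
})

test_that("per-sample distribution includes zero-count samples", {
  v <- rbind(make_variants("S3"), make_variants("S4", pos = 110),
             make_variants("S4", pos = 120),
             make_variants("S4", pos = 130))
  res <- structure(list(variants = v, samples = paste0("S", 1:4),
                        findings = data.frame(sample_id = character(0),
                                              requirement_satisfied =
                                                logical(0))),
                   class = "g2p_findings")
  res$sample_summary <- g2pfilter:::.sample_summary(v, res$findings,
                                                    res$samples)
  d <- findings_per_sample_distribution(res)
  expect_equal(d$mean, 1.0)
  expect_equal(d$histogram$proportion[d$histogram$count == 0], 0.5)
  expect_equal(d$histogram$proportion[d$histogram$count == 1], 0.25)
  expect_equal(d$histogram$proportion[d$histogram$count == 3], 0.25)
  expect_equal(sum(d$histogram$proportion), 1.0)

  # all-zero cohort
  res0 <- res; res0$variants <- v[0, ]
  res0$sample_summary <- g2pfilter:::.sample_summary(res0$variants,
                                                     res$findings,
                                                     res$samples)
  d0 <- findings_per_sample_distribution(res0)
  expect_equal(d0$mean, 0)
  expect_equal(d0$sd, 0)
})

test_that("MAF ratio is the control/case mean ratio and flags empty strata", {
  case <- as_findings(make_variants(c("A1", "A2"), af = 1e-5),
                      paste0("A", 1:2))
  control <- as_findings(make_variants(c("B1", "B2"), af = 2e-5),
                         paste0("B", 1:2))
  r <- maf_ratio(case, control)
  expect_equal(r$ratio, 2.0)
  expect_equal(maf_ratio(case, case)$ratio, 1.0)
  r2 <- maf_ratio(case, control, stratum = list(consequence_class = "lof"))
  expect_true(r2$undefined)
})

test_that("odds ratios centre on 1 when both arms share the generative model", {
  # same simulation settings, disjoint seeds, controls only
  log_ors <- vapply(1:6, function(k) {
    cfg_a <- simulation_config(seed = 100L + k, n_case_samples = 0L,
                               n_control_samples = 30L)
    cfg_b <- simulation_config(seed = 200L + k, n_case_samples = 0L,
                               n_control_samples = 30L)
    sim_a <- generate_cohort(cfg_a, dir = withr::local_tempdir())
    sim_b <- generate_cohort(cfg_b, dir = withr::local_tempdir())
    res_a <- filter_cohort(sim_a$vcf, sim_a$panel)
    res_b <- filter_cohort(sim_b$vcf, sim_b$panel)
    carriers <- function(res) sum(res$sample_summary$n_qualifying > 0)
    a <- carriers(res_a); b <- length(res_a$samples) - a
    c_ <- carriers(res_b); d <- length(res_b$samples) - c_
    log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)))
  }, numeric(1))
  # mean log OR near 0 at this replicate count
  expect_lt(abs(mean(log_ors)), 0.75)
})
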