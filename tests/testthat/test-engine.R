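test_that("variant validity applies canonical, class, MAF and concordance in order", {
  cfg <- filter_config()
  lof_mono <- make_lgmdet(allelic_requirement = "monoallelic",
                          mutation_consequence = "loss_of_function")
  # AF above the 1-in-10,000 monoallelic cut-off is invalid even for a
  # canonical stop gain
  v <- variant_is_valid(make_tc(so_terms = "stop_gained", gnomAD_AF = 2e-4),
                        lof_mono, cfg)
  expect_false(v$valid)
  expect_equal(v$reason, "maf")
  # an allele unseen in every source is frequency-valid
  v2 <- variant_is_valid(make_tc(so_terms = "missense_variant"),
                         lof_mono, cfg)
  expect_true(v2$valid)
  expect_equal(v2$max_af, 0)
  # non-canonical fails first
  v3 <- variant_is_valid(make_tc(so_terms = "stop_gained",
                                 is_canonical = FALSE, gnomAD_AF = 2e-4),
                         lof_mono, cfg)
  expect_equal(v3$reason, "not_canonical")
  # mechanism not detectable from coding consequences
  v4 <- variant_is_valid(make_tc(so_terms = "missense_variant"),
                         make_lgmdet(mutation_consequence = "utr_mutation"),
                         cfg)
  expect_equal(v4$reason, "unsupported_mechanism")
  # gene mismatch is a hard error
  expect_error(variant_is_valid(make_tc(gene_symbol = "ZZZ9"), lof_mono,
                                cfg), "does not match")
  # SIFT/PolyPhen concordance as an optional missense sub-filter
  cfg_sp <- filter_config(require_sift_polyphen_concordance = TRUE)
  v5 <- variant_is_valid(make_tc(so_terms = "missense_variant",
                                 sift_prediction = "tolerated",
                                 polyphen_prediction = "probably_damaging"),
                         lof_mono, cfg_sp)
  expect_equal(v5$reason, "sift_polyphen_discordant")
  v6 <- variant_is_valid(make_tc(so_terms = "missense_variant",
                                 sift_prediction = "deleterious",
                                 polyphen_prediction = "possibly_damaging"),
                         lof_mono, cfg_sp)
  expect_true(v6$valid)
})

test_that("validity verdicts match independent rule evaluation over a full grid", {
  cfg <- filter_config()
  grid <- expand.grid(
    canonical = c(TRUE, FALSE),
    so_term = c("stop_gained", "missense_variant", "inframe_deletion",
                "splice_region_variant", "synonymous_variant"),
    af = c(0, 5e-5, 1e-4, 2e-4, 1e-3, 6e-3),
    req = c("monoallelic", "biallelic", "hemizygous", "imprinted"),
    mc = c("loss_of_function", "all_missense_in_frame", "activating",
           "uncertain", "cis_regulatory"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- variant_is_valid(
      make_tc(so_terms = g$so_term, is_canonical = g$canonical,
              gnomAD_AF = if (g$af > 0) g$af else NA_real_),
      make_lgmdet(allelic_requirement = g$req, mutation_consequence = g$mc),
      cfg)
    cls <- oracle_classify(g$so_term)
    cutoff <- if (g$req == "biallelic") 5e-3 else 1e-4
    want <- g$canonical && cls %in% oracle_allowed(g$mc) && g$af < cutoff
    expect_identical(got$valid, want)
  }
})

test_that("genotype aggregation honours each allelic requirement", {
  bi <- make_lgmdet(allelic_requirement = "biallelic")
  vrow <- function(pos, zygosity) {
    data.frame(chrom = "1", pos = pos, ref = "A", alt = "T",
               zygosity = zygosity, stringsAsFactors = FALSE)
  }
  # one het never satisfies a biallelic entry
  f1 <- aggregate_gene_findings("S", bi, vrow(100, "het"))
  expect_false(f1$requirement_satisfied)
  expect_equal(f1$genotype_pattern, "not_satisfied")
  # a homozygote alone suffices
  f2 <- aggregate_gene_findings("S", bi, vrow(100, "hom_alt"))
  expect_true(f2$requirement_satisfied)
  expect_equal(f2$genotype_pattern, "hom_alt")
  # two distinct het sites form a possible compound heterozygote
  f3 <- aggregate_gene_findings("S", bi, rbind(vrow(100, "het"),
                                               vrow(200, "het")))
  expect_true(f3$requirement_satisfied)
  expect_equal(f3$genotype_pattern, "two_or_more_hets")
  # the same site twice does not
  f4 <- aggregate_gene_findings("S", bi, rbind(vrow(100, "het"),
                                               vrow(100, "het")))
  expect_false(f4$requirement_satisfied)
  # hemizygous: het qualifies for female/unknown sex only
  hemi <- make_lgmdet(allelic_requirement = "hemizygous")
  expect_false(aggregate_gene_findings("S", hemi, vrow(1, "het"),
                                       sex = "male")$requirement_satisfied)
  expect_true(aggregate_gene_findings("S", hemi, vrow(1, "het"),
                                      sex = "female")$requirement_satisfied)
  expect_true(aggregate_gene_findings("S", hemi, vrow(1, "hemi"),
                                      sex = "male")$requirement_satisfied)
  # digenic entries are reported, never satisfied
  dig <- make_lgmdet(allelic_requirement = "digenic")
  fd <- aggregate_gene_findings("S", dig, vrow(1, "hom_alt"))
  expect_false(fd$requirement_satisfied)
  expect_match(fd$reason, "digenic")
  # incidental-finding flag propagates
  fi <- aggregate_gene_findings(
    "S", make_lgmdet(confidence = "both_rd_and_if"), vrow(1, "het"))
  expect_true(fi$incidental_flag)
})

test_that("aggregation matches a truth-table oracle on random zygosity multisets", {
  set.seed(41)
  reqs <- c("monoallelic", "biallelic", "hemizygous", "imprinted", "mosaic",
            "x_linked_dominant", "digenic", "mitochondrial", "uncertain")
  for (i in 1:300) {
    req <- sample(reqs, 1)
    sex <- sample(c("male", "female", "unknown"), 1)
    k <- sample(1:4, 1)
    pos <- sample(1:3, k, replace = TRUE)  # repeated sites possible
    zy <- sample(c("het", "hom_alt", "hemi"), k, replace = TRUE)
    v <- data.frame(chrom = "1", pos = pos * 100, ref = "A", alt = "T",
                    zygosity = zy, stringsAsFactors = FALSE)
    got <- aggregate_gene_findings(
      "S", make_lgmdet(allelic_requirement = req), v, sex = sex)
    n_het_sites <- length(unique(pos[zy == "het"]))
    expect_identical(got$requirement_satisfied,
                     oracle_requirement(req, zy, n_het_sites, sex),
                     label = sprintf("req=%s zy=%s sex=%s", req,
                                     paste(zy, collapse = ","), sex))
    # structural invariants on the emitted pattern
    if (got$requirement_satisfied && req == "biallelic") {
      expect_true(got$genotype_pattern %in% c("hom_alt", "two_or_more_hets"))
      if (got$genotype_pattern == "two_or_more_hets") {
        expect_gte(n_het_sites, 2L)
      }
    }
  }
})

test_that("cohort filtering recovers exactly the planted genotypes when noiseless", {
  cfg_sim <- simulation_config(seed = 5L, n_case_samples = 12L,
                               n_control_samples = 8L,
                               planted_fraction = 1, background_rate = 0)
  sim <- generate_cohort(cfg_sim, dir = withr::local_tempdir())
  res <- filter_cohort(sim$vcf, sim$panel, sex_table = read_ped(sim$ped))
  cc <- score_findings(res, sim$truth)
  expect_equal(cc$sensitivity, 1.0)
  expect_equal(cc$fp, 0L)
  # one satisfied finding per planted case, none in controls
  sat <- res$findings[res$findings$requirement_satisfied, ]
  expect_setequal(unique(sat$sample_id), unique(sim$truth$sample_id))
  expect_false(any(grepl("^CTRL", sat$sample_id)))
  # compound-het plants carry the two-site pattern
  two_site <- names(which(table(sim$truth$sample_id) == 2))
  if (length(two_site) > 0) {
    expect_true(all(sat$genotype_pattern[sat$sample_id %in% two_site] ==
                      "two_or_more_hets"))
  }
})

test_that("engine output equals a brute-force re-evaluation on a 120-sample cohort", {
  sim <- cached_sim()
  res <- filter_cohort(sim$vcf, sim$panel, sex_table = read_ped(sim$ped))
  oracle <- oracle_engine_findings(sim)
  # qualifying variant observations agree as sets
  got_q <- sort(paste(res$variants$sample_id, res$variants$gene_symbol,
                      res$variants$allelic_requirement, res$variants$chrom,
                      res$variants$pos, res$variants$zygosity))
  want_q <- sort(paste(oracle$qualifying$sample_id,
                       oracle$qualifying$gene_symbol,
                       oracle$qualifying$allelic_requirement,
                       oracle$qualifying$chrom, oracle$qualifying$pos,
                       oracle$qualifying$zygosity))
  expect_equal(got_q, want_q)
  # per (sample, entry) satisfaction agrees
  got_f <- res$findings[order(res$findings$sample_id,
                              res$findings$lgmdet_id), ]
  want_f <- oracle$findings[order(oracle$findings$sample_id,
                                  oracle$findings$entry_id), ]
  expect_equal(nrow(got_f), nrow(want_f))
  expect_equal(paste(got_f$sample_id, got_f$lgmdet_id),
               paste(want_f$sample_id, want_f$entry_id))
  expect_equal(got_f$requirement_satisfied, want_f$satisfied)
})

test_that("genes outside the reportable panel never reach the output", {
  sim <- cached_sim()
  res <- filter_cohort(sim$vcf, sim$panel)
  reportable_genes <- panel_genes(reportable_entries(sim$panel))
  expect_true(all(res$variants$gene_symbol %in% reportable_genes))
  expect_true(all(res$findings$gene_symbol %in% reportable_genes))
  possible_genes <- setdiff(panel_genes(sim$panel), reportable_genes)
  expect_true(length(possible_genes) > 0)
  expect_false(any(res$variants$gene_symbol %in% possible_genes))
})

test_that("MAF thresholds act monotonically on findings", {
  sim <- cached_sim()
  loose <- filter_cohort(sim$vcf, sim$panel,
                         filter_config(maf_monoallelic = 1e-4,
                                       maf_biallelic = 5e-3))
  tight <- filter_cohort(sim$vcf, sim$panel,
                         filter_config(maf_monoallelic = 1e-5,
                                       maf_biallelic = 1e-4))
  key <- function(r) paste(r$variants$sample_id, r$variants$chrom,
                           r$variants$pos, r$variants$lgmdet_id)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gte(nrow(loose$variants), nrow(tight$variants))
})

test_that("identical inputs give byte-identical findings reports", {
  sim <- cached_sim()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_findings(filter_cohort(sim$vcf, sim$panel), p1)
  write_findings(filter_cohort(sim$vcf, sim$panel), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("undecomposed records are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Format: ",
           "Allele|Consequence|SYMBOL|Feature|CANONICAL\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t500\t.\tA\tT,C\t.\tPASS\tCSQ=T|missense_variant|AAA1|ENST1|YES\tGT\t0/1"),
    path)
  expect_error(filter_cohort(path, fixture_panel()), "1:500")
})
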