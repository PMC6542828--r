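## Deterministic synthetic panels and annotated cohort VCFs with planted
## causative genotypes, background variation, sex tables and truth sets, so
## the whole pipeline is testable without managed-access clinical data.

## Restore the caller's RNG state after seeded generation.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Default panel composition for the generator
#'
#' Counts of reportable entries per (allelic requirement, mutation
#' consequence) cell; a small panel mixing the dominant mechanisms seen in
#' curated developmental-disorder panels (mostly loss-of-function, a majority
#' of biallelic plus monoallelic entries, a few X-linked).
#' @export
default_panel_spec <- function() {
  data.frame(
    allelic_requirement = c("monoallelic", "biallelic", "monoallelic",
                            "biallelic", "hemizygous", "monoallelic"),
    mutation_consequence = c("loss_of_function", "loss_of_function",
                             "all_missense_in_frame",
                             "all_missense_in_frame", "loss_of_function",
                             "activating"),
    n = c(3L, 3L, 2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param seed RNG seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_case_samples,n_control_samples cohort sizes (default 60 each:
#'   large enough for carrier-burden contrasts at desk scale).
#' @param panel_spec entry counts per (requirement, consequence) cell, see
#'   [default_panel_spec()].
#' @param planted_fraction fraction of case samples given a causative
#'   genotype (default 0.9: most, not all, cases carry a detectable cause).
#' @param background_rate expected number of *qualifying* background variants
#'   per sample after filtering (default 2.0, the order observed in
#'   population controls); the generator inflates its raw draw by the
#'   analytic acceptance probability so this calibration holds.
#' @param af_spectrum population-frequency distribution of generated alleles:
#'   `p_zero` mass at 0 (unseen in every reference source), the rest
#'   log-uniform on `[af_min, af_max]`, so both arms of every MAF cut-off are
#'   exercised.
#' @param quality_model `p_low_quality` is the probability that a generated
#'   genotype call deliberately fails one quality rule (and is reset to a
#'   no-call by the engine); `gq`/`dp` are the good-call values.
#' @return List of class `g2p_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_case_samples = 60L,
                              n_control_samples = 60L,
                              panel_spec = default_panel_spec(),
                              planted_fraction = 0.9,
                              background_rate = 2.0,
                              af_spectrum = list(p_zero = 0.6,
                                                 af_min = 1e-6,
                                                 af_max = 1e-3),
                              quality_model = list(p_low_quality = 0.1,
                                                   gq = 99, dp = 40)) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            background_rate >= 0,
            af_spectrum$p_zero >= 0, af_spectrum$p_zero <= 1,
            af_spectrum$af_min > 0, af_spectrum$af_min <= af_spectrum$af_max,
            quality_model$p_low_quality >= 0,
            quality_model$p_low_quality <= 1)
  structure(list(seed = as.integer(seed),
                 n_case_samples = as.integer(n_case_samples),
                 n_control_samples = as.integer(n_control_samples),
                 panel_spec = panel_spec,
                 planted_fraction = planted_fraction,
                 background_rate = background_rate,
                 af_spectrum = af_spectrum,
                 quality_model = quality_model),
            class = "g2p_sim_config")
}

#' Generate a synthetic panel
#'
#' Builds one entry per unit of `panel_spec` (confirmed/probable assigned
#' alternately) and always appends one possible-confidence entry (to exercise
#' reportability filtering) and one entry flagged as relevant for both the
#' disease and an incidental finding. X-linked requirements are placed on
#' chromosome X, everything else alternates over two autosomes; each gene
#' owns a disjoint coordinate window used by [generate_cohort()].
#'
#' @param cfg a [simulation_config()].
#' @return A [g2p_panel()] whose entries carry a `chrom` attribute mapping
#'   (`attr(panel, "gene_map")`: gene, chrom, window start).
#' @export
generate_panel <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "g2p_sim_config"))
  spec <- cfg$panel_spec
  stopifnot(nrow(spec) > 0L)
  .with_seed(cfg$seed, {
    req <- rep(spec$allelic_requirement, spec$n)
    mc <- rep(spec$mutation_consequence, spec$n)
    conf <- rep_len(c("confirmed", "probable"), length(req))
    ## the two sentinel entries: one non-reportable, one incidental-finding
    req <- c(req, "monoallelic", "biallelic")
    mc <- c(mc, "loss_of_function", "loss_of_function")
    conf <- c(conf, "possible", "both_rd_and_if")
    n <- length(req)
    gene <- sprintf("GENE%03d", seq_len(n))
    on_x <- req %in% c("hemizygous", "x_linked_dominant",
                       "x_linked_over_dominance")
    chrom <- ifelse(on_x, "X", rep_len(c("1", "2"), n))
    entries <- data.frame(
      gene_symbol = gene,
      gene_ids = sprintf("HGNC:%d", 1000L + seq_len(n)),
      disease_name = sprintf("SYNTHETIC DISORDER %d", seq_len(n)),
      confidence = conf,
      allelic_requirement = req,
      mutation_consequence = mc,
      hpo_terms = sprintf("HP:%07d;HP:%07d", seq_len(n), 5000L + seq_len(n)),
      organ_specificity = "Brain",
      pmids = sprintf("%d", 20000000L + seq_len(n)),
      stringsAsFactors = FALSE
    )
    panel <- g2p_panel(entries, name = "synthetic_panel")
    attr(panel, "gene_map") <- data.frame(
      gene_symbol = gene, chrom = chrom,
      window_start = 100000L * seq_len(n), stringsAsFactors = FALSE)
    panel
  })
}

## P(max population AF passes the cut-off) under the generator's spectrum.
.af_pass_prob <- function(cutoff, spectrum) {
  if (cutoff <= 0) return(spectrum$p_zero)
  tail_p <- if (cutoff <= spectrum$af_min) 0
  else if (cutoff >= spectrum$af_max) 1
  else (log(cutoff) - log(spectrum$af_min)) /
    (log(spectrum$af_max) - log(spectrum$af_min))
  spectrum$p_zero + (1 - spectrum$p_zero) * tail_p
}

#' Analytic acceptance probability of a background variant
#'
#' The probability that one generated background variant survives the filter:
#' its allele frequency passes the cut-off of its gene's allelic requirement
#' (averaged over the genes background variants are assigned to) times the
#' probability its genotype call is not deliberately low quality. Used by
#' [generate_cohort()] to inflate the raw background draw so that
#' `background_rate` is the expected number of variants per sample *after*
#' filtering.
#'
#' @param panel the generated panel.
#' @param cfg a [simulation_config()].
#' @param filter_cfg the [filter_config()] the cohort will be filtered with.
#' @return Probability in \[0,1\].
#' @export
background_acceptance_probability <- function(panel,
                                              cfg = simulation_config(),
                                              filter_cfg = filter_config()) {
  eligible <- .background_genes(panel)
  thr <- maf_threshold_for(eligible$allelic_requirement, filter_cfg)
  p_af <- vapply(thr, .af_pass_prob, numeric(1), spectrum = cfg$af_spectrum)
  mean(p_af) * (1 - cfg$quality_model$p_low_quality)
}

## Genes that can receive background variants: reportable, with a mechanism
## detectable from coding consequences.
.background_genes <- function(panel) {
  e <- reportable_entries(panel)$entries
  detectable <- vapply(e$mutation_consequence,
                       function(mc) length(allowed_classes(mc)) > 0L,
                       logical(1))
  e[detectable & !duplicated(e$gene_symbol), , drop = FALSE]
}

.CSQ_FIELDS <- c("Allele", "Consequence", "SYMBOL", "Feature", "CANONICAL",
                 "SIFT", "PolyPhen", "CADD_PHRED", "gnomAD_AF", "TOPMed_AF",
                 "UK10K_AF")

.draw_af <- function(n, spectrum) {
  zero <- stats::runif(n) < spectrum$p_zero
  af <- exp(stats::runif(n, log(spectrum$af_min), log(spectrum$af_max)))
  af[zero] <- 0
  ## freeze to the precision written into the VCF so the in-memory table and
  ## the re-parsed file agree exactly
  as.numeric(sprintf("%.6g", af))
}

.draw_af_passing <- function(n, spectrum, cutoff) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      af <- .draw_af(1L, spectrum)
      if (maf_passes(af, cutoff)) { out[i] <- af; break }
    }
  }
  out
}

## SO term for a consequence class (frameshift implies an indel).
.term_for_class <- function(class) {
  switch(class,
         lof = sample(c("stop_gained", "frameshift_variant",
                        "splice_donor_variant"), 1L,
                      prob = c(0.5, 0.3, 0.2)),
         missense = "missense_variant",
         inframe = "inframe_deletion",
         splice_region = "splice_region_variant")
}

#' Generate a synthetic annotated cohort
#'
#' Writes a decomposed, normalised, CSQ-annotated multi-sample VCF, a PED
#' sample-sex table and a truth TSV of the planted causative variants.
#' Case samples receive, with probability `planted_fraction`, one causative
#' genotype respecting a randomly chosen reportable panel entry (heterozygous
#' for monoallelic entries; homozygous or two heterozygous sites for
#' biallelic ones; hemizygous on X for hemizygous entries, in a male).
#' All samples receive Poisson background variants in panel genes, with
#' allele frequencies from the configured spectrum (including mass above the
#' cut-offs) and deliberately low-quality calls at the configured rate, so
#' filter failures of every kind are present.
#'
#' @param cfg a [simulation_config()].
#' @param panel panel from [generate_panel()] (regenerated from `cfg` when
#'   omitted).
#' @param dir output directory (created if needed).
#' @param filter_cfg the filter configuration the cohort is calibrated
#'   against (MAF cut-offs used when drawing passing frequencies).
#' @return List: `vcf`, `ped`, `truth_tsv` (paths), `truth` (data frame),
#'   `panel_csv`, `panel`, `samples`, `records` (the generator's in-memory
#'   account of every written variant: carrier, gene, class, frequency,
#'   quality and whether it was built to survive filtering).
#' @export
generate_cohort <- function(cfg = simulation_config(),
                            panel = generate_panel(cfg),
                            dir = tempfile("g2p_sim_"),
                            filter_cfg = filter_config()) {
  stopifnot(inherits(cfg, "g2p_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_map <- attr(panel, "gene_map")
  if (is.null(gene_map)) {
    stop("panel lacks the generator's gene coordinate map; use generate_panel()",
         call. = FALSE)
  }
  .with_seed(cfg$seed + 1L, {
    cases <- if (cfg$n_case_samples > 0L)
      sprintf("CASE%03d", seq_len(cfg$n_case_samples)) else character(0)
    controls <- if (cfg$n_control_samples > 0L)
      sprintf("CTRL%03d", seq_len(cfg$n_control_samples)) else character(0)
    samples <- c(cases, controls)
    stopifnot(length(samples) > 0L)
    sex <- sample(c("male", "female"), length(samples), replace = TRUE)
    names(sex) <- samples

    rep_entries <- reportable_entries(panel)$entries
    plantable <- rep_entries[
      rep_entries$allelic_requirement %in%
        c(MONOALLELIC_LIKE_REQUIREMENTS, "biallelic") &
        vapply(rep_entries$mutation_consequence,
               function(mc) length(allowed_classes(mc)) > 0L, logical(1)), ,
      drop = FALSE]
    bg_genes <- .background_genes(panel)
    p_accept <- background_acceptance_probability(panel, cfg, filter_cfg)
    raw_rate <- if (p_accept > 0) cfg$background_rate / p_accept else 0

    ## per-gene position allocator: disjoint deterministic offsets
    pos_counter <- new.env(parent = emptyenv())
    next_pos <- function(gene) {
      k <- if (is.null(pos_counter[[gene]])) 0L else pos_counter[[gene]]
      pos_counter[[gene]] <- k + 1L
      gm <- gene_map[gene_map$gene_symbol == gene, ]
      list(chrom = gm$chrom, pos = gm$window_start + 10L * k + 1L)
    }

    records <- list()
    truth <- list()
    add_record <- function(sample_id, entry, class, af, zygosity,
                           low_quality, planted) {
      loc <- next_pos(entry$gene_symbol)
      term <- .term_for_class(class)
      is_indel <- term %in% c("frameshift_variant", "inframe_deletion")
      bases <- c("A", "C", "G", "T")
      ref1 <- sample(bases, 1L)
      if (is_indel) {
        ref <- paste0(ref1, sample(bases, 1L))
        alt <- ref1
      } else {
        ref <- ref1
        alt <- sample(setdiff(bases, ref1), 1L)
      }
      ## hemizygous calls on X for males
      if (loc$chrom == "X" && sex[[sample_id]] == "male" &&
          zygosity != "no_plant") {
        zygosity <- if (zygosity == "hom_alt") "hemi" else
          if (zygosity == "het") "hemi" else zygosity
      }
      cadd <- if (class == "missense")
        round(stats::runif(1L, 5, 45), 1) else
          round(stats::runif(1L, 20, 50), 1)
      records[[length(records) + 1L]] <<- data.frame(
        sample_id = sample_id, gene_symbol = entry$gene_symbol,
        allelic_requirement = entry$allelic_requirement,
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
        so_term = term, consequence_class = class, af = af,
        cadd_phred = cadd, zygosity = zygosity,
        low_quality = low_quality, planted = planted,
        stringsAsFactors = FALSE)
      list(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
           gene = entry$gene_symbol)
    }

    ## plant causative genotypes in case samples
    for (s in cases) {
      if (stats::runif(1L) >= cfg$planted_fraction) next
      pool <- plantable
      if (sex[[s]] == "female") {
        pool <- pool[pool$allelic_requirement != "hemizygous", , drop = FALSE]
      }
      entry <- pool[sample.int(nrow(pool), 1L), , drop = FALSE]
      class <- allowed_classes(entry$mutation_consequence)[1L]
      cutoff <- maf_threshold_for(entry$allelic_requirement, filter_cfg)
      if (entry$allelic_requirement == "biallelic" &&
          stats::runif(1L) < 0.5) {
        ## possible compound heterozygote: two distinct het sites
        for (k in 1:2) {
          af <- .draw_af_passing(1L, cfg$af_spectrum, cutoff)
          loc <- add_record(s, entry, class, af, "het", FALSE, TRUE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = s, chrom = loc$chrom, pos = loc$pos, ref = loc$ref,
            alt = loc$alt, gene_symbol = loc$gene,
            expected_requirement = entry$allelic_requirement,
            stringsAsFactors = FALSE)
        }
      } else {
        zy <- if (entry$allelic_requirement == "biallelic") "hom_alt"
        else if (entry$allelic_requirement == "hemizygous") "hemi"
        else "het"
        af <- .draw_af_passing(1L, cfg$af_spectrum, cutoff)
        loc <- add_record(s, entry, class, af, zy, FALSE, TRUE)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = s, chrom = loc$chrom, pos = loc$pos, ref = loc$ref,
          alt = loc$alt, gene_symbol = loc$gene,
          expected_requirement = entry$allelic_requirement,
          stringsAsFactors = FALSE)
      }
    }

    ## background variation for everyone
    for (s in samples) {
      n_bg <- stats::rpois(1L, raw_rate)
      for (k in seq_len(n_bg)) {
        entry <- bg_genes[sample.int(nrow(bg_genes), 1L), , drop = FALSE]
        cls_pool <- allowed_classes(entry$mutation_consequence)
        class <- cls_pool[sample.int(length(cls_pool), 1L)]
        af <- .draw_af(1L, cfg$af_spectrum)
        low_q <- stats::runif(1L) < cfg$quality_model$p_low_quality
        add_record(s, entry, class, af, "het", low_q, FALSE)
      }
    }

    records <- if (length(records) > 0L) do.call(rbind, records) else NULL
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(sample_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 gene_symbol = character(0),
                 expected_requirement = character(0),
                 stringsAsFactors = FALSE)
    if (is.null(records)) {
      stop("simulation produced no variants; increase rates or cohort size",
           call. = FALSE)
    }

    vcf_path <- file.path(dir, "cohort.vcf")
    .write_synthetic_vcf(records, samples, sex, cfg, vcf_path)
    ped_path <- file.path(dir, "cohort.ped")
    phen <- ifelse(samples %in% cases, "2", "1")
    writeLines(paste(samples, samples, "0", "0",
                     ifelse(sex == "male", "1", "2"), phen, sep = "\t"),
               ped_path)
    truth_path <- file.path(dir, "truth.tsv")
    write_truth_tsv(truth, truth_path)
    panel_path <- file.path(dir, "panel.csv")
    write_g2p_csv(panel, panel_path)
    list(vcf = vcf_path, ped = ped_path, truth_tsv = truth_path,
         truth = truth, panel_csv = panel_path, panel = panel,
         samples = samples, sex = sex, records = records)
  })
}

## Serialise the generated records as a sorted VCF 4.2 text file with one
## CSQ block pair (canonical + non-canonical) per record.
.write_synthetic_vcf <- function(records, samples, sex, cfg, path) {
  ord <- order(match(records$chrom, c("1", "2", "X")), records$pos)
  records <- records[ord, , drop = FALSE]
  qm <- cfg$quality_model
  fmt_af <- function(af) ifelse(af > 0, sprintf("%.6g", af), "")
  csq <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    allele <- if (nchar(r$ref) > nchar(r$alt)) "-" else r$alt
    sift <- if (r$consequence_class == "missense") "deleterious(0.01)" else ""
    poly <- if (r$consequence_class == "missense")
      "probably_damaging(0.95)" else ""
    canon <- paste(allele, r$so_term, r$gene_symbol,
                   sprintf("ENST%08d", r$pos), "YES", sift, poly,
                   sprintf("%.1f", r$cadd_phred), fmt_af(r$af), "",
                   fmt_af(r$af), sep = "|")
    ## a second, non-canonical transcript with a milder consequence
    alt_tx <- paste(allele, "splice_region_variant", r$gene_symbol,
                    sprintf("ENST%08d", r$pos + 1L), "", "", "",
                    sprintf("%.1f", r$cadd_phred), fmt_af(r$af), "",
                    fmt_af(r$af), sep = "|")
    paste(canon, alt_tx, sep = ",")
  }, character(1))

  gt_field <- function(r, s) {
    if (r$sample_id != s) {
      dp <- qm$dp
      return(sprintf("0/0:%d:%d:%d,0", qm$gq, dp, dp))
    }
    dp <- qm$dp
    gq <- qm$gq
    ad_alt <- switch(r$zygosity,
                     het = as.integer(round(dp / 2)),
                     hom_alt = dp, hemi = dp, 0L)
    if (isTRUE(r$low_quality)) {
      ## rotate the deliberate failure mode by position for variety
      mode <- r$pos %% 3L
      if (mode == 0L) gq <- 5L
      else if (mode == 1L) dp <- 2L
      else ad_alt <- as.integer(ceiling(dp * 0.1))
      if (mode == 1L) ad_alt <- 1L
    }
    gt <- switch(r$zygosity, het = "0/1", hom_alt = "1/1", hemi = "1",
                 "0/0")
    sprintf("%s:%d:%d:%d,%d", gt, gq, dp, max(dp - ad_alt, 0L), ad_alt)
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=50000000>",
    "##contig=<ID=2,length=50000000>",
    "##contig=<ID=X,length=50000000>",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
           "Consequence annotations from Ensembl VEP. Format: ",
           paste(.CSQ_FIELDS, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    geno <- vapply(samples, function(s) gt_field(r, s), character(1))
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, "100", "PASS",
            sprintf("MQ=60;CSQ=%s", csq[i]), "GT:GQ:DP:AD", geno),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Build a findings/truth pair with a prescribed confusion matrix
#'
#' A minimal synthetic predicted-variant set and truth set whose
#' [score_findings()] output has exactly `tp = recovered`,
#' `fn = truth_size - recovered` and `tp + fp = surviving`. Useful for
#' validating the accuracy formulas against published counts.
#'
#' @param truth_size number of truth variants.
#' @param recovered number of truth variants present among predictions.
#' @param surviving total number of predicted variants.
#' @return List: `findings` (predicted-variant data frame), `truth`.
#' @export
generate_worked_confusion <- function(truth_size, recovered, surviving) {
  if (!(recovered <= truth_size && recovered <= surviving)) {
    stop("need recovered <= truth_size and recovered <= surviving",
         call. = FALSE)
  }
  mk <- function(pos) {
    data.frame(sample_id = "S1", chrom = "1", pos = pos, ref = "A",
               alt = "T",
               gene_symbol = sprintf("GENE%05d", pos),
               stringsAsFactors = FALSE)
  }
  truth <- mk(seq_len(truth_size))
  predicted <- mk(c(seq_len(recovered),
                    truth_size + seq_len(surviving - recovered)))
  list(findings = predicted, truth = truth)
}
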