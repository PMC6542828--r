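# Shared in-code fixtures: a small hand-written panel, CSQ strings and a
# cached synthetic cohort reused across test files.

fixture_panel_df <- function() {
  data.frame(
    gene_symbol = c("AAA1", "BBB2", "CCC3", "DDD4", "EEE5"),
    disease_name = paste("DISORDER", 1:5),
    confidence = c("confirmed", "confirmed", "confirmed", "probable",
                   "possible"),
    allelic_requirement = c("monoallelic", "biallelic", "hemizygous",
                            "monoallelic", "biallelic"),
    mutation_consequence = c("loss_of_function", "loss_of_function",
                             "all_missense_in_frame", "activating",
                             "loss_of_function"),
    hpo_terms = c("HP:0000001;HP:0000002", "", "HP:0000003", "", ""),
    pmids = c("123;456", "789", "", "", ""),
    stringsAsFactors = FALSE
  )
}

fixture_panel <- function() g2p_panel(fixture_panel_df(), name = "fixture")

fixture_csq_header <- function() {
  paste0("Consequence annotations from Ensembl VEP. Format: ",
         "Allele|Consequence|SYMBOL|Feature|CANONICAL|SIFT|PolyPhen|",
         "CADD_PHRED|gnomAD_AF|TOPMed_AF|UK10K_AF")
}

make_csq_block <- function(allele = "T", consequence = "missense_variant",
                           symbol = "AAA1", feature = "ENST00000001",
                           canonical = "YES", sift = "", polyphen = "",
                           cadd = "", gnomad = "", topmed = "", uk10k = "") {
  paste(allele, consequence, symbol, feature, canonical, sift, polyphen,
        cadd, gnomad, topmed, uk10k, sep = "|")
}

make_tc <- function(gene_symbol = "AAA1", so_terms = "missense_variant",
                    is_canonical = TRUE, gnomAD_AF = NA_real_,
                    sift_prediction = NA_character_,
                    polyphen_prediction = NA_character_,
                    cadd_phred = NA_real_) {
  list(gene_symbol = gene_symbol, transcript_id = "ENST00000001",
       so_terms = so_terms, is_canonical = is_canonical,
       sift_prediction = sift_prediction,
       polyphen_prediction = polyphen_prediction,
       cadd_phred = cadd_phred, gnomAD_AF = gnomAD_AF)
}

make_lgmdet <- function(gene_symbol = "AAA1",
                        allelic_requirement = "monoallelic",
                        mutation_consequence = "loss_of_function",
                        confidence = "confirmed") {
  list(gene_symbol = gene_symbol, disease_name = "DISORDER",
       confidence = confidence, allelic_requirement = allelic_requirement,
       mutation_consequence = mutation_consequence)
}

# one seeded cohort, generated once per test run and reused
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 42L)
      cache <<- generate_cohort(cfg, dir = file.path(tempdir(), "sim_main"))
    }
    cache
  }
})
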