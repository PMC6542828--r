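## Reading of annotated multi-sample VCFs (via vcfR) into the flat
## structures the filtering engine works on. Input VCFs are expected to be
## decomposed and normalised upstream: exactly one alternate allele per
## record.

#' Read a VEP-annotated multi-sample VCF
#'
#' Loads the record table, the CSQ annotation strings with their
#' header-declared subfield order, and the genotype quality fields
#' (GT/GQ/DP/AD from FORMAT, MQ from INFO or FORMAT).
#'
#' @param path VCF path (plain or bgzipped).
#' @param csq_key INFO key holding the VEP annotations, default `"CSQ"`.
#' @return A list of class `g2p_vcf`: `fix` (data frame chrom/pos/ref/alt),
#'   `samples`, `csq` (one string per record), `csq_description` (the header
#'   Format declaration), genotype matrices `gt`, `gq`, `dp`, `ad_alt`, `mq`
#'   (records x samples; `mq` recycled from INFO when not a FORMAT field),
#'   and `zygosity` (pre-QC zygosity codes).
#' @export
read_annotated_vcf <- function(path, csq_key = "CSQ") {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  fixdf <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  multi <- grepl(",", fixdf$alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf(
      "record %s:%d carries multiple alternate alleles; decompose and normalize the VCF first",
      fixdf$chrom[i], fixdf$pos[i]), call. = FALSE)
  }
  meta <- vcf@meta
  csq_line <- grep(sprintf("^##INFO=<ID=%s[,>]", csq_key), meta, value = TRUE)
  if (length(csq_line) == 0L) {
    stop(sprintf("VCF header has no INFO line for the %s annotation key",
                 csq_key), call. = FALSE)
  }
  desc <- sub(sprintf('^.*Description="'), "", csq_line[1L])
  desc <- sub('".*$', "", desc)
  csq <- vcfR::extract.info(vcf, element = csq_key)
  samples <- colnames(vcf@gt)[-1L]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  num_mat <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) {
      m <- matrix(NA_real_, nrow = n, ncol = length(samples))
    }
    m
  }
  gq <- num_mat("GQ")
  dp <- num_mat("DP")
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  ad_alt <- if (is.null(ad)) {
    matrix(NA_real_, nrow = n, ncol = length(samples))
  } else {
    matrix(vapply(strsplit(as.vector(ad), ",", fixed = TRUE), function(p) {
      if (length(p) >= 2L) suppressWarnings(as.numeric(p[2L])) else NA_real_
    }, numeric(1)), nrow = n)
  }
  mq_fmt <- tryCatch(vcfR::extract.gt(vcf, element = "MQ",
                                      as.numeric = TRUE),
                     error = function(e) NULL)
  if (!is.null(mq_fmt) && any(!is.na(mq_fmt))) {
    mq <- mq_fmt
  } else {
    mq_info <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "MQ")))
    mq <- matrix(rep(mq_info, times = length(samples)), nrow = n)
  }
  zyg <- gt_zygosity_matrix(gt, fixdf)
  structure(list(fix = fixdf, samples = samples, csq = as.character(csq),
                 csq_description = desc, gt = gt, gq = gq, dp = dp,
                 ad_alt = ad_alt, mq = mq, zygosity = zyg),
            class = "g2p_vcf")
}

#' Zygosity code of a genotype string
#'
#' Maps a VCF GT value (after upstream decomposition, so allele indices are
#' 0/1 only) onto one of `hom_ref`, `het`, `hom_alt`, `hemi` (haploid
#' alternate), `no_call`. A genotype containing an allele index above 1 means
#' the record was not decomposed and raises an error.
#'
#' @param gt character vector of GT strings (`"0/1"`, `"1|1"`, `"1"`, ...).
#' @return Character vector of zygosity codes.
#' @export
gt_zygosity <- function(gt) {
  lut <- vapply(unique(gt), .one_zygosity, character(1))
  unname(lut[gt])
}

.one_zygosity <- function(g) {
  if (is.na(g) || g == "" || g == ".") return("no_call")
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(!alleles %in% c("0", "1", "."))) {
    stop(sprintf(
      "genotype '%s' references an allele index above 1; decompose the VCF first",
      g), call. = FALSE)
  }
  if (any(alleles == ".")) return("no_call")
  if (length(alleles) == 1L) {
    return(if (alleles == "1") "hemi" else "hom_ref")
  }
  n_alt <- sum(alleles == "1")
  if (n_alt == 0L) "hom_ref" else if (n_alt == length(alleles)) "hom_alt"
  else "het"
}

gt_zygosity_matrix <- function(gt, fixdf) {
  zy <- tryCatch(gt_zygosity(as.vector(gt)), error = function(e) e)
  if (inherits(zy, "error")) {
    ## relocate the error with record coordinates
    per_rec <- apply(gt, 1L, function(row)
      tryCatch({ gt_zygosity(row); NA_character_ },
               error = function(e) conditionMessage(e)))
    i <- which(!is.na(per_rec))[1L]
    stop(sprintf("record %s:%d: %s", fixdf$chrom[i], fixdf$pos[i],
                 per_rec[i]), call. = FALSE)
  }
  matrix(zy, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a PED-style sample sex table
#'
#' Standard 6-column PED: family, individual, father, mother, sex (1 = male,
#' 2 = female, other = unknown), phenotype. Only individual id and sex are
#' used.
#'
#' @param path PED path.
#' @return Data frame `sample_id`, `sex` in `{male, female, unknown}`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path, call. = FALSE)
  ped <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(ped) < 5L) {
    ped <- utils::read.table(path, header = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  }
  if (ncol(ped) < 5L) stop("PED file needs at least 5 columns", call. = FALSE)
  sex <- c("1" = "male", "2" = "female")[ped[[5L]]]
  sex[is.na(sex)] <- "unknown"
  data.frame(sample_id = ped[[2L]], sex = unname(sex),
             stringsAsFactors = FALSE)
}
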