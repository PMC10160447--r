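# VCF input/output for the four-sample BSA design (two parents, two bulks).

#' Default sample names of a BSA VCF
#'
#' @param parent_green,parent_yellow,bulk_green,bulk_yellow Sample names.
#' @return Named character vector.
#' @export
bsa_samples <- function(parent_green = "parentG", parent_yellow = "parentY",
                        bulk_green = "G_pool", bulk_yellow = "Y_pool") {
  c(parent_green = parent_green, parent_yellow = parent_yellow,
    bulk_green = bulk_green, bulk_yellow = bulk_yellow)
}

#' Write simulated variant sites as a VCF
#'
#' Emits a minimal VCF 4.2 with GT:AD:DP fields for the two parents and two
#' bulks. The output is deterministic (no timestamps), so identical inputs
#' give byte-identical files.
#'
#' @param sites A `variant_sites` data frame (see [simulate_read_counts()]).
#' @param path Output file path.
#' @param samples Sample naming, see [bsa_samples()].
#' @return `path`, invisibly.
#' @export
write_bsa_vcf <- function(sites, path, samples = bsa_samples()) {
  stopifnot(is.data.frame(sites))
  gt_pool <- function(ref, alt) ifelse(alt == 0L & ref > 0L, "0/0",
                                ifelse(ref == 0L & alt > 0L, "1/1", "0/1"))
  fmt <- function(gt, ref, alt) sprintf("%s:%d,%d:%d", gt, ref, alt, ref + alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(samples)), collapse = "\t"))
  body <- if (nrow(sites)) {
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS", ".",
          "GT:AD:DP",
          fmt(sites$parentG_gt, sites$parentG_ref, sites$parentG_alt),
          fmt(sites$parentY_gt, sites$parentY_ref, sites$parentY_alt),
          fmt(gt_pool(sites$G_pool_ref, sites$G_pool_alt),
              sites$G_pool_ref, sites$G_pool_alt),
          fmt(gt_pool(sites$Y_pool_ref, sites$Y_pool_alt),
              sites$Y_pool_ref, sites$Y_pool_alt),
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read biallelic variant sites with allele depths from a VCF
#'
#' Parses a VCF holding the two parents and the two bulks, keeping one record
#' per biallelic row; multiallelic rows are skipped with a message giving the
#' count. Allele depths come from the per-sample AD field.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param samples Sample naming, see [bsa_samples()]. All four must be present.
#' @return A `variant_sites` data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `type` (`"SNP"`/`"InDel"`), parent GT strings and per-sample
#'   ref/alt depths.
#' @export
read_variants <- function(path, samples = bsa_samples()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)
  miss <- setdiff(unname(samples), have)
  if (length(miss))
    stop("sample(s) missing from VCF: ", paste(miss, collapse = ", "))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0),
                      parentG_gt = character(0), parentY_gt = character(0),
                      parentG_ref = integer(0), parentG_alt = integer(0),
                      parentY_ref = integer(0), parentY_alt = integer(0),
                      G_pool_ref = integer(0), G_pool_alt = integer(0),
                      Y_pool_ref = integer(0), Y_pool_alt = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("variant_sites", "data.frame")
  if (nrow(v@fix) == 0L) return(empty)
  if (!any(grepl("(^|:)AD(:|$)", v@gt[, "FORMAT"])))
    stop("allele-depth field (AD) missing from VCF FORMAT")
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic site(s) skipped")
  keep <- which(!multi & !is.na(alt))
  if (!length(keep)) return(empty)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_field <- function(sample, record) {
    x <- strsplit(ad[keep, sample], ",", fixed = TRUE)
    vapply(x, function(p) {
      if (length(p) < record || is.na(p[record])) NA_integer_
      else suppressWarnings(as.integer(p[record]))
    }, integer(1))
  }
  ref <- v@fix[keep, "REF"]
  alt <- alt[keep]
  out <- data.frame(
    chrom = v@fix[keep, "CHROM"], pos = as.integer(v@fix[keep, "POS"]),
    ref = ref, alt = alt,
    type = ifelse(nchar(ref) != nchar(alt), "InDel", "SNP"),
    parentG_gt = unname(gt[keep, samples[["parent_green"]]]),
    parentY_gt = unname(gt[keep, samples[["parent_yellow"]]]),
    parentG_ref = ad_field(samples[["parent_green"]], 1L),
    parentG_alt = ad_field(samples[["parent_green"]], 2L),
    parentY_ref = ad_field(samples[["parent_yellow"]], 1L),
    parentY_alt = ad_field(samples[["parent_yellow"]], 2L),
    G_pool_ref = ad_field(samples[["bulk_green"]], 1L),
    G_pool_alt = ad_field(samples[["bulk_green"]], 2L),
    Y_pool_ref = ad_field(samples[["bulk_yellow"]], 1L),
    Y_pool_alt = ad_field(samples[["bulk_yellow"]], 2L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Site filtering configuration
#'
#' @param min_depth Minimum total depth per bulk (default 8). Applies to the
#'   bulks only; parents are judged on their genotype call.
#' @param snp_only Drop InDels, keeping SNPs (default `FALSE`; the index
#'   statistic treats both identically).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 8, snp_only = FALSE) {
  stopifnot(min_depth >= 1)
  structure(list(min_depth = min_depth, snp_only = snp_only),
            class = "filter_config")
}

#' Retain parent-informative sites
#'
#' Keeps sites where the two parents are homozygous for opposite alleles
#' (heterozygous or missing parent calls disqualify the site: the inbred
#' parents should be fixed), both bulks reach `min_depth` and no sample's
#' depth is missing. Input order is preserved; the filter is idempotent.
#'
#' @param sites A `variant_sites` data frame from [read_variants()].
#' @param cfg A [filter_config()].
#' @return The qualifying subset (possibly empty).
#' @export
filter_informative <- function(sites, cfg = filter_config()) {
  stopifnot(is.data.frame(sites))
  if (!inherits(cfg, "filter_config")) stop("cfg must be a filter_config")
  if (nrow(sites) == 0L) return(sites)
  hom_ref <- function(gt) !is.na(gt) & gt %in% c("0/0", "0|0")
  hom_alt <- function(gt) !is.na(gt) & gt %in% c("1/1", "1|1")
  informative <- (hom_ref(sites$parentG_gt) & hom_alt(sites$parentY_gt)) |
    (hom_alt(sites$parentG_gt) & hom_ref(sites$parentY_gt))
  depth_cols <- c("parentG_ref", "parentG_alt", "parentY_ref", "parentY_alt",
                  "G_pool_ref", "G_pool_alt", "Y_pool_ref", "Y_pool_alt")
  no_missing <- !Reduce(`|`, lapply(sites[depth_cols], is.na))
  dp_G <- sites$G_pool_ref + sites$G_pool_alt
  dp_Y <- sites$Y_pool_ref + sites$Y_pool_alt
  deep <- !is.na(dp_G) & !is.na(dp_Y) &
    dp_G >= cfg$min_depth & dp_Y >= cfg$min_depth
  keep <- informative & no_missing & deep
  if (cfg$snp_only) keep <- keep & sites$type == "SNP"
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
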