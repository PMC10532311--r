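# Site-level and genotype-level VCF quality control.

#' QC configuration
#'
#' Thresholds for the two QC layers. Sites are removed when multi-allelic
#' (more than `max_total_alleles` alleles counting REF and all ALTs), not
#' `PASS`, or with QUAL below `min_site_quality`; individual genotypes are
#' masked to missing when read depth or genotype quality fall below their
#' minima. All comparisons are strict (`< threshold` fails; a value exactly
#' at the threshold is kept).
#'
#' @param min_site_quality Minimum site QUAL (default 30).
#' @param require_pass Require `FILTER == "PASS"` (default `TRUE`).
#' @param max_total_alleles Maximum REF+ALT allele count (default 2, i.e.
#'   bi-allelic only).
#' @param min_depth Minimum per-genotype read depth (default 10).
#' @param min_genotype_quality Minimum per-genotype GQ (default 20).
#' @param genotype_rule `"or"` (default) masks a genotype when *either*
#'   depth or GQ fails; `"and"` preserves the literal conjunction reading
#'   and masks only when both fail.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_site_quality = 30, require_pass = TRUE,
                      max_total_alleles = 2L, min_depth = 10L,
                      min_genotype_quality = 20L,
                      genotype_rule = c("or", "and")) {
  genotype_rule <- match.arg(genotype_rule)
  stopifnot(min_site_quality >= 0, max_total_alleles >= 0,
            min_depth >= 0, min_genotype_quality >= 0)
  structure(list(min_site_quality = min_site_quality,
                 require_pass = isTRUE(require_pass),
                 max_total_alleles = as.integer(max_total_alleles),
                 min_depth = as.integer(min_depth),
                 min_genotype_quality = as.integer(min_genotype_quality),
                 genotype_rule = genotype_rule),
            class = "qc_config")
}

#' Site-level QC verdicts
#'
#' Evaluates each site against the site rules, with one drop reason per
#' failing site. Reasons are assigned in a fixed priority order:
#' `multiallelic`, then `non-pass`, then `low-qual`. A missing QUAL fails
#' as `low-qual` (quality cannot be certified).
#'
#' @param x A `famseg_variants` object.
#' @param cfg A [qc_config()].
#' @return Data frame with columns `key`, `pass` (logical), `reason`
#'   (`NA` for passing sites).
#' @export
site_qc <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "famseg_variants"), inherits(cfg, "qc_config"))
  s <- x$sites
  n_alleles <- 1L + vapply(strsplit(s$alt, ",", fixed = TRUE), length,
                           integer(1))
  reason <- rep(NA_character_, nrow(s))
  reason[is.na(reason) & n_alleles > cfg$max_total_alleles] <- "multiallelic"
  if (cfg$require_pass) {
    reason[is.na(reason) & s$filter != "PASS"] <- "non-pass"
  }
  reason[is.na(reason) & (is.na(s$qual) | s$qual < cfg$min_site_quality)] <-
    "low-qual"
  data.frame(key = variant_keys(x), pass = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Mask low-confidence genotypes
#'
#' Sets individual genotype calls to missing (`"./."`) when their read
#' depth or genotype quality cannot be certified: under the default `"or"`
#' rule a call is masked when depth `< min_depth` *or* GQ
#' `< min_genotype_quality`; under `"and"` only when both fail. A missing
#' DP or GQ value (including a wholly absent matrix) counts as failing
#' that criterion. Alleles, positions, and sample identity are never
#' edited. The operation is idempotent.
#'
#' @param x A `famseg_variants` object.
#' @param cfg A [qc_config()].
#' @return A list: `variants` (the masked `famseg_variants`) and
#'   `mask_reasons` (counts of masked genotypes by reason, `low-depth`
#'   taking priority over `low-gq` when both fail).
#' @export
mask_genotypes <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "famseg_variants"), inherits(cfg, "qc_config"))
  dim_gt <- dim(x$gt)
  fail_dp <- if (is.null(x$dp)) matrix(TRUE, dim_gt[1], dim_gt[2]) else
    (is.na(x$dp) | x$dp < cfg$min_depth)
  fail_gq <- if (is.null(x$gq)) matrix(TRUE, dim_gt[1], dim_gt[2]) else
    (is.na(x$gq) | x$gq < cfg$min_genotype_quality)
  mask <- if (cfg$genotype_rule == "or") fail_dp | fail_gq else
    fail_dp & fail_gq
  already <- genotype_class(x$gt) == "missing"
  newly <- mask & !already
  gt <- x$gt
  gt[mask] <- "./."
  reasons <- c(
    "low-depth" = sum(newly & fail_dp),
    "low-gq"    = sum(newly & !fail_dp & fail_gq)
  )
  list(variants = variant_set(x$sites, gt, x$dp, x$gq),
       mask_reasons = reasons)
}

#' Per-site call rate
#'
#' Fraction of the listed subjects whose (post-masking) genotype is not
#' missing at each site.
#'
#' @param x A `famseg_variants` object.
#' @param subject_ids Subjects over which to compute the rate; must all be
#'   present in `x` and non-empty.
#' @return Numeric vector in `[0, 1]`, one value per site.
#' @export
call_rate <- function(x, subject_ids) {
  stopifnot(inherits(x, "famseg_variants"))
  if (length(subject_ids) == 0L) stop("subject_ids must be non-empty")
  missing_ids <- setdiff(subject_ids, variant_samples(x))
  if (length(missing_ids) > 0L) {
    stop("subjects not in variant set: ", paste(missing_ids, collapse = ", "))
  }
  cls <- genotype_class(x$gt[, subject_ids, drop = FALSE])
  rowMeans(cls != "missing")
}

#' Apply full QC to a variant set
#'
#' Removes failing sites (logging one reason each) and masks failing
#' genotypes. QC never edits alleles, positions or sample identity, and
#' applying it twice yields the same call-set as once.
#'
#' @param x A `famseg_variants` object.
#' @param cfg A [qc_config()].
#' @return A list: `variants` (filtered and masked set), `site_log`
#'   (data frame `chrom`, `pos`, `ref`, `alt`, `reason` for removed
#'   sites), `mask_reasons` (named counts of masked genotypes).
#' @export
apply_qc <- function(x, cfg = qc_config()) {
  verdict <- site_qc(x, cfg)
  dropped <- x$sites[!verdict$pass, c("chrom", "pos", "ref", "alt")]
  dropped$reason <- verdict$reason[!verdict$pass]
  kept <- subset_sites(x, verdict$pass)
  masked <- mask_genotypes(kept, cfg)
  list(variants = masked$variants, site_log = dropped,
       mask_reasons = masked$mask_reasons)
}
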