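# Multi-sample variant container and VCF input/output.
#
# A famseg_variants object holds the fields the QC and segregation stages
# need: the fixed site columns plus per-sample GT/DP/GQ matrices. Alt
# alleles are kept as the comma-joined VCF string; multi-allelic sites are
# removed (not split) by QC.

#' Construct a variant set
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt` (comma-joined for multi-allelic sites), `qual`
#'   (numeric, `NA` allowed) and `filter`.
#' @param gt Character matrix (variants x samples) of GT strings
#'   (`"0/1"`, `"0|1"`, `"./."`, ...); column names are sample ids.
#' @param dp,gq Optional numeric matrices of read depth and genotype
#'   quality with the same shape as `gt`; `NULL` means the field is absent
#'   (treated as uncertifiable by genotype QC).
#' @return An object of class `famseg_variants`.
#' @export
variant_set <- function(sites, gt, dp = NULL, gq = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "id", "ref", "alt", "qual", "filter")
                %in% names(sites)),
            is.matrix(gt), nrow(gt) == nrow(sites),
            !is.null(colnames(gt)))
  if (anyDuplicated(colnames(gt))) stop("duplicate sample ids")
  if (any(sites$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  for (m in list(dp, gq)) {
    if (!is.null(m)) stopifnot(identical(dim(m), dim(gt)))
  }
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq),
            class = "famseg_variants")
}

#' @export
print.famseg_variants <- function(x, ...) {
  cat(sprintf("famseg_variants: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$gt)))
  cat("  samples:", paste(colnames(x$gt), collapse = ", "), "\n")
  invisible(x)
}

#' Variant keys
#'
#' Canonical `chrom:pos:ref:alt` key for each site; the same position with
#' different alleles is distinct.
#'
#' @param x A `famseg_variants` object or a `sites`-shaped data frame.
#' @return Character vector of keys.
#' @export
variant_keys <- function(x) {
  s <- if (inherits(x, "famseg_variants")) x$sites else x
  paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
}

#' Sample ids of a variant set
#' @param x A `famseg_variants` object.
#' @return Character vector.
#' @export
variant_samples <- function(x) colnames(x$gt)

#' Subset a variant set by site
#' @param x A `famseg_variants` object.
#' @param i Row index (logical or integer).
#' @return A `famseg_variants` with the selected sites.
#' @export
subset_sites <- function(x, i) {
  variant_set(x$sites[i, , drop = FALSE],
              x$gt[i, , drop = FALSE],
              if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
              if (!is.null(x$gq)) x$gq[i, , drop = FALSE])
}

#' Classify diploid genotype strings
#'
#' Collapses phased and unphased separators and maps each GT string to one
#' of `hom_ref`, `het`, `hom_alt`, `missing`. Half-calls (one missing
#' allele) are `missing`; genotypes with both alleles non-reference
#' (including mixed alt/alt calls at multi-allelic sites) are `hom_alt`.
#'
#' @param gt Character vector or matrix of GT strings.
#' @return Same shape as `gt`, values in
#'   `c("hom_ref","het","hom_alt","missing")`.
#' @export
genotype_class <- function(gt) {
  cls <- function(g) {
    if (is.na(g) || g == "." || !nzchar(g)) return("missing")
    alleles <- strsplit(g, "[/|]", perl = TRUE)[[1L]]
    if (length(alleles) != 2L || any(alleles == ".") || any(!nzchar(alleles))) {
      return("missing")
    }
    n_ref <- sum(alleles == "0")
    if (n_ref == 2L) "hom_ref" else if (n_ref == 1L) "het" else "hom_alt"
  }
  out <- vapply(as.vector(gt), cls, character(1), USE.NAMES = FALSE)
  if (is.matrix(gt)) {
    out <- matrix(out, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  } else {
    names(out) <- names(gt)
  }
  out
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF 4.x file via \pkg{vcfR} and extracts the fields the QC and
#' segregation stages use: CHROM/POS/ID/REF/ALT/QUAL/FILTER plus per-sample
#' GT (required), DP and GQ. Coordinates are 1-based, contig names are used
#' verbatim, and multi-allelic ALT strings are kept joined.
#'
#' @param path Path to a `.vcf` (or `.vcf.gz`) file.
#' @return A `famseg_variants` object.
#' @export
read_family_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", as.character(fix[, "ID"])),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", as.character(fix[, "FILTER"])),
    stringsAsFactors = FALSE
  )
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF FORMAT must include GT")
  gt <- vcfR::extract.gt(v, element = "GT")
  has <- function(el) any(grepl(paste0("(^|:)", el, "(:|$)"), fmt))
  dp <- if (has("DP")) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- if (has("GQ")) vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  strip <- function(m) {
    if (is.null(m)) return(NULL)
    dimnames(m) <- list(NULL, colnames(m))
    m
  }
  variant_set(sites, strip(gt), strip(dp), strip(gq))
}

#' Write a variant set as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with FORMAT `GT:DP:GQ` (DP/GQ as `.` when the
#' matrices are absent). Output is deterministic: the same object always
#' produces byte-identical text.
#'
#' @param x A `famseg_variants` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_family_vcf <- function(x, path) {
  stopifnot(inherits(x, "famseg_variants"))
  s <- x$sites
  contigs <- unique(s$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg",
    sprintf("##contig=<ID=%s>", contigs),
    "##FILTER=<ID=q10,Description=\"Low site quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$gt)), collapse = "\t")
  )
  fmt_num <- function(m, i, j) {
    if (is.null(m) || is.na(m[i, j])) "." else format(m[i, j], scientific = FALSE)
  }
  body <- vapply(seq_len(nrow(s)), function(i) {
    calls <- vapply(seq_len(ncol(x$gt)), function(j) {
      paste(ifelse(is.na(x$gt[i, j]), "./.", x$gt[i, j]),
            fmt_num(x$dp, i, j), fmt_num(x$gq, i, j), sep = ":")
    }, character(1))
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i],
            if (is.na(s$qual[i])) "." else sprintf("%.2f", s$qual[i]),
            s$filter[i], ".", "GT:DP:GQ", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
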