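# Shared fixtures and an exhaustive per-sample oracle for the dominant
# co-segregation filter.

fam_phenotypes <- read_phenotypes(famseg_fixture("phenotypes"))
fam_annotations <- read_annotations(famseg_fixture("annotations"))
fam_designs <- family_designs(fam_phenotypes)

# Build a one-row-per-variant set from explicit per-sample genotype
# strings; DP/GQ default to clean values.
toy_variants <- function(gt_rows, chrom = "5", pos = NULL, ref = "A",
                         alt = "G", qual = 100, filter = "PASS",
                         dp = 50, gq = 90) {
  gt <- do.call(rbind, gt_rows)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      id = ".", ref = rep_len(ref, n),
                      alt = rep_len(alt, n), qual = rep_len(qual, n),
                      filter = rep_len(filter, n), stringsAsFactors = FALSE)
  mk <- function(v) matrix(rep_len(v, n * ncol(gt)), n, ncol(gt),
                           dimnames = list(NULL, colnames(gt)))
  variant_set(sites, gt, mk(dp), mk(gq))
}

# Genotype vector helpers over the 12 WES members.
wes_samples <- sort(design_members(fam_designs$FVIII))

gt_pattern <- function(design, samples = wes_samples) {
  g <- setNames(rep("0/0", length(samples)), samples)
  g[design$cases] <- "0/1"
  g
}

# Literal, sample-by-sample oracle for the dominant filter: walks each
# member one at a time and applies the stated rule directly.
oracle_reason <- function(gts, design) {
  for (s in c(design$cases, design$controls)) {
    if (genotype_class(gts[[s]]) == "missing") return("incomplete-call-rate")
  }
  for (s in design$cases) {
    if (genotype_class(gts[[s]]) != "het") return("case-not-het")
  }
  for (s in design$controls) {
    if (genotype_class(gts[[s]]) != "hom_ref") return("control-not-homref")
  }
  "survivor"
}
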