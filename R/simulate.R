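# Seeded simulator for every pipeline input: a 12-member family VCF with
# planted co-segregating variants among single-rule decoys, genotype-linked
# expression cohorts, and family-scale qPCR Ct tables. The family's raw WES
# data are not publicly deposited, so these generators stand in for them at
# desk scale; fixtures produced here are synthetic.

.DECOY_CLASSES <- c("het_in_control", "het_in_subset_of_cases",
                    "missing_genotype", "low_depth", "low_gq",
                    "non_pass", "multiallelic", "low_qual")

#' Default planted variants
#'
#' The candidate variants of the bundled annotation fixture, tagged with
#' the analysis approach whose genotype pattern they realize (`FVIII` for
#' approach A rows, `VWF` for approach B rows).
#'
#' @return Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `design` (`"FVIII"`, `"VWF"`, or `"both"`).
#' @export
default_planted_variants <- function() {
  ann <- read_annotations(famseg_fixture("annotations"))
  data.frame(chrom = ann$chrom, pos = ann$pos,
             id = ifelse(is.na(ann$dbsnp_id), ".", ann$dbsnp_id),
             ref = ann$ref, alt = ann$alt,
             design = ifelse(ann$approach == "A", "FVIII", "VWF"),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed Integer seed fixing all randomness end to end.
#' @param n_decoys Number of decoy variants, each engineered to violate
#'   exactly one QC or segregation rule.
#' @param decoy_mix Named proportions over the decoy classes
#'   `het_in_control`, `het_in_subset_of_cases`, `missing_genotype`,
#'   `low_depth`, `low_gq`, `non_pass`, `multiallelic`, `low_qual`; must
#'   sum to 1.
#' @param planted Data frame of variants to plant (columns `chrom`, `pos`,
#'   `id`, `ref`, `alt`, `design` in `FVIII`/`VWF`/`both`); defaults to
#'   [default_planted_variants()].
#' @param chrom Contig for decoys (default `"5"`, the region the planted
#'   candidates occupy, so span statistics stay exercised).
#' @param region Two-element window of decoy positions (default
#'   148.5-157.5 Mb).
#' @param expression List of cohort-generator settings: `n_hom`, `n_het`
#'   (defaults 386 and 35, the post-exclusion group sizes of the cohort
#'   replication stage), `effect_delta` (downward shift in normalized
#'   units applied to het carriers), `noise_sd`, `raw_count_mean`.
#' @param qpcr List of family qPCR generator settings: `shift_ct` (Ct
#'   increase in het carriers; +0.5 cycles is a "slight" reduction, RQ
#'   ratio about 0.71), `sd_subject`, `sd_rep`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_decoys = 500L,
                       decoy_mix = c(het_in_control = 0.25,
                                     het_in_subset_of_cases = 0.25,
                                     missing_genotype = 0.10,
                                     low_depth = 0.10, low_gq = 0.10,
                                     non_pass = 0.08, multiallelic = 0.06,
                                     low_qual = 0.06),
                       planted = default_planted_variants(),
                       chrom = "5",
                       region = c(148500000L, 157500000L),
                       expression = list(n_hom = 386L, n_het = 35L,
                                         effect_delta = 0, noise_sd = 1,
                                         raw_count_mean = 100),
                       qpcr = list(shift_ct = 0.5, sd_subject = 0.3,
                                   sd_rep = 0.15)) {
  stopifnot(n_decoys >= 0L, length(region) == 2L, region[1L] < region[2L])
  if (!setequal(names(decoy_mix), .DECOY_CLASSES)) {
    stop("decoy_mix must name exactly the classes: ",
         paste(.DECOY_CLASSES, collapse = ", "))
  }
  if (abs(sum(decoy_mix) - 1) > 1e-8) stop("decoy_mix must sum to 1")
  if (!is.null(planted)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt", "design") %in%
                    names(planted)),
              all(planted$design %in% c("FVIII", "VWF", "both")))
    if (!"id" %in% names(planted)) planted$id <- "."
  }
  structure(list(seed = as.integer(seed), n_decoys = as.integer(n_decoys),
                 decoy_mix = decoy_mix[.DECOY_CLASSES], planted = planted,
                 chrom = chrom, region = as.integer(region),
                 expression = expression, qpcr = qpcr),
            class = "sim_config")
}

# Genotype pattern (GT strings over all WES samples) realizing the dominant
# co-segregation rule for one design: het in every case, hom-ref elsewhere.
.pattern_gts <- function(design, samples) {
  gt <- stats::setNames(rep("0/0", length(samples)), samples)
  gt[design$cases] <- "0/1"
  gt
}

# Would this genotype vector survive the dominant filter under a design?
# (Generator-internal predicate used to guarantee decoys fail both designs.)
.pattern_survives <- function(gts, design) {
  cls <- genotype_class(gts[design_members(design)])
  !any(cls == "missing") &&
    all(cls[design$cases] == "het") &&
    all(cls[design$controls] == "hom_ref")
}

#' Simulate the 12-member family VCF
#'
#' Planted variants are heterozygous in all cases and reference-homozygous
#' in all controls of their designated design, with depth >= 10, GQ >= 20,
#' `PASS` and QUAL >= 30; variants designated `"both"` carry the pattern of
#' the VWF design (the sample that switches sides between designs is set
#' hom-ref, so such variants satisfy the VWF partition and necessarily fail
#' the FVIII one - the two survivor sets are disjoint in this pedigree).
#' Each decoy violates exactly its assigned rule and satisfies all others;
#' pattern decoys are re-drawn (bounded retries) if the perturbation would
#' accidentally realize the other design's survivor pattern. Records are
#' sorted by position and the output is deterministic under the seed.
#'
#' @param cfg A [sim_config()].
#' @param designs Named list of the two designs (default
#'   [family_designs()]).
#' @return List with `variants` (a `famseg_variants`), `truth` (data frame
#'   `key`, `role`, `class`, `perturbed_sample`) and `config`.
#' @examples
#' sim <- simulate_family_vcf(sim_config(seed = 7, n_decoys = 40))
#' table(sim$truth$role)
#' @export
simulate_family_vcf <- function(cfg = sim_config(),
                                designs = family_designs()) {
  stopifnot(inherits(cfg, "sim_config"), length(designs) == 2L,
            all(c("FVIII", "VWF") %in% names(designs)))
  set.seed(cfg$seed)
  samples <- sort(unique(unlist(lapply(designs, design_members))))
  n_samples <- length(samples)
  nt <- c("A", "C", "G", "T")

  planted <- cfg$planted
  n_planted <- if (is.null(planted)) 0L else nrow(planted)

  # decoy class counts and unique positions away from the planted sites
  counts <- if (cfg$n_decoys > 0L) {
    drop(stats::rmultinom(1L, cfg$n_decoys, cfg$decoy_mix))
  } else {
    stats::setNames(integer(length(.DECOY_CLASSES)), .DECOY_CLASSES)
  }
  width <- cfg$region[2L] - cfg$region[1L] + 1L
  pos_pool <- cfg$region[1L] - 1L + sample.int(width, cfg$n_decoys)
  tries <- 0L
  while (any(dup <- pos_pool %in% planted$pos | duplicated(pos_pool))) {
    tries <- tries + 1L
    if (tries > 100L) stop("could not place decoys away from planted sites")
    pos_pool[dup] <- cfg$region[1L] - 1L + sample.int(width, sum(dup))
  }

  n_total <- n_planted + cfg$n_decoys
  gt <- matrix("0/0", n_total, n_samples, dimnames = list(NULL, samples))
  dp <- matrix(10L + stats::rpois(n_total * n_samples, 50), n_total,
               n_samples, dimnames = list(NULL, samples))
  gq <- matrix(sample(60:99, n_total * n_samples, replace = TRUE), n_total,
               n_samples, dimnames = list(NULL, samples))
  sites <- data.frame(chrom = character(n_total), pos = integer(n_total),
                      id = rep(".", n_total), ref = character(n_total),
                      alt = character(n_total),
                      qual = round(stats::runif(n_total, 50, 2000), 2),
                      filter = rep("PASS", n_total), stringsAsFactors = FALSE)
  truth <- data.frame(role = character(n_total), class = character(n_total),
                      perturbed_sample = rep(NA_character_, n_total),
                      stringsAsFactors = FALSE)

  if (n_planted > 0L) {
    idx <- seq_len(n_planted)
    sites$chrom[idx] <- planted$chrom
    sites$pos[idx] <- planted$pos
    sites$id[idx] <- planted$id
    sites$ref[idx] <- planted$ref
    sites$alt[idx] <- planted$alt
    truth$role[idx] <- "planted"
    truth$class[idx] <- planted$design
    for (i in idx) {
      d <- if (planted$design[i] == "FVIII") designs$FVIII else designs$VWF
      gt[i, ] <- .pattern_gts(d, samples)
    }
  }

  classes <- rep(names(counts), counts)
  for (j in seq_along(classes)) {
    i <- n_planted + j
    cl <- classes[[j]]
    base_name <- sample(c("FVIII", "VWF"), 1L)
    base <- designs[[base_name]]
    ref <- sample(nt, 1L)
    alt <- sample(setdiff(nt, ref), 1L)
    sites$chrom[i] <- cfg$chrom
    sites$pos[i] <- pos_pool[[j]]
    sites$ref[i] <- ref
    sites$alt[i] <- alt
    truth$role[i] <- "decoy"
    truth$class[i] <- cl
    row_gt <- .pattern_gts(base, samples)
    if (cl == "het_in_control") {
      for (try in 1:50) {
        s <- sample(base$controls, 1L)
        cand <- row_gt; cand[s] <- "0/1"
        if (!.pattern_survives(cand, designs$FVIII) &&
            !.pattern_survives(cand, designs$VWF)) break
        if (try == 50L) stop("could not construct het_in_control decoy")
      }
      row_gt <- cand
      truth$perturbed_sample[i] <- s
    } else if (cl == "het_in_subset_of_cases") {
      for (try in 1:50) {
        s <- sample(base$cases, 1L)
        cand <- row_gt; cand[s] <- "0/0"
        if (!.pattern_survives(cand, designs$FVIII) &&
            !.pattern_survives(cand, designs$VWF)) break
        if (try == 50L) stop("could not construct het_in_subset decoy")
      }
      row_gt <- cand
      truth$perturbed_sample[i] <- s
    } else if (cl == "missing_genotype") {
      s <- sample(samples, 1L)
      row_gt[s] <- "./."
      truth$perturbed_sample[i] <- s
    } else if (cl == "low_depth") {
      s <- sample(samples, 1L)
      dp[i, s] <- sample(0:9, 1L)
      truth$perturbed_sample[i] <- s
    } else if (cl == "low_gq") {
      s <- sample(samples, 1L)
      gq[i, s] <- sample(0:19, 1L)
      truth$perturbed_sample[i] <- s
    } else if (cl == "non_pass") {
      sites$filter[i] <- "q10"
    } else if (cl == "multiallelic") {
      alt2 <- sample(setdiff(nt, c(ref, alt)), 1L)
      sites$alt[i] <- paste(alt, alt2, sep = ",")
    } else if (cl == "low_qual") {
      sites$qual[i] <- round(stats::runif(1L, 1, 29.9), 2)
    }
    gt[i, ] <- row_gt
  }

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  gt <- gt[ord, , drop = FALSE]
  dp <- dp[ord, , drop = FALSE]
  gq <- gq[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]; rownames(truth) <- NULL
  vs <- variant_set(sites, gt, dp, gq)
  truth <- cbind(data.frame(key = variant_keys(vs),
                            stringsAsFactors = FALSE), truth)
  list(variants = vs, truth = truth, config = cfg)
}

#' Simulate a genotype-linked expression cohort
#'
#' Normalized values for reference-homozygous samples are drawn from a
#' Gaussian baseline; heterozygous carriers are shifted *down* by
#' `effect_delta` (carriers show lower expression). An optional raw-count
#' matrix (Poisson with mean `raw_count_mean`) feeds the low-expression
#' gate, and genotypes are attached per sample.
#'
#' @param n_hom,n_het Group sizes (each >= 2); defaults mirror the cohort
#'   replication stage (386 hom-ref vs 35 het).
#' @param effect_delta Downward shift, in normalized units, applied to het
#'   carriers (0 = null).
#' @param noise_sd Gaussian noise SD (> 0).
#' @param baseline Baseline mean of the normalized values.
#' @param raw_count_mean Mean of the Poisson raw counts; `NULL` omits the
#'   raw matrix.
#' @param feature_ids Feature names (one row per feature).
#' @param seed Optional seed (set once here when given).
#' @return An `expression_dataset`: `feature_ids`, `sample_ids`,
#'   `normalized`, `raw_counts`, `genotype`.
#' @export
simulate_expression_cohort <- function(n_hom = 386L, n_het = 35L,
                                       effect_delta = 0, noise_sd = 1,
                                       baseline = 10,
                                       raw_count_mean = 100,
                                       feature_ids = "feature_1",
                                       seed = NULL) {
  stopifnot(n_hom >= 2L, n_het >= 2L)
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- n_hom + n_het
  sample_ids <- sprintf("S%04d", seq_len(n))
  genotype <- stats::setNames(rep(c("hom_ref", "het"), c(n_hom, n_het)),
                              sample_ids)
  nf <- length(feature_ids)
  shift <- rep(c(0, -effect_delta), c(n_hom, n_het))
  normalized <- matrix(baseline + stats::rnorm(nf * n, sd = noise_sd),
                       nf, n, dimnames = list(feature_ids, sample_ids))
  normalized <- sweep(normalized, 2L, shift, `+`)
  raw <- if (!is.null(raw_count_mean)) {
    matrix(stats::rpois(nf * n, raw_count_mean), nf, n,
           dimnames = list(feature_ids, sample_ids))
  }
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids,
                 normalized = normalized, raw_counts = raw,
                 genotype = genotype),
            class = "expression_dataset")
}

#' Simulate a family qPCR Ct table
#'
#' Six family members (three heterozygous carriers, three
#' reference-homozygous) with duplicate Ct measurements of a target and a
#' reference gene. Carriers receive a `shift_ct` increase of the target Ct
#' (higher Ct = lower expression); subject-to-subject biology and replicate
#' noise are Gaussian.
#'
#' @param shift_ct Target-Ct increase in het carriers (default 0.5
#'   cycles, i.e. a slight reduction, RQ ratio about 0.71).
#' @param sd_subject Between-subject SD of true Ct (default 0.3).
#' @param sd_rep Replicate (technical) SD (default 0.15).
#' @param n_replicates Replicates per sample (default 2 duplicates).
#' @param seed Optional seed.
#' @return Data frame with `subject_id`, `genotype_group` and list columns
#'   `target_ct`, `reference_ct`, suitable for
#'   [family_expression_report()].
#' @export
simulate_family_qpcr <- function(shift_ct = 0.5, sd_subject = 0.3,
                                 sd_rep = 0.15, n_replicates = 2L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- data.frame(
    subject_id = c("II-8", "II-5", "II-9", "III-4", "III-6", "III-9"),
    genotype_group = rep(c("het", "hom_ref"), each = 3L),
    stringsAsFactors = FALSE)
  base_target <- 25; base_ref <- 20
  n <- nrow(subjects)
  true_target <- base_target + stats::rnorm(n, sd = sd_subject) +
    ifelse(subjects$genotype_group == "het", shift_ct, 0)
  true_ref <- base_ref + stats::rnorm(n, sd = sd_subject)
  subjects$target_ct <- lapply(true_target, function(mu) {
    mu + stats::rnorm(n_replicates, sd = sd_rep)
  })
  subjects$reference_ct <- lapply(true_ref, function(mu) {
    mu + stats::rnorm(n_replicates, sd = sd_rep)
  })
  subjects
}
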