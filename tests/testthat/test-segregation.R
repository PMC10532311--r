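# Dominant-model co-segregation filtering.

test_that("the dominant filter assigns the specified reason codes", {
  fv <- fam_designs$FVIII
  survivor <- gt_pattern(fv)
  one_case_ref <- survivor; one_case_ref[[fv$cases[1]]] <- "0/0"
  one_ctrl_het <- survivor; one_ctrl_het[[fv$controls[1]]] <- "0/1"
  one_missing <- survivor; one_missing[[fv$controls[2]]] <- "./."
  case_hom_alt <- survivor; case_hom_alt[[fv$cases[2]]] <- "1/1"
  vs <- toy_variants(list(survivor, one_case_ref, one_ctrl_het, one_missing,
                          case_hom_alt))
  expect_equal(dominant_cosegregation(vs, fv),
               c("survivor", "case-not-het", "control-not-homref",
                 "incomplete-call-rate", "case-not-het"))
  # carrier mode accepts hom-alt cases
  expect_equal(dominant_cosegregation(vs, fv, case_genotype = "carrier")[5],
               "survivor")
})

test_that("degenerate designs and sample mismatches error clearly", {
  fv <- fam_designs$FVIII
  empty <- fv; empty$controls <- character(0)
  vs <- toy_variants(list(gt_pattern(fv)))
  expect_error(dominant_cosegregation(vs, empty), "empty")
  narrow <- toy_variants(list(gt_pattern(fv)[1:5]))
  expect_error(dominant_cosegregation(narrow, fv), "missing from")
  expect_error(run_dual_analysis(narrow, fam_designs), "missing from the VCF")
})

test_that("the dual analysis recovers exactly the planted survivor sets", {
  sim <- simulate_family_vcf(sim_config(seed = 11, n_decoys = 80),
                             fam_designs)
  res <- run_dual_analysis(sim$variants, fam_designs)
  planted <- sim$truth[sim$truth$role == "planted", ]
  expect_setequal(res$reports$FVIII$survivors,
                  planted$key[planted$class == "FVIII"])
  expect_setequal(res$reports$VWF$survivors,
                  planted$key[planted$class == "VWF"])
  expect_setequal(res$union$key, planted$key)
  # no decoy survives either design
  expect_length(intersect(res$union$key,
                          sim$truth$key[sim$truth$role == "decoy"]), 0L)
})

test_that("an empty site list yields two empty reports", {
  sim <- simulate_family_vcf(sim_config(seed = 11, n_decoys = 0,
                                        planted = NULL), fam_designs)
  res <- run_dual_analysis(sim$variants, fam_designs)
  expect_length(res$reports$FVIII$survivors, 0L)
  expect_length(res$reports$VWF$survivors, 0L)
  expect_equal(nrow(res$union), 0L)
})

test_that("filter agrees with the exhaustive per-sample oracle on every fixture variant", {
  sim <- simulate_family_vcf(sim_config(seed = 12, n_decoys = 150),
                             fam_designs)
  qcd <- apply_qc(sim$variants)
  vs <- qcd$variants
  for (dn in names(fam_designs)) {
    got <- dominant_cosegregation(vs, fam_designs[[dn]])
    want <- vapply(seq_len(nrow(vs$sites)), function(i) {
      oracle_reason(as.list(vs$gt[i, ]), fam_designs[[dn]])
    }, character(1))
    expect_identical(got, want, label = paste("design", dn))
  }
})

test_that("perturbing any single genotype of a planted variant removes it", {
  for (dn in c("FVIII", "VWF")) {
    d <- fam_designs[[dn]]
    base <- gt_pattern(d)
    for (s in wes_samples) {
      g <- base
      g[[s]] <- if (genotype_class(base[[s]]) == "het") "0/0" else "0/1"
      vs <- toy_variants(list(g))
      expect_false(
        dominant_cosegregation(vs, d) == "survivor",
        label = sprintf("%s design, perturbed %s", dn, s))
    }
  }
})

test_that("a planted variant made het in control III-1 vanishes from both lists", {
  sim <- simulate_family_vcf(sim_config(seed = 13, n_decoys = 40),
                             fam_designs)
  vs <- sim$variants
  planted_keys <- sim$truth$key[sim$truth$role == "planted"]
  target <- match(planted_keys[1], variant_keys(vs))
  vs$gt[target, "III-1"] <- "0/1"
  res <- run_dual_analysis(vs, fam_designs)
  expect_false(planted_keys[1] %in% res$reports$FVIII$survivors)
  expect_false(planted_keys[1] %in% res$reports$VWF$survivors)
  expect_false(planted_keys[1] %in% res$union$key)
})

test_that("swapping cases and controls never keeps a planted variant", {
  for (dn in c("FVIII", "VWF")) {
    d <- fam_designs[[dn]]
    swapped <- d
    swapped$cases <- d$controls
    swapped$controls <- d$cases
    vs <- toy_variants(list(gt_pattern(d)))
    expect_false(dominant_cosegregation(vs, swapped) == "survivor")
  }
})

test_that("variant order does not affect the reports", {
  sim <- simulate_family_vcf(sim_config(seed = 14, n_decoys = 50),
                             fam_designs)
  res1 <- run_dual_analysis(sim$variants, fam_designs)
  set.seed(1)
  perm <- sample(nrow(sim$variants$sites))
  res2 <- run_dual_analysis(subset_sites(sim$variants, perm), fam_designs)
  expect_setequal(res1$reports$FVIII$survivors, res2$reports$FVIII$survivors)
  expect_identical(res1$union$key, res2$union$key)
})

test_that("every post-QC variant carries exactly one reason and survivors match", {
  sim <- simulate_family_vcf(sim_config(seed = 15, n_decoys = 100),
                             fam_designs)
  res <- run_dual_analysis(sim$variants, fam_designs)
  for (r in res$reports) {
    expect_equal(nrow(r$table), nrow(sim$variants$sites))
    expect_false(anyNA(r$table$reason))
    expect_setequal(r$survivors, r$table$key[r$table$reason == "survivor"])
  }
})

test_that("decoys fail for exactly their engineered reason class", {
  sim <- simulate_family_vcf(sim_config(seed = 16, n_decoys = 200),
                             fam_designs)
  res <- run_dual_analysis(sim$variants, fam_designs)
  truth <- sim$truth[sim$truth$role == "decoy", ]
  # expected segregation-level reason per engineered class, evaluated under
  # the decoy's base pattern design is not recorded; instead verify the
  # pipeline-level mapping that must hold under *some* design and that QC
  # classes are logged with the matching site reason.
  site_reason <- setNames(res$qc_log$reason,
                          variant_keys(res$qc_log))
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class[i]; key <- truth$key[i]
    reasons <- vapply(res$reports, function(r) {
      r$table$reason[r$table$key == key]
    }, character(1))
    if (cl %in% c("non_pass", "multiallelic", "low_qual")) {
      expect_true(all(reasons == "failed-site-qc"), label = cl)
      expect_equal(unname(site_reason[[key]]),
                   c(non_pass = "non-pass", multiallelic = "multiallelic",
                     low_qual = "low-qual")[[cl]])
    } else if (cl %in% c("missing_genotype", "low_depth", "low_gq")) {
      expect_true(all(reasons == "incomplete-call-rate"), label = cl)
    } else if (cl == "het_in_control") {
      expect_true(any(reasons == "control-not-homref") &&
                    !any(reasons == "survivor"), label = cl)
    } else if (cl == "het_in_subset_of_cases") {
      expect_true(any(reasons == "case-not-het") &&
                    !any(reasons == "survivor"), label = cl)
    }
  }
})
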