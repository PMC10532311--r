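# qPCR relative quantitation and genotype-stratified matrix testing.

test_that("2^-ddCt relative quantitation evaluates its closed form", {
  expect_equal(relative_quantity(4.1, 4.1), 1)
  expect_equal(relative_quantity(5.1, 4.1), 0.5)
  expect_equal(relative_quantity(5.3, 4.1), 2^-1.2, tolerance = 1e-12)
  expect_error(relative_quantity(5, c(1, 2)))
})

test_that("the calibrator group has geometric mean RQ 1 by construction", {
  q <- simulate_family_qpcr(seed = 21)
  rq <- qpcr_relative_quantities(q)
  cal <- rq$rq[rq$genotype_group == "hom_ref"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
  expect_error(qpcr_relative_quantities(q, calibrator_group = "hom_alt"),
               "calibrator")
})

test_that("qPCR tables read from TSV with comma-separated replicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tgenotype_group\ttarget_ct\treference_ct",
               "II-8\thet\t25.1,25.3\t20.0,20.2",
               "III-4\thom_ref\t24.6,24.4\t20.1,19.9"), path)
  q <- read_qpcr(path)
  expect_equal(q$target_ct[[1]], c(25.1, 25.3))
  rq <- qpcr_relative_quantities(q)
  expect_equal(rq$delta_ct, c(25.2 - 20.1, 24.5 - 20.0))
})

test_that("Tukey-fence exclusion uses interpolated quartiles, single pass", {
  r <- iqr_exclude(c(1, 2, 3, 4, 100))
  expect_equal(r$excluded_idx, 5L)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(unname(r$fences), c(-1, 7))  # Q1=2, Q3=4, IQR=2

  same <- iqr_exclude(rep(5, 8))
  expect_length(same$excluded_idx, 0L)

  r4 <- iqr_exclude(c(1, 2, 3, 4))
  expect_length(r4$excluded_idx, 0L)

  expect_warning(iqr_exclude(c(1, 2, 3)), "fewer than 4")

  # idempotent on the kept set when fences come from the original sample
  set.seed(31)
  v <- c(rnorm(40), 25, -30)
  r1 <- iqr_exclude(v)
  r2 <- iqr_exclude(r1$kept)
  expect_length(r2$excluded_idx, 0L)
})

test_that("the low-expression gate is strict at its threshold", {
  expect_true(low_expression_gate(c(6.9, 6.9)))
  expect_false(low_expression_gate(c(7, 7)))
  expect_true(low_expression_gate(rep(0, 10)))
  expect_warning(expect_false(low_expression_gate(NULL)), "not applied")
  expect_error(low_expression_gate(c(-1, 3)), ">= 0")
})

test_that("two-group test is symmetric and respects the normality gate", {
  x <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  t1 <- test_two_groups(x, x)
  expect_equal(t1$p_value, 1)
  expect_equal(t1$direction, 0)

  set.seed(32)
  a <- rnorm(30); b <- rnorm(25, 1)
  fwd <- test_two_groups(a, b)
  rev <- test_two_groups(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$direction, -rev$direction)

  # clearly non-normal pooled data takes the Mann-Whitney branch
  set.seed(33)
  nn <- test_two_groups(rexp(60), rexp(60, 0.5))
  expect_equal(nn$test_used, "mann_whitney_u")
  # clearly normal pooled data takes the t branch
  set.seed(34)
  nrm <- test_two_groups(rnorm(60), rnorm(60))
  expect_equal(nrm$test_used, "t_test")

  expect_error(test_two_groups(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney p is invariant under common monotone affine maps", {
  set.seed(35)
  a <- rexp(40); b <- rexp(30, 0.6)
  p0 <- test_two_groups(a, b)$p_value
  p1 <- test_two_groups(3 * a + 2, 3 * b + 2)$p_value
  expect_equal(p0, p1)
})

test_that("detection power at the study's group-size regime matches the oracle band", {
  # direct Monte-Carlo oracle estimate at n=(400,35), 0.5 SD shift: 0.81
  set.seed(36)
  rej <- 0L
  for (i in 1:200) {
    a <- rnorm(400); b <- rnorm(35, -0.5)
    rej <- rej + test_two_groups(a, b)$significant
  }
  expect_gte(rej / 200, 0.72)
  expect_lte(rej / 200, 0.90)
})

test_that("genotype partition splits samples and counts drops", {
  g <- c("II-8" = "het", "II-5" = "het", "II-9" = "het",
         "III-4" = "hom_ref", "III-6" = "hom_ref", "III-9" = "hom_ref")
  p <- genotype_partition(names(g), g)
  expect_setequal(p$het, c("II-8", "II-5", "II-9"))
  expect_setequal(p$hom_ref, c("III-4", "III-6", "III-9"))
  expect_equal(p$n_dropped, 0L)

  g2 <- c(g, "X-1" = "missing")
  p2 <- genotype_partition(c(names(g), "X-1", "X-2"), g2)
  expect_equal(p2$n_dropped, 2L)

  expect_error(genotype_partition(c("A", "B"), c(C = "het")), "overlap")
})

test_that("matrix differential expression gates, excludes and tests per feature", {
  ds <- simulate_expression_cohort(n_hom = 60, n_het = 20, effect_delta = 2,
                                   noise_sd = 1, raw_count_mean = 100,
                                   feature_ids = c("f1", "f2"), seed = 37)
  # plant outliers in f1 to exercise the fence
  ds$normalized["f1", 1:3] <- ds$normalized["f1", 1:3] + 50
  de <- diff_expression(ds)
  expect_equal(de$feature_id, c("f1", "f2"))
  expect_equal(de$n_outliers[1], 3L)
  expect_equal(de$n_outliers_hom_ref[1], 3L)
  expect_equal(de$n_hom_ref[1], 57L)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_equal(de$direction[2], -1L)  # carriers shifted down
  expect_true(de$significant[2])

  # low-expression rows are skipped, not tested
  low <- simulate_expression_cohort(n_hom = 30, n_het = 10,
                                    raw_count_mean = 2, seed = 38)
  de_low <- diff_expression(low)
  expect_equal(de_low$test_used, "skipped_low_expression")
  expect_true(is.na(de_low$p_value))
})

test_that("expression matrices read from the flat cohort layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2\tS3",
               "miR-143\t1.5\t2.5\t3.5",
               "miR-145\t0.1\t0.2\t0.3"), path)
  ds <- read_expression_matrix(path)
  expect_equal(ds$feature_ids, c("miR-143", "miR-145"))
  expect_equal(ds$sample_ids, c("S1", "S2", "S3"))
  expect_equal(unname(ds$normalized["miR-143", ]), c(1.5, 2.5, 3.5))
})

test_that("family qPCR report states direction and significance", {
  r <- family_expression_report(simulate_family_qpcr(seed = 39))
  expect_equal(r$n_het, 3L)
  expect_equal(r$n_hom_ref, 3L)
  expect_true(r$direction %in% c(-1, 0, 1))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_type(r$significant, "logical")
})
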