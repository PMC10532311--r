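# Genotype-stratified expression comparison: qPCR relative quantitation
# (2^-ddCt) at family scale, and matrix testing at cohort scale with
# Tukey-fence outlier exclusion, a Shapiro-Wilk normality gate, and
# Mann-Whitney / Student tests.

#' 2^-ddCt relative quantity
#'
#' Relative quantitation of a qPCR sample: `RQ = 2^-(dCt - calibrator_dCt)`
#' where `dCt` is the sample's mean target Ct minus mean reference-gene Ct
#' and `calibrator_dCt` is the mean dCt of the calibrator group.
#'
#' @param delta_ct Sample delta-Ct value(s).
#' @param calibrator_delta_ct Calibrator delta-Ct (scalar).
#' @return Relative quantity (1 for the calibrator average).
#' @examples
#' relative_quantity(5.3, 4.1)  # 2^-1.2 ~= 0.435
#' @export
relative_quantity <- function(delta_ct, calibrator_delta_ct) {
  stopifnot(is.numeric(delta_ct), length(calibrator_delta_ct) == 1L,
            is.finite(calibrator_delta_ct))
  2^(-(delta_ct - calibrator_delta_ct))
}

#' Read a qPCR Ct table
#'
#' TSV with columns `subject_id`, `genotype_group` (`hom_ref`, `het`,
#' `hom_alt`), `target_ct`, `reference_ct`; replicate Ct values are
#' comma-separated within a cell (the assay runs two duplicates per
#' sample).
#'
#' @param path Path to the TSV.
#' @return Data frame with list columns `target_ct` and `reference_ct`.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "")
  need <- c("subject_id", "genotype_group", "target_ct", "reference_ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("qPCR table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  parse_ct <- function(x) {
    v <- as.numeric(strsplit(x, ",")[[1L]])
    if (anyNA(v) || any(v <= 0)) stop("Ct values must be positive numbers: ", x)
    v
  }
  df$target_ct <- lapply(df$target_ct, parse_ct)
  df$reference_ct <- lapply(df$reference_ct, parse_ct)
  df
}

#' Relative quantities for a qPCR sample table
#'
#' Averages replicate Cts per sample, computes each sample's delta-Ct
#' (target minus reference gene), takes the mean delta-Ct of the
#' calibrator genotype group as calibrator, and returns per-sample
#' `2^-ddCt` relative quantities. By construction the calibrator group has
#' geometric mean RQ 1.
#'
#' @param qpcr Data frame as returned by [read_qpcr()] (list columns of
#'   replicate Cts, or plain numeric columns for single measurements).
#' @param calibrator_group Genotype group used as calibrator (default
#'   `"hom_ref"`).
#' @return The input with added columns `delta_ct` and `rq`.
#' @export
qpcr_relative_quantities <- function(qpcr, calibrator_group = "hom_ref") {
  mean_ct <- function(col) {
    if (is.list(col)) {
      vapply(col, function(v) {
        if (length(v) == 0L || anyNA(v)) stop("missing Ct replicates")
        mean(v)
      }, numeric(1))
    } else {
      if (anyNA(col)) stop("missing Ct values")
      as.numeric(col)
    }
  }
  tgt <- mean_ct(qpcr$target_ct)
  ref <- mean_ct(qpcr$reference_ct)
  dct <- tgt - ref
  cal <- qpcr$genotype_group == calibrator_group
  if (!any(cal)) stop("no samples in calibrator group '", calibrator_group, "'")
  qpcr$delta_ct <- dct
  qpcr$rq <- relative_quantity(dct, mean(dct[cal]))
  qpcr
}

#' Tukey-fence outlier exclusion
#'
#' Single-pass exclusion of values outside `[Q1 - k*IQR, Q3 + k*IQR]`, with
#' quartiles by linear interpolation between order statistics and
#' `IQR = Q3 - Q1`. Fences are computed once from the full sample; with
#' fewer than 4 values no exclusion is attempted (warning).
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return List with `kept` (values inside the fences), `excluded_idx`
#'   (indices into `values` of the excluded points) and `fences`
#'   (lower, upper).
#' @examples
#' iqr_exclude(c(1, 2, 3, 4, 100))$excluded_idx  # 5
#' @export
iqr_exclude <- function(values, k = 1.5) {
  stopifnot(is.numeric(values), k >= 0)
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outlier exclusion attempted")
    return(list(kept = values, excluded_idx = integer(0),
                fences = c(lower = -Inf, upper = Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE,
                       na.rm = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = q[1L] - k * iqr, upper = q[2L] + k * iqr)
  out <- which(values < fences[["lower"]] | values > fences[["upper"]])
  list(kept = if (length(out)) values[-out] else values,
       excluded_idx = out, fences = fences)
}

#' Low-expression gate on raw counts
#'
#' A feature is too lowly expressed for differential testing when the mean
#' of its unnormalized count row is strictly below `min_mean` (default 7).
#'
#' @param raw_counts_row Numeric vector of raw counts for one feature, or
#'   `NULL` when no raw matrix is available (gate not applied, with a
#'   warning).
#' @param min_mean Gate threshold on the row mean.
#' @return `TRUE` when the feature should be skipped.
#' @export
low_expression_gate <- function(raw_counts_row, min_mean = 7) {
  if (is.null(raw_counts_row)) {
    warning("raw counts absent; low-expression gate not applied")
    return(FALSE)
  }
  if (any(raw_counts_row < 0, na.rm = TRUE)) stop("raw counts must be >= 0")
  mean(raw_counts_row) < min_mean
}

#' Two-group expression test with a normality gate
#'
#' Shapiro-Wilk is run on the pooled values of both groups; when its
#' p-value is below `alpha` (non-normal) a two-sided Mann-Whitney U test is
#' used (exact for small tie-free samples, normal approximation with
#' continuity/tie correction otherwise), else a two-sided Student's t-test.
#' Direction is the sign of `median(y) - median(x)` (conventionally x =
#' reference genotype group, y = carrier group).
#'
#' @param x,y Numeric vectors, each of length >= 2, outliers already
#'   excluded.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return List of class `famseg_test`: `test_used` (`"mann_whitney_u"` or
#'   `"t_test"`), `p_value`, `normality_p`, `direction` (-1/0/1), `n`
#'   (per-group sizes), `alpha`, `significant`.
#' @export
test_two_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  pooled <- c(x, y)
  if (length(pooled) > 5000L) {
    stop("Shapiro-Wilk normality gate supports at most 5000 pooled values")
  }
  norm_p <- if (length(unique(pooled)) < 3L) {
    NA_real_  # (near-)constant sample: no meaningful normality test
  } else {
    stats::shapiro.test(pooled)$p.value
  }
  non_normal <- is.na(norm_p) || norm_p < alpha
  if (non_normal) {
    exact <- max(length(x), length(y)) <= 20L && !anyDuplicated(pooled)
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = exact, correct = TRUE)$p.value
    used <- "mann_whitney_u"
  } else {
    p <- stats::t.test(x, y, alternative = "two.sided",
                       var.equal = TRUE)$p.value
    used <- "t_test"
  }
  structure(list(test_used = used, p_value = p, normality_p = norm_p,
                 direction = sign(stats::median(y) - stats::median(x)),
                 n = c(x = length(x), y = length(y)), alpha = alpha,
                 significant = is.finite(p) && p < alpha),
            class = "famseg_test")
}

#' @export
print.famseg_test <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (normality p = %s), direction %+d, n = %d vs %d\n",
              x$test_used, x$p_value,
              if (is.na(x$normality_p)) "NA" else sprintf("%.4g", x$normality_p),
              x$direction, x$n[["x"]], x$n[["y"]]))
  invisible(x)
}

#' Partition expression samples by genotype
#'
#' @param ds An `expression_dataset` (see [simulate_expression_cohort()] /
#'   [read_expression_matrix()]), or a character vector of sample ids.
#' @param genotypes Named character vector mapping sample id to `hom_ref`,
#'   `het`, `hom_alt` or `missing`; defaults to the dataset's own genotype
#'   map.
#' @return List with sample-id vectors `hom_ref`, `het`, `hom_alt` and a
#'   count `n_dropped` of samples with missing or unavailable genotype.
#' @export
genotype_partition <- function(ds, genotypes = NULL) {
  ids <- if (is.character(ds)) ds else ds$sample_ids
  if (is.null(genotypes)) {
    if (is.character(ds) || is.null(ds$genotype)) {
      stop("no genotype map supplied")
    }
    genotypes <- ds$genotype
  }
  overlap <- intersect(ids, names(genotypes))
  if (length(overlap) == 0L) {
    stop("no overlap between expression samples and genotype map")
  }
  g <- genotypes[overlap]
  keep <- g %in% c("hom_ref", "het", "hom_alt")
  list(hom_ref = overlap[keep & g == "hom_ref"],
       het = overlap[keep & g == "het"],
       hom_alt = overlap[keep & g == "hom_alt"],
       n_dropped = (length(ids) - length(overlap)) + sum(!keep))
}

#' Read an expression matrix in the flat cohort layout
#'
#' Features in rows, samples in columns, first column the feature id (the
#' layout used by the public cohort flat files).
#'
#' @param path Path to the TSV.
#' @return List of class `expression_dataset` with `feature_ids`,
#'   `sample_ids`, `normalized` (feature x sample matrix), `raw_counts`
#'   (`NULL`) and `genotype` (`NULL`).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  structure(list(feature_ids = df[[1L]], sample_ids = colnames(m),
                 normalized = m, raw_counts = NULL, genotype = NULL),
            class = "expression_dataset")
}

#' Genotype-stratified differential expression over a matrix
#'
#' For each feature: (i) skip when the raw-count row mean is below the
#' low-expression gate; (ii) exclude outliers from the pooled
#' hom-ref + het values with a single-pass Tukey fence; (iii) test
#' post-exclusion groups via [test_two_groups()] (Shapiro-Wilk gate
#' choosing Mann-Whitney U vs Student's t). Direction is the sign of the
#' het-minus-hom-ref median difference.
#'
#' @param ds An `expression_dataset` with a genotype map (or supply
#'   `genotypes`).
#' @param genotypes Optional named genotype vector overriding `ds$genotype`.
#' @param k Tukey fence multiplier (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @param min_raw_mean Low-expression gate threshold (default 7).
#' @return Data frame with one row per feature: `feature_id`, `n_hom_ref`,
#'   `n_het`, `n_outliers`, `n_outliers_hom_ref`, `n_outliers_het`,
#'   `normality_p`, `test_used`, `p_value`, `direction`, `significant`.
#' @export
diff_expression <- function(ds, genotypes = NULL, k = 1.5, alpha = 0.05,
                            min_raw_mean = 7) {
  part <- genotype_partition(ds, genotypes)
  if (length(part$hom_ref) < 2L || length(part$het) < 2L) {
    stop("need at least 2 hom_ref and 2 het samples")
  }
  rows <- lapply(seq_along(ds$feature_ids), function(i) {
    fid <- ds$feature_ids[[i]]
    base <- data.frame(feature_id = fid, n_hom_ref = NA_integer_,
                       n_het = NA_integer_, n_outliers = NA_integer_,
                       n_outliers_hom_ref = NA_integer_,
                       n_outliers_het = NA_integer_,
                       normality_p = NA_real_, test_used = NA_character_,
                       p_value = NA_real_, direction = NA_integer_,
                       significant = NA, stringsAsFactors = FALSE)
    if (!is.null(ds$raw_counts) &&
        low_expression_gate(ds$raw_counts[i, ], min_raw_mean)) {
      base$test_used <- "skipped_low_expression"
      return(base)
    }
    a <- ds$normalized[i, part$hom_ref]
    b <- ds$normalized[i, part$het]
    pooled <- c(a, b)
    grp <- rep(c("hom_ref", "het"), c(length(a), length(b)))
    excl <- iqr_exclude(pooled, k = k)
    keep <- !seq_along(pooled) %in% excl$excluded_idx
    a2 <- pooled[keep & grp == "hom_ref"]
    b2 <- pooled[keep & grp == "het"]
    tt <- test_two_groups(a2, b2, alpha = alpha)
    base$n_hom_ref <- length(a2); base$n_het <- length(b2)
    base$n_outliers <- length(excl$excluded_idx)
    base$n_outliers_hom_ref <- sum(grp[excl$excluded_idx] == "hom_ref")
    base$n_outliers_het <- sum(grp[excl$excluded_idx] == "het")
    base$normality_p <- tt$normality_p
    base$test_used <- tt$test_used
    base$p_value <- tt$p_value
    base$direction <- tt$direction
    base$significant <- tt$significant
    base
  })
  do.call(rbind, rows)
}

#' Family-scale qPCR expression report
#'
#' Descriptive comparison of relative quantities between carrier (het) and
#' reference-homozygous family members: Student's t-test on the RQ values
#' (appropriate at qPCR family scale), median direction, and a
#' significance flag. At n = 3 vs 3 the comparison is reported
#' descriptively; power is very limited.
#'
#' @param qpcr A qPCR table (see [read_qpcr()]); relative quantities are
#'   computed here with the hom-ref group as calibrator.
#' @param alpha Significance level (default 0.05).
#' @return List of class `family_expression_report`: `rq` (per-sample
#'   table with RQ), `n_het`, `n_hom_ref`, `direction` (sign of het minus
#'   hom-ref median RQ), `p_value`, `significant`.
#' @export
family_expression_report <- function(qpcr, alpha = 0.05) {
  rq <- qpcr_relative_quantities(qpcr, calibrator_group = "hom_ref")
  a <- rq$rq[rq$genotype_group == "hom_ref"]
  b <- rq$rq[rq$genotype_group == "het"]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 samples per genotype group")
  }
  p <- stats::t.test(b, a, var.equal = TRUE)$p.value
  structure(list(rq = rq, n_het = length(b), n_hom_ref = length(a),
                 direction = sign(stats::median(b) - stats::median(a)),
                 p_value = p, significant = is.finite(p) && p < alpha),
            class = "family_expression_report")
}

#' @export
print.family_expression_report <- function(x, ...) {
  cat(sprintf(
    "Family qPCR comparison: het (n=%d) vs hom_ref (n=%d)\n", x$n_het,
    x$n_hom_ref))
  cat(sprintf("  median RQ direction in carriers: %s\n",
              c("-1" = "lower", "0" = "equal", "1" = "higher")[as.character(x$direction)]))
  cat(sprintf("  Student's t-test p = %.3f (%s at alpha = 0.05)\n", x$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
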