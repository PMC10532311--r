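# Phenotype table handling and quantitative-trait case/control designs.

.TRAITS <- c("FVIII:C" = "fviii_c", "FVIII:Ag" = "fviii_ag",
             "VWF:Ag" = "vwf_ag", "VWF:RCo" = "vwf_rco")

# Default case thresholds (percent of normal) for the two traits the
# co-segregation analysis stratifies on.
.DEFAULT_THRESHOLDS <- c("FVIII:C" = 150, "VWF:Ag" = 180)

#' Read a per-subject phenotype table
#'
#' Reads a TSV with one row per subject and columns `subject_id`, `sex`,
#' `age`, `blood_group`, `wes_analyzed`, `fviii_c`, `fviii_ag`, `vwf_ag`,
#' `vwf_rco`, `covariates`. Repeated measurements of a trait are stacked in
#' one cell as a comma-separated list of percent-of-normal values (e.g.
#' `"397,225"`); they are parsed into numeric vectors held as list columns.
#'
#' @param path Path to the phenotype TSV.
#' @return A data frame of class `famseg_phenotypes` with list columns for
#'   the four trait measurement series.
#' @examples
#' ph <- read_phenotypes(famseg_fixture("phenotypes"))
#' ph$fviii_c[ph$subject_id == "II-5"]
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = TRUE,
                          na.strings = c("NA"), quote = "",
                          check.names = TRUE)
  need <- c("subject_id", "sex", "age", "blood_group", "wes_analyzed",
            unname(.TRAITS))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in phenotype table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  for (col in unname(.TRAITS)) {
    df[[col]] <- lapply(df[[col]], .parse_measurements, col = col)
  }
  df$age <- suppressWarnings(as.integer(df$age))
  df$wes_analyzed <- toupper(trimws(df$wes_analyzed)) %in% c("TRUE", "T", "1")
  if (!"covariates" %in% names(df)) df$covariates <- NA_character_
  # every subject must carry at least one measurement
  any_meas <- vapply(seq_len(nrow(df)), function(i) {
    any(vapply(unname(.TRAITS), function(col) length(df[[col]][[i]]) > 0L,
               logical(1)))
  }, logical(1))
  if (!all(any_meas)) {
    stop("subjects without any measurement: ",
         paste(df$subject_id[!any_meas], collapse = ", "))
  }
  class(df) <- c("famseg_phenotypes", "data.frame")
  df
}

.parse_measurements <- function(x, col) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  vals <- suppressWarnings(as.numeric(strsplit(trimws(x), ",")[[1]]))
  if (anyNA(vals)) stop("non-numeric measurement in column ", col, ": ", x)
  if (any(vals <= 0)) stop("non-positive measurement in column ", col, ": ", x)
  vals
}

#' Summarize a repeated quantitative measurement series
#'
#' A subject's level for classification is characterized by the maximum of
#' the repeated measurements (levels reported as "up to X percent"); `first`
#' and `mean` are available for sensitivity analysis.
#'
#' @param values Numeric vector of percent-of-normal values, all `> 0`.
#' @param method Summary statistic: `"max"` (default), `"first"` or `"mean"`.
#' @param subject,trait Optional labels used in error messages.
#' @return A single summarized percent value.
#' @examples
#' summarize_level(c(397, 225))  # 397
#' @export
summarize_level <- function(values, method = c("max", "first", "mean"),
                            subject = NULL, trait = NULL) {
  method <- match.arg(method)
  if (length(values) == 0L) {
    stop("missing measurement",
         if (!is.null(trait)) paste0(" for trait ", trait),
         if (!is.null(subject)) paste0(" in subject ", subject))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("measurements must be finite and > 0")
  }
  switch(method,
         max   = max(values),
         first = values[[1L]],
         mean  = mean(values))
}

#' Partition WES-analyzed subjects into cases and controls
#'
#' Classifies every WES-analyzed subject on a named quantitative trait:
#' case if the summarized level is strictly above the threshold, control if
#' strictly below. A level exactly at the threshold is excluded with reason
#' `"at-threshold"` (the classification rule uses strict inequalities on
#' both sides); a subject lacking the trait entirely is excluded with
#' reason `"no-measurement"`. Subjects not analyzed by WES are never
#' partitioned.
#'
#' @param subjects A `famseg_phenotypes` table from [read_phenotypes()].
#' @param trait One of `"FVIII:C"`, `"FVIII:Ag"`, `"VWF:Ag"`, `"VWF:RCo"`.
#' @param threshold Case threshold in percent of normal; defaults to 150
#'   for FVIII:C and 180 for VWF:Ag, and must be given for other traits.
#' @param summary Measurement summary passed to [summarize_level()].
#' @return An object of class `case_control_design`: a list with elements
#'   `trait`, `threshold`, `summary`, `cases`, `controls` (sorted subject
#'   id vectors), `levels` (named summarized levels) and `excluded`
#'   (data frame `subject_id`, `reason`).
#' @examples
#' ph <- read_phenotypes(famseg_fixture("phenotypes"))
#' assign_case_control(ph, "FVIII:C")
#' @export
assign_case_control <- function(subjects, trait, threshold = NULL,
                                summary = "max") {
  if (!inherits(subjects, "famseg_phenotypes")) {
    stop("subjects must be a famseg_phenotypes table (see read_phenotypes)")
  }
  if (!trait %in% names(.TRAITS)) {
    stop("unknown trait '", trait, "'; expected one of: ",
         paste(names(.TRAITS), collapse = ", "))
  }
  if (is.null(threshold)) {
    if (!trait %in% names(.DEFAULT_THRESHOLDS)) {
      stop("no default threshold for trait ", trait,
           "; supply threshold explicitly")
    }
    threshold <- .DEFAULT_THRESHOLDS[[trait]]
  }
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")

  wes <- subjects[subjects$wes_analyzed, , drop = FALSE]
  col <- .TRAITS[[trait]]
  cases <- character(0); controls <- character(0)
  excl_id <- character(0); excl_reason <- character(0)
  levels <- numeric(0)
  for (i in seq_len(nrow(wes))) {
    id <- wes$subject_id[[i]]
    vals <- wes[[col]][[i]]
    if (length(vals) == 0L) {
      excl_id <- c(excl_id, id); excl_reason <- c(excl_reason, "no-measurement")
      next
    }
    lev <- summarize_level(vals, method = summary, subject = id, trait = trait)
    levels[[id]] <- lev
    if (lev > threshold) {
      cases <- c(cases, id)
    } else if (lev < threshold) {
      controls <- c(controls, id)
    } else {
      excl_id <- c(excl_id, id); excl_reason <- c(excl_reason, "at-threshold")
    }
  }
  structure(list(
    trait = trait, threshold = threshold, summary = summary,
    cases = sort(cases), controls = sort(controls),
    levels = levels[order(names(levels))],
    excluded = data.frame(subject_id = excl_id, reason = excl_reason,
                          stringsAsFactors = FALSE)
  ), class = "case_control_design")
}

#' @export
print.case_control_design <- function(x, ...) {
  cat(sprintf("Case/control design on %s (threshold %g%%, summary = %s)\n",
              x$trait, x$threshold, x$summary))
  cat(sprintf("  cases   (n=%d): %s\n", length(x$cases),
              paste(x$cases, collapse = ", ")))
  cat(sprintf("  controls(n=%d): %s\n", length(x$controls),
              paste(x$controls, collapse = ", ")))
  if (nrow(x$excluded) > 0L) {
    cat(sprintf("  excluded(n=%d): %s\n", nrow(x$excluded),
                paste(sprintf("%s [%s]", x$excluded$subject_id,
                              x$excluded$reason), collapse = ", ")))
  }
  invisible(x)
}

#' Members of a case/control design
#'
#' @param design A `case_control_design`.
#' @return Character vector of all partitioned subject ids (cases then
#'   controls).
#' @export
design_members <- function(design) {
  stopifnot(inherits(design, "case_control_design"))
  c(design$cases, design$controls)
}

#' The two trait designs of the family study
#'
#' Convenience constructor for the dual stratification: FVIII:C with a 150%
#' case threshold and VWF:Ag with a 180% threshold, both max-summarized.
#'
#' @param phenotypes A `famseg_phenotypes` table; defaults to the bundled
#'   fixture.
#' @return Named list with elements `FVIII` and `VWF`, each a
#'   `case_control_design`.
#' @examples
#' d <- family_designs()
#' length(d$FVIII$cases)  # 7
#' @export
family_designs <- function(phenotypes = read_phenotypes(famseg_fixture("phenotypes"))) {
  list(
    FVIII = assign_case_control(phenotypes, "FVIII:C", 150),
    VWF   = assign_case_control(phenotypes, "VWF:Ag", 180)
  )
}

#' Write a case/control design to TSV
#'
#' One row per WES-analyzed subject with its class (`case`, `control`,
#' `excluded`), summarized level, and exclusion reason where applicable.
#'
#' @param design A `case_control_design`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "case_control_design"))
  rows <- rbind(
    data.frame(subject_id = design$cases, trait = design$trait,
               class = "case", stringsAsFactors = FALSE),
    data.frame(subject_id = design$controls, trait = design$trait,
               class = "control", stringsAsFactors = FALSE),
    if (nrow(design$excluded) > 0L)
      data.frame(subject_id = design$excluded$subject_id,
                 trait = design$trait, class = "excluded",
                 stringsAsFactors = FALSE)
  )
  rows$summarized_level <- unname(design$levels[rows$subject_id])
  rows$reason <- ""
  if (nrow(design$excluded) > 0L) {
    m <- match(design$excluded$subject_id, rows$subject_id)
    rows$reason[m] <- design$excluded$reason
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
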