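# Dominant-model co-segregation filtering over one or two case/control
# designs.

.SEG_REASONS <- c("survivor", "case-not-het", "control-not-homref",
                  "incomplete-call-rate", "failed-site-qc")

#' Dominant co-segregation verdict for each site
#'
#' Under the autosomal dominant model a candidate variant must be
#' heterozygous in every case and reference-homozygous in every control
#' ("absent" means hom-ref, not merely uncalled), with a 100% call rate
#' over cases and controls. Reasons are assigned in priority order:
#' `incomplete-call-rate` (any case or control genotype missing), then
#' `case-not-het`, then `control-not-homref`, else `survivor`.
#'
#' @param x A `famseg_variants` object; sites are expected to have passed
#'   site QC and genotype masking.
#' @param design A `case_control_design` with non-empty cases and controls.
#' @param case_genotype `"het"` (default) requires every case to be
#'   heterozygous; `"carrier"` also accepts hom-alt cases.
#' @return Character vector of reason codes, one per site.
#' @export
dominant_cosegregation <- function(x, design,
                                   case_genotype = c("het", "carrier")) {
  stopifnot(inherits(x, "famseg_variants"),
            inherits(design, "case_control_design"))
  case_genotype <- match.arg(case_genotype)
  if (length(design$cases) == 0L || length(design$controls) == 0L) {
    stop("co-segregation filter undefined: design has empty cases or controls")
  }
  members <- design_members(design)
  absent <- setdiff(members, variant_samples(x))
  if (length(absent) > 0L) {
    stop("design subjects missing from variant set: ",
         paste(absent, collapse = ", "))
  }
  cls <- genotype_class(x$gt[, members, drop = FALSE])
  if (nrow(x$sites) == 0L) return(character(0))
  case_cls <- cls[, design$cases, drop = FALSE]
  ctrl_cls <- cls[, design$controls, drop = FALSE]
  any_missing <- rowSums(cls == "missing") > 0L
  case_ok <- if (case_genotype == "het") {
    rowSums(case_cls != "het") == 0L
  } else {
    rowSums(case_cls != "het" & case_cls != "hom_alt") == 0L
  }
  ctrl_ok <- rowSums(ctrl_cls != "hom_ref") == 0L
  ifelse(any_missing, "incomplete-call-rate",
         ifelse(!case_ok, "case-not-het",
                ifelse(!ctrl_ok, "control-not-homref", "survivor")))
}

#' Run the co-segregation filter for one design
#'
#' @inheritParams dominant_cosegregation
#' @param qc_dropped Optional data frame of sites removed by site QC
#'   (`chrom`, `pos`, `ref`, `alt`, `reason`); they are carried into the
#'   report with reason `failed-site-qc` so every input variant has exactly
#'   one recorded reason.
#' @return An object of class `segregation_report`: list with `design`,
#'   `table` (data frame `key`, `chrom`, `pos`, `ref`, `alt`, `reason`),
#'   and `survivors` (keys with reason `survivor`).
#' @export
segregate <- function(x, design, case_genotype = "het", qc_dropped = NULL) {
  reason <- dominant_cosegregation(x, design, case_genotype)
  tab <- data.frame(key = variant_keys(x),
                    x$sites[, c("chrom", "pos", "ref", "alt")],
                    reason = reason, stringsAsFactors = FALSE)
  if (!is.null(qc_dropped) && nrow(qc_dropped) > 0L) {
    extra <- data.frame(key = variant_keys(qc_dropped),
                        qc_dropped[, c("chrom", "pos", "ref", "alt")],
                        reason = "failed-site-qc", stringsAsFactors = FALSE)
    tab <- rbind(tab, extra)
  }
  tab <- tab[order(tab$chrom, tab$pos, tab$ref, tab$alt), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(design = design, table = tab,
                 survivors = tab$key[tab$reason == "survivor"]),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("Segregation report (%s, threshold %g%%): %d survivors of %d variants\n",
              x$design$trait, x$design$threshold,
              length(x$survivors), nrow(x$table)))
  print(table(x$table$reason))
  invisible(x)
}

#' Run the dual (FVIII- and VWF-based) co-segregation analysis
#'
#' Applies QC once (unless `qc = NULL`) and then filters independently
#' under each design. A variant may survive one, both, or neither design;
#' the union of distinct survivors across designs is summarized.
#'
#' @param x A `famseg_variants` object (raw; QC is applied here).
#' @param designs Named list of `case_control_design` objects, e.g. from
#'   [family_designs()]. All designs must partition the same sample set.
#' @param qc A [qc_config()], or `NULL` to skip QC (sites assumed
#'   pre-filtered and pre-masked).
#' @param case_genotype Passed to [dominant_cosegregation()].
#' @return Object of class `famseg_dual`: list with `reports` (named list
#'   of `segregation_report`), `union` (data frame of distinct survivor
#'   keys with per-design membership flags), `qc_log` and `mask_reasons`.
#' @examples
#' sim <- simulate_family_vcf(sim_config(seed = 1, n_decoys = 50))
#' res <- run_dual_analysis(sim$variants, family_designs())
#' res
#' @export
run_dual_analysis <- function(x, designs, qc = qc_config(),
                              case_genotype = "het") {
  stopifnot(inherits(x, "famseg_variants"), is.list(designs),
            length(designs) >= 1L)
  member_sets <- lapply(designs, function(d) sort(design_members(d)))
  if (length(unique(member_sets)) != 1L) {
    stop("designs must partition the same WES sample set")
  }
  absent <- setdiff(member_sets[[1L]], variant_samples(x))
  if (length(absent) > 0L) {
    stop("samples required by the designs are missing from the VCF: ",
         paste(absent, collapse = ", "))
  }
  if (!is.null(qc)) {
    qcd <- apply_qc(x, qc)
    vs <- qcd$variants; site_log <- qcd$site_log
    mask_reasons <- qcd$mask_reasons
  } else {
    vs <- x
    site_log <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           reason = character(0))
    mask_reasons <- c("low-depth" = 0L, "low-gq" = 0L)
  }
  reports <- lapply(designs, function(d) {
    segregate(vs, d, case_genotype = case_genotype, qc_dropped = site_log)
  })
  surv_keys <- sort(unique(unlist(lapply(reports, `[[`, "survivors"))))
  membership <- vapply(reports, function(r) surv_keys %in% r$survivors,
                       logical(length(surv_keys)))
  if (length(surv_keys) == 1L) membership <- matrix(membership, nrow = 1L,
                                                    dimnames = list(NULL, names(reports)))
  union_df <- data.frame(key = surv_keys, stringsAsFactors = FALSE)
  if (length(surv_keys) > 0L) {
    union_df <- cbind(union_df, as.data.frame(membership))
  } else {
    for (nm in names(reports)) union_df[[nm]] <- logical(0)
  }
  structure(list(reports = reports, union = union_df,
                 qc_log = site_log, mask_reasons = mask_reasons),
            class = "famseg_dual")
}

#' @export
print.famseg_dual <- function(x, ...) {
  cat("Dual co-segregation analysis\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %s design: %d survivors\n", nm, length(r$survivors)))
  }
  cat(sprintf("  union: %d distinct survivors\n", nrow(x$union)))
  cat(sprintf("  sites removed by QC: %d; genotypes masked: %d\n",
              nrow(x$qc_log), sum(x$mask_reasons)))
  invisible(x)
}

#' Write dual-analysis outputs
#'
#' One survivor TSV per design, a union TSV, and a drop-reason log.
#'
#' @param res A `famseg_dual` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dual_analysis <- function(res, dir) {
  stopifnot(inherits(res, "famseg_dual"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$reports)) {
    r <- res$reports[[nm]]
    surv <- r$table[r$table$reason == "survivor", , drop = FALSE]
    utils::write.table(surv, file.path(dir, paste0("survivors_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$table, file.path(dir, paste0("reasons_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$union, file.path(dir, "survivors_union.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$qc_log, file.path(dir, "qc_dropped_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
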