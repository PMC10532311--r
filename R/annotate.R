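# Survivor annotation and the summary statistics reported for them:
# allele-frequency classes, region spans, gene-locus and consequence counts.

.CONSEQUENCES <- c("intronic", "synonymous", "missense", "five_prime_utr",
                   "upstream")

#' Read a variant annotation table
#'
#' TSV with columns `approach` (optional; `A`/`B` analysis membership),
#' `chrom`, `pos`, `ref`, `alt`, `dbsnp_id`, `maf`, `gene`, `refseq`,
#' `cdna`, `protein`, `consequence`. `"."` marks an absent dbSNP id or MAF
#' (a variant absent from dbSNP is "novel"). cDNA/protein strings are
#' carried verbatim, never parsed.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame of class `famseg_annotations` with a `key` column.
#' @examples
#' ann <- read_annotations(famseg_fixture("annotations"))
#' table(ann$approach)
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  if ("maf" %in% names(df)) {
    df$maf[df$maf %in% c(".", "")] <- NA_character_
    df$maf <- as.numeric(df$maf)
  } else {
    df$maf <- NA_real_
  }
  if ("dbsnp_id" %in% names(df)) {
    df$dbsnp_id[df$dbsnp_id %in% c(".", "")] <- NA_character_
  }
  bad <- !df$consequence %in% .CONSEQUENCES
  if (any(bad)) {
    stop("unknown consequence class(es): ",
         paste(unique(df$consequence[bad]), collapse = ", "))
  }
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  class(df) <- c("famseg_annotations", "data.frame")
  df
}

#' Classify a minor allele frequency
#'
#' Conventional frequency bins: `novel` when the variant is not reported
#' (MAF absent), `rare` when MAF < 1%, `low_frequency` when 1% <= MAF <
#' 5%, `common` when MAF >= 5%. MAF values must lie in (0, 0.5].
#'
#' @param maf Numeric vector of minor allele frequencies; `NA` = absent
#'   from dbSNP.
#' @return Character vector in
#'   `c("novel","rare","low_frequency","common")`.
#' @examples
#' classify_maf(c(0.037, 0.001, NA, 0.229))
#' @export
classify_maf <- function(maf) {
  bad <- !is.na(maf) & (maf <= 0 | maf > 0.5)
  if (any(bad)) {
    stop("MAF values must lie in (0, 0.5]: ",
         paste(maf[bad], collapse = ", "))
  }
  ifelse(is.na(maf), "novel",
         ifelse(maf < 0.01, "rare",
                ifelse(maf < 0.05, "low_frequency", "common")))
}

#' Genomic span of a variant cluster in Kb
#'
#' Span of positions on one contig, `round((max - min) / 1000)` to the
#' nearest integer kilobase. A single position has span 0.
#'
#' @param positions Non-empty vector of 1-based positions.
#' @param chrom Optional vector of contig names (recycled); mixing contigs
#'   is an error.
#' @return Integer span in Kb.
#' @examples
#' region_span_kb(c(156714137, 156727692, 156766037, 156770209))  # 56
#' @export
region_span_kb <- function(positions, chrom = NULL) {
  if (length(positions) == 0L) stop("positions must be non-empty")
  if (!is.null(chrom) && length(unique(chrom)) > 1L) {
    stop("positions span multiple contigs: ",
         paste(unique(chrom), collapse = ", "))
  }
  as.integer(round((max(positions) - min(positions)) / 1000))
}

#' Count distinct gene loci
#'
#' Number of distinct gene labels among annotated records. Compound labels
#' naming a co-regulated cluster (e.g. a shared-promoter miRNA pair
#' written as one label) count as a single locus.
#'
#' @param records A `famseg_annotations` data frame (or any data frame
#'   with a `gene` column).
#' @return Integer count.
#' @export
count_gene_loci <- function(records) {
  if (nrow(records) == 0L) return(0L)
  if (!"gene" %in% names(records) || anyNA(records$gene) ||
      any(!nzchar(records$gene))) {
    stop("every record must carry a gene label")
  }
  length(unique(records$gene))
}

#' Tabulate consequence classes
#'
#' Counts per consequence class over the closed vocabulary (`intronic`,
#' `synonymous`, `missense`, `five_prime_utr`, `upstream`); classes with
#' no records report 0, and the counts sum to the record count.
#'
#' @param records A data frame with a `consequence` column.
#' @return Named integer vector over all consequence classes.
#' @export
tabulate_consequences <- function(records) {
  bad <- setdiff(unique(records$consequence), .CONSEQUENCES)
  if (length(bad) > 0L) {
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(records$consequence, levels = .CONSEQUENCES))
  stats::setNames(as.integer(tab), .CONSEQUENCES)
}

#' Join survivors with annotation records
#'
#' Exact join on `(chrom, pos, ref, alt)`. Survivors with no annotation
#' row are retained with frequency class `"unannotated"`, never silently
#' dropped.
#'
#' @param survivors A `segregation_report`, or a character vector of
#'   `chrom:pos:ref:alt` keys.
#' @param annotations A `famseg_annotations` table.
#' @return Data frame with annotation columns plus `freq_class`.
#' @export
annotate_survivors <- function(survivors, annotations) {
  keys <- if (inherits(survivors, "segregation_report")) {
    survivors$survivors
  } else {
    as.character(survivors)
  }
  m <- match(keys, annotations$key)
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  carry <- setdiff(names(annotations), "key")
  for (col in carry) out[[col]] <- annotations[[col]][m]
  parts <- strsplit(keys, ":", fixed = TRUE)
  out$chrom <- vapply(parts, `[[`, character(1), 1L)
  out$pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  out$ref <- vapply(parts, `[[`, character(1), 3L)
  out$alt <- vapply(parts, `[[`, character(1), 4L)
  out$freq_class <- ifelse(is.na(m), "unannotated", classify_maf(out$maf))
  out
}

#' Summarize an annotated survivor set
#'
#' The descriptive statistics reported for a survivor list: variant count,
#' distinct gene-locus count, region span, frequency-class histogram and
#' consequence histogram.
#'
#' @param annotated Output of [annotate_survivors()] (only annotated rows
#'   enter the gene/consequence counts; unannotated rows are counted
#'   separately).
#' @return A list of class `survivor_summary` with elements `n_variants`,
#'   `n_unannotated`, `n_gene_loci`, `span_kb`, `freq_classes`,
#'   `consequences`.
#' @export
summarize_survivors <- function(annotated) {
  ann <- annotated[annotated$freq_class != "unannotated", , drop = FALSE]
  freq <- table(factor(annotated$freq_class,
                       levels = c("common", "low_frequency", "rare", "novel",
                                  "unannotated")))
  structure(list(
    n_variants = nrow(annotated),
    n_unannotated = sum(annotated$freq_class == "unannotated"),
    n_gene_loci = count_gene_loci(ann),
    span_kb = if (nrow(annotated) > 0L)
      region_span_kb(annotated$pos, annotated$chrom) else NA_integer_,
    freq_classes = stats::setNames(as.integer(freq), names(freq)),
    consequences = tabulate_consequences(ann)
  ), class = "survivor_summary")
}

#' @export
print.survivor_summary <- function(x, ...) {
  cat(sprintf("%d survivor variants in %d gene loci spanning %s Kb\n",
              x$n_variants, x$n_gene_loci,
              format(x$span_kb)))
  cat("  frequency classes:",
      paste(sprintf("%s=%d", names(x$freq_classes), x$freq_classes),
            collapse = ", "), "\n")
  cat("  consequences:",
      paste(sprintf("%s=%d", names(x$consequences), x$consequences),
            collapse = ", "), "\n")
  if (x$n_unannotated > 0L) {
    cat(sprintf("  (%d survivors had no annotation row)\n", x$n_unannotated))
  }
  invisible(x)
}
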