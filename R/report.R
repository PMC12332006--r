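#' Round half away from zero
#'
#' Percentage tables are reported with conventional half-up rounding (R's
#' `round()` rounds half to even, which would print 2.65% as 2.6%).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize gene-level event categories as counts and percentages
#'
#' Percentages are always computed against the detected total (not the
#' affected subtotal) and rounded half-up to `decimals`. An `affected` row
#' (IR + AS + both) and a `normal` row (the remainder) are derived.
#'
#' @param category_counts named numeric vector with entries `IR`, `AS`,
#'   `IR_and_AS` (any subset; missing entries count 0).
#' @param detected_total number of detected genes (> 0).
#' @param decimals decimals for the percentage column (default 1).
#' @return `data.table(category, count, pct)` with rows IR, AS, IR_and_AS,
#'   affected, normal, detected.
#' @export
summarize_categories <- function(category_counts, detected_total, decimals = 1L) {
  if (detected_total <= 0) stop("detected_total must be positive")
  get0n <- function(nm) if (nm %in% names(category_counts)) as.numeric(category_counts[[nm]]) else 0
  ir <- get0n("IR"); as_ <- get0n("AS"); both <- get0n("IR_and_AS")
  affected <- ir + as_ + both
  if (affected > detected_total) stop("category counts exceed detected_total")
  normal <- detected_total - affected
  dt <- data.table(
    category = c("IR", "AS", "IR_and_AS", "affected", "normal", "detected"),
    count = c(ir, as_, both, affected, normal, detected_total)
  )
  dt[, pct := round_half_up(100 * count / detected_total, decimals)]
  dt[category == "detected", pct := 100]
  dt[]
}

#' Minor-versus-major retention enrichment
#'
#' Percent retained within each intron class, and their ratio. Percentages
#' are rounded half-up to the requested decimals before the ratio is taken,
#' mirroring how such enrichments are quoted from printed percentages; a
#' zero major-class percentage yields an `Inf` ratio (logged) rather than an
#' error. A chi-square goodness-of-fit of the retained counts against the
#' detected class proportions is attached.
#'
#' @param minor_retained,minor_detected counts for minor introns.
#' @param major_retained,major_detected counts for major introns.
#' @param decimals_minor,decimals_major rounding for the two percentages
#'   (defaults 0 and 2, the mixed precision such results are quoted at).
#' @return list `(pct_minor, pct_major, ratio, chisq)`.
#' @export
enrichment_ratio <- function(minor_retained, minor_detected,
                             major_retained, major_detected,
                             decimals_minor = 0L, decimals_major = 2L) {
  if (minor_detected <= 0 || major_detected <= 0) stop("detected counts must be positive")
  pct_minor <- round_half_up(100 * minor_retained / minor_detected, decimals_minor)
  pct_major <- round_half_up(100 * major_retained / major_detected, decimals_major)
  ratio <- if (pct_major == 0) {
    message("zero major-class retention percentage; enrichment ratio reported as Inf")
    Inf
  } else pct_minor / pct_major
  chisq <- chi_square_gof(
    c(minor_retained, major_retained),
    c(minor_detected, major_detected) / (minor_detected + major_detected)
  )
  list(pct_minor = pct_minor, pct_major = pct_major, ratio = ratio, chisq = chisq)
}

#' Differential-expression cross-tabulation of minor-intron genes
#'
#' Intersects an external differential-expression table with a list of
#' minor-intron-containing genes (MIGs) and tallies significantly down- and
#' up-regulated MIGs (FDR <= `fdr_max`, sign of log2FC; no fold-change
#' cutoff). Percentages are against detected MIGs;
#' `fold_propensity = pct_down / pct_up` on the rounded percentages.
#'
#' @param de_table data.frame with columns `gene`, `log2FC`, `FDR`
#'   (unique gene ids).
#' @param mig_list character vector of MIG gene ids.
#' @param fdr_max significance threshold (default 0.05).
#' @param decimals_down,decimals_up rounding for the two percentages
#'   (defaults 0 and 1).
#' @return list `(n_mig_detected, n_down, n_up, pct_down, pct_up,
#'   fold_propensity)`.
#' @export
summarize_de_migs <- function(de_table, mig_list, fdr_max = 0.05,
                              decimals_down = 0L, decimals_up = 1L) {
  de <- as.data.table(de_table)
  need <- c("gene", "log2FC", "FDR")
  if (!all(need %in% names(de))) stop("DE table needs columns gene, log2FC, FDR")
  if (anyDuplicated(de$gene)) stop("DE table gene ids must be unique")
  migs <- de[gene %in% mig_list]
  if (nrow(migs) == 0L) {
    warning("no MIGs found in the DE table")
    return(list(n_mig_detected = 0L, n_down = 0L, n_up = 0L,
                pct_down = 0, pct_up = 0, fold_propensity = NA_real_))
  }
  n_down <- migs[FDR <= fdr_max & log2FC < 0, .N]
  n_up <- migs[FDR <= fdr_max & log2FC > 0, .N]
  pct_down <- round_half_up(100 * n_down / nrow(migs), decimals_down)
  pct_up <- round_half_up(100 * n_up / nrow(migs), decimals_up)
  list(n_mig_detected = nrow(migs), n_down = n_down, n_up = n_up,
       pct_down = pct_down, pct_up = pct_up,
       fold_propensity = if (pct_up == 0) NA_real_ else pct_down / pct_up)
}

#' Write a summary table and plain-text report
#'
#' @param summary a `data.table` (e.g. from [summarize_categories()]).
#' @param dir output directory.
#' @param extra optional named list of scalar results appended to the text
#'   report.
#' @return `dir`, invisibly.
#' @export
write_report <- function(summary, dir, extra = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(summary, file.path(dir, "summary.tsv"), sep = "\t")
  txt <- c("misplice summary",
           "================",
           sprintf("%-12s %8s %8s", "category", "count", "pct"),
           summary[, sprintf("%-12s %8g %8g", category, count, pct)])
  if (!is.null(extra)) {
    txt <- c(txt, "", vapply(names(extra),
                             function(k) sprintf("%s: %s", k, format(extra[[k]])),
                             character(1L)))
  }
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
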