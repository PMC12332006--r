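#' Welch's unequal-variance t-test
#'
#' Two-tailed two-sample t-test with the Welch–Satterthwaite degrees of
#' freedom. Degenerate zero-variance cases (common when replicate MSI values
#' are all 0) are handled explicitly rather than propagating NaN: if both
#' groups have zero variance, equal means give `t = 0, p = 1` and unequal
#' means give a machine-minimum p sentinel with infinite `t`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list `(t, df, p)`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (d == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(d) * Inf, df = na + nb - 2, p = .Machine$double.xmin))
  }
  se2 <- va / na + vb / nb
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Audic–Claverie exact test for two counts
#'
#' Compares tag count `x` from a library of size `N1` with count `y` from a
#' library of size `N2`. The conditional law of `y` given `x`,
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`,
#' is the negative binomial with size `x+1` and success probability
#' `N1/(N1+N2)`, which is used for numerically stable tails. The two-sided
#' p-value is `2 * min(P(Y<=y|x), P(X<=x|y))` capped at 1, where the second
#' term is the lower tail of the swapped orientation (by an exact identity it
#' equals `P(Y>y|x)`, i.e. the upper tail with the observed point assigned to
#' the lower tail only); this form is symmetric under
#' `(x, y, N1, N2) -> (y, x, N2, N1)`, which the naive
#' `2 * min(P(Y<=y), P(Y>=y))` is not.
#'
#' @param x,y non-negative integer counts.
#' @param N1,N2 positive library sizes (`N1` belongs with `x`).
#' @return list `(p, p_point)`: two-sided p-value and the point probability
#'   `p(y|x)`.
#' @export
audic_claverie_test <- function(x, y, N1 = 1, N2 = 1) {
  if (x < 0 || y < 0 || x != round(x) || y != round(y)) {
    stop("counts must be non-negative integers")
  }
  if (N1 <= 0 || N2 <= 0) stop("library sizes must be positive")
  prob <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  lower_swapped <- stats::pnbinom(x, size = y + 1, prob = 1 - prob)
  list(p = min(1, 2 * min(lower, lower_swapped)),
       p_point = stats::dnbinom(y, size = x + 1, prob = prob))
}

#' Benjamini–Hochberg step-up FDR adjustment
#'
#' `q_i = min_{j >= rank(i)} p_(j) * m / j`, clipped to 1, returned in input
#' order. Ties are resolved by a stable sort on `(p, input index)`, so the
#' output is reproducible.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals, seq_len(m))  # stable on ties
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Chi-square goodness-of-fit test
#'
#' @param observed vector of counts (total > 0).
#' @param expected_proportions proportions summing to 1; every expected count
#'   must be positive.
#' @return list `(chi2, df, p)`.
#' @export
chi_square_gof <- function(observed, expected_proportions) {
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("expected proportions must sum to 1")
  }
  total <- sum(observed)
  if (total <= 0) stop("observed total must be positive")
  E <- total * expected_proportions
  if (any(E == 0)) stop("zero expected count")
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-condition design
#'
#' @param samples character vector of sample ids.
#' @param conditions character vector, same length, with exactly two levels.
#' @param treated,control which condition labels play the treated/control
#'   roles (defaults: first and second level in order of appearance).
#'   Condition roles always come from this object, never from column order.
#' @return list with class `"condition_design"`.
#' @export
condition_design <- function(samples, conditions, treated = NULL, control = NULL) {
  if (length(samples) != length(conditions)) stop("samples/conditions length mismatch")
  if (anyDuplicated(samples)) stop("every sample must be mapped exactly once")
  lev <- unique(conditions)
  if (length(lev) != 2L) stop("exactly two conditions required, got: ", length(lev))
  if (is.null(treated)) treated <- lev[1L]
  if (is.null(control)) control <- lev[2L]
  if (!all(c(treated, control) %in% lev)) stop("treated/control must name the two conditions")
  structure(list(samples = as.character(samples), conditions = as.character(conditions),
                 treated = treated, control = control), class = "condition_design")
}

design_samples <- function(design, role) {
  design$samples[design$conditions == design[[role]]]
}

#' MSI-based mis-splicing significance per intron
#'
#' For each intron, Welch's t-test compares replicate MSI values between the
#' two conditions. An intron is IR-significant iff the MSI_ret p-value is at
#' most `alpha` and MSI_ret is elevated in the treated condition by at least
#' `min_delta` percentage points; AS-significance is defined analogously on
#' MSI_AS. This is the raw-p path used for per-event calls; the FDR-filtered
#' IR-ratio path lives in [call_differential_retention()].
#'
#' @param msi table with `intron_id`, `sample_id`, `msi_ret`, `msi_as`
#'   ([quantify_introns()] output).
#' @param design [condition_design()] with >= 2 replicates per condition.
#' @param alpha p-value threshold (default 0.05).
#' @param min_delta minimum treated-minus-control MSI difference in
#'   percentage points (default 5).
#' @return `data.table` per intron: means per condition, deltas, p-values,
#'   `ir_sig`, `as_sig`.
#' @export
call_missplicing_msi <- function(msi, design, alpha = 0.05, min_delta = 5) {
  trt <- design_samples(design, "treated")
  ctl <- design_samples(design, "control")
  if (length(trt) < 2L || length(ctl) < 2L) stop(">= 2 replicates per condition required")
  dt <- as.data.table(msi)
  out <- dt[sample_id %in% c(trt, ctl), {
    at <- msi_ret[sample_id %in% trt]; ac <- msi_ret[sample_id %in% ctl]
    bt <- msi_as[sample_id %in% trt]; bc <- msi_as[sample_id %in% ctl]
    wr <- welch_t_test(at, ac)
    wa <- welch_t_test(bt, bc)
    list(mean_msi_ret_treated = mean(at), mean_msi_ret_control = mean(ac),
         delta_msi_ret = mean(at) - mean(ac), p_ret = wr$p, t_ret = wr$t,
         mean_msi_as_treated = mean(bt), mean_msi_as_control = mean(bc),
         delta_msi_as = mean(bt) - mean(bc), p_as = wa$p, t_as = wa$t)
  }, by = intron_id]
  out[, ir_sig := p_ret <= alpha & delta_msi_ret >= min_delta]
  out[, as_sig := p_as <= alpha & delta_msi_as >= min_delta]
  out[]
}

#' Four-rule differential intron-retention filter
#'
#' Applies the retention-calling rule set to a per-intron table:
#' `retained_in_treated` iff `fdr <= fdr_max` AND full (100%) intron coverage
#' in every treated sample AND treated IR ratio >= `ratio_min` AND treated
#' minus control IR ratio >= `delta_min`; `retained_in_control` is the
#' mirrored predicate; anything else is `not_significant`. Rows missing any
#' predicate input are excluded with a message.
#'
#' @param table data.frame with columns `intron_id`, `fdr`,
#'   `cov_ok_treated`, `cov_ok_control` (logical), `ratio_treated`,
#'   `ratio_control` (fractions in `[0, 1]`).
#' @param fdr_max FDR gate (default 0.05).
#' @param ratio_min minimum IR ratio in the called condition (default 0.10).
#' @param delta_min minimum IR-ratio excess over the other condition
#'   (default 0.05).
#' @return the table with a `call` column added.
#' @export
call_differential_retention <- function(table, fdr_max = 0.05,
                                        ratio_min = 0.10, delta_min = 0.05) {
  dt <- as.data.table(table)
  need <- c("intron_id", "fdr", "cov_ok_treated", "cov_ok_control",
            "ratio_treated", "ratio_control")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(dt[, need, with = FALSE])
  if (any(!ok)) {
    message("excluding ", sum(!ok), " intron(s) with missing predicate inputs")
    dt <- dt[ok]
  }
  dt[, call := "not_significant"]
  dt[fdr <= fdr_max & cov_ok_treated & ratio_treated >= ratio_min &
       ratio_treated - ratio_control >= delta_min, call := "retained_in_treated"]
  dt[call == "not_significant" &
       fdr <= fdr_max & cov_ok_control & ratio_control >= ratio_min &
       ratio_control - ratio_treated >= delta_min, call := "retained_in_control"]
  dt[]
}

#' Differential retention pipeline over a quantification table
#'
#' Aggregates a [quantify_introns()] table by condition and produces one
#' differential row per intron. Two methods mirror the two published
#' pipelines:
#' * `"msi"` — Welch's t-test on replicate MSI_ret/MSI_AS with raw p-value
#'   and minimum-delta gates ([call_missplicing_msi()]).
#' * `"irratio"` — the four-rule FDR filter on IR ratios: the
#'   Audic–Claverie test on boundary-read counts pooled per condition
#'   (library size = pooled locus depth), BH-adjusted across introns,
#'   combined with per-condition coverage and IR-ratio predicates
#'   ([call_differential_retention()]). Welch statistics on the replicate IR
#'   ratios are reported alongside.
#'
#' @param quant [quantify_introns()] output.
#' @param design [condition_design()].
#' @param method `"msi"` or `"irratio"`.
#' @param catalog optional catalog to annotate `gene_id`/`intron_class`.
#' @param alpha,min_delta gates for the msi method.
#' @param fdr_max,ratio_min,delta_min gates for the irratio method.
#' @return per-intron `data.table`; the irratio method adds `p_ac`, `fdr`
#'   and `call`, the msi method adds `ir_sig`/`as_sig`.
#' @export
diff_retention <- function(quant, design, method = c("msi", "irratio"),
                           catalog = NULL, alpha = 0.05, min_delta = 5,
                           fdr_max = 0.05, ratio_min = 0.10, delta_min = 0.05) {
  method <- match.arg(method)
  dt <- as.data.table(quant)
  if (method == "msi") {
    out <- call_missplicing_msi(dt, design, alpha = alpha, min_delta = min_delta)
  } else {
    trt <- design_samples(design, "treated")
    ctl <- design_samples(design, "control")
    if (length(trt) < 2L || length(ctl) < 2L) stop(">= 2 replicates per condition required")
    out <- dt[sample_id %in% c(trt, ctl), {
      rt <- ir_ratio[sample_id %in% trt]; rc <- ir_ratio[sample_id %in% ctl]
      xt <- sum(n5[sample_id %in% trt] + n3[sample_id %in% trt])
      xc <- sum(n5[sample_id %in% ctl] + n3[sample_id %in% ctl])
      Nt <- sum(depth[sample_id %in% trt]); Nc <- sum(depth[sample_id %in% ctl])
      w <- welch_t_test(rt, rc)
      ac <- audic_claverie_test(xt, xc, max(Nt, 1), max(Nc, 1))
      list(ratio_treated = mean(rt), ratio_control = mean(rc),
           delta = mean(rt) - mean(rc),
           t_stat = w$t, df = w$df, p_welch = w$p, p_ac = ac$p,
           cov_ok_treated = all(coverage[sample_id %in% trt] >= 1),
           cov_ok_control = all(coverage[sample_id %in% ctl] >= 1))
    }, by = intron_id]
    out[, fdr := bh_fdr(p_ac)]
    out <- call_differential_retention(out, fdr_max = fdr_max,
                                       ratio_min = ratio_min, delta_min = delta_min)
  }
  if (!is.null(catalog)) {
    ann <- as.data.table(catalog)[, .(intron_id, gene_id, intron_class)]
    out <- merge(ann, out, by = "intron_id")
  }
  out[]
}

#' Gene-level event categories
#'
#' Assigns each detected gene one category: `IR` (>= 1 IR-significant intron,
#' no AS), `AS` (the converse), `IR_and_AS` (at least one of each),
#' `unaffected` (detected, nothing significant). Genes present in the catalog
#' but with no intron in `calls` are reported as `not_detected` and excluded
#' from the detected total.
#'
#' @param calls per-intron table with `intron_id`, `ir_sig`, `as_sig`
#'   ([call_missplicing_msi()] output; a `call` column from the irratio path
#'   is accepted and mapped to `ir_sig`).
#' @param catalog intron catalog supplying `gene_id` and `intron_class`.
#' @param intron_class restrict to introns of this class (e.g. `"minor"` for
#'   a minor-intron-containing-gene summary); `NULL` keeps all.
#' @return list `(genes, counts)`: per-gene categories and a named count
#'   vector `(IR, AS, IR_and_AS, unaffected, detected)`.
#' @export
categorize_genes <- function(calls, catalog, intron_class = NULL) {
  cl <- as.data.table(calls)
  if (!"ir_sig" %in% names(cl) && "call" %in% names(cl)) {
    cl[, ir_sig := call == "retained_in_treated"]
  }
  if (!"as_sig" %in% names(cl)) cl[, as_sig := FALSE]
  cat_dt <- as.data.table(catalog)
  wanted_class <- intron_class
  ann <- cat_dt[, .(intron_id, gene_id, class = intron_class)]
  if (!is.null(wanted_class)) ann <- ann[class %in% wanted_class]
  dt <- merge(ann, cl[, .(intron_id, ir_sig, as_sig)], by = "intron_id")
  genes <- dt[, .(ir = any(ir_sig), as = any(as_sig)), by = gene_id]
  genes[, category := fifelse(ir & as, "IR_and_AS",
                       fifelse(ir, "IR", fifelse(as, "AS", "unaffected")))]
  missing_genes <- setdiff(unique(ann$gene_id), genes$gene_id)
  if (length(missing_genes) > 0L) {
    genes <- rbind(genes, data.table(gene_id = missing_genes, ir = NA, as = NA,
                                     category = "not_detected"))
  }
  counts <- c(
    IR = sum(genes$category == "IR"),
    AS = sum(genes$category == "AS"),
    IR_and_AS = sum(genes$category == "IR_and_AS"),
    unaffected = sum(genes$category == "unaffected"),
    detected = sum(genes$category != "not_detected")
  )
  list(genes = genes[], counts = counts)
}

#' Flanking major-intron analysis
#'
#' For each retained minor intron, identifies the major introns immediately
#' upstream/downstream by ordinal within each transcript (the catalog's
#' `tx_map` attribute) and reports whether those flanking majors are
#' themselves retained, plus the fraction of all retained major introns that
#' flank a minor intron versus those that do not. Minor introns first or last
#' in a transcript simply lack that flank.
#'
#' @param catalog classified catalog with its `tx_map` attribute.
#' @param calls per-intron table with a retention flag: `ir_sig` (msi path)
#'   or `call == "retained_in_treated"` (irratio path).
#' @return list `(pairs, summary)`; `pairs` has one row per (retained minor
#'   intron, flanking major intron) and `summary` the flanking/non-flanking
#'   retained-major fractions.
#' @export
flanking_major_ir <- function(catalog, calls) {
  cat_dt <- as.data.table(catalog)
  tx_map <- attr(catalog, "tx_map")
  if (is.null(tx_map)) stop("catalog lacks the tx_map attribute (re-run extract_introns)")
  cl <- as.data.table(calls)
  if (!"ir_sig" %in% names(cl)) {
    if (!"call" %in% names(cl)) stop("calls need ir_sig or call")
    cl[, ir_sig := call == "retained_in_treated"]
  }
  retained <- cl[ir_sig == TRUE, intron_id]
  ann <- merge(as.data.table(tx_map),
               cat_dt[, .(intron_id, intron_class)], by = "intron_id")
  minors <- ann[intron_class == "minor" & intron_id %in% retained]
  pairs <- data.table(minor_intron = character(), transcript_id = character(),
                      side = character(), flank_intron = character(),
                      flank_retained = logical())
  if (nrow(minors) > 0L) {
    pairs <- rbindlist(lapply(seq_len(nrow(minors)), function(i) {
      tx <- minors$transcript_id[i]; o <- minors$ordinal[i]
      nb <- ann[transcript_id == tx & ordinal %in% c(o - 1L, o + 1L) &
                  intron_class == "major"]
      if (nrow(nb) == 0L) return(NULL)
      data.table(minor_intron = minors$intron_id[i], transcript_id = tx,
                 side = ifelse(nb$ordinal < o, "upstream", "downstream"),
                 flank_intron = nb$intron_id,
                 flank_retained = nb$intron_id %in% retained)
    }))
    if (is.null(pairs) || nrow(pairs) == 0L) {
      pairs <- data.table(minor_intron = character(), transcript_id = character(),
                          side = character(), flank_intron = character(),
                          flank_retained = logical())
    }
  }
  majors_retained <- intersect(retained, cat_dt[intron_class == "major", intron_id])
  # majors flanking ANY minor intron (retained or not), for the denominator split
  minor_all <- ann[intron_class == "minor"]
  flank_any <- unique(unlist(lapply(seq_len(nrow(minor_all)), function(i) {
    ann[transcript_id == minor_all$transcript_id[i] &
          ordinal %in% c(minor_all$ordinal[i] - 1L, minor_all$ordinal[i] + 1L) &
          intron_class == "major", intron_id]
  })))
  n_flank <- sum(majors_retained %in% flank_any)
  summary <- data.table(
    n_retained_major = length(majors_retained),
    n_flanking = n_flank,
    n_non_flanking = length(majors_retained) - n_flank,
    frac_flanking = if (length(majors_retained) == 0L) NA_real_
                    else n_flank / length(majors_retained)
  )
  list(pairs = pairs, summary = summary)
}
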