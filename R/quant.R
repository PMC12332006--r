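#' Read spliced alignments into a block table
#'
#' SAM/BAM is decoded with Rsamtools/GenomicAlignments; CIGAR M/=/X consume
#' reference into aligned blocks, N opens a gap (a spliced-out region), D
#' consumes reference *within* a block, and I/S/H/P follow the SAM spec. SAM
#' input is converted to BAM in a temporary directory first.
#'
#' The block table is the package's lightweight alignment representation: one
#' row per aligned block, columns `read_id` (unique within a sample),
#' `sample_id`, `chrom`, `bstart`, `bend` (0-based half-open), with blocks of
#' a read sorted and non-overlapping.
#'
#' @param path SAM or BAM file (extension decides).
#' @param sample_id sample label to attach; defaults to the file name.
#' @return `data.table(read_id, sample_id, chrom, bstart, bend)`.
#' @export
read_alignments <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.(sam|bam)$", "", basename(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  galn <- GenomicAlignments::readGAlignments(path)
  grl <- GenomicAlignments::grglist(galn, drop.D.ranges = FALSE)
  u <- unlist(grl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(grl)
  dt <- data.table(
    read_id = rep(seq_along(grl), n),
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(u)),
    bstart = GenomicRanges::start(u) - 1L,
    bend = GenomicRanges::end(u)
  )
  setorder(dt, sample_id, read_id, bstart)
  dt[]
}

# Gaps (spliced-out regions) between consecutive blocks of each read, with
# the lengths of the two flanking blocks for the overhang rule.
read_gaps <- function(blocks) {
  b <- blocks[order(sample_id, read_id, bstart)]
  b[, {
    k <- .N
    if (k < 2L) NULL else list(
      chrom = chrom[1L],
      gstart = bend[-k], gend = bstart[-1L],
      llen = bend[-k] - bstart[-k], rlen = bend[-1L] - bstart[-1L]
    )
  }, by = .(sample_id, read_id)]
}

#' Count boundary, junction and coverage evidence for one intron
#'
#' Read classes for an intron `[start, end)` with minimum overhang `m`:
#' * `n5` — reads with one aligned block fully covering the 5' boundary
#'   window `[start-m, start+m)`; `n3` analogously at the 3' boundary.
#'   Boundary-spanning reads are evidence of an unspliced (retained) intron.
#' * `n_canonical` — spliced reads with a between-block gap exactly equal to
#'   the intron, both flanking blocks at least `m` long.
#' * `aberrant` — spliced reads whose gap shares exactly one endpoint with the
#'   intron (cryptic donor/acceptor), or whose gap contains the intron while
#'   skipping a flanking exon (gap reaches past the genomic extremes of the
#'   flanking exons), sharing neither endpoint; same overhang rule. Tallied
#'   per junction.
#' * `coverage` — fraction of intronic bases covered by at least one block.
#' * `depth` — number of reads with any block overlapping the locus
#'   (flanking-exon span `[up_start, down_end)`).
#' * `intronic_depth` — trimmed mean per-base depth across the intron after
#'   discarding the highest and lowest 5% of positions (the abundance fed to
#'   [ir_ratio()]).
#'
#' Boundary and junction windows are measured on the genome, so results are
#' strand-agnostic and independent of read order.
#'
#' @param intron single-row intron record (list or one-row data.frame with
#'   `chrom, start, end, up_start, down_end`).
#' @param reads block table ([read_alignments()]) for one sample.
#' @param min_overhang minimum anchored bases on each side of a boundary or
#'   junction; must be >= 1 (default 6).
#' @return list with `n5`, `n3`, `n_canonical`, `aberrant` (data.table
#'   `gstart, gend, count`), `coverage`, `depth`, `intronic_depth`.
#' @export
count_intron_evidence <- function(intron, reads, min_overhang = 6L) {
  if (min_overhang < 1L) stop("min_overhang must be >= 1")
  intron <- as.list(as.data.frame(intron))
  s <- intron$start; e <- intron$end; m <- as.integer(min_overhang)
  # genomic extremes of the flanking exons (up/down are transcript-oriented)
  flank_lo <- min(intron$up_start, intron$down_start)
  flank_hi <- max(intron$up_end, intron$down_end)
  b <- as.data.table(reads)[chrom == intron$chrom]
  empty <- list(n5 = 0L, n3 = 0L, n_canonical = 0L,
                aberrant = data.table(gstart = integer(), gend = integer(), count = integer()),
                coverage = 0, depth = 0L, intronic_depth = 0)
  if (nrow(b) == 0L) return(empty)

  n5 <- b[bstart <= s - m & bend >= s + m, uniqueN(read_id)]
  n3 <- b[bstart <= e - m & bend >= e + m, uniqueN(read_id)]

  g <- read_gaps(b)
  n_can <- 0L
  ab <- empty$aberrant
  if (nrow(g) > 0L) {
    g <- g[llen >= m & rlen >= m]
    n_can <- g[gstart == s & gend == e, .N]
    one_end <- g[xor(gstart == s, gend == e)]
    skip <- g[gstart <= s & gend >= e & gstart != s & gend != e &
                (gstart <= flank_lo | gend >= flank_hi)]
    ab_rows <- rbind(one_end[, .(gstart, gend)], skip[, .(gstart, gend)])
    if (nrow(ab_rows) > 0L) ab <- ab_rows[, .(count = .N), by = .(gstart, gend)]
  }

  ov <- b[bend > s & bstart < e]
  coverage <- 0; intronic_depth <- 0
  if (nrow(ov) > 0L) {
    ir <- IRanges::IRanges(start = pmax(ov$bstart, s) + 1L, end = pmin(ov$bend, e))
    cov <- IRanges::coverage(ir, width = e)
    depths <- as.integer(S4Vectors::window(cov, s + 1L, e))
    coverage <- mean(depths > 0L)
    intronic_depth <- trimmed_depth(depths)
  }
  depth <- b[bend > flank_lo & bstart < flank_hi, uniqueN(read_id)]
  list(n5 = n5, n3 = n3, n_canonical = n_can, aberrant = ab,
       coverage = coverage, depth = depth, intronic_depth = intronic_depth)
}

# Mean per-base depth after dropping the floor(5% n) highest and lowest
# positions; approximates IRFinder's exclusion of outlier features.
trimmed_depth <- function(depths, trim = 0.05) {
  n <- length(depths)
  k <- floor(trim * n)
  d <- sort(depths)
  if (n - 2L * k <= 0L) return(mean(d))
  mean(d[(k + 1L):(n - k)])
}

#' Mis-splicing index for intron retention
#'
#' `B = (n5 + n3) / 2` is one intron's worth of boundary evidence (the two
#' boundaries of a retained intron are symmetric, so their mean — not their
#' sum — counts retained molecules). In `"fraction"` mode (default, bounded):
#' `MSI_ret = 100 B / (B + n_canonical)`; in `"literal"` mode (the ratio *to*
#' canonical reads): `100 B / n_canonical`, returning `Inf` when
#' `n_canonical = 0` with `B > 0`. `B = 0` gives 0 in both modes. Vectorised.
#'
#' @param n5,n3 boundary read counts.
#' @param n_canonical canonical junction read count.
#' @param mode `"fraction"` or `"literal"`.
#' @return percentage(s); in fraction mode within `[0, 100]`.
#' @export
msi_ret <- function(n5, n3, n_canonical, mode = c("fraction", "literal")) {
  mode <- match.arg(mode)
  B <- (n5 + n3) / 2
  if (mode == "fraction") {
    ifelse(B == 0, 0, 100 * B / (B + n_canonical))
  } else {
    ifelse(B == 0, 0, ifelse(n_canonical == 0, Inf, 100 * B / n_canonical))
  }
}

#' Mis-splicing index for alternative splicing
#'
#' With `A` the total aberrant-junction read count and `C` the canonical
#' count: fraction mode `100 A / (A + C)`; literal mode `100 A / C` with the
#' same undefined-safe rule as [msi_ret()]. Vectorised.
#'
#' @param n_aberrant total aberrant junction reads.
#' @param n_canonical canonical junction reads.
#' @param mode `"fraction"` or `"literal"`.
#' @return percentage(s).
#' @export
msi_as <- function(n_aberrant, n_canonical, mode = c("fraction", "literal")) {
  mode <- match.arg(mode)
  A <- n_aberrant
  if (mode == "fraction") {
    ifelse(A == 0, 0, 100 * A / (A + n_canonical))
  } else {
    ifelse(A == 0, 0, ifelse(n_canonical == 0, Inf, 100 * A / n_canonical))
  }
}

#' IRFinder-style intron-retention ratio
#'
#' `intronic / (intronic + spliced)`, where `intronic` is the trimmed-mean
#' per-base intron depth and `spliced` the canonical junction count. Both
#' zero yields 0; negative input is an error. Vectorised.
#'
#' @param intronic_abundance non-negative intronic abundance.
#' @param spliced non-negative spliced (canonical junction) count.
#' @return fraction(s) in `[0, 1]`.
#' @export
ir_ratio <- function(intronic_abundance, spliced) {
  if (any(intronic_abundance < 0) || any(spliced < 0)) {
    stop("ir_ratio inputs must be non-negative")
  }
  tot <- intronic_abundance + spliced
  ifelse(tot == 0, 0, intronic_abundance / tot)
}

#' Quantify all introns across samples
#'
#' Vectorised multi-intron, multi-sample version of
#' [count_intron_evidence()] with the MSI and IR-ratio statistics appended.
#' Every (intron, sample) pair present in the design is reported, zero-filled
#' where no reads were seen.
#'
#' @param catalog intron catalog ([extract_introns()], classified or not).
#' @param reads block table with a `sample_id` column; may hold many samples.
#' @param min_overhang minimum overhang (default 6).
#' @param mode MSI mode, `"fraction"` (default) or `"literal"`.
#' @param samples sample ids to report (default: those present in `reads`).
#' @return `data.table` with one row per intron per sample: `intron_id`,
#'   `sample_id`, `n5`, `n3`, `n_canonical`, `n_aberrant`, `coverage`,
#'   `depth`, `intronic_depth`, `msi_ret`, `msi_as`, `ir_ratio`.
#' @export
quantify_introns <- function(catalog, reads, min_overhang = 6L,
                             mode = c("fraction", "literal"), samples = NULL) {
  mode <- match.arg(mode)
  if (min_overhang < 1L) stop("min_overhang must be >= 1")
  m <- as.integer(min_overhang)
  b <- as.data.table(reads)
  if (is.null(samples)) samples <- sort(unique(b$sample_id))
  cat_dt <- copy(as.data.table(catalog))
  cat_dt[, `:=`(flank_lo = pmin(up_start, down_start),
                flank_hi = pmax(up_end, down_end))]

  grid <- CJ(intron_id = cat_dt$intron_id, sample_id = samples, unique = TRUE)

  key5 <- cat_dt[, .(intron_id, chrom, lo = start - m, hi = start + m)]
  key3 <- cat_dt[, .(intron_id, chrom, lo = end - m, hi = end + m)]
  # non-equi joins rename join columns; carry explicit copies (bs/be) instead
  b2 <- b[, .(sample_id, read_id, chrom, bstart, bend, bs = bstart, be = bend)]
  cnt_boundary <- function(key) {
    hits <- b2[key, on = .(chrom, bstart <= lo, bend >= hi), nomatch = NULL,
               allow.cartesian = TRUE,
               .(intron_id = i.intron_id, sample_id, read_id)]
    if (nrow(hits) == 0L) return(data.table(intron_id = character(), sample_id = character(), N = integer()))
    unique(hits)[, .N, by = .(intron_id, sample_id)]
  }
  d5 <- cnt_boundary(key5); setnames(d5, "N", "n5")
  d3 <- cnt_boundary(key3); setnames(d3, "N", "n3")

  g <- read_gaps(b)
  if (nrow(g) > 0L) g <- g[llen >= m & rlen >= m]
  can <- data.table(intron_id = character(), sample_id = character(), N = integer())
  ab <- copy(can)  # setnames mutates by reference; never alias these
  if (nrow(g) > 0L) {
    g2 <- g[, .(sample_id, read_id, chrom, gstart, gend, gs = gstart, ge = gend)]
    can <- g2[cat_dt[, .(intron_id, chrom, start, end)],
              on = .(chrom, gstart = start, gend = end), nomatch = NULL,
              .(intron_id = i.intron_id, sample_id)][, .(N = .N), by = .(intron_id, sample_id)]
    # aberrant: share exactly one endpoint, or contain intron and skip a flank
    a5 <- g2[cat_dt[, .(intron_id, chrom, start, end)],
             on = .(chrom, gstart = start), nomatch = NULL,
             .(intron_id = i.intron_id, sample_id, ge, iend = i.end)][ge != iend]
    a3 <- g2[cat_dt[, .(intron_id, chrom, start, end)],
             on = .(chrom, gend = end), nomatch = NULL,
             .(intron_id = i.intron_id, sample_id, gs, istart = i.start)][gs != istart]
    sk <- g2[cat_dt[, .(intron_id, chrom, start, end, flank_lo, flank_hi)],
             on = .(chrom, gstart <= start, gend >= end), nomatch = NULL,
             allow.cartesian = TRUE,
             .(intron_id = i.intron_id, sample_id, gs, ge,
               istart = i.start, iend = i.end, flo = i.flank_lo, fhi = i.flank_hi)]
    sk <- sk[gs != istart & ge != iend & (gs <= flo | ge >= fhi)]
    ab_rows <- rbind(a5[, .(intron_id, sample_id)], a3[, .(intron_id, sample_id)],
                     sk[, .(intron_id, sample_id)])
    if (nrow(ab_rows) > 0L) ab <- ab_rows[, .(N = .N), by = .(intron_id, sample_id)]
  }
  setnames(can, "N", "n_canonical"); setnames(ab, "N", "n_aberrant")

  # coverage / trimmed depth / locus depth per (intron, sample)
  ovl <- b2[cat_dt[, .(intron_id, chrom, start, end)],
            on = .(chrom, bend > start, bstart < end), nomatch = NULL,
            allow.cartesian = TRUE,
            .(intron_id = i.intron_id, sample_id, bs, be, istart = i.start, iend = i.end)]
  covdt <- data.table(intron_id = character(), sample_id = character(),
                      coverage = numeric(), intronic_depth = numeric())
  if (nrow(ovl) > 0L) {
    covdt <- ovl[, {
      width <- iend[1L] - istart[1L]
      ir <- IRanges::IRanges(start = pmax(bs, istart[1L]) - istart[1L] + 1L,
                             end = pmin(be, iend[1L]) - istart[1L])
      depths <- as.integer(IRanges::coverage(ir, width = width))
      list(coverage = mean(depths > 0L), intronic_depth = trimmed_depth(depths))
    }, by = .(intron_id, sample_id)]
  }
  loc <- b2[cat_dt[, .(intron_id, chrom, flank_lo, flank_hi)],
            on = .(chrom, bend > flank_lo, bstart < flank_hi), nomatch = NULL,
            allow.cartesian = TRUE,
            .(intron_id = i.intron_id, sample_id, read_id)]
  locdt <- data.table(intron_id = character(), sample_id = character(), depth = integer())
  if (nrow(loc) > 0L) locdt <- unique(loc)[, .(depth = .N), by = .(intron_id, sample_id)]

  out <- Reduce(function(x, y) merge(x, y, by = c("intron_id", "sample_id"), all.x = TRUE),
                list(grid, d5, d3, can, ab, covdt, locdt))
  for (col in c("n5", "n3", "n_canonical", "n_aberrant", "depth")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  for (col in c("coverage", "intronic_depth")) {
    set(out, which(is.na(out[[col]])), col, 0)
  }
  out[, msi_ret := msi_ret(n5, n3, n_canonical, mode = mode)]
  out[, msi_as := msi_as(n_aberrant, n_canonical, mode = mode)]
  out[, ir_ratio := ir_ratio(intronic_depth, n_canonical)]
  setorder(out, intron_id, sample_id)
  out[]
}

#' Write a quantification table as TSV
#'
#' @param quant table from [quantify_introns()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_quant <- function(quant, path) {
  fwrite(quant, path, sep = "\t")
  invisible(path)
}
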