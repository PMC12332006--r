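#' Simulation configuration
#'
#' The generator's world: a single toy chromosome carrying non-overlapping
#' genes (one transcript each), a fraction of which contain exactly one
#' planted minor intron among major introns; two conditions with replicated
#' samples; and per-intron read sampling in three classes — retained
#' (exon–intron boundary evidence), aberrant (a fixed cryptic junction) and
#' canonical. Per intron and sample, the number of junction-informative
#' events is `D ~ Poisson(depth)`; each event is retained with probability
#' `rho`, aberrant with probability `alpha`, canonical otherwise, so the
#' expected fraction-mode MSI_ret is `100 rho` (at `alpha = 0`) and MSI_AS is
#' `100 alpha` (at `rho = 0`).
#'
#' Defaults state a world resembling a minor-spliceosome knockdown
#' experiment: 4 replicates per condition; minor introns retained at
#' `rho = 0.15` under treatment versus `0.02` in control with a small
#' aberrant fraction, major introns near-clean in both conditions.
#'
#' @param n_genes number of genes (default 12).
#' @param exons_per_gene integer range `c(min, max)` (default 4..6).
#' @param exon_len,intron_len length ranges in nt (defaults 80..160, 150..300).
#' @param minor_intron_fraction fraction of genes carrying one minor intron
#'   (default 0.5).
#' @param read_length read length in nt (default 100; must exceed
#'   `2 * min_overhang`).
#' @param min_overhang minimum overhang `m` the reads are built to satisfy
#'   (default 6).
#' @param depth Poisson mean junction depth per intron per sample
#'   (default 200).
#' @param replicates replicates per condition (default 4).
#' @param conditions two condition labels (default treated/control).
#' @param rho named list of two-element vectors `c(treated, control)` of true
#'   retention fractions per intron class (`minor`, `major`).
#' @param alpha same structure for aberrant-splicing fractions.
#' @param tiling if `TRUE` (default) every retained event additionally lays a
#'   deterministic set of intron-body reads covering each intronic base, so
#'   the 100%-coverage filter is satisfiable and intronic depth scales with
#'   retention; set `FALSE` to exercise the coverage gate.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return list with class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 12L, exons_per_gene = c(4L, 6L),
                       exon_len = c(80L, 160L), intron_len = c(150L, 300L),
                       minor_intron_fraction = 0.5,
                       read_length = 100L, min_overhang = 6L, depth = 200,
                       replicates = 4L,
                       conditions = c("treated", "control"),
                       rho = list(minor = c(treated = 0.15, control = 0.02),
                                  major = c(treated = 0.01, control = 0.01)),
                       alpha = list(minor = c(treated = 0.03, control = 0.01),
                                    major = c(treated = 0.005, control = 0.005)),
                       tiling = TRUE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              minor_intron_fraction = minor_intron_fraction,
              read_length = as.integer(read_length), min_overhang = as.integer(min_overhang),
              depth = depth, replicates = as.integer(replicates),
              conditions = conditions, rho = rho, alpha = alpha,
              tiling = isTRUE(tiling), seed = as.integer(seed))
  if (cfg$read_length <= 2L * cfg$min_overhang) {
    stop("read_length must exceed 2 * min_overhang")
  }
  if (any(cfg$exon_len <= 0L) || any(cfg$intron_len <= 0L)) stop("lengths must be positive")
  if (cfg$intron_len[1L] < 41L) stop("intron_len minimum must be >= 41 for branch-point planting")
  # exons must be long enough that (a) the cryptic acceptor sits 50 nt inside
  # an exon with an m-anchored block beyond it, and (b) reads anchored across
  # the cryptic junction can avoid neighbouring splice-site windows:
  # E >= (L - 2m + 52) / 2 and E >= 51
  min_exon <- max(51L, as.integer(ceiling((cfg$read_length - 2L * cfg$min_overhang + 52L) / 2)))
  if (cfg$exon_len[1L] < min_exon) {
    stop("exon_len minimum must be >= ", min_exon,
         " for this read_length/min_overhang (cryptic-junction feasibility)")
  }
  for (cls in c("minor", "major")) {
    r <- cfg$rho[[cls]]; a <- cfg$alpha[[cls]]
    if (any(r < 0) || any(a < 0) || any(r + a > 1)) {
      stop("need 0 <= rho, alpha and rho + alpha <= 1 per class/condition")
    }
  }
  if (length(cfg$conditions) != 2L) stop("exactly two conditions")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# sample() treats a length-1 numeric vector as 1:x; this does not
resample <- function(x, ...) x[sample.int(length(x), ...)]

# overwrite genomic interval [start, end) (0-based) with seq given in
# TRANSCRIPT orientation; reverse-complemented first for '-' strand genes
plant <- function(chromseq, start, seq, strand) {
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  paste0(substr(chromseq, 1L, start), seq,
         substr(chromseq, start + nchar(seq) + 1L, nchar(chromseq)))
}

# genomic coordinates (0-based) of a width-w element at transcript-oriented
# intron offset `off` (0-based from the intron 5' end)
oriented_pos <- function(start, end, strand, off, w) {
  if (strand == "+") start + off else end - off - w
}

#' Generate a toy genome, annotation and minor-intron list
#'
#' Deterministic given `config$seed`. Genes are laid out left to right on one
#' chromosome with intergenic gaps; strands alternate. A configured fraction
#' of genes carries exactly one minor intron at a random interior position:
#' minor introns receive the model 5' splice-site consensus at intron
#' positions +1..+8 and the branch-point consensus ending 16 nt upstream of
#' the 3' splice site (inside the default -40..-5 search window), ending in
#' AG; all other introns get plain GT..AG ends. Major introns that would
#' accidentally score as minor under `motif` are re-randomised, so motif
#' classification can recover the planted set exactly.
#'
#' @param config [sim_config()].
#' @param motif [motif_model()] whose consensus strings are planted
#'   (default model).
#' @param dir if non-NULL, writes `genome.fa`, `annotation.gtf`,
#'   `minor_introns.tsv` there.
#' @return list: `genome` (named character), `transcripts` (exon table),
#'   `catalog` (classified intron catalog with planted truth in
#'   `intron_class`), `minor_list`, `config`, and file paths when `dir` was
#'   given.
#' @export
make_toy_reference <- function(config = sim_config(), motif = motif_model(), dir = NULL) {
  set.seed(config$seed)
  pad <- 300L
  chrom <- "chrT"
  genes <- vector("list", config$n_genes)
  pos <- pad
  n_mig <- round(config$n_genes * config$minor_intron_fraction)
  mig_genes <- sort(sample.int(config$n_genes, n_mig))
  for (gi in seq_len(config$n_genes)) {
    k <- resample(seq.int(config$exons_per_gene[1L], config$exons_per_gene[2L]), 1L)
    elens <- resample(seq.int(config$exon_len[1L], config$exon_len[2L]), k, replace = TRUE)
    ilens <- if (k > 1L) {
      resample(seq.int(config$intron_len[1L], config$intron_len[2L]), k - 1L, replace = TRUE)
    } else integer()
    strand <- if (gi %% 2L == 1L) "+" else "-"
    starts <- integer(k); ends <- integer(k)
    p <- pos
    for (j in seq_len(k)) {
      starts[j] <- p; ends[j] <- p + elens[j]
      p <- ends[j] + if (j < k) ilens[j] else 0L
    }
    minor_ord <- NA_integer_
    if (gi %in% mig_genes && k > 1L) {
      minor_ord <- sample.int(k - 1L, 1L)  # ordinal in transcript orientation
    }
    genes[[gi]] <- list(gene_id = sprintf("g%03d", gi),
                        transcript_id = sprintf("g%03d.t1", gi),
                        strand = strand, exon_start = starts, exon_end = ends,
                        minor_ordinal = minor_ord)
    pos <- p + pad
  }
  glen <- pos + pad
  chromseq <- rand_dna(glen)

  tx <- rbindlist(lapply(genes, function(g) {
    data.table(transcript_id = g$transcript_id, gene_id = g$gene_id,
               chrom = chrom, strand = g$strand,
               exon_start = g$exon_start, exon_end = g$exon_end)
  }))
  catalog <- extract_introns(tx)
  tx_map <- attr(catalog, "tx_map")

  # planted class by (gene, transcript-oriented ordinal)
  minor_ids <- character()
  for (g in genes) {
    if (is.na(g$minor_ordinal)) next
    id <- tx_map[transcript_id == g$transcript_id & ordinal == g$minor_ordinal, intron_id]
    minor_ids <- c(minor_ids, id)
  }
  catalog[, intron_class := ifelse(intron_id %in% minor_ids, "minor", "major")]

  five_cons <- paste(rownames(motif$pwm_5ss)[apply(motif$pwm_5ss, 2L, which.max)], collapse = "")
  bps_cons <- paste(rownames(motif$pwm_bps)[apply(motif$pwm_bps, 2L, which.max)], collapse = "")
  wb <- nchar(bps_cons)
  plant_intron <- function(chromseq, s, e, strand, class) {
    L <- e - s
    if (class == "minor") {
      chromseq <- plant(chromseq, oriented_pos(s, e, strand, 0L, nchar(five_cons)),
                        five_cons, strand)
      # branch point ends 16 nt upstream of the 3'ss: offsets L-16-wb .. L-17
      chromseq <- plant(chromseq, oriented_pos(s, e, strand, L - 16L - wb, wb),
                        bps_cons, strand)
      chromseq <- plant(chromseq, oriented_pos(s, e, strand, L - 2L, 2L), "AG", strand)
    } else {
      chromseq <- plant(chromseq, oriented_pos(s, e, strand, 0L, 2L), "GT", strand)
      chromseq <- plant(chromseq, oriented_pos(s, e, strand, L - 2L, 2L), "AG", strand)
    }
    chromseq
  }
  for (i in seq_len(nrow(catalog))) {
    chromseq <- plant_intron(chromseq, catalog$start[i], catalog$end[i],
                             catalog$strand[i], catalog$intron_class[i])
  }
  # guard: re-randomise any major intron that accidentally scores as minor
  genome <- setNames(chromseq, chrom)
  for (i in which(catalog$intron_class == "major")) {
    for (try in 1:10) {
      sq <- intron_sequence(genome, chrom, catalog$start[i], catalog$end[i], catalog$strand[i])
      ok5 <- score_motif(substr(sq, 1L, ncol(motif$pwm_5ss)), motif$pwm_5ss,
                         motif$background) >= motif$min_score_5ss
      okb <- best_bps_score(sq, motif) >= motif$min_score_bps
      if (!(ok5 && okb)) break
      L <- catalog$end[i] - catalog$start[i]
      body <- rand_dna(L - 4L)
      chromseq <- plant(genome[[chrom]],
                        oriented_pos(catalog$start[i], catalog$end[i], catalog$strand[i], 2L, L - 4L),
                        body, catalog$strand[i])
      chromseq <- plant_intron(chromseq, catalog$start[i], catalog$end[i],
                               catalog$strand[i], "major")
      genome <- setNames(chromseq, chrom)
    }
  }

  minor_list <- catalog[intron_class == "minor", .(chrom, start, end, strand)]
  out <- list(genome = genome, transcripts = tx, catalog = catalog,
              minor_list = minor_list, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
    gtf <- file.path(dir, "annotation.gtf")
    lines <- tx[, sprintf(
      '%s\tmisplice\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      chrom, exon_start + 1L, exon_end, strand, gene_id, transcript_id)]
    writeLines(lines, gtf)
    ml <- file.path(dir, "minor_introns.tsv")
    fwrite(minor_list, ml, sep = "\t")
    out$paths <- list(fasta = fa, gtf = gtf, minor_list = ml)
  }
  out
}

#' Simulate replicated read sets with known mis-splicing truth
#'
#' One RNG stream per sample, keyed by `(seed, sample index)`, so samples are
#' independent and the whole output is reproducible. Per intron and sample,
#' `D ~ Poisson(depth)` events are drawn and split multinomially into
#' retained / aberrant / canonical classes with the class- and
#' condition-specific `(rho, alpha)`:
#' * a retained event emits one exon–intron boundary read at *each* boundary
#'   (so `n5 = n3 =` retained events, and the mean-of-boundaries MSI_ret
#'   estimator is unbiased: `E[MSI_ret] = 100 rho` at `alpha = 0`);
#' * an aberrant event emits a spliced read across the intron's fixed cryptic
#'   junction (alternative 3' splice site 50 nt into the downstream exon,
#'   sharing the canonical donor);
#' * a canonical event emits a spliced read with gap exactly the intron.
#'
#' Read start positions are drawn uniformly over the placements that satisfy
#' the `min_overhang` rule — and clipped away from neighbouring splice-site
#' windows — so no emitted read is ever discarded or miscounted by the
#' counter. When tiling is enabled, each retained event also lays one
#' deterministic read set over the intron body (clipped to the intron, so
#' tiling never touches a boundary window): coverage is complete whenever
#' retention occurred, and the trimmed per-base intron depth tracks the
#' retained-event count so the IR ratio lands near `rho`.
#'
#' @param reference output of [make_toy_reference()].
#' @param config [sim_config()]; defaults to the reference's own config.
#' @param dir if non-NULL, writes one coordinate-sorted `<sample>.sam` per
#'   sample plus `truth.tsv`.
#' @return list: `reads` (block table for all samples), `truth` (per intron
#'   per sample realized class counts), `design` ([condition_design()]),
#'   and `sam_paths`/`truth_path` when `dir` was given.
#' @export
simulate_reads <- function(reference, config = reference$config, dir = NULL) {
  cat_dt <- reference$catalog
  L <- config$read_length; m <- config$min_overhang
  if (L <= 2L * m) stop("read_length must exceed 2 * min_overhang")
  cond <- config$conditions
  samples <- data.table(
    sample_id = paste0(rep(cond, each = config$replicates), "_", seq_len(config$replicates)),
    condition = rep(cond, each = config$replicates)
  )
  all_reads <- vector("list", nrow(samples))
  all_truth <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    set.seed((config$seed %% 1000000L) * 1000L + si)
    smp <- samples$sample_id[si]
    cnd <- samples$condition[si]
    cond_role <- if (cnd == cond[1L]) "treated" else "control"
    blocks <- vector("list", nrow(cat_dt))
    truth <- vector("list", nrow(cat_dt))
    rid0 <- 0L
    for (ii in seq_len(nrow(cat_dt))) {
      s <- cat_dt$start[ii]; e <- cat_dt$end[ii]
      strand <- cat_dt$strand[ii]
      cls <- cat_dt$intron_class[ii]
      if (is.na(cls)) cls <- "major"
      # genomic-left / genomic-right flanking exon bounds (up/down are stored
      # in transcript orientation)
      if (strand == "+") {
        left_start <- cat_dt$up_start[ii]; right_end <- cat_dt$down_end[ii]
      } else {
        left_start <- cat_dt$down_start[ii]; right_end <- cat_dt$up_end[ii]
      }
      rho <- config$rho[[cls]][[cond_role]]
      alpha <- config$alpha[[cls]][[cond_role]]
      D <- stats::rpois(1L, config$depth)
      nclass <- if (D > 0L) {
        as.integer(stats::rmultinom(1L, D, c(rho, alpha, 1 - rho - alpha)))
      } else c(0L, 0L, 0L)
      n_ret <- nclass[1L]; n_ab <- nclass[2L]; n_can <- nclass[3L]

      # placements are clipped so no block reaches into a NEIGHBOURING
      # splice-site window with >= m overhang: block starts stay right of
      # left_start - m, block ends stay left of right_end + m
      unif <- function(n, lo, hi) {
        if (hi < lo) stop("infeasible read placement for intron ", cat_dt$intron_id[ii])
        lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
      }
      rows <- list()
      if (n_ret > 0L) {
        # one boundary read at each boundary per retained event
        u5 <- unif(n_ret, max(s + m - L, left_start - m + 1L), s - m)
        u3 <- unif(n_ret, e + m - L, min(e - m, right_end + m - 1L - L))
        rows[[length(rows) + 1L]] <- data.table(
          read_id = rid0 + seq_len(2L * n_ret),
          bstart = c(u5, u3), bend = c(u5, u3) + L)
        rid0 <- rid0 + 2L * n_ret
      }
      spliced <- function(n, gap_s, gap_e, rid0) {
        # left anchor length l: l <= gap_s - (left_start - m + 1) keeps the
        # left block clear of the left neighbour window; L - l <=
        # right_end + m - 1 - gap_e keeps the right block clear of the right
        l <- unif(n, max(m, L - (right_end + m - 1L - gap_e)),
                  min(L - m, gap_s - left_start + m - 1L))
        data.table(read_id = rid0 + rep(seq_len(n), 2L),
                   bstart = c(gap_s - l, rep(gap_e, n)),
                   bend = c(rep(gap_s, n), gap_e + L - l))
      }
      if (n_can > 0L) {
        rows[[length(rows) + 1L]] <- spliced(n_can, s, e, rid0)
        rid0 <- rid0 + n_can
      }
      if (n_ab > 0L) {
        # cryptic 3' splice site 50 nt into the transcript-downstream exon,
        # sharing the canonical donor (strand-oriented)
        if (strand == "+") {
          rows[[length(rows) + 1L]] <- spliced(n_ab, s, e + 50L, rid0)
        } else {
          rows[[length(rows) + 1L]] <- spliced(n_ab, s - 50L, e, rid0)
        }
        rid0 <- rid0 + n_ab
      }
      n_tile <- 0L
      if (config$tiling && n_ret > 0L) {
        # one deterministic tiling set over the intron body per retained
        # event: guarantees 100% coverage whenever retention was seen, and
        # makes per-base intron depth track the retained-molecule count so
        # the IR ratio lands near rho
        starts <- seq.int(s, e - 1L, by = L)
        tb <- data.table(
          read_id = rid0 + rep(seq_len(n_ret * length(starts))),
          bstart = rep(starts, n_ret))
        tb[, bend := pmin(bstart + L, e)]
        n_tile <- nrow(tb)
        rows[[length(rows) + 1L]] <- tb
        rid0 <- rid0 + n_tile
      }
      if (length(rows) > 0L) {
        rr <- rbindlist(rows)
        rr[, `:=`(chrom = cat_dt$chrom[ii])]
        blocks[[ii]] <- rr
      }
      truth[[ii]] <- data.table(
        intron_id = cat_dt$intron_id[ii], intron_class = cls, sample_id = smp,
        condition = cnd, rho = rho, alpha = alpha,
        n_ret = n_ret, n_can = n_can, n_ab = n_ab, n_tile = n_tile)
    }
    rd <- rbindlist(blocks)
    if (nrow(rd) > 0L) rd[, sample_id := smp]
    all_reads[[si]] <- rd
    all_truth[[si]] <- rbindlist(truth)
  }
  reads <- rbindlist(all_reads, use.names = TRUE)
  setcolorder(reads, c("read_id", "sample_id", "chrom", "bstart", "bend"))
  setorder(reads, sample_id, read_id, bstart)
  truth <- rbindlist(all_truth)
  design <- condition_design(samples$sample_id, samples$condition,
                             treated = cond[1L], control = cond[2L])
  out <- list(reads = reads, truth = truth, design = design, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$sam_paths <- vapply(samples$sample_id, function(smp) {
      write_sam(reads[sample_id == smp], reference$genome,
                file.path(dir, paste0(smp, ".sam")))
    }, character(1L))
    out$truth_path <- file.path(dir, "truth.tsv")
    fwrite(truth, out$truth_path, sep = "\t")
  }
  out
}

#' Write a block table as a valid SAM file
#'
#' Emits a coordinate-sorted SAM with `@SQ` headers; each read's CIGAR is
#' `<len>M` per block joined by `<gap>N`, and the sequence is taken from the
#' genome blocks (so seq length always matches the CIGAR).
#'
#' @param blocks block table for one sample.
#' @param genome named character vector of chromosome sequences.
#' @param path output `.sam` path.
#' @return `path`, invisibly usable; returned visibly for convenience.
#' @export
write_sam <- function(blocks, genome, path) {
  b <- as.data.table(blocks)[order(chrom, bstart)]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  reads <- b[, {
    o <- order(bstart)
    bs <- bstart[o]; be <- bend[o]
    cig <- paste0(be[1L] - bs[1L], "M")
    if (.N > 1L) {
      for (j in 2L:.N) {
        cig <- paste0(cig, bs[j] - be[j - 1L], "N", be[j] - bs[j], "M")
      }
    }
    sq <- paste(substring(genome[[chrom[1L]]], bs + 1L, be), collapse = "")
    list(pos = bs[1L] + 1L, cigar = cig, seq = sq)
  }, by = .(chrom, read_id)]
  setorder(reads, chrom, pos)
  lines <- reads[, sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                           read_id, chrom, pos, cigar, seq)]
  writeLines(c(hdr, lines), path)
  path
}

#' Verify a simulation's truth table against its emitted alignments
#'
#' Re-counts read classes from the SAM files (or an in-memory block table)
#' with the quantification engine and checks equality with the realized
#' counts recorded in the truth table: `n5 = n3 = n_ret`,
#' `n_canonical = n_can`, `n_aberrant = n_ab`. Keyed by
#' `(intron_id, sample_id)`, so row order in the truth table is irrelevant.
#'
#' @param sam_files character vector of SAM/BAM paths, or a block table.
#' @param truth truth table from [simulate_reads()].
#' @param catalog the reference catalog.
#' @param min_overhang overhang used at generation time.
#' @return list `(ok, mismatches)`; `mismatches` itemizes every disagreeing
#'   (intron, sample, field) with expected and observed values.
#' @export
verify_truth <- function(sam_files, truth, catalog, min_overhang = 6L) {
  reads <- if (is.character(sam_files)) {
    rbindlist(lapply(sam_files, read_alignments))
  } else {
    as.data.table(sam_files)
  }
  q <- quantify_introns(catalog, reads, min_overhang = min_overhang,
                        samples = unique(truth$sample_id))
  tr <- as.data.table(truth)
  cmp <- merge(tr, q, by = c("intron_id", "sample_id"), all.x = TRUE)
  long <- rbind(
    cmp[, .(intron_id, sample_id, field = "n5", expected = n_ret, observed = n5)],
    cmp[, .(intron_id, sample_id, field = "n3", expected = n_ret, observed = n3)],
    cmp[, .(intron_id, sample_id, field = "n_canonical", expected = n_can, observed = n_canonical)],
    cmp[, .(intron_id, sample_id, field = "n_aberrant", expected = n_ab, observed = n_aberrant)]
  )
  mism <- long[is.na(observed) | expected != observed]
  list(ok = nrow(mism) == 0L, mismatches = mism[])
}
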