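# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops over one read at a time, independent of
# the data.table join machinery in the package.

# one intron record as count_intron_evidence expects it
toy_intron <- function(start = 100L, end = 200L, chrom = "c", strand = "+",
                       up_start = start - 100L, up_end = start,
                       down_start = end, down_end = end + 100L) {
  list(intron_id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
       gene_id = "g", transcript_ids = "t", chrom = chrom, start = start,
       end = end, strand = strand, intron_class = "minor", ordinal = 1L,
       up_start = up_start, up_end = up_end,
       down_start = down_start, down_end = down_end)
}

# blocks table from a list of reads, each read a list of c(start, end) blocks
toy_reads <- function(block_list, chrom = "c", sample_id = "s1") {
  if (length(block_list) == 0L) {
    return(data.table::data.table(read_id = integer(), sample_id = character(),
                                  chrom = character(), bstart = integer(),
                                  bend = integer()))
  }
  rows <- do.call(rbind, lapply(seq_along(block_list), function(i) {
    b <- block_list[[i]]
    if (is.numeric(b)) b <- list(b)
    do.call(rbind, lapply(b, function(x) {
      data.frame(read_id = i, sample_id = sample_id, chrom = chrom,
                 bstart = x[1], bend = x[2])
    }))
  }))
  data.table::as.data.table(rows)
}

# brute-force per-read rule checker (oracle for count_intron_evidence)
brute_count <- function(intron, reads, m) {
  s <- intron$start; e <- intron$end
  flank_lo <- min(intron$up_start, intron$down_start)
  flank_hi <- max(intron$up_end, intron$down_end)
  n5 <- 0L; n3 <- 0L; ncan <- 0L; depth <- 0L
  ab <- character()
  dvec <- integer(e - s)
  rd <- as.data.frame(reads)
  rd <- rd[rd$chrom == intron$chrom, , drop = FALSE]
  for (rid in unique(rd$read_id)) {
    blk <- rd[rd$read_id == rid, , drop = FALSE]
    blk <- blk[order(blk$bstart), , drop = FALSE]
    hit5 <- FALSE; hit3 <- FALSE; locus <- FALSE
    for (i in seq_len(nrow(blk))) {
      b1 <- blk$bstart[i]; b2 <- blk$bend[i]
      if (b1 <= s - m && b2 >= s + m) hit5 <- TRUE
      if (b1 <= e - m && b2 >= e + m) hit3 <- TRUE
      if (b2 > s && b1 < e) {
        idx <- (max(b1, s) + 1L - s):(min(b2, e) - s)
        dvec[idx] <- dvec[idx] + 1L
      }
      if (b2 > flank_lo && b1 < flank_hi) locus <- TRUE
    }
    if (hit5) n5 <- n5 + 1L
    if (hit3) n3 <- n3 + 1L
    if (locus) depth <- depth + 1L
    if (nrow(blk) > 1L) {
      for (i in seq_len(nrow(blk) - 1L)) {
        gstart <- blk$bend[i]; gend <- blk$bstart[i + 1L]
        llen <- blk$bend[i] - blk$bstart[i]
        rlen <- blk$bend[i + 1L] - blk$bstart[i + 1L]
        if (llen < m || rlen < m) next
        if (gstart == s && gend == e) {
          ncan <- ncan + 1L
        } else if (xor(gstart == s, gend == e)) {
          ab <- c(ab, paste(gstart, gend))
        } else if (gstart <= s && gend >= e &&
                   (gstart <= flank_lo || gend >= flank_hi)) {
          ab <- c(ab, paste(gstart, gend))
        }
      }
    }
  }
  k <- floor(0.05 * length(dvec))
  dsort <- sort(dvec)
  trimmed <- if (length(dvec) - 2L * k <= 0L) mean(dsort) else
    mean(dsort[(k + 1L):(length(dvec) - k)])
  list(n5 = n5, n3 = n3, n_canonical = ncan,
       aberrant = sort(ab), coverage = mean(dvec > 0L), depth = depth,
       intronic_depth = trimmed)
}

# randomized small counting instance: intron + <= n_max reads mixing
# unspliced, canonical, near-miss and exon-skipping geometries
rand_instance <- function(seed, n_max = 50L) {
  set.seed(seed)
  s <- sample(150:250, 1L)
  e <- s + sample(30:120, 1L)
  up_len <- sample(20:80, 1L); down_len <- sample(20:80, 1L)
  intron <- toy_intron(start = s, end = e,
                       up_start = s - up_len, down_end = e + down_len)
  m <- sample(c(3L, 6L), 1L)
  n <- sample(0:n_max, 1L)
  mk_read <- function() {
    if (runif(1) < 0.45) {  # unspliced block near a boundary or inside
      len <- sample(6:40, 1L)
      anchor <- sample(c(s, e, sample(s:e, 1L)), 1L)
      st <- anchor + sample((-len):len, 1L)
      list(c(st, st + len))
    } else {                # spliced read; endpoints drawn near/at the intron
      cand_s <- c(s, s, s + sample(-15:15, 1L), intron$up_start - sample(0:10, 1L))
      cand_e <- c(e, e, e + sample(-15:15, 1L), intron$down_end + sample(0:10, 1L))
      gs <- sample(cand_s, 1L); ge <- sample(cand_e, 1L)
      if (ge <= gs) return(list(c(gs - 10L, gs + 10L)))
      l1 <- sample(2:20, 1L); l2 <- sample(2:20, 1L)
      blocks <- list(c(gs - l1, gs), c(ge, ge + l2))
      if (runif(1) < 0.15) {  # occasionally a third block / second gap
        g2 <- ge + l2 + sample(5:20, 1L)
        blocks[[3L]] <- c(g2, g2 + sample(3:15, 1L))
      }
      blocks
    }
  }
  reads <- if (n == 0L) {
    data.table::data.table(read_id = integer(), sample_id = character(),
                           chrom = character(), bstart = integer(), bend = integer())
  } else {
    toy_reads(replicate(n, mk_read(), simplify = FALSE))
  }
  list(intron = intron, reads = reads, m = m)
}

ab_key <- function(ab_table) {
  if (nrow(ab_table) == 0L) return(character())
  sort(rep(paste(ab_table$gstart, ab_table$gend), ab_table$count))
}

# brute-force BH step-up, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o][rank_i:m] * m / (rank_i:m)))
  }
  q
}

# direct summation of the Audic-Claverie conditional law; the second tail is
# the lower tail of the swapped orientation (symmetric two-sided form)
brute_ac <- function(x, y, N1, N2) {
  pmf <- function(k, x0, r) exp(k * log(r) + lgamma(x0 + k + 1) - lgamma(x0 + 1) -
                                  lgamma(k + 1) - (x0 + k + 1) * log(1 + r))
  lower <- sum(vapply(0:y, pmf, numeric(1L), x0 = x, r = N2 / N1))
  lower_swapped <- sum(vapply(0:x, pmf, numeric(1L), x0 = y, r = N1 / N2))
  list(p = min(1, 2 * min(lower, lower_swapped)), p_point = pmf(y, x, N2 / N1))
}

# small fast simulation world shared by several tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 6L, exons_per_gene = c(3L, 4L), depth = 80, seed = 11L),
    list(...))
  do.call(sim_config, args)
}
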