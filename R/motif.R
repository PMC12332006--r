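#' Build a position-probability matrix from a consensus string
#'
#' Each column gives probability `major` to the consensus base and splits the
#' remainder over the other three bases (defaults 0.91 / 0.03, which sum to
#' one). Probabilities below `floor` are raised to it and the column is
#' renormalised, so log-odds scores stay finite.
#'
#' @param consensus nucleotide string over A,C,G,T.
#' @param major probability of the consensus base per column.
#' @param floor minimum probability for any base.
#' @return 4 x nchar(consensus) matrix with rownames A,C,G,T; columns sum to 1.
#' @export
build_pwm <- function(consensus, major = 0.91, floor = 0.001) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(chars %in% bases)) stop("consensus must be over A,C,G,T")
  minor <- (1 - major) / 3
  pwm <- matrix(minor, nrow = 4L, ncol = length(chars), dimnames = list(bases, NULL))
  pwm[cbind(match(chars, bases), seq_along(chars))] <- major
  pwm <- pmax(pwm, floor)
  sweep(pwm, 2L, colSums(pwm), "/")
}

#' Log-odds score of a sequence against a position-probability matrix
#'
#' `score = sum_i log2(p_i(seq_i) / bg(seq_i))`, in bits. `N` bases contribute
#' zero. Deterministic; errors if the sequence length does not match the PWM
#' width.
#'
#' @param seq nucleotide string (A,C,G,T,N), same length as `ncol(pwm)`.
#' @param pwm position-probability matrix with rownames A,C,G,T.
#' @param background base frequencies, named or in A,C,G,T order; default uniform.
#' @return numeric log-odds score in bits.
#' @export
score_motif <- function(seq, pwm, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (length(chars) != ncol(pwm)) {
    stop("sequence length ", length(chars), " != PWM width ", ncol(pwm))
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(names(background))) names(background) <- bases
  idx <- match(chars, bases)
  keep <- !is.na(idx)  # N (or other ambiguity codes) contribute 0
  if (!all(chars[!keep] == "N")) stop("bases must be in {A,C,G,T,N}")
  if (!any(keep)) return(0)
  cols <- which(keep)
  sum(log2(pwm[cbind(idx[keep], cols)] / background[bases[idx[keep]]]))
}

#' Splice-motif model for minor-intron classification
#'
#' Bundles a 5' splice-site PWM (intron positions +1..+8), a branch-point
#' PWM (width 9) searched in a window upstream of the 3' splice site (best
#' placement wins), a background distribution, and per-motif minimum log-odds
#' scores. By default the thresholds are `threshold_frac` (50%) of each PWM's
#' maximal attainable score; they can be set explicitly. The default consensus
#' strings are the canonical human U12-type elements (GT-AG subtype 5'ss
#' GTATCCTT; branch point TTCCTTAAC); the matrices are a configurable
#' approximation, not a published database model.
#'
#' @param five_ss_consensus 5' splice-site consensus (intron positions +1..+8).
#' @param bps_consensus branch-point consensus (width 9 by default).
#' @param bps_search_window integer c(from, to): offsets of the search region
#'   relative to the 3' splice site, default -40..-5 (intron 3'-end coordinates).
#' @param background base frequencies.
#' @param major,floor passed to [build_pwm()].
#' @param threshold_frac fraction of the maximal score used as threshold.
#' @param min_score_5ss,min_score_bps explicit thresholds (override
#'   `threshold_frac`).
#' @return list with class `"splice_motif_model"`.
#' @export
motif_model <- function(five_ss_consensus = "GTATCCTT",
                        bps_consensus = "TTCCTTAAC",
                        bps_search_window = c(-40L, -5L),
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        major = 0.91, floor = 0.001,
                        threshold_frac = 0.5,
                        min_score_5ss = NULL, min_score_bps = NULL) {
  pwm5 <- build_pwm(five_ss_consensus, major = major, floor = floor)
  pwmb <- build_pwm(bps_consensus, major = major, floor = floor)
  # maximal attainable score uses the background of the argmax base; with a
  # uniform background this is just sum(log2(max_col / 0.25))
  max5 <- sum(log2(apply(pwm5, 2L, max) / background[rownames(pwm5)[apply(pwm5, 2L, which.max)]]))
  maxb <- sum(log2(apply(pwmb, 2L, max) / background[rownames(pwmb)[apply(pwmb, 2L, which.max)]]))
  structure(list(
    pwm_5ss = pwm5,
    pwm_bps = pwmb,
    bps_search_window = as.integer(bps_search_window),
    background = background,
    min_score_5ss = if (is.null(min_score_5ss)) threshold_frac * max5 else min_score_5ss,
    min_score_bps = if (is.null(min_score_bps)) threshold_frac * maxb else min_score_bps
  ), class = "splice_motif_model")
}

# Intron sequence in transcript orientation from a genome (named character
# vector of chromosome sequences or DNAStringSet). Returns NA if unavailable.
intron_sequence <- function(genome, chrom, start, end, strand) {
  if (inherits(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  if (!chrom %in% names(genome)) return(NA_character_)
  chromseq <- genome[[chrom]]
  if (end > nchar(chromseq) || start < 0L) return(NA_character_)
  s <- substr(chromseq, start + 1L, end)  # 0-based half-open -> substr
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# Best branch-point log-odds over all placements of the BPS PWM inside the
# search window (offsets relative to the intron's 3' end, transcript
# orientation). Window clipped to the intron; -Inf if no placement fits.
best_bps_score <- function(intron_seq, model) {
  w <- ncol(model$pwm_bps)
  L <- nchar(intron_seq)
  lo <- max(1L, L + model$bps_search_window[1L] + 1L)  # first base of window, 1-based
  hi <- L + model$bps_search_window[2L]                # last base of window
  starts <- seq.int(lo, hi - w + 1L)
  if (hi - w + 1L < lo) return(-Inf)
  best <- -Inf
  for (p in starts) {
    sc <- score_motif(substr(intron_seq, p, p + w - 1L), model$pwm_bps, model$background)
    if (sc > best) best <- sc
  }
  best
}

#' Classify introns as minor (U12-type) or major (U2-type)
#'
#' Two routes, mirroring how minor introns are called in practice: (1) lookup
#' in a minor-intron database export ([read_minor_list()] coordinates) — the
#' faithful path; (2) motif scoring with a [motif_model()] — an intron is
#' minor iff both its 5' splice-site score and its best branch-point score
#' reach the model thresholds. List lookup takes precedence: listed introns
#' are minor regardless of motif; introns not in the list fall through to the
#' motif route when a model and genome are supplied, and default to major
#' otherwise. Introns whose sequence cannot be retrieved are classified major
#' with a message. Classification is deterministic and independent of input
#' order.
#'
#' @param introns catalog from [extract_introns()].
#' @param minor_list optional `data.table(chrom, start, end, strand)`.
#' @param genome named character vector / `DNAStringSet` of chromosome
#'   sequences; required for the motif route.
#' @param motif optional [motif_model()].
#' @return the catalog with `intron_class` filled in (`"minor"`/`"major"`),
#'   plus `score5`/`scoreB` columns when the motif route ran.
#' @export
classify_introns <- function(introns, minor_list = NULL, genome = NULL, motif = NULL) {
  if (is.null(minor_list) && (is.null(motif) || is.null(genome))) {
    stop("either a minor_list or both a motif model and a genome are required")
  }
  out <- copy(introns)
  setattr(out, "tx_map", attr(introns, "tx_map"))
  out[, intron_class := "major"]

  if (!is.null(motif) && !is.null(genome)) {
    seqs <- mapply(intron_sequence, chrom = out$chrom, start = out$start,
                   end = out$end, strand = out$strand,
                   MoreArgs = list(genome = genome), USE.NAMES = FALSE)
    w5 <- ncol(motif$pwm_5ss)
    s5 <- ifelse(is.na(seqs) | nchar(seqs) < w5, -Inf,
                 vapply(seqs, function(s) {
                   if (is.na(s) || nchar(s) < w5) return(-Inf)
                   score_motif(substr(s, 1L, w5), motif$pwm_5ss, motif$background)
                 }, numeric(1L)))
    sB <- vapply(seqs, function(s) {
      if (is.na(s)) return(-Inf)
      best_bps_score(s, motif)
    }, numeric(1L))
    out[, `:=`(score5 = s5, scoreB = sB)]
    out[score5 >= motif$min_score_5ss & scoreB >= motif$min_score_bps,
        intron_class := "minor"]
    if (anyNA(seqs)) {
      message(sum(is.na(seqs)), " intron(s) without retrievable sequence classified major")
    }
  }

  if (!is.null(minor_list)) {
    ml <- as.data.table(minor_list)
    key_cat <- out[, paste(chrom, start, end, strand)]
    key_list <- ml[, paste(chrom, start, end, strand)]
    hit <- key_cat %in% key_list
    out[hit, intron_class := "minor"]
    orphan <- setdiff(key_list, key_cat)
    if (length(orphan) > 0L) {
      warning(length(orphan), " minor-list coordinate(s) absent from the catalog")
    }
  }
  out[]
}
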