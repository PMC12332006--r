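#' Validate a transcript-model table
#'
#' Transcript models are plain data.frames with one row per exon and columns
#' `transcript_id`, `gene_id`, `chrom`, `strand`, `exon_start`, `exon_end`
#' (0-based half-open genomic coordinates). Exons of a transcript must be
#' non-overlapping, on a single chromosome and strand, with `exon_end >
#' exon_start`. Transcripts violating these invariants are dropped with a
#' warning naming the offender; the remainder is returned sorted by genomic
#' start within transcript.
#'
#' @param transcripts data.frame of exons as described above.
#' @return A validated `data.table` of exons.
#' @export
validate_transcripts <- function(transcripts) {
  tx <- as.data.table(transcripts)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "exon_start", "exon_end")
  miss <- setdiff(need, names(tx))
  if (length(miss) > 0L) {
    stop("transcript table missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(tx$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tx$exon_end <= tx$exon_start)) stop("exon_end must exceed exon_start")
  setorder(tx, transcript_id, exon_start)
  bad <- tx[, {
    overl <- .N > 1L && any(exon_start[-1L] < exon_end[-.N])
    multi <- length(unique(chrom)) > 1L || length(unique(strand)) > 1L
    list(bad = overl || multi)
  }, by = transcript_id][bad == TRUE, transcript_id]
  if (length(bad) > 0L) {
    warning("dropping transcript(s) with overlapping exons or mixed chrom/strand: ",
            paste(bad, collapse = ", "))
    tx <- tx[!transcript_id %in% bad]
  }
  tx[]
}

#' Enumerate introns from transcript models
#'
#' Every transcript with k exons yields exactly k-1 introns (single-exon
#' transcripts yield none). Introns identical in (chrom, start, end, strand)
#' across transcripts are collapsed into one record carrying the union of
#' transcript ids; gene-level statistics downstream use the collapsed record.
#' Ordinals are 1-based positions in transcript orientation (5' to 3'), and
#' the flanking exons stored with each intron are likewise the transcript's
#' 5' (upstream) and 3' (downstream) neighbours. The full per-transcript
#' intron/ordinal map is attached as attribute `"tx_map"` and is used by
#' [flanking_major_ir()].
#'
#' @param transcripts exon table accepted by [validate_transcripts()].
#' @return `data.table` with columns `intron_id` (`chrom:start-end:strand`),
#'   `gene_id`, `transcript_ids` (comma-separated), `chrom`, `start`, `end`,
#'   `strand`, `intron_class` (`NA` until [classify_introns()]), `ordinal`,
#'   `up_start`, `up_end`, `down_start`, `down_end`.
#' @export
extract_introns <- function(transcripts) {
  tx <- validate_transcripts(transcripts)
  per_tx <- tx[, {
    k <- .N
    if (k < 2L) {
      NULL
    } else {
      s <- exon_end[-k]     # intron start = end of left exon
      e <- exon_start[-1L]  # intron end   = start of right exon
      if (any(e <= s)) stop("zero-length intron in transcript ", transcript_id[1L])
      plus <- strand[1L] == "+"
      idx <- seq_len(k - 1L)
      list(
        gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
        start = s, end = e,
        ordinal = if (plus) idx else rev(idx),
        # flanking exons in transcript orientation
        up_start   = if (plus) exon_start[-k] else exon_start[-1L],
        up_end     = if (plus) exon_end[-k]   else exon_end[-1L],
        down_start = if (plus) exon_start[-1L] else exon_start[-k],
        down_end   = if (plus) exon_end[-1L]   else exon_end[-k]
      )
    }
  }, by = transcript_id]
  if (nrow(per_tx) == 0L) {
    out <- data.table(
      intron_id = character(), gene_id = character(), transcript_ids = character(),
      chrom = character(), start = integer(), end = integer(), strand = character(),
      intron_class = character(), ordinal = integer(),
      up_start = integer(), up_end = integer(),
      down_start = integer(), down_end = integer()
    )
    setattr(out, "tx_map", data.table(transcript_id = character(),
                                      intron_id = character(), ordinal = integer()))
    return(out)
  }
  per_tx[, intron_id := sprintf("%s:%d-%d:%s", chrom, start, end, strand)]
  tx_map <- per_tx[, .(transcript_id, intron_id, ordinal)]
  out <- per_tx[, .(
    gene_id = gene_id[1L],
    transcript_ids = paste(sort(unique(transcript_id)), collapse = ","),
    chrom = chrom[1L], start = start[1L], end = end[1L], strand = strand[1L],
    intron_class = NA_character_,
    ordinal = ordinal[1L],
    up_start = up_start[1L], up_end = up_end[1L],
    down_start = down_start[1L], down_end = down_end[1L]
  ), by = intron_id]
  setcolorder(out, c("intron_id", "gene_id", "transcript_ids", "chrom", "start",
                     "end", "strand", "intron_class", "ordinal",
                     "up_start", "up_end", "down_start", "down_end"))
  setorder(out, chrom, start, end)
  setattr(out, "tx_map", tx_map)
  out[]
}

#' Read transcript models from GTF/GFF3
#'
#' Uses rtracklayer; keeps `exon` features and groups them by transcript.
#' GTF attribute keys `gene_id`/`transcript_id` and GFF3 `ID`/`Parent` are
#' both understood. Coordinates are converted from 1-based inclusive to the
#' package-internal 0-based half-open convention.
#'
#' @param path GTF or GFF3 file.
#' @return exon table suitable for [extract_introns()].
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  txid <- if (!is.null(mc$transcript_id)) {
    as.character(mc$transcript_id)
  } else if (!is.null(mc$Parent)) {
    as.character(unlist(mc$Parent))
  } else {
    stop("no transcript_id or Parent attribute on exon features in ", path)
  }
  gid <- if (!is.null(mc$gene_id)) as.character(mc$gene_id) else txid
  data.table(
    transcript_id = txid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_start = GenomicRanges::start(gr) - 1L,
    exon_end = GenomicRanges::end(gr)
  )
}

#' Write / read an intron catalog
#'
#' The catalog is written as BED6 (`catalog.bed`: 0-based half-open, name =
#' intron_id, score = 0) plus a TSV sidecar (`catalog.tsv`) holding the class,
#' ordinal, gene id, transcript ids and flanking-exon bounds. Reading the pair
#' back reproduces coordinates and classes exactly.
#'
#' @param catalog intron table from [extract_introns()].
#' @param dir output directory (created if needed).
#' @return `write_catalog()` the directory, invisibly; `read_catalog()` the
#'   catalog `data.table` (with its `tx_map` attribute if present on disk).
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- catalog[, .(chrom, start, end, name = intron_id, score = 0L, strand)]
  utils::write.table(bed, file.path(dir, "catalog.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- catalog[, .(intron_id, gene_id, intron_class, ordinal, transcript_ids,
                      up_start, up_end, down_start, down_end)]
  fwrite(side, file.path(dir, "catalog.tsv"), sep = "\t")
  tx_map <- attr(catalog, "tx_map")
  if (!is.null(tx_map)) fwrite(tx_map, file.path(dir, "tx_map.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(dir) {
  bed <- fread(file.path(dir, "catalog.bed"), sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "intron_id", "score", "strand"))
  side <- fread(file.path(dir, "catalog.tsv"), sep = "\t")
  out <- merge(bed[, .(intron_id, chrom, start, end, strand)], side, by = "intron_id")
  out[, intron_class := as.character(intron_class)]
  setcolorder(out, c("intron_id", "gene_id", "transcript_ids", "chrom", "start",
                     "end", "strand", "intron_class", "ordinal",
                     "up_start", "up_end", "down_start", "down_end"))
  setorder(out, chrom, start, end)
  txp <- file.path(dir, "tx_map.tsv")
  if (file.exists(txp)) setattr(out, "tx_map", fread(txp, sep = "\t"))
  out[]
}

#' Read a minor-intron list (MiDB-style TSV or BED)
#'
#' Dialect is auto-detected by column count: 4 columns are taken as
#' `chrom, start, end, strand` (0-based half-open); 6 or more as BED6
#' (columns 1-3 and 6). Header lines are detected and skipped.
#'
#' @param path TSV/BED file of minor-intron coordinates.
#' @return `data.table(chrom, start, end, strand)`.
#' @export
read_minor_list <- function(path) {
  dt <- fread(path, sep = "\t", header = "auto")
  if (is.character(dt[[2L]])) dt <- fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) >= 6L) {
    out <- dt[, c(1L, 2L, 3L, 6L), with = FALSE]
  } else if (ncol(dt) == 4L) {
    out <- dt
  } else {
    stop("minor-intron list must have 4 (TSV) or >=6 (BED) columns; got ", ncol(dt))
  }
  setnames(out, c("chrom", "start", "end", "strand"))
  out[, `:=`(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand))]
  out[]
}
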