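test_that("extract_introns applies the k-1 rule, collapses shared introns and orients ordinals", {
  tx <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2", "t2", "t3"),
    gene_id = c("g1", "g1", "g1", "g1", "g1", "g2"),
    chrom = "c", strand = "+",
    exon_start = c(0, 200, 0, 200, 400, 1000),
    exon_end = c(100, 300, 100, 300, 500, 1100)
  )
  introns <- extract_introns(tx)
  # t1 and t2 share (100,200); t2 adds (300,400); t3 is single-exon
  expect_equal(nrow(introns), 2L)
  shared <- introns[introns$start == 100, ]
  expect_equal(shared$end, 200L)
  expect_equal(shared$transcript_ids, "t1,t2")
  expect_equal(shared$ordinal, 1L)
  expect_equal(introns[introns$start == 300, ]$up_start, 200L)
  expect_equal(introns[introns$start == 300, ]$down_end, 500L)
  tx_map <- attr(introns, "tx_map")
  expect_equal(nrow(tx_map), 3L)  # one row per transcript-intron pair

  # minus strand: ordinal 1 is the genomically RIGHTMOST intron, and the
  # transcript-upstream exon abuts the intron END
  txm <- data.frame(transcript_id = "m1", gene_id = "gm", chrom = "c", strand = "-",
                    exon_start = c(0, 200, 400), exon_end = c(100, 300, 500))
  im <- extract_introns(txm)
  first <- im[im$ordinal == 1L, ]
  expect_equal(first$start, 300L)
  expect_equal(c(first$up_start, first$up_end), c(400L, 500L))
  expect_equal(c(first$down_start, first$down_end), c(200L, 300L))
})

test_that("degenerate transcripts are handled per contract", {
  single <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                       strand = "+", exon_start = 0, exon_end = 100)
  expect_equal(nrow(extract_introns(single)), 0L)

  overlapping <- data.frame(transcript_id = c("t", "t"), gene_id = "g", chrom = "c",
                            strand = "+", exon_start = c(0, 50), exon_end = c(100, 200))
  expect_warning(out <- extract_introns(overlapping), "overlapping")
  expect_equal(nrow(out), 0L)
})

test_that("catalog round-trips through BED + TSV with identical coordinates and classes", {
  ref <- make_toy_reference(quick_config())
  dir <- withr::local_tempdir()
  write_catalog(ref$catalog, dir)
  back <- read_catalog(dir)
  cols <- c("intron_id", "gene_id", "chrom", "start", "end", "strand",
            "intron_class", "ordinal", "up_start", "up_end", "down_start", "down_end")
  expect_equal(as.data.frame(back)[cols], as.data.frame(ref$catalog)[cols])
  expect_equal(attr(back, "tx_map"), attr(ref$catalog, "tx_map"))
})

test_that("GTF and minor-list files written by the generator read back consistently", {
  dir <- withr::local_tempdir()
  ref <- make_toy_reference(quick_config(), dir = dir)
  tx <- read_gtf_transcripts(ref$paths$gtf)
  introns <- extract_introns(tx)
  expect_setequal(introns$intron_id, ref$catalog$intron_id)
  ml <- read_minor_list(ref$paths$minor_list)
  cl <- classify_introns(introns, minor_list = ml)
  expect_equal(
    cl[order(cl$intron_id), ]$intron_class,
    ref$catalog[order(ref$catalog$intron_id), ]$intron_class
  )
})

test_that("score_motif matches hand arithmetic and its boundary properties", {
  # two-column PWM A/C at 0.5 each (floored elsewhere), uniform background:
  # score("AA") = 2 * log2(0.5 / 0.25) = 2 bits
  pwm <- matrix(c(0.5, 0.5, 0.001, 0.001), nrow = 4L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- cbind(pwm[, 1], pwm[, 1])
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  expect_equal(score_motif("AA", pwm), unname(2 * log2(pwm["A", 1] / 0.25)))

  # PWM equal to background scores 0 for any sequence
  flat <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(score_motif("GATTC", flat), 0)

  # argmax sequence attains the maximum; any other sequence scores less
  pwm8 <- build_pwm("GTATCCTT")
  best <- score_motif("GTATCCTT", pwm8)
  set.seed(1)
  for (i in 1:20) {
    other <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    expect_lte(score_motif(other, pwm8), best)
  }
  # N contributes zero
  expect_equal(score_motif("NTATCCTT", pwm8),
               unname(best - log2(pwm8["G", 1] / 0.25)))
  expect_error(score_motif("GTAT", pwm8), "width")
})

test_that("classification precedence and motif thresholds behave as specified", {
  cfg <- quick_config()
  ref <- make_toy_reference(cfg)
  cat0 <- extract_introns(ref$transcripts)

  # list lookup path: exactly the listed coordinates become minor
  cl <- classify_introns(cat0, minor_list = ref$minor_list)
  expect_setequal(cl[cl$intron_class == "minor", ]$intron_id,
                  ref$catalog[ref$catalog$intron_class == "minor", ]$intron_id)

  # a list coordinate absent from the catalog warns but does not error
  phantom <- rbind(ref$minor_list,
                   data.frame(chrom = "c9", start = 1L, end = 50L, strand = "+"))
  expect_warning(classify_introns(cat0, minor_list = phantom), "absent")

  # empty minor list with no motif fails the precondition check
  expect_error(classify_introns(cat0), "minor_list")

  # consensus intron passes at thresholds set to 50% of maximal score
  model <- motif_model()
  expect_lt(model$min_score_5ss, score_motif("GTATCCTT", model$pwm_5ss))
  cl2 <- classify_introns(cat0, genome = ref$genome, motif = model)
  expect_setequal(cl2[cl2$intron_class == "minor", ]$intron_id,
                  ref$catalog[ref$catalog$intron_class == "minor", ]$intron_id)

  # classification is deterministic and order-independent
  perm <- cat0[sample(nrow(cat0)), ]
  cl3 <- classify_introns(perm, genome = ref$genome, motif = model)
  expect_equal(cl3[order(cl3$intron_id), ]$intron_class,
               cl2[order(cl2$intron_id), ]$intron_class)
})
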