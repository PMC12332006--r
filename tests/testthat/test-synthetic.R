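test_that("reference generation is deterministic and honours the minor fraction", {
  cfg <- quick_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- make_toy_reference(cfg, dir = d1)
  r2 <- make_toy_reference(cfg, dir = d2)
  expect_identical(readLines(r1$paths$fasta), readLines(r2$paths$fasta))
  expect_identical(readLines(r1$paths$gtf), readLines(r2$paths$gtf))
  expect_identical(r1$catalog$intron_class, r2$catalog$intron_class)

  # exact minor-intron count: round(n_genes * fraction) genes carry one each
  expect_equal(sum(r1$catalog$intron_class == "minor"),
               round(cfg$n_genes * cfg$minor_intron_fraction))

  none <- make_toy_reference(quick_config(minor_intron_fraction = 0))
  expect_equal(nrow(none$minor_list), 0L)

  # planted splice sites: minor introns start with the 5'ss consensus, major
  # introns with GT, and all introns end in AG (transcript orientation)
  model <- motif_model()
  for (i in seq_len(nrow(r1$catalog))) {
    sq <- misplice:::intron_sequence(r1$genome, r1$catalog$chrom[i],
                                     r1$catalog$start[i], r1$catalog$end[i],
                                     r1$catalog$strand[i])
    if (r1$catalog$intron_class[i] == "minor") {
      expect_equal(substr(sq, 1, 8), "GTATCCTT")
    } else {
      expect_equal(substr(sq, 1, 2), "GT")
    }
    expect_equal(substr(sq, nchar(sq) - 1, nchar(sq)), "AG")
  }
})

test_that("same seed reproduces reads; different seeds differ but share expectations", {
  cfg <- quick_config()
  ref <- make_toy_reference(cfg)
  s1 <- simulate_reads(ref, cfg)
  s2 <- simulate_reads(ref, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  cfg3 <- quick_config(seed = 12L)
  s3 <- simulate_reads(make_toy_reference(quick_config()), cfg3)
  expect_false(identical(s1$truth$n_ret, s3$truth$n_ret))
})

test_that("verify_truth passes on unmodified output and itemizes tampering", {
  cfg <- quick_config()
  ref <- make_toy_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  v <- verify_truth(sim$reads, sim$truth, ref$catalog)
  expect_true(v$ok)

  # deleting one canonical read is caught with a count difference of one
  g <- misplice:::read_gaps(sim$reads)
  canon <- paste(ref$catalog$start, ref$catalog$end)
  victim <- g[paste(g$gstart, g$gend) %in% canon, ][1L, ]
  tampered <- sim$reads[!(sim$reads$read_id == victim$read_id &
                            sim$reads$sample_id == victim$sample_id), ]
  v2 <- verify_truth(tampered, sim$truth, ref$catalog)
  expect_false(v2$ok)
  expect_equal(v2$mismatches$field[1L], "n_canonical")
  expect_equal(v2$mismatches$expected - v2$mismatches$observed, 1L)

  # truth row order is irrelevant (re-keyed by intron and sample)
  v3 <- verify_truth(sim$reads, sim$truth[sample(nrow(sim$truth)), ], ref$catalog)
  expect_true(v3$ok)
})

test_that("extreme retention fractions hit the MSI limits", {
  base <- list(n_genes = 4L, exons_per_gene = c(3L, 3L), depth = 60, seed = 3L,
               minor_intron_fraction = 0)
  clean_cfg <- do.call(sim_config, c(base, list(
    rho = list(minor = c(treated = 0, control = 0), major = c(treated = 0, control = 0)),
    alpha = list(minor = c(treated = 0, control = 0), major = c(treated = 0, control = 0)))))
  ref <- make_toy_reference(clean_cfg)
  q0 <- quantify_introns(ref$catalog, simulate_reads(ref, clean_cfg)$reads)
  expect_true(all(q0$msi_ret == 0))
  expect_true(all(q0$msi_as == 0))

  full_cfg <- do.call(sim_config, c(base, list(
    rho = list(minor = c(treated = 1, control = 1), major = c(treated = 1, control = 1)),
    alpha = list(minor = c(treated = 0, control = 0), major = c(treated = 0, control = 0)))))
  q1 <- quantify_introns(ref$catalog, simulate_reads(ref, full_cfg)$reads)
  expect_true(all(q1$n_canonical == 0))
  expect_true(all(q1$msi_ret[q1$n5 > 0] == 100))
})

test_that("disabling tiling breaks the coverage gate, enabling it satisfies it", {
  cfg_on <- quick_config()
  ref <- make_toy_reference(cfg_on)
  q_on <- quantify_introns(ref$catalog, simulate_reads(ref, cfg_on)$reads)
  minors <- ref$catalog$intron_id[ref$catalog$intron_class == "minor"]
  trt <- q_on$sample_id %in% paste0("treated_", 1:4)
  expect_true(all(q_on$coverage[q_on$intron_id %in% minors & trt] == 1))

  # long introns: boundary reads alone can never tile the interior
  cfg_off <- quick_config(tiling = FALSE, intron_len = c(250L, 350L))
  ref_off <- make_toy_reference(cfg_off)
  q_off <- quantify_introns(ref_off$catalog, simulate_reads(ref_off, cfg_off)$reads)
  minors_off <- ref_off$catalog$intron_id[ref_off$catalog$intron_class == "minor"]
  trt_off <- q_off$sample_id %in% paste0("treated_", 1:4)
  expect_true(all(q_off$coverage[q_off$intron_id %in% minors_off & trt_off] < 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(read_length = 12L, min_overhang = 6L), "read_length")
  expect_error(sim_config(rho = list(minor = c(treated = 0.8, control = 0),
                                     major = c(treated = 0, control = 0)),
                          alpha = list(minor = c(treated = 0.5, control = 0),
                                       major = c(treated = 0, control = 0))),
               "rho")
  expect_error(sim_config(exon_len = c(40L, 160L)), "exon_len")
})
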