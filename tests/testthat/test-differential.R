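test_that("welch_t_test matches closed-form arithmetic and the stats oracle", {
  w <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.0214, tolerance = 1e-2)

  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    w <- welch_t_test(a, b)
    o <- stats::t.test(a, b)  # Welch by default
    expect_equal(w$t, unname(o$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(o$parameter), tolerance = 1e-10)
    expect_equal(w$p, o$p.value, tolerance = 1e-10)
  }

  # degenerate zero-variance rules
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")], list(t = 0, p = 1))
  d <- welch_t_test(c(0, 0, 0), c(5, 5, 5))
  expect_equal(d$p, .Machine$double.xmin)
  expect_true(is.infinite(d$t))
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("audic_claverie_test reproduces the exact law, its symmetry and tail monotonicity", {
  # printed check-points of the conditional law
  expect_equal(audic_claverie_test(0, 0, 1, 1)$p_point, 0.5)
  expect_equal(audic_claverie_test(0, 0, 1, 1)$p, 1)
  expect_equal(audic_claverie_test(5, 5, 1, 1)$p_point, 252 / 2048)

  # against direct summation of the published formula, unequal libraries too
  for (case in list(c(0, 3, 1, 1), c(5, 5, 2, 1), c(10, 2, 1, 3), c(7, 19, 1e6, 2e6))) {
    got <- audic_claverie_test(case[1], case[2], case[3], case[4])
    want <- brute_ac(case[1], case[2], case[3], case[4])
    expect_equal(got$p, want$p, tolerance = 1e-9)
    expect_equal(got$p_point, want$p_point, tolerance = 1e-9)
  }

  # symmetry of the two-sided p under (x, y, N1, N2) -> (y, x, N2, N1)
  set.seed(9)
  for (i in 1:30) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    N1 <- sample(1000:5000, 1); N2 <- sample(1000:5000, 1)
    expect_equal(audic_claverie_test(x, y, N1, N2)$p,
                 audic_claverie_test(y, x, N2, N1)$p, tolerance = 1e-9)
  }

  # two-sided p decreases as y runs away from x = 0
  ps <- vapply(c(2, 5, 10, 20, 40), function(y) audic_claverie_test(0, y)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(audic_claverie_test(1.5, 2), "integer")
})

test_that("bh_fdr implements the step-up rule and matches p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))  # BH never deflates
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi_square_gof computes the statistic directly", {
  expect_equal(chi_square_gof(c(50, 50), c(0.5, 0.5))[c("chi2", "p")],
               list(chi2 = 0, p = 1))
  expect_equal(chi_square_gof(c(10, 0), c(0.5, 0.5))$chi2, 10)  # 25/5 + 25/5
  obs <- c(60, 539)
  props <- c(599, 179463) / (599 + 179463)
  got <- chi_square_gof(obs, props)
  E <- sum(obs) * props
  expect_equal(got$chi2, sum((obs - E)^2 / E))
  expect_equal(got$df, 1L)
  expect_error(chi_square_gof(c(1, 1), c(1, 0)), "zero expected")
})

test_that("the four-rule retention filter matches row-by-row hand evaluation", {
  tab <- data.frame(
    intron_id = c("a", "b", "c"),
    fdr = c(0.01, 0.01, 0.2),
    cov_ok_treated = TRUE, cov_ok_control = TRUE,
    ratio_treated = c(0.12, 0.12, 0.12),
    ratio_control = c(0.05, 0.09, 0.01)
  )
  out <- call_differential_retention(tab)
  expect_equal(out$call, c("retained_in_treated",  # all four predicates hold
                           "not_significant",      # delta 3% < 5%
                           "not_significant"))     # FDR gate

  # mirrored control-side predicate
  tabc <- data.frame(intron_id = "d", fdr = 0.02, cov_ok_treated = FALSE,
                     cov_ok_control = TRUE, ratio_treated = 0.02, ratio_control = 0.3)
  expect_equal(call_differential_retention(tabc)$call, "retained_in_control")

  # rows with missing inputs are excluded with a message
  tabm <- rbind(tab, data.frame(intron_id = "e", fdr = NA, cov_ok_treated = TRUE,
                                cov_ok_control = TRUE, ratio_treated = 0.5,
                                ratio_control = 0))
  expect_message(out2 <- call_differential_retention(tabm), "excluding")
  expect_equal(nrow(out2), 3L)
})

test_that("MSI significance calls respect the p and delta gates", {
  design <- condition_design(paste0(rep(c("t", "c"), each = 4), 1:4),
                             rep(c("treated", "control"), each = 4))
  mk_msi <- function(ret_t, ret_c, as_t = rep(0, 4), as_c = rep(0, 4)) {
    data.frame(intron_id = "i1",
               sample_id = design$samples,
               msi_ret = c(ret_t, ret_c),
               msi_as = c(as_t, as_c))
  }
  # clearly elevated retention
  out <- call_missplicing_msi(mk_msi(c(20, 22, 18, 21), c(2, 3, 1, 2)), design)
  expect_true(out$ir_sig)
  expect_false(out$as_sig)
  expect_equal(out$p_ret, welch_t_test(c(20, 22, 18, 21), c(2, 3, 1, 2))$p)

  # identical groups are never significant
  expect_false(call_missplicing_msi(mk_msi(c(5, 6, 7, 8), c(5, 6, 7, 8)), design)$ir_sig)

  # tiny delta fails the gate even at p < 0.001
  out3 <- call_missplicing_msi(mk_msi(c(10, 10.1, 9.9, 10), c(6, 6.1, 5.9, 6)), design)
  expect_lt(out3$p_ret, 0.001)
  expect_false(out3$ir_sig)
})

test_that("gene categories tally correctly and sum to the detected total", {
  tx <- data.frame(
    transcript_id = rep(paste0("t", 1:6), each = 2),
    gene_id = rep(paste0("g", 1:6), each = 2),
    chrom = "c", strand = "+",
    exon_start = rep(c(0, 200), 6) + rep(0:5 * 1000, each = 2),
    exon_end = rep(c(100, 300), 6) + rep(0:5 * 1000, each = 2)
  )
  catalog <- extract_introns(tx)
  catalog$intron_class <- "minor"
  calls <- data.frame(
    intron_id = catalog$intron_id[1:5],  # g6 undetected
    ir_sig = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    as_sig = c(FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  res <- categorize_genes(calls, catalog)
  expect_equal(unname(res$counts[c("IR", "AS", "IR_and_AS", "unaffected")]),
               c(2L, 1L, 1L, 1L))
  expect_equal(unname(res$counts["detected"]), 5L)
  expect_equal(sum(res$counts[c("IR", "AS", "IR_and_AS", "unaffected")]),
               unname(res$counts["detected"]))
  expect_equal(res$genes$category[res$genes$gene_id == "g6"], "not_detected")
})

test_that("flanking-major analysis uses ordinal adjacency within transcripts", {
  # one transcript, introns: major, minor, major, major
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c", strand = "+",
                   exon_start = c(0, 200, 400, 600, 800),
                   exon_end = c(100, 300, 500, 700, 900))
  catalog <- extract_introns(tx)
  catalog$intron_class <- c("major", "minor", "major", "major")
  ids <- catalog$intron_id[order(catalog$ordinal)]

  # retained: the minor (ordinal 2) and the adjacent major (ordinal 3)
  calls <- data.frame(intron_id = ids[2:3], ir_sig = TRUE)
  res <- flanking_major_ir(catalog, calls)
  expect_equal(nrow(res$pairs), 2L)  # both neighbours of the minor reported
  expect_equal(sort(res$pairs$flank_intron), sort(ids[c(1, 3)]))
  expect_equal(res$pairs$flank_retained[res$pairs$flank_intron == ids[3]], TRUE)
  expect_equal(res$summary$n_retained_major, 1L)
  expect_equal(res$summary$frac_flanking, 1)

  # a retained major two ordinals away is non-flanking
  calls2 <- data.frame(intron_id = ids[c(2, 4)], ir_sig = TRUE)
  res2 <- flanking_major_ir(catalog, calls2)
  expect_equal(res2$summary$n_non_flanking, 1L)

  # no retained minor introns -> empty pair table
  res3 <- flanking_major_ir(catalog, data.frame(intron_id = ids[1], ir_sig = TRUE))
  expect_equal(nrow(res3$pairs), 0L)
})
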