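test_that("allele fractions follow the worked two-base example", {
  calls <- compute_allele_fractions(make_pileup(c(2, 0, 98, 0)),
                                    min_depth = 50)
  expect_equal(calls$major_base, "G")
  expect_equal(calls$minor_base, "A")
  expect_equal(calls$minor_fraction, 0.02)
  expect_equal(calls$status, "candidate")

  # symmetric tie: shares 50/50
  tie <- compute_allele_fractions(make_pileup(c(50, 0, 50, 0)),
                                  min_depth = 50)
  expect_equal(tie$minor_fraction, 0.5)
  # tie broken by fixed base order A < C < G < T
  expect_equal(tie$major_base, "A")
  expect_equal(tie$minor_base, "G")

  empty <- compute_allele_fractions(make_pileup(c(0, 0, 0, 0)),
                                    min_depth = 100)
  expect_equal(empty$status, "low_depth_excluded")
  expect_error(compute_allele_fractions(make_pileup(c(1, 0, 0, 0))[0, ]),
               "empty")
})

test_that("the 30-70% band excludes heterozygous loci, boundary inclusive", {
  calls <- compute_allele_fractions(
    make_pileup(c(2, 0, 98, 0),    # 2/98: homozygous candidate
                c(40, 0, 60, 0),   # 40/60: inside band
                c(30, 0, 70, 0),   # exactly on the boundary
                c(29, 0, 71, 0)),  # just outside
    min_depth = 50
  )
  calls <- classify_informative(calls)
  expect_equal(calls$status,
               c("candidate", "heterozygous_excluded",
                 "heterozygous_excluded", "candidate"))
  expect_error(classify_informative(calls, 0.7, 0.3), "band_low")
})

test_that("background error estimation is robust and enforces its precondition", {
  zero <- compute_allele_fractions(
    do.call(make_pileup, rep(list(c(0, 0, 1000, 0)), 12)), min_depth = 50
  )
  zero <- classify_informative(zero)
  expect_equal(estimate_background_error(zero), 0)

  nine <- compute_allele_fractions(
    do.call(make_pileup, rep(list(c(0, 0, 1000, 0)), 9)), min_depth = 50
  )
  expect_error(estimate_background_error(classify_informative(nine)),
               "at least 10")
})

test_that("background estimate recovers a simulated error floor at zero donor fraction", {
  panel <- make_default_panel(202, seed = 21)
  set.seed(22)
  ests <- replicate(20, {
    gt <- simulate_genotype_pair(panel)
    smp <- simulate_pileup(gt, donor_fraction = 0, error_rate = 0.001)
    calls <- classify_informative(compute_allele_fractions(smp))
    estimate_background_error(calls)
  })
  # uniform substitution at rate 1e-3 puts ~e/3 on the minor base
  expect_true(all(ests >= 0.0003 & ests <= 0.002))
})

test_that("signal/background split applies the k-sigma threshold per locus depth", {
  calls <- compute_allele_fractions(
    make_pileup(c(100, 0, 4900, 0),  # 2% at depth 5000
                c(5, 0, 4995, 0)),   # 0.1% = at the error level
    min_depth = 50
  )
  calls <- classify_informative(calls)
  out <- split_signal_background(calls, error_rate = 0.001, k_sigma = 3)
  expect_equal(out$status, c("informative_signal", "background"))
})

test_that("a single clear signal locus yields the per-SNP donor fraction", {
  smp <- cfdna_sample("S", "P", 30, make_pileup(c(2, 0, 98, 0)))
  res <- estimate_dd_fraction(smp, mode = "paper_faithful",
                              config = tiny_quant_config())
  expect_equal(res$dd_fraction_percent, 2.0)
  expect_equal(res$n_informative, 1L)

  # all-background sample: zero estimate with a no-signal flag
  bg <- cfdna_sample("S", "P", 30,
                     do.call(make_pileup, rep(list(c(0, 0, 500, 0)), 15)))
  res0 <- estimate_dd_fraction(bg, config = tiny_quant_config())
  expect_equal(res0$dd_fraction_percent, 0)
  expect_true("no_signal" %in% res0$flags)
})

test_that("estimator equals the hand-computed mean on tiny panels", {
  # three signal loci with minor fractions 1%, 2%, 3% -> mean 2%
  smp <- make_pileup(c(10, 0, 990, 0), c(20, 0, 980, 0), c(30, 0, 970, 0))
  res <- estimate_dd_fraction(smp, mode = "paper_faithful",
                              config = tiny_quant_config(error_rate = 0))
  expect_equal(res$dd_fraction_percent, 2.0)
})

test_that("estimate is invariant to count rescaling and allele relabeling", {
  pile <- separated_pileup(n_bg = 20, n_sig = 10, depth = 1000)
  cfg <- tiny_quant_config()
  base <- estimate_dd_fraction(pile, config = cfg)$dd_fraction_percent

  scaled <- pile
  scaled[, c("A", "C", "G", "T")] <- scaled[, c("A", "C", "G", "T")] * 7
  expect_equal(estimate_dd_fraction(scaled, config = cfg)$dd_fraction_percent,
               base)

  relabeled <- pile[, c("locus_id", "T", "G", "C", "A")]
  names(relabeled) <- c("locus_id", "A", "C", "G", "T")
  expect_equal(
    estimate_dd_fraction(relabeled, config = cfg)$dd_fraction_percent,
    base
  )
  expect_true(base >= 0 && base <= 100)
})

test_that("single-locus estimate is strictly increasing in the minor count", {
  cfg <- tiny_quant_config(error_rate = 0)
  ests <- vapply(c(5, 10, 20, 40), function(k) {
    estimate_dd_fraction(make_pileup(c(k, 0, 1000 - k, 0)),
                         mode = "paper_faithful",
                         config = cfg)$dd_fraction_percent
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("bias-corrected mode recovers truth where the plain average is diluted", {
  panel <- make_default_panel(202, seed = 31)
  set.seed(32)
  f <- 2
  pair <- replicate(40, {
    gt <- simulate_genotype_pair(panel)
    smp <- simulate_pileup(gt, donor_fraction = f)
    c(corrected = estimate_dd_fraction(smp)$dd_fraction_percent,
      faithful = estimate_dd_fraction(
        smp, mode = "paper_faithful")$dd_fraction_percent)
  })
  expect_lt(abs(mean(pair["corrected", ]) - f) / f, 0.1)
  # donor-heterozygous informative loci carry only half the donor signal,
  # so the plain average sits well below truth
  expect_lt(mean(pair["faithful", ]), 0.8 * f)
})

test_that("zero-donor samples classify almost all homozygous loci as background", {
  panel <- make_default_panel(202, seed = 41)
  set.seed(42)
  shares <- replicate(30, {
    gt <- simulate_genotype_pair(panel)
    smp <- simulate_pileup(gt, donor_fraction = 0)
    calls <- estimate_dd_fraction(smp)$per_locus_calls
    hom <- calls$status %in% c("informative_signal", "background")
    mean(calls$status[hom] == "background")
  })
  expect_true(all(shares >= 0.95))
})

test_that("QC passes clean samples and fails empty ones", {
  panel <- make_default_panel(202, seed = 51)
  gt <- simulate_genotype_pair(panel, seed = 52)
  smp <- simulate_pileup(gt, donor_fraction = 1, seed = 53)
  qc <- qc_sample(smp)
  expect_true(qc$pass)
  expect_false(qc$contamination_flag)

  zero <- do.call(make_pileup, rep(list(c(0, 0, 0, 0)), 5))
  qc0 <- qc_sample(zero)
  expect_false(qc0$pass)
  expect_false(qc0$checks[["total_reads"]])

  # hard QC failure refuses the estimate with a diagnostic
  expect_error(estimate_dd_fraction(zero), "refused")
})

test_that("an injected contaminant genome trips the contamination flag", {
  panel <- make_default_panel(202, seed = 61)
  set.seed(62)
  flags <- replicate(100, {
    gt <- simulate_genotype_pair(panel)
    smp <- simulate_pileup(gt, donor_fraction = 0.5,
                           contamination = list(fraction = 0.05))
    estimate_dd_fraction(smp)$qc$contamination_flag
  })
  expect_gte(mean(flags), 0.8)
  clean <- replicate(30, {
    gt <- simulate_genotype_pair(panel)
    smp <- simulate_pileup(gt, donor_fraction = 0.5)
    estimate_dd_fraction(smp)$qc$contamination_flag
  })
  expect_lte(mean(clean), 0.1)
})

test_that("cutoff classification is inclusive at the threshold", {
  expect_equal(classify_cutoff(1.0), "elevated")
  expect_equal(classify_cutoff(0.99), "not_elevated")
  expect_equal(classify_cutoff(0.61), "not_elevated")
  expect_equal(classify_cutoff(c(2, 0.5)), c("elevated", "not_elevated"))
  expect_error(classify_cutoff(1, cutoff = -1), "non-negative")
})
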