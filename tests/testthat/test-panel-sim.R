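test_that("default panel has the requested size, valid loci, and is seed-reproducible", {
  panel <- make_default_panel(202, seed = 1)
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 202)
  expect_equal(anyDuplicated(panel$locus_id), 0)
  expect_true(all(panel$ref != panel$alt))
  expect_true(all(panel$alt_freq > 0 & panel$alt_freq < 1))
  expect_true(all(panel$chromosome %in% 1:22))

  expect_equal(nrow(make_default_panel(1, seed = 2)), 1)
  expect_error(make_default_panel(0), "positive")

  expect_identical(make_default_panel(202, seed = 9),
                   make_default_panel(202, seed = 9))
})

test_that("genotype sampling follows Hardy-Weinberg and is deterministic", {
  # at alt_freq = 0.5 the donor-hom / recipient-hom-different probability
  # is 2 * (1/4 * 1/4) = 0.125
  panel <- snp_panel(sprintf("s%05d", 1:10000), 1, "A", "G",
                     rep(0.5, 10000))
  gt <- simulate_genotype_pair(panel, seed = 3)
  opp_hom <- (gt$donor_1 == gt$donor_2) &
    (gt$recipient_1 == gt$recipient_2) &
    (gt$donor_1 != gt$recipient_1)
  se <- sqrt(0.125 * 0.875 / 10000)
  expect_lt(abs(mean(opp_hom) - 0.125), 3 * se)

  expect_identical(simulate_genotype_pair(panel, seed = 4),
                   simulate_genotype_pair(panel, seed = 4))

  # degenerate frequency: essentially zero alt frequency gives ref/ref
  tiny <- snp_panel(sprintf("t%03d", 1:100), 1, "A", "G", rep(1e-12, 100))
  gt0 <- simulate_genotype_pair(tiny, seed = 5)
  expect_true(all(gt0$donor_1 == "A" & gt0$donor_2 == "A" &
                    gt0$recipient_1 == "A" & gt0$recipient_2 == "A"))
})

test_that("pileup mixture recovers the donor fraction at informative loci", {
  # hand-built genotypes: donor AA / recipient GG at every locus
  n <- 50
  gt <- data.frame(
    locus_id = sprintf("m%02d", 1:n), ref = "G", alt = "A",
    alt_freq = 0.5,
    donor_1 = "A", donor_2 = "A", recipient_1 = "G", recipient_2 = "G",
    stringsAsFactors = FALSE
  )
  class(gt) <- c("genotype_pairs", "data.frame")
  smp <- simulate_pileup(gt, donor_fraction = 2, error_rate = 0,
                         depth_model = list(mean = 1e5, size = 1e6),
                         seed = 6)
  cnt <- smp$pileup
  frac_a <- cnt$A / (cnt$A + cnt$C + cnt$G + cnt$T)
  se <- sqrt(0.02 * 0.98 / 1e5)
  expect_lt(abs(mean(frac_a) - 0.02), 3 * se / sqrt(n))
  # read counts are non-negative integers and only the two true bases occur
  expect_true(all(cnt$C == 0 & cnt$T == 0))

  # donor heterozygous: expected alt fraction is f/200 of reads
  gt_het <- gt
  gt_het$donor_2 <- "G"
  smp_het <- simulate_pileup(gt_het, donor_fraction = 4, error_rate = 0,
                             depth_model = list(mean = 1e5, size = 1e6),
                             seed = 7)
  frac_het <- smp_het$pileup$A /
    (smp_het$pileup$A + smp_het$pileup$G)
  expect_lt(abs(mean(frac_het) - 0.02), 3 * se / sqrt(n))
})

test_that("zero donor fraction with no error leaves only recipient alleles", {
  panel <- make_default_panel(100, seed = 8)
  gt <- simulate_genotype_pair(panel, seed = 9)
  smp <- simulate_pileup(gt, donor_fraction = 0, error_rate = 0, seed = 10)
  hom <- gt$recipient_1 == gt$recipient_2
  cnt <- as.matrix(smp$pileup[, c("A", "C", "G", "T")])
  for (i in which(hom)) {
    expect_equal(sum(cnt[i, ] > 0), as.integer(cnt[i, gt$recipient_1[i]] > 0))
  }
  expect_error(simulate_pileup(gt, donor_fraction = 101), "0, 100")
})

test_that("pileup simulation is bit-identical under a fixed seed", {
  panel <- make_default_panel(50, seed = 11)
  gt <- simulate_genotype_pair(panel, seed = 12)
  expect_identical(simulate_pileup(gt, 2, seed = 13)$pileup,
                   simulate_pileup(gt, 2, seed = 13)$pileup)
})

test_that("tacrolimus series generator matches its model", {
  const <- simulate_tacrolimus_series(
    list(days = c(1, 10, 20, 30), mean = 10, cv = 0, dose = 8), seed = 1
  )
  expect_equal(cv_percent(const), 0)
  expect_true(all(diff(const$day) > 0))

  # default model is calibrated to a 12.5 ng/mL mean trough
  set.seed(2)
  means <- replicate(300, mean(simulate_tacrolimus_series()$level))
  expect_lt(abs(mean(means) - 12.5), 0.15)

  expect_identical(simulate_tacrolimus_series(seed = 5),
                   simulate_tacrolimus_series(seed = 5))
  expect_error(simulate_tacrolimus_series(list(days = numeric(0))), "empty")
  expect_error(simulate_tacrolimus_series(list(days = 35, mean = 10)),
               "0-30")
})

test_that("cohort simulation respects prevalences, hierarchy and schema", {
  cfg0 <- cohort_config(
    n_patients = 60, seed = 1, generate_reads = FALSE,
    outcome_model = list(p_abmr = 0, p_tcmr = 0.1, p_other_trouble = 0.2,
                         p_first_year_extra = 0.05)
  )
  coh0 <- simulate_cohort(cfg0)
  expect_false(any(coh0$patients$abmr_1m))

  coh <- simulate_cohort(cohort_config(n_patients = 42, seed = 2))
  p <- coh$patients
  # label hierarchy: AbMR => acute rejection => troubled graft
  expect_true(all(!p$abmr_1m | p$rejection_1m))
  expect_true(all(!p$rejection_1m | p$troubled_1m))
  # complete records: one sample per patient, covariates present
  expect_setequal(names(coh$samples), p$patient_id)
  expect_false(any(is.na(p$egfr_1m)) || any(is.na(p$albuminuria_1m)) ||
                 any(is.na(p$mpa_trough)))
  expect_setequal(unique(coh$tacrolimus$patient_id), p$patient_id)
  expect_setequal(unique(coh$typings$patient_id), p$patient_id)

  expect_error(
    cohort_config(outcome_model = list(p_abmr = 0.7, p_tcmr = 0.4,
                                       p_other_trouble = 0.2,
                                       p_first_year_extra = 0)),
    "prevalences"
  )
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- cohort_config(n_patients = 10, seed = 33)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("group medians of true donor fraction track the calibration targets", {
  coh <- simulate_cohort(cohort_config(n_patients = 500, seed = 4,
                                       generate_reads = FALSE,
                                       generate_typings = FALSE))
  p <- coh$patients
  med_abmr <- median(p$true_dd_fraction[p$abmr_1m])
  med_rest <- median(p$true_dd_fraction[!p$abmr_1m])
  expect_lt(abs(med_abmr - 1.64) / 1.64, 0.15)
  expect_lt(abs(med_rest - 0.58) / 0.58, 0.15)
})
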