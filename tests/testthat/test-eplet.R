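test_that("eplet table loading validates schema and collapses duplicates", {
  tab <- toy_eplet_table()
  expect_s3_class(tab, "eplet_table")
  expect_equal(length(unique(tab$allele)), 3)

  dup <- load_eplet_table(data.frame(
    allele = c("X*01:01", "X*01:01"), eplet = c("e1", "e1"), class = "I"
  ))
  expect_equal(nrow(dup), 1)

  expect_error(
    load_eplet_table(data.frame(allele = "X*01:01", eplet = "e1")),
    "class"
  )
  expect_error(
    load_eplet_table(data.frame(allele = "X*01:01", eplet = "e1",
                                class = "III")),
    "'I' or 'II'"
  )
})

test_that("eplet mismatch load is the donor-minus-recipient set difference", {
  tab <- toy_eplet_table()
  donor <- one_locus_typing("DQB1", "DQB1*01:01")     # {e1,e2,e3}
  recip <- one_locus_typing("DQB1", "DQB1*02:01")     # {e1}
  expect_equal(eplet_mismatch_load(donor, recip, tab, "DQB1"), 2)
  expect_equal(eplet_mismatch_load(donor, recip, tab, "classII"), 2)
  # asymmetry: recipient-against-donor differs in general
  expect_equal(eplet_mismatch_load(recip, donor, tab, "DQB1"), 0)

  # identical typings give zero at every scope
  expect_equal(eplet_mismatch_load(donor, donor, tab, "DQB1"), 0)
  expect_equal(eplet_mismatch_load(donor, donor, tab, "classII"), 0)

  # homozygous donor counts its repertoire once (union semantics)
  het <- one_locus_typing("DQB1", "DQB1*01:01", "DQB1*01:01")
  expect_equal(eplet_mismatch_load(het, recip, tab, "DQB1"), 2)

  expect_error(
    eplet_mismatch_load(one_locus_typing("DQB1", "DQB1*99:99"), recip,
                        tab, "DQB1"),
    "DQB1\\*99:99"
  )
})

test_that("loads agree with brute-force set enumeration on random toy tables", {
  set.seed(7)
  for (rep in 1:25) {
    alleles <- sprintf("DQB1*%02d:01", 1:6)
    tab <- load_eplet_table(data.frame(
      allele = rep(alleles, each = 8),
      eplet = sprintf("e%d", sample(20, 48, replace = TRUE)),
      class = "II"
    ))
    d <- sample(alleles, 2)
    r <- sample(alleles, 2)
    donor <- one_locus_typing("DQB1", d[1], d[2])
    recip <- one_locus_typing("DQB1", r[1], r[2])
    expect_equal(eplet_mismatch_load(donor, recip, tab, "DQB1"),
                 brute_force_load(d, r, tab))
  }
})

test_that("adding donor eplets never decreases the load; recipient eplets never increase it", {
  set.seed(8)
  alleles <- sprintf("A*%02d:01", 1:4)
  base <- data.frame(
    allele = rep(alleles, each = 5),
    eplet = sprintf("e%d", sample(15, 20, replace = TRUE)),
    class = "I"
  )
  donor <- one_locus_typing("A", alleles[1], alleles[2])
  recip <- one_locus_typing("A", alleles[3], alleles[4])
  for (i in 1:20) {
    tab <- load_eplet_table(base)
    load0 <- eplet_mismatch_load(donor, recip, tab, "A")
    extra_d <- load_eplet_table(rbind(base, data.frame(
      allele = alleles[1], eplet = sprintf("x%d", i), class = "I"
    )))
    expect_gte(eplet_mismatch_load(donor, recip, extra_d, "A"), load0)
    extra_r <- load_eplet_table(rbind(base, data.frame(
      allele = alleles[3], eplet = sample(base$eplet, 1), class = "I"
    )))
    expect_lte(eplet_mismatch_load(donor, recip, extra_r, "A"), load0)
  }
})

test_that("class II load is bounded by the per-locus sum, equal for disjoint loci", {
  loci <- c("DRB1", "DQB1", "DQA1")
  disjoint <- load_eplet_table(data.frame(
    allele = paste0(rep(loci, each = 2), "*0", 1:2, ":01"),
    eplet = sprintf("e%d", 1:6),
    class = "II"
  ))
  typing_of <- function(suffix) {
    hla_typing(data.frame(
      locus = loci,
      allele1 = paste0(loci, "*0", suffix, ":01"),
      allele2 = paste0(loci, "*0", suffix, ":01")
    ))
  }
  donor <- typing_of(1)
  recip <- typing_of(2)
  per_locus <- sum(vapply(loci, function(l) {
    eplet_mismatch_load(donor, recip, disjoint, l)
  }, numeric(1)))
  expect_equal(eplet_mismatch_load(donor, recip, disjoint, "classII"),
               per_locus)

  # an eplet shared across loci is counted once in the pooled class II
  # scope but once per locus in the per-locus sum
  shared <- load_eplet_table(rbind(
    as.data.frame(disjoint),
    data.frame(allele = c("DRB1*01:01", "DQB1*01:01"),
               eplet = "shared", class = "II")
  ))
  cII <- eplet_mismatch_load(donor, recip, shared, "classII")
  per_locus_shared <- sum(vapply(loci, function(l) {
    eplet_mismatch_load(donor, recip, shared, l)
  }, numeric(1)))
  expect_lt(cII, per_locus_shared)
})

test_that("antigen mismatches count unique donor antigen names absent in the recipient", {
  loci <- c("A", "B", "C", "DRB1", "DQA1", "DQB1")
  full_d <- hla_typing(data.frame(
    locus = loci,
    allele1 = paste0(loci, "*01:01"), allele2 = paste0(loci, "*02:01")
  ))
  full_r <- hla_typing(data.frame(
    locus = loci,
    allele1 = paste0(loci, "*03:01"), allele2 = paste0(loci, "*04:01")
  ))
  expect_equal(antigen_mismatch_count(full_d, full_d), 0)
  expect_equal(antigen_mismatch_count(full_d, full_r), 12)

  # homozygous mismatched donor locus contributes one unique antigen
  hom_d <- full_d
  hom_d$allele2[1] <- hom_d$allele1[1]
  expect_equal(antigen_mismatch_count(hom_d, full_r), 11)

  expect_error(antigen_mismatch_count(full_d, full_r, loci = c("A", "DPB1")),
               "DPB1")
})

test_that("cohort loads round-trip the simulator's ground truth exactly", {
  coh <- simulate_cohort(cohort_config(n_patients = 25, seed = 5,
                                       generate_reads = FALSE))
  loads <- cohort_loads(coh)
  m <- merge(loads, coh$truth_loads, by = "patient_id",
             suffixes = c("", ".truth"))
  for (col in c("antigen_mm_total", "classI_eplet_load",
                "classII_eplet_load", "drb1_eplet_load",
                "dqb1_eplet_load", "dqa1_eplet_load", "dpb1_eplet_load")) {
    expect_equal(m[[col]], m[[paste0(col, ".truth")]])
  }

  # a typing using an allele missing from the table names the allele
  bad <- coh$typings[coh$typings$patient_id == coh$patients$patient_id[1], ]
  bad$allele1[1] <- "A*UNKNOWN:01"
  expect_error(cohort_loads(bad, table = coh$eplet_table),
               "A\\*UNKNOWN:01")
})

test_that("identical donor and recipient typings give all-zero loads", {
  tab <- toy_eplet_table()
  t1 <- one_locus_typing("DQB1", "DQB1*01:01", "DQB1*03:01")
  typings <- rbind(
    data.frame(patient_id = "P1", role = "donor", locus = "DQB1",
               allele1 = "DQB1*01:01", allele2 = "DQB1*03:01"),
    data.frame(patient_id = "P1", role = "recipient", locus = "DQB1",
               allele1 = "DQB1*01:01", allele2 = "DQB1*03:01")
  )
  loads <- cohort_loads(typings, table = tab,
                        antigen_loci = "DQB1")
  expect_equal(loads$classII_eplet_load, 0)
  expect_equal(loads$antigen_mm_total, 0)
  expect_equal(eplet_mismatch_load(t1, t1, tab, "classII"), 0)
})
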