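#' Construct a biallelic SNP panel
#'
#' A panel is the set of autosomal biallelic loci at which cell-free DNA is
#' read-counted. Chimerism panels select common variants (allele frequencies
#' near 0.5) so that many loci end up homozygous-different between two
#' unrelated genomes and therefore informative for the donor fraction.
#'
#' @param locus_id Character vector of unique locus identifiers.
#' @param chromosome Autosome labels, integers in 1..22 (recycled).
#' @param ref,alt Reference/alternate nucleotides (`A`/`C`/`G`/`T`, distinct
#'   per locus).
#' @param alt_freq Population alternate-allele frequencies, strictly inside
#'   (0, 1).
#' @return A `data.frame` of class `snp_panel` with one row per locus.
#' @seealso [make_default_panel()]
#' @export
snp_panel <- function(locus_id, chromosome, ref, alt, alt_freq) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) {
    stop("panel locus_ids must be unique", call. = FALSE)
  }
  chromosome <- as.integer(chromosome)
  if (any(is.na(chromosome)) || any(chromosome < 1L) || any(chromosome > 22L)) {
    stop("panel chromosomes must be autosomes 1..22", call. = FALSE)
  }
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    stop("ref/alt alleles must be one of A, C, G, T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ at every locus", call. = FALSE)
  }
  if (any(alt_freq <= 0) || any(alt_freq >= 1)) {
    stop("alt_freq must lie strictly inside (0, 1)", call. = FALSE)
  }
  panel <- data.frame(
    locus_id = locus_id,
    chromosome = rep_len(chromosome, length(locus_id)),
    ref = rep_len(ref, length(locus_id)),
    alt = rep_len(alt, length(locus_id)),
    alt_freq = rep_len(as.numeric(alt_freq), length(locus_id)),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Generate a default SNP panel
#'
#' Draws a panel of `n_loci` biallelic autosomal loci with alternate-allele
#' frequencies from `freq_spec`. The default frequency model is
#' Uniform(0.3, 0.7): quantification panels are enriched for common variants
#' to maximise the yield of informative loci.
#'
#' @param n_loci Number of loci (default 202, the size of the targeted
#'   assay the pipeline emulates).
#' @param freq_spec Function of `n` returning `n` allele frequencies in
#'   (0, 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   panel bit for bit.
#' @return An [snp_panel] of `n_loci` rows, chromosomes assigned cyclically
#'   over 1..22.
#' @examples
#' panel <- make_default_panel(202, seed = 1)
#' nrow(panel)
#' @export
make_default_panel <- function(n_loci = 202L,
                               freq_spec = function(n) stats::runif(n, 0.3, 0.7),
                               seed = NULL) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || is.na(n_loci) ||
      n_loci < 1) {
    stop("`n_loci` must be a positive count", call. = FALSE)
  }
  n_loci <- as.integer(n_loci)
  with_seed(seed, {
    freq <- freq_spec(n_loci)
    ref_idx <- sample.int(4L, n_loci, replace = TRUE)
    alt_shift <- sample.int(3L, n_loci, replace = TRUE)
    alt_idx <- ((ref_idx - 1L + alt_shift) %% 4L) + 1L
    snp_panel(
      locus_id = sprintf("snp%04d", seq_len(n_loci)),
      chromosome = ((seq_len(n_loci) - 1L) %% 22L) + 1L,
      ref = BASES[ref_idx],
      alt = BASES[alt_idx],
      alt_freq = freq
    )
  })
}

#' Simulate donor and recipient genotypes at panel loci
#'
#' Donor and recipient are treated as unrelated individuals; at each locus
#' each genome receives two independent allele draws with the panel's
#' alternate-allele frequency (Hardy-Weinberg sampling).
#'
#' @param panel An [snp_panel].
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `genotype_pairs` with columns `locus_id`,
#'   `ref`, `alt`, `alt_freq`, `donor_1`, `donor_2`, `recipient_1`,
#'   `recipient_2` (nucleotide codes).
#' @export
simulate_genotype_pair <- function(panel, seed = NULL) {
  if (!inherits(panel, "snp_panel")) {
    stop("`panel` must be an snp_panel", call. = FALSE)
  }
  n <- nrow(panel)
  with_seed(seed, {
    draw <- function() {
      ifelse(stats::runif(n) < panel$alt_freq, panel$alt, panel$ref)
    }
    out <- data.frame(
      locus_id = panel$locus_id,
      ref = panel$ref,
      alt = panel$alt,
      alt_freq = panel$alt_freq,
      donor_1 = draw(),
      donor_2 = draw(),
      recipient_1 = draw(),
      recipient_2 = draw(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("genotype_pairs", "data.frame")
    out
  })
}

# Per-locus base-probability matrix (loci x A,C,G,T) for one genome.
#' @noRd
genotype_base_prob <- function(a1, a2) {
  p <- matrix(0, nrow = length(a1), ncol = 4L, dimnames = list(NULL, BASES))
  for (b in BASES) {
    p[, b] <- ((a1 == b) + (a2 == b)) / 2
  }
  p
}

#' Simulate a cell-free DNA read pileup
#'
#' Models post-transplant plasma cfDNA as a mixture of recipient and donor
#' genomes (optionally plus an unrelated contaminant genome). Each read
#' originates from the donor with probability `donor_fraction/100`, from the
#' contaminant with probability `contamination$fraction`, otherwise from the
#' recipient; its base is drawn from the originating genotype (heterozygote
#' reads split 50/50) and then substituted, uniformly to one of the other
#' three bases, with probability `error_rate`. Per-locus depths are drawn
#' from a negative binomial so that depth non-uniformity is realistic.
#'
#' @param genotypes A `genotype_pairs` object from [simulate_genotype_pair()].
#' @param donor_fraction True donor fraction, percent in \[0, 100\].
#' @param depth_model List with `mean` (mean depth, default 5000) and `size`
#'   (negative-binomial dispersion, default 10; larger is more uniform).
#' @param error_rate Per-read substitution probability in \[0, 0.05\].
#' @param contamination Optional list with `fraction` (third-genome mixing
#'   proportion in \[0, 1\)) and optionally `a1`, `a2` (nucleotide vectors of
#'   the contaminant genotype per locus; drawn Hardy-Weinberg from the panel
#'   frequencies when absent).
#' @param sample_id,patient_id,collection_day Sample metadata.
#' @param seed Optional integer seed.
#' @return A list of class `cfdna_sample` with fields `sample_id`,
#'   `patient_id`, `collection_day` and `pileup` (a `data.frame` with
#'   `locus_id` and integer read counts `A`, `C`, `G`, `T`).
#' @export
simulate_pileup <- function(genotypes,
                            donor_fraction,
                            depth_model = list(mean = 5000, size = 10),
                            error_rate = 0.001,
                            contamination = NULL,
                            sample_id = "S1",
                            patient_id = "P1",
                            collection_day = 30,
                            seed = NULL) {
  if (!inherits(genotypes, "genotype_pairs")) {
    stop("`genotypes` must come from simulate_genotype_pair()", call. = FALSE)
  }
  if (!is.numeric(donor_fraction) || length(donor_fraction) != 1L ||
      is.na(donor_fraction) || donor_fraction < 0 || donor_fraction > 100) {
    stop("`donor_fraction` must be a percent in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.05) {
    stop("`error_rate` must lie in [0, 0.05]", call. = FALSE)
  }
  n <- nrow(genotypes)
  fd <- donor_fraction / 100
  with_seed(seed, {
    fc <- 0
    p_cont <- NULL
    if (!is.null(contamination)) {
      fc <- contamination$fraction
      stopifnot_scalar_prob(fc, "contamination$fraction")
      if (fd + fc > 1) {
        stop("donor fraction plus contamination exceeds 100%", call. = FALSE)
      }
      if (is.null(contamination$a1)) {
        u1 <- ifelse(stats::runif(n) < genotypes$alt_freq,
                     genotypes$alt, genotypes$ref)
        u2 <- ifelse(stats::runif(n) < genotypes$alt_freq,
                     genotypes$alt, genotypes$ref)
        p_cont <- genotype_base_prob(u1, u2)
      } else {
        p_cont <- genotype_base_prob(contamination$a1, contamination$a2)
      }
    }
    p <- (1 - fd - fc) *
      genotype_base_prob(genotypes$recipient_1, genotypes$recipient_2) +
      fd * genotype_base_prob(genotypes$donor_1, genotypes$donor_2)
    if (fc > 0) {
      p <- p + fc * p_cont
    }
    # uniform substitution error: a read of true base b is observed as each
    # of the other three bases with probability error_rate/3
    p <- p * (1 - error_rate) + (1 - p) * (error_rate / 3)
    depth <- stats::rnbinom(n, mu = depth_model$mean, size = depth_model$size)
    counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
    for (i in seq_len(n)) {
      if (depth[i] > 0L) {
        counts[i, ] <- stats::rmultinom(1L, depth[i], p[i, ])[, 1L]
      }
    }
    pileup <- data.frame(
      locus_id = genotypes$locus_id,
      A = counts[, "A"], C = counts[, "C"],
      G = counts[, "G"], T = counts[, "T"],
      stringsAsFactors = FALSE
    )
    cfdna_sample(sample_id, patient_id, collection_day, pileup)
  })
}

#' Assemble a cfDNA sample from a pileup table
#'
#' @param sample_id,patient_id Identifiers.
#' @param collection_day Days post-transplant (non-negative).
#' @param pileup `data.frame` with columns `locus_id`, `A`, `C`, `G`, `T`
#'   (non-negative integer read counts).
#' @return A list of class `cfdna_sample`.
#' @export
cfdna_sample <- function(sample_id, patient_id, collection_day, pileup) {
  need <- c("locus_id", BASES)
  if (!is.data.frame(pileup) || !all(need %in% names(pileup))) {
    stop("`pileup` must have columns locus_id, A, C, G, T", call. = FALSE)
  }
  if (nrow(pileup) == 0L) {
    stop("`pileup` is empty", call. = FALSE)
  }
  cnt <- as.matrix(pileup[, BASES])
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(collection_day) || collection_day < 0) {
    stop("`collection_day` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      patient_id = as.character(patient_id),
      collection_day = as.numeric(collection_day),
      pileup = pileup[, need]
    ),
    class = "cfdna_sample"
  )
}

#' @export
print.cfdna_sample <- function(x, ...) {
  cat(sprintf(
    "<cfdna_sample> %s (patient %s, day %g): %d loci, %s total reads\n",
    x$sample_id, x$patient_id, x$collection_day, nrow(x$pileup),
    format(sum(as.matrix(x$pileup[, BASES])), big.mark = ",")
  ))
  invisible(x)
}
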