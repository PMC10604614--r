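#' Quantification settings
#'
#' Bundles the tunable parameters of the genotype-free donor-fraction
#' estimator. All defaults are documented package choices; the assay vendor
#' publishes none.
#'
#' @param min_depth Minimum total reads for a locus to enter the analysis
#'   (default 100); shallower loci are excluded as `low_depth_excluded`.
#' @param band_low,band_high Two-base-share band defining heterozygosity
#'   (defaults 0.30 and 0.70). Shares strictly outside the closed band mark
#'   a homozygous, potentially informative locus; exact 30%/70% shares count
#'   as heterozygous ("outside" read strictly).
#' @param k_sigma Signal threshold in binomial standard errors above the
#'   background error (default 3).
#' @param error_rate Optional known per-read background error on the
#'   minor-fraction scale; when `NULL` it is estimated from the sample by
#'   [estimate_background_error()].
#' @param min_background_loci Minimum homozygous loci required to estimate
#'   the background (default 10); with fewer loci the background is taken
#'   as 0 and the result is flagged.
#' @param qc QC thresholds from [qc_thresholds()].
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(min_depth = 100L,
                         band_low = 0.30,
                         band_high = 0.70,
                         k_sigma = 3,
                         error_rate = NULL,
                         min_background_loci = 10L,
                         qc = qc_thresholds()) {
  if (band_low >= band_high) {
    stop("`band_low` must be smaller than `band_high`", call. = FALSE)
  }
  structure(
    list(
      min_depth = min_depth, band_low = band_low, band_high = band_high,
      k_sigma = k_sigma, error_rate = error_rate,
      min_background_loci = min_background_loci, qc = qc
    ),
    class = "quant_config"
  )
}

#' QC thresholds for a cfDNA sample
#'
#' @param min_total_reads Minimum total reads across the panel (default
#'   1e5); failing this refuses the estimate.
#' @param max_depth_cv Maximum coefficient of variation of per-locus depth
#'   (default 1.0).
#' @param max_outlier_loci Maximum tolerated minor-fraction outlier loci
#'   before the contamination flag is raised (default 10).
#' @param outlier_k_mad Outlier cut in median-absolute-deviations from the
#'   signal-cluster median (default 4).
#' @param max_dispersion_ratio Maximum tolerated ratio of the robust spread
#'   of the heterozygote-doubled signal fractions to the binomial noise
#'   expected at the cluster's depth (default 2.0). A single donor genome
#'   produces a signal cluster whose spread is binomial-scale; a third
#'   genome mixed in widens it well beyond that even when no individual
#'   locus is a gross outlier.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_reads = 1e5,
                          max_depth_cv = 1.0,
                          max_outlier_loci = 10L,
                          outlier_k_mad = 4,
                          max_dispersion_ratio = 2.0) {
  structure(
    list(
      min_total_reads = min_total_reads, max_depth_cv = max_depth_cv,
      max_outlier_loci = max_outlier_loci, outlier_k_mad = outlier_k_mad,
      max_dispersion_ratio = max_dispersion_ratio
    ),
    class = "qc_thresholds"
  )
}

#' Per-locus allele fractions
#'
#' For every locus the two most-read bases define the major and minor
#' allele; the minor fraction is the minor count divided by the two-base
#' total. Ties between bases with equal counts are broken by the fixed base
#' order A < C < G < T so that output is deterministic.
#'
#' @param sample A `cfdna_sample`, or a pileup `data.frame` with columns
#'   `locus_id`, `A`, `C`, `G`, `T`.
#' @param min_depth Loci with total depth below this are marked
#'   `low_depth_excluded`.
#' @return A `data.frame` of per-locus calls: `locus_id`, `major_base`,
#'   `minor_base`, `major_count`, `minor_count`, `depth`, `minor_fraction`
#'   and `status` (`"candidate"` or `"low_depth_excluded"` at this stage).
#' @export
compute_allele_fractions <- function(sample, min_depth = 100L) {
  pileup <- if (inherits(sample, "cfdna_sample")) sample$pileup else sample
  if (!is.data.frame(pileup) || nrow(pileup) == 0L) {
    stop("pileup is empty", call. = FALSE)
  }
  cnt <- as.matrix(pileup[, BASES])
  storage.mode(cnt) <- "double"
  n <- nrow(cnt)
  # rank bases by count, ties by base order A < C < G < T
  major_idx <- integer(n)
  minor_idx <- integer(n)
  for (i in seq_len(n)) {
    o <- order(-cnt[i, ], seq_len(4L))
    major_idx[i] <- o[1L]
    minor_idx[i] <- o[2L]
  }
  major_count <- cnt[cbind(seq_len(n), major_idx)]
  minor_count <- cnt[cbind(seq_len(n), minor_idx)]
  two_base <- major_count + minor_count
  depth <- rowSums(cnt)
  minor_fraction <- ifelse(two_base > 0, minor_count / two_base, NA_real_)
  status <- ifelse(depth < min_depth, "low_depth_excluded", "candidate")
  data.frame(
    locus_id = as.character(pileup$locus_id),
    major_base = BASES[major_idx],
    minor_base = BASES[minor_idx],
    major_count = as.integer(major_count),
    minor_count = as.integer(minor_count),
    depth = as.integer(depth),
    minor_fraction = minor_fraction,
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Heterozygous-locus exclusion by the 30-70% rule
#'
#' A locus whose two-base shares both lie inside the closed band
#' \[`band_low`, `band_high`\] is read as heterozygous in the recipient and
#' excluded; only loci with shares strictly outside the band remain
#' homozygous candidates.
#'
#' @param calls Output of [compute_allele_fractions()].
#' @param band_low,band_high Band bounds on the two-base-share scale.
#' @return `calls` with `status` updated to `heterozygous_excluded` where
#'   applicable.
#' @export
classify_informative <- function(calls, band_low = 0.30, band_high = 0.70) {
  if (band_low >= band_high) {
    stop("`band_low` must be smaller than `band_high`", call. = FALSE)
  }
  # both shares inside [low, high]  <=>  minor share >= max(low, 1 - high);
  # the small tolerance keeps exact boundary shares (e.g. 30/100) inside
  # the band despite floating-point rounding of 1 - band_high
  cut <- max(band_low, 1 - band_high) - 1e-9
  het <- calls$status == "candidate" &
    !is.na(calls$minor_fraction) & calls$minor_fraction >= cut
  calls$status[het] <- "heterozygous_excluded"
  calls
}

#' Background sequencing-error estimate
#'
#' Homozygous loci where donor and recipient happen to share the genotype
#' carry no donor signal; their minor fractions reflect sequencing error
#' only. The background is estimated as the median minor fraction over the
#' lowest-fraction half of the homozygous candidates, a robust location
#' that true donor-signal loci (in the upper half) cannot drag upwards.
#'
#' @param calls Calls after [classify_informative()].
#' @return Estimated background error on the minor-fraction scale.
#' @export
estimate_background_error <- function(calls) {
  x <- calls$minor_fraction[calls$status == "candidate"]
  x <- x[!is.na(x)]
  if (length(x) < 10L) {
    stop("background estimation needs at least 10 homozygous candidate loci",
         call. = FALSE)
  }
  x <- sort(x)
  stats::median(x[seq_len(ceiling(length(x) / 2))])
}

#' Separate donor signal from background among homozygous loci
#'
#' A homozygous candidate is called `informative_signal` when its minor
#' fraction exceeds the background error by more than `k_sigma` binomial
#' standard errors at its own two-base depth; otherwise it is `background`
#' (donor indistinguishable from recipient at that locus).
#'
#' @param calls Calls after [classify_informative()].
#' @param error_rate Background error on the minor-fraction scale.
#' @param k_sigma Threshold in binomial standard errors (default 3).
#' @return `calls` with candidates resolved to `informative_signal` or
#'   `background`.
#' @export
split_signal_background <- function(calls, error_rate, k_sigma = 3) {
  cand <- calls$status == "candidate"
  two_base <- calls$major_count + calls$minor_count
  se <- sqrt(error_rate * (1 - error_rate) / pmax(two_base, 1))
  thr <- error_rate + k_sigma * se
  sig <- cand & !is.na(calls$minor_fraction) & calls$minor_fraction > thr
  calls$status[sig] <- "informative_signal"
  calls$status[cand & !sig] <- "background"
  calls
}

# Assign signal-locus minor fractions to donor-homozygous (~f) vs
# donor-heterozygous (~f/2) clusters by a deterministic fixed-point
# iteration on the common scale f. Returns a logical vector: TRUE = het.
#' @noRd
assign_het_clusters <- function(x, max_iter = 100L) {
  n <- length(x)
  if (n == 0L) {
    return(logical(0))
  }
  f <- stats::quantile(x, 0.9, names = FALSE)  # start inside the hom cluster
  if (f <= 0) {
    return(rep(FALSE, n))
  }
  het <- x < 0.75 * f  # midpoint of f and f/2
  for (i in seq_len(max_iter)) {
    f <- mean(ifelse(het, 2 * x, x))
    het_new <- x < 0.75 * f
    if (identical(het_new, het)) {
      break
    }
    het <- het_new
  }
  het
}

#' Estimate the donor-derived cfDNA fraction
#'
#' Runs the full genotype-free estimator: per-locus allele fractions,
#' heterozygous exclusion by the 30-70% two-base-share rule, background
#' error separation, and averaging of the informative-SNP minor fractions.
#'
#' Two modes are exposed. `"paper_faithful"` averages the raw minor
#' fractions of the informative loci, mirroring the assay software's
#' described average; on panels without donor genotypes this underestimates
#' the true fraction because loci where the donor is heterozygous contribute
#' only half the donor fraction. `"bias_corrected"` (default) subtracts the
#' estimated background error and assigns signal loci to donor-homozygous
#' versus donor-heterozygous clusters, doubling the heterozygous-cluster
#' fractions before averaging, which restores parameter recovery.
#'
#' @param sample A `cfdna_sample` (or pileup `data.frame`).
#' @param mode `"bias_corrected"` or `"paper_faithful"`.
#' @param config A [quant_config()].
#' @return A list of class `ddcfdna_result`: `dd_fraction_percent`,
#'   `n_informative`, `mode`, `background_error`, `per_locus_calls`, `qc`
#'   (a `qc_report`) and `flags` (character).
#' @examples
#' pan <- make_default_panel(202, seed = 7)
#' gt <- simulate_genotype_pair(pan, seed = 8)
#' smp <- simulate_pileup(gt, donor_fraction = 2, seed = 9)
#' res <- estimate_dd_fraction(smp)
#' res$dd_fraction_percent
#' @export
estimate_dd_fraction <- function(sample,
                                 mode = c("bias_corrected", "paper_faithful"),
                                 config = quant_config()) {
  mode <- match.arg(mode)
  calls <- compute_allele_fractions(sample, min_depth = config$min_depth)
  calls <- classify_informative(calls, config$band_low, config$band_high)
  flags <- character(0)

  if (!is.null(config$error_rate)) {
    bg <- config$error_rate
    calls <- split_signal_background(calls, bg, config$k_sigma)
  } else if (sum(calls$status == "candidate") >= config$min_background_loci) {
    # First pass: the lowest-half median is conservative when most
    # homozygous loci carry donor signal, so refine the estimate on the
    # loci the first split leaves in the background class. The lower
    # quartile is used there because donor-heterozygous loci censored by
    # the inflated first threshold can dominate that class at low donor
    # fractions, while true error-only loci always form its lowest block.
    bg <- estimate_background_error(calls)
    for (iter in 1:5) {
      split <- split_signal_background(calls, bg, config$k_sigma)
      in_bg <- split$status == "background" & !is.na(split$minor_fraction)
      bg_class <- split$minor_fraction[in_bg]
      if (length(bg_class) < config$min_background_loci) {
        break
      }
      med <- stats::median(bg_class)
      q25 <- stats::quantile(bg_class, 0.25, names = FALSE)
      # A clean background class is unimodal with binomial-scale spread
      # around the error rate; a class wider than that, or with a large
      # median/lower-quartile gap, still contains censored donor-signal
      # loci, and only its lowest block is error-only.
      n_ref <- stats::median(split$major_count[in_bg] +
                               split$minor_count[in_bg])
      binom_sd <- sqrt(max(med, 1e-6) / max(n_ref, 1))
      mixed <- stats::mad(bg_class) > 2 * binom_sd ||
        (q25 > 0 && med > 3 * q25)
      bg_new <- if (mixed) q25 else med
      if (abs(bg_new - bg) < 1e-7) {
        bg <- bg_new
        break
      }
      bg <- bg_new
    }
    calls <- split_signal_background(calls, bg, config$k_sigma)
  } else {
    bg <- 0
    flags <- c(flags, "background_assumed_zero")
    calls <- split_signal_background(calls, bg, config$k_sigma)
  }

  qc <- qc_sample(sample, thresholds = config$qc, calls = calls)
  if (qc$total_reads < config$qc$min_total_reads) {
    stop(sprintf(
      "sample fails hard QC: total reads %d below threshold %g; estimate refused",
      qc$total_reads, config$qc$min_total_reads
    ), call. = FALSE)
  }

  sig <- calls$status == "informative_signal"
  calls$cluster <- NA_character_
  if (!any(sig)) {
    est <- 0
    flags <- c(flags, "no_signal")
  } else if (mode == "paper_faithful") {
    est <- 100 * mean(calls$minor_fraction[sig])
  } else {
    x <- pmax(calls$minor_fraction[sig] - bg, 0)
    het <- assign_het_clusters(x)
    calls$cluster[sig] <- ifelse(het, "donor_het", "donor_hom")
    est <- 100 * mean(ifelse(het, 2 * x, x))
  }

  structure(
    list(
      dd_fraction_percent = clamp(est, 0, 100),
      n_informative = sum(sig),
      mode = mode,
      background_error = bg,
      per_locus_calls = calls,
      qc = qc,
      flags = flags
    ),
    class = "ddcfdna_result"
  )
}

#' @export
print.ddcfdna_result <- function(x, ...) {
  cat(sprintf(
    "<ddcfdna_result> dd-cfDNA = %.2f%% (%s mode, %d informative SNPs)\n",
    x$dd_fraction_percent, x$mode, x$n_informative
  ))
  cat(sprintf(
    "  background error %.5f | QC %s%s\n",
    x$background_error, if (x$qc$pass) "pass" else "FAIL",
    if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ", "))
    else ""
  ))
  invisible(x)
}

#' Sample-level quality control
#'
#' Computes total reads, the coefficient of variation of per-locus depth
#' (read uniformity), and minor-fraction outlier loci. Outliers are signal
#' loci whose heterozygote-doubled minor fraction deviates from the signal
#' cluster's median by more than `outlier_k_mad` median absolute deviations;
#' an excess of outliers beyond `max_outlier_loci` raises the contamination
#' flag, since a third genome scatters extra loci away from the single
#' donor-fraction cluster.
#'
#' @param sample A `cfdna_sample` (or pileup `data.frame`).
#' @param thresholds A [qc_thresholds()].
#' @param calls Optional pre-computed per-locus calls (with signal split
#'   applied); recomputed from the sample when absent.
#' @return A list of class `qc_report`: `total_reads`, `depth_uniformity`,
#'   `n_outlier_loci`, `dispersion_ratio`, `contamination_flag`, `checks`
#'   (named logicals) and `pass`.
#' @export
qc_sample <- function(sample, thresholds = qc_thresholds(), calls = NULL) {
  pileup <- if (inherits(sample, "cfdna_sample")) sample$pileup else sample
  cnt <- as.matrix(pileup[, BASES])
  depth <- rowSums(cnt)
  total_reads <- sum(depth)
  depth_cv <- if (mean(depth) > 0) stats::sd(depth) / mean(depth) else Inf

  if (is.null(calls)) {
    calls <- compute_allele_fractions(pileup)
    calls <- classify_informative(calls)
    bg <- tryCatch(estimate_background_error(calls), error = function(e) 0)
    calls <- split_signal_background(calls, bg)
  }
  sig <- calls$status == "informative_signal"
  x <- calls$minor_fraction[sig]
  n_outlier <- 0L
  dispersion_ratio <- NA_real_
  if (length(x) >= 3L) {
    x2 <- ifelse(assign_het_clusters(x), 2 * x, x)
    med <- stats::median(x2)
    mad <- stats::mad(x2)
    n_two_base <- stats::median(calls$major_count[sig] +
                                  calls$minor_count[sig])
    binom_sd <- sqrt(max(med, 1e-6) / max(n_two_base, 1))
    dispersion_ratio <- mad / binom_sd
    # floor the spread at the binomial noise scale so a tight cluster does
    # not flag its own tails
    spread <- max(mad, binom_sd)
    n_outlier <- sum(abs(x2 - med) > thresholds$outlier_k_mad * spread)
  }
  contamination_flag <- n_outlier > thresholds$max_outlier_loci ||
    (!is.na(dispersion_ratio) &&
       dispersion_ratio > thresholds$max_dispersion_ratio)
  checks <- c(
    total_reads = total_reads >= thresholds$min_total_reads,
    depth_uniformity = depth_cv <= thresholds$max_depth_cv,
    contamination = !contamination_flag
  )
  structure(
    list(
      total_reads = as.integer(total_reads),
      depth_uniformity = depth_cv,
      n_outlier_loci = as.integer(n_outlier),
      dispersion_ratio = dispersion_ratio,
      contamination_flag = contamination_flag,
      checks = checks,
      pass = all(checks)
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s | total reads %s, depth CV %.3f, outlier loci %d%s\n",
    if (x$pass) "pass" else "FAIL",
    format(x$total_reads, big.mark = ","), x$depth_uniformity,
    x$n_outlier_loci,
    if (x$contamination_flag) " [contamination suspected]" else ""
  ))
  invisible(x)
}

#' Dichotomize a dd-cfDNA estimate at a cutoff
#'
#' The clinical decision rule flags results at or above the cutoff
#' (inclusive, default 1.0%) as elevated.
#'
#' @param result A `ddcfdna_result` or a numeric dd-cfDNA percentage.
#' @param cutoff Non-negative percent cutoff (default 1.0).
#' @return `"elevated"` or `"not_elevated"` (vectorized over numeric input).
#' @examples
#' classify_cutoff(1.0)   # "elevated"
#' classify_cutoff(0.99)  # "not_elevated"
#' @export
classify_cutoff <- function(result, cutoff = 1.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0) {
    stop("`cutoff` must be a non-negative percent", call. = FALSE)
  }
  value <- if (inherits(result, "ddcfdna_result")) {
    result$dd_fraction_percent
  } else {
    result
  }
  ifelse(value >= cutoff, "elevated", "not_elevated")
}
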