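# Shared fixtures and independent oracles used across the test files.

# A pileup data.frame from explicit per-locus counts.
make_pileup <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    cnt <- rows[[i]]
    data.frame(locus_id = sprintf("L%02d", i),
               A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4])
  }))
  df
}

# Relaxed QC for tiny hand-built samples.
tiny_quant_config <- function(...) {
  quant_config(qc = qc_thresholds(min_total_reads = 0), ...)
}

# Toy eplet table: three class II alleles with known repertoires.
toy_eplet_table <- function() {
  load_eplet_table(data.frame(
    allele = c(rep("DQB1*01:01", 3), "DQB1*02:01", rep("DQB1*03:01", 2)),
    eplet = c("e1", "e2", "e3", "e1", "e4", "e5"),
    class = "II"
  ))
}

one_locus_typing <- function(locus, a1, a2 = a1) {
  hla_typing(data.frame(locus = locus, allele1 = a1, allele2 = a2))
}

# Brute-force eplet mismatch oracle: accumulate donor eplets one allele at
# a time and strike out anything the recipient carries.
brute_force_load <- function(donor_alleles, recipient_alleles, table) {
  donor_ep <- character(0)
  for (a in donor_alleles) {
    donor_ep <- union(donor_ep, table$eplet[table$allele == a])
  }
  recip_ep <- character(0)
  for (a in recipient_alleles) {
    recip_ep <- union(recip_ep, table$eplet[table$allele == a])
  }
  sum(!donor_ep %in% recip_ep)
}

# Numerical-integration oracle for the Rosendaal TTR: sample the piecewise
# linear trajectory at the midpoints of a fine grid (50k cells, so the
# quadrature error stays well below 0.01 percentage points regardless of
# the series' span) and count time in/above range.
ttr_numeric_oracle <- function(series, low = 8, high = 12, n_cells = 5e4) {
  span <- max(series$day) - min(series$day)
  step <- span / n_cells
  t_mid <- min(series$day) + (seq_len(n_cells) - 0.5) * step
  y <- approx(series$day, series$level, xout = t_mid)$y
  c(
    in_range = 100 * mean(y >= low & y <= high),
    above = 100 * mean(y > high)
  )
}

# Full-enumeration Mann-Whitney oracle for small untied samples: the
# two-sided p is the null share of arrangements at least as extreme (in
# |U - nA*nB/2|) as observed.
mw_exact_oracle <- function(a, b) {
  nA <- length(a)
  nB <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    xa <- pooled[idx]
    xb <- pooled[-idx]
    sum(outer(xa, xb, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  centre <- nA * nB / 2
  combos <- utils::combn(nA + nB, nA)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - centre) >= abs(u_obs - centre))
}

# A well-separated synthetic pileup: `n_bg` pure-background loci plus
# `n_sig` clear donor-signal loci at the given minor fraction.
separated_pileup <- function(n_bg = 20, n_sig = 10, depth = 1000,
                             signal_fraction = 0.02) {
  sig_minor <- round(depth * signal_fraction)
  df <- rbind(
    data.frame(locus_id = sprintf("B%02d", seq_len(n_bg)),
               A = 0, C = 0, G = depth, T = 0),
    data.frame(locus_id = sprintf("S%02d", seq_len(n_sig)),
               A = sig_minor, C = 0, G = depth - sig_minor, T = 0)
  )
  df
}
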