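---
title: "Genotype-free dd-cfDNA quantification and cohort analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-free dd-cfDNA quantification and cohort analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcfdna)
```

## The measurement problem

After a kidney transplant, a fraction of the circulating cell-free DNA
(cfDNA) in the recipient's plasma originates from the graft. That donor
fraction — dd-cfDNA%, typically well below 5% — rises with graft injury and
is used as a non-invasive rejection biomarker, with 1.0% as the
conventional decision cutoff. Targeted assays read a panel of a few hundred
common biallelic SNPs (here 202, spread over the 22 autosomes) at high
depth and must estimate the donor fraction **without donor or recipient
genotypes**, because only the post-transplant plasma sample is available.

The estimator in this package works from the per-locus nucleotide read
counts alone:

1. **Allele fractions.** At each locus the two most-read bases define the
   major and minor allele; the minor fraction is
   $x_i = m_i / (M_i + m_i)$ over the two-base total. Ties are broken by
   the fixed base order A < C < G < T so results are deterministic. Loci
   below a minimum depth (default 100 reads) are excluded.
2. **Heterozygous exclusion.** If both two-base shares lie inside the
   closed band [30%, 70%], the recipient is heterozygous at that locus and
   it carries no usable donor signal; only loci with shares strictly
   outside the band remain homozygous candidates. We read "outside" as
   strict, so shares of exactly 30/70 are excluded — the conservative
   choice at the boundary.
3. **Background separation.** Among homozygous candidates, loci where the
   donor happens to carry the same homozygous genotype show only
   sequencing error. With uniform substitution errors at rate $e$, the
   minor base collects about $e/3$ of the reads. The background is first
   estimated as the median of the lowest-fraction half of the candidates,
   then refined iteratively: after a provisional signal/background split,
   the background class is re-estimated from its own loci (its median when
   it is unimodal at binomial-noise width; its lower quartile when its
   spread or median/quartile gap betrays censored donor-signal loci still
   inside it). A candidate is called **informative signal** when
   $x_i > \hat e + k \sqrt{\hat e(1-\hat e)/n_i}$ with $k = 3$ at its own
   two-base depth $n_i$. This separation step is not specified by the
   assay vendor; it is this package's documented interpretation, required
   for the average over "informative" loci to be meaningful at all.
4. **Averaging and the donor-heterozygote correction.** Informative loci
   are of two kinds: donor homozygous for the other allele (minor fraction
   ≈ $f$) and donor heterozygous (≈ $f/2$). Under Hardy–Weinberg sampling
   with panel frequencies near 0.5, heterozygous informative loci
   outnumber homozygous ones roughly 2:1, so the plain average of minor
   fractions estimates only about 0.65·$f$. The package exposes both
   conventions:
   * `paper_faithful` — the plain average of the informative-SNP minor
     fractions, mirroring the assay software's described computation;
   * `bias_corrected` (default) — background-subtracted fractions are
     assigned to the $f$ vs $f/2$ clusters by a deterministic fixed-point
     iteration (initialised at the 90th percentile, boundary at
     $0.75\hat f$, the midpoint of the two cluster centres), the
     heterozygous cluster is doubled, and the result averaged. The
     background subtraction matters at low fractions: without it the
     $e/3$ error floor (≈ 0.03 percentage points at $e = 0.1\%$) plus its
     doubling would consume much of the accuracy budget at $f = 0.5\%$.

   The whole-panel average is unweighted; whether the commercial
   implementation weights loci by depth is unstated, and unweighted is the
   simpler convention.

In simulations at depth 5000 and error 0.1% (200 replicates per point,
202 loci), `bias_corrected` recovers true fractions of 0.5–5% with mean
relative bias under 7%, while `paper_faithful` shows the predicted ≈ 35%
heterozygote dilution. Both numbers are recomputed by the test suite and
`scripts/acceptance.R`; nothing in this vignette is asserted beyond what
those runs compute.

## Quality control

Three sample-level checks, with configurable thresholds
(`qc_thresholds()`), mirror the assay's stated quality parameters:

* **Total reads** (default minimum 10^5^): failing this refuses the
  estimate outright.
* **Depth uniformity**: the coefficient of variation of per-locus depth
  (default maximum 1.0).
* **Contamination**: a third genome in the sample scatters loci away from
  the single donor-fraction cluster. Two detectors run on the
  heterozygote-doubled signal fractions: a count of loci deviating more
  than 4 median absolute deviations from the cluster median (flag above
  10 loci), and a dispersion ratio — the robust spread divided by the
  binomial noise expected at the cluster's depth — with threshold 2.0. In
  calibration simulations a clean sample's ratio stays below ≈ 1.8 across
  donor fractions 0.5–5%, while a 5% contaminant pushes it above 2 in the
  large majority of replicates; the combination flags ≥ 80% of 5%-spiked
  samples with no false flags observed in clean ones.

The detection limit of the estimator itself sits near the error floor:
donor fractions approaching $e/3$ per locus (≈ 0.03% at the default error
rate) cannot be separated from background, and heterozygous-locus signal
(at $f/2$) is censored first.

## HLA mismatch loads

Eplets are small polymorphic amino-acid configurations on HLA molecules;
the **eplet mismatch load** counts eplets carried by the donor's alleles
(union over both alleles, so homozygosity counts once) and absent from the
recipient's repertoire, within a scope — one locus, class I (A, B, C) or
class II. The computation consumes a long-format allele→eplet table in the
style of HLAMatchmaker / HLA Epitope Registry exports; the package ships
no registry data and any table in that schema can be supplied. Antigen
mismatches truncate allele names to their first field and count donor
antigen names absent from the recipient, 0–2 per locus, by default over
A, B, C, DRB1, DQA1, DQB1 (maximum 12). The load is directional
(donor-against-recipient) and deliberately asymmetric.

Pooled class II loads can exceed the sum of the three routinely reported
loci (DRB1, DQB1, DQA1) because typings may include further class II loci
(DRB3/4/5, DP); conversely, an eplet shared across loci is counted once in
the pooled scope, so the pooled load is bounded above by the per-locus
sum over the same loci.

## Immunosuppressive exposure

Tacrolimus trough series over the first month are summarised by:

* **Rosendaal time in therapeutic range**: the trough trajectory is
  interpolated linearly between observations, range crossings are solved
  exactly on each segment, and time in [8, 12] ng/mL and above 12 ng/mL is
  expressed as a percentage of the first-to-last observation span (no
  extrapolation outside the observed span). Boundary levels count as in
  range; "above" is strict.
* **CV%** = 100·sd/mean over all levels, with the sample (n−1) standard
  deviation — the usual intra-patient variability metric; the population
  variant differs by a factor immaterial at these series lengths but the
  choice is stated here for reproducibility.
* **C/D ratio**: month-1 trough (the observation nearest day 30, later day
  on ties) divided by the daily dose; ratios strictly below 1.05 define
  fast metabolizers.
* **Low-exposure flags**: any level strictly below 5 (resp. 6) ng/mL at
  any time in the month. All three thresholds are strict, reading "below"
  literally.

Whether the study's TTR denominator began at day 0 or the first
measurement is unstated; this package uses the first measurement, the
standard Rosendaal convention.

## Cohort statistics

Patients are dichotomized at the 1.0% cutoff (inclusive: 1.00% is
elevated). Continuous variables are summarised as median [IQR] (linear
interpolation between order statistics, `quantile()` type 7) and compared
with the Mann–Whitney U test — exact by enumeration when the combined
sample is ≤ 12 without ties, otherwise the tie-corrected normal
approximation with continuity correction. Binary variables use the
uncorrected Pearson chi-square on the 2×2 table; the uncorrected statistic
reproduces the published association p-values from their printed counts
(0.004, 0.041, 0.013), which fixes the convention, and a Yates-corrected
variant remains available by flag. ROC analyses report the
trapezoidal/Mann–Whitney AUC with a DeLong 95% interval (Hanley–McNeil
optional); the score direction is fixed so cases are expected to score
higher, and an AUC below 0.5 is reported as such rather than silently
flipped.

The covariate-adjusted association between an elevated result and AbMR is
fitted as a Firth-penalized logistic regression (outcome ~ elevated +
eGFR), written in-package as a modified-score IRLS with step damping. It
is labelled an *analogue*: the published hazard-ratio-style estimate comes
from an unstated model family on unavailable patient-level data, so no
numerical agreement is claimed — the penalized fit simply provides a
finite, separation-robust effect estimate on the same question.

## The synthetic cohort generator

No patient-level data are deposited, so the pipeline is exercised on a
generator whose defaults encode the study conditions:

* **Outcome strata** for n = 42: AbMR 5/42, other acute rejection 2/42,
  other graft trouble (obstruction, infection) 7/42, the rest untroubled —
  giving the label hierarchy AbMR ⊂ acute rejection ⊂ troubled graft by
  construction, and a first-year rejection probability topped up to
  ≈ 21% by later events.
* **True donor fractions** are log-normal per stratum (positive and
  right-skewed, as observed concentrations are): medians 1.64% (AbMR),
  0.64% (other rejection), 1.00% (other trouble), 0.50% (untroubled), with
  sdlog 0.5–0.6 chosen to match the published group IQRs (1.15 and 0.42
  around the AbMR and untroubled medians).
* **Reads**: per-locus depth is negative binomial (mean 5000, size 10 —
  realistic non-uniformity for the QC check; the assay publishes no
  depths), sequencing error 0.1% uniform substitution (unpublished;
  a typical targeted-NGS floor), panel allele frequencies Uniform(0.3,
  0.7) as chimerism panels select common variants. Reads are multinomial
  draws from the recipient/donor (plus optional contaminant) mixture.
* **Eplet loads** are negative binomial per component with means set so
  the component *medians* hit the published group medians (class I 20/16,
  DRB1 10/9, DQB1 9/7, DQA1 3/1 for latent-elevated vs not). A DPB1
  component (medians 24/4) stands for the class II loci beyond the three
  reported ones, lifting the class II totals to medians near 46 vs 21 as
  published. Typings and a synthetic eplet table are then *constructed*
  to realize the drawn loads exactly (patient-private alleles and
  eplets), which gives the load computation an exact round-trip test.
  The table is synthetic and is not the HLA Epitope Registry.
* **Tacrolimus**: patient mean levels normal around 12.5 ng/mL (between-
  patient SD 2), within-patient log-normal variation at CV 28%, constant
  daily dose around 7.5 mg — matching the published exposure medians
  (mean trough 12.5, CV ≈ 28%, C/D ratio ≈ 1.7).
* **Covariates**: log-normal eGFR (medians 43/51 by latent group),
  albuminuria (57.5/53) and MPA trough (2.0).

Each patient is generated from a seed drawn from the master seed, so a
configuration reproduces its dataset bit for bit.

What the generator does **not** emulate: linkage between panel SNPs,
related donors (relatedness halves informative-locus yield), UMI/PCR
duplicate structure, GC- or fragment-length-dependent depth, real HLA
allele and eplet frequencies, treatment-driven feedback between exposure
and outcome, and longitudinal dd-cfDNA kinetics. Passing tests therefore
demonstrate correctness of the computations under the stated statistical
model, not clinical performance on real samples.

## Numerical choices and degenerate inputs

* Ties in base counts, in cluster assignment and in nearest-day lookups
  are broken deterministically (base order, midpoint boundary, later
  day).
* A sample with no informative-signal loci reports 0% with a `no_signal`
  flag rather than NA, and a sample below the total-read floor refuses
  estimation with a diagnostic.
* Background estimation needs ≥ 10 homozygous candidates; below that the
  background is taken as 0 and flagged (`background_assumed_zero`) — the
  right behaviour for tiny hand-built examples.
* The Firth IRLS runs to a 10^-8^ step tolerance with steps capped at 5
  on the logit scale; non-convergence is reported, not hidden.
* The fixed-point cluster assignment runs at most 100 sweeps and is
  deterministic given the data.

## Problem sizes used by the checks

The test suite and acceptance script size their simulations as: 200
replicates per true fraction for parameter recovery; 100 replicates for
contamination detection; 100 random series for the TTR-vs-quadrature
comparison; 100 cohorts of n = 500 (truth-level, no reads) for the
group-structure reproduction; and an ensemble of 25 read-level cohorts of
n = 42 for the end-to-end figures. These sizes give Monte-Carlo standard
errors comfortably below the tolerances they are checked against.
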