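Package: ddcfdna
Title: Genotype-Free Donor-Derived Cell-Free DNA Quantification and
    Kidney-Transplant Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the donor fraction of plasma cell-free DNA
    after kidney transplantation from targeted SNP read counts without prior
    donor or recipient genotyping, and for relating it to pre-transplant HLA
    compatibility and immunosuppressive exposure. Implements homozygous
    informative-SNP selection by the 30-70 percent two-base-share rule,
    background-error separation, donor-heterozygote bias correction, and
    sample quality control; HLA antigen and eplet mismatch loads from
    donor/recipient typings and an allele-to-eplet table; Rosendaal
    time-in-therapeutic-range, coefficient-of-variation and
    concentration/dose metrics for tacrolimus trough series; and the
    dichotomized cohort statistics (Mann-Whitney, chi-square, ROC with
    DeLong intervals, penalized logistic association). A seeded synthetic
    cohort generator emulates the read-count, mismatch-load and
    drug-exposure structure of a one-month post-transplant cohort for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pROC,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
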