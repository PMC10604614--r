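CLASS_I_LOCI <- c("A", "B", "C")
CLASS_II_LOCI <- c("DRB1", "DRB3", "DRB4", "DRB5",
                   "DQA1", "DQB1", "DPA1", "DPB1")

#' Construct an HLA typing
#'
#' @param df `data.frame` with columns `locus`, `allele1`, `allele2`
#'   (allele name strings; homozygosity is a repeated name).
#' @return A `data.frame` of class `hla_typing`, one row per typed locus.
#' @export
hla_typing <- function(df) {
  need <- c("locus", "allele1", "allele2")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("typing needs columns locus, allele1, allele2", call. = FALSE)
  }
  if (anyDuplicated(df$locus)) {
    stop("each locus may appear only once in a typing", call. = FALSE)
  }
  out <- data.frame(
    locus = as.character(df$locus),
    allele1 = as.character(df$allele1),
    allele2 = as.character(df$allele2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hla_typing", "data.frame")
  out
}

#' Load an allele-to-eplet table
#'
#' Reads (or validates) a long-format table mapping each HLA allele to the
#' eplets its protein carries, in the style of HLAMatchmaker / HLA Epitope
#' Registry exports: one row per (allele, eplet) with the eplet's HLA class.
#' Duplicate rows are collapsed (set semantics).
#'
#' @param x Path to a CSV with columns `allele`, `eplet`, `class`, or an
#'   equivalent `data.frame`.
#' @return A `data.frame` of class `eplet_table`.
#' @export
load_eplet_table <- function(x) {
  tab <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    x
  }
  need <- c("allele", "eplet", "class")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("eplet table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab <- data.frame(
    allele = as.character(tab$allele),
    eplet = as.character(tab$eplet),
    class = as.character(tab$class),
    stringsAsFactors = FALSE
  )
  if (any(is.na(tab$allele)) || any(tab$allele == "") ||
      any(is.na(tab$eplet)) || any(tab$eplet == "")) {
    stop("eplet table has malformed allele/eplet entries", call. = FALSE)
  }
  if (!all(tab$class %in% c("I", "II"))) {
    stop("eplet class labels must be 'I' or 'II'", call. = FALSE)
  }
  tab <- unique(tab)
  class(tab) <- c("eplet_table", "data.frame")
  tab
}

# Union of eplets over the alleles of `typing` at `loci`, restricted to
# `eplet_class` when given. Errors on alleles absent from the table.
#' @noRd
eplet_union <- function(typing, table, loci, eplet_class = NULL) {
  rows <- typing[typing$locus %in% loci, , drop = FALSE]
  alleles <- unique(c(rows$allele1, rows$allele2))
  known <- unique(table$allele)
  absent <- setdiff(alleles, known)
  if (length(absent)) {
    stop(sprintf("allele(s) missing from eplet table: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- table[table$allele %in% alleles, , drop = FALSE]
  if (!is.null(eplet_class)) {
    sub <- sub[sub$class == eplet_class, , drop = FALSE]
  }
  unique(sub$eplet)
}

#' @noRd
resolve_scope <- function(typing, scope) {
  if (length(scope) == 1L && scope %in% c("classI", "classII")) {
    loci <- intersect(
      typing$locus,
      if (scope == "classI") CLASS_I_LOCI else CLASS_II_LOCI
    )
    list(loci = loci, class = sub("class", "", scope))
  } else {
    missing_loci <- setdiff(scope, typing$locus)
    if (length(missing_loci)) {
      stop(sprintf("locus/loci absent from typing: %s",
                   paste(missing_loci, collapse = ", ")), call. = FALSE)
    }
    list(loci = scope, class = NULL)
  }
}

#' Eplet mismatch load
#'
#' Counts the eplets present on the donor's alleles (union over both
#' alleles, so homozygosity counts once) but absent from the recipient's
#' eplet repertoire, within the requested scope. This is the directed
#' donor-against-recipient load that drives antibody recognition; it is not
#' symmetric in donor and recipient.
#'
#' @param donor,recipient [hla_typing] objects.
#' @param table An [load_eplet_table()] table.
#' @param scope `"classI"`, `"classII"`, or a character vector of loci
#'   (e.g. `"DQB1"`).
#' @return Integer load (non-negative).
#' @export
eplet_mismatch_load <- function(donor, recipient, table, scope = "classII") {
  sc_d <- resolve_scope(donor, scope)
  sc_r <- resolve_scope(recipient, scope)
  e_donor <- eplet_union(donor, table, sc_d$loci, sc_d$class)
  e_recip <- eplet_union(recipient, table, sc_r$loci, sc_r$class)
  length(setdiff(e_donor, e_recip))
}

#' Antigen-level HLA mismatch count
#'
#' Antigen names are derived by truncating allele names to their first
#' field (before the `:`). Per locus, the donor's unique antigen names not
#' carried by the recipient count as mismatches (0-2 per locus), summed
#' over the requested loci.
#'
#' @param donor,recipient [hla_typing] objects covering `loci`.
#' @param loci Loci to count over (default A, B, C, DRB1, DQA1, DQB1;
#'   maximum mismatch 12).
#' @return Integer mismatch count.
#' @export
antigen_mismatch_count <- function(donor, recipient,
                                   loci = c("A", "B", "C",
                                            "DRB1", "DQA1", "DQB1")) {
  missing_loci <- setdiff(loci, intersect(donor$locus, recipient$locus))
  if (length(missing_loci)) {
    stop(sprintf("locus/loci absent from typing: %s",
                 paste(missing_loci, collapse = ", ")), call. = FALSE)
  }
  antigen <- function(a) sub(":.*$", "", a)
  total <- 0L
  for (lc in loci) {
    d <- donor[donor$locus == lc, ]
    r <- recipient[recipient$locus == lc, ]
    d_ag <- unique(antigen(c(d$allele1, d$allele2)))
    r_ag <- unique(antigen(c(r$allele1, r$allele2)))
    total <- total + length(setdiff(d_ag, r_ag))
  }
  total
}

#' Mismatch loads for one donor-recipient pair
#'
#' @param donor,recipient [hla_typing] objects.
#' @param table Eplet table.
#' @param antigen_loci Loci entering the antigen mismatch count.
#' @return One-row `data.frame`: `antigen_mm_total`, `classI_eplet_load`,
#'   `classII_eplet_load`, and per-locus loads `drb1_eplet_load`,
#'   `dqb1_eplet_load`, `dqa1_eplet_load` (plus `dpb1_eplet_load` when
#'   DPB1 is typed).
#' @export
mismatch_loads <- function(donor, recipient, table,
                           antigen_loci = c("A", "B", "C",
                                            "DRB1", "DQA1", "DQB1")) {
  per_locus <- function(lc) {
    if (lc %in% donor$locus && lc %in% recipient$locus) {
      eplet_mismatch_load(donor, recipient, table, scope = lc)
    } else {
      NA_integer_
    }
  }
  out <- data.frame(
    antigen_mm_total = antigen_mismatch_count(donor, recipient, antigen_loci),
    classI_eplet_load = eplet_mismatch_load(donor, recipient, table, "classI"),
    classII_eplet_load = eplet_mismatch_load(donor, recipient, table,
                                             "classII"),
    drb1_eplet_load = per_locus("DRB1"),
    dqb1_eplet_load = per_locus("DQB1"),
    dqa1_eplet_load = per_locus("DQA1"),
    stringsAsFactors = FALSE
  )
  if ("DPB1" %in% donor$locus) {
    out$dpb1_eplet_load <- per_locus("DPB1")
  }
  out
}

#' Mismatch loads for a whole cohort
#'
#' Applies [mismatch_loads()] to every donor-recipient pair of a cohort,
#' reading typings from the cohort's long-format typing table.
#'
#' @param cohort A `cohort_dataset` from [simulate_cohort()], or a
#'   long-format typing `data.frame` with columns `patient_id`, `role`
#'   (`"donor"`/`"recipient"`), `locus`, `allele1`, `allele2`.
#' @param table Eplet table; defaults to the cohort's own table when a
#'   `cohort_dataset` is given.
#' @param antigen_loci Passed to [mismatch_loads()].
#' @return `data.frame` with one row per patient, `patient_id` first.
#' @export
cohort_loads <- function(cohort, table = NULL,
                         antigen_loci = c("A", "B", "C",
                                          "DRB1", "DQA1", "DQB1")) {
  if (inherits(cohort, "cohort_dataset")) {
    typings <- cohort$typings
    if (is.null(table)) {
      table <- cohort$eplet_table
    }
  } else {
    typings <- cohort
  }
  if (is.null(table)) {
    stop("an eplet table is required", call. = FALSE)
  }
  ids <- unique(typings$patient_id)
  rows <- lapply(ids, function(id) {
    tt <- typings[typings$patient_id == id, ]
    donor <- hla_typing(tt[tt$role == "donor", ])
    recip <- hla_typing(tt[tt$role == "recipient", ])
    cbind(
      data.frame(patient_id = id, stringsAsFactors = FALSE),
      mismatch_loads(donor, recip, table, antigen_loci)
    )
  })
  do.call(rbind, rows)
}
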