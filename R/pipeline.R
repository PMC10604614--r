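#' Quantify every sample of a cohort
#'
#' @param cohort A `cohort_dataset` with read pileups.
#' @param mode Estimator mode, see [estimate_dd_fraction()].
#' @param config A [quant_config()].
#' @return `data.frame` with `patient_id`, `dd_fraction_percent`,
#'   `n_informative`, `qc_pass`.
#' @export
quantify_cohort <- function(cohort, mode = "bias_corrected",
                            config = quant_config()) {
  if (!length(cohort$samples)) {
    stop("cohort has no read pileups (generate_reads was FALSE?)",
         call. = FALSE)
  }
  rows <- lapply(cohort$samples, function(s) {
    res <- estimate_dd_fraction(s, mode = mode, config = config)
    data.frame(
      patient_id = s$patient_id,
      dd_fraction_percent = res$dd_fraction_percent,
      n_informative = res$n_informative,
      qc_pass = res$qc$pass,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @noRd
exposure_table <- function(tacro, mpa_by_patient) {
  ids <- unique(tacro$patient_id)
  rows <- lapply(ids, function(id) {
    s <- tacro[tacro$patient_id == id, ]
    m <- summarize_exposure(
      tacrolimus_series(s$day, s$level, s$dose),
      mpa_trough = mpa_by_patient[[id]]
    )
    data.frame(
      patient_id = id,
      ttr_8_12 = m$ttr_8_12, ttr_above_12 = m$ttr_above_12,
      mean_level = m$mean_level, cv_percent = m$cv_percent,
      trough_month1 = m$trough_month1, cd_ratio = m$cd_ratio,
      fast_metabolizer = m$fast_metabolizer,
      any_below_5 = m$any_below_5, any_below_6 = m$any_below_6,
      mpa_trough = m$mpa_trough,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full synthetic study pipeline
#'
#' Simulates a cohort, quantifies every sample, computes mismatch loads
#' and exposure metrics, and assembles the dichotomized group-comparison
#' tables and ROC analyses for AbMR, acute rejection and troubled graft.
#' Reruns with the same configuration are bit-identical.
#'
#' @param config A [cohort_config()] (must have `generate_reads = TRUE`).
#' @param quant A [quant_config()] for the estimator.
#' @param cutoff Cutoff (%) splitting the cohort (default 1.0, inclusive).
#' @param out_dir Optional directory; when given, tables are written as
#'   TSV and test/ROC results as JSON (requires the jsonlite package).
#' @return A list of class `ddcfdna_report`: `data` (the merged per-patient
#'   table), `table_clinical`, `table_mismatch`, `rocs` (list of
#'   `roc_result` for abmr/rejection/troubled), `association`
#'   (AbMR ~ elevated + eGFR), `qc_fail_ids`, `cohort`, `cutoff`, `seed`.
#' @export
run_pipeline <- function(config = cohort_config(seed = 1),
                         quant = quant_config(),
                         cutoff = 1.0,
                         out_dir = NULL) {
  cohort <- simulate_cohort(config)
  estimates <- quantify_cohort(cohort, config = quant)
  loads <- cohort_loads(cohort)
  mpa <- stats::setNames(as.list(cohort$patients$mpa_trough),
                         cohort$patients$patient_id)
  exposures <- exposure_table(cohort$tacrolimus, mpa)

  data <- Reduce(
    function(a, b) merge(a, b, by = "patient_id"),
    list(cohort$patients, estimates, loads,
         exposures[, setdiff(names(exposures), "mpa_trough")])
  )

  clinical_vars <- c("rejection_1m", "abmr_1m", "troubled_1m",
                     "rejection_1y", "egfr_1m", "albuminuria_1m",
                     "ttr_8_12", "ttr_above_12", "mean_level",
                     "trough_month1", "mpa_trough", "any_below_5",
                     "any_below_6", "cv_percent", "cd_ratio",
                     "fast_metabolizer")
  mismatch_vars <- c("antigen_mm_total", "classI_eplet_load",
                     "classII_eplet_load", "drb1_eplet_load",
                     "dqb1_eplet_load", "dqa1_eplet_load")
  table_clinical <- build_group_comparison(data, clinical_vars,
                                           cutoff = cutoff)
  table_mismatch <- build_group_comparison(data, mismatch_vars,
                                           cutoff = cutoff)

  roc_for <- function(label_col) {
    tryCatch(
      roc_auc_ci(data$dd_fraction_percent, data[[label_col]]),
      error = function(e) NULL
    )
  }
  rocs <- list(
    abmr = roc_for("abmr_1m"),
    rejection = roc_for("rejection_1m"),
    troubled = roc_for("troubled_1m")
  )
  association <- tryCatch(
    adjusted_association(
      data$abmr_1m,
      classify_cutoff(data$dd_fraction_percent, cutoff) == "elevated",
      data$egfr_1m
    ),
    error = function(e) NULL
  )

  report <- structure(
    list(
      data = data,
      table_clinical = table_clinical,
      table_mismatch = table_mismatch,
      rocs = rocs,
      association = association,
      qc_fail_ids = data$patient_id[!data$qc_pass],
      cohort = cohort,
      cutoff = cutoff,
      seed = config$seed
    ),
    class = "ddcfdna_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

#' @noRd
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed: %s | cutoff: %g", report$seed, report$cutoff)
  for (nm in c("table_clinical", "table_mismatch")) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      as.data.frame(report[[nm]]), path, sep = "\t", row.names = FALSE,
      quote = FALSE, append = TRUE
    ))
  }
  utils::write.table(report$data, file.path(out_dir, "patients.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    rocs <- lapply(report$rocs, function(r) {
      if (is.null(r)) NULL else r[c("auc", "ci_low", "ci_high",
                                    "n_pos", "n_neg")]
    })
    jsonlite::write_json(
      list(seed = report$seed, cutoff = report$cutoff, rocs = rocs),
      file.path(out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(out_dir)
}

#' @export
print.ddcfdna_report <- function(x, ...) {
  n <- attr(x$table_clinical, "group_n")
  cat(sprintf(
    "<ddcfdna_report> %d patients | dd-cfDNA >= %.1f%% (n = %d) vs < %.1f%% (n = %d)\n",
    n["total"], x$cutoff, n["elevated"], x$cutoff, n["not_elevated"]
  ))
  for (nm in names(x$rocs)) {
    r <- x$rocs[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  ROC %-9s AUC %.1f%% (95%%CI %.1f-%.1f)\n",
                  nm, 100 * r$auc, 100 * r$ci_low, 100 * r$ci_high))
    }
  }
  cat("\nClinical comparison:\n")
  print(x$table_clinical)
  cat("\nHLA mismatch comparison:\n")
  print(x$table_mismatch)
  invisible(x)
}

#' Validate a set of pipeline input files
#'
#' Schema-checks each provided input (path or data.frame) and checks
#' cross-file identifier consistency: every patient in the outcomes table
#' should have a sample, a donor and recipient typing, and a drug series.
#' Returns diagnostics instead of erroring so all problems are reported
#' at once.
#'
#' @param outcomes `data.frame`/CSV path with `patient_id` plus outcome
#'   columns.
#' @param pileups Named list of `cfdna_sample` (names = patient ids), or
#'   `NULL`.
#' @param typings Typings table/path (see [read_typings()]), or `NULL`.
#' @param eplet_table Eplet table/path, or `NULL`.
#' @param series Tacrolimus table/path (see [read_tacrolimus()]), or
#'   `NULL`.
#' @return Character vector of diagnostics; empty when everything is
#'   consistent.
#' @export
validate_inputs <- function(outcomes = NULL, pileups = NULL, typings = NULL,
                            eplet_table = NULL, series = NULL) {
  diags <- character(0)
  note <- function(...) diags <<- c(diags, sprintf(...))
  # read from path (or pass a data.frame through), then apply the same
  # schema validation either way; failures become diagnostics
  load_df <- function(x, reader, need, what) {
    tryCatch({
      df <- if (is.character(x)) {
        utils::read.csv(x, stringsAsFactors = FALSE)
      } else {
        x
      }
      check_columns(df, need, what)
      reader(df)
    }, error = function(e) {
      note("%s: %s", what, conditionMessage(e))
      NULL
    })
  }
  outcomes_df <- if (!is.null(outcomes)) {
    load_df(outcomes, identity, "patient_id", "outcomes")
  }
  typings_df <- if (!is.null(typings)) {
    load_df(typings, identity,
            c("patient_id", "role", "locus", "allele1", "allele2"),
            "typings")
  }
  series_df <- if (!is.null(series)) {
    load_df(series, identity, c("patient_id", "day", "level", "dose"),
            "tacrolimus series")
  }
  if (!is.null(eplet_table)) {
    tab <- load_df(eplet_table, load_eplet_table,
                   c("allele", "eplet", "class"), "eplet table")
    if (!is.null(tab) && !is.null(typings_df)) {
      used <- unique(c(typings_df$allele1, typings_df$allele2))
      absent <- setdiff(used, tab$allele)
      if (length(absent)) {
        note("eplet table: %d typed allele(s) missing, e.g. %s",
             length(absent), absent[1L])
      }
    }
  }
  if (!is.null(outcomes_df)) {
    ids <- unique(outcomes_df$patient_id)
    check_cover <- function(have, what) {
      orphan_out <- setdiff(ids, have)
      orphan_in <- setdiff(have, ids)
      if (length(orphan_out)) {
        note("%s: no entry for patient(s) %s", what,
             paste(orphan_out, collapse = ", "))
      }
      if (length(orphan_in)) {
        note("%s: unknown patient(s) %s", what,
             paste(orphan_in, collapse = ", "))
      }
    }
    if (!is.null(pileups)) {
      check_cover(names(pileups), "pileups")
    }
    if (!is.null(typings_df)) {
      check_cover(unique(typings_df$patient_id), "typings")
      by_role <- table(unique(typings_df[, c("patient_id", "role")]))
      if (any(by_role < 1)) {
        note("typings: some patients lack a donor or recipient typing")
      }
    }
    if (!is.null(series_df)) {
      check_cover(unique(series_df$patient_id), "series")
    }
  }
  diags
}
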