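#' @noRd
check_columns <- function(df, need, what) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a SNP panel CSV
#'
#' Columns: `locus_id`, `chromosome`, `ref`, `alt`, `alt_freq`.
#'
#' @param path File path.
#' @return An [snp_panel].
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("locus_id", "chromosome", "ref", "alt", "alt_freq"),
                "panel file")
  snp_panel(df$locus_id, df$chromosome, df$ref, df$alt, df$alt_freq)
}

#' @rdname read_panel
#' @param panel An [snp_panel] to write.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a read-count pileup TSV
#'
#' Columns: `locus_id`, `A`, `C`, `G`, `T` (integer read counts).
#'
#' @param path File path.
#' @param sample_id,patient_id,collection_day Metadata attached to the
#'   returned sample.
#' @return A `cfdna_sample`.
#' @export
read_pileup <- function(path, sample_id = basename(path), patient_id = NA,
                        collection_day = 30) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("locus_id", BASES), "pileup file")
  cfdna_sample(sample_id, patient_id, collection_day, df)
}

#' @rdname read_pileup
#' @param sample A `cfdna_sample` to write.
#' @export
write_pileup <- function(sample, path) {
  utils::write.table(sample$pileup, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an HLA typings CSV
#'
#' Long format: `patient_id`, `role` (`donor`/`recipient`), `locus`,
#' `allele1`, `allele2`.
#'
#' @param path File path.
#' @return A `data.frame` suitable for [cohort_loads()].
#' @export
read_typings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "role", "locus", "allele1", "allele2"),
                "typings file")
  if (!all(df$role %in% c("donor", "recipient"))) {
    stop("typing roles must be 'donor' or 'recipient'", call. = FALSE)
  }
  df
}

#' Read a tacrolimus series CSV
#'
#' Columns: `patient_id`, `day`, `level`, `dose`.
#'
#' @param path File path.
#' @return Long-format `data.frame`; use [tacrolimus_series()] per patient.
#' @export
read_tacrolimus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "day", "level", "dose"),
                "tacrolimus file")
  df
}
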