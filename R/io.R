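# --- tabular input ------------------------------------------------------

#' Read a patient karyotype table
#'
#' Reads a UTF-8 delimited text file with one patient per row and at
#' least the columns `patient_id`, `diagnosis`, `karyotype` (ISCN
#' string). Karyotypes are not parsed here; feed the `karyotype` column
#' to [parse_karyotype()] / [cohort_features()].
#'
#' @param path Path to a TSV (or `sep`-delimited) file.
#' @param sep Field separator, default tab.
#' @return A tibble.
#' @export
read_patient_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("patient_id", "karyotype")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("patient table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a variant call table
#'
#' Reads a delimited variant table carrying the candidate-somatic QC
#' fields (see [variant_filter_report()]); flag columns are coerced to
#' logical.
#'
#' @inheritParams read_patient_table
#' @return A tibble.
#' @export
read_variant_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  needed <- c("patient_id", "gene", "genomic_change", variant_qc_fields)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("variant table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in c("known_cancer_flag", "damaging_flag")) {
    df[[f]] <- as.logical(df[[f]])
  }
  tibble::as_tibble(df)
}
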