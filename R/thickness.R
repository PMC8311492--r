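#' Column names of the thickness-table schema
#'
#' The thickness table holds one row per subject: demographics, scanner,
#' estimated intracranial volume, a quality-control flag, and per-parcel,
#' per-hemisphere mean thickness (mm) and gray-matter volume (mm^3) with
#' column names `<parcel>_<hemi>_thickness` / `<parcel>_<hemi>_volume`
#' (hemi `lh`/`rh`, Desikan-Killiany parcel labels).
#'
#' @return Character vector of the fixed (non-parcel) columns.
#' @export
thickness_id_columns <- function() {
  c("subject_id", "age", "sex", "race_ethnicity", "scanner_id", "etiv",
    "qc_pass")
}

#' @noRd
thickness_cols <- function(df) grep("_thickness$", names(df), value = TRUE)

#' @noRd
volume_cols <- function(df) grep("_volume$", names(df), value = TRUE)

#' Read and validate a cortical-thickness table
#'
#' Drops rows failing quality control (the `qc_pass` flag, mirroring an
#' automated QC tool's verdict) with a message, and validates plausibility:
#' thickness must lie in (0.5, 5) mm and eTIV must be positive.
#'
#' @param path CSV path.
#' @param drop_qc_fail Drop `qc_pass == FALSE` rows (default `TRUE`).
#' @return Validated data frame.
#' @export
read_thickness_table <- function(path, drop_qc_fail = TRUE) {
  df <- utils::read.csv(path)
  validate_thickness_table(df)
  if (drop_qc_fail) {
    n_fail <- sum(!df$qc_pass)
    if (n_fail > 0) {
      message(sprintf("dropping %d subject(s) failing quality control", n_fail))
      df <- df[df$qc_pass, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_thickness_table
#' @param df Thickness table data frame.
#' @export
validate_thickness_table <- function(df) {
  assert_columns(df, thickness_id_columns(), "thickness table")
  tc <- thickness_cols(df)
  if (!length(tc)) stop("thickness table has no *_thickness columns",
                        call. = FALSE)
  vals <- as.matrix(df[, tc, drop = FALSE])
  if (any(vals <= 0.5 | vals >= 5.0, na.rm = TRUE)) {
    stop("thickness values outside the (0.5, 5.0) mm plausibility band",
         call. = FALSE)
  }
  if (any(!is.finite(df$etiv)) || any(df$etiv <= 0)) {
    stop("etiv must be positive", call. = FALSE)
  }
  if (anyNA(df$scanner_id)) stop("scanner_id has missing values",
                                 call. = FALSE)
  invisible(df)
}

#' Write a thickness table CSV
#'
#' @param df Thickness table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thickness_table <- function(df, path) {
  validate_thickness_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
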