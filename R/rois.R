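#' Region-of-interest parcel membership
#'
#' Desikan-Killiany parcels making up each ROI. The ACC combines its rostral
#' and caudal parcels, the OFC its medial and lateral parcels; the PCC is the
#' posterior cingulate parcel alone (the isthmus cingulate is deliberately
#' excluded). `whole_brain` uses every parcel present in the table.
#'
#' @return Named list mapping ROI names to parcel label vectors.
#' @export
roi_parcels <- function() {
  list(insula = "insula",
       ofc = c("medialorbitofrontal", "lateralorbitofrontal"),
       acc = c("rostralanteriorcingulate", "caudalanteriorcingulate"),
       pcc = "posteriorcingulate")
}

#' Build ROI thickness measures
#'
#' Each ROI is the volume-weighted mean thickness of its constituent parcels
#' across both hemispheres:
#' `sum(thickness_p * volume_p) / sum(volume_p)`. The whole-brain measure
#' applies the same weighting across every parcel in the table.
#'
#' @param table A (harmonized) thickness table.
#' @param rois Parcel membership, as [roi_parcels()].
#' @return Data frame with `subject_id`, one column per ROI, and
#'   `whole_brain` (all in mm).
#' @export
build_rois <- function(table, rois = roi_parcels()) {
  assert_columns(table, "subject_id", "thickness table")
  tc <- thickness_cols(table)
  parcels_present <- unique(sub("_(lh|rh)_thickness$", "", tc))

  weighted_mean_cols <- function(parcels) {
    cols_t <- as.vector(outer(parcels, c("lh", "rh"),
                              function(p, h) paste0(p, "_", h, "_thickness")))
    cols_v <- sub("_thickness$", "_volume", cols_t)
    missing <- setdiff(c(cols_t, cols_v), names(table))
    if (length(missing)) {
      stop(sprintf("required parcel column(s) absent: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    th <- as.matrix(table[, cols_t, drop = FALSE])
    vol <- as.matrix(table[, cols_v, drop = FALSE])
    rowSums(th * vol) / rowSums(vol)
  }

  out <- data.frame(subject_id = table$subject_id)
  for (nm in names(rois)) out[[nm]] <- weighted_mean_cols(rois[[nm]])
  out$whole_brain <- weighted_mean_cols(parcels_present)
  out
}
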