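#' Build a peak table
#'
#' Peaks are stored as a tibble with columns `mz` (Th) and `intensity`
#' (arbitrary units), sorted ascending by m/z. Peaks coinciding within
#' `merge_tol` are merged: intensities are summed and the merged m/z is the
#' intensity-weighted mean.
#'
#' @param mz Numeric vector of m/z values (Th), all > 0.
#' @param intensity Numeric vector of non-negative intensities.
#' @param annotation Optional character vector of ion labels.
#' @param merge_tol Peaks closer than this (Th) are merged. Default `1e-4`.
#' @return A tibble with columns `mz`, `intensity` (and `annotation` if given).
#' @export
peak_table <- function(mz, intensity, annotation = NULL, merge_tol = 1e-4) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have equal length.")
  }
  if (length(mz) == 0) {
    out <- tibble(mz = double(), intensity = double())
    if (!is.null(annotation)) out$annotation <- character()
    return(out)
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) abort("all `mz` must be finite and > 0")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("all `intensity` must be finite and >= 0")
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (!is.null(annotation)) annotation <- annotation[ord]
  # single-linkage chain merge of coincident peaks
  grp <- cumsum(c(1, diff(mz) > merge_tol))
  if (max(grp) < length(mz)) {
    tot <- as.vector(rowsum(intensity, grp))
    wmz <- as.vector(rowsum(mz * intensity, grp))
    # weighted mean; fall back to plain mean for all-zero-intensity groups
    mzm <- ifelse(tot > 0, wmz / tot, as.vector(rowsum(mz, grp)) / tabulate(grp))
    if (!is.null(annotation)) {
      annotation <- vapply(split(annotation, grp), function(a) a[[1]], character(1))
    }
    mz <- mzm
    intensity <- tot
  }
  if (is.null(annotation)) new_tbl(mz = unname(mz), intensity = unname(intensity))
  else new_tbl(mz = unname(mz), intensity = unname(intensity),
               annotation = unname(annotation))
}

#' Build a spectra table
#'
#' A spectra table holds one MS/MS spectrum per row: `spectrum_id`,
#' `precursor_mz` (Th), `precursor_charge`, optional `retention_time`
#' (seconds), and a `peaks` list-column of peak tables (see [peak_table()]).
#'
#' @param spectrum_id Character vector of unique identifiers.
#' @param precursor_mz Numeric precursor m/z (Th).
#' @param precursor_charge Integer precursor charge, 1-6.
#' @param peaks List of peak tables.
#' @param retention_time Optional numeric, seconds.
#' @return A tibble with one row per spectrum.
#' @export
spectra_table <- function(spectrum_id, precursor_mz, precursor_charge, peaks,
                          retention_time = NA_real_) {
  out <- tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    retention_time = as.numeric(retention_time),
    peaks = peaks
  )
  validate_spectra(out)
}

#' Validate a spectra table
#'
#' Checks identifiers are unique, precursor charges are in 1-6, and peak
#' tables are sorted with positive m/z.
#'
#' @param spectra A spectra table.
#' @return The input, invisibly usable, after validation.
#' @export
validate_spectra <- function(spectra) {
  req <- c("spectrum_id", "precursor_mz", "precursor_charge", "peaks")
  missing_cols <- setdiff(req, names(spectra))
  if (length(missing_cols)) {
    abort(paste0("spectra table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(spectra$spectrum_id)) abort("duplicated spectrum_id values")
  if (nrow(spectra) && (any(spectra$precursor_charge < 1L) || any(spectra$precursor_charge > 6L))) {
    abort("precursor_charge must be in 1..6")
  }
  ok <- vapply(spectra$peaks, function(p) {
    nrow(p) == 0 || (all(p$mz > 0) && !is.unsorted(p$mz, strictly = TRUE))
  }, logical(1))
  if (!all(ok)) {
    abort(paste0(
      "peaks not strictly sorted by mz (or non-positive mz) in spectra: ",
      paste(spectra$spectrum_id[!ok], collapse = ", ")
    ))
  }
  spectra
}
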