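#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water plus any modification
#' delta masses carried by the PSM.
#'
#' @param sequence Uppercase residue string over the 20 standard amino acids.
#' @param modifications Optional tibble with columns `position`, `name`,
#'   `delta_mass` (position 0 = N-terminus).
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(sequence, modifications = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a non-empty residue string")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(RESIDUE_MASS))
  if (length(unknown)) abort(paste0("unknown residue(s): ", paste(unknown, collapse = ", ")))
  m <- sum(RESIDUE_MASS[res]) + H2O_MASS
  if (!is.null(modifications) && nrow(modifications)) m <- m + sum(modifications$delta_mass)
  unname(m)
}

#' Precursor m/z from neutral mass and charge
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z in Th: `(neutral_mass + charge * proton) / charge`.
#' @export
precursor_mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) abort("`charge` must be >= 1")
  (neutral_mass + charge * PROTON_MASS) / charge
}

span_has <- function(res, start, end, set) {
  vapply(seq_along(start), function(i) any(res[start[i]:end[i]] %in% set), logical(1))
}

# mass of the residues + modifications inside a fragment span;
# N-terminal modifications (position 0) belong to a/b fragments only.
span_mod_mass <- function(mods, start, end, nterm_included) {
  if (is.null(mods) || nrow(mods) == 0) return(0)
  inside <- (mods$position >= start & mods$position <= end) |
    (mods$position == 0L & nterm_included)
  sum(mods$delta_mass[inside])
}

#' Enumerate theoretical a/b/y fragment ions
#'
#' All a-, b- and y-series ions for ordinals `1..L-1` at charges
#' `1..min(max_fragment_charge, precursor charge)`, with ammonia loss
#' variants for fragments containing R/K/N/Q and water loss variants for
#' fragments containing S/T/E/D. Combined ammonia+water losses are not
#' generated. Fragments whose span contains a phosphorylated S/T (a
#' modification of +79.9663 Da or named `phospho`) additionally get a
#' phosphoric acid (H3PO4) loss variant.
#'
#' @param sequence Residue string.
#' @param charge Precursor charge (caps fragment charge).
#' @param modifications Optional modification tibble (see [read_psm_table()]).
#' @param max_fragment_charge Highest fragment charge to emit, default 2.
#' @return A tibble: `series`, `ordinal`, `loss` (`none`/`NH3`/`H2O`/`H3PO4`),
#'   `charge`, `mz`, `span_start`, `span_end`.
#' @export
generate_fragments <- function(sequence, charge = 2L, modifications = NULL,
                               max_fragment_charge = 2L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  if (L < 2) abort("peptide must have at least 2 residues to fragment")
  unknown <- setdiff(res, names(RESIDUE_MASS))
  if (length(unknown)) abort(paste0("unknown residue(s): ", paste(unknown, collapse = ", ")))
  zmax <- max(1L, min(max_fragment_charge, charge))
  ords <- seq_len(L - 1L)
  prefix <- cumsum(RESIDUE_MASS[res])

  phospho_pos <- integer()
  if (!is.null(modifications) && nrow(modifications)) {
    is_phos <- grepl("phospho", modifications$name, ignore.case = TRUE) |
      abs(modifications$delta_mass - HPO3_MASS) < 0.01
    phospho_pos <- modifications$position[is_phos & modifications$position >= 1L]
    phospho_pos <- phospho_pos[res[phospho_pos] %in% c("S", "T")]
  }

  rows <- list()
  for (series in c("a", "b", "y")) {
    if (series %in% c("a", "b")) {
      start <- rep(1L, length(ords)); end <- ords
      base <- prefix[ords]
      if (series == "a") base <- base - CO_MASS
    } else {
      start <- L - ords + 1L; end <- rep(L, length(ords))
      base <- (prefix[L] - c(0, prefix)[start]) + H2O_MASS
    }
    modm <- vapply(seq_along(ords), function(i) {
      span_mod_mass(modifications, start[i], end[i], nterm_included = series != "y")
    }, double(1))
    neutral <- unname(base) + modm
    has_nh3 <- span_has(res, start, end, NH3_LOSS_RESIDUES)
    has_h2o <- span_has(res, start, end, H2O_LOSS_RESIDUES)
    has_phos <- vapply(seq_along(ords), function(i) {
      any(phospho_pos >= start[i] & phospho_pos <= end[i])
    }, logical(1))
    for (loss in c("none", "NH3", "H2O", "H3PO4")) {
      keep <- switch(loss, none = rep(TRUE, length(ords)), NH3 = has_nh3,
                     H2O = has_h2o, H3PO4 = has_phos)
      if (!any(keep)) next
      lm <- switch(loss, none = 0, NH3 = NH3_MASS, H2O = H2O_MASS, H3PO4 = H3PO4_MASS)
      for (z in seq_len(zmax)) {
        nk <- sum(keep)
        rows[[length(rows) + 1L]] <- new_tbl(
          series = rep(series, nk), ordinal = ords[keep],
          loss = rep(loss, nk), charge = rep(z, nk),
          mz = (neutral[keep] - lm + z * PROTON_MASS) / z,
          span_start = start[keep], span_end = unname(end[keep])
        )
      }
    }
  }
  arrange(bind_rows(rows), .data$series, .data$ordinal, .data$charge, .data$loss)
}

# ion label like "y4", "b3-NH3", "y7+p-H3PO4", with "^2" for 2+ fragments
ion_label <- function(series, ordinal, loss, charge, phospho = FALSE) {
  paste0(
    series, ordinal, ifelse(phospho, "+p", ""),
    ifelse(loss == "none", "", paste0("-", loss)),
    ifelse(charge > 1, paste0("^", charge), "")
  )
}

#' Annotate observed peaks with theoretical fragments
#'
#' Each theoretical fragment is matched to its nearest observed peak within
#' `tol_mz`; a peak can carry at most one annotation and a fragment can
#' claim at most one peak. Conflicts are resolved by smallest absolute m/z
#' difference, then by higher peak intensity.
#'
#' @param spectrum_peaks A peak table (sorted by m/z).
#' @param fragments A fragment tibble from [generate_fragments()].
#' @param tol_mz Matching tolerance in Th (> 0), default 0.05.
#' @return A tibble: `peak_index`, `series`, `ordinal`, `loss`, `charge`,
#'   `theoretical_mz`, `span_start`, `span_end`, `mass_error` (Da at
#'   singly-charged scale).
#' @export
annotate_spectrum <- function(spectrum_peaks, fragments, tol_mz = FRAGMENT_TOL_DEFAULT) {
  if (tol_mz <= 0) abort("`tol_mz` must be > 0")
  empty <- tibble(
    peak_index = integer(), series = character(), ordinal = integer(),
    loss = character(), charge = integer(), theoretical_mz = double(),
    span_start = integer(), span_end = integer(), mass_error = double()
  )
  if (nrow(spectrum_peaks) == 0 || nrow(fragments) == 0) return(empty)
  mz <- spectrum_peaks$mz
  pos <- findInterval(fragments$mz, mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(mz))
  d_lo <- abs(mz[lo] - fragments$mz)
  d_hi <- abs(mz[hi] - fragments$mz)
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  delta <- mz[nearest] - fragments$mz
  keep <- abs(delta) <= tol_mz
  if (!any(keep)) return(empty)
  cand <- new_tbl(
    peak_index = nearest[keep],
    series = fragments$series[keep], ordinal = fragments$ordinal[keep],
    loss = fragments$loss[keep], charge = fragments$charge[keep],
    theoretical_mz = fragments$mz[keep],
    span_start = fragments$span_start[keep], span_end = fragments$span_end[keep],
    mass_error = delta[keep] * fragments$charge[keep]
  )
  cand <- cand[order(abs(cand$mass_error / cand$charge),
                     -spectrum_peaks$intensity[cand$peak_index],
                     cand$series, cand$ordinal, cand$loss, cand$charge), ]
  cand <- cand[!duplicated(cand$peak_index), ]
  arrange(cand, .data$peak_index)
}
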