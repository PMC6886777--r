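#' Simulation condition
#'
#' Bundles the relative intensities of predicted phospho ions and the set of
#' neutral-loss template ions used by the simulator:
#' * `r_intact_st`: pS/pT intact-ion intensity relative to the source
#'   nonphosphorylated ion,
#' * `r_nlp`: phosphoric acid neutral-loss (NL-P) ion relative intensity,
#' * `r_intact_y`: pY intact-ion relative intensity,
#' * `nl_sources`: which neutral-loss template ions (besides plain a/b/y)
#'   spawn predictions: `character(0)` = NL-P, `"NH3"` = NL-PA,
#'   `"H2O"` = NL-PW, `c("NH3","H2O")` = NL-PAW.
#'
#' @param r_intact_st,r_nlp,r_intact_y Fractions in (0, 10].
#' @param nl_sources Subset of `c("NH3", "H2O")`.
#' @return A `sim_config` list with a descriptive `label`.
#' @export
#' @examples
#' sim_config(0.5, 0.5, 1, character(0)) # the "50-50-100, NL-P" condition
sim_config <- function(r_intact_st = 0.10, r_nlp = 1.00, r_intact_y = 1.00,
                       nl_sources = c("NH3", "H2O")) {
  ratios <- c(r_intact_st, r_nlp, r_intact_y)
  if (any(!is.finite(ratios)) || any(ratios <= 0) || any(ratios > 10)) {
    abort("intensity ratios must be in (0, 10]")
  }
  nl_sources <- as.character(nl_sources)
  if (!all(nl_sources %in% c("NH3", "H2O"))) abort("nl_sources must be a subset of NH3/H2O")
  nl_label <- paste0("NL-P", if ("NH3" %in% nl_sources) "A" else "",
                     if ("H2O" %in% nl_sources) "W" else "")
  structure(
    list(
      r_intact_st = r_intact_st, r_nlp = r_nlp, r_intact_y = r_intact_y,
      nl_sources = nl_sources,
      intensity_label = sprintf("%d-%d-%d", round(100 * r_intact_st),
                                round(100 * r_nlp), round(100 * r_intact_y)),
      nl_label = nl_label
    ),
    class = "sim_config"
  )
}

#' @export
format.sim_config <- function(x, ...) paste0(x$intensity_label, ", ", x$nl_label)

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Named simulation presets
#'
#' `"default"` is the 10%-100%-100% intensity condition with all
#' neutral-loss templates (NL-PAW); `"optimized-A"` and `"optimized-B"` are
#' the 50-50-100 and 50-50-50 conditions with plain templates only (NL-P),
#' the conditions that maximize correct localizations at 1% FLR.
#'
#' @param name One of `"default"`, `"optimized-A"`, `"optimized-B"`.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("default", "optimized-A", "optimized-B")) {
  switch(match.arg(name),
    "default" = sim_config(0.10, 1.00, 1.00, c("NH3", "H2O")),
    "optimized-A" = sim_config(0.50, 0.50, 1.00, character(0)),
    "optimized-B" = sim_config(0.50, 0.50, 0.50, character(0))
  )
}

#' The full simulation-condition grid
#'
#' The 4 intensity settings (10-100-100, 50-100-100, 50-50-100, 50-50-50)
#' crossed with the 4 neutral-loss template sets (NL-PAW, NL-PA, NL-PW,
#' NL-P): 16 conditions.
#'
#' @return A list of 16 [sim_config()] objects.
#' @export
sim_condition_grid <- function() {
  intensities <- list(c(0.10, 1.00, 1.00), c(0.50, 1.00, 1.00),
                      c(0.50, 0.50, 1.00), c(0.50, 0.50, 0.50))
  nls <- list(c("NH3", "H2O"), "NH3", "H2O", character(0))
  out <- list()
  for (r in intensities) for (s in nls) {
    out[[length(out) + 1L]] <- sim_config(r[1], r[2], r[3], s)
  }
  out
}

#' Enumerate candidate phosphorylation sites
#'
#' @param sequence Residue string.
#' @return Tibble of all S/T/Y positions: `site` (1-based), `residue`.
#' @export
enumerate_sites <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- which(res %in% c("S", "T", "Y"))
  tibble(site = as.integer(idx), residue = res[idx])
}

#' Simulate one phosphosite onto a dephosphorylated-peptide spectrum
#'
#' Implements the single-phosphorylation prediction: peaks annotated to
#' fragments containing `site` are replaced by the predicted phospho ions;
#' all other peaks (including unannotated ones) are copied unchanged.
#' For an annotated site-containing peak whose loss type is `none` or in
#' `config$nl_sources`:
#' * S/T site: an intact ion at `mz + 79.966331/z` scaled by
#'   `r_intact_st`, and an NL-P ion at `mz - 18.010565/z` scaled by `r_nlp`;
#' * Y site: only the intact ion, scaled by `r_intact_y`.
#' Site-containing template peaks with other loss types are removed without
#' replacement. Coinciding product m/z (within 1e-4 Th) are merged by
#' intensity sum and the precursor shifts by `+79.966331/charge`.
#'
#' @param spectrum One-row spectra table slice (or list) with
#'   `precursor_mz`, `precursor_charge`, `spectrum_id`, `peaks`.
#' @param annotations Annotations of that spectrum from [annotate_spectrum()].
#' @param sequence Peptide sequence of the template PSM.
#' @param site 1-based S/T/Y position to phosphorylate.
#' @param config A [sim_config()].
#' @return A one-row simulated-entry tibble: `source_id`, `sequence`,
#'   `site`, `residue`, `charge`, `precursor_mz`, `peaks`.
#' @export
simulate_site <- function(spectrum, annotations, sequence, site, config = sim_config()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (site < 1 || site > length(res)) abort("site outside sequence")
  residue <- res[[site]]
  if (!residue %in% c("S", "T", "Y")) {
    abort(paste0("site ", site, " is ", residue, ", not S/T/Y"))
  }
  pk <- spectrum$peaks[[1]]
  n <- nrow(pk)
  ann <- annotations
  contains <- logical(n)
  allowed <- logical(n)
  zfrag <- rep(1L, n)
  label <- rep("?", n)
  if (nrow(ann)) {
    contains[ann$peak_index] <- ann$span_start <= site & ann$span_end >= site
    allowed[ann$peak_index] <- ann$loss %in% c("none", config$nl_sources)
    zfrag[ann$peak_index] <- ann$charge
    label[ann$peak_index] <- ion_label(ann$series, ann$ordinal, ann$loss, ann$charge)
  }

  keep <- !contains
  out_mz <- pk$mz[keep]
  out_in <- pk$intensity[keep]
  out_lab <- label[keep]

  src <- which(contains & allowed)
  if (length(src)) {
    z <- zfrag[src]
    r_int <- if (residue == "Y") config$r_intact_y else config$r_intact_st
    out_mz <- c(out_mz, pk$mz[src] + HPO3_MASS / z)
    out_in <- c(out_in, pk$intensity[src] * r_int)
    out_lab <- c(out_lab, paste0(sub("\\^.*$", "", label[src]), "+p",
                                 ifelse(z > 1, paste0("^", z), "")))
    if (residue %in% c("S", "T")) {
      out_mz <- c(out_mz, pk$mz[src] - H2O_MASS / z)
      out_in <- c(out_in, pk$intensity[src] * config$r_nlp)
      out_lab <- c(out_lab, paste0(sub("\\^.*$", "", label[src]), "+p-H3PO4",
                                   ifelse(z > 1, paste0("^", z), "")))
    }
  }
  charge <- spectrum$precursor_charge[[1]]
  new_tbl(
    source_id = spectrum$spectrum_id[[1]],
    sequence = sequence,
    site = as.integer(site),
    residue = residue,
    charge = as.integer(charge),
    precursor_mz = spectrum$precursor_mz[[1]] + HPO3_MASS / charge,
    peaks = list(peak_table(out_mz, out_in, annotation = out_lab))
  )
}

has_phospho_mod <- function(mods) {
  !is.null(mods) && nrow(mods) > 0 &&
    any(grepl("phospho", mods$name, ignore.case = TRUE) |
          abs(mods$delta_mass - HPO3_MASS) < 0.01)
}

#' Simulate all single-phosphorylation isoforms for a PSM set
#'
#' Template PSMs with probability below `min_probability`, or already
#' carrying a phospho modification, are skipped; each remaining PSM yields
#' one simulated entry per S/T/Y position of its sequence.
#'
#' @param psms PSM tibble (see [read_psm_table()]).
#' @param spectra Spectra table holding every PSM's spectrum.
#' @param config A [sim_config()].
#' @param min_probability Minimum PSM probability, default 0.95.
#' @param annotations Optional precomputed list of annotation tibbles named
#'   by spectrum_id (reused across conditions by [condition_sweep()]).
#' @param fragment_tol_mz Annotation tolerance (Th).
#' @return A simulated-entry tibble (rows as in [simulate_site()]).
#' @export
simulate_all <- function(psms, spectra, config = sim_config(),
                         min_probability = 0.95, annotations = NULL,
                         fragment_tol_mz = FRAGMENT_TOL_DEFAULT) {
  keep <- psms$probability >= min_probability &
    !vapply(psms$modifications, has_phospho_mod, logical(1))
  psms <- psms[keep, , drop = FALSE]
  missing_ids <- setdiff(psms$spectrum_id, spectra$spectrum_id)
  if (length(missing_ids)) {
    abort(paste0("PSM spectra not found: ", paste(missing_ids, collapse = ", ")))
  }
  if (is.null(annotations)) {
    annotations <- annotate_psm_spectra(psms, spectra, fragment_tol_mz)
  }
  rows <- vector("list", 0L)
  idx <- match(psms$spectrum_id, spectra$spectrum_id)
  for (k in seq_len(nrow(psms))) {
    sites <- enumerate_sites(psms$sequence[[k]])
    if (nrow(sites) == 0) next
    sp <- spectra[idx[[k]], ]
    ann <- annotations[[psms$spectrum_id[[k]]]]
    for (j in seq_len(nrow(sites))) {
      rows[[length(rows) + 1L]] <- simulate_site(sp, ann, psms$sequence[[k]],
                                                 sites$site[[j]], config)
    }
  }
  if (!length(rows)) {
    return(tibble(source_id = character(), sequence = character(),
                  site = integer(), residue = character(), charge = integer(),
                  precursor_mz = double(), peaks = list()))
  }
  bind_rows(rows)
}

#' Annotate the template spectra of a PSM set
#'
#' Convenience used by [simulate_all()] and [condition_sweep()]: annotation
#' does not depend on the simulation condition, so it can be computed once
#' and shared across conditions.
#'
#' @inheritParams simulate_all
#' @return A named list of annotation tibbles keyed by spectrum_id.
#' @export
annotate_psm_spectra <- function(psms, spectra,
                                 fragment_tol_mz = FRAGMENT_TOL_DEFAULT) {
  idx <- match(psms$spectrum_id, spectra$spectrum_id)
  if (anyNA(idx)) {
    abort(paste0("PSM spectra not found: ",
                 paste(psms$spectrum_id[is.na(idx)], collapse = ", ")))
  }
  out <- purrr::map(seq_len(nrow(psms)), function(k) {
    frags <- generate_fragments(psms$sequence[[k]], psms$charge[[k]],
                                psms$modifications[[k]])
    annotate_spectrum(spectra$peaks[[idx[[k]]]], frags, fragment_tol_mz)
  })
  setNames(out, psms$spectrum_id)
}
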