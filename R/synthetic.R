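#' Parameters of the synthetic paired phospho/dephospho experiment
#'
#' The generator emulates a before/after enzymatic-dephosphorylation
#' LC-MS/MS experiment on singly phosphorylated tryptic peptides: for each
#' peptide a clean b/y fragment ladder is drawn once, its phosphorylated
#' counterpart derived from it, and replicate spectra produced by applying
#' the corruption model (noise peaks, peak dropout, m/z jitter) to each
#' form.
#'
#' @param n_peptides Number of distinct peptide sequences, default 24.
#' @param length_range Residue-length range (min >= 6), default `c(8, 16)`.
#' @param replicates Spectra per form per peptide, default 3.
#' @param phi_intact True retained intensity of site-containing intact
#'   phospho fragments relative to the dephospho ladder, default 0.5.
#' @param phi_nlp True relative intensity of phosphoric acid neutral-loss
#'   fragments (S/T sites only), default 0.5.
#' @param noise_peaks Random noise peaks added per spectrum, default 30.
#' @param dropout_prob Per-peak dropout probability, default 0.25.
#' @param mz_jitter_sd Gaussian fragment m/z jitter (Th), default 0.015.
#' @param multi_sty_fraction Fraction of peptides required to carry at
#'   least two S/T/Y (so localization is non-trivial), default 0.8.
#' @param charge Precursor charge of generated ions, default 2.
#' @param seed Integer seed; the dataset is a pure function of the
#'   parameters and this seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_peptides = 24L, length_range = c(8L, 16L),
                         replicates = 3L, phi_intact = 0.5, phi_nlp = 0.5,
                         noise_peaks = 30L, dropout_prob = 0.25,
                         mz_jitter_sd = 0.015, multi_sty_fraction = 0.8,
                         charge = 2L, seed = 1L) {
  if (length_range[1] < 6) abort("minimum peptide length is 6")
  fr <- c(phi_intact, phi_nlp, dropout_prob, multi_sty_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must be in [0, 1]")
  structure(
    list(
      n_peptides = as.integer(n_peptides), length_range = as.integer(length_range),
      replicates = as.integer(replicates), phi_intact = phi_intact,
      phi_nlp = phi_nlp, noise_peaks = as.integer(noise_peaks),
      dropout_prob = dropout_prob, mz_jitter_sd = mz_jitter_sd,
      multi_sty_fraction = multi_sty_fraction, charge = as.integer(charge),
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

# all template fragment channels of the dephospho spectrum (b/y charge 1
# plus eligible NL satellites); used both to build ladders and to check
# channel separation
template_channels <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  prefix <- cumsum(RESIDUE_MASS[res])
  ords <- seq_len(L - 1L)
  b <- tibble(series = "b", ordinal = ords, span_start = 1L, span_end = ords,
              neutral = unname(prefix[ords]))
  y <- tibble(series = "y", ordinal = ords, span_start = L - ords + 1L,
              span_end = L, neutral = unname(prefix[L] - c(0, prefix)[L - ords + 1L] + H2O_MASS))
  parents <- bind_rows(b, y)
  parents$loss <- "none"
  sat <- list()
  for (loss in c("NH3", "H2O")) {
    set <- if (loss == "NH3") NH3_LOSS_RESIDUES else H2O_LOSS_RESIDUES
    eligible <- span_has(res, parents$span_start, parents$span_end, set)
    if (any(eligible)) {
      s <- parents[eligible, ]
      s$loss <- loss
      s$neutral <- s$neutral - if (loss == "NH3") NH3_MASS else H2O_MASS
      sat[[loss]] <- s
    }
  }
  ch <- bind_rows(c(list(parents), unname(sat)))
  ch$mz <- ch$neutral + PROTON_MASS
  ch
}

valid_synthetic_peptide <- function(sequence, need_multi_sty) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  if (!res[L] %in% c("K", "R")) return(FALSE)
  if (any(res[-L] %in% c("K", "R"))) return(FALSE)
  n_sty <- sum(res %in% c("S", "T", "Y"))
  if (n_sty < 1 || (need_multi_sty && n_sty < 2)) return(FALSE)
  # fragment channels must be unambiguous: all template peaks well separated
  ch <- sort(template_channels(sequence)$mz)
  all(diff(ch) > 0.11)
}

#' Generate synthetic tryptic peptide sequences
#'
#' Seeded random sequences over the 20 residues: C-terminal K/R, no
#' internal K/R (fully tryptic), at least one S/T/Y (at least two in
#' `multi_sty_fraction` of the peptides), lengths uniform in
#' `length_range`, duplicates removed. Sequences are additionally required
#' to have all template fragment channels separated by more than 0.11 Th,
#' so every generated peak has an unambiguous fragment identity.
#'
#' @param params A [synth_params()] (its `seed` drives generation unless
#'   the caller has already seeded the RNG via `use_current_rng`).
#' @param use_current_rng Internal: draw from the current RNG state instead
#'   of seeding. Default `FALSE`.
#' @return Character vector of `n_peptides` unique sequences.
#' @export
generate_peptides <- function(params = synth_params(), use_current_rng = FALSE) {
  draw <- function() {
    out <- character(0)
    residues <- names(RESIDUE_MASS)
    internal <- setdiff(residues, c("K", "R"))
    n_multi <- ceiling(params$multi_sty_fraction * params$n_peptides)
    attempts <- 0L
    while (length(out) < params$n_peptides) {
      attempts <- attempts + 1L
      if (attempts > 20000L) abort("could not satisfy peptide constraints")
      lens <- params$length_range[1]:params$length_range[2]
      L <- lens[sample.int(length(lens), 1L)]
      seqn <- paste(c(sample(internal, L - 1L, replace = TRUE),
                      sample(c("K", "R"), 1L)), collapse = "")
      need_multi <- length(out) < n_multi
      if (valid_synthetic_peptide(seqn, need_multi) && !seqn %in% out) {
        out <- c(out, seqn)
      }
    }
    out
  }
  if (use_current_rng) draw() else local_rng(params$seed, draw())
}

# clean (uncorrupted) dephospho/phospho spectrum pair for one peptide
clean_spectrum_pair <- function(sequence, true_site, charge, params) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!res[true_site] %in% c("S", "T", "Y")) abort("true_site is not S/T/Y")
  ch <- template_channels(sequence)
  parents <- ch[ch$loss == "none", ]
  base_int <- rlnorm(nrow(parents), meanlog = 0, sdlog = 1)
  base_int <- base_int / max(base_int) * 10000
  parents$intensity <- base_int
  key <- paste(ch$series, ch$ordinal)
  ch$intensity <- ifelse(ch$loss == "none",
                         base_int[match(key, paste(parents$series, parents$ordinal))],
                         0.3 * base_int[match(key, paste(parents$series, parents$ordinal))])
  ch$label <- ion_label(ch$series, ch$ordinal, ch$loss, 1L)
  contains <- ch$span_start <= true_site & ch$span_end >= true_site

  dep <- peak_table(ch$mz, ch$intensity, annotation = ch$label)

  keep <- ch[!contains, ]
  site_parents <- ch[contains & ch$loss == "none", ]
  ph_mz <- c(keep$mz, site_parents$mz + HPO3_MASS)
  ph_in <- c(keep$intensity, site_parents$intensity * params$phi_intact)
  ph_lab <- c(keep$label, paste0(site_parents$label, "+p"))
  if (res[true_site] %in% c("S", "T")) {
    ph_mz <- c(ph_mz, site_parents$mz - H2O_MASS)
    ph_in <- c(ph_in, site_parents$intensity * params$phi_nlp)
    ph_lab <- c(ph_lab, paste0(site_parents$label, "+p-H3PO4"))
  }
  nz <- ph_in > 0 # a phi of 0 means the ion is simply not produced
  phos <- peak_table(ph_mz[nz], ph_in[nz], annotation = ph_lab[nz])

  m_dep <- peptide_mass(sequence)
  list(
    dephospho = list(peaks = dep, precursor_mz = precursor_mz(m_dep, charge)),
    phospho = list(peaks = phos,
                   precursor_mz = precursor_mz(m_dep + HPO3_MASS, charge))
  )
}

corrupt_peaks <- function(peaks, params) {
  pk <- peaks
  n <- nrow(pk)
  if (params$dropout_prob > 0 && n > 0) {
    drop <- runif(n) < params$dropout_prob
    if (all(drop)) drop[which.max(pk$intensity)] <- FALSE # keep the base peak
    pk <- pk[!drop, , drop = FALSE]
  }
  mz <- pk$mz
  if (params$mz_jitter_sd > 0 && nrow(pk) > 0) {
    mz <- mz + rnorm(nrow(pk), sd = params$mz_jitter_sd)
  }
  intensity <- pk$intensity
  ann <- if ("annotation" %in% names(pk)) pk$annotation else NULL
  if (params$noise_peaks > 0) {
    base <- if (length(intensity)) max(intensity) else 10000
    mz <- c(mz, runif(params$noise_peaks, MZ_RANGE_DEFAULT[1], MZ_RANGE_DEFAULT[2]))
    intensity <- c(intensity, runif(params$noise_peaks, 0, 0.05 * base))
    if (!is.null(ann)) ann <- c(ann, rep("?", params$noise_peaks))
  }
  peak_table(mz, intensity, annotation = ann)
}

#' Generate one dephospho/phospho spectrum pair
#'
#' Builds the clean fragment ladder (log-normal parent intensities scaled
#' to a base peak of 10000, ammonia/water neutral-loss satellites at 30%
#' of their parents where residue-eligible), derives the phosphorylated
#' spectrum by replacing site-containing fragments with intact
#' (`+79.966331`, scaled by `phi_intact`) and, for S/T sites, phosphoric
#' acid neutral-loss (`-18.010565`, scaled by `phi_nlp`) ions (satellites
#' of site-containing fragments are not retained), then applies the
#' corruption model to both forms. Precursors differ by exactly
#' `79.966331 / charge` and are never jittered. Draws from the current RNG
#' state; seed externally for reproducibility.
#'
#' @param sequence Peptide sequence.
#' @param true_site 1-based S/T/Y position carrying the phosphate.
#' @param charge Precursor charge.
#' @param params A [synth_params()] (corruption fields are honoured;
#'   set noise/dropout/jitter to 0 for clean spectra).
#' @param ids Character vector of length 2: dephospho and phospho spectrum
#'   ids.
#' @return A two-row spectra table (dephospho row first).
#' @export
generate_spectrum_pair <- function(sequence, true_site, charge = 2L,
                                   params = synth_params(),
                                   ids = c("dephospho", "phospho")) {
  pair <- clean_spectrum_pair(sequence, true_site, charge, params)
  spectra_table(
    spectrum_id = ids,
    precursor_mz = c(pair$dephospho$precursor_mz, pair$phospho$precursor_mz),
    precursor_charge = c(charge, charge),
    peaks = list(corrupt_peaks(pair$dephospho$peaks, params),
                 corrupt_peaks(pair$phospho$peaks, params))
  )
}

#' Generate a full synthetic dataset
#'
#' For each peptide one true site is chosen uniformly among its S/T/Y
#' positions; `replicates` dephosphorylated spectra (with a PSM table at
#' probability 0.99) and `replicates` phosphopeptide query spectra are
#' produced, with one ground-truth row per query spectrum. The result is a
#' pure function of `params` (including its seed).
#'
#' @param params A [synth_params()].
#' @param out_dir Optional directory: writes `dephospho.mgf`,
#'   `phospho.mgf`, `psms.tsv`, `truth.tsv` and a `manifest.json`
#'   recording the parameters.
#' @return A list: `dephospho_spectra`, `query_spectra`, `psms`, `truth`,
#'   `peptides` (tibble of sequence, true site, charge), `params`.
#' @export
generate_dataset <- function(params = synth_params(), out_dir = NULL) {
  data <- local_rng(params$seed, {
    peptides <- generate_peptides(params, use_current_rng = TRUE)
    pep_tbl <- bind_rows(lapply(peptides, function(sq) {
      sites <- enumerate_sites(sq)
      tibble(sequence = sq,
             true_site = sites$site[[sample.int(nrow(sites), 1L)]],
             charge = params$charge)
    }))
    dep_rows <- list(); query_rows <- list()
    for (i in seq_len(nrow(pep_tbl))) {
      clean <- clean_spectrum_pair(pep_tbl$sequence[[i]], pep_tbl$true_site[[i]],
                                   pep_tbl$charge[[i]], params)
      for (r in seq_len(params$replicates)) {
        dep_rows[[length(dep_rows) + 1L]] <- spectra_table(
          sprintf("pep%02d_dep_r%d", i, r), clean$dephospho$precursor_mz,
          pep_tbl$charge[[i]], list(corrupt_peaks(clean$dephospho$peaks, params))
        )
        query_rows[[length(query_rows) + 1L]] <- spectra_table(
          sprintf("pep%02d_query_r%d", i, r), clean$phospho$precursor_mz,
          pep_tbl$charge[[i]], list(corrupt_peaks(clean$phospho$peaks, params))
        )
      }
    }
    dep <- bind_rows(dep_rows)
    qry <- bind_rows(query_rows)
    psms <- tibble(
      spectrum_id = dep$spectrum_id,
      sequence = rep(pep_tbl$sequence, each = params$replicates),
      modifications = rep(list(tibble(position = integer(), name = character(),
                                      delta_mass = double())), nrow(dep)),
      charge = rep(pep_tbl$charge, each = params$replicates),
      probability = 0.99
    )
    truth_seq <- rep(pep_tbl$sequence, each = params$replicates)
    truth_site <- rep(pep_tbl$true_site, each = params$replicates)
    truth <- tibble(
      spectrum_id = qry$spectrum_id,
      sequence = truth_seq,
      true_site = truth_site,
      residue = substr(truth_seq, truth_site, truth_site)
    )
    list(dephospho_spectra = dep, query_spectra = qry, psms = psms,
         truth = truth, peptides = pep_tbl, params = params)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(data$dephospho_spectra, file.path(out_dir, "dephospho.mgf"))
    write_mgf(data$query_spectra, file.path(out_dir, "phospho.mgf"))
    write_psm_table(data$psms, file.path(out_dir, "psms.tsv"))
    write_truth_table(data$truth, file.path(out_dir, "truth.tsv"))
    jsonlite::write_json(unclass(params), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  data
}
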