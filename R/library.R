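#' Group simulated entries into replicate sets
#'
#' @param entries Simulated-entry tibble from [simulate_all()].
#' @return The entries with a `group` key column added
#'   (`sequence/site/charge`), ordered by group.
#' @export
group_replicates <- function(entries) {
  entries |>
    mutate(group = paste(.data$sequence, .data$site, .data$charge, sep = "/")) |>
    arrange(.data$group)
}

#' Build a consensus spectrum from replicate spectra
#'
#' Peaks from all replicates are clustered by single linkage within
#' `tol_mz`; each cluster's m/z is the intensity-weighted mean and its
#' intensity is the mean over the replicates that contain the peak. With
#' three or more replicates, clusters present in fewer than
#' `min_presence` of them are dropped. The consensus precursor m/z is the
#' replicate mean.
#'
#' @param peaks_list List of peak tables (the replicates), length >= 1.
#' @param precursor_mzs Numeric precursor m/z per replicate.
#' @param tol_mz Clustering tolerance (Th), default 0.05.
#' @param min_presence Minimum fraction of replicates containing a cluster,
#'   default 0.5.
#' @return A list with `peaks` (a peak table) and `precursor_mz`.
#' @export
build_consensus <- function(peaks_list, precursor_mzs, tol_mz = FRAGMENT_TOL_DEFAULT,
                            min_presence = 0.5) {
  nrep <- length(peaks_list)
  if (nrep == 0) abort("consensus of zero spectra")
  mz <- unlist(lapply(peaks_list, function(p) p$mz))
  intensity <- unlist(lapply(peaks_list, function(p) p$intensity))
  rep_id <- rep(seq_len(nrep), vapply(peaks_list, nrow, integer(1)))
  has_ann <- all(vapply(peaks_list, function(p) "annotation" %in% names(p), logical(1)))
  ann <- if (has_ann) unlist(lapply(peaks_list, function(p) p$annotation)) else NULL
  if (length(mz) == 0) {
    return(list(peaks = peak_table(double(), double()),
                precursor_mz = mean(precursor_mzs)))
  }
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]; rep_id <- rep_id[ord]
  if (!is.null(ann)) ann <- ann[ord]
  grp <- cumsum(c(1, diff(mz) > tol_mz))
  splits <- split(seq_along(mz), grp)
  out <- lapply(splits, function(ix) {
    present <- unique(rep_id[ix])
    if (nrep >= 3 && length(present) / nrep < min_presence) return(NULL)
    per_rep <- rowsum(intensity[ix], rep_id[ix]) # replicate totals inside cluster
    w <- intensity[ix]
    cmz <- if (sum(w) > 0) sum(mz[ix] * w) / sum(w) else mean(mz[ix])
    lab <- if (!is.null(ann)) {
      known <- ann[ix][ann[ix] != "?"]
      if (length(known)) names(sort(table(known), decreasing = TRUE))[1] else "?"
    } else NULL
    list(mz = cmz, intensity = mean(per_rep), annotation = lab)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  list(
    peaks = peak_table(
      vapply(out, `[[`, double(1), "mz"),
      vapply(out, `[[`, double(1), "intensity"),
      annotation = if (has_ann) vapply(out, `[[`, character(1), "annotation")
    ),
    precursor_mz = mean(precursor_mzs)
  )
}

# fragment m/z for an arbitrary (series, ordinal, loss, charge) of a
# (possibly phosphorylated) sequence, without eligibility checks
fragment_mz_for <- function(sequence, site, series, ordinal, loss, charge) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  prefix <- cumsum(RESIDUE_MASS[res])
  n <- length(series)
  start <- ifelse(series == "y", L - ordinal + 1L, 1L)
  end <- ifelse(series == "y", L, ordinal)
  base <- ifelse(series == "y",
                 prefix[L] - c(0, prefix)[start] + H2O_MASS,
                 prefix[ordinal])
  base <- base - ifelse(series == "a", CO_MASS, 0)
  if (!is.na(site)) {
    base <- base + ifelse(site >= start & site <= end, HPO3_MASS, 0)
  }
  lm <- c(none = 0, NH3 = NH3_MASS, H2O = H2O_MASS, H3PO4 = H3PO4_MASS)[loss]
  (base - unname(lm) + charge * PROTON_MASS) / charge
}

#' Generate a decoy library entry by shuffle-and-reposition
#'
#' Residues 1..L-1 are permuted with a seeded generator (the C-terminal
#' residue is kept, preserving tryptic character) and the phosphosite rides
#' its residue through the shuffle. Peaks of the target spectrum that
#' annotate to theoretical fragments of the target phosphopeptide are moved
#' to the corresponding fragment m/z of the shuffled phosphopeptide,
#' keeping their intensities; unannotated peaks keep their m/z. The
#' precursor is unchanged (the residue multiset is preserved). A shuffle
#' colliding with any sequence in `avoid` (or the original) is redrawn up
#' to 10 times, then two internal residues are swapped.
#'
#' @param entry One-row library-entry tibble (a target).
#' @param seed Integer seed for the shuffle.
#' @param avoid Character vector of sequences the decoy must not equal.
#' @param tol_mz Annotation tolerance (Th).
#' @return A one-row decoy entry tibble.
#' @export
generate_decoy <- function(entry, seed, avoid = character(), tol_mz = FRAGMENT_TOL_DEFAULT) {
  sequence <- entry$sequence[[1]]
  site <- entry$site[[1]]
  charge <- entry$charge[[1]]
  L <- nchar(sequence)
  if (L < 3) abort("sequence too short to shuffle (L < 3)")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  avoid <- unique(c(avoid, sequence))

  perm <- local_rng(seed, {
    found <- NULL
    for (attempt in 1:10) {
      p <- c(sample(L - 1L), L)
      if (!paste(res[p], collapse = "") %in% avoid) { found <- p; break }
    }
    if (is.null(found)) {
      found <- c(sample(L - 1L), L)
      pool <- if (L >= 4L) 2:(L - 1L) else 1:2 # two swappable positions
      swap <- pool[sample.int(length(pool), 2L)]
      found[swap] <- found[rev(swap)]
    }
    found
  })
  dec_seq <- paste(res[perm], collapse = "")
  dec_site <- if (is.na(site)) NA_integer_ else as.integer(which(perm == site))

  mods <- if (!is.na(site)) {
    tibble(position = as.integer(site), name = "phospho", delta_mass = HPO3_MASS)
  } else NULL
  frags <- generate_fragments(sequence, charge, mods)
  ann <- annotate_spectrum(entry$peaks[[1]], frags, tol_mz)
  pk <- entry$peaks[[1]]
  new_mz <- pk$mz
  if (nrow(ann)) {
    # a fragment that carried the phosphate in the target keeps it in the
    # decoy (the modification travels with the repositioned peak, keeping
    # every repositioned m/z chemically plausible)
    phospho_frag <- if (is.na(site)) rep(FALSE, nrow(ann)) else {
      ann$span_start <= site & ann$span_end >= site
    }
    new_mz[ann$peak_index] <- fragment_mz_for(dec_seq, NA_integer_, ann$series,
                                              ann$ordinal, ann$loss, ann$charge) +
      ifelse(phospho_frag, HPO3_MASS / ann$charge, 0)
  }
  out_pk <- peak_table(new_mz, pk$intensity,
                       annotation = if ("annotation" %in% names(pk)) pk$annotation,
                       merge_tol = 1e-9)
  tibble(
    sequence = dec_seq, site = dec_site,
    residue = if (is.na(dec_site)) NA_character_ else substr(dec_seq, dec_site, dec_site),
    charge = as.integer(charge),
    precursor_mz = entry$precursor_mz[[1]],
    status = "decoy",
    num_replicates = entry$num_replicates[[1]],
    peaks = list(out_pk)
  )
}

#' Assemble a searchable spectral library
#'
#' Groups simulated entries by (sequence, site, charge), builds one
#' consensus target per group, adds one shuffle-and-reposition decoy per
#' target (1:1), and indexes entries by precursor m/z.
#'
#' @param entries Simulated-entry tibble from [simulate_all()].
#' @param tol_mz Consensus clustering tolerance (Th).
#' @param seed Integer seed driving decoy generation (recorded on the
#'   library and in its file header).
#' @param min_presence Consensus peak-presence threshold, default 0.5.
#' @return A `phosphosim_library` tibble: `sequence`, `site`, `residue`,
#'   `charge`, `precursor_mz`, `status`, `num_replicates`, `peaks`, sorted
#'   by precursor m/z.
#' @export
build_library <- function(entries, tol_mz = FRAGMENT_TOL_DEFAULT, seed = 1L,
                          min_presence = 0.5) {
  empty <- tibble(
    sequence = character(), site = integer(), residue = character(),
    charge = integer(), precursor_mz = double(), status = character(),
    num_replicates = integer(), peaks = list()
  )
  if (nrow(entries) == 0) {
    attr(empty, "seed") <- as.integer(seed)
    class(empty) <- c("phosphosim_library", class(empty))
    return(empty)
  }
  grouped <- group_replicates(entries)
  keys <- split(seq_len(nrow(grouped)), grouped$group)
  targets <- bind_rows(lapply(keys, function(ix) {
    g <- grouped[ix, ]
    cons <- build_consensus(g$peaks, g$precursor_mz, tol_mz, min_presence)
    tibble(
      sequence = g$sequence[[1]], site = g$site[[1]], residue = g$residue[[1]],
      charge = g$charge[[1]], precursor_mz = cons$precursor_mz,
      status = "target", num_replicates = length(ix), peaks = list(cons$peaks)
    )
  }))
  target_seqs <- unique(targets$sequence)
  decoys <- bind_rows(lapply(seq_len(nrow(targets)), function(k) {
    generate_decoy(targets[k, ], seed = seed + k, avoid = target_seqs, tol_mz = tol_mz)
  }))
  lib <- arrange(bind_rows(targets, decoys), .data$precursor_mz)
  attr(lib, "seed") <- as.integer(seed)
  class(lib) <- c("phosphosim_library", class(lib))
  lib
}

#' Query library entries by precursor window
#'
#' @param lib A `phosphosim_library`.
#' @param mz Query precursor m/z (Th).
#' @param tol_mz Half-window (Th); entries with
#'   `|precursor_mz - mz| <= tol_mz` are returned.
#' @return The matching library rows.
#' @export
library_candidates <- function(lib, mz, tol_mz) {
  lo <- findInterval(mz - tol_mz, lib$precursor_mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + tol_mz, lib$precursor_mz)
  if (hi < lo) return(lib[0, ])
  lib[lo:hi, ]
}

#' @method glance phosphosim_library
#' @export
glance.phosphosim_library <- function(x, ...) {
  tibble(
    n_entries = nrow(x),
    n_targets = sum(x$status == "target"),
    n_decoys = sum(x$status == "decoy"),
    n_sequences = length(unique(x$sequence[x$status == "target"])),
    seed = attr(x, "seed") %||% NA_integer_
  )
}
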