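#' Bin a spectrum into a unit-norm square-root-intensity vector
#'
#' Each peak contributes the square root of its intensity to bin
#' `floor((mz - mz_min) / bin_width)`; peaks outside `[mz_min, mz_max)` are
#' dropped and the vector is scaled to unit Euclidean norm. The default
#' bin width of 0.05 Th corresponds to 20 bins per m/z.
#'
#' @param peaks A peak table.
#' @param bin_width Bin width in Th (> 0), default 0.05.
#' @param mz_min,mz_max Binning range (Th), default 100-1600.
#' @return A `binned_spectrum`: list with integer `idx`, unit weights `w`,
#'   pre-normalization Euclidean `norm`, and the binning parameters.
#' @export
bin_spectrum <- function(peaks, bin_width = 0.05,
                         mz_min = MZ_RANGE_DEFAULT[1], mz_max = MZ_RANGE_DEFAULT[2]) {
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  if (mz_max <= mz_min) abort("`mz_max` must exceed `mz_min`")
  keep <- peaks$mz >= mz_min & peaks$mz < mz_max
  mz <- peaks$mz[keep]
  w <- sqrt(peaks$intensity[keep])
  idx <- as.integer(floor((mz - mz_min) / bin_width))
  if (length(idx)) {
    tot <- rowsum(w, idx)
    idx <- as.integer(rownames(tot))
    w <- as.vector(tot)
    ord <- order(idx)
    idx <- idx[ord]; w <- w[ord]
  }
  nrm <- sqrt(sum(w^2))
  structure(
    list(idx = idx, w = if (nrm > 0) w / nrm else w, norm = nrm,
         bin_width = bin_width, mz_min = mz_min, mz_max = mz_max),
    class = "binned_spectrum"
  )
}

#' Dot product and dot bias of two binned spectra
#'
#' `dot` is the inner product of the unit vectors (cosine similarity of the
#' square-root intensity profiles); `dot_bias` measures how concentrated
#' the product is in few bins: `sqrt(sum((a_i b_i)^2)) / dot` (0 when the
#' dot product is 0). A bias near 1 flags matches dominated by one peak.
#'
#' @param a,b `binned_spectrum` objects with identical binning parameters.
#' @return A list with `dot` in \[0, 1\] and `dot_bias` in \[0, 1\].
#' @export
dot_product <- function(a, b) {
  if (a$bin_width != b$bin_width || a$mz_min != b$mz_min || a$mz_max != b$mz_max) {
    abort("binned spectra have mismatched binning parameters")
  }
  m <- match(a$idx, b$idx)
  hit <- !is.na(m)
  if (!any(hit)) return(list(dot = 0, dot_bias = 0))
  prods <- a$w[hit] * b$w[m[hit]]
  dot <- min(sum(prods), 1)
  list(dot = dot, dot_bias = if (dot > 0) min(sqrt(sum(prods^2)) / dot, 1) else 0)
}

#' Rank-based spectral similarity (v5-like surrogate)
#'
#' Query peaks are matched to library peaks within `tol_mz` (nearest match,
#' one-to-one); the Spearman rank correlation of the matched intensities is
#' mapped to \[0, 1\] via `(rho + 1) / 2` and multiplied by the fraction of
#' library peaks matched. Fewer than 3 matched peaks (or zero intensity
#' variance) gives 0. This is a documented surrogate for rank-based library
#' scoring, not a reproduction of any specific implementation.
#'
#' @param query_peaks,library_peaks Peak tables.
#' @param tol_mz Matching tolerance (Th), default 0.05.
#' @return Similarity in \[0, 1\].
#' @export
score_rank_based <- function(query_peaks, library_peaks, tol_mz = FRAGMENT_TOL_DEFAULT) {
  nq <- nrow(query_peaks); nl <- nrow(library_peaks)
  if (nq == 0 || nl == 0) return(0)
  qmz <- query_peaks$mz
  pos <- findInterval(library_peaks$mz, qmz)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, nq)
  d_lo <- abs(qmz[lo] - library_peaks$mz)
  d_hi <- abs(qmz[hi] - library_peaks$mz)
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  delta <- abs(qmz[nearest] - library_peaks$mz)
  cand <- which(delta <= tol_mz)
  if (length(cand) == 0) return(0)
  ord <- cand[order(delta[cand])]
  ord <- ord[!duplicated(nearest[ord])] # one query peak serves one library peak
  if (length(ord) < 3) return(0)
  qi <- query_peaks$intensity[nearest[ord]]
  li <- library_peaks$intensity[ord]
  rho <- suppressWarnings(cor(qi, li, method = "spearman"))
  if (is.na(rho)) return(0)
  ((rho + 1) / 2) * (length(ord) / nl)
}

#' Combined discriminant score (F-value)
#'
#' `F = w_dot * dot + w_delta * deltadot - penalty`, with the penalty
#' applied when the dot bias falls outside `bias_window` (a match dominated
#' by a single bin, or suspiciously flat). The constants are configuration,
#' chosen to approximate discriminant scoring of spectral search engines.
#'
#' @param dot Dot product in \[0, 1\].
#' @param deltadot Deltadot score (>= 0).
#' @param dot_bias Dot bias in \[0, 1\].
#' @param w_dot,w_delta Blend weights, default 0.6 / 0.4.
#' @param penalty Penalty subtracted outside the bias window, default 0.12.
#' @param bias_window Acceptable dot-bias interval, default `c(0.09, 0.57)`.
#' @return The F-value (real).
#' @export
compute_fvalue <- function(dot, deltadot, dot_bias, w_dot = 0.6, w_delta = 0.4,
                           penalty = 0.12, bias_window = c(0.09, 0.57)) {
  pen <- ifelse(dot_bias < bias_window[1] | dot_bias > bias_window[2], penalty, 0)
  pen <- ifelse(dot == 0, 0, pen) # no-match hits stay at 0
  w_dot * dot + w_delta * deltadot - pen
}

# deltadot of each rank against its own suffix:
# HOM1 compares to the next rank regardless of sequence; HOM4 compares to
# the first of the next three ranks with a different (unmodified) sequence,
# falling back to the third-next (or last available). A rank with no
# successor keeps its own score as delta.
deltadot_suffix <- function(dots, sequences, mode = c("HOM1", "HOM4")) {
  mode <- match.arg(mode)
  n <- length(dots)
  if (n == 0) abort("empty ranking")
  vapply(seq_len(n), function(r) {
    if (r == n) return(dots[r])
    if (mode == "HOM1") return(dots[r] - dots[r + 1])
    cand <- seq(r + 1, min(r + 3, n))
    other <- cand[sequences[cand] != sequences[r]]
    comp <- if (length(other)) other[1] else cand[length(cand)]
    dots[r] - dots[comp]
  }, double(1))
}

#' Compute deltadot scores on a ranked hit table
#'
#' HOM1 compares each hit to the next-ranked hit even when it is a site
#' isoform of the same sequence; HOM4 skips homologous sequences (identical
#' unmodified sequence) up to three ranks down before comparing, falling
#' back to the last of those ranks when all are homologous. A query with a
#' single hit gets its own score as deltadot.
#'
#' @param hits A hits tibble (possibly several queries; grouped by
#'   `query_id`), ranked by the `score_field` within each query.
#' @param mode `"HOM1"` or `"HOM4"`.
#' @param score_field Column holding the similarity score, default `"dot"`.
#' @return `hits` with the `deltadot_hom1` or `deltadot_hom4` column filled.
#' @export
compute_deltadot <- function(hits, mode = c("HOM1", "HOM4"), score_field = "dot") {
  mode <- match.arg(mode)
  if (nrow(hits) == 0) abort("empty ranking")
  col <- if (mode == "HOM1") "deltadot_hom1" else "deltadot_hom4"
  hits |>
    group_by(.data$query_id) |>
    mutate(!!col := deltadot_suffix(.data[[score_field]], .data$sequence, mode)) |>
    ungroup()
}

#' Search query spectra against a spectral library
#'
#' For each query, library entries within `precursor_tol_mz` of the query
#' precursor are scored -- by the binned square-root-intensity dot product
#' (`scoring = "v4"`) or the rank-based surrogate (`"v5like"`) -- and ranked
#' by score (descending; ties broken target-before-decoy, then sequence,
#' then site). HOM1/HOM4 deltadot and the F-value (computed with the HOM4
#' deltadot) are filled per hit. Queries with no peaks or no candidates
#' yield no rows.
#'
#' @param queries Spectra table of query spectra.
#' @param lib A `phosphosim_library`.
#' @param precursor_tol_mz Precursor window (Th), default 3.
#' @param scoring `"v4"` (dot product) or `"v5like"` (rank-based surrogate).
#' @param max_rank Keep at most this many hits per query, default 10.
#' @param bin_width,mz_min,mz_max Binning parameters for v4 scoring.
#' @param fragment_tol_mz Peak-matching tolerance for v5-like scoring.
#' @return A hits tibble: `query_id`, `sequence`, `site`, `residue`,
#'   `charge`, `status`, `rank`, `dot`, `dot_bias`, `deltadot_hom1`,
#'   `deltadot_hom4`, `fvalue`, `precursor_delta_mz`.
#' @export
search_spectra <- function(queries, lib, precursor_tol_mz = 3,
                           scoring = c("v4", "v5like"), max_rank = 10L,
                           bin_width = 0.05, mz_min = MZ_RANGE_DEFAULT[1],
                           mz_max = MZ_RANGE_DEFAULT[2],
                           fragment_tol_mz = FRAGMENT_TOL_DEFAULT) {
  scoring <- match.arg(scoring)
  if (nrow(lib) == 0) abort("library is empty")
  lib_binned <- if (scoring == "v4") {
    lapply(lib$peaks, bin_spectrum, bin_width = bin_width, mz_min = mz_min, mz_max = mz_max)
  }
  out <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    qpk <- queries$peaks[[q]]
    if (nrow(qpk) == 0) {
      inform(paste0("query ", queries$spectrum_id[[q]], " has no peaks; skipped"))
      next
    }
    qmz <- queries$precursor_mz[[q]]
    lo <- findInterval(qmz - precursor_tol_mz, lib$precursor_mz, left.open = TRUE) + 1L
    hi <- findInterval(qmz + precursor_tol_mz, lib$precursor_mz)
    if (hi < lo) next
    cand <- lo:hi
    if (scoring == "v4") {
      qb <- bin_spectrum(qpk, bin_width, mz_min, mz_max)
      scored <- lapply(lib_binned[cand], dot_product, a = qb)
      dot <- vapply(scored, `[[`, double(1), "dot")
      bias <- vapply(scored, `[[`, double(1), "dot_bias")
    } else {
      dot <- vapply(cand, function(k) score_rank_based(qpk, lib$peaks[[k]], fragment_tol_mz),
                    double(1))
      bias <- rep(NA_real_, length(cand))
    }
    ord <- order(-dot, lib$status[cand] != "target", lib$sequence[cand],
                 lib$site[cand])
    ord <- utils::head(ord, max_rank)
    k <- cand[ord]
    out[[q]] <- new_tbl(
      query_id = rep(queries$spectrum_id[[q]], length(k)),
      sequence = lib$sequence[k], site = lib$site[k], residue = lib$residue[k],
      charge = lib$charge[k], status = lib$status[k],
      rank = seq_along(k),
      dot = dot[ord], dot_bias = bias[ord],
      precursor_delta_mz = qmz - lib$precursor_mz[k]
    )
  }
  hits <- bind_rows(out)
  if (nrow(hits) == 0) {
    return(tibble(
      query_id = character(), sequence = character(), site = integer(),
      residue = character(), charge = integer(), status = character(),
      rank = integer(), dot = double(), dot_bias = double(),
      deltadot_hom1 = double(), deltadot_hom4 = double(), fvalue = double(),
      precursor_delta_mz = double()
    ))
  }
  hits <- compute_deltadot(hits, "HOM1")
  hits <- compute_deltadot(hits, "HOM4")
  hits$fvalue <- compute_fvalue(hits$dot, hits$deltadot_hom4,
                                ifelse(is.na(hits$dot_bias), 0.3, hits$dot_bias))
  hits[, c("query_id", "sequence", "site", "residue", "charge", "status",
           "rank", "dot", "dot_bias", "deltadot_hom1", "deltadot_hom4",
           "fvalue", "precursor_delta_mz")]
}

#' Post-search precursor m/z filter
#'
#' Removes hits whose absolute precursor delta exceeds `tol_mz` after
#' scoring; surviving hits keep their scores unchanged. Applying a narrow
#' precursor window only after scoring keeps deltadot informative.
#'
#' @param hits A hits tibble.
#' @param tol_mz Tolerance (Th), default 0.05.
#' @return The filtered hits tibble.
#' @export
apply_precursor_postfilter <- function(hits, tol_mz = 0.05) {
  filter(hits, abs(.data$precursor_delta_mz) <= tol_mz)
}
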