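# Independent reference implementations used to cross-check the package.

# Dense-vector, linear-scan spectral search: bins with plain arithmetic and
# dense numeric vectors, scans every library entry, and applies the same
# tie-break order. Deliberately shares no code with search_spectra().
oracle_search_one <- function(query_row, lib, precursor_tol = 3,
                              bin_width = 0.05, mz_min = 100, mz_max = 1600) {
  nbin <- ceiling((mz_max - mz_min) / bin_width)
  densify <- function(pk) {
    v <- numeric(nbin)
    for (i in seq_len(nrow(pk))) {
      if (pk$mz[i] >= mz_min && pk$mz[i] < mz_max) {
        b <- floor((pk$mz[i] - mz_min) / bin_width) + 1
        v[b] <- v[b] + sqrt(pk$intensity[i])
      }
    }
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }
  qv <- densify(query_row$peaks[[1]])
  rows <- list()
  for (k in seq_len(nrow(lib))) {
    if (abs(lib$precursor_mz[k] - query_row$precursor_mz[[1]]) > precursor_tol) next
    lv <- densify(lib$peaks[[k]])
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = lib$sequence[k], site = lib$site[k], charge = lib$charge[k],
      status = lib$status[k], dot = sum(qv * lv)
    )
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df[order(-df$dot, df$status != "target", df$sequence, df$site), ]
}

# Exhaustive prefix scan for the FLR cutoff: given per-hit scores and
# correctness flags, try every distinct-score prefix and return the deepest
# one whose FLR <= target.
oracle_cutoff <- function(scores, correct, target) {
  ord <- order(-scores)
  scores <- scores[ord]; correct <- correct[ord]
  best <- list(cutoff = Inf, n_correct = 0L)
  for (d in seq_along(scores)) {
    if (d < length(scores) && scores[d + 1] == scores[d]) next # ties share a prefix
    flr <- sum(!correct[1:d]) / d
    if (flr <= target) best <- list(cutoff = scores[d], n_correct = sum(correct[1:d]))
  }
  best
}

# Tiny helper: a spectra table with one spectrum.
one_spectrum <- function(id, pmz, z, mz, intensity) {
  spectra_table(id, pmz, z, list(peak_table(mz, intensity)))
}

# Clean (corruption-free) generator parameters for closed-loop checks.
clean_params <- function(n, seed, ...) {
  synth_params(n_peptides = n, noise_peaks = 0L, dropout_prob = 0,
               mz_jitter_sd = 0, seed = seed, ...)
}
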