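#' Decoy-based false discovery rate
#'
#' Simple counting estimator on rank-1 hits:
#' `FDR(t) = #decoys(score >= t) / max(1, #targets(score >= t))`, capped at
#' 1 for reporting.
#'
#' @param hits Hits tibble carrying a `status` column (rank-1 hits are
#'   used; other ranks are dropped if a `rank` column is present).
#' @param score_field Score column name, e.g. `"dot"` or `"fvalue"`.
#' @param threshold Score threshold t.
#' @return FDR fraction in \[0, 1\].
#' @export
compute_decoy_fdr <- function(hits, score_field, threshold) {
  if (!score_field %in% names(hits)) {
    abort(paste0("unknown score field: ", score_field))
  }
  if ("rank" %in% names(hits)) hits <- filter(hits, .data$rank == 1L)
  above <- hits[hits[[score_field]] >= threshold, ]
  n_decoy <- sum(above$status == "decoy")
  n_target <- sum(above$status == "target")
  min(n_decoy / max(1L, n_target), 1)
}

#' Largest hit set at a decoy-FDR level
#'
#' Scans distinct-score prefixes of the rank-1 hits sorted by descending
#' score and returns the deepest prefix whose decoy FDR is at or below
#' `level` (targets and decoys both included; filter on `status` to keep
#' accepted identifications).
#'
#' @inheritParams compute_decoy_fdr
#' @param level Target FDR level, e.g. 0.01.
#' @return The hits in the accepted prefix (possibly zero rows).
#' @export
filter_decoy_fdr <- function(hits, score_field, level = 0.01) {
  if (!score_field %in% names(hits)) abort(paste0("unknown score field: ", score_field))
  if ("rank" %in% names(hits)) hits <- filter(hits, .data$rank == 1L)
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(-hits[[score_field]]), ]
  s <- hits[[score_field]]
  cum_decoy <- cumsum(hits$status == "decoy")
  cum_target <- cumsum(hits$status == "target")
  fdr <- cum_decoy / pmax(1L, cum_target)
  # prefixes end at the last index of each distinct score (ties share a prefix)
  ends <- which(!duplicated(s, fromLast = TRUE))
  ok <- ends[fdr[ends] <= level]
  if (length(ok) == 0) return(hits[0, ])
  hits[seq_len(max(ok)), ]
}

#' False-localization-rate curve
#'
#' Joins rank-1 hits to the ground truth by `query_id`, scores each hit as
#' a correct or false localization (`site == true_site`), and accumulates
#' counts down the list sorted by descending `score_field`. Hits whose
#' matched sequence differs from the true sequence are excluded from the
#' curve and counted separately (attribute `n_sequence_errors`), unless
#' `count_wrong_seq_as_false` is `TRUE`, in which case they count as false
#' localizations. Decoy hits are treated as wrong-sequence matches. One
#' row is emitted per distinct score (ties share a prefix).
#'
#' @param hits Hits tibble.
#' @param truth Ground-truth tibble from [read_truth_table()] (or with the
#'   same columns).
#' @param score_field Score column, default `"deltadot_hom1"`.
#' @param count_wrong_seq_as_false Conservative mode; default `FALSE`.
#' @return A `phosphosim_flr` tibble: `score`, `n_correct`, `n_false`,
#'   `flr`, with attributes `score_field` and `n_sequence_errors`.
#' @export
compute_flr_curve <- function(hits, truth, score_field = "deltadot_hom1",
                              count_wrong_seq_as_false = FALSE) {
  if (!score_field %in% names(hits)) abort(paste0("unknown score field: ", score_field))
  if ("rank" %in% names(hits)) hits <- filter(hits, .data$rank == 1L)
  missing_ids <- setdiff(hits$query_id, truth$spectrum_id)
  if (length(missing_ids)) {
    abort(paste0("query ids absent from truth: ", paste(missing_ids, collapse = ", ")))
  }
  joined <- inner_join(
    hits,
    dplyr::select(truth, query_id = "spectrum_id", true_sequence = "sequence",
                  true_site = "true_site"),
    by = "query_id"
  )
  wrong_seq <- joined$sequence != joined$true_sequence | joined$status == "decoy"
  n_seq_err <- sum(wrong_seq)
  if (count_wrong_seq_as_false) {
    joined$correct <- !wrong_seq & joined$site == joined$true_site
  } else {
    joined <- joined[!wrong_seq, , drop = FALSE]
    joined$correct <- joined$site == joined$true_site
  }
  joined <- joined[order(-joined[[score_field]]), ]
  s <- joined[[score_field]]
  cum_c <- cumsum(joined$correct)
  cum_f <- cumsum(!joined$correct)
  ends <- which(!duplicated(s, fromLast = TRUE))
  out <- tibble(
    score = s[ends],
    n_correct = cum_c[ends],
    n_false = cum_f[ends],
    flr = cum_f[ends] / pmax(1L, cum_c[ends] + cum_f[ends])
  )
  attr(out, "score_field") <- score_field
  attr(out, "n_sequence_errors") <- n_seq_err
  class(out) <- c("phosphosim_flr", class(out))
  out
}

#' Score cutoff at a target FLR
#'
#' Returns the smallest score threshold (deepest prefix of the FLR curve)
#' whose FLR does not exceed `target`, together with the number of correct
#' localizations in that prefix. When no prefix qualifies the cutoff is
#' `Inf` with 0 correct matches.
#'
#' @param curve A `phosphosim_flr` curve.
#' @param target FLR level in (0, 1\], default 0.01.
#' @return A one-row tibble: `cutoff`, `n_correct`, `flr`.
#' @export
cutoff_at_flr <- function(curve, target = 0.01) {
  if (!is.numeric(target) || target <= 0 || target > 1) {
    abort("`target` must be in (0, 1]")
  }
  ok <- which(curve$flr <= target)
  if (length(ok) == 0 || nrow(curve) == 0) {
    return(tibble(cutoff = Inf, n_correct = 0L, flr = NA_real_))
  }
  k <- max(ok) # deepest qualifying prefix
  tibble(cutoff = curve$score[[k]], n_correct = curve$n_correct[[k]],
         flr = curve$flr[[k]])
}

#' Sweep simulation conditions and scorings
#'
#' For every (condition, scoring) pair: simulate all single-phospho
#' isoforms of the dephosphorylated-peptide PSMs, build a consensus library
#' with decoys (one shared seed), search the phosphopeptide queries, apply
#' the precursor post-filter, compute the FLR curve on the HOM1 deltadot
#' score and extract the cutoff at `flr_target`. Template annotations are
#' computed once and reused across conditions.
#'
#' @param dephos_psms PSM tibble for the dephosphorylated run.
#' @param dephos_spectra Spectra table for the dephosphorylated run.
#' @param query_spectra Spectra table of phosphopeptide queries.
#' @param truth Ground-truth tibble.
#' @param conditions List of [sim_config()]s; default [sim_condition_grid()].
#' @param scorings Character vector from `c("v4", "v5like")`.
#' @param seed Seed for decoy generation (shared across conditions).
#' @param flr_target FLR level, default 0.01.
#' @param min_probability PSM probability filter, default 0.95.
#' @param precursor_tol_mz Search window (Th), default 3.
#' @param postfilter_tol_mz Post-search precursor filter (Th), default 0.05.
#' @return A `phosphosim_sweep` tibble: `condition`, `intensity_label`,
#'   `nl_label`, `scoring`, `cutoff`, `n_correct`, `n_hits`,
#'   `n_sequence_errors`.
#' @export
condition_sweep <- function(dephos_psms, dephos_spectra, query_spectra, truth,
                            conditions = sim_condition_grid(),
                            scorings = c("v4", "v5like"), seed = 1L,
                            flr_target = 0.01, min_probability = 0.95,
                            precursor_tol_mz = 3, postfilter_tol_mz = 0.05) {
  keep <- dephos_psms$probability >= min_probability &
    !vapply(dephos_psms$modifications, has_phospho_mod, logical(1))
  psms <- dephos_psms[keep, , drop = FALSE]
  ann <- annotate_psm_spectra(psms, dephos_spectra)
  rows <- list()
  for (cfg in conditions) {
    entries <- simulate_all(psms, dephos_spectra, cfg,
                            min_probability = min_probability, annotations = ann)
    lib <- build_library(entries, seed = seed)
    for (sc in scorings) {
      hits <- search_spectra(query_spectra, lib, precursor_tol_mz, scoring = sc)
      hits <- apply_precursor_postfilter(hits, postfilter_tol_mz)
      curve <- compute_flr_curve(hits, truth, "deltadot_hom1")
      cut <- cutoff_at_flr(curve, flr_target)
      rows[[length(rows) + 1L]] <- tibble(
        condition = format(cfg),
        intensity_label = cfg$intensity_label,
        nl_label = cfg$nl_label,
        scoring = sc,
        cutoff = cut$cutoff,
        n_correct = cut$n_correct,
        n_hits = sum(hits$rank == 1L),
        n_sequence_errors = attr(curve, "n_sequence_errors")
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("phosphosim_sweep", class(out))
  out
}

#' Agreement between two search result sets
#'
#' Compares rank-1 hits of two searches keyed by `query_id`: how many query
#' spectra are shared, on how many the peptide sequences agree, and on how
#' many of those sequence-agreeing spectra the phosphorylation sites also
#' agree.
#'
#' @param hits_a,hits_b Hits tibbles (rank-1 rows are used).
#' @return A one-row tibble: `n_shared`, `n_sequence_agree`,
#'   `sequence_agree_frac`, `n_site_agree`, `site_agree_frac` (site
#'   fractions are relative to sequence-agreeing spectra; `NA` when
#'   denominators are 0).
#' @export
agreement_analysis <- function(hits_a, hits_b) {
  if ("rank" %in% names(hits_a)) hits_a <- filter(hits_a, .data$rank == 1L)
  if ("rank" %in% names(hits_b)) hits_b <- filter(hits_b, .data$rank == 1L)
  j <- inner_join(
    dplyr::select(hits_a, "query_id", seq_a = "sequence", site_a = "site"),
    dplyr::select(hits_b, "query_id", seq_b = "sequence", site_b = "site"),
    by = "query_id"
  )
  n_shared <- nrow(j)
  seq_agree <- j$seq_a == j$seq_b
  n_seq <- sum(seq_agree)
  n_site <- sum(seq_agree & j$site_a == j$site_b)
  tibble(
    n_shared = n_shared,
    n_sequence_agree = n_seq,
    sequence_agree_frac = if (n_shared > 0) n_seq / n_shared else NA_real_,
    n_site_agree = n_site,
    site_agree_frac = if (n_seq > 0) n_site / n_seq else NA_real_
  )
}
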