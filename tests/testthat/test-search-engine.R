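test_that("binning sums square-root intensities and normalizes to unit length", {
  b1 <- bin_spectrum(peak_table(500.0, 123))
  expect_equal(length(b1$idx), 1L)
  expect_equal(b1$w, 1)
  # peaks 0.01 Th apart share a 0.05 Th bin; weights add before normalization
  b2 <- bin_spectrum(peak_table(c(100.00, 100.01), c(4, 9)))
  expect_equal(length(b2$idx), 1L)
  expect_equal(b2$norm, sqrt(4) + sqrt(9))
  # intensity scaling leaves the normalized vector unchanged
  pk <- peak_table(c(150.3, 420.7, 890.1), c(5, 50, 500))
  pk2 <- peak_table(pk$mz, pk$intensity * 37)
  expect_equal(bin_spectrum(pk)$w, bin_spectrum(pk2)$w, tolerance = 1e-12)
  # out-of-range peaks are dropped; range errors are caught
  expect_equal(length(bin_spectrum(peak_table(c(50, 1700), c(1, 1)))$idx), 0L)
  expect_error(bin_spectrum(pk, mz_min = 500, mz_max = 100), "exceed")
})

test_that("dot product and dot bias behave as cosine similarity of sqrt spectra", {
  x <- bin_spectrum(peak_table(c(100.2, 200.4, 300.6), c(10, 40, 90)))
  expect_equal(dot_product(x, x)$dot, 1, tolerance = 1e-12)
  y <- bin_spectrum(peak_table(c(500.2, 600.4), c(10, 40)))
  expect_equal(dot_product(x, y)$dot, 0)
  # two shared unit-weight bins out of two each: dot = 0.5
  a <- bin_spectrum(peak_table(c(100.2, 200.4), c(1, 1)))
  b <- bin_spectrum(peak_table(c(100.2, 300.6), c(1, 1)))
  expect_equal(dot_product(a, b)$dot, 0.5, tolerance = 1e-12)
  expect_error(dot_product(a, bin_spectrum(peak_table(100, 1), bin_width = 0.1)),
               "mismatched")
})

test_that("deltadot follows the HOM1/HOM4 homology rules", {
  mk <- function(dots, seqs) tibble::tibble(
    query_id = "q1", sequence = seqs, site = seq_along(dots), charge = 2L,
    status = "target", rank = seq_along(dots), dot = dots
  )
  h <- mk(c(0.9, 0.7), c("AAK", "CCK"))
  h <- compute_deltadot(compute_deltadot(h, "HOM1"), "HOM4")
  expect_equal(h$deltadot_hom1[1], 0.2, tolerance = 1e-12)
  expect_equal(h$deltadot_hom4[1], 0.2, tolerance = 1e-12)

  # runner-up is a site isoform: HOM1 sees it, HOM4 skips to the next sequence
  h2 <- mk(c(0.9, 0.85, 0.6), c("AAK", "AAK", "CCK"))
  h2 <- compute_deltadot(compute_deltadot(h2, "HOM1"), "HOM4")
  expect_equal(h2$deltadot_hom1[1], 0.05, tolerance = 1e-12)
  expect_equal(h2$deltadot_hom4[1], 0.3, tolerance = 1e-12)

  # all of ranks 2..4 homologous: fall back to rank 4
  h3 <- mk(c(0.9, 0.8, 0.7, 0.6, 0.5), rep("AAK", 5))
  h3 <- compute_deltadot(h3, "HOM4")
  expect_equal(h3$deltadot_hom4[1], 0.3, tolerance = 1e-12)

  # single hit: deltadot equals its own score
  h4 <- compute_deltadot(mk(0.8, "AAK"), "HOM1")
  expect_equal(h4$deltadot_hom1[1], 0.8)
  expect_error(compute_deltadot(mk(numeric(), character()), "HOM1"), "empty")
})

test_that("the F-value blends dot and deltadot with a dot-bias penalty", {
  expect_equal(compute_fvalue(0.9, 0.2, 0.30), 0.62, tolerance = 1e-12)
  expect_equal(compute_fvalue(0, 0, 0.3), 0)
  expect_equal(compute_fvalue(0.9, 0.2, 0.05), 0.50, tolerance = 1e-12) # penalized
  expect_equal(compute_fvalue(0.9, 0.2, 0.60), 0.50, tolerance = 1e-12) # high-bias side
})

test_that("search retrieves identical spectra at rank 1 and respects the window", {
  d <- generate_dataset(clean_params(6, seed = 31))
  ents <- simulate_all(d$psms, d$dephospho_spectra, sim_preset("optimized-A"))
  lib <- build_library(ents, seed = 5L)
  # query a library target spectrum against the library: rank 1, dot 1
  t1 <- which(lib$status == "target")[1]
  q <- spectra_table("q_self", lib$precursor_mz[t1], lib$charge[t1],
                     list(lib$peaks[[t1]]))
  hits <- search_spectra(q, lib)
  expect_equal(hits$dot[hits$rank == 1], 1, tolerance = 1e-9)
  expect_equal(hits$sequence[hits$rank == 1], lib$sequence[t1])
  expect_equal(hits$site[hits$rank == 1], lib$site[t1])

  # precursor far from every entry: no hits
  far <- spectra_table("q_far", max(lib$precursor_mz) + 10, 2L, list(lib$peaks[[t1]]))
  expect_equal(nrow(search_spectra(far, lib)), 0L)

  # empty query: skipped with a message
  none <- spectra_table("q_none", lib$precursor_mz[t1], 2L,
                        list(peak_table(double(), double())))
  expect_message(out <- search_spectra(none, lib), "no peaks")
  expect_equal(nrow(out), 0L)

  # global intensity scaling of the query leaves the ranking unchanged
  qs <- q
  qs$peaks[[1]] <- peak_table(q$peaks[[1]]$mz, q$peaks[[1]]$intensity * 1000)
  hs <- search_spectra(qs, lib)
  expect_equal(hs[, c("sequence", "site", "rank")], hits[, c("sequence", "site", "rank")])
  expect_equal(hs$dot, hits$dot, tolerance = 1e-9)
})

test_that("post-search precursor filtering drops hits without rescoring", {
  hits <- tibble::tibble(
    query_id = c("a", "b"), sequence = "AAK", site = 1L, charge = 2L,
    status = "target", rank = 1L, dot = c(0.9, 0.8), dot_bias = 0.3,
    deltadot_hom1 = c(0.2, 0.1), deltadot_hom4 = c(0.2, 0.1),
    fvalue = c(0.62, 0.52), precursor_delta_mz = c(0.02, 1.5)
  )
  out <- apply_precursor_postfilter(hits, 0.05)
  expect_equal(out$query_id, "a")
  expect_equal(out$fvalue, 0.62) # scores untouched
})

test_that("the rank-based similarity surrogate behaves at its limits", {
  pk <- peak_table(c(100.5, 200.5, 300.5, 400.5), c(10, 20, 30, 40))
  expect_equal(score_rank_based(pk, pk), 1, tolerance = 1e-12)
  other <- peak_table(c(150.5, 250.5, 350.5), c(1, 2, 3))
  expect_equal(score_rank_based(pk, other), 0)
  # rank-reversed intensities: perfect anticorrelation maps to 0
  anti <- peak_table(pk$mz, rev(pk$intensity))
  expect_equal(score_rank_based(anti, pk), 0, tolerance = 1e-12)
  # fewer than 3 matched peaks scores 0
  two <- peak_table(c(100.5, 200.5), c(10, 20))
  expect_equal(score_rank_based(two, two), 0)
})

test_that("HOM4 deltadot is never below HOM1 on a full synthetic search", {
  d <- generate_dataset(synth_params(n_peptides = 8, seed = 41))
  ents <- simulate_all(d$psms, d$dephospho_spectra, sim_preset("optimized-A"))
  lib <- build_library(ents, seed = 41L)
  hits <- search_spectra(d$query_spectra, lib)
  expect_true(all(hits$deltadot_hom4 >= hits$deltadot_hom1 - 1e-12))
})
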