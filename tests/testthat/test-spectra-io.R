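test_that("MGF write/read round-trips spectra at the written precision", {
  sp <- spectra_table(
    spectrum_id = c("specA", "specB", "empty"),
    precursor_mz = c(460.2514, 680.346780, 300.1),
    precursor_charge = c(2L, 3L, 2L),
    peaks = list(
      peak_table(c(200.123456, 100.5), c(10.1234, 999)), # unsorted on purpose
      peak_table(c(150.0, 150.2, 800.77), c(1, 2, 3)),
      peak_table(double(), double())
    )
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_equal(back$spectrum_id, sp$spectrum_id)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  expect_equal(back$precursor_charge, sp$precursor_charge)
  for (i in 1:3) {
    expect_equal(back$peaks[[i]]$mz, sp$peaks[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$peaks[[i]]$intensity, sp$peaks[[i]]$intensity, tolerance = 1e-4)
  }
  # peaks came back sorted even though input listed them unsorted
  expect_false(is.unsorted(back$peaks[[1]]$mz))
})

test_that("MGF parser maps fields, skips PEPMASS-less blocks, errors on junk", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=ok1", "PEPMASS=460.2514 12345.6", "CHARGE=2+",
    "100.0 1.0", "200.0 2.0", "END IONS",
    "BEGIN IONS", "TITLE=nopepmass", "CHARGE=2+", "100.0 1.0", "END IONS",
    "BEGIN IONS", "PEPMASS=500.1", "300.0 3.0", "END IONS"
  ), path)
  expect_warning(sp <- read_mgf(path), "missing PEPMASS")
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$precursor_mz[[1]], 460.2514)
  expect_equal(sp$precursor_charge[[1]], 2L)
  expect_equal(nrow(sp$peaks[[1]]), 2L)
  # TITLE-less block gets a synthesized id
  expect_match(sp$spectrum_id[[2]], "#3$")

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "oops peak", "END IONS"), bad)
  expect_error(read_mgf(bad), "line 3")

  unterminated <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "100.0 1.0"), unterminated)
  expect_error(read_mgf(unterminated), "unterminated")

  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(), empty)
  expect_equal(nrow(read_mgf(empty)), 0L)
})

test_that("PSM tables parse modifications and validate probabilities", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "spectrum_id\tsequence\tmodifications\tcharge\tprobability",
    "sp1\tSGAQASSTPLSPTR\t\t2\t0.99",
    "sp2\tACDEFGHK\t0:acetyl:42.010565;2:carbamidomethyl:57.021464\t2\t0.97"
  ), path)
  psms <- read_psm_table(path)
  expect_equal(nrow(psms), 2L)
  expect_equal(nrow(psms$modifications[[1]]), 0L)
  expect_equal(psms$modifications[[2]]$position, c(0L, 2L))
  expect_equal(psms$modifications[[2]]$delta_mass[1], 42.010565)

  # round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, out)
  back <- read_psm_table(out)
  expect_equal(back$sequence, psms$sequence)
  expect_equal(back$modifications[[2]]$name, psms$modifications[[2]]$name)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tsequence\tmodifications\tcharge\tprobability",
               "sp1\tPEPTIDEK\t\t2\t1.2"), bad)
  expect_error(read_psm_table(bad), "probability")

  extra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tsequence\tmodifications\tcharge\tprobability\tbonus",
               "sp1\tPEPTIDEK\t\t2\t0.9\tx"), extra)
  expect_error(read_psm_table(extra), "unknown")
})

test_that("truth tables derive the residue and reject non-S/T/Y sites", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tsequence\ttrue_site", "sp9\tSGAQASSTPLSPTR\t11"), path)
  truth <- read_truth_table(path)
  expect_equal(truth$residue, "S")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tsequence\ttrue_site", "sp9\tSGAQASSTPLSPTR\t3"), bad)
  expect_error(read_truth_table(bad), "S/T/Y")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("spectrum_id\tsequence\ttrue_site", empty)
  expect_equal(nrow(read_truth_table(empty)), 0L)
})

test_that("library write/read is an identity and enforces entry invariants", {
  d <- generate_dataset(synth_params(n_peptides = 4L, seed = 3L))
  ents <- simulate_all(d$psms, d$dephospho_spectra, sim_preset("optimized-A"))
  lib <- build_library(ents, seed = 5L)
  path <- withr::local_tempfile(fileext = ".msp")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(back$sequence, lib$sequence)
  expect_equal(back$site, lib$site)
  expect_equal(back$status, lib$status)
  expect_equal(back$num_replicates, lib$num_replicates)
  expect_equal(back$precursor_mz, lib$precursor_mz, tolerance = 1e-6)
  expect_equal(attr(back, "seed"), attr(lib, "seed"))
  for (i in seq_len(nrow(lib))) {
    expect_equal(back$peaks[[i]]$mz, lib$peaks[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$peaks[[i]]$intensity, lib$peaks[[i]]$intensity, tolerance = 1e-4)
  }

  dup <- lib[c(1, 1), ]
  expect_error(write_library(dup, withr::local_tempfile()), "duplicate")

  broken <- lib[1, ]
  broken$peaks[[1]] <- tibble::tibble(mz = c(200, 100), intensity = c(1, 2))
  expect_error(write_library(broken, withr::local_tempfile()), "unsorted")

  # empty library round-trips to empty
  e <- build_library(ents[0, ], seed = 1L)
  p2 <- withr::local_tempfile()
  write_library(e, p2)
  expect_equal(nrow(read_library(p2)), 0L)
})

test_that("hit tables round-trip through TSV", {
  d <- generate_dataset(synth_params(n_peptides = 3L, seed = 8L))
  ents <- simulate_all(d$psms, d$dephospho_spectra, sim_preset("optimized-A"))
  lib <- build_library(ents, seed = 2L)
  hits <- search_spectra(d$query_spectra[1:3, ], lib)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$dot, hits$dot, tolerance = 1e-12)
  expect_equal(back$deltadot_hom1, hits$deltadot_hom1, tolerance = 1e-12)
})
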