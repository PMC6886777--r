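test_that("site enumeration finds every S/T/Y in order", {
  s <- enumerate_sites("SGAQASSTPLSPTR")
  expect_equal(s$site, c(1L, 6L, 7L, 8L, 11L, 13L))
  expect_equal(s$residue, c("S", "S", "S", "T", "S", "T"))
  expect_equal(nrow(enumerate_sites("GGAL")), 0L)
  expect_equal(enumerate_sites("Y"), tibble::tibble(site = 1L, residue = "Y"))
})

test_that("pS simulation shifts site fragments by +79.9663 and -18.0106 at set ratios", {
  sq <- "SGAQASSTPLSPTR"
  sp <- one_spectrum("s1", precursor_mz(peptide_mass(sq), 2), 2L,
                     c(216.0978824, 460.2514229), c(500, 1000))
  ann <- annotate_spectrum(sp$peaks[[1]], generate_fragments(sq, 2L))
  ent <- simulate_site(sp, ann, sq, 11L, sim_config()) # default 10-100-100
  pk <- ent$peaks[[1]]
  # y4 spans (11,14): replaced by intact at +79.966331 and NL-P at -18.010565
  expect_equal(sort(pk$mz), sort(c(216.0978824, 460.2514229 + 79.966331,
                                   460.2514229 - 18.010565)), tolerance = 1e-5)
  intact <- pk[abs(pk$mz - 540.2177534) < 1e-4, ]
  nlp <- pk[abs(pk$mz - 442.2408582) < 1e-4, ]
  expect_equal(intact$intensity, 0.10 * 1000) # pS/pT intact ratio, default 10%
  expect_equal(nlp$intensity, 1.00 * 1000)    # NL-P ratio, default 100%
  # b3 spans (1,3), excludes site 11: copied unchanged
  b3 <- pk[abs(pk$mz - 216.0978824) < 1e-4, ]
  expect_equal(b3$intensity, 500)
  # precursor shifts by +79.966331 / charge
  expect_equal(ent$precursor_mz - sp$precursor_mz, 79.966331 / 2, tolerance = 1e-5)
  # unannotated source y4 peak is gone
  expect_false(any(abs(pk$mz - 460.2514229) < 1e-3))
})

test_that("pY sites get the intact ion only, never an NL-P ion", {
  sq <- "GAYAGASK"
  fr <- generate_fragments(sq, 2L)
  y6 <- fr$mz[fr$series == "y" & fr$ordinal == 6 & fr$loss == "none" & fr$charge == 1]
  sp <- one_spectrum("s1", precursor_mz(peptide_mass(sq), 2), 2L, y6, 800)
  ann <- annotate_spectrum(sp$peaks[[1]], fr)
  ent <- simulate_site(sp, ann, sq, 3L, sim_config(0.5, 0.5, 0.7, character(0)))
  pk <- ent$peaks[[1]]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, y6 + 79.966331, tolerance = 1e-5)
  expect_equal(pk$intensity, 0.7 * 800) # scaled by the pY ratio
})

test_that("neutral-loss template gating follows the NL condition", {
  sq <- "GASTGAGK"
  fr <- generate_fragments(sq, 2L)
  pick <- function(series, ordinal, loss) {
    fr$mz[fr$series == series & fr$ordinal == ordinal & fr$loss == loss & fr$charge == 1]
  }
  # y6 contains S and T -> parent, NH3 (no: y6 = STGAGK has K -> yes NH3), H2O
  mzs <- c(pick("y", 6, "none"), pick("y", 6, "NH3"), pick("y", 6, "H2O"))
  sp <- one_spectrum("s1", precursor_mz(peptide_mass(sq), 2), 2L, mzs, c(1000, 300, 300))
  ann <- annotate_spectrum(sp$peaks[[1]], fr)
  # NL-P condition: satellites are removed and spawn nothing
  ent <- simulate_site(sp, ann, sq, 3L, sim_config(0.5, 0.5, 0.5, character(0)))
  expect_equal(nrow(ent$peaks[[1]]), 2L) # intact + NL-P from the parent only
  # NL-PAW condition: each satellite also spawns intact + NL-P
  ent2 <- simulate_site(sp, ann, sq, 3L, sim_config(0.5, 0.5, 0.5, c("NH3", "H2O")))
  expect_equal(nrow(ent2$peaks[[1]]), 6L)
  # the ammonia satellite position itself is never copied; the peak sitting at
  # the water-satellite position is the parent's NL-P ion, not the satellite
  expect_false(any(abs(ent2$peaks[[1]]$mz - mzs[2]) < 1e-4))
  at_w <- ent2$peaks[[1]][abs(ent2$peaks[[1]]$mz - mzs[3]) < 1e-4, ]
  expect_equal(at_w$intensity, 0.5 * 1000)
})

test_that("simulate_all filters templates and emits one entry per site", {
  sq <- "SGAQASSTPLSPTR"
  mk_spec <- function(id) one_spectrum(id, precursor_mz(peptide_mass(sq), 2), 2L,
                                       c(216.0978824, 460.2514229), c(500, 1000))
  spectra <- dplyr::bind_rows(mk_spec("a"), mk_spec("b"), mk_spec("c"))
  no_mods <- list(tibble::tibble(position = integer(), name = character(),
                                 delta_mass = double()))
  psms <- tibble::tibble(
    spectrum_id = c("a", "b", "c"),
    sequence = c(sq, sq, "GGALGGAK"),
    modifications = c(no_mods, list(tibble::tibble(position = 11L, name = "phospho",
                                                   delta_mass = 79.966331)), no_mods),
    charge = 2L,
    probability = c(0.99, 0.99, 0.99)
  )
  ents <- simulate_all(psms, spectra, sim_config())
  # "a" yields 6 site isoforms; "b" is already phosphorylated (skipped);
  # "c" has no S/T/Y (no entries)
  expect_equal(nrow(ents), 6L)
  expect_equal(unique(ents$source_id), "a")
  expect_equal(ents$site, c(1L, 6L, 7L, 8L, 11L, 13L))

  low <- psms[1, ]
  low$probability <- 0.90
  expect_equal(nrow(simulate_all(low, spectra, sim_config(), min_probability = 0.95)), 0L)

  orphan <- psms[1, ]
  orphan$spectrum_id <- "missing"
  expect_error(simulate_all(orphan, spectra, sim_config()), "missing")
})

test_that("simulation conserves mass and leaves non-site peaks untouched", {
  d <- generate_dataset(clean_params(6, seed = 9))
  ents <- simulate_all(d$psms, d$dephospho_spectra, sim_preset("optimized-B"))
  # isoform count per template equals the S/T/Y count of its sequence
  counts <- table(ents$source_id)
  for (id in names(counts)) {
    sq <- d$psms$sequence[d$psms$spectrum_id == id]
    expect_equal(unname(counts[[id]]), nrow(enumerate_sites(sq)))
  }
  idx <- match(ents$source_id, d$dephospho_spectra$spectrum_id)
  for (k in seq_len(nrow(ents))) {
    z <- ents$charge[[k]]
    src <- d$dephospho_spectra[idx[[k]], ]
    # exact +79.966331 Da precursor mass conservation at every charge
    expect_equal((ents$precursor_mz[[k]] - src$precursor_mz) * z, 79.966331,
                 tolerance = 1e-5)
    # peaks from fragments not containing the site are bit-identical
    ann <- annotate_spectrum(src$peaks[[1]],
                             generate_fragments(ents$sequence[[k]], z))
    non_site <- ann$peak_index[!(ann$span_start <= ents$site[[k]] &
                                   ann$span_end >= ents$site[[k]])]
    kept <- src$peaks[[1]]$mz[non_site]
    expect_true(all(kept %in% ents$peaks[[k]]$mz))
  }
})
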