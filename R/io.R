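#' Read an MGF peak-list file
#'
#' Parses Mascot generic format (`BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, `CHARGE`, `TITLE`, optional `RTINSECONDS`). The spectrum
#' identifier is the `TITLE` line, or `<basename>#<index>` when absent.
#' Blocks lacking `PEPMASS` are skipped with a warning naming the line;
#' structurally malformed input (peak lines outside a block, unterminated
#' blocks, unparsable peak lines) is an error naming the line number.
#'
#' @param path Path to an MGF file.
#' @return A spectra table (see [spectra_table()]); peaks sorted by m/z.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  base <- basename(path)
  ids <- character(); pmz <- double(); pz <- integer(); rt <- double()
  pk <- list()
  i <- 1L; n <- length(lines); block_no <- 0L
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "#") || grepl("^[A-Z]+=", line) && !startsWith(line, "BEGIN")) {
      # headers outside blocks (e.g. global CHARGE=) are ignored
      if (line != "" && !startsWith(line, "#") && !grepl("^[A-Z_]+=", line)) {
        abort(paste0("MGF parse error at line ", i, ": unexpected content outside BEGIN IONS"))
      }
      i <- i + 1L
      next
    }
    if (line != "BEGIN IONS") {
      abort(paste0("MGF parse error at line ", i, ": expected BEGIN IONS"))
    }
    begin_line <- i
    block_no <- block_no + 1L
    i <- i + 1L
    title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_; rtime <- NA_real_
    mzv <- double(); inv <- double()
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (line == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (line == "") { i <- i + 1L; next }
      if (grepl("^[A-Za-z_]+=", line)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[A-Za-z_]+=", "", line)
        if (key == "TITLE") title <- val
        if (key == "PEPMASS") pepmass <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1]][1]))
        if (key == "CHARGE") {
          charge <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", trimws(val))))
          if (grepl("-", val, fixed = TRUE)) {
            abort(paste0("MGF parse error at line ", i, ": negative charge unsupported"))
          }
        }
        if (key == "RTINSECONDS") rtime <- suppressWarnings(as.numeric(val))
      } else {
        fields <- strsplit(line, "[ \t]+")[[1]]
        m <- suppressWarnings(as.numeric(fields[1]))
        iy <- suppressWarnings(as.numeric(fields[2]))
        if (length(fields) < 2 || is.na(m) || is.na(iy)) {
          abort(paste0("MGF parse error at line ", i, ": bad peak line '", line, "'"))
        }
        mzv <- c(mzv, m); inv <- c(inv, iy)
      }
      i <- i + 1L
    }
    if (!closed) abort(paste0("MGF parse error at line ", begin_line, ": unterminated BEGIN IONS"))
    if (is.na(pepmass)) {
      warn(paste0("skipping MGF block at line ", begin_line, ": missing PEPMASS"))
      next
    }
    ids <- c(ids, if (is.na(title)) paste0(base, "#", block_no) else title)
    pmz <- c(pmz, pepmass)
    pz <- c(pz, if (is.na(charge)) 2L else charge)
    rt <- c(rt, rtime)
    pk[[length(pk) + 1L]] <- peak_table(mzv, inv)
  }
  spectra_table(ids, pmz, pz, pk, rt)
}

#' Write a spectra table to MGF
#'
#' m/z values are written to 6 decimals and intensities to 4, so
#' `read_mgf(write_mgf(x))` round-trips at that precision.
#'
#' @param spectra A spectra table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  validate_spectra(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(spectra))) {
    p <- spectra$peaks[[k]]
    rt <- if ("retention_time" %in% names(spectra)) spectra$retention_time[[k]] else NA_real_
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[[k]]),
      paste0("PEPMASS=", sprintf("%.6f", spectra$precursor_mz[[k]])),
      paste0("CHARGE=", spectra$precursor_charge[[k]], "+"),
      if (!is.na(rt)) paste0("RTINSECONDS=", sprintf("%.3f", rt)),
      if (nrow(p)) sprintf("%.6f %.4f", p$mz, p$intensity),
      "END IONS",
      ""
    )
    writeLines(block, con)
  }
  invisible(path)
}

parse_modifications <- function(x, row_id = NULL) {
  where <- if (is.null(row_id)) "" else paste0(" (", row_id, ")")
  if (is.na(x) || !nzchar(trimws(x))) {
    return(tibble(position = integer(), name = character(), delta_mass = double()))
  }
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) != 3L
  if (any(bad)) abort(paste0("bad modification syntax", where, ": '", x, "' (expect pos:name:delta)"))
  tibble(
    position = as.integer(vapply(fields, `[[`, character(1), 1)),
    name = vapply(fields, `[[`, character(1), 2),
    delta_mass = as.numeric(vapply(fields, `[[`, character(1), 3))
  )
}

format_modifications <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0) return("")
  paste(sprintf("%d:%s:%.6f", mods$position, mods$name, mods$delta_mass), collapse = ";")
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Tab-separated with header columns `spectrum_id`, `sequence`,
#' `modifications`, `charge`, `probability`. Modifications use the
#' `pos:name:delta` syntax joined by `;` (position 0 = peptide N-terminus);
#' an empty field means no modifications.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `modifications` list-column of tibbles
#'   (`position`, `name`, `delta_mass`).
#' @export
read_psm_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    sequence = readr::col_character(),
    modifications = readr::col_character(),
    charge = readr::col_integer(),
    probability = readr::col_double()
  ))
  extra <- setdiff(names(df), c("spectrum_id", "sequence", "modifications", "charge", "probability"))
  if (length(extra)) abort(paste0("unknown PSM table column(s): ", paste(extra, collapse = ", ")))
  req <- setdiff(c("spectrum_id", "sequence", "modifications", "charge", "probability"), names(df))
  if (length(req)) abort(paste0("missing PSM table column(s): ", paste(req, collapse = ", ")))
  bad <- which(!is.finite(df$probability) | df$probability < 0 | df$probability > 1)
  if (length(bad)) {
    abort(paste0("probability outside [0,1] in PSM row(s): ", paste(bad, collapse = ", ")))
  }
  df$modifications <- purrr::map2(
    df$modifications, df$spectrum_id,
    function(m, id) {
      mods <- parse_modifications(m, id)
      if (nrow(mods)) {
        seq_len_i <- nchar(df$sequence[match(id, df$spectrum_id)])
        if (any(mods$position < 0 | mods$position > seq_len_i)) {
          abort(paste0("modification position out of range for ", id))
        }
        if (anyDuplicated(mods$position)) {
          abort(paste0("multiple modifications at one position for ", id))
        }
      }
      mods
    }
  )
  df[, c("spectrum_id", "sequence", "modifications", "charge", "probability")]
}

#' Write a PSM table
#'
#' @param psms A PSM tibble as returned by [read_psm_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- tibble(
    spectrum_id = psms$spectrum_id,
    sequence = psms$sequence,
    modifications = vapply(psms$modifications, format_modifications, character(1)),
    charge = psms$charge,
    probability = psms$probability
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a ground-truth site table
#'
#' Tab-separated with columns `spectrum_id`, `sequence`, `true_site`
#' (1-based). The phosphorylated residue is derived from the sequence and
#' validated to be S, T or Y.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `spectrum_id`, `sequence`, `true_site`,
#'   `residue`.
#' @export
read_truth_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    sequence = readr::col_character(),
    true_site = readr::col_integer()
  ))
  req <- setdiff(c("spectrum_id", "sequence", "true_site"), names(df))
  if (length(req)) abort(paste0("missing truth table column(s): ", paste(req, collapse = ", ")))
  if (nrow(df) == 0) return(dplyr::mutate(df, residue = character()))
  residue <- substr(df$sequence, df$true_site, df$true_site)
  bad <- which(df$true_site < 1 | df$true_site > nchar(df$sequence) | !residue %in% c("S", "T", "Y"))
  if (length(bad)) {
    abort(paste0(
      "true_site does not point at S/T/Y in row(s): ",
      paste(df$spectrum_id[bad], collapse = ", ")
    ))
  }
  dplyr::mutate(df, residue = residue)
}

#' Write a ground-truth site table
#'
#' @param truth Tibble with `spectrum_id`, `sequence`, `true_site`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth[, c("spectrum_id", "sequence", "true_site")], path)
  invisible(path)
}

site_tagged_name <- function(sequence, site, residue, charge) {
  tagged <- if (is.na(site)) sequence else paste0(
    substr(sequence, 1, site), "[p", residue, "]",
    substr(sequence, site + 1, nchar(sequence))
  )
  paste0(tagged, "/", charge)
}

#' Write a spectral library
#'
#' Text format in the MSP/sptxt family: one record per entry with `Name:`
#' (sequence with a `[pS]`/`[pT]`/`[pY]` tag after the phosphosite, slash,
#' charge), `Sequence:`, `Site:`, `PrecursorMZ:`, `Status:` (target|decoy),
#' `NumReplicates:`, `NumPeaks:` and tab-separated peak lines
#' (m/z, intensity, annotation). `read_library()` inverts it exactly at the
#' written precision (6 decimals m/z, 4 intensity).
#'
#' @param lib A spectral library (see [build_library()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  key <- paste(lib$sequence, lib$site, lib$charge, lib$status)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate library key(s): ", paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  ok <- vapply(lib$peaks, function(p) nrow(p) == 0 || !is.unsorted(p$mz, strictly = TRUE), logical(1))
  if (!all(ok)) abort("library entries with unsorted peaks are not writable")
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(lib, "seed")
  writeLines(c(
    "### phosphosim spectral library",
    paste0("### entries: ", nrow(lib)),
    if (!is.null(seed)) paste0("### seed: ", seed),
    ""
  ), con)
  for (k in seq_len(nrow(lib))) {
    p <- lib$peaks[[k]]
    ann <- if ("annotation" %in% names(p)) p$annotation else rep("?", nrow(p))
    writeLines(c(
      paste0("Name: ", site_tagged_name(lib$sequence[[k]], lib$site[[k]],
                                        lib$residue[[k]], lib$charge[[k]])),
      paste0("Sequence: ", lib$sequence[[k]]),
      paste0("Site: ", lib$site[[k]]),
      paste0("PrecursorMZ: ", sprintf("%.6f", lib$precursor_mz[[k]])),
      paste0("Status: ", lib$status[[k]]),
      paste0("NumReplicates: ", lib$num_replicates[[k]]),
      paste0("NumPeaks: ", nrow(p)),
      if (nrow(p)) sprintf("%.6f\t%.4f\t%s", p$mz, p$intensity, ann),
      ""
    ), con)
  }
  invisible(path)
}

#' Read a spectral library written by [write_library()]
#'
#' @param path Path to the library file.
#' @return A spectral library tibble.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  seed <- NA_integer_
  hdr <- grep("^### seed: ", lines, value = TRUE)
  if (length(hdr)) seed <- as.integer(sub("^### seed: ", "", hdr[[1]]))
  starts <- grep("^Name: ", lines)
  entries <- purrr::map(starts, function(s) {
    i <- s
    fields <- list()
    while (i <= length(lines) && grepl("^[A-Za-z]+: ", lines[[i]])) {
      key <- sub(":.*$", "", lines[[i]])
      fields[[key]] <- sub("^[A-Za-z]+: ", "", lines[[i]])
      i <- i + 1L
    }
    npk <- as.integer(fields$NumPeaks)
    pk_lines <- if (npk > 0) lines[i:(i + npk - 1L)] else character()
    mat <- strsplit(pk_lines, "\t", fixed = TRUE)
    site <- suppressWarnings(as.integer(fields$Site))
    sequence <- fields$Sequence
    residue <- if (is.na(site)) NA_character_ else substr(sequence, site, site)
    pk <- peak_table(
      mz = as.numeric(vapply(mat, `[[`, character(1), 1)),
      intensity = as.numeric(vapply(mat, `[[`, character(1), 2)),
      annotation = vapply(mat, function(x) if (length(x) >= 3) x[[3]] else "?", character(1))
    )
    tibble(
      sequence = sequence, site = site, residue = residue,
      charge = as.integer(sub("^.*/", "", fields$Name)),
      precursor_mz = as.numeric(fields$PrecursorMZ),
      status = fields$Status,
      num_replicates = as.integer(fields$NumReplicates),
      peaks = list(pk)
    )
  })
  out <- if (length(entries)) bind_rows(entries) else tibble(
    sequence = character(), site = integer(), residue = character(),
    charge = integer(), precursor_mz = double(), status = character(),
    num_replicates = integer(), peaks = list()
  )
  attr(out, "seed") <- if (is.na(seed)) NULL else seed
  class(out) <- c("phosphosim_library", class(out))
  out
}

#' Write / read search-hit tables
#'
#' One row per hit with columns `query_id`, `sequence`, `site`, `charge`,
#' `status`, `rank`, `dot`, `dot_bias`, `deltadot_hom1`, `deltadot_hom4`,
#' `fvalue`, `precursor_delta_mz`.
#'
#' @param hits A hits tibble from [search_spectra()].
#' @param path TSV path.
#' @return `path` (write) or the hits tibble (read).
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "sequence", "site", "charge", "status", "rank", "dot",
            "dot_bias", "deltadot_hom1", "deltadot_hom4", "fvalue",
            "precursor_delta_mz")
  readr::write_tsv(hits[, intersect(cols, names(hits))], path)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    query_id = readr::col_character(),
    sequence = readr::col_character(),
    site = readr::col_integer(),
    charge = readr::col_integer(),
    status = readr::col_character(),
    rank = readr::col_integer(),
    .default = readr::col_double()
  ))
}
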