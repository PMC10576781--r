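# Readers and writers for the package's plain-text interchange formats.

#' Write / read an ion table as TSV
#'
#' Columns: `ion_id`, `mz`, `stori_slope`, `scan_index`, `line_index` (plus
#' `charge`, `neutral_mass`, `vote_share` when present).
#'
#' @param ions Ion tibble.
#' @param path File path.
#' @return `write_ion_tsv()` returns `path` invisibly; `read_ion_tsv()` a
#'   tibble.
#' @export
write_ion_tsv <- function(ions, path) {
  readr::write_tsv(ions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ion_tsv
#' @export
read_ion_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a ground-truth table as TSV
#'
#' The truth table parallels the ion table row-for-row: `ion_id`, `source`
#' (proteoform id or `"noise"`), `true_charge`, `true_isotope`, `true_mass`.
#'
#' @param truth Truth tibble from [simulate_line_scan()].
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a feature table as TSV
#'
#' Flat columns only (`feature_id`, `monoisotopic_mass`, `apex_mass`,
#' `n_isotopes`, `ion_count`, `relative_abundance`, `isotope_fit_score`);
#' isotope masses are reconstructed from the mass and isotope count on read.
#' Reported masses are monoisotopic by convention (recorded in the header
#' comment).
#'
#' @param features A [pick_features()] table.
#' @param path File path.
#' @export
write_feature_tsv <- function(features, path) {
  flat <- features[, c("feature_id", "monoisotopic_mass", "apex_mass",
                       "n_isotopes", "ion_count", "relative_abundance",
                       "isotope_fit_score")]
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  flat$isotope_masses <- purrr::map2(flat$monoisotopic_mass, flat$n_isotopes,
    function(m, n) m + .major_isotope_offsets(m, n) * ISOTOPE_SPACING)
  flat$member_ion_ids <- purrr::map(seq_len(nrow(flat)), ~character())
  class(flat) <- c("pims_features", class(flat))
  flat
}

#' Write a mass-domain spectrum as two-column TSV
#'
#' @param spectrum A [build_mass_spectrum()] result.
#' @param path File path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pims_spectrum"))
  readr::write_tsv(tibble::tibble(mass = spectrum$mass_grid,
                                  density = spectrum$density),
                   path, progress = FALSE)
  invisible(path)
}

#' Write a proteoform image as a TSV matrix
#'
#' @param image A [build_image()] result.
#' @param path File path.
#' @export
write_image_tsv <- function(image, path) {
  stopifnot(inherits(image, "pims_image"))
  utils::write.table(image$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Monoisotopic residue masses of the 20 standard amino acids.
.residue_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.water_mono <- 18.010565

#' Monoisotopic mass of a protein sequence
#'
#' Sum of standard monoisotopic residue masses plus one water.
#'
#' @param sequence Character vector of amino-acid sequences (one-letter
#'   codes; unknown letters are an error).
#' @return Monoisotopic mass(es) in Da.
#' @export
protein_monoisotopic_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, names(.residue_mono))
    if (length(bad) > 0L) {
      rlang::abort(sprintf("Unknown residue(s): %s",
                           paste(unique(bad), collapse = ", ")),
                   class = "pimsr_invalid_input")
    }
    sum(.residue_mono[aa]) + .water_mono
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a protein database
#'
#' Either a TSV with columns `accession`, `name` (optional) and
#' `monoisotopic_mass`, or a FASTA file (via Biostrings) whose sequence
#' masses are computed with [protein_monoisotopic_mass()].
#'
#' @param path File path (`.tsv`/`.txt` or `.fasta`/`.fa`/`.faa`).
#' @return Tibble `accession`, `name`, `base_mass`, ready for
#'   [imt_candidates()].
#' @export
read_protein_db <- function(path) {
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      rlang::abort("Reading FASTA requires the Biostrings package.",
                   class = "pimsr_missing_dependency")
    }
    seqs <- Biostrings::readAAStringSet(path)
    acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    tibble::tibble(
      accession = acc,
      name = names(seqs),
      base_mass = protein_monoisotopic_mass(as.character(seqs))
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("accession", "monoisotopic_mass") %in% names(df)))
    tibble::tibble(
      accession = as.character(df$accession),
      name = if ("name" %in% names(df)) as.character(df$name) else
        as.character(df$accession),
      base_mass = df$monoisotopic_mass
    )
  }
}

#' Read a JSON configuration file
#'
#' Flat JSON object of configuration keys (tolerances, window widths, FDR Q,
#' collision-energy defaults, ...), returned as a named list.
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_pims_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
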