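# Region-of-interest label-free quantitation.

# match each ion to the feature owning the major-isotope mass it falls on
# (+/- ppm), or NA
.match_ions_to_features <- function(neutral_masses, features, ppm = 10) {
  pos <- unlist(features$isotope_masses)
  fid <- rep(features$feature_id, lengths(features$isotope_masses))
  ord <- order(pos)
  pos <- pos[ord]; fid <- fid[ord]
  out <- rep(NA_character_, length(neutral_masses))
  ok <- which(is.finite(neutral_masses))
  if (length(ok) == 0L) return(out)
  m <- neutral_masses[ok]
  idx <- findInterval(m, pos)
  lo <- pmax(1L, idx); hi <- pmin(length(pos), idx + 1L)
  d_lo <- abs(m - pos[lo]); d_hi <- abs(m - pos[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  best_d <- pmin(d_lo, d_hi)
  tol <- pos[best] * ppm * 1e-6
  inside <- best_d <= tol
  out[ok[inside]] <- fid[best[inside]]
  out
}

#' Build per-region proteoform count profiles
#'
#' Tiles the scan stream into consecutive regions of `scans_per_region`
#' adjacent MS scans (45--50 by convention) and counts, per region and
#' proteoform, the ions falling within +/- `match_ppm` of the proteoform's
#' major isotope masses. `total_ions` counts every ion in the region,
#' matched or not.
#'
#' @param ions Ion tibble with `neutral_mass`, `scan_index`, `line_index`.
#' @param features A [pick_features()] table.
#' @param geometry A [scan_geometry()] (defines scans per line for the global
#'   scan order).
#' @param scans_per_region Scans per sampled region (45--50).
#' @param class_labels Optional vector of class labels, one per region
#'   (recycled), or `NULL`.
#' @param match_ppm Matching tolerance in ppm.
#' @return Wide tibble: `region_id`, `class_label`, `first_scan`,
#'   `last_scan`, `total_ions`, then one count column per feature (column
#'   names in the `feature_cols` attribute).
#' @export
build_regions <- function(ions, features, geometry, scans_per_region = 48L,
                          class_labels = NULL, match_ppm = 10) {
  if (scans_per_region < 45 || scans_per_region > 50) {
    rlang::abort("`scans_per_region` must be in 45..50.",
                 class = "pimsr_invalid_input")
  }
  stopifnot(inherits(geometry, "pims_geometry"))
  gscan <- ions$line_index * geometry$scans_per_line + ions$scan_index
  n_regions <- max(1L, (geometry$n_lines * geometry$scans_per_line) %/%
                     as.integer(scans_per_region))
  region <- pmin(n_regions - 1L, gscan %/% as.integer(scans_per_region))
  fmatch <- .match_ions_to_features(ions$neutral_mass, features, match_ppm)

  feat <- features$feature_id
  counts <- matrix(0L, nrow = n_regions, ncol = length(feat),
                   dimnames = list(NULL, feat))
  okm <- !is.na(fmatch)
  if (any(okm)) {
    tb <- table(factor(region[okm], levels = 0:(n_regions - 1L)),
                factor(fmatch[okm], levels = feat))
    counts <- matrix(as.integer(tb), nrow = n_regions,
                     dimnames = list(NULL, feat))
  }
  totals <- tabulate(region + 1L, nbins = n_regions)
  out <- tibble::tibble(
    region_id = sprintf("R%04d", seq_len(n_regions)),
    class_label = if (is.null(class_labels)) NA_character_ else
      as.character(rep_len(class_labels, n_regions)),
    first_scan = (seq_len(n_regions) - 1L) * as.integer(scans_per_region),
    last_scan = seq_len(n_regions) * as.integer(scans_per_region) - 1L,
    total_ions = as.integer(totals)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  attr(out, "feature_cols") <- feat
  out
}

# feature columns of a region table
.region_feature_cols <- function(regions) {
  fc <- attr(regions, "feature_cols")
  if (!is.null(fc)) return(fc)
  meta <- c("region_id", "class_label", "first_scan", "last_scan",
            "total_ions")
  setdiff(names(regions), meta)
}

#' Quality-control filter on sampled regions
#'
#' Regions with fewer than `min_total_ions` total ions (empty-probe or
#' contaminated regions) are discarded; the rest are kept. The two outputs
#' partition the input.
#'
#' @param regions A region table ([build_regions()] or
#'   [simulate_two_class_regions()]).
#' @param min_total_ions Minimum total ion count to keep a region.
#' @return List with `kept` and `discarded` region tables.
#' @export
qc_filter <- function(regions, min_total_ions = 1000) {
  keep <- regions$total_ions >= min_total_ions
  fc <- .region_feature_cols(regions)
  kept <- regions[keep, ]
  discarded <- regions[!keep, ]
  attr(kept, "feature_cols") <- fc
  attr(discarded, "feature_cols") <- fc
  list(kept = kept, discarded = discarded)
}

#' Benjamini-Hochberg critical value
#'
#' `-log10(i * Q / m)`: the rank-dependent significance threshold that a
#' proteoform's `-log10(p)` must exceed.
#'
#' @param i Rank(s) of the p-score (1 = smallest p).
#' @param Q User-defined FDR.
#' @param m Total number of tests (or regions, under the alternative
#'   convention).
#' @return Critical value(s) in -log10 units.
#' @examples
#' bh_critical(1, 0.01, 100)   # 4
#' bh_critical(100, 0.01, 100) # 2
#' @export
bh_critical <- function(i, Q, m) {
  -log10(i * Q / m)
}

#' Per-proteoform differential test with B-H filtering
#'
#' Runs a two-sample T-test (Welch by default) per proteoform between the two
#' region classes, ranks proteoforms by `-log10(p)` descending, and applies
#' the Benjamini-Hochberg critical-value rule at FDR `Q` as the classical
#' step-up procedure: every proteoform ranked at or better than the largest
#' rank whose `-log10(p)` exceeds [bh_critical()] is significant. Fold change
#' is the mean ion count in the numerator class over the denominator class
#' (alphabetically first/second class by default, e.g. stroma/tumor).
#'
#' @param regions A QC-passed region table with a `class_label` column
#'   containing exactly two classes and at least two regions per class.
#' @param Q Target FDR.
#' @param m_convention `"tests"` (default; m = number of proteoforms tested)
#'   or `"regions"` (m = number of sampled regions).
#' @param var_equal `FALSE` for Welch (default), `TRUE` for Student.
#' @param pseudocount Added to both class means for the fold change when
#'   either mean is zero (flagged in `fc_pseudo`).
#' @param numerator,denominator Class labels for the fold change; default the
#'   alphabetically first and second class.
#' @return A `pims_diff` tibble ordered by rank: `feature_id`,
#'   `mean_<numerator>`, `mean_<denominator>`, `p_score`, `rank_i`,
#'   `bh_critical`, `significant`, `log2_fc`, `fc_pseudo`, `degenerate`.
#'   Attributes: `Q`, `m`, `m_convention`, `classes`.
#' @export
differential_test <- function(regions, Q = 0.01,
                              m_convention = c("tests", "regions"),
                              var_equal = FALSE, pseudocount = 0.5,
                              numerator = NULL, denominator = NULL) {
  m_convention <- match.arg(m_convention)
  if (!(Q > 0 && Q < 1)) {
    rlang::abort("`Q` must be in (0, 1).", class = "pimsr_invalid_input")
  }
  classes <- sort(unique(regions$class_label))
  if (length(classes) != 2L) {
    rlang::abort("`regions` must contain exactly two classes.",
                 class = "pimsr_invalid_input")
  }
  if (is.null(numerator)) numerator <- classes[1]
  if (is.null(denominator)) denominator <- classes[2]
  fc <- .region_feature_cols(regions)
  g_num <- regions$class_label == numerator
  g_den <- regions$class_label == denominator
  n1 <- sum(g_num); n2 <- sum(g_den)
  if (n1 < 2 || n2 < 2) {
    rlang::abort("Need at least two regions per class.",
                 class = "pimsr_invalid_input")
  }
  x1 <- as.matrix(regions[g_num, fc])
  x2 <- as.matrix(regions[g_den, fc])
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(fc))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- (v1 == 0 & v2 == 0) | !is.finite(p)
  p[degenerate] <- 1

  m_total <- if (m_convention == "tests") length(fc) else nrow(regions)
  ord <- order(p, fc)
  rank_i <- integer(length(fc)); rank_i[ord] <- seq_along(fc)
  crit <- bh_critical(rank_i, Q, m_total)
  # classical step-up: largest rank whose p beats its own threshold
  pass <- p[ord] < rank_i[ord] * Q / m_total
  i_star <- if (any(pass)) max(which(pass)) else 0L
  significant <- rank_i <= i_star

  zero <- m1 == 0 | m2 == 0
  l2fc <- ifelse(zero,
                 log2((m1 + pseudocount) / (m2 + pseudocount)),
                 log2(m1 / m2))
  out <- tibble::tibble(
    feature_id = fc,
    "mean_{numerator}" := unname(m1),
    "mean_{denominator}" := unname(m2),
    p_score = unname(p), rank_i = rank_i, bh_critical = unname(crit),
    significant = unname(significant), log2_fc = unname(l2fc),
    fc_pseudo = unname(zero), degenerate = unname(degenerate)
  )
  out <- out[order(out$rank_i), ]
  structure(out, class = c("pims_diff", class(tibble::tibble())),
            Q = Q, m = m_total, m_convention = m_convention,
            classes = c(numerator = numerator, denominator = denominator))
}

#' @export
print.pims_diff <- function(x, ...) {
  cl <- attr(x, "classes")
  cat(sprintf(
    "<pims_diff> %d proteoforms, %d significant at Q = %g (m = %d); fold change %s/%s\n",
    nrow(x), sum(x$significant), attr(x, "Q"), attr(x, "m"),
    cl[["numerator"]], cl[["denominator"]]))
  NextMethod()
}

#' Differentially abundant proteoform list
#'
#' Significant proteoforms with `|log2 fold change|` strictly above the cut,
#' sorted by effect size.
#'
#' @param results A [differential_test()] table.
#' @param log2fc_cut Absolute log2 fold-change cut (strict).
#' @return Subset of `results` sorted by decreasing `|log2_fc|`.
#' @export
differential_list <- function(results, log2fc_cut = 0.5) {
  out <- results[results$significant & abs(results$log2_fc) > log2fc_cut, ]
  out[order(-abs(out$log2_fc)), ]
}

#' PCA scores of sampled regions
#'
#' Normalises each region's proteoform counts by its total ion count,
#' mean-centres, and returns the scores on the first two principal
#' components with their explained-variance fractions.
#'
#' @param regions A region table (>= 3 regions).
#' @param features Optional subset of feature columns to use (e.g. the
#'   significant proteoforms); default all.
#' @return A `pims_pca` tibble: `region_id`, `class_label`, `PC1`, `PC2`;
#'   attribute `var_explained` holds the full explained-variance fractions.
#' @export
pca_scores <- function(regions, features = NULL) {
  fc <- .region_feature_cols(regions)
  if (!is.null(features)) fc <- intersect(fc, features)
  if (nrow(regions) < 3L) {
    rlang::abort("Need at least three regions for PCA.",
                 class = "pimsr_invalid_input")
  }
  x <- as.matrix(regions[, fc])
  tot <- regions$total_ions
  if (is.null(tot) || any(!is.finite(tot)) || any(tot <= 0)) tot <- rowSums(x)
  x <- x / tot
  x <- sweep(x, 2L, colMeans(x))
  if (max(abs(x)) == 0) {
    rlang::abort("Degenerate input: no variance across regions.",
                 class = "pimsr_degenerate")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble::tibble(
    region_id = regions$region_id,
    class_label = if ("class_label" %in% names(regions))
      regions$class_label else NA_character_,
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  structure(out, class = c("pims_pca", class(tibble::tibble())),
            var_explained = ve)
}

#' @export
print.pims_pca <- function(x, ...) {
  ve <- attr(x, "var_explained")
  cat(sprintf("<pims_pca> %d regions; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x), 100 * ve[1], 100 * ve[2]))
  NextMethod()
}
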