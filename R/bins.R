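# Spatial bin allocation of MS2 targets along the line.

#' Low-resolution spatial profiles of targets
#'
#' Divides the line region into `n_bins` equally sized bins and sums each
#' target's assigned-ion counts from the scans falling in each bin (scan
#' coordinates from [scan_coordinate()]).
#'
#' @param ions Ion tibble with `ion_id` and `scan_index`.
#' @param assignments An [assign_ions()] table.
#' @param geometry A [scan_geometry()].
#' @param n_bins Number of bins over the line region.
#' @return Long tibble `feature_id`, `bin_index` (1-based), `bin_start`,
#'   `bin_end` (um), `count`, with one row per target x bin; bin edges kept
#'   in the `bin_edges` attribute.
#' @export
bin_profiles <- function(ions, assignments, geometry, n_bins) {
  stopifnot(inherits(geometry, "pims_geometry"), n_bins >= 1)
  n_bins <- as.integer(n_bins)
  length_um <- line_length(geometry)
  edges <- seq(0, length_um, length.out = n_bins + 1L)
  df <- dplyr::inner_join(assignments, ions[, c("ion_id", "scan_index")],
                          by = "ion_id")
  df <- df[!is.na(df$feature_id), ]
  coord <- scan_coordinate(geometry, df$scan_index)
  bin <- pmin(n_bins, findInterval(coord, edges, rightmost.closed = TRUE))
  counts <- dplyr::count(
    tibble::tibble(feature_id = df$feature_id, bin_index = bin),
    .data$feature_id, .data$bin_index, name = "count")
  full <- tidyr::expand_grid(feature_id = sort(unique(assignments$feature_id)),
                             bin_index = seq_len(n_bins))
  out <- dplyr::left_join(full, counts, by = c("feature_id", "bin_index"))
  out$count[is.na(out$count)] <- 0L
  out$bin_start <- edges[out$bin_index]
  out$bin_end <- edges[out$bin_index + 1L]
  out <- out[, c("feature_id", "bin_index", "bin_start", "bin_end", "count")]
  attr(out, "bin_edges") <- edges
  out
}

#' Number of bins from a physical bin size
#'
#' @param geometry A [scan_geometry()].
#' @param bin_size Bin size in micrometres (150--300 um is typical for
#'   multi-bin individual-ion MS2 allocation).
#' @return Integer bin count (>= 1).
#' @export
n_bins_for_size <- function(geometry, bin_size) {
  stopifnot(bin_size > 0)
  max(1L, as.integer(floor(line_length(geometry) / bin_size)))
}

# profiles long tibble -> counts matrix (targets x bins) + metadata
.profiles_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles[, c("feature_id", "bin_index", "count")],
                             names_from = "bin_index", values_from = "count",
                             values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' Allocate spatial bins to targets
#'
#' Iterative allocation so each target is fragmented at or near its spatial
#' abundance maximum. Each round, every unassigned target claims its
#' best-count remaining bin (ties to the lower bin index). A bin claimed by a
#' single target is granted immediately; a contested bin goes to the claimant
#' with the lowest total ion count (the weakest target; ties to the lower
#' target mass, then target id), and losers return to the pool for the next
#' round. Iterating until every target holds a unique bin converges in at
#' most one round per target.
#'
#' In `"multi"` mode a second pass grants one extra bin per target (up to
#' `max_bins_per_target`), in ascending order of target total abundance,
#' each target taking its best remaining bin.
#'
#' @param profiles A [bin_profiles()] table. An optional `mass` column (or a
#'   `feature_mass` attribute, named by feature) is used for contest
#'   tie-breaks.
#' @param mode `"single"` (one bin per target) or `"multi"`.
#' @param max_iterations Iteration cap; exceeding it raises a
#'   non-convergence error carrying the partial assignment.
#' @param max_bins_per_target Bin cap per target in multi mode.
#' @param contest_rule `"total"` resolves contested bins by the target's
#'   line-total ion count; `"in_bin"` by its count inside the contested bin.
#' @return A `pims_binassign`: tibble `bin_index`, `bin_start`, `bin_end`,
#'   `feature_id`, `pass`, with attributes `iterations`, `mode`,
#'   `unassigned_bins`.
#' @export
allocate_bins <- function(profiles, mode = c("single", "multi"),
                          max_iterations = 50L, max_bins_per_target = 2L,
                          contest_rule = c("total", "in_bin")) {
  mode <- match.arg(mode)
  contest_rule <- match.arg(contest_rule)
  m <- .profiles_matrix(profiles)
  targets <- rownames(m)
  n_t <- nrow(m)
  n_b <- ncol(m)
  if (n_b < n_t) {
    rlang::abort(sprintf("Infeasible: %d targets but only %d bins.", n_t, n_b),
                 class = "pimsr_infeasible")
  }
  mass <- attr(profiles, "feature_mass")
  if (is.null(mass) && "mass" %in% names(profiles)) {
    mass <- tapply(profiles$mass, profiles$feature_id, `[`, 1L)
  }
  if (is.null(mass)) mass <- stats::setNames(rep(NA_real_, n_t), targets)
  mass <- mass[targets]
  totals <- rowSums(m)
  # deterministic target precedence in contests: lowest total, then lowest
  # mass, then id
  rank_key <- order(totals, ifelse(is.na(mass), Inf, mass), targets)
  precedence <- integer(n_t)
  precedence[rank_key] <- seq_len(n_t)

  assign_round <- function(unassigned, bins_left, holder, iter_cap) {
    iters <- 0L
    while (length(unassigned) > 0L) {
      iters <- iters + 1L
      if (iters > iter_cap) {
        rlang::abort("Bin allocation did not converge within `max_iterations`.",
                     class = "pimsr_nonconvergence",
                     partial = holder, iterations = iters - 1L)
      }
      # which.max ties -> first = lower bin index
      claims <- vapply(unassigned, function(t) {
        cnt <- m[t, bins_left]
        bins_left[which.max(cnt)]
      }, integer(1))
      granted <- character(0)
      for (b in unique(claims)) {
        who <- unassigned[claims == b]
        if (length(who) > 1L) {
          key <- if (contest_rule == "in_bin") {
            order(m[who, b], precedence[match(who, targets)])
          } else {
            order(precedence[match(who, targets)])
          }
          who <- who[key[1L]]
        }
        holder[[who]] <- b
        granted <- c(granted, who)
        bins_left <- setdiff(bins_left, b)
      }
      unassigned <- setdiff(unassigned, granted)
    }
    list(holder = holder, bins_left = bins_left, iterations = iters)
  }

  holder <- stats::setNames(vector("list", n_t), targets)
  res <- assign_round(targets, seq_len(n_b), holder, max_iterations)
  pass1 <- res$holder
  iterations <- res$iterations
  rows <- tibble::tibble(
    feature_id = targets,
    bin_index = unname(vapply(pass1[targets], identity, integer(1))),
    pass = 1L
  )
  if (mode == "multi" && max_bins_per_target >= 2L &&
      length(res$bins_left) > 0L) {
    order2 <- targets[order(totals, ifelse(is.na(mass), Inf, mass), targets)]
    bins_left <- res$bins_left
    extra <- list()
    for (t in order2) {
      if (length(bins_left) == 0L) break
      cnt <- m[t, bins_left]
      b <- bins_left[which.max(cnt)]
      extra[[t]] <- b
      bins_left <- setdiff(bins_left, b)
    }
    if (length(extra) > 0L) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        feature_id = names(extra),
        bin_index = unlist(extra, use.names = FALSE),
        pass = 2L
      ))
    }
    res$bins_left <- bins_left
  }
  edges <- attr(profiles, "bin_edges")
  if (is.null(edges)) {
    lut <- unique(profiles[, c("bin_index", "bin_start", "bin_end")])
    rows$bin_start <- lut$bin_start[match(rows$bin_index, lut$bin_index)]
    rows$bin_end <- lut$bin_end[match(rows$bin_index, lut$bin_index)]
  } else {
    rows$bin_start <- edges[rows$bin_index]
    rows$bin_end <- edges[rows$bin_index + 1L]
  }
  rows <- rows[order(rows$bin_index),
               c("bin_index", "bin_start", "bin_end", "feature_id", "pass")]
  structure(rows,
            class = c("pims_binassign", class(tibble::tibble())),
            iterations = iterations, mode = mode,
            unassigned_bins = setdiff(seq_len(n_b), rows$bin_index))
}

#' @export
print.pims_binassign <- function(x, ...) {
  cat(sprintf("<pims_binassign> %s mode, %d bins assigned, %d iteration(s)\n",
              attr(x, "mode"), nrow(x), attr(x, "iterations")))
  NextMethod()
}
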