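make_feature_table <- function(masses, n_iso = 5L) {
  dplyr::bind_rows(purrr::map(seq_along(masses), function(i) {
    offs <- pimsr:::.major_isotope_offsets(masses[i], n_iso)
    tibble::tibble(
      feature_id = sprintf("F%03d", i),
      monoisotopic_mass = masses[i],
      apex_mass = masses[i] + (which.max(pimsr:::.averagine_pmf(masses[i])) - 1) *
        ISOTOPE_SPACING,
      n_isotopes = n_iso,
      isotope_masses = list(masses[i] + offs * ISOTOPE_SPACING),
      ion_count = 0L, member_ion_ids = list(character()),
      relative_abundance = 1, isotope_fit_score = NA_real_
    )
  }))
}

simple_ions <- function(masses, z = 10L) {
  tibble::tibble(
    ion_id = sprintf("i%05d", seq_along(masses)),
    mz = mz_from_mass(masses, z), stori_slope = 1,
    scan_index = 0L, line_index = 0L,
    charge = as.integer(z), neutral_mass = masses
  )
}

test_that("ions on a feature isotope are assigned; distant ions are not", {
  ft <- make_feature_table(c(9000, 12000))
  iso <- ft$isotope_masses[[1]]
  ions <- simple_ions(c(iso[2], 9000 + 50, 12000 - 40))
  asg <- assign_ions(ions, ft, inclusion_halfwidth = 2)
  expect_equal(asg$feature_id, c("F001", NA, NA))
  expect_equal(asg$mass_delta[1], 0)
})

test_that("exact midpoint ties go to the lower feature mass", {
  ft <- make_feature_table(c(9000, 9010))
  hi1 <- max(ft$isotope_masses[[1]])
  lo2 <- min(ft$isotope_masses[[2]])
  mid <- (hi1 + lo2) / 2
  ions <- simple_ions(mid)
  asg <- assign_ions(ions, ft, inclusion_halfwidth = (lo2 - hi1) / 2 + 0.1)
  expect_equal(asg$feature_id, "F001")
})

test_that("assignment on a two-proteoform mixture is >= 99% accurate and a partition", {
  fx <- two_proteoform_ions(seed = 101)
  sp <- build_mass_spectrum(fx$ions)
  ft <- pick_features(sp, fx$ions, 0.05)
  asg <- assign_ions(fx$ions, ft)
  expect_equal(nrow(asg), nrow(fx$ions))
  expect_equal(asg$ion_id, fx$ions$ion_id)  # no double assignment by shape
  truth <- fx$dataset$truth
  # map picked features to true proteoforms by mass
  map <- ft$feature_id[vapply(c(9000, 12000), function(m)
    which.min(abs(ft$monoisotopic_mass - m)), integer(1))]
  assigned <- !is.na(asg$feature_id) & truth$source != "noise" &
    !is.na(fx$ions$charge)
  acc <- mean(asg$feature_id[assigned] ==
                ifelse(truth$source[assigned] == "P1", map[1], map[2]))
  expect_gte(acc, 0.99)
})

test_that("enlarging the inclusion half-width never loses assigned ions", {
  fx <- two_proteoform_ions(seed = 103)
  sp <- build_mass_spectrum(fx$ions)
  ft <- pick_features(sp, fx$ions, 0.05)
  counts <- vapply(c(0.5, 1, 2, 4), function(hw) {
    sum(!is.na(assign_ions(fx$ions, ft, hw)$feature_id))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("empty feature table is rejected", {
  ions <- simple_ions(9000)
  expect_error(assign_ions(ions, NULL), class = "pimsr_invalid_input")
})

test_that("reconstructed m/z profiles resolve charge states and partition the ions", {
  geom <- test_geometry()
  spec <- proteoform_spec("P1", 9000, 4000, charge_mu = 10, charge_sigma = 1.2)
  ds <- simulate_line_scan(spec, geom, calib_slope = 12.5,
                           slope_noise_cv = 0.005, seed = 7)
  set.seed(7)
  ions <- assign_charge(ds$ions, 12.5)
  sp <- build_mass_spectrum(ions)
  ft <- pick_features(sp, ions, 0.05)
  asg <- assign_ions(ions, ft)
  prof <- reconstruct_mz_profile(asg, ions, ft$feature_id[1], mz_bin = 2)
  expect_equal(sum(prof$count),
               sum(!is.na(asg$feature_id) & asg$feature_id == ft$feature_id[1]))
  # charge-state clusters at (mass + z*Mp)/z for z = 8..12
  apex <- ft$apex_mass[1]
  hits <- vapply(8:12, function(z) {
    mzc <- mz_from_mass(apex, z)
    any(abs(prof$mz_center - mzc) < 3 & prof$count > 5)
  }, logical(1))
  expect_gte(sum(hits), 3)

  # single-ion profile: one nonzero bin
  one <- reconstruct_mz_profile(asg[asg$ion_id == asg$ion_id[1], ],
                                ions, asg$feature_id[1], mz_bin = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 1L)

  # partition: per-feature profiles plus the unassigned pool tile the data
  all_counts <- sum(vapply(unique(stats::na.omit(asg$feature_id)), function(f)
    sum(reconstruct_mz_profile(asg, ions, f, 1)$count), numeric(1))) +
    sum(reconstruct_mz_profile(asg, ions, NA, 1)$count)
  expect_equal(all_counts, nrow(ions))

  expect_error(reconstruct_mz_profile(asg, ions, "nope", 1),
               class = "pimsr_lookup_error")
})

test_that("window purity is the target fraction and bounds hold", {
  # hand-built: 8 target ions and 2 foreign ions in one window
  ft <- make_feature_table(c(9000, 12000))
  t_mz <- rep(mz_from_mass(ft$isotope_masses[[1]][1], 10), 8)
  o_mz <- rep(mz_from_mass(ft$isotope_masses[[2]][1], 10) , 2)
  ions <- tibble::tibble(
    ion_id = sprintf("i%02d", 1:10),
    mz = c(t_mz, o_mz - o_mz + t_mz[1] + 0.5),  # foreigners inside the window
    stori_slope = 1, scan_index = 0L, line_index = 0L,
    charge = 10L,
    neutral_mass = c(rep(ft$isotope_masses[[1]][1], 8),
                     rep(ft$isotope_masses[[2]][1], 2))
  )
  asg <- assign_ions(ions, ft, 2)
  w <- score_windows(asg, ions, "F001", window_width = 4,
                     center_grid_step = 0.5, annotate_top = Inf)
  expect_equal(w$purity[1], 0.8)
  expect_equal(w$target_ion_count[1], 8L)
  expect_equal(w$other_ion_count[1], 2L)
  expect_true(all(w$purity >= 0 & w$purity <= 1))
  expect_true(all((w$purity == 1) == (w$other_ion_count == 0)))
  co <- w$coisolating[[1]]
  expect_equal(co$feature_id, "F002")
  expect_equal(co$ion_count, 2L)
})

test_that("top-ranked window equals the exhaustive grid maximum", {
  for (seed in c(5, 6, 7)) {
    geom <- test_geometry(scans_per_line = 100L)
    specs <- dplyr::bind_rows(
      proteoform_spec("P1", 9000, 250, charge_mu = 9, charge_sigma = 1.5),
      proteoform_spec("P2", 9600, 200, charge_mu = 9, charge_sigma = 1.5)
    )
    ds <- simulate_line_scan(specs, geom, calib_slope = 12.5,
                             noise_ion_rate = 0.2, slope_noise_cv = 0.01,
                             seed = seed)
    set.seed(seed)
    ions <- assign_charge(ds$ions, 12.5)
    sp <- build_mass_spectrum(ions)
    ft <- pick_features(sp, ions, 0.05)
    asg <- assign_ions(ions, ft)
    for (fid in ft$feature_id) {
      w <- score_windows(asg, ions, fid, window_width = 4,
                         center_grid_step = 0.5)
      if (nrow(w) == 0) next
      oracle <- oracle_best_window(asg, ions, fid, 4, 0.5)
      expect_equal(w$score[1], oracle$score, info = sprintf("seed %d", seed))
      expect_equal(w$center_mz[1], oracle$center)
      expect_equal(w$purity[1], oracle$purity)
    }
  }
})

test_that("select_targets filters, honours min_purity, and orders by mass", {
  fx <- two_proteoform_ions(seed = 107)
  sp <- build_mass_spectrum(fx$ions)
  ft <- pick_features(sp, fx$ions, 0.05)
  asg <- assign_ions(fx$ions, ft)

  none <- select_targets(ft, asg, fx$ions, rel_abundance_threshold = 1.01)
  expect_equal(nrow(none), 0L)

  all_in <- select_targets(ft, asg, fx$ions, min_purity = 0)
  expect_true(all(all_in$has_window))
  expect_false(is.unsorted(all_in$monoisotopic_mass))

  strict <- select_targets(ft, asg, fx$ions, min_purity = 1.0000001)
  expect_false(any(strict$has_window))

  ranged <- select_targets(ft, asg, fx$ions, mass_range = c(8000, 10000),
                           min_purity = 0)
  expect_true(all(ranged$monoisotopic_mass >= 8000 &
                    ranged$monoisotopic_mass <= 10000))
})
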