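test_that("regions tile the scan stream", {
  geom <- test_geometry(scans_per_line = 90L)
  spec <- proteoform_spec("P1", 9000, 2000, charge_mu = 10)
  ds <- simulate_line_scan(spec, geom, calib_slope = 12.5,
                           slope_noise_cv = 0.005, seed = 301)
  set.seed(301)
  ions <- assign_charge(ds$ions, 12.5)
  sp <- build_mass_spectrum(ions)
  ft <- pick_features(sp, ions, 0.05)
  reg <- build_regions(ions, ft, geom, scans_per_region = 45)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$first_scan, c(0L, 45L))
  expect_equal(reg$last_scan, c(44L, 89L))
  # grand totals: matched counts never exceed the region ion total
  fc <- attr(reg, "feature_cols")
  expect_true(all(rowSums(reg[, fc]) <= reg$total_ions))
  expect_equal(sum(reg$total_ions), nrow(ions))
  expect_error(build_regions(ions, ft, geom, scans_per_region = 44),
               class = "pimsr_invalid_input")
})

test_that("per-region counts track the generator means within Poisson error", {
  geom <- test_geometry(scans_per_line = 480L)
  spec <- proteoform_spec("P1", 9000, 9600, charge_mu = 10,
                          spatial_profile = 1)  # flat profile
  ds <- simulate_line_scan(spec, geom, calib_slope = 12.5,
                           slope_noise_cv = 0.005, seed = 303)
  set.seed(303)
  ions <- assign_charge(ds$ions, 12.5)
  sp <- build_mass_spectrum(ions)
  ft <- pick_features(sp, ions, 0.05)
  reg <- build_regions(ions, ft, geom, scans_per_region = 48)
  fc <- attr(reg, "feature_cols")
  counts <- reg[[fc[1]]]
  # expected ~ 960/region of which the major-isotope windows capture the
  # assigned, matched share; Poisson spread around the common mean
  expect_lt((max(counts) - min(counts)) / mean(counts), 8 / sqrt(mean(counts)))
})

test_that("QC keeps regions at or above the ion floor and partitions the input", {
  reg <- tibble::tibble(region_id = c("a", "b", "c"),
                        class_label = "tumor",
                        total_ions = c(1200L, 999L, 1000L),
                        P1 = c(1L, 2L, 3L))
  attr(reg, "feature_cols") <- "P1"
  qc <- qc_filter(reg, 1000)
  expect_equal(qc$kept$region_id, c("a", "c"))
  expect_equal(qc$discarded$region_id, "b")
  expect_equal(nrow(qc$kept) + nrow(qc$discarded), nrow(reg))
  all_in <- qc_filter(reg, 0)
  expect_equal(nrow(all_in$kept), 3L)
  expect_equal(nrow(all_in$discarded), 0L)
})

test_that("QC recovers injected empty-probe dropouts", {
  sim <- simulate_two_class_regions(50, 240, dispersion = 0.05, seed = 305,
                                    mean_log = log(60))
  regions <- sim$regions
  set.seed(305)
  dropped <- sample.int(nrow(regions), round(0.02 * nrow(regions)))
  fc <- attr(regions, "feature_cols")
  regions[dropped, fc] <- as.list(rep(0L, length(fc)))
  regions$total_ions[dropped] <- sample(0:999, length(dropped), replace = TRUE)
  qc <- qc_filter(regions, 1000)
  expect_equal(sort(qc$discarded$region_id), sort(regions$region_id[dropped]))
})

test_that("B-H critical values match the closed form", {
  expect_equal(bh_critical(1, 0.01, 100), 4)
  expect_equal(bh_critical(100, 0.01, 100), 2)
  expect_equal(bh_critical(5, 0.05, 50), -log10(5 * 0.05 / 50))
})

test_that("the critical-value rule reproduces classical step-up B-H decisions", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(20:400, 1)
    # mixtures of null and signal p-values
    p <- c(stats::runif(round(n * 0.7)), stats::rbeta(n - round(n * 0.7), 0.2, 5))
    Q <- sample(c(0.01, 0.05, 0.1), 1)
    regions <- NULL
    ord <- order(p)
    pass <- p[ord] < seq_along(p) * Q / n
    istar <- if (any(pass)) max(which(pass)) else 0L
    mine <- integer(0)
    if (istar > 0) mine <- sort(ord[seq_len(istar)])
    classical <- which(stats::p.adjust(p, "BH") <= Q)
    expect_equal(mine, classical)
  }
})

test_that("differential_test agrees with stats::t.test per proteoform", {
  sim <- simulate_two_class_regions(40, 15, frac_differential = 0.3,
                                    effect_log2fc = 1, seed = 307)
  dt <- differential_test(sim$regions, Q = 0.05)
  fc <- attr(sim$regions, "feature_cols")
  cls <- sim$regions$class_label
  for (f in sample(fc, 10)) {
    ref <- stats::t.test(sim$regions[[f]][cls == "stroma"],
                         sim$regions[[f]][cls == "tumor"])
    expect_equal(dt$p_score[dt$feature_id == f], unname(ref$p.value),
                 tolerance = 1e-12)
  }
  # and Student flavor against var.equal = TRUE
  dts <- differential_test(sim$regions, Q = 0.05, var_equal = TRUE)
  f <- fc[1]
  ref <- stats::t.test(sim$regions[[f]][cls == "stroma"],
                       sim$regions[[f]][cls == "tumor"], var.equal = TRUE)
  expect_equal(dts$p_score[dts$feature_id == f], unname(ref$p.value),
               tolerance = 1e-12)
})

test_that("fold changes are antisymmetric under class swap", {
  sim <- simulate_two_class_regions(30, 12, seed = 309)
  dt1 <- differential_test(sim$regions, Q = 0.05)
  swapped <- sim$regions
  swapped$class_label <- ifelse(swapped$class_label == "stroma",
                                "tumor", "stroma")
  attr(swapped, "feature_cols") <- attr(sim$regions, "feature_cols")
  dt2 <- differential_test(swapped, Q = 0.05)
  idx <- match(dt1$feature_id, dt2$feature_id)
  expect_equal(dt1$log2_fc, -dt2$log2_fc[idx], tolerance = 1e-12)
})

test_that("degenerate and zero-mean proteoforms are flagged, not dropped", {
  reg <- tibble::tibble(
    region_id = sprintf("r%d", 1:8),
    class_label = rep(c("stroma", "tumor"), each = 4),
    total_ions = 100L,
    Pconst = rep(5L, 8),
    Pzero = c(0L, 0L, 0L, 0L, 3L, 4L, 2L, 3L),
    Pok = c(10L, 12L, 9L, 11L, 3L, 4L, 2L, 3L)
  )
  attr(reg, "feature_cols") <- c("Pconst", "Pzero", "Pok")
  dt <- differential_test(reg, Q = 0.05)
  expect_true(dt$degenerate[dt$feature_id == "Pconst"])
  expect_equal(dt$p_score[dt$feature_id == "Pconst"], 1)
  expect_true(dt$fc_pseudo[dt$feature_id == "Pzero"])
  expect_equal(dt$log2_fc[dt$feature_id == "Pzero"],
               log2(0.5 / 3.5), tolerance = 1e-12)
  expect_false(dt$fc_pseudo[dt$feature_id == "Pok"])
})

test_that("the differential list applies a strict fold-change cut", {
  base <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    p_score = c(1e-6, 1e-6, 1e-6, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    log2_fc = c(0.5, -0.50001, 1.2, 3)
  )
  out <- differential_list(base, log2fc_cut = 0.5)
  expect_equal(out$feature_id, c("c", "b"))
  none <- differential_list(base[base$significant == FALSE, ])
  expect_equal(nrow(none), 0L)
})

test_that("differential recovery on the generator meets recall/precision bounds", {
  sim <- simulate_two_class_regions(300, 120, frac_differential = 0.3,
                                    effect_log2fc = 1, seed = 311)
  dt <- differential_test(sim$regions, Q = 0.01)
  dl <- differential_list(dt, log2fc_cut = 0.5)
  truth <- sim$truth
  called <- truth$feature_id %in% dl$feature_id
  recall <- mean(called[truth$differential])
  precision <- mean(truth$differential[match(dl$feature_id,
                                             truth$feature_id)])
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.95)
})

test_that("PCA scores separate classes and expose explained variance", {
  sim <- simulate_two_class_regions(200, 80, frac_differential = 0.3,
                                    effect_log2fc = 1, seed = 313)
  pc <- pca_scores(sim$regions)
  ve <- attr(pc, "var_explained")
  expect_true(all(ve >= 0 & ve <= 1))
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-9)
  km <- stats::kmeans(cbind(pc$PC1, pc$PC2), 2, nstart = 10)
  agree <- max(mean((km$cluster == 1) == (pc$class_label == "stroma")),
               mean((km$cluster == 2) == (pc$class_label == "stroma")))
  expect_gte(agree, 0.95)
})

test_that("constant regions make PCA degenerate and few regions are rejected", {
  reg <- tibble::tibble(region_id = c("a", "b", "c"),
                        class_label = c("s", "s", "t"),
                        total_ions = c(10L, 10L, 10L),
                        P1 = c(5L, 5L, 5L), P2 = c(5L, 5L, 5L))
  attr(reg, "feature_cols") <- c("P1", "P2")
  expect_error(pca_scores(reg), class = "pimsr_degenerate")
  expect_error(pca_scores(reg[1:2, ]), class = "pimsr_invalid_input")
})

test_that("m_convention switches the B-H denominator", {
  sim <- simulate_two_class_regions(50, 30, seed = 315)
  dt_tests <- differential_test(sim$regions, Q = 0.01, m_convention = "tests")
  dt_reg <- differential_test(sim$regions, Q = 0.01, m_convention = "regions")
  expect_equal(attr(dt_tests, "m"), 50L)
  expect_equal(attr(dt_reg, "m"), 60L)
  expect_equal(dt_reg$bh_critical[dt_reg$rank_i == 1],
               -log10(0.01 / 60), tolerance = 1e-12)
})
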