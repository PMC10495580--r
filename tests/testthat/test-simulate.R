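test_that("Lorentzian lineshape meets its amplitude and half-maximum contract", {
  ax <- canonical_axis()
  peak <- metabolite_peak("NAA", 2.01, 1.0, 0.04)
  sp <- simulate_clean_spectrum(list(peak), ax)
  step <- mean(diff(ax$ppm))
  at <- function(ppm) sp$intensities[which.min(abs(ax$ppm - ppm))]
  # grid-offset tolerance: the nearest grid point sits within step/2 of the
  # nominal position
  # the half-maximum points sit on the steep flank: a grid offset of step/2
  # (~0.0016 ppm) moves the Lorentzian by up to ~8.5% there
  expect_equal(at(2.01), 1.0, tolerance = 0.01)
  expect_equal(at(2.01 + 0.02), 0.5, tolerance = 0.1)
  expect_equal(at(2.01 - 0.02), 0.5, tolerance = 0.1)
  expect_true(all(sp$intensities >= 0))
})

test_that("clean simulation is a superposition, linear in amplitudes", {
  ax <- canonical_axis()
  p1 <- metabolite_peak("NAA", 2.01, 1.0, 0.035)
  p2 <- metabolite_peak("Cho", 3.22, 0.65, 0.04)
  both <- simulate_clean_spectrum(list(p1, p2), ax)$intensities
  solo <- simulate_clean_spectrum(list(p1), ax)$intensities +
          simulate_clean_spectrum(list(p2), ax)$intensities
  expect_equal(both, solo, tolerance = 1e-12)
  doubled <- metabolite_peak("NAA", 2.01, 2.0, 0.035)
  expect_equal(simulate_clean_spectrum(list(doubled), ax)$intensities,
               2 * simulate_clean_spectrum(list(p1), ax)$intensities,
               tolerance = 1e-12)
  flat <- simulate_clean_spectrum(list(), ax)
  expect_identical(flat$intensities, numeric(850))
})

test_that("identity artifact profile leaves the spectrum unchanged", {
  sp <- simulate_clean_spectrum(default_peaks(), canonical_axis())
  out <- inject_artifacts(sp, artifact_profile(noise_sigma = 0))
  expect_identical(out$intensities, sp$intensities)
})

test_that("a one-grid-step frequency shift equals an index roll", {
  ax <- canonical_axis()
  sp <- simulate_clean_spectrum(default_peaks(), ax)
  step <- mean(diff(ax$ppm))
  out <- inject_artifacts(sp, artifact_profile(freq_shift = step,
                                               noise_sigma = 0))
  n <- length(sp$intensities)
  expect_equal(out$intensities, c(sp$intensities[n], sp$intensities[-n]),
               tolerance = 1e-12)
})

test_that("additive noise has the configured scale (Monte Carlo)", {
  sp <- simulate_clean_spectrum(default_peaks(), canonical_axis())
  s <- 0.07
  set.seed(123)
  # 40 replicates x 850 points = 34,000 noise draws for the moment check
  devs <- replicate(40, {
    inject_artifacts(sp, artifact_profile(noise_sigma = s))$intensities -
      sp$intensities
  })
  expect_equal(sd(as.numeric(devs)), s, tolerance = 0.05 * s)
  expect_lt(abs(mean(as.numeric(devs))), 0.05 * s)
})

test_that("broadening widens lines while preserving area", {
  ax <- canonical_axis()
  sp <- simulate_clean_spectrum(list(metabolite_peak("NAA", 2.75, 1, 0.035)),
                                ax)
  out <- inject_artifacts(sp, artifact_profile(broadening_factor = 3,
                                               noise_sigma = 0))
  fwhm_of <- function(y) {
    half <- max(y) / 2
    sum(y >= half) * mean(diff(ax$ppm))
  }
  expect_gt(fwhm_of(out$intensities), 2 * fwhm_of(sp$intensities))
  expect_lt(max(out$intensities), max(sp$intensities))
  expect_equal(sum(out$intensities), sum(sp$intensities), tolerance = 0.02)
})

test_that("truth labels follow the worst-criterion threshold rule", {
  thr <- qc_thresholds(0.5)
  quiet <- specqc:::severity_to_profile(0.1, 0.1, 0.05, 0.1)
  set.seed(1)
  lab <- assign_truth_label(quiet, thr, rater_noise = 0)
  expect_identical(lab$truth, "good")
  expect_identical(lab$consensus, "good")

  lipid_heavy <- specqc:::severity_to_profile(0.1, 0.1, 0.9, 0.1)
  lab2 <- assign_truth_label(lipid_heavy, thr, rater_noise = 0)
  expect_identical(lab2$truth, "bad")
  expect_identical(lab2$consensus, "bad")
})

test_that("rater disagreement at the threshold matches independent flips", {
  thr <- qc_thresholds(0.5)
  at_cut <- specqc:::severity_to_profile(0.5, 0.2, 0.2, 0.2)  # severity exactly 0.5
  expect_equal(severity_score(at_cut), 0.5, tolerance = 1e-12)
  set.seed(77)
  n <- 10000
  disagree <- 0L
  for (i in seq_len(n)) {
    lab <- assign_truth_label(at_cut, thr, rater_noise = 0.5)
    disagree <- disagree + (lab$rater_a != lab$rater_b)
  }
  # independent flips at p = 0.5: disagreement probability 2 p (1 - p) = 0.5
  expect_equal(disagree / n, 0.5, tolerance = 0.03)
})

test_that("cohorts are seed-reproducible and hit the target balance", {
  cfg <- sim_config(n_subjects = 8, voxels_per_subject = 150, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$manifest, b$manifest)
  expect_equal(mean(a$manifest$consensus == "bad"), 0.46, tolerance = 0.03)

  all_good <- generate_cohort(sim_config(n_subjects = 2,
                                         voxels_per_subject = 40,
                                         fraction_bad = 0, seed = 3))
  expect_true(all(all_good$manifest$consensus == "good"))
})

test_that("severity separation 1 is threshold-separable; 0 decouples labels", {
  sep1 <- generate_cohort(sim_config(n_subjects = 6, voxels_per_subject = 80,
                                     severity_separation = 1, rater_noise = 0,
                                     seed = 13))
  score <- severity_score(sep1)
  bad <- sep1$manifest$consensus == "bad"
  # exhaustive threshold scan: some cut classifies every voxel correctly
  cuts <- sort(unique(score))
  perfect <- any(vapply(cuts, function(cc)
    all((score > cc) == bad) || all((score >= cc) == bad), logical(1)))
  expect_true(perfect)

  sep0 <- generate_cohort(sim_config(n_subjects = 8, voxels_per_subject = 250,
                                     severity_separation = 0, seed = 1))
  s0 <- severity_score(sep0)
  lab0 <- sep0$manifest$consensus
  expect_gt(stats::wilcox.test(s0[lab0 == "good"], s0[lab0 == "bad"])$p.value,
            0.01)
  expect_equal(mean(lab0 == "bad"), 0.46, tolerance = 0.03)
})

test_that("generated spectra survive preprocessing (no zero variance)", {
  coh <- quick_cohort(n_subjects = 3, voxels = 25, seed = 15,
                      preprocessed = FALSE)
  expect_no_error(pp <- preprocess(coh))
  expect_equal(dim(pp$spectra), c(75L, 850L))
  sds <- apply(pp$spectra, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_equal(unname(sds), rep(1, 75), tolerance = 1e-9)
})

test_that("tumor mode flags lesions with altered NAA/Cho metabolism", {
  coh <- generate_cohort(sim_config(n_subjects = 6, voxels_per_subject = 120,
                                    tumor_mode = TRUE, fraction_bad = 0.29,
                                    seed = 16))
  m <- coh$manifest
  expect_true(all(m$cohort_tag == "tumor"))
  expect_gt(sum(m$lesion_flag), 0)
  expect_equal(mean(m$lesion_flag), 0.195, tolerance = 0.06)
  ax <- coh$axis$ppm
  naa_band <- ax > 1.95 & ax < 2.07
  cho_band <- ax > 3.16 & ax < 3.28
  naa <- apply(coh$spectra[, naa_band], 1, max)
  cho <- apply(coh$spectra[, cho_band], 1, max)
  ratio <- cho / naa
  expect_gt(median(ratio[m$lesion_flag]), 2 * median(ratio[!m$lesion_flag]))
})
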