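test_that("spectral axis validates monotonicity and length", {
  expect_error(spectral_axis(c(1, 1, 2)), "ascending")
  expect_error(spectral_axis(3), "at least 2")
  expect_error(spectral_axis(c(1, Inf)), "finite")
  ax <- canonical_axis()
  expect_equal(ax$n_points, 850L)
  expect_equal(range(ax$ppm), c(1.4, 4.1))
})

test_that("take_real extracts real parts and is idempotent", {
  ax <- spectral_axis(c(1, 2))
  v <- voxel_spectrum(c(1 + 2i, 3 - 1i), ax, "s1")
  expect_identical(take_real(v)$intensities, c(1, 3))
  r <- voxel_spectrum(c(0.5, -2), ax, "s1")
  expect_identical(take_real(r), r)
  set.seed(4)
  z <- complex(real = rnorm(50), imaginary = rnorm(50))
  v2 <- voxel_spectrum(z, spectral_axis(seq(1, 5, length.out = 50)), "s2")
  expect_identical(take_real(v2)$intensities,
                   vapply(z, function(ci) Re(ci), numeric(1)))
})

test_that("cropping keeps exactly the closed-interval points", {
  cfg <- preprocess_config()
  exact <- voxel_spectrum(rnorm(850), canonical_axis(), "s1")
  expect_equal(crop_to_window(exact, cfg)$axis$n_points, 850L)
  expect_equal(crop_to_window(exact, cfg)$intensities, exact$intensities)

  wide_ax <- spectral_axis(seq(0, 5, length.out = 1000))
  wide <- voxel_spectrum(rnorm(1000), wide_ax, "s1")
  cropped <- crop_to_window(wide, cfg)
  brute <- sum(wide_ax$ppm >= 1.4 & wide_ax$ppm <= 4.1)
  expect_equal(cropped$axis$n_points, brute)
  expect_equal(cropped$intensities,
               wide$intensities[wide_ax$ppm >= 1.4 & wide_ax$ppm <= 4.1])

  short <- voxel_spectrum(rnorm(100), spectral_axis(seq(2, 4.1, length.out = 100)), "s1")
  expect_error(crop_to_window(short, cfg), "lower window bound")
  high <- voxel_spectrum(rnorm(100), spectral_axis(seq(1.4, 3, length.out = 100)), "s1")
  expect_error(crop_to_window(high, cfg), "upper window bound")
})

test_that("z-normalization hits population moments and rejects constants", {
  ax2 <- spectral_axis(c(1, 2))
  v <- voxel_spectrum(c(-1, 1), ax2, "s1")
  expect_equal(znormalize(v)$intensities, c(-1, 1))
  expect_error(znormalize(voxel_spectrum(c(0, 0), ax2, "s1")), "zero-variance")

  set.seed(11)
  z <- znormalize(voxel_spectrum(rnorm(850, 5, 3), canonical_axis(), "s1"))
  expect_lt(abs(mean(z$intensities)), 1e-9)
  expect_lt(abs(sqrt(mean((z$intensities - mean(z$intensities))^2)) - 1), 1e-9)
})

test_that("z-normalization is idempotent and the chain deterministic", {
  set.seed(3)
  v <- voxel_spectrum(complex(real = rnorm(850), imaginary = rnorm(850)),
                      canonical_axis(), "s1")
  once <- preprocess(v)
  twice <- znormalize(once)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-9)
  expect_identical(preprocess(v)$intensities, once$intensities)
})

test_that("consensus rule equals logical AND over all verdict pairs", {
  grid <- expand.grid(a = c("good", "bad"), b = c("good", "bad"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    expected <- if (grid$a[i] == "good" && grid$b[i] == "good") "good" else "bad"
    expect_identical(aggregate_labels(grid$a[i], grid$b[i]), expected)
  }
  expect_error(aggregate_labels("good", NA_character_), "missing|good")
  expect_error(aggregate_labels(character(0), character(0)), "no verdicts")
  lab <- qc_label("good", "bad")
  expect_identical(lab$consensus, "bad")
})

test_that("cohort round-trip through the text container is exact", {
  coh <- quick_cohort(n_subjects = 2, voxels = 6, preprocessed = FALSE,
                      seed = 5)
  path <- file.path(tempdir(), "coh_txt")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(back$spectra, coh$spectra)
  expect_identical(back$axis$ppm, coh$axis$ppm)
  expect_identical(back$manifest$subject_id, coh$manifest$subject_id)
  expect_identical(back$manifest$lesion_flag, coh$manifest$lesion_flag)
  expect_identical(back$manifest$consensus, coh$manifest$consensus)
  expect_identical(sort(cohort_subjects(back)), sort(cohort_subjects(coh)))
  expect_length(cohort_subjects(back), 2L)
  unlink(path, recursive = TRUE)
})

test_that("complex spectra round-trip and manifest schema is validated", {
  coh <- quick_cohort(n_subjects = 2, voxels = 3, preprocessed = FALSE,
                      seed = 6)
  coh$spectra <- coh$spectra + 0.5i * coh$spectra
  path <- file.path(tempdir(), "coh_cplx")
  write_cohort(coh, path)
  expect_identical(read_cohort(path)$spectra, coh$spectra)

  bad <- utils::read.csv(file.path(path, "manifest.csv"),
                         colClasses = "character")
  bad$subject_id <- NULL
  utils::write.csv(bad, file.path(path, "manifest.csv"), row.names = FALSE)
  expect_error(read_cohort(path), "subject_id")
  unlink(path, recursive = TRUE)
})

test_that("HDF5 container round-trips when rhdf5 is present", {
  skip_if_not_installed("rhdf5")
  coh <- quick_cohort(n_subjects = 2, voxels = 4, preprocessed = FALSE,
                      seed = 8)
  path <- file.path(tempdir(), "coh.h5")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(back$spectra, coh$spectra)
  expect_identical(back$manifest$consensus, coh$manifest$consensus)
  unlink(c(path, sub("\\.h5$", ".csv", path)))
})

test_that("resampling preprocessing handles non-canonical grids", {
  ax <- spectral_axis(seq(1.0, 4.5, length.out = 1200))
  set.seed(9)
  v <- voxel_spectrum(rnorm(1200) + 2, ax, "s1")
  out <- preprocess(v)
  expect_equal(out$axis$n_points, 850L)
  expect_lt(abs(mean(out$intensities)), 1e-9)
})
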