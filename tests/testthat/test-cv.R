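test_that("rotating scheme: one subject per cohort type in test and val", {
  coh <- quick_cohort(n_subjects = 40, voxels = 4, seed = 51,
                      preprocessed = FALSE)
  plan <- make_split_plan(coh, "nd_rotating", seed = 3)
  expect_length(plan$folds, 10L)
  tags <- coh$manifest$cohort_tag[!duplicated(coh$manifest$subject_id)]
  names(tags) <- unique(coh$manifest$subject_id)
  for (fold in plan$folds) {
    expect_length(fold$test_subjects, 4L)
    expect_length(fold$val_subjects, 4L)
    expect_setequal(unname(tags[fold$test_subjects]),
                    c("healthy", "MDD", "MS", "PD"))
    expect_setequal(unname(tags[fold$val_subjects]),
                    c("healthy", "MDD", "MS", "PD"))
    expect_length(fold$train_subjects, 32L)
  }
  # test subjects consumed without replacement across the 10 repeats
  all_test <- unlist(lapply(plan$folds, `[[`, "test_subjects"))
  expect_equal(anyDuplicated(all_test), 0L)
  # balanced subjects: roughly 75 / 12.5 / 12.5 voxel proportions
  n <- nrow(coh$spectra)
  f1 <- plan$folds[[1]]
  prop <- function(s) sum(coh$manifest$subject_id %in% s) / n
  expect_equal(prop(f1$train_subjects), 0.80, tolerance = 0.07)
  expect_equal(prop(f1$val_subjects), 0.10, tolerance = 0.05)
  expect_equal(prop(f1$test_subjects), 0.10, tolerance = 0.05)
})

test_that("leave-one-out scheme: 1 test + 2 validation subjects per fold", {
  coh <- quick_cohort(n_subjects = 13, voxels = 4, seed = 52, tumor = TRUE,
                      preprocessed = FALSE)
  plan <- make_split_plan(coh, "bt_leave_one_out", seed = 5)
  expect_length(plan$folds, 13L)
  for (fold in plan$folds) {
    expect_length(fold$test_subjects, 1L)
    expect_length(fold$val_subjects, 2L)
    expect_length(fold$train_subjects, 10L)
  }
  expect_setequal(vapply(plan$folds, `[[`, character(1), "test_subjects"),
                  cohort_subjects(coh))
})

test_that("every fold partitions subjects disjointly (exhaustive scan)", {
  coh <- quick_cohort(n_subjects = 12, voxels = 3, seed = 53,
                      preprocessed = FALSE)
  for (scheme in c("nd_rotating", "bt_leave_one_out")) {
    plan <- make_split_plan(coh, scheme, seed = 9, n_repeats = 3)
    for (fold in plan$folds) {
      sets <- fold[c("train_subjects", "val_subjects", "test_subjects")]
      for (i in 1:2) for (j in (i + 1):3)
        expect_length(intersect(sets[[i]], sets[[j]]), 0L)
      expect_setequal(unlist(sets), cohort_subjects(coh))
    }
  }
})

test_that("split plans are deterministic and fail on deficient cohorts", {
  coh <- quick_cohort(n_subjects = 8, voxels = 3, seed = 54,
                      preprocessed = FALSE)
  p1 <- make_split_plan(coh, "nd_rotating", seed = 7, n_repeats = 2)
  p2 <- make_split_plan(coh, "nd_rotating", seed = 7, n_repeats = 2)
  expect_identical(p1$folds, p2$folds)

  tumor3 <- quick_cohort(n_subjects = 3, voxels = 3, seed = 55, tumor = TRUE,
                         preprocessed = FALSE)
  expect_error(make_split_plan(tumor3, "bt_leave_one_out"), "at least 4")
  expect_error(make_split_plan(tumor3, "nd_rotating"), "healthy")
  expect_error(make_split_plan(coh, "nd_rotating", n_repeats = 5),
               "per-tag")
})

test_that("network training refuses subject leakage and honors epochs", {
  coh <- quick_cohort(n_subjects = 4, voxels = 15, seed = 56)
  subj <- cohort_subjects(coh)
  tr <- cohort_subset(coh, subjects = subj[1:3])
  leaky_val <- cohort_subset(coh, subjects = subj[3:4])
  expect_error(
    qc_fit(tr, spec = small_spec("cnn"), train = train_config(epochs = 1),
           val_x = leaky_val),
    "leakage")

  va <- cohort_subset(coh, subjects = subj[4])
  fit <- qc_fit(tr, spec = small_spec("cnn"),
                train = train_config(epochs = 3), val_x = va, seed = 1)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(c("train_loss", "train_acc", "val_loss", "val_acc")
                  %in% names(fit$history)))
  expect_false(anyNA(fit$history$val_acc))
})

test_that("zero learning rate leaves parameters and loss untouched", {
  coh <- quick_cohort(n_subjects = 3, voxels = 12, seed = 57)
  spec <- small_spec("cnn")
  frozen <- qc_fit(coh, spec = spec,
                   train = train_config(learning_rate = 0, epochs = 3),
                   seed = 5)
  init <- build_model(spec, seed = 5)
  expect_identical(frozen$net$layers[[1]]$params$W,
                   init$net$layers[[1]]$params$W)
  expect_lt(diff(range(frozen$history$train_loss)), 1e-7)
})

test_that("cross-validation reports one fold each, test subjects only", {
  coh <- quick_cohort(n_subjects = 12, voxels = 25, separation = 1, seed = 58)
  plan <- make_split_plan(coh, "nd_rotating", seed = 2, n_repeats = 2)
  cv <- run_cross_validation(coh, model_spec("rf"), plan = plan, seed = 4)
  expect_length(cv$fold_reports, 2L)
  expect_s3_class(cv$aggregate, "metrics_aggregate")
  n_test1 <- sum(coh$manifest$subject_id %in% plan$folds[[1]]$test_subjects)
  expect_equal(cv$fold_reports[[1]]$n_voxels, n_test1)

  single <- run_cross_validation(coh, model_spec("rf"), plan = plan,
                                 seed = 4, folds = 1L)
  expect_equal(unname(single$aggregate$sd["auc"]), 0)

  cv2 <- run_cross_validation(coh, model_spec("rf"), plan = plan, seed = 4)
  expect_identical(cv$aggregate, cv2$aggregate)
})

test_that("lesion-only reports appear for tumor cohorts", {
  coh <- quick_cohort(n_subjects = 6, voxels = 60, separation = 1, seed = 59,
                      tumor = TRUE, fraction_bad = 0.29)
  plan <- make_split_plan(coh, "bt_leave_one_out", seed = 2)
  cv <- run_cross_validation(coh, model_spec("rf"), plan = plan, seed = 4,
                             folds = 1:2)
  expect_false(is.null(cv$lesion_reports))
  expect_true(all(vapply(cv$lesion_reports, `[[`, character(1),
                         "subset_tag") == "lesion_only"))
  expect_true(all(vapply(cv$lesion_reports, `[[`, integer(1), "n_voxels") <
                  vapply(cv$fold_reports[seq_along(cv$lesion_reports)],
                         `[[`, integer(1), "n_voxels")))
})
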