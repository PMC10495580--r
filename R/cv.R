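#' Network optimization hyperparameters
#'
#' Adam on the categorical cross-entropy, initial learning rate 1e-4, batch
#' size 64, 15 epochs. Batches are reshuffled each epoch with a seeded
#' generator and the last partial batch is kept; final-epoch parameters are
#' used (no early stopping).
#'
#' @param learning_rate Adam step size, > 0 (0 allowed for the degenerate
#'   no-update case).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set, >= 1.
#' @param seed Seed for initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         epochs = 15L, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = epochs,
                 loss = "categorical_crossentropy", seed = as.integer(seed)),
            class = "train_config")
}

#' Build a subject-grouped cross-validation plan
#'
#' Two schemes, both leakage-free at the subject level:
#' \describe{
#'   \item{nd_rotating}{each fold reserves 4 test subjects (one per cohort
#'     tag among healthy/MDD/MS/PD) and 4 validation subjects (likewise one
#'     per tag); remaining subjects train. Repeated `n_repeats` (default 10)
#'     times with a seeded within-tag permutation consuming test subjects
#'     without replacement, so no subject is tested twice. With balanced
#'     subjects this gives roughly a 75/12.5/12.5 voxel split.}
#'   \item{bt_leave_one_out}{one fold per subject: that subject tests, 2
#'     validation subjects are redrawn per fold with a per-fold seed, the
#'     rest train.}
#' }
#'
#' @param dataset A [qc_cohort].
#' @param scheme `"nd_rotating"` or `"bt_leave_one_out"`.
#' @param seed Integer seed; the plan is deterministic given it.
#' @param n_repeats Folds for the rotating scheme (at most the smallest
#'   per-tag subject count).
#' @return An object of class `split_plan`: list of folds, each with
#'   `train_subjects`, `val_subjects`, `test_subjects`.
#' @export
make_split_plan <- function(dataset,
                            scheme = c("nd_rotating", "bt_leave_one_out"),
                            seed = 1L, n_repeats = 10L) {
  stopifnot(inherits(dataset, "qc_cohort"))
  scheme <- match.arg(scheme)
  m <- dataset$manifest
  subj_tag <- m$cohort_tag[!duplicated(m$subject_id)]
  names(subj_tag) <- m$subject_id[!duplicated(m$subject_id)]
  folds <- if (scheme == "nd_rotating") {
    tags <- c("healthy", "MDD", "MS", "PD")
    by_tag <- split(names(subj_tag), factor(subj_tag, levels = tags))
    deficient <- tags[vapply(by_tag, length, integer(1L)) < 2L]
    if (length(deficient))
      stop("rotating scheme needs at least 2 subjects per cohort tag; ",
           "deficient tag(s): ", paste(deficient, collapse = ", "))
    n_repeats <- as.integer(n_repeats)
    max_folds <- min(vapply(by_tag, length, integer(1L)))
    if (n_repeats > max_folds)
      stop("n_repeats = ", n_repeats, " exceeds the smallest per-tag ",
           "subject count (", max_folds, ")")
    set.seed(seed)
    perm <- lapply(by_tag, sample)      # within-tag test order
    lapply(seq_len(n_repeats), function(f) {
      test <- vapply(perm, `[[`, character(1L), f)
      val <- vapply(tags, function(tg) {
        pool <- setdiff(by_tag[[tg]], test)
        pool[sample.int(length(pool), 1L)]
      }, character(1L))
      list(train_subjects = setdiff(names(subj_tag), c(test, val)),
           val_subjects = unname(val), test_subjects = unname(test))
    })
  } else {
    subjects <- names(subj_tag)
    if (length(subjects) < 4L)
      stop("leave-one-out scheme needs at least 4 subjects (1 test + 2 ",
           "validation + training)")
    set.seed(seed)
    fold_seeds <- sample.int(.Machine$integer.max - 1L, length(subjects))
    lapply(seq_along(subjects), function(f) {
      test <- subjects[f]
      set.seed(fold_seeds[f])
      pool <- setdiff(subjects, test)
      val <- sample(pool, 2L)
      list(train_subjects = setdiff(pool, val),
           val_subjects = val, test_subjects = test)
    })
  }
  plan <- structure(list(scheme = scheme, folds = folds, seed = seed),
                    class = "split_plan")
  check_split_plan(plan, unique(m$subject_id))
  plan
}

# asserted, not assumed: pairwise disjointness and full coverage per fold
check_split_plan <- function(plan, all_subjects) {
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    sets <- fold[c("train_subjects", "val_subjects", "test_subjects")]
    for (i in 1:2) for (j in (i + 1):3) {
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov))
        stop("fold ", f, ": subject(s) in multiple partitions: ",
             paste(ov, collapse = ", "))
    }
    if (!setequal(unlist(sets), all_subjects))
      stop("fold ", f, ": partitions do not cover the subjects exactly")
  }
  invisible(TRUE)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d fold(s), seed %d\n", x$scheme,
              length(x$folds), x$seed))
  f1 <- x$folds[[1L]]
  cat(sprintf("  fold sizes (subjects): train %d / val %d / test %d\n",
              length(f1$train_subjects), length(f1$val_subjects),
              length(f1$test_subjects)))
  invisible(x)
}

#' Run subject-grouped cross-validation
#'
#' For each fold of the plan: fits the requested model kind on the training
#' subjects' voxels (networks receive the validation subjects for epoch
#' curves), predicts the held-out test subjects, and scores ROC-AUC, AUC-PR
#' and accuracy on them. When the cohort contains lesion-flagged voxels a
#' lesion-only report is added per fold. Per-fold seeds derive from `seed`.
#'
#' @param dataset A preprocessed [qc_cohort].
#' @param spec A [model_spec] (any of the five kinds).
#' @param train_cfg A [train_config()] for network training.
#' @param plan A [split_plan] from [make_split_plan()].
#' @param seed Master seed for per-fold training seeds.
#' @param folds Optional integer subset of fold indices to run.
#' @return An object of class `qc_cv`: per-fold reports, lesion-only
#'   reports where available, and aggregate mean +/- sd per metric.
#' @export
run_cross_validation <- function(dataset, spec, train_cfg = train_config(),
                                 plan, seed = 1L, folds = NULL) {
  stopifnot(inherits(dataset, "qc_cohort"), inherits(spec, "model_spec"),
            inherits(plan, "split_plan"))
  if (is.null(folds)) folds <- seq_along(plan$folds)
  m <- dataset$manifest
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L,
                           length(plan$folds))
  reports <- list(); lesion_reports <- list(); fold_info <- list()
  for (f in folds) {
    fold <- plan$folds[[f]]
    if (!length(fold$test_subjects) ||
        !any(m$subject_id %in% fold$test_subjects))
      stop("fold ", f, " has an empty test set")
    tr <- cohort_subset(dataset, subjects = fold$train_subjects)
    te <- cohort_subset(dataset, subjects = fold$test_subjects)
    va <- if (length(fold$val_subjects))
      cohort_subset(dataset, subjects = fold$val_subjects)
    fit <- if (spec$kind == "rf") {
      qc_fit(tr, spec = spec, seed = fold_seeds[f])
    } else {
      qc_fit(tr, spec = spec, train = train_cfg, val_x = va,
             seed = fold_seeds[f])
    }
    p_good <- predict(fit, te)[, "good"]
    labels <- te$manifest$consensus
    reports[[length(reports) + 1L]] <- subset_report(labels, p_good,
                                                     subset_tag = "all")
    if (any(te$manifest$lesion_flag)) {
      lesion_reports[[length(lesion_reports) + 1L]] <-
        subset_report(labels, p_good, mask = te$manifest$lesion_flag,
                      subset_tag = "lesion_only")
    }
    fold_info[[length(fold_info) + 1L]] <-
      list(fold = f, n_train = nrow(tr$spectra), n_test = nrow(te$spectra),
           history = fit$history)
  }
  structure(list(kind = spec$kind, scheme = plan$scheme,
                 fold_reports = reports,
                 lesion_reports = if (length(lesion_reports)) lesion_reports,
                 aggregate = aggregate_folds(reports),
                 lesion_aggregate = if (length(lesion_reports))
                   aggregate_folds(lesion_reports),
                 fold_info = fold_info, seed = seed),
            class = "qc_cv")
}

#' @export
print.qc_cv <- function(x, ...) {
  cat(sprintf("<qc_cv> %s model, %s scheme, %d fold(s)\n", x$kind, x$scheme,
              length(x$fold_reports)))
  print(x$aggregate)
  if (!is.null(x$lesion_aggregate)) {
    cat("Lesion-only (T2L) voxels:\n")
    print(x$lesion_aggregate)
  }
  invisible(x)
}
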