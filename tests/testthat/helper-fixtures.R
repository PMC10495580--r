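# Shared fixtures: reduced-width model specs (the layer-count contracts are
# unchanged; channel widths are config, and the synthetic task needs far
# less capacity than the clinical-scale defaults), small simulated cohorts,
# and independent metric oracles.

small_spec <- function(kind) {
  model_spec(kind,
             cnn_channels = c(4L, 8L, 8L, 16L, 16L, 32L),
             icnn_channels = c(4L, 8L),
             inception_branch_channels = 4L,
             fc_widths = c(64L, 64L))
}

quick_cohort <- function(n_subjects = 4, voxels = 30, separation = 0.9,
                         seed = 1, tumor = FALSE, fraction_bad = 0.46,
                         rater_noise = 0.1, preprocessed = TRUE) {
  coh <- generate_cohort(sim_config(
    n_subjects = n_subjects, voxels_per_subject = voxels,
    fraction_bad = fraction_bad, severity_separation = separation,
    rater_noise = rater_noise, tumor_mode = tumor, seed = seed))
  if (preprocessed) preprocess(coh) else coh
}

# O(n^2) pairwise-concordance oracle for ROC-AUC (ties credited 0.5)
oracle_auc <- function(labels, scores) {
  y <- as.integer(as.character(labels) == "good" | labels == 1)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# direct-summation average-precision oracle: walk distinct thresholds in
# descending order, recompute precision/recall from scratch at each
oracle_ap <- function(labels, scores) {
  y <- as.integer(as.character(labels) == "good" | labels == 1)
  n_pos <- sum(y)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(y[sel]) / sum(sel)
    recall <- sum(y[sel]) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# toy differentiable "model" whose class-1 score is exactly linear, w . x;
# used to check integrated-gradients closed forms
make_toy_linear <- function(w, offset = 0) {
  obj <- structure(list(w = w, offset = offset, trained = TRUE,
                        classes = c("good", "bad"),
                        spec = list(input_length = length(w))),
                   class = c("toy_linear", "qc_model"))
  registerS3method("input_gradient", "toy_linear",
                   function(model, X, class_idx) {
                     sgn <- if (class_idx == 1L) 1 else -1
                     matrix(rep(sgn * model$w, each = nrow(X)), nrow(X))
                   },
                   envir = asNamespace("specqc"))
  registerS3method("predict_prob_matrix", "toy_linear",
                   function(object, X) {
                     s <- as.numeric(X %*% object$w) + object$offset
                     cbind(s, 1 - s)
                   },
                   envir = asNamespace("specqc"))
  obj
}

# tiny trained CNN shared across attribution/model tests (built lazily once)
shared_cnn_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- quick_cohort(n_subjects = 6, voxels = 40, separation = 1,
                          seed = 21)
      subj <- cohort_subjects(coh)
      cache <<- list(
        fit = qc_fit(cohort_subset(coh, subjects = subj[1:4]),
                     spec = small_spec("cnn"),
                     train = train_config(learning_rate = 1e-3, epochs = 4),
                     seed = 9),
        cohort = coh,
        test = cohort_subset(coh, subjects = subj[5:6]))
    }
    cache
  }
})
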