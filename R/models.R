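#' Model architecture specification
#'
#' Houses the architecture constants of the five classifier variants:
#' \describe{
#'   \item{rf}{random forest on raw spectra: 200 trees, per-split feature
#'     subsample of `floor(sqrt(input_length))` = 29 for 850-point input
#'     (some conventions round to 30; the exact integer is a config field).}
#'   \item{cnn}{6 blocks of (1D convolution, ReLU, max pooling), then two
#'     fully connected layers the second of which has 64 nodes, then a
#'     2-way softmax head.}
#'   \item{icnn}{2 (convolution, ReLU, max pooling) blocks, 2 inception
#'     modules (parallel kernel-1/3/5 branches plus a pooled branch,
#'     channel-concatenated) each followed by max pooling, then the same
#'     fully connected tail.}
#'   \item{cnn_rf, icnn_rf}{hybrids: an RF (200 trees, mtry
#'     `floor(sqrt(64))` = 8) fitted on the trained network's 64-node
#'     penultimate features.}
#' }
#' Kernel sizes, channel counts and FC widths are not part of the layer-count
#' contract and are exposed here with conventional 1D-CNN defaults.
#'
#' @param kind One of `"rf"`, `"cnn"`, `"icnn"`, `"cnn_rf"`, `"icnn_rf"`.
#' @param input_length Number of spectral points the model accepts.
#' @param rf_n_estimators Number of trees for RF (and hybrid RF) models.
#' @param rf_max_features Per-split feature subsample for the raw-spectra RF.
#' @param cnn_channels Output channels of the 6 CNN conv blocks.
#' @param icnn_channels Output channels of the 2 ICNN conv blocks.
#' @param inception_branch_channels Channels per inception branch (4 branches
#'   concatenate).
#' @param kernel_size Convolution kernel width (odd).
#' @param fc_widths Widths of the two fully connected layers; the second must
#'   be the 64-node penultimate block.
#' @param n_classes Number of output classes (2: good/bad).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("rf", "cnn", "icnn", "cnn_rf", "icnn_rf"),
                       input_length = 850L,
                       rf_n_estimators = 200L,
                       rf_max_features = floor(sqrt(input_length)),
                       cnn_channels = c(16L, 32L, 64L, 128L, 256L, 512L),
                       icnn_channels = c(16L, 32L),
                       inception_branch_channels = 16L,
                       kernel_size = 5L,
                       fc_widths = c(256L, 64L),
                       n_classes = 2L) {
  kind <- match.arg(kind)
  input_length <- as.integer(input_length)
  if (input_length < 64L) stop("input_length too short for the pooling stack")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  if (length(cnn_channels) != 6L)
    stop("cnn_channels must list 6 conv-block widths (6 convolution layers)")
  if (length(icnn_channels) != 2L)
    stop("icnn_channels must list 2 conv-block widths")
  if (length(fc_widths) != 2L)
    stop("fc_widths must list 2 fully connected widths")
  if (fc_widths[2L] != 64L)
    stop("the penultimate fully connected layer must have 64 nodes")
  structure(list(kind = kind,
                 input_length = input_length,
                 rf_n_estimators = as.integer(rf_n_estimators),
                 rf_max_features = as.integer(rf_max_features),
                 cnn_conv_layers = 6L,
                 icnn_conv_layers = 2L,
                 icnn_inception_modules = 2L,
                 fc_layers = 2L,
                 penultimate_width = 64L,
                 cnn_channels = as.integer(cnn_channels),
                 icnn_channels = as.integer(icnn_channels),
                 inception_branch_channels = as.integer(inception_branch_channels),
                 kernel_size = as.integer(kernel_size),
                 fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "input length", x$input_length, "\n")
  if (x$kind %in% c("rf", "cnn_rf", "icnn_rf"))
    cat(sprintf("  RF: %d trees, mtry %d (raw) / %d (hybrid features)\n",
                x$rf_n_estimators, x$rf_max_features,
                floor(sqrt(x$penultimate_width))))
  if (x$kind %in% c("cnn", "cnn_rf"))
    cat(sprintf("  CNN: %d conv blocks (channels %s), FC %s, softmax %d\n",
                x$cnn_conv_layers, paste(x$cnn_channels, collapse = "-"),
                paste(x$fc_widths, collapse = "-"), x$n_classes))
  if (x$kind %in% c("icnn", "icnn_rf"))
    cat(sprintf(
      "  ICNN: %d conv blocks + %d inception modules (%d ch/branch), FC %s\n",
      x$icnn_conv_layers, x$icnn_inception_modules,
      x$inception_branch_channels, paste(x$fc_widths, collapse = "-")))
  invisible(x)
}

.qc_classes <- c("good", "bad")   # "good" is the positive class throughout

as_label_vector <- function(y) {
  y <- as.character(y)
  if (anyNA(y) || !all(y %in% .qc_classes))
    stop("labels must be \"good\" or \"bad\"")
  y
}

#' Build an untrained model
#'
#' Instantiates the architecture of a [model_spec]: initialized network
#' parameters for `cnn`/`icnn`, or an empty forest placeholder for `rf`
#' (random forests have no untrained parameter state). Prediction on an
#' untrained model is an error; use [qc_fit()] to train.
#'
#' @param spec A [model_spec].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `qc_model` (subclass by kind), untrained.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind %in% c("cnn_rf", "icnn_rf"))
    stop("hybrids are assembled from a trained network; fit via qc_fit() ",
         "or build_hybrid()")
  obj <- list(spec = spec, kind = spec$kind, trained = FALSE,
              classes = .qc_classes, fingerprint = NULL)
  if (spec$kind == "cnn") {
    set.seed(seed)
    obj$net <- build_cnn_net(spec)
    class(obj) <- c("qc_cnn", "qc_net", "qc_model")
  } else if (spec$kind == "icnn") {
    set.seed(seed)
    obj$net <- build_icnn_net(spec)
    class(obj) <- c("qc_icnn", "qc_net", "qc_model")
  } else {
    obj$forest <- NULL
    class(obj) <- c("qc_rf", "qc_model")
  }
  obj
}

# resolve (x, y) from a matrix + labels or a preprocessed cohort
resolve_xy <- function(x, y = NULL) {
  if (inherits(x, "qc_cohort")) {
    list(X = x$spectra,
         y = if (is.null(y)) as_label_vector(x$manifest$consensus)
             else as_label_vector(y),
         subjects = x$manifest$subject_id)
  } else {
    list(X = as.matrix(x),
         y = if (is.null(y)) stop("labels y required for matrix input")
             else as_label_vector(y),
         subjects = NULL)
  }
}

check_input_length <- function(model, X) {
  if (ncol(X) != model$spec$input_length)
    stop("model expects ", model$spec$input_length,
         "-point spectra; got ", ncol(X), " points")
  if (!is.null(model$fingerprint) &&
      !isTRUE(all.equal(model$fingerprint$n_points, ncol(X))))
    stop("input does not match the model's preprocessing fingerprint")
  invisible(TRUE)
}

#' Fit a spectral quality-control classifier
#'
#' The single fitting front-end for all five model variants. Input spectra
#' must already be preprocessed ([preprocess()]): real, cropped to the
#' analysis window, z-normalized, `input_length` points.
#'
#' Networks train with Adam on the categorical cross-entropy (defaults:
#' learning rate 1e-4, batch size 64, 15 epochs; see [train_config()]),
#' recording per-epoch loss/accuracy curves for the training and, when
#' given, validation set; the final-epoch parameters are kept (no early
#' stopping). A subject-level leakage guard refuses training/validation sets
#' that share subjects. Hybrids first train their base network, then fit a
#' 200-tree RF on its 64-node penultimate features.
#'
#' @param x Preprocessed spectra: numeric matrix (voxels x points) or a
#'   preprocessed [qc_cohort].
#' @param y Labels (`"good"`/`"bad"`); taken from the cohort consensus when
#'   `x` is a [qc_cohort].
#' @param kind Model kind; ignored when `spec` is supplied.
#' @param spec A [model_spec]; defaults to `model_spec(kind)`.
#' @param train A [train_config()] for network kinds.
#' @param val_x,val_y Validation set (matrix + labels, or a [qc_cohort]) for
#'   network curves.
#' @param subjects,val_subjects Subject ids backing the leakage guard;
#'   inferred from cohorts.
#' @param seed Seed governing initialization, batch shuffling and RF
#'   bootstraps.
#' @return A fitted `qc_model` (subclass `qc_rf`, `qc_cnn`, `qc_icnn`,
#'   `qc_hybrid`).
#' @examples
#' \donttest{
#' coh <- preprocess(generate_cohort(sim_config(n_subjects = 4,
#'                                              voxels_per_subject = 30)))
#' fit <- qc_fit(coh, kind = "rf")
#' head(predict(fit, coh))
#' }
#' @export
qc_fit <- function(x, y = NULL,
                   kind = c("rf", "cnn", "icnn", "cnn_rf", "icnn_rf"),
                   spec = NULL, train = train_config(),
                   val_x = NULL, val_y = NULL,
                   subjects = NULL, val_subjects = NULL,
                   seed = train$seed) {
  if (is.null(spec)) spec <- model_spec(match.arg(kind))
  stopifnot(inherits(spec, "model_spec"))
  xy <- resolve_xy(x, y)
  if (is.null(subjects)) subjects <- xy$subjects
  if (spec$kind == "rf")
    return(fit_rf(xy$X, xy$y, spec, seed))
  if (spec$kind %in% c("cnn", "icnn")) {
    vxy <- if (!is.null(val_x)) resolve_xy(val_x, val_y)
    if (!is.null(vxy) && is.null(val_subjects)) val_subjects <- vxy$subjects
    return(fit_network(xy$X, xy$y, spec, train, seed,
                       val_X = vxy$X, val_y = vxy$y,
                       subjects = subjects, val_subjects = val_subjects))
  }
  # hybrids: train the base network, then the feature forest
  base_kind <- sub("_rf$", "", spec$kind)
  base_spec <- spec
  base_spec$kind <- base_kind
  vxy <- if (!is.null(val_x)) resolve_xy(val_x, val_y)
  if (!is.null(vxy) && is.null(val_subjects)) val_subjects <- vxy$subjects
  base <- fit_network(xy$X, xy$y, base_spec, train, seed,
                      val_X = vxy$X, val_y = vxy$y,
                      subjects = subjects, val_subjects = val_subjects)
  build_hybrid(base, xy$X, xy$y, seed = seed)
}

# stable feature names so randomForest matches columns between fit/predict
with_feature_names <- function(X) {
  colnames(X) <- paste0("p", seq_len(ncol(X)))
  X
}

fit_rf <- function(X, y, spec, seed) {
  if (length(unique(y)) < 2L)
    stop("cannot fit a classifier on single-class training labels")
  check_spec_length <- ncol(X)
  if (check_spec_length != spec$input_length)
    stop("model expects ", spec$input_length, "-point spectra; got ",
         check_spec_length)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = with_feature_names(X), y = factor(y, levels = .qc_classes),
    ntree = spec$rf_n_estimators, mtry = spec$rf_max_features)
  structure(list(spec = spec, kind = "rf", trained = TRUE,
                 classes = .qc_classes, forest = forest,
                 fingerprint = list(n_points = ncol(X)), seed = seed),
            class = c("qc_rf", "qc_model"))
}

fit_network <- function(X, y, spec, train, seed, val_X = NULL, val_y = NULL,
                        subjects = NULL, val_subjects = NULL) {
  stopifnot(inherits(train, "train_config"))
  if (!is.null(subjects) && !is.null(val_subjects)) {
    overlap <- intersect(unique(subjects), unique(val_subjects))
    if (length(overlap))
      stop("subject-level leakage between training and validation sets: ",
           paste(overlap, collapse = ", "))
  }
  if (length(unique(y)) < 2L)
    stop("cannot fit a classifier on single-class training labels")
  model <- build_model(spec, seed)
  check_input_length(model, X)
  y_idx <- match(y, .qc_classes)
  val_idx <- if (!is.null(val_X)) match(as_label_vector(val_y), .qc_classes)
  net <- model$net
  state <- adam_init(net)
  n <- nrow(X)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  set.seed(seed + 1L)
  for (epoch in seq_len(train$epochs)) {
    perm <- sample.int(n)
    starts <- seq.int(1L, n, by = train$batch_size)
    ep_loss <- 0; ep_correct <- 0
    for (s in starts) {
      idx <- perm[s:min(s + train$batch_size - 1L, n)]
      fwd <- nn_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
      lg <- ce_loss_grad(fwd$logits, y_idx[idx])
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(lg$p, ties.method = "first") == y_idx[idx])
      if (train$learning_rate > 0) {
        bwd <- nn_backward(net, fwd, lg$dZ)
        upd <- adam_step(net, bwd$grads, state, train$learning_rate)
        net <- upd$net
        state <- upd$state
      }
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val_X)) {
      vp <- net_predict_matrix(net, val_X)
      vl <- -mean(log(pmax(vp[cbind(seq_along(val_idx), val_idx)], 1e-12)))
      row$val_loss <- vl
      row$val_acc <- mean(max.col(vp, ties.method = "first") == val_idx)
    }
    hist <- rbind(hist, row)
  }
  model$net <- net
  model$trained <- TRUE
  model$history <- hist
  model$train_cfg <- train
  model$seed <- seed
  model$fingerprint <- list(n_points = ncol(X))
  model
}

# forward in chunks to bound memory; returns batch x n_classes probabilities
net_predict_matrix <- function(net, X, chunk = 256L) {
  out <- matrix(NA_real_, nrow(X), net$n_classes)
  for (s in seq.int(1L, nrow(X), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(X))
    fwd <- nn_forward(net, X[idx, , drop = FALSE])
    out[idx, ] <- softmax_rows(fwd$logits)
  }
  out
}

#' Predict quality probabilities or classes
#'
#' @param object A fitted `qc_model`.
#' @param newdata Preprocessed spectra matrix or [qc_cohort].
#' @param type `"prob"` for a (voxels x 2) probability matrix with columns
#'   `good`, `bad` (rows sum to 1), or `"class"` for argmax labels.
#' @param ... Unused.
#' @return Matrix of probabilities or character vector of classes.
#' @export
predict.qc_model <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained))
    stop("model has not been fitted; call qc_fit() first")
  X <- if (inherits(newdata, "qc_cohort")) newdata$spectra
       else as.matrix(newdata)
  check_input_length(object, X)
  p <- predict_prob_matrix(object, X)
  colnames(p) <- object$classes
  rownames(p) <- rownames(X)
  if (type == "prob") p
  else object$classes[max.col(p, ties.method = "first")]
}

predict_prob_matrix <- function(object, X) UseMethod("predict_prob_matrix")

#' @export
predict_prob_matrix.qc_rf <- function(object, X) {
  p <- stats::predict(object$forest, with_feature_names(X), type = "prob")
  p[, .qc_classes, drop = FALSE]
}

#' @export
predict_prob_matrix.qc_net <- function(object, X) {
  net_predict_matrix(object$net, X)
}

#' @export
predict_prob_matrix.qc_hybrid <- function(object, X) {
  feats <- extract_penultimate_features(object$base, X)
  p <- stats::predict(object$forest, with_feature_names(feats),
                      type = "prob")
  p[, .qc_classes, drop = FALSE]
}

#' Extract 64-node penultimate deep features
#'
#' Forwards spectra through a trained network and returns the activations of
#' the 64-node layer immediately before the output layer — the features the
#' hybrid models feed to their random forest.
#'
#' @param model A trained `qc_cnn` or `qc_icnn`.
#' @param spectra Preprocessed spectra matrix or [qc_cohort].
#' @return Numeric matrix (voxels x 64).
#' @export
extract_penultimate_features <- function(model, spectra) {
  if (!inherits(model, "qc_net"))
    stop("penultimate features exist only for network models (cnn/icnn), ",
         "not ", class(model)[1L])
  if (!isTRUE(model$trained))
    stop("model has not been fitted; call qc_fit() first")
  X <- if (inherits(spectra, "qc_cohort")) spectra$spectra
       else as.matrix(spectra)
  check_input_length(model, X)
  out <- matrix(NA_real_, nrow(X), model$spec$penultimate_width)
  for (s in seq.int(1L, nrow(X), by = 256L)) {
    idx <- s:min(s + 255L, nrow(X))
    fwd <- nn_forward(model$net, X[idx, , drop = FALSE])
    out[idx, ] <- fwd$penult
  }
  out
}

#' Assemble a hybrid deep-feature random forest
#'
#' Fits a 200-tree random forest (per-split feature subsample
#' `floor(sqrt(64))` = 8) on the penultimate features of an already-trained
#' network; the hybrid's predictions are the forest's probabilities on
#' extracted features.
#'
#' @param trained_net A trained `qc_cnn` or `qc_icnn`.
#' @param x Training spectra (matrix or preprocessed [qc_cohort]).
#' @param y Labels; from cohort consensus if omitted.
#' @param seed RF bootstrap seed.
#' @param rf_spec Optional [model_spec] overriding tree count.
#' @return A fitted `qc_hybrid` model.
#' @export
build_hybrid <- function(trained_net, x, y = NULL, seed = 1L,
                         rf_spec = NULL) {
  if (!inherits(trained_net, "qc_net") || !isTRUE(trained_net$trained))
    stop("build_hybrid needs a trained cnn/icnn base network")
  xy <- resolve_xy(x, y)
  feats <- extract_penultimate_features(trained_net, xy$X)
  n_trees <- if (is.null(rf_spec)) trained_net$spec$rf_n_estimators
             else rf_spec$rf_n_estimators
  mtry <- floor(sqrt(ncol(feats)))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = with_feature_names(feats), y = factor(xy$y, levels = .qc_classes),
    ntree = n_trees, mtry = mtry)
  spec <- trained_net$spec
  spec$kind <- paste0(trained_net$kind, "_rf")
  structure(list(spec = spec, kind = spec$kind, trained = TRUE,
                 classes = .qc_classes, base = trained_net, forest = forest,
                 rf_mtry = mtry,
                 fingerprint = trained_net$fingerprint, seed = seed),
            class = c("qc_hybrid", "qc_model"))
}

#' Layer census of a model
#'
#' Counts the structural elements the architecture contracts are stated in:
#' convolution layers, inception modules, fully connected layers,
#' penultimate width, tree count.
#'
#' @param model A `qc_model` (trained or untrained).
#' @return Named list of counts.
#' @export
layer_census <- function(model) {
  stopifnot(inherits(model, "qc_model"))
  out <- list(kind = model$kind)
  if (inherits(model, "qc_net")) {
    types <- vapply(model$net$layers, function(l) l$type, character(1L))
    dense_widths <- vapply(model$net$layers[types == "dense"],
                           function(l) l$f_out, integer(1L))
    out$conv_layers <- sum(types == "conv")
    out$inception_modules <- sum(types == "inception")
    # the final dense layer is the softmax head, not a hidden FC layer
    out$fc_layers <- length(dense_widths) - 1L
    out$penultimate_width <- dense_widths[length(dense_widths) - 1L]
    out$output_classes <- dense_widths[length(dense_widths)]
  }
  if (inherits(model, "qc_rf")) {
    out$n_trees <- if (is.null(model$forest)) model$spec$rf_n_estimators
                   else model$forest$ntree
    out$mtry <- if (is.null(model$forest)) model$spec$rf_max_features
                else model$forest$mtry
  }
  if (inherits(model, "qc_hybrid")) {
    out$n_trees <- model$forest$ntree
    out$rf_input_features <- nrow(model$forest$importance)
    out$base <- layer_census(model$base)
  }
  out
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf("<%s> %s model, %s\n", class(x)[1L], x$kind,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  print(x$spec)
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs; final train loss %.4f acc %.3f%s\n",
                nrow(x$history), last$train_loss, last$train_acc,
                if (!is.na(last$val_acc))
                  sprintf(", val loss %.4f acc %.3f",
                          last$val_loss, last$val_acc) else ""))
  }
  invisible(x)
}

#' @export
summary.qc_model <- function(object, ...) {
  census <- layer_census(object)
  cat("Layer census:\n")
  utils::str(census, give.attr = FALSE)
  invisible(census)
}

#' Plot network training curves
#'
#' Loss and accuracy per epoch for the training and (if recorded)
#' validation sets.
#'
#' @param x A trained `qc_cnn`/`qc_icnn` (or hybrid whose base recorded
#'   curves).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.qc_net <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("blue", "darkgreen"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("blue", "darkgreen"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("blue", "darkgreen"),
                    xlab = "epoch", ylab = "accuracy", ...)
  invisible(h)
}

#' @export
plot.qc_hybrid <- function(x, ...) plot.qc_net(x$base, ...)

#' Save / load a fitted model archive
#'
#' The archive is self-describing: `path` holds the parameter payload (RDS)
#' and `<path>.json` a JSON rendering of the [model_spec].
#'
#' @param model A fitted `qc_model`.
#' @param path Archive path.
#' @return `path` (save) or the restored `qc_model` (load).
#' @export
save_qc_model <- function(model, path) {
  stopifnot(inherits(model, "qc_model"))
  saveRDS(model, path)
  jsonlite::write_json(model$spec[setdiff(names(model$spec), "")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_qc_model
#' @export
load_qc_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "qc_model")) stop("not a qc_model archive: ", path)
  model
}
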