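#' A single voxel spectrum with metadata
#'
#' One spatial voxel of an MRSI acquisition: an intensity per axis point
#' (real or complex, arbitrary units) plus the subject it came from, whether
#' the voxel overlaps a T2-hyperintense lesion, and the cohort type of the
#' subject.
#'
#' @param intensities Numeric or complex vector, one value per axis point.
#' @param axis A [spectral_axis] of matching length.
#' @param subject_id Non-empty character scalar identifying the subject.
#' @param lesion_flag Logical: does the voxel overlap the T2L region?
#' @param cohort_tag One of `"healthy"`, `"MDD"`, `"MS"`, `"PD"`, `"tumor"`.
#' @return An object of class `voxel_spectrum`.
#' @export
voxel_spectrum <- function(intensities, axis, subject_id,
                           lesion_flag = FALSE, cohort_tag = "healthy") {
  stopifnot(inherits(axis, "spectral_axis"))
  if (length(intensities) != axis$n_points)
    stop("intensities length (", length(intensities),
         ") does not match axis length (", axis$n_points, ")")
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id))
    stop("subject_id must be a single non-empty string")
  cohort_tag <- match.arg(cohort_tag, c("healthy", "MDD", "MS", "PD", "tumor"))
  structure(list(intensities = intensities, axis = axis,
                 subject_id = subject_id,
                 lesion_flag = isTRUE(lesion_flag),
                 cohort_tag = cohort_tag),
            class = "voxel_spectrum")
}

#' @export
print.voxel_spectrum <- function(x, ...) {
  cat(sprintf("<voxel_spectrum> subject %s (%s%s), %d points [%.3g, %.3g] ppm, %s\n",
              x$subject_id, x$cohort_tag,
              if (x$lesion_flag) ", T2L" else "",
              x$axis$n_points, x$axis$ppm[1L], x$axis$ppm[x$axis$n_points],
              if (is.complex(x$intensities)) "complex" else "real"))
  invisible(x)
}

#' Two-rater quality verdicts with consensus
#'
#' Stores per-rater good/bad verdicts and the consensus derived with
#' [aggregate_labels()]: a voxel is "good" only when both raters call it good.
#'
#' @param rater_a,rater_b `"good"` or `"bad"`.
#' @return An object of class `qc_label` with fields `rater_a`, `rater_b`,
#'   `consensus`.
#' @export
qc_label <- function(rater_a, rater_b) {
  consensus <- aggregate_labels(rater_a, rater_b)
  structure(list(rater_a = match.arg(rater_a, c("good", "bad")),
                 rater_b = match.arg(rater_b, c("good", "bad")),
                 consensus = consensus),
            class = "qc_label")
}

#' Construct a labeled spectral cohort
#'
#' A `qc_cohort` is the subject-grouped collection of labeled voxel spectra
#' that the classifiers train and evaluate on. All spectra share one axis;
#' every voxel carries per-rater and consensus quality labels.
#'
#' @param spectra Numeric or complex matrix, one row per voxel, one column per
#'   axis point.
#' @param axis A [spectral_axis] with `ncol(spectra)` points.
#' @param manifest Data frame with one row per voxel and columns `voxel_id`,
#'   `subject_id`, `cohort_tag`, `lesion_flag`, `rater_a`, `rater_b`,
#'   `consensus`. `consensus` must equal the two-rater AND rule.
#' @return An object of class `qc_cohort`.
#' @seealso [generate_cohort()], [read_cohort()], [write_cohort()]
#' @export
qc_cohort <- function(spectra, axis, manifest) {
  stopifnot(inherits(axis, "spectral_axis"))
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != axis$n_points)
    stop("spectra have ", ncol(spectra), " columns but axis has ",
         axis$n_points, " points")
  required <- c("voxel_id", "subject_id", "cohort_tag", "lesion_flag",
                "rater_a", "rater_b", "consensus")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(manifest) != nrow(spectra))
    stop("manifest has ", nrow(manifest), " rows but spectra have ",
         nrow(spectra))
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  manifest$voxel_id <- as.character(manifest$voxel_id)
  manifest$subject_id <- as.character(manifest$subject_id)
  manifest$lesion_flag <- as.logical(manifest$lesion_flag)
  for (col in c("rater_a", "rater_b", "consensus")) {
    bad <- !manifest[[col]] %in% c("good", "bad")
    if (any(bad))
      stop("manifest column '", col, "' contains values other than good/bad")
  }
  expected <- aggregate_labels(manifest$rater_a, manifest$rater_b)
  if (!identical(expected, manifest$consensus))
    stop("manifest column 'consensus' violates the two-rater AND rule")
  if (any(is.na(manifest$subject_id) | !nzchar(manifest$subject_id)))
    stop("manifest column 'subject_id' has empty entries")
  rownames(spectra) <- manifest$voxel_id
  structure(list(spectra = spectra, axis = axis, manifest = manifest),
            class = "qc_cohort")
}

#' @export
print.qc_cohort <- function(x, ...) {
  n <- nrow(x$spectra)
  subj <- unique(x$manifest$subject_id)
  good <- sum(x$manifest$consensus == "good")
  cat(sprintf("<qc_cohort> %d voxels from %d subjects, %d axis points\n",
              n, length(subj), x$axis$n_points))
  cat(sprintf("  consensus labels: %d good / %d bad (%.0f:%.0f)\n",
              good, n - good, 100 * good / n, 100 * (n - good) / n))
  tags <- table(x$manifest$cohort_tag[!duplicated(x$manifest$subject_id)])
  cat("  subjects per cohort tag: ",
      paste(names(tags), tags, sep = "=", collapse = ", "), "\n", sep = "")
  if (any(x$manifest$lesion_flag))
    cat(sprintf("  lesion (T2L) voxels: %d\n", sum(x$manifest$lesion_flag)))
  invisible(x)
}

#' @export
summary.qc_cohort <- function(object, ...) {
  m <- object$manifest
  by_subj <- table(m$subject_id)
  out <- list(
    n_voxels = nrow(m),
    n_subjects = length(by_subj),
    voxels_per_subject = as.vector(by_subj),
    n_good = sum(m$consensus == "good"),
    n_bad = sum(m$consensus == "bad"),
    n_lesion = sum(m$lesion_flag),
    rater_disagreement = mean(m$rater_a != m$rater_b)
  )
  class(out) <- "summary.qc_cohort"
  out
}

#' @export
print.summary.qc_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d voxels / %d subjects\n", x$n_voxels, x$n_subjects))
  cat(sprintf("  good:bad = %d:%d (%.1f%% bad)\n", x$n_good, x$n_bad,
              100 * x$n_bad / x$n_voxels))
  cat(sprintf("  rater disagreement rate: %.3f\n", x$rater_disagreement))
  if (x$n_lesion > 0) cat(sprintf("  T2L voxels: %d\n", x$n_lesion))
  invisible(x)
}

#' Subjects of a cohort
#' @param cohort A [qc_cohort].
#' @return Character vector of unique subject ids, in first-appearance order.
#' @export
cohort_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "qc_cohort"))
  unique(cohort$manifest$subject_id)
}

#' Subset a cohort by voxel or by subject
#'
#' @param cohort A [qc_cohort].
#' @param voxels Optional logical/integer index over voxels.
#' @param subjects Optional character vector of subject ids to keep.
#' @return A [qc_cohort] restricted to the selection.
#' @export
cohort_subset <- function(cohort, voxels = NULL, subjects = NULL) {
  stopifnot(inherits(cohort, "qc_cohort"))
  keep <- rep(TRUE, nrow(cohort$spectra))
  if (!is.null(subjects))
    keep <- keep & cohort$manifest$subject_id %in% subjects
  if (!is.null(voxels)) {
    sel <- rep(FALSE, length(keep))
    sel[voxels] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) stop("cohort subset selects no voxels")
  qc_cohort(cohort$spectra[keep, , drop = FALSE], cohort$axis,
            cohort$manifest[keep, , drop = FALSE])
}

#' Extract one voxel as a voxel_spectrum
#' @param cohort A [qc_cohort].
#' @param i Voxel row index or voxel_id string.
#' @return A [voxel_spectrum].
#' @export
cohort_voxel <- function(cohort, i) {
  stopifnot(inherits(cohort, "qc_cohort"))
  if (is.character(i)) i <- match(i, cohort$manifest$voxel_id)
  if (is.na(i) || i < 1L || i > nrow(cohort$spectra))
    stop("voxel index out of range")
  m <- cohort$manifest[i, ]
  voxel_spectrum(cohort$spectra[i, ], cohort$axis, m$subject_id,
                 m$lesion_flag, m$cohort_tag)
}
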