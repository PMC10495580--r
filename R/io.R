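#' Write a cohort to disk
#'
#' Two container backends are supported:
#' \describe{
#'   \item{HDF5}{`path` ending in `.h5`/`.hdf5` (requires the `rhdf5`
#'     package): datasets `/spectra` (n_voxels x n_points; for complex input,
#'     `/spectra_real` and `/spectra_imag`) and `/ppm` (n_points), plus a CSV
#'     manifest written next to the container (`<path>.csv` with the
#'     extension swapped) with columns `voxel_id`, `subject_id`,
#'     `cohort_tag`, `lesion_flag`, `rater_a`, `rater_b`, `consensus`.}
#'   \item{text}{any other `path` is treated as a directory holding
#'     `manifest.csv`, `ppm.txt` and `spectra.txt` (plus `spectra_imag.txt`
#'     for complex data), numbers serialized with 17 significant digits so a
#'     write/read round-trip is bit-exact.}
#' }
#'
#' @param cohort A [qc_cohort].
#' @param path Output path (`.h5` file or directory).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "qc_cohort"))
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    write_cohort_h5(cohort, path)
  } else {
    write_cohort_text(cohort, path)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]; accepts either container backend and
#' validates the manifest schema, failing with the name of any offending
#' field.
#'
#' @param path A `.h5` container or a text-container directory.
#' @return A [qc_cohort].
#' @export
read_cohort <- function(path) {
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    read_cohort_h5(path)
  } else {
    read_cohort_text(path)
  }
}

manifest_path_for_h5 <- function(path) sub("\\.h5$|\\.hdf5$", ".csv", path,
                                           ignore.case = TRUE)

write_cohort_h5 <- function(cohort, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the HDF5 backend needs the 'rhdf5' package; ",
         "use a directory path for the plain-text container instead")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (is.complex(cohort$spectra)) {
    rhdf5::h5write(Re(cohort$spectra), path, "spectra_real")
    rhdf5::h5write(Im(cohort$spectra), path, "spectra_imag")
  } else {
    rhdf5::h5write(cohort$spectra, path, "spectra")
  }
  rhdf5::h5write(cohort$axis$ppm, path, "ppm")
  rhdf5::h5closeAll()
  utils::write.csv(cohort$manifest, manifest_path_for_h5(path),
                   row.names = FALSE)
  invisible(path)
}

read_cohort_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading an HDF5 cohort needs the 'rhdf5' package")
  if (!file.exists(path)) stop("no such cohort container: ", path)
  contents <- rhdf5::h5ls(path)$name
  if ("spectra" %in% contents) {
    spectra <- rhdf5::h5read(path, "spectra")
  } else if (all(c("spectra_real", "spectra_imag") %in% contents)) {
    spectra <- complex(real = rhdf5::h5read(path, "spectra_real"),
                       imaginary = rhdf5::h5read(path, "spectra_imag"))
    dim(spectra) <- dim(rhdf5::h5read(path, "spectra_real"))
  } else {
    stop("HDF5 container lacks a 'spectra' dataset")
  }
  ppm <- as.numeric(rhdf5::h5read(path, "ppm"))
  rhdf5::h5closeAll()
  manifest <- read_manifest(manifest_path_for_h5(path))
  qc_cohort(spectra, spectral_axis(ppm), manifest)
}

# 17 significant digits round-trips IEEE doubles exactly through text
fmt_full <- function(x) sprintf("%.17g", x)

write_num_table <- function(m, path) {
  txt <- apply(m, 1L, function(row) paste(fmt_full(row), collapse = "\t"))
  writeLines(txt, path)
}

read_num_table <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

write_cohort_text <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  writeLines(fmt_full(cohort$axis$ppm), file.path(path, "ppm.txt"))
  if (is.complex(cohort$spectra)) {
    write_num_table(Re(cohort$spectra), file.path(path, "spectra.txt"))
    write_num_table(Im(cohort$spectra), file.path(path, "spectra_imag.txt"))
  } else {
    write_num_table(cohort$spectra, file.path(path, "spectra.txt"))
    imag <- file.path(path, "spectra_imag.txt")
    if (file.exists(imag)) unlink(imag)
  }
  invisible(path)
}

read_cohort_text <- function(path) {
  if (!dir.exists(path)) stop("no such cohort directory: ", path)
  manifest <- read_manifest(file.path(path, "manifest.csv"))
  ppm <- as.numeric(readLines(file.path(path, "ppm.txt")))
  spectra <- read_num_table(file.path(path, "spectra.txt"))
  imag_path <- file.path(path, "spectra_imag.txt")
  if (file.exists(imag_path)) {
    im <- read_num_table(imag_path)
    spectra <- matrix(complex(real = spectra, imaginary = im),
                      nrow = nrow(spectra))
  }
  qc_cohort(spectra, spectral_axis(ppm), manifest)
}

read_manifest <- function(path) {
  if (!file.exists(path)) stop("cohort manifest not found: ", path)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  required <- c("voxel_id", "subject_id", "cohort_tag", "lesion_flag",
                "rater_a", "rater_b", "consensus")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  manifest$lesion_flag <- as.logical(manifest$lesion_flag)
  manifest
}
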