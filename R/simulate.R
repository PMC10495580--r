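#' Metabolite peak description
#'
#' One Lorentzian resonance: center (ppm), amplitude (relative units) and
#' full width at half maximum (ppm).
#'
#' @param name Metabolite label.
#' @param center Chemical shift of the peak maximum, ppm.
#' @param amplitude Peak height at the center, relative units, >= 0.
#' @param fwhm Full width at half maximum, ppm, > 0.
#' @return An object of class `metabolite_peak`.
#' @export
metabolite_peak <- function(name, center, amplitude, fwhm) {
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  structure(list(name = as.character(name), center = center,
                 amplitude = amplitude, fwhm = fwhm),
            class = "metabolite_peak")
}

#' Default short-echo brain metabolite basis
#'
#' The dominant singlets of a short-echo brain spectrum in the 1.4-4.1 ppm
#' window: NAA (2.01 ppm), creatine CH3 (3.03) and CH2 (3.93), choline
#' (3.22), plus broad low-amplitude Glx (2.35) and myo-inositol (3.56)
#' contributions. Amplitudes are relative to NAA = 1.
#'
#' @return List of [metabolite_peak] objects.
#' @export
default_peaks <- function() {
  list(
    metabolite_peak("NAA", 2.01, 1.00, 0.035),
    metabolite_peak("Cr",  3.03, 0.80, 0.035),
    metabolite_peak("Cho", 3.22, 0.65, 0.035),
    metabolite_peak("Cr2", 3.93, 0.45, 0.040),
    metabolite_peak("Glx", 2.35, 0.25, 0.090),
    metabolite_peak("mI",  3.56, 0.30, 0.060)
  )
}

# Lorentzian with L(center) = amplitude and L(center +- fwhm/2) = amplitude/2
lorentzian <- function(x, center, amplitude, fwhm) {
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / ((x - center)^2 + hw2)
}

#' Simulate a clean (noise-free) metabolite spectrum
#'
#' Sums one Lorentzian lineshape per peak on the given axis. An empty peak
#' list yields a flat (all-zero) spectrum, allowed but degenerate: it will be
#' rejected later by z-normalization unless noise is added.
#'
#' @param peaks List of [metabolite_peak]s.
#' @param axis A [spectral_axis].
#' @param subject_id,lesion_flag,cohort_tag Metadata passed to
#'   [voxel_spectrum()].
#' @return A [voxel_spectrum] with real intensities.
#' @export
simulate_clean_spectrum <- function(peaks, axis, subject_id = "sim",
                                    lesion_flag = FALSE,
                                    cohort_tag = "healthy") {
  stopifnot(inherits(axis, "spectral_axis"))
  y <- numeric(axis$n_points)
  for (p in peaks) {
    stopifnot(inherits(p, "metabolite_peak"))
    y <- y + lorentzian(axis$ppm, p$center, p$amplitude, p$fwhm)
  }
  voxel_spectrum(y, axis, subject_id, lesion_flag, cohort_tag)
}

#' Artifact severity profile for one voxel
#'
#' The five artifact knobs the simulator layers onto a clean spectrum:
#' lipid contamination amplitude, residual-water baseline amplitude,
#' multiplicative linewidth broadening, frequency shift, and additive noise
#' scale.
#'
#' @param lipid_amplitude Height of the broad 1.3-ppm lipid resonance,
#'   relative units, >= 0.
#' @param water_tail_amplitude Height scale of the residual 4.7-ppm water
#'   tail entering at the 4.1 ppm edge, >= 0.
#' @param broadening_factor Multiplicative FWHM scale, >= 1 (1 = no
#'   broadening).
#' @param freq_shift Frequency offset, ppm (circular axis shift).
#' @param noise_sigma Additive Gaussian noise standard deviation, > 0 for
#'   usable spectra.
#' @return An object of class `artifact_profile`.
#' @export
artifact_profile <- function(lipid_amplitude = 0, water_tail_amplitude = 0,
                             broadening_factor = 1, freq_shift = 0,
                             noise_sigma = 0.01) {
  if (lipid_amplitude < 0 || water_tail_amplitude < 0)
    stop("artifact amplitudes must be >= 0")
  if (broadening_factor < 1) stop("broadening_factor must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(lipid_amplitude = lipid_amplitude,
                 water_tail_amplitude = water_tail_amplitude,
                 broadening_factor = broadening_factor,
                 freq_shift = freq_shift,
                 noise_sigma = noise_sigma),
            class = "artifact_profile")
}

# physical ranges spanned as severity runs 0 -> 1; the linewidth reference is
# the nominal singlet FWHM of the clean basis
.sim_const <- list(
  noise_lo = 0.01, noise_hi = 0.15,
  broaden_hi = 3.5,
  lipid_hi = 2.2,
  water_hi = 1.8,
  ref_fwhm = 0.035,
  lipid_center = 1.3, lipid_fwhm = 0.30,
  water_center = 4.7, water_fwhm = 0.60,
  rater_band = 0.10,
  lesion_fraction = 0.195
)

severity_to_profile <- function(s_noise, s_broad, s_lipid, s_water,
                                freq_shift = 0) {
  k <- .sim_const
  artifact_profile(
    lipid_amplitude = k$lipid_hi * s_lipid,
    water_tail_amplitude = k$water_hi * s_water,
    broadening_factor = 1 + (k$broaden_hi - 1) * s_broad,
    freq_shift = freq_shift,
    noise_sigma = k$noise_lo + (k$noise_hi - k$noise_lo) * s_noise
  )
}

profile_severities <- function(profile) {
  k <- .sim_const
  c(noise = (profile$noise_sigma - k$noise_lo) / (k$noise_hi - k$noise_lo),
    broadening = (profile$broadening_factor - 1) / (k$broaden_hi - 1),
    lipid = profile$lipid_amplitude / k$lipid_hi,
    water = profile$water_tail_amplitude / k$water_hi)
}

#' Scalar artifact-severity score
#'
#' The worst (maximum) of the four normalized criterion severities implied by
#' an artifact profile: noise level (inverse SNR), linewidth broadening,
#' lipid-contamination ratio and residual-water ratio, each mapped linearly
#' onto \[0, 1\] over its simulated range. The simulator's ground-truth rule
#' is a threshold on this score.
#'
#' @param x An [artifact_profile], or a simulated [qc_cohort] whose manifest
#'   carries the per-voxel profile columns.
#' @return Numeric score (vector, for a cohort).
#' @export
severity_score <- function(x) UseMethod("severity_score")

#' @export
severity_score.artifact_profile <- function(x) max(profile_severities(x))

#' @export
severity_score.qc_cohort <- function(x) {
  m <- x$manifest
  need <- c("noise_sigma", "broadening_factor", "lipid_amplitude",
            "water_tail_amplitude")
  if (!all(need %in% names(m)))
    stop("cohort manifest lacks simulated artifact-profile columns")
  k <- .sim_const
  pmax((as.numeric(m$noise_sigma) - k$noise_lo) / (k$noise_hi - k$noise_lo),
       (as.numeric(m$broadening_factor) - 1) / (k$broaden_hi - 1),
       as.numeric(m$lipid_amplitude) / k$lipid_hi,
       as.numeric(m$water_tail_amplitude) / k$water_hi)
}

#' Quality thresholds in physical units
#'
#' Converts one severity cut into the four per-criterion physical thresholds
#' a rater applies: minimum SNR (NAA-referenced), maximum linewidth
#' broadening factor, maximum lipid amplitude, maximum residual-water
#' amplitude.
#'
#' @param severity Severity cut in \[0, 1\]; a voxel is bad when any
#'   normalized criterion severity exceeds it.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(severity = 0.5) {
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop("severity cut must lie in [0, 1]")
  k <- .sim_const
  sigma_max <- k$noise_lo + (k$noise_hi - k$noise_lo) * severity
  structure(list(
    severity = severity,
    snr_min = 1 / sigma_max,            # unit-amplitude NAA reference
    broadening_max = 1 + (k$broaden_hi - 1) * severity,
    lipid_max = k$lipid_hi * severity,
    water_max = k$water_hi * severity
  ), class = "qc_thresholds")
}

# verdict with near-threshold rater jitter: the flip probability decays
# linearly from `noise` at the cut to 0 outside the band
jittered_verdict <- function(s, cut, noise) {
  verdict <- if (s > cut) "bad" else "good"
  flip_p <- noise * max(0, 1 - abs(s - cut) / .sim_const$rater_band)
  if (flip_p > 0 && stats::runif(1L) < flip_p)
    verdict <- if (verdict == "bad") "good" else "bad"
  verdict
}

#' Ground-truth label and simulated rater verdicts for a profile
#'
#' The simulator's labeling rule: a voxel is truly "bad" iff any of the four
#' artifact criteria (SNR, linewidth, lipid ratio, water-tail ratio) exceeds
#' its threshold. Two simulated raters apply the same thresholds; each flips
#' near-threshold verdicts independently with probability up to
#' `rater_noise`. The consensus follows [aggregate_labels()].
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param profile An [artifact_profile].
#' @param thresholds A [qc_thresholds].
#' @param rater_noise Maximum verdict-flip probability at the threshold.
#' @return List with `truth`, `rater_a`, `rater_b`, `consensus`.
#' @export
assign_truth_label <- function(profile, thresholds = qc_thresholds(),
                               rater_noise = 0) {
  stopifnot(inherits(profile, "artifact_profile"),
            inherits(thresholds, "qc_thresholds"))
  s <- severity_score(profile)
  cut <- thresholds$severity
  truth <- if (s > cut) "bad" else "good"
  a <- jittered_verdict(s, cut, rater_noise)
  b <- jittered_verdict(s, cut, rater_noise)
  list(truth = truth, rater_a = a, rater_b = b,
       consensus = aggregate_labels(a, b))
}

# circular shift of a vector by k indices (k > 0 moves content up-field)
roll_vec <- function(y, k) {
  n <- length(y)
  k <- ((k %% n) + n) %% n
  if (k == 0) y else c(y[(n - k + 1L):n], y[1L:(n - k)])
}

# area-preserving discrete Lorentzian smoothing kernel; fwhm in ppm
lorentz_kernel <- function(step, fwhm) {
  half <- max(1L, ceiling(4 * fwhm / step))
  x <- (-half:half) * step
  k <- lorentzian(x, 0, 1, fwhm)
  k / sum(k)
}

conv_same <- function(y, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  full <- stats::convolve(y, rev(kernel), type = "open")
  full[(half + 1L):(half + length(y))]
}

#' Inject acquisition artifacts into a clean spectrum
#'
#' Applies, in order: circular frequency shift, Lorentzian linewidth
#' broadening (convolution with an area-preserving kernel whose FWHM is
#' `(broadening_factor - 1)` times the nominal singlet linewidth, so final
#' linewidths scale by `broadening_factor`), lipid contamination (broad
#' resonance at 1.3 ppm truncated into the window at the 1.4 ppm edge),
#' residual-water baseline (the down-field tail of the 4.7 ppm water line
#' entering at the 4.1 ppm edge), and additive Gaussian noise.
#'
#' Deterministic given the RNG state; seed beforehand for reproducibility.
#'
#' @param spectrum A clean [voxel_spectrum] on the analysis axis.
#' @param profile An [artifact_profile].
#' @return The contaminated [voxel_spectrum].
#' @export
inject_artifacts <- function(spectrum, profile) {
  stopifnot(inherits(spectrum, "voxel_spectrum"),
            inherits(profile, "artifact_profile"))
  k <- .sim_const
  y <- spectrum$intensities
  ppm <- spectrum$axis$ppm
  step <- axis_step(spectrum$axis)
  shift_idx <- round(profile$freq_shift / step)
  if (shift_idx != 0) y <- roll_vec(y, shift_idx)
  if (profile$broadening_factor > 1) {
    kern_fwhm <- (profile$broadening_factor - 1) * k$ref_fwhm
    y <- conv_same(y, lorentz_kernel(step, kern_fwhm))
  }
  if (profile$lipid_amplitude > 0)
    y <- y + lorentzian(ppm, k$lipid_center, profile$lipid_amplitude,
                        k$lipid_fwhm)
  if (profile$water_tail_amplitude > 0)
    y <- y + lorentzian(ppm, k$water_center, profile$water_tail_amplitude,
                        k$water_fwhm)
  if (profile$noise_sigma > 0)
    y <- y + stats::rnorm(length(y), 0, profile$noise_sigma)
  spectrum$intensities <- y
  spectrum
}

#' Simulation configuration
#'
#' Defaults emulate the aggregated neurological-disease cohort: 40 subjects
#' (10 each of healthy, MDD, MS, PD), roughly 419 voxels per subject and a
#' 46% bad fraction. For a brain-tumor-style cohort set `tumor_mode = TRUE`,
#' `n_subjects = 13` and `fraction_bad = 0.29`.
#'
#' @param n_subjects Number of subjects.
#' @param voxels_per_subject Scalar count, or length-2 range sampled
#'   uniformly per subject.
#' @param fraction_bad Target proportion of consensus-"bad" voxels.
#' @param severity_separation In \[0, 1\]: 1 gives classes cleanly separable
#'   by the severity score; 0 makes labels independent of the artifact
#'   profile (pure label noise).
#' @param rater_noise Near-threshold verdict flip probability per rater.
#' @param tumor_mode Logical; tumor-tagged subjects with a T2L lesion
#'   fraction whose lesion voxels have suppressed NAA and elevated choline.
#' @param seed Integer master seed; subject-level seeds are derived from it
#'   so cohorts are bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 40L, voxels_per_subject = 419L,
                       fraction_bad = 0.46, severity_separation = 0.9,
                       rater_noise = 0.1, tumor_mode = FALSE, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  if (!all(is.finite(voxels_per_subject)) || any(voxels_per_subject < 1))
    stop("voxels_per_subject must be positive")
  if (length(voxels_per_subject) > 2L)
    stop("voxels_per_subject must be a count or a length-2 range")
  if (!is.finite(fraction_bad) || fraction_bad < 0 || fraction_bad > 1)
    stop("fraction_bad must lie in [0, 1]")
  if (severity_separation < 0 || severity_separation > 1)
    stop("severity_separation must lie in [0, 1]")
  if (rater_noise < 0 || rater_noise > 1)
    stop("rater_noise must lie in [0, 1]")
  structure(list(n_subjects = n_subjects,
                 voxels_per_subject = as.integer(voxels_per_subject),
                 fraction_bad = fraction_bad,
                 severity_separation = severity_separation,
                 rater_noise = rater_noise,
                 tumor_mode = isTRUE(tumor_mode),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw a latent severity consistent with the intended class; the class gap
# grows with separation so that separation = 1 leaves a clean margin around
# the cut
draw_severity <- function(bad, cut, separation) {
  gap <- 0.15 * separation
  if (bad) stats::runif(1L, min(cut + gap, 0.999), 1)
  else stats::runif(1L, 0, max(cut - gap, 0.001))
}

#' Generate a labeled synthetic cohort
#'
#' Builds a subject-grouped cohort on the canonical 850-point axis. Each
#' voxel draws an intended class (Bernoulli `fraction_bad`) and a latent
#' artifact severity consistent with it; the worst-affected criterion gets
#' the full severity and the others a random fraction of it, artifacts are
#' injected accordingly, and two simulated raters judge a *perceived*
#' severity that equals the true one with probability `severity_separation`
#' (else an independent redraw), so separation 1 gives threshold-separable
#' classes and separation 0 decouples labels from spectra while preserving
#' the target class balance.
#'
#' One master seed drives subject-level seeds, so identical configs give
#' bit-identical cohorts.
#'
#' @param cfg A [sim_config].
#' @param peaks Metabolite basis, default [default_peaks()].
#' @return A [qc_cohort] whose manifest also records the per-voxel artifact
#'   profile and latent severity.
#' @export
generate_cohort <- function(cfg = sim_config(), peaks = default_peaks()) {
  stopifnot(inherits(cfg, "sim_config"))
  axis <- canonical_axis()
  cut <- 1 - cfg$fraction_bad
  tags <- if (cfg$tumor_mode) rep("tumor", cfg$n_subjects)
          else rep(c("healthy", "MDD", "MS", "PD"),
                   length.out = cfg$n_subjects)
  set.seed(cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)
  rows <- vector("list", cfg$n_subjects)
  mats <- vector("list", cfg$n_subjects)
  for (si in seq_len(cfg$n_subjects)) {
    set.seed(subj_seeds[si])
    subj <- sprintf("S%03d", si)
    nv <- if (length(cfg$voxels_per_subject) == 2L)
      sample(cfg$voxels_per_subject[1L]:cfg$voxels_per_subject[2L], 1L)
    else cfg$voxels_per_subject
    mat <- matrix(0, nrow = nv, ncol = axis$n_points)
    man <- vector("list", nv)
    for (vi in seq_len(nv)) {
      intended_bad <- stats::runif(1L) < cfg$fraction_bad
      s_true <- draw_severity(intended_bad, cut, cfg$severity_separation)
      perceived <- if (stats::runif(1L) < cfg$severity_separation) s_true
                   else draw_severity(stats::runif(1L) < cfg$fraction_bad,
                                      cut, cfg$severity_separation)
      sub <- s_true * stats::runif(4L, 0, 0.8)
      sub[sample.int(4L, 1L)] <- s_true            # dominant criterion
      freq_shift <- max(-0.15, min(0.15,
        stats::rnorm(1L, 0, 0.005 + 0.03 * s_true)))
      profile <- severity_to_profile(sub[1L], sub[2L], sub[3L], sub[4L],
                                     freq_shift)
      lesion <- cfg$tumor_mode &&
        stats::runif(1L) < .sim_const$lesion_fraction
      vox_peaks <- lapply(peaks, function(p) {
        amp <- p$amplitude * exp(stats::rnorm(1L, 0, 0.08))
        if (lesion) {
          if (p$name == "NAA") amp <- amp * 0.35
          if (p$name == "Cho") amp <- amp * 1.8
        }
        metabolite_peak(p$name, p$center, amp,
                        p$fwhm * stats::runif(1L, 0.9, 1.15))
      })
      clean <- simulate_clean_spectrum(vox_peaks, axis, subj, lesion,
                                       tags[si])
      dirty <- inject_artifacts(clean, profile)
      a <- jittered_verdict(perceived, cut, cfg$rater_noise)
      b <- jittered_verdict(perceived, cut, cfg$rater_noise)
      mat[vi, ] <- dirty$intensities
      man[[vi]] <- data.frame(
        voxel_id = sprintf("%s_v%04d", subj, vi),
        subject_id = subj, cohort_tag = tags[si], lesion_flag = lesion,
        rater_a = a, rater_b = b, consensus = aggregate_labels(a, b),
        severity = s_true,
        noise_sigma = profile$noise_sigma,
        broadening_factor = profile$broadening_factor,
        lipid_amplitude = profile$lipid_amplitude,
        water_tail_amplitude = profile$water_tail_amplitude,
        freq_shift = profile$freq_shift,
        stringsAsFactors = FALSE)
    }
    mats[[si]] <- mat
    rows[[si]] <- do.call(rbind, man)
  }
  qc_cohort(do.call(rbind, mats), axis, do.call(rbind, rows))
}
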