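#' Pipeline configuration
#'
#' Collects every tunable constant of the IRI modelling pipeline in one
#' validated list. Defaults are the published protocol where the protocol
#' states them (100 histogram bins to a 0.5 nm cutoff, 70 %MGS activity
#' threshold, L2 weight 0.005, 300 epochs, 10% validation fraction,
#' classification probability threshold 0.5, uncertainty cut at 15 %MGS,
#' Tanimoto 0.7 and logP 1.8 screening cuts) and documented package choices
#' elsewhere (the seven evenly spaced fixed hydration cutoffs, hydrogen-bond
#' geometry, shell-detection range and smoothing).
#'
#' @param histogram_bins Number of uniform bins of the hydration histogram.
#' @param histogram_cutoff_nm Distance cutoff \eqn{D_{cut}} of the hydration
#'   histogram (nm).
#' @param fixed_cutoffs_nm Seven fixed hydration-number cutoffs (nm) in
#'   \[0.20, 0.50\].
#' @param activity_threshold_mgs %MGS below which a compound is labelled
#'   active.
#' @param l2_sigma L2 (ridge) regularisation weight for network training.
#' @param max_epochs Maximum training epochs.
#' @param val_fraction Fraction of each training fold held out for early
#'   stopping.
#' @param classification_prob_threshold Probability above which the positive
#'   (active) class is predicted.
#' @param uncertainty_sd_max Screening predictions with ensemble SD above this
#'   (%MGS) are discarded.
#' @param tanimoto_min Library candidates must exceed this Tanimoto similarity
#'   to at least one activity seed.
#' @param logp_max Candidates with calculated logP above this are discarded
#'   (likely insoluble).
#' @param hbond_dist_max_nm,hbond_angle_max_deg Geometric hydrogen-bond
#'   criteria (donor-acceptor distance; hydrogen-donor-acceptor angle).
#' @param shell_detect_cutoff_nm Histogram range used for solvation-shell
#'   minima detection (wider than the descriptor histogram).
#' @param shell_smooth_window Moving-average window (bins) applied before
#'   minima detection.
#' @param n_conformations Number of evenly spaced frames sampled when
#'   averaging hydration quantities over a trajectory.
#' @param water_residues Residue names recognised as water in GRO files.
#' @param seed Integer seed from which all pipeline randomness derives.
#'
#' @return A named list of class `iri_config`.
#' @export
#' @examples
#' cfg <- iri_config()
#' cfg$histogram_cutoff_nm / cfg$histogram_bins  # bin width 0.005 nm
iri_config <- function(histogram_bins = 100,
                       histogram_cutoff_nm = 0.5,
                       fixed_cutoffs_nm = seq(0.20, 0.50, by = 0.05),
                       activity_threshold_mgs = 70,
                       l2_sigma = 0.005,
                       max_epochs = 300,
                       val_fraction = 0.10,
                       classification_prob_threshold = 0.5,
                       uncertainty_sd_max = 15,
                       tanimoto_min = 0.7,
                       logp_max = 1.8,
                       hbond_dist_max_nm = 0.35,
                       hbond_angle_max_deg = 30,
                       shell_detect_cutoff_nm = 0.8,
                       shell_smooth_window = 5,
                       n_conformations = 100,
                       water_residues = c("SOL", "HOH", "WAT", "TIP4"),
                       seed = 1L) {
  stopifnot(
    histogram_bins >= 1, histogram_cutoff_nm > 0,
    all(fixed_cutoffs_nm >= 0.20 - 1e-9), all(fixed_cutoffs_nm <= 0.50 + 1e-9),
    activity_threshold_mgs > 0,
    l2_sigma >= 0, max_epochs >= 1,
    val_fraction > 0, val_fraction < 1,
    classification_prob_threshold > 0, classification_prob_threshold < 1,
    uncertainty_sd_max > 0, tanimoto_min > 0, tanimoto_min <= 1,
    hbond_dist_max_nm > 0, hbond_angle_max_deg > 0,
    shell_detect_cutoff_nm > 0, shell_smooth_window >= 1,
    n_conformations >= 1
  )
  structure(list(
    histogram_bins = as.integer(histogram_bins),
    histogram_cutoff_nm = histogram_cutoff_nm,
    fixed_cutoffs_nm = fixed_cutoffs_nm,
    activity_threshold_mgs = activity_threshold_mgs,
    l2_sigma = l2_sigma,
    max_epochs = as.integer(max_epochs),
    val_fraction = val_fraction,
    classification_prob_threshold = classification_prob_threshold,
    uncertainty_sd_max = uncertainty_sd_max,
    tanimoto_min = tanimoto_min,
    logp_max = logp_max,
    hbond_dist_max_nm = hbond_dist_max_nm,
    hbond_angle_max_deg = hbond_angle_max_deg,
    shell_detect_cutoff_nm = shell_detect_cutoff_nm,
    shell_smooth_window = as.integer(shell_smooth_window),
    n_conformations = as.integer(n_conformations),
    water_residues = water_residues,
    seed = as.integer(seed)
  ), class = "iri_config")
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Vector values are comma-separated. Unknown keys are an
#' error; values override [iri_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return An `iri_config` list.
#' @export
read_iri_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  defaults <- iri_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(lapply(seq_along(keys), function(i) {
    parts <- trimws(strsplit(vals[i], ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  }), keys)
  do.call(iri_config, args)
}

# Derive a per-fold / per-model child seed from a global seed, kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %% 2147483647L)
}
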