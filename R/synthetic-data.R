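# Seed-deterministic generators for every input the pipeline consumes:
# QTOF-style sodiated MS/MS peak lists (ppm-scale Gaussian mass error,
# uniform decoy peaks, simple intensity model with the water-loss-dominance
# signature), Michaelis-Menten velocity datasets with multiplicative noise
# on the reported substrate grid, and positive-truncated-normal distance
# trajectories.

#' Simulate a metabolite MS/MS spectrum
#'
#' Renders [expected_peaks()] for a truth modification set with Gaussian
#' mass error in ppm, appends uniform decoy peaks (kept at least 10 ppm
#' away from every expected ion), and sets the precursor to the shifted
#' molecular ion. Fragment, molecular-ion and diagnostic peaks get the base
#' intensity; methanol-loss satellites half of it; water-loss satellites
#' `waterloss_factor` times it (the rule-R2 signature for C23/C24 truths).
#'
#' @param lib A `fragment_library`.
#' @param truth A `mod_set` (or string for [parse_mods()]).
#' @param ppm_sigma Gaussian mass-error scale in ppm (>= 0; default 2).
#' @param n_decoys Number of decoy peaks (default 20).
#' @param decoy_range m/z interval for decoys (default c(150, 1000)).
#' @param seed Integer seed (mandatory).
#' @param base_intensity Base peak intensity (arbitrary units, default 100).
#' @param waterloss_factor Intensity multiple for dominant water-loss
#'   satellites (default 1.5).
#' @param rules_on Satellite rules active in the forward model.
#' @param id Spectrum identifier.
#' @return A `spectrum`.
#' @export
simulate_spectrum <- function(lib, truth, ppm_sigma = 2, n_decoys = 20,
                              decoy_range = c(150, 1000), seed,
                              base_intensity = 100, waterloss_factor = 1.5,
                              rules_on = c("R1", "R2"), id = "") {
  if (missing(seed)) stop("seed is required")
  stopifnot(ppm_sigma >= 0, n_decoys >= 0)
  if (is.character(truth)) truth <- parse_mods(truth)
  exp <- expected_peaks(lib, truth, rules_on = rules_on)
  set.seed(seed)
  intensity <- ifelse(exp$kind == "satellite",
                      ifelse(exp$dominant_intensity,
                             waterloss_factor * base_intensity,
                             0.5 * base_intensity),
                      base_intensity)
  mz <- exp$mz * (1 + stats::rnorm(nrow(exp), 0, ppm_sigma) / 1e6)
  if (n_decoys > 0) {
    lo <- decoy_range[1]; hi <- decoy_range[2]
    if (hi <= lo) stop("empty decoy range")
    decoys <- numeric(0)
    tries <- 0L
    while (length(decoys) < n_decoys) {
      tries <- tries + 1L
      if (tries > 1000L * n_decoys) stop("decoy range empty after exclusions")
      d <- stats::runif(1, lo, hi)
      if (all(ppm_error(d, exp$mz) > 10)) decoys <- c(decoys, d)
    }
    mz <- c(mz, decoys)
    intensity <- c(intensity, stats::runif(n_decoys, 0.05, 0.5) * base_intensity)
  }
  mol <- exp$kind == "molecular_ion"
  spectrum(data.frame(mz = mz, intensity = intensity),
           precursor_mz = mz[which(mol)[1]],
           id = if (nzchar(id)) id else format(truth))
}

#' Simulate a Michaelis-Menten kinetics dataset
#'
#' `v = vmax * S / (km + S)` with multiplicative log-normal noise
#' (`meanlog = 0`, `sdlog = cv`), `n_rep` replicates per concentration on
#' the reported substrate grid.
#'
#' @param vmax,km True parameters (pmol/mg protein/min; µM).
#' @param substrate_uM Concentration grid (default the reported
#'   3.25-120 µM, 7 points).
#' @param n_rep Replicates per concentration (default 4).
#' @param cv Multiplicative noise coefficient (>= 0, default 0.1).
#' @param seed Integer seed (mandatory).
#' @param metabolite_id Identifier.
#' @return A `kinetics_dataset`.
#' @export
simulate_kinetics <- function(vmax, km,
                              substrate_uM = c(3.25, 7.5, 15, 30, 60, 90, 120),
                              n_rep = 4, cv = 0.1, seed, metabolite_id = "") {
  if (missing(seed)) stop("seed is required")
  stopifnot(vmax > 0, km > 0, cv >= 0, n_rep >= 1)
  set.seed(seed)
  S <- rep(substrate_uM, each = n_rep)
  v <- vmax * S / (km + S)
  if (cv > 0) v <- v * stats::rlnorm(length(v), meanlog = 0, sdlog = cv)
  kinetics_dataset(S, v, replicate = rep(seq_len(n_rep), times = length(substrate_uM)),
                   metabolite_id = metabolite_id)
}

#' Simulate an atom-to-heme-iron distance trajectory
#'
#' Positive-truncated Normal(mu, sigma) draws, one per frame.
#'
#' @param mu Mean distance (Å, > 0).
#' @param sigma Spread (Å, >= 0).
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory).
#' @param atom_id Atom label.
#' @return A `distance_trajectory`.
#' @export
simulate_distance_traj <- function(mu, sigma, n_frames, seed, atom_id = "atom") {
  if (missing(seed)) stop("seed is required")
  stopifnot(mu > 0, sigma >= 0, n_frames >= 1)
  set.seed(seed)
  if (sigma == 0) {
    d <- rep(mu, n_frames)
  } else {
    d <- stats::rnorm(n_frames, mu, sigma)
    while (any(d <= 0)) {
      bad <- d <= 0
      d[bad] <- stats::rnorm(sum(bad), mu, sigma)
    }
  }
  distance_trajectory(atom_id, d)
}
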