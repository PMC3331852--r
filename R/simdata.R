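# Synthetic-data generators. Every generator takes an integer seed and is
# fully deterministic under it (R's default Mersenne-Twister stream). Truth
# tables carry the planted ground truth so downstream metrics can be
# computed without re-simulation.

random_sequences <- function(n, min_len = 8, max_len = 16) {
  letters20 <- names(MASS_CONSTANTS$residues)
  vapply(seq_len(n), function(i) {
    paste(sample(letters20, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Configuration for the identification-set generator
#'
#' Targets score near 1 (Beta(20, 1) by default), false matches near 0
#' (Beta(1, 20)); false matches land on a target or a decoy sequence with
#' equal probability, which is the working assumption of target-decoy FDR
#' estimation. Observed masses get a Gaussian error plus an occasional +1 /
#' +2 13C isotope-cluster offset.
#'
#' @param n_spectra Number of peptide-spectrum matches to simulate.
#' @param n_target_peptides,n_decoy_peptides Sizes of the sequence pools.
#' @param p_false Probability that a match is false.
#' @param score_shape_target,score_shape_false Beta shape pairs.
#' @param mass_sigma Gaussian mass-error SD, Da.
#' @param isotope_probs Probabilities of 0/+1/+2 13C offsets.
#' @param n_bad_mass Matches planted with a mass error beyond any
#'   tolerance (0.5-1.5 Da past 2 x 13C).
#' @param n_forbidden_mod Matches planted with a non-whitelisted
#'   modification (deamidation).
#' @return List of class `"sim_id_config"`.
#' @export
sim_id_config <- function(n_spectra = 600, n_target_peptides = 40,
                          n_decoy_peptides = 400, p_false = 0.1,
                          score_shape_target = c(20, 1),
                          score_shape_false = c(1, 20),
                          mass_sigma = 0.02,
                          isotope_probs = c(0.7, 0.2, 0.1),
                          n_bad_mass = 0, n_forbidden_mod = 0) {
  stopifnot(p_false >= 0, p_false <= 1, mass_sigma > 0,
            abs(sum(isotope_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "sim_id_config")
}

#' Simulate a target/decoy identification set with known truth
#'
#' @param config A [sim_id_config()].
#' @param seed Integer seed.
#' @return List with `records` (an [id_records()] table) and `truth`
#'   (data.frame `spectrum_id`, `is_correct`).
#' @export
simulate_identifications <- function(config = sim_id_config(), seed = 1) {
  set.seed(seed)
  targets <- random_sequences(config$n_target_peptides)
  decoys <- random_sequences(config$n_decoy_peptides)
  n <- config$n_spectra
  is_correct <- stats::runif(n) >= config$p_false
  seqs <- character(n); prot <- character(n); dec <- logical(n)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    if (is_correct[i]) {
      seqs[i] <- sample(targets, 1)
      prot[i] <- "TARGET_PROT"
      conf[i] <- stats::rbeta(1, config$score_shape_target[1],
                              config$score_shape_target[2])
    } else {
      dec[i] <- stats::runif(1) < 0.5
      seqs[i] <- if (dec[i]) sample(decoys, 1) else sample(targets, 1)
      prot[i] <- if (dec[i]) "DECOY_PROT" else "TARGET_PROT"
      conf[i] <- stats::rbeta(1, config$score_shape_false[1],
                              config$score_shape_false[2])
    }
  }
  theo <- vapply(seqs, function(s) monoisotopic_mass(peptide(s)), numeric(1))
  offs <- sample(0:2, n, replace = TRUE, prob = config$isotope_probs)
  obs <- theo + offs * MASS_CONSTANTS$d13C +
    stats::rnorm(n, 0, config$mass_sigma)
  mods <- vector("list", n)
  idx_bad <- utils::head(seq_len(n), config$n_bad_mass)
  if (length(idx_bad))
    obs[idx_bad] <- theo[idx_bad] + 2 * MASS_CONSTANTS$d13C +
      stats::runif(length(idx_bad), 0.5, 1.5)
  idx_mod <- setdiff(seq_len(n), idx_bad)
  idx_mod <- utils::head(idx_mod, config$n_forbidden_mod)
  for (i in idx_mod) {
    mods[[i]] <- data.frame(position = 1L, mass_delta = 0.984016,
                            name = "deamidation", stringsAsFactors = FALSE)
    obs[i] <- obs[i] + 0.984016
  }
  ids <- sprintf("sim.%05d", seq_len(n))
  rec <- id_records(spectrum_id = ids, sequence = seqs,
                    charge = sample(2:4, n, replace = TRUE),
                    confidence = conf, observed_neutral_mass = obs,
                    is_decoy = dec, proteins = prot, modifications = mods)
  list(records = rec,
       truth = data.frame(spectrum_id = ids, is_correct = is_correct,
                          stringsAsFactors = FALSE))
}

fragment_table <- function(pep, mz_min = 150, mz_max = 2000) {
  pep <- as_peptide(pep)
  enumerate_candidates(pep, enumeration_settings(
    precursor_charges = 2L, fragment_charges = 1:2,
    min_index = 1L, mz_min = mz_min, mz_max = mz_max))
}

#' Simulate replicate MS/MS spectra for a peptide ion
#'
#' Peaks sit at the theoretical y/b fragment m/z (1+ and 2+, within the
#' acquisition window) with log-normal base intensities biased by series:
#' the default `"y-dominant"` profile mimics Arg/Lys C-terminal peptides,
#' `"b2-dominant"` mimics precursors whose strongest fragments are doubly
#' charged b-ions. Replicates add multiplicative log-normal intensity
#' noise, small m/z jitter and spurious noise peaks; one designated
#' replicate is generated at much lower noise and is the planted
#' ground-truth representative.
#'
#' @param pep A [peptide()] or sequence.
#' @param charge Precursor charge.
#' @param n_replicates Number of replicate spectra.
#' @param seed Integer seed.
#' @param profile `"y-dominant"` or `"b2-dominant"`.
#' @param intensities Optional named vector of relative intensities, names
#'   like `"y8"` (charge 1) or `"b14^2"` (charge 2); named fragments
#'   dominate the spectrum in the given order and all others are scaled
#'   well below them.
#' @param noise_cv Log-normal intensity CV of ordinary replicates.
#' @param representative_noise_cv Intensity CV of the planted
#'   representative.
#' @param mz_jitter_sd m/z jitter SD in Th for ordinary replicates; the
#'   representative's jitter is scaled down by the same factor as its
#'   intensity noise (high SNR on both axes).
#' @param n_noise_peaks Spurious peaks added to ordinary replicates.
#' @param n_outliers Number of replicates corrupted with heavy noise
#'   (five-fold `noise_cv` and triple the noise peaks).
#' @param id_prefix Spectrum-id prefix.
#' @return List with `spectra` (list of [spectrum()]) and
#'   `representative_id`.
#' @export
simulate_spectra <- function(pep, charge, n_replicates = 5, seed = 1,
                             profile = c("y-dominant", "b2-dominant"),
                             intensities = NULL, noise_cv = 0.35,
                             representative_noise_cv = 0.02,
                             mz_jitter_sd = 0.003, n_noise_peaks = 6,
                             n_outliers = 0,
                             id_prefix = "rep") {
  set.seed(seed)
  profile <- match.arg(profile)
  pep <- as_peptide(pep)
  frags <- fragment_table(pep)
  key <- ifelse(frags$fragment_charge == 1, frags$fragment,
                paste0(frags$fragment, "^", frags$fragment_charge))
  weight <- switch(profile,
    "y-dominant" = ifelse(frags$series == "y",
                          ifelse(frags$fragment_charge == 1, 1.0, 0.15),
                          ifelse(frags$fragment_charge == 1, 0.30, 0.08)),
    "b2-dominant" = ifelse(frags$series == "b",
                           ifelse(frags$fragment_charge == 2, 1.0, 0.20),
                           0.08))
  base <- weight * stats::rlnorm(nrow(frags), log(1000), 0.7)
  if (!is.null(intensities)) {
    miss <- setdiff(names(intensities), key)
    if (length(miss)) stop("unknown fragment name(s): ",
                           paste(miss, collapse = ", "))
    floor_base <- 0.3 * min(intensities) * 1000
    base <- pmin(base, floor_base * stats::runif(length(base), 0.2, 1))
    base[match(names(intensities), key)] <- intensities * 1000
  }
  rep_idx <- 1L
  rep_jitter <- mz_jitter_sd * representative_noise_cv / noise_cv
  outlier_idx <- if (n_outliers > 0)
    seq.int(n_replicates - n_outliers + 1L, n_replicates) else integer(0)
  spectra <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cv <- if (r == rep_idx) representative_noise_cv
          else if (r %in% outlier_idx) 5 * noise_cv else noise_cv
    jit <- if (r == rep_idx) rep_jitter else mz_jitter_sd
    inten <- base * stats::rlnorm(length(base), 0, cv)
    mz <- frags$product_mz + stats::rnorm(length(base), 0, jit)
    if (r != rep_idx) {
      extra <- if (r %in% outlier_idx) 3 * n_noise_peaks else n_noise_peaks
      if (extra > 0) {
        mz <- c(mz, stats::runif(extra, 150, 2000))
        inten <- c(inten, stats::rlnorm(extra, log(stats::median(base)), 0.5))
      }
    }
    spectra[[r]] <- spectrum(sprintf("%s.%02d", id_prefix, r),
                             precursor_mz = precursor_mz(pep, charge),
                             precursor_charge = charge,
                             mz = mz, intensity = inten)
  }
  list(spectra = spectra,
       representative_id = spectra[[rep_idx]]$spectrum_id)
}

#' Simulate MRM chromatograms for a light/heavy transition panel
#'
#' Gaussian elution peaks (default SD 0.05 min on a 20-min run sampled
#' every 0.01 min); for each transition the heavy-channel area is
#' proportional to the internal-standard spike and the light-channel area
#' to the planted concentration, so that light/heavy = concentration/spike
#' up to noise. Optional planted carry-over (blank runs) and cross-talk
#' (bleed into the counterpart channel) percentages.
#'
#' @param panel List with `light`/`heavy` data.frames from
#'   [heavy_counterparts()] (a `peptide_id` column is added from
#'   `sequence`).
#' @param concentrations Named numeric vector, fmol/ul, keyed by sequence.
#' @param spikes Named numeric vector, fmol/ul of heavy standard, keyed by
#'   sequence.
#' @param seed Integer seed.
#' @param snr Peak-height signal-to-noise ratio of the additive noise.
#' @param rt Named numeric vector of retention times (min) by sequence;
#'   sequences absent default to 10.
#' @param peak_sigma_min Chromatographic peak SD, minutes.
#' @param run_time,interval Time axis, minutes.
#' @param response_per_fmol Detector response scale (area counts x min per
#'   fmol).
#' @param carryover_percent If > 0, blank traces with this percentage of
#'   the preceding sample's area are generated per transition.
#' @param crosstalk_percent If > 0, each channel receives this percentage
#'   of its counterpart's area.
#' @return List with `chromatograms` (long data.frame `transition_id`,
#'   `time_min`, `intensity`), `truth` (per-transition planted areas and
#'   ratios) and `blanks` (long data.frame, empty unless carry-over was
#'   planted).
#' @export
simulate_mrm_runs <- function(panel, concentrations, spikes, seed = 1,
                              snr = 100, rt = c(DSGEGDFLAEGGGVR = 9.78,
                                                SSKITHRIHWESASLL = 9.61,
                                                NGFKSHALQLNNRQI = 9.32),
                              peak_sigma_min = 0.05, run_time = 20,
                              interval = 0.01, response_per_fmol = 1000,
                              carryover_percent = 0,
                              crosstalk_percent = 0) {
  set.seed(seed)
  time <- seq(0, run_time, by = interval)
  tab <- rbind(panel$light, panel$heavy)
  rows <- list(); truth <- list(); blank_rows <- list()
  gauss_area <- function(area, mu) {
    area / (peak_sigma_min * sqrt(2 * pi)) *
      exp(-(time - mu)^2 / (2 * peak_sigma_min^2))
  }
  for (i in seq_len(nrow(tab))) {
    seqc <- tab$sequence[i]
    amount <- if (tab$form[i] == "light") concentrations[[seqc]]
              else spikes[[seqc]]
    counterpart <- if (tab$form[i] == "light") spikes[[seqc]]
                   else concentrations[[seqc]]
    mu <- if (seqc %in% names(rt)) rt[[seqc]] else 10
    area <- amount * response_per_fmol +
      counterpart * response_per_fmol * crosstalk_percent / 100
    sig <- gauss_area(area, mu)
    height <- max(sig)
    noise <- stats::rnorm(length(time), 0, height / snr)
    id <- sprintf("%s.%s.%d+.%s", seqc, tab$form[i],
                  tab$precursor_charge[i], tab$fragment[i])
    rows[[i]] <- data.frame(transition_id = id, time_min = time,
                            intensity = pmax(0, sig + noise),
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(transition_id = id, sequence = seqc,
                             form = tab$form[i], planted_area = area,
                             rt = mu, stringsAsFactors = FALSE)
    if (carryover_percent > 0) {
      bsig <- gauss_area(area * carryover_percent / 100, mu)
      bnoise <- stats::rnorm(length(time), 0, max(bsig) / snr)
      blank_rows[[i]] <- data.frame(transition_id = id, time_min = time,
                                    intensity = pmax(0, bsig + bnoise),
                                    stringsAsFactors = FALSE)
    }
  }
  list(chromatograms = do.call(rbind, rows),
       truth = do.call(rbind, truth),
       blanks = if (length(blank_rows)) do.call(rbind, blank_rows)
                else data.frame(transition_id = character(),
                                time_min = numeric(),
                                intensity = numeric()))
}

#' Write simulated chromatograms to long-format CSV
#'
#' @param sim Output of [simulate_mrm_runs()].
#' @param path CSV path for the chromatograms.
#' @param truth_path Optional TSV path for the truth table.
#' @return `path`, invisibly.
#' @export
write_mrm_csv <- function(sim, path, truth_path = NULL) {
  utils::write.csv(sim$chromatograms, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}
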