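# Synthetic NADH-like inputs with known ground truth: a three-state
# (La / CT / Nic*) LVC model with high-frequency tuning modes and
# low-frequency CT-Nic* coupling modes, and TA maps built from sequential
# kinetics convolved with a Gaussian IRF plus noise.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the folded NADH study conditions: tuning modes at ~1400
#' and ~1600 cm^-1 (donor C-C/C-N stretches), a low-frequency band carrying
#' the CT-acceptor vibronic coupling, donor bright state at the 4.7 eV pump
#' resonance, CT state 0.5 eV below it, CT-energy disorder of 1 eV FWHM, and
#' TA kinetics on the 157/894 fs scale with a 30 fs IRF at SNR 50.  The
#' absolute Nic* and CT energies are synthetic defaults (only bands, not
#' values, are known for them).
#'
#' @param seed RNG seed used by the generators.
#' @param tuning_freqs tuning-mode frequencies (cm^-1).
#' @param coupling_freqs low-frequency CT-acceptor coupling modes (cm^-1).
#' @param E_La donor bright-state vertical energy (eV).
#' @param E_acceptor acceptor (Nic*) vertical energy (eV).
#' @param ct_offset `E_CT - E_La` at the Franck-Condon point (eV).
#' @param kappa_La,kappa_CT,kappa_acceptor tuning gradients per tuning mode
#'   (eV).
#' @param lam_direct La-Nic* vibronic couplings on the tuning modes (eV).
#' @param lam_la_ct La-CT vibronic couplings on the tuning modes (eV);
#'   larger than the direct ones (one-electron character).
#' @param lam_ct_acceptor CT-Nic* vibronic couplings on the low-frequency
#'   modes (eV).
#' @param V0_la_ct,V0_ct_acceptor,V0_direct constant electronic couplings
#'   (eV); the default `V0_la_ct` realizes |V/Delta| = 0.268 at the 0.5 eV
#'   gap.
#' @param ct_fwhm CT-energy disorder FWHM (eV).
#' @param taus TA lifetimes (fs) of the sequential components.
#' @param irf_fwhm TA instrument response FWHM (fs).
#' @param snr TA signal-to-noise ratio (peak |dA| over noise sd).
#' @param delays,probes TA axes (fs / eV).
#' @param t0 TA time zero (fs).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         tuning_freqs = c(1400, 1600),
                         coupling_freqs = c(200, 450),
                         E_La = 4.7,
                         E_acceptor = 4.2,
                         ct_offset = -0.5,
                         kappa_La = c(-0.21, -0.26),
                         kappa_CT = c(-0.12, -0.15),
                         kappa_acceptor = c(0.03, 0.04),
                         lam_direct = c(0.04, 0.05),
                         lam_la_ct = c(0.06, 0.08),
                         lam_ct_acceptor = c(0.05, 0.07),
                         V0_la_ct = 0.268 * 0.5,
                         V0_ct_acceptor = 0.08,
                         V0_direct = 0.03,
                         ct_fwhm = 1.0,
                         taus = c(157, 894),
                         irf_fwhm = 30,
                         snr = 50,
                         delays = seq(-100, 1500, by = 10),
                         probes = seq(1.9, 3.2, length.out = 60),
                         t0 = 0) {
  cfg <- as.list(environment())
  if (any(c(cfg$tuning_freqs, cfg$coupling_freqs) <= 0))
    stop("synth_config: frequencies must be positive")
  if (cfg$snr <= 0) stop("synth_config: snr must be positive")
  structure(cfg, class = "synth_config")
}

#' Synthetic NADH-like LVC model
#'
#' Three diabatic states (La donor, CT intermediate, Nic* acceptor), tuning
#' gradients concentrated on the donor along the high-frequency stretches,
#' direct La-Nic* vibronic coupling on those same modes, CT-Nic* coupling on
#' the low-frequency modes, and electronic couplings with the La-CT one
#' dominating.  Deterministic per configuration.
#'
#' @param config a [synth_config()].
#' @return A `vibronic_model` with states `La`, `CT`, `Nic`.
#' @export
make_nadh_model <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  nt <- length(config$tuning_freqs)
  nc <- length(config$coupling_freqs)
  nm <- nt + nc
  omega <- c(config$tuning_freqs, config$coupling_freqs)
  labs <- c("La", "CT", "Nic")
  E <- c(config$E_La, config$E_La + config$ct_offset, config$E_acceptor)
  kappa <- matrix(0, 3, nm)
  kappa[1, seq_len(nt)] <- config$kappa_La
  kappa[2, seq_len(nt)] <- config$kappa_CT
  kappa[3, seq_len(nt)] <- config$kappa_acceptor
  lam <- array(0, c(3, 3, nm))
  for (k in seq_len(nt)) {
    lam[1, 3, k] <- lam[3, 1, k] <- config$lam_direct[k]
    lam[1, 2, k] <- lam[2, 1, k] <- config$lam_la_ct[k]
  }
  for (k in seq_len(nc)) {
    lam[2, 3, nt + k] <- lam[3, 2, nt + k] <- config$lam_ct_acceptor[k]
  }
  V0 <- matrix(0, 3, 3)
  V0[1, 2] <- V0[2, 1] <- config$V0_la_ct
  V0[2, 3] <- V0[3, 2] <- config$V0_ct_acceptor
  V0[1, 3] <- V0[3, 1] <- config$V0_direct
  vibronic_model(labs, E, omega, kappa, lam, V0)
}

#' Recommended basis for the synthetic NADH model
#'
#' Tuning modes go to the system tier, low-frequency coupling modes to the
#' bath tier.  The default ladder sizes (14/10) hold the displaced
#' wavepacket of the default couplings with negligible leakage while keeping
#' exact propagation affordable.
#'
#' @param config a [synth_config()].
#' @param n_tuning,n_coupling ladder sizes for the two tiers.
#' @return A [basis_spec()] matching [make_nadh_model()]'s mode order.
#' @export
nadh_basis <- function(config = synth_config(), n_tuning = 14L,
                       n_coupling = 10L) {
  nt <- length(config$tuning_freqs)
  nc <- length(config$coupling_freqs)
  basis_spec(c(rep(n_tuning, nt), rep(n_coupling, nc)),
             tier = c(rep("system", nt), rep("bath", nc)))
}

#' Synthetic TA map with known ground truth
#'
#' Builds `dA = C(t; taus, IRF, t0) %*% t(EAS)` from sequential-model
#' concentrations and smooth component spectra, then adds i.i.d. Gaussian
#' noise scaled to `max|dA| / snr`.  The first component is a broad donor
#' photoinduced absorption peaking above 3 eV; the second a narrower
#' long-lived acceptor band at 3.1 eV.
#'
#' @param config a [synth_config()].
#' @return A list with the noisy `map` (a [ta_map()]) and `truth`
#'   (`taus`, `t0`, `irf_fwhm`, `EAS`, the noiseless map, `noise_sd`).
#' @export
make_ta_map <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  t <- config$delays
  E <- config$probes
  taus <- config$taus
  C <- sequential_concentrations(t, taus, config$irf_fwhm, config$t0)
  nc <- length(taus)
  EAS <- matrix(0, length(E), nc)
  # broad donor PA rising toward the blue with a sharp >3 eV peak
  EAS[, 1] <- 4 + 2.5 * (E - min(E)) + 6 * exp(-((E - 3.1) / 0.12)^2)
  if (nc >= 2)  # long-lived acceptor PA at 3.1 eV
    EAS[, 2] <- 3.5 * exp(-((E - 3.1) / 0.18)^2) + 0.3
  if (nc >= 3) for (j in 3:nc)
    EAS[, j] <- 0.5 * exp(-((E - (2.2 + 0.3 * j)) / 0.3)^2)
  clean <- C %*% t(EAS)
  set.seed(config$seed)
  noise_sd <- max(abs(clean)) / config$snr
  noisy <- clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                          nrow(clean), ncol(clean))
  list(map = ta_map(t, E, noisy, irf_fwhm = config$irf_fwhm, pump_ev = 4.7),
       truth = list(taus = taus, t0 = config$t0, irf_fwhm = config$irf_fwhm,
                    EAS = EAS, clean = clean, noise_sd = noise_sd))
}
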