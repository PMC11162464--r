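---
title: "Vibronically coherent energy transfer: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronically coherent energy transfer: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibroneet)
```

## The physical problem

In closely stacked chromophore dimers — the adenine (Ade) / nicotinamide
(Nic) pair of the coenzyme NADH is the motivating case — excitation energy
transfer (EET) from the photoexcited donor to the acceptor can run on a tens
of femtoseconds timescale, far too fast for Förster theory, which assumes
weak coupling and incoherent hopping.  Two ingredients drive this regime:

* **tuning modes**: impulsively excited intramolecular vibrations (here the
  donor's C–C and C–N stretches near 1400 and 1600 cm⁻¹) that modulate the
  electronic energy gaps and periodically carry the donor and acceptor
  surfaces through degeneracy, and
* **electronic and vibronic interstate couplings** that convert each gap
  closing into population transfer, assisted in polar solvents by a dark
  Nic→Ade charge-transfer (CT) state that can be pulled below the bright
  donor state by solvent fluctuations and act as a doorway.

`vibroneet` implements the desk-scale computational chain behind this
picture: the linear vibronic coupling (LVC) Hamiltonian with coupling
ablations, numerically exact wavepacket propagation, fragment-excitation-
difference (FED) diabatization, photoactive-mode ranking, solvent-disorder
ensembles, and the transient-absorption (TA) kinetic decomposition that
turns measured lifetimes into an EET time constant.

## The LVC model

With dimensionless mass-frequency-scaled normal coordinates $q_k$ (ground-
state minimum at $q=0$) and frequencies $\tilde\omega_k$ expressed as
energies, the Hamiltonian is

$$
H = \sum_k \frac{\tilde\omega_k}{2}\left(p_k^2+q_k^2\right)\mathbf{1}
  + \sum_i |i\rangle\langle i|\Big(E_i + \sum_k \kappa_{ik} q_k\Big)
  + \sum_{i\neq j} |i\rangle\langle j|\Big(V^0_{ij} + \sum_k \lambda_{ijk} q_k\Big).
$$

Units are fixed package-wide: energies in eV, frequencies in cm⁻¹
(1 cm⁻¹ = 1.239841984×10⁻⁴ eV), time in fs, ħ = 0.6582119569 eV·fs.  The
electronic ground state is *not* a dynamical state: internal conversion back
to it enters only through the kinetics module, so wavepacket norm is
conserved exactly.

Sign conventions for $\kappa$, $\lambda$, $V^0$ are gauge: flipping the sign
of every coupling into one diabatic state is a per-state phase flip that
leaves populations and coherence magnitudes unchanged (this invariance is
tested).  `ablate()` zeroes one class of terms — `electronic` ($V^0$),
`interstate_vibronic` ($\lambda$), `intrastate_tuning` ($\kappa$) — to
dissect mechanisms; `ablate_state_couplings()` decouples one state entirely
(the "no LE–CT couplings" control).

## Wavepacket propagation

The wavefunction lives on the product of the electronic space and truncated
harmonic ladders ($q_k$ couples $n \leftrightarrow n\pm1$ with element
$\sqrt{n/2}$).  The propagator is a short-time Lanczos (Krylov-subspace)
action of $\exp(-iH\Delta t/\hbar)$ on the state vector with full
reorthogonalization, an a-posteriori residual estimate, and recursive step
bisection until the per-step tolerance (default 10⁻⁹) is met.  The full
multilayer MCTDH machinery used for 62-mode production runs is deliberately
out of scope; instead, reduced mode sets (≤ ~6 modes at practical ladder
sizes) are propagated *numerically exactly*, which is the role the
`mode_reduction` module's ranking and system/bath partition serves.  On
models small enough to diagonalize densely the Krylov propagator agrees with
the matrix-exponential oracle to better than 10⁻⁸ in every population
sample, and norm and energy are conserved to 10⁻⁶ over the 200 fs production
window (defaults: `t_final = 200`, `dt_out = 0.25` fs).

Observables recorded along a trajectory: diabatic populations, electronic
coherence magnitudes $|\rho_{ij}|$ of the nuclear-traced electronic density
matrix (the modulus is adopted as the coherence measure; it obeys
$|\rho_{ij}| \le \sqrt{P_iP_j} \le 1/2$), energy, norm, per-mode $\langle
q_k\rangle$, and a leakage monitor (population in the top two ladder levels
of any mode; a warning names the offending mode above 1%).  Population-
transfer *burst times* are defined operationally as the local maxima of the
acceptor's $dP/dt$ on the output grid; for a single tuning mode sweeping two
surfaces through degeneracy twice per period, their mean spacing is half the
vibrational period (10.42 fs at 1600 cm⁻¹).

Basis sizes follow the two-tier convention (30 primitive levels for system
modes, 15 for bath modes).  For the four-mode synthetic models shipped here,
convergence is reached much earlier; `nadh_basis()` defaults to 14/10
levels, at which doubling the ladders moves populations by under 0.01 and
leakage stays below 1%.

## FED diabatization

Adiabatic states mix locally excited (LE) and CT character near crossings.
The fragment excitation difference construction diagonalizes the
excitation-difference matrix $\Delta x$; eigenvalues near +1/−1 tag the two
LE states and an eigenvalue near 0 tags the CT state.  The eigenvector
matrix $U$ rotates the adiabatic Hamiltonian, $H^{dia} = U^T H^{ad} U$,
whose off-diagonals are the electronic couplings $V$; adiabatic state
gradients rotate identically and yield the diabatic $\kappa$ (diagonal) and
$\lambda$ (off-diagonal) tables per mode.  Gauge is fixed reproducibly:
columns ordered by descending $\Delta x$ eigenvalue, signs chosen so each
eigenvector's largest component is positive.  Eigenvalues farther than
`eigenvalue_tol = 0.2` from every target in {+1, −1, 0} raise an "ambiguous
diabatic character" error (the tolerance is a package choice; the method
itself only promises "approximately" integer eigenvalues), and degenerate
$\Delta x$ eigenvalues are refused rather than disambiguated silently.
Because $\Delta x$ is symmetric its eigenvectors are orthogonal by
construction, so no re-orthogonalization step is needed.  Hole/electron
centroids for `eh_distance()` are inputs (Å); computing them from
wavefunctions is out of scope.

## TA global analysis and the EET time constant

A TA map $\Delta A$(delay, probe energy) is fit by variable projection to a
sequential kinetic chain convolved with a Gaussian instrument response
(closed form in `irf_exp()`, $\sigma = \mathrm{FWHM}/2.3548$): lifetimes,
time zero (and optionally the IRF width) are optimized by
Levenberg–Marquardt while the evolution-associated spectra are solved
linearly at each step.  Lifetime uncertainties come from the covariance of
the nonlinear stage.  A parallel (sum-of-exponentials) reading of the EAS is
not separately implemented since the linear stage is identical; the chain
model is the default and only kinetic scheme.

The folded/unfolded decomposition then proceeds in two closed-form steps:

1. the observed fast lifetime of the conformer mixture is the
   population-weighted average
   $\tau_{mix} = (1-f)\,\tau_{unfolded} + f\,\tau_{folded}$, inverted by
   `folded_lifetime()`;
2. the folded donor's total decay rate is the sum of internal conversion
   and transfer, $k_{total} = k_{IC} + k_{ET}$, inverted by `eet_time()`.

With the experimental inputs (τ_mix = 122 fs, τ_unfolded = 157 fs, f = 0.3,
τ_IC = 157 fs) this gives τ_folded ≈ 40.3 fs and τ_EET ≈ 54.3 fs:

```{r kinetics}
tau_folded <- folded_lifetime(122, 157, 0.3)
tau_eet <- eet_time(tau_folded, 157)
c(tau_folded = tau_folded, tau_eet = tau_eet)
```

`mc_uncertainty()` propagates independent Gaussian 1σ errors through this
chain by resampling.  A caveat worth stating plainly: propagating ±4 fs on
both measured lifetimes through the mixture inversion gives
σ(τ_folded) ≈ 16 fs, substantially larger than the ±6 fs quoted alongside
the 40 fs value in the experimental literature; the exact error treatment
behind such quotes typically involves correlated fit uncertainties not
recoverable from summary numbers, so this package treats central values as
the reproducible quantities and reports its own MC spread separately.

## Synthetic data: what it emulates and what it does not

`make_nadh_model()` builds a three-state (La/CT/Nic*) four-mode LVC model
emulating the folded-NADH study conditions: tuning modes at 1400/1600 cm⁻¹
with gradients concentrated on the donor, direct La–Nic* vibronic coupling
on the same stretches, CT–Nic* coupling on a low-frequency band, and
electronic couplings with the La–CT term dominating (its default, 0.134 eV,
realizes the strong-mixing ratio |V/Δ| = 0.268 at the 0.5 eV gap).  The
donor sits at the 4.7 eV pump resonance; the acceptor and CT defaults (4.2
eV, i.e. 0.5 eV below the donor) are *synthetic placeholders* — only energy
bands, not values, are published for those states — as is the identity of
the low-frequency coupling modes (a 200/450 cm⁻¹ pair stands in for a
conformer-dependent 100–600 cm⁻¹ band).  Magnitudes of the remaining
couplings were chosen once, on physical grounds (surfaces must cross within
the Franck–Condon excursion; CT couplings exceed their direct counterparts),
so that the model reproduces the qualitative regime reported for folded
NADH: CT doorway population within tens of fs, acceptor-dominant population
well inside 100 fs.

`sample_disorder()` adds the solvent: Gaussian shifts of the CT energy
(default FWHM 1 eV) and optional relative jitter of CT couplings (default
10% where used — a labelled assumption; per-snapshot coupling statistics are
not published).  Disorder touches electronic parameters only, consistent
with a frozen solute in varying solvent cavities; the model deliberately
lacks *dynamic* solvent relaxation, so CT-trapped trajectories at small
|E_CT − E_La| are expected to be an artifact of the static-disorder picture.
`make_ta_map()` builds TA maps from the sequential model (defaults: τ =
157/894 fs, IRF FWHM 30 fs, delays −100…1500 fs, probes 1.9–3.2 eV) with
i.i.d. Gaussian noise scaled to peak |ΔA|/SNR (default SNR 50).  None of
this emulates coherent artifacts, solvated-electron signals, spectral
lineshapes, or absolute ΔA magnitudes — passing tests show the *analysis
chain* is correct at the stated scales, not that real NADH data would be
noise-free or strictly sequential.

## Numerical choices and degenerate inputs

* Near-degenerate lifetimes make the sequential (Bateman) closed form
  singular; `sequential_concentrations()` refuses relative rate gaps below
  10⁻⁸ rather than switching to the confluent limit.
* Zero gaps are rejected in `coupling_gap_ratio()` (the ratio is undefined);
  zero-gap and zero-coupling LVC models are legal and propagate stably.
* Mode selection is count-driven (top *n* by score, ties broken by
  ascending index); the ~0.02 eV activity floor seen in the source data is
  available as an optional `score_floor`, not a hard filter.
* Ensemble population maps are indexed by gap *rank*, not binned, so
  permuting snapshots cannot change the summary.
* All randomness (disorder draws, synthetic noise, MC resampling) flows
  from explicit integer seeds; generators are bit-reproducible per seed.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run the four-mode NADH model at
the 14/10-level basis (≈ 5.9×10⁴ complex amplitudes) to 100 fs, two-state
burst fixtures at 50 levels to 100 fs, 200 fs conservation runs on two-mode
models, ensembles of 3–4 snapshots at reduced ladders, and 20-seed
global-fit recovery studies — sizes chosen so every check is exact or
convergence-verified while the whole chain remains a desk-scale computation.

## Known limitations

Exact propagation caps the mode count near six at production ladder sizes;
larger models must be reduced first (that reduction, not a tensor-tree
wavefunction, is this package's answer to high dimensionality).  The
kinetics module assumes a Gaussian IRF and unidirectional sequential
kinetics.  Disorder is static and Gaussian.  The CT coherence measure is
the traced-density-matrix modulus; alternative normalizations exist in the
literature and would rescale, not reorder, the reported coherences.
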