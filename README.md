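# vibroneet

Vibronic wavepacket dynamics and transient-absorption kinetics for
ultrafast excitation energy transfer (EET) in closely stacked chromophore
dimers — the motivating system being the adenine/nicotinamide pair of the
coenzyme NADH, where transfer from the photoexcited adenine L\_a state to
the nicotinamide ππ\* state (Nic\*) completes within ~100 fs, assisted by a
dark Nic→Ade charge-transfer (CT) state.

The package is aimed at spectroscopists and simulators who want a tested,
desk-scale implementation of the full analysis chain:

* **Linear vibronic coupling (LVC) models.**
  `H = Σₖ (ω̃ₖ/2)(pₖ²+qₖ²)·1 + Σᵢ|i⟩⟨i|(Eᵢ + Σₖ κᵢₖqₖ) +
  Σᵢ≠ⱼ|i⟩⟨j|(E⁰ᵢⱼ + Σₖ λᵢⱼₖqₖ)` in dimensionless normal coordinates, with
  selective ablation of electronic (`E⁰`), interstate vibronic (`λᵢⱼ`) or
  tuning (`κᵢᵢ`) terms to dissect transfer mechanisms.
* **Numerically exact wavepacket propagation** (Krylov/Lanczos short-time
  propagator on truncated harmonic ladders) yielding diabatic populations,
  nuclear-traced electronic coherences, population-transfer burst times,
  and pathway classification (direct / CT-mediated / CT-trapped).
* **FED diabatization**: diagonalizing the fragment excitation-difference
  matrix (eigenvalues +1/−1 for locally excited states, 0 for CT) to
  recover diabatic energies, couplings `V`, and per-mode κ/λ tables, plus
  CT descriptors (|V/Δ|, electron–hole distance, the 0.5 eV solvent
  accessibility rule).
* **Photoactive-mode ranking** (score = max |κ|, |λ| per mode at
  Franck–Condon) with count-driven selection and system/bath partitioning.
* **Solvent-disorder ensembles**: Gaussian CT-energy disorder (~1 eV FWHM)
  and coupling jitter, with population maps ordered by the CT–donor gap.
* **TA global analysis**: variable-projection fits of delay × probe-energy
  maps to sequential kinetics convolved with a Gaussian IRF, and the
  lifetime decomposition `τ_mix = (1−f)·τ_unfolded + f·τ_folded`,
  `k_total = k_IC + k_ET` that extracts the EET time constant.
* **Synthetic-data generators** for all of the above with known ground
  truth, bit-reproducible per seed.

## Worked example

The kinetic decomposition that turns measured lifetimes into an EET time
constant — inputs are the fast lifetimes of the donor-only reference
(157 fs), the folded/unfolded mixture (122 fs), the folded fraction (0.3)
and the internal-conversion lifetime (157 fs):

```r
library(vibroneet)
tau_folded <- folded_lifetime(tau_mix = 122, tau_unfolded = 157, f_folded = 0.3)
tau_eet    <- eet_time(tau_folded, tau_ic = 157)
c(tau_folded = tau_folded, tau_eet = tau_eet)
#> tau_folded    tau_eet
#>   40.33333   54.27714
```

So the folded conformers decay with a ~40 fs total lifetime, and removing
the internal-conversion rate leaves a ~54 fs energy-transfer time.

Those measured lifetimes come from a global fit; on a synthetic map at the
same scales (τ = 157/894 fs, 30 fs IRF, signal-to-noise 50):

```r
g   <- make_ta_map(synth_config(seed = 1))
fit <- ta_global_fit(g$map, n_components = 2)
fit
#> Sequential global fit: 2 components
#>   tau_1 = 156.5 fs (se 1.31 fs)
#>   tau_2 = 886.7 fs (se 12.4 fs)
#>   t0 = -0.07989 fs, IRF FWHM = 30 fs, RSS = 498.9
```

both lifetimes land within 1% of the generator's truth.  On the dynamics
side, the default synthetic NADH-like model (donor at the 4.7 eV pump
resonance, CT 0.5 eV below it) transfers population to the acceptor through
the CT doorway well inside 100 fs:

```r
m  <- make_nadh_model()
tr <- propagate(m, nadh_basis(), initial_state = "La",
                t_final = 100, dt_out = 0.5, track_q = FALSE)
tr
#> LVC trajectory: 201 samples over 100 fs (dt_out = 0.5 fs)
#>   final populations: La=0.1938, CT=0.4132, Nic=0.3930
#>   norm drift: 5.15e-14  energy drift (eV): 2.57e-13
classify_pathway(tr)
#> [1] "ct_mediated"
```

By 50 fs the acceptor is already the most populated state
(La/CT/Nic ≈ 0.30/0.33/0.38).  A minimal two-state model with a single
1600 cm⁻¹ tuning mode shows why the transfer is pulsed: the gap closes
twice per 20.85 fs vibrational period, so acceptor-population bursts arrive
every ~10.4 fs (`burst_times()`; measured mean spacing 10.28 fs).

The same functionality is scriptable from a shell through the thin CLI at
`inst/cli/vibroneet.R` (subcommands `synth-model`, `synth-ta`, `propagate`,
`ablate`, `diabatize`, `rank-modes`, `fit-ta`, `decompose`, `ensemble`),
e.g.

```sh
Rscript inst/cli/vibroneet.R decompose --tau-mix 122 --tau-unfolded 157 \
        --f-folded 0.3 --tau-ic 157
# tau_folded_fs  40.3333
# tau_EET_fs     54.2771
```

## Layout

* `R/` — model containers, Hamiltonian assembly, propagator, diabatization,
  mode ranking, kinetics, ensembles, synthetic data, file I/O.
* `tests/testthat/` — unit, property and end-to-end suites (closed-form and
  dense-matrix oracles, recovery studies, round-trips).
* `vignettes/coherent-eet-methods.Rmd` — the model, assumptions, parameter
  defaults, numerical choices, and known limitations.
* `inst/cli/vibroneet.R` — command-line front end.
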