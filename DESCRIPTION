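Package: vibroneet
Title: Vibronic Wavepacket Dynamics and Transient-Absorption Kinetics of
    Ultrafast Excitation Energy Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models sub-picosecond excitation energy transfer (EET) in closely
    stacked chromophore heterodimers such as the adenine/nicotinamide pair of
    the coenzyme NADH.  Provides linear vibronic coupling (LVC) Hamiltonians
    with selective coupling ablations, numerically exact Krylov-subspace
    wavepacket propagation yielding diabatic populations and electronic
    coherences, fragment-excitation-difference (FED) diabatization of
    locally-excited and charge-transfer states, photoactive-mode ranking and
    system/bath partitioning, solvent-disorder ensembles of the
    charge-transfer energy, and global analysis of transient-absorption maps
    with the sequential-model lifetime decomposition that extracts the EET
    time constant from folded/unfolded conformer mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
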