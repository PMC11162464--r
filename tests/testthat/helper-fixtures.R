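# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; oracles never reuse the propagator.

# two degenerate states, pure electronic coupling (Rabi problem)
rabi_model <- function(V0 = 0.1) {
  vibronic_model(c("D", "A"), c(0, 0),
                 V0 = matrix(c(0, V0, V0, 0), 2))
}

# two-state curve-crossing driven by a single high-frequency tuning mode:
# gap 0.3 eV at FC, donor gradient steep enough to cross within the
# wavepacket excursion, weak constant coupling
crossing_model <- function(freq = 1600) {
  vibronic_model(c("D", "A"), c(0.3, 0), freq,
                 kappa = matrix(c(-0.25, 0.05), 2, 1),
                 V0 = matrix(c(0, 0.02, 0.02, 0), 2))
}

# random symmetric small LVC model (seeded)
random_small_model <- function(seed, ns = 2, nm = 2, coupled = TRUE) {
  set.seed(seed)
  labs <- paste0("S", seq_len(ns))
  E <- sort(runif(ns, 0, 0.6), decreasing = TRUE)
  omega <- runif(nm, 400, 1700)
  kappa <- matrix(rnorm(ns * nm, 0, 0.08), ns, nm)
  lam <- array(0, c(ns, ns, nm))
  V0 <- matrix(0, ns, ns)
  if (coupled) {
    for (k in seq_len(nm)) {
      L <- matrix(rnorm(ns * ns, 0, 0.03), ns, ns)
      L <- (L + t(L)) / 2; diag(L) <- 0
      lam[, , k] <- L
    }
    V0 <- matrix(rnorm(ns * ns, 0, 0.04), ns, ns)
    V0 <- (V0 + t(V0)) / 2; diag(V0) <- 0
  }
  vibronic_model(labs, E, omega, kappa, lam, V0)
}

# dense matrix-exponential reference: diabatic populations at the requested
# times via full diagonalization (independent of the Krylov propagator)
dense_reference <- function(m, basis, initial_state, times) {
  ham <- build_hamiltonian(m, basis)
  H <- as.matrix(ham$H)
  eg <- eigen(H, symmetric = TRUE)
  psi0 <- initial_wavepacket(m, basis, initial_state)$coef
  c0 <- as.vector(crossprod(eg$vectors, Re(psi0))) +
    1i * as.vector(crossprod(eg$vectors, Im(psi0)))
  ns <- length(m$state_labels)
  t(vapply(times, function(tt) {
    ph <- exp(-1i * tt / HBAR_EV_FS * eg$values)
    psi <- eg$vectors %*% (ph * c0)
    colSums(Mod(matrix(psi, ham$dim_nuc, ns))^2)
  }, numeric(ns)))
}

# planted three-state LE/LE/CT diabatic problem rotated to an adiabatic
# basis; the FED input plus the planted ground truth
planted_fed_case <- function(seed, n_grad_modes = 3) {
  set.seed(seed)
  H_dia <- matrix(c(4.6, 0.13, 0.05,
                    0.13, 4.2, 0.08,
                    0.05, 0.08, 4.15), 3, 3)
  dx_dia <- diag(c(1, -1, 0))
  grads_dia <- NULL
  if (n_grad_modes > 0) {
    grads_dia <- lapply(seq_len(n_grad_modes), function(k) {
      G <- matrix(rnorm(9, 0, 0.05), 3, 3)
      G <- (G + t(G)) / 2
      G
    })
  }
  eg <- eigen(H_dia, symmetric = TRUE)
  Ut <- eg$vectors                      # diabatic -> adiabatic columns
  H_ad <- diag(eg$values)
  dx_ad <- t(Ut) %*% dx_dia %*% Ut
  grads_ad <- NULL
  if (!is.null(grads_dia)) {
    # FED takes only the diagonal (state gradients) in the adiabatic basis;
    # plant purely diagonal adiabatic gradients so rotation is exact
    grads_ad <- matrix(rnorm(3 * n_grad_modes, 0, 0.05), 3, n_grad_modes)
    grads_dia <- lapply(seq_len(n_grad_modes), function(k)
      Ut %*% diag(grads_ad[, k]) %*% t(Ut))
  }
  list(H_dia = H_dia, dx_dia = dx_dia, Ut = Ut,
       input = fed_input(diag(H_ad), dx_ad, grads_ad),
       grads_dia = grads_dia)
}

# run the CLI script in a child R process with the current library path
run_cli <- function(args) {
  script <- system.file("cli", "vibroneet.R", package = "vibroneet")
  rls <- paste(.libPaths(), collapse = .Platform$path.sep)
  withr::with_envvar(c(R_LIBS = rls, R_LIBS_USER = rls), {
    out <- suppressWarnings(
      system2(file.path(R.home("bin"), "Rscript"), c(script, args),
              stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    list(output = out, status = if (is.null(status)) 0L else status)
  })
}
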