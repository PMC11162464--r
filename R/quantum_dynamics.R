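# Numerically exact wavepacket propagation on reduced-dimensional LVC models.
# The propagator is a short-time Lanczos (Krylov-subspace) action of
# exp(-i H dt / hbar) on the state vector with adaptive inner stepping; H is
# real symmetric, the state complex, so one H application costs two real
# sparse matvecs.

#' Franck-Condon initial wavepacket
#'
#' Vertical excitation of the ground-state vibrational ground level: unit
#' electronic amplitude on `initial_state`, every mode in its lowest ladder
#' level, all coordinate expectations zero.
#'
#' @param m a [vibronic_model()].
#' @param basis a [basis_spec()].
#' @param initial_state a state label of `m`.
#' @return An object of class `wavepacket` (complex coefficient vector plus
#'   metadata), unit norm.
#' @export
initial_wavepacket <- function(m, basis, initial_state) {
  s <- match(initial_state, m$state_labels)
  if (is.na(s))
    stop("unknown state label '", initial_state, "'; model has: ",
         paste(m$state_labels, collapse = ", "))
  if (length(basis$sizes) != n_modes(m))
    stop("basis/mode mismatch")
  dim_nuc <- if (n_modes(m) > 0) prod(basis$sizes) else 1L
  coef <- complex(real = numeric(n_states(m) * dim_nuc))
  coef[(s - 1) * dim_nuc + 1] <- 1 + 0i
  structure(list(coef = coef, state_labels = m$state_labels, basis = basis,
                 dim_nuc = dim_nuc, time = 0),
            class = "wavepacket")
}

# one complex matvec through a real sparse matrix (packed as a two-column
# real product so the matrix is traversed once)
cplx_matvec <- function(H, z) {
  W <- as.matrix(H %*% cbind(Re(z), Im(z)))
  complex(real = W[, 1], imaginary = W[, 2])
}

# exp(-i * dt/hbar * H) psi by Lanczos; returns list(psi, err, m_used).
# T_m is real symmetric tridiagonal because H is real symmetric.
lanczos_expv <- function(H, psi, dt, m_max = 30L, tol = 1e-10) {
  nrm <- sqrt(sum(Mod(psi)^2))
  if (nrm == 0) return(list(psi = psi, err = 0, m = 0L))
  V <- matrix(0i, length(psi), m_max)
  alpha <- numeric(m_max)
  beta <- numeric(m_max)       # beta[j] links v_j and v_{j+1}
  V[, 1] <- psi / nrm
  w <- cplx_matvec(H, V[, 1])
  alpha[1] <- Re(sum(Conj(V[, 1]) * w))
  w <- w - alpha[1] * V[, 1]
  m <- 1L
  while (m < m_max) {
    b <- sqrt(sum(Mod(w)^2))
    if (b < 1e-13) { beta[m] <- 0; break }   # happy breakdown: exact subspace
    beta[m] <- b
    V[, m + 1] <- w / b
    w <- cplx_matvec(H, V[, m + 1])
    alpha[m + 1] <- Re(sum(Conj(V[, m + 1]) * w))
    w <- w - alpha[m + 1] * V[, m + 1] - b * V[, m]
    # full reorthogonalization keeps the small subspace numerically clean
    h <- crossprod(Conj(V[, seq_len(m + 1), drop = FALSE]), w)
    w <- w - V[, seq_len(m + 1), drop = FALSE] %*% h
    m <- m + 1L
  }
  Tm <- diag(alpha[seq_len(m)], m, m)
  if (m > 1) {
    idx <- cbind(seq_len(m - 1), seq_len(m - 1) + 1)
    Tm[idx] <- beta[seq_len(m - 1)]
    Tm[idx[, 2:1, drop = FALSE]] <- beta[seq_len(m - 1)]
  }
  eg <- eigen(Tm, symmetric = TRUE)
  phase <- exp(-1i * dt / HBAR_EV_FS * eg$values)
  w1 <- eg$vectors %*% (phase * eg$vectors[1, ])
  err <- if (m < m_max && beta[m] == 0) 0 else beta[m] * Mod(w1[m])
  psi_new <- nrm * as.vector(V[, seq_len(m), drop = FALSE] %*% w1)
  list(psi = psi_new, err = err, m = m)
}

# advance by dt with recursive bisection until the Krylov residual meets tol
krylov_step <- function(H, psi, dt, m_max, tol, depth = 0L) {
  st <- lanczos_expv(H, psi, dt, m_max = m_max, tol = tol)
  if (st$err <= tol || depth >= 12L) return(st$psi)
  half <- krylov_step(H, psi, dt / 2, m_max, tol / 2, depth + 1L)
  krylov_step(H, half, dt / 2, m_max, tol / 2, depth + 1L)
}

#' Propagate a wavepacket on an LVC model
#'
#' Unitary time evolution under the assembled LVC Hamiltonian, sampled on a
#' fixed output grid.  Records diabatic populations, electronic coherence
#' magnitudes (modulus of the nuclear-traced electronic density matrix),
#' energy and norm (both conserved to the requested tolerance), per-mode
#' coordinate expectations, and a basis-leakage monitor (population in the
#' top two ladder levels of any mode).
#'
#' @param m a [vibronic_model()].
#' @param basis a [basis_spec()].
#' @param psi0 a [initial_wavepacket()]; alternatively give `initial_state`.
#' @param t_final final time (fs).
#' @param dt_out output sampling interval (fs).
#' @param tol target unitarity/accuracy tolerance per output step.
#' @param initial_state state label used when `psi0` is `NULL`.
#' @param track_q logical: record `<q_k>(t)` per mode.
#' @param m_max maximal Krylov dimension per step.
#' @param leak_warn leakage fraction above which a warning names the mode.
#' @return An object of class `lvc_trajectory` with elements `time`, `pop`
#'   (matrix, one column per state), `coh` (matrix, one column per state
#'   pair), `energy`, `norm`, `qexp`, `leak`, and the model/basis.
#' @examples
#' m <- vibronic_model(c("D", "A"), E = c(0, 0),
#'                     V0 = matrix(c(0, .1, .1, 0), 2))
#' tr <- propagate(m, basis_spec(integer(0)), initial_state = "D",
#'                 t_final = 10, dt_out = 0.5)
#' max(tr$pop[, "A"])  # Rabi inversion
#' @export
propagate <- function(m, basis, psi0 = NULL, t_final = 200, dt_out = 0.25,
                      tol = 1e-9, initial_state = NULL, track_q = TRUE,
                      m_max = 30L, leak_warn = 0.01) {
  if (t_final <= 0) stop("t_final must be positive")
  if (dt_out <= 0 || dt_out > t_final) stop("dt_out must lie in (0, t_final]")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(psi0)) {
    if (is.null(initial_state))
      stop("give either psi0 or initial_state")
    psi0 <- initial_wavepacket(m, basis, initial_state)
  }
  ham <- build_hamiltonian(m, basis)
  ns <- n_states(m)
  nm <- n_modes(m)
  dim_nuc <- ham$dim_nuc
  if (length(psi0$coef) != ham$dim)
    stop("wavepacket dimension does not match model/basis")

  times <- seq(0, t_final, by = dt_out)
  nt <- length(times)
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  pair_names <- paste(m$state_labels[pairs[, 1]], m$state_labels[pairs[, 2]],
                      sep = "|")
  pop <- matrix(NA_real_, nt, ns, dimnames = list(NULL, m$state_labels))
  coh <- matrix(NA_real_, nt, nrow(pairs), dimnames = list(NULL, pair_names))
  energy <- norm_t <- leak <- numeric(nt)
  qexp <- if (track_q && nm > 0)
    matrix(NA_real_, nt, nm, dimnames = list(NULL, m$mode_labels)) else NULL

  # per-mode masks for occupation of the top two ladder levels (leak monitor)
  leak_mask <- NULL
  if (nm > 0) {
    leak_mask <- matrix(FALSE, nm, dim_nuc)
    occ <- arrayInd(seq_len(dim_nuc), .dim = rev(basis$sizes))
    for (k in seq_len(nm)) {
      lev <- occ[, nm - k + 1] - 1  # mode k is the slowest index
      leak_mask[k, ] <- lev >= basis$sizes[k] - 2
    }
  }

  psi <- psi0$coef
  worst_mode <- NA_integer_
  step_tol <- tol
  for (it in seq_len(nt)) {
    if (it > 1) psi <- krylov_step(ham$H, psi, dt_out, m_max, step_tol)
    Cmat <- matrix(psi, dim_nuc, ns)
    prob_state <- colSums(Mod(Cmat)^2)
    pop[it, ] <- prob_state
    rho <- crossprod(Conj(Cmat), Cmat)   # ns x ns nuclear-traced density
    coh[it, ] <- Mod(rho[pairs])
    hp <- cplx_matvec(ham$H, psi)
    energy[it] <- Re(sum(Conj(psi) * hp))
    norm_t[it] <- sum(Mod(psi)^2)
    if (nm > 0) {
      prob_nuc <- rowSums(Mod(Cmat)^2)
      lk <- as.vector(leak_mask %*% prob_nuc)
      leak[it] <- max(lk)
      if (leak[it] >= max(leak[seq_len(it)])) worst_mode <- which.max(lk)
      if (track_q) for (k in seq_len(nm)) {
        qc <- 0
        for (s in seq_len(ns))
          qc <- qc + Re(sum(Conj(Cmat[, s]) *
                              cplx_matvec(ham$Q[[k]], Cmat[, s])))
        qexp[it, k] <- qc
      }
    }
  }
  if (nm > 0 && max(leak) > leak_warn)
    warning("basis leakage: population ", signif(max(leak), 3),
            " in the top two ladder levels (worst mode ", worst_mode,
            "); increase basis sizes")
  structure(list(time = times, pop = pop, coh = coh, energy = energy,
                 norm = norm_t, qexp = qexp, leak = leak, model = m,
                 basis = basis, dt_out = dt_out, tol = tol),
            class = "lvc_trajectory")
}

#' @method print lvc_trajectory
#' @export
print.lvc_trajectory <- function(x, ...) {
  nt <- length(x$time)
  cat("LVC trajectory: ", nt, " samples over ", max(x$time), " fs (dt_out = ",
      x$dt_out, " fs)\n", sep = "")
  cat("  final populations:",
      paste(sprintf("%s=%.4f", colnames(x$pop), x$pop[nt, ]),
            collapse = ", "), "\n")
  cat("  norm drift:", format(max(abs(x$norm - 1)), digits = 3),
      " energy drift (eV):",
      format(max(abs(x$energy - x$energy[1])), digits = 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.lvc_trajectory <- function(x, ...) {
  d <- data.frame(time_fs = x$time)
  p <- as.data.frame(x$pop); names(p) <- paste0("pop_", colnames(x$pop))
  cpairs <- sub("\\|", "_", colnames(x$coh))
  co <- as.data.frame(x$coh); names(co) <- paste0("coh_", cpairs)
  d <- cbind(d, p, co, energy_eV = x$energy, norm = x$norm)
  if (!is.null(x$qexp)) {
    q <- as.data.frame(x$qexp)
    names(q) <- paste0("q_", seq_len(ncol(q)))
    d <- cbind(d, q)
  }
  d
}

#' @export
plot.lvc_trajectory <- function(x, what = c("pop", "coh", "q"), ...) {
  what <- match.arg(what)
  y <- switch(what, pop = x$pop, coh = x$coh, q = x$qexp)
  if (is.null(y)) stop("nothing recorded for '", what, "'")
  graphics::matplot(x$time, y, type = "l", lty = 1, xlab = "time (fs)",
                    ylab = switch(what, pop = "diabatic population",
                                  coh = "|coherence|", q = "<q>"), ...)
  graphics::legend("topright", colnames(y), col = seq_len(ncol(y)), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Electronic coherence between two diabatic states
#'
#' Time series of the modulus of the off-diagonal element of the electronic
#' density matrix obtained by tracing the wavepacket over all nuclear degrees
#' of freedom.  Bounded by the Cauchy-Schwarz limit
#' \eqn{|\rho_{ij}| \le \sqrt{P_i P_j} \le 1/2}.
#'
#' @param traj an `lvc_trajectory`.
#' @param pair character vector of two state labels.
#' @return Numeric vector along `traj$time`.
#' @export
coherences <- function(traj, pair) {
  if (length(pair) != 2) stop("'pair' must name two states")
  labs <- colnames(traj$pop)
  if (!all(pair %in% labs))
    stop("unknown state in pair; trajectory has: ",
         paste(labs, collapse = ", "))
  nm1 <- paste(pair[1], pair[2], sep = "|")
  nm2 <- paste(pair[2], pair[1], sep = "|")
  j <- match(c(nm1, nm2), colnames(traj$coh))
  traj$coh[, j[!is.na(j)][1]]
}

#' Classify the energy-transfer pathway of a trajectory
#'
#' Labels a trajectory `"direct"` when the charge-transfer state is never
#' appreciably populated, `"ct_trapped"` when population remains stuck there
#' at the end of the run, and `"ct_mediated"` otherwise (the CT state acts as
#' a transient doorway).
#'
#' @param traj an `lvc_trajectory`.
#' @param ct_label label of the CT state (default `"CT"`).
#' @param thresholds list with `peak` (doorway detection threshold on
#'   max P_CT, default 0.2) and `trapped` (final-population threshold,
#'   default 0.5).
#' @return One of `"direct"`, `"ct_mediated"`, `"ct_trapped"`.
#' @export
classify_pathway <- function(traj, ct_label = "CT",
                             thresholds = list(peak = 0.2, trapped = 0.5)) {
  if (!ct_label %in% colnames(traj$pop))
    stop("trajectory has no state '", ct_label, "'")
  pct <- traj$pop[, ct_label]
  if (max(pct) < thresholds$peak) return("direct")
  if (pct[length(pct)] >= thresholds$trapped) return("ct_trapped")
  "ct_mediated"
}

#' Population-transfer burst times
#'
#' Times of the local maxima of the acceptor population growth rate
#' dP/dt (finite differences on the output grid).  When a single tuning mode
#' sweeps two surfaces through degeneracy twice per vibrational period, the
#' mean spacing of these bursts is half the vibrational period.
#'
#' @param traj an `lvc_trajectory`.
#' @param state acceptor state label.
#' @param min_frac optional noise guard: discard maxima whose rate is below
#'   this fraction of the largest rate (default 0 keeps every strict local
#'   maximum, the operational definition).
#' @return Numeric vector of burst times (fs); use `mean(diff(...))` for the
#'   burst period.
#' @export
burst_times <- function(traj, state, min_frac = 0) {
  p <- traj$pop[, state]
  t <- traj$time
  dp <- c(NA, (p[-(1:2)] - p[1:(length(p) - 2)]) /
               (t[-(1:2)] - t[1:(length(t) - 2)]), NA)
  n <- length(dp)
  pk <- which(!is.na(dp) & dp >= c(Inf, dp[-n]) & dp > c(dp[-1], Inf))
  if (min_frac > 0) pk <- pk[dp[pk] > min_frac * max(dp, na.rm = TRUE)]
  t[pk]
}
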