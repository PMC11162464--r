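#' Linear vibronic coupling (LVC) model
#'
#' Container for a multi-state, multi-mode LVC Hamiltonian specification:
#' diabatic vertical energies `E` (eV), harmonic mode frequencies `omega`
#' (cm^-1), intrastate gradients (tuning constants) `kappa` (eV per
#' dimensionless coordinate), interstate vibronic couplings `lam` (eV) and
#' constant electronic couplings `V0` (eV).  Diabatic states keep their
#' physical character (e.g. a locally excited "La", a charge-transfer "CT"
#' and an acceptor "Nic" state), so populations in this basis are directly
#' comparable to kinetic schemes.
#'
#' @param state_labels character vector of unique diabatic state labels.
#' @param E numeric vector of diabatic vertical energies (eV), one per state.
#' @param omega numeric vector of mode frequencies (cm^-1), strictly positive.
#' @param kappa `n_states x n_modes` matrix of intrastate gradients (eV);
#'   defaults to zeros.
#' @param lam `n_states x n_states x n_modes` array of interstate vibronic
#'   couplings (eV), symmetric in the first two indices with zero diagonal;
#'   defaults to zeros.
#' @param V0 `n_states x n_states` symmetric matrix of constant electronic
#'   couplings (eV) with zero diagonal; defaults to zeros.
#' @param mode_labels optional character vector of mode names.
#' @return An object of class `vibronic_model`.
#' @seealso [ablate()], [build_hamiltonian()], [propagate()]
#' @examples
#' m <- vibronic_model(c("La", "Nic"), E = c(4.7, 4.2), omega = 1600,
#'                     kappa = matrix(c(-0.2, 0), 2, 1))
#' m
#' @export
vibronic_model <- function(state_labels, E, omega = numeric(0),
                           kappa = NULL, lam = NULL, V0 = NULL,
                           mode_labels = NULL) {
  ns <- length(state_labels)
  nm <- length(omega)
  if (is.null(kappa)) kappa <- matrix(0, ns, nm)
  if (is.null(lam))   lam   <- array(0, c(ns, ns, nm))
  if (is.null(V0))    V0    <- matrix(0, ns, ns)
  kappa <- as.matrix(kappa)
  V0 <- as.matrix(V0)
  if (nm == 1 && is.null(dim(lam))) lam <- array(lam, c(ns, ns, 1))
  if (is.null(mode_labels)) {
    mode_labels <- if (nm > 0) sprintf("mode%02d_%gcm1", seq_len(nm), omega)
                   else character(0)
  }
  dimnames(kappa) <- list(state_labels, mode_labels)
  dimnames(V0) <- list(state_labels, state_labels)
  dimnames(lam) <- list(state_labels, state_labels, mode_labels)
  m <- structure(list(
    state_labels = as.character(state_labels),
    E = as.numeric(E),
    omega = as.numeric(omega),
    kappa = kappa,
    lam = lam,
    V0 = V0,
    mode_labels = mode_labels,
    ablation = list(electronic = FALSE, interstate_vibronic = FALSE,
                    intrastate_tuning = FALSE)
  ), class = "vibronic_model")
  validate_vibronic_model(m)
}

#' Validate an LVC model
#'
#' Checks all `vibronic_model` invariants (positive frequencies, symmetric
#' coupling tables with zero diagonal, finite entries, unique labels) and
#' stops with an error naming the offending field.
#'
#' @param m a `vibronic_model`.
#' @return `m`, invisibly usable, after validation.
#' @export
validate_vibronic_model <- function(m) {
  ns <- length(m$state_labels)
  nm <- length(m$omega)
  if (anyDuplicated(m$state_labels))
    stop("invalid vibronic_model: 'state_labels' must be unique")
  if (length(m$E) != ns || !all(is.finite(m$E)))
    stop("invalid vibronic_model: 'E' must be ", ns, " finite energies (eV)")
  if (nm > 0 && (!all(is.finite(m$omega)) || any(m$omega <= 0)))
    stop("invalid vibronic_model: 'omega' must be strictly positive (cm^-1)")
  if (!all(dim(m$kappa) == c(ns, nm)) || !all(is.finite(m$kappa)))
    stop("invalid vibronic_model: 'kappa' must be a finite ", ns, "x", nm,
         " matrix (eV)")
  if (!all(dim(m$lam) == c(ns, ns, nm)) || !all(is.finite(m$lam)))
    stop("invalid vibronic_model: 'lam' must be a finite ", ns, "x", ns, "x",
         nm, " array (eV)")
  if (!all(dim(m$V0) == c(ns, ns)) || !all(is.finite(m$V0)))
    stop("invalid vibronic_model: 'V0' must be a finite ", ns, "x", ns,
         " matrix (eV)")
  if (!isTRUE(all.equal(m$V0, t(m$V0), tolerance = 1e-12)) ||
      any(abs(diag(m$V0)) > 0))
    stop("invalid vibronic_model: 'V0' must be symmetric with zero diagonal")
  for (k in seq_len(nm)) {
    lk <- matrix(m$lam[, , k], ns, ns)
    if (!isTRUE(all.equal(lk, t(lk), tolerance = 1e-12)) ||
        any(abs(diag(lk)) > 0))
      stop("invalid vibronic_model: 'lam' must be symmetric with zero ",
           "diagonal for every mode (mode ", k, ")")
  }
  m
}

n_states <- function(m) length(m$state_labels)
n_modes <- function(m) length(m$omega)

#' @method print vibronic_model
#' @export
print.vibronic_model <- function(x, ...) {
  cat("LVC vibronic model:", n_states(x), "diabatic states,",
      n_modes(x), "modes\n")
  cat("  states:", paste(sprintf("%s (%.4g eV)", x$state_labels, x$E),
                         collapse = ", "), "\n")
  if (n_modes(x) > 0)
    cat("  modes (cm^-1):", paste(signif(x$omega, 6), collapse = ", "), "\n")
  offd <- x$V0[upper.tri(x$V0)]
  if (length(offd)) cat("  |V0| range (eV):", signif(min(abs(offd)), 3), "-",
                        signif(max(abs(offd)), 3), "\n")
  ab <- names(Filter(isTRUE, x$ablation))
  if (length(ab)) cat("  ablated:", paste(ab, collapse = ", "), "\n")
  invisible(x)
}

#' Switch off a class of couplings (ablation)
#'
#' Returns a copy of the model with one class of terms zeroed: the constant
#' electronic couplings (`electronic`), the interstate vibronic couplings
#' (`interstate_vibronic`), or the intrastate tuning gradients
#' (`intrastate_tuning`).  Used to dissect which couplings drive population
#' transfer, e.g. forcing purely electronic dynamics by removing all tuning.
#'
#' @param m a `vibronic_model`.
#' @param which one of `"none"`, `"electronic"`, `"interstate_vibronic"`,
#'   `"intrastate_tuning"`.
#' @param mode_subset optional integer vector of mode indices to which the
#'   ablation is restricted (ignored for `"electronic"`).
#' @return A `vibronic_model` with the selected terms set to zero; everything
#'   else identical to the input.
#' @examples
#' m <- vibronic_model(c("A", "B"), c(0, 1), 1600,
#'                     V0 = matrix(c(0, .1, .1, 0), 2))
#' ablate(m, "electronic")$V0
#' @export
ablate <- function(m, which = c("none", "electronic", "interstate_vibronic",
                                "intrastate_tuning"),
                   mode_subset = NULL) {
  which <- match.arg(which)
  if (!is.null(mode_subset)) {
    mode_subset <- as.integer(mode_subset)
    if (length(mode_subset) &&
        (min(mode_subset) < 1 || max(mode_subset) > n_modes(m)))
      stop("mode_subset out of range: model has ", n_modes(m), " modes")
  } else {
    mode_subset <- seq_len(n_modes(m))
  }
  out <- m
  if (which == "none") return(out)
  if (which == "electronic") {
    out$V0[] <- 0
    out$ablation$electronic <- TRUE
  } else if (which == "interstate_vibronic") {
    out$lam[, , mode_subset] <- 0
    if (identical(mode_subset, seq_len(n_modes(m))))
      out$ablation$interstate_vibronic <- TRUE
  } else {
    out$kappa[, mode_subset] <- 0
    if (identical(mode_subset, seq_len(n_modes(m))))
      out$ablation$intrastate_tuning <- TRUE
  }
  out
}

#' Zero every coupling into one state
#'
#' Removes a state from the coupling network by zeroing all constant
#' electronic couplings and interstate vibronic couplings involving it (its
#' energy and tuning gradients stay).  Used as the control in which the
#' charge-transfer doorway is switched off.
#'
#' @param m a `vibronic_model`.
#' @param state a state label of `m`.
#' @return A `vibronic_model` with the state decoupled.
#' @export
ablate_state_couplings <- function(m, state) {
  i <- match(state, m$state_labels)
  if (is.na(i)) stop("unknown state label '", state, "'")
  out <- m
  out$V0[i, ] <- out$V0[, i] <- 0
  out$lam[i, , ] <- 0
  out$lam[, i, ] <- 0
  out
}

#' Primitive basis specification
#'
#' Number of harmonic-ladder levels retained per mode, with an optional
#' system/bath tier label per mode.  System modes (largest
#' gradients/couplings) get a larger primitive basis than bath modes,
#' mirroring common multiconfigurational practice.
#'
#' @param sizes integer vector, one entry per mode, each >= 2.
#' @param tier optional character vector (`"system"` or `"bath"`) per mode.
#' @return An object of class `basis_spec`.
#' @seealso [tiered_basis()]
#' @export
basis_spec <- function(sizes, tier = NULL) {
  sizes <- as.integer(sizes)
  if (length(sizes) && any(sizes < 2))
    stop("basis_spec: all primitive-basis sizes must be >= 2")
  if (is.null(tier)) tier <- rep("system", length(sizes))
  if (length(tier) != length(sizes) || !all(tier %in% c("system", "bath")))
    stop("basis_spec: 'tier' must be 'system'/'bath', one per mode")
  structure(list(sizes = sizes, tier = tier), class = "basis_spec")
}

#' Two-tier basis for a model
#'
#' Assigns `n_system` levels to the listed system modes and `n_bath` levels to
#' the rest.  Defaults (30/15) follow the usual primitive counts for
#' system/bath partitions of LVC dynamics.
#'
#' @param m a `vibronic_model`.
#' @param system_modes integer indices of system-tier modes (default: all).
#' @param n_system,n_bath ladder sizes for the two tiers.
#' @return A `basis_spec` covering every mode of `m` exactly once.
#' @export
tiered_basis <- function(m, system_modes = seq_len(n_modes(m)),
                         n_system = 30L, n_bath = 15L) {
  nm <- n_modes(m)
  if (length(system_modes) && (min(system_modes) < 1 || max(system_modes) > nm))
    stop("tiered_basis: system_modes out of range")
  sizes <- rep(as.integer(n_bath), nm)
  tier <- rep("bath", nm)
  sizes[system_modes] <- as.integer(n_system)
  tier[system_modes] <- "system"
  basis_spec(sizes, tier)
}

#' @method print basis_spec
#' @export
print.basis_spec <- function(x, ...) {
  cat("basis_spec:", length(x$sizes), "modes; sizes",
      paste(x$sizes, collapse = ","), "\n")
  invisible(x)
}
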