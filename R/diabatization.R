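# Fragment Excitation Difference (FED) diabatization: the excitation-
# difference matrix delta_x has eigenvalues +1/-1 for states locally excited
# on either fragment and 0 for the charge-transfer state; its eigenvectors
# rotate the adiabatic Hamiltonian (and gradients) to the diabatic basis.

#' FED input bundle
#'
#' @param H_ad adiabatic electronic Hamiltonian (eV): a diagonal matrix or a
#'   vector of adiabatic energies.
#' @param delta_x symmetric excitation-difference matrix in the adiabatic
#'   basis (dimensionless).
#' @param gradients optional `n_states x n_modes` matrix of adiabatic-state
#'   gradients (eV) at the Franck-Condon point.
#' @return An object of class `fed_input`.
#' @export
fed_input <- function(H_ad, delta_x, gradients = NULL) {
  if (is.vector(H_ad)) H_ad <- diag(H_ad, length(H_ad))
  H_ad <- as.matrix(H_ad); delta_x <- as.matrix(delta_x)
  n <- nrow(H_ad)
  if (!all(dim(H_ad) == c(n, n)) || !all(dim(delta_x) == c(n, n)))
    stop("fed_input: H_ad and delta_x must be square matrices of equal size")
  if (!isTRUE(all.equal(delta_x, t(delta_x), tolerance = 1e-10)))
    stop("fed_input: delta_x must be symmetric")
  if (!isTRUE(all.equal(H_ad, t(H_ad), tolerance = 1e-10)))
    stop("fed_input: H_ad must be symmetric")
  if (!is.null(gradients)) {
    gradients <- as.matrix(gradients)
    if (nrow(gradients) != n)
      stop("fed_input: gradients must have one row per state")
  }
  structure(list(H_ad = H_ad, delta_x = delta_x, gradients = gradients),
            class = "fed_input")
}

#' Fragment-excitation-difference diabatization
#'
#' Diagonalizes the excitation-difference matrix; eigenvalues near +1 and -1
#' identify the states locally excited on each fragment, an eigenvalue near 0
#' the charge-transfer state.  The (orthogonal) eigenvector matrix transforms
#' the adiabatic Hamiltonian into the diabatic one, whose off-diagonal
#' elements are the electronic couplings V; adiabatic gradients are rotated
#' identically, yielding the diabatic tuning (`kappa`, diagonal) and
#' interstate vibronic coupling (`lam`, off-diagonal) tables per mode.
#'
#' Gauge: eigenvector signs are fixed by making the largest-magnitude
#' component positive, columns ordered by descending delta_x eigenvalue.
#'
#' @param input a [fed_input()].
#' @param eigenvalue_tol how far an eigenvalue may sit from its nearest
#'   target in \{+1, -1, 0\} before the diabatic character is declared
#'   ambiguous (default 0.2).
#' @return An object of class `fed_result`: `U` (orthogonal), `H_dia` (eV),
#'   `eigenvalues`, `labels` (`"LE+"`, `"LE-"`, `"CT"`), `V` (off-diagonal of
#'   `H_dia`), and, when gradients were given, `kappa` and `lam`.
#' @examples
#' r <- fed_diabatize(fed_input(c(4, 5), matrix(c(0, 1, 1, 0), 2)))
#' diag(r$H_dia)  # (4.5, 4.5): symmetric homodimer pair
#' @export
fed_diabatize <- function(input, eigenvalue_tol = 0.2) {
  if (!inherits(input, "fed_input")) input <- do.call(fed_input, input)
  eg <- eigen(input$delta_x, symmetric = TRUE)
  vals <- eg$values          # descending
  if (length(vals) > 1 && min(abs(diff(vals))) < 1e-8)
    stop("degenerate delta_x eigenvalues: diabatic characters cannot be ",
         "assigned automatically; disambiguate manually")
  U <- eg$vectors
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  targets <- c(`LE+` = 1, `LE-` = -1, CT = 0)
  lab <- character(length(vals))
  for (j in seq_along(vals)) {
    d <- abs(vals[j] - targets)
    if (min(d) > eigenvalue_tol)
      stop("ambiguous diabatic character: delta_x eigenvalue ",
           signif(vals[j], 4), " is farther than ", eigenvalue_tol,
           " from every target in {+1, -1, 0}")
    lab[j] <- names(targets)[which.min(d)]
  }
  H_dia <- t(U) %*% input$H_ad %*% U
  H_dia <- (H_dia + t(H_dia)) / 2
  dimnames(H_dia) <- list(lab, lab)
  V <- H_dia; diag(V) <- 0
  out <- list(U = U, H_dia = H_dia, eigenvalues = vals, labels = lab, V = V)
  if (!is.null(input$gradients)) {
    nmod <- ncol(input$gradients)
    ns <- nrow(H_dia)
    kappa <- matrix(0, ns, nmod, dimnames = list(lab, NULL))
    lam <- array(0, c(ns, ns, nmod), dimnames = list(lab, lab, NULL))
    for (k in seq_len(nmod)) {
      G <- t(U) %*% diag(input$gradients[, k], ns) %*% U
      G <- (G + t(G)) / 2
      kappa[, k] <- diag(G)
      diag(G) <- 0
      lam[, , k] <- G
    }
    out$kappa <- kappa
    out$lam <- lam
  }
  structure(out, class = "fed_result")
}

#' @method print fed_result
#' @export
print.fed_result <- function(x, ...) {
  cat("FED diabatization:", length(x$labels), "states\n")
  cat("  delta_x eigenvalues:",
      paste(sprintf("%s=%.4f", x$labels, x$eigenvalues), collapse = ", "),
      "\n")
  cat("  diabatic energies (eV):",
      paste(signif(diag(x$H_dia), 6), collapse = ", "), "\n")
  off <- x$V[upper.tri(x$V)]
  cat("  |V| (eV):", paste(signif(abs(off), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mean coupling-to-gap ratio |V/Delta|
#'
#' Arithmetic mean of the absolute ratio between electronic coupling and
#' diabatic energy gap over a set of conformations; values of order 0.2-0.3
#' indicate strong wavefunction mixing at the Franck-Condon point.
#'
#' @param V numeric vector of couplings (eV).
#' @param gap numeric vector of energy gaps (eV), same length, nonzero.
#' @return Mean of `|V/gap|`.
#' @export
coupling_gap_ratio <- function(V, gap) {
  if (length(V) != length(gap))
    stop("V and gap must have equal length")
  if (any(gap == 0)) stop("zero energy gap: ratio undefined")
  mean(abs(V / gap))
}

#' Electron-hole centroid distance
#'
#' Euclidean distance (in Angstrom) between the centroids of the hole and the
#' transferred electron of a charge-transfer state; stacked dimer geometries
#' typically give 3-5 Angstrom.
#'
#' @param hole_centroid,electron_centroid numeric length-3 Cartesian
#'   coordinates (Angstrom).
#' @return Nonnegative distance (Angstrom).
#' @export
eh_distance <- function(hole_centroid, electron_centroid) {
  if (length(hole_centroid) != 3 || length(electron_centroid) != 3 ||
      !all(is.finite(c(hole_centroid, electron_centroid))))
    stop("centroids must be finite length-3 coordinates")
  sqrt(sum((hole_centroid - electron_centroid)^2))
}

#' Is the CT state solvent-accessible?
#'
#' A charge-transfer state lying more than `threshold` (default 0.5 eV) above
#' the donor bright state in gas phase cannot be brought into resonance by
#' solvent fluctuations and is considered inaccessible.
#'
#' @param E_CT_gas,E_La gas-phase vertical energies (eV).
#' @param threshold accessibility window (eV).
#' @return `TRUE` iff `E_CT_gas - E_La <= threshold`.
#' @export
ct_accessible <- function(E_CT_gas, E_La, threshold = 0.5) {
  if (!all(is.finite(c(E_CT_gas, E_La)))) stop("energies must be finite")
  (E_CT_gas - E_La) <= threshold
}
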