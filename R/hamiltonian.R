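# Assembly of the LVC Hamiltonian on the electronic (x) nuclear product space.
# Basis ordering: full index = (state - 1) * D_nuc + nuclear index, i.e. full
# operators are kronecker(electronic, nuclear).  Within the nuclear space mode
# 1 is the slowest-varying index (kronecker over modes in order).

# position operator q on an n-level harmonic ladder:
# <n-1|q|n> = sqrt(n/2) (dimensionless mass-frequency-scaled coordinate)
ladder_q <- function(n) {
  if (n == 1) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  od <- sqrt(seq_len(n - 1) / 2)
  Matrix::bandSparse(n, n, k = c(-1, 1), diagonals = list(od, od),
                     symmetric = FALSE)
}

# number operator diag(0..n-1)
ladder_n <- function(n) Matrix::Diagonal(n, x = seq_len(n) - 1)

# lift a single-mode operator to the full nuclear space
mode_lift <- function(op, sizes, k) {
  left <- prod(sizes[seq_len(k - 1)])
  right <- prod(sizes[-seq_len(k)])
  out <- op
  if (left > 1) out <- Matrix::Diagonal(left) %x% out
  if (right > 1) out <- out %x% Matrix::Diagonal(right)
  out
}

#' Build the LVC Hamiltonian matrix
#'
#' Assembles the Hermitian operator
#' \deqn{H = \sum_k \tilde\omega_k (N_k + 1/2) \otimes 1 +
#'   \sum_i |i\rangle\langle i| (E_i + \sum_k \kappa_{ik} q_k) +
#'   \sum_{i \ne j} |i\rangle\langle j| (V^0_{ij} + \sum_k \lambda_{ijk} q_k)}
#' on the product of the electronic space and truncated harmonic ladders
#' (\eqn{q_k} couples occupations \eqn{n \leftrightarrow n \pm 1} with matrix
#' element \eqn{\sqrt{n/2}}).  Frequencies are converted from cm^-1 to eV
#' internally; the matrix is in eV.
#'
#' @param m a validated [vibronic_model()].
#' @param basis a [basis_spec()] covering every mode of `m`.
#' @return An object of class `lvc_hamiltonian`: a list with the sparse
#'   symmetric matrix `H` (eV), the nuclear dimension `dim_nuc`, the full
#'   dimension `dim`, and the model/basis used.
#' @examples
#' m <- vibronic_model("S1", E = 1.0)
#' build_hamiltonian(m, basis_spec(integer(0)))$H  # the scalar 1.0 eV
#' @export
build_hamiltonian <- function(m, basis) {
  validate_vibronic_model(m)
  if (!inherits(basis, "basis_spec")) stop("'basis' must be a basis_spec")
  ns <- n_states(m)
  nm <- n_modes(m)
  if (length(basis$sizes) != nm)
    stop("basis/mode mismatch: model has ", nm, " modes but basis covers ",
         length(basis$sizes))
  sizes <- basis$sizes
  dim_nuc <- if (nm > 0) prod(sizes) else 1L
  I_nuc <- Matrix::Diagonal(dim_nuc)

  # state-independent harmonic part (incl. zero-point energy), eV
  Hvib <- Matrix::Matrix(0, dim_nuc, dim_nuc, sparse = TRUE)
  Q <- vector("list", nm)  # full nuclear q_k operators, reused for couplings
  for (k in seq_len(nm)) {
    w <- cm1_to_ev(m$omega[k])
    Hvib <- Hvib + w * mode_lift(ladder_n(sizes[k]) +
                                   Matrix::Diagonal(sizes[k], 0.5), sizes, k)
    Q[[k]] <- mode_lift(ladder_q(sizes[k]), sizes, k)
  }

  blocks <- vector("list", ns * ns)  # column-major blocks of the full matrix
  zero <- Matrix::Matrix(0, dim_nuc, dim_nuc, sparse = TRUE)
  for (j in seq_len(ns)) for (i in seq_len(ns)) {
    if (i == j) {
      B <- Hvib + m$E[i] * I_nuc
      for (k in seq_len(nm)) if (m$kappa[i, k] != 0)
        B <- B + m$kappa[i, k] * Q[[k]]
    } else {
      B <- if (m$V0[i, j] != 0) m$V0[i, j] * I_nuc else zero
      for (k in seq_len(nm)) if (m$lam[i, j, k] != 0)
        B <- B + m$lam[i, j, k] * Q[[k]]
    }
    blocks[[(j - 1) * ns + i]] <- B
  }
  rows <- lapply(seq_len(ns), function(i)
    do.call(cbind, blocks[(seq_len(ns) - 1) * ns + i]))
  H <- methods::as(do.call(rbind, rows), "generalMatrix")
  H <- methods::as(H, "CsparseMatrix")
  structure(list(H = H, model = m, basis = basis, dim_nuc = dim_nuc,
                 dim = ns * dim_nuc, Q = Q),
            class = "lvc_hamiltonian")
}

#' @method print lvc_hamiltonian
#' @export
print.lvc_hamiltonian <- function(x, ...) {
  cat("LVC Hamiltonian:", n_states(x$model), "states x", x$dim_nuc,
      "nuclear basis states =", x$dim, "dimensions;",
      Matrix::nnzero(x$H), "nonzeros\n")
  invisible(x)
}
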