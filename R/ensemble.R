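# Solvent-disorder ensembles: the charge-transfer state energy fluctuates
# strongly with solvent configuration (Gaussian band of ~1 eV FWHM) while the
# locally excited states are comparatively stable.  Each disorder realization
# is propagated independently and the population maps are ordered by the
# CT - donor energy gap at the Franck-Condon point.

#' Sample solvent-disorder realizations of an LVC model
#'
#' Draws `n` copies of `base` with the CT vertical energy shifted by Gaussian
#' noise of the given FWHM and, optionally, every electronic/vibronic
#' coupling involving the CT state multiplied by `1 + coupling_jitter * N(0,1)`
#' (independently per entry, kept symmetric).  Frequencies and all
#' non-CT parameters are untouched (frozen solute, varying solvent).
#'
#' @param base a [vibronic_model()] containing `ct_label`.
#' @param n number of realizations.
#' @param ct_fwhm FWHM (eV) of the Gaussian CT-energy disorder.
#' @param coupling_jitter relative jitter of CT couplings (fraction).
#' @param seed RNG seed; draws are reproducible.
#' @param ct_label label of the CT state.
#' @return A list of `vibronic_model`s; each carries attribute `dE`, the
#'   realized `E_CT - E_donor` gap (donor = first state).
#' @export
sample_disorder <- function(base, n, ct_fwhm, coupling_jitter = 0,
                            seed = 1L, ct_label = "CT") {
  ict <- match(ct_label, base$state_labels)
  if (is.na(ict)) stop("base model has no state '", ct_label, "'")
  if (n < 1) stop("n must be >= 1")
  if (ct_fwhm < 0) stop("ct_fwhm must be >= 0")
  set.seed(seed)
  sigma <- fwhm_to_sigma(ct_fwhm)
  ns <- n_states(base)
  nm <- n_modes(base)
  others <- setdiff(seq_len(ns), ict)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- base
    m$E[ict] <- base$E[ict] + stats::rnorm(1, 0, sigma)
    if (coupling_jitter > 0) {
      for (j in others) {
        f <- 1 + coupling_jitter * stats::rnorm(1)
        m$V0[ict, j] <- m$V0[j, ict] <- base$V0[ict, j] * f
        for (k in seq_len(nm)) {
          fk <- 1 + coupling_jitter * stats::rnorm(1)
          m$lam[ict, j, k] <- m$lam[j, ict, k] <- base$lam[ict, j, k] * fk
        }
      }
    }
    attr(m, "dE") <- m$E[ict] - m$E[1]
    out[[i]] <- m
  }
  out
}

#' Propagate an ensemble of disorder realizations
#'
#' Runs one wavepacket propagation per model, classifies each trajectory's
#' pathway, and assembles per-state population maps whose rows are ordered by
#' the CT - donor energy gap (snapshot rank, not binned).  Per-snapshot
#' propagation failures are recorded and the ensemble continues; results are
#' independent of execution order.
#'
#' @param models list of `vibronic_model`s (e.g. from [sample_disorder()]).
#' @param basis a [basis_spec()] shared by all models.
#' @param t_final propagation time (fs).
#' @param initial_state initially excited state label.
#' @param dt_out output grid spacing (fs).
#' @param ct_label CT-state label used for gaps and pathway classes.
#' @param ... further arguments passed to [propagate()].
#' @return An object of class `eet_ensemble`: `snapshots` (data frame with
#'   `snapshot`, `dE_eV`, `class`, `t_ct_peak_fs`, `ok`), `trajectories`
#'   (list, in sorted order), `pop_maps` (per state: matrix snapshots x
#'   time), `time`.
#' @export
run_ensemble <- function(models, basis, t_final = 200, initial_state,
                         dt_out = 0.25, ct_label = "CT", ...) {
  if (!length(models)) stop("empty model list")
  dE <- vapply(models, function(m) {
    ict <- match(ct_label, m$state_labels)
    m$E[ict] - m$E[1]
  }, numeric(1))
  ord <- order(dE)
  trajs <- vector("list", length(models))
  cls <- rep(NA_character_, length(models))
  tpk <- rep(NA_real_, length(models))
  ok <- logical(length(models))
  for (i in seq_along(models)) {
    tr <- tryCatch(
      propagate(models[[ord[i]]], basis, t_final = t_final, dt_out = dt_out,
                initial_state = initial_state, track_q = FALSE, ...),
      error = function(e) e)
    if (inherits(tr, "error")) {
      trajs[[i]] <- NULL
      next
    }
    trajs[[i]] <- tr
    ok[i] <- TRUE
    cls[i] <- classify_pathway(tr, ct_label)
    pct <- tr$pop[, ct_label]
    tpk[i] <- tr$time[which.max(pct)]
  }
  good <- which(ok)
  if (!length(good)) stop("every snapshot failed to propagate")
  time <- trajs[[good[1]]]$time
  labs <- models[[1]]$state_labels
  pop_maps <- lapply(labs, function(s) {
    mp <- matrix(NA_real_, length(models), length(time))
    for (i in good) mp[i, ] <- trajs[[i]]$pop[, s]
    mp
  })
  names(pop_maps) <- labs
  snap <- data.frame(snapshot = ord, dE_eV = dE[ord], class = cls,
                     t_ct_peak_fs = tpk, ok = ok)
  structure(list(snapshots = snap, trajectories = trajs, pop_maps = pop_maps,
                 time = time, ct_label = ct_label),
            class = "eet_ensemble")
}

#' @method print eet_ensemble
#' @export
print.eet_ensemble <- function(x, ...) {
  cat("EET disorder ensemble:", nrow(x$snapshots), "snapshots;",
      sum(x$snapshots$ok), "propagated\n")
  cat("  dE range (eV):", signif(min(x$snapshots$dE_eV), 3), "..",
      signif(max(x$snapshots$dE_eV), 3), "\n")
  print(table(x$snapshots$class))
  invisible(x)
}

#' @export
plot.eet_ensemble <- function(x, state = x$ct_label, ...) {
  mp <- x$pop_maps[[state]]
  graphics::image(x$time, seq_len(nrow(mp)), t(mp),
                  xlab = "time (fs)", ylab = "snapshot (sorted by dE)",
                  main = paste("population of", state), ...)
  invisible(x)
}

#' Write an ensemble summary table
#'
#' Delimited text with one row per snapshot: id, energy gap, pathway class,
#' CT peak time, and populations at the requested sample times.
#'
#' @param ens an `eet_ensemble`.
#' @param path output file.
#' @param sample_times times (fs) at which populations are tabulated.
#' @return `path`, invisibly.
#' @export
write_ensemble_summary <- function(ens, path,
                                   sample_times = c(25, 50, 100, 200)) {
  d <- ens$snapshots
  labs <- names(ens$pop_maps)
  for (s in labs) for (tt in sample_times) {
    j <- which.min(abs(ens$time - tt))
    d[[sprintf("pop_%s_%gfs", s, ens$time[j])]] <- ens$pop_maps[[s]][, j]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
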