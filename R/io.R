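# Text-based file formats: LVC model files are a small JSON dialect with a
# schema version and explicit unit annotations; TA maps are delimited text
# with a JSON metadata sidecar; trajectories and ensemble summaries are TSV.

MODEL_SCHEMA_VERSION <- "1.0"

#' Write an LVC model file
#'
#' Single-document JSON with a `schema_version` field, explicit unit
#' annotations and 12 significant digits; [read_model()] round-trips it.
#'
#' @param m a [vibronic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  validate_vibronic_model(m)
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    units = list(E = "eV", omega = "cm^-1", kappa = "eV", lam = "eV",
                 V0 = "eV"),
    state_labels = m$state_labels,
    mode_labels = m$mode_labels,
    E = signif(m$E, 12),
    omega = signif(m$omega, 12),
    kappa = signif(unclass(m$kappa), 12),
    lam = lapply(seq_len(n_modes(m)),
                 function(k) signif(unclass(m$lam[, , k]), 12)),
    V0 = signif(unclass(m$V0), 12),
    ablation = m$ablation
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an LVC model file
#'
#' @param path a file written by [write_model()].
#' @return A validated `vibronic_model`.
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed model file '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$schema_version))
    stop("model file '", path, "': missing field 'schema_version'")
  if (!identical(as.character(doc$schema_version), MODEL_SCHEMA_VERSION))
    stop("model file '", path, "': schema version '", doc$schema_version,
         "' not supported (expected ", MODEL_SCHEMA_VERSION, ")")
  for (f in c("state_labels", "E", "omega"))
    if (is.null(doc[[f]]))
      stop("model file '", path, "': missing field '", f, "'")
  ns <- length(doc$state_labels)
  nm <- length(doc$omega)
  lam <- array(0, c(ns, ns, nm))
  if (nm > 0 && !is.null(doc$lam)) {
    lam_list <- doc$lam
    if (is.array(lam_list) && length(dim(lam_list)) == 3) {
      for (k in seq_len(nm)) lam[, , k] <- lam_list[k, , ]
    } else {
      for (k in seq_len(nm)) lam[, , k] <- as.matrix(lam_list[[k]])
    }
  }
  mode_labels <- as.character(unlist(doc$mode_labels))
  m <- vibronic_model(doc$state_labels, doc$E, as.numeric(unlist(doc$omega)),
                      kappa = if (nm == 0 || is.null(doc$kappa)) NULL
                              else matrix(unlist(doc$kappa), ns, nm),
                      lam = lam,
                      V0 = if (is.null(doc$V0)) NULL
                           else matrix(unlist(doc$V0), ns, ns),
                      mode_labels = if (length(mode_labels)) mode_labels
                                    else NULL)
  if (!is.null(doc$ablation)) m$ablation <- lapply(doc$ablation, isTRUE)
  m
}

#' Write / read a TA map
#'
#' Delimited text: first row the probe energies (eV), first column the delays
#' (fs), cells the differential absorption (mOD); IRF and pump metadata go to
#' a JSON sidecar `<path>.meta.json`.
#'
#' @param map a [ta_map()].
#' @param path output file.
#' @return `path` (writer) or a `ta_map` (reader).
#' @export
write_ta_map <- function(map, path) {
  stopifnot(inherits(map, "ta_map"))
  M <- cbind(delay_fs = map$delays, map$dA)
  colnames(M) <- c("delay_fs", signif(map$probes, 12))
  utils::write.table(format(M, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(irf_fwhm_fs = map$irf_fwhm,
                            pump_ev = map$pump_ev),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ta_map
#' @export
read_ta_map <- function(path) {
  M <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(irf_fwhm_fs = 0, pump_ev = NA_real_)
  ta_map(M[[1]], as.numeric(colnames(M)[-1]), as.matrix(M[, -1]),
         irf_fwhm = meta$irf_fwhm_fs, pump_ev = meta$pump_ev)
}

#' Write a trajectory as delimited text
#'
#' Columns: `time_fs`, one `pop_<label>` per state, one `coh_<i>_<j>` per
#' state pair, `energy_eV`, `norm`, and `q_<k>` per tracked mode; 12
#' significant digits.
#'
#' @param traj an `lvc_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  utils::write.table(format(d, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
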