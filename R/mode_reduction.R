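# Photoactive-mode ranking: a mode's activity score is the largest absolute
# gradient or interstate coupling it carries at the Franck-Condon point; the
# top-ranked modes are kept and partitioned into system and bath tiers.

#' Rank vibrational modes by Franck-Condon activity
#'
#' For each mode the score is the maximum over states and state pairs of
#' \{|kappa_ik|, |lambda_ijk|\}.  Modes with negligible score do not promote
#' population transfer and can be discarded.
#'
#' @param kappa_table `n_states x n_modes` matrix of intrastate gradients
#'   (eV), or a [vibronic_model()] (in which case `lambda_table` is ignored).
#' @param lambda_table `n_states x n_states x n_modes` array of interstate
#'   couplings (eV).
#' @param omega optional frequencies (cm^-1) carried through to the output.
#' @return A `mode_ranking` data frame with columns `mode`, `frequency_cm1`,
#'   `score_eV`, `rank` (1 = most active), and a placeholder `tier`.
#' @seealso [select_and_partition()]
#' @export
rank_modes <- function(kappa_table, lambda_table = NULL, omega = NULL) {
  if (inherits(kappa_table, "vibronic_model")) {
    m <- kappa_table
    lambda_table <- m$lam
    omega <- m$omega
    kappa_table <- m$kappa
  }
  kappa_table <- as.matrix(kappa_table)
  nm <- ncol(kappa_table)
  if (is.null(lambda_table))
    lambda_table <- array(0, c(nrow(kappa_table), nrow(kappa_table), nm))
  if (dim(lambda_table)[3] != nm)
    stop("kappa and lambda tables disagree on the number of modes")
  score <- vapply(seq_len(nm), function(k)
    max(abs(kappa_table[, k]), abs(lambda_table[, , k])), numeric(1))
  rk <- rank(-score, ties.method = "first")  # ties: ascending mode index
  out <- data.frame(mode = seq_len(nm),
                    frequency_cm1 = if (is.null(omega)) NA_real_ else omega,
                    score_eV = score,
                    rank = as.integer(rk),
                    tier = "discarded",
                    stringsAsFactors = FALSE)
  class(out) <- c("mode_ranking", "data.frame")
  out
}

#' Select the most active modes and split them into system/bath tiers
#'
#' Keeps the `n_select` highest-scoring modes, assigns the strongest
#' `n_system` of them to the system tier and the remainder to the bath tier;
#' everything else is discarded.  Ties break by ascending mode index.  An
#' optional `score_floor` additionally drops selected modes below a score
#' threshold (the count-driven selection is the primary rule).
#'
#' @param ranking a `mode_ranking` from [rank_modes()].
#' @param n_select number of modes to keep.
#' @param n_system number of those assigned to the system tier.
#' @param score_floor optional minimal score (eV) for selection.
#' @return The ranking with `tier` filled in (`"system"`, `"bath"`,
#'   `"discarded"`).
#' @examples
#' r <- rank_modes(matrix(c(0.5, 0.01, 0.03), 1, 3))
#' select_and_partition(r, n_select = 2, n_system = 1)$tier
#' @export
select_and_partition <- function(ranking, n_select, n_system,
                                 score_floor = NULL) {
  nm <- nrow(ranking)
  if (n_system > n_select || n_select > nm || n_system < 0)
    stop("need 0 <= n_system <= n_select <= number of modes (", nm, ")")
  tier <- rep("discarded", nm)
  sel <- ranking$rank <= n_select
  if (!is.null(score_floor)) sel <- sel & ranking$score_eV >= score_floor
  tier[sel & ranking$rank <= n_system] <- "system"
  tier[sel & ranking$rank > n_system] <- "bath"
  ranking$tier <- tier
  ranking
}

#' @method print mode_ranking
#' @export
print.mode_ranking <- function(x, ...) {
  cat("mode ranking:", nrow(x), "modes;",
      sum(x$tier == "system"), "system,", sum(x$tier == "bath"), "bath,",
      sum(x$tier == "discarded"), "discarded\n")
  print.data.frame(utils::head(x[order(x$rank), ], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a mode ranking as delimited text
#'
#' @param ranking a `mode_ranking`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
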