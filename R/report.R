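# Plateau diagnostics and the comparison report tying the EM-constrained
# decomposition and the PCA baseline together.

#' Detect the explained-variance plateau
#'
#' Returns the first factor count after which the curve stops rising by at
#' least `threshold_pp` percentage points, i.e. the suggested number of
#' principal modes (or latent variables). If the curve never flattens, the
#' last factor count is returned.
#'
#' @param theta_curve cumulative explained-variance fractions, one per
#'   factor count.
#' @param threshold_pp plateau threshold in percentage points of explained
#'   variance (default 0.1).
#' @return the plateau factor count (integer).
#' @export
detect_plateau <- function(theta_curve, threshold_pp = 0.1) {
  stopifnot(length(theta_curve) >= 1L)
  if (length(theta_curve) == 1L) return(1L)
  deltas_pp <- diff(theta_curve) * 100
  flat <- which(deltas_pp < threshold_pp)
  if (length(flat) == 0L) return(length(theta_curve))
  flat[1L]
}

#' Comparison report: EM decomposition vs PCA baseline
#'
#' Collects the explained-variance curves of the branch-and-bound result,
#' the greedy trace and (when given) the PCA baseline, detects the plateau
#' of each curve, and exports the weight matrix at the suggested number of
#' principal modes as heatmap-ready data.
#'
#' @param result a `pema_result` from [pema_fit()].
#' @param pca optionally, a `pema_pca` from [pca_variance_curve()]; when
#'   missing the report covers the EM decomposition only, with a warning.
#' @param threshold_pp plateau threshold, see [detect_plateau()].
#' @return an object of class `pema_report`: `curves` (data frame with one
#'   row per factor count), `plateau` (per method), `suggested_n_pem`,
#'   `selected_at_plateau`, `weights_at_plateau` (modes x experiments).
#' @export
pema_report <- function(result, pca = NULL, threshold_pp = 0.1) {
  stopifnot(inherits(result, "pema_result"))
  k <- seq_len(result$n_fac)
  greedy_curve <- rep(NA_real_, result$n_fac)
  greedy_curve[seq_along(result$greedy$theta_curve)] <- result$greedy$theta_curve
  curves <- data.frame(n_fac = k,
                       pema_theta = result$theta,
                       greedy_theta = greedy_curve)
  plateau <- list(pema = detect_plateau(result$theta, threshold_pp))
  if (!is.null(pca)) {
    stopifnot(inherits(pca, "pema_pca"))
    pca_curve <- rep(NA_real_, result$n_fac)
    take <- seq_len(min(result$n_fac, length(pca$variance_curve)))
    pca_curve[take] <- pca$variance_curve[take]
    curves$pca_theta <- pca_curve
    plateau$pca <- detect_plateau(pca$variance_curve, threshold_pp)
  } else {
    warning("no PCA baseline supplied; reporting the EM decomposition only",
            call. = FALSE)
  }
  at <- result$factors[[plateau$pema]]
  structure(list(curves = curves,
                 plateau = plateau,
                 threshold_pp = threshold_pp,
                 suggested_n_pem = plateau$pema,
                 selected_at_plateau = annotate_ids(
                   at$ids, result$problem$ambiguity$groups),
                 weights_at_plateau = at$weights),
            class = "pema_report")
}

#' @export
print.pema_report <- function(x, ...) {
  cat("Explained-variance comparison (percent, on scaled data)\n")
  tab <- x$curves
  for (col in setdiff(names(tab), "n_fac")) tab[[col]] <- round(100 * tab[[col]], 2)
  print(tab, row.names = FALSE)
  cat(sprintf("\nPlateau (rise < %.2f pp): %d principal modes",
              x$threshold_pp, x$suggested_n_pem))
  if (!is.null(x$plateau$pca))
    cat(sprintf("; PCA plateau at %d latent variables", x$plateau$pca))
  cat("\nSelected at plateau:", paste(x$selected_at_plateau, collapse = " "),
      "\n")
  invisible(x)
}
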