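# Greedy deflation core. A unit-norm mode's weights per experiment are its
# projections onto the residual, clipped at zero (weights must be
# nonnegative); its contribution is the rank-<=1 outer product; selecting
# the best mode and subtracting its contribution deflates the residual.
# Because clipping zeroes a column's weight exactly when the projection is
# negative, each deflation removes exactly sum(p^2) of residual energy, so
# the captured-variance bookkeeping is exact (direct and fast forms agree).

#' Nonnegative projection weights of one mode
#'
#' For a unit-norm mode vector, the per-experiment weight is the ordinary
#' least-squares projection `t(e) %*% V`, with negative values replaced by
#' zero: the nonnegativity of pathway weights is enforced per experiment,
#' so a weight vector may be partially clipped.
#'
#' @param e_n unit-norm mode vector (length = number of measured fluxes).
#' @param V residual flux matrix (fluxes x experiments).
#' @return numeric vector of nonnegative weights, one per experiment.
#' @export
project_weights <- function(e_n, V) {
  if (length(e_n) != nrow(V))
    stop("mode vector length does not match flux matrix rows", call. = FALSE)
  nrm <- sqrt(sum(e_n^2))
  if (abs(nrm - 1) > 1e-12)
    stop("mode vector must be unit-norm (got ", format(nrm), ")", call. = FALSE)
  pmax(as.numeric(crossprod(e_n, V)), 0)
}

#' Flux contribution of one weighted mode
#'
#' @param e_n unit-norm mode vector.
#' @param p nonnegative weight vector (one entry per experiment).
#' @return the rank-<=1 estimated flux matrix `e_n %o% p`.
#' @export
contribution <- function(e_n, p) {
  if (any(p < 0)) stop("weights must be nonnegative", call. = FALSE)
  outer(e_n, p)
}

#' Explained variance, direct form
#'
#' `1 - sum((V_mes - V_est)^2) / sum(V_mes^2)`: one minus the residual sum
#' of squares over the total *uncentered* sum of squares. May be negative
#' for a poor estimate; it is reported as computed, never clamped.
#'
#' @param V_mes measured flux matrix.
#' @param V_est estimated flux matrix of the same shape.
#' @return a fraction <= 1.
#' @export
explained_variance_direct <- function(V_mes, V_est) {
  if (!all(dim(V_mes) == dim(V_est)))
    stop("matrices must have the same shape", call. = FALSE)
  tot <- sum(V_mes^2)
  if (tot == 0) stop("measured flux matrix is all zero", call. = FALSE)
  1 - sum((V_mes - V_est)^2) / tot
}

#' Explained variance, fast form
#'
#' For weights produced by the sequential project-clip-deflate procedure,
#' the cumulative explained variance equals `sum(p^2) / sum(V_mes^2)`
#' without forming any reconstruction: each deflation removes exactly
#' `sum(p^2)` of residual energy.
#'
#' @param weights numeric vector or matrix of all weights produced so far.
#' @param V_mes the original measured flux matrix.
#' @return a fraction in `[0, 1]` (up to roundoff).
#' @export
explained_variance_fast <- function(weights, V_mes) {
  tot <- sum(V_mes^2)
  if (tot == 0) stop("measured flux matrix is all zero", call. = FALSE)
  if (length(weights) == 0L) return(0)
  sum(weights^2) / tot
}

#' Deflate a residual by a selected contribution
#'
#' @param V_iter current residual matrix.
#' @param V_est_selected contribution of the selected mode
#'   (see [contribution()]).
#' @return the next residual `V_iter - V_est_selected`.
#' @export
deflate <- function(V_iter, V_est_selected) {
  if (!all(dim(V_iter) == dim(V_est_selected)))
    stop("matrices must have the same shape", call. = FALSE)
  V_iter - V_est_selected
}

# Per-mode variance gains (fraction of total_ss) of all candidate columns
# on a residual; one clipped cross-product per call.
mode_gains <- function(E, V, total_ss) {
  P <- crossprod(E, V)
  P[P < 0] <- 0
  unname(rowSums(P * P)) / total_ss
}

# index of the maximal gain, ties within tie_tol broken towards the
# lexicographically lowest id
pick_best <- function(gains, ids, tie_tol) {
  top <- max(gains)
  tied <- which(gains >= top - tie_tol)
  tied[order(ids[tied])][1L]
}

#' Greedy best-first EM decomposition
#'
#' Iteratively scores every remaining candidate mode by the variance it
#' captures from the current residual, selects the best (ties towards the
#' lowest mode id), subtracts its contribution, and repeats. The iteration
#' stops when `n_fac` factors have been selected, when the number of
#' measured fluxes is reached, or when no mode captures any variance.
#' The resulting selection serves as the incumbent (lower bound) for
#' [branch_and_bound_fit()].
#'
#' @param problem a `pema_problem` from [build_problem()].
#' @param n_fac maximum number of modes to select.
#' @param tie_tol tolerance for tie-breaking on equal gains.
#' @return an object of class `pema_greedy`: `selected_ids`, `theta_curve`
#'   (cumulative explained variance per factor), `weights_scaled`
#'   (selected modes x experiments, in unit-norm scale), `weights` (same,
#'   mapped back to input EM scale), `residual`.
#' @export
greedy_fit <- function(problem, n_fac, tie_tol = 1e-12) {
  stopifnot(inherits(problem, "pema_problem"))
  n_fac <- as.integer(n_fac)
  if (is.na(n_fac) || n_fac < 1L) stop("n_fac must be >= 1", call. = FALSE)
  E <- problem$E
  V <- problem$V
  total_ss <- problem$total_ss
  ids <- colnames(E)
  k_max <- min(n_fac, nrow(V), ncol(E))

  selected <- integer(0)
  theta_curve <- numeric(0)
  weights <- matrix(0, 0, ncol(V), dimnames = list(NULL, colnames(V)))
  theta <- 0
  for (it in seq_len(k_max)) {
    gains <- mode_gains(E, V, total_ss)
    gains[selected] <- -Inf
    best <- pick_best(gains, ids, tie_tol)
    if (gains[best] <= tie_tol) break  # nothing left to capture
    p <- pmax(as.numeric(crossprod(E[, best], V)), 0)
    V <- V - outer(E[, best], p)
    theta <- theta + gains[best]
    selected <- c(selected, best)
    theta_curve <- c(theta_curve, theta)
    weights <- rbind(weights, p)
  }
  rownames(weights) <- ids[selected]
  structure(list(selected_ids = ids[selected],
                 theta_curve = theta_curve,
                 weights_scaled = weights,
                 weights = weights / problem$column_norms[selected],
                 residual = V),
            class = "pema_greedy")
}

#' @export
print.pema_greedy <- function(x, ...) {
  cat("Greedy best-first EM decomposition\n")
  if (length(x$selected_ids) == 0L) {
    cat("  (no modes selected)\n")
    return(invisible(x))
  }
  tab <- data.frame(factor = seq_along(x$selected_ids),
                    mode = x$selected_ids,
                    theta_pct = round(100 * x$theta_curve, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}
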