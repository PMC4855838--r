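# PCA baseline: explained-variance curve per number of latent variables,
# directly comparable with the PEM analysis theta curve.

#' PCA explained-variance curve
#'
#' Decomposes the flux matrix by SVD and returns the cumulative explained
#' variance per number of latent variables. The default is *uncentered*:
#' the denominator is the total uncentered sum of squares, which makes the
#' curve directly comparable to the explained-variance criterion used for
#' the EM decomposition. With `centered = TRUE`, row (per-flux) means are
#' subtracted first, giving the conventional PCA definition.
#'
#' Because rank-k truncated SVD is the unconstrained optimum over all
#' rank-k reconstructions, this curve dominates the EM-constrained curve
#' at every k on the same scaled data.
#'
#' @param V_mes numeric flux matrix (fluxes x experiments), typically the
#'   scaled matrix from a `pema_problem`.
#' @param max_lv number of latent variables, at most `min(dim(V_mes))`.
#' @param centered subtract row means first?
#' @return an object of class `pema_pca`: `variance_curve` (cumulative
#'   fractions), `loadings` (fluxes x max_lv), `scores`
#'   (max_lv x experiments), `singular_values`, `centered`.
#' @export
pca_variance_curve <- function(V_mes, max_lv = min(dim(V_mes)),
                               centered = FALSE) {
  V_mes <- as.matrix(V_mes)
  if (all(V_mes == 0)) stop("flux matrix is all zero", call. = FALSE)
  if (max_lv < 1L || max_lv > min(dim(V_mes)))
    stop("max_lv must be between 1 and min(dim(V_mes))", call. = FALSE)
  X <- if (centered) V_mes - rowMeans(V_mes) else V_mes
  total <- sum(X^2)
  if (total == 0) stop("matrix has no variance after centering", call. = FALSE)
  sv <- svd(X)
  curve <- cumsum(sv$d^2)[seq_len(max_lv)] / total
  structure(list(variance_curve = curve,
                 loadings = sv$u[, seq_len(max_lv), drop = FALSE],
                 scores = diag(sv$d[seq_len(max_lv)], nrow = max_lv) %*%
                   t(sv$v[, seq_len(max_lv), drop = FALSE]),
                 singular_values = sv$d,
                 centered = centered),
            class = "pema_pca")
}

#' @export
print.pema_pca <- function(x, ...) {
  cat(sprintf("PCA baseline (%s)\n",
              if (x$centered) "row-centered" else "uncentered"))
  print(data.frame(n_lv = seq_along(x$variance_curve),
                   theta_pct = round(100 * x$variance_curve, 2)),
        row.names = FALSE)
  invisible(x)
}
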