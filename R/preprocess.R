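# Step-1 pre-selection: restrict the EM matrix to the measured fluxes,
# scale rows, drop modes that oppose the observed flux directions, group
# modes indistinguishable on the measured fluxes, unit-normalize columns.

#' Mean-scale flux rows and the matching EM rows
#'
#' Divides each measured flux row (in both the flux matrix and the
#' measured-row-restricted EM matrix) by a per-flux factor, to reduce the
#' impact of magnitude differences between fluxes. `abs_mean` uses the mean
#' of absolute values across experiments, `signed_mean` the arithmetic
#' mean, `none` leaves rows unscaled. Rows whose factor magnitude falls
#' below 1e-12 carry no usable information and are dropped with a warning.
#'
#' @param flux numeric matrix of measured fluxes (fluxes x experiments).
#' @param ems_restricted numeric matrix of EM entries on the same fluxes
#'   (same row order as `flux`).
#' @param mode one of `"abs_mean"`, `"signed_mean"`, `"none"`.
#' @return list with `flux`, `ems` (scaled, possibly with rows dropped),
#'   `scale_factors` (for kept rows) and `dropped_fluxes`.
#' @export
mean_scale <- function(flux, ems_restricted,
                       mode = c("abs_mean", "signed_mean", "none")) {
  mode <- match.arg(mode)
  stopifnot(nrow(flux) == nrow(ems_restricted))
  factors <- switch(mode,
                    abs_mean = rowMeans(abs(flux)),
                    signed_mean = rowMeans(flux),
                    none = rep(1, nrow(flux)))
  names(factors) <- rownames(flux)
  keep <- abs(factors) >= 1e-12
  if (!all(keep)) {
    warning("dropping uninformative flux row(s) with ~zero scale factor: ",
            paste(rownames(flux)[!keep], collapse = ", "), call. = FALSE)
  }
  factors <- factors[keep]
  list(flux = flux[keep, , drop = FALSE] / factors,
       ems = ems_restricted[keep, , drop = FALSE] / factors,
       scale_factors = factors,
       dropped_fluxes = rownames(flux)[!keep])
}

#' Remove modes that oppose the measured flux directions
#'
#' A reaction cannot carry flux in both directions at once, so a mode whose
#' entry for some measured flux has the sign strictly opposite to that
#' flux's observed direction cannot contribute under nonnegative weights.
#' In `"global"` mode a flux constrains the modes only when its nonzero
#' values share one sign across all experiments; mixed-sign fluxes impose
#' nothing (and are flagged, since they may indicate direction errors in
#' the data, which this function deliberately does not auto-correct).
#'
#' @param ems_restricted measured-row EM matrix (possibly scaled).
#' @param flux measured flux matrix on the same rows (possibly scaled).
#' @param tol entries with magnitude below `tol` count as zero.
#' @param mode `"global"` or `"off"`.
#' @return list with `ems` (columns kept) and `removed_ids`.
#' @export
filter_by_direction <- function(ems_restricted, flux, tol = 1e-9,
                                mode = c("global", "off")) {
  mode <- match.arg(mode)
  if (mode == "off" || ncol(ems_restricted) == 0L)
    return(list(ems = ems_restricted, removed_ids = character()))
  drop <- rep(FALSE, ncol(ems_restricted))
  for (j in seq_len(nrow(flux))) {
    vals <- flux[j, ]
    nz <- vals[abs(vals) > tol]
    if (length(nz) == 0L) next
    s <- sign(nz[1L])
    if (!all(sign(nz) == s)) {
      message("flux '", rownames(flux)[j],
              "' has mixed signs across experiments; no direction ",
              "constraint applied (check data directions)")
      next
    }
    opposing <- s * ems_restricted[j, ] < -tol
    if (any(opposing & !drop)) {
      message("direction filter: flux '", rownames(flux)[j], "' removes ",
              sum(opposing & !drop), " mode(s)")
    }
    drop <- drop | opposing
  }
  list(ems = ems_restricted[, !drop, drop = FALSE],
       removed_ids = colnames(ems_restricted)[drop])
}

#' Group modes indistinguishable on the measured fluxes
#'
#' Modes whose restriction to the measured fluxes is (numerically) zero
#' cannot be seen in the data at all and are removed. Modes whose unit-
#' normalized restrictions are positively proportional (cosine similarity
#' >= 1 - tol) behave identically under nonnegative weights and are
#' grouped; only the lexicographically lowest id of each group is kept as
#' representative, but full group membership is retained so a selected
#' representative can be reported together with its indistinguishable
#' alternatives. Opposite-sign restrictions are *not* grouped: under
#' nonnegative weights they act differently.
#'
#' @param ems_restricted measured-row EM matrix (restriction applied).
#' @param tol cosine tolerance; also the relative 2-norm threshold
#'   (`tol * max column norm`) below which a restriction counts as zero.
#' @return list with `ems` (representatives only), `groups` (list of id
#'   vectors, each of size >= 2, named by representative) and
#'   `removed_zero_measured`.
#' @export
detect_ambiguous <- function(ems_restricted, tol = 1e-9) {
  norms <- sqrt(colSums(ems_restricted^2))
  max_norm <- max(norms, 0)
  zero <- norms < tol * max_norm | norms == 0
  removed_zero <- colnames(ems_restricted)[zero]
  ems <- ems_restricted[, !zero, drop = FALSE]
  norms <- norms[!zero]
  if (ncol(ems) == 0L)
    return(list(ems = ems, groups = list(), removed_zero_measured = removed_zero))
  # order columns by id so group representatives are the lowest ids
  ord <- order(colnames(ems))
  unit <- sweep(ems[, ord, drop = FALSE], 2, norms[ord], "/")
  cosine <- crossprod(unit)
  assigned <- integer(ncol(unit))  # 0 = unassigned, else representative index
  for (j in seq_len(ncol(unit))) {
    if (assigned[j] > 0L) next
    assigned[j] <- j
    dup <- which(assigned == 0L & cosine[j, ] >= 1 - tol)
    assigned[dup] <- j
  }
  reps <- unique(assigned)
  groups <- lapply(reps, function(r) colnames(unit)[assigned == r])
  names(groups) <- colnames(unit)[reps]
  groups <- groups[lengths(groups) >= 2L]
  # keep representatives, preserving the original column order
  keep <- intersect(colnames(ems), colnames(unit)[reps])
  list(ems = ems[, keep, drop = FALSE],
       groups = groups,
       removed_zero_measured = removed_zero)
}

#' Build the scaled problem handed to the solvers
#'
#' Pipeline: restrict the EM matrix to the measured fluxes (matched by id,
#' never by position) -> [mean_scale()] -> [filter_by_direction()] ->
#' [detect_ambiguous()] -> unit-normalize the surviving columns, recording
#' each column's 2-norm so reported weights can be mapped back to the
#' original EM scale (`p = p_n / norm`).
#'
#' @param flux a [flux_data()] object (rows must be a subset of the EM
#'   set's reaction ids).
#' @param ems an [em_set()] object.
#' @param config a [pema_config()].
#' @return an object of class `pema_problem` with elements `V` (scaled flux
#'   matrix), `E` (unit-norm scaled restricted EM columns), `column_norms`,
#'   `scale_factors`, `kept_mode_ids`, `ambiguity`, `removed_by_direction`,
#'   `removed_zero_measured`, `dropped_fluxes`, `total_ss`.
#' @export
build_problem <- function(flux, ems, config = pema_config()) {
  validate_flux_data(flux)
  idx <- match(rownames(flux), rownames(ems))
  if (anyNA(idx))
    stop("measured flux id(s) not present in the EM matrix: ",
         paste(rownames(flux)[is.na(idx)], collapse = ", "), call. = FALSE)
  E_restr <- unclass(ems)[idx, , drop = FALSE]
  V <- unclass(flux)

  sc <- mean_scale(V, E_restr, config$scaling_mode)
  if (nrow(sc$flux) == 0L)
    stop("all measured fluxes dropped during scaling", call. = FALSE)

  dir <- filter_by_direction(sc$ems, sc$flux, config$direction_tol,
                             config$direction_filter_mode)
  amb <- detect_ambiguous(dir$ems, config$ambiguity_tol)
  E_kept <- amb$ems
  if (ncol(E_kept) == 0L)
    stop("no feasible EM candidates after pre-selection", call. = FALSE)

  norms <- sqrt(colSums(E_kept^2))
  E_norm <- sweep(E_kept, 2, norms, "/")
  structure(list(V = sc$flux,
                 E = E_norm,
                 column_norms = norms,
                 scale_factors = sc$scale_factors,
                 kept_mode_ids = colnames(E_kept),
                 ambiguity = list(groups = amb$groups,
                                  representatives = names(amb$groups)),
                 removed_by_direction = dir$removed_ids,
                 removed_zero_measured = amb$removed_zero_measured,
                 dropped_fluxes = sc$dropped_fluxes,
                 total_ss = sum(sc$flux^2),
                 flux_ids = rownames(sc$flux),
                 experiment_ids = colnames(sc$flux),
                 n_modes_input = ncol(ems)),
            class = "pema_problem")
}

#' @export
print.pema_problem <- function(x, ...) {
  cat("Scaled PEM analysis problem\n")
  cat(sprintf("  measured fluxes : %d (%s)\n", nrow(x$V),
              paste(utils::head(x$flux_ids, 6), collapse = ", ")))
  cat(sprintf("  experiments     : %d\n", ncol(x$V)))
  cat(sprintf("  candidate modes : %d kept of %d input\n",
              length(x$kept_mode_ids), x$n_modes_input))
  cat(sprintf("  removed         : %d by direction, %d zero on measured, %d ambiguous duplicates\n",
              length(x$removed_by_direction), length(x$removed_zero_measured),
              sum(lengths(x$ambiguity$groups)) - length(x$ambiguity$groups)))
  invisible(x)
}
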