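# Branch-and-bound selection of principal elementary modes. The greedy
# decomposition provides the incumbent (lower bound); nodes are pruned
# when theta so far plus the sum of the remaining-slot largest single-mode
# gains on the node residual cannot beat it. A dedicated search is run for
# every factor count 1..n_fac: the best set is not in general nested.

#' Score an ordered EM sequence
#'
#' Applies project -> clip -> deflate in the given order and returns the
#' cumulative explained variance together with the weights and the final
#' residual. Order matters for non-orthogonal modes: the same set scored
#' in a different order can capture a different amount of variance.
#'
#' @param problem a `pema_problem`.
#' @param mode_ids distinct mode ids present in the problem, in scoring
#'   order.
#' @return list with `theta`, `theta_steps` (cumulative, per factor),
#'   `weights_scaled` (modes x experiments), `weights` (input EM scale),
#'   `residual`.
#' @export
score_sequence <- function(problem, mode_ids) {
  stopifnot(inherits(problem, "pema_problem"))
  if (anyDuplicated(mode_ids))
    stop("duplicate mode id in sequence", call. = FALSE)
  idx <- match(mode_ids, colnames(problem$E))
  if (anyNA(idx))
    stop("mode id(s) not in problem: ",
         paste(mode_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  V <- problem$V
  theta_steps <- numeric(length(idx))
  W <- matrix(0, length(idx), ncol(V),
              dimnames = list(mode_ids, colnames(V)))
  theta <- 0
  for (t in seq_along(idx)) {
    e <- problem$E[, idx[t]]
    p <- pmax(as.numeric(crossprod(e, V)), 0)
    V <- V - outer(e, p)
    theta <- theta + sum(p^2) / problem$total_ss
    theta_steps[t] <- theta
    W[t, ] <- p
  }
  list(theta = theta,
       theta_steps = theta_steps,
       weights_scaled = W,
       weights = W / problem$column_norms[idx],
       residual = V)
}

#' Upper bound on the variance achievable from a search node
#'
#' The bound is theta so far plus the sum of the `remaining` largest
#' single-mode variance gains computed on the node's residual, capped at
#' one. The gains are recomputed on the node residual (not cached from the
#' root) because deflation with non-orthogonal modes changes them. The
#' bound is attained when the completing modes are mutually independent;
#' it is guaranteed to dominate any sequential completion whenever the
#' surviving measured restrictions are sign-consistent with the data (the
#' situation the direction filter establishes) — see the methods vignette
#' for the limits of this guarantee with mixed-sign fluxes.
#'
#' @param problem a `pema_problem`.
#' @param residual residual matrix at the node.
#' @param theta_so_far cumulative explained variance at the node.
#' @param remaining number of factors still to choose (`n_fac - depth`).
#' @param exclude_ids mode ids already chosen along the branch.
#' @return the bound, a fraction <= 1.
#' @export
node_upper_bound <- function(problem, residual, theta_so_far, remaining,
                             exclude_ids = character()) {
  stopifnot(remaining >= 1)
  keep <- !(colnames(problem$E) %in% exclude_ids)
  gains <- mode_gains(problem$E[, keep, drop = FALSE], residual,
                      problem$total_ss)
  top <- sort(gains, decreasing = TRUE)[seq_len(min(remaining, length(gains)))]
  min(1, theta_so_far + sum(top))
}

#' Branch-and-bound identification of principal elementary modes
#'
#' For every factor count `k = 1..n_fac`, finds the combination of `k`
#' candidate modes that captures the most variance of the scaled flux
#' data, using [greedy_fit()] as the initial incumbent and the additive
#' single-mode gain bound for pruning. Each unordered combination is
#' visited at most once; within a branch modes are appended in descending-
#' gain (step-wise greedy) order, and the order actually used is recorded
#' in the result. Each factor count is a dedicated search (selections are
#' not nested), but the searches are linked: the `k`-factor search also
#' considers the best `(k-1)`-factor sequence extended by its best single
#' completion, so the reported explained-variance curve is nondecreasing
#' in the factor count. `n_fac` is capped at the number of measured
#' fluxes and at the number of surviving candidate modes.
#'
#' @param problem a `pema_problem` from [build_problem()].
#' @param config a [pema_config()]; `n_fac`, `tie_tol`, `prune_tol`,
#'   `prune` and `max_nodes` are used here.
#' @return an object of class `pema_result`: per-factor selections
#'   (`factors`), the explained-variance curve (`theta`), the greedy trace
#'   (`greedy`), search statistics (`stats`), the problem and config.
#' @export
branch_and_bound_fit <- function(problem, config = pema_config()) {
  stopifnot(inherits(problem, "pema_problem"))
  E <- problem$E
  V <- problem$V
  ids <- colnames(E)
  m <- ncol(E)
  k_max <- min(config$n_fac, nrow(V), m)
  if (k_max < config$n_fac)
    warning("n_fac capped at ", k_max,
            " (number of measured fluxes / candidate modes)", call. = FALSE)
  id_rank <- rank(ids, ties.method = "first")
  greedy <- greedy_fit(problem, k_max, config$tie_tol)

  factors <- vector("list", k_max)
  stats <- vector("list", k_max)
  theta <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    t0 <- proc.time()[["elapsed"]]
    # incumbent 1: the greedy prefix of length <= k (the greedy sequence
    # is itself in canonical step-wise best order)
    g_len <- min(k, length(greedy$selected_ids))
    inc_ids <- greedy$selected_ids[seq_len(g_len)]
    inc_theta <- if (g_len > 0L) greedy$theta_curve[g_len] else 0
    # incumbent 2: the best (k-1)-factor sequence plus its best single
    # completion. This links the per-k searches and guarantees a theta
    # curve nondecreasing in the factor count, which canonical-order
    # scoring of independent k-sets alone does not (the canonical order
    # of a larger set can score below a good smaller set).
    if (!is.null(prev)) {
      sc <- score_sequence(problem, prev$ids)
      open <- setdiff(ids, prev$ids)
      if (length(open)) {
        gains <- mode_gains(E[, open, drop = FALSE], sc$residual,
                            problem$total_ss)
        best <- pick_best(gains, open, config$tie_tol)
        if (sc$theta + gains[best] > inc_theta) {
          inc_ids <- c(prev$ids, open[best])
          inc_theta <- sc$theta + gains[best]
        }
      }
    }
    res <- bnb_search_cpp(E, V, problem$total_ss, k, inc_theta,
                          match(inc_ids, ids), id_rank,
                          config$prune, config$prune_tol, config$max_nodes)
    sel_ids <- ids[res$sequence]
    sc <- score_sequence(problem, sel_ids)
    elapsed <- proc.time()[["elapsed"]] - t0
    factors[[k]] <- list(
      ids = sel_ids,
      theta = res$theta,
      weights_scaled = sc$weights_scaled,
      weights = sc$weights,
      ambiguous = problem$ambiguity$groups[
        names(problem$ambiguity$groups) %in% sel_ids],
      proven_optimal = isTRUE(res$complete))
    stats[[k]] <- list(
      n_fac = k,
      nodes_evaluated = res$nodes_evaluated,
      nodes_pruned = res$nodes_pruned,
      n_comb_theoretical = choose(m, k),
      complete = isTRUE(res$complete),
      elapsed_s = elapsed)
    theta[k] <- res$theta
    prev <- list(ids = sel_ids, theta = res$theta)
  }
  structure(list(factors = factors,
                 theta = theta,
                 n_fac = k_max,
                 greedy = greedy,
                 stats = stats,
                 problem = problem,
                 config = config),
            class = "pema_result")
}

#' Fit a principal elementary mode analysis
#'
#' Convenience wrapper: [build_problem()] then [branch_and_bound_fit()].
#'
#' @param flux a [flux_data()] object.
#' @param ems an [em_set()] object.
#' @param n_fac number of factors; overrides `config$n_fac` when given.
#' @param config a [pema_config()].
#' @return a `pema_result` (see [branch_and_bound_fit()]).
#' @export
pema_fit <- function(flux, ems, n_fac = NULL, config = pema_config()) {
  if (!is.null(n_fac)) config$n_fac <- as.integer(n_fac)
  problem <- build_problem(flux, ems, config)
  branch_and_bound_fit(problem, config)
}

# selected ids annotated with their indistinguishable alternatives,
# e.g. "EM4/EM22" when EM22 is ambiguous with the representative EM4
annotate_ids <- function(ids, groups) {
  vapply(ids, function(id) {
    if (!is.null(groups[[id]])) paste(groups[[id]], collapse = "/") else id
  }, character(1))
}

#' @export
print.pema_result <- function(x, ...) {
  cat("Principal elementary mode analysis\n")
  cat(sprintf("  %d candidate modes after pre-selection, %d experiments, %d measured fluxes\n",
              ncol(x$problem$E), ncol(x$problem$V), nrow(x$problem$V)))
  cat("  explained variance is computed on the scaled flux matrix\n\n")
  rows <- lapply(seq_len(x$n_fac), function(k) {
    f <- x$factors[[k]]
    data.frame(n_fac = k,
               modes = paste(annotate_ids(f$ids, x$problem$ambiguity$groups),
                             collapse = " "),
               theta_pct = round(100 * f$theta, 2),
               optimal = ifelse(f$proven_optimal, "yes", "budget"),
               stringsAsFactors = FALSE)
  })
  print(do.call(rbind, rows), row.names = FALSE)
  g <- x$greedy
  if (length(g$selected_ids)) {
    cat(sprintf("\n  greedy best-first: %s (theta %s%%)\n",
                paste(g$selected_ids, collapse = " "),
                paste(round(100 * g$theta_curve, 2), collapse = " ")))
  }
  invisible(x)
}
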