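# Independent oracles used to cross-check the solvers.
#
# The oracle scores a candidate set with plain element-wise loops (no code
# shared with the package's vectorized path): at each step it picks the
# set member capturing the most variance from the current residual,
# projects, clips, and deflates, exactly the canonical within-set order
# the search uses.

oracle_score_set <- function(E, V, set_idx) {
  total <- sum(V^2)
  remaining <- set_idx
  theta <- 0
  while (length(remaining) > 0L) {
    gains <- numeric(length(remaining))
    for (s in seq_along(remaining)) {
      e <- E[, remaining[s]]
      g <- 0
      for (j in seq_len(ncol(V))) {
        proj <- sum(e * V[, j])
        if (proj > 0) g <- g + proj^2
      }
      gains[s] <- g / total
    }
    best <- which.max(gains)
    e <- E[, remaining[best]]
    for (j in seq_len(ncol(V))) {
      proj <- sum(e * V[, j])
      if (proj > 0) V[, j] <- V[, j] - e * proj
    }
    theta <- theta + gains[best]
    remaining <- remaining[-best]
  }
  theta
}

# exhaustive maximum explained variance over all k-subsets of candidates
oracle_best_theta <- function(E, V, k) {
  sets <- utils::combn(ncol(E), k)
  best <- -Inf
  for (s in seq_len(ncol(sets))) {
    th <- oracle_score_set(E, V, sets[, s])
    if (th > best) best <- th
  }
  best
}

# score an explicitly ordered sequence (no within-set reordering)
oracle_score_ordered <- function(E, V, seq_idx) {
  total <- sum(V^2)
  theta <- 0
  for (i in seq_idx) {
    e <- E[, i]
    for (j in seq_len(ncol(V))) {
      proj <- sum(e * V[, j])
      if (proj > 0) {
        theta <- theta + proj^2 / total
        V[, j] <- V[, j] - e * proj
      }
    }
  }
  list(theta = theta, residual = V)
}

# ordered sequence attaining the canonical (step-wise best within set) score
oracle_canonical_order <- function(E, V, set_idx) {
  remaining <- set_idx
  out <- integer(0)
  while (length(remaining) > 0L) {
    gains <- vapply(remaining, function(i) {
      g <- 0
      for (j in seq_len(ncol(V))) {
        proj <- sum(E[, i] * V[, j])
        if (proj > 0) g <- g + proj^2
      }
      g
    }, numeric(1))
    best <- remaining[which.max(gains)]
    for (j in seq_len(ncol(V))) {
      proj <- sum(E[, best] * V[, j])
      if (proj > 0) V[, j] <- V[, j] - E[, best] * proj
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# full exhaustive replica of the linked per-k searches: for each k the
# candidates are every k-set scored in canonical order plus the previous
# best sequence extended by its best single completion
oracle_curve <- function(E, V, k_max) {
  thetas <- numeric(k_max)
  prev_seq <- integer(0)
  for (k in seq_len(k_max)) {
    best_theta <- -Inf
    best_seq <- NULL
    sets <- utils::combn(ncol(E), k)
    for (s in seq_len(ncol(sets))) {
      ord <- oracle_canonical_order(E, V, sets[, s])
      th <- oracle_score_ordered(E, V, ord)$theta
      if (th > best_theta) {
        best_theta <- th
        best_seq <- ord
      }
    }
    if (length(prev_seq)) {
      sc <- oracle_score_ordered(E, V, prev_seq)
      open <- setdiff(seq_len(ncol(E)), prev_seq)
      gains <- vapply(open, function(i) {
        g <- 0
        for (j in seq_len(ncol(sc$residual))) {
          proj <- sum(E[, i] * sc$residual[, j])
          if (proj > 0) g <- g + proj^2
        }
        g / sum(V^2)
      }, numeric(1))
      ext_theta <- sc$theta + max(gains)
      if (ext_theta > best_theta) {
        best_theta <- ext_theta
        best_seq <- c(prev_seq, open[which.max(gains)])
      }
    }
    thetas[k] <- best_theta
    prev_seq <- best_seq
  }
  thetas
}

# random direction-consistent problem: nonnegative EM restrictions and
# fluxes, as the direction filter guarantees for single-signed data
random_problem <- function(n_flux = 4, n_modes = 8, n_exp = 3, n_active = 3,
                           seed = 1, noise_sd = 0.05) {
  set.seed(seed)
  E <- matrix(runif(n_flux * n_modes) * (runif(n_flux * n_modes) < 0.7),
              nrow = n_flux)
  E[, colSums(E) == 0] <- runif(n_flux)
  ems <- em_set(E, reaction_ids = paste0("f", seq_len(n_flux)),
                mode_ids = sprintf("EM%02d", seq_len(n_modes)))
  act <- sample(n_modes, n_active)
  P <- matrix(runif(n_active * n_exp, 0.2, 1), nrow = n_active)
  V <- E[, act, drop = FALSE] %*% P
  V <- V * (1 + matrix(rnorm(length(V), sd = noise_sd), nrow = nrow(V)))
  V <- pmax(V, 0)
  if (all(V == 0)) V[1, 1] <- 1
  flux <- flux_data(V, flux_ids = rownames(ems),
                    experiment_ids = paste0("e", seq_len(n_exp)))
  cfg <- pema_config(scaling_mode = "none", direction_filter_mode = "off")
  build_problem(flux, ems, cfg)
}
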