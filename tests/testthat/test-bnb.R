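test_that("score_sequence is order-dependent and matches hand values", {
  ems <- em_set(cbind(a = c(1, 0), c = c(1, 1) / sqrt(2)),
                reaction_ids = c("f1", "f2"))
  flux <- flux_data(matrix(c(3, 1), 2, dimnames = list(c("f1", "f2"), "A")))
  cfg <- pema_config(scaling_mode = "none", direction_filter_mode = "off")
  prob <- build_problem(flux, ems, cfg)
  expect_equal(score_sequence(prob, c("a", "c"))$theta, 0.95, tolerance = 1e-12)
  expect_equal(score_sequence(prob, c("c", "a"))$theta, 0.90, tolerance = 1e-12)
  expect_equal(score_sequence(prob, character(0))$theta, 0)
  expect_error(score_sequence(prob, c("a", "a")), "duplicate")
  expect_error(score_sequence(prob, "nope"), "nope")
})

test_that("node upper bound is tight one level above the leaves", {
  prob <- random_problem(n_flux = 4, n_modes = 6, n_exp = 3, seed = 11)
  # depth n_fac - 1: bound equals theta plus the best single gain, attainable
  g1 <- greedy_fit(prob, 1)
  sc <- score_sequence(prob, g1$selected_ids)
  b <- node_upper_bound(prob, sc$residual, sc$theta, remaining = 1,
                        exclude_ids = g1$selected_ids)
  g2 <- greedy_fit(prob, 2)
  expect_equal(b, g2$theta_curve[2], tolerance = 1e-12)
  # zero residual: bound collapses to theta so far
  expect_equal(node_upper_bound(prob, 0 * prob$V, 0.7, remaining = 3), 0.7)
})

test_that("node upper bound dominates the exhaustive best completion", {
  for (seed in 1:10) {
    prob <- random_problem(n_flux = 4, n_modes = 6, n_exp = 3,
                           n_active = 3, seed = seed)
    for (k in 2:3) {
      bound <- node_upper_bound(prob, prob$V, 0, remaining = k)
      best <- oracle_best_theta(prob$E, prob$V, k)
      expect_gte(bound + 1e-12, best)
    }
  }
})

test_that("branch and bound escapes the greedy trap", {
  fx <- toy_fixtures("greedy_trap")
  res <- pema_fit(fx$flux, fx$ems, n_fac = 2)
  expect_setequal(res$factors[[2]]$ids, c("a", "b"))
  expect_equal(res$theta[2], 1, tolerance = 1e-12)
  expect_equal(res$greedy$theta_curve[2], 11.7125 / 18.02, tolerance = 1e-12)
  expect_identical(res$stats[[2]]$n_comb_theoretical, 3)
})

test_that("a single matching candidate is returned immediately", {
  ems <- em_set(matrix(c(3, 4), 2, dimnames = list(c("f1", "f2"), "EM1")))
  flux <- flux_data(matrix(c(6, 8, 3, 4), 2,
                           dimnames = list(c("f1", "f2"), c("A", "B"))))
  cfg <- pema_config(scaling_mode = "none", direction_filter_mode = "off")
  res <- pema_fit(flux, ems, n_fac = 1, config = cfg)
  expect_identical(res$factors[[1]]$ids, "EM1")
  expect_equal(res$theta[1], 1, tolerance = 1e-12)
  expect_identical(res$stats[[1]]$nodes_evaluated, 1)
  # unscaled weights recover the generating coefficients of E %*% P
  expect_equal(unname(res$factors[[1]]$weights["EM1", ]), c(2, 1),
               tolerance = 1e-12)
})

test_that("search equals exhaustive enumeration on random problems", {
  for (seed in 1:12) {
    prob <- random_problem(n_flux = 5, n_modes = 8, n_exp = 3,
                           n_active = 3, seed = seed)
    cfg <- pema_config(n_fac = 3, scaling_mode = "none",
                       direction_filter_mode = "off")
    res <- branch_and_bound_fit(prob, cfg)
    curve <- oracle_curve(prob$E, prob$V, res$n_fac)
    for (k in seq_len(res$n_fac)) {
      expect_equal(res$theta[k], curve[k], tolerance = 1e-12)
      expect_lte(res$stats[[k]]$nodes_evaluated,
                 res$stats[[k]]$n_comb_theoretical)
    }
  }
})

test_that("pruning changes node counts but never the result", {
  for (seed in c(2, 5, 9)) {
    prob <- random_problem(n_flux = 5, n_modes = 9, n_exp = 4,
                           n_active = 4, seed = seed)
    on_ <- branch_and_bound_fit(prob, pema_config(n_fac = 3, prune = TRUE))
    off <- branch_and_bound_fit(prob, pema_config(n_fac = 3, prune = FALSE))
    expect_equal(on_$theta, off$theta, tolerance = 1e-12)
    for (k in 1:3)
      expect_lte(on_$stats[[k]]$nodes_evaluated,
                 off$stats[[k]]$nodes_evaluated)
    # without pruning the full combination count is evaluated
    expect_equal(off$stats[[3]]$nodes_evaluated,
                 off$stats[[3]]$n_comb_theoretical)
  }
})

test_that("search dominates greedy and is monotone in the factor count", {
  for (seed in 1:10) {
    prob <- random_problem(n_flux = 6, n_modes = 10, n_exp = 4,
                           n_active = 5, seed = seed + 100)
    res <- branch_and_bound_fit(prob, pema_config(n_fac = 4))
    g <- greedy_fit(prob, 4)
    for (k in seq_len(res$n_fac)) {
      if (k <= length(g$theta_curve))
        expect_gte(res$theta[k], g$theta_curve[k] - 1e-12)
    }
    expect_true(all(diff(res$theta) >= -1e-12))
    expect_true(all(res$theta <= 1 + 1e-12))
  }
})

test_that("well-separated generating modes are recovered exactly", {
  # orthogonal-ish sparse actives: noise-free data, n_fac = number of
  # actives, the generating set is the unique optimum
  for (seed in 1:6) {
    set.seed(seed)
    n_flux <- 8
    E <- matrix(runif(n_flux * 12) * (runif(n_flux * 12) < 0.3), n_flux)
    E[, colSums(E) == 0] <- runif(n_flux)
    # three actives on disjoint supports
    E[, 1] <- c(runif(2, 0.5, 1), rep(0, 6))
    E[, 2] <- c(0, 0, runif(3, 0.5, 1), rep(0, 3))
    E[, 3] <- c(rep(0, 5), runif(3, 0.5, 1))
    ems <- em_set(E, reaction_ids = paste0("f", 1:n_flux),
                  mode_ids = sprintf("EM%02d", 1:12))
    unit <- sweep(E[, 1:3], 2, sqrt(colSums(E[, 1:3]^2)), "/")
    if (max(crossprod(unit) - diag(3)) > 0.95) next
    P <- matrix(runif(3 * 5, 0.5, 2), 3)
    V <- E[, 1:3] %*% P
    flux <- flux_data(V, flux_ids = rownames(ems))
    res <- pema_fit(flux, ems, n_fac = 3,
                    config = pema_config(scaling_mode = "none",
                                         direction_filter_mode = "off"))
    expect_setequal(res$factors[[3]]$ids, c("EM01", "EM02", "EM03"))
    expect_equal(res$theta[3], 1, tolerance = 1e-10)
  }
})

test_that("node budget returns the incumbent flagged as not proven optimal", {
  prob <- random_problem(n_flux = 6, n_modes = 12, n_exp = 4,
                         n_active = 5, seed = 4)
  cfg <- pema_config(n_fac = 3, max_nodes = 2, prune = FALSE)
  res <- branch_and_bound_fit(prob, cfg)
  expect_false(res$factors[[3]]$proven_optimal)
  g <- greedy_fit(prob, 3)
  expect_gte(res$theta[3], g$theta_curve[3] - 1e-12)
})

test_that("n_fac beyond the measured flux count is capped with a warning", {
  fx <- toy_fixtures("greedy_trap")
  expect_warning(res <- pema_fit(fx$flux, fx$ems, n_fac = 5), "capped")
  expect_identical(res$n_fac, 2L)
})
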