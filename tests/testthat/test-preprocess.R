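test_that("mean_scale divides rows by the chosen per-flux factor", {
  V <- matrix(c(2, 4), 1, dimnames = list("vGlc", c("A", "B")))
  E <- matrix(c(1, 2), 1, dimnames = list("vGlc", c("EM1", "EM2")))
  sc <- mean_scale(V, E, "abs_mean")
  expect_equal(unname(sc$scale_factors), 3)
  expect_equal(unname(sc$flux[1, ]), c(2 / 3, 4 / 3))
  expect_equal(unname(sc$ems[1, ]), c(1 / 3, 2 / 3))
  expect_equal(unname(mean_scale(V, E, "none")$flux), unname(V))
})

test_that("signed_mean scaling drops a mixed-sign flux averaging to zero", {
  V <- matrix(c(-2, 2, 1, 1), 2, byrow = TRUE,
              dimnames = list(c("vAc", "vO2"), c("A", "B")))
  E <- matrix(1, 2, 2, dimnames = list(c("vAc", "vO2"), c("EM1", "EM2")))
  expect_warning(sc <- mean_scale(V, E, "signed_mean"), "vAc")
  expect_identical(sc$dropped_fluxes, "vAc")
  expect_identical(rownames(sc$flux), "vO2")
})

test_that("direction filter removes opposing modes, ignores mixed-sign and zero entries", {
  # vO2 positive in all experiments: a mode with a negative vO2 entry is out
  V <- matrix(c(1, 2, 0.5), 1, dimnames = list("vO2", c("A", "B", "C")))
  E <- matrix(c(-0.3, 0, 0.4), 1,
              dimnames = list("vO2", c("EM1", "EM2", "EM3")))
  out <- filter_by_direction(E, V, mode = "global")
  expect_identical(out$removed_ids, "EM1")
  expect_identical(colnames(out$ems), c("EM2", "EM3"))  # zero entry kept

  # mixed signs across experiments impose no constraint
  Vmix <- matrix(c(1, -1), 1, dimnames = list("vAc", c("A", "B")))
  expect_message(out2 <- filter_by_direction(E, Vmix, mode = "global"),
                 "mixed signs")
  expect_length(out2$removed_ids, 0)

  expect_length(filter_by_direction(E, V, mode = "off")$removed_ids, 0)
})

test_that("ambiguity grouping keeps one representative per positively proportional group", {
  # EM1 and EM2 positively proportional on the measured rows; EM3 distinct
  E <- cbind(EM2 = c(1, 0), EM1 = c(2, 0), EM3 = c(0, 1))
  rownames(E) <- c("f1", "f2")
  amb <- detect_ambiguous(E)
  expect_identical(sort(colnames(amb$ems)), c("EM1", "EM3"))
  expect_identical(amb$groups, list(EM1 = c("EM1", "EM2")))

  # zero measured restriction is removed, not grouped
  Ez <- cbind(EM1 = c(1, 0), EM2 = c(0, 0))
  amb2 <- detect_ambiguous(Ez)
  expect_identical(amb2$removed_zero_measured, "EM2")

  # opposite directions behave differently under nonnegative weights
  Eo <- cbind(EM1 = c(1, 0), EM2 = c(-1, 0))
  amb3 <- detect_ambiguous(Eo)
  expect_length(amb3$groups, 0)
})

test_that("opposite-direction modes capture different variance, so must not be merged", {
  ems <- em_set(cbind(EMpos = c(1, 0), EMneg = c(-1, 0)),
                reaction_ids = c("f1", "f2"))
  flux <- flux_data(matrix(c(1, 0), 2, 1,
                           dimnames = list(c("f1", "f2"), "A")))
  cfg <- pema_config(scaling_mode = "none", direction_filter_mode = "off")
  prob <- build_problem(flux, ems, cfg)
  th_pos <- score_sequence(prob, "EMpos")$theta
  th_neg <- score_sequence(prob, "EMneg")$theta
  expect_equal(th_pos, 1)
  expect_equal(th_neg, 0)  # projection clipped to zero
})

test_that("build_problem restricts, normalizes and records norms", {
  ems <- em_set(cbind(EM1 = c(1, 0, 5), EM2 = c(0, 1, -2), EM3 = c(3, 4, 0)),
                reaction_ids = c("f1", "f2", "hidden"))
  flux <- flux_data(matrix(c(1, 2, 2, 4), 2,
                           dimnames = list(c("f1", "f2"), c("A", "B"))))
  cfg <- pema_config(scaling_mode = "none", direction_filter_mode = "off")
  prob <- build_problem(flux, ems, cfg)
  expect_equal(unname(prob$column_norms), c(1, 1, 5))
  expect_equal(unname(colSums(prob$E^2)), rep(1, 3), tolerance = 1e-12)
  expect_identical(prob$kept_mode_ids, c("EM1", "EM2", "EM3"))
  # the hidden (unmeasured) row never enters
  expect_identical(nrow(prob$E), 2L)
  expect_error(build_problem(flux_data(matrix(1, 1, 1,
                                              dimnames = list("vX", "A"))),
                             ems, cfg), "vX")
})

test_that("pre-selection partitions the input modes", {
  for (seed in 1:5) {
    set.seed(seed)
    n_modes <- 12
    E <- matrix(runif(4 * n_modes, -0.2, 1), 4)
    E[, 3] <- 2 * E[, 2]            # ambiguous pair
    E[, 4] <- 0; E[4, 4] <- 1       # zero on measured rows (only rows 1-3 measured)
    ems <- em_set(E, reaction_ids = paste0("f", 1:4),
                  mode_ids = sprintf("EM%02d", 1:n_modes))
    flux <- flux_data(matrix(runif(9, 0.5, 2), 3,
                             dimnames = list(paste0("f", 1:3), paste0("e", 1:3))))
    prob <- build_problem(flux, ems, pema_config())
    n_dups <- sum(lengths(prob$ambiguity$groups)) - length(prob$ambiguity$groups)
    expect_identical(length(prob$kept_mode_ids) +
                       length(prob$removed_by_direction) +
                       length(prob$removed_zero_measured) + n_dups,
                     ncol(ems))
    expect_equal(unname(colSums(prob$E^2)),
                 rep(1, ncol(prob$E)), tolerance = 1e-12)
  }
})

test_that("solution is invariant to EM column order and positive rescaling", {
  prob0 <- random_problem(seed = 42)
  fx <- toy_fixtures("greedy_trap")
  cfg <- pema_config(n_fac = 2)
  base <- pema_fit(fx$flux, fx$ems, config = cfg)

  # permute candidate columns
  perm <- c(3, 1, 2)
  ems_p <- em_set(unclass(fx$ems)[, perm])
  res_p <- pema_fit(fx$flux, ems_p, config = cfg)
  expect_equal(res_p$theta, base$theta, tolerance = 1e-12)
  expect_setequal(res_p$factors[[2]]$ids, base$factors[[2]]$ids)

  # multiply columns by arbitrary positive scalars: unit normalization
  # makes the fit scale-free
  set.seed(7)
  scal <- runif(3, 0.1, 10)
  ems_s <- em_set(sweep(unclass(fx$ems), 2, scal, "*"))
  res_s <- pema_fit(fx$flux, ems_s, config = cfg)
  expect_equal(res_s$theta, base$theta, tolerance = 1e-12)
  expect_identical(res_s$factors[[2]]$ids, base$factors[[2]]$ids)

  # rescaling a measured flux row of both inputs is undone by mean scaling
  V2 <- unclass(fx$flux); V2["f1", ] <- V2["f1", ] * 37
  E2 <- unclass(fx$ems); E2["f1", ] <- E2["f1", ] * 37
  res_r <- pema_fit(flux_data(V2), em_set(E2),
                    config = pema_config(n_fac = 2, scaling_mode = "abs_mean"))
  expect_equal(res_r$theta, base$theta, tolerance = 1e-12)
})
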