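# Synthetic flux data with known ground truth, and brute-force elementary
# mode enumeration for small test networks, so the whole pipeline can be
# validated end to end without any external EM sets.

# run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate measured flux data from known active modes
#'
#' Emulates a simulation study in which a known subset of modes is active:
#' each active mode contributes to each experiment with a weight drawn
#' uniformly from `[weight_low, weight_high]` (optionally switched off per
#' experiment with probability `1 - activation_prob`), the clean flux
#' matrix is the nonnegative combination `E[, active] %*% P_true`, and
#' Gaussian noise is added. The default noise is multiplicative relative
#' (`V * (1 + eps)`, `eps ~ N(0, (noise_pct/100)^2)` per entry); the
#' `"additive"` alternative uses `sd = noise_pct/100` times the RMS of the
#' clean matrix.
#'
#' @param ems an [em_set()].
#' @param active_ids mode ids of the generating (active) subset.
#' @param n_experiments number of experiments (columns).
#' @param weight_low,weight_high bounds of the uniform weight sampler;
#'   `0 <= weight_low < weight_high`.
#' @param noise_pct Gaussian noise level in percent, >= 0.
#' @param seed integer seed; the same seed reproduces identical output.
#' @param activation_prob probability that an active mode contributes to a
#'   given experiment (1 = always). Experiments left with no active mode
#'   get one randomly re-activated so no column is all zero.
#' @param mode_intensity optional nonnegative per-active-mode intensity
#'   multiplier (named by mode id or in `active_ids` order), emulating
#'   pathways whose overall activity differs by orders of magnitude.
#' @param noise_type `"relative"` or `"additive"`.
#' @return list with `flux` (a [flux_data()] over all reactions of `ems`)
#'   and `truth` (class `pema_truth`: `active_ids`, `P_true`, `V_clean`,
#'   `noise_pct`, `seed`).
#' @export
simulate_flux_data <- function(ems, active_ids, n_experiments = 12L,
                               weight_low = 0.1, weight_high = 1,
                               noise_pct = 0, seed = 1L,
                               activation_prob = 1,
                               mode_intensity = NULL,
                               noise_type = c("relative", "additive")) {
  noise_type <- match.arg(noise_type)
  if (length(active_ids) == 0L) stop("active set is empty", call. = FALSE)
  if (!all(active_ids %in% colnames(ems)))
    stop("active id(s) not in EM set: ",
         paste(setdiff(active_ids, colnames(ems)), collapse = ", "),
         call. = FALSE)
  if (!(weight_low >= 0 && weight_low < weight_high))
    stop("need 0 <= weight_low < weight_high", call. = FALSE)
  if (noise_pct < 0) stop("noise_pct must be >= 0", call. = FALSE)
  if (!is.null(mode_intensity)) {
    if (!is.null(names(mode_intensity)))
      mode_intensity <- mode_intensity[active_ids]
    if (length(mode_intensity) != length(active_ids) ||
        anyNA(mode_intensity) || any(mode_intensity < 0))
      stop("mode_intensity must give one nonnegative value per active mode",
           call. = FALSE)
  }

  E_act <- unclass(ems)[, active_ids, drop = FALSE]
  out <- with_local_seed(seed, {
    P <- matrix(runif(length(active_ids) * n_experiments,
                      weight_low, weight_high),
                nrow = length(active_ids),
                dimnames = list(active_ids,
                                paste0("exp", seq_len(n_experiments))))
    if (activation_prob < 1) {
      mask <- matrix(runif(length(P)) <= activation_prob, nrow = nrow(P))
      P <- P * mask
      for (d in which(colSums(P) == 0))
        P[sample.int(nrow(P), 1L), d] <- runif(1, weight_low, weight_high)
    }
    if (!is.null(mode_intensity)) P <- P * as.numeric(mode_intensity)
    V_clean <- E_act %*% P
    V <- V_clean
    if (noise_pct > 0) {
      if (noise_type == "relative") {
        V <- V_clean * (1 + matrix(rnorm(length(V_clean),
                                         sd = noise_pct / 100),
                                   nrow = nrow(V_clean)))
      } else {
        rms <- sqrt(mean(V_clean^2))
        V <- V_clean + matrix(rnorm(length(V_clean),
                                    sd = noise_pct / 100 * rms),
                              nrow = nrow(V_clean))
      }
    }
    list(P = P, V_clean = V_clean, V = V)
  })
  truth <- structure(list(active_ids = active_ids,
                          P_true = out$P,
                          V_clean = out$V_clean,
                          noise_pct = noise_pct,
                          seed = as.integer(seed)),
                     class = "pema_truth")
  list(flux = flux_data(out$V, flux_ids = rownames(ems)),
       truth = truth)
}

# one-dimensional nullspace basis of a matrix, or NULL
nullspace_1d <- function(A, tol = 1e-10) {
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- c(sv$d, rep(0, ncol(A) - length(sv$d)))
  thresh <- max(dim(A)) * max(d, 0) * .Machine$double.eps * 100
  null_dim <- sum(d <= max(thresh, tol * max(d, 1)))
  if (null_dim != 1L) return(NULL)
  sv$v[, ncol(A)]
}

#' Brute-force elementary mode enumeration for small networks
#'
#' Enumerates elementary flux modes by support: for every subset of
#' reactions, the stoichiometry restricted to that support must have a
#' one-dimensional nullspace whose basis vector is nonzero throughout the
#' support and can be oriented to satisfy every irreversibility
#' constraint (both orientations are tried; a fully reversible support
#' yields both directions). Vectors whose support strictly contains
#' another mode's support are discarded (elementarity). This is an
#' exponential fixture-grade enumerator for networks of at most 20
#' reactions; use a dedicated enumeration tool beyond that.
#'
#' @param network a [network_spec()].
#' @param tol numeric tolerance for zero tests.
#' @return an [em_set()] with modes scaled to unit 2-norm, satisfying
#'   `max(abs(S %*% e)) < 1e-12`.
#' @export
enumerate_ems_bruteforce <- function(network, tol = 1e-10) {
  stopifnot(inherits(network, "network_spec"))
  S <- network$stoichiometry
  n <- ncol(S)
  if (n > 20L)
    stop("brute-force enumeration is limited to 20 reactions; ",
         "use a dedicated EM enumeration tool", call. = FALSE)
  irr <- !network$reversible
  supports <- list()
  vectors <- list()
  for (mask in seq_len(2^n - 1L)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    v <- nullspace_1d(S[, supp, drop = FALSE], tol)
    if (is.null(v)) next
    if (min(abs(v)) <= tol * max(abs(v))) next  # true support is smaller
    for (sgn in c(1, -1)) {
      e_sub <- sgn * v
      if (any(e_sub[irr[supp]] < -tol)) next
      e <- numeric(n)
      e[supp] <- e_sub / sqrt(sum(e_sub^2))
      vectors[[length(vectors) + 1L]] <- e
      supports[[length(supports) + 1L]] <- supp
    }
  }
  if (length(vectors) == 0L)
    stop("network has no elementary modes", call. = FALSE)
  # elementarity: drop any mode whose support strictly contains another's
  keep <- vapply(seq_along(supports), function(i) {
    !any(vapply(seq_along(supports), function(j) {
      i != j && length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])
    }, logical(1)))
  }, logical(1))
  vectors <- vectors[keep]
  E <- do.call(cbind, vectors)
  # dedupe identical oriented vectors
  E <- E[, !duplicated(round(t(E), 12)), drop = FALSE]
  resid <- max(abs(S %*% E))
  if (resid >= 1e-12)
    stop("enumerated mode violates steady state (residual ", resid, ")",
         call. = FALSE)
  em_set(E, reaction_ids = network$reaction_ids,
         mode_ids = paste0("EM", seq_len(ncol(E))),
         network = network)
}

#' Canned test fixtures
#'
#' Named, seed-fixed cases used across the test suite:
#' \describe{
#'   \item{`chain`}{linear pathway uptake -> A -> B -> secretion; exactly
#'     one elementary mode.}
#'   \item{`branch`}{uptake of A branching to B or C, each secreted; two
#'     elementary modes with supports \{r1,r2,r4\} and \{r1,r3,r5\}.}
#'   \item{`greedy_trap`}{three modes on two measured fluxes where the
#'     greedy decomposition picks the diagonal compromise mode first and
#'     is beaten by the exact search: data `[[3, 0.1], [0.1, 3]]`, modes
#'     `a = (1,0)`, `b = (0,1)`, `c = (1,1)/sqrt(2)`.}
#'   \item{`pichia_like`}{a synthetic 98-mode EM matrix over 44 reactions
#'     of which 9 are measured exchange fluxes (3 substrate uptakes, O2,
#'     CO2, 3 products, biomass), with sparse nonnegative exchange
#'     restrictions; 16 active modes over 12 experiments with weights
#'     Uniform(0.1, 1), mirroring a central-carbon-metabolism simulation
#'     study.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed (used by `pichia_like`).
#' @param noise_pct Gaussian noise percent for `pichia_like` flux data.
#' @return list with components `network` (or NULL), `ems`, `flux` (or
#'   NULL), `truth` (or NULL). For `pichia_like`, `flux` contains only the
#'   9 measured exchange rows.
#' @export
toy_fixtures <- function(name = c("chain", "branch", "greedy_trap",
                                  "pichia_like"),
                         seed = 0L, noise_pct = 0) {
  name <- match.arg(name)
  if (name == "chain") {
    S <- matrix(c(1, -1, 0,
                  0, 1, -1), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
    net <- network_spec(S)
    return(list(network = net, ems = enumerate_ems_bruteforce(net),
                flux = NULL, truth = NULL))
  }
  if (name == "branch") {
    S <- matrix(c(1, -1, -1, 0, 0,
                  0, 1, 0, -1, 0,
                  0, 0, 1, 0, -1), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"),
                                c("r1", "r2", "r3", "r4", "r5")))
    net <- network_spec(S)
    return(list(network = net, ems = enumerate_ems_bruteforce(net),
                flux = NULL, truth = NULL))
  }
  if (name == "greedy_trap") {
    ems <- em_set(cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2)),
                  reaction_ids = c("f1", "f2"))
    flux <- flux_data(matrix(c(3, 0.1, 0.1, 3), nrow = 2,
                             dimnames = list(c("f1", "f2"),
                                             c("exp1", "exp2"))))
    return(list(network = NULL, ems = ems, flux = flux, truth = NULL))
  }
  # pichia_like: 98 modes over 44 reactions, 9 of which are measured
  # exchange fluxes; 30 distinct measured behaviors (pairwise cosine
  # <= 0.9), each represented by a family of positively proportional
  # modes that an ambiguity analysis collapses; 16 active modes of which
  # 9 dominate with a decaying intensity spectrum and 7 contribute at
  # trace level; 12 experiments, weights Uniform(0.1, 1) with a 0.5
  # per-experiment activation mask. See the methods vignette for why the
  # dominant behaviors concentrate on a single measured flux each (the
  # identifiability regime of deflation-based selection).
  measured <- c("vGlc", "vGly", "vMet", "vO2", "vCO2", "vEth", "vCit",
                "vPyr", "vBio")
  substrates <- c("vGlc", "vGly", "vMet")
  n_modes <- 98L
  n_beh <- 30L
  built <- with_local_seed(seed, {
    B <- matrix(0, length(measured), n_beh, dimnames = list(measured, NULL))
    # dominant behaviors: one per measured flux, concentrated on it (the
    # mode's remaining exchanges are unmeasured) plus small side entries
    for (j in 1:9) {
      B[j, j] <- runif(1, 0.8, 1.5)
      B[sample(setdiff(1:9, j), 2L), j] <- runif(2, 0.02, 0.08)
    }
    # remaining behaviors: substrate plus 1-3 other exchanges, kept
    # separated from everything accepted so far (cosine <= 0.9)
    j <- 10L
    while (j <= n_beh) {
      v <- numeric(9)
      names(v) <- measured
      v[sample(substrates, 1L)] <- runif(1, 0.3, 1.5)
      oth <- sample(setdiff(measured, substrates), sample(1:3, 1L))
      v[oth] <- runif(length(oth), 0.1, 1.5)
      u <- v / sqrt(sum(v^2))
      Bn <- sweep(B[, 1:(j - 1L), drop = FALSE], 2,
                  sqrt(colSums(B[, 1:(j - 1L), drop = FALSE]^2)), "/")
      if (max(crossprod(u, Bn)) <= 0.9) {
        B[, j] <- v
        j <- j + 1L
      }
    }
    beh <- sample(c(1:n_beh, sample.int(n_beh, n_modes - n_beh, replace = TRUE)))
    M <- B[, beh] * rep(runif(n_modes, 0.5, 2), each = length(measured))
    colnames(M) <- paste0("EM", seq_len(n_modes))
    U <- matrix(abs(rnorm(35L * n_modes)) * (runif(35L * n_modes) < 0.25),
                nrow = 35L,
                dimnames = list(paste0("r", 10:44), colnames(M)))
    act_beh <- c(1:9, sample(10:n_beh, 7L))
    active <- sort(colnames(M)[vapply(act_beh, function(b)
      which(beh == b)[1L], integer(1))])
    dom_ids <- colnames(M)[vapply(1:9, function(b)
      which(beh == b)[1L], integer(1))]
    intensity <- stats::setNames(rep(0.05, 16L), active)
    intensity[dom_ids] <- 0.85^(0:8) * runif(9, 0.85, 1.15)
    list(ems = em_set(rbind(M, U)), active = active, intensity = intensity)
  })
  sim <- simulate_flux_data(built$ems, built$active, n_experiments = 12L,
                            weight_low = 0.1, weight_high = 1,
                            noise_pct = noise_pct, seed = seed + 1000000L,
                            activation_prob = 0.5,
                            mode_intensity = built$intensity)
  flux <- flux_data(unclass(sim$flux)[measured, , drop = FALSE])
  list(network = NULL, ems = built$ems, flux = flux, truth = sim$truth)
}
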