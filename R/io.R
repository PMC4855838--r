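#' pema: Principal Elementary Mode Analysis of flux data
#'
#' Tools to identify the subset of elementary flux modes (EMs) whose
#' nonnegative combination best explains measured reaction flux data.
#' The workflow is: read an EM matrix and a flux table
#' ([read_em_matrix()], [read_flux_table()]), build a scaled problem
#' ([build_problem()]), fit by greedy deflation and branch-and-bound
#' ([pema_fit()]), and compare against an uncentered PCA baseline
#' ([pca_variance_curve()]). A synthetic generator with known ground truth
#' ([simulate_flux_data()], [toy_fixtures()]) supports validation.
#'
#' @useDynLib pema, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.table write.table combn head
#' @keywords internal
"_PACKAGE"

# ---- domain types -----------------------------------------------------------

#' Measured flux data container
#'
#' A numeric matrix of measured reaction fluxes (rows, e.g. mmol/gDW/h)
#' across experiments (columns), with unique row and column identifiers.
#'
#' @param values numeric matrix, fluxes x experiments.
#' @param flux_ids,experiment_ids character identifiers; default to the
#'   dimnames of `values`.
#' @return an object of class `flux_data` (a matrix with mandatory dimnames).
#' @export
flux_data <- function(values, flux_ids = rownames(values),
                      experiment_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(flux_ids)) flux_ids <- paste0("flux", seq_len(nrow(values)))
  if (is.null(experiment_ids)) experiment_ids <- paste0("exp", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(flux_ids), as.character(experiment_ids))
  class(values) <- c("flux_data", "matrix", "array")
  validate_flux_data(values)
  values
}

validate_flux_data <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("flux_data needs at least one flux and one experiment", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate flux ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate experiment ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("flux_data values must all be finite (no NA/NaN/Inf)", call. = FALSE)
  if (all(x == 0))
    stop("flux_data is all zero", call. = FALSE)
  invisible(x)
}

#' Elementary flux mode set
#'
#' A numeric matrix of elementary flux modes: rows are reactions, columns
#' are modes (flux per unit weight, arbitrary positive scale). Columns must
#' be nonzero. If a [network_spec()] is supplied, each mode is checked for
#' steady state and for sign-consistency with reaction reversibility.
#'
#' @param modes numeric matrix, reactions x modes.
#' @param reaction_ids,mode_ids character identifiers; default to dimnames.
#' @param network optional [network_spec()] used for validation only.
#' @return an object of class `em_set`.
#' @export
em_set <- function(modes, reaction_ids = rownames(modes),
                   mode_ids = colnames(modes), network = NULL) {
  modes <- as.matrix(modes)
  storage.mode(modes) <- "double"
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(nrow(modes)))
  if (is.null(mode_ids)) mode_ids <- paste0("EM", seq_len(ncol(modes)))
  dimnames(modes) <- list(as.character(reaction_ids), as.character(mode_ids))
  class(modes) <- c("em_set", "matrix", "array")
  validate_em_set(modes, network)
  modes
}

validate_em_set <- function(x, network = NULL) {
  if (anyDuplicated(colnames(x)))
    stop("duplicate mode ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate reaction ids in EM matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop("EM matrix values must all be finite", call. = FALSE)
  zero <- colSums(abs(x)) == 0
  if (any(zero))
    stop("all-zero EM column(s): ", paste(colnames(x)[zero], collapse = ", "),
         call. = FALSE)
  if (!is.null(network)) {
    idx <- match(network$reaction_ids, rownames(x))
    if (anyNA(idx))
      stop("network reaction ids missing from EM matrix", call. = FALSE)
    irr <- !network$reversible
    sub <- x[idx[irr], , drop = FALSE]
    if (any(sub < -1e-9))
      stop("EM entries negative on irreversible reactions", call. = FALSE)
  }
  invisible(x)
}

#' Metabolic network specification
#'
#' Stoichiometry of balanced (internal) metabolites by reactions, with
#' per-reaction reversibility. Used by the toy elementary-mode enumerator
#' and for optional validation of externally supplied EM sets.
#'
#' @param stoichiometry numeric matrix, metabolites x reactions.
#' @param reversible logical vector, one entry per reaction.
#' @param reaction_ids,metabolite_ids character identifiers.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(stoichiometry,
                         reversible = rep(FALSE, ncol(stoichiometry)),
                         reaction_ids = colnames(stoichiometry),
                         metabolite_ids = rownames(stoichiometry)) {
  stoichiometry <- as.matrix(stoichiometry)
  storage.mode(stoichiometry) <- "double"
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(ncol(stoichiometry)))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(nrow(stoichiometry)))
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(reversible) != ncol(stoichiometry))
    stop("reversible must have one entry per reaction", call. = FALSE)
  if (anyDuplicated(reaction_ids) || anyDuplicated(metabolite_ids))
    stop("duplicate reaction or metabolite ids", call. = FALSE)
  dimnames(stoichiometry) <- list(metabolite_ids, reaction_ids)
  structure(list(stoichiometry = stoichiometry,
                 reversible = as.logical(reversible),
                 reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids),
            class = "network_spec")
}

#' Analysis configuration
#'
#' @param n_fac number of factors (EMs to combine), >= 1.
#' @param tie_tol tolerance within which variance gains count as tied
#'   (ties broken towards the lexicographically lowest mode id).
#' @param ambiguity_tol cosine tolerance for grouping positively
#'   proportional measured restrictions, and the relative-norm threshold
#'   below which a restriction counts as zero.
#' @param direction_tol magnitude below which a flux value or EM entry is
#'   treated as zero by the direction filter.
#' @param prune_tol slack added to the incumbent when pruning.
#' @param direction_filter_mode `"global"` (sign constraints from fluxes
#'   single-signed across all experiments) or `"off"`.
#' @param scaling_mode `"abs_mean"` (default; rows scaled by the mean of
#'   absolute values), `"signed_mean"` (arithmetic mean), or `"none"`.
#' @param prune logical; disable to force exhaustive enumeration (the
#'   selections must not change, only the node counts).
#' @param max_nodes node budget for the branch-and-bound search; when
#'   exhausted the incumbent is returned flagged as not proven optimal.
#' @param seed integer seed recorded in results and used by helpers that
#'   accept a config.
#' @return an object of class `pema_config`.
#' @export
pema_config <- function(n_fac = 1L,
                        tie_tol = 1e-12,
                        ambiguity_tol = 1e-9,
                        direction_tol = 1e-9,
                        prune_tol = 1e-12,
                        direction_filter_mode = c("global", "off"),
                        scaling_mode = c("abs_mean", "signed_mean", "none"),
                        prune = TRUE,
                        max_nodes = Inf,
                        seed = 1L) {
  n_fac <- as.integer(n_fac)
  if (is.na(n_fac) || n_fac < 1L) stop("n_fac must be a positive integer", call. = FALSE)
  tols <- c(tie_tol = tie_tol, ambiguity_tol = ambiguity_tol,
            direction_tol = direction_tol, prune_tol = prune_tol)
  if (any(tols < 0)) stop("tolerances must be nonnegative", call. = FALSE)
  structure(list(n_fac = n_fac,
                 tie_tol = tie_tol,
                 ambiguity_tol = ambiguity_tol,
                 direction_tol = direction_tol,
                 prune_tol = prune_tol,
                 direction_filter_mode = match.arg(direction_filter_mode),
                 scaling_mode = match.arg(scaling_mode),
                 prune = isTRUE(prune),
                 max_nodes = max_nodes,
                 seed = as.integer(seed)),
            class = "pema_config")
}

#' Read a configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file whose keys mirror the arguments of [pema_config()].
#' @return a `pema_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pema_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pema_config, vals)
}

# ---- delimited matrix I/O ---------------------------------------------------

read_matrix_file <- function(path, dialect = c("csv", "tsv"), what) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8", comment.char = "")
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column in ", path,
                          call. = FALSE)
  ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                 what, ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                 body[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  num
}

write_matrix_file <- function(x, path, dialect = c("csv", "tsv"), id_header) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(rownames(x), format(unclass(x), digits = 17, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, colnames(x))
  utils::write.table(df, path, sep = sep, row.names = FALSE, col.names = TRUE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measured flux table
#'
#' First row: experiment ids; first column: flux ids; numeric body.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return a [flux_data()] object with row/column order preserved.
#' @export
read_flux_table <- function(path, dialect = c("csv", "tsv")) {
  flux_data(read_matrix_file(path, dialect, "flux table"))
}

#' Write a measured flux table
#' @param flux a [flux_data()] object.
#' @inheritParams read_flux_table
#' @export
write_flux_table <- function(flux, path, dialect = c("csv", "tsv")) {
  write_matrix_file(flux, path, dialect, id_header = "flux")
}

#' Read an elementary flux mode matrix
#'
#' Rows are reactions, columns are mode ids, as produced by external EM
#' enumeration tools and exported to delimited text.
#'
#' @inheritParams read_flux_table
#' @return an [em_set()] object.
#' @export
read_em_matrix <- function(path, dialect = c("csv", "tsv")) {
  em_set(read_matrix_file(path, dialect, "EM matrix"))
}

#' Write an elementary flux mode matrix
#' @param ems an [em_set()] object.
#' @inheritParams read_flux_table
#' @export
write_em_matrix <- function(ems, path, dialect = c("csv", "tsv")) {
  write_matrix_file(ems, path, dialect, id_header = "reaction")
}

# ---- result serialization ---------------------------------------------------

run_manifest <- function(config, seed, input_files = character()) {
  hashes <- if (length(input_files)) as.list(tools::md5sum(input_files)) else NULL
  list(tool = "pema",
       version = as.character(utils::packageVersion("pema")),
       seed = seed,
       config = unclass(config),
       input_md5 = hashes,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write an analysis result to disk
#'
#' Writes `<path>.json` (machine readable: selections, explained-variance
#' curve, weight matrices, pre-selection report, search statistics, config
#' echo and seed) and `<path>.txt` (the printed summary table).
#'
#' @param result a `pema_result` from [pema_fit()].
#' @param path output path prefix (without extension).
#' @param input_files optional paths hashed into the run manifest.
#' @return invisibly, the JSON path.
#' @export
write_result <- function(result, path, input_files = character()) {
  stopifnot(inherits(result, "pema_result"))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  payload <- list(
    manifest = run_manifest(result$config, result$config$seed, input_files),
    n_fac = result$n_fac,
    theta = result$theta,
    greedy_theta = result$greedy$theta_curve,
    factors = lapply(result$factors, function(f) {
      list(ids = f$ids,
           theta = f$theta,
           proven_optimal = f$proven_optimal,
           weights_scaled = as.data.frame(f$weights_scaled),
           weights = as.data.frame(f$weights))
    }),
    preselection = list(
      kept_mode_ids = result$problem$kept_mode_ids,
      removed_by_direction = result$problem$removed_by_direction,
      removed_zero_measured = result$problem$removed_zero_measured,
      ambiguity_groups = result$problem$ambiguity$groups
    ),
    stats = result$stats
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  writeLines(utils::capture.output(print(result)), txt_path)
  invisible(json_path)
}

#' Read back a result JSON written by [write_result()]
#' @param path path to the `.json` file.
#' @return the deserialized list.
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
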