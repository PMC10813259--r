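# Latin hypercube sampling of the 16 probabilistic inputs and generation
# of the trial dataset linking inputs to laxity.

.laxity_metric_names <- function(flexions = c(0, 30, 45, 60, 90),
                                 torques = c(1, 5),
                                 directions = c("internal", "external",
                                                "abduction", "adduction")) {
  unlist(lapply(directions, function(d)
    unlist(lapply(flexions, function(fx)
      paste0(d, "_", fx, "_", torques, "Nm")))))
}

.mech_param_names <- c(paste0("sector", 1:6, "_stiffness"),
                       paste0("sector", 1:6, "_prestrain"))
.pc_param_names <- paste0("pc", 1:4)

#' Default probabilistic input distributions
#'
#' The 16 independent input variables of the probabilistic capsule model:
#' six sector stiffnesses and six sector pre-strains as truncated normal
#' distributions covering 95% of the population variability (truncation
#' at +/-1.96 SD), and four attachment-site PC scores as standard normals
#' truncated at +/-2 SD.
#'
#' @return Object of class `parameter_distributions`: a data frame with
#'   columns `name`, `mean`, `sd` and `trunc_sd` (the symmetric truncation
#'   bound in SD units).
#' @export
default_distributions <- function() {
  d <- data.frame(
    name = c(.mech_param_names, .pc_param_names),
    mean = c(61.0, 62.3, 58.5, 53.9, 70.5, 50.4,
             0.99, 0.71, 0.62, 0.57, 0.48, 0.57,
             0, 0, 0, 0),
    sd = c(rep(15.0, 6L), rep(0.05, 6L), rep(1, 4L)),
    trunc_sd = c(rep(1.96, 12L), rep(2.0, 4L)))
  class(d) <- c("parameter_distributions", "data.frame")
  d
}

#' Latin hypercube sample of the probabilistic inputs
#'
#' Draws `n` samples of each input from its truncated normal distribution
#' with Latin hypercube stratification: each marginal places exactly one
#' sample in each of `n` equal-probability bins of the truncated
#' distribution (stratified uniforms on the truncated CDF range mapped
#' through the normal quantile function), with the pairing across
#' columns randomized.
#'
#' @param n number of samples (>= 2).
#' @param dists a [default_distributions()]-style registry.
#' @param seed optional integer seed for reproducibility.
#' @return n x 16 numeric matrix with the registry's parameter names as
#'   column names.
#' @export
lhs_normal <- function(n, dists = default_distributions(), seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(dists)
  U <- lhs::randomLHS(n, k)
  X <- matrix(NA_real_, n, k, dimnames = list(NULL, dists$name))
  for (j in seq_len(k)) {
    plo <- stats::pnorm(-dists$trunc_sd[j])
    phi <- stats::pnorm(dists$trunc_sd[j])
    X[, j] <- dists$mean[j] +
      dists$sd[j] * stats::qnorm(plo + U[, j] * (phi - plo))
  }
  X
}

# capsule_parameters from a named input row
.row_params <- function(row) {
  capsule_parameters(stiffness = row[paste0("sector", 1:6, "_stiffness")],
                     pre_strain = row[paste0("sector", 1:6, "_prestrain")])
}

#' Generate the probabilistic trial dataset
#'
#' For each Latin-hypercube sample of the 16 inputs: reconstructs the
#' attachment geometry from the PC scores through the shape model, builds
#' the capsule spring mesh, and evaluates the full 40-metric laxity
#' profile. Trials whose equilibrium solve fails are retained with
#' `ok = FALSE` rather than dropped.
#'
#' @param n_trials number of trials (e.g. 500).
#' @param shape_model a [fit_shape_model()] result with >= 4 modes.
#' @param dists input distribution registry.
#' @param mesh_config a [default_mesh_config()]-style list.
#' @param seed optional integer seed; the dataset is deterministic given
#'   the seed.
#' @param verbose log per-trial progress to stderr.
#' @return Object of class `capsule_trials`: a data frame with `trial_id`,
#'   the 16 input columns, the 40 laxity columns
#'   (`direction_flexion_torqueNm`) and `ok`; the shape model, mesh
#'   configuration, distribution registry and seed are kept as
#'   attributes.
#' @export
generate_trial_dataset <- function(n_trials, shape_model,
                                   dists = default_distributions(),
                                   mesh_config = default_mesh_config(),
                                   seed = NULL, verbose = FALSE) {
  X <- lhs_normal(n_trials, dists, seed = seed)
  lax_names <- .laxity_metric_names()
  L <- matrix(NA_real_, n_trials, length(lax_names),
              dimnames = list(NULL, lax_names))
  ok <- rep(TRUE, n_trials)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_trials)) {
    res <- tryCatch(
      .simulate_trial(X[i, ], shape_model, mesh_config),
      error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE
      warning("trial ", i, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      L[i, ] <- res
    }
    if (verbose && (i %% 25L == 0L || i == n_trials))
      message(sprintf("  trial %d/%d (%.1f s elapsed)", i, n_trials,
                      proc.time()[["elapsed"]] - t0))
  }
  out <- data.frame(trial_id = seq_len(n_trials), X, L, ok,
                    check.names = FALSE)
  attr(out, "shape_model") <- shape_model
  attr(out, "mesh_config") <- mesh_config
  attr(out, "dists") <- dists
  attr(out, "seed") <- seed
  class(out) <- c("capsule_trials", "data.frame")
  out
}

# simulate the 40 laxity metrics for one input row (named numeric vector)
.simulate_trial <- function(row, shape_model, mesh_config) {
  pair <- reconstruct_attachments(shape_model, row[.pc_param_names])
  mesh <- .mesh_from_pair(pair, mesh_config)
  prof <- evaluate_laxity_profile(mesh, .row_params(row))
  stats::setNames(prof$rotation_deg,
                  paste0(prof$direction, "_", prof$flexion_deg, "_",
                         prof$torque_Nm, "Nm"))[.laxity_metric_names()]
}

#' @export
print.capsule_trials <- function(x, ...) {
  cat(sprintf(
    "Probabilistic capsule trials: %d trials (%d complete), 16 inputs, %d laxity metrics\n",
    nrow(x), sum(x$ok), length(.laxity_metric_names())))
  invisible(x)
}

#' Split a trial dataset into training and validation subsets
#'
#' Random split preserving the dataset attributes; with the defaults a
#' 500-trial dataset yields the 450/50 training/validation partition used
#' for surrogate calibration.
#'
#' @param dataset a [generate_trial_dataset()] result.
#' @param n_validation number of validation trials (default 10% of the
#'   dataset).
#' @param seed optional integer seed for the permutation.
#' @return list with `train` and `validation` subsets (both
#'   `capsule_trials`).
#' @export
split_trials <- function(dataset, n_validation = round(nrow(dataset) / 10),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset)
  stopifnot(n_validation >= 1L, n_validation < n)
  idx <- sample.int(n)
  val <- sort(idx[seq_len(n_validation)])
  list(train = .subset_trials(dataset, setdiff(seq_len(n), val)),
       validation = .subset_trials(dataset, val))
}

.subset_trials <- function(dataset, rows) {
  out <- dataset[rows, , drop = FALSE]
  for (a in c("shape_model", "mesh_config", "dists", "seed"))
    attr(out, a) <- attr(dataset, a)
  class(out) <- c("capsule_trials", "data.frame")
  out
}
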