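# Closed-loop validation of the surrogate: predict capsule parameters
# from laxity, re-simulate, and score the round-trip RMSE; plus the
# training-size convergence study and between-set comparisons.

#' Closed-loop validation of a trained surrogate
#'
#' For each validation trial: predicts the capsule parameters from the
#' trial's laxity subset and PC scores, rebuilds the capsule mesh from the
#' trial's true attachment PC scores, re-simulates the full 40-metric
#' laxity profile with the predicted parameters, and computes the RMSE
#' against the trial's original laxities (always over all 40 metrics,
#' regardless of which subset trained the surrogate). Trials whose
#' re-simulation fails to converge are excluded from the aggregates and
#' counted in `n_failed`.
#'
#' @param model a [capsule_surrogate()].
#' @param validation_trials `capsule_trials` rows disjoint from the
#'   training trials.
#' @param mesh_config mesh configuration; defaults to the one stored on
#'   the dataset.
#' @param parameters optional n x 12 matrix of capsule parameters to
#'   re-simulate instead of the surrogate predictions (diagnostic use,
#'   e.g. feeding back the true parameters must give zero RMSE).
#' @return Object of class `validation_report`: `per_trial_rmse` (deg),
#'   `per_metric_rmse` (deg, across trials), `composite_mean`,
#'   `composite_sd`, `set_id`, `n_train`, `n_failed`, and the per-trial
#'   laxity error matrix `errors`.
#' @export
closed_loop_validate <- function(model, validation_trials,
                                 mesh_config = NULL, parameters = NULL) {
  shape_model <- attr(validation_trials, "shape_model")
  if (is.null(mesh_config)) mesh_config <- attr(validation_trials, "mesh_config")
  if (is.null(shape_model) || is.null(mesh_config))
    stop("validation trials must carry their shape model and mesh config")
  d <- validation_trials[validation_trials$ok, , drop = FALSE]
  lax_names <- .laxity_metric_names()
  n <- nrow(d)
  E <- matrix(NA_real_, n, length(lax_names),
              dimnames = list(d$trial_id, lax_names))
  failed <- 0L
  for (i in seq_len(n)) {
    row <- as.numeric(d[i, ])
    names(row) <- names(d)
    prm <- if (is.null(parameters)) {
      predict(model, d[i, , drop = FALSE][c(model$predictor_names)])
    } else {
      v <- stats::setNames(parameters[i, ], .mech_param_names)
      capsule_parameters(v[1:6], v[7:12])   # diagnostic override: as given
    }
    sim <- tryCatch({
      pair <- reconstruct_attachments(shape_model, row[.pc_param_names])
      mesh <- .mesh_from_pair(pair, mesh_config)
      prof <- evaluate_laxity_profile(mesh, prm)
      stats::setNames(prof$rotation_deg,
                      paste0(prof$direction, "_", prof$flexion_deg, "_",
                             prof$torque_Nm, "Nm"))[lax_names]
    }, error = function(e) e)
    if (inherits(sim, "error")) failed <- failed + 1L
    else E[i, ] <- sim - row[lax_names]
  }
  per_trial <- sqrt(rowMeans(E^2))
  per_metric <- sqrt(colMeans(E^2, na.rm = TRUE))
  done <- is.finite(per_trial)
  structure(list(per_trial_rmse = per_trial[done],
                 per_metric_rmse = per_metric,
                 composite_mean = mean(per_trial[done]),
                 composite_sd = stats::sd(per_trial[done]),
                 set_id = model$set$set_id, n_train = model$n_trials,
                 n_failed = failed, errors = E[done, , drop = FALSE]),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Closed-loop validation (set %d, %d training trials): RMSE %.2f +/- %.2f deg over %d trials",
    x$set_id, x$n_train, x$composite_mean, x$composite_sd,
    length(x$per_trial_rmse)))
  if (x$n_failed > 0) cat(sprintf(" (%d failed re-simulations)", x$n_failed))
  cat("\n")
  invisible(x)
}

#' Training-size convergence study
#'
#' Trains surrogates on nested training subsets of increasing size,
#' validates each against the same held-out validation trials, and flags
#' convergence when the relative change in composite RMSE between the two
#' largest sizes is below 5%.
#'
#' @param dataset a full `capsule_trials` dataset.
#' @param set a [training_set_spec()].
#' @param sizes strictly increasing training sizes (default
#'   `c(100, 200, 300, 400, 450)`).
#' @param n_validation held-out validation trial count (default 50).
#' @param seed seed controlling the split and the nesting order.
#' @param ... passed to [capsule_surrogate()].
#' @return Object of class `convergence_study` with `curve` (data frame
#'   `size`, `rmse`, `rmse_sd`), `converged`, `reports`.
#' @export
convergence_study <- function(dataset, set = training_set_spec(1),
                              sizes = c(100, 200, 300, 400, 450),
                              n_validation = 50, seed = NULL, ...) {
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (max(sizes) + n_validation > nrow(dataset))
    stop("dataset too small for max(sizes) + ", n_validation, " trials")
  sp <- split_trials(dataset, n_validation = n_validation, seed = seed)
  ord <- sample.int(nrow(sp$train))        # nesting order (seeded above)
  reports <- lapply(sizes, function(sz) {
    sub <- .subset_trials(sp$train, sort(ord[seq_len(sz)]))
    m <- capsule_surrogate(sub, set = set, ...)
    m$n_trials <- sz
    closed_loop_validate(m, sp$validation)
  })
  rmse <- vapply(reports, function(r) r$composite_mean, numeric(1L))
  rel <- abs(diff(rmse)) / rmse[-length(rmse)]
  structure(list(curve = data.frame(
    size = sizes, rmse = rmse,
    rmse_sd = vapply(reports, function(r) r$composite_sd, numeric(1L))),
    converged = rel[length(rel)] < 0.05,
    relative_change = rel, reports = reports, set_id = set$set_id),
    class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat(sprintf("Training-size convergence (set %d): %s\n", x$set_id,
              if (x$converged) "converged (<5% change)" else "not converged"))
  print(x$curve, digits = 3)
  invisible(x)
}

#' @export
plot.convergence_study <- function(x, ...) {
  graphics::plot(x$curve$size, x$curve$rmse, type = "b", pch = 19,
                 xlab = "training trials", ylab = "composite RMSE (deg)",
                 main = "Surrogate convergence", ...)
  invisible(x)
}

#' Compare validation RMSE between training sets
#'
#' Two-sample Student's t-tests (equal-variance pooling, two-sided) on the
#' per-trial RMSE samples of every pair of validation reports, with
#' significance flags at alpha = 0.05.
#'
#' @param reports list of [closed_loop_validate()] reports (>= 2), each
#'   with at least 2 per-trial RMSE values.
#' @param alpha significance level.
#' @return Object of class `set_comparison` with symmetric matrices `t`,
#'   `p` and `significant`.
#' @export
compare_sets <- function(reports, alpha = 0.05) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  if (any(vapply(reports, function(r) length(r$per_trial_rmse),
                 integer(1L)) < 2L))
    stop("each report needs at least 2 per-trial RMSE values")
  ids <- vapply(seq_along(reports), function(i) {
    id <- reports[[i]]$set_id
    if (is.null(id)) paste0("report", i) else paste0("set", id)
  }, character(1L))
  ids <- make.unique(ids)
  k <- length(reports)
  Tm <- Pm <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    Tm[i, i] <- 0; Pm[i, i] <- 1
    for (j in seq_len(k)) if (j > i) {
      tt <- stats::t.test(reports[[i]]$per_trial_rmse,
                          reports[[j]]$per_trial_rmse, var.equal = TRUE)
      Tm[i, j] <- Tm[j, i] <- unname(tt$statistic)
      Pm[i, j] <- Pm[j, i] <- tt$p.value
    }
  }
  structure(list(t = Tm, p = Pm, significant = Pm < alpha, alpha = alpha),
            class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("Pairwise Student's t-tests on per-trial RMSE (alpha = %g)\n",
              x$alpha))
  cat("p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}
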