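# Stepwise multilinear regression surrogate: predicts the 12 capsule
# mechanical parameters from a chosen subset of laxity metrics plus the
# 4 attachment-site PC scores.

#' Training-set registry
#'
#' The nine candidate laxity subsets used to train the surrogate: which
#' rotation families (I-E and/or Ad-Ab) and which flexion angles are
#' included; both torque levels (1 and 5 N m) are always used. `n_laxity`
#' is the resulting laxity predictor count N.
#'
#' @param set_id integer 1-9.
#' @return Object of class `training_set_spec` with elements `set_id`,
#'   `directions`, `flexions`, `torques` and `n_laxity`.
#' @export
training_set_spec <- function(set_id) {
  ie <- c("internal", "external"); adab <- c("abduction", "adduction")
  reg <- list(
    list(dirs = c(ie, adab), flex = c(0, 30, 60, 90)),
    list(dirs = ie,          flex = c(0, 30, 60, 90)),
    list(dirs = adab,        flex = c(0, 30, 60, 90)),
    list(dirs = c(ie, adab), flex = c(0, 45, 90)),
    list(dirs = ie,          flex = c(0, 45, 90)),
    list(dirs = adab,        flex = c(0, 45, 90)),
    list(dirs = c(ie, adab), flex = c(0, 90)),
    list(dirs = ie,          flex = c(0, 90)),
    list(dirs = adab,        flex = c(0, 90)))
  set_id <- as.integer(set_id)
  if (!(set_id %in% seq_along(reg))) stop("set_id must be 1..9")
  r <- reg[[set_id]]
  structure(list(set_id = set_id, directions = r$dirs, flexions = r$flex,
                 torques = c(1, 5),
                 n_laxity = length(r$dirs) * length(r$flex) * 2L),
            class = "training_set_spec")
}

#' @export
print.training_set_spec <- function(x, ...) {
  cat(sprintf("Training set %d: %s at flexion %s (N = %d laxity predictors)\n",
              x$set_id, paste(x$directions, collapse = "/"),
              paste(x$flexions, collapse = ", "), x$n_laxity))
  invisible(x)
}

# laxity predictor column names of a training-set spec
.spec_predictors <- function(spec) {
  .laxity_metric_names(flexions = spec$flexions, torques = spec$torques,
                       directions = spec$directions)
}

#' Forward-backward stepwise linear regression
#'
#' Builds a linear model (with intercept) by alternately adding the
#' candidate predictor with the smallest partial-F p-value below
#' `p_enter` and removing the included predictor with the largest p-value
#' above `p_remove`, until no move changes the model. Deterministic for
#' fixed inputs; ties resolve to the earliest column.
#'
#' @param X numeric matrix of candidate predictors (named columns,
#'   >= 10 rows, no constant columns).
#' @param y numeric response vector.
#' @param p_enter,p_remove entry and removal p-value thresholds (defaults
#'   0.05 and 0.10).
#' @return list with `terms` (selected column names), `coefficients`
#'   (named, first element `(Intercept)`), `fitted`, `residuals` and
#'   `rmse` (training root-mean-square residual).
#' @export
stepwise_fit <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10L) stop("at least 10 rows are required")
  if (length(y) != n) stop("X and y dimensions differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant candidate columns: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (anyDuplicated(colnames(X)))
    stop("candidate column names must be unique")

  sel <- character(0)
  cand <- colnames(X)
  repeat {
    changed <- FALSE
    # forward: best addition by partial-F against the current model
    avail <- setdiff(cand, sel)
    rss0 <- sum(stats::lm.fit(cbind(1, X[, sel, drop = FALSE]),
                              y)$residuals^2)
    # an (essentially) perfect fit admits no further meaningful entry
    if (length(avail) > 0L && rss0 > 1e-12 * (sum(y^2) + 1)) {
      p_add <- vapply(avail, function(nm) {
        Z <- cbind(1, X[, c(sel, nm), drop = FALSE])
        qz <- qr(Z)
        if (qz$rank < ncol(Z)) return(NA_real_)   # collinear addition
        df2 <- n - ncol(Z)
        if (df2 <= 0) return(NA_real_)
        rss1 <- sum(qr.resid(qz, y)^2)
        fstat <- (rss0 - rss1) / (rss1 / df2)
        stats::pf(fstat, 1, df2, lower.tail = FALSE)
      }, numeric(1L))
      if (any(is.finite(p_add)) && min(p_add, na.rm = TRUE) < p_enter) {
        best <- avail[which.min(p_add)]
        sel <- c(sel, best)
        changed <- TRUE
      }
    }
    # backward: worst removal
    if (length(sel) > 0L) {
      pv <- .term_p_values(X[, sel, drop = FALSE], y)
      if (max(pv) > p_remove) {
        worst <- sel[which.max(pv)]
        sel <- setdiff(sel, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                             X[, sel, drop = FALSE]), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(terms = sel, coefficients = co, fitted = y - fit$residuals,
       residuals = fit$residuals,
       rmse = sqrt(mean(fit$residuals^2)))
}

# p-values of every included term (t-tests from the full fit)
.term_p_values <- function(Xs, y) {
  Z <- cbind(1, Xs)
  fit <- stats::lm.fit(Z, y)
  n <- length(y); p <- ncol(Z)
  df <- n - p
  s2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(qr.R(qr(Z)))
  se <- sqrt(s2 * diag(XtXi))
  tstat <- fit$coefficients / se
  pv <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  stats::setNames(pv[-1L], colnames(Xs))
}

#' Train the capsule-parameter surrogate
#'
#' Fits one stepwise multilinear regression per capsule mechanical
#' parameter (12 fits), with the training-set's laxity metrics plus the
#' four attachment PC scores as candidate predictors:
#' `p_k = intercept_k + sum_i l_i L_i + sum_i p_i PC_i`.
#'
#' @param dataset a [generate_trial_dataset()] result (or training subset
#'   from [split_trials()]); at least 50 complete trials.
#' @param set a [training_set_spec()] (default Set 1, the full I-E +
#'   Ad-Ab baseline).
#' @param p_enter,p_remove stepwise thresholds.
#' @return Object of class `capsule_surrogate`.
#' @export
capsule_surrogate <- function(dataset, set = training_set_spec(1),
                              p_enter = 0.05, p_remove = 0.10) {
  stopifnot(inherits(set, "training_set_spec"))
  d <- dataset[dataset$ok, , drop = FALSE]
  if (nrow(d) < 50L)
    stop("at least 50 complete trials are required, got ", nrow(d))
  preds <- c(.spec_predictors(set), .pc_param_names)
  missing <- setdiff(preds, names(d))
  if (length(missing) > 0L)
    stop("dataset lacks predictor columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(d[, preds, drop = FALSE])
  fits <- lapply(.mech_param_names, function(out) {
    tryCatch(stepwise_fit(X, d[[out]], p_enter, p_remove),
             error = function(e)
               stop("stepwise fit failed for output '", out, "': ",
                    conditionMessage(e), call. = FALSE))
  })
  names(fits) <- .mech_param_names
  out_range <- vapply(.mech_param_names,
                      function(out) range(d[[out]]), numeric(2L))
  structure(list(fits = fits, set = set, predictor_names = preds,
                 n_trials = nrow(d), p_enter = p_enter,
                 p_remove = p_remove,
                 training_means = colMeans(X),
                 output_range = out_range),
            class = "capsule_surrogate")
}

#' @rdname capsule_surrogate
#' @export
train_surrogate <- capsule_surrogate

#' @export
print.capsule_surrogate <- function(x, ...) {
  cat(sprintf(
    "Capsule surrogate: training set %d (%d laxity + 4 PC candidates), %d trials\n",
    x$set$set_id, x$set$n_laxity, x$n_trials))
  nt <- vapply(x$fits, function(f) length(f$terms), integer(1L))
  cat(sprintf("  terms per output: %d-%d (median %g)\n",
              min(nt), max(nt), stats::median(nt)))
  invisible(x)
}

#' @export
summary.capsule_surrogate <- function(object, ...) {
  tab <- data.frame(
    output = names(object$fits),
    n_terms = vapply(object$fits, function(f) length(f$terms), integer(1L)),
    train_rmse = vapply(object$fits, function(f) f$rmse, numeric(1L)),
    row.names = NULL)
  structure(list(set = object$set, n_trials = object$n_trials, table = tab),
            class = "summary.capsule_surrogate")
}

#' @export
print.summary.capsule_surrogate <- function(x, ...) {
  cat(sprintf("Capsule surrogate trained on %d trials (set %d)\n",
              x$n_trials, x$set$set_id))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.capsule_surrogate <- function(object, ...) {
  cols <- c("(Intercept)", object$predictor_names)
  M <- matrix(0, length(object$fits), length(cols),
              dimnames = list(names(object$fits), cols))
  for (out in names(object$fits)) {
    co <- object$fits[[out]]$coefficients
    M[out, names(co)] <- co
  }
  M
}

#' @export
residuals.capsule_surrogate <- function(object, ...) {
  sapply(object$fits, function(f) f$residuals)
}

#' @export
fitted.capsule_surrogate <- function(object, ...) {
  sapply(object$fits, function(f) f$fitted)
}

#' Predict capsule parameters from laxity and shape scores
#'
#' Evaluates the per-output regression equations on new predictor values.
#' `newdata` may be a data frame (one prediction per row) or a named
#' numeric vector containing every selected predictor.
#'
#' @param object a [capsule_surrogate()].
#' @param newdata data frame or named vector with the laxity metric and
#'   `pc1..pc4` columns the model selected.
#' @param ... unused.
#' @return For a single row, a [capsule_parameters()] with the predicted
#'   values (also attached as attribute `values`, the raw named
#'   12-vector); for multiple rows, an n x 12 matrix.
#' @export
predict.capsule_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  used <- unique(unlist(lapply(object$fits, `[[`, "terms")))
  missing <- setdiff(used, names(newdata))
  if (length(missing) > 0L)
    stop("missing predictors: ", paste(missing, collapse = ", "))
  n <- nrow(newdata)
  M <- matrix(NA_real_, n, length(object$fits),
              dimnames = list(NULL, names(object$fits)))
  for (out in names(object$fits)) {
    co <- object$fits[[out]]$coefficients
    terms <- object$fits[[out]]$terms
    v <- rep(co[["(Intercept)"]], n)
    if (length(terms) > 0L)
      v <- v + as.matrix(newdata[, terms, drop = FALSE]) %*% co[terms]
    M[, out] <- v
  }
  if (n == 1L) {
    vals <- M[1L, ]
    prm <- .predicted_parameters(vals, object$output_range)
    attr(prm, "values") <- vals
    prm
  } else M
}

#' @rdname predict.capsule_surrogate
#' @param model a `capsule_surrogate`.
#' @param laxity a `laxity_profile` data frame (or named laxity vector).
#' @param scores PC scores, named `pc1..pc4` or positional.
#' @export
predict_parameters <- function(model, laxity, scores) {
  if (inherits(laxity, "data.frame") && "rotation_deg" %in% names(laxity)) {
    laxity <- stats::setNames(laxity$rotation_deg,
                              paste0(laxity$direction, "_",
                                     laxity$flexion_deg, "_",
                                     laxity$torque_Nm, "Nm"))
  }
  scores <- stats::setNames(as.numeric(scores),
                            paste0("pc", seq_along(scores)))
  predict(model, c(laxity, scores))
}

# Clip raw regression output into the domain where the surrogate is
# valid: the observed training range of each output (a linear surrogate
# has no support outside the sampled population, and extrapolated
# parameters can be unsimulatable). Without a range, fall back to the
# simulator's physical domain.
.predicted_parameters <- function(vals, output_range = NULL) {
  if (!is.null(output_range)) {
    nm <- names(vals)
    vals <- pmin(pmax(vals, output_range[1L, nm]), output_range[2L, nm])
  }
  st <- pmax(vals[paste0("sector", 1:6, "_stiffness")], 1e-3)
  ps <- pmin(pmax(vals[paste0("sector", 1:6, "_prestrain")], 1e-3), 1.5)
  capsule_parameters(st, ps)
}
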