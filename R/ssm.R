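# Statistical shape model of the paired capsule attachment loops:
# mean-centered PCA of the concatenated acetabular + femoral node
# coordinates, with scores expressed in per-mode standard-deviation units.

.flatten_pair <- function(pair) {
  c(t(pair$acetabular$nodes), t(pair$femoral$nodes))
}

.unflatten_pair <- function(x, n_ace, n_fem) {
  ace <- matrix(x[seq_len(3L * n_ace)], ncol = 3L, byrow = TRUE)
  fem <- matrix(x[3L * n_ace + seq_len(3L * n_fem)], ncol = 3L, byrow = TRUE)
  list(acetabular = attachment_nodes(ace, "acetabular"),
       femoral = attachment_nodes(fem, "femoral"))
}

#' Fit a statistical shape model of the attachment sites
#'
#' Performs a mean-centered principal component analysis on the flattened
#' 3D node coordinates of a population of corresponded attachment-loop
#' pairs. Mode standard deviations are the sample standard deviations of
#' the training scores, so training scores re-expressed through the model
#' have unit standard deviation per mode (z-scores); Fig-style "+/-2 SD"
#' shapes correspond to scores of +/-2.
#'
#' @param population list of pairs, each a list with `acetabular` and
#'   `femoral` [attachment_nodes()] of identical node counts and
#'   correspondence across subjects.
#' @param n_modes number of modes to retain (default 4).
#' @return Object of class `shape_model` with elements `mean_vector`,
#'   `pc_vectors` (retained modes as rows, orthonormal), `mode_sd`,
#'   `variance_fraction` (over all modes), `n_modes_retained`, `scores`
#'   (training scores in SD units) and the node counts.
#' @export
fit_shape_model <- function(population, n_modes = 4L) {
  n_modes <- as.integer(n_modes)
  n_subj <- length(population)
  if (n_subj < n_modes + 1L)
    stop("need at least n_modes + 1 subjects (", n_modes + 1L,
         "), got ", n_subj)
  n_ace <- nrow(population[[1L]]$acetabular$nodes)
  n_fem <- nrow(population[[1L]]$femoral$nodes)
  X <- t(vapply(population, .flatten_pair, numeric(3L * (n_ace + n_fem))))
  if (!all(vapply(population, function(p)
    nrow(p$acetabular$nodes) == n_ace && nrow(p$femoral$nodes) == n_fem,
    logical(1L))))
    stop("all subjects must share node counts and correspondence")

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L)
  sdev <- sv$d / sqrt(n_subj - 1L)
  total <- sum(sdev^2)
  varfrac <- if (total > 1e-20) sdev^2 / total else rep(NA_real_, length(sdev))
  keep <- seq_len(min(n_modes, length(sdev)))
  V <- t(sv$v[, keep, drop = FALSE])      # modes as rows
  sd_keep <- sdev[keep]
  scores <- Xc %*% t(V)
  scores <- sweep(scores, 2L, ifelse(sd_keep > 1e-12, sd_keep, 1), `/`)
  sd_keep[sd_keep <= 1e-12] <- 0
  colnames(scores) <- paste0("pc", keep)
  structure(list(mean_vector = mu, pc_vectors = V, mode_sd = sd_keep,
                 variance_fraction = varfrac,
                 n_modes_retained = length(keep), scores = scores,
                 n_ace = n_ace, n_fem = n_fem, n_subjects = n_subj),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "Attachment-site shape model: %d subjects, %d + %d nodes, %d modes retained\n",
    x$n_subjects, x$n_ace, x$n_fem, x$n_modes_retained))
  vf <- x$variance_fraction[seq_len(x$n_modes_retained)]
  if (all(is.finite(vf)))
    cat("  variance fractions:",
        paste(sprintf("%.1f%%", 100 * vf), collapse = ", "),
        sprintf("(cumulative %.1f%%)\n", 100 * sum(vf)))
  invisible(x)
}

#' Reconstruct attachment geometry from shape-model scores
#'
#' Adds the score-weighted mode perturbations to the mean attachment
#' coordinates: `x = mean + sum_i score_i * mode_sd_i * pc_vector_i`
#' (scores in SD units), and reshapes the result into the paired node
#' loops.
#'
#' @param model a [fit_shape_model()] result.
#' @param scores numeric vector of length at most `n_modes_retained`.
#' @return list with `acetabular` and `femoral` [attachment_nodes()].
#' @export
reconstruct_attachments <- function(model, scores) {
  scores <- as.numeric(scores)
  if (length(scores) > model$n_modes_retained)
    stop("score length (", length(scores), ") exceeds retained modes (",
         model$n_modes_retained, ")")
  if (!all(is.finite(scores))) stop("scores must be finite")
  x <- model$mean_vector
  if (length(scores) > 0L) {
    w <- scores * model$mode_sd[seq_along(scores)]
    x <- x + drop(w %*% model$pc_vectors[seq_along(scores), , drop = FALSE])
  }
  .unflatten_pair(x, model$n_ace, model$n_fem)
}

#' @rdname reconstruct_attachments
#' @param object a `shape_model`.
#' @param ... unused.
#' @export
predict.shape_model <- function(object, scores = numeric(0), ...) {
  reconstruct_attachments(object, scores)
}

#' Express an attachment pair as shape-model scores
#'
#' Projects a pair of attachment loops onto the retained modes, returning
#' standardized (SD-unit) scores.
#'
#' @param model a [fit_shape_model()] result.
#' @param pair list with `acetabular` and `femoral` [attachment_nodes()].
#' @return numeric vector of length `n_modes_retained`.
#' @export
project_attachments <- function(model, pair) {
  x <- .flatten_pair(pair) - model$mean_vector
  raw <- drop(model$pc_vectors %*% x)
  sd <- ifelse(model$mode_sd > 0, model$mode_sd, 1)
  stats::setNames(raw / sd, paste0("pc", seq_len(model$n_modes_retained)))
}
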