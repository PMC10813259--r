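# Attachment-site geometry: anatomic frames, 3D ellipse fitting and
# equal-arc-length resampling of attachment ellipses into corresponded
# node loops.

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) stop("cannot normalize a zero vector")
  v / nv
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Anatomic coordinate frame
#'
#' A right-handed orthonormal triad locating the anatomic directions of a
#' hip: anterior-posterior (A-P), superior-inferior (S-I) and
#' medial-lateral (M-L). All geometry in the package is expressed in a
#' frame of this kind with its origin at the hip rotation center (the
#' femoral head center). The default frame has +x anterior, +y superior
#' and +z lateral (a right hip).
#'
#' @param origin 3-vector, frame origin in mm.
#' @param axes 3x3 matrix whose columns are the A-P, S-I and M-L unit
#'   directions. Must be orthonormal and right-handed to 1e-9.
#' @return An object of class `anatomic_frame` with elements `origin` and
#'   `axes` (columns named `AP`, `SI`, `ML`).
#' @export
anatomic_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal to 1e-9")
  if (abs(det(axes) - 1) > 1e-9)
    stop("frame axes must be right-handed (det = +1)")
  colnames(axes) <- c("AP", "SI", "ML")
  structure(list(origin = origin, axes = axes), class = "anatomic_frame")
}

#' Ellipse in 3D space
#'
#' Container for a planar ellipse used to represent a capsule attachment
#' site (acetabular rim or femoral intertrochanteric crest).
#'
#' @param center 3-vector, ellipse center (mm).
#' @param plane_normal 3-vector, normal of the ellipse plane (normalized
#'   internally).
#' @param major_axis_dir 3-vector, direction of the semi-major axis; must
#'   be perpendicular to `plane_normal`.
#' @param semi_major,semi_minor semi-axis lengths in mm,
#'   `semi_major >= semi_minor > 0`.
#' @return An object of class `ellipse3d`.
#' @export
ellipse3d <- function(center, plane_normal, major_axis_dir,
                      semi_major, semi_minor) {
  center <- as.numeric(center)
  plane_normal <- .unit(as.numeric(plane_normal))
  major_axis_dir <- .unit(as.numeric(major_axis_dir))
  stopifnot(length(center) == 3L)
  if (!(semi_major >= semi_minor && semi_minor > 0))
    stop("ellipse axes must satisfy semi_major >= semi_minor > 0")
  if (abs(sum(plane_normal * major_axis_dir)) > 1e-9)
    stop("major_axis_dir must lie in the ellipse plane (dot < 1e-9)")
  structure(list(center = center, plane_normal = plane_normal,
                 major_axis_dir = major_axis_dir,
                 semi_major = semi_major, semi_minor = semi_minor),
            class = "ellipse3d")
}

#' @export
print.ellipse3d <- function(x, ...) {
  cat(sprintf("3D ellipse: a = %.3f mm, b = %.3f mm\n",
              x$semi_major, x$semi_minor))
  cat(sprintf("  center (%.2f, %.2f, %.2f), normal (%.3f, %.3f, %.3f)\n",
              x$center[1], x$center[2], x$center[3],
              x$plane_normal[1], x$plane_normal[2], x$plane_normal[3]))
  invisible(x)
}

# in-plane basis (u along the major axis, v completing a right-handed set
# with the plane normal)
.ellipse_basis <- function(e) {
  u <- e$major_axis_dir
  v <- .unit(.cross3(e$plane_normal, u))
  list(u = u, v = v)
}

# evaluate the ellipse at parameter angles theta (vectorized)
.ellipse_points <- function(e, theta) {
  b <- .ellipse_basis(e)
  outer(rep(1, length(theta)), e$center) +
    outer(e$semi_major * cos(theta), b$u) +
    outer(e$semi_minor * sin(theta), b$v)
}

#' Fit an ellipse to 3D points
#'
#' Fits the best plane through the points by least squares (the direction
#' of smallest variance is taken as the plane normal), projects the points
#' into that plane and performs a direct least-squares conic fit
#' constrained to an ellipse (Halir--Flusser stabilization of the
#' Fitzgibbon method).
#'
#' @param points numeric matrix with at least 6 rows and 3 columns (mm).
#' @return An [ellipse3d()] object.
#' @export
fit_ellipse_3d <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 6L)
    stop("invalid input: at least 6 points are required to fit an ellipse")
  if (!all(is.finite(points))) stop("invalid input: non-finite coordinates")
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  sv <- svd(X)
  # collinear or coincident point sets have no unique fitting plane
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("invalid input: points are collinear or coincident (rank-deficient)")
  e1 <- sv$v[, 1L]; e2 <- sv$v[, 2L]; nrm <- sv$v[, 3L]
  u <- X %*% e1
  v <- X %*% e2

  # Halir & Flusser direct ellipse-specific least squares on (u, v)
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, rep(1, length(u)))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("invalid input: rank-deficient configuration for conic fitting"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ei <- eigen(M)
  evec <- Re(ei$vectors)
  cond <- 4 * evec[1L, ] * evec[3L, ] - evec[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    stop("invalid input: no ellipse solution (degenerate configuration)")
  a1 <- evec[, ok[1L]]
  coefs <- c(a1, Tm %*% a1)        # A u^2 + B uv + C v^2 + D u + E v + F = 0
  A <- coefs[1L]; B <- coefs[2L]; C <- coefs[3L]
  D <- coefs[4L]; E <- coefs[5L]; Fc <- coefs[6L]

  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # recenter: xi' Q xi = -f(center) with Q the quadratic-form matrix
  f0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -f0 / eq$values
  if (!all(is.finite(ax2)) || !all(ax2 > 0))
    stop("invalid input: fitted conic is not an ellipse")
  i_maj <- which.max(ax2)
  a2 <- ax2[i_maj]; b2 <- ax2[-i_maj][1L]
  maj <- eq$vectors[1L, i_maj] * e1 + eq$vectors[2L, i_maj] * e2
  ellipse3d(center = ctr + cx * e1 + cy * e2,
            plane_normal = nrm, major_axis_dir = .unit(maj),
            semi_major = sqrt(a2), semi_minor = sqrt(b2))
}

#' Attachment node loop
#'
#' An ordered closed loop of corresponded 3D nodes along an attachment
#' site, with node 1 at the most superior point of the loop.
#'
#' @param nodes n x 3 numeric matrix of coordinates (mm).
#' @param side `"acetabular"` or `"femoral"`.
#' @return Object of class `attachment_nodes`.
#' @export
attachment_nodes <- function(nodes, side = c("acetabular", "femoral")) {
  side <- match.arg(side)
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3L, nrow(nodes) >= 3L, all(is.finite(nodes)))
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  structure(list(nodes = nodes, side = side), class = "attachment_nodes")
}

#' @export
print.attachment_nodes <- function(x, ...) {
  cat(sprintf("%s attachment loop: %d nodes\n", x$side, nrow(x$nodes)))
  invisible(x)
}

#' Resample an ellipse into an equally spaced node loop
#'
#' Places `n` nodes at equal arc-length spacing along the ellipse using a
#' dense numeric arc-length parameterization. Node 1 sits exactly at the
#' loop point with the maximal superior (S-I) coordinate; traversal is
#' counter-clockwise when viewed from the lateral (+M-L) side so that
#' corresponded indices on the two attachment loops pair anatomically.
#'
#' @param ellipse an [ellipse3d()].
#' @param n number of nodes, at least 8 (default 360).
#' @param frame an [anatomic_frame()] supplying the S-I and M-L directions.
#' @param side passed to [attachment_nodes()].
#' @return An [attachment_nodes()] loop of `n` nodes.
#' @export
resample_ellipse <- function(ellipse, n = 360L, frame = anatomic_frame(),
                             side = c("acetabular", "femoral")) {
  side <- match.arg(side)
  n <- as.integer(n)
  if (n < 8L) stop("n must be at least 8")
  b <- .ellipse_basis(ellipse)
  si <- frame$axes[, "SI"]; ml <- frame$axes[, "ML"]; ap <- frame$axes[, "AP"]

  # most superior point of the ellipse, in closed form:
  # maximize (a cos t u + b sin t v) . SI
  cu <- ellipse$semi_major * sum(b$u * si)
  cv <- ellipse$semi_minor * sum(b$v * si)
  t0 <- if (abs(cu) < 1e-15 && abs(cv) < 1e-15) 0 else atan2(cv, cu)

  # traversal orientation: increasing parameter sweeps about u x v = normal;
  # require that to agree with +ML (fallbacks for planes containing ML)
  ori <- sum(ellipse$plane_normal * ml)
  if (abs(ori) < 1e-12) ori <- sum(ellipse$plane_normal * ap)
  if (abs(ori) < 1e-12) ori <- sum(ellipse$plane_normal * si)
  sgn <- if (ori >= 0) 1 else -1

  # dense arc-length table starting at the superior point
  m <- max(20000L, 60L * n)
  tg <- t0 + sgn * seq(0, 2 * pi, length.out = m + 1L)
  pts <- .ellipse_points(ellipse, tg)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- s[m + 1L] * (seq_len(n) - 1L) / n
  tq <- stats::approx(s, tg, xout = target, ties = "ordered")$y
  tq[1L] <- t0
  attachment_nodes(.ellipse_points(ellipse, tq), side = side)
}

#' Intertrochanteric plane of the femoral capsule insertion
#'
#' Approximates the intertrochanteric crest plane: the plane normal is the
#' cross product of the greater-to-lesser trochanter vector with the
#' anterior-posterior axis, and the plane is positioned so that it
#' contains the most prominent point on the posterior aspect of the femur
#' (for a fixed normal, translating the plane along the femoral neck axis
#' until it first touches the posterior-most surface point places it
#' exactly through that point).
#'
#' @param greater_troch,lesser_troch 3-vectors, most prominent trochanter
#'   points (mm).
#' @param frame an [anatomic_frame()].
#' @param femur_surface n x 3 matrix of femoral surface points.
#' @return list with `point` (a point on the plane: the posterior-most
#'   surface vertex) and `normal` (unit normal).
#' @export
intertrochanteric_plane <- function(greater_troch, lesser_troch, frame,
                                    femur_surface) {
  gt <- as.numeric(greater_troch); lt <- as.numeric(lesser_troch)
  femur_surface <- as.matrix(femur_surface)
  if (nrow(femur_surface) < 1L) stop("femur surface must be non-empty")
  v <- gt - lt
  if (sqrt(sum(v^2)) < 1e-12)
    stop("degenerate geometry: trochanter points coincide")
  ap <- frame$axes[, "AP"]
  nrm <- .cross3(v, ap)
  if (sqrt(sum(nrm^2)) < 1e-9 * sqrt(sum(v^2)))
    stop("degenerate geometry: trochanter axis is parallel to the A-P axis")
  nrm <- .unit(nrm)
  post <- femur_surface[which.min(femur_surface %*% ap), ]
  list(point = as.numeric(post), normal = nrm)
}
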