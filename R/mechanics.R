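# Reduced-order quasi-static capsule mechanics: tension-only nonlinear
# path-springs wrapping the femoral head sphere, torque-rotation
# equilibrium, and the 40-metric laxity profile.

#' Six-sector capsule mechanical parameters
#'
#' The twelve mechanical parameters of the sleeve model: a total stiffness
#' (N/mm) and a pre-strain (dimensionless) for each of the six
#' circumferential sectors, numbered from the most superior attachment.
#' Sector stiffness is the total for the sector and is divided across the
#' parallel spring lines of that sector; pre-strain controls the slack
#' length of each line (slack length = as-meshed length / pre-strain), so
#' larger pre-strain means a tauter capsule.
#'
#' @param stiffness numeric length 6, sector stiffnesses in N/mm (> 0).
#' @param pre_strain numeric length 6, sector pre-strains in (0, 1.5].
#' @return Object of class `capsule_parameters`.
#' @export
capsule_parameters <- function(stiffness, pre_strain) {
  stiffness <- as.numeric(stiffness); pre_strain <- as.numeric(pre_strain)
  stopifnot(length(stiffness) == 6L, length(pre_strain) == 6L)
  if (!all(is.finite(stiffness)) || any(stiffness <= 0))
    stop("sector stiffness must be positive and finite")
  if (!all(is.finite(pre_strain)) || any(pre_strain <= 0) ||
      any(pre_strain > 1.5))
    stop("sector pre-strain must lie in (0, 1.5]")
  structure(list(stiffness = stiffness, pre_strain = pre_strain),
            class = "capsule_parameters")
}

#' @export
print.capsule_parameters <- function(x, ...) {
  cat("Capsule mechanical parameters (sectors 1-6):\n")
  cat("  stiffness (N/mm):", sprintf("%.1f", x$stiffness), "\n")
  cat("  pre-strain      :", sprintf("%.3f", x$pre_strain), "\n")
  invisible(x)
}

#' Nonlinear tension-only spring law
#'
#' Piecewise toe-linear ligament force law: zero in compression, a
#' quadratic toe region `f = k d^2 / (4 dt)` for elongations up to twice
#' the toe elongation `dt`, then linear `f = k (d - dt)`. The two branches
#' meet with continuous value and slope at `d = 2 dt`.
#'
#' @param elongation elongation d in mm (vectorized).
#' @param line_stiffness linear-region stiffness k in N/mm (> 0).
#' @param toe_elongation toe elongation dt in mm (> 0).
#' @return force in N, same length as `elongation`.
#' @export
spring_force <- function(elongation, line_stiffness, toe_elongation) {
  if (any(line_stiffness <= 0)) stop("line_stiffness must be positive")
  if (any(toe_elongation <= 0)) stop("toe_elongation must be positive")
  d <- elongation; k <- line_stiffness; dt <- toe_elongation
  ifelse(d <= 0, 0,
         ifelse(d <= 2 * dt, k * d^2 / (4 * dt), k * (d - dt)))
}

# strain energy of the toe-linear law (analytic integral of spring_force)
.spring_energy <- function(d, k, dt) {
  e_toe <- k * pmin(pmax(d, 0), 2 * dt)^3 / (12 * dt)
  lin <- d > 2 * dt
  e <- e_toe
  if (any(lin)) {
    dl <- d[lin]
    kl <- if (length(k) > 1L) k[lin] else k
    dtl <- if (length(dt) > 1L) dt[lin] else dt
    e[lin] <- kl * (2 / 3) * dtl^2 + kl * ((dl - dtl)^2 - dtl^2) / 2
  }
  e
}

# Vectorized single-sphere wrapping geometry. P0, P1: n x 3 endpoint
# matrices; center length-3; r >= 0. Returns path lengths, the unit force
# direction at the P1 end (pointing along the departing path), and a
# wrapped flag. Shortest path is straight if the segment clears the
# sphere, else tangent-arc-tangent in the plane through both endpoints
# and the center.
.wrap_geom <- function(P0, P1, center, r) {
  A <- sweep(P0, 2L, center)
  B <- sweep(P1, 2L, center)
  d0 <- sqrt(rowSums(A^2))
  d1 <- sqrt(rowSums(B^2))
  if (r > 0 && (any(d0 <= r) || any(d1 <= r)))
    stop("invalid geometry: spring endpoint inside the head sphere")
  W <- A - B                       # from p1 toward p0
  chord <- sqrt(rowSums(W^2))
  chord <- pmax(chord, 1e-300)
  U <- W / chord                   # straight-line force direction at p1
  len <- chord
  wrapped <- rep(FALSE, nrow(P0))
  if (r > 0) {
    # closest approach of the segment to the sphere center
    tpar <- pmin(pmax(-rowSums(B * W) / chord^2, 0), 1)
    # segment param from B: point = B + t*(A-B) = B + t*W
    Cl <- B + tpar * W
    mdist <- sqrt(rowSums(Cl^2))
    wrapped <- mdist < r
    if (any(wrapped)) {
      Aw <- A[wrapped, , drop = FALSE]; Bw <- B[wrapped, , drop = FALSE]
      d0w <- d0[wrapped]; d1w <- d1[wrapped]
      ca <- rowSums(Aw * Bw) / (d0w * d1w)
      alpha <- acos(pmin(pmax(ca, -1), 1))
      b0 <- acos(pmin(r / d0w, 1))
      b1 <- acos(pmin(r / d1w, 1))
      arc <- pmax(alpha - b0 - b1, 0)
      len[wrapped] <- sqrt(d0w^2 - r^2) + sqrt(d1w^2 - r^2) + r * arc
      # departure tangent at p1: toward the tangent point nearest p1
      E1 <- Bw / d1w
      Aperp <- Aw - rowSums(Aw * E1) * E1
      npa <- sqrt(rowSums(Aperp^2))
      npa <- pmax(npa, 1e-300)
      E2 <- Aperp / npa
      Tp <- r * (cos(b1) * E1 + sin(b1) * E2)   # tangent point (centered)
      Dir <- Tp - Bw
      nd <- pmax(sqrt(rowSums(Dir^2)), 1e-300)
      U[wrapped, ] <- Dir / nd
    }
  }
  list(length = len, force_dir = U, wrapped = wrapped)
}

#' Shortest wrapped path length around the femoral head sphere
#'
#' Length of the shortest path between two points that does not enter the
#' head sphere: the Euclidean distance when the straight segment clears
#' the sphere, otherwise the tangent--arc--tangent geodesic over the
#' sphere surface.
#'
#' @param p0,p1 3-vectors (mm), both strictly outside the sphere.
#' @param sphere list with `center` (3-vector, mm) and `radius` (mm,
#'   `>= 0`; radius 0 disables wrapping).
#' @return path length in mm.
#' @export
wrapped_length <- function(p0, p1, sphere) {
  g <- .wrap_geom(matrix(as.numeric(p0), 1L), matrix(as.numeric(p1), 1L),
                  sphere$center, sphere$radius)
  g$length[1L]
}

#' Hip pose
#'
#' Femur orientation as a three-cylindric open chain: flexion about the
#' M-L axis, then ab/adduction about the rotated A-P axis, then
#' internal/external rotation about the rotated S-I (femoral shaft) axis,
#' applied intrinsically in that order. Angles in degrees; abduction and
#' internal rotation positive.
#'
#' @param flexion,abduction,internal_rotation angles in degrees.
#' @return Object of class `hip_pose`.
#' @export
hip_pose <- function(flexion = 0, abduction = 0, internal_rotation = 0) {
  stopifnot(is.finite(flexion), is.finite(abduction),
            is.finite(internal_rotation))
  structure(list(flexion = flexion, abduction = abduction,
                 internal_rotation = internal_rotation), class = "hip_pose")
}

.rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}
.rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L)
}
.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

# rotation matrix of a pose (degrees), intrinsic flexion -> ab/ad -> I-E
.pose_rotation <- function(flexion, abduction, internal_rotation) {
  d2r <- pi / 180
  .rot_z(flexion * d2r) %*% .rot_x(abduction * d2r) %*%
    .rot_y(internal_rotation * d2r)
}

# unit axis along which an isolated torque in `direction` acts, at the
# given flexion (other DOFs neutral); sign so that +rotation = loaded
# direction
.test_axis <- function(direction, flexion) {
  d2r <- pi / 180
  Rf <- .rot_z(flexion * d2r)
  switch(direction,
         internal = Rf %*% c(0, 1, 0),
         external = -(Rf %*% c(0, 1, 0)),
         abduction = Rf %*% c(1, 0, 0),
         adduction = -(Rf %*% c(1, 0, 0)),
         stop("unknown direction: ", direction))[, 1L]
}

# pose with the loaded DOF set to theta (deg) in `direction`
.directed_pose <- function(direction, flexion, theta) {
  switch(direction,
         internal  = hip_pose(flexion, 0, theta),
         external  = hip_pose(flexion, 0, -theta),
         abduction = hip_pose(flexion, theta, 0),
         adduction = hip_pose(flexion, -theta, 0),
         stop("unknown direction: ", direction))
}

# precompute per-line quantities reused across torque evaluations
.line_props <- function(mesh, params) {
  sec <- mesh$line_sector
  per <- mesh$n_lines / 6L
  L0 <- mesh$reference_length / params$pre_strain[sec]
  list(L0 = L0,
       k_line = params$stiffness[sec] / per,
       toe = 0.03 * L0,
       I0c = sweep(mesh$insertion_nodes, 2L, mesh$head_sphere$center))
}

# torque vector (N.m) exerted by the capsule on the femur about the hip
# center, with the femur rotated by Rm
.capsule_torque_vec <- function(mesh, lp, Rm) {
  ctr <- mesh$head_sphere$center
  P1 <- lp$I0c %*% t(Rm)
  P1 <- sweep(P1, 2L, ctr, `+`)
  g <- .wrap_geom(mesh$origin_nodes, P1, ctr, mesh$head_sphere$radius)
  f <- spring_force(g$length - lp$L0, lp$k_line, lp$toe)
  Fv <- g$force_dir * f
  Rr <- sweep(P1, 2L, ctr)
  tq <- c(sum(Rr[, 2L] * Fv[, 3L] - Rr[, 3L] * Fv[, 2L]),
          sum(Rr[, 3L] * Fv[, 1L] - Rr[, 1L] * Fv[, 3L]),
          sum(Rr[, 1L] * Fv[, 2L] - Rr[, 2L] * Fv[, 1L]))
  tq / 1000                       # N.mm -> N.m
}

#' Capsule restoring torque about a test axis
#'
#' Rigidly rotates the femoral insertion nodes about the hip center by the
#' pose, recomputes each line's wrapped length and tension-only spring
#' force (slack length = as-meshed length / sector pre-strain; line
#' stiffness = sector stiffness / lines per sector), and sums the moments
#' of the insertion forces about the hip center. Wrap contact forces on
#' the head are radial through the hip center and contribute no moment.
#'
#' @param mesh a [build_capsule_mesh()] result.
#' @param params a [capsule_parameters()].
#' @param pose a [hip_pose()].
#' @param axis unit 3-vector, axis onto which the torque is projected.
#' @return torque component in N m.
#' @export
restoring_torque <- function(mesh, params, pose, axis) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be a unit vector")
  lp <- .line_props(mesh, params)
  Rm <- .pose_rotation(pose$flexion, pose$abduction, pose$internal_rotation)
  sum(.capsule_torque_vec(mesh, lp, Rm) * axis)
}

#' Total capsule strain energy at a pose
#'
#' Sum of the per-line spring strain energies (analytic integral of the
#' toe-linear force law over elongation), in mJ. The restoring torque
#' equals minus the derivative of this energy with respect to the loaded
#' rotation angle (in radians), which the test suite uses as an energy
#' consistency check.
#'
#' @inheritParams restoring_torque
#' @return strain energy in N mm (mJ).
#' @export
capsule_energy <- function(mesh, params, pose) {
  lp <- .line_props(mesh, params)
  Rm <- .pose_rotation(pose$flexion, pose$abduction, pose$internal_rotation)
  ctr <- mesh$head_sphere$center
  P1 <- sweep(lp$I0c %*% t(Rm), 2L, ctr, `+`)
  g <- .wrap_geom(mesh$origin_nodes, P1, ctr, mesh$head_sphere$radius)
  sum(.spring_energy(g$length - lp$L0, lp$k_line, lp$toe))
}

#' Solve the torque-rotation equilibrium for one laxity value
#'
#' Finds the rotation angle at which the capsule's restoring torque
#' balances the applied torque, by geometric bracket growth followed by
#' bisection on the monotone torque-rotation curve. The returned angle is
#' positive in the loaded direction (a taut capsule can yield a small
#' negative equilibrium angle).
#'
#' @param mesh a [build_capsule_mesh()] result.
#' @param params a [capsule_parameters()].
#' @param flexion flexion angle in degrees (other unloaded DOFs held
#'   neutral).
#' @param direction one of `"internal"`, `"external"`, `"abduction"`,
#'   `"adduction"`.
#' @param torque_target applied torque in N m (> 0).
#' @param tol bisection interval tolerance in degrees (default 1e-3).
#' @param theta_max search limit in degrees; targets unreachable within
#'   `c(-theta_max, theta_max)` raise a non-convergence error.
#' @return equilibrium rotation in degrees.
#' @export
solve_laxity <- function(mesh, params, flexion, direction,
                         torque_target, tol = 1e-3, theta_max = 175) {
  if (torque_target <= 0) stop("torque_target must be positive")
  direction <- match.arg(direction,
                         c("internal", "external", "abduction", "adduction"))
  lp <- .line_props(mesh, params)
  axis <- .test_axis(direction, flexion)
  g <- function(theta) {
    p <- .directed_pose(direction, flexion, theta)
    Rm <- .pose_rotation(p$flexion, p$abduction, p$internal_rotation)
    -sum(.capsule_torque_vec(mesh, lp, Rm) * axis)   # resistance, N.m
  }
  .bisect_laxity(g, torque_target, tol, theta_max, direction, flexion)
}

# bracket + bisection for the first crossing of the resistance curve g
# (N.m vs deg). The bracket is marched outward in fixed 5-degree steps so
# that a crossing below a local torque peak cannot be stepped over.
.bisect_laxity <- function(g, target, tol, theta_max, direction, flexion,
                           step = 5, start = 0) {
  fail <- function() stop(sprintf(
    "non-convergence: %g N m torque unreachable within +/-%g deg (%s, flexion %g)",
    target, theta_max, direction, flexion))
  if (g(start) < target) {
    lo <- start; hi <- start + step
    while (g(hi) < target) {
      lo <- hi; hi <- hi + step
      if (hi > theta_max) fail()
    }
  } else {
    hi <- start; lo <- start - step
    while (g(lo) > target) {
      hi <- lo; lo <- lo - step
      if (lo < -theta_max) fail()
    }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Evaluate the full 40-metric laxity profile
#'
#' Applies isolated torques in internal, external, abduction and adduction
#' rotation at 0, 30, 45, 60 and 90 degrees of flexion (20 equilibrium
#' problems) and records the rotation reached at 1 N m (the slack-to-stiff
#' transition of the capsule) and at 5 N m, yielding 40 laxity metrics.
#'
#' @param mesh a [build_capsule_mesh()] result.
#' @param params a [capsule_parameters()].
#' @param flexions flexion angles in degrees.
#' @param torques torque levels in N m (reported per solve direction).
#' @param tol bisection tolerance in degrees.
#' @return A `laxity_profile`: data frame with columns `direction`,
#'   `flexion_deg`, `torque_Nm`, `rotation_deg` (40 rows with defaults).
#' @export
evaluate_laxity_profile <- function(mesh, params,
                                    flexions = c(0, 30, 45, 60, 90),
                                    torques = c(1, 5), tol = 1e-3) {
  dirs <- c("internal", "external", "abduction", "adduction")
  torques <- sort(torques)
  out <- vector("list", length(dirs) * length(flexions))
  k <- 0L
  lp <- .line_props(mesh, params)
  for (dir in dirs) {
    for (fx in flexions) {
      axis <- .test_axis(dir, fx)
      g <- function(theta) {
        p <- .directed_pose(dir, fx, theta)
        Rm <- .pose_rotation(p$flexion, p$abduction, p$internal_rotation)
        -sum(.capsule_torque_vec(mesh, lp, Rm) * axis)
      }
      rot <- numeric(length(torques))
      start <- 0
      for (ti in seq_along(torques)) {
        rot[ti] <- tryCatch(
          .bisect_laxity(g, torques[ti], tol, 175, dir, fx, start = start),
          error = function(e) stop(sprintf(
            "laxity solve failed (%s, flexion %g, %g N m): %s",
            dir, fx, torques[ti], conditionMessage(e)), call. = FALSE))
        start <- rot[ti]      # targets ascend, so roots do too
      }
      k <- k + 1L
      out[[k]] <- data.frame(direction = dir, flexion_deg = fx,
                             torque_Nm = torques, rotation_deg = rot)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("laxity_profile", "data.frame")
  res
}

#' @export
print.laxity_profile <- function(x, ...) {
  cat(sprintf("Laxity profile: %d metrics (%d directions x %d flexions x %d torques)\n",
              nrow(x), length(unique(x$direction)),
              length(unique(x$flexion_deg)), length(unique(x$torque_Nm))))
  print.data.frame(x, ...)
  invisible(x)
}
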