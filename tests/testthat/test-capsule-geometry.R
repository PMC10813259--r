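# Attachment geometry: ellipse fitting, resampling, the femoral
# insertion plane and the capsule mesh builder.

random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

test_that("ellipse fit recovers exact and noisy generating parameters", {
  set.seed(101)
  # exact circle: both semi-axes equal the radius
  th <- runif(100, 0, 2 * pi)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  f <- fit_ellipse_3d(circ)
  expect_equal(f$semi_major, 10, tolerance = 1e-6)
  expect_equal(f$semi_minor, 10, tolerance = 1e-6)

  # noisy ellipse in a tilted plane: recovery within 0.1 mm
  e <- ellipse3d(center = c(5, -3, 12), plane_normal = c(1, 2, 2),
                 major_axis_dir = c(2, -1, 0), semi_major = 25,
                 semi_minor = 18)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  pts <- capsulereg:::.ellipse_points(e, th) +
    matrix(rnorm(3 * 360, sd = 0.1), ncol = 3)
  f <- fit_ellipse_3d(pts)
  expect_lt(abs(f$semi_major - 25), 0.1)
  expect_lt(abs(f$semi_minor - 18), 0.1)
  expect_lt(sqrt(sum((f$center - e$center)^2)), 0.1)
})

test_that("ellipse fit rejects invalid inputs", {
  expect_error(fit_ellipse_3d(matrix(rnorm(15), 5, 3)), "at least 6")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_ellipse_3d(line), "collinear")
})

test_that("ellipse fit commutes with rigid transformation", {
  set.seed(102)
  e <- ellipse3d(c(0, 0, 0), c(0, 1, 1), c(1, 0, 0), 20, 12)
  pts <- capsulereg:::.ellipse_points(e, runif(80, 0, 2 * pi))
  f0 <- fit_ellipse_3d(pts)
  for (i in 1:5) {
    tr <- random_rigid_transform()
    f1 <- fit_ellipse_3d(sweep(pts %*% t(tr$R), 2, tr$t, `+`))
    expect_equal(f1$semi_major, f0$semi_major, tolerance = 1e-6)
    expect_equal(f1$semi_minor, f0$semi_minor, tolerance = 1e-6)
    expect_equal(as.numeric(f1$center),
                 as.numeric(tr$R %*% f0$center + tr$t), tolerance = 1e-6)
  }
})

test_that("resampled loops are equally spaced and start superiorly", {
  fr <- anatomic_frame()
  circ <- ellipse3d(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), 10, 10)
  ns <- resample_ellipse(circ, 360, fr)
  chords <- sqrt(rowSums((ns$nodes - ns$nodes[c(2:360, 1), ])^2))
  expect_lt(diff(range(chords)) / mean(chords), 1e-9)
  # perimeter converges to the analytic circle circumference
  expect_lt(abs(sum(chords) - 2 * pi * 10) / (2 * pi * 10), 1e-4)

  # equal arc-length spacing on an eccentric ellipse, against an
  # independent quadrature oracle
  e <- ellipse3d(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), 2, 1)
  ns8 <- resample_ellipse(e, 8, fr)
  ang <- atan2(ns8$nodes[, 2] / 1, ns8$nodes[, 1] / 2)
  speed <- function(t) sqrt(4 * sin(t)^2 + cos(t)^2)
  perim <- stats::integrate(speed, 0, 2 * pi, rel.tol = 1e-12)$value
  arcs <- vapply(seq_len(8), function(i) {
    t0 <- ang[i]; t1 <- ang[ifelse(i == 8, 1, i + 1)]
    dt <- (t1 - t0) %% (2 * pi)
    stats::integrate(function(u) speed(t0 + u * dt), 0, 1,
                     rel.tol = 1e-12)$value * dt
  }, numeric(1))
  expect_true(all(abs(abs(arcs) - perim / 8) < 1e-6))

  # most superior point leads the loop, for arbitrary ellipses
  set.seed(103)
  for (i in 1:10) {
    nrm <- rnorm(3); u <- capsulereg:::.cross3(nrm, rnorm(3))
    ee <- ellipse3d(rnorm(3, sd = 10), nrm, u, 20 + runif(1, 0, 10),
                    10 + runif(1, 0, 9))
    nn <- resample_ellipse(ee, 36, fr)
    expect_true(all(nn$nodes[1, 2] >= nn$nodes[, 2] - 1e-9))
  }
  expect_error(resample_ellipse(e, 7, fr), "at least 8")
})

test_that("intertrochanteric plane follows the trochanter axis and the posterior surface", {
  fr <- anatomic_frame()
  # GT - LT along S-I and A-P axis anterior: normal must be along M-L
  pl <- intertrochanteric_plane(c(0, 5, 0), c(0, -5, 0), fr,
                                femur_surface = cbind(0, 0, 0))
  expect_equal(abs(sum(pl$normal * c(0, 0, 1))), 1, tolerance = 1e-12)

  # plane contains the unique most-posterior vertex of a synthetic cloud
  set.seed(104)
  cloud <- matrix(rnorm(300, sd = 5), ncol = 3)
  cloud[17, ] <- c(-40, 2, 1)     # far anterior-negative: most posterior
  pl <- intertrochanteric_plane(c(3, 6, 1), c(-2, -7, 2), fr, cloud)
  expect_lt(abs(sum((cloud[17, ] - pl$point) * pl$normal)), 1e-9)

  expect_error(intertrochanteric_plane(c(1, 1, 1), c(1, 1, 1), fr,
                                       cbind(0, 0, 0)), "degenerate")
  expect_error(intertrochanteric_plane(c(1, 0, 0), c(-1, 0, 0), fr,
                                       cbind(0, 0, 0)), "degenerate")
})

test_that("capsule mesh partitions lines into six sectors with wrapped reference lengths", {
  bg <- base_attachment_geometry(360)
  sph <- list(center = c(0, 0, 0), radius = 22)
  mesh <- build_capsule_mesh(bg$acetabular, bg$femoral, sph, 36)
  expect_identical(as.integer(table(mesh$line_sector)), rep(6L, 6))
  expect_equal(sum(table(mesh$line_sector)), mesh$n_lines)
  chord <- sqrt(rowSums((mesh$origin_nodes - mesh$insertion_nodes)^2))
  expect_true(all(mesh$reference_length >= chord - 1e-9))

  # radius 0 disables wrapping: reference lengths are chords
  mesh0 <- build_capsule_mesh(bg$acetabular, bg$femoral,
                              list(center = c(0, 0, 0), radius = 0), 36)
  chord0 <- sqrt(rowSums((mesh0$origin_nodes - mesh0$insertion_nodes)^2))
  expect_equal(mesh0$reference_length, chord0, tolerance = 1e-12)

  # stacked identical circles: all lines equal the axial offset
  th <- seq(0, 2 * pi, length.out = 31)[-31]
  ring <- cbind(30 * cos(th), 30 * sin(th), 0)
  lower <- attachment_nodes(ring, "acetabular")
  upper <- attachment_nodes(sweep(ring, 2, c(0, 0, 25), `+`), "femoral")
  m2 <- build_capsule_mesh(lower, upper,
                           list(center = c(0, 0, 0), radius = 0), 6)
  expect_equal(m2$reference_length, rep(25, 6), tolerance = 1e-12)

  bad <- attachment_nodes(ring[1:20, ], "femoral")
  expect_error(build_capsule_mesh(lower, bad, sph), "mismatched")
  expect_error(build_capsule_mesh(lower, upper, sph, n_lines = 10),
               "divisible by 6")
})
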