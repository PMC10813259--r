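# Parametric six-sector capsule spring mesh between the attachment loops.

#' Build the six-sector capsule spring mesh
#'
#' Connects index-corresponded nodes on the acetabular and femoral
#' attachment loops with longitudinal path-spring lines (subsampled
#' uniformly from the full node loops), wrapping each line around the
#' femoral head sphere where the straight segment would penetrate it.
#' Lines are assigned to six equal contiguous circumferential sectors
#' numbered from the most superior line. Each line's as-meshed
#' (reference) length is its wrapped path length at the neutral pose.
#'
#' @param acetabular,femoral [attachment_nodes()] loops with the same node
#'   count and correspondence.
#' @param head_sphere list with `center` (3-vector, mm; the hip rotation
#'   center) and `radius` (mm; 0 disables wrapping).
#' @param n_lines number of longitudinal lines; must divide the node
#'   count and be divisible by 6 (default 36, i.e. 10 degree spacing).
#' @return Object of class `capsule_mesh` with elements `origin_nodes`,
#'   `insertion_nodes` (n_lines x 3), `line_sector`, `n_lines`,
#'   `reference_length` and `head_sphere`.
#' @export
build_capsule_mesh <- function(acetabular, femoral, head_sphere,
                               n_lines = 36L) {
  stopifnot(inherits(acetabular, "attachment_nodes"),
            inherits(femoral, "attachment_nodes"))
  n_lines <- as.integer(n_lines)
  n_ace <- nrow(acetabular$nodes); n_fem <- nrow(femoral$nodes)
  if (n_ace != n_fem)
    stop("attachment loops have mismatched node counts (",
         n_ace, " vs ", n_fem, ")")
  if (n_lines %% 6L != 0L)
    stop("n_lines must be divisible by 6")
  if (n_ace %% n_lines != 0L)
    stop("n_lines must divide the attachment node count")
  if (is.null(head_sphere$center) || is.null(head_sphere$radius) ||
      head_sphere$radius < 0)
    stop("head_sphere needs a center and a non-negative radius")
  # subsample at the centers of equal circumferential cells (midpoint
  # rule): the sector force sums then converge quadratically in n_lines
  step <- n_ace %/% n_lines
  idx <- seq(1L + step %/% 2L, n_ace, by = step)
  orig <- acetabular$nodes[idx, , drop = FALSE]
  ins <- femoral$nodes[idx, , drop = FALSE]
  g <- .wrap_geom(orig, ins, head_sphere$center, head_sphere$radius)
  structure(list(origin_nodes = orig, insertion_nodes = ins,
                 line_sector = rep(1:6, each = n_lines %/% 6L),
                 n_lines = n_lines, reference_length = g$length,
                 head_sphere = list(center = as.numeric(head_sphere$center),
                                    radius = head_sphere$radius)),
            class = "capsule_mesh")
}

#' @export
print.capsule_mesh <- function(x, ...) {
  cat(sprintf("Capsule mesh: %d lines (%d per sector), head radius %.1f mm\n",
              x$n_lines, x$n_lines %/% 6L, x$head_sphere$radius))
  cat(sprintf("  reference lengths %.1f-%.1f mm\n",
              min(x$reference_length), max(x$reference_length)))
  invisible(x)
}

#' Default mesh configuration
#'
#' Head sphere of radius 22 mm (dual-mobility liner scale) centered at the
#' hip rotation center (the frame origin) and 36 longitudinal lines
#' (10 degree circumferential spacing).
#'
#' @param head_center 3-vector, hip center (mm).
#' @param head_radius head sphere radius (mm).
#' @param n_lines number of longitudinal spring lines.
#' @return list usable as the `mesh_config` argument throughout.
#' @export
default_mesh_config <- function(head_center = c(0, 0, 0), head_radius = 22,
                                n_lines = 36L) {
  list(head_center = as.numeric(head_center), head_radius = head_radius,
       n_lines = as.integer(n_lines))
}

# build a mesh from a reconstructed attachment pair and a mesh_config
.mesh_from_pair <- function(pair, mesh_config) {
  build_capsule_mesh(pair$acetabular, pair$femoral,
                     head_sphere = list(center = mesh_config$head_center,
                                        radius = mesh_config$head_radius),
                     n_lines = mesh_config$n_lines)
}
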