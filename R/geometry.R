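# Pure 3-D geometry: sphere fitting, anatomical frame construction,
# axis-angle rotation, distances.  All coordinates in mm, angles in degrees.

# Condition-number threshold above which a landmark configuration is treated
# as degenerate (coplanar cloud for the sphere fit, collinear landmarks for
# the frame).
DEGENERATE_KAPPA <- 1e8

#' Stop with a classed condition
#' @noRd
abort_class <- function(class, message) {
  stop(errorCondition(message, class = c(class, "uclstrain_error")))
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    abort_class("invalid_point", sprintf("%s must be 3 finite coordinates", what))
  p
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, as_point3))
  } else {
    m <- matrix(as.numeric(points), ncol = 3L, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 3L || any(!is.finite(m)))
    abort_class("invalid_point", "points must be an n x 3 matrix of finite coordinates")
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12)
    abort_class("degenerate_plane", sprintf("cannot normalize near-zero %s", what))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean distance between two points
#'
#' @param a,b numeric length-3 coordinate vectors (mm).
#' @return Distance in mm.
#' @export
#' @examples
#' dist3(c(0, 0, 0), c(3, 4, 0))  # 5
dist3 <- function(a, b) {
  vnorm(as_point3(b, "b") - as_point3(a, "a"))
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud, as used to locate the glenohumeral
#' rotation center from a digitized cloud on the humeral head.  The
#' algebraic method solves the linear least-squares problem obtained by
#' expanding the sphere equation \eqn{|p - c|^2 = r^2}; the geometric
#' method refines that solution by minimizing the sum of squared radial
#' residuals \eqn{\sum_i (|p_i - c| - r)^2} over the center (the optimal
#' radius given a center is the mean distance to it).
#'
#' @param points an n x 3 matrix (or list of length-3 vectors) of
#'   coordinates in mm; at least 4 non-coplanar points.
#' @param method \code{"algebraic"} (default) or \code{"geometric"}.
#' @return An object of class \code{sphere_fit}: list with \code{center}
#'   (length-3), \code{radius} (mm), \code{rms_residual} (mm, RMS of
#'   distance-to-center minus radius), and \code{method}.
#' @export
fit_sphere <- function(points, method = c("algebraic", "geometric")) {
  method <- match.arg(method)
  m <- as_point_matrix(points)
  n <- nrow(m)
  if (n < 4L)
    abort_class("insufficient_points",
                sprintf("sphere fit needs at least 4 points, got %d", n))

  # center and scale so the degeneracy check is invariant to placement/units
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  s <- sqrt(mean(rowSums(mc^2)))
  if (s < 1e-12)
    abort_class("degenerate_configuration", "all points coincide")
  mc <- mc / s

  # |p|^2 = 2 c . p + (r^2 - |c|^2): linear in (c, d)
  A <- cbind(2 * mc, 1)
  y <- rowSums(mc * mc)
  AtA <- crossprod(A)
  sv <- svd(AtA, nu = 0, nv = 0)$d
  kappa <- if (sv[4] <= 0) Inf else sv[1] / sv[4]
  if (!is.finite(kappa) || kappa > DEGENERATE_KAPPA)
    abort_class("degenerate_configuration",
                "points are coplanar or collinear within tolerance; sphere is not identifiable")
  beta <- solve(AtA, crossprod(A, y))
  center <- as.numeric(beta[1:3]) * s + mu
  r2 <- (beta[4] + sum(beta[1:3]^2)) * s^2
  if (r2 <= 0)
    abort_class("degenerate_configuration", "algebraic fit produced non-positive radius")
  radius <- sqrt(r2)

  if (method == "geometric") {
    obj <- function(c3) {
      d <- sqrt(rowSums((m - matrix(c3, n, 3, byrow = TRUE))^2))
      sum((d - mean(d))^2)
    }
    opt <- stats::optim(center, obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    center <- opt$par
    radius <- mean(sqrt(rowSums((m - matrix(center, n, 3, byrow = TRUE))^2)))
  }

  center <- unname(center)
  d <- sqrt(rowSums((m - matrix(center, n, 3, byrow = TRUE))^2))
  structure(
    list(center = center, radius = radius,
         rms_residual = sqrt(mean((d - radius)^2)), method = method),
    class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Sphere fit (%s): center (%.3f, %.3f, %.3f) mm, radius %.3f mm, RMS residual %.4f mm\n",
              x$method, x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

#' Humerus-fixed anatomical coordinate frame
#'
#' Builds the anatomical frame from the glenohumeral rotation center and
#' the two epicondyle tips.  The origin is the midpoint of the epicondyle
#' tips; the Y-axis points from the origin toward the glenohumeral center
#' (proximal); the X-axis is the unit normal of the plane through the
#' three landmarks, signed per side so that a positive rotation about it
#' is valgus; the Z-axis completes a right-handed frame (x cross y = z)
#' and is the flexion-extension axis (positive rotation = flexion).
#'
#' @param ghc glenohumeral rotation center (length-3, mm).
#' @param me,le medial and lateral epicondyle tips (length-3, mm).
#' @param side \code{"left"} or \code{"right"}.  The X-axis sign follows
#'   the medial-to-lateral ordering of the epicondyle arguments, which
#'   mirrors between sides, so a positive rotation about it is valgus on
#'   either side.  A right-handed frame cannot also keep the flexion sign
#'   anatomical on both sides, so for \code{side = "right"} a positive
#'   rotation about the Z-axis is extension; [pose_points()] compensates.
#' @return An object of class \code{coordinate_frame}: list with
#'   \code{origin}, \code{x_axis}, \code{y_axis}, \code{z_axis},
#'   \code{side}.
#' @export
build_frame <- function(ghc, me, le, side = c("left", "right")) {
  side <- match.arg(side)
  ghc <- as_point3(ghc, "ghc"); me <- as_point3(me, "me"); le <- as_point3(le, "le")
  origin <- (me + le) / 2

  u <- le - me
  v <- ghc - me
  nrm <- cross3(u, v)
  if (vnorm(nrm) < 1e-9 * max(vnorm(u) * vnorm(v), 1))
    abort_class("degenerate_plane",
                "epicondyle tips and glenohumeral center are collinear; frame is undefined")
  x_axis <- unitize(nrm, "plane normal")

  y_axis <- unitize(ghc - origin, "long axis")
  z_axis <- unitize(cross3(x_axis, y_axis), "flexion axis")
  # re-orthogonalize x against y to kill residual numeric skew
  x_axis <- unitize(cross3(y_axis, z_axis), "valgus axis")

  structure(list(origin = origin, x_axis = x_axis, y_axis = y_axis,
                 z_axis = z_axis, side = side),
            class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat(sprintf("Anatomical frame (%s side)\n", x$side))
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.6f, %.6f, %.6f)\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Rotate points about an arbitrary axis
#'
#' Rodrigues axis-angle rotation of one or more points about the line
#' through \code{axis_origin} with unit direction \code{axis_dir}.
#'
#' @param p a length-3 point or an n x 3 matrix of points (mm).
#' @param axis_origin a point on the rotation axis (length-3, mm).
#' @param axis_dir unit direction of the axis (length-3).
#' @param angle_deg rotation angle in degrees (right-hand rule about
#'   \code{axis_dir}).
#' @return Rotated point(s), same shape as \code{p}.
#' @export
rotate_about_axis <- function(p, axis_origin, axis_dir, angle_deg) {
  axis_origin <- as_point3(axis_origin, "axis_origin")
  axis_dir <- as.numeric(axis_dir)
  if (length(axis_dir) != 3L || abs(vnorm(axis_dir) - 1) > 1e-9)
    abort_class("non_unit_axis", "axis_dir must be a unit vector (norm 1 within 1e-9)")
  if (angle_deg == 0) return(p)  # exact identity, no round-off at the reference
  single <- !is.matrix(p)
  m <- as_point_matrix(if (single) list(p) else p)
  R <- rotation_matrix(axis_dir, angle_deg)
  out <- sweep(sweep(m, 2, axis_origin) %*% t(R), 2, axis_origin, "+")
  if (single) as.numeric(out) else out
}

#' Rotation matrix for an axis-angle rotation
#' @noRd
rotation_matrix <- function(axis_dir, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis_dir
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
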