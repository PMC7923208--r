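# Independent oracles and fixture builders used across the test files.
# Everything here is computed with plain matrix algebra, deliberately not
# through the package's own rotation/frame code paths.

# rotation matrix about a unit axis, built directly from the angle-addition
# expansion (independent of the package's Rodrigues implementation)
oracle_rotmat <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  ct <- cos(th); st <- sin(th); vt <- 1 - ct
  matrix(c(ct + ux^2 * vt,      ux * uy * vt - uz * st, ux * uz * vt + uy * st,
           uy * ux * vt + uz * st, ct + uy^2 * vt,      uy * uz * vt - ux * st,
           uz * ux * vt - uy * st, uz * uy * vt + ux * st, ct + uz^2 * vt),
         3, 3, byrow = TRUE)
}

oracle_rotate <- function(p, origin, axis, angle_deg) {
  as.numeric(oracle_rotmat(axis, angle_deg) %*% (p - origin) + origin)
}

# random rigid transform (rotation + translation) as a closure
random_rigid_transform <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- oracle_rotmat(ax, stats::runif(1, -180, 180))
  t <- stats::runif(3, -50, 50)
  function(p) {
    if (is.matrix(p)) t(apply(p, 1, function(r) as.numeric(R %*% r + t)))
    else as.numeric(R %*% p + t)
  }
}

apply_transform_to_specimen <- function(sp, f) {
  sp$medial_epicondyle_tip <- f(sp$medial_epicondyle_tip)
  sp$lateral_epicondyle_tip <- f(sp$lateral_epicondyle_tip)
  sp$humeral_head_cloud <- f(sp$humeral_head_cloud)
  sp$attachments <- lapply(sp$attachments, f)
  sp
}

# exact noiseless cloud: 6 axis-aligned points plus extras on the sphere,
# so the algebraic fit recovers the center to machine precision
exact_sphere_cloud <- function(center, radius, n_extra = 10) {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  extra <- matrix(stats::rnorm(3 * n_extra), n_extra, 3)
  extra <- extra / sqrt(rowSums(extra^2))
  sweep(rbind(axes, extra) * radius, 2, center, "+")
}

# axis-aligned specimen with exact geometry: frame is known in closed form
# (origin 0, y = +Y, x = +Z, z = -X for a left elbow), so strains can be
# recomputed with explicit rotation matrices
exact_test_specimen <- function(group = "I") {
  at <- list(
    act_proximal         = c(-19, 1, 3),    act_distal    = c(-10, -14, 22),
    pct_proximal         = c(-19, -1, -3),  pct_distal    = c(-10, -15, 19),
    ab_ant_origin        = c(-19.5, 1, 2),  ab_ant_insertion = c(-13, -9, 10),
    ab_post_origin       = c(-19.5, -1, 2), ab_post_insertion = c(-13, -10, 8),
    pb_ant_origin        = c(-19.5, -2, -1), pb_ant_insertion = c(-12, -3, -10),
    pb_antcen_origin     = c(-20, 0, 2),    pb_antcen_insertion = c(-7, -1, 2),
    pb_postcen_origin    = c(-20, 0, -2),   pb_postcen_insertion = c(-7, -1, 1),
    pb_post_origin       = c(-19, -1, -3),  pb_post_insertion = c(-11, -1, -11))
  specimen_landmarks(
    specimen_id = "exact", group = group, side = "left",
    medial_epicondyle_tip = c(-20, 0, 0), lateral_epicondyle_tip = c(20, 0, 0),
    humeral_head_cloud = exact_sphere_cloud(c(0, 300, 0), 25),
    attachments = at)
}
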