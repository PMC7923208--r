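# Seeded generator of anatomically plausible specimens for the three
# morphology groups, standing in for unpublished cadaver coordinates.

#' Generator parameters
#'
#' @param seed integer RNG seed; every stochastic element (head-cloud
#'   sampling, digitizer noise, attachment jitter, digitizer placement)
#'   is a deterministic function of it.
#' @param group morphology group, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param side \code{"left"} (default) or \code{"right"} (mirrored).
#' @param humeral_head_radius radius of the humeral head sphere (mm).
#' @param head_cloud_size number of digitized head points (>= 4).
#' @param digitizer_noise_sd isotropic Gaussian noise applied to the head
#'   cloud (mm); default 0.23, the stated precision of the digitizer.
#' @param epicondyle_width distance between the epicondyle tips (mm).
#' @param humerus_length epicondyle midpoint to glenohumeral center (mm).
#' @param pb_central_offset offset of each capsule digitization site for
#'   the posterior-bundle central bands from the medial epicondyle tip in
#'   Groups II/III (mm); the two sites straddle the tip, so their spread
#'   is twice this value.
#' @param attachment_jitter_sd per-seed Gaussian jitter applied to the
#'   attachment landmarks (mm) so different seeds give distinct but
#'   conforming specimens; the Group II/III capsule sites are exempt
#'   (they are placed exactly at \code{pb_central_offset}).
#' @return validated parameter list of class \code{generator_params}.
#' @export
generator_params <- function(seed = 1L, group = "I", side = "left",
                             humeral_head_radius = 22.5,
                             head_cloud_size = 40L,
                             digitizer_noise_sd = 0.23,
                             epicondyle_width = 55,
                             humerus_length = 290,
                             pb_central_offset = 2.0,
                             attachment_jitter_sd = 0.3) {
  p <- list(seed = as.integer(seed),
            group = match.arg(as.character(group), MORPHOLOGY_GROUPS),
            side = match.arg(side, c("left", "right")),
            humeral_head_radius = as.numeric(humeral_head_radius),
            head_cloud_size = as.integer(head_cloud_size),
            digitizer_noise_sd = as.numeric(digitizer_noise_sd),
            epicondyle_width = as.numeric(epicondyle_width),
            humerus_length = as.numeric(humerus_length),
            pb_central_offset = as.numeric(pb_central_offset),
            attachment_jitter_sd = as.numeric(attachment_jitter_sd))
  lens <- c(p$humeral_head_radius, p$epicondyle_width, p$humerus_length,
            p$pb_central_offset)
  if (any(!is.finite(lens)) || any(lens <= 0))
    abort_class("invalid_params", "all generator lengths must be finite and > 0")
  if (p$head_cloud_size < 4L)
    abort_class("invalid_params", "head_cloud_size must be at least 4")
  if (!is.finite(p$digitizer_noise_sd) || p$digitizer_noise_sd < 0 ||
      !is.finite(p$attachment_jitter_sd) || p$attachment_jitter_sd < 0)
    abort_class("invalid_params", "noise standard deviations must be >= 0")
  class(p) <- "generator_params"
  p
}

# run code with a temporary, seeded RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cloud in canonical coordinates; caller manages the RNG state
sample_head_cloud <- function(params, center) {
  n <- params$head_cloud_size
  dirs <- matrix(stats::rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs[, 2] <- abs(dirs[, 2])  # proximal hemisphere
  pts <- matrix(center, n, 3, byrow = TRUE) + params$humeral_head_radius * dirs
  if (params$digitizer_noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(3 * n, sd = params$digitizer_noise_sd), n, 3)
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Synthetic humeral-head cloud
#'
#' Samples \code{head_cloud_size} points on the proximal hemisphere of a
#' sphere of the configured radius, perturbed by isotropic Gaussian noise
#' of sd \code{digitizer_noise_sd}; deterministic per seed.  The sphere
#' center sits \code{humerus_length} proximal of the canonical elbow
#' origin.
#'
#' @param params a \code{generator_params} object.
#' @return list with \code{points} (n x 3 matrix) and \code{center}
#'   (true sphere center, for testing recovery).
#' @export
generate_humeral_head <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  center <- c(0, params$humerus_length, 0)
  pts <- with_seed(params$seed, sample_head_cloud(params, center))
  list(points = pts, center = center)
}

# Canonical attachment layout, left side, mm.  Axes: +x lateral, +y
# proximal, +z anterior; origin at the epicondyle midpoint, so the
# flexion-extension axis is the x-axis line through both epicondyle tips
# and the digitized posture is 90 degrees flexion.  Humeral origins sit on
# the medial epicondyle within a few mm of the flexion axis; ulnar
# insertions sit distal-anterior of it (sublime tubercle for the anterior
# bundle, semilunar notch rim and olecranon for the posterior bundle,
# proximal forearm for the tendons).  Values are representative adult
# anatomy placed so the morphology groups reproduce the published
# qualitative strain patterns (anterior structures taut in extension,
# posterior common tendon taut in flexion in Groups I/II, medial fibers
# taut under valgus); they are frozen design constants, not measurements.
canonical_attachments <- function(group, med_x, pb_central_offset) {
  me <- c(med_x, 0, 0)
  at <- list(
    act_proximal         = c(med_x + 1.0,   1.03,   2.82),
    act_distal           = c(med_x + 10.5, -17.21, 24.57),
    pct_proximal         = c(med_x + 1.0,  -1.09,  -3.01),
    pct_distal           = c(med_x + 10.5, -18.00, 21.45),
    ab_ant_origin        = c(med_x + 0.5,   1.06,   2.27),
    ab_ant_insertion     = c(med_x + 7.5,  -10.37, 11.52),
    ab_post_origin       = c(med_x + 0.5,  -1.10,   1.91),
    ab_post_insertion    = c(med_x + 7.5,  -10.78,  9.70),
    pb_ant_origin        = c(med_x + 0.5,  -2.77,  -1.60),
    pb_ant_insertion     = c(med_x + 8.5,   -3.71, -11.41),
    pb_antcen_origin     = c(med_x + 0.5,  -2.23,  -2.01),
    pb_antcen_insertion  = c(med_x + 8.5,   -2.60, -12.23),
    pb_postcen_origin    = c(med_x + 0.5,  -1.72,  -2.46),
    pb_postcen_insertion = c(med_x + 8.5,   -1.81, -12.87),
    pb_post_origin       = c(med_x + 1.0,  -1.27,  -3.15),
    pb_post_insertion    = c(med_x + 9.5,   -0.47, -13.49))

  if (group %in% c("II", "III")) {
    # PB central bands digitized on the joint capsule: origins straddle
    # the medial epicondyle tip along the anteroposterior direction, and
    # the capsule fibers run to the deep rim of the semilunar notch, close
    # to the flexion axis, rather than to the discrete bundle's footprint
    at$pb_antcen_origin     <- me + c(0, 0,  pb_central_offset)
    at$pb_postcen_origin    <- me + c(0, 0, -pb_central_offset)
    at$pb_antcen_insertion  <- c(med_x + 14.0, -0.68,  1.88)
    at$pb_postcen_insertion <- c(med_x + 14.0, -1.15,  1.64)
  }
  if (group == "III") {
    # continuous sheet: the AB edges merge with the adjacent tendons and
    # the digitized "PCT" fibers sit anterior of their Group I/II
    # position, which flips the PCT toward an extension-taut pattern
    at$ab_ant_origin  <- c(med_x + 1.0,  0.62, 2.93)
    at$ab_post_origin <- c(med_x + 1.0,  0.11, 3.10)
    at$pct_proximal   <- c(med_x + 1.0, -0.29, 3.29)
  }
  at
}

#' Generate a synthetic specimen
#'
#' Builds a full landmark set for one synthetic elbow of the requested
#' morphology group: epicondyle tips separated by
#' \code{epicondyle_width}, glenohumeral center \code{humerus_length}
#' proximal, a noisy head cloud, and the 16 attachment landmarks laid out
#' per group (common tendons just anterior/posterior of the anterior
#' bundle; Group II/III capsule sites exactly \code{pb_central_offset}
#' from the medial epicondyle tip).  Attachments receive seeded Gaussian
#' jitter (\code{attachment_jitter_sd}) and the whole specimen is mapped
#' by a seeded rigid transform into an arbitrary digitizer space, as a
#' real digitizer session would record it.  Deterministic per seed.
#'
#' @param params a \code{generator_params} object.
#' @return a \code{specimen_landmarks} object that passes
#'   [validate_specimen()] with no issues at default parameters.
#' @export
generate_specimen <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  hw <- params$epicondyle_width / 2

  with_seed(params$seed, {
    ghc <- c(0, params$humerus_length, 0)
    cloud <- sample_head_cloud(params, ghc)

    me <- c(-hw, 0, 0)
    le <- c(hw, 0, 0)
    at <- canonical_attachments(params$group, -hw, params$pb_central_offset)

    if (params$attachment_jitter_sd > 0) {
      exempt <- if (params$group %in% c("II", "III"))
        c("pb_antcen_origin", "pb_postcen_origin") else character()
      for (nm in names(at)) {
        jit <- stats::rnorm(3, sd = params$attachment_jitter_sd)
        if (!nm %in% exempt) at[[nm]] <- at[[nm]] + jit
      }
    }

    if (params$side == "right") {
      mir <- function(p) p * c(-1, 1, 1)
      me <- mir(me); le <- mir(le); at <- lapply(at, mir)
      cloud[, 1] <- -cloud[, 1]
    }

    # seeded rigid placement in digitizer space
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -180, 180)
    shift <- stats::runif(3, -100, 100)
    R <- rotation_matrix(ax, ang)
    place <- function(p) as.numeric(R %*% p + shift)
    cloud <- sweep(cloud %*% t(R), 2, shift, "+")
    colnames(cloud) <- c("x", "y", "z")

    specimen_landmarks(
      specimen_id = sprintf("synthetic_%s_%s_seed%d", params$group, params$side,
                            params$seed),
      group = params$group, side = params$side,
      medial_epicondyle_tip = place(me), lateral_epicondyle_tip = place(le),
      humeral_head_cloud = cloud,
      attachments = lapply(at, place))
  })
}

#' Read or write generator parameters as a JSON config file
#'
#' One key per parameter field; unknown keys are rejected so config drift
#' fails loudly.
#'
#' @param params a \code{generator_params} object.
#' @param path file path.
#' @return \code{read_generator_params} returns a \code{generator_params}
#'   object; \code{write_generator_params} returns \code{path} invisibly.
#' @export
write_generator_params <- function(params, path) {
  stopifnot(inherits(params, "generator_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_params
#' @export
read_generator_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(obj), names(formals(generator_params)))
  if (length(unknown))
    abort_class("invalid_params",
                paste0("unknown generator parameter(s): ",
                       paste(unknown, collapse = ", ")))
  do.call(generator_params, obj)
}

#' Add digitization noise to a specimen
#'
#' Adds independent isotropic Gaussian noise to every attachment landmark
#' (and optionally the head cloud), for sensitivity analyses of strain to
#' digitization error.  Deterministic per seed.
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @param noise_sd noise standard deviation (mm, >= 0).
#' @param seed RNG seed.
#' @param include_cloud also perturb the humeral-head cloud.
#' @return a perturbed \code{specimen_landmarks} object.
#' @export
perturb_specimen <- function(landmarks, noise_sd, seed = 1L, include_cloud = FALSE) {
  if (!is.finite(noise_sd) || noise_sd < 0)
    abort_class("invalid_params", "noise_sd must be >= 0")
  if (noise_sd == 0) return(landmarks)
  with_seed(seed, {
    landmarks$attachments <- lapply(landmarks$attachments, function(p)
      p + stats::rnorm(3, sd = noise_sd))
    if (include_cloud) {
      n <- nrow(landmarks$humeral_head_cloud)
      landmarks$humeral_head_cloud <- landmarks$humeral_head_cloud +
        matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    }
    landmarks
  })
}
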