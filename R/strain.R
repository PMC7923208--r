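# Pose the ulna-fixed insertion points over the flexion x valgus grid and
# compute percent strain per fiber, plus per-pose averages.

REFERENCE_FLEXION <- 90
REFERENCE_VALGUS <- 0
DEFAULT_FLEXION_GRID <- c(0, 30, 60, 90, 120)
DEFAULT_VALGUS_GRID <- c(0, 10)

#' Percent strain relative to a reference length
#'
#' \code{(LT - LST) / LST * 100}: the percent change of fiber length from
#' its reference length \code{LST} (measured at 90 degrees flexion, 0
#' degrees valgus) to the posed length \code{LT}.  Positive = taut,
#' negative = shortened.  Vectorized.
#'
#' @param LT posed length (mm).
#' @param LST reference length (mm, > 0).
#' @return strain in percent.
#' @export
#' @examples
#' strain_percent(44, 40)  # 10
strain_percent <- function(LT, LST) {
  if (any(!is.finite(LST)) || any(LST <= 0))
    abort_class("nonpositive_reference_length", "reference length LST must be > 0")
  (LT - LST) / LST * 100
}

#' Rigidly pose ulna-fixed points
#'
#' Rotates points fixed to the ulna from the digitized posture (90
#' degrees flexion, 0 degrees valgus) to a target pose: first by
#' \code{flexion_deg - 90} about the frame's flexion (Z) axis, then by
#' \code{valgus_deg} about its varus/valgus (X) axis, both axes
#' humerus-fixed and passing through the frame origin (the epicondyle
#' midpoint).  \code{order = "valgus_first"} swaps the two rotations for
#' sensitivity checks.
#'
#' @param points n x 3 matrix (or length-3 vector) of ulna-fixed points.
#' @param frame a \code{coordinate_frame}.
#' @param flexion_deg,valgus_deg target pose in degrees.
#' @param order \code{"flexion_first"} (default) or \code{"valgus_first"}.
#' @return posed points, same shape as \code{points}.
#' @export
pose_points <- function(points, frame, flexion_deg, valgus_deg,
                        order = c("flexion_first", "valgus_first")) {
  order <- match.arg(order)
  stopifnot(inherits(frame, "coordinate_frame"))
  # the right-handed frame flips the Z-axis sense on right elbows; mirror
  # the flexion delta so the anatomical motion is the same on both sides
  flex_sign <- if (identical(frame$side, "right")) -1 else 1
  rot_flex <- function(p) rotate_about_axis(p, frame$origin, frame$z_axis,
                                            flex_sign * (flexion_deg - REFERENCE_FLEXION))
  rot_valg <- function(p) rotate_about_axis(p, frame$origin, frame$x_axis, valgus_deg)
  if (order == "flexion_first") rot_valg(rot_flex(points)) else rot_flex(rot_valg(points))
}

#' Posed insertion points for every fiber
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @param frame a \code{coordinate_frame}.
#' @param pose numeric length-2 \code{c(flexion_deg, valgus_deg)} or a list
#'   with those fields.
#' @param order rotation order, see [pose_points()].
#' @return 9 x 3 matrix of posed ulnar insertion points, rows named by fiber.
#' @export
pose_insertions <- function(landmarks, frame, pose,
                            order = c("flexion_first", "valgus_first")) {
  pose <- as_pose(pose)
  fib <- derive_fibers(landmarks)
  pose_points(fib$insertions, frame, pose[1], pose[2], order = match.arg(order))
}

as_pose <- function(pose) {
  if (is.list(pose)) pose <- c(pose$flexion_deg, pose$valgus_deg)
  pose <- as.numeric(pose)
  if (length(pose) != 2L || any(!is.finite(pose)))
    abort_class("invalid_pose", "pose must be c(flexion_deg, valgus_deg)")
  pose
}

#' Run the full strain study over a flexion x valgus grid
#'
#' Pipeline: fit the glenohumeral rotation center to the humeral-head
#' cloud (least-squares sphere), build the anatomical frame from it and
#' the epicondyle tips, derive the nine fibers, then for every pose on
#' the grid rigidly rotate the ulna-fixed insertions and compute each
#' fiber's percent strain against its reference length at 90 degrees
#' flexion / 0 degrees valgus.
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @param flexion_grid flexion angles in degrees; must contain 90.
#' @param valgus_grid valgus angles in degrees; must contain 0.
#' @param sphere_method passed to [fit_sphere()].
#' @param order rotation order, see [pose_points()].
#' @return A \code{strain_table}: data frame in long format with columns
#'   \code{specimen_id}, \code{group}, \code{fiber}, \code{flexion_deg},
#'   \code{valgus_deg}, \code{reference_length_mm}, \code{posed_length_mm},
#'   \code{strain_pct}; poses ordered valgus-major, flexion ascending,
#'   fibers in canonical order within each pose.
#' @export
run_strain_study <- function(landmarks,
                             flexion_grid = DEFAULT_FLEXION_GRID,
                             valgus_grid = DEFAULT_VALGUS_GRID,
                             sphere_method = c("algebraic", "geometric"),
                             order = c("flexion_first", "valgus_first")) {
  order <- match.arg(order)
  flexion_grid <- sort(unique(as.numeric(flexion_grid)))
  valgus_grid <- sort(unique(as.numeric(valgus_grid)))
  if (!length(flexion_grid) || !length(valgus_grid))
    abort_class("invalid_grid", "flexion and valgus grids must be non-empty")
  if (!REFERENCE_FLEXION %in% flexion_grid || !REFERENCE_VALGUS %in% valgus_grid)
    abort_class("missing_reference_pose",
                "flexion grid must contain 90 and valgus grid must contain 0 (the reference pose)")

  sph <- fit_sphere(landmarks$humeral_head_cloud, method = match.arg(sphere_method))
  frame <- build_frame(sph$center, landmarks$medial_epicondyle_tip,
                       landmarks$lateral_epicondyle_tip, landmarks$side)
  fib <- derive_fibers(landmarks)

  lst <- sqrt(rowSums((fib$insertions - fib$origins)^2))  # reference lengths

  rows <- vector("list", length(valgus_grid) * length(flexion_grid))
  k <- 0L
  for (vg in valgus_grid) for (fx in flexion_grid) {
    posed <- pose_points(fib$insertions, frame, fx, vg, order = order)
    lt <- sqrt(rowSums((posed - fib$origins)^2))
    k <- k + 1L
    rows[[k]] <- data.frame(
      specimen_id = landmarks$specimen_id, group = landmarks$group,
      fiber = fib$names, flexion_deg = fx, valgus_deg = vg,
      reference_length_mm = lst, posed_length_mm = lt,
      strain_pct = strain_percent(lt, lst),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "frame") <- frame
  attr(out, "sphere_fit") <- sph
  class(out) <- c("strain_table", "data.frame")
  out
}

#' Average strain over the nine fibers at each pose
#'
#' Unweighted arithmetic mean of the nine fiber strains per pose, the
#' cohort summary used to compare morphology groups.
#'
#' @param table a \code{strain_table} from [run_strain_study()].
#' @return data frame with \code{flexion_deg}, \code{valgus_deg},
#'   \code{strain_pct} (one row per pose, same pose ordering).
#' @export
average_strain <- function(table) {
  check_complete(table)
  agg <- stats::aggregate(strain_pct ~ valgus_deg + flexion_deg, data = table, FUN = mean)
  agg <- agg[order(agg$valgus_deg, agg$flexion_deg), c("flexion_deg", "valgus_deg", "strain_pct")]
  row.names(agg) <- NULL
  agg
}

check_complete <- function(table) {
  n_pose <- nrow(unique(table[, c("flexion_deg", "valgus_deg")]))
  counts <- table(table$fiber)
  if (length(counts) != length(FIBER_NAMES) || any(counts != n_pose) ||
      nrow(table) != n_pose * length(FIBER_NAMES))
    abort_class("incomplete_table",
                "strain table must hold one result per fiber-pose pair for all 9 fibers")
  invisible(TRUE)
}

#' Wide strain table for one valgus setting
#'
#' Reshapes the long table into the conventional reporting layout: one
#' row per fiber, one column per flexion angle, plus an \code{Average}
#' row, values rounded for display (internal computation stays at full
#' precision in the long table).
#'
#' @param table a \code{strain_table}.
#' @param valgus_deg which valgus setting to extract.
#' @param decimals rounding for display (default 1, i.e. 0.1 %).
#' @return data frame with columns \code{fiber} then one per flexion angle
#'   (named e.g. \code{flex_0}).
#' @export
widen_strain_table <- function(table, valgus_deg = 0, decimals = 1) {
  check_complete(table)
  sub <- table[table$valgus_deg == valgus_deg, ]
  if (!nrow(sub))
    abort_class("invalid_grid", sprintf("no results at valgus %g", valgus_deg))
  flex <- sort(unique(sub$flexion_deg))
  wide <- data.frame(fiber = c(FIBER_NAMES, "Average"), stringsAsFactors = FALSE)
  for (fx in flex) {
    col <- vapply(FIBER_NAMES, function(f)
      sub$strain_pct[sub$fiber == f & sub$flexion_deg == fx], numeric(1))
    wide[[paste0("flex_", fx)]] <- round(c(col, mean(col)), decimals)
  }
  wide
}

#' Write strain tables to CSV
#'
#' Writes the long table at full precision and, per valgus setting, a
#' wide table rounded for display.
#'
#' @param table a \code{strain_table}.
#' @param dir output directory (created if needed).
#' @param formats any of \code{"long_csv"}, \code{"wide_csv"}, \code{"json"}.
#' @param decimals display rounding for the wide tables.
#' @return character vector of written paths, invisibly.
#' @export
write_strain_tables <- function(table, dir, formats = c("long_csv", "wide_csv"),
                                decimals = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("long_csv" %in% formats) {
    p <- file.path(dir, "strain_long.csv")
    utils::write.csv(as.data.frame(table), p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("wide_csv" %in% formats) {
    for (vg in sort(unique(table$valgus_deg))) {
      p <- file.path(dir, sprintf("strain_wide_valgus%g.csv", vg))
      utils::write.csv(widen_strain_table(table, vg, decimals), p,
                       row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "strain_long.json")
    jsonlite::write_json(as.data.frame(table), p, dataframe = "rows", digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
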