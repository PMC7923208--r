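# Landmark schema, fiber taxonomy, morphology-group metadata, landmark I/O.

MORPHOLOGY_GROUPS <- c("I", "II", "III")

#' Canonical fiber names, in reporting order
#' @export
FIBER_NAMES <- c("ACT", "PCT", "AB1", "AB2", "AB3", "PB1", "PB2", "PB3", "PB4")

# Controlled vocabulary of attachment landmarks.  The AB central band
# (ab_cen_*) is optional: when absent it is derived as the midpoints of the
# AB anterior/posterior edges.
REQUIRED_ATTACHMENTS <- c(
  "act_proximal", "act_distal",
  "pct_proximal", "pct_distal",
  "ab_ant_origin", "ab_ant_insertion",
  "ab_post_origin", "ab_post_insertion",
  "pb_ant_origin", "pb_ant_insertion",
  "pb_antcen_origin", "pb_antcen_insertion",
  "pb_postcen_origin", "pb_postcen_insertion",
  "pb_post_origin", "pb_post_insertion")
OPTIONAL_ATTACHMENTS <- c("ab_cen_origin", "ab_cen_insertion")
ATTACHMENT_NAMES <- c(REQUIRED_ATTACHMENTS, OPTIONAL_ATTACHMENTS)

# File precision: 0.001 mm (one order finer than the 0.23 mm digitizer
# precision, so write/read round-trips are exact).
FILE_DIGITS <- 3L

#' Digitized landmark set for one elbow specimen
#'
#' Container for all digitized points of one specimen: the epicondyle
#' tips, the humeral-head cloud used to locate the glenohumeral rotation
#' center, and the ligament/tendon attachment points (anterior/posterior
#' common tendon 2 points each, anterior bundle 6, posterior bundle 8),
#' plus the dissection-assigned morphology group and the side.
#'
#' @param specimen_id character identifier.
#' @param group morphology group label, \code{"I"}, \code{"II"} or
#'   \code{"III"} (declared metadata from dissection, never inferred).
#' @param side \code{"left"} or \code{"right"}.
#' @param medial_epicondyle_tip,lateral_epicondyle_tip length-3 points (mm).
#' @param humeral_head_cloud n x 3 matrix of points on the humeral head
#'   (n >= 4; conventionally about 40).
#' @param attachments named list of length-3 points using the canonical
#'   landmark vocabulary (\code{act_proximal}, \code{ab_ant_origin}, ...).
#'   \code{ab_cen_origin}/\code{ab_cen_insertion} are optional.
#' @return An object of class \code{specimen_landmarks}.
#' @export
specimen_landmarks <- function(specimen_id, group, side,
                               medial_epicondyle_tip, lateral_epicondyle_tip,
                               humeral_head_cloud, attachments) {
  group <- match.arg(as.character(group), MORPHOLOGY_GROUPS)
  side <- match.arg(side, c("left", "right"))
  me <- as_point3(medial_epicondyle_tip, "medial_epicondyle_tip")
  le <- as_point3(lateral_epicondyle_tip, "lateral_epicondyle_tip")
  cloud <- as_point_matrix(humeral_head_cloud)

  unknown <- setdiff(names(attachments), ATTACHMENT_NAMES)
  if (length(unknown))
    abort_class("schema_violation",
                paste0("unknown attachment landmark(s): ", paste(unknown, collapse = ", ")))
  missing <- setdiff(REQUIRED_ATTACHMENTS, names(attachments))
  if (length(missing))
    abort_class("missing_landmark",
                paste0("missing attachment landmark(s): ", paste(missing, collapse = ", ")))
  attachments <- lapply(attachments, as_point3)
  attachments <- attachments[intersect(ATTACHMENT_NAMES, names(attachments))]

  structure(list(specimen_id = as.character(specimen_id), group = group,
                 side = side, medial_epicondyle_tip = me,
                 lateral_epicondyle_tip = le, humeral_head_cloud = cloud,
                 attachments = attachments),
            class = "specimen_landmarks")
}

#' @export
print.specimen_landmarks <- function(x, ...) {
  cat(sprintf("Specimen '%s' (Group %s, %s side): %d head-cloud points, %d attachment landmarks\n",
              x$specimen_id, x$group, x$side, nrow(x$humeral_head_cloud),
              length(x$attachments)))
  invisible(x)
}

#' Derive the nine modeled fibers from a specimen's landmarks
#'
#' Returns the nine straight-line fibers in canonical order: the anterior
#' and posterior common tendons (ACT, PCT), the anterior, central and
#' posterior bands of the anterior bundle (AB1-AB3), and the four bands
#' of the posterior bundle (PB1-PB4).  The AB central band is the line
#' joining the midpoints of the AB anterior/posterior edge origins and
#' insertions unless it was digitized explicitly.
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @return A \code{fiber_set}: list with \code{names} (character 9),
#'   \code{origins} and \code{insertions} (9 x 3 matrices; rows named by
#'   fiber).  Origins are humerus-fixed, insertions ulna-fixed.
#' @export
derive_fibers <- function(landmarks) {
  at <- landmarks$attachments
  need <- function(nm) {
    if (is.null(at[[nm]])) abort_class("missing_landmark", paste0("missing landmark: ", nm))
    at[[nm]]
  }
  ab_cen_o <- if (!is.null(at$ab_cen_origin)) at$ab_cen_origin else
    (need("ab_ant_origin") + need("ab_post_origin")) / 2
  ab_cen_i <- if (!is.null(at$ab_cen_insertion)) at$ab_cen_insertion else
    (need("ab_ant_insertion") + need("ab_post_insertion")) / 2

  origins <- rbind(ACT = need("act_proximal"), PCT = need("pct_proximal"),
                   AB1 = need("ab_ant_origin"), AB2 = ab_cen_o,
                   AB3 = need("ab_post_origin"), PB1 = need("pb_ant_origin"),
                   PB2 = need("pb_antcen_origin"), PB3 = need("pb_postcen_origin"),
                   PB4 = need("pb_post_origin"))
  insertions <- rbind(ACT = need("act_distal"), PCT = need("pct_distal"),
                      AB1 = need("ab_ant_insertion"), AB2 = ab_cen_i,
                      AB3 = need("ab_post_insertion"), PB1 = need("pb_ant_insertion"),
                      PB2 = need("pb_antcen_insertion"), PB3 = need("pb_postcen_insertion"),
                      PB4 = need("pb_post_insertion"))
  colnames(origins) <- colnames(insertions) <- c("x", "y", "z")

  if (any(sqrt(rowSums((origins - insertions)^2)) < 1e-9))
    abort_class("invalid_fiber", "fiber with coincident origin and insertion")

  structure(list(names = FIBER_NAMES, origins = origins, insertions = insertions),
            class = "fiber_set")
}

# ---- landmark file I/O ------------------------------------------------------

fmt_mm <- function(v) formatC(round(v, FILE_DIGITS), format = "f",
                              digits = FILE_DIGITS)

landmark_rows <- function(landmarks) {
  cloud <- landmarks$humeral_head_cloud
  nm <- c("medial_epicondyle_tip", "lateral_epicondyle_tip",
          sprintf("head_%03d", seq_len(nrow(cloud))),
          names(landmarks$attachments))
  xyz <- rbind(landmarks$medial_epicondyle_tip, landmarks$lateral_epicondyle_tip,
               cloud, do.call(rbind, landmarks$attachments))
  data.frame(specimen_id = landmarks$specimen_id, group = landmarks$group,
             side = landmarks$side, landmark_name = nm,
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Write a specimen landmark file
#'
#' CSV schema: header \code{specimen_id,group,side,landmark_name,x_mm,y_mm,z_mm},
#' one row per landmark, head-cloud points named \code{head_001} ...; JSON is a
#' structural mirror.  Coordinates are written with 3 decimal places
#' (0.001 mm), one order finer than digitizer precision, and field order
#' is deterministic so identical specimens produce identical files.
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @param path output file path; if \code{NULL}, the text is returned.
#' @param format \code{"csv"} or \code{"json"}.
#' @return The file text, invisibly when written to \code{path}.
#' @export
write_landmarks <- function(landmarks, path = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- landmark_rows(landmarks)
    lines <- c("specimen_id,group,side,landmark_name,x_mm,y_mm,z_mm",
               sprintf("%s,%s,%s,%s,%s,%s,%s", df$specimen_id, df$group, df$side,
                       df$landmark_name, fmt_mm(df$x_mm), fmt_mm(df$y_mm),
                       fmt_mm(df$z_mm)))
    text <- paste0(paste(lines, collapse = "\n"), "\n")
  } else {
    obj <- list(
      specimen_id = landmarks$specimen_id, group = landmarks$group,
      side = landmarks$side,
      medial_epicondyle_tip = round(landmarks$medial_epicondyle_tip, FILE_DIGITS),
      lateral_epicondyle_tip = round(landmarks$lateral_epicondyle_tip, FILE_DIGITS),
      humeral_head_cloud = round(unname(landmarks$humeral_head_cloud), FILE_DIGITS),
      attachments = lapply(landmarks$attachments, round, digits = FILE_DIGITS))
    text <- paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE), "\n")
  }
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Read a specimen landmark file
#'
#' @param source a file path, or a character string holding the file text.
#' @param format \code{"csv"} or \code{"json"}.
#' @return A \code{specimen_landmarks} object.
#' @seealso [write_landmarks()] for the schema; the two round-trip exactly
#'   at the declared 0.001 mm precision.
#' @export
read_landmarks <- function(source, format = c("csv", "json")) {
  format <- match.arg(format)
  text <- if (length(source) == 1L && !grepl("[\n,{]", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else paste(source, collapse = "\n")

  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(text = text, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "character",
                                     "character", "numeric", "numeric", "numeric")),
      error = function(e) abort_class("parse_error", conditionMessage(e)))
    expected <- c("specimen_id", "group", "side", "landmark_name", "x_mm", "y_mm", "z_mm")
    if (!identical(names(df), expected))
      abort_class("schema_violation",
                  paste0("expected header: ", paste(expected, collapse = ",")))
    is_head <- grepl("^head_[0-9]+$", df$landmark_name)
    known <- df$landmark_name %in% c("medial_epicondyle_tip", "lateral_epicondyle_tip",
                                     ATTACHMENT_NAMES) | is_head
    if (any(!known))
      abort_class("schema_violation",
                  sprintf("unknown landmark_name '%s' at data row %d",
                          df$landmark_name[which(!known)[1]], which(!known)[1]))
    pick <- function(nm) {
      i <- which(df$landmark_name == nm)
      if (length(i) != 1L)
        abort_class("schema_violation",
                    sprintf("landmark '%s' must appear exactly once (found %d)", nm, length(i)))
      c(df$x_mm[i], df$y_mm[i], df$z_mm[i])
    }
    heads <- df[is_head, ]
    heads <- heads[order(heads$landmark_name), ]
    att_names <- intersect(ATTACHMENT_NAMES, df$landmark_name)
    specimen_landmarks(
      specimen_id = df$specimen_id[1], group = df$group[1], side = df$side[1],
      medial_epicondyle_tip = pick("medial_epicondyle_tip"),
      lateral_epicondyle_tip = pick("lateral_epicondyle_tip"),
      humeral_head_cloud = as.matrix(heads[, c("x_mm", "y_mm", "z_mm")]),
      attachments = stats::setNames(lapply(att_names, pick), att_names))
  } else {
    obj <- tryCatch(jsonlite::fromJSON(text),
                    error = function(e) abort_class("parse_error", conditionMessage(e)))
    needed <- c("specimen_id", "group", "side", "medial_epicondyle_tip",
                "lateral_epicondyle_tip", "humeral_head_cloud", "attachments")
    if (!all(needed %in% names(obj)))
      abort_class("schema_violation",
                  paste0("missing JSON field(s): ",
                         paste(setdiff(needed, names(obj)), collapse = ", ")))
    specimen_landmarks(
      specimen_id = obj$specimen_id, group = obj$group, side = obj$side,
      medial_epicondyle_tip = obj$medial_epicondyle_tip,
      lateral_epicondyle_tip = obj$lateral_epicondyle_tip,
      humeral_head_cloud = obj$humeral_head_cloud,
      attachments = lapply(obj$attachments, as.numeric))
  }
}

# ---- specimen validation ----------------------------------------------------

issue_df <- function(code = character(), message = character()) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

#' Validate a specimen against the digitization conventions
#'
#' Returns a data frame of issues (empty when the specimen conforms):
#' head-cloud size, epicondyle distinctness, coincident fiber endpoints,
#' and — for Groups II and III, where the posterior-bundle central bands
#' are digitized on the joint capsule — that the anterior-central and
#' posterior-central origin sites sit about 2 mm anterior and 2 mm
#' posterior of the medial epicondyle tip (combined spread about 4 mm,
#' the published width of the posterior-bundle origin).
#'
#' @param landmarks a \code{specimen_landmarks} object.
#' @param site_tolerance_mm allowed deviation of each capsule site from
#'   its nominal 2 mm offset (default 1 mm); deviations at or beyond the
#'   tolerance are flagged.
#' @return data frame with columns \code{code}, \code{message}; zero rows
#'   when no issues are found.
#' @export
validate_specimen <- function(landmarks, site_tolerance_mm = 1.0) {
  issues <- issue_df()
  add <- function(code, message) {
    issues <<- rbind(issues, issue_df(code, message))
  }

  if (nrow(landmarks$humeral_head_cloud) < 4L)
    add("cloud_too_small",
        sprintf("humeral head cloud has %d points; at least 4 required",
                nrow(landmarks$humeral_head_cloud)))
  if (dist3(landmarks$medial_epicondyle_tip, landmarks$lateral_epicondyle_tip) < 1e-6)
    add("epicondyles_coincident", "medial and lateral epicondyle tips coincide")

  fib <- tryCatch(derive_fibers(landmarks), error = function(e) e)
  if (inherits(fib, "error")) {
    add("fiber_derivation_failed", conditionMessage(fib))
  }

  if (landmarks$group %in% c("II", "III")) {
    me <- landmarks$medial_epicondyle_tip
    a <- landmarks$attachments$pb_antcen_origin
    p <- landmarks$attachments$pb_postcen_origin
    if (!is.null(a) && !is.null(p)) {
      da <- dist3(me, a); dp <- dist3(me, p); spread <- dist3(a, p)
      if (abs(da - 2) >= site_tolerance_mm - 1e-9)
        add("pb_antcen_site_offset",
            sprintf("anterior-central PB site is %.2f mm from the medial epicondyle tip (expected ~2 mm)", da))
      if (abs(dp - 2) >= site_tolerance_mm - 1e-9)
        add("pb_postcen_site_offset",
            sprintf("posterior-central PB site is %.2f mm from the medial epicondyle tip (expected ~2 mm)", dp))
      if (abs(spread - 4) >= 2 * site_tolerance_mm - 1e-9)
        add("pb_central_site_spread",
            sprintf("central PB sites are %.2f mm apart (expected ~4 mm)", spread))
    }
  }
  issues
}
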