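# The five radiographic angles. All unsigned angles (mLDFA, mMPTA, TGA, BA)
# are resolved purely from landmark names, so they are invariant under any
# rigid motion, uniform scaling and mirroring of the image. Only the HKA sign
# needs a handedness convention; see hka_deviation().

# Medial/lateral tangent points: drawn directly by the observer, or derived
# from digitised facet contours when only contours are present.
trochlear_tangents <- function(ann) {
  pts <- ann$points
  have_pts <- all(c("trochlear_tangent_medial", "trochlear_tangent_lateral")
                  %in% names(pts))
  if (have_pts) {
    return(list(medial = pts$trochlear_tangent_medial,
                lateral = pts$trochlear_tangent_lateral))
  }
  have_ctr <- all(CONTOUR_VOCABULARY %in% names(ann$contours))
  if (!have_ctr) {
    km_stop("missing_landmark",
            sprintf("trochlear tangent points or facet contours required (subject %s)",
                    ann$subject_id))
  }
  apex <- need_points(ann, "trochlear_apex", "trochlear_angles")[[1L]]
  hint <- if (all(c("condyle_medial", "condyle_lateral") %in% names(pts))) {
    pts$condyle_medial - pts$condyle_lateral
  } else NULL
  list(
    medial = tangent_from_point(apex, ann$contours$trochlear_contour_medial,
                                branch = "medial", side = ann$side,
                                medial_hint = hint),
    lateral = tangent_from_point(apex, ann$contours$trochlear_contour_lateral,
                                 branch = "lateral", side = ann$side,
                                 medial_hint = hint)
  )
}

#' Trochlear groove angle and proximal bisector direction
#'
#' Two tangent rays are taken from the apical midpoint of the intercondylar
#' groove to the medial and lateral trochlear facets (either digitised tangent
#' contact points, or computed from facet contours). The trochlear groove
#' angle (TGA) is the angle these rays subtend at the apex; the trochlear
#' groove bisector (TGB) bisects it. The returned direction is the proximal
#' orientation of the TGB: the internal bisector points distally (toward the
#' tangent points), so its negation points up the femoral shaft.
#'
#' @param ann A [landmark_annotation()].
#' @return List with `tga` (degrees) and `tgb_proximal` (unit length-2
#'   vector).
#' @export
trochlear_angles <- function(ann) {
  apex <- need_points(ann, "trochlear_apex", "trochlear_angles")[[1L]]
  tg <- trochlear_tangents(ann)
  if (all(tg$medial == tg$lateral)) {
    # coincident tangents: zero-opening groove, bisector along the single ray
    d <- unit(tg$medial - apex, "tangent ray")
    return(list(tga = 0, tgb_proximal = -d))
  }
  tga <- angle_at_vertex(apex, tg$medial, tg$lateral)
  bis <- bisector_direction(apex, tg$medial, tg$lateral)
  list(tga = tga, tgb_proximal = -bis)
}

#' Trochlear bisector angle (BA)
#'
#' The medial angle between the trochlear groove bisector and the distal
#' femoral joint line (the line through the two most prominent condyle
#' points). Measured between the proximally oriented bisector and the
#' lateral-to-medial joint-line vector, so perpendicularity reads exactly 90
#' degrees and values below 90 mean the proximal bisector tip leans medially.
#'
#' @inheritParams trochlear_angles
#' @return Angle in degrees, in (0, 180).
#' @export
bisector_angle <- function(ann) {
  p <- need_points(ann, c("condyle_medial", "condyle_lateral"), "bisector_angle")
  if (all(p$condyle_medial == p$condyle_lateral)) {
    km_stop("degenerate_geometry", "condyle points coincide; joint line undefined")
  }
  tr <- trochlear_angles(ann)
  jm <- p$condyle_medial - p$condyle_lateral  # lateral -> medial
  angle_between(tr$tgb_proximal, jm)
}

# Handedness of the image frame: +1 when the frame is 'direct' (equivalent to
# the standard AP display frame: y proximal, medial at +x for a right limb),
# -1 when mirrored (e.g. y-down pixel frames). Derived from the joint-line
# landmarks when present; otherwise the direct frame is assumed.
frame_orientation <- function(ann) {
  pts <- ann$points
  pair <- if (all(c("condyle_medial", "condyle_lateral") %in% names(pts))) {
    c("condyle_medial", "condyle_lateral")
  } else if (all(c("plateau_medial", "plateau_lateral") %in% names(pts))) {
    c("plateau_medial", "plateau_lateral")
  } else {
    return(1)
  }
  prox_from <- intersect(c("hip_center", "femoral_notch_center",
                           "tibial_spines_center"), names(pts))[1L]
  dist_from <- rev(intersect(c("femoral_notch_center", "tibial_spines_center",
                               "ankle_center"), names(pts)))[1L]
  if (is.na(prox_from) || is.na(dist_from) || prox_from == dist_from) return(1)
  prox <- pts[[prox_from]] - pts[[dist_from]]
  med <- pts[[pair[1L]]] - pts[[pair[2L]]]
  h <- sign(cross2(unit(prox), unit(med)))
  if (h == 0) return(1)
  side_factor <- if (ann$side == "right") 1 else -1
  # In the direct frame cross(proximal, medial) is -1 for right, +1 for left.
  -h * side_factor
}

#' Hip-knee-ankle deviation from 180 degrees
#'
#' Angle between the femoral mechanical axis (hip centre to femoral notch) and
#' the tibial mechanical axis (tibial spines centre to ankle centre),
#' expressed as a signed deviation from 180 degrees: negative when the knee
#' apex points laterally (varus), positive for valgus. The sign is resolved
#' from the `side` field together with the image handedness, which is derived
#' from the condylar/plateau landmarks when present and otherwise assumed to
#' be the standard AP display frame.
#'
#' @inheritParams trochlear_angles
#' @return Signed degrees in (-90, 90).
#' @export
hka_deviation <- function(ann) {
  p <- need_points(ann, c("hip_center", "femoral_notch_center",
                          "tibial_spines_center", "ankle_center"),
                   "hka_deviation")
  u <- unit(p$femoral_notch_center - p$hip_center, "femoral mechanical axis")
  v <- unit(p$ankle_center - p$tibial_spines_center, "tibial mechanical axis")
  delta <- atan2(cross2(u, v), sum(u * v)) * DEG
  side_factor <- if (ann$side == "right") 1 else -1
  -side_factor * frame_orientation(ann) * delta
}

#' Mechanical lateral distal femoral angle (mLDFA)
#'
#' The lateral angle between the femoral mechanical axis and the distal
#' femoral joint line: measured between the proximally directed axis (notch to
#' hip) and the medial-to-lateral joint-line vector.
#'
#' @inheritParams trochlear_angles
#' @return Degrees in (0, 180); about 87-88 in healthy limbs.
#' @export
mldfa <- function(ann) {
  p <- need_points(ann, c("hip_center", "femoral_notch_center",
                          "condyle_medial", "condyle_lateral"), "mldfa")
  if (all(p$condyle_medial == p$condyle_lateral)) {
    km_stop("degenerate_geometry", "condyle points coincide; joint line undefined")
  }
  axis_prox <- p$hip_center - p$femoral_notch_center
  jl_lat <- p$condyle_lateral - p$condyle_medial
  angle_between(axis_prox, jl_lat)
}

#' Mechanical medial proximal tibial angle (mMPTA)
#'
#' The medial angle between the tibial mechanical axis and the tibial plateau
#' line (through `plateau_medial` / `plateau_lateral`): measured between the
#' distally directed axis (spines to ankle) and the lateral-to-medial plateau
#' vector.
#'
#' @inheritParams trochlear_angles
#' @return Degrees in (0, 180); about 87-88 in healthy limbs.
#' @export
mmpta <- function(ann) {
  p <- need_points(ann, c("tibial_spines_center", "ankle_center",
                          "plateau_medial", "plateau_lateral"), "mmpta")
  if (all(p$plateau_medial == p$plateau_lateral)) {
    km_stop("degenerate_geometry", "plateau points coincide; plateau line undefined")
  }
  axis_dist <- p$ankle_center - p$tibial_spines_center
  pl_med <- p$plateau_medial - p$plateau_lateral
  angle_between(axis_dist, pl_med)
}

#' Measure all five angles of one annotation
#'
#' @inheritParams trochlear_angles
#' @param strict If `TRUE` (default) a missing landmark raises a
#'   `kneemetry_missing_landmark` error naming it; if `FALSE`, angles whose
#'   landmarks are absent are reported as `NA`.
#' @return An [angle_set()].
#' @export
measure_all <- function(ann, strict = TRUE) {
  one <- function(fn) {
    if (strict) return(fn(ann))
    tryCatch(fn(ann), kneemetry_missing_landmark = function(e) NA_real_)
  }
  angle_set(
    hka_deviation = one(hka_deviation),
    mldfa = one(mldfa),
    mmpta = one(mmpta),
    tga = one(function(a) trochlear_angles(a)$tga),
    ba = one(bisector_angle)
  )
}
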