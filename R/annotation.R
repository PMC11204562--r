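# LandmarkAnnotation: one observer's digitised named points for one limb at
# one occasion. Points live in an arbitrary image frame; anatomy is carried by
# the landmark names plus the side field, never by coordinate signs.

#' Landmark vocabulary
#'
#' Named single-point landmarks accepted on a full-leg AP radiograph
#' annotation. `plateau_medial`/`plateau_lateral` are the tibial joint-surface
#' points used for the mMPTA plateau line; the `condyle_*` pair is the distal
#' femoral joint line. Facet contours are supplied separately as
#' `trochlear_contour_medial` / `trochlear_contour_lateral` polylines.
#'
#' @format Character vector of landmark names.
#' @export
LANDMARK_VOCABULARY <- c(
  "hip_center", "femoral_notch_center", "trochlear_apex",
  "trochlear_tangent_medial", "trochlear_tangent_lateral",
  "condyle_medial", "condyle_lateral",
  "tibial_spines_center", "ankle_center",
  "plateau_medial", "plateau_lateral"
)

#' @rdname LANDMARK_VOCABULARY
#' @export
CONTOUR_VOCABULARY <- c("trochlear_contour_medial", "trochlear_contour_lateral")

#' Construct a landmark annotation
#'
#' @param subject_id,observer_id Identifiers (coerced to character).
#' @param side `"left"` or `"right"`.
#' @param occasion Positive integer measurement occasion (1 for a single
#'   reading).
#' @param points Named list of length-2 numeric coordinates; names must come
#'   from [LANDMARK_VOCABULARY].
#' @param contours Optional named list of two-column coordinate matrices with
#'   names from `CONTOUR_VOCABULARY`.
#' @return Object of class `landmark_annotation`.
#' @export
landmark_annotation <- function(subject_id, side, observer_id = "obs1",
                                occasion = 1L, points = list(),
                                contours = list()) {
  side <- match.arg(side, c("left", "right"))
  occasion <- as.integer(occasion)
  km_assert(length(occasion) == 1L && !is.na(occasion) && occasion >= 1L,
            "invalid_annotation", "occasion must be a positive integer")
  bad <- setdiff(names(points), LANDMARK_VOCABULARY)
  if (length(bad)) {
    km_stop("vocabulary", paste0("unknown landmark name(s): ",
                                 paste(bad, collapse = ", ")))
  }
  points <- lapply(points, as_point)
  badc <- setdiff(names(contours), CONTOUR_VOCABULARY)
  if (length(badc)) {
    km_stop("vocabulary", paste0("unknown contour name(s): ",
                                 paste(badc, collapse = ", ")))
  }
  contours <- lapply(contours, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    km_assert(ncol(m) == 2L && nrow(m) >= 1L && all(is.finite(m)),
              "invalid_annotation", "contours must be finite n x 2 matrices")
    dimnames(m) <- NULL
    m
  })
  structure(
    list(subject_id = as.character(subject_id), side = side,
         observer_id = as.character(observer_id), occasion = occasion,
         points = points, contours = contours),
    class = "landmark_annotation"
  )
}

#' @export
print.landmark_annotation <- function(x, ...) {
  cat(sprintf("<landmark_annotation> subject %s (%s), observer %s, occasion %d\n",
              x$subject_id, x$side, x$observer_id, x$occasion))
  cat("  points:", paste(names(x$points), collapse = ", "), "\n")
  if (length(x$contours)) {
    cat("  contours:", paste(sprintf("%s[%d]", names(x$contours),
                                     vapply(x$contours, nrow, 1L)),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

need_points <- function(ann, names, op) {
  missing <- setdiff(names, names(ann$points))
  if (length(missing)) {
    km_stop("missing_landmark",
            sprintf("%s requires landmark(s) %s (subject %s, observer %s, occasion %d)",
                    op, paste(missing, collapse = ", "),
                    ann$subject_id, ann$observer_id, ann$occasion))
  }
  ann$points[names]
}

#' The five measured angles for one annotation
#'
#' Container for one reading of a limb: HKA expressed as signed deviation from
#' 180 degrees (negative varus, positive valgus), mLDFA, mMPTA, TGA and the
#' trochlear bisector angle BA, all in degrees.
#'
#' @param hka_deviation,mldfa,mmpta,tga,ba Angles in degrees (`NA` allowed for
#'   angles not measured).
#' @return Object of class `angle_set` (a named numeric vector).
#' @export
angle_set <- function(hka_deviation = NA_real_, mldfa = NA_real_,
                      mmpta = NA_real_, tga = NA_real_, ba = NA_real_) {
  x <- c(hka_deviation = as.numeric(hka_deviation), mldfa = as.numeric(mldfa),
         mmpta = as.numeric(mmpta), tga = as.numeric(tga), ba = as.numeric(ba))
  chk <- function(v, lo, hi, nm) {
    if (!is.na(v) && (v <= lo || v >= hi)) {
      km_stop("invalid_angle", sprintf("%s = %g out of (%g, %g)", nm, v, lo, hi))
    }
  }
  chk(x[["hka_deviation"]], -90, 90, "hka_deviation")
  for (nm in c("mldfa", "mmpta", "ba")) chk(x[[nm]], 0, 180, nm)
  # tga = 0 (coincident tangent rays) is a legal degenerate reading
  tga <- x[["tga"]]
  if (!is.na(tga) && (tga < 0 || tga >= 180)) {
    km_stop("invalid_angle", sprintf("tga = %g out of [0, 180)", tga))
  }
  structure(x, class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat("<angle_set> (degrees)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

ANGLE_NAMES <- c("hka_deviation", "mldfa", "mmpta", "tga", "ba")
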