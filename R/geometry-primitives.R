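# Pure 2D vector geometry on landmark coordinates. Angles are in degrees
# throughout the public surface; radians never leak out of a function.

DEG <- 180 / pi

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) {
    km_stop("degenerate_geometry",
            sprintf("%s must be two finite coordinates", what))
  }
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n == 0) km_stop("degenerate_geometry", sprintf("zero-length %s", what))
  v / n
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

rot2 <- function(v, theta_deg) {
  t <- theta_deg / DEG
  c(cos(t) * v[1L] - sin(t) * v[2L],
    sin(t) * v[1L] + cos(t) * v[2L])
}

# Unsigned angle in [0, 180] between two direction vectors.
angle_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  atan2(abs(cross2(u, v)), sum(u * v)) * DEG
}

#' Angle subtended at a vertex by two rays
#'
#' Computes the unsigned angle, in degrees, between the rays `apex -> p1` and
#' `apex -> p2`. This is the primitive behind the trochlear groove angle: two
#' tangent lines drawn from the apical midpoint of the intercondylar groove
#' subtend exactly this angle.
#'
#' @param apex Numeric length-2: the vertex.
#' @param p1,p2 Numeric length-2 points defining the two rays. Neither may
#'   coincide with `apex`.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_at_vertex(c(0, 0), c(1, 0), c(0, 1)) # 90
#' @export
angle_at_vertex <- function(apex, p1, p2) {
  apex <- as_point(apex, "apex")
  p1 <- as_point(p1, "p1")
  p2 <- as_point(p2, "p2")
  if (all(p1 == apex) || all(p2 == apex)) {
    km_stop("degenerate_geometry", "ray endpoint coincides with apex")
  }
  angle_between(p1 - apex, p2 - apex)
}

#' Internal angle bisector direction
#'
#' Unit vector from `apex` bisecting the internal angle between rays
#' `apex -> p1` and `apex -> p2`, computed as the normalised sum of the two
#' unit ray directions. The result makes equal angles with both rays.
#'
#' @inheritParams angle_at_vertex
#' @return Unit length-2 numeric vector.
#' @examples
#' bisector_direction(c(0, 0), c(1, 0), c(0, 1)) # c(sqrt(2)/2, sqrt(2)/2)
#' @export
bisector_direction <- function(apex, p1, p2) {
  apex <- as_point(apex, "apex")
  p1 <- as_point(p1, "p1")
  p2 <- as_point(p2, "p2")
  if (all(p1 == apex) || all(p2 == apex)) {
    km_stop("degenerate_geometry", "ray endpoint coincides with apex")
  }
  u <- unit(p1 - apex)
  v <- unit(p2 - apex)
  s <- u + v
  if (vnorm(s) < 1e-12) {
    km_stop("undefined_bisector",
            "rays are opposite (180 degrees); internal bisector undefined")
  }
  s / vnorm(s)
}

#' Supporting tangent point of a contour seen from an external apex
#'
#' Given an ordered polyline digitised along one trochlear facet, returns the
#' contour point at which the line from `apex` supports the contour: every
#' contour point lies on one closed side of the line `apex`--result. This
#' emulates drawing a tangent line from the groove apex to a facet. The
#' branch/side pair picks which of the two supporting rays (the extreme polar
#' angles about the apex) is wanted: the medial branch takes the ray that is
#' extremal toward the medial side, the lateral branch toward the lateral
#' side.
#'
#' Ties in polar angle are broken in favour of the point farther from the
#' apex (the drawn tangent line touches the outermost such point).
#'
#' @param apex Numeric length-2 external point.
#' @param contour Two-column numeric matrix (or list of length-2 points), at
#'   least one point; must not contain `apex` in its convex hull.
#' @param branch `"medial"` or `"lateral"`: which facet tangent is requested.
#' @param side `"left"` or `"right"` limb; with `branch`, fixes which extreme
#'   supporting ray is the answer via the medial direction hint.
#' @param medial_hint Optional length-2 vector pointing medially in the image
#'   frame (e.g. `condyle_medial - condyle_lateral`). When supplied it
#'   resolves medial/lateral directly and `side` is ignored.
#' @return The selected contour point (length-2 numeric).
#' @export
tangent_from_point <- function(apex, contour, branch = c("medial", "lateral"),
                               side = c("right", "left"), medial_hint = NULL) {
  branch <- match.arg(branch)
  side <- match.arg(side)
  apex <- as_point(apex, "apex")
  if (is.list(contour)) contour <- do.call(rbind, lapply(contour, as_point))
  contour <- as.matrix(contour)
  if (nrow(contour) < 1L) km_stop("empty_input", "contour has no points")
  storage.mode(contour) <- "double"
  if (!all(is.finite(contour))) {
    km_stop("degenerate_geometry", "contour has non-finite coordinates")
  }
  if (nrow(contour) == 1L) return(contour[1L, ])

  d <- sweep(contour, 2L, apex)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) km_stop("no_tangent", "apex lies on the contour")

  # Reference direction: apex -> contour centroid; all visible points of a
  # convex-ish contour subtend polar angles within (-180, 180) of it.
  ctr <- colMeans(contour)
  ref <- ctr - apex
  if (vnorm(ref) < 1e-12) km_stop("no_tangent", "apex coincides with contour centroid")
  ref <- unit(ref)
  ang <- atan2(d[, 2L] / r * ref[1L] - d[, 1L] / r * ref[2L],   # cross(ref, dir)
               (d[, 1L] * ref[1L] + d[, 2L] * ref[2L]) / r) * DEG
  if (max(ang) - min(ang) >= 180 - 1e-9) {
    km_stop("no_tangent",
            "apex lies inside or on the convex hull of the contour")
  }

  # Which rotational sense is 'medial'? Positive ang is counter-clockwise of
  # the reference ray. Use the medial hint if given, else assume the standard
  # AP display frame (y proximal; medial = +x for a right limb).
  if (is.null(medial_hint)) {
    medial_hint <- if (side == "right") c(1, 0) else c(-1, 0)
  }
  medial_is_ccw <- cross2(ref, unit(medial_hint)) > 0
  want_max <- (branch == "medial") == medial_is_ccw

  key <- if (want_max) ang else -ang
  top <- which(key > max(key) - 1e-9)
  if (length(top) > 1L) top <- top[which.max(r[top])]  # tie: farthest from apex
  contour[top, ]
}
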