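# Shared fixture builders and independent oracles.

# random feasible true-angle set around the healthy-population means
random_true_angles <- function() {
  angle_set(
    hka_deviation = runif(1, -12, 12),
    mldfa = runif(1, 82, 94),
    mmpta = runif(1, 82, 94),
    tga = runif(1, 100, 165),
    ba = runif(1, 84, 96)
  )
}

# apply a rigid motion / scaling / mirror to every coordinate of an annotation
transform_annotation <- function(ann, rotate = 0, translate = c(0, 0),
                                 scale = 1, mirror_x = FALSE, flip_side = FALSE) {
  f <- function(p) {
    if (mirror_x) p[1L] <- -p[1L]
    t <- rotate * pi / 180
    p <- scale * c(cos(t) * p[1L] - sin(t) * p[2L],
                   sin(t) * p[1L] + cos(t) * p[2L])
    p + translate
  }
  pts <- lapply(ann$points, f)
  ctrs <- lapply(ann$contours, function(m) t(apply(m, 1L, f)))
  side <- ann$side
  if (flip_side) side <- if (side == "left") "right" else "left"
  landmark_annotation(ann$subject_id, side, ann$observer_id, ann$occasion,
                      points = pts, contours = ctrs)
}

# independent signed-difference-of-atan2 oracle for the vertex angle
atan2_angle_oracle <- function(apex, p1, p2) {
  a1 <- atan2(p1[2] - apex[2], p1[1] - apex[1])
  a2 <- atan2(p2[2] - apex[2], p2[1] - apex[1])
  d <- abs(a1 - a2) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi
}

# brute-force sums-of-squares oracle via stats::aov on the long table
aov_mean_squares <- function(v) {
  n <- dim(v)[1]; m <- dim(v)[2]; r <- dim(v)[3]
  long <- expand.grid(i = factor(seq_len(n)), j = factor(seq_len(m)),
                      k = seq_len(r))
  long$y <- v[cbind(as.integer(long$i), as.integer(long$j), long$k)]
  get_ms <- function(sm, term) sm[match(term, trimws(rownames(sm))), "Mean Sq"]
  if (r == 1) {
    sm <- summary(stats::aov(y ~ i + j, data = long))[[1]]
    list(ms_rows = get_ms(sm, "i"), ms_cols = get_ms(sm, "j"),
         ms_error = get_ms(sm, "Residuals"))
  } else {
    sm <- summary(stats::aov(y ~ i * j, data = long))[[1]]
    list(ms_rows = get_ms(sm, "i"), ms_cols = get_ms(sm, "j"),
         ms_interaction = get_ms(sm, "i:j"),
         ms_error = get_ms(sm, "Residuals"))
  }
}

expect_angle_equal <- function(object, expected, tol = 1e-9) {
  expect_lt(abs(object - expected), tol)
}
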