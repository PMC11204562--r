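# Synthetic cohorts for validating the geometry and agreement machinery
# without radiographs. Two levels: angle-level tables drawn straight from the
# two-way random-effects model, and landmark-level limbs whose digitisation is
# perturbed per observer so measurement error arises mechanistically.

#' Population configuration
#'
#' Between-subject distributions of the five angles in a healthy adult cohort.
#' Defaults follow the reference population: HKA deviation 0 (SD 2.48), mLDFA
#' 87.6 (SD 1.88), mMPTA 88 (SD 2.2), BA 89.4. The BA between-subject SD is
#' not reported at subject level anywhere; 1.1 deg (within the observed
#' per-observer SD range) is the package default. TGA mean/SD are free
#' parameters of the stylised trochlea.
#'
#' @param n_subjects Number of limbs to simulate.
#' @param bilateral_fraction Fraction of patients contributing both limbs
#'   (metadata only; limbs are treated as independent).
#' @param means,sds Named numeric vectors over
#'   `c("hka_deviation","mldfa","mmpta","tga","ba")`; partial vectors override
#'   the defaults.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_subjects = 110L, bilateral_fraction = 51 / 59,
                              means = NULL, sds = NULL) {
  mu <- c(hka_deviation = 0, mldfa = 87.6, mmpta = 88, tga = 140, ba = 89.4)
  sg <- c(hka_deviation = 2.48, mldfa = 1.88, mmpta = 2.2, tga = 4, ba = 1.1)
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sg[names(sds)] <- sds
  km_assert(all(sg >= 0), "invalid_config", "angle SDs must be >= 0")
  km_assert(n_subjects >= 1, "invalid_config", "n_subjects must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 bilateral_fraction = bilateral_fraction,
                 means = mu, sds = sg),
            class = "population_config")
}

#' Observer/measurement-error configuration
#'
#' Crossed measurement design and its error magnitudes: `sigma_observer` is
#' the between-observer SD (degrees at angle level; a systematic landmark
#' offset at landmark level), `sigma_interaction` the subject-by-observer
#' interaction SD, `sigma_residual` the within-cell SD, and
#' `landmark_jitter_sd` the isotropic per-landmark digitisation jitter (same
#' length unit as the anatomy, mm by default).
#'
#' @param m_observers,r_occasions Design dimensions.
#' @param sigma_observer,sigma_interaction,sigma_residual Degrees (>= 0).
#'   `sigma_residual` may be a vector of length `m_observers` to give each
#'   observer their own within-cell SD (angle-level simulation only).
#' @param landmark_jitter_sd Length units (>= 0).
#' @param observer_bias_sd Length units: SD of each observer's fixed
#'   per-landmark bias vector (landmark-level simulation).
#' @param seed Integer seed; mandatory for every stochastic call.
#' @return Object of class `observer_config`.
#' @export
observer_config <- function(m_observers = 3L, r_occasions = 1L,
                            sigma_observer = 0.15, sigma_interaction = 0,
                            sigma_residual = 0.65,
                            landmark_jitter_sd = 0.33, observer_bias_sd = 0.3,
                            seed = NULL) {
  sds <- c(sigma_observer, sigma_interaction, sigma_residual,
           landmark_jitter_sd, observer_bias_sd)
  km_assert(all(sds >= 0), "invalid_config", "all SDs must be >= 0")
  structure(list(m_observers = as.integer(m_observers),
                 r_occasions = as.integer(r_occasions),
                 sigma_observer = sigma_observer,
                 sigma_interaction = sigma_interaction,
                 sigma_residual = sigma_residual,
                 landmark_jitter_sd = landmark_jitter_sd,
                 observer_bias_sd = observer_bias_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "observer_config")
}

#' Stylised limb template dimensions
#'
#' Length parameters (mm) of the synthetic limb used by
#' [build_subject_geometry()]. Defaults approximate an adult lower limb on a
#' full-leg radiograph.
#'
#' @param femur_length,tibia_length Mechanical axis lengths (mm).
#' @param condylar_width Distal femoral joint line width (mm).
#' @param notch_depth Distance from the groove apex down to the joint line
#'   (mm).
#' @param facet_arc_radius Radius of the circular facet arcs used when
#'   contours are emitted (mm).
#' @param contour_points Samples per facet contour (>= 3).
#' @return Object of class `anatomy_config`.
#' @export
anatomy_config <- function(femur_length = 430, tibia_length = 370,
                           condylar_width = 80, notch_depth = 25,
                           facet_arc_radius = 30, contour_points = 25L) {
  km_assert(all(c(femur_length, tibia_length, condylar_width, notch_depth,
                  facet_arc_radius) > 0), "invalid_config",
            "anatomy lengths must be positive")
  km_assert(contour_points >= 3L, "invalid_config",
            "need >= 3 contour points per facet")
  structure(list(femur_length = femur_length, tibia_length = tibia_length,
                 condylar_width = condylar_width, notch_depth = notch_depth,
                 facet_arc_radius = facet_arc_radius,
                 contour_points = as.integer(contour_points)),
            class = "anatomy_config")
}

check_seed <- function(obs) {
  km_assert(!is.null(obs$seed), "invalid_config",
            "observer_config$seed is mandatory for stochastic simulation")
  obs$seed
}

#' Simulate a crossed angle measurement table
#'
#' Draws `y_ijk = mu + a_i + b_j + ab_ij + e_ijk` with independent zero-mean
#' normal components: `a_i ~ N(0, sd_angle^2)` between subjects, `b_j` between
#' observers (`sigma_observer`), `ab_ij` interaction (`sigma_interaction`),
#' `e_ijk` residual (`sigma_residual`).
#'
#' @param pop A [population_config()].
#' @param obs An [observer_config()] with a seed.
#' @param angle_name Which angle's population mean/SD to use.
#' @param observer_means Optional numeric vector of length `m_observers`
#'   giving each observer's own expected value (overrides `mu + b_j`; the
#'   between-observer draw is then skipped). Used for calibration to known
#'   per-observer summaries.
#' @param subject_sd Optional override of the between-subject SD.
#' @return A [measurement_table()].
#' @export
simulate_angle_table <- function(pop, obs, angle_name = "ba",
                                 observer_means = NULL, subject_sd = NULL) {
  seed <- check_seed(obs)
  n <- pop$n_subjects; m <- obs$m_observers; r <- obs$r_occasions
  mu <- pop$means[[angle_name]]
  sa <- if (is.null(subject_sd)) pop$sds[[angle_name]] else subject_sd
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    expr
  }
  v <- withr_seed({
    a <- stats::rnorm(n, 0, sa)
    b <- if (is.null(observer_means)) stats::rnorm(m, 0, obs$sigma_observer) else
      observer_means - mu
    ab <- matrix(stats::rnorm(n * m, 0, obs$sigma_interaction), n, m)
    sd_e <- rep(rep(obs$sigma_residual, length.out = m), each = n)
    e <- array(stats::rnorm(n * m * r, 0, sd_e), c(n, m, r))
    # the n x m matrix of subject/observer/interaction effects recycles over
    # the occasion slices
    mu + array(outer(a, rep(1, m)) + outer(rep(1, n), b) + ab, c(n, m, r)) + e
  })
  dimnames(v) <- list(paste0("S", seq_len(n)), paste0("obs", seq_len(m)),
                      seq_len(r))
  measurement_table(v, angle_name)
}

#' Construct a noise-free synthetic limb realizing given true angles
#'
#' Inverts the five angle definitions: lays out landmarks in a canonical frame
#' (+y proximal, +x medial for a right limb; left limbs are mirrored) such
#' that [measure_all()] returns exactly the requested angles. The trochlear
#' facets can additionally be emitted as circular-arc contours whose apex
#' tangents touch precisely at the stored tangent points.
#'
#' @param true_angles An [angle_set()] with all five angles present.
#' @param anatomy An [anatomy_config()].
#' @param side `"left"` or `"right"`.
#' @param subject_id,observer_id,occasion Annotation identity fields.
#' @param include_contours Emit facet arc contours (default `FALSE`).
#' @return A [landmark_annotation()].
#' @export
build_subject_geometry <- function(true_angles, anatomy = anatomy_config(),
                                   side = "right", subject_id = "synthetic",
                                   observer_id = "truth", occasion = 1L,
                                   include_contours = FALSE) {
  th <- unclass(true_angles)
  if (anyNA(th)) {
    km_stop("construction", "all five true angles must be given")
  }
  if (th[["tga"]] <= 0 || th[["tga"]] >= 180) {
    km_stop("construction", "tga must be in (0, 180) for a constructible groove")
  }
  for (nm in c("mldfa", "mmpta", "ba")) {
    if (th[[nm]] <= 0 || th[[nm]] >= 180) {
      km_stop("construction", sprintf("%s must be in (0, 180)", nm))
    }
  }
  if (abs(th[["hka_deviation"]]) >= 90) {
    km_stop("construction", "hka_deviation must be in (-90, 90)")
  }

  Lf <- anatomy$femur_length; Lt <- anatomy$tibia_length
  w <- anatomy$condylar_width / 2; nd <- anatomy$notch_depth

  notch <- c(0, 0)
  hip <- c(0, Lf)

  # distal femoral joint line: lateral direction tilted so the lateral angle
  # with the proximal mechanical axis is mldfa
  t_f <- 90 - th[["mldfa"]]
  l_dir <- c(-cos(t_f / DEG), sin(t_f / DEG))
  jc <- c(0, -nd)
  condyle_lateral <- jc + w * l_dir
  condyle_medial <- jc - w * l_dir
  jm_u <- -l_dir                         # lateral -> medial unit vector

  # trochlear bisector: rotate the joint line by +ba so values < 90 lean the
  # proximal tip medially
  tgb_proximal <- rot2(jm_u, th[["ba"]])
  apex <- notch
  b_dist <- -tgb_proximal
  half <- th[["tga"]] / 2
  ray_med <- rot2(b_dist, half)
  ray_lat <- rot2(b_dist, -half)
  tl <- 1.3 * nd
  tangent_medial <- apex + tl * ray_med
  tangent_lateral <- apex + tl * ray_lat

  # tibia: distal axis rotated from the femoral axis prolongation by -hka
  spines <- c(0, -nd - 8)
  v_dist <- rot2(c(0, -1), -th[["hka_deviation"]])
  ankle <- spines + Lt * v_dist
  q_med <- rot2(v_dist, th[["mmpta"]])
  wt <- 0.95 * w
  plateau_medial <- spines + wt * q_med
  plateau_lateral <- spines - wt * q_med

  pts <- list(hip_center = hip, femoral_notch_center = notch,
              trochlear_apex = apex,
              trochlear_tangent_medial = tangent_medial,
              trochlear_tangent_lateral = tangent_lateral,
              condyle_medial = condyle_medial, condyle_lateral = condyle_lateral,
              tibial_spines_center = spines, ankle_center = ankle,
              plateau_medial = plateau_medial, plateau_lateral = plateau_lateral)

  contours <- list()
  if (include_contours) {
    arc <- function(contact, ray, sgn) {
      R <- anatomy$facet_arc_radius
      nhat <- rot2(ray, sgn * -90)       # interior-side normal (dot > 0 with b_dist)
      ctr <- contact + R * nhat
      ts <- seq(-15, 55, length.out = anatomy$contour_points)
      t(vapply(ts, function(t) ctr + rot2(contact - ctr, sgn * t),
               numeric(2)))
    }
    contours <- list(
      trochlear_contour_medial = arc(tangent_medial, ray_med, +1),
      trochlear_contour_lateral = arc(tangent_lateral, ray_lat, -1)
    )
  }

  if (side == "left") {
    pts <- lapply(pts, function(p) c(-p[1L], p[2L]))
    contours <- lapply(contours, function(m) {
      m[, 1L] <- -m[, 1L]; m
    })
  }
  landmark_annotation(subject_id, side, observer_id, occasion,
                      points = pts, contours = contours)
}

#' Simulate a digitised cohort of synthetic limbs
#'
#' Per limb: draw true angles from the population, build the noise-free
#' geometry, then for each observer and occasion perturb every point landmark
#' by the observer's fixed bias vector (drawn once per observer and landmark,
#' SD `observer_bias_sd`) plus independent isotropic jitter
#' (`landmark_jitter_sd`). Limb laterality follows the cohort table when
#' given, else alternates.
#'
#' @param pop A [population_config()]; `n_subjects` is the number of limbs.
#' @param obs An [observer_config()] with a seed.
#' @param anatomy An [anatomy_config()].
#' @param cohort Optional data.frame with columns `subject_id`, `side` (one
#'   row per limb), e.g. from [cohort_limbs()]; overrides `pop$n_subjects`.
#' @param include_contours Emit facet contours on each annotation.
#' @return List with `annotations` (list of [landmark_annotation()]: truth is
#'   excluded), `truth` (data.frame of true angles per limb), and `cohort`.
#' @export
simulate_annotations <- function(pop, obs, anatomy = anatomy_config(),
                                 cohort = NULL, include_contours = FALSE) {
  seed <- check_seed(obs)
  if (is.null(cohort)) {
    n <- pop$n_subjects
    cohort <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      side = rep(c("right", "left"), length.out = n),
      stringsAsFactors = FALSE
    )
  }
  n <- nrow(cohort)
  m <- obs$m_observers; r <- obs$r_occasions
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  draw <- function(nm) stats::rnorm(n, pop$means[[nm]], pop$sds[[nm]])
  truth <- data.frame(subject_id = cohort$subject_id, side = cohort$side,
                      hka_deviation = draw("hka_deviation"),
                      mldfa = draw("mldfa"), mmpta = draw("mmpta"),
                      tga = draw("tga"), ba = draw("ba"),
                      stringsAsFactors = FALSE)

  lm_names <- LANDMARK_VOCABULARY
  biases <- lapply(seq_len(m), function(j) {
    b <- matrix(stats::rnorm(2L * length(lm_names), 0, obs$observer_bias_sd),
                ncol = 2L)
    rownames(b) <- lm_names
    b
  })

  annotations <- vector("list", n * m * r)
  idx <- 1L
  for (i in seq_len(n)) {
    th <- angle_set(truth$hka_deviation[i], truth$mldfa[i], truth$mmpta[i],
                    truth$tga[i], truth$ba[i])
    base <- build_subject_geometry(th, anatomy, side = cohort$side[i],
                                   subject_id = cohort$subject_id[i],
                                   include_contours = include_contours)
    for (j in seq_len(m)) {
      for (k in seq_len(r)) {
        pts <- base$points
        for (nm in names(pts)) {
          pts[[nm]] <- pts[[nm]] + biases[[j]][nm, ] +
            stats::rnorm(2L, 0, obs$landmark_jitter_sd)
        }
        ctrs <- base$contours
        if (length(ctrs) && obs$landmark_jitter_sd > 0) {
          ctrs <- lapply(ctrs, function(mm) {
            mm + matrix(stats::rnorm(length(mm), 0, obs$landmark_jitter_sd),
                        nrow = nrow(mm))
          })
        }
        annotations[[idx]] <- landmark_annotation(
          cohort$subject_id[i], cohort$side[i],
          observer_id = sprintf("obs%d", j), occasion = k,
          points = pts, contours = ctrs)
        idx <- idx + 1L
      }
    }
  }
  list(annotations = annotations, truth = truth, cohort = cohort,
       seed = seed)
}

#' Cohort laterality table
#'
#' Expands a patient-level cohort into one row per limb: `n_bilateral`
#' patients contribute both limbs, the rest one limb each.
#'
#' @param n_patients Number of patients.
#' @param n_bilateral Number of patients imaged bilaterally
#'   (`<= n_patients`).
#' @return data.frame with columns `subject_id` (limb id), `patient_id`,
#'   `side`.
#' @export
cohort_limbs <- function(n_patients = 59L, n_bilateral = 51L) {
  km_assert(n_bilateral <= n_patients, "invalid_config",
            "n_bilateral cannot exceed n_patients")
  rows <- list()
  for (p in seq_len(n_patients)) {
    sides <- if (p <= n_bilateral) c("right", "left") else
      if (p %% 2L == 0L) "left" else "right"
    for (s in sides) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("P%03d_%s", p, s), patient_id = sprintf("P%03d", p),
        side = s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
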