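# Reliability statistics for a fully crossed subjects x observers
# (x occasions) measurement design: two-way random-effects ANOVA mean
# squares, method-of-moments variance components, absolute-agreement ICC with
# F-based confidence intervals, limits of agreement with the mean (LOAM) for
# multiple observers, extended Bland-Altman plot data, and the 1986
# Bland-Altman repeatability coefficient.

#' Crossed measurement table
#'
#' A complete subjects x observers x occasions array of one angle. Intra-rater
#' data (one observer, several occasions) is stored with `m = 1` and `r >= 2`
#' and, for the two-way machinery, re-dimensioned with occasions in the
#' observer slot (see [mean_squares()]).
#'
#' @param values Numeric array `n x m x r`, or an `n x m` matrix (then
#'   `r = 1`). Dimnames, if any, label subjects / observers / occasions.
#' @param angle_name Identifier of the measured quantity (e.g. `"ba"`).
#' @return Object of class `measurement_table`.
#' @export
measurement_table <- function(values, angle_name = "ba") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L),
                                         dimnames = c(dimnames(values), list(NULL)))
  km_assert(is.array(values) && length(dim(values)) == 3L, "incomplete_design",
            "values must be an n x m x r array or n x m matrix")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    km_stop("incomplete_design",
            sprintf("missing/non-finite cell at subject %d, observer %d, occasion %d",
                    bad[1L], bad[2L], bad[3L]))
  }
  km_assert(d[1L] >= 2L, "incomplete_design", "need at least 2 subjects")
  km_assert(d[2L] >= 2L || d[3L] >= 2L, "incomplete_design",
            "need at least 2 observers, or 1 observer with >= 2 occasions")
  structure(list(values = values, angle_name = as.character(angle_name)),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<measurement_table> %s: %d subjects x %d observers x %d occasions\n",
              x$angle_name, d[1L], d[2L], d[3L]))
  invisible(x)
}

table_dims <- function(table) {
  d <- dim(table$values)
  list(n = d[1L], m = d[2L], r = d[3L])
}

# Intra-rater tables (m = 1, r > 1) are fed through the two-way machinery
# with occasions playing the observer role.
effective_values <- function(table) {
  v <- table$values
  d <- dim(v)
  if (d[2L] == 1L && d[3L] > 1L) v <- array(v[, 1L, ], c(d[1L], d[3L], 1L))
  v
}

#' Two-way crossed ANOVA mean squares
#'
#' Mean squares of the two-way crossed random-effects design
#' `y_ijk = mu + subject_i + observer_j + interaction_ij + error_ijk`.
#' With a single occasion (`r = 1`) the interaction and error strata are not
#' separable and merge into one residual mean square (returned as `ms_error`
#' with `ms_interaction = NA`). A table with `m = 1, r > 1` is analysed with
#' occasions in the observer slot.
#'
#' @param table A [measurement_table()].
#' @return List `ms_rows`, `ms_cols`, `ms_interaction`, `ms_error`, and `dof`
#'   (named degrees-of-freedom vector), plus the effective `n`, `m`, `r`.
#' @export
mean_squares <- function(table) {
  v <- effective_values(table)
  n <- dim(v)[1L]; m <- dim(v)[2L]; r <- dim(v)[3L]
  km_assert(m >= 2L, "incomplete_design", "need >= 2 columns in the crossed design")
  gm <- mean(v)
  row_means <- apply(v, 1L, mean)
  col_means <- apply(v, 2L, mean)
  cell_means <- apply(v, c(1L, 2L), mean)

  ss_rows <- m * r * sum((row_means - gm)^2)
  ss_cols <- n * r * sum((col_means - gm)^2)
  ss_int <- r * sum((cell_means - outer(row_means, rep(1, m)) -
                       outer(rep(1, n), col_means) + gm)^2)
  df_rows <- n - 1L
  df_cols <- m - 1L
  df_int <- (n - 1L) * (m - 1L)

  if (r == 1L) {
    ms <- list(
      ms_rows = ss_rows / df_rows,
      ms_cols = ss_cols / df_cols,
      ms_interaction = NA_real_,
      ms_error = ss_int / df_int,
      dof = c(rows = df_rows, cols = df_cols, interaction = NA_integer_,
              error = df_int)
    )
  } else {
    ss_err <- sum(sweep(v, c(1L, 2L), cell_means)^2)
    df_err <- n * m * (r - 1L)
    ms <- list(
      ms_rows = ss_rows / df_rows,
      ms_cols = ss_cols / df_cols,
      ms_interaction = ss_int / df_int,
      ms_error = ss_err / df_err,
      dof = c(rows = df_rows, cols = df_cols, interaction = df_int,
              error = df_err)
    )
  }
  c(ms, list(n = n, m = m, r = r))
}

#' Method-of-moments variance components
#'
#' Equates the two-way crossed mean squares to their expectations. With
#' `r = 1`: `sigma2_residual = MSE`, `sigma2_observer = (MSC - MSE) / n`,
#' `sigma2_subject = (MSR - MSE) / m`, and the interaction component is not
#' estimable (reported as 0 with `NA` raw value). With `r > 1` the interaction
#' mean square separates: `sigma2_interaction = (MSI - MSE) / r`,
#' `sigma2_observer = (MSC - MSI) / (n r)`, `sigma2_subject = (MSR - MSI) /
#' (m r)`. Negative moment estimates are truncated to zero; the raw values are
#' kept in the `raw` field.
#'
#' @param ms Output of [mean_squares()] (or a compatible list).
#' @param n,m,r Design dimensions; default to those recorded in `ms`.
#' @return Object of class `variance_components` with fields `sigma2_subject`,
#'   `sigma2_observer`, `sigma2_interaction`, `sigma2_residual`, and `raw`.
#' @export
variance_components <- function(ms, n = ms$n, m = ms$m, r = ms$r) {
  if (r == 1L) {
    raw <- c(subject = (ms$ms_rows - ms$ms_error) / m,
             observer = (ms$ms_cols - ms$ms_error) / n,
             interaction = NA_real_,
             residual = ms$ms_error)
  } else {
    raw <- c(subject = (ms$ms_rows - ms$ms_interaction) / (m * r),
             observer = (ms$ms_cols - ms$ms_interaction) / (n * r),
             interaction = (ms$ms_interaction - ms$ms_error) / r,
             residual = ms$ms_error)
  }
  trunc0 <- function(x) if (is.na(x)) 0 else max(0, x)
  structure(
    list(sigma2_subject = trunc0(raw[["subject"]]),
         sigma2_observer = trunc0(raw[["observer"]]),
         sigma2_interaction = trunc0(raw[["interaction"]]),
         sigma2_residual = max(0, raw[["residual"]]),
         raw = raw, n = n, m = m, r = r),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> (deg^2)\n")
  print(round(c(subject = x$sigma2_subject, observer = x$sigma2_observer,
                interaction = x$sigma2_interaction,
                residual = x$sigma2_residual), 6))
  invisible(x)
}

#' Absolute-agreement intraclass correlation (two-way random effects)
#'
#' ICC(A,1) (single measurement) and ICC(A,k) (average over the k observers)
#' of the two-way random-effects model, with F-based confidence intervals
#' using Satterthwaite degrees of freedom. Tables with `r > 1` are collapsed
#' to subject x observer occasion means first; intra-rater tables (`m = 1`)
#' put occasions in the observer slot.
#'
#' @param table A [measurement_table()].
#' @param form `"average"` (default; multiple raters are averaged) or
#'   `"single"`.
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return Object of class `icc_result`: `form`, `estimate`, `ci_low`,
#'   `ci_high`, `alpha`, `k`, `n`.
#' @export
icc_absolute <- function(table, form = c("average", "single"), alpha = 0.05) {
  form <- match.arg(form)
  v <- effective_values(table)
  if (dim(v)[3L] > 1L) v <- array(apply(v, c(1L, 2L), mean), c(dim(v)[1:2], 1L))
  ms <- mean_squares(measurement_table(v[, , 1L], table$angle_name))
  n <- ms$n; k <- ms$m
  msr <- ms$ms_rows; msc <- ms$ms_cols; mse <- ms$ms_error

  denom1 <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom1 <= 0 || (msr <= 0 && msc <= 0 && mse <= 0)) {
    km_stop("undefined_icc",
            "total variance is zero; ICC undefined for a constant table")
  }
  est1 <- (msr - mse) / denom1

  # Satterthwaite df for the weighted denominator mean square (McGraw & Wong).
  a <- (k * est1) / (n * (1 - est1))
  b <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
  vnum <- (a * msc + b * mse)^2
  vden <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  # degenerate strata (mse = 0 or est1 = 1) make the Satterthwaite ratio
  # 0/0; any finite df then yields the same closed-form bounds
  vdf <- if (is.finite(vnum) && is.finite(vden) && vden > 0) vnum / vden else n - 1
  f1 <- stats::qf(1 - alpha / 2, n - 1, vdf)
  f2 <- stats::qf(1 - alpha / 2, vdf, n - 1)
  low1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)

  sb <- function(x) k * x / (1 + (k - 1) * x)  # Spearman-Brown step-up
  if (form == "single") {
    est <- est1; lo <- low1; hi <- up1
  } else {
    denomk <- msr + (msc - mse) / n
    est <- if (denomk != 0) (msr - mse) / denomk else sb(est1)
    lo <- sb(low1); hi <- sb(up1)
  }
  lo <- min(lo, est); hi <- max(hi, est)
  structure(list(form = form, estimate = est, ci_low = lo, ci_high = hi,
                 alpha = alpha, k = k, n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%s) = %.3f (%d%% CI %.3f-%.3f), n = %d, k = %d\n",
              if (x$form == "single") "1" else "k", x$estimate,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

# Variance of one measurement's deviation from its subject mean under the
# two-way model: Var(y_ijk - ybar_i..).
loam_variance <- function(comp, m, r) {
  (1 - 1 / m) * (comp$sigma2_observer + comp$sigma2_interaction) +
    (1 - 1 / (m * r)) * comp$sigma2_residual
}

#' Limits of agreement with the mean (LOAM)
#'
#' How far an individual observer's measurement may deviate from the mean of
#' all observers for the same subject, generalising Bland-Altman limits to
#' more than two raters. For `r = 1` occasions the half-width is
#' `z * sqrt(((m - 1) / m) * (sigma2_observer + sigma2_residual))`; with
#' replicates the interaction component joins the observer variance and the
#' residual term becomes `(1 - 1/(m r)) * sigma2_residual`.
#'
#' @param table A [measurement_table()] with at least two observers (an
#'   intra-rater table with `m = 1, r >= 2` is treated with occasions as the
#'   rater slot).
#' @param z Normal quantile multiplier; 1.96 for 95% limits.
#' @return List `halfwidth` (degrees) and `components`
#'   (a [variance_components()] object).
#' @export
loam <- function(table, z = 1.96) {
  d <- table_dims(table)
  if (d$m == 1L && d$r == 1L) {
    km_stop("loam_undefined", "LOAM needs multiple observers or occasions")
  }
  ms <- mean_squares(table)
  comp <- variance_components(ms)
  halfwidth <- z * sqrt(loam_variance(comp, ms$m, ms$r))
  list(halfwidth = halfwidth, components = comp)
}

#' Extended Bland-Altman plot data
#'
#' One point per measurement: the subject's overall mean on the x-axis and
#' the measurement's difference from that mean on the y-axis, labelled by
#' observer, together with the horizontal reference lines at zero and at the
#' LOAM limits.
#'
#' @inheritParams loam
#' @return List with `points` (data.frame `subject`, `observer`, `occasion`,
#'   `subject_mean`, `difference`) and `lines` (named vector: `center`,
#'   `lower`, `upper`).
#' @export
extended_ba_plot_data <- function(table, z = 1.96) {
  v <- effective_values(table)
  n <- dim(v)[1L]; m <- dim(v)[2L]; r <- dim(v)[3L]
  subj <- dimnames(table$values)[[1L]]
  if (is.null(subj)) subj <- as.character(seq_len(n))
  obs <- dimnames(table$values)[[2L]]
  d0 <- table_dims(table)
  intra <- d0$m == 1L && d0$r > 1L
  if (is.null(obs)) obs <- as.character(seq_len(d0$m))
  subject_means <- apply(v, 1L, mean)
  idx <- expand.grid(i = seq_len(n), j = seq_len(m), k = seq_len(r))
  pts <- data.frame(
    subject = subj[idx$i],
    observer = if (intra) obs[1L] else obs[idx$j],
    occasion = if (intra) idx$j else idx$k,
    subject_mean = subject_means[idx$i],
    difference = v[as.matrix(idx)] - subject_means[idx$i],
    stringsAsFactors = FALSE
  )
  hw <- loam(table, z = z)$halfwidth
  list(points = pts, lines = c(center = 0, lower = -hw, upper = hw))
}

#' Bland-Altman (1986) repeatability coefficient
#'
#' For repeated measurements by one observer: `RC = z * sqrt(2) * s_w`, where
#' `s_w^2` is the pooled within-subject variance across occasions (the
#' one-way ANOVA residual). At 95% probability the difference between two
#' repeated measurements of the same subject is expected to stay below RC.
#' Because the within/between phrasing is ambiguous in parts of the applied
#' literature, the analogous between-subject spread statistic
#' `z * sqrt(2) * s_b` (with `s_b` the SD of subject means) is also returned.
#'
#' @param table A [measurement_table()] with one observer and `r >= 2`
#'   occasions (or any table whose replicate slot should be pooled; `m` and
#'   `r` are collapsed into replicates per subject).
#' @param z Normal multiplier, default 1.96.
#' @return List `rc` (within-subject form, degrees), `rc_between`, `s_w`,
#'   `s_b`.
#' @export
repeatability_coefficient <- function(table, z = 1.96) {
  v <- table$values
  reps <- matrix(v, nrow = dim(v)[1L])  # subjects x (m*r) replicates
  if (ncol(reps) < 2L) {
    km_stop("insufficient_replicates",
            "repeatability needs >= 2 measurements per subject")
  }
  subject_means <- rowMeans(reps)
  sw2 <- sum((reps - subject_means)^2) / (nrow(reps) * (ncol(reps) - 1L))
  sb <- stats::sd(subject_means)
  list(rc = z * sqrt(2) * sqrt(sw2),
       rc_between = z * sqrt(2) * sb,
       s_w = sqrt(sw2), s_b = sb)
}

#' Full agreement report for one measurement table
#'
#' Aggregates everything the reliability analysis of a crossed measurement
#' study needs: per-observer mean/SD summaries, LOAM, both ICC forms with
#' confidence intervals, the repeatability coefficient (when replicates
#' exist), extended Bland-Altman plot data, variance components and run
#' metadata.
#'
#' @inheritParams loam
#' @param alpha ICC confidence level is `1 - alpha`.
#' @param seed Optional integer recorded in the metadata (the report itself is
#'   deterministic).
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(table, z = 1.96, alpha = 0.05, seed = NULL) {
  d <- table_dims(table)
  v <- effective_values(table)
  obs_names <- dimnames(table$values)[[2L]]
  if (is.null(obs_names)) obs_names <- paste0("obs", seq_len(d$m))
  intra <- d$m == 1L && d$r > 1L
  col_lab <- if (intra) paste0(obs_names[1L], "_time", seq_len(d$r)) else obs_names
  per_observer <- data.frame(
    observer = col_lab,
    mean = apply(v, 2L, mean),
    sd = apply(v, 2L, function(x) stats::sd(as.vector(x))),
    stringsAsFactors = FALSE
  )

  constant <- stats::sd(as.vector(table$values)) == 0
  icc_avg <- icc_sng <- NULL
  if (!constant) {
    icc_avg <- icc_absolute(table, "average", alpha)
    icc_sng <- icc_absolute(table, "single", alpha)
  }
  lo <- loam(table, z = z)
  plot_data <- extended_ba_plot_data(table, z = z)
  rc <- if (d$m == 1L && d$r >= 2L) repeatability_coefficient(table, z = z) else NULL

  structure(
    list(angle_name = table$angle_name,
         per_observer_summary = per_observer,
         loam_halfwidth = lo$halfwidth,
         components = lo$components,
         icc_average = icc_avg, icc_single = icc_sng,
         undefined_icc = constant,
         rc = rc,
         ba_plot = plot_data,
         meta = list(n = d$n, m = d$m, r = d$r, z = z, alpha = alpha,
                     seed = seed, intra = intra,
                     package_version = as.character(utils::packageVersion("kneemetry")))),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<agreement_report> %s: %d subjects x %d observers x %d occasions%s\n",
              x$angle_name, m$n, m$m, m$r,
              if (isTRUE(m$intra)) " (intra-rater)" else ""))
  po <- x$per_observer_summary
  for (i in seq_len(nrow(po))) {
    cat(sprintf("  %s: %.1f (SD %.2f)\n", po$observer[i], po$mean[i], po$sd[i]))
  }
  cat(sprintf("  LOAM: +/- %.1f deg\n", x$loam_halfwidth))
  if (x$undefined_icc) {
    cat("  ICC: undefined (zero total variance)\n")
  } else {
    cat("  "); print(x$icc_average)
    cat("  "); print(x$icc_single)
  }
  if (!is.null(x$rc)) cat(sprintf("  RC: +/- %.1f deg\n", x$rc$rc))
  invisible(x)
}
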