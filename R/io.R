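# CSV/JSON readers and writers for the two tabular schemas.
#
# Landmarks CSV (long, one row per digitised point):
#   subject_id, side, observer_id, occasion, landmark, index, x, y
# where `index` is empty/NA for single-point landmarks and 1..k for contour
# points. Angles CSV (wide, one row per reading):
#   subject_id, side, observer_id, occasion, hka_deviation, mldfa, mmpta,
#   tga, ba

LANDMARK_COLS <- c("subject_id", "side", "observer_id", "occasion",
                   "landmark", "index", "x", "y")
ANGLE_COLS <- c("subject_id", "side", "observer_id", "occasion", ANGLE_NAMES)

#' Read a landmarks CSV into annotations
#'
#' Strict parsing: the header must contain the schema columns, landmark names
#' must match the vocabulary exactly (no trimming), sides must be
#' left/right, occasions positive integers, coordinates finite, and no
#' duplicate (subject, observer, occasion, landmark \[, index\]) rows.
#'
#' @param path CSV file path.
#' @return List of [landmark_annotation()] objects, ordered by subject,
#'   observer, occasion.
#' @export
read_landmarks <- function(path) {
  km_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  miss <- setdiff(LANDMARK_COLS, header)
  if (length(miss)) {
    km_stop("named_column", paste0("landmarks CSV lacks column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       observer_id = "character",
                                       landmark = "character",
                                       side = "character"))
  ok_lm <- df$landmark %in% c(LANDMARK_VOCABULARY, CONTOUR_VOCABULARY)
  if (!all(ok_lm)) {
    row <- which(!ok_lm)[1L]
    km_stop("vocabulary",
            sprintf("row %d: unknown landmark name \"%s\"", row, df$landmark[row]))
  }
  ok_side <- df$side %in% c("left", "right")
  if (!all(ok_side)) {
    km_stop("vocabulary", sprintf("row %d: side must be left or right",
                                  which(!ok_side)[1L]))
  }
  if (!all(is.finite(df$x) & is.finite(df$y))) {
    km_stop("io", sprintf("row %d: non-finite coordinates",
                          which(!(is.finite(df$x) & is.finite(df$y)))[1L]))
  }

  is_contour <- df$landmark %in% CONTOUR_VOCABULARY
  key <- paste(df$subject_id, df$observer_id, df$occasion, df$landmark,
               ifelse(is_contour, df$index, ""), sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    km_stop("duplicate_row",
            sprintf("row %d: duplicate point for (subject %s, observer %s, occasion %s, %s)",
                    row, df$subject_id[row], df$observer_id[row],
                    df$occasion[row], df$landmark[row]))
  }

  grp <- paste(df$subject_id, df$observer_id, df$occasion, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(grp, levels = unique(grp))),
                function(rows) {
    sub <- df[rows, , drop = FALSE]
    if (length(unique(sub$side)) != 1L) {
      km_stop("io", sprintf("inconsistent side for subject %s, observer %s, occasion %s",
                            sub$subject_id[1L], sub$observer_id[1L], sub$occasion[1L]))
    }
    pts_rows <- sub[!(sub$landmark %in% CONTOUR_VOCABULARY), , drop = FALSE]
    points <- stats::setNames(
      lapply(seq_len(nrow(pts_rows)), function(i) c(pts_rows$x[i], pts_rows$y[i])),
      pts_rows$landmark)
    contours <- list()
    for (cn in intersect(unique(sub$landmark), CONTOUR_VOCABULARY)) {
      cs <- sub[sub$landmark == cn, , drop = FALSE]
      cs <- cs[order(as.integer(cs$index)), , drop = FALSE]
      contours[[cn]] <- cbind(cs$x, cs$y)
    }
    landmark_annotation(sub$subject_id[1L], sub$side[1L], sub$observer_id[1L],
                        as.integer(sub$occasion[1L]),
                        points = points, contours = contours)
  })
  names(out) <- NULL
  ord <- order(vapply(out, function(a) a$subject_id, ""),
               vapply(out, function(a) a$observer_id, ""),
               vapply(out, function(a) a$occasion, 1L))
  out[ord]
}

#' Write annotations to a landmarks CSV
#'
#' @param annotations List of [landmark_annotation()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    pt <- data.frame(
      subject_id = a$subject_id, side = a$side, observer_id = a$observer_id,
      occasion = a$occasion, landmark = names(a$points), index = NA_integer_,
      x = vapply(a$points, `[`, 0, 1L), y = vapply(a$points, `[`, 0, 2L),
      stringsAsFactors = FALSE)
    ct <- do.call(rbind, lapply(names(a$contours), function(cn) {
      m <- a$contours[[cn]]
      data.frame(subject_id = a$subject_id, side = a$side,
                 observer_id = a$observer_id, occasion = a$occasion,
                 landmark = cn, index = seq_len(nrow(m)),
                 x = m[, 1L], y = m[, 2L], stringsAsFactors = FALSE)
    }))
    rbind(pt, ct)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Measure a list of annotations into a wide angles table
#'
#' @param annotations List of [landmark_annotation()].
#' @param strict Passed to [measure_all()].
#' @return data.frame in the Angles CSV schema (full precision).
#' @export
measure_annotations <- function(annotations, strict = TRUE) {
  rows <- lapply(annotations, function(a) {
    s <- measure_all(a, strict = strict)
    cbind(data.frame(subject_id = a$subject_id, side = a$side,
                     observer_id = a$observer_id, occasion = a$occasion,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(s))))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Read/write the wide angles CSV
#'
#' @param path CSV path.
#' @return `read_angles`: data.frame with the Angles CSV columns.
#' @export
read_angles <- function(path) {
  km_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  miss <- setdiff(ANGLE_COLS, header)
  if (length(miss)) {
    km_stop("named_column", paste0("angles CSV lacks column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       observer_id = "character"))
  df
}

#' @rdname read_angles
#' @param df Angles data.frame.
#' @param digits Rounding applied on write (default full precision).
#' @export
write_angles <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    for (nm in ANGLE_NAMES) df[[nm]] <- round(df[[nm]], digits)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build a measurement table from a wide angles data.frame
#'
#' Pivots one angle of the wide table into the complete crossed
#' subjects x observers x occasions array; incomplete designs are an error
#' naming the first missing cell.
#'
#' @param df Angles data.frame (or long data.frame with columns `subject_id`,
#'   `observer_id`, `occasion`, `value`).
#' @param angle Angle column to extract (ignored for long input).
#' @return A [measurement_table()].
#' @export
angles_to_table <- function(df, angle = "ba") {
  value_col <- if ("value" %in% names(df)) "value" else angle
  km_assert(value_col %in% names(df), "named_column",
            sprintf("no column \"%s\" in angles table", value_col))
  subs <- unique(df$subject_id)
  obs <- sort(unique(df$observer_id))
  occ <- sort(unique(as.integer(df$occasion)))
  arr <- array(NA_real_, c(length(subs), length(obs), length(occ)),
               dimnames = list(subs, obs, occ))
  i <- match(df$subject_id, subs)
  j <- match(df$observer_id, obs)
  k <- match(as.integer(df$occasion), occ)
  if (anyDuplicated(cbind(i, j, k))) {
    km_stop("duplicate_row", "duplicate (subject, observer, occasion) readings")
  }
  arr[cbind(i, j, k)] <- df[[value_col]]
  if (anyNA(arr)) {
    bad <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    km_stop("incomplete_design",
            sprintf("missing cell: subject %s, observer %s, occasion %s",
                    subs[bad[1L]], obs[bad[2L]], occ[bad[3L]]))
  }
  measurement_table(arr, angle)
}

report_to_list <- function(report) {
  comp <- report$components
  icc_block <- function(icc) {
    if (is.null(icc)) return(NULL)
    list(form = icc$form, estimate = icc$estimate, ci_low = icc$ci_low,
         ci_high = icc$ci_high, alpha = icc$alpha, k = icc$k, n = icc$n)
  }
  list(
    schema_version = "1.0",
    angle_name = report$angle_name,
    meta = report$meta,
    per_observer_summary = report$per_observer_summary,
    printed = list(  # paper-style precision: angles 0.1, ICC 3 decimals
      per_observer_mean = round(report$per_observer_summary$mean, 1),
      per_observer_sd = round(report$per_observer_summary$sd, 2),
      loam_halfwidth = round(report$loam_halfwidth, 1),
      icc_average = if (!is.null(report$icc_average))
        round(report$icc_average$estimate, 3),
      icc_single = if (!is.null(report$icc_single))
        round(report$icc_single$estimate, 3),
      rc = if (!is.null(report$rc)) round(report$rc$rc, 1)
    ),
    loam_halfwidth = report$loam_halfwidth,
    icc_average = icc_block(report$icc_average),
    icc_single = icc_block(report$icc_single),
    undefined_icc = report$undefined_icc,
    rc = report$rc,
    variance_components = list(
      sigma2_subject = comp$sigma2_subject,
      sigma2_observer = comp$sigma2_observer,
      sigma2_interaction = comp$sigma2_interaction,
      sigma2_residual = comp$sigma2_residual,
      raw = as.list(comp$raw)
    )
  )
}

#' Serialize an agreement report to JSON
#'
#' Stable key order, full precision values plus a `printed` block rounded the
#' way clinical tables print (angles to 0.1 degree, ICC to 3 decimals).
#'
#' @param report An [agreement_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Write extended Bland-Altman plot data to CSV
#'
#' @param report An [agreement_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ba_plot_csv <- function(report, path) {
  pts <- report$ba_plot$points
  out <- data.frame(subject_mean = pts$subject_mean,
                    difference = pts$difference,
                    observer_id = pts$observer,
                    occasion = pts$occasion, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
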