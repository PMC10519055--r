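# TT-TG metrology. The measurement plane is the FIXED scanner axial plane
# (xy): the posterior condylar line (PCL) direction is re-derived from the
# (possibly rotated) condylar landmarks at every angle and the TT-TG
# distance is the component of the axial TT-TG offset along that direction.
# Re-anchoring the plane perpendicular to the rotated femoral axis instead
# would null the pendulum effect entirely; the fixed-plane convention is
# the crux of the observed per-angle decrease.

#' Posterior condylar line direction in the axial plane
#'
#' Unit 2-vector along the axial projection of
#' `lat_condyle_posterior - med_condyle_posterior`, oriented
#' medial-to-lateral (so `(+1, 0)` for an untilted right knee in the
#' canonical frame).
#'
#' @param knee a [knee_model()]; a left knee is mirrored to the canonical
#'   right frame first.
#' @return unit numeric length-2 vector.
#' @export
posterior_condylar_direction <- function(knee) {
  stopifnot(inherits(knee, "knee_model"))
  lm <- canonical_landmarks(knee)
  d <- project_axial(lm["lat_condyle_posterior", ]) -
    project_axial(lm["med_condyle_posterior", ])
  n <- sqrt(sum(d * d))
  if (n < 1e-6)
    stop("degenerate posterior condylar direction: condylar axial ",
         "projections are closer than 1e-6 mm")
  unname(d / n)
}

#' Measure the TT-TG distance of a knee model
#'
#' Projects the tibial tuberosity midpoint (TT) and the deepest trochlear
#' groove point (TG) into the fixed axial plane and takes the component of
#' TT - TG along the posterior condylar direction. Positive values mean the
#' tuberosity lies lateral to the groove. Left knees are mirrored to the
#' canonical right frame, so the sign convention is side-independent.
#'
#' @param knee a [knee_model()].
#' @return an object of class `tttg_measurement` with fields
#'   `distance` (mm, full precision), `display` (mm rounded to 0.1),
#'   `angle` (degrees, from the model metadata) and `pcl_direction`.
#' @export
measure_tttg <- function(knee) {
  stopifnot(inherits(knee, "knee_model"))
  u <- posterior_condylar_direction(knee)
  lm <- canonical_landmarks(knee)
  v <- project_axial(lm["tibial_tuberosity_mid", ]) -
    project_axial(lm["trochlear_groove_deepest", ])
  d <- sum(v * u)
  if (abs(d) > 60)
    warning("measured |TT-TG| exceeds 60 mm; anatomically implausible model")
  ang <- knee$metadata$applied_angle_deg
  structure(list(distance = d, display = round(d, 1),
                 angle = if (is.null(ang)) NA_real_ else ang,
                 pcl_direction = u),
            class = "tttg_measurement")
}

#' @export
print.tttg_measurement <- function(x, ...) {
  cat(sprintf("TT-TG = %.1f mm (full precision %.6f mm%s)\n",
              x$display, x$distance,
              if (is.na(x$angle)) "" else
                sprintf(", at %g deg varus", x$angle)))
  invisible(x)
}

#' Per-angle TT-TG series for one knee
#'
#' @param angles numeric vector of varus angles (degrees), strictly
#'   increasing.
#' @param distances numeric vector of TT-TG distances (mm), same length.
#' @param subject_id subject identifier.
#' @return an object of class `tttg_series`: a data frame with columns
#'   `angle_deg` and `tttg_mm`.
#' @export
tttg_series <- function(angles, distances, subject_id = NA) {
  stopifnot(length(angles) == length(distances),
            all(diff(angles) > 0))
  structure(data.frame(angle_deg = as.numeric(angles),
                       tttg_mm = as.numeric(distances)),
            subject_id = subject_id,
            class = c("tttg_series", "data.frame"))
}

#' @export
print.tttg_series <- function(x, ...) {
  cat(sprintf("<tttg_series: subject %s, %d angles>\n",
              as.character(attr(x, "subject_id")), nrow(x)))
  print(data.frame(angle_deg = x$angle_deg,
                   tttg_mm = round(x$tttg_mm, 3)))
  invisible(x)
}

#' Write / read a per-angle results table
#'
#' Columns: `subject_id, angle_deg, tttg_mm, tttg_mm_rounded` (full
#' precision and 0.1 mm display value).
#'
#' @param series_list list of [tttg_series()].
#' @param path CSV path.
#' @return `write_results_csv` returns `path` invisibly; `read_results_csv`
#'   returns a list of `tttg_series`.
#' @export
write_results_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(subject_id = attr(s, "subject_id"),
               angle_deg = s$angle_deg,
               tttg_mm = s$tttg_mm,
               tttg_mm_rounded = round(s$tttg_mm, 1))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "angle_deg", "tttg_mm")
  if (nrow(df) == 0L) stop("empty results table: ", path)
  if (!all(need %in% names(df)))
    stop("malformed results table '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$angle_deg), ]
    tttg_series(d$angle_deg, d$tttg_mm, subject_id = d$subject_id[1])
  })
}
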