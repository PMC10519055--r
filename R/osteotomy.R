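# Lateral opening-wedge distal femoral osteotomy (LDF-OWO) construction and
# virtual varus correction. The osteotomy trajectory runs from a lateral
# cortex entry 2 cm proximal to the lateral epicondyle, aiming distally to
# the adductor tubercle; the hinge pivot sits 1 cm from the medial cortex at
# the apex, and the varus rotation axis is exactly anteroposterior (+y),
# i.e. a pure coronal-plane rotation. The distal femoral fragment and the
# tibia are treated as one merged rigid body.

#' Construct an osteotomy plan for a knee
#'
#' Entry point: `lateral_epicondyle + 20 mm` proximally. Apex: the medial
#' cortex landmark at the adductor-tubercle level. The osteotomy plane
#' contains both and is parallel to the anteroposterior axis (its normal
#' has zero y-component). The pivot lies on the plane, 10 mm from the apex
#' toward the lateral side along the entry-apex direction projected into
#' the xz-plane.
#'
#' @param knee a [knee_model()]; a left knee is mirrored to the canonical
#'   right frame (plans are always expressed in that frame).
#' @return an object of class `osteotomy_plan` with fields `entry`, `apex`,
#'   `plane` ([plane3()]), `pivot` and `axis_dir` (always +y).
#' @export
build_osteotomy_plan <- function(knee) {
  stopifnot(inherits(knee, "knee_model"))
  lm <- canonical_landmarks(knee)
  entry <- lm["lateral_epicondyle", ] +
    c(0, 0, ANATOMY_CONSTANTS$entry_dz)
  apex <- lm["medial_cortex_apex", ]
  delta <- entry - apex
  dxz <- sqrt(delta[1]^2 + delta[3]^2)
  if (dxz < 1e-6)
    stop("degenerate osteotomy plan: entry and apex coincide in the ",
         "coronal projection")
  # plane through entry and apex, parallel to y: normal in the xz-plane,
  # perpendicular to the xz-projection of the trajectory, oriented proximal
  normal <- c(-delta[3], 0, delta[1])
  if (normal[3] < 0) normal <- -normal
  plane <- plane3(apex, normal)
  dir_xz <- c(delta[1], 0, delta[3]) / dxz
  pivot <- apex + ANATOMY_CONSTANTS$pivot_offset * dir_xz
  structure(list(entry = unname(entry), apex = unname(apex), plane = plane,
                 pivot = unname(pivot), axis_dir = c(0, 1, 0)),
            class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat("<osteotomy_plan>\n")
  cat(sprintf("  entry  : (%.2f, %.2f, %.2f) mm\n",
              x$entry[1], x$entry[2], x$entry[3]))
  cat(sprintf("  apex   : (%.2f, %.2f, %.2f) mm\n",
              x$apex[1], x$apex[2], x$apex[3]))
  cat(sprintf("  pivot  : (%.2f, %.2f, %.2f) mm (%.1f mm from apex)\n",
              x$pivot[1], x$pivot[2], x$pivot[3],
              sqrt(sum((x$pivot - x$apex)^2))))
  cat("  axis   : +y (anteroposterior; coronal-plane rotation)\n")
  invisible(x)
}

#' Serialise / deserialise an osteotomy plan
#'
#' @param plan an [build_osteotomy_plan()] result.
#' @param path JSON path.
#' @return `read_plan_json` returns an `osteotomy_plan`.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "osteotomy_plan"))
  jsonlite::write_json(
    list(entry = plan$entry, apex = plan$apex,
         plane = list(point = plan$plane$point, normal = plan$plane$normal),
         pivot = plan$pivot, axis_dir = plan$axis_dir),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(entry = obj$entry, apex = obj$apex,
                 plane = plane3(obj$plane$point, obj$plane$normal),
                 pivot = obj$pivot, axis_dir = obj$axis_dir),
            class = "osteotomy_plan")
}

#' Label landmarks as proximal or distal to the osteotomy
#'
#' Membership is by side of the osteotomy plane (the plane normal points
#' proximally, so negative signed distance means distal), with two fixed
#' rules: tibial landmarks are always distal (the tibia is merged with the
#' distal fragment), and the hinge landmark `medial_cortex_apex` — which
#' lies on the plane by construction — is labelled proximal, since the
#' hinge cortex stays attached and undisplaced in an opening wedge. Any
#' other landmark within 1e-9 mm of the plane raises an ambiguity error
#' rather than being silently assigned.
#'
#' @param knee a [knee_model()].
#' @param plan an [build_osteotomy_plan()] result.
#' @return named character vector (`"proximal"`/`"distal"`) over all
#'   landmarks.
#' @export
classify_fragment <- function(knee, plan) {
  stopifnot(inherits(knee, "knee_model"), inherits(plan, "osteotomy_plan"))
  lm <- canonical_landmarks(knee)
  d <- signed_distance(lm, plan$plane)
  lab <- ifelse(d < 0, "distal", "proximal")
  names(lab) <- rownames(lm)
  lab[TIBIAL_LANDMARKS] <- "distal"        # merged-bone rule
  lab["medial_cortex_apex"] <- "proximal"  # hinge stays with the shaft
  amb <- setdiff(names(lab)[abs(d) < 1e-9], "medial_cortex_apex")
  if (length(amb))
    stop("ambiguous fragment label: landmark(s) ",
         paste(amb, collapse = ", "), " lie exactly on the osteotomy plane")
  lab
}

#' Apply a varus rotation to the distal fragment
#'
#' Rotates every distal-labelled landmark by `angle_deg` about the axis
#' through `plan$pivot` along +y, signed so that points distal to the pivot
#' displace medially (correction of a valgus knee). Proximal landmarks are
#' unchanged. Rotations are always applied to the native model, never
#' compounded.
#'
#' @param knee a [knee_model()] (native, unrotated).
#' @param plan an [build_osteotomy_plan()] result.
#' @param angle_deg varus opening angle in degrees, in `[0, 30]`.
#' @return a new [knee_model()]; `metadata$applied_angle_deg` records the
#'   angle. For a left knee the result is re-mirrored to the left side.
#' @export
apply_varus <- function(knee, plan, angle_deg) {
  stopifnot(inherits(knee, "knee_model"), inherits(plan, "osteotomy_plan"))
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg > 30)
    stop("varus angle must lie in [0, 30] degrees")
  was_left <- knee$side == "left"
  work <- if (was_left) mirror_knee(knee) else knee
  lab <- classify_fragment(work, plan)
  lm <- work$landmarks
  rot <- rigid_rotation(plan$pivot, plan$axis_dir, angle_deg)
  distal <- names(lab)[lab == "distal"]
  lm[distal, ] <- rotate_points(lm[distal, , drop = FALSE], rot)
  work$landmarks <- lm
  work$metadata$applied_angle_deg <- angle_deg
  if (was_left) mirror_knee(work) else work
}

#' Closed-form pendulum model of the TT-TG change under varus rotation
#'
#' Both TT and TG sit on the distal rigid body, so a coronal-plane rotation
#' tilts the fixed TT-TG offset vector while the measurement stays in the
#' fixed axial plane: the apparent mediolateral distance changes with the
#' viewing perspective (the pendulum effect). This function rotates the
#' TT-TG offset vector `v` and the posterior-condylar-line vector `m` by
#' the varus rotation, projects both axially, and returns
#' `dot(project_axial(R v), unit(project_axial(R m)))`.
#'
#' With `m` purely mediolateral and `v = (native_tttg, vy, -dz)` this
#' reduces to `native_tttg * cos(theta) - dz * sin(theta)`.
#'
#' @param native_tttg native TT-TG distance (mm).
#' @param dz longitudinal groove-to-tuberosity offset, groove z minus
#'   tuberosity z, > 0 (mm).
#' @param angle_deg varus angle(s) in degrees, each in `[0, 30]`;
#'   vectorised.
#' @param pcl_vector optional 3-vector for the posterior condylar line
#'   (default purely mediolateral).
#' @param tt_minus_tg optional explicit TT - TG 3-vector (mm); defaults to
#'   `(native_tttg, 0, -dz)`.
#' @return predicted TT-TG distance(s) in mm.
#' @export
closed_form_tttg <- function(native_tttg, dz, angle_deg,
                             pcl_vector = c(1, 0, 0),
                             tt_minus_tg = NULL) {
  stopifnot(all(is.finite(angle_deg)), all(angle_deg >= 0),
            all(angle_deg <= 30))
  v <- if (is.null(tt_minus_tg)) c(native_tttg, 0, -dz)
       else as.numeric(tt_minus_tg)
  m <- as.numeric(pcl_vector)
  vapply(angle_deg, function(a) {
    R <- .rotation_matrix(c(0, 1, 0), a)
    mv <- project_axial(drop(R %*% m))
    nm <- sqrt(sum(mv * mv))
    if (nm < 1e-6)
      stop("degenerate posterior condylar vector: axial projection < 1e-6 mm")
    sum(project_axial(drop(R %*% v)) * (mv / nm))
  }, numeric(1))
}

#' Run the varus-angle schedule for one knee
#'
#' For each scheduled angle, applies the varus rotation to the NATIVE model
#' (equivalent to incremental application, by rotation composition) and
#' measures the TT-TG distance.
#'
#' @param knee a native [knee_model()].
#' @param plan optional [build_osteotomy_plan()]; built from `knee` when
#'   omitted.
#' @param angles sorted varus schedule in degrees (default 0-12 in 2-degree
#'   steps).
#' @return a [tttg_series()].
#' @export
run_schedule <- function(knee, plan = NULL, angles = seq(0, 12, by = 2)) {
  stopifnot(inherits(knee, "knee_model"))
  if (is.unsorted(angles, strictly = TRUE))
    stop("angle schedule must be strictly increasing")
  if (any(angles < 0 | angles > 30))
    stop("angle schedule must lie within [0, 30] degrees")
  if (is.null(plan)) plan <- build_osteotomy_plan(knee)
  d <- vapply(angles,
              function(a) measure_tttg(apply_varus(knee, plan, a))$distance,
              numeric(1))
  tttg_series(angles, d, subject_id = knee$metadata$subject_id)
}
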