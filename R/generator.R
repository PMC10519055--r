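# Fixed anatomical offsets (mm, canonical right-knee frame, knee centre at
# the trochlear groove level). One block so plausibility can be audited in
# one place; these are literature-plausible constants, not fitted values.
ANATOMY_CONSTANTS <- list(
  groove_y            = 5,                # TG sits slightly anterior
  tuberosity_y        = 18,               # TT is the most anterior tibial point
  lateral_epicondyle  = c(30, -8, 2),
  adductor_tubercle   = c(-27, -6, 12),
  medial_cortex_apex  = c(-27, -6, 15),   # hinge cortex, just proximal to the
                                          # adductor tubercle
  lat_tibial_condyle  = c(18, -30, -10),
  entry_dz            = 20,               # osteotomy entry 2 cm proximal to
                                          # the lateral epicondyle
  pivot_offset        = 10                # hinge pivot 1 cm from the medial
                                          # cortex at the apex
)

#' Parameters of the synthetic valgus-knee generator
#'
#' Defaults reproduce the statistical structure of the six-knee valgus
#' cohort the package is calibrated to: native TT-TG 21.0 +/- 2.1 mm
#' truncated to 18-24 mm, hip-knee-ankle (HKA) valgus 3.2 deg in 1.5-6 deg,
#' mean lateral distal femoral angle (LDFA) 82.2 deg and medial proximal
#' tibial angle (MPTA) 87.7 deg. The groove-to-tuberosity longitudinal
#' offset default (47 mm) is solved from the closed-form pendulum model so
#' a noise-free knee with native TT-TG 21 mm reproduces the reference mean
#' at 12 degrees of varus.
#'
#' @param n_subjects number of knees per cohort (>= 1).
#' @param tttg_mean,tttg_sd,tttg_range native TT-TG sampling distribution
#'   (mm); truncated normal, resampled into `tttg_range`.
#' @param groove_tuberosity_dz_mean,groove_tuberosity_dz_sd,groove_tuberosity_dz_range
#'   longitudinal groove-to-tuberosity offset Delta-z (mm), truncated normal.
#' @param condylar_halfwidth posterior condyles at x = +/- this value (mm).
#' @param posterior_offset condylar posterior landmarks' y coordinate (mm).
#' @param hka_mean,hka_sd,hka_range HKA valgus angle (degrees), truncated
#'   normal.
#' @param ldfa_mean,mpta_mean coronal deformity descriptors (degrees),
#'   carried as metadata.
#' @param condyle_dz_jitter_sd sd of the condylar landmarks' longitudinal
#'   jitter (mm).
#' @param seed integer seed for the cohort; each subject uses a
#'   deterministic substream derived from `seed` and its subject id.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_subjects = 6L,
                             tttg_mean = 21.0, tttg_sd = 2.1,
                             tttg_range = c(18, 24),
                             groove_tuberosity_dz_mean = 47.0,
                             groove_tuberosity_dz_sd = 3.0,
                             groove_tuberosity_dz_range = c(40, 58),
                             condylar_halfwidth = 22,
                             posterior_offset = -35,
                             hka_mean = 3.2, hka_sd = 1.1,
                             hka_range = c(1.5, 6.0),
                             ldfa_mean = 82.2, mpta_mean = 87.7,
                             condyle_dz_jitter_sd = 1.0,
                             seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            tttg_mean = tttg_mean, tttg_sd = tttg_sd,
            tttg_range = as.numeric(tttg_range),
            groove_tuberosity_dz_mean = groove_tuberosity_dz_mean,
            groove_tuberosity_dz_sd = groove_tuberosity_dz_sd,
            groove_tuberosity_dz_range = as.numeric(groove_tuberosity_dz_range),
            condylar_halfwidth = condylar_halfwidth,
            posterior_offset = posterior_offset,
            hka_mean = hka_mean, hka_sd = hka_sd,
            hka_range = as.numeric(hka_range),
            ldfa_mean = ldfa_mean, mpta_mean = mpta_mean,
            condyle_dz_jitter_sd = condyle_dz_jitter_sd,
            seed = as.integer(seed))
  if (p$n_subjects < 1L) stop("n_subjects must be >= 1")
  sds <- c(p$tttg_sd, p$groove_tuberosity_dz_sd, p$hka_sd,
           p$condyle_dz_jitter_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  for (rg in list(p$tttg_range, p$groove_tuberosity_dz_range, p$hka_range))
    if (length(rg) != 2L || rg[1] > rg[2]) stop("ranges must be ordered pairs")
  .check_truncation(p$tttg_mean, p$tttg_sd, p$tttg_range, "tttg")
  .check_truncation(p$groove_tuberosity_dz_mean, p$groove_tuberosity_dz_sd,
                    p$groove_tuberosity_dz_range, "groove_tuberosity_dz")
  .check_truncation(p$hka_mean, p$hka_sd, p$hka_range, "hka")
  structure(p, class = "generator_params")
}

# generator-config error when the truncation window is effectively
# unreachable (> 6 sd from the mean on one side)
.check_truncation <- function(mean, sd, range, what) {
  lo <- range[1]; hi <- range[2]
  if (mean < lo && (lo - mean) > 6 * sd)
    stop("generator config error: ", what, " range excludes the mean by > 6 sd")
  if (mean > hi && (mean - hi) > 6 * sd)
    stop("generator config error: ", what, " range excludes the mean by > 6 sd")
  invisible(TRUE)
}

# truncated-normal draw by rejection; sd = 0 degenerates to the mean
# (which must then lie inside the range)
.rtrunc <- function(mean, sd, range) {
  if (sd == 0) {
    if (mean < range[1] || mean > range[2])
      stop("generator config error: zero-sd draw outside its range")
    return(mean)
  }
  for (i in 1:10000) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  stop("generator config error: truncated sampling failed to accept")
}

# deterministic per-subject substream seed (< 2^31), independent of the
# order in which subjects are drawn
.subject_seed <- function(seed, subject_id) {
  as.integer((as.double(seed) * 48271 + as.double(subject_id) * 16807) %%
               2147483647)
}

# run expr under a private RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample one synthetic knee
#'
#' Draws native TT-TG, the groove-to-tuberosity longitudinal offset and the
#' HKA angle from truncated normals, jitters the condylar landmarks'
#' longitudinal positions, and places all remaining landmarks at the fixed
#' anatomical offsets in `ANATOMY_CONSTANTS`. The model is constructed so
#' the measured native TT-TG ([measure_tttg()]) equals the sampled target
#' exactly: the trochlear groove sits at the origin and the tuberosity at
#' `(TT-TG, y_const, -dz)`, while HKA tilts the (non-measurement) lateral
#' tibial condyle landmark about the knee centre.
#'
#' @param params a [generator_params()].
#' @param subject_id positive integer identifying the subject's RNG
#'   substream; identical `(params, subject_id)` give bitwise-identical
#'   models.
#' @return a [knee_model()] (right knee) whose metadata records the applied
#'   angle (0), subject id, HKA/LDFA/MPTA and the generator's true
#'   `tttg_native` and `dz` values.
#' @export
sample_knee <- function(params, subject_id = 1L) {
  stopifnot(inherits(params, "generator_params"), subject_id >= 1)
  .with_seed(.subject_seed(params$seed, subject_id), {
    tttg <- .rtrunc(params$tttg_mean, params$tttg_sd, params$tttg_range)
    dz <- .rtrunc(params$groove_tuberosity_dz_mean,
                  params$groove_tuberosity_dz_sd,
                  params$groove_tuberosity_dz_range)
    hka <- .rtrunc(params$hka_mean, params$hka_sd, params$hka_range)
    jit <- stats::rnorm(2L, 0, params$condyle_dz_jitter_sd)

    ac <- ANATOMY_CONSTANTS
    hw <- params$condylar_halfwidth
    po <- params$posterior_offset
    # valgus tilt of the tibia: distal points displace laterally (+x),
    # i.e. rotation by -hka about +y through the knee centre
    tilt <- rigid_rotation(c(0, 0, 0), c(0, 1, 0), -hka)
    lm <- rbind(
      trochlear_groove_deepest     = c(0, ac$groove_y, 0),
      tibial_tuberosity_mid        = c(tttg, ac$tuberosity_y, -dz),
      med_condyle_posterior        = c(-hw, po, jit[1]),
      lat_condyle_posterior        = c(hw, po, jit[2]),
      lat_tibial_condyle_posterior = rotate_points(ac$lat_tibial_condyle, tilt),
      lateral_epicondyle           = ac$lateral_epicondyle,
      adductor_tubercle            = ac$adductor_tubercle,
      medial_cortex_apex           = ac$medial_cortex_apex)
    knee_model(lm, side = "right",
               metadata = list(subject_id = subject_id,
                               hka_deg = hka,
                               ldfa_deg = params$ldfa_mean -
                                 (hka - params$hka_mean),
                               mpta_deg = params$mpta_mean,
                               tttg_native = tttg, dz = dz,
                               applied_angle_deg = 0))
  })
}

#' Sample a cohort of synthetic knees
#'
#' @param params a [generator_params()]; `params$n_subjects` knees are drawn
#'   from subject-indexed substreams of `params$seed`.
#' @return list of [knee_model()] objects.
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  lapply(seq_len(params$n_subjects),
         function(i) sample_knee(params, subject_id = i))
}
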