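#' Landmark set required on every knee model
#'
#' All positions are mm in the canonical frame (+x lateral, +y anterior,
#' +z proximal for a right knee; left knees are stored mirrored and
#' re-mirrored on demand).
#' @export
KNEE_LANDMARKS <- c(
  "trochlear_groove_deepest",     # TG: deepest point of the trochlear groove
  "tibial_tuberosity_mid",        # TT: midpoint of the tibial tuberosity
  "med_condyle_posterior",        # most posterior point, medial femoral condyle
  "lat_condyle_posterior",        # most posterior point, lateral femoral condyle
  "lat_tibial_condyle_posterior", # most posterior point, lateral tibial condyle
  "lateral_epicondyle",           # lateral epicondyle (osteotomy entry ref)
  "adductor_tubercle",            # adductor tubercle (osteotomy aim point)
  "medial_cortex_apex"            # medial cortex at the osteotomy apex (hinge)
)

# landmarks that belong to the tibia; after the osteotomy the tibia is merged
# with the distal femoral fragment, so these always travel with it
TIBIAL_LANDMARKS <- c("tibial_tuberosity_mid", "lat_tibial_condyle_posterior")

#' Knee landmark model
#'
#' A named set of 3D anatomical landmarks for one knee, plus side and
#' clinical metadata. The canonical frame is that of a right knee:
#' +x lateral, +y anterior, +z proximal, millimetres. A `side = "left"` model
#' stores its landmarks as acquired (mirror image in x); all internal
#' computations convert to the canonical right frame first.
#'
#' @param landmarks numeric matrix with one row per landmark (rownames must
#'   cover [KNEE_LANDMARKS]) and columns x, y, z in mm.
#' @param side `"right"` or `"left"`.
#' @param metadata named list of clinical descriptors (e.g. `subject_id`,
#'   `hka_deg`, `ldfa_deg`, `mpta_deg`); free-form, carried through the
#'   pipeline.
#' @param mesh_paths optional named list with `femur`/`tibia` STL paths.
#' @return an object of class `knee_model`.
#' @export
knee_model <- function(landmarks, side = c("right", "left"),
                       metadata = list(), mesh_paths = NULL) {
  side <- match.arg(side)
  lm <- as.matrix(landmarks)
  if (is.null(rownames(lm)) || !all(KNEE_LANDMARKS %in% rownames(lm)))
    stop("landmarks must carry rownames covering: ",
         paste(setdiff(KNEE_LANDMARKS, rownames(lm)), collapse = ", "))
  lm <- lm[KNEE_LANDMARKS, , drop = FALSE]
  storage.mode(lm) <- "double"
  if (ncol(lm) != 3L) stop("landmarks must have 3 columns (x, y, z)")
  colnames(lm) <- c("x", "y", "z")
  if (!all(is.finite(lm))) stop("landmark coordinates must be finite")
  obj <- structure(list(side = side, landmarks = lm,
                        metadata = metadata, mesh_paths = mesh_paths),
                   class = "knee_model")
  validate_knee_model(obj)
  obj
}

#' @rdname knee_model
#' @param x a `knee_model`.
#' @export
validate_knee_model <- function(x) {
  lm <- x$landmarks
  if (lm["trochlear_groove_deepest", "z"] <= lm["tibial_tuberosity_mid", "z"])
    stop("trochlear groove must be proximal (larger z) to the tibial tuberosity")
  cv <- canonical_landmarks(x)
  if (cv["lat_condyle_posterior", "x"] <= cv["med_condyle_posterior", "x"])
    stop("lateral condyle must be lateral (+x, canonical right frame) ",
         "to the medial condyle")
  invisible(x)
}

# landmarks in the canonical right-knee frame (mirror a left knee)
canonical_landmarks <- function(knee) {
  lm <- knee$landmarks
  if (knee$side == "left") lm[, "x"] <- -lm[, "x"]
  lm
}

#' Mirror a knee model to the opposite side
#'
#' Reflects every landmark across the sagittal midplane (x -> -x) and flips
#' the recorded side. Mirroring twice is the identity.
#'
#' @param knee a [knee_model()].
#' @return the mirrored `knee_model`.
#' @export
mirror_knee <- function(knee) {
  stopifnot(inherits(knee, "knee_model"))
  lm <- knee$landmarks
  lm[, "x"] <- -lm[, "x"]
  knee$landmarks <- lm
  knee$side <- if (knee$side == "right") "left" else "right"
  knee
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<knee_model: %s knee, %d landmarks>\n",
              x$side, nrow(x$landmarks)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  print(round(x$landmarks, 3))
  invisible(x)
}

#' Read / write landmark files
#'
#' JSON dialect: `{"side": ..., "metadata": {...},
#' "landmarks": {"name": [x, y, z], ...}}` with coordinates in mm.
#' CSV dialect: flat table with columns `name,x,y,z` (side/metadata are not
#' carried by the CSV form; `side` defaults to right).
#'
#' @param knee a [knee_model()].
#' @param path file path.
#' @return `read_*` return a `knee_model`; `write_*` return `path` invisibly.
#' @name landmark_io
NULL

#' @rdname landmark_io
#' @export
write_landmarks_json <- function(knee, path) {
  stopifnot(inherits(knee, "knee_model"))
  lms <- lapply(seq_len(nrow(knee$landmarks)),
                function(i) unname(knee$landmarks[i, ]))
  names(lms) <- rownames(knee$landmarks)
  jsonlite::write_json(
    list(side = knee$side, metadata = knee$metadata, landmarks = lms),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$landmarks))
    stop("malformed landmark file '", path, "': missing field 'landmarks'")
  missing <- setdiff(KNEE_LANDMARKS, names(obj$landmarks))
  if (length(missing))
    stop("malformed landmark file '", path, "': missing landmark(s) ",
         paste(missing, collapse = ", "))
  bad_len <- names(obj$landmarks)[vapply(obj$landmarks, length, 1L) != 3L]
  if (length(bad_len))
    stop("malformed landmark file '", path, "': landmark '", bad_len[1],
         "' does not have 3 coordinates")
  lm <- do.call(rbind, obj$landmarks[KNEE_LANDMARKS])
  rownames(lm) <- KNEE_LANDMARKS
  knee_model(lm, side = if (is.null(obj$side)) "right" else obj$side,
             metadata = as.list(obj$metadata))
}

#' @rdname landmark_io
#' @export
write_landmarks_csv <- function(knee, path) {
  stopifnot(inherits(knee, "knee_model"))
  df <- data.frame(name = rownames(knee$landmarks),
                   x = knee$landmarks[, "x"],
                   y = knee$landmarks[, "y"],
                   z = knee$landmarks[, "z"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("malformed landmark file '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lm <- as.matrix(df[, c("x", "y", "z")])
  rownames(lm) <- df$name
  knee_model(lm, side = "right")
}
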