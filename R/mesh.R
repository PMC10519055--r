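# Optional parametric triangle-mesh layer. The femur is modelled as two
# condylar ellipsoids plus a shaft cylinder, the tibia as a plateau slab
# with an anterior tuberosity boss. Each primitive is watertight (every
# undirected edge shared by exactly two triangles); their disjoint union is
# therefore watertight as a whole. The condylar ellipsoids are oriented with
# their pole along -y so the mesh carries a vertex exactly at each condyle's
# posterior extremum.

tri_mesh <- function(vertices, faces) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  stopifnot(ncol(v) == 3L, ncol(f) == 3L,
            min(f) >= 1L, max(f) <= nrow(v))
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces, %s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) "watertight" else "NOT watertight"))
  invisible(x)
}

.merge_meshes <- function(...) {
  parts <- list(...)
  off <- 0L
  v <- list(); f <- list()
  for (m in parts) {
    v[[length(v) + 1L]] <- m$vertices
    f[[length(f) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  tri_mesh(do.call(rbind, v), do.call(rbind, f))
}

#' Edge-manifold watertightness check
#'
#' @param mesh a `tri_mesh`.
#' @return TRUE iff every undirected edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# UV ellipsoid with its polar axis along y, so vertices sit exactly at the
# +/- y poles; centre c(3), semi-axes r = c(rx, ry, rz), n_seg segments
.ellipsoid_mesh <- function(centre, r, n_seg) {
  n_ring <- max(3L, n_seg %/% 2L)
  # poles at v index 1 (south, -y) and 2 (north, +y)
  verts <- rbind(centre + c(0, -r[2], 0), centre + c(0, r[2], 0))
  for (i in seq_len(n_ring - 1L)) {
    phi <- pi * i / n_ring  # angle from the -y pole
    for (j in seq_len(n_seg)) {
      lam <- 2 * pi * (j - 1L) / n_seg
      verts <- rbind(verts, centre +
                       c(r[1] * sin(phi) * cos(lam),
                         -r[2] * cos(phi),
                         r[3] * sin(phi) * sin(lam)))
    }
  }
  idx <- function(i, j) 2L + (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  faces <- NULL
  for (j in seq_len(n_seg)) {  # pole caps
    faces <- rbind(faces,
                   c(1L, idx(1L, j), idx(1L, j + 1L)),
                   c(2L, idx(n_ring - 1L, j + 1L), idx(n_ring - 1L, j)))
  }
  if (n_ring > 2L)
    for (i in seq_len(n_ring - 2L))
      for (j in seq_len(n_seg))
        faces <- rbind(faces,
                       c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  tri_mesh(verts, faces)
}

# capped cylinder along z from z0 to z1, radius rad, centre axis (cx, cy)
.cylinder_mesh <- function(cx, cy, z0, z1, rad, n_seg) {
  ring <- function(z) t(vapply(seq_len(n_seg), function(j) {
    lam <- 2 * pi * (j - 1L) / n_seg
    c(cx + rad * cos(lam), cy + rad * sin(lam), z)
  }, numeric(3)))
  verts <- rbind(c(cx, cy, z0), c(cx, cy, z1), ring(z0), ring(z1))
  b <- function(j) 2L + ((j - 1L) %% n_seg) + 1L       # bottom ring
  t_ <- function(j) 2L + n_seg + ((j - 1L) %% n_seg) + 1L  # top ring
  faces <- NULL
  for (j in seq_len(n_seg))
    faces <- rbind(faces,
                   c(1L, b(j + 1L), b(j)),            # bottom cap
                   c(2L, t_(j), t_(j + 1L)),          # top cap
                   c(b(j), b(j + 1L), t_(j + 1L)),    # wall
                   c(b(j), t_(j + 1L), t_(j)))
  tri_mesh(verts, faces)
}

# axis-aligned box given two opposite corners
.box_mesh <- function(lo, hi) {
  g <- expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                   z = c(lo[3], hi[3]))
  v <- as.matrix(g)  # binary order: index = 1 + x + 2y + 4z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(quad(1, 3, 4, 2),  # z = lo
             quad(5, 6, 8, 7),  # z = hi
             quad(1, 2, 6, 5),  # y = lo
             quad(3, 7, 8, 4),  # y = hi
             quad(1, 5, 7, 3),  # x = lo
             quad(2, 4, 8, 6))  # x = hi
  tri_mesh(v, f)
}

#' Build a parametric bone mesh for a knee model
#'
#' Constructs a watertight triangle mesh (femoral condylar ellipsoids +
#' shaft cylinder, tibial plateau slab + tuberosity boss) whose posterior
#' extremum vertices coincide with the knee's condylar posterior landmarks;
#' intended for exercising the mesh-mode landmark-extraction path, not for
#' visual realism.
#'
#' @param knee a [knee_model()].
#' @param resolution azimuthal subdivision count (>= 8).
#' @return a `tri_mesh`.
#' @export
build_parametric_mesh <- function(knee, resolution = 32L) {
  stopifnot(inherits(knee, "knee_model"))
  resolution <- as.integer(resolution)
  if (resolution < 8L)
    stop("mesh quality error: resolution must be >= 8 subdivisions")
  lm <- canonical_landmarks(knee)
  r_cond <- c(10, 12, 14)  # condylar ellipsoid semi-axes (mm)
  cond <- function(name) {
    p <- lm[name, ]
    # centre the ellipsoid so its -y pole sits exactly on the landmark
    .ellipsoid_mesh(p + c(0, r_cond[2], 0), r_cond, resolution)
  }
  tt <- lm["tibial_tuberosity_mid", ]
  .merge_meshes(
    cond("med_condyle_posterior"),
    cond("lat_condyle_posterior"),
    .cylinder_mesh(0, -5, 5, 60, 14, resolution),               # femoral shaft
    .box_mesh(c(-24, -28, tt[3] - 8), c(24, 12, tt[3] + 30)),   # tibial slab
    .box_mesh(tt + c(-6, -2, -5), tt + c(6, 1, 5)))             # tuberosity boss
}

#' Extract posterior condylar landmarks from a mesh
#'
#' Per region (medial/lateral split at the x-midline), returns the vertex
#' with minimal y (most posterior); ties within 1e-9 mm are broken by the
#' lowest vertex index, so extraction is deterministic.
#'
#' @param mesh a `tri_mesh` in the canonical right-knee frame.
#' @param midline_x mediolateral split coordinate (mm).
#' @return 2 x 3 matrix with rows `med_condyle_posterior`,
#'   `lat_condyle_posterior`.
#' @export
extract_posterior_landmarks <- function(mesh, midline_x = 0) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  pick <- function(rows) {
    if (!length(rows)) stop("extraction error: empty medial/lateral region")
    ys <- v[rows, 2]
    cand <- rows[ys <= min(ys) + 1e-9]
    v[min(cand), ]  # lowest index among minima
  }
  out <- rbind(med_condyle_posterior = pick(which(v[, 1] < midline_x)),
               lat_condyle_posterior = pick(which(v[, 1] >= midline_x)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Read / write STL meshes
#'
#' Binary STL (80-byte header, little-endian triangle records) by default;
#' ASCII STL also supported. `read_stl` welds vertices that coincide within
#' 1e-6 mm so the reconstructed mesh is edge-manifold again.
#'
#' @param mesh a `tri_mesh`.
#' @param path file path.
#' @param format `"binary"` or `"ascii"`.
#' @return `read_stl` returns a `tri_mesh`; `write_stl` returns `path`
#'   invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices; f <- mesh$faces
  tri <- function(i) v[f[i, ], , drop = FALSE]
  normal <- function(tv) {
    n <- c((tv[2, 2] - tv[1, 2]) * (tv[3, 3] - tv[1, 3]) -
             (tv[2, 3] - tv[1, 3]) * (tv[3, 2] - tv[1, 2]),
           (tv[2, 3] - tv[1, 3]) * (tv[3, 1] - tv[1, 1]) -
             (tv[2, 1] - tv[1, 1]) * (tv[3, 3] - tv[1, 3]),
           (tv[2, 1] - tv[1, 1]) * (tv[3, 2] - tv[1, 2]) -
             (tv[2, 2] - tv[1, 2]) * (tv[3, 1] - tv[1, 1]))
    nn <- sqrt(sum(n * n))
    if (nn < 1e-12) c(0, 0, 0) else n / nn
  }
  if (format == "binary") {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      tv <- tri(i)
      writeBin(c(normal(tv), t(tv)), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tv <- tri(i); n <- normal(tv)
      writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           tv[, 1], tv[, 2], tv[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  is_ascii <- identical(rawToChar(header[1:5]), "solid") && {
    sz <- file.info(path)$size
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    sz != 84 + 50 * nt
  }
  close(con)
  tris <- if (is_ascii) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    mat <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
    mat
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    out <- matrix(0, nt * 3L, 3L)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      out[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    out
  }
  # weld coincident vertices (1e-6 mm) to restore shared edges
  key <- apply(round(tris * 1e6), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  vid <- match(key, key[uniq])
  tri_mesh(tris[uniq, , drop = FALSE],
           matrix(vid, ncol = 3, byrow = TRUE))
}
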