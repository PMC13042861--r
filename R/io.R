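#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3) {
    stop("vertices must be n x 3 and faces m x 3")
  }
  if (nrow(faces) < 1) stop("mesh must contain at least one face")
  if (any(faces < 1) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# weld vertices closer than tol and drop degenerate faces
weld_mesh <- function(vertices, faces, tol = 1e-7) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = "|")
  uid <- match(key, unique(key))
  vert <- vertices[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid[faces], ncol = 3)
  area2 <- function(f) {
    a <- vert[f[1], ]; b <- vert[f[2], ]; c <- vert[f[3], ]
    v1 <- b - a; v2 <- c - a
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    sqrt(sum(n^2))
  }
  degen <- apply(faces, 1, function(f) {
    anyDuplicated(f) > 0 || area2(f) < 1e-14
  })
  n_dropped <- sum(degen)
  if (n_dropped > 0) {
    message(sprintf("dropped %d degenerate face(s)", n_dropped))
    faces <- faces[!degen, , drop = FALSE]
  }
  m <- triangle_mesh(vert, faces)
  m$dropped_faces <- n_dropped
  m
}

#' Read an STL mesh (binary or ASCII)
#'
#' The encoding is auto-detected. Duplicate vertices are welded and degenerate
#' faces dropped (with a logged count).
#'
#' @param path file path.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) {
    stop(sprintf("STL parse error at byte 0: file too short (%s bytes)", sz))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  # keep printable ASCII only: binary STL headers contain arbitrary bytes
  printable <- head_raw[head_raw %in% as.raw(c(9L, 10L, 13L, 32:126))]
  head_txt <- rawToChar(printable)
  is_ascii <- grepl("^\\s*solid", head_txt) &&
    grepl("facet", head_txt, fixed = TRUE)
  close(con); on.exit(NULL)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0) stop("STL parse error: no vertex records found")
  if (length(vl) %% 3 != 0) {
    stop("STL parse error: vertex count not a multiple of 3 (line ",
         vl[length(vl)], ")")
  }
  coords <- do.call(rbind, lapply(strsplit(trimws(lines[vl]), "\\s+"),
                                  function(p) as.numeric(p[2:4])))
  if (anyNA(coords)) stop("STL parse error: non-numeric vertex coordinate")
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  weld_mesh(coords, faces)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + n_tri * 50
  if (n_tri < 1 || expected != sz) {
    stop(sprintf("STL parse error at byte 80: triangle count %d inconsistent with file size %d",
                 n_tri, sz))
  }
  body <- readBin(con, "raw", n = n_tri * 50)
  dim(body) <- c(50, n_tri)
  vals <- matrix(readBin(as.vector(body[1:48, ]), "numeric", size = 4,
                         n = 12 * n_tri, endian = "little"),
                 nrow = 12)
  coords <- matrix(as.vector(vals[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  weld_mesh(coords, faces)
}

#' Write an STL mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  normals <- t(apply(f, 1, function(fi) {
    v1 <- v[fi[2], ] - v[fi[1], ]; v2 <- v[fi[3], ] - v[fi[1], ]
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    l <- sqrt(sum(n^2)); if (l > 0) n / l else c(0, 0, 1)
  }))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(normals[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    lines <- c("solid surface")
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("  facet normal %.9g %.9g %.9g",
                         normals[i, 1], normals[i, 2], normals[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "    endloop", "  endfacet")
    }
    writeLines(c(lines, "endsolid surface"), path)
  }
  invisible(path)
}

#' Convert a height map to a triangle mesh
#'
#' Each grid cell is split into two triangles; useful for round-trip testing
#' of the STL pathway.
#'
#' @param map a [height_map()].
#' @return A [triangle_mesh()].
#' @export
heightmap_to_mesh <- function(map) {
  assert_heightmap(map)
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  x <- hm_x(map); y <- hm_y(map)
  verts <- cbind(rep(x, each = nr), rep(y, nc), as.vector(map$heights))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1), nc - 1)
  j <- rep(seq_len(nc - 1), each = nr - 1)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  triangle_mesh(verts, rbind(f1, f2))
}

#' Rasterize a mesh to a height map
#'
#' The mesh is projected onto its least-squares reference plane (it must be a
#' height field over that plane); heights are sampled at the grid nodes by
#' barycentric interpolation within each covering triangle. Nodes not covered
#' by any triangle are masked; mask gaps of up to 3 cells are linearly
#' interpolated and flagged in the metadata.
#'
#' @param mesh a [triangle_mesh()].
#' @param spacing grid spacing in mm.
#' @return A [height_map()].
#' @export
rasterize_mesh <- function(mesh, spacing) {
  stopifnot(inherits(mesh, "triangle_mesh"), spacing > 0)
  v <- mesh$vertices
  # least-squares reference plane z = a + bx + cy
  A <- cbind(1, v[, 1], v[, 2])
  coef <- qr.solve(A, v[, 3])
  nrm <- c(-coef[2], -coef[3], 1); nrm <- nrm / sqrt(sum(nrm^2))
  e1 <- c(1, 0, coef[2]); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  ctr <- colMeans(v)
  P <- sweep(v, 2, ctr) %*% cbind(e1, e2, nrm)  # (u, v, w) plane coordinates
  u0 <- min(P[, 1]); v0 <- min(P[, 2])
  nu <- floor((max(P[, 1]) - u0) / spacing + 1e-9) + 1L
  nv <- floor((max(P[, 2]) - v0) / spacing + 1e-9) + 1L
  z <- matrix(NA_real_, nv, nu)
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- P[mesh$faces[k, ], , drop = FALSE]
    j0 <- max(1L, floor((min(tri[, 1]) - u0) / spacing) + 1L)
    j1 <- min(nu, ceiling((max(tri[, 1]) - u0) / spacing) + 1L)
    i0 <- max(1L, floor((min(tri[, 2]) - v0) / spacing) + 1L)
    i1 <- min(nv, ceiling((max(tri[, 2]) - v0) / spacing) + 1L)
    if (j0 > j1 || i0 > i1) next
    gu <- u0 + (j0:j1 - 1) * spacing
    gv <- v0 + (i0:i1 - 1) * spacing
    pu <- rep(gu, each = length(gv)); pv <- rep(gv, length(gu))
    d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
      (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
    if (abs(d) < 1e-14) next
    l1 <- ((tri[2, 2] - tri[3, 2]) * (pu - tri[3, 1]) +
             (tri[3, 1] - tri[2, 1]) * (pv - tri[3, 2])) / d
    l2 <- ((tri[3, 2] - tri[1, 2]) * (pu - tri[3, 1]) +
             (tri[1, 1] - tri[3, 1]) * (pv - tri[3, 2])) / d
    l3 <- 1 - l1 - l2
    eps <- -1e-9
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) next
    w <- l1 * tri[1, 3] + l2 * tri[2, 3] + l3 * tri[3, 3]
    sub <- z[i0:i1, j0:j1]
    sub[inside] <- w[inside]
    z[i0:i1, j0:j1] <- sub
  }
  frac_masked <- mean(is.na(z))
  if (frac_masked > 0.5) {
    stop(sprintf("rasterization failed: %.0f%% of grid nodes uncovered (mesh not a height field over its reference plane?)",
                 100 * frac_masked))
  }
  interpolated <- 0L
  if (anyNA(z)) {
    filled <- apply(z, 2, function(col) zoo::na.approx(col, maxgap = 3, na.rm = FALSE))
    filled <- t(apply(filled, 1, function(row) zoo::na.approx(row, maxgap = 3, na.rm = FALSE)))
    interpolated <- sum(is.na(z) & !is.na(filled))
    z <- filled
  }
  height_map(z, spacing, origin = c(0, 0),
             meta = list(source = "mesh", interpolated_cells = interpolated,
                         reference_plane = coef))
}

#' Read/write height maps as CSV grid + YAML sidecar
#'
#' The grid is stored as a headerless CSV of heights in mm (`NA` for masked
#' cells); the sidecar `<path>.yml` records spacing, units, origin and
#' provenance. Round trips are lossless.
#'
#' @param map a [height_map()].
#' @param path CSV path; the sidecar path is derived from it.
#' @return `read_heightmap` returns a [height_map()]; `write_heightmap`
#'   returns `path` invisibly.
#' @export
write_heightmap <- function(map, path) {
  assert_heightmap(map)
  z <- map$heights
  z[!map$mask] <- NA
  utils::write.table(z, path, sep = ",", row.names = FALSE, col.names = FALSE)
  side <- list(spacing = map$spacing, units = "mm",
               origin = as.numeric(map$origin),
               mask_encoding = "NA cells are masked",
               meta = rapply(map$meta, unclass, how = "replace"))
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(path) {
  sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar)) stop("missing YAML sidecar: ", sidecar)
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$spacing) || side$spacing <= 0) {
    stop("sidecar validation error: spacing must be positive")
  }
  z <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(z) <- NULL
  height_map(z, side$spacing,
             origin = if (!is.null(side$origin)) unlist(side$origin) else c(0, 0),
             meta = if (!is.null(side$meta)) side$meta else list())
}
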