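# Triangulated articular surfaces and STL I/O.
#
# Meshes are generated from the same analytic primitives used for contact
# (spherical caps, spherical dish, planar patch), as lat-long grids with a
# target edge length. They exist for export/visualisation and for reading
# user-supplied surfaces; the simulator itself evaluates contact analytically.

new_surface <- function(side, compartment, vertices, triangles, radius) {
  structure(list(side = side, compartment = compartment,
                 vertices = vertices, triangles = triangles,
                 radius = radius),
            class = "articular_surface")
}

# spherical cap around the -Y pole of a sphere; concave = TRUE flips the
# outward direction (a dish seen from inside the sphere). Constant ring size
# (regular grid) keeps the triangulation manifold with a clean seam.
sphere_cap_mesh <- function(center, radius, half_angle, edge, concave = FALSE) {
  n_rings <- max(2L, ceiling(radius * half_angle / edge))
  m <- max(6L, ceiling(2 * pi * radius * sin(half_angle) / edge))
  phis <- seq(0, half_angle, length.out = n_rings + 1)
  th <- 2 * pi * (seq_len(m) - 1) / m
  verts <- matrix(c(0, -radius, 0), 1, 3)
  for (r in 2:(n_rings + 1)) {
    phi <- phis[r]
    verts <- rbind(verts, cbind(radius * sin(phi) * cos(th),
                                -radius * cos(phi),
                                radius * sin(phi) * sin(th)))
  }
  ring0 <- function(r) 2L + (r - 2L) * m  # first vertex index of ring r (r >= 2)
  tris <- vector("list", n_rings)
  j <- seq_len(m)
  j2 <- j %% m + 1L
  tris[[1]] <- cbind(ring0(2L) + j - 1L, ring0(2L) + j2 - 1L, 1L)  # pole fan
  for (r in 3:(n_rings + 1)) {
    a <- ring0(r - 1L); b <- ring0(r)
    tris[[r - 1L]] <- rbind(cbind(b + j - 1L, b + j2 - 1L, a + j - 1L),
                            cbind(a + j - 1L, b + j2 - 1L, a + j2 - 1L))
  }
  tri <- do.call(rbind, tris)
  verts <- verts + matrix(center, nrow(verts), 3, byrow = TRUE)
  # enforce outward-consistent winding against the analytic normal
  orient_triangles(verts, tri, center, concave)
}

# orient triangle winding so that the geometric normal agrees with the
# analytic outward normal (away from the sphere center; toward it if concave)
orient_triangles <- function(verts, tri, center, concave) {
  for (i in seq_len(nrow(tri))) {
    v <- verts[tri[i, ], ]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    outward <- colMeans(v) - center
    if (concave) outward <- -outward
    if (sum(n * outward) < 0) tri[i, ] <- tri[i, c(1, 3, 2)]
  }
  list(vertices = verts, triangles = tri)
}

plane_patch_mesh <- function(center, halfwidth, edge, normal = c(0, 1, 0)) {
  m <- max(2L, ceiling(2 * halfwidth / edge))
  s <- seq(-halfwidth, halfwidth, length.out = m + 1)
  g <- expand.grid(x = s, z = s)
  verts <- cbind(center[1] + g$x, center[2], center[3] + g$z)
  idx <- function(i, j) (j - 1L) * (m + 1L) + i
  tris <- list()
  for (j in seq_len(m)) for (i in seq_len(m)) {
    # winding gives +Y normals: (x, z), (x+dx, z), (x, z+dz) -> n = dx x dz ...
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
    tris[[length(tris) + 1L]] <- c(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
  }
  tri <- do.call(rbind, tris)
  # orient against the plane normal
  for (i in seq_len(nrow(tri))) {
    v <- verts[tri[i, ], ]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(n * normal) < 0) tri[i, ] <- tri[i, c(1, 3, 2)]
  }
  list(vertices = verts, triangles = tri)
}

#' Generate the triangulated articular surfaces of a knee model
#'
#' @param model a `knee_model`
#' @return named list of four `articular_surface` objects
#'   (`femur_medial`, `femur_lateral`, `tibia_medial`, `tibia_lateral`)
#' @export
build_surfaces <- function(model) {
  g <- model$config$geometry
  edge <- g$mesh_edge
  cm <- model$contact$medial
  cl <- model$contact$lateral
  fm <- sphere_cap_mesh(cm$femur_center, cm$femur_radius, deg2rad(75), edge)
  fl <- sphere_cap_mesh(cl$femur_center, cl$femur_radius, deg2rad(75), edge)
  dish_half <- asin(min(1, g$dish_rim_radius / cm$socket_radius))
  tm <- sphere_cap_mesh(cm$socket_center, cm$socket_radius, dish_half, edge,
                        concave = TRUE)
  tl <- plane_patch_mesh(cl$plane_point, g$lateral_patch_halfwidth, edge,
                         cl$plane_normal)
  list(
    femur_medial = new_surface("femur", "medial", fm$vertices, fm$triangles,
                               cm$femur_radius),
    femur_lateral = new_surface("femur", "lateral", fl$vertices, fl$triangles,
                                cl$femur_radius),
    tibia_medial = new_surface("tibia", "medial", tm$vertices, tm$triangles,
                               cm$socket_radius),
    tibia_lateral = new_surface("tibia", "lateral", tl$vertices, tl$triangles,
                                g$lateral_radius))
}

#' Check manifold and orientation consistency of a triangle mesh
#'
#' Verifies that every edge is used by at most two triangles and that shared
#' edges are traversed in opposite directions (consistent winding), i.e. the
#' mesh is watertight or an open manifold with consistent normals.
#'
#' @param vertices n x 3 matrix
#' @param triangles m x 3 integer matrix (1-based)
#' @return TRUE, or an error describing the defect
#' @export
check_mesh <- function(vertices, triangles) {
  he <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (any(duplicated(key)))
    stop("inconsistent winding: a directed edge is used twice")
  ukey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  if (any(table(ukey) > 2)) stop("non-manifold edge (used by > 2 triangles)")
  TRUE
}

# --- STL I/O ----------------------------------------------------------------

#' Write a triangle mesh to STL
#'
#' @param mesh list with `vertices` (n x 3) and `triangles` (m x 3, 1-based),
#'   e.g. an `articular_surface`
#' @param path output file
#' @param ascii write the ASCII dialect (default: binary little-endian)
#' @param name solid name for the ASCII dialect
#' @return `path`, invisibly
#' @export
write_stl <- function(mesh, path, ascii = FALSE, name = "surface") {
  V <- mesh$vertices
  Tm <- mesh$triangles
  n <- nrow(Tm)
  v1 <- V[Tm[, 1], , drop = FALSE]
  v2 <- V[Tm[, 2], , drop = FALSE]
  v3 <- V[Tm[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  N <- cbind(nx / nn, ny / nn, nz / nn)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", name), con)
    block <- sprintf(
      "  facet normal %.9e %.9e %.9e\n    outer loop\n      vertex %.9e %.9e %.9e\n      vertex %.9e %.9e %.9e\n      vertex %.9e %.9e %.9e\n    endloop\n  endfacet",
      N[, 1], N[, 2], N[, 3],
      v1[, 1], v1[, 2], v1[, 3],
      v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(block, con)
    writeLines(paste("endsolid", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC(name, width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    dat <- t(cbind(N, v1, v2, v3))  # 12 floats per facet
    for (i in seq_len(n)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' Vertices are deduplicated exactly; coordinates are preserved to float32
#' precision (the STL storage precision). Malformed binary files are
#' reported with the byte offset at which the data end prematurely.
#'
#' @param path STL file
#' @return list with `vertices` and `triangles`
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("STL format error: empty file ", path)
  head <- readBin(path, "raw", n = min(sz, 512))
  printable <- head >= as.raw(32) & head <= as.raw(126) | head == as.raw(10)
  head_txt <- tolower(rawToChar(head[printable]))
  is_ascii <- startsWith(trimws(head_txt), "solid") &&
    grepl("facet", head_txt, fixed = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt)
  if (!length(vl)) stop("STL format error: ASCII file with no vertex lines")
  if (length(vl) %% 3 != 0)
    stop("STL format error: vertex count not a multiple of 3")
  parts <- strsplit(trimws(txt[vl]), "\\s+")
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords)) stop("STL format error: unparseable vertex coordinates")
  soup_to_mesh(coords)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84)
    stop("STL format error: truncated header at byte offset ", sz)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  expected <- 84 + 50 * n
  if (sz < expected)
    stop("STL format error: expected ", expected, " bytes for ", n,
         " facets, data end at byte offset ", sz)
  coords <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  soup_to_mesh(coords)
}

soup_to_mesh <- function(coords) {
  key <- apply(coords, 1, paste, collapse = ",")
  uid <- !duplicated(key)
  verts <- coords[uid, , drop = FALSE]
  index <- match(key, key[uid])
  tri <- matrix(index, ncol = 3, byrow = TRUE)
  list(vertices = verts, triangles = tri)
}

#' Write all articular surfaces of a model as STL files
#'
#' @param model a `knee_model`
#' @param dir output directory (created if missing)
#' @param ascii write ASCII STL instead of binary
#' @return named character vector of file paths, invisibly
#' @export
write_surfaces <- function(model, dir, ascii = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surfaces <- build_surfaces(model)
  paths <- vapply(names(surfaces), function(nm) {
    p <- file.path(dir, paste0(nm, ".stl"))
    write_stl(surfaces[[nm]], p, ascii = ascii, name = nm)
    p
  }, character(1))
  invisible(paths)
}

#' Read articular surface STL files from a directory
#'
#' @param dir directory containing `*.stl`
#' @return named list of meshes
#' @export
read_surfaces <- function(dir) {
  files <- list.files(dir, pattern = "\\.stl$", full.names = TRUE)
  if (!length(files)) stop("no STL files found in ", dir)
  out <- lapply(files, read_stl)
  names(out) <- sub("\\.stl$", "", basename(files))
  out
}
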