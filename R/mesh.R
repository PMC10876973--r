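# Triangular surface meshes for ensemble EEG power estimation, with ASCII
# OFF/PLY I/O and two built-in generators (flat square, icosphere).

#' Triangular surface mesh
#'
#' @param vertices `n x 3` matrix of coordinates, mm.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @param mu neuron density per mm^2 of surface (default 1e5).
#' @return object of class `cortical_mesh` with per-face `areas` (mm^2) and
#'   unit `normals`, plus a `watertight` flag (every edge shared by exactly
#'   two faces).
#' @export
cortical_mesh <- function(vertices, faces, mu = 1e5) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  a <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  b <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- sqrt(rowSums(cr^2))
  if (any(nrm < 1e-12)) stop("degenerate face (zero area)", call. = FALSE)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  watertight <- all(table(ek) == 2)
  structure(list(vertices = vertices, faces = faces, areas = nrm / 2,
                 normals = cr / nrm, mu = mu, watertight = watertight),
            class = "cortical_mesh")
}

#' @rdname cortical_mesh
#' @param side edge length of the square, mm.
#' @param n grid subdivisions per side.
#' @export
flat_square_mesh <- function(side = 100, n = 8, mu = 1e5) {
  g <- seq(0, side, length.out = n + 1)
  vid <- function(i, j) (j - 1) * (n + 1) + i
  verts <- cbind(rep(g, n + 1), rep(g, each = n + 1), 0)
  faces <- NULL
  for (j in seq_len(n)) for (i in seq_len(n)) {
    v00 <- vid(i, j); v10 <- vid(i + 1, j)
    v01 <- vid(i, j + 1); v11 <- vid(i + 1, j + 1)
    faces <- rbind(faces, c(v00, v10, v11), c(v00, v11, v01))
  }
  cortical_mesh(verts, faces, mu = mu)
}

#' @rdname cortical_mesh
#' @param radius sphere radius, mm.
#' @param subdivisions icosphere subdivision level (default 4).
#' @export
icosphere_mesh <- function(radius = 50, subdivisions = 4, mu = 1e5) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_cache[[key]]
      if (!is.null(m)) return(m)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  cortical_mesh(v * radius, f, mu = mu)
}

#' Read / write meshes as ASCII OFF or PLY
#'
#' @param path file path; format chosen by extension (`.off` / `.ply`).
#' @param mesh a [cortical_mesh()].
#' @param mu neuron density attached to the mesh on read.
#' @return `read_mesh` returns a [cortical_mesh()].
#' @export
read_mesh <- function(path, mu = 1e5) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    stopifnot(trimws(lines[1]) == "OFF")
    counts <- scan(text = lines[2], quiet = TRUE)
    nv <- counts[1]; nf <- counts[2]
    verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3,
                    byrow = TRUE)
    fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 nf, 4, byrow = TRUE)
    stopifnot(all(fl[, 1] == 3))
    cortical_mesh(verts, fl[, 2:4] + 1, mu = mu)
  } else if (ext == "ply") {
    hdr_end <- which(trimws(lines) == "end_header")[1]
    nv <- as.integer(sub(".*element vertex ", "",
                         grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face ", "",
                         grep("element face", lines, value = TRUE)[1]))
    verts <- matrix(scan(text = lines[hdr_end + 1:nv], quiet = TRUE), nv, 3,
                    byrow = TRUE)
    fl <- matrix(scan(text = lines[hdr_end + nv + 1:nf], quiet = TRUE), nf, 4,
                 byrow = TRUE)
    stopifnot(all(fl[, 1] == 3))
    cortical_mesh(verts, fl[, 2:4] + 1, mu = mu)
  } else stop("unsupported mesh format: ", ext, call. = FALSE)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  vtxt <- apply(mesh$vertices, 1, paste, collapse = " ")
  ftxt <- apply(mesh$faces - 1, 1, function(r) paste(c(3, r), collapse = " "))
  if (ext == "off") {
    writeLines(c("OFF", paste(nv, nf, 0), vtxt, ftxt), path)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nv),
                 "property float x", "property float y", "property float z",
                 paste("element face", nf),
                 "property list uchar int vertex_indices", "end_header",
                 vtxt, ftxt), path)
  } else stop("unsupported mesh format: ", ext, call. = FALSE)
  invisible(path)
}
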