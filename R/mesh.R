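# Triangular surface meshes ------------------------------------------------
#
# A surface_mesh is a list with
#   vertices : n x 3 numeric matrix, coordinates in mm
#   faces    : m x 3 integer matrix, 1-based vertex indices, counter-clockwise
#              when viewed from outside (outward normals)
#   boundary : logical n-vector, TRUE where the vertex lies on an open
#              boundary edge or was marked as a cap by a generator

#' Construct a triangular surface mesh
#'
#' Builds a [surface_mesh] from a vertex coordinate matrix and a face index
#' matrix, optionally cleaning it: duplicate vertices are merged within a
#' tolerance of `merge_tol` times the bounding-box diagonal, faces with
#' repeated indices are dropped, duplicate faces are dropped, and
#' unreferenced vertices are removed. Boundary vertices (incident to an edge
#' bordered by exactly one face) are flagged.
#'
#' @param vertices numeric matrix with 3 columns (coordinates in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param clean logical; merge duplicates and drop degenerate faces.
#' @param merge_tol vertex merge tolerance as a fraction of the bounding-box
#'   diagonal.
#' @param boundary optional logical vector of generator-supplied boundary /
#'   cap flags; combined (OR) with the topological boundary flags.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, clean = TRUE, merge_tol = 1e-8,
                         boundary = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    tm_stop("`vertices` must have 3 columns", "tm_bad_mesh")
  if (ncol(faces) != 3L)
    tm_stop("faces must be triangles (3 indices per face)",
            "tm_unsupported_topology")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    tm_stop("face indices out of range", "tm_bad_mesh")
  if (!is.null(boundary) && length(boundary) != nrow(vertices))
    tm_stop("`boundary` length must equal the vertex count", "tm_bad_mesh")

  mesh <- structure(
    list(vertices = vertices, faces = faces,
         boundary = if (is.null(boundary)) logical(nrow(vertices))
                    else as.logical(boundary)),
    class = "surface_mesh")
  if (clean) mesh <- clean_mesh(mesh, merge_tol = merge_tol)
  mesh$boundary <- mesh$boundary | boundary_vertices(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", n_vertices(x),
              n_faces(x)))
  nb <- sum(x$boundary)
  if (nb > 0) cat(sprintf(", %d boundary vertices", nb))
  cat(sprintf("\n  area %.3f cm^2, Euler characteristic %d\n",
              surface_area(x), euler_characteristic(x)))
  invisible(x)
}

#' Vertex and face counts
#' @param mesh a [surface_mesh].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Unique undirected edges as a 2-column matrix (each row sorted).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh].
#' @return Integer; 2 for a watertight genus-0 mesh.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

#' Is every edge shared by exactly two faces?
#' @param mesh a [surface_mesh].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

# Logical flags for vertices incident to an edge bordering exactly one face.
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  out <- logical(n_vertices(mesh))
  if (nrow(f) == 0L) return(out)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  open <- names(cnt)[cnt == 1L]
  if (length(open)) {
    idx <- do.call(rbind, strsplit(open, " ", fixed = TRUE))
    out[as.integer(idx)] <- TRUE
  }
  out
}

# Merge coincident vertices, drop degenerate and duplicate faces, drop
# unreferenced vertices. Tolerance is relative to the bounding-box diagonal.
clean_mesh <- function(mesh, merge_tol = 1e-8) {
  v <- mesh$vertices
  f <- mesh$faces
  b <- mesh$boundary
  if (nrow(v) == 0L) return(mesh)
  diag_len <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  tol <- merge_tol * max(diag_len, .Machine$double.eps)
  # grid snapping: vertices falling in the same tol-cell are merged
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])  # values are 1..k in first-seen order
  v <- v[first, , drop = FALSE]
  b <- rowsum(as.numeric(b), remap)[, 1] > 0  # OR of merged flags
  if (nrow(f) > 0L) {
    f[] <- remap[f]
    # degenerate: repeated index within a face
    ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[ok, , drop = FALSE]
    # duplicate faces irrespective of rotation/orientation
    fkey <- apply(f, 1L, function(r) paste(sort(r), collapse = " "))
    f <- f[!duplicated(fkey), , drop = FALSE]
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap2 <- integer(nrow(v))
    remap2[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    b <- b[used]
    if (nrow(f) > 0L) f[] <- remap2[f]
  }
  structure(list(vertices = v, faces = f, boundary = b),
            class = "surface_mesh")
}

#' Vertex adjacency of a mesh
#'
#' Builds the symmetric edge graph of the mesh: two vertices are neighbors
#' iff they share a face edge. This graph carries the edge-count distance r
#' used by the topographical pair correlation function.
#'
#' @param mesh a [surface_mesh].
#' @return An object of class `vertex_adjacency`: a list with `neighbors`
#'   (list of integer vectors) and `n` (vertex count).
#' @export
vertex_adjacency <- function(mesh) {
  n <- n_vertices(mesh)
  e <- mesh_edges(mesh)
  nb <- vector("list", n)
  if (nrow(e) > 0L) {
    ii <- c(e[, 1L], e[, 2L])
    jj <- c(e[, 2L], e[, 1L])
    o <- order(ii)
    nb_split <- split(jj[o], factor(ii[o], levels = seq_len(n)))
    nb <- unname(lapply(nb_split, function(x) sort(unique(as.integer(x)))))
  }
  structure(list(neighbors = nb, n = n), class = "vertex_adjacency")
}

#' @export
print.vertex_adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("vertex_adjacency: %d vertices, %d edges, valence %d-%d\n",
              x$n, sum(deg) / 2L, min(deg), max(deg)))
  invisible(x)
}

# Induced subgraph of an adjacency on `keep` (logical or index vector);
# vertices are renumbered 1..sum(keep) in original order.
subset_adjacency <- function(adj, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  remap <- integer(adj$n)
  remap[idx] <- seq_along(idx)
  nb <- lapply(adj$neighbors[idx], function(v) {
    r <- remap[v]
    r[r > 0L]
  })
  structure(list(neighbors = nb, n = length(idx)), class = "vertex_adjacency")
}

#' Total surface area
#'
#' Sum of the areas of all triangles. Coordinates are in mm; the result is
#' reported in cm^2 (the scale on which aortic surface areas are usually
#' quoted, 100-1000 cm^2).
#'
#' @param mesh a [surface_mesh].
#' @return Area in cm^2.
#' @export
surface_area <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  v <- mesh$vertices
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- row_cross(a, b)
  sum(sqrt(rowSums(cr^2))) / 2 / 100  # mm^2 -> cm^2
}

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a^2))

# Normalize rows; zero rows are left at zero.
row_unit <- function(a) {
  n <- row_norm(a)
  n[n == 0] <- 1
  a / n
}

# Signed volume via the divergence theorem; positive for outward-oriented
# watertight meshes.
signed_volume <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  p0 <- v[f[, 1L], , drop = FALSE]
  p1 <- v[f[, 2L], , drop = FALSE]
  p2 <- v[f[, 3L], , drop = FALSE]
  sum(rowSums(p0 * row_cross(p1 - p0, p2 - p0))) / 6
}
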