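# Mesh file input/output ----------------------------------------------------
#
# Supported formats: STL (ascii and binary), PLY (ascii), OBJ, OFF.
# STL stores vertices per facet, so loading always re-merges coincident
# vertices before the edge graph is built.

format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("stl", "ply", "obj", "off"))
    tm_stop(sprintf("cannot infer mesh format from extension '.%s'", ext),
            "tm_format_error")
  ext
}

#' Read a triangular surface mesh from file
#'
#' Reads STL (ascii or binary, auto-detected), PLY (ascii), OBJ or OFF and
#' returns a cleaned [surface_mesh]: coincident vertices merged within
#' 1e-8 of the bounding-box diagonal, degenerate faces dropped, boundary
#' vertices flagged. Non-triangular faces are refused.
#'
#' @param path file path.
#' @param fmt one of `"stl"`, `"ply"`, `"obj"`, `"off"`; inferred from the
#'   file extension when missing.
#' @return A [surface_mesh].
#' @export
load_mesh <- function(path, fmt = NULL) {
  if (!file.exists(path))
    tm_stop(sprintf("file not found: %s", path), "tm_format_error")
  fmt <- tolower(if (is.null(fmt)) format_from_path(path) else fmt)
  raw <- switch(fmt,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    off = read_off(path),
    tm_stop(sprintf("unsupported format '%s'", fmt), "tm_format_error"))
  surface_mesh(raw$vertices, raw$faces, clean = TRUE)
}

#' Write a triangular surface mesh to file
#'
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @param fmt one of `"stl"` (ascii), `"stl_binary"`, `"ply"`, `"obj"`,
#'   `"off"`; inferred from the extension when missing (`.stl` writes binary).
#' @param attributes optional data frame of per-vertex scalar attributes,
#'   written as extra vertex properties (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = NULL, attributes = NULL) {
  fmt <- tolower(if (is.null(fmt)) {
    e <- format_from_path(path)
    if (e == "stl") "stl_binary" else e
  } else fmt)
  switch(fmt,
    stl        = write_stl_ascii(mesh, path),
    stl_binary = write_stl_binary(mesh, path),
    ply        = write_ply(mesh, path, attributes),
    obj        = write_obj(mesh, path),
    off        = write_off(mesh, path),
    tm_stop(sprintf("unsupported format '%s'", fmt), "tm_format_error"))
  invisible(path)
}

# STL -----------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  close(con)
  # binary STL: 80-byte header + uint32 count; ascii starts with "solid"
  # but that prefix alone is not reliable, so check the facet count against
  # the file size.
  is_binary <- {
    sz <- file.size(path)
    if (sz >= 84) {
      con <- file(path, "rb")
      invisible(readBin(con, "raw", n = 80L))
      nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      close(con)
      !is.na(nfac) && nfac >= 0 && sz == 84 + 50 * as.numeric(nfac)
    } else FALSE
  }
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = 50L * nfac)
  if (length(rec) < 50L * nfac)
    tm_stop("truncated binary STL", "tm_format_error")
  m <- matrix(rec, nrow = 50L)
  coords <- vapply(seq_len(nfac), function(i) {
    readBin(m[13:48, i], "double", n = 9L, size = 4L, endian = "little")
  }, numeric(9L))
  verts <- matrix(as.vector(coords), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nfac), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- grep("^vertex[ \t]", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    tm_stop("not a valid ascii STL (vertex count not a multiple of 3)",
            "tm_format_error")
  nums <- lapply(strsplit(sub("^vertex[ \t]+", "", vl), "[ \t]+"), as.numeric)
  if (any(lengths(nums) != 3L) || anyNA(unlist(nums)))
    tm_stop("malformed vertex line in ascii STL", "tm_format_error")
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

stl_facet_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  row_unit(row_cross(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
                     v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]))
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- stl_facet_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid tpcfmesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (c in 1:3) {
      p <- v[f[i, c], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]),
                 con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid tpcfmesh", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- stl_facet_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- rbind(nrm[i, ], v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ])
    writeBin(as.numeric(t(tri)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

# PLY (ascii) ---------------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    tm_stop("not a PLY file", "tm_format_error")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) tm_stop("PLY header not terminated", "tm_format_error")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr)))
    tm_stop("only ascii PLY is supported", "tm_format_error")
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    tm_stop("PLY header lacks vertex/face elements", "tm_format_error")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtxt <- strsplit(trimws(body[seq_len(nv)]), "[ \t]+")
  verts <- t(vapply(vtxt, function(x) as.numeric(x[1:3]), numeric(3L)))
  ftxt <- strsplit(trimws(body[nv + seq_len(nf)]), "[ \t]+")
  fnum <- lapply(ftxt, as.integer)
  cnt <- vapply(fnum, `[`, integer(1L), 1L)
  if (any(cnt != 3L))
    tm_stop("PLY contains non-triangular faces", "tm_unsupported_topology")
  faces <- t(vapply(fnum, function(x) x[2:4], integer(3L))) + 1L
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path, attributes = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  prop_lines <- c("property double x", "property double y",
                  "property double z")
  attr_txt <- NULL
  if (!is.null(attributes)) {
    attributes <- as.data.frame(attributes)
    stopifnot(nrow(attributes) == nrow(v))
    prop_lines <- c(prop_lines,
                    sprintf("property double %s", names(attributes)))
    attr_txt <- do.call(cbind, lapply(attributes, function(col)
      sprintf("%.17g", as.numeric(col))))
  }
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)), prop_lines,
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  vtxt <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  if (!is.null(attr_txt))
    vtxt <- paste(vtxt, apply(attr_txt, 1L, paste, collapse = " "))
  writeLines(vtxt, con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

# OBJ -----------------------------------------------------------------------

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v[ \t]", lines, value = TRUE)
  fl <- grep("^f[ \t]", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    tm_stop("OBJ file has no vertices or faces", "tm_format_error")
  verts <- t(vapply(strsplit(sub("^v[ \t]+", "", vl), "[ \t]+"),
                    function(x) as.numeric(x[1:3]), numeric(3L)))
  ftok <- strsplit(sub("^f[ \t]+", "", fl), "[ \t]+")
  if (any(lengths(ftok) != 3L))
    tm_stop("OBJ contains non-triangular faces", "tm_unsupported_topology")
  faces <- t(vapply(ftok, function(x)
    as.integer(sub("/.*$", "", x)), integer(3L)))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}

# OFF -----------------------------------------------------------------------

read_off <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || lines[1] != "OFF")
    tm_stop("not an OFF file", "tm_format_error")
  counts <- as.integer(strsplit(lines[2], "[ \t]+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- t(vapply(strsplit(lines[2 + seq_len(nv)], "[ \t]+"),
                    function(x) as.numeric(x[1:3]), numeric(3L)))
  fnum <- lapply(strsplit(lines[2 + nv + seq_len(nf)], "[ \t]+"), as.integer)
  if (any(vapply(fnum, `[`, integer(1L), 1L) != 3L))
    tm_stop("OFF contains non-triangular faces", "tm_unsupported_topology")
  faces <- t(vapply(fnum, function(x) x[2:4], integer(3L))) + 1L
  list(vertices = verts, faces = faces)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("OFF",
               sprintf("%d %d %d", nrow(v), nrow(f), 0L),
               sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
}
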