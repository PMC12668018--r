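# Decimation to a fixed element count --------------------------------------

#' Decimate a mesh to an exact face count
#'
#' Simplifies the mesh by iterative edge collapse ordered by quadric error
#' (Garland-Heckbert) until exactly `target_faces` triangles remain.
#' Collapsing every mesh to the same element count makes graph distances
#' comparable across meshes of very different physical size, which is the
#' premise of the edge-distance pair correlation analysis; 5000 elements is
#' the reference count used for aortic surfaces. Boundary rims are held in
#' place by penalty quadrics, so open meshes can be decimated too.
#'
#' @param mesh a [surface_mesh].
#' @param target_faces requested face count; must not exceed the current
#'   count.
#' @param boundary_weight weight of the boundary-edge penalty quadric.
#' @param hausdorff logical; attach a sampled two-sided vertex-to-vertex
#'   Hausdorff distance estimate (mm) between input and output as attribute
#'   `"hausdorff_mm"` (a diagnostic, not an exact surface distance).
#' @return A [surface_mesh] with exactly `target_faces` faces.
#' @export
decimate_to_count <- function(mesh, target_faces, boundary_weight = 1e3,
                              hausdorff = TRUE) {
  target_faces <- as.integer(target_faces)
  if (target_faces <= 0L)
    tm_stop("`target_faces` must be positive", "tm_usage_error")
  if (target_faces > n_faces(mesh))
    tm_stop(sprintf(
      "cannot upsample: target %d exceeds current face count %d",
      target_faces, n_faces(mesh)), "tm_cannot_upsample")
  if (target_faces == n_faces(mesh)) {
    if (hausdorff) attr(mesh, "hausdorff_mm") <- 0
    return(mesh)
  }
  res <- qem_decimate_cpp(mesh$vertices, mesh$faces - 1L, target_faces,
                          boundary_weight)
  if (res$faces_left != target_faces)
    tm_stop(sprintf(
      "decimation stalled at %d faces (target %d); mesh may be non-manifold or the target unreachable by manifold collapses",
      res$faces_left, target_faces), "tm_decimation_failed")
  out <- surface_mesh(res$vertices, res$faces + 1L, clean = FALSE)
  if (n_faces(out) != target_faces)
    tm_stop("decimation produced degenerate faces", "tm_decimation_failed")
  if (hausdorff)
    attr(out, "hausdorff_mm") <- hausdorff_estimate(mesh$vertices,
                                                    out$vertices)
  out
}

#' Decimation target from a constant element density
#'
#' Alternative meshing mode: instead of a fixed element count, request a
#' fixed number of faces per unit area (faces per cm^2), so that element
#' size is constant across a cohort and larger surfaces get more elements.
#'
#' @param mesh a [surface_mesh].
#' @param density faces per cm^2.
#' @return Integer face target, `round(area * density)` clamped to at least
#'   4 and at most the current face count.
#' @export
density_face_target <- function(mesh, density) {
  if (density <= 0) tm_stop("`density` must be positive", "tm_usage_error")
  min(max(4L, as.integer(round(surface_area(mesh) * density))), n_faces(mesh))
}

# Sampled symmetric vertex-to-nearest-vertex Hausdorff distance. Cheap
# diagnostic; an upper-bound flavored estimate, not exact point-to-surface.
hausdorff_estimate <- function(va, vb, max_sample = 1000L) {
  one_sided <- function(a, b) {
    if (nrow(a) > max_sample)
      a <- a[seq(1L, nrow(a), length.out = max_sample), , drop = FALSE]
    mx <- 0
    step <- 2000L
    for (s in seq(1L, nrow(a), by = step)) {
      blk <- a[s:min(s + step - 1L, nrow(a)), , drop = FALSE]
      d2 <- outer(rowSums(blk^2), rowSums(b^2), "+") -
        2 * tcrossprod(blk, b)
      mx <- max(mx, sqrt(pmax(0, apply(d2, 1L, min))))
    }
    mx
  }
  max(one_sided(va, vb), one_sided(vb, va))
}
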