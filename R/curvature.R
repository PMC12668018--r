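# Per-vertex principal curvatures ------------------------------------------
#
# Estimator: per-face second fundamental forms from finite differences of
# vertex normals along the face edges (least squares in the face tangent
# frame), averaged into per-vertex shape operators with mixed-Voronoi-area
# corner weights, then eigen-decomposed. Sign convention: with outward
# normals a sphere has k1 = k2 = +1/R.

# Angle-weighted vertex normals. Assumes consistently oriented faces.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- n_vertices(mesh)
  p0 <- v[f[, 1L], , drop = FALSE]
  p1 <- v[f[, 2L], , drop = FALSE]
  p2 <- v[f[, 3L], , drop = FALSE]
  fn <- row_unit(row_cross(p1 - p0, p2 - p0))
  ang <- corner_angles(p0, p1, p2)
  vn <- matrix(0, n, 3L)
  for (c in 1:3) {
    w <- ang[, c]
    acc <- rowsum(fn * w, f[, c])
    idx <- as.integer(rownames(acc))
    vn[idx, ] <- vn[idx, ] + acc
  }
  row_unit(vn)
}

# Interior angles at corners 1..3 of each face; columns match face columns.
corner_angles <- function(p0, p1, p2) {
  ang_at <- function(a, b, c) {
    u <- b - a
    w <- c - a
    cosang <- rowSums(u * w) / pmax(row_norm(u) * row_norm(w),
                                    .Machine$double.xmin)
    acos(pmin(1, pmax(-1, cosang)))
  }
  cbind(ang_at(p0, p1, p2), ang_at(p1, p2, p0), ang_at(p2, p0, p1))
}

# Mixed Voronoi corner areas (Meyer et al.), clamped for obtuse triangles:
# the obtuse corner gets area/2, the other two area/4.
corner_areas <- function(p0, p1, p2) {
  ang <- corner_angles(p0, p1, p2)
  area <- row_norm(row_cross(p1 - p0, p2 - p0)) / 2
  cot <- function(x) cos(x) / pmax(sin(x), 1e-12)
  l01 <- rowSums((p1 - p0)^2)
  l12 <- rowSums((p2 - p1)^2)
  l20 <- rowSums((p0 - p2)^2)
  # Voronoi area of corner i: (|e_ij|^2 cot(angle_k) + |e_ik|^2 cot(angle_j))/8
  a0 <- (l01 * cot(ang[, 3]) + l20 * cot(ang[, 2])) / 8
  a1 <- (l01 * cot(ang[, 3]) + l12 * cot(ang[, 1])) / 8
  a2 <- (l20 * cot(ang[, 2]) + l12 * cot(ang[, 1])) / 8
  w <- cbind(a0, a1, a2)
  obtuse <- ang > pi / 2
  any_obtuse <- rowSums(obtuse) > 0L
  if (any(any_obtuse)) {
    for (c in 1:3) {
      w[any_obtuse, c] <- ifelse(obtuse[any_obtuse, c],
                                 area[any_obtuse] / 2,
                                 area[any_obtuse] / 4)
    }
  }
  w
}

#' Per-vertex principal curvatures
#'
#' Estimates the maximum and minimum signed normal curvatures (kappa1 >=
#' kappa2, units 1/mm) at every vertex by averaging per-face shape-operator
#' estimates with mixed-Voronoi-area weights. The faces must be
#' consistently oriented with outward normals; then convex regions (sphere)
#' have positive curvatures.
#'
#' @param mesh a [surface_mesh] (cleaned, consistently oriented).
#' @return An object of class `principal_curvatures`: list with `kappa1`,
#'   `kappa2` (numeric n-vectors, 1/mm), `dir1`, `dir2` (n x 3 unit tangent
#'   matrices, diagnostic), `normals` (n x 3), and `boundary` copied from
#'   the mesh.
#' @export
principal_curvatures <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L)
    tm_stop("mesh has no faces", "tm_bad_mesh")
  n <- n_vertices(mesh)
  vn <- vertex_normals(mesh)
  if (any(rowSums(vn^2) < 0.5))
    tm_stop("mesh appears unoriented or non-manifold (zero vertex normals)",
            "tm_orientation_error")

  p0 <- v[f[, 1L], , drop = FALSE]
  p1 <- v[f[, 2L], , drop = FALSE]
  p2 <- v[f[, 3L], , drop = FALSE]
  n0 <- vn[f[, 1L], , drop = FALSE]
  n1 <- vn[f[, 2L], , drop = FALSE]
  n2 <- vn[f[, 3L], , drop = FALSE]

  fn <- row_unit(row_cross(p1 - p0, p2 - p0))
  fu <- row_unit(p1 - p0)            # face tangent frame (fu, fv, fn)
  fv <- row_cross(fn, fu)

  # least-squares second fundamental form per face from the three edges
  e0 <- p2 - p1; d0 <- n2 - n1
  e1 <- p0 - p2; d1 <- n0 - n2
  e2 <- p1 - p0; d2 <- n1 - n0
  a0 <- rowSums(e0 * fu); b0 <- rowSums(e0 * fv)
  a1 <- rowSums(e1 * fu); b1 <- rowSums(e1 * fv)
  a2 <- rowSums(e2 * fu); b2 <- rowSums(e2 * fv)
  c0 <- rowSums(d0 * fu); q0 <- rowSums(d0 * fv)
  c1 <- rowSums(d1 * fu); q1 <- rowSums(d1 * fv)
  c2 <- rowSums(d2 * fu); q2 <- rowSums(d2 * fv)

  M11 <- a0^2 + a1^2 + a2^2
  M33 <- b0^2 + b1^2 + b2^2
  M12 <- a0 * b0 + a1 * b1 + a2 * b2
  M22 <- M11 + M33
  M23 <- M12
  r1 <- a0 * c0 + a1 * c1 + a2 * c2
  r2 <- b0 * c0 + b1 * c1 + b2 * c2 + a0 * q0 + a1 * q1 + a2 * q2
  r3 <- b0 * q0 + b1 * q1 + b2 * q2

  det3 <- function(x11, x12, x13, x21, x22, x23, x31, x32, x33)
    x11 * (x22 * x33 - x23 * x32) - x12 * (x21 * x33 - x23 * x31) +
      x13 * (x21 * x32 - x22 * x31)
  D  <- det3(M11, M12, 0,  M12, M22, M23, 0,  M23, M33)
  Du <- det3(r1,  M12, 0,  r2,  M22, M23, r3, M23, M33)
  Dm <- det3(M11, r1,  0,  M12, r2,  M23, 0,  r3,  M33)
  Dv <- det3(M11, M12, r1, M12, M22, r2,  0,  M23, r3)
  scale_d <- pmax((M11 + M22 + M33) / 3, .Machine$double.xmin)^3
  ok <- abs(D) > 1e-12 * scale_d
  euu <- ifelse(ok, Du / D, 0)
  euv <- ifelse(ok, Dm / D, 0)
  evv <- ifelse(ok, Dv / D, 0)

  # per-corner: rotate the face tensor into each vertex's tangent frame
  w <- corner_areas(p0, p1, p2)
  vu <- tangent_basis_u(vn)
  vv2 <- row_cross(vn, vu)

  Auu <- numeric(n); Auv <- numeric(n); Avv <- numeric(n); W <- numeric(n)
  for (c in 1:3) {
    vid <- f[, c]
    nvv <- vn[vid, , drop = FALSE]
    rot <- rotate_between(fn, nvv)            # list(uf, vf) rotated frame
    ufr <- rot$apply(fu)
    vfr <- rot$apply(fv)
    uvb <- vu[vid, , drop = FALSE]
    vvb <- vv2[vid, , drop = FALSE]
    r11 <- rowSums(uvb * ufr); r12 <- rowSums(uvb * vfr)
    r21 <- rowSums(vvb * ufr); r22 <- rowSums(vvb * vfr)
    nuu <- r11^2 * euu + 2 * r11 * r12 * euv + r12^2 * evv
    nuv <- r11 * r21 * euu + (r11 * r22 + r12 * r21) * euv + r12 * r22 * evv
    nvvt <- r21^2 * euu + 2 * r21 * r22 * euv + r22^2 * evv
    wc <- w[, c]
    acc <- rowsum(cbind(wc * nuu, wc * nuv, wc * nvvt, wc), vid)
    idx <- as.integer(rownames(acc))
    Auu[idx] <- Auu[idx] + acc[, 1]
    Auv[idx] <- Auv[idx] + acc[, 2]
    Avv[idx] <- Avv[idx] + acc[, 3]
    W[idx] <- W[idx] + acc[, 4]
  }
  W <- pmax(W, .Machine$double.xmin)
  Auu <- Auu / W; Auv <- Auv / W; Avv <- Avv / W

  h <- (Auu + Avv) / 2
  delta <- sqrt(((Auu - Avv) / 2)^2 + Auv^2)
  k1 <- h + delta
  k2 <- h - delta
  # principal direction of k1 in the vertex tangent frame
  dx <- ifelse(abs(Auv) > 1e-30, Auv, 1)
  dy <- ifelse(abs(Auv) > 1e-30, k1 - Auu, 0)
  dl <- sqrt(dx^2 + dy^2)
  dir1 <- (dx / dl) * vu + (dy / dl) * vv2
  dir2 <- row_cross(vn, dir1)

  structure(list(kappa1 = k1, kappa2 = k2, dir1 = dir1, dir2 = dir2,
                 normals = vn, boundary = mesh$boundary),
            class = "principal_curvatures")
}

#' @export
print.principal_curvatures <- function(x, ...) {
  cat(sprintf(
    "principal_curvatures: %d vertices\n  kappa1 [%.4g, %.4g], kappa2 [%.4g, %.4g] (1/mm)\n",
    length(x$kappa1), min(x$kappa1), max(x$kappa1), min(x$kappa2),
    max(x$kappa2)))
  invisible(x)
}

# Any unit vector field orthogonal to the given unit normals.
tangent_basis_u <- function(nrm) {
  # pick the global axis least aligned with each normal
  ax <- matrix(0, nrow(nrm), 3L)
  which_min <- max.col(-abs(nrm))
  ax[cbind(seq_len(nrow(nrm)), which_min)] <- 1
  row_unit(row_cross(nrm, ax))
}

# Minimal rotation taking unit vectors `from` onto unit vectors `to`
# (Rodrigues), returned as a closure applied to row-matched vectors.
# Nearly antipodal normals fall back to projection onto the target plane.
rotate_between <- function(from, to) {
  axis <- row_cross(from, to)
  s <- row_norm(axis)
  cth <- rowSums(from * to)
  k <- axis / pmax(s, .Machine$double.xmin)
  degen <- s < 1e-12
  anti <- cth < -0.9
  list(apply = function(x) {
    kx <- row_cross(k, x)
    kdx <- rowSums(k * x)
    out <- x * cth + kx * s + k * kdx * (1 - cth)
    if (any(degen)) out[degen, ] <- x[degen, , drop = FALSE]
    if (any(anti)) {
      # project onto the plane of `to` and renormalize
      pr <- x[anti, , drop = FALSE] -
        to[anti, , drop = FALSE] *
          rowSums(x[anti, , drop = FALSE] * to[anti, , drop = FALSE])
      out[anti, ] <- row_unit(pr) *
        row_norm(x[anti, , drop = FALSE])
    }
    out
  })
}
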