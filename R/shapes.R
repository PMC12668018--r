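# Synthetic calibration shapes ----------------------------------------------
#
# Ideal and perturbed spheres and cylinders calibrate the curvature
# estimator and the TPCF: an ideal shape has a constant (or
# deterministically varying) curvature field, so its TPCF plateaus at 1; a
# perturbed shape decorrelates, with a plateau level set by the
# perturbation intensity.

#' Icosphere
#'
#' Icosahedron subdivided `subdivisions` times, vertices projected to the
#' requested radius; watertight, 20 * 4^subdivisions faces, outward
#' orientation.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 face subdivisions (>= 0).
#' @return A [surface_mesh].
#' @export
make_sphere <- function(radius = 10, subdivisions = 4L) {
  if (radius <= 0) tm_stop("`radius` must be positive", "tm_usage_error")
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L)
    tm_stop("`subdivisions` must be >= 0", "tm_usage_error")
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  phi, 0,   1,  phi, 0,  -1, -phi, 0,   1, -phi, 0,
     0, -1,  phi,  0,  1,  phi,  0, -1, -phi,  0,  1, -phi,
     phi, 0, -1,   phi, 0,  1,  -phi, 0, -1,  -phi, 0,  1),
    ncol = 3L, byrow = TRUE)
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
    ncol = 3L, byrow = TRUE)
  for (i in seq_len(subdivisions)) {
    sub <- subdivide_once(v, f)
    v <- sub$vertices
    f <- sub$faces
  }
  v <- v * (radius / row_norm(v))
  mesh <- surface_mesh(v, f, clean = FALSE)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# Loop-style 4-to-1 topological subdivision with shared edge midpoints.
subdivide_once <- function(v, f) {
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(ekey)
  eidx <- match(ekey, uk)                       # per face-edge midpoint id
  ue <- e[!duplicated(ekey), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mid_id <- nrow(v) + eidx
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23),
                cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = newf)
}

#' Cylinder mesh
#'
#' Lateral surface triangulated on a `sections` x `segments` angular/axial
#' grid, axis along z from 0 to `height`, outward orientation. Open
#' cylinders have their two rim rings boundary-flagged; capped cylinders
#' are watertight, with the cap fans (rim rings and apex vertices) marked
#' as generator caps so curvature analysis can exclude the crease.
#'
#' @param radius cylinder radius (mm).
#' @param height cylinder height (mm).
#' @param sections angular subdivisions (>= 3).
#' @param segments axial subdivisions (>= 1).
#' @param capped close the ends with triangle fans.
#' @return A [surface_mesh]; `2 * sections * segments` lateral faces.
#' @export
make_cylinder <- function(radius = 10, height = 100, sections = 64L,
                          segments = 40L, capped = FALSE) {
  if (radius <= 0 || height <= 0)
    tm_stop("`radius` and `height` must be positive", "tm_usage_error")
  sections <- as.integer(sections)
  segments <- as.integer(segments)
  if (sections < 3L || segments < 1L)
    tm_stop("need `sections` >= 3 and `segments` >= 1", "tm_usage_error")
  theta <- 2 * pi * (seq_len(sections) - 1L) / sections
  z <- height * (0:segments) / segments
  v <- cbind(radius * cos(rep(theta, segments + 1L)),
             radius * sin(rep(theta, segments + 1L)),
             rep(z, each = sections))
  vid <- function(j, k) (k %% (segments + 1L)) * sections +
    ((j - 1L) %% sections) + 1L
  j <- rep(seq_len(sections), segments)
  k <- rep(0:(segments - 1L), each = sections)
  a <- vid(j, k); b <- vid(j + 1L, k); cc <- vid(j + 1L, k + 1L)
  d <- vid(j, k + 1L)
  f <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  boundary <- logical(nrow(v))
  rim <- c(vid(seq_len(sections), 0L), vid(seq_len(sections), segments))
  if (capped) {
    cbot <- nrow(v) + 1L
    ctop <- nrow(v) + 2L
    v <- rbind(v, c(0, 0, 0), c(0, 0, height))
    jj <- seq_len(sections)
    fbot <- cbind(vid(jj + 1L, 0L), vid(jj, 0L), cbot)      # normal -z
    ftop <- cbind(vid(jj, segments), vid(jj + 1L, segments), ctop)  # +z
    f <- rbind(f, fbot, ftop)
    boundary <- c(boundary, TRUE, TRUE)
    boundary[rim] <- TRUE                      # generator-marked cap crease
  } else {
    boundary[rim] <- TRUE
  }
  surface_mesh(v, f, clean = FALSE, boundary = boundary)
}

#' Perturbation specification
#'
#' Describes a surface perturbation: `amplitude` (mm) is the intensity,
#' `frequency` (integer) the angular/axial mode count. Deterministic mode
#' displaces vertices by a separable sinusoid in the shape's surface
#' coordinates; `random-bumps` superimposes seeded smooth Gaussian bumps
#' scaled so the largest displacement equals `amplitude`.
#'
#' @param amplitude displacement amplitude in mm (>= 0; 0 reproduces the
#'   ideal shape exactly).
#' @param frequency integer mode count (>= 1).
#' @param mode `"deterministic-sinusoidal"` or `"random-bumps"`.
#' @param seed integer seed (random-bumps only).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(amplitude, frequency = 6L,
                              mode = c("deterministic-sinusoidal",
                                       "random-bumps"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (amplitude < 0) tm_stop("`amplitude` must be >= 0", "tm_usage_error")
  if (frequency < 1) tm_stop("`frequency` must be >= 1", "tm_usage_error")
  structure(list(amplitude = amplitude, frequency = as.integer(frequency),
                 mode = mode, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Perturb a synthetic shape
#'
#' Displaces every non-boundary vertex along its outward normal. For
#' `geometry = "sphere"` the deterministic displacement is
#' `amplitude * sin(f * theta) * sin(f * phi)` in spherical angles about
#' the centroid; for `"cylinder"` it is
#' `amplitude * sin(f * theta) * sin(2 * pi * f * z / height)` in
#' cylindrical coordinates about the z axis. Random-bump mode is geometry
#' agnostic. Connectivity is unchanged. Amplitudes large enough to
#' self-intersect are not detected (a warning is emitted when the amplitude
#' exceeds a quarter of the shape scale).
#'
#' @param mesh a [surface_mesh] from [make_sphere] or [make_cylinder].
#' @param spec a [perturbation_spec].
#' @param geometry `"sphere"` or `"cylinder"`; picks the surface
#'   coordinates of the deterministic sinusoid.
#' @return A [surface_mesh] with the same faces and displaced vertices.
#' @export
perturb <- function(mesh, spec, geometry = c("sphere", "cylinder")) {
  geometry <- match.arg(geometry)
  if (!inherits(spec, "perturbation_spec"))
    tm_stop("`spec` must be a perturbation_spec", "tm_usage_error")
  if (spec$amplitude == 0) return(mesh)
  v <- mesh$vertices
  nrm <- vertex_normals(mesh)
  scale_ref <- if (geometry == "sphere") {
    ctr <- colMeans(v)
    mean(row_norm(sweep(v, 2L, ctr)))
  } else {
    mean(sqrt(v[, 1]^2 + v[, 2]^2))
  }
  if (spec$amplitude > scale_ref / 4)
    warning("perturbation amplitude exceeds a quarter of the shape scale; ",
            "the surface may self-intersect")
  disp <- if (spec$mode == "deterministic-sinusoidal") {
    fq <- spec$frequency
    if (geometry == "sphere") {
      ctr <- colMeans(v)
      x <- sweep(v, 2L, ctr)
      r <- row_norm(x)
      theta <- atan2(x[, 2], x[, 1])
      phi <- acos(pmin(1, pmax(-1, x[, 3] / pmax(r, 1e-300))))
      spec$amplitude * sin(fq * theta) * sin(fq * phi)
    } else {
      zmin <- min(v[, 3]); zmax <- max(v[, 3])
      h <- max(zmax - zmin, .Machine$double.eps)
      theta <- atan2(v[, 2], v[, 1])
      spec$amplitude * sin(fq * theta) *
        sin(2 * pi * fq * (v[, 3] - zmin) / h)
    }
  } else {
    random_bump_field(v, spec)
  }
  disp[mesh$boundary] <- 0
  out <- mesh
  out$vertices <- v + nrm * disp
  out
}

# Seeded smooth bump field: frequency^2 Gaussian bumps at random surface
# vertices with random signs, width ~ shape scale / frequency, normalized
# so max |displacement| = amplitude.
random_bump_field <- function(v, spec) {
  with_seed(spec$seed, {
    nb <- max(4L, spec$frequency^2)
    ctr <- colMeans(v)
    scale_ref <- mean(row_norm(sweep(v, 2L, ctr)))
    sigma <- 2 * scale_ref / spec$frequency
    centers <- v[sample.int(nrow(v), nb, replace = nb > nrow(v)), ,
                 drop = FALSE]
    signs <- sample(c(-1, 1), nb, replace = TRUE)
    fld <- numeric(nrow(v))
    for (b in seq_len(nb)) {
      d2 <- rowSums(sweep(v, 2L, centers[b, ])^2)
      fld <- fld + signs[b] * exp(-d2 / (2 * sigma^2))
    }
    mx <- max(abs(fld))
    if (mx == 0) fld else spec$amplitude * fld / mx
  })
}

#' Synthetic two-class cohorts
#'
#' Generates a seeded collection of perturbed shapes in two classes — class
#' 0 with mild and class 1 with strong surface perturbation — emulating a
#' healthy versus pathological imaging cohort. Radius, height, frequency
#' and a multiplicative amplitude jitter are drawn from the same
#' distributions in both classes, so with `amplitudes = c(0, 0)` the two
#' classes are statistically identical; only the perturbation amplitude
#' separates them. Each mesh is decimated to `target_faces` elements and
#' its analytic mean radius (mm) recorded.
#'
#' The default perturbation regimes mimic the two phenotypes: class 0
#' carries fine-scale, low-amplitude surface texture (modes 8-12, 0.3 mm)
#' while class 1 carries coarse, high-amplitude bulges (modes 4-6, 2.0 mm),
#' the synthetic analogue of aneurysmal/dissected wall deformation on an
#' otherwise smooth tube.
#'
#' @param n_per_class meshes per class (>= 1).
#' @param base `"cylinder"` (open tubes, the aorta analogue) or `"sphere"`.
#' @param amplitudes length-2 numeric, mild and strong perturbation
#'   amplitude in mm (`amplitudes[1] < amplitudes[2]` unless both 0).
#' @param frequency_range inclusive integer range(s) of perturbation mode
#'   counts: either one `c(lo, hi)` range used for both classes, or a list
#'   of two ranges (class 0, class 1).
#' @param radius_mm,radius_sd_mm mean and s.d. of the per-mesh base radius.
#' @param height_mm,height_sd_mm mean and s.d. of the cylinder height.
#' @param target_faces decimation target per mesh.
#' @param bend circular-arc centerline bend angle (radians) applied to
#'   cylinders of class 1; 0 disables bending.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A list of records, each `list(mesh, label, mean_radius, id)`,
#'   with class `synthetic_cohort`.
#' @export
make_cohorts <- function(n_per_class = 20L, base = c("cylinder", "sphere"),
                         amplitudes = c(0.3, 2.0),
                         frequency_range = list(c(8L, 12L), c(4L, 6L)),
                         radius_mm = 15, radius_sd_mm = 2,
                         height_mm = 200, height_sd_mm = 20,
                         target_faces = 5000L, bend = 0, seed = 1L) {
  base <- match.arg(base)
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L)
    tm_stop("`n_per_class` must be >= 1", "tm_usage_error")
  if (length(amplitudes) != 2L || any(amplitudes < 0) ||
      (amplitudes[1] >= amplitudes[2] && any(amplitudes > 0)))
    tm_stop("`amplitudes` must be two values with amplitudes[1] < amplitudes[2]",
            "tm_usage_error")
  if (!is.list(frequency_range))
    frequency_range <- list(frequency_range, frequency_range)
  with_seed(seed, {
    recs <- vector("list", 2L * n_per_class)
    idx <- 0L
    for (label in 0:1) {
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1L
        radius <- max(radius_mm / 3, rnorm(1, radius_mm, radius_sd_mm))
        amp <- amplitudes[label + 1L] * runif(1, 0.8, 1.2)
        fr <- frequency_range[[label + 1L]]
        freq <- sample(seq(fr[1], fr[2]), 1L)
        if (base == "cylinder") {
          height <- max(height_mm / 3, rnorm(1, height_mm, height_sd_mm))
          mesh <- cylinder_for_target(radius, height, target_faces)
          spec <- perturbation_spec(amp, freq)
          mesh <- perturb(mesh, spec, geometry = "cylinder")
          if (bend > 0 && label == 1L) mesh <- bend_cylinder(mesh, bend)
        } else {
          mesh <- make_sphere(radius, subdivisions = 4L)
          spec <- perturbation_spec(amp, freq)
          mesh <- perturb(mesh, spec, geometry = "sphere")
        }
        mesh <- decimate_to_count(mesh, target_faces, hausdorff = FALSE)
        recs[[idx]] <- list(mesh = mesh, label = label,
                            mean_radius = radius,
                            id = sprintf("%s_%d_%02d", base, label, i))
      }
    }
    structure(recs, class = "synthetic_cohort")
  })
}

# Open cylinder with ~12% more lateral faces than `target_faces`, grid
# aspect matched to the circumference/height ratio.
cylinder_for_target <- function(radius, height, target_faces) {
  f0 <- ceiling(target_faces * 1.12)
  circ <- 2 * pi * radius
  sections <- max(8L, as.integer(round(sqrt(f0 / 2 * circ / height))))
  segments <- max(1L, as.integer(ceiling(f0 / (2 * sections))))
  make_cylinder(radius, height, sections, segments, capped = FALSE)
}

# Sweep a z-axis cylinder along a circular arc subtending `angle` radians,
# preserving arc length; emulates aortic centerline curvature.
bend_cylinder <- function(mesh, angle) {
  v <- mesh$vertices
  zmin <- min(v[, 3])
  h <- max(v[, 3]) - zmin
  rc <- h / angle
  t <- (v[, 3] - zmin) / h * angle
  x <- v[, 1]
  out <- mesh
  # bend in the x-z plane about a center at (-rc, zmin)
  out$vertices <- cbind((rc + x) * sin(t),
                        v[, 2],
                        zmin + rc - (rc + x) * cos(t))
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, numeric(1), "label")
  cat(sprintf("synthetic_cohort: %d meshes (%d class 0, %d class 1)\n",
              length(x), sum(labs == 0), sum(labs == 1)))
  invisible(x)
}
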