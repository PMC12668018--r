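test_that("file round-trips preserve geometry in every format", {
  mesh <- perturb(make_sphere(10, 2), perturbation_spec(1, 4), "sphere")
  for (fmt in c("stl", "stl_binary", "ply", "obj", "off")) {
    path <- tempfile(fileext = paste0(".", sub("_.*", "", fmt)))
    write_mesh(mesh, path, fmt = fmt)
    back <- load_mesh(path)
    expect_equal(n_vertices(back), n_vertices(mesh), info = fmt)
    expect_equal(n_faces(back), n_faces(mesh), info = fmt)
    # vertex sets match up to reindexing and format precision: map each
    # reloaded vertex to its nearest original
    d2 <- outer(rowSums(back$vertices^2), rowSums(mesh$vertices^2), "+") -
      2 * tcrossprod(back$vertices, mesh$vertices)
    map <- apply(d2, 1L, which.min)
    tol <- if (startsWith(fmt, "stl")) 1e-6 else 1e-12
    # recompute the matched distances directly (d2 itself carries
    # cancellation error ~1e-12)
    dtrue <- sqrt(rowSums((back$vertices -
                             mesh$vertices[map, , drop = FALSE])^2))
    expect_lte(max(dtrue) / max(abs(mesh$vertices)), tol)
    expect_identical(sort(map), seq_len(n_vertices(mesh)))  # bijection
    # face set identical up to that relabeling
    face_sig <- function(f) sort(apply(f, 1, function(r)
      paste(sort(r), collapse = "-")))
    remapped <- matrix(map[back$faces], ncol = 3)
    expect_identical(face_sig(remapped), face_sig(mesh$faces), info = fmt)
    unlink(path)
  }
})

test_that("loading merges coincident vertices and drops bad faces", {
  tet <- tetrahedron()
  path <- tempfile(fileext = ".stl")
  write_mesh(tet, path, fmt = "stl")
  back <- load_mesh(path)   # STL duplicates every vertex per facet
  expect_equal(n_vertices(back), 4L)
  expect_equal(n_faces(back), 4L)
  expect_true(is_watertight(back))

  # two coincident vertices merge into one
  v <- rbind(tet$vertices, tet$vertices[1, ])
  f <- rbind(tet$faces[-1, ], c(5L, 3L, 2L))
  m <- surface_mesh(v, f)
  expect_equal(n_vertices(m), 4L)

  # a quad face is refused
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), off)
  expect_error(load_mesh(off), class = "tm_unsupported_topology")
  unlink(c(path, off))
})

test_that("vertex adjacency has the right valences and symmetry", {
  adj_tet <- vertex_adjacency(tetrahedron())
  expect_identical(lengths(adj_tet$neighbors), rep(3L, 4L))

  ico <- make_sphere(1, 0)
  adj_ico <- vertex_adjacency(ico)
  expect_identical(lengths(adj_ico$neighbors), rep(5L, 12L))

  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(1:3), clean = FALSE)
  expect_identical(lengths(vertex_adjacency(tri)$neighbors), rep(2L, 3L))

  # symmetry and no self loops, on a perturbed shape
  m <- perturb(make_sphere(5, 2), perturbation_spec(0.5, 5), "sphere")
  adj <- vertex_adjacency(m)
  for (i in sample(adj$n, 25L)) {
    expect_false(i %in% adj$neighbors[[i]])
    for (j in adj$neighbors[[i]])
      expect_true(i %in% adj$neighbors[[j]])
  }
  # edge count is 3F/2 on a watertight mesh
  expect_equal(sum(lengths(adj$neighbors)) / 2, 3 * n_faces(m) / 2)
})

test_that("surface area matches closed forms and the scaling law", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0),
                            c(0.5, sqrt(3) / 2, 0)),
                      rbind(1:3), clean = FALSE)
  expect_equal(surface_area(tri), sqrt(3) / 4 / 100)

  s <- make_sphere(10, 4)
  expect_lt(abs(surface_area(s) * 100 - 4 * pi * 100) / (4 * pi * 100),
            0.01)

  s2 <- s
  s2$vertices <- s$vertices * 2
  expect_equal(surface_area(s2), 4 * surface_area(s))
})

test_that("decimation reaches the exact target and preserves topology", {
  s <- make_sphere(10, 4)          # 5120 faces
  d <- decimate_to_count(s, 1280L)
  expect_identical(n_faces(d), 1280L)
  expect_identical(euler_characteristic(d), 2L)
  expect_true(is_watertight(d))
  expect_true(is.finite(attr(d, "hausdorff_mm")))

  # unchanged when the target equals the current count
  same <- decimate_to_count(s, n_faces(s))
  expect_identical(same$faces, s$faces)

  expect_error(decimate_to_count(tetrahedron(), 5000L),
               class = "tm_cannot_upsample")

  # open meshes: boundary rim survives decimation
  cy <- make_cylinder(10, 60, 32, 20)
  dcy <- decimate_to_count(cy, 600L, hausdorff = FALSE)
  expect_identical(n_faces(dcy), 600L)
  rads <- sqrt(dcy$vertices[dcy$boundary, 1]^2 +
                 dcy$vertices[dcy$boundary, 2]^2)
  expect_lt(max(abs(rads - 10)), 0.5)
})

test_that("constant-density mode converts area to a face target", {
  s <- make_sphere(10, 4)
  target <- density_face_target(s, 200)   # 200 faces per cm^2
  expect_equal(target, round(surface_area(s) * 200))
  expect_error(density_face_target(s, -1), class = "tm_usage_error")
})
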