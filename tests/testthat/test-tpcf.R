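test_that("distance shells match hand-derived graph distances", {
  # tetrahedron: complete graph, diameter 1
  sh <- bfs_shells(vertex_adjacency(tetrahedron()), 2L)
  ns <- shell_sizes(sh)
  expect_identical(ns[1, ], rep(1L, 4L))   # shell(0, i) = {i}
  expect_identical(ns[2, ], rep(3L, 4L))
  expect_identical(ns[3, ], rep(0L, 4L))

  # 6-cycle
  sh6 <- bfs_shells(cycle_adjacency(6L), 3L)
  ns6 <- shell_sizes(sh6)
  expect_identical(ns6[, 1], c(1L, 2L, 2L, 1L))

  # path of 3, end vertex
  shp <- bfs_shells(path3_adjacency(), 2L)
  expect_identical(shell_sizes(shp)[, 1], c(1L, 1L, 1L))

  # shells partition the reachable set
  expect_equal(colSums(shell_sizes(sh6)), rep(6, 6))
})

test_that("the hand-computed path-of-3 example is reproduced", {
  sh <- bfs_shells(path3_adjacency(), 2L)
  curve <- tpcf_curve(c(1, 2, 3), sh)
  expect_equal(curve$g, c(1, 6 / 7, 3 / 7))
  expect_equal(tpcf_auc(curve, 0, 2), 11 / 7)
  expect_identical(curve$n_sources, c(3L, 3L, 2L))
})

test_that("normalization identities hold", {
  m <- perturb(make_sphere(8, 2), perturbation_spec(1, 5), "sphere")
  adj <- vertex_adjacency(m)
  sh <- bfs_shells(adj, 10L)

  # constant field: g(r) = 1 wherever a shell is nonempty
  gc <- tpcf_curve(rep(2.5, n_vertices(m)), sh)
  expect_equal(gc$g[gc$n_sources > 0], rep(1, sum(gc$n_sources > 0)),
               tolerance = 1e-12)

  # g(0) = 1 exactly for arbitrary nonzero fields
  set.seed(1)
  for (i in 1:5) {
    p <- rnorm(n_vertices(m))
    cv <- tpcf_curve(p, sh)
    expect_equal(cv$g[1], 1, tolerance = 1e-12)
    expect_true(all(is.finite(cv$g)))
    # field-scaling invariance, including sign flip
    for (alpha in c(3.7, -1)) {
      expect_equal(tpcf_curve(alpha * p, sh)$g, cv$g, tolerance = 1e-12)
    }
  }
})

test_that("shell-based evaluation equals the brute-force double loop", {
  set.seed(20240917)
  for (rep in 1:20) {
    mf <- random_mesh_and_field()
    expect_lte(n_vertices(mf$mesh), 700L)
    adj <- vertex_adjacency(mf$mesh)
    r_max <- sample(3:12, 1)
    got <- tpcf_curve(mf$field, bfs_shells(adj, r_max))
    want <- oracle_tpcf(adj$neighbors, mf$field, r_max)
    expect_equal(got$g, want, tolerance = 1e-12)
  }
})

test_that("degenerate fields and bad arguments are refused", {
  sh <- bfs_shells(path3_adjacency(), 2L)
  expect_error(tpcf_curve(c(0, 0, 0), sh), class = "tm_degenerate_field")
  expect_error(tpcf_curve(c(1, 2), sh), class = "tm_usage_error")
  cv <- tpcf_curve(c(1, 2, 3), sh)
  expect_error(tpcf_auc(cv, 2, 2), class = "tm_usage_error")
  expect_error(tpcf_auc(cv, 0, 5), class = "tm_usage_error")
  expect_error(bfs_shells(list(), 3), class = "tm_usage_error")
})

test_that("invalid vertices are removed before shell construction", {
  cy <- make_cylinder(10, 60, 24, 12)
  fld <- curvature_metric(principal_curvatures(cy), "S")
  expect_true(any(!fld$valid))       # boundary rims are excluded
  # the high-level wrapper works on the valid subgraph
  cv <- tpcf(cy, fld, r_max = 8)
  expect_equal(cv$g[1], 1, tolerance = 1e-12)
  # handing full-mesh shells with an invalid-carrying field is an error
  sh_full <- bfs_shells(vertex_adjacency(cy), 8L)
  expect_error(tpcf_curve(fld, sh_full), class = "tm_usage_error")
  # equivalence with a manual subgraph evaluation
  sub <- tpcfmesh:::subset_adjacency(vertex_adjacency(cy), fld$valid)
  cv2 <- tpcf_curve(fld$values[fld$valid], bfs_shells(sub, 8L))
  expect_equal(cv$g, cv2$g)
})

test_that("AUC handles rectangle and zero curves", {
  mkcurve <- function(g) structure(list(metric = "S", r = 0:30, g = g,
                                        n_sources = rep(1L, 31)),
                                   class = "tpcf_curve")
  expect_equal(tpcf_auc(mkcurve(rep(1, 31)), 0, 30), 30)
  expect_equal(tpcf_auc(mkcurve(rep(0, 31)), 0, 30), 0)
  expect_equal(tpcf_auc(mkcurve(c(rep(1, 16), rep(0, 15))), 0, 15), 15)
})

test_that("ideal shapes give plateau-at-1 correlation curves", {
  s <- make_sphere(10, 3)
  curves <- tpcf_curves(s, metrics = c("K", "H", "S"), r_max = 10)
  for (m in names(curves))
    expect_true(all(curves[[m]]$g >= 0.95 & curves[[m]]$g <= 1.05),
                info = m)
  cy <- make_cylinder(10, 100, 48, 30)
  ccy <- tpcf_curves(cy, metrics = c("H", "S"), r_max = 10)
  for (m in names(ccy))
    expect_true(all(ccy[[m]]$g >= 0.9 & ccy[[m]]$g <= 1.1), info = m)
})

test_that("mean-centering option changes the curve as documented", {
  m <- perturb(make_sphere(8, 2), perturbation_spec(1, 5), "sphere")
  fld <- curvature_metric(principal_curvatures(m), "H")
  raw <- tpcf(m, fld, r_max = 6)
  cen <- tpcf(m, fld, r_max = 6, centered = TRUE)
  expect_equal(cen$g[1], 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(raw$g, cen$g)))
})

test_that("finite meshes exhaust their shells beyond the analysis window", {
  d <- decimate_to_count(make_sphere(10, 5), 5000L, hausdorff = FALSE)
  sh <- bfs_shells(vertex_adjacency(d), 60L)
  co <- shell_cutoff(sh)
  expect_gt(co$cutoff, 30)
})
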