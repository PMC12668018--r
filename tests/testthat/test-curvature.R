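test_that("principal curvatures recover analytic sphere curvature", {
  s <- make_sphere(10, 4)
  pc <- principal_curvatures(s)
  rel1 <- abs(pc$kappa1 - 0.1) / 0.1
  rel2 <- abs(pc$kappa2 - 0.1) / 0.1
  expect_gte(mean(rel1 < 0.02), 0.99)
  expect_gte(mean(rel2 < 0.02), 0.99)
  # outward orientation makes a sphere convex: positive curvatures
  expect_true(all(pc$kappa1 > 0))
  # kappa1 >= kappa2 everywhere, by construction and numerically
  expect_true(all(pc$kappa1 >= pc$kappa2))
  # directions are unit tangent vectors
  expect_lt(max(abs(rowSums(pc$dir1^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(pc$dir1 * pc$normals))), 1e-6)
})

test_that("open cylinder interior matches 1/R and 0", {
  cy <- make_cylinder(10, 100, 64, 40)
  pc <- principal_curvatures(cy)
  interior <- !cy$boundary
  expect_lt(max(abs(pc$kappa1[interior] - 0.1) / 0.1), 0.05)
  expect_lt(max(abs(pc$kappa2[interior])), 0.005)
})

test_that("a flat patch has zero curvature away from the boundary", {
  g <- flat_grid(12, 12)
  pc <- principal_curvatures(g)
  interior <- !g$boundary
  expect_lt(max(abs(pc$kappa1[interior])), 1e-9)
  expect_lt(max(abs(pc$kappa2[interior])), 1e-9)
})

test_that("derived metrics satisfy their closed forms", {
  # synthetic principal-curvature object: formulas are checked directly
  fake_pc <- function(k1, k2) {
    structure(list(kappa1 = k1, kappa2 = k2,
                   boundary = logical(length(k1))),
              class = "principal_curvatures")
  }
  pc <- fake_pc(c(3, 1, 1, 2), c(2, 0, -1, 2))
  expect_equal(curvature_metric(pc, "K")$values, c(6, 0, -1, 4))
  expect_equal(curvature_metric(pc, "H")$values, c(2.5, 0.5, 0, 2))
  S <- curvature_metric(pc, "S")
  expect_equal(S$values, c(2 / pi * atan(5), 0.5, 0, 1))
  expect_true(all(S$valid))
  R <- curvature_metric(pc, "R")
  expect_equal(R$values, c(2 / 3, 0, -1, 1))

  # flat points: S invalid; near-zero kappa1: R invalid
  pc0 <- fake_pc(c(0, 1e-12), c(0, -1e-12))
  expect_false(any(curvature_metric(pc0, "S")$valid))
  expect_false(any(curvature_metric(pc0, "R")$valid))
  expect_equal(curvature_metric(pc0, "R")$values, c(0, 0))

  # magnitude-ordered bending ratio stays in [-1, 1]
  pc2 <- fake_pc(c(1e-6, 1), c(-2, -3))
  Rm <- curvature_metric(pc2, "R", magnitude_ordering = TRUE)
  expect_true(all(abs(Rm$values[Rm$valid]) <= 1))

  expect_error(curvature_metric(pc, "Q"))
})

test_that("curvature obeys the scaling laws", {
  s1 <- make_sphere(10, 3)
  s2 <- s1
  s2$vertices <- s1$vertices * 3
  pc1 <- principal_curvatures(s1)
  pc2 <- principal_curvatures(s2)
  expect_equal(pc2$kappa1, pc1$kappa1 / 3, tolerance = 1e-10)
  expect_equal(pc2$kappa2, pc1$kappa2 / 3, tolerance = 1e-10)
  # K ~ 1/s^2, H ~ 1/s, S and R scale free
  expect_equal(curvature_metric(pc2, "K")$values,
               curvature_metric(pc1, "K")$values / 9, tolerance = 1e-10)
  expect_equal(curvature_metric(pc2, "H")$values,
               curvature_metric(pc1, "H")$values / 3, tolerance = 1e-10)
  expect_equal(curvature_metric(pc2, "S")$values,
               curvature_metric(pc1, "S")$values, tolerance = 1e-10)
  expect_equal(curvature_metric(pc2, "R")$values,
               curvature_metric(pc1, "R")$values, tolerance = 1e-10)
})

test_that("shape index is antisymmetric under orientation flip", {
  k1 <- c(2, 1, 0.5, -0.2)
  k2 <- c(1, -1, 0.5, -0.8)
  fake_pc <- function(k1, k2)
    structure(list(kappa1 = k1, kappa2 = k2,
                   boundary = logical(length(k1))),
              class = "principal_curvatures")
  s_fwd <- curvature_metric(fake_pc(k1, k2), "S")$values
  s_rev <- curvature_metric(fake_pc(-k2, -k1), "S")$values
  expect_equal(s_fwd, -s_rev)
  # and monotone in (k1+k2)/(k1-k2) at fixed difference
  k1s <- seq(-1, 3, by = 0.5)
  vals <- curvature_metric(fake_pc(k1s + 1, k1s - 1), "S")$values
  expect_true(all(diff(vals) > 0))
})

test_that("estimates converge to 1/R with mesh refinement", {
  err <- vapply(2:4, function(sub) {
    pc <- principal_curvatures(make_sphere(10, sub))
    max(abs(c(pc$kappa1, pc$kappa2) - 0.1) / 0.1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("curvature table exports all metrics per vertex", {
  m <- make_sphere(5, 2)
  df <- curvature_table(m)
  expect_identical(nrow(df), n_vertices(m))
  expect_true(all(c("kappa1", "kappa2", "K", "H", "S", "R", "valid") %in%
                    names(df)))
  expect_equal(df$K, df$kappa1 * df$kappa2)
  expect_equal(df$H, (df$kappa1 + df$kappa2) / 2)
  path <- tempfile(fileext = ".csv")
  curvature_table(m, path)
  expect_equal(read.csv(path)$K, df$K)
  unlink(path)
})
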