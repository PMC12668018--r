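# Fixtures and independent oracles, all built in code.

# Regular tetrahedron with unit-ish edge length, outward orientation.
tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f, clean = FALSE)
}

# Hand-built adjacency structures (no mesh behind them).
adjacency_from_list <- function(neighbors) {
  structure(list(neighbors = lapply(neighbors, as.integer),
                 n = length(neighbors)), class = "vertex_adjacency")
}

path3_adjacency <- function() adjacency_from_list(list(2L, c(1L, 3L), 2L))

cycle_adjacency <- function(n) {
  adjacency_from_list(lapply(seq_len(n), function(i)
    c((i - 2L) %% n + 1L, i %% n + 1L)))
}

# Flat grid patch in the z = 0 plane (open boundary).
flat_grid <- function(nx = 10L, ny = 10L, spacing = 1) {
  g <- expand.grid(x = 0:(nx - 1L), y = 0:(ny - 1L))
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_mesh(v, f, clean = FALSE)
}

# Small random connected mesh (<= ~500 vertices) with a random field:
# perturbed spheres/cylinders with random parameters.
random_mesh_and_field <- function() {
  if (runif(1) < 0.5) {
    m <- make_sphere(runif(1, 5, 20), sample(1:2, 1))
    m <- perturb(m, perturbation_spec(runif(1, 0, 2), sample(2:8, 1),
                                      mode = "random-bumps",
                                      seed = sample.int(1e6, 1)),
                 geometry = "sphere")
  } else {
    m <- make_cylinder(runif(1, 5, 20), runif(1, 30, 120),
                       sample(6:16, 1), sample(4:14, 1),
                       capped = runif(1) < 0.5)
  }
  list(mesh = m, field = rnorm(n_vertices(m)))
}

# Independent brute-force TPCF: pure-R breadth-first search per source and
# an explicit double loop over shell members (no igraph, no C++).
oracle_tpcf <- function(neighbors, p, r_max) {
  n <- length(neighbors)
  g <- numeric(r_max + 1L)
  for (i in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    frontier <- i
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(neighbors[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    for (r in 0:r_max) {
      shell <- which(!is.na(dist) & dist == r)
      if (length(shell))
        g[r + 1L] <- g[r + 1L] + p[i] * sum(p[shell]) / length(shell)
    }
  }
  g / sum(p^2)
}
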