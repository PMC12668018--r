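# Topographical pair correlation function ----------------------------------
#
# g(r) = (1 / sum_k p_k^2) * sum_i [ (1 / n(r,i)) * sum_{j in shell(r,i)}
#        p_i p_j ]
# where shell(r,i) is the set of vertices whose minimum edge distance from
# vertex i is exactly r (vertices reachable in fewer edges are excluded)
# and n(r,i) its size. Sources with an empty shell at r contribute 0.
# g(0) = 1 whenever the field is not identically zero, a built-in check.

#' Breadth-first distance shells
#'
#' For every source vertex, computes the minimum edge distance to every
#' other vertex (breadth-first search through igraph) up to `r_max`. The
#' shell of radius r around i is the set of vertices at distance exactly r;
#' a vertex belongs to exactly one shell per source.
#'
#' @param adj a [vertex_adjacency].
#' @param r_max largest shell radius of interest (edges); the default 30 is
#'   the range over which TPCF curves are analyzed.
#' @return An object of class `distance_shells`: list with `dist` (n x n
#'   numeric matrix of edge distances, `Inf` where unreachable), `r_max`,
#'   `n`.
#' @export
bfs_shells <- function(adj, r_max = 30L) {
  if (!inherits(adj, "vertex_adjacency"))
    tm_stop("`adj` must come from vertex_adjacency()", "tm_usage_error")
  r_max <- as.integer(r_max)
  if (r_max < 0L) tm_stop("`r_max` must be >= 0", "tm_usage_error")
  n <- adj$n
  if (n == 0L)
    return(structure(list(dist = matrix(numeric(0), 0, 0), r_max = r_max,
                          n = 0L), class = "distance_shells"))
  deg <- lengths(adj$neighbors)
  src <- rep.int(seq_len(n), deg)
  dst <- unlist(adj$neighbors, use.names = FALSE)
  keep <- src < dst
  g <- igraph::graph_from_edgelist(cbind(src[keep], dst[keep]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- NULL
  structure(list(dist = d, r_max = r_max, n = n), class = "distance_shells")
}

#' @export
print.distance_shells <- function(x, ...) {
  cat(sprintf("distance_shells: %d vertices, r_max %d\n", x$n, x$r_max))
  invisible(x)
}

#' Shell sizes n(r, i)
#'
#' @param shells a [bfs_shells] result.
#' @return Integer matrix with `r_max + 1` rows (r = 0..r_max) and one
#'   column per source vertex; entry \[r+1, i\] is n(r, i).
#' @export
shell_sizes <- function(shells) {
  vapply(0:shells$r_max,
         function(r) as.integer(colSums(shells$dist == r)),
         integer(shells$n))  |> t()
}

#' Topographical pair correlation function curve
#'
#' Evaluates g(r) for r = 0..r_max from a scalar curvature field and the
#' distance shells of the same vertex set. Invalid vertices must already be
#' removed: `shells` has to be built on the subgraph induced by the valid
#' vertices (see [tpcf]), so that they neither dilute the shell counts nor
#' contribute zero products.
#'
#' @param field a [curvature_metric] field, or a plain numeric vector (all
#'   values valid).
#' @param shells a [bfs_shells] result over exactly the valid vertices.
#' @param centered subtract the field mean before correlating (classical
#'   fluctuation PCF). Off by default: the reference definition correlates
#'   the raw field.
#' @return An object of class `tpcf_curve`: data-frame-like list with `r`,
#'   `g`, `n_sources` (number of source vertices with a nonempty shell at
#'   each r, a finite-size diagnostic) and the metric name.
#' @export
tpcf_curve <- function(field, shells, centered = FALSE) {
  if (!inherits(shells, "distance_shells"))
    tm_stop("`shells` must come from bfs_shells()", "tm_usage_error")
  if (inherits(field, "curvature_field")) {
    p <- field$values[field$valid]
    metric <- field$metric
    if (shells$n == length(field$values) && any(!field$valid))
      tm_stop(paste("`shells` covers all vertices but the field has",
                    "invalid vertices; rebuild shells on the valid",
                    "subgraph (see ?tpcf)"), "tm_usage_error")
  } else {
    p <- as.numeric(field)
    metric <- "field"
  }
  if (shells$n != length(p))
    tm_stop("field and shells describe different vertex sets",
            "tm_usage_error")
  norm <- sum(p^2)
  if (length(p) == 0L || norm <= 0)
    tm_stop("degenerate field: all values zero or invalid", "tm_degenerate_field")
  if (centered) {
    p <- p - mean(p)
    norm <- sum(p^2)
    if (norm <= 0)
      tm_stop("degenerate field after centering", "tm_degenerate_field")
  }
  rs <- 0:shells$r_max
  acc <- tpcf_accum_cpp(shells$dist, p, shells$r_max)
  g <- acc$gnum / norm
  nsrc <- acc$n_sources
  structure(list(metric = metric, r = rs, g = g, n_sources = nsrc),
            class = "tpcf_curve")
}

#' @export
print.tpcf_curve <- function(x, ...) {
  cat(sprintf("tpcf_curve (%s): r = 0..%d, g(0) = %.6f\n",
              x$metric, max(x$r), x$g[1]))
  print(utils::head(data.frame(r = x$r, g = x$g, n_sources = x$n_sources),
                    10L))
  if (length(x$r) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.tpcf_curve <- function(x, ...) {
  data.frame(metric = x$metric, r = x$r, g = x$g, n_sources = x$n_sources)
}

#' @export
plot.tpcf_curve <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "b", pch = 16, xlab = "r (edges)",
                 ylab = "g(r)", main = sprintf("TPCF (%s)", x$metric), ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey50")
  invisible(x)
}

#' TPCF of a curvature metric on a mesh
#'
#' High-level wrapper: computes the metric field (unless given), removes
#' invalid vertices, builds distance shells on the remaining subgraph, and
#' evaluates the correlation curve.
#'
#' @param mesh a [surface_mesh].
#' @param field a [curvature_metric] field for this mesh, or a metric name
#'   (`"K"`, `"H"`, `"S"`, `"R"`).
#' @param r_max largest distance (edges).
#' @param adj optional precomputed [vertex_adjacency] of the full mesh.
#' @param centered see [tpcf_curve].
#' @return A [tpcf_curve].
#' @export
tpcf <- function(mesh, field = "S", r_max = 30L, adj = NULL,
                 centered = FALSE) {
  if (is.character(field)) {
    pc <- principal_curvatures(mesh)
    field <- curvature_metric(pc, field)
  }
  if (length(field$values) != n_vertices(mesh))
    tm_stop("field and mesh describe different vertex sets",
            "tm_usage_error")
  if (is.null(adj)) adj <- vertex_adjacency(mesh)
  sub <- subset_adjacency(adj, field$valid)
  shells <- bfs_shells(sub, r_max = r_max)
  p <- field$values[field$valid]
  curve <- tpcf_curve(p, shells, centered = centered)
  curve$metric <- field$metric
  curve
}

#' Area under a TPCF curve
#'
#' Trapezoidal integral of g(r) over the edge-distance window
#' \[`r_lo`, `r_hi`\]; the scalar feature used for classification.
#'
#' @param curve a [tpcf_curve].
#' @param r_lo,r_hi integration bounds in edges, `r_lo < r_hi`, both within
#'   the curve's range.
#' @return Dimensionless scalar.
#' @export
tpcf_auc <- function(curve, r_lo = 0L, r_hi = max(curve$r)) {
  if (r_hi <= r_lo)
    tm_stop("`r_hi` must exceed `r_lo`", "tm_usage_error")
  if (r_lo < min(curve$r) || r_hi > max(curve$r))
    tm_stop("integration bounds outside the curve range", "tm_usage_error")
  idx <- which(curve$r >= r_lo & curve$r <= r_hi)
  g <- curve$g[idx]
  r <- curve$r[idx]
  sum((g[-1] + g[-length(g)]) / 2 * diff(r))
}

#' Edge-distance cutoff of a mesh
#'
#' Finite meshes run out of new vertices at large r: the mean shell size
#' grows, peaks, and collapses. This reports the smallest r at which the
#' mean shell size falls below `frac` of its maximum — the distance beyond
#' which the TPCF is dominated by finite-size effects. For ~5000-element
#' meshes this cutoff lies beyond 30 edges.
#'
#' @param shells a [bfs_shells] result (use a generous `r_max`).
#' @param frac collapse threshold as a fraction of the peak mean shell size.
#' @return List with `cutoff` (smallest r past the peak with mean shell
#'   size < `frac` * max; `Inf` if never within `r_max`) and `mean_n`
#'   (mean shell size at each r).
#' @export
shell_cutoff <- function(shells, frac = 0.1) {
  ns <- shell_sizes(shells)
  mean_n <- rowMeans(ns)
  pk <- which.max(mean_n)
  below <- which(mean_n < frac * max(mean_n))
  below <- below[below > pk]
  cutoff <- if (length(below)) shells$r_max + 1L else NA_integer_
  if (length(below)) cutoff <- below[1L] - 1L  # rows are r = 0..r_max
  list(cutoff = if (length(below)) cutoff else Inf, mean_n = mean_n)
}
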