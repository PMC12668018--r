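# Scalar curvature metrics --------------------------------------------------
#
# From the principal curvatures k1 >= k2 the four per-vertex metrics are
#   K = k1 * k2                                (Gaussian curvature, 1/mm^2)
#   H = (k1 + k2) / 2                          (mean curvature, 1/mm)
#   S = (2/pi) * atan((k1 + k2) / (k1 - k2))   (shape index, dimensionless)
#   R = k2 / k1                                (bending ratio, dimensionless)
# S is undefined at umbilics (k1 = k2): the limit is sign(k1) for curved
# umbilics and undefined at flat points; R is undefined where k1 ~ 0.

TM_METRICS <- c("K", "H", "S", "R")

#' Derived scalar curvature metric field
#'
#' Computes one of the four scalar curvature metrics from a
#' [principal_curvatures] field, with a per-vertex validity flag. Vertices
#' where the metric is undefined (flat points for the shape index, near-zero
#' maximum curvature for the bending ratio) are flagged invalid and carry
#' value 0. Boundary/cap vertices are flagged invalid for every metric when
#' `exclude_boundary = TRUE`, since one-ring shape operators are biased
#' there.
#'
#' @param pc a [principal_curvatures] object.
#' @param metric one of `"K"`, `"H"`, `"S"`, `"R"`.
#' @param exclude_boundary flag boundary vertices invalid.
#' @param eps_flat curvature magnitude (1/mm) below which kappa1 counts as
#'   zero for the bending ratio, and both kappas as zero for the shape
#'   index's flat-point rule.
#' @param magnitude_ordering for `"R"` only: divide the smaller-magnitude
#'   curvature by the larger-magnitude one instead of kappa2/kappa1, which
#'   bounds R to \[-1, 1\]. Off by default (the signed definition is the
#'   reference one).
#' @return An object of class `curvature_field`: list with `metric`,
#'   `values` (numeric), `valid` (logical), `boundary`.
#' @export
curvature_metric <- function(pc, metric = c("K", "H", "S", "R"),
                             exclude_boundary = TRUE, eps_flat = 1e-8,
                             magnitude_ordering = FALSE) {
  if (!inherits(pc, "principal_curvatures"))
    tm_stop("`pc` must come from principal_curvatures()", "tm_usage_error")
  metric <- match.arg(metric)
  k1 <- pc$kappa1
  k2 <- pc$kappa2
  valid <- rep(TRUE, length(k1))
  vals <- switch(metric,
    K = k1 * k2,
    H = (k1 + k2) / 2,
    S = {
      num <- k1 + k2
      den <- k1 - k2
      s <- (2 / pi) * atan2(num, den)   # den >= 0 since k1 >= k2
      umb <- den < eps_flat
      flat <- umb & abs(k1) < eps_flat
      s[umb] <- sign(k1[umb])           # limit of the shape index at umbilics
      valid[flat] <- FALSE
      s
    },
    R = {
      if (magnitude_ordering) {
        hi <- pmax(abs(k1), abs(k2))
        lo_signed <- ifelse(abs(k1) >= abs(k2), k2, k1)
        hi_signed <- ifelse(abs(k1) >= abs(k2), k1, k2)
        bad <- hi < eps_flat
        valid[bad] <- FALSE
        out <- ifelse(bad, 0, lo_signed / ifelse(bad, 1, hi_signed))
        out
      } else {
        bad <- abs(k1) < eps_flat
        valid[bad] <- FALSE
        ifelse(bad, 0, k2 / ifelse(bad, 1, k1))
      }
    })
  if (exclude_boundary) valid[pc$boundary] <- FALSE
  vals[!valid] <- 0
  structure(list(metric = metric, values = as.numeric(vals),
                 valid = valid, boundary = pc$boundary),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf(
    "curvature_field '%s': %d vertices (%d valid), range [%.4g, %.4g]\n",
    x$metric, length(x$values), sum(x$valid),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' All four curvature metric fields of a mesh
#'
#' Convenience wrapper: principal curvatures plus the K, H, S and R fields.
#'
#' @inheritParams curvature_metric
#' @param mesh a [surface_mesh].
#' @return Named list of [curvature_metric] fields (`K`, `H`, `S`, `R`).
#' @export
curvature_fields <- function(mesh, exclude_boundary = TRUE,
                             eps_flat = 1e-8) {
  pc <- principal_curvatures(mesh)
  out <- lapply(TM_METRICS, function(m)
    curvature_metric(pc, m, exclude_boundary = exclude_boundary,
                     eps_flat = eps_flat))
  names(out) <- TM_METRICS
  out
}

#' Export per-vertex curvature data as a data frame / CSV
#'
#' One row per vertex with kappa1, kappa2, the four metrics and a combined
#' validity flag, suitable for `write.csv` or for attaching to a PLY file
#' via [write_mesh]'s `attributes` argument.
#'
#' @param mesh a [surface_mesh].
#' @param path optional CSV output path.
#' @inheritParams curvature_metric
#' @return Data frame (invisibly when `path` is given).
#' @export
curvature_table <- function(mesh, path = NULL, exclude_boundary = TRUE) {
  pc <- principal_curvatures(mesh)
  flds <- lapply(TM_METRICS, function(m)
    curvature_metric(pc, m, exclude_boundary = exclude_boundary))
  names(flds) <- TM_METRICS
  df <- data.frame(vertex = seq_along(pc$kappa1),
                   kappa1 = pc$kappa1, kappa2 = pc$kappa2,
                   K = flds$K$values, H = flds$H$values,
                   S = flds$S$values, R = flds$R$values,
                   valid = Reduce(`&`, lapply(flds, `[[`, "valid")))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
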