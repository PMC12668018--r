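# Featurization and support-vector classification ---------------------------
#
# The two features per mesh and metric are (1) the area under the TPCF
# curve over r = 0..r_max and (2) the mean radius in mm. A linear
# support-vector machine on the standardized 2D feature space separates
# class 0 (normal anatomy) from classes 1 and 2 (post-TEVAR without / with
# secondary intervention).

#' Single-point curvature statistics
#'
#' Baseline (non-spatial) summary of one curvature metric field: histogram,
#' mean and standard deviation over the valid vertices. The standard
#' deviation uses the population convention (divide by n), matching the
#' definition of the Gaussian-curvature fluctuation descriptor deltaK.
#'
#' @param field a [curvature_metric] field or numeric vector.
#' @param bins number of histogram bins.
#' @return List with `metric`, `mean`, `sd`, `n_valid`, `breaks`, `counts`.
#' @export
point_stats <- function(field, bins = 50L) {
  if (inherits(field, "curvature_field")) {
    v <- field$values[field$valid]
    metric <- field$metric
  } else {
    v <- as.numeric(field)
    metric <- "field"
  }
  if (length(v) == 0L)
    tm_stop("no valid vertices", "tm_degenerate_field")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  mu <- mean(v)
  structure(list(metric = metric, mean = mu,
                 sd = sqrt(mean((v - mu)^2)), n_valid = length(v),
                 breaks = h$breaks, counts = h$counts),
            class = "point_stats")
}

#' @export
print.point_stats <- function(x, ...) {
  cat(sprintf("point_stats (%s): n = %d, mean = %.6g, sd = %.6g\n",
              x$metric, x$n_valid, x$mean, x$sd))
  invisible(x)
}

#' Per-mesh TPCF curves for several metrics
#'
#' Computes curvature fields once and the TPCF for each requested metric,
#' reusing the full-mesh adjacency (the per-metric valid subgraphs are
#' induced from it).
#'
#' @param mesh a [surface_mesh].
#' @param metrics character vector from `"K"`, `"H"`, `"S"`, `"R"`.
#' @param r_max largest edge distance.
#' @return Named list of [tpcf_curve] objects.
#' @export
tpcf_curves <- function(mesh, metrics = TM_METRICS, r_max = 30L) {
  pc <- principal_curvatures(mesh)
  adj <- vertex_adjacency(mesh)
  out <- lapply(metrics, function(m) {
    fld <- curvature_metric(pc, m)
    tpcf(mesh, fld, r_max = r_max, adj = adj)
  })
  names(out) <- metrics
  out
}

#' Build the classification feature table
#'
#' One row per mesh: TPCF area under the curve per metric, mean radius in
#' mm, the 3-way outcome label (0 normal; 1 TEVAR without secondary
#' intervention; 2 secondary intervention) and the binary grouping
#' (0 versus 1 or 2).
#'
#' @param records list of records, each a list with elements `curves`
#'   (named list of [tpcf_curve], one per metric), `mean_radius`, `label`
#'   and optionally `id`; or a `synthetic_cohort` (curves computed here).
#' @param metrics metrics to require.
#' @param r_max edge-distance range for the AUC (and for curve computation
#'   when given a cohort).
#' @param path optional CSV output path.
#' @return Data frame of class `feature_table` with columns `id`, `auc_<m>`
#'   for each metric, `mean_radius_mm`, `label`, `binary_label`.
#' @export
build_feature_table <- function(records, metrics = TM_METRICS, r_max = 30L,
                                path = NULL) {
  if (inherits(records, "synthetic_cohort"))
    records <- lapply(records, function(rec) {
      rec$curves <- tpcf_curves(rec$mesh, metrics = metrics, r_max = r_max)
      rec
    })
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    if (is.null(rec$curves) || !all(metrics %in% names(rec$curves)))
      tm_stop(sprintf("record %d lacks a TPCF curve for a requested metric",
                      i), "tm_incomplete_record")
    if (!rec$label %in% 0:2)
      tm_stop(sprintf("record %d: label must be 0, 1 or 2", i),
              "tm_usage_error")
    aucs <- vapply(metrics, function(m)
      tpcf_auc(rec$curves[[m]], 0L, min(r_max, max(rec$curves[[m]]$r))),
      numeric(1))
    cbind(data.frame(id = if (is.null(rec$id)) sprintf("mesh_%03d", i)
                          else rec$id),
          as.data.frame(as.list(stats::setNames(aucs,
                                                paste0("auc_", metrics)))),
          data.frame(mean_radius_mm = rec$mean_radius, label = rec$label,
                     binary_label = as.integer(rec$label > 0)))
  })
  tbl <- if (length(rows)) do.call(rbind, rows) else {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(metrics)), paste0("auc_", metrics)))
    cbind(data.frame(id = character(0)), empty,
          data.frame(mean_radius_mm = numeric(0), label = integer(0),
                     binary_label = integer(0)))
  }
  class(tbl) <- c("feature_table", "data.frame")
  if (!is.null(path)) write.csv(tbl, path, row.names = FALSE)
  tbl
}

feature_cols <- function(metric) c(paste0("auc_", metric), "mean_radius_mm")

check_table <- function(table, metric) {
  cols <- feature_cols(metric)
  if (!all(cols %in% names(table)))
    tm_stop(sprintf("feature table lacks columns %s",
                    paste(setdiff(cols, names(table)), collapse = ", ")),
            "tm_usage_error")
  if (length(unique(table$binary_label)) < 2L)
    tm_stop("feature table contains a single class", "tm_degenerate_labels")
  invisible(cols)
}

#' Fit a support-vector classifier on (TPCF AUC, mean radius)
#'
#' Standardizes the two features (zero mean, unit variance), fits an SVM on
#' the binary labels, and evaluates the decision function on a dense grid
#' for plotting a decision boundary.
#'
#' @param table a [build_feature_table] result.
#' @param metric which metric's AUC to use.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost SVM regularization weight.
#' @param seed RNG seed (libsvm fitting is deterministic, but a seed is
#'   fixed for reproducibility of any randomized kernel defaults).
#' @param grid_n grid resolution per axis for the boundary.
#' @return An object of class `svm_boundary`: list with the fitted `model`,
#'   standardization `center`/`scale`, `grid` (data frame with the two
#'   features in original units and the predicted class), `metric`,
#'   `train_accuracy`.
#' @export
fit_svm <- function(table, metric = "S", kernel = c("linear", "radial"),
                    cost = 1, seed = 1L, grid_n = 101L) {
  kernel <- match.arg(kernel)
  cols <- check_table(table, metric)
  x <- as.matrix(table[, cols])
  y <- factor(table$binary_label, levels = c(0L, 1L))
  if (min(table(y)) < 2L)
    tm_stop("need at least 2 rows per class", "tm_degenerate_labels")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  model <- with_seed(seed,
    e1071::svm(xs, y, kernel = kernel, cost = cost, scale = FALSE))
  pred <- predict(model, xs)
  rng <- apply(xs, 2L, range)
  pad <- 0.1 * (rng[2, ] - rng[1, ])
  g1 <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = grid_n)
  g2 <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = grid_n)
  gs <- as.matrix(expand.grid(g1, g2))
  colnames(gs) <- cols
  gpred <- predict(model, gs)
  grid <- data.frame(gs[, 1] * scl[1] + ctr[1], gs[, 2] * scl[2] + ctr[2],
                     class = as.integer(as.character(gpred)))
  names(grid)[1:2] <- cols
  structure(list(model = model, center = ctr, scale = scl, grid = grid,
                 metric = metric, kernel = kernel,
                 train_accuracy = mean(pred == y)),
            class = "svm_boundary")
}

#' @export
print.svm_boundary <- function(x, ...) {
  cat(sprintf(
    "svm_boundary: metric %s, %s kernel, training accuracy %.3f\n",
    x$metric, x$kernel, x$train_accuracy))
  invisible(x)
}

#' Plot an SVM decision boundary
#'
#' Shaded decision regions over the (AUC, mean radius) plane with the
#' training points overlaid, the two-feature analogue of a cohort
#' classification figure.
#'
#' @param boundary a [fit_svm] result.
#' @param table the feature table the classifier was fitted on.
#' @param ... passed to [graphics::plot].
#' @export
plot_decision_boundary <- function(boundary, table, ...) {
  cols <- feature_cols(boundary$metric)
  g <- boundary$grid
  graphics::plot(g[[1]], g[[2]], pch = 15, cex = 0.6,
                 col = ifelse(g$class == 1, "#fddbc7", "#d1e5f0"),
                 xlab = sprintf("TPCF AUC (%s)", boundary$metric),
                 ylab = "mean radius (mm)", ...)
  graphics::points(table[[cols[1]]], table[[cols[2]]], pch = 21,
                   bg = ifelse(table$binary_label == 1, "#b2182b",
                               "#2166ac"))
  invisible(boundary)
}

# Seeded stratified fold assignment: within each class, folds 1..k are
# dealt out in shuffled order.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds)
        tm_stop(sprintf(
          "class %s has %d members, fewer than %d folds", cl,
          length(idx), folds), "tm_fold_error")
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    assign
  })
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of the two-feature SVM on the binary
#' labels. Standardization parameters are estimated on each training split
#' only.
#'
#' @inheritParams fit_svm
#' @param folds number of folds (>= 2); every class must have at least
#'   `folds` members.
#' @return List of class `cv_accuracy` with `accuracy` (mean over folds),
#'   `fold_accuracy`, `fold_assignment`, `metric`, `kernel`, `seed`.
#' @export
evaluate_accuracy <- function(table, metric = "S",
                              kernel = c("linear", "radial"), folds = 5L,
                              cost = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  folds <- as.integer(folds)
  if (folds < 2L) tm_stop("`folds` must be >= 2", "tm_usage_error")
  cols <- check_table(table, metric)
  x <- as.matrix(table[, cols])
  y <- factor(table$binary_label, levels = c(0L, 1L))
  fa <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fa != k
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], ctr, scl)
    xte <- scale(x[!tr, , drop = FALSE], ctr, scl)
    model <- with_seed(seed,
      e1071::svm(xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE))
    mean(predict(model, xte) == y[!tr])
  }, numeric(1))
  structure(list(accuracy = mean(acc), fold_accuracy = acc,
                 fold_assignment = fa, metric = metric, kernel = kernel,
                 folds = folds, seed = seed),
            class = "cv_accuracy")
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat(sprintf(
    "cv_accuracy: metric %s, %s kernel, %d-fold accuracy %.3f (folds: %s)\n",
    x$metric, x$kernel, x$folds, x$accuracy,
    paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}
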