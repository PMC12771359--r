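#' Pearson correlation matrix of a feature table
#'
#' @param table Feature data frame.
#' @param include_target Append the target column as a pseudo-feature.
#' @param target Target column name.
#' @return A `gag_cormat`: the symmetric correlation matrix plus the feature
#'   list.  Constant columns have undefined correlations and raise an error
#'   naming them.
#' @export
pearson_matrix <- function(table, include_target = TRUE,
                           target = "mmgbsa_kcal_mol") {
  stopifnot(nrow(table) >= 3L)
  cols <- feature_names(table)
  if (include_target && target %in% names(table)) cols <- c(cols, target)
  X <- as.matrix(table[, cols, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column(s), correlation undefined: ",
         paste(cols[sds == 0], collapse = ", "))
  structure(list(r = cor(X), features = cols), class = "gag_cormat")
}

#' @export
print.gag_cormat <- function(x, ...) {
  cat("gag_cormat over", length(x$features), "columns\n")
  invisible(x)
}

#' Hierarchical clustering of features by correlation magnitude
#'
#' Agglomerative average-linkage clustering on the distance `1 - |r|`, so
#' strongly (anti-)correlated — i.e. redundant — features merge early.
#'
#' @param cormat A [pearson_matrix()] result.
#' @return The `hclust` object with an added `leaf_order` component.
#' @export
cluster_features <- function(cormat) {
  stopifnot(inherits(cormat, "gag_cormat"))
  d <- stats::as.dist(1 - abs(cormat$r))
  hc <- stats::hclust(d, method = "average")
  hc$leaf_order <- cormat$features[hc$order]
  hc
}

#' Plot a clustered correlation matrix
#' @param x A `gag_cormat`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the leaf order used.
#' @export
plot.gag_cormat <- function(x, ...) {
  ord <- cluster_features(x)$order
  r <- x$r[ord, ord]
  n <- ncol(r)
  graphics::image(seq_len(n), seq_len(n), r[, n:1], zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(n), rownames(r), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(n), rev(rownames(r)), las = 2, cex.axis = 0.6)
  invisible(rownames(r))
}

new_importance <- function(method, raw, family) {
  m <- max(abs(raw))
  structure(list(method = method, family = family, raw = raw,
                 normalized = if (m > 0) raw / m else raw),
            class = "gag_importance")
}

#' @export
print.gag_importance <- function(x, ...) {
  cat("gag_importance (", x$method, ", ", x$family, ")\n", sep = "")
  ord <- order(-abs(x$normalized))
  print(round(x$normalized[ord], 4))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean increase in evaluation MSE when that
#' column is randomly permuted, over `n_repeats` seeded shuffles.
#'
#' @param model A fitted `gag_model`.
#' @param table Evaluation feature data frame with target.
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @param target Target column name.
#' @return A `gag_importance` (method `PERMUTATION`).
#' @export
permutation_importance <- function(model, table, n_repeats = 10, seed = 1L,
                                   target = "mmgbsa_kcal_mol") {
  y <- table[[target]]
  base_mse <- mean((predict(model, table) - y)^2)
  feats <- model$features
  raw <- local_seed(seed, vapply(feats, function(f) {
    mean(vapply(seq_len(n_repeats), function(i) {
      tb <- table
      tb[[f]] <- sample(tb[[f]])
      mean((predict(model, tb) - y)^2) - base_mse
    }, numeric(1)))
  }, numeric(1)))
  new_importance("PERMUTATION", raw, model$config$family)
}

#' Leave-one-feature-out importance
#'
#' For every feature, the model family is retrained without it; the
#' importance is the evaluation-set MSE of the reduced model minus that of
#' the all-feature model (positive means the feature helps).
#'
#' @param config A [model_config()].
#' @param table Training feature data frame.
#' @param validation_table Evaluation table (defaults to `table`).
#' @param target Target column name.
#' @return A `gag_importance` (method `LOFO_MSE`).
#' @export
lofo_importance <- function(config, table, validation_table = NULL,
                            target = "mmgbsa_kcal_mol") {
  if (is.null(validation_table)) validation_table <- table
  feats <- feature_names(table)
  if (!config$use_lie_features)
    feats <- setdiff(feats, c("lie_elec", "lie_vdw"))
  y <- validation_table[[target]]
  full <- gag_train(config, table, target = target, features = feats)
  full_mse <- mean((predict(full, validation_table) - y)^2)
  raw <- vapply(feats, function(f) {
    m <- gag_train(config, table, target = target,
                   features = setdiff(feats, f))
    mean((predict(m, validation_table) - y)^2) - full_mse
  }, numeric(1))
  new_importance("LOFO_MSE", raw, config$family)
}

#' Coefficient-based importance for linear families
#'
#' Absolute standardized coefficients, normalized to a maximum of 1.
#'
#' @param model A linear-family `gag_model`.
#' @return A `gag_importance` (method `COEFFICIENTS`).
#' @export
coefficient_importance <- function(model) {
  fam <- model$config$family
  if (!fam %in% c("elastic_net", "linear_regression", "linear_svr") &&
      !(fam == "fcnn" && length(model$fit$sizes) == 2L))
    stop("unsupported method: coefficient importance needs a linear family")
  cf <- coef(model)
  new_importance("COEFFICIENTS", abs(cf[model$features]), fam)
}

#' Built-in importance of tree ensembles
#'
#' Impurity importance for the random forest; total gain for the boosting
#' families.
#'
#' @param model A tree-family `gag_model`.
#' @return A `gag_importance` (method `BUILTIN`).
#' @export
builtin_importance <- function(model) {
  fam <- model$config$family
  raw <- if (fam == "random_forest") {
    ranger::importance(model$fit)
  } else if (fam %in% c("gradient_boost", "hist_gradient_boost")) {
    imp <- xgboost::xgb.importance(model = model$fit)
    v <- setNames(rep(0, length(model$features)), model$features)
    v[imp$Feature] <- imp$Gain
    v
  } else stop("unsupported method: built-in importance needs a tree family")
  new_importance("BUILTIN", raw[model$features], fam)
}

#' Benchmark the model families
#'
#' Runs [run_repetitions()] for every requested family; with
#' `ablate_lie = TRUE` each family is additionally retrained with the two
#' LIE columns removed from the feature set.  A family that errors is
#' recorded and the others continue.
#'
#' @param table Development feature data frame.
#' @param validation_table Held-out group table.
#' @param families Families to run (default all eight).
#' @param ablate_lie Also run the LIE-ablated configuration.
#' @param n_reps Repetitions per cell.
#' @param seed Integer seed.
#' @param target Target column name.
#' @param configs Optional named list of [model_config()]s overriding the
#'   per-family defaults.
#' @return A `gag_benchmark`: `report` data frame (family, lie, set, metric,
#'   mean, sd) plus per-cell repetition objects and any errors.
#' @export
run_benchmark <- function(table, validation_table = NULL,
                          families = MODEL_FAMILIES, ablate_lie = FALSE,
                          n_reps = 10, seed = 1L,
                          target = "mmgbsa_kcal_mol", configs = NULL) {
  lie_opts <- if (ablate_lie) c(TRUE, FALSE) else TRUE
  cells <- list()
  errors <- list()
  rows <- list()
  for (fam in families) for (lie in lie_opts) {
    cfg <- if (!is.null(configs) && fam %in% names(configs)) configs[[fam]]
           else model_config(fam)
    cfg$use_lie_features <- lie
    cfg$seed <- seed
    key <- paste0(fam, if (!lie) "_nolie")
    res <- tryCatch(
      run_repetitions(cfg, table, n_reps = n_reps,
                      validation_table = validation_table, seed = seed,
                      target = target),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      next
    }
    cells[[key]] <- res
    s <- res$summary
    s$family <- fam
    s$lie <- lie
    rows[[key]] <- s
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, cells = cells, errors = errors,
                 n_reps = n_reps, seed = seed),
            class = "gag_benchmark")
}

#' @export
print.gag_benchmark <- function(x, ...) {
  r <- x$report
  r <- r[r$metric == "r2" & r$set == max(r$set), ]
  cat("gag_benchmark (", x$n_reps, " reps); ranked by ", unique(r$set),
      " R^2:\n", sep = "")
  r <- r[order(-r$mean), c("family", "lie", "mean", "sd")]
  print(r, row.names = FALSE)
  if (length(x$errors))
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Predicted-vs-actual density scatter
#'
#' Scatter of predictions against targets coloured by a 2D kernel density
#' estimate, with the ideal y = x line.
#'
#' @param predicted,actual Numeric vectors.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-point density values.
#' @export
plot_density_scatter <- function(predicted, actual, ...) {
  k <- MASS::kde2d(actual, predicted, n = 50)
  dens <- k$z[cbind(findInterval(actual, k$x), findInterval(predicted, k$y))]
  cols <- grDevices::hcl.colors(64, "viridis")[
    cut(dens, 64, labels = FALSE)]
  graphics::plot(actual, predicted, col = cols, pch = 16, cex = 0.5,
                 xlab = "calculated (kcal/mol)",
                 ylab = "predicted (kcal/mol)", ...)
  graphics::abline(0, 1, col = "red", lty = 2)
  invisible(dens)
}

#' Architecture / dropout / activation sweep for the FCNN
#'
#' Trains one FCNN per grid cell (seeded) and reports train/test/validation
#' metrics for each (architecture, dropout, activation) combination.
#'
#' @param table Development feature data frame.
#' @param validation_table Held-out group table.
#' @param architectures List of hidden-layer integer vectors (use
#'   `integer(0)` for the zero-hidden-layer network).
#' @param dropouts Dropout rates to test.
#' @param activations Activation names to test.
#' @param n_reps Repetitions per cell.
#' @param seed Integer seed.
#' @param target Target column name.
#' @return Data frame with one row per cell x set x metric.
#' @export
fcnn_sweep <- function(table, validation_table = NULL,
                       architectures = list(integer(0), 12L, c(12L, 6L),
                                            c(12L, 6L, 3L)),
                       dropouts = c(0, 0.01, 0.05, 0.3),
                       activations = "relu", n_reps = 1, seed = 1L,
                       target = "mmgbsa_kcal_mol") {
  stopifnot(length(architectures) > 0, length(dropouts) > 0,
            length(activations) > 0)
  rows <- list()
  for (ai in seq_along(architectures)) for (dr in dropouts)
    for (acti in activations) {
      arch <- architectures[[ai]]
      cfg <- model_config("fcnn", seed = seed, hidden = arch, dropout = dr,
                          activation = acti)
      res <- run_repetitions(cfg, table, n_reps = n_reps,
                             validation_table = validation_table,
                             seed = seed, target = target)
      s <- res$summary
      s$architecture <- paste(c(length(feature_names(table)), arch, 1),
                              collapse = "-")
      s$dropout <- dr
      s$activation <- acti
      rows[[length(rows) + 1L]] <- s
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation accuracy under training-data reduction
#'
#' For every stride k, keeps every k-th development row, retrains the model
#' from scratch and evaluates on the validation table.  Points whose thinned
#' table falls under 50 rows are skipped with a message.
#'
#' @param config A [model_config()].
#' @param table Development feature data frame (time-ordered rows).
#' @param validation_table Held-out group table.
#' @param k_values Strides to test (k = 1 is the full-data baseline).
#' @param test_fraction Test fraction of each split.
#' @param seed Integer seed.
#' @param target Target column name.
#' @return Data frame with `k`, `fraction_retained`, `n_train` and
#'   validation `r2`, `mse`, `mae`.
#' @export
data_reduction_curve <- function(config, table, validation_table,
                                 k_values = c(1, 2, 5, 10, 25, 50, 100),
                                 test_fraction = 0.2, seed = 1L,
                                 target = "mmgbsa_kcal_mol") {
  stopifnot(all(k_values >= 1))
  rows <- list()
  for (k in k_values) {
    sub <- subsample_every_kth(table, k)
    if (nrow(sub) < 50L) {
      message("skipping k = ", k, ": only ", nrow(sub), " rows")
      next
    }
    sp <- split_random(sub, test_fraction, seed = seed + k)
    cfg <- config
    cfg$seed <- config$seed + k
    m <- gag_train(cfg, sp$train, target = target)
    met <- compute_metrics(predict(m, validation_table),
                           validation_table[[target]])
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, fraction_retained = nrow(sub) / nrow(table),
                 n_train = nrow(sp$train), r2 = met$r2, mse = met$mse,
                 mae = met$mae)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trajectory-mean evaluation
#'
#' Frame-level predictions are averaged per trajectory and compared with the
#' per-trajectory mean calculated energies.
#'
#' @param model A fitted `gag_model`.
#' @param table Per-frame feature data frame with target.
#' @param group_col Column identifying the trajectory.
#' @param target Target column name.
#' @return List with the per-trajectory table (`mean_predicted`,
#'   `mean_actual`), `pearson_r` and `mae` of the means.
#' @export
trajectory_mean_eval <- function(model, table, group_col = "system_id",
                                 target = "mmgbsa_kcal_mol") {
  g <- table[[group_col]]
  stopifnot(length(unique(g)) >= 2L)
  pred <- predict(model, table)
  per <- data.frame(
    group = sort(unique(g)),
    mean_predicted = as.numeric(tapply(pred, g, mean)[as.character(sort(unique(g)))]),
    mean_actual = as.numeric(tapply(table[[target]], g,
                                    mean)[as.character(sort(unique(g)))]))
  r <- if (sd(per$mean_predicted) == 0 || sd(per$mean_actual) == 0) {
    warning("degenerate means; correlation undefined")
    NA_real_
  } else cor(per$mean_predicted, per$mean_actual)
  list(per_trajectory = per, pearson_r = r,
       mae = mean(abs(per$mean_predicted - per$mean_actual)))
}

#' First-frame screening
#'
#' Predicts the energy of each trajectory's first frame only and compares it
#' with the trajectory-mean calculated energy — the single-structure
#' screening scenario.  Trajectories are partitioned into strong/weak binders
#' at an energy threshold (strong = at or below, i.e. more favourable).
#'
#' @param model A fitted `gag_model`.
#' @param table Per-frame feature data frame with target and `frame_index`.
#' @param group_col Column identifying the trajectory.
#' @param threshold Energy threshold (kcal/mol) for the binder partition.
#' @param target Target column name.
#' @return List with the per-trajectory table (frame-0 prediction, mean
#'   actual, class), `pearson_r`, `r2` and `mae`.
#' @export
first_frame_screen <- function(model, table, group_col = "system_id",
                               threshold = NULL,
                               target = "mmgbsa_kcal_mol") {
  groups <- sort(unique(table[[group_col]]))
  rows <- list()
  for (g in groups) {
    sub <- table[table[[group_col]] == g, , drop = FALSE]
    sub <- set_features(sub, feature_names(table))
    f0 <- sub[sub$frame_index == 0L, , drop = FALSE]
    if (!nrow(f0)) {
      message("skipping trajectory ", g, ": no frame 0")
      next
    }
    f0 <- set_features(f0[1L, , drop = FALSE], feature_names(table))
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, frame0_predicted = predict(model, f0),
      mean_actual = mean(sub[[target]]))
  }
  per <- do.call(rbind, rows)
  r <- cor(per$frame0_predicted, per$mean_actual)
  met <- compute_metrics(per$frame0_predicted, per$mean_actual)
  if (!is.null(threshold))
    per$class <- ifelse(per$frame0_predicted <= threshold, "strong", "weak")
  per <- per[order(per$frame0_predicted), ]
  list(per_trajectory = per, pearson_r = r, r2 = met$r2, mae = met$mae,
       threshold = threshold)
}
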