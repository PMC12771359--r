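MODEL_FAMILIES <- c("elastic_net", "linear_regression", "linear_svr",
                    "rbf_sampler_linear_svr", "gradient_boost",
                    "hist_gradient_boost", "random_forest", "fcnn")

model_defaults <- list(
  elastic_net = list(alpha = 1.0, l1_ratio = 0.5),
  linear_regression = list(),
  linear_svr = list(C = 1.0, epsilon = 0.1, max_iter = 10000),
  rbf_sampler_linear_svr = list(C = 1.0, epsilon = 0.1, max_iter = 10000,
                                n_components = 100, gamma = NULL),
  gradient_boost = list(n_estimators = 200, max_depth = 8,
                        learning_rate = 0.1, subsample = 0.8,
                        colsample_bytree = 0.8),
  hist_gradient_boost = list(max_iter = 200, max_depth = 6,
                             learning_rate = 0.1, l2_regularization = 0.1,
                             max_bins = 255),
  random_forest = list(n_estimators = 200, max_depth = 30,
                       min_samples_split = 2, min_samples_leaf = 1,
                       max_features = "sqrt"),
  fcnn = list(hidden = integer(0), dropout = 0.01, activation = "relu",
              learning_rate = 1e-3, weight_decay = 1e-4, batch_size = 256,
              max_epochs = 200, min_steps = 25000, patience = 15,
              lr_factor = 0.5, lr_patience = 7, val_fraction = 0.1,
              mc_passes = 30))

#' Specify a regression model
#'
#' Eight families share one train/predict contract: elastic net (regularization
#' strength 1.0, equal L1/L2 weighting), plain linear regression, linear
#' epsilon-SVR (C = 1, epsilon = 0.1), linear SVR on a random-Fourier RBF
#' feature map (100 components), gradient-boosted trees (200 rounds, depth 8,
#' learning rate 0.1, row/column subsampling 0.8), histogram gradient boosting
#' (200 iterations, depth 6, learning rate 0.1, L2 0.1), random forest (200
#' trees, depth 30, sqrt feature sampling) and a fully connected neural
#' network (no hidden layers, dropout 0.01, ReLU by default).  Defaults are
#' the best-performing settings of each family's tuning grid.
#'
#' @param family One of `r paste0('\x60', MODEL_FAMILIES, '\x60', collapse = ", ")`.
#' @param seed Integer seed governing all randomness of the fit.
#' @param use_lie_features If `FALSE`, `lie_elec` and `lie_vdw` are removed
#'   from the feature set before training (the LIE-ablated configuration).
#' @param ... Family-specific hyperparameters; unknown names are rejected.
#' @return A `gag_model_config`.
#' @export
model_config <- function(family, seed = 1L, use_lie_features = TRUE, ...) {
  family <- match.arg(family, MODEL_FAMILIES)
  hp <- model_defaults[[family]]
  extra <- list(...)
  unknown <- setdiff(names(extra), names(hp))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  hp[names(extra)] <- extra
  structure(list(family = family, seed = as.integer(seed),
                 use_lie_features = isTRUE(use_lie_features),
                 hyperparameters = hp),
            class = "gag_model_config")
}

model_matrix <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss)) {
    extra <- setdiff(feature_names(table), features)
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  as.matrix(table[, features, drop = FALSE])
}

#' Train a model on a feature table
#'
#' Features are standardized with training-set statistics (z-scores with
#' population standard deviation); the fitted scaler travels with the model
#' and is applied to any table passed to [predict.gag_model()].  All
#' randomness (subsampling, initialisation, dropout, tree seeds) derives from
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @param table Training feature data frame with the target column.
#' @param target Target column name (kcal/mol).
#' @param features Feature columns; defaults to the table's feature set,
#'   minus the LIE columns when `config$use_lie_features` is `FALSE`.
#' @return A `gag_model` with `predict`, `print`, `summary` and (for linear
#'   families) `coef` methods.
#' @export
gag_train <- function(config, table, target = "mmgbsa_kcal_mol",
                      features = NULL) {
  stopifnot(inherits(config, "gag_model_config"))
  if (!target %in% names(table)) stop("no target column '", target, "'")
  if (is.null(features)) features <- feature_names(table)
  if (!config$use_lie_features)
    features <- setdiff(features, c("lie_elec", "lie_vdw"))
  if (nrow(table) < 50L)
    warning("fewer than 50 training rows; fit may be unstable")
  scaler <- zscore_fit(table, features)
  scaled <- zscore_apply(table, scaler)
  X <- model_matrix(scaled, scaler$features)
  y <- table[[target]]
  hp <- config$hyperparameters
  if (sd(y) == 0) {
    # degenerate constant target: every family reduces to the constant fit
    return(structure(list(config = config, scaler = scaler,
                          fit = list(constant = y[1L]),
                          features = scaler$features, target = target,
                          schema_version = 1L),
                     class = "gag_model"))
  }
  fit <- switch(config$family,
    elastic_net = glmnet::glmnet(X, y, alpha = hp$l1_ratio,
                                 lambda = hp$alpha, standardize = FALSE),
    linear_regression = {
      f <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      list(coef = f$coefficients)
    },
    linear_svr = e1071::svm(X, y, type = "eps-regression",
                            kernel = "linear", cost = hp$C,
                            epsilon = hp$epsilon, scale = FALSE),
    rbf_sampler_linear_svr = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(X) else hp$gamma
      proj <- local_seed(config$seed, list(
        W = matrix(rnorm(ncol(X) * hp$n_components, sd = sqrt(2 * gamma)),
                   ncol(X), hp$n_components),
        b = runif(hp$n_components, 0, 2 * pi)))
      Z <- rbf_transform(X, proj)
      list(proj = proj,
           svr = e1071::svm(Z, y, type = "eps-regression",
                            kernel = "linear", cost = hp$C,
                            epsilon = hp$epsilon, scale = FALSE))
    },
    gradient_boost = local_seed(config$seed, xgboost::xgb.train(
      params = list(max_depth = hp$max_depth, eta = hp$learning_rate,
                    subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    objective = "reg:squarederror", nthread = 1,
                    seed = config$seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$n_estimators, verbose = 0)),
    hist_gradient_boost = local_seed(config$seed, xgboost::xgb.train(
      params = list(max_depth = hp$max_depth, eta = hp$learning_rate,
                    lambda = hp$l2_regularization, tree_method = "hist",
                    max_bin = hp$max_bins,
                    objective = "reg:squarederror", nthread = 1,
                    seed = config$seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$max_iter, verbose = 0)),
    random_forest = {
      mtry <- switch(as.character(hp$max_features),
                     sqrt = max(1L, floor(sqrt(ncol(X)))),
                     log2 = max(1L, floor(log2(ncol(X)))),
                     ncol(X))
      ranger::ranger(x = X, y = y, num.trees = hp$n_estimators,
                     max.depth = hp$max_depth,
                     min.node.size = hp$min_samples_split,
                     min.bucket = hp$min_samples_leaf, mtry = mtry,
                     seed = config$seed, num.threads = 1,
                     importance = "impurity")
    },
    fcnn = fcnn_train(X, y, hidden = hp$hidden, dropout = hp$dropout,
                      activation = hp$activation,
                      learning_rate = hp$learning_rate,
                      weight_decay = hp$weight_decay,
                      batch_size = hp$batch_size,
                      max_epochs = hp$max_epochs, min_steps = hp$min_steps,
                      patience = hp$patience,
                      lr_factor = hp$lr_factor, lr_patience = hp$lr_patience,
                      val_fraction = hp$val_fraction, seed = config$seed))
  structure(list(config = config, scaler = scaler, fit = fit,
                 features = scaler$features, target = target,
                 schema_version = 1L),
            class = "gag_model")
}

rbf_transform <- function(X, proj) {
  sqrt(2 / ncol(proj$W)) *
    cos(X %*% proj$W + rep(proj$b, each = nrow(X)))
}

#' Predict binding energies for new rows
#'
#' @param object A `gag_model`.
#' @param newdata Feature data frame containing every training feature.
#' @param ... Unused.
#' @return Numeric vector of predictions (kcal/mol), deterministic.
#' @export
predict.gag_model <- function(object, newdata, ...) {
  scaled <- zscore_apply(newdata, object$scaler)
  X <- model_matrix(scaled, object$features)
  fit <- object$fit
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(X)))
  out <- switch(object$config$family,
    elastic_net = predict(fit, X, s = object$config$hyperparameters$alpha),
    linear_regression = drop(cbind(1, X) %*% fit$coef),
    linear_svr = predict(fit, X),
    rbf_sampler_linear_svr = predict(fit$svr, rbf_transform(X, fit$proj)),
    gradient_boost = predict(fit, xgboost::xgb.DMatrix(X)),
    hist_gradient_boost = predict(fit, xgboost::xgb.DMatrix(X)),
    random_forest = predict(fit, data = X, num.threads = 1)$predictions,
    fcnn = predict(fit, X))
  as.numeric(out)
}

#' Coefficients of a linear-family model
#'
#' Standardized-space coefficients, with attribute `original_scale` giving
#' slopes per original feature unit (standardized slope divided by the
#' training standard deviation).
#'
#' @param object A `gag_model` of a linear family (elastic net, linear
#'   regression, linear SVR, or a zero-hidden-layer FCNN).
#' @param ... Unused.
#' @return Named coefficient vector (intercept first).
#' @export
coef.gag_model <- function(object, ...) {
  fam <- object$config$family
  fit <- object$fit
  std <- switch(fam,
    elastic_net = {
      cf <- as.matrix(coef(fit, s = object$config$hyperparameters$alpha))
      setNames(drop(cf), rownames(cf))
    },
    linear_regression = fit$coef,
    linear_svr = {
      w <- drop(crossprod(fit$coefs, fit$SV))
      c(`(Intercept)` = -fit$rho, setNames(w, object$features))
    },
    fcnn = {
      if (length(fit$sizes) != 2L)
        stop("coefficients are only defined for a zero-hidden-layer network")
      c(`(Intercept)` = fit$b[[1L]] * fit$y_scale + fit$y_center,
        setNames(drop(fit$W[[1L]]) * fit$y_scale, object$features))
    },
    stop("coefficients unsupported for family ", fam))
  slopes <- std[object$features]
  attr(std, "original_scale") <- slopes / object$scaler$sd[object$features]
  std
}

#' @export
print.gag_model_config <- function(x, ...) {
  cat("gag_model_config:", x$family,
      if (!x$use_lie_features) "(LIE-ablated)", "seed", x$seed, "\n")
  hp <- x$hyperparameters
  if (length(hp))
    cat("  ", paste(names(hp),
                    vapply(hp, function(v) paste(format(v), collapse = ","),
                           character(1)),
                    sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gag_model <- function(x, ...) {
  cat("gag_model (", x$config$family, "), ", length(x$features),
      " features, target '", x$target, "'\n", sep = "")
  invisible(x)
}

#' @export
summary.gag_model <- function(object, ...) {
  print(object)
  print(object$config)
  invisible(object)
}

#' Monte Carlo dropout uncertainty for an FCNN model
#'
#' @param model A `gag_model` with family `fcnn` (dropout must be positive
#'   for a non-degenerate spread).
#' @param table Feature data frame.
#' @param n_passes Stochastic forward passes (default 30).
#' @param seed Integer seed.
#' @return List with per-row `mean` and `sd`.
#' @export
mc_dropout_predict <- function(model, table, n_passes = 30, seed = 1L) {
  stopifnot(inherits(model, "gag_model"), model$config$family == "fcnn")
  scaled <- zscore_apply(table, model$scaler)
  X <- model_matrix(scaled, model$features)
  fcnn_mc_dropout(model$fit, X, n_passes = n_passes, seed = seed)
}

#' Per-row prediction spread over repeated cross-validation
#'
#' Runs `rounds` seeded k-fold partitions; in each, every row is predicted by
#' a model trained on the other folds, and the per-row population standard
#' deviation over rounds is the uncertainty estimate.
#'
#' @param config A [model_config()].
#' @param table Feature data frame with target.
#' @param rounds Number of repeated partitions (default 30).
#' @param folds Folds per round (default 10).
#' @param seed Integer seed.
#' @param target Target column name.
#' @return List with per-row `mean`, `sd` and the rounds-by-rows prediction
#'   matrix.
#' @export
repeated_cv_prediction_std <- function(config, table, rounds = 30,
                                       folds = 10, seed = 1L,
                                       target = "mmgbsa_kcal_mol") {
  n <- nrow(table)
  stopifnot(n >= folds)
  preds <- matrix(NA_real_, rounds, n)
  for (r in seq_len(rounds)) {
    fold_of <- local_seed(seed + r, sample(rep_len(seq_len(folds), n)))
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      cfg <- config
      cfg$seed <- config$seed + r
      m <- suppressWarnings(
        gag_train(cfg, table[!hold, , drop = FALSE], target = target))
      preds[r, hold] <- predict(m, table[hold, , drop = FALSE])
    }
  }
  mu <- colMeans(preds)
  list(mean = mu, sd = sqrt(colMeans(sweep(preds, 2, mu)^2)),
       predictions = preds)
}

#' Repeated independent trainings with fresh splits
#'
#' Trains `n_reps` models of one configuration, regenerating the 80/20
#' train/test split before each, and aggregates train/test/validation metrics
#' as mean and population standard deviation across repetitions.
#'
#' @param config A [model_config()].
#' @param table Development feature data frame (split into train/test).
#' @param n_reps Number of repetitions (default 10).
#' @param validation_table Optional held-out group table, never split.
#' @param test_fraction Test fraction of each split.
#' @param seed Base seed; repetition r uses `seed + r` for both split and fit.
#' @param target Target column name.
#' @return A `gag_repetitions` list: `summary` data frame (set, metric, mean,
#'   sd) and the per-repetition `raw` metrics.
#' @export
run_repetitions <- function(config, table, n_reps = 10,
                            validation_table = NULL, test_fraction = 0.2,
                            seed = 1L, target = "mmgbsa_kcal_mol") {
  sets <- c("train", "test", if (!is.null(validation_table)) "validation")
  raw <- list()
  for (r in seq_len(n_reps)) {
    sp <- split_random(table, test_fraction, seed = seed + r)
    cfg <- config
    cfg$seed <- config$seed + r
    m <- gag_train(cfg, sp$train, target = target)
    one <- list(
      train = compute_metrics(predict(m, sp$train), sp$train[[target]]),
      test = compute_metrics(predict(m, sp$test), sp$test[[target]]))
    if (!is.null(validation_table))
      one$validation <- compute_metrics(predict(m, validation_table),
                                        validation_table[[target]])
    raw[[r]] <- one
  }
  summ <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(c("r2", "mse", "mae"), function(met) {
      v <- vapply(raw, function(x) x[[s]][[met]], numeric(1))
      data.frame(set = s, metric = met, mean = mean(v),
                 sd = sqrt(mean((v - mean(v))^2)))
    }))
  }))
  structure(list(summary = summ, raw = raw, config = config,
                 n_reps = n_reps),
            class = "gag_repetitions")
}

#' @export
print.gag_repetitions <- function(x, ...) {
  cat("gag_repetitions:", x$config$family, "x", x$n_reps, "reps\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

rep_metric <- function(reps, set, metric) {
  s <- reps$summary
  s$mean[s$set == set & s$metric == metric]
}

#' Save / load a fitted model archive
#'
#' The archive stores the fitted state, its configuration and scaler plus a
#' schema version; loading refuses archives from other schema versions.
#'
#' @param model A `gag_model`.
#' @param path Archive path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gag_model"))
  if (model$config$family %in% c("gradient_boost", "hist_gradient_boost"))
    model$fit <- xgboost::xgb.save.raw(model$fit)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!identical(model$schema_version, 1L))
    stop("unsupported model archive schema version")
  if (model$config$family %in% c("gradient_boost", "hist_gradient_boost"))
    model$fit <- xgboost::xgb.load.raw(model$fit)
  model
}
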