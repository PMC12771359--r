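METADATA_COLUMNS <- c("system_id", "protein_id", "gag_type", "gag_length",
                      "pose", "frame_index")

#' Feature names of a table
#'
#' Uses the `features` attribute when present, otherwise every column that is
#' neither metadata nor the target.
#'
#' @param table Feature data frame.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  f <- attr(table, "features")
  if (!is.null(f)) return(intersect(f, names(table)))
  setdiff(names(table), c(METADATA_COLUMNS, "mmgbsa_kcal_mol"))
}

set_features <- function(table, features) {
  attr(table, "features") <- features
  table
}

#' Drop rows with missing feature or target values
#' @param table Feature data frame.
#' @param target Target column name (ignored when absent).
#' @return Table without incomplete rows; the number dropped is messaged.
#' @export
drop_incomplete <- function(table, target = "mmgbsa_kcal_mol") {
  cols <- c(feature_names(table), intersect(target, names(table)))
  ok <- stats::complete.cases(table[, cols, drop = FALSE])
  if (any(!ok)) message("dropping ", sum(!ok), " incomplete row(s)")
  set_features(table[ok, , drop = FALSE], feature_names(table))
}

#' Fit z-score scaling parameters on a training table
#'
#' Per-feature mean and population (divide-by-n) standard deviation.
#' Constant features cannot be scaled and are dropped with a warning;
#' downstream models then never see them.
#'
#' @param table Training feature data frame.
#' @param features Feature columns to scale.
#' @return A `gag_scaler` with `mean`, `sd` and the retained `features`.
#' @export
zscore_fit <- function(table, features = feature_names(table)) {
  stopifnot(nrow(table) >= 2L)
  X <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdev > 0
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(features[!keep], collapse = ", "))
  structure(list(mean = mu[keep], sd = sdev[keep], features = features[keep]),
            class = "gag_scaler")
}

#' Apply fitted scaling parameters
#'
#' Test and validation tables must be transformed with the training scaler;
#' their transformed columns will generally not have mean 0.
#'
#' @param table Feature data frame.
#' @param params A `gag_scaler` from [zscore_fit()].
#' @return Table with scaled feature columns (non-retained features removed
#'   from the feature set).
#' @export
zscore_apply <- function(table, params) {
  stopifnot(inherits(params, "gag_scaler"))
  miss <- setdiff(params$features, names(table))
  if (length(miss))
    stop("table lacks feature(s): ", paste(miss, collapse = ", "))
  for (f in params$features)
    table[[f]] <- (table[[f]] - params$mean[[f]]) / params$sd[[f]]
  set_features(table, params$features)
}

#' Random train/test split
#'
#' Seeded row shuffle into disjoint, exhaustive train and test parts; the
#' test part holds `floor(n * test_fraction)` rows.
#'
#' @param table Feature data frame (at least 5 rows).
#' @param test_fraction Fraction of rows held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` tables.
#' @export
split_random <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(table)
  if (n < 5L) stop("too few rows to split (need at least 5)")
  n_test <- floor(n * test_fraction)
  perm <- local_seed(seed, sample.int(n))
  test_idx <- sort(perm[seq_len(n_test)])
  feats <- feature_names(table)
  list(train = set_features(table[-test_idx, , drop = FALSE], feats),
       test = set_features(table[test_idx, , drop = FALSE], feats))
}

#' Group-wise holdout split
#'
#' Places every row whose `group_key` value is in `held_groups` into the
#' validation part; nothing from a held group ever reaches development.
#'
#' @param table Feature data frame.
#' @param group_key Grouping column name (e.g. `protein_id`).
#' @param held_groups Values of `group_key` to hold out.
#' @return List with `development` and `validation` tables.
#' @export
split_group_holdout <- function(table, group_key, held_groups) {
  stopifnot(length(held_groups) >= 1L)
  if (!group_key %in% names(table)) stop("no such group column: ", group_key)
  absent <- setdiff(held_groups, unique(table[[group_key]]))
  if (length(absent))
    stop("held group(s) absent from table: ", paste(absent, collapse = ", "))
  hold <- table[[group_key]] %in% held_groups
  if (all(hold)) stop("empty development set: all groups held out")
  feats <- feature_names(table)
  list(development = set_features(table[!hold, , drop = FALSE], feats),
       validation = set_features(table[hold, , drop = FALSE], feats))
}

#' Keep every k-th row
#'
#' Retains rows at 0-based index 0, k, 2k, ... in the table's current order.
#' Because rows are ordered (system, trajectory, frame), this emulates
#' thinning time-correlated trajectory data.
#'
#' @param table Feature data frame.
#' @param k Stride (k = 1 is the identity).
#' @return Thinned table of `ceiling(n / k)` rows.
#' @export
subsample_every_kth <- function(table, k) {
  stopifnot(k >= 1)
  idx <- seq(1L, nrow(table), by = k)
  set_features(table[idx, , drop = FALSE], feature_names(table))
}

#' Regression metrics
#'
#' `r2 = 1 - SS_res / SS_tot` (against the evaluated set's own mean), mean
#' squared error and mean absolute error.
#'
#' @param predicted,actual Equal-length numeric vectors (length at least 2).
#' @return List with `r2`, `mse` (kcal^2/mol^2) and `mae` (kcal/mol); `r2` is
#'   `NA` when the actual values have zero variance.
#' @export
compute_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 2L)
  res <- actual - predicted
  sstot <- sum((actual - mean(actual))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  list(r2 = r2, mse = mean(res^2), mae = mean(abs(res)))
}

#' Read a feature table CSV
#'
#' @param path CSV path with one row per frame.
#' @param column_map Optional named character vector mapping external column
#'   names (values) onto canonical names (names), so deposited descriptor
#'   tables with different headers can be ingested.
#' @param features Feature columns; defaults to the canonical names present.
#' @return Feature data frame with the `features` attribute set.
#' @export
read_feature_csv <- function(path, column_map = NULL, features = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(tab))
    if (length(miss))
      stop("column_map refers to absent column(s): ",
           paste(miss, collapse = ", "))
    names(tab)[match(column_map, names(tab))] <- names(column_map)
  }
  if (is.null(features)) features <- intersect(CANONICAL_FEATURES, names(tab))
  if (!length(features)) stop("no recognizable feature columns in ", path)
  set_features(tab, features)
}

#' Write a feature table CSV
#' @param table Feature data frame.
#' @param path Output path.
#' @return Invisibly, the table.
#' @export
write_feature_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

# run expr under a local RNG seed without disturbing the caller's RNG state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
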