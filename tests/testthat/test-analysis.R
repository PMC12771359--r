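test_that("Pearson matrix matches hand values and flags constants", {
  tab <- mk_table(cbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(-1, -2, -3)),
                  c(0, 1, 2))
  cm <- pearson_matrix(tab, include_target = FALSE)
  expect_equal(cm$r["a", "b"], 0.981981, tolerance = 1e-5)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))

  dup <- mk_table(cbind(a = c(1, 2, 3), b = c(1, 2, 3)), c(0, 0, 1))
  expect_equal(pearson_matrix(dup, FALSE)$r["a", "b"], 1)

  cst <- mk_table(cbind(a = c(1, 2, 3), b = c(7, 7, 7)), c(0, 0, 1))
  expect_error(pearson_matrix(cst, FALSE), "constant column")

  cm_t <- pearson_matrix(tab, include_target = TRUE)
  expect_true("mmgbsa_kcal_mol" %in% cm_t$features)
})

test_that("feature clustering merges redundancy first and recovers blocks", {
  set.seed(1)
  x <- rnorm(50)
  tab <- mk_table(cbind(a = x, b = x + rnorm(50, sd = 1e-6), c = rnorm(50)),
                  rnorm(50))
  hc <- cluster_features(pearson_matrix(tab, FALSE))
  expect_lt(hc$height[1], 1e-3)          # duplicated pair merges at ~0
  expect_setequal(stats::cutree(hc, 2)[c("a", "b")], 1)

  # three-block design recovered from generated data
  blocks <- list(b1 = c("f1", "f2", "f3"), b2 = c("f4", "f5"),
                 b3 = c("f6", "f7"))
  feats <- unlist(blocks)
  R <- diag(7)
  for (b in blocks) {
    idx <- match(b, feats)
    R[idx, idx] <- 0.9
  }
  diag(R) <- 1
  gen <- gen_feature_table(table_spec(n_rows = 4000, features = feats,
                                      correlation = R, seed = 2))
  hc2 <- cluster_features(pearson_matrix(gen$table, FALSE))
  got <- stats::cutree(hc2, 3)
  truth <- rep(seq_along(blocks), lengths(blocks))
  # same partition up to label permutation
  expect_equal(length(unique(paste(got, truth))), 3L)
})

test_that("orthogonal features merge last at distance near 1", {
  gen <- gen_feature_table(table_spec(n_rows = 20000,
                                      features = c("u", "v", "w"), seed = 3))
  hc <- cluster_features(pearson_matrix(gen$table, FALSE))
  expect_gt(min(hc$height), 0.9)
})

one_signal_table <- function(n = 2000, seed = 4) {
  gen <- gen_feature_table(table_spec(n_rows = n,
                                      features = paste0("x", 1:5),
                                      weights = c(3, 0, 0, 0, 0),
                                      noise_sd = 0.3, seed = seed))
  gen$table
}

test_that("permutation importance isolates predictive features", {
  tab <- one_signal_table()
  m <- gag_train(model_config("linear_regression"), tab)
  imp <- permutation_importance(m, tab, n_repeats = 5, seed = 1)
  expect_equal(names(which.max(imp$normalized)), "x1")
  expect_equal(max(abs(imp$normalized)), 1)
  # null features stay near zero
  expect_lt(max(abs(imp$raw[paste0("x", 2:5)])), 0.05 * imp$raw["x1"])
  # noiseless single signal: permutation doubles the variance in MSE terms
  pure <- mk_table(cbind(x1 = rnorm(20000)), NULL)
  pure$mmgbsa_kcal_mol <- pure$x1
  mp <- gag_train(model_config("linear_regression"), pure)
  ip <- permutation_importance(mp, pure, n_repeats = 3, seed = 2)
  expect_equal(unname(ip$raw["x1"]), 2 * var(pure$x1), tolerance = 0.1)
})

test_that("duplicated features split tree importance and null LOFO", {
  set.seed(5)
  x1 <- rnorm(1200)
  dup <- mk_table(cbind(x1 = x1, x2 = x1 + rnorm(1200, sd = 0.01),
                        x3 = rnorm(1200)), 3 * x1 + rnorm(1200, sd = 0.3))
  single <- mk_table(cbind(x1 = x1, x3 = rnorm(1200)),
                     dup$mmgbsa_kcal_mol)
  m_dup <- gag_train(model_config("random_forest", seed = 1), dup)
  m_one <- gag_train(model_config("random_forest", seed = 1), single)
  i_dup <- permutation_importance(m_dup, dup, n_repeats = 5, seed = 3)
  i_one <- permutation_importance(m_one, single, n_repeats = 5, seed = 3)
  expect_lt(i_dup$raw["x1"], i_one$raw["x1"])
  expect_lt(i_dup$raw["x2"], i_one$raw["x1"])

  lofo <- lofo_importance(model_config("linear_regression"), dup)
  expect_lt(abs(lofo$raw["x2"]), 0.05)   # redundant copy: removal is free
  expect_lt(abs(lofo$raw["x3"]), 0.05)   # pure noise feature
})

test_that("LOFO on the sole predictive feature recovers the target variance", {
  pure <- mk_table(cbind(x1 = rnorm(5000), x2 = rnorm(5000)), NULL)
  pure$mmgbsa_kcal_mol <- pure$x1
  lofo <- lofo_importance(model_config("linear_regression"), pure)
  expect_equal(unname(lofo$raw["x1"]), var(pure$mmgbsa_kcal_mol),
               tolerance = 0.05)
})

test_that("coefficient importance normalizes to the largest weight", {
  set.seed(6)
  tab <- mk_table(cbind(x1 = rnorm(500), x2 = rnorm(500)), NULL)
  tab$mmgbsa_kcal_mol <- 2 * tab$x1 - 4 * tab$x2
  m <- gag_train(model_config("linear_regression"), tab)
  imp <- coefficient_importance(m)
  expect_equal(unname(imp$normalized["x2"]), 1, tolerance = 1e-6)
  # standardized-coefficient ratio: |2 sd(x1)| / |4 sd(x2)| on this sample
  sdp <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(imp$normalized["x1"]),
               2 * sdp(tab$x1) / (4 * sdp(tab$x2)), tolerance = 1e-6)
  m_rf <- gag_train(model_config("random_forest"), tab)
  expect_error(coefficient_importance(m_rf), "unsupported method")
  expect_s3_class(builtin_importance(m_rf), "gag_importance")
  expect_error(builtin_importance(m), "unsupported method")
})

test_that("benchmark reports every requested family and isolates failures", {
  gen <- gen_feature_table(table_spec_paperlike(n_rows = 1200, seed = 7))
  sp <- split_group_holdout(gen$table, "protein_id", "catS")
  bm <- run_benchmark(sp$development, sp$validation,
                      families = c("linear_regression", "random_forest"),
                      n_reps = 2, seed = 1)
  expect_setequal(unique(bm$report$family),
                  c("linear_regression", "random_forest"))
  expect_setequal(unique(bm$report$set), c("train", "test", "validation"))
  expect_length(bm$errors, 0)
})

test_that("LIE-ablated models never see the LIE columns", {
  gen <- gen_feature_table(table_spec_paperlike(n_rows = 1200, seed = 8))
  sp <- split_group_holdout(gen$table, "protein_id", "catS")
  cfg <- model_config("linear_regression", use_lie_features = FALSE)
  m <- gag_train(cfg, sp$development)
  expect_false(any(c("lie_elec", "lie_vdw") %in% m$features))
  expect_length(setdiff(CANONICAL_FEATURES, c(m$features, "lie_elec",
                                              "lie_vdw")), 0)
})

test_that("a one-cell FCNN sweep reduces to plain repetitions", {
  gen <- gen_feature_table(table_spec(n_rows = 400, features = c("x1", "x2"),
                                      weights = c(2, -1), noise_sd = 0.5,
                                      seed = 9))
  grid <- fcnn_sweep(gen$table, architectures = list(integer(0)),
                     dropouts = 0.01, activations = "relu", n_reps = 1,
                     seed = 3)
  direct <- run_repetitions(model_config("fcnn", seed = 3, hidden = integer(0),
                                         dropout = 0.01), gen$table,
                            n_reps = 1, seed = 3)
  expect_equal(grid$mean, direct$summary$mean, tolerance = 1e-12)
  expect_equal(unique(grid$architecture), "2-1")
})

test_that("tree and hidden-layer models beat linear ones on interaction targets", {
  gen <- gen_feature_table(table_spec(
    n_rows = 4000, features = c("x1", "x2", "x3"), weights = c(1, 0.5, 0),
    interactions = list(list("x1", "x2", 2)), noise_sd = 0.3, seed = 10,
    validation_group = "val", validation_fraction = 0.25))
  sp <- split_group_holdout(gen$table, "protein_id", "val")
  r2_of <- function(cfg) {
    m <- gag_train(cfg, sp$development)
    compute_metrics(predict(m, sp$validation),
                    sp$validation$mmgbsa_kcal_mol)$r2
  }
  lin <- r2_of(model_config("linear_regression"))
  gb <- r2_of(model_config("gradient_boost", seed = 1))
  deep <- r2_of(model_config("fcnn", seed = 1, hidden = c(16L, 8L)))
  expect_gt(gb, lin + 0.1)
  expect_gt(deep, lin + 0.1)
})

test_that("trajectory-mean evaluation and first-frame screening behave", {
  sp <- table_spec_paperlike(n_rows = 3000, seed = 11)
  sp$first_frame_drift <- 3
  gen <- gen_feature_table(sp)
  hold <- split_group_holdout(gen$table, "protein_id", "catS")
  m <- gag_train(model_config("linear_regression"), hold$development)
  tm <- trajectory_mean_eval(m, hold$validation)
  frame_r <- cor(predict(m, hold$validation), hold$validation$mmgbsa_kcal_mol)
  expect_gt(tm$pearson_r, frame_r)   # averaging cancels frame noise

  ff <- first_frame_screen(m, hold$validation, threshold = -30)
  expect_gt(ff$mae, tm$mae)          # drifted first frames are less accurate
  expect_setequal(unique(ff$per_trajectory$class), c("strong", "weak"))
  hi <- first_frame_screen(m, hold$validation, threshold = 1e6)
  expect_equal(unique(hi$per_trajectory$class), "strong")

  # an oracle model reproduces trajectory means exactly
  oracle_tab <- hold$validation
  oracle_dev <- hold$development
  oracle_dev$mmgbsa_kcal_mol <- oracle_dev$lie_elec
  oracle_tab$mmgbsa_kcal_mol <- oracle_tab$lie_elec
  mo <- gag_train(model_config("linear_regression"), oracle_dev,
                  features = "lie_elec")
  tmo <- trajectory_mean_eval(mo, oracle_tab)
  expect_equal(tmo$pearson_r, 1, tolerance = 1e-6)
  expect_lt(tmo$mae, 1e-6)
})

test_that("density scatter returns a finite density per point", {
  set.seed(12)
  pred <- rnorm(200)
  act <- pred + rnorm(200, sd = 0.3)
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path)
  dens <- plot_density_scatter(pred, act)
  grDevices::dev.off()
  expect_length(dens, 200)
  expect_true(all(is.finite(dens)))
})
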