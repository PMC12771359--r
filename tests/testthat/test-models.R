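lin2_table <- function(n = 400, noise = 0, seed = 1) {
  gen <- gen_feature_table(table_spec(n_rows = n, features = c("x1", "x2"),
                                      weights = c(2, -3), noise_sd = noise,
                                      seed = seed))
  gen$table
}

test_that("unknown hyperparameters and families are rejected", {
  expect_error(model_config("random_forest", bogus = 1), "unknown hyperparameter")
  expect_error(model_config("flux_capacitor"), "arg")
  cfg <- model_config("fcnn", dropout = 0.3)
  expect_equal(cfg$hyperparameters$dropout, 0.3)
  expect_equal(cfg$hyperparameters$activation, "relu")
})

test_that("linear regression recovers exact weights on noiseless data", {
  tab <- lin2_table()
  m <- gag_train(model_config("linear_regression"), tab)
  slopes <- attr(coef(m), "original_scale")
  expect_equal(unname(slopes), c(2, -3), tolerance = 1e-6)
  # agrees with the closed-form normal-equations solution
  X <- cbind(1, tab$x1, tab$x2)
  beta <- solve(crossprod(X), crossprod(X, tab$mmgbsa_kcal_mol))
  expect_equal(unname(slopes), unname(beta[2:3]), tolerance = 1e-8)
  expect_equal(predict(m, tab), tab$mmgbsa_kcal_mol, tolerance = 1e-8)
})

test_that("every family handles a constant target", {
  tab <- lin2_table()
  tab$mmgbsa_kcal_mol <- -5
  for (fam in c("linear_regression", "elastic_net", "random_forest",
                "gradient_boost", "fcnn")) {
    m <- gag_train(model_config(fam, seed = 1), tab)
    expect_equal(predict(m, tab[1:10, ]), rep(-5, 10), tolerance = 0.05,
                 info = fam)
  }
})

test_that("prediction is deterministic, row-independent and schema-checked", {
  tab <- lin2_table(noise = 1)
  for (fam in c("random_forest", "fcnn", "gradient_boost",
                "rbf_sampler_linear_svr")) {
    m <- gag_train(model_config(fam, seed = 3), tab)
    p1 <- predict(m, tab)
    expect_identical(p1, predict(m, tab), info = fam)
    perm <- sample(nrow(tab))
    expect_equal(predict(m, tab[perm, ]), p1[perm], info = fam)
  }
  m <- gag_train(model_config("linear_regression"), tab)
  bad <- tab
  names(bad)[names(bad) == "x2"] <- "z9"
  attr(bad, "features") <- c("x1", "z9")
  expect_error(predict(m, bad), "x2")
})

test_that("identical config, table and seed reproduce metrics exactly", {
  tab <- lin2_table(n = 300, noise = 1, seed = 5)
  for (fam in c("fcnn", "gradient_boost", "random_forest",
                "rbf_sampler_linear_svr")) {
    r1 <- run_repetitions(model_config(fam, seed = 7), tab, n_reps = 2,
                          seed = 9)
    r2 <- run_repetitions(model_config(fam, seed = 7), tab, n_reps = 2,
                          seed = 9)
    expect_identical(r1$summary, r2$summary, info = fam)
  }
})

test_that("an interpolating forest memorizes its training rows", {
  tab <- lin2_table(n = 300, noise = 1, seed = 2)
  m <- gag_train(model_config("random_forest"), tab)
  met <- compute_metrics(predict(m, tab), tab$mmgbsa_kcal_mol)
  expect_gt(met$r2, 0.9)
})

test_that("elastic net at full strength induces exact sparsity on weak signal", {
  gen <- gen_feature_table(table_spec(n_rows = 500,
                                      features = paste0("x", 1:6),
                                      weights = c(0.2, rep(0, 5)),
                                      noise_sd = 2, seed = 3))
  m <- gag_train(model_config("elastic_net"), gen$table)
  cf <- coef(m)[feature_names(gen$table)]
  expect_true(any(cf == 0))
})

test_that("zero-hidden FCNN approaches the least-squares solution as dropout vanishes", {
  tab <- lin2_table(n = 20000)
  m0 <- gag_train(model_config("fcnn", seed = 2, dropout = 0), tab)
  expect_equal(unname(attr(coef(m0), "original_scale")), c(2, -3),
               tolerance = 0.01)
  m01 <- gag_train(model_config("fcnn", seed = 2, dropout = 0.01), tab)
  expect_equal(unname(attr(coef(m01), "original_scale")), c(2, -3),
               tolerance = 0.05)
})

test_that("all activation functions train a working network", {
  gen <- gen_feature_table(table_spec(n_rows = 600, features = c("x1", "x2"),
                                      weights = c(2, -1),
                                      interactions = list(list("x1", "x2", 1)),
                                      noise_sd = 0.5, seed = 4))
  sp <- split_random(gen$table, 0.25, seed = 1)
  for (act in c("relu", "elu", "gelu", "leakyrelu", "sigmoid", "tanh")) {
    cfg <- model_config("fcnn", seed = 1, hidden = 8L, activation = act,
                        min_steps = 4000)
    m <- gag_train(cfg, sp$train)
    met <- compute_metrics(predict(m, sp$test), sp$test$mmgbsa_kcal_mol)
    expect_gt(met$r2, 0.5, label = paste("test R2 for", act))
  }
})

test_that("MC dropout spread behaves across dropout rates and pass counts", {
  tab <- lin2_table(n = 500, noise = 0.5, seed = 6)
  m0 <- gag_train(model_config("fcnn", dropout = 0, min_steps = 2000), tab)
  mc0 <- mc_dropout_predict(m0, tab[1:30, ], n_passes = 10, seed = 1)
  expect_equal(max(mc0$sd), 0)

  m3 <- gag_train(model_config("fcnn", dropout = 0.3, min_steps = 2000), tab)
  mc_one <- mc_dropout_predict(m3, tab[1:30, ], n_passes = 1, seed = 1)
  expect_equal(max(mc_one$sd), 0)

  m01 <- gag_train(model_config("fcnn", dropout = 0.01, min_steps = 2000), tab)
  mc3 <- mc_dropout_predict(m3, tab[1:30, ], n_passes = 30, seed = 1)
  mc01 <- mc_dropout_predict(m01, tab[1:30, ], n_passes = 30, seed = 1)
  expect_gt(mean(mc3$sd), mean(mc01$sd))
})

test_that("repeated cross-validation spread reflects fold sensitivity", {
  tab <- lin2_table(n = 120, noise = 0, seed = 8)
  cv <- repeated_cv_prediction_std(model_config("linear_regression"), tab,
                                   rounds = 3, folds = 5, seed = 2)
  expect_lt(max(cv$sd), 1e-6)   # deterministic linear law: no fold sensitivity
  one <- repeated_cv_prediction_std(model_config("linear_regression"), tab,
                                    rounds = 1, folds = 5, seed = 2)
  expect_equal(max(one$sd), 0)
})

test_that("repetition summaries aggregate with population spread", {
  tab <- lin2_table(n = 300, noise = 1, seed = 9)
  r <- run_repetitions(model_config("linear_regression"), tab, n_reps = 1,
                       seed = 1)
  expect_equal(r$summary$sd, rep(0, nrow(r$summary)))
  expect_setequal(unique(r$summary$set), c("train", "test"))
})

test_that("model archives round-trip through save and load", {
  tab <- lin2_table(n = 300, noise = 0.5, seed = 10)
  for (fam in c("fcnn", "gradient_boost", "linear_svr")) {
    m <- gag_train(model_config(fam, seed = 4), tab)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(m, path)
    back <- load_model(path)
    expect_equal(predict(back, tab[1:20, ]), predict(m, tab[1:20, ]),
                 tolerance = 1e-10, info = fam)
  }
  # schema version guard
  m <- gag_train(model_config("linear_regression"), tab)
  m$schema_version <- 99L
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, p)
  expect_error(load_model(p), "schema version")
})

test_that("no family anti-learns on the shifted-group benchmark", {
  gen <- gen_feature_table(table_spec(
    n_rows = 1500, features = paste0("x", 1:4), weights = c(3, -2, 1, 0),
    noise_sd = 1, groups = "dev", validation_group = "val",
    validation_shift = c(x1 = 1, x4 = 2), frames_per_traj = 5L, seed = 11))
  sp <- split_group_holdout(gen$table, "protein_id", "val")
  for (fam in c("linear_regression", "random_forest", "fcnn")) {
    m <- gag_train(model_config(fam, seed = 2), sp$development)
    tr <- compute_metrics(predict(m, sp$development),
                          sp$development$mmgbsa_kcal_mol)
    va <- compute_metrics(predict(m, sp$validation),
                          sp$validation$mmgbsa_kcal_mol)
    expect_lte(tr$mse, va$mse + 1e-8, label = paste("train vs val MSE,", fam))
  }
})
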