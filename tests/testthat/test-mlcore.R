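test_that("make_split gives 75/25 with balanced folds and is deterministic", {
  ids <- sprintf("s%03d", 1:100)
  labs <- rep(c("ESIPT", "CONVENTIONAL"), 50)
  plan <- make_split(ids, labs, seed = 7)
  expect_length(plan$train_ids, 75)
  expect_length(plan$test_ids, 25)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_equal(unname(sapply(plan$cv_folds, function(f) length(f$val))),
               rep(15, 5))
  # folds partition the training ids
  expect_setequal(unlist(lapply(plan$cv_folds, `[[`, "val")), plan$train_ids)
  plan2 <- make_split(ids, labs, seed = 7)
  expect_identical(plan, plan2)
  plan3 <- make_split(ids, labs, seed = 8)
  expect_false(identical(plan$test_ids, plan3$test_ids))
})

test_that("stratification preserves a 40/60 imbalance within one sample per fold", {
  ids <- sprintf("s%03d", 1:100)
  labs <- rep(c("A", "B"), c(40, 60))
  plan <- make_split(ids, labs, seed = 3)
  lab_of <- setNames(labs, ids)
  expect_equal(sum(lab_of[plan$test_ids] == "A"), 10)
  for (f in plan$cv_folds) {
    nA <- sum(lab_of[f$val] == "A")
    expect_lte(abs(nA - 0.4 * length(f$val)), 1)
  }
  expect_error(make_split(sprintf("s%d", 1:20), rep(c("A", "B"), c(17, 3)), k = 5),
               "stratification")
})

test_that("every algorithm separates a linearly separable toy problem", {
  set.seed(42)
  n <- 80
  X <- cbind(x1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             x2 = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- rep(c("CONVENTIONAL", "ESIPT"), each = n / 2)
  fm <- feature_matrix(X, "DESC2D")
  plan <- make_split(rownames(X), y, seed = 1)
  for (alg in c("RF", "SVM", "GBT", "KNN", "DT", "MLP")) {
    hp <- if (alg == "RF") list(ntree = 60) else if (alg == "GBT") list(nrounds = 40) else list()
    res <- fit_model(model_config(alg, "classify", hp, seed = 1), fm,
                     setNames(y, rownames(X)), plan)
    expect_equal(res$report$test$ACC, 1,
                 info = paste("algorithm", alg))
  }
})

test_that("fits are reproducible bit-for-bit under a fixed seed", {
  fm <- random_fm(60, 10, seed = 9)
  set.seed(99)
  y <- exp(rnorm(60) + unclass(fm)[, 1])
  plan <- make_split(rownames(fm), NULL, seed = 2)
  for (alg in c("RF", "GBT", "SVM", "MLP")) {
    hp <- if (alg == "RF") list(ntree = 30) else if (alg == "GBT") list(nrounds = 20) else list()
    cfg <- model_config(alg, "regress", hp, seed = 5)
    r1 <- fit_model(cfg, fm, y, plan)
    r2 <- fit_model(cfg, fm, y, plan)
    expect_identical(predict(r1$model, fm), predict(r2$model, fm),
                     info = paste("algorithm", alg))
    expect_identical(r1$report$test$RMSE, r2$report$test$RMSE)
  }
})

test_that("permuted labels give chance-level CV AUC", {
  aucs <- sapply(1:20, function(rep_i) {
    fm <- random_fm(100, 8, seed = 100 + rep_i)
    set.seed(200 + rep_i)
    y <- sample(rep(c("A", "ESIPT"), 50))
    plan <- make_split(rownames(fm), y, seed = rep_i)
    res <- fit_model(model_config("RF", "classify", list(ntree = 50),
                                  seed = rep_i),
                     fm, setNames(y, rownames(fm)), plan)
    res$report$cv$AUC
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("degenerate and malformed inputs are rejected", {
  fm <- random_fm(30, 5)
  expect_error(fit_model(model_config("RF", "classify"), fm,
                         rep("ESIPT", 30)),
               "single-class")
  bad <- unclass(fm); bad[1, 1] <- NA
  expect_error(fit_model(model_config("RF", "classify"),
                         feature_matrix(bad, "MACCS"),
                         rep(c("A", "ESIPT"), 15)),
               "non-finite")
})

test_that("predict refuses mismatched feature manifests", {
  model <- toy_rf_model()
  fm <- random_fm(5, 6, seed = 30)
  colnames(fm) <- paste0("other", 1:6)
  expect_error(predict(model, fm), "manifest")
  reordered <- unclass(random_fm(5, 6, seed = 30))[, c(2, 1, 3:6)]
  expect_error(predict(model, feature_matrix(reordered, "MACCS")), "manifest")
})

test_that("model artifacts round-trip with manifest enforcement", {
  model <- toy_rf_model()
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  fm <- random_fm(10, 6, seed = 44)
  expect_identical(predict(model, fm), predict(back, fm))
  saveRDS(list(not = "a model"), path)
  expect_error(load_model(path), "not a recognised")
})

test_that("RFE recovers planted informative features and is monotone", {
  hits <- sapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 120
    X <- matrix(rnorm(n * 25), n, 25,
                dimnames = list(sprintf("s%03d", 1:n),
                                c(sprintf("inf%02d", 1:5), sprintf("nse%02d", 1:20))))
    y <- as.numeric(X[, 1:5] %*% c(2, -2, 1.5, 1.5, -1.5) + rnorm(n, 0, 0.5))
    cfg <- model_config("RF", "regress", list(ntree = 150), seed = s)
    sel5 <- rfe_select(cfg, feature_matrix(X, "DESC2D"), y, target_n = 5)
    sum(grepl("^inf", sel5))
  })
  expect_gte(mean(hits >= 4), 0.9)

  # monotone nesting of selections under one config
  set.seed(77)
  X <- matrix(rnorm(80 * 12), 80, 12,
              dimnames = list(sprintf("s%d", 1:80), sprintf("f%02d", 1:12)))
  y <- as.numeric(X[, 1] * 2 + rnorm(80, 0, 0.3))
  cfg <- model_config("RF", "regress", list(ntree = 100), seed = 4)
  s8 <- rfe_select(cfg, feature_matrix(X, "DESC2D"), y, target_n = 8)
  s4 <- rfe_select(cfg, feature_matrix(X, "DESC2D"), y, target_n = 4)
  expect_true(all(s4 %in% s8))
  expect_true("f01" %in% s4)
  # identity and single-feature edge cases
  s12 <- rfe_select(cfg, feature_matrix(X, "DESC2D"), y, target_n = 12)
  expect_setequal(s12, colnames(X))
  s1 <- rfe_select(cfg, feature_matrix(X, "DESC2D"), y, target_n = 1)
  expect_equal(as.character(s1), "f01")
  expect_error(rfe_select(model_config("SVM", "regress"),
                          feature_matrix(X, "DESC2D"), y),
               "unsupported")
})

test_that("ECOD flags the extreme point and matches the brute-force oracle", {
  x <- matrix(c(rep(0, 49), 100), ncol = 1,
              dimnames = list(sprintf("p%02d", 1:50), "v"))
  res <- ecod_outliers(x, contamination = 0.1)
  expect_equal(names(which.max(res$scores)), "p50")
  expect_true("p50" %in% res$outlier_ids)

  set.seed(8)
  X <- matrix(rnorm(90), 30, 3,
              dimnames = list(sprintf("s%02d", 1:30), c("a", "b", "c")))
  res2 <- ecod_outliers(X, contamination = 0.2)
  expect_equal(unname(res2$scores), oracle_ecod(X))
  expect_error(ecod_outliers(X, contamination = 0.6), "contamination")
})

test_that("ECOD recovers planted 8-sigma outliers", {
  found <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(95 * 3), 95, 3)
    planted <- matrix(rnorm(5 * 3, mean = 8), 5, 3)
    all_x <- rbind(X, planted)
    rownames(all_x) <- c(sprintf("n%02d", 1:95), sprintf("o%d", 1:5))
    res <- ecod_outliers(all_x, contamination = 0.05)
    all(sprintf("o%d", 1:5) %in% res$outlier_ids)
  })
  expect_gte(sum(found), 9)
})
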