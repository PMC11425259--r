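test_that("tree attribution equals exact coalition-enumeration Shapley", {
  model <- toy_rf_model(n = 100, p = 6, seed = 21, ntree = 25)
  fm_all <- random_fm(100, 6, seed = 21)
  bg <- feature_matrix(unclass(fm_all)[1:15, , drop = FALSE], "MACCS")
  Xe <- feature_matrix(unclass(fm_all)[16:21, , drop = FALSE], "MACCS")
  att <- shapley_attribution(model, Xe, bg, method = "tree")
  pf <- function(M) {
    colnames(M) <- model$feature_names
    rownames(M) <- sprintf("h%d", seq_len(nrow(M)))
    unname(predict(model, feature_matrix(M, "MACCS")))
  }
  for (i in seq_len(nrow(Xe))) {
    exact <- oracle_shapley(pf, unclass(Xe)[i, ], unclass(bg), 6)
    expect_equal(unname(att$per_sample[i, ]), exact, tolerance = 1e-6)
  }
})

test_that("additivity holds on every sample and ignored features get zero", {
  # signal only on f001/f002; with enough data the forest never splits
  # on a constant column
  n <- 150
  fm <- random_fm(n, 5, seed = 31)
  m <- unclass(fm)
  m[, 5] <- 0  # constant -> cannot be split on
  fm <- feature_matrix(m, "MACCS")
  y <- ifelse(m[, 1] == 1, "ESIPT", "OTHER")
  model <- fit_model(model_config("RF", "classify", list(ntree = 30), seed = 2),
                     fm, y)$model
  bg <- feature_matrix(m[1:40, ], "MACCS")
  Xe <- feature_matrix(m[41:90, ], "MACCS")
  att <- shapley_attribution(model, Xe, bg, method = "tree")
  pred <- unname(predict(model, Xe))
  expect_equal(unname(att$base_value + rowSums(att$per_sample)), pred,
               tolerance = 1e-6)
  expect_equal(unname(att$per_sample[, 5]), rep(0, nrow(Xe)))
})

test_that("sampling estimator agrees with the tree-exact values approximately", {
  model <- toy_rf_model(n = 80, p = 4, seed = 51, ntree = 20)
  fm_all <- random_fm(80, 4, seed = 51)
  bg <- feature_matrix(unclass(fm_all)[1:10, ], "MACCS")
  Xe <- feature_matrix(unclass(fm_all)[11:13, ], "MACCS")
  exact <- shapley_attribution(model, Xe, bg, method = "tree")
  approx <- shapley_attribution(model, Xe, bg, method = "sampling",
                                nsim = 400, seed = 9)
  expect_lt(max(abs(exact$per_sample - approx$per_sample)), 0.1)
  # sampling additivity telescopes to the sampled background mean
  pred <- unname(predict(model, Xe))
  expect_equal(unname(approx$base_value + rowSums(approx$per_sample)), pred,
               tolerance = 0.1)
})

test_that("top_features ranks by mean |Shapley| with lexicographic ties", {
  rep_fake <- structure(list(
    per_sample = matrix(0, 1, 4),
    global_importance = c(zeta = 0.5, beta = 0.2, alpha = 0.2, delta = 0.9),
    feature_names = c("zeta", "beta", "alpha", "delta")),
    class = "attribution_report")
  expect_equal(top_features(rep_fake, 4), c("delta", "zeta", "alpha", "beta"))
  expect_error(top_features(rep_fake, 9), "k <= ")
})

test_that("overlap_features intersects top-k lists", {
  mk <- function(g) structure(list(global_importance = g,
                                   feature_names = names(g)),
                              class = "attribution_report")
  a <- mk(c(f1 = 3, f2 = 2, f3 = 1, f4 = 0.5))
  b <- mk(c(f1 = 0.1, f2 = 5, f3 = 4, f4 = 3))
  ov <- overlap_features(a, b, k = 2)
  expect_equal(ov$shared, "f2")
  expect_equal(unname(ov$counts["shared"]), 1)
  identical_ov <- overlap_features(a, a, k = 3)
  expect_length(identical_ov$shared, 3)
  disjoint <- overlap_features(mk(c(f1 = 2, f2 = 1, f3 = 0, f4 = 0)),
                               mk(c(f1 = 0, f2 = 0, f3 = 1, f4 = 2)), k = 2)
  expect_length(disjoint$shared, 0)
})

test_that("force_breakdown is ordered, annotated, and additive", {
  model <- toy_rf_model(n = 100, p = 6, seed = 61, ntree = 30)
  fm_all <- random_fm(100, 6, seed = 61)
  bg <- feature_matrix(unclass(fm_all)[1:20, ], "MACCS")
  x1 <- feature_matrix(unclass(fm_all)[25, , drop = FALSE], "MACCS")
  fb <- force_breakdown(model, x1, bg, method = "tree")
  expect_equal(nrow(fb), 6)
  expect_true(all(diff(abs(fb$contribution)) <= 1e-12))
  expect_equal(fb$present, fb$value != 0)
  expect_equal(attr(fb, "base_value") + sum(fb$contribution),
               attr(fb, "prediction"), tolerance = 1e-6)
})

test_that("MACCS keys map to their published substructure definitions", {
  hydroxy <- bit_to_substructure("MACCS139")
  expect_false(hydroxy$composite)
  # the hydroxy SMARTS must match phenol's O-H
  ms <- molecule_set("phenol", "Oc1ccccc1")
  sdf <- esiptscreen:::ms_to_sdf(ms)
  hits <- ChemmineR::smartsSearchOB(sdf, hydroxy$smarts, uniqueMatches = TRUE)
  expect_gte(as.numeric(hits), 1)

  amine <- bit_to_substructure(151)
  ms2 <- molecule_set("aniline", "Nc1ccccc1")
  hits2 <- ChemmineR::smartsSearchOB(esiptscreen:::ms_to_sdf(ms2),
                                     amine$smarts, uniqueMatches = TRUE)
  expect_gte(as.numeric(hits2), 1)

  expect_error(bit_to_substructure(0), "1..166")
  expect_error(bit_to_substructure(167), "1..166")
})

test_that("every MACCS key 1-166 yields a usable SMARTS or a composite flag", {
  probe <- esiptscreen:::ms_to_sdf(
    molecule_set("probe", "Oc1ccccc1-c1nc2ccccc2s1"))
  for (k in 1:166) {
    info <- bit_to_substructure(k)
    if (is.na(info$smarts)) {
      expect_true(info$composite, info = paste("key", k))
    } else {
      parses <- tryCatch({
        ChemmineR::smartsSearchOB(probe, info$smarts, uniqueMatches = TRUE)
        TRUE
      }, error = function(e) FALSE)
      expect_true(parses, info = paste("key", k, info$smarts))
    }
  }
})

test_that("substructure rules carry sign-consistent directions", {
  model <- toy_rf_model(n = 120, p = 6, seed = 71, ntree = 40)
  fm_all <- random_fm(120, 6, seed = 71)
  # rename features to MACCS-style names
  m <- unclass(fm_all)
  colnames(m) <- sprintf("MACCS%d", c(139, 151, 97, 144, 53, 90))
  fmM <- feature_matrix(m, "MACCS")
  model2 <- fit_model(model_config("RF", "classify", list(ntree = 40), seed = 71),
                      fmM, ifelse(m[, 1] == 1, "ESIPT", "OTHER"))$model
  att <- shapley_attribution(model2, fmM, fmM, method = "tree",
                             max_background = 50)
  rules <- substructure_rules(att, k = 6)
  expect_equal(nrow(rules), 6)
  expect_equal(rules$direction, ifelse(rules$evidence >= 0,
                                       "promotes", "suppresses"))
})
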