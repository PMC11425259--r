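test_that("prefilter applies closed MW/logP windows from computed properties", {
  ms <- molecule_set(c("benzene", "glucose", "hbt"),
                     c("c1ccccc1", "OCC1OC(O)C(O)C(O)C1O",
                       "Oc1ccccc1-c1nc2ccccc2s1"))
  kept <- prefilter(ms, cascade_config())
  expect_true("benzene" %in% kept$id)          # MW 78, logP ~ 1.7
  expect_false("glucose" %in% kept$id)         # logP < 1
  expect_false("hbt" %in% kept$id)             # MW 227 > 200
  log <- attr(kept, "rejection_log")
  expect_setequal(log$id, c("glucose", "hbt"))
  expect_equal(log$reason[log$id == "hbt"], "mw")

  # boundary: a window whose endpoints equal the computed values retains
  props <- esiptscreen:::molecule_properties(ms)
  cfg <- cascade_config(mw_range = c(props$MW[1], props$MW[1]),
                        logp_range = c(props$logP[1], props$logP[1]))
  expect_true("benzene" %in% prefilter(ms, cfg)$id)
})

test_that("vacuous thresholds pass everything and impossible thresholds nothing", {
  fx <- cascade_fixture()
  cfg0 <- cascade_config(mw_range = fx$config$mw_range,
                         logp_range = fx$config$logp_range,
                         p_threshold_ecm = 0, p_threshold_efl = 0)
  res0 <- run_cascade(fx$lib, fx$ecm, fx$efl, NULL, cfg0)
  pre <- prefilter(fx$lib, cfg0)
  expect_setequal(res0$id[res0$survived], pre$id)

  cfg1 <- cascade_config(mw_range = fx$config$mw_range,
                         logp_range = fx$config$logp_range,
                         p_threshold_ecm = 1, p_threshold_efl = 1)
  res1 <- run_cascade(fx$lib, fx$ecm_svm, fx$efl_svm, NULL, cfg1)
  expect_equal(sum(res1$survived), 0)
  expect_error(cascade_config(p_threshold_ecm = 1.01), "p_threshold")
})

test_that("survivor counts are monotone in both thresholds and traces partition", {
  fx <- cascade_fixture()
  thresholds <- c(0, 0.5, 0.8, 0.9, 0.95, 1.0)
  counts <- sapply(thresholds, function(t) {
    cfg <- cascade_config(mw_range = fx$config$mw_range,
                          logp_range = fx$config$logp_range,
                          p_threshold_ecm = t, p_threshold_efl = t)
    res <- run_cascade(fx$lib, fx$ecm, fx$efl, NULL, cfg)
    # every molecule appears exactly once; stages partition the input
    expect_setequal(res$id, fx$lib$id)
    expect_equal(nrow(res), nrow(fx$lib))
    expect_equal(sum(table(res$stage_of_rejection)), nrow(fx$lib))
    expect_equal(sum(res$stage_of_rejection == "none"), sum(res$survived))
    sum(res$survived)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("the cascade recovers planted positives with high precision", {
  fx <- cascade_fixture()
  cfg <- cascade_config(mw_range = fx$config$mw_range,
                        logp_range = fx$config$logp_range,
                        p_threshold_ecm = 0.9, p_threshold_efl = 0.9)
  res <- run_cascade(fx$lib, fx$ecm, fx$efl, fx$ebar, cfg)
  surv <- res$id[res$survived]
  truth <- setNames(fx$lib$label, fx$lib$id)
  expect_gt(length(surv), 0)
  precision <- mean(truth[surv] == "ESIPT")
  expect_gte(precision, 0.8)
  # survivors carry barrier annotations with consistent feasibility
  ann <- res[res$survived, ]
  expect_true(all(is.finite(ann$predicted_barrier)))
  expect_equal(ann$feasibility,
               barrier_feasibility(ann$predicted_barrier, cfg$barrier_cutoff))
})

test_that("the pipeline is deterministic and robust to unparseable molecules", {
  fx <- cascade_fixture()
  lib2 <- rbind(as.data.frame(fx$lib)[1:20, ],
                data.frame(id = "broken", smiles = "xx$$yy", label = NA,
                           barrier = NA, source = NA))
  class(lib2) <- c("molecule_set", "data.frame")
  r1 <- suppressWarnings(run_cascade(lib2, fx$ecm, fx$efl, NULL, fx$config))
  r2 <- suppressWarnings(run_cascade(lib2, fx$ecm, fx$efl, NULL, fx$config))
  expect_identical(r1, r2)
  expect_equal(r1$stage_of_rejection[r1$id == "broken"], "featurization")
  expect_false(r1$survived[r1$id == "broken"])
})

test_that("relaxing the threshold grows the pool and dedup collapses clusters", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$lib, fx$ecm, fx$efl, NULL, fx$config)
  strict <- res$id[res$survived]
  relaxed_all <- res$id[res$passed_prefilter &
                          !is.na(res$p_ecm) & res$p_ecm >= 0.8 &
                          !is.na(res$p_efl) & res$p_efl >= 0.8]
  expect_true(all(strict %in% relaxed_all))

  # equal thresholds reproduce the strict survivor set before dedup
  same <- relax_and_diversify(fx$lib, res,
                              relaxed_threshold = fx$config$p_threshold_ecm,
                              dedup_similarity = 1)
  expect_setequal(same$id, strict)

  # clustered survivors collapse to one representative per cluster
  clus <- clustered_molecules()
  fake <- data.frame(id = clus$id, passed_prefilter = TRUE,
                     p_ecm = 0.99, p_efl = 0.99,
                     predicted_barrier = NA_real_,
                     feasibility = NA_character_, survived = TRUE,
                     stage_of_rejection = "none", stringsAsFactors = FALSE)
  div <- relax_and_diversify(clus, fake, relaxed_threshold = 0.9,
                             dedup_similarity = 0.8, fingerprint = "MACCS")
  expect_equal(nrow(div), length(unique(attr(clus, "cluster"))))

  # all-identical survivors collapse to one
  same3 <- molecule_set(c("a", "b", "c"), rep("Oc1ccccc1", 3))
  fake3 <- fake[1:3, ]; fake3$id <- same3$id
  expect_equal(nrow(relax_and_diversify(same3, fake3, 0.5, 0.8)), 1)
})
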