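# Small trained cascade (E-CM, E-FL, E-Barrier) over synthetic data,
# built once per test run and reused across cascade tests.
cascade_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synthetic_spec(n_per_class = 120, seed = 42)
    pos <- gen_esipt_positives(spec)
    con <- gen_conventional_negatives(spec)
    flu <- gen_fluor_negatives(spec)

    train_pair <- function(a, b, seed) {
      ms <- molecule_set(c(a$id, b$id), c(a$smiles, b$smiles),
                         c(a$label, b$label))
      fp <- compute_ecfp4(ms)
      y <- setNames(ms$label, ms$id)[rownames(fp)]
      fit_model(model_config("RF", "classify", list(ntree = 80), seed = seed),
                fp, y)$model
    }
    ecm <- train_pair(pos, con, seed = 1)
    efl <- train_pair(pos, flu, seed = 2)

    # SVM versions give probabilities strictly inside (0, 1)
    train_svm <- function(a, b, seed) {
      ms <- molecule_set(c(a$id, b$id), c(a$smiles, b$smiles),
                         c(a$label, b$label))
      fp <- compute_ecfp4(ms)
      y <- setNames(ms$label, ms$id)[rownames(fp)]
      fit_model(model_config("SVM", "classify", seed = seed), fp, y)$model
    }
    ecm_svm <- train_svm(pos, con, seed = 3)
    efl_svm <- train_svm(pos, flu, seed = 4)

    posb <- gen_barriers(pos, spec)
    dm <- compute_descriptors_2d(posb)
    pruned <- prune_features(dm)$matrix
    yb <- setNames(posb$barrier, posb$id)[rownames(pruned)]
    ebar <- fit_model(model_config("RF", "regress", list(ntree = 120),
                                   seed = 5),
                      pruned, yb)$model

    # an unseen screening library with known planted truth
    lib_spec <- synthetic_spec(n_per_class = 80, seed = 77)
    lpos <- gen_esipt_positives(lib_spec)
    lcon <- gen_conventional_negatives(lib_spec)
    lflu <- gen_fluor_negatives(lib_spec)
    lib <- molecule_set(
      paste0("L", c(lpos$id, lcon$id, lflu$id)),
      c(lpos$smiles, lcon$smiles, lflu$smiles),
      c(lpos$label, lcon$label, lflu$label))

    cfg <- cascade_config(mw_range = c(50, 400), logp_range = c(-2, 8))
    cache <<- list(ecm = ecm, efl = efl, ecm_svm = ecm_svm, efl_svm = efl_svm,
                   ebar = ebar, lib = lib, config = cfg)
    cache
  }
})
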