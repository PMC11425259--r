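# Shared small fixtures built in code.

tiny_molecules <- function() {
  molecule_set(
    c("phenol", "hbt", "benzene", "ethanol", "water", "hexane", "toluene"),
    c("Oc1ccccc1", "Oc1ccccc1-c1nc2ccccc2s1", "c1ccccc1", "CCO", "O",
      "CCCCCC", "Cc1ccccc1"))
}

# A molecule set forming `k` similarity clusters: within a cluster,
# heavily decorated variants of one scaffold (high pairwise similarity);
# across clusters, unrelated scaffolds.
clustered_molecules <- function() {
  clusters <- list(
    c("Oc1ccccc1-c1nc2ccccc2s1", "Oc1ccc(C)cc1-c1nc2ccccc2s1",
      "Oc1ccc(F)cc1-c1nc2ccccc2s1"),
    c("CCCCCCCCCC", "CCCCCCCCCCC", "CCCCCCCCC"),
    c("O=c1ccc2ccccc2o1", "O=c1ccc2cc(C)ccc2o1", "O=c1ccc2cc(F)ccc2o1"),
    c("CN1C(=O)c2cccc3cccc(c23)C1=O", "CCN1C(=O)c2cccc3cccc(c23)C1=O"))
  smiles <- unlist(clusters)
  ms <- molecule_set(sprintf("c%02d", seq_along(smiles)), smiles)
  attr(ms, "cluster") <- rep(seq_along(clusters), lengths(clusters))
  ms
}

# Random binary feature matrix with ids.
random_fm <- function(n, p, seed = 1, kind = "MACCS") {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  feature_matrix(m, kind)
}

# A small RF model over binary features with signal on the first two.
toy_rf_model <- function(n = 120, p = 6, seed = 11, ntree = 40) {
  fm <- random_fm(n, p, seed = seed)
  set.seed(seed + 1)
  y <- ifelse(unclass(fm)[, 1] + unclass(fm)[, 2] >= 1 + rbinom(n, 1, 0.2),
              "ESIPT", "OTHER")
  if (length(unique(y)) < 2) y[1:2] <- c("ESIPT", "OTHER")
  fit_model(model_config("RF", "classify", list(ntree = ntree), seed = seed),
            fm, y)$model
}
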