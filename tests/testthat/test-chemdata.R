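test_that("read_molecules reads CSV, skips unparseable SMILES, and errors usefully", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "m1,c1ccccc1", "m2,not_a_smiles"), csv)
  expect_warning(read_molecules(csv), "unparseable")
  ms <- suppressWarnings(read_molecules(csv))
  expect_equal(nrow(ms), 1)
  expect_equal(ms$id, "m1")
  expect_equal(attr(ms, "skipped"), 1)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("name,structure", "m1,CCO"), bad)
  expect_error(read_molecules(bad), "columns 'id' and 'smiles'")

  none <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "m1,xxx"), none)
  expect_error(suppressWarnings(read_molecules(none)), "no parseable")
})

test_that("read_molecules handles .smi and SDF dialects", {
  smi <- tempfile(fileext = ".smi")
  writeLines("Oc1ccccc1C(=O)N m3", smi)
  ms <- read_molecules(smi)
  expect_equal(ms$id, "m3")
  expect_equal(ms$smiles, "Oc1ccccc1C(=O)N")

  # build an SDF with 3 valid molblocks via the package's own writer path
  src <- molecule_set(c("a", "b", "c"), c("CCO", "c1ccccc1", "CC(=O)O"))
  sdf_path <- tempfile(fileext = ".sdf")
  sdf <- esiptscreen:::ms_to_sdf(src)
  ChemmineR::write.SDF(sdf, sdf_path)
  back <- read_molecules(sdf_path)
  expect_equal(nrow(back), 3)
})

test_that("CSV round-trips preserve records including labels and barriers", {
  ms <- molecule_set(c("x1", "x2"), c("CCO", "c1ccccc1"),
                     label = c("ESIPT", "CONVENTIONAL"), barrier = c(3.2, NA))
  path <- tempfile(fileext = ".csv")
  write_molecules(ms, path)
  back <- read_molecules(path)
  expect_equal(back$id, ms$id)
  expect_equal(back$smiles, ms$smiles)
  expect_equal(back$label, ms$label)
  expect_equal(back$barrier, ms$barrier)
})

test_that("molecule_set validates ids, labels, and barriers", {
  expect_error(molecule_set(c("a", "a"), c("C", "CC")), "unique")
  expect_error(molecule_set("a", "C", label = "WHAT"), "unknown label")
  expect_error(molecule_set("a", "C", barrier = -1), "positive")
})

test_that("canonical_dedup merges SMILES spellings and is idempotent", {
  ms <- molecule_set(paste0("m", 1:3), c("OCC", "C(O)C", "CCO"))
  dd <- canonical_dedup(ms)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$id, "m1")  # first occurrence kept

  ms2 <- molecule_set(c("a", "b"), c("CCO", "CCN"))
  expect_equal(nrow(canonical_dedup(ms2)), 2)

  dd2 <- canonical_dedup(dd)
  expect_equal(as.data.frame(dd2), as.data.frame(dd))
})

test_that("canonical_dedup collapses permuted duplicates to the unique set", {
  # 60 distinct alkane/alcohol-like molecules written two ways each:
  # 40 of the 100 records are spelling permutations of the other 60
  base <- c(sprintf("C%sO", strrep("C", 1:20)),       # alcohols C2..C21
            sprintf("CC(C)%s", strrep("C", 1:20)),    # branched alkanes
            sprintf("O=C(O)%s", strrep("C", 1:20)))   # acids
  permuted <- c(sprintf("OC%s", strrep("C", 1:20)),   # same alcohols, reversed
                sprintf("%sC(C)C", strrep("C", 1:20)))
  ms <- molecule_set(sprintf("d%03d", 1:100), c(base, permuted))
  dd <- canonical_dedup(ms)
  expect_equal(nrow(dd), 60)
  # oracle: the set of canonical strings
  expect_equal(sort(dd$smiles), sort(unique(canonical_smiles(c(base, permuted)))))
})

test_that("salt stripping keeps the largest covalent fragment", {
  ms <- molecule_set("salt", "CC(=O)O.[Na+]")
  expect_equal(canonical_dedup(ms)$smiles, canonical_smiles("CC(=O)O"))
})

test_that("similarity_filter honors threshold semantics and partitions candidates", {
  refs <- molecule_set(c("r1", "r2"), c("Oc1ccccc1-c1nc2ccccc2s1", "CCCCCC"))
  cands <- molecule_set(
    c("dup", "far", "mid"),
    c("Oc1ccccc1-c1nc2ccccc2s1",        # identical to r1
      "ClP(Cl)Cl",                      # shares essentially nothing
      "Oc1ccc(C)cc1-c1nc2ccccc2s1"))    # decorated r1
  below <- similarity_filter(cands, refs, "MACCS", 0.95, "keep_below")
  expect_false("dup" %in% below$id)     # self-similarity 1 is excluded
  expect_true("far" %in% below$id)      # Tanimoto ~0 is retained
  above <- similarity_filter(cands, refs, "MACCS", 0.95, "keep_above")
  expect_setequal(c(below$id, above$id), cands$id)
  expect_length(intersect(below$id, above$id), 0)
  expect_error(similarity_filter(cands, refs, "MACCS", 1.2), "\\[0, 1\\]")
})

test_that("similarity_filter agrees with exhaustive pairwise Tanimoto", {
  ms <- clustered_molecules()
  cands <- esiptscreen:::ms_subset(ms, 1:8)
  refs <- esiptscreen:::ms_subset(ms, 9:11)
  fpc <- unclass(compute_maccs(cands))
  fpr <- unclass(compute_maccs(refs))
  maxsim <- sapply(seq_len(nrow(fpc)), function(i) {
    max(sapply(seq_len(nrow(fpr)), function(j) oracle_tanimoto(fpc[i, ], fpr[j, ])))
  })
  for (thr in c(0.2, 0.5, 0.8)) {
    got <- similarity_filter(cands, refs, "MACCS", thr, "keep_below")
    expect_setequal(got$id, cands$id[maxsim < thr])
  }
})

test_that("internal dedup retains one representative per similarity cluster", {
  ms <- clustered_molecules()
  truth <- attr(ms, "cluster")
  kept <- internal_dedup_by_similarity(ms, "MACCS", threshold = 0.8)
  expect_equal(nrow(kept), length(unique(truth)))
  # first-kept-wins: the first member of each cluster is the survivor
  first_of_cluster <- ms$id[!duplicated(truth)]
  expect_equal(kept$id, first_of_cluster)
  # no retained pair exceeds the threshold (exhaustive scan)
  fp <- unclass(compute_maccs(kept))
  for (i in seq_len(nrow(fp) - 1)) for (j in (i + 1):nrow(fp)) {
    expect_lte(oracle_tanimoto(fp[i, ], fp[j, ]), 0.8)
  }
})

test_that("internal dedup handles identical molecules and empty sets", {
  same <- molecule_set(c("a", "b", "c"), rep("Oc1ccccc1", 3))
  expect_equal(nrow(internal_dedup_by_similarity(same, "MACCS", 0.8)), 1)
  empty <- molecule_set(character(0), character(0))
  expect_equal(nrow(internal_dedup_by_similarity(empty, "MACCS", 0.8)), 0)
})
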