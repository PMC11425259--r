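#' Shapley-value feature attribution
#'
#' Attributes each model prediction to its features relative to a
#' background expectation. Random-forest models get exact interventional
#' tree Shapley values: for every background row the coalition game
#' \eqn{v(S) = f(x_S, b_{\setminus S})} is solved in closed form per
#' tree leaf, then averaged over trees and background rows. Other
#' algorithms use a seeded permutation-sampling estimator. In both
#' cases additivity holds: `base_value + rowSums(per_sample)` equals the
#' model prediction for every explained sample (exactly for trees, in
#' expectation-per-permutation for sampling, where it telescopes to the
#' sampled background mean).
#'
#' @param model a `trained_model`.
#' @param X `feature_matrix` of samples to explain (manifest must match
#'   the model).
#' @param background `feature_matrix` of background rows; at most
#'   `max_background` rows are used (seeded subsample).
#' @param method `"auto"` (tree path for RF, sampling otherwise),
#'   `"tree"`, or `"sampling"`.
#' @param nsim permutations per sample for the sampling estimator.
#' @param max_background background rows retained (default 200).
#' @param seed RNG seed for subsampling/permutations.
#' @return an `attribution_report`: `per_sample` (n x p Shapley matrix),
#'   `base_value`, `global_importance` (mean absolute Shapley value per
#'   feature), `prediction` (model output per sample), `feature_names`.
#' @export
shapley_attribution <- function(model, X, background,
                                method = c("auto", "tree", "sampling"),
                                nsim = 100, max_background = 200, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "trained_model"))
  Xm <- as_plain_matrix(X)
  Bm <- as_plain_matrix(background)
  if (!identical(colnames(Xm), model$feature_names) ||
      !identical(colnames(Bm), model$feature_names)) {
    stop("feature manifest mismatch between model, X, and background")
  }
  if (nrow(Bm) > max_background) {
    keep <- with_seed(seed, sample(nrow(Bm), max_background))
    Bm <- Bm[keep, , drop = FALSE]
  }
  if (method == "auto") {
    method <- if (model$config$algorithm == "RF") "tree" else "sampling"
  }
  if (method == "tree") {
    if (model$config$algorithm != "RF") {
      stop("exact tree attribution is implemented for RF models; ",
           "use method = 'sampling'")
    }
    trees <- rf_tree_tables(model)
    res <- .forest_shap_cpp(trees, Xm, Bm)
    phi <- res$phi
    base <- res$base
  } else {
    res <- sampling_shap(model, Xm, Bm, nsim = nsim, seed = seed)
    phi <- res$phi
    base <- res$base
  }
  dimnames(phi) <- dimnames(Xm)
  pred <- predict(model, X)
  structure(list(per_sample = phi, base_value = base,
                 global_importance = colMeans(abs(phi)),
                 prediction = pred, feature_names = colnames(Xm),
                 feature_values = Xm, method = method),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report %s> %d sample(s) x %d feature(s), base %.4f\n",
              x$method, nrow(x$per_sample), ncol(x$per_sample), x$base_value))
  top <- head(top_features(x, min(5, length(x$feature_names))), 5)
  cat("top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

# Convert a fitted randomForest into flat tree tables for the C++ walker:
# columns [left, right, var, split, value]; classification leaf values are
# 1/0 votes for the positive class so that the ensemble mean is the
# predicted probability.
rf_tree_tables <- function(model) {
  rf <- model$fit
  stopifnot(inherits(rf, "randomForest"))
  classify <- model$config$task == "classify"
  pos_idx <- if (classify) match(model$positive, colnames(rf$votes)) else NA
  lapply(seq_len(rf$ntree), function(k) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    value <- if (classify) as.numeric(tr[, "prediction"] == pos_idx)
             else tr[, "prediction"]
    value[tr[, "status"] != -1] <- 0
    var <- ifelse(tr[, "status"] == -1, 0, tr[, "split var"])
    cbind(left = tr[, "left daughter"], right = tr[, "right daughter"],
          var = var, split = tr[, "split point"], value = value)
  })
}

# Seeded permutation-sampling Shapley estimator (for non-tree models).
sampling_shap <- function(model, Xm, Bm, nsim = 100, seed = 1L) {
  p <- ncol(Xm)
  phi <- matrix(0, nrow(Xm), p)
  bases <- numeric(nrow(Xm))
  with_seed(seed, {
    for (i in seq_len(nrow(Xm))) {
      x <- Xm[i, ]
      acc <- numeric(p)
      bsum <- 0
      for (s in seq_len(nsim)) {
        b <- Bm[sample(nrow(Bm), 1), ]
        perm <- sample(p)
        # hybrid rows: z_0 = b, z_k adds the k-th permuted feature from x
        Z <- matrix(rep(b, p + 1), nrow = p + 1, byrow = TRUE)
        for (k in seq_len(p)) {
          Z[(k + 1):(p + 1), perm[k]] <- x[perm[k]]
        }
        colnames(Z) <- colnames(Xm)
        rownames(Z) <- sprintf("z%d", 0:p)
        f <- unname(predict(model, Z))
        acc[perm] <- acc[perm] + diff(f)
        bsum <- bsum + f[1]
      }
      phi[i, ] <- acc / nsim
      bases[i] <- bsum / nsim
    }
  })
  list(phi = phi, base = mean(bases))
}

#' Top features by global Shapley importance
#'
#' Ranks features by mean absolute Shapley value, descending; exact ties
#' broken lexicographically by feature name.
#'
#' @param report an `attribution_report`.
#' @param k how many features (default 20).
#' @return character vector of feature names.
#' @export
top_features <- function(report, k = 20) {
  g <- report$global_importance
  stopifnot(k <= length(g))
  ord <- order(-g, names(g))
  names(g)[ord][seq_len(k)]
}

#' Overlap of two models' top-k feature lists
#'
#' @param report_a,report_b `attribution_report`s over the same feature
#'   space.
#' @param k list length compared (default 20).
#' @return list with `shared`, `only_a`, `only_b`, and `counts`
#'   (a Venn-style named vector).
#' @export
overlap_features <- function(report_a, report_b, k = 20) {
  if (!setequal(report_a$feature_names, report_b$feature_names)) {
    stop("reports cover different feature spaces")
  }
  ta <- top_features(report_a, k)
  tb <- top_features(report_b, k)
  shared <- intersect(ta, tb)
  list(shared = shared,
       only_a = setdiff(ta, tb),
       only_b = setdiff(tb, ta),
       counts = c(shared = length(shared),
                  only_a = k - length(shared),
                  only_b = k - length(shared)))
}

#' Per-molecule force-style Shapley breakdown
#'
#' Explains a single prediction: each feature's signed contribution,
#' annotated with whether the feature (e.g. a fingerprint bit) is
#' present in the molecule, ordered by absolute contribution. The
#' contributions plus the base value sum to the model output.
#'
#' @param model a `trained_model`.
#' @param x single-row `feature_matrix` (or one-row matrix).
#' @param background background `feature_matrix`.
#' @param ... passed to [shapley_attribution()].
#' @return data frame `feature`, `value`, `present`, `contribution`,
#'   with attributes `base_value` and `prediction`.
#' @export
force_breakdown <- function(model, x, background, ...) {
  Xm <- as_plain_matrix(x)
  if (nrow(Xm) != 1) stop("force_breakdown explains exactly one sample")
  att <- shapley_attribution(model, x, background, ...)
  contrib <- att$per_sample[1, ]
  ord <- order(-abs(contrib), names(contrib))
  out <- data.frame(feature = colnames(Xm)[ord],
                    value = unname(Xm[1, ord]),
                    present = unname(Xm[1, ord] != 0),
                    contribution = unname(contrib[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "base_value") <- att$base_value
  attr(out, "prediction") <- unname(att$prediction[1])
  out
}

# ---- MACCS key definitions -------------------------------------------------

.esipt_env <- new.env(parent = emptyenv())

maccs_key_table <- function() {
  if (!is.null(.esipt_env$maccs)) return(.esipt_env$maccs)
  path <- file.path(ob_data_dir(), "MACCS.txt")
  lines <- readLines(path, warn = FALSE)
  m <- regmatches(lines,
                  regexec("^\\s*(\\d+):\\('(.*)',(\\d+)\\),?\\s*(#\\s*(.*))?$", lines))
  rows <- Filter(function(x) length(x) > 0, m)
  tab <- data.frame(
    key = vapply(rows, function(r) as.integer(r[2]), 0L),
    smarts = vapply(rows, `[`, "", 3),
    min_count = vapply(rows, function(r) as.integer(r[4]) + 1L, 0L),
    description = trimws(vapply(rows, `[`, "", 6)),
    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$key) & tab$key >= 1 & tab$key <= 166, ]
  tab <- tab[order(tab$key), ]
  .esipt_env$maccs <- tab
  tab
}

#' Map a MACCS key to its substructure definition
#'
#' Returns the published SMARTS definition behind a MACCS fingerprint
#' bit, for turning Shapley-ranked bits into structural rules (e.g. key
#' 139 is the hydroxy O-H pattern, key 151 the N-H pattern). Keys whose
#' definition requires a minimum match count (> 1) or has no SMARTS
#' (key 1, isotope) are flagged as composite.
#'
#' @param feature a MACCS key index 1-166, or a feature name like
#'   `"MACCS139"`.
#' @return list with `feature`, `key`, `smarts` (`NA` for undefined),
#'   `min_count`, `composite`, `description`.
#' @export
bit_to_substructure <- function(feature) {
  key <- if (is.character(feature)) {
    as.integer(sub("^MACCS", "", feature))
  } else as.integer(feature)
  if (is.na(key) || key < 1 || key > 166) {
    stop("MACCS key index must be in 1..166")
  }
  tab <- maccs_key_table()
  row <- tab[tab$key == key, ]
  if (nrow(row) == 0) stop("no definition found for MACCS key ", key)
  smarts <- row$smarts
  undefined <- smarts %in% c("?", "")
  list(feature = paste0("MACCS", key), key = key,
       smarts = if (undefined) NA_character_ else smarts,
       min_count = row$min_count,
       composite = undefined || row$min_count > 1,
       description = row$description)
}

#' Substructure rules from a MACCS attribution report
#'
#' Combines the top-k globally important MACCS bits with their SMARTS
#' definitions and the sign of their Shapley evidence. Evidence is the
#' mean Shapley value over molecules in which the fragment is present
#' (its contribution when "MACCS = 1"); a positive value marks a
#' substructure whose presence promotes the positive-class prediction,
#' a negative one a suppressing fragment. Features never present fall
#' back to the overall mean.
#'
#' @param report an `attribution_report` over MACCS features.
#' @param k number of top features to convert (default 20).
#' @return data frame `feature`, `smarts`, `direction`, `evidence`,
#'   `composite`, `description`.
#' @export
substructure_rules <- function(report, k = 20) {
  feats <- top_features(report, k)
  evidence <- vapply(feats, function(f) {
    present <- report$feature_values[, f] != 0
    if (any(present)) mean(report$per_sample[present, f])
    else mean(report$per_sample[, f])
  }, 0)
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[i]
    info <- if (grepl("^MACCS[0-9]+$", f)) bit_to_substructure(f) else {
      list(smarts = NA_character_, composite = NA, description = "")
    }
    data.frame(feature = f, smarts = info$smarts,
               direction = if (evidence[i] >= 0) "promotes" else "suppresses",
               evidence = unname(evidence[i]),
               composite = info$composite,
               description = info$description,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
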