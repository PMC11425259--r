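#' Model configuration
#'
#' Describes one learner of the screening system. Algorithms: random
#' forest (`"RF"`), support vector machine with RBF kernel (`"SVM"`),
#' gradient-boosted trees (`"GBT"`), k-nearest neighbours (`"KNN"`),
#' decision tree (`"DT"`), and a single-hidden-layer neural network
#' (`"MLP"`). Hyperparameters not given fall back to documented
#' defaults (`RF` 500 trees; `GBT` 300 rounds of depth 6, eta 0.1;
#' `SVM` RBF with probability output; `KNN` k = 5; `MLP` 8 hidden
#' units). All fits are reproducible under `seed`.
#'
#' @param algorithm one of `"RF"`, `"SVM"`, `"GBT"`, `"KNN"`, `"DT"`,
#'   `"MLP"`.
#' @param task `"classify"` or `"regress"`.
#' @param hyperparameters named list of overrides.
#' @param seed integer RNG seed used for the fit.
#' @return a `model_config`.
#' @export
model_config <- function(algorithm = c("RF", "SVM", "GBT", "KNN", "DT", "MLP"),
                         task = c("classify", "regress"),
                         hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  defaults <- switch(algorithm,
    RF  = list(ntree = 500, mtry = NULL),
    SVM = list(kernel = "radial", cost = 1, gamma = NULL),
    GBT = list(nrounds = 300, max_depth = 6, eta = 0.1),
    KNN = list(k = 5),
    DT  = list(cp = 0.01, minsplit = 20),
    MLP = list(size = 8, decay = 1e-4, maxit = 200))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, task = task, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train/test split with stratified cross-validation folds
#'
#' Randomly holds out `test_fraction` of the ids (75/25 by default) and
#' partitions the remaining training ids into `k` cross-validation
#' folds. With labels, both the test set and every fold are stratified:
#' class proportions are preserved to within one sample (largest
#' remainder allocation for the test set, per-class round robin for the
#' folds). Deterministic under `seed`.
#'
#' @param ids character vector of sample ids.
#' @param labels optional class labels for stratification.
#' @param test_fraction held-out fraction (default 0.25).
#' @param k number of CV folds (default 5).
#' @param seed RNG seed.
#' @return a `split_plan` with `train_ids`, `test_ids`, `cv_folds`
#'   (list of `list(train, val)`), and `seed`.
#' @export
make_split <- function(ids, labels = NULL, test_fraction = 0.25, k = 5,
                       seed = 1L) {
  ids <- as.character(ids)
  stopifnot(length(ids) >= 2 * k, !anyDuplicated(ids),
            test_fraction > 0, test_fraction < 1)
  if (is.null(labels)) labels <- rep("all", length(ids))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(ids))
  tab <- table(labels)
  if (any(tab < k)) {
    stop("stratification error: class(es) with fewer than k = ", k,
         " members: ", paste(names(tab)[tab < k], collapse = ", "))
  }
  classes <- sort(names(tab))
  n <- length(ids)
  n_test <- round(n * test_fraction)
  quota <- n_test * as.numeric(tab[classes]) / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  names(base) <- classes
  test_ids <- character(0)
  train_seq <- character(0)
  with_seed(seed, {
    for (cl in classes) {
      members <- sample(ids[labels == cl])
      nt <- base[[cl]]
      test_ids <- c(test_ids, members[seq_len(nt)])
      train_seq <- c(train_seq, members[-seq_len(nt)])
    }
  })
  # one round-robin over the class-blocked sequence: fold sizes balance
  # globally to within one sample, and each class stays balanced across
  # folds to within one sample as well
  fold_assign <- setNames((seq_along(train_seq) - 1L) %% k + 1L, train_seq)
  train_ids <- ids[!ids %in% test_ids]
  fold_assign <- fold_assign[train_ids]  # restore input order
  cv_folds <- lapply(seq_len(k), function(f) {
    list(train = train_ids[fold_assign != f], val = train_ids[fold_assign == f])
  })
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' Fit a model and evaluate it by cross-validation and held-out test
#'
#' Runs k-fold cross-validation over `plan$cv_folds`, refits on the full
#' training partition, and evaluates on the test partition. Metrics come
#' from [classification_metrics()] / [regression_metrics()]; the CV
#' block is the across-fold mean.
#'
#' @param config a [model_config()].
#' @param X a `feature_matrix` (rows must cover the plan's ids).
#' @param y labels (factor/character for classification) or numeric
#'   response, aligned with `rownames(X)`.
#' @param plan a [make_split()] plan; `NULL` fits on all rows of `X`
#'   without evaluation.
#' @param positive positive-class label; defaults to `"ESIPT"` when
#'   present, else the alphabetically last label.
#' @param featurizer optional featurizer descriptor recorded on the
#'   model so that screening pipelines can re-derive its inputs from raw
#'   molecules: a list with `kind` (`"ECFP4"`, `"MACCS"`, `"DESC2D"`)
#'   and, for ECFP4, `n_bits`. Defaults to the `kind` attribute of `X`
#'   when present.
#' @return a list with `model` (a `trained_model`) and `report` (an
#'   `eval_report` with `cv`, `cv_folds`, `test`).
#' @export
fit_model <- function(config, X, y, plan = NULL, positive = NULL,
                      featurizer = NULL) {
  if (is.null(featurizer) && !is.null(attr(X, "kind"))) {
    featurizer <- list(kind = attr(X, "kind"),
                       n_bits = if (attr(X, "kind") == "ECFP4") ncol(X) else NULL)
  }
  stopifnot(inherits(config, "model_config"))
  Xm <- as_plain_matrix(X)
  if (!all(is.finite(Xm))) stop("non-finite feature values in X")
  if (is.null(rownames(Xm))) stop("X must carry molecule ids as rownames")
  y <- setNames(y, rownames(Xm))
  if (config$task == "classify") {
    y <- as.character(y)
    if (length(unique(y)) < 2) stop("degenerate single-class training labels")
    if (is.null(positive)) {
      positive <- if ("ESIPT" %in% y) "ESIPT" else sort(unique(y))[length(unique(y))]
    }
    y <- setNames(y, rownames(Xm))
  }
  if (is.null(plan)) {
    fit <- algo_fit(config, Xm, y, positive)
    model <- new_trained_model(config, colnames(Xm), fit, positive, featurizer)
    return(list(model = model, report = NULL))
  }
  need <- unique(c(plan$train_ids, plan$test_ids))
  if (!all(need %in% rownames(Xm))) stop("X rows do not cover the split plan ids")

  fold_reports <- lapply(plan$cv_folds, function(f) {
    fit <- algo_fit(config, Xm[f$train, , drop = FALSE], y[f$train], positive)
    sc <- algo_predict(fit, config, Xm[f$val, , drop = FALSE], positive)
    if (config$task == "classify") {
      classification_metrics(y[f$val] == positive, sc)
    } else {
      regression_metrics(y[f$val], sc, ids = f$val)
    }
  })
  cv <- summarize_folds(fold_reports, config$task)

  fit <- algo_fit(config, Xm[plan$train_ids, , drop = FALSE], y[plan$train_ids],
                  positive)
  sc_test <- algo_predict(fit, config, Xm[plan$test_ids, , drop = FALSE], positive)
  test <- if (config$task == "classify") {
    classification_metrics(y[plan$test_ids] == positive, sc_test)
  } else {
    regression_metrics(y[plan$test_ids], sc_test, ids = plan$test_ids)
  }
  model <- new_trained_model(config, colnames(Xm), fit, positive, featurizer)
  report <- structure(list(cv = cv, cv_folds = fold_reports, test = test),
                      class = "eval_report")
  list(model = model, report = report)
}

new_trained_model <- function(config, feature_names, fit, positive,
                              featurizer = NULL) {
  structure(list(config = config, feature_names = feature_names, fit = fit,
                 positive = positive, featurizer = featurizer,
                 version = "esiptscreen-model-1"),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s/%s> %d feature(s)%s\n",
              x$config$algorithm, x$config$task, length(x$feature_names),
              if (!is.null(x$featurizer)) paste0(", featurizer ", x$featurizer$kind) else ""))
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("cross-validation (fold mean):\n  "); print(x$cv)
  cat("test:\n  "); print(x$test)
  invisible(x)
}

summarize_folds <- function(reports, task) {
  if (task == "classify") {
    out <- list(ACC = mean(vapply(reports, `[[`, 0, "ACC")),
                SP = mean(vapply(reports, `[[`, 0, "SP")),
                SE = mean(vapply(reports, `[[`, 0, "SE")),
                F1 = mean(vapply(reports, `[[`, 0, "F1")),
                AUC = mean(vapply(reports, `[[`, 0, "AUC")),
                auc_defined = all(vapply(reports, `[[`, TRUE, "auc_defined")),
                confusion = list(
                  TP = sum(vapply(reports, function(r) r$confusion$TP, 0)),
                  TN = sum(vapply(reports, function(r) r$confusion$TN, 0)),
                  FP = sum(vapply(reports, function(r) r$confusion$FP, 0)),
                  FN = sum(vapply(reports, function(r) r$confusion$FN, 0))))
    class(out) <- "classification_report"
  } else {
    rates <- rowMeans(vapply(reports, function(r) r$fold_rates,
                             reports[[1]]$fold_rates))
    out <- list(R2 = mean(vapply(reports, `[[`, 0, "R2")),
                MAE = mean(vapply(reports, `[[`, 0, "MAE")),
                RMSE = mean(vapply(reports, `[[`, 0, "RMSE")),
                pearson_correlation = mean(vapply(reports, `[[`, 0, "pearson_correlation")),
                folds = NULL, fold_rates = rates)
    class(out) <- "regression_report"
  }
  out
}

as_plain_matrix <- function(X) {
  m <- unclass(X)
  attr(m, "kind") <- NULL
  as.matrix(m)
}

# ---- algorithm dispatch ----------------------------------------------------

algo_fit <- function(config, X, y, positive) {
  hp <- config$hyperparameters
  classify <- config$task == "classify"
  if (classify) {
    yf <- factor(y, levels = c(setdiff(sort(unique(y)), positive), positive))
    if (nlevels(yf) < 2 || any(table(yf) == 0)) {
      stop("degenerate single-class training labels")
    }
  }
  with_seed(config$seed, switch(config$algorithm,
    RF = {
      if (classify) {
        randomForest::randomForest(x = X, y = yf, ntree = hp$ntree,
          mtry = hp$mtry %||% floor(sqrt(ncol(X))))
      } else {
        randomForest::randomForest(x = X, y = as.numeric(y), ntree = hp$ntree,
          mtry = hp$mtry %||% max(floor(ncol(X) / 3), 1))
      }
    },
    SVM = {
      scale_cols <- apply(X, 2, var) > 0  # skip constant (e.g. unused bit) columns
      if (classify) {
        e1071::svm(x = X, y = yf, kernel = hp$kernel, cost = hp$cost,
                   gamma = hp$gamma %||% 1 / ncol(X), probability = TRUE,
                   scale = scale_cols)
      } else {
        e1071::svm(x = X, y = as.numeric(y), kernel = hp$kernel,
                   cost = hp$cost, gamma = hp$gamma %||% 1 / ncol(X),
                   scale = scale_cols)
      }
    },
    GBT = {
      dtrain <- xgboost::xgb.DMatrix(X,
        label = if (classify) as.numeric(yf == positive) else as.numeric(y))
      params <- list(
        objective = if (classify) "binary:logistic" else "reg:squarederror",
        max_depth = hp$max_depth, eta = hp$eta, nthread = 1,
        seed = config$seed)
      xgboost::xgb.train(params = params, data = dtrain, nrounds = hp$nrounds,
                         verbose = 0)
    },
    KNN = e1071::gknn(x = X, y = if (classify) yf else as.numeric(y), k = hp$k),
    DT = {
      df <- data.frame(.y = if (classify) yf else as.numeric(y), X,
                       check.names = FALSE)
      rpart::rpart(.y ~ ., data = df,
                   method = if (classify) "class" else "anova",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit))
    },
    MLP = {
      if (classify) {
        nnet::nnet(x = X, y = nnet::class.ind(yf), size = hp$size,
                   decay = hp$decay, maxit = hp$maxit, softmax = TRUE,
                   MaxNWts = 1e6, trace = FALSE)
      } else {
        nnet::nnet(x = X, y = as.numeric(y), size = hp$size, decay = hp$decay,
                   maxit = hp$maxit, linout = TRUE, MaxNWts = 1e6,
                   trace = FALSE)
      }
    }))
}

algo_predict <- function(fit, config, X, positive) {
  classify <- config$task == "classify"
  out <- switch(config$algorithm,
    RF = if (classify) predict(fit, X, type = "prob")[, positive]
         else predict(fit, X),
    SVM = if (classify) {
      p <- predict(fit, X, probability = TRUE)
      attr(p, "probabilities")[, positive]
    } else predict(fit, X),
    GBT = predict(fit, xgboost::xgb.DMatrix(X)),
    KNN = if (classify) {
      v <- predict(fit, X, type = "votes")
      (v / rowSums(v))[, positive]
    } else predict(fit, X),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      if (classify) predict(fit, df, type = "prob")[, positive]
      else predict(fit, df)
    },
    MLP = if (classify) predict(fit, X)[, positive] else as.numeric(predict(fit, X)))
  unname(out)
}

#' Predict scores or values from a trained model
#'
#' Refuses matrices whose feature names do not match the model's feature
#' manifest exactly (names and order).
#'
#' @param object a `trained_model`.
#' @param newdata a `feature_matrix` or plain matrix.
#' @param ... unused.
#' @return numeric vector: positive-class probability (classification)
#'   or predicted value (regression), named by row.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  Xm <- as_plain_matrix(newdata)
  if (!identical(colnames(Xm), object$feature_names)) {
    stop("feature manifest mismatch: newdata columns must equal the ",
         "model's feature_names (same names, same order)")
  }
  sc <- algo_predict(object$fit, object$config, Xm, object$positive)
  setNames(sc, rownames(Xm))
}

#' Save / load a trained model artifact
#'
#' The artifact embeds a format version and the feature-name manifest;
#' [predict.trained_model()] refuses matrices that do not match it.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `load_model` returns the `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model") || !identical(m$version, "esiptscreen-model-1")) {
    stop("not a recognised esiptscreen model artifact")
  }
  m
}

# ---- recursive feature elimination -----------------------------------------

#' Recursive feature elimination under an importance-based learner
#'
#' Iteratively refits the configured learner and drops the `step`
#' least-important features until `target_n` remain. Supported
#' algorithms: `"RF"` (Gini / node-purity importance) and `"GBT"` (gain).
#' Deterministic under the config seed. The attribute
#' `elimination_order` lists dropped features in elimination order, so
#' the selected set at a larger `target_n` is always a superset of the
#' set at a smaller one under the same config.
#'
#' @param config a [model_config()] with an importance-exposing algorithm.
#' @param X a `feature_matrix`.
#' @param y response aligned with rows of `X`.
#' @param target_n number of features to keep (default 25).
#' @param step features dropped per iteration (default 1).
#' @param positive positive label for classification.
#' @return character vector of selected feature names (in original
#'   column order) with attribute `elimination_order`.
#' @export
rfe_select <- function(config, X, y, target_n = 25, step = 1, positive = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!config$algorithm %in% c("RF", "GBT")) {
    stop("unsupported algorithm for RFE (no feature importances): ",
         config$algorithm)
  }
  Xm <- as_plain_matrix(X)
  if (ncol(Xm) < target_n) stop("X has fewer than target_n features")
  if (config$task == "classify" && is.null(positive)) {
    positive <- if ("ESIPT" %in% y) "ESIPT" else sort(unique(as.character(y)))[length(unique(y))]
  }
  current <- colnames(Xm)
  eliminated <- character(0)
  while (length(current) > target_n) {
    fit <- algo_fit(config, Xm[, current, drop = FALSE], y, positive)
    imp <- feature_importance(fit, config, current)
    drop_n <- min(step, length(current) - target_n)
    # drop lowest-importance features; ties broken by later column order
    ord <- order(imp, -match(names(imp), current), decreasing = FALSE)
    victims <- names(imp)[ord][seq_len(drop_n)]
    eliminated <- c(eliminated, victims)
    current <- setdiff(current, victims)
  }
  structure(current, elimination_order = eliminated)
}

feature_importance <- function(fit, config, feature_names) {
  if (config$algorithm == "RF") {
    im <- randomForest::importance(fit)
    setNames(im[, 1], rownames(im))[feature_names]
  } else {
    tab <- xgboost::xgb.importance(model = fit)
    imp <- setNames(rep(0, length(feature_names)), feature_names)
    imp[tab$Feature] <- tab$Gain
    imp
  }
}

# ---- ECOD outlier detection ------------------------------------------------

#' ECOD unsupervised outlier scores
#'
#' Empirical-cumulative-distribution outlier detection: for every
#' dimension the left and right empirical tail probabilities of each
#' value are turned into negative log scores and summed across
#' dimensions; each dimension also contributes a skewness-corrected
#' score (left tail when the sample skewness is negative, right tail
#' otherwise). A sample's outlier score is the maximum of the three
#' aggregates, and the top `contamination` fraction by score is flagged.
#'
#' @param X numeric matrix (n >= 10 rows).
#' @param contamination expected outlier fraction, in `(0, 0.5]`.
#' @return list with `inlier_ids`, `outlier_ids`, and named `scores`.
#' @export
ecod_outliers <- function(X, contamination = 0.15) {
  Xm <- as_plain_matrix(X)
  n <- nrow(Xm)
  stopifnot(n >= 10)
  if (contamination <= 0 || contamination > 0.5) {
    stop("contamination must be in (0, 0.5]")
  }
  ids <- rownames(Xm) %||% as.character(seq_len(n))
  Ul <- Ur <- Us <- matrix(0, n, ncol(Xm))
  for (j in seq_len(ncol(Xm))) {
    x <- Xm[, j]
    r_left <- vapply(x, function(v) sum(x <= v), 0) / n
    r_right <- vapply(x, function(v) sum(x >= v), 0) / n
    ul <- -log(r_left); ur <- -log(r_right)
    m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
    skew <- if (m2 > 0) m3 / m2^1.5 else 0
    Ul[, j] <- ul; Ur[, j] <- ur
    Us[, j] <- if (skew < 0) ul else ur
  }
  score <- pmax(rowSums(Ul), rowSums(Ur), rowSums(Us))
  names(score) <- ids
  n_out <- floor(contamination * n)
  ord <- order(-score, seq_len(n))
  out_idx <- if (n_out > 0) ord[seq_len(n_out)] else integer(0)
  list(inlier_ids = ids[sort(setdiff(seq_len(n), out_idx))],
       outlier_ids = ids[out_idx],
       scores = score)
}
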