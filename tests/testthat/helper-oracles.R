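# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with the package.

# Confusion-table classification metrics by direct counting.
oracle_classification <- function(y, s, thr = 0.5) {
  pred <- ifelse(s >= thr, 1, 0)
  TP <- 0; TN <- 0; FP <- 0; FN <- 0
  for (i in seq_along(y)) {
    if (pred[i] == 1 && y[i] == 1) TP <- TP + 1
    if (pred[i] == 0 && y[i] == 0) TN <- TN + 1
    if (pred[i] == 1 && y[i] == 0) FP <- FP + 1
    if (pred[i] == 0 && y[i] == 1) FN <- FN + 1
  }
  # all-pairs AUC with half-credit ties
  pos <- s[y == 1]; neg <- s[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  list(ACC = (TP + TN) / length(y),
       SP = TN / (TN + FP), SE = TP / (TP + FN),
       F1 = 2 * TP / (2 * TP + FP + FN),
       AUC = wins / (length(pos) * length(neg)),
       TP = TP, TN = TN, FP = FP, FN = FN)
}

# Formula-by-formula regression metrics.
oracle_regression <- function(y, yh, ks = c(2, 3)) {
  n <- length(y)
  ss_res <- sum((y - yh)^2); ss_tot <- sum((y - mean(y))^2)
  folds <- numeric(n)
  for (i in seq_len(n)) folds[i] <- 1 + abs(yh[i] - y[i]) / y[i]
  rates <- sapply(ks, function(k) sum(folds < k) / n)
  list(R2 = 1 - ss_res / ss_tot, MAE = sum(abs(y - yh)) / n,
       RMSE = sqrt(ss_res / n), r = cor(y, yh),
       folds = folds, rates = rates)
}

# Brute-force ECOD scores: per-dimension ECDF tails, three aggregates.
oracle_ecod <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Ol <- Or <- Os <- numeric(n)
  for (j in seq_len(p)) {
    x <- X[, j]
    skew <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
    for (i in seq_len(n)) {
      pl <- sum(x <= x[i]) / n
      pr <- sum(x >= x[i]) / n
      Ol[i] <- Ol[i] - log(pl)
      Or[i] <- Or[i] - log(pr)
      Os[i] <- Os[i] - log(if (skew < 0) pl else pr)
    }
  }
  pmax(Ol, Or, Os)
}

# Exact Shapley values by full coalition enumeration, with the
# interventional value function v(S) = mean_b f(x_S, b_~S).
oracle_shapley <- function(predict_fn, x, B, p) {
  subsets <- lapply(0:(2^p - 1), function(k) which(bitwAnd(k, 2^(0:(p - 1))) > 0))
  key <- vapply(subsets, function(S) paste(S, collapse = ","), "")
  vS <- vapply(subsets, function(S) {
    H <- B
    if (length(S)) H[, S] <- matrix(rep(x[S], each = nrow(B)), nrow(B))
    mean(predict_fn(H))
  }, 0)
  names(vS) <- key
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (k in seq_along(subsets)) {
      S <- subsets[[k]]
      if (j %in% S) next
      w <- fact[length(S) + 1] * fact[p - length(S)] / fact[p + 1]
      phi[j] <- phi[j] + w * (vS[[paste(sort(c(S, j)), collapse = ",")]] - vS[[k]])
    }
  }
  phi
}

# Tanimoto similarity of two 0/1 vectors by set counting.
oracle_tanimoto <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}
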