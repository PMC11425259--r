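#' @importFrom stats cor predict quantile rbinom rnorm runif sd var aggregate setNames
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tanimoto similarity between two sets of binary fingerprints
#'
#' Computes the full pairwise Tanimoto (Jaccard) similarity matrix
#' \eqn{|A \cap B| / |A \cup B|} between the rows of two 0/1 fingerprint
#' matrices. Pairs where both fingerprints are empty are assigned
#' similarity 0.
#'
#' @param A,B numeric 0/1 matrices with one fingerprint per row. `B`
#'   defaults to `A`.
#' @return a `nrow(A) x nrow(B)` matrix of similarities in `[0, 1]`.
#' @export
tanimoto_matrix <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  inter <- A %*% t(B)
  a <- rowSums(A)
  b <- rowSums(B)
  union <- outer(a, b, "+") - inter
  sim <- ifelse(union > 0, inter / union, 0)
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}

# Locate Open Babel's data directory (for the MACCS key SMARTS table).
ob_data_dir <- function() {
  env <- Sys.getenv("BABEL_DATADIR", unset = "")
  if (nzchar(env) && dir.exists(env)) return(env)
  ob <- Sys.which("obabel")
  if (nzchar(ob)) {
    root <- file.path(dirname(dirname(ob)), "share", "openbabel")
    if (dir.exists(root)) {
      vers <- list.dirs(root, recursive = FALSE)
      for (v in vers) if (file.exists(file.path(v, "MACCS.txt"))) return(v)
      if (file.exists(file.path(root, "MACCS.txt"))) return(root)
    }
  }
  stop("cannot locate the Open Babel data directory (MACCS.txt); ",
       "set BABEL_DATADIR if Open Babel is installed in a non-standard place")
}
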