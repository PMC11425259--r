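#' Feature matrices
#'
#' A `feature_matrix` is a numeric matrix with molecule ids as row names,
#' feature names as column names, and a `kind` attribute
#' (`"MACCS"`, `"ECFP4"`, or `"DESC2D"`). Fingerprint matrices contain
#' only 0/1 values.
#'
#' @param values numeric matrix.
#' @param kind one of `"MACCS"`, `"ECFP4"`, `"DESC2D"`.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  structure(values, kind = kind, class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s> %d molecule(s) x %d feature(s)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

# Subset that preserves class/kind.
fm_subset <- function(fm, i = NULL, j = NULL) {
  kind <- attr(fm, "kind")
  m <- unclass(fm)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  feature_matrix(m, kind)
}

#' MACCS structural key fingerprints
#'
#' Computes the 166-bit MACCS keyed fingerprint for every molecule, with
#' standard key numbering (columns `MACCS1` ... `MACCS166`), so that key
#' indices map to their published substructure definitions (e.g. key 139
#' = hydroxy, key 151 = N-H; see [bit_to_substructure()]).
#'
#' @param ms a `molecule_set`.
#' @return a 0/1 `feature_matrix` of kind `"MACCS"`.
#' @export
compute_maccs <- function(ms) {
  keep <- validate_smiles_rows(ms)
  rows <- ChemmineOB::forEachMol(
    "SMILES", paste(ms$smiles[keep], collapse = "\n"),
    function(mol) ChemmineOB::fingerprint_OB(list(mol), "MACCS"))
  m <- do.call(rbind, rows)[, 1:166, drop = FALSE]
  if (nrow(m) != sum(keep)) stop("internal: fingerprint row mismatch")
  storage.mode(m) <- "double"
  rownames(m) <- ms$id[keep]
  colnames(m) <- paste0("MACCS", 1:166)
  feature_matrix(m, "MACCS")
}

#' ECFP4 circular fingerprints
#'
#' Extended-connectivity fingerprint of radius 2 (diameter 4), folded to
#' `n_bits` by OR-ing congruent positions of the 4096-bit raw
#' fingerprint. `n_bits` must divide 4096.
#'
#' @param ms a `molecule_set`.
#' @param n_bits folded length (default 2048).
#' @return a 0/1 `feature_matrix` of kind `"ECFP4"`.
#' @export
compute_ecfp4 <- function(ms, n_bits = 2048) {
  stopifnot(n_bits >= 1, 4096 %% n_bits == 0)
  keep <- validate_smiles_rows(ms)
  raw <- ob_ecfp4_raw(ms$smiles[keep], ms$id[keep])
  folds <- ncol(raw) / n_bits
  m <- raw[, 1:n_bits, drop = FALSE]
  if (folds > 1) {
    for (k in seq_len(folds - 1)) {
      m <- pmax(m, raw[, k * n_bits + 1:n_bits, drop = FALSE])
    }
  }
  colnames(m) <- sprintf("ECFP4_%04d", seq_len(n_bits))
  feature_matrix(m, "ECFP4")
}

# Raw 4096-bit ECFP4 fingerprints through the obabel command-line FPS
# writer (far faster than per-molecule binding calls). FPS hex encodes
# the bit vector bytewise, least-significant bit first within each byte.
ob_ecfp4_raw <- function(smiles, ids) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) stop("obabel executable not found on PATH")
  key <- sprintf("t%06d", seq_along(smiles))
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".fps")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste(smiles, key), fin)
  system2(obabel, c("-ismi", fin, "-ofps", "-xfECFP4", "-O", fout, "-e"),
          stdout = FALSE, stderr = FALSE)
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  titles <- vapply(parts, function(p) p[length(p)], "")
  hexes <- vapply(parts, `[`, "", 1)
  hit <- match(titles, key)
  ok <- !is.na(hit)
  m <- matrix(0, length(smiles), 4096,
              dimnames = list(ids, NULL))
  for (r in which(ok)) {
    bytes <- strtoi(substring(hexes[r], seq(1, 1023, 2), seq(2, 1024, 2)), 16L)
    bits <- matrix(as.integer(intToBits(bytes)), nrow = 32)[1:8, ]
    m[hit[r], ] <- as.double(bits)
  }
  m
}

# Rows of a molecule_set whose SMILES parse; warns about the rest.
validate_smiles_rows <- function(ms) {
  stopifnot(nrow(ms) > 0)
  can <- ob_convert_smiles(ms$smiles, "CAN")
  keep <- !is.na(can)
  if (!any(keep)) stop("no parseable molecules")
  if (any(!keep)) {
    warning(sum(!keep), " molecule(s) failed to parse and were dropped")
  }
  keep
}

#' 2D physicochemical and topological descriptor panel
#'
#' Computes a fixed panel of >150 2D descriptors per molecule:
#' bulk properties from Open Babel (molecular weight, logP, TPSA, molar
#' refractivity, H-bond donor/acceptor counts), an ESOL-style estimated
#' logS, Gasteiger partial-charge summaries, graph statistics (ring
#' count, aromatic proportion, rotatable bonds, heteroatom fractions),
#' and substructure counts for a curated SMARTS panel spanning H-bond
#' donors/acceptors, acidity and basicity proxies, conjugation, oxygen
#' content, and charge. A molecule on which a descriptor fails gets `NA`
#' in that cell and is listed in the `flagged` attribute.
#'
#' @param ms a `molecule_set`.
#' @return a `feature_matrix` of kind `"DESC2D"`.
#' @export
compute_descriptors_2d <- function(ms) {
  keep <- validate_smiles_rows(ms)
  ids <- ms$id[keep]
  n <- length(ids)

  # one OBMol per molecule; bulk properties, graph counts, and the whole
  # SMARTS panel computed on it in a single pass
  graph_pats <- c(heavy_atoms = "[*]", n_bonds = "*~*")
  row_list <- ChemmineOB::forEachMol(
    "SMILES", paste(ms$smiles[keep], collapse = "\n"),
    function(mol) {
      prop <- tryCatch(ChemmineOB::prop_OB(list(mol)),
                       error = function(e) NULL)
      base <- if (is.null(prop)) rep(NA_real_, 8) else
        c(prop$MW, prop$logP, prop$TPSA, prop$MR, prop$HBD, prop$HBA1,
          prop$HBA2, prop$nF)
      counts <- vapply(c(graph_pats, smarts_panel), function(p) {
        tryCatch(as.numeric(ChemmineOB::smartsSearch_OB(list(mol), p,
                                                        uniqueMatches = TRUE)),
                 error = function(e) NA_real_)
      }, 0)
      c(base, counts)
    })
  m <- do.call(rbind, row_list)
  if (nrow(m) != n) stop("internal: descriptor row mismatch")
  dimnames(m) <- list(ids, c("MW", "logP", "TPSA", "MR", "HBD", "HBA1",
                             "HBA2", "nF", names(graph_pats),
                             paste0("n_", names(smarts_panel))))
  # cyclomatic ring count (connected-molecule convention; salts are
  # stripped upstream)
  m <- cbind(m, n_rings = pmax(0, m[, "n_bonds"] - m[, "heavy_atoms"] + 1))

  # derived descriptors
  m <- cbind(m,
    frac_sp3 = ifelse(m[, "n_atom_C"] > 0, m[, "n_C_sp3"] / m[, "n_atom_C"], 0),
    frac_aromatic = ifelse(m[, "heavy_atoms"] > 0, m[, "n_arom_any"] / m[, "heavy_atoms"], 0),
    frac_hetero = ifelse(m[, "heavy_atoms"] > 0, m[, "n_heteroatom"] / m[, "heavy_atoms"], 0),
    net_charge = m[, "n_pos_charge"] - m[, "n_neg_charge"],
    mw_per_ring = m[, "MW"] / (1 + m[, "n_rings"]),
    logS_esol = 0.16 - 0.63 * m[, "logP"] - 0.0062 * m[, "MW"] +
      0.066 * m[, "n_rotatable"] -
      0.74 * ifelse(m[, "heavy_atoms"] > 0, m[, "n_arom_any"] / m[, "heavy_atoms"], 0))

  chg <- gasteiger_summaries(ms, ids)
  m <- cbind(m, chg)
  rownames(m) <- ids

  flagged <- ids[apply(m, 1, anyNA)]
  fm <- feature_matrix(m, "DESC2D")
  attr(fm, "flagged") <- flagged
  fm
}

# Gasteiger partial-charge summaries via Open Babel's MOL2 writer (which
# assigns Gasteiger charges to heavy atoms).
gasteiger_summaries <- function(ms, ids) {
  cols <- c("q_min", "q_max", "q_mean_abs", "q_sum_pos", "q_sum_neg",
            "q_min_O", "q_min_N")
  out <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  key <- sprintf("t%06d", seq_len(nrow(ms)))
  input <- paste0(paste(ms$smiles, key, collapse = "\n"), "\n")
  opts <- data.frame(names = "e", args = "", stringsAsFactors = FALSE)
  mol2 <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", input, options = opts)),
    error = function(e) "")
  if (!nzchar(mol2)) return(out)
  blocks <- strsplit(mol2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  for (b in blocks) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    title <- trimws(lines[1])
    row <- match(ms$id[match(title, key)], ids)
    if (is.na(row)) next
    a0 <- which(lines == "@<TRIPOS>ATOM")
    if (length(a0) != 1) next
    a1 <- grep("^@<TRIPOS>", lines)
    a1 <- a1[a1 > a0]
    end <- if (length(a1)) min(a1) - 1 else length(lines)
    if (end <= a0) next
    fields <- strsplit(trimws(lines[(a0 + 1):end]), "[ \t]+")
    q <- suppressWarnings(vapply(fields, function(f) as.numeric(f[9]), 0))
    el <- vapply(fields, function(f) sub("\\..*$", "", f[6]), "")
    if (anyNA(q)) next
    out[row, ] <- c(min(q), max(q), mean(abs(q)),
                    sum(q[q > 0]), sum(q[q < 0]),
                    if (any(el == "O")) min(q[el == "O"]) else 0,
                    if (any(el == "N")) min(q[el == "N"]) else 0)
  }
  out
}

#' Prune zero-variance and highly correlated features
#'
#' Two-step pruning used before descriptor-based modelling:
#' (1) drop features with variance `<= variance_eps`; (2) walk the
#' surviving features in column order and drop any feature whose absolute
#' Pearson correlation with an earlier kept feature exceeds `corr_cut`
#' (the earlier-ordered feature is kept; a single pass over the upper
#' triangle). Constant-after-step-1 pairs with undefined correlation are
#' treated as uncorrelated.
#'
#' @param fm a `feature_matrix` with at least 2 rows.
#' @param variance_eps variance threshold (default 0: drop exactly
#'   constant features).
#' @param corr_cut absolute-correlation threshold (default 0.95).
#' @return a list with elements `matrix` (pruned `feature_matrix`) and
#'   `report` (a `pruning_report` with `dropped_zero_variance` and
#'   `dropped_correlated`).
#' @export
prune_features <- function(fm, variance_eps = 0, corr_cut = 0.95) {
  stopifnot(nrow(fm) >= 2)
  m <- unclass(fm)
  v <- apply(m, 2, var)
  v[is.na(v)] <- 0
  zero_var <- colnames(m)[v <= variance_eps]
  m2 <- m[, v > variance_eps, drop = FALSE]
  dropped_cor <- data.frame(dropped = character(0), kept = character(0),
                            correlation = numeric(0), stringsAsFactors = FALSE)
  if (ncol(m2) >= 2) {
    cm <- suppressWarnings(abs(cor(m2)))
    cm[is.na(cm)] <- 0
    keep <- rep(TRUE, ncol(m2))
    for (j in 2:ncol(m2)) {
      earlier <- which(keep[seq_len(j - 1)])
      if (!length(earlier)) next
      hits <- earlier[cm[earlier, j] > corr_cut]
      if (length(hits)) {
        keep[j] <- FALSE
        dropped_cor <- rbind(dropped_cor, data.frame(
          dropped = colnames(m2)[j], kept = colnames(m2)[hits[1]],
          correlation = cm[hits[1], j], stringsAsFactors = FALSE))
      }
    }
    m2 <- m2[, keep, drop = FALSE]
  }
  report <- structure(list(dropped_zero_variance = zero_var,
                           dropped_correlated = dropped_cor),
                      class = "pruning_report")
  list(matrix = feature_matrix(m2, attr(fm, "kind")), report = report)
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf("<pruning_report> %d zero-variance, %d correlated feature(s) dropped\n",
              length(x$dropped_zero_variance), nrow(x$dropped_correlated)))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' First column `id`, remaining columns the features, header row carries
#' feature names.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm), unclass(fm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param kind the feature kind to stamp on the result.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, kind = "DESC2D") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  feature_matrix(m, kind)
}
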