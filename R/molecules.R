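#' Molecule sets
#'
#' A `molecule_set` is a data frame with one row per molecule and columns
#' `id`, `smiles`, `label`, `barrier`, `source`. `label` is one of
#' `"ESIPT"`, `"CONVENTIONAL"`, `"FLUOR_NON_ESIPT"`, `"UNKNOWN"`;
#' `barrier` is an excited-state proton-transfer activation energy in
#' kcal/mol (`NA` when unknown, must be positive and finite otherwise).
#' Row order is meaningful: deduplication and greedy similarity filters
#' are defined in input order.
#'
#' @param id character vector of unique molecule identifiers.
#' @param smiles character vector of SMILES strings.
#' @param label optional class labels (recycled if length 1).
#' @param barrier optional positive barriers in kcal/mol.
#' @param source optional free-text provenance tags.
#' @param name a name for the set.
#' @return a `molecule_set` data frame.
#' @export
molecule_set <- function(id, smiles, label = NA_character_, barrier = NA_real_,
                         source = NA_character_, name = "molecules") {
  id <- as.character(id)
  smiles <- as.character(smiles)
  stopifnot(length(id) == length(smiles))
  if (anyDuplicated(id)) stop("molecule ids must be unique within a set")
  label <- rep_len(as.character(label), length(id))
  known <- c("ESIPT", "CONVENTIONAL", "FLUOR_NON_ESIPT", "UNKNOWN")
  bad <- !is.na(label) & !label %in% known
  if (any(bad)) stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "))
  barrier <- rep_len(as.numeric(barrier), length(id))
  if (any(!is.na(barrier) & (barrier <= 0 | !is.finite(barrier)))) {
    stop("barriers must be positive and finite (kcal/mol)")
  }
  ms <- data.frame(id = id, smiles = smiles, label = label, barrier = barrier,
                   source = rep_len(as.character(source), length(id)),
                   stringsAsFactors = FALSE)
  rownames(ms) <- NULL
  class(ms) <- c("molecule_set", "data.frame")
  attr(ms, "set_name") <- name
  ms
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set '%s'> %d molecule(s)\n",
              attr(x, "set_name") %||% "molecules", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

ms_subset <- function(ms, idx) {
  out <- as.data.frame(ms)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("molecule_set", "data.frame")
  attr(out, "set_name") <- attr(ms, "set_name")
  out
}

# Convert arbitrary SMILES through Open Babel, tolerating unparseable
# records. Returns a character vector aligned with `smiles`, NA where the
# SMILES could not be parsed. `format` is an Open Babel output format id.
ob_convert_smiles <- function(smiles, format = "CAN") {
  if (length(smiles) == 0) return(character(0))
  key <- sprintf("t%06d", seq_along(smiles))
  input <- paste0(paste(smiles, key, collapse = "\n"), "\n")
  opts <- data.frame(names = "e", args = "", stringsAsFactors = FALSE)
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", format, input, options = opts))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("[ \t]", lines), invert = TRUE)
  got <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, "")
  val <- vapply(parts, `[`, "", 1)
  res <- rep(NA_character_, length(smiles))
  hit <- match(got, key)
  ok <- !is.na(hit)
  res[hit[ok]] <- val[ok]
  res
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical isomeric SMILES. With
#' `strip_salts = TRUE`, multi-fragment inputs are reduced to their
#' largest covalent fragment (by heavy-atom count, ties to the first)
#' before canonicalization. Unparseable SMILES map to `NA`.
#'
#' @param smiles character vector of SMILES.
#' @param strip_salts keep only the largest covalent fragment.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles, strip_salts = TRUE) {
  can <- ob_convert_smiles(smiles, "CAN")
  if (strip_salts) {
    multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
    for (i in multi) {
      frags <- strsplit(can[i], ".", fixed = TRUE)[[1]]
      # heavy atoms ~ element tokens; count via a cheap SMILES scan
      heavy <- vapply(frags, count_heavy_atoms, 0L)
      best <- ob_convert_smiles(frags[which.max(heavy)], "CAN")
      can[i] <- best
    }
  }
  can
}

# Rough heavy-atom count from a SMILES string (sufficient for picking the
# largest fragment of a salt): counts element symbols outside H.
count_heavy_atoms <- function(smi) {
  # two-letter organic-subset + bracket atoms
  n <- 0L
  toks <- gregexpr("Cl|Br|\\[[^]]+\\]|B|C|N|O|P|S|F|I|b|c|n|o|p|s", smi)[[1]]
  if (toks[1] == -1) return(0L)
  m <- regmatches(smi, gregexpr("Cl|Br|\\[[^]]+\\]|B|C|N|O|P|S|F|I|b|c|n|o|p|s", smi))[[1]]
  for (t in m) {
    if (grepl("^\\[", t) && grepl("^\\[[0-9]*H[0-9+-]*\\]$", t)) next  # [H], [2H]
    n <- n + 1L
  }
  n
}

# Parse a molecule_set into a ChemmineR SDFset with cids = molecule ids.
# Molecules must already have valid SMILES (use read_molecules /
# canonical_smiles first); rows that still fail to parse are dropped with
# a warning.
ms_to_sdf <- function(ms) {
  stopifnot(nrow(ms) > 0)
  key <- sprintf("t%06d", seq_len(nrow(ms)))
  input <- setNames(ms$smiles, key)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(input))
  got <- ChemmineR::cid(sdf)
  hit <- match(got, key)
  if (anyNA(hit)) stop("internal: unexpected molecule ids from parser")
  if (length(hit) < nrow(ms)) {
    warning(nrow(ms) - length(hit), " molecule(s) failed to parse and were dropped")
  }
  sdf@ID <- ms$id[hit]
  attr(sdf, "ms_rows") <- hit
  sdf
}

#' Read molecules from CSV, SMILES, or SDF files
#'
#' CSV files must have columns `id,smiles` and may have `label` and
#' `barrier`. `.smi` files carry one `SMILES id` pair per line
#' (whitespace-separated; a missing id yields `mol<row>`). SDF files are
#' read with standard molblock parsing; ids come from the molblock title.
#' Rows whose SMILES (or molblock) cannot be parsed are skipped with a
#' warning and counted in the `skipped` attribute.
#'
#' @param path path to the input file.
#' @param format `"csv"`, `"smi"`, or `"sdf"`; default guesses from the
#'   file extension.
#' @param name set name; defaults to the file name.
#' @return a `molecule_set`; attribute `skipped` holds the number of
#'   unparseable records.
#' @export
read_molecules <- function(path, format = c("auto", "csv", "smi", "sdf"),
                           name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smi", sdf = "sdf", mol = "sdf",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("CSV must have columns 'id' and 'smiles'")
    }
    lab <- if ("label" %in% names(df)) df$label else NA_character_
    lab[!is.na(lab) & lab == ""] <- NA_character_
    bar <- if ("barrier" %in% names(df)) suppressWarnings(as.numeric(df$barrier)) else NA_real_
    ids <- as.character(df$id); smi <- df$smiles
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%d", i)
    }, "")
    lab <- NA_character_; bar <- NA_real_
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdf)
    n_bad <- sum(!valid)
    sdf <- sdf[valid]
    if (length(sdf) == 0) stop("no parseable molecules in ", path)
    smi_all <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | ids == ""] <- sprintf("mol%d", which(is.na(ids) | ids == ""))
    ids <- make.unique(ids)
    ms <- molecule_set(ids, smi_all, name = name)
    attr(ms, "skipped") <- n_bad
    if (n_bad > 0) warning(n_bad, " unparseable molblock(s) skipped")
    return(ms)
  }
  can <- ob_convert_smiles(smi, "CAN")
  keep <- !is.na(can)
  if (!any(keep)) stop("no parseable molecules in ", path)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with unparseable SMILES skipped: ",
            paste(head(ids[!keep], 5), collapse = ", "))
  }
  ms <- molecule_set(ids[keep], smi[keep],
                     label = if (length(lab) > 1) lab[keep] else lab,
                     barrier = if (length(bar) > 1) bar[keep] else bar,
                     name = name)
  attr(ms, "skipped") <- sum(!keep)
  ms
}

#' Write a molecule set to CSV or SMILES
#'
#' Mirrors [read_molecules()] so that write/read round-trips preserve
#' records exactly.
#'
#' @param ms a `molecule_set`.
#' @param path output path.
#' @param format `"csv"` or `"smi"`.
#' @export
write_molecules <- function(ms, path, format = c("csv", "smi")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(ms)[, c("id", "smiles", "label", "barrier")],
              path, row.names = FALSE, na = "")
  } else {
    writeLines(paste(ms$smiles, ms$id), path)
  }
  invisible(path)
}

#' Deduplicate a molecule set by canonical SMILES
#'
#' Canonicalizes all SMILES (stripping salts) and keeps the first
#' occurrence of each canonical structure; order is otherwise preserved.
#' The retained records' `smiles` are replaced by their canonical form.
#'
#' @param ms a `molecule_set`.
#' @param strip_salts passed to [canonical_smiles()].
#' @return the deduplicated `molecule_set`.
#' @export
canonical_dedup <- function(ms, strip_salts = TRUE) {
  if (nrow(ms) == 0) return(ms)
  can <- canonical_smiles(ms$smiles, strip_salts = strip_salts)
  if (anyNA(can)) {
    warning(sum(is.na(can)), " unparseable SMILES dropped during dedup")
  }
  keep <- !is.na(can) & !duplicated(can)
  out <- ms_subset(ms, keep)
  out$smiles <- can[keep]
  out
}

#' Filter candidates by fingerprint similarity to a reference set
#'
#' For each candidate, computes the maximum Tanimoto similarity to any
#' reference molecule on the chosen fingerprint. `keep_below` retains
#' candidates with maximum similarity strictly below `threshold`
#' (e.g. to exclude near-duplicates of known positives from a negative
#' set); `keep_above` retains the complement.
#'
#' @param candidates,references non-empty `molecule_set`s.
#' @param fingerprint `"MACCS"` or `"ECFP4"`.
#' @param threshold similarity threshold in `[0, 1]`.
#' @param mode `"keep_below"` or `"keep_above"`.
#' @return the retained `molecule_set`; attribute `max_similarity` gives
#'   each retained candidate's maximum similarity to the references.
#' @export
similarity_filter <- function(candidates, references,
                              fingerprint = c("MACCS", "ECFP4"),
                              threshold = 0.95,
                              mode = c("keep_below", "keep_above")) {
  fingerprint <- match.arg(fingerprint)
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (nrow(candidates) == 0 || nrow(references) == 0) {
    stop("both candidate and reference sets must be non-empty")
  }
  fpc <- fingerprints_of(candidates, fingerprint)
  fpr <- fingerprints_of(references, fingerprint)
  sim <- tanimoto_matrix(fpc, fpr)
  maxsim <- apply(sim, 1, max)
  keep <- if (mode == "keep_below") maxsim < threshold else maxsim >= threshold
  out <- ms_subset(candidates, keep)
  attr(out, "max_similarity") <- unname(maxsim[keep])
  out
}

#' Greedy internal deduplication by fingerprint similarity
#'
#' Single pass in input order: a molecule is retained iff its Tanimoto
#' similarity to every previously retained molecule is `<= threshold`.
#' The result is maximal under that rule, and no retained pair has
#' similarity above the threshold.
#'
#' @param ms a `molecule_set`.
#' @param fingerprint `"MACCS"` or `"ECFP4"`.
#' @param threshold similarity above which a later duplicate is dropped.
#' @return the retained `molecule_set`.
#' @export
internal_dedup_by_similarity <- function(ms, fingerprint = c("ECFP4", "MACCS"),
                                         threshold = 0.8) {
  fingerprint <- match.arg(fingerprint)
  if (nrow(ms) <= 1) return(ms)
  fp <- fingerprints_of(ms, fingerprint)
  sim <- tanimoto_matrix(fp)
  keep_idx <- integer(0)
  for (i in seq_len(nrow(ms))) {
    if (length(keep_idx) == 0 || all(sim[i, keep_idx] <= threshold)) {
      keep_idx <- c(keep_idx, i)
    }
  }
  ms_subset(ms, keep_idx)
}

# Fingerprint rows for a molecule_set (helper shared by the curation ops).
fingerprints_of <- function(ms, fingerprint) {
  switch(fingerprint,
         MACCS = compute_maccs(ms),
         ECFP4 = compute_ecfp4(ms),
         stop("unknown fingerprint: ", fingerprint))
}
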