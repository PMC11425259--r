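#' Strategy rule tables
#'
#' The three candidate-scoring strategies aggregate categorical ADMET
#' ratings into a score: each property contributes `+1 * weight` for an
#' `"Excellent"` rating, `+0.5 * weight` for `"Medium"`, and `0` for
#' `"Poor"`. The safety strategy covers LD50, AMES mutagenicity, skin
#' sensitization, hERG inhibition, and DILI; the pharmacokinetic
#' strategy covers VDss, fraction unbound (Fu), clearance (CL),
#' half-life (T1/2), and plasma-protein binding (PPB). The innovation
#' strategy is structural (see [innovation_rank()]) and carries no
#' default property list.
#'
#' @param strategy `"safety"`, `"pharmacokinetic"`, or `"innovation"`.
#' @param properties property names; defaults per strategy.
#' @param weights per-property weights (default 1), recycled.
#' @return a `strategy_rules` object.
#' @export
strategy_rules <- function(strategy = c("safety", "pharmacokinetic", "innovation"),
                           properties = NULL, weights = 1) {
  strategy <- match.arg(strategy)
  if (is.null(properties)) {
    properties <- switch(strategy,
      safety = c("LD50", "AMES", "SkinSensitization", "hERG", "DILI"),
      pharmacokinetic = c("VDss", "Fu", "CL", "T1/2", "PPB"),
      innovation = character(0))
  }
  weights <- rep_len(weights, length(properties))
  structure(list(strategy = strategy, properties = properties,
                 weights = setNames(weights, properties),
                 rating_points = c(Excellent = 1, Medium = 0.5, Poor = 0)),
            class = "strategy_rules")
}

#' Property rating tables
#'
#' A per-molecule table of categorical property ratings
#' (`"Excellent"`, `"Medium"`, `"Poor"`; `NA` marks a missing rating).
#' Ratings typically come from an external ADMET predictor export
#' ([read_rating_table()]) or the synthetic provider
#' ([gen_rating_table()]).
#'
#' @param df data frame with an `id` column and one column per property.
#' @return a `property_rating_table`.
#' @export
property_rating_table <- function(df) {
  stopifnot("id" %in% names(df))
  props <- setdiff(names(df), "id")
  for (p in props) {
    v <- as.character(df[[p]])
    v[!is.na(v) & v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% c("Excellent", "Medium", "Poor")
    if (any(bad)) {
      stop("invalid rating(s) in property '", p, "': ",
           paste(unique(v[bad]), collapse = ", "))
    }
    df[[p]] <- v
  }
  if (anyDuplicated(df$id)) stop("duplicate molecule ids in rating table")
  class(df) <- c("property_rating_table", "data.frame")
  df
}

#' @rdname property_rating_table
#' @param path CSV file with columns `id` plus properties.
#' @export
read_rating_table <- function(path) {
  property_rating_table(read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}

#' Score candidates under a strategy rule table
#'
#' The score of a molecule is the weighted sum of rating points over the
#' rule table's properties (Excellent 1, Medium 0.5, Poor 0, times the
#' property weight); with unit weights and five properties scores lie in
#' `[0, 5]`. Missing ratings contribute 0 and are counted in
#' `n_missing`. Candidates are ranked by descending score, ties broken
#' by id.
#'
#' @param ratings a [property_rating_table()].
#' @param rules a [strategy_rules()] with a non-empty property list.
#' @return data frame `id`, `score`, `n_missing`, `rank`, ordered by
#'   rank.
#' @export
score_strategy <- function(ratings, rules) {
  stopifnot(inherits(rules, "strategy_rules"))
  if (!length(rules$properties)) {
    stop("rule table has no properties; the innovation strategy is ",
         "scored structurally via innovation_rank()")
  }
  missing_cols <- setdiff(rules$properties, names(ratings))
  if (length(missing_cols)) {
    stop("rating table lacks propert(ies): ",
         paste(missing_cols, collapse = ", "))
  }
  pts <- rules$rating_points
  score <- numeric(nrow(ratings))
  n_missing <- integer(nrow(ratings))
  for (p in rules$properties) {
    v <- as.character(ratings[[p]])
    bad <- !is.na(v) & !v %in% names(pts)
    if (any(bad)) stop("rating outside {Excellent, Medium, Poor} in ", p)
    contrib <- ifelse(is.na(v), 0, pts[v] * rules$weights[[p]])
    score <- score + contrib
    n_missing <- n_missing + is.na(v)
  }
  out <- data.frame(id = as.character(ratings$id), score = score,
                    n_missing = n_missing, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Murcko scaffold of a molecule
#'
#' Extracts the ring-systems-plus-linkers framework: side-chain atoms
#' are stripped by iterative terminal removal, then substituents
#' multiply bonded to the framework (e.g. carbonyl oxygens on a linker)
#' are re-attached. Acyclic molecules map to the empty scaffold `""`
#' with the `acyclic` attribute set.
#'
#' @param smiles a single SMILES string (or a one-row `molecule_set`).
#' @return canonical scaffold SMILES (`""` for acyclic molecules), with
#'   attribute `acyclic`.
#' @export
murcko_scaffold <- function(smiles) {
  if (inherits(smiles, "molecule_set")) {
    stopifnot(nrow(smiles) == 1)
    smiles <- smiles$smiles
  }
  stopifnot(length(smiles) == 1)
  ms <- molecule_set("m", smiles)
  sdf <- ms_to_sdf(ms)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  n <- nrow(ab)
  if (is.null(bb) || n == 0 || nrow(bb) == 0) {
    return(structure("", acyclic = TRUE))
  }
  b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2])
  order_ <- as.integer(bb[, 3])
  # phase 1: strip all terminal atoms iteratively -> rings plus linkers
  alive <- rep(TRUE, n)
  bond_alive <- rep(TRUE, length(b1))
  repeat {
    deg <- tabulate(c(b1[bond_alive], b2[bond_alive]), n)
    drop <- alive & deg <= 1
    if (!any(drop)) break
    alive[drop] <- FALSE
    bond_alive <- bond_alive & alive[b1] & alive[b2]
  }
  if (!any(alive)) return(structure("", acyclic = TRUE))
  # phase 2: re-attach atoms multiply bonded to the framework (C=O etc.)
  for (k in seq_along(b1)) {
    if (order_[k] >= 2) {
      if (alive[b1[k]] && !alive[b2[k]]) alive[b2[k]] <- TRUE
      else if (alive[b2[k]] && !alive[b1[k]]) alive[b1[k]] <- TRUE
    }
  }
  bond_alive <- alive[b1] & alive[b2]
  scaffold_smiles <- subgraph_smiles(ab, b1, b2, order_, alive, bond_alive)
  structure(scaffold_smiles, acyclic = FALSE)
}

# Rebuild a canonical SMILES for an atom-induced subgraph by writing a
# V2000 molblock and round-tripping it through Open Babel.
subgraph_smiles <- function(ab, b1, b2, order_, alive, bond_alive) {
  idx <- which(alive)
  remap <- match(seq_along(alive), idx)
  sym <- sub("_.*$", "", rownames(ab)[idx])
  coords <- ab[idx, 1:3, drop = FALSE]
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        coords[, 1], coords[, 2], coords[, 3], sym)
  kb <- which(bond_alive)
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        remap[b1[kb]], remap[b2[kb]], order_[kb])
  block <- c("scaffold", "  esiptscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(idx), length(kb)),
             atom_lines, bond_lines, "M  END", "$$$$")
  out <- ob_convert_molblock(paste0(paste(block, collapse = "\n"), "\n"))
  if (is.na(out)) "" else out
}

ob_convert_molblock <- function(text) {
  opts <- data.frame(names = "e", args = "", stringsAsFactors = FALSE)
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", text, options = opts)),
    error = function(e) "")
  line <- strsplit(res, "\n", fixed = TRUE)[[1]][1]
  if (is.null(line) || is.na(line) || !nzchar(line)) return(NA_character_)
  strsplit(line, "[ \t]")[[1]][1]
}

#' Scaffolds for every molecule of a set
#'
#' @param ms a `molecule_set`.
#' @return data frame `id`, `scaffold`, `acyclic`.
#' @export
murcko_scaffolds <- function(ms) {
  res <- lapply(ms$smiles, function(s) {
    sc <- tryCatch(murcko_scaffold(s), error = function(e) structure("", acyclic = TRUE))
    data.frame(scaffold = as.character(sc), acyclic = isTRUE(attr(sc, "acyclic")))
  })
  out <- do.call(rbind, res)
  data.frame(id = ms$id, out, stringsAsFactors = FALSE)
}

#' Structural diversity of a molecule set
#'
#' One minus the mean pairwise Tanimoto similarity over all unordered
#' pairs: 0 for an all-identical set, approaching 1 for molecules with
#' disjoint fingerprints. Inserting a duplicate molecule can never
#' increase the score.
#'
#' @param ms a `molecule_set` with at least 2 molecules.
#' @param fingerprint `"ECFP4"` or `"MACCS"`.
#' @return a number in `[0, 1]`.
#' @export
diversity_score <- function(ms, fingerprint = c("ECFP4", "MACCS")) {
  fingerprint <- match.arg(fingerprint)
  if (nrow(ms) < 2) stop("diversity_score needs at least 2 molecules")
  fp <- fingerprints_of(ms, fingerprint)
  sim <- tanimoto_matrix(fp)
  n <- nrow(sim)
  mean_pairwise <- (sum(sim) - sum(diag(sim))) / (n * (n - 1))
  1 - mean_pairwise
}

#' Rank candidates by structural innovation
#'
#' Combines per-candidate novelty (one minus the maximum Tanimoto
#' similarity to any reference molecule) with scaffold rarity (the
#' inverse frequency of the candidate's Murcko scaffold within the
#' candidate set). The innovation score is
#' `w_novelty * novelty + w_rarity * rarity`; candidates are ranked
#' descending, ties broken by id.
#'
#' @param ms candidate `molecule_set`.
#' @param reference known-ESIPT reference `molecule_set`.
#' @param fingerprint fingerprint for the novelty term.
#' @param w_novelty,w_rarity combination weights.
#' @return data frame `id`, `novelty`, `scaffold`, `rarity`, `score`,
#'   `rank`, ordered by rank.
#' @export
innovation_rank <- function(ms, reference, fingerprint = "ECFP4",
                            w_novelty = 0.5, w_rarity = 0.5) {
  stopifnot(nrow(ms) > 0, nrow(reference) > 0)
  fpc <- fingerprints_of(ms, fingerprint)
  fpr <- fingerprints_of(reference, fingerprint)
  novelty <- 1 - apply(tanimoto_matrix(fpc, fpr), 1, max)
  sc <- murcko_scaffolds(ms)
  freq <- table(sc$scaffold)
  rarity <- 1 / as.numeric(freq[sc$scaffold])
  out <- data.frame(id = ms$id, novelty = unname(novelty[ms$id]),
                    scaffold = sc$scaffold, rarity = rarity,
                    score = w_novelty * unname(novelty[ms$id]) + w_rarity * rarity,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
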