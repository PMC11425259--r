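#' Synthetic molecule generation with planted ESIPT motifs
#'
#' The generator builds labelled molecule sets with known ground truth
#' so that every stage of the screening system is testable without
#' external data. Positives decorate classic ESIPT scaffolds -- HBT
#' (2-(2'-hydroxyphenyl)benzothiazole), HBO (benzoxazole), HBI
#' (benzimidazole) and a salicylaldehyde azine -- all carrying the
#' intramolecular proton-transfer motif: an o-hydroxyaryl donor adjacent
#' to a =N- acceptor. Conventional negatives are small drug-like
#' mono/acyclic templates; fluorescent negatives are conjugated
#' polycyclic dyes (coumarins, naphthalimide, stilbene, anthracene)
#' without the o-hydroxy donor, deliberately closer in fingerprint space
#' to the positives than the conventional set is. Every generated
#' molecule is checked against the motif SMARTS: positives must match,
#' negatives must not (rejection sampling).
#'
#' @param n_per_class molecules per generated class.
#' @param seed RNG seed (all generators are deterministic under it).
#' @param decorations substituent SMILES fragments used to decorate
#'   template scaffolds.
#' @param max_decorations maximum substituents per molecule.
#' @param barrier_weights named coefficients (over 2D descriptor names)
#'   of the synthetic barrier model.
#' @param noise_sd barrier noise standard deviation relative to the
#'   standard deviation of the descriptor signal.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 500, seed = 1L,
                           decorations = c("F", "Cl", "Br", "C", "OC",
                                           "N(C)C", "C#N", "[N+](=O)[O-]"),
                           max_decorations = 3,
                           barrier_weights = c(TPSA = 0.8, logP = -0.6,
                                               MW = 0.5, n_arom_any = -0.7,
                                               HBD = 0.6),
                           noise_sd = 0.3) {
  stopifnot(n_per_class >= 1, max_decorations >= 0)
  structure(list(n_per_class = n_per_class, seed = as.integer(seed),
                 decorations = decorations,
                 max_decorations = max_decorations,
                 barrier_weights = barrier_weights, noise_sd = noise_sd),
            class = "synthetic_spec")
}

#' The planted ESIPT donor-acceptor motif, as SMARTS
#'
#' Matches an aromatic hydroxy donor ortho to a carbon bearing a
#' two-coordinate nitrogen acceptor -- the substructure every generated
#' positive carries and no generated negative does.
#'
#' @return a SMARTS string.
#' @export
esipt_motif_smarts <- function() "[OX2H]c1ccccc1[#6]~[#7X2]"

#' Does each molecule carry the ESIPT donor-acceptor motif?
#'
#' @param ms a `molecule_set`.
#' @return logical vector aligned with `ms` rows.
#' @export
has_esipt_motif <- function(ms) {
  keep <- validate_smiles_rows(ms)
  pat <- esipt_motif_smarts()
  hits <- ChemmineOB::forEachMol(
    "SMILES", paste(ms$smiles[keep], collapse = "\n"),
    function(mol) as.numeric(ChemmineOB::smartsSearch_OB(list(mol), pat,
                                                         uniqueMatches = TRUE)))
  out <- rep(FALSE, nrow(ms))
  out[keep] <- unlist(hits) > 0
  out
}

# Scaffold templates. Placeholders {1}, {2}, {3} are optional aromatic
# substitution sites filled with "(X)" or dropped.
positive_templates <- c(
  HBT = "Oc1cc{1}cc{2}c1-c1nc2cc{3}ccc2s1",
  HBO = "Oc1cc{1}cc{2}c1-c1nc2cc{3}ccc2o1",
  HBI = "Oc1cc{1}cc{2}c1-c1nc2cc{3}ccc2[nH]1",
  SAA = "Oc1cc{1}ccc1/C=N/N=C/c1ccc{2}cc1O")

conventional_templates <- c(
  anilide = "CC(=O)Nc1cc{1}cc{2}c1",
  benzoate = "CCOC(=O)c1cc{1}cc{2}c1",
  phenethylamine = "CN(C)CCOc1cc{1}cc{2}c1",
  benzylalcohol = "OCc1cc{1}cc{2}c1",
  cyclohexylamide = "O=C(NC1CCCCC1)C{1}C",
  piperidine = "CC(=O)N1CCC(C{1})CC1",
  aliphatic_ester = "CCCCOC(=O)CC{1}C",
  sulfonamide = "CS(=O)(=O)Nc1cc{1}cc{2}c1",
  alkylurea = "CCNC(=O)NC1CC{1}CC1",
  morpholine = "O=C(CC{1})N1CCOCC1")

fluor_templates <- c(
  coumarin = "O=c1ccc2cc{1}cc{2}c2o1",
  aminocoumarin = "CN(C)c1cc{1}c2ccc(=O)oc2c1",
  naphthalimide = "CN1C(=O)c2ccc{1}c3cc{2}cc(c23)C1=O",
  stilbene = "c1cc{1}ccc1/C=C/c1ccc{2}cc1",
  anthracene = "c1ccc2cc3cc{1}ccc3cc2c1",
  cyanonaphthalene = "N#Cc1ccc2cc{1}ccc2c1",
  methoxyflavone = "COc1cc{1}c2c(=O)cc(-c3ccc{2}cc3)oc2c1")

# Fill the {k} placeholders of a template: chosen sites get "(X)",
# the rest are removed.
fill_template <- function(template, subs) {
  n_sites <- length(gregexpr("\\{[0-9]\\}", template)[[1]])
  for (k in seq_len(max(n_sites, 0))) {
    rep_with <- if (!is.null(subs[[as.character(k)]])) {
      paste0("(", subs[[as.character(k)]], ")")
    } else ""
    template <- gsub(sprintf("{%d}", k), rep_with, template, fixed = TRUE)
  }
  template
}

template_sites <- function(template) {
  m <- gregexpr("\\{([0-9])\\}", template)[[1]]
  if (m[1] == -1) return(character(0))
  unique(gsub("[{}]", "", regmatches(template, gregexpr("\\{[0-9]\\}", template))[[1]]))
}

# Shared rejection-sampled generator over a template family.
gen_from_templates <- function(templates, spec, prefix, label, want_motif,
                               rng_offset = 0L) {
  n <- spec$n_per_class
  smiles <- character(n)
  with_seed(spec$seed + rng_offset, {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:20) {
        tpl <- templates[[sample(length(templates), 1)]]
        sites <- template_sites(tpl)
        ndec <- sample(0:min(spec$max_decorations, length(sites)), 1)
        subs <- list()
        if (ndec > 0) {
          chosen <- sample(sites, ndec)
          for (s in chosen) subs[[s]] <- sample(spec$decorations, 1)
        }
        cand <- fill_template(tpl, subs)
        can <- ob_convert_smiles(cand, "CAN")
        if (is.na(can)) next
        motif <- has_esipt_motif(molecule_set("t", cand))
        if (motif == want_motif) { smiles[i] <- cand; ok <- TRUE; break }
      }
      if (!ok) {
        # fall back to the undecorated first template (always valid)
        smiles[i] <- fill_template(templates[[1]], list())
      }
    }
  })
  molecule_set(sprintf("%s%04d", prefix, seq_len(n)), smiles, label = label,
               source = "synthetic", name = paste0("synthetic_", label))
}

#' Generate ESIPT-positive molecules
#'
#' Decorated ESIPT scaffolds, every one matching the planted
#' donor-acceptor motif; deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a `molecule_set` labelled `ESIPT`.
#' @export
gen_esipt_positives <- function(spec = synthetic_spec()) {
  gen_from_templates(positive_templates, spec, "pos", "ESIPT",
                     want_motif = TRUE, rng_offset = 0L)
}

#' Generate conventional (non-fluorescent) negative molecules
#'
#' Drug-like mono/acyclic templates, none matching the ESIPT motif.
#'
#' @param spec a [synthetic_spec()].
#' @return a `molecule_set` labelled `CONVENTIONAL`.
#' @export
gen_conventional_negatives <- function(spec = synthetic_spec()) {
  gen_from_templates(conventional_templates, spec, "con", "CONVENTIONAL",
                     want_motif = FALSE, rng_offset = 1000L)
}

#' Generate fluorescent non-ESIPT negative molecules
#'
#' Conjugated dye scaffolds (two or more conjugated rings) without the
#' o-hydroxyaryl donor; structurally closer to the positives than the
#' conventional negatives, making the second-stage classification
#' deliberately harder.
#'
#' @param spec a [synthetic_spec()].
#' @return a `molecule_set` labelled `FLUOR_NON_ESIPT`.
#' @export
gen_fluor_negatives <- function(spec = synthetic_spec()) {
  gen_from_templates(fluor_templates, spec, "flu", "FLUOR_NON_ESIPT",
                     want_motif = FALSE, rng_offset = 2000L)
}

#' Attach synthetic proton-transfer barriers to molecules
#'
#' Barriers are a smooth monotone function of standardized 2D
#' descriptors, not physics: with standardized linear signal
#' `s = Z w` (`Z` the z-scored descriptor columns named in
#' `spec$barrier_weights`) and noise `e ~ N(0, noise_sd)` (relative to
#' `sd(s) = 1`),
#' `barrier = 0.3 + 2.2 * softplus(1.2 * (s + e) + 2)`, capped at 20
#' kcal/mol -- positive, right-skewed, and spanning the feasible range.
#' The generating weights are returned in the `barrier_weights`
#' attribute for recovery tests.
#'
#' @param ms a `molecule_set` of featurizable molecules.
#' @param spec a [synthetic_spec()].
#' @return `ms` with the `barrier` column filled; attributes
#'   `barrier_weights` (true coefficients) and `barrier_signal` (the
#'   noise-free standardized signal).
#' @export
gen_barriers <- function(ms, spec = synthetic_spec()) {
  fm <- compute_descriptors_2d(ms)
  w <- spec$barrier_weights
  missing <- setdiff(names(w), colnames(fm))
  if (length(missing)) stop("descriptor(s) absent: ", paste(missing, collapse = ", "))
  Z <- scale(unclass(fm)[, names(w), drop = FALSE])
  Z[!is.finite(Z)] <- 0
  s <- as.numeric(Z %*% w)
  if (sd(s) > 0) s <- (s - mean(s)) / sd(s)
  eps <- with_seed(spec$seed + 3000L, rnorm(nrow(ms), 0, spec$noise_sd))
  softplus <- function(x) log1p(exp(x))
  barrier <- pmin(0.3 + 2.2 * softplus(1.2 * (s + eps) + 2), 20)
  out <- ms
  out$barrier <- barrier[match(ms$id, rownames(fm))]
  attr(out, "barrier_weights") <- w
  attr(out, "barrier_signal") <- setNames(s, rownames(fm))
  out
}

#' Generate a synthetic ADMET rating table
#'
#' Independent categorical ratings per property and molecule, drawn
#' from a fixed `(Excellent, Medium, Poor)` probability vector;
#' deterministic under the seed.
#'
#' @param ids molecule ids.
#' @param seed RNG seed.
#' @param distribution probabilities for Excellent/Medium/Poor (must sum
#'   to 1).
#' @param properties property column names.
#' @return a [property_rating_table()].
#' @export
gen_rating_table <- function(ids, seed = 1L,
                             distribution = c(Excellent = 1/3, Medium = 1/3,
                                              Poor = 1/3),
                             properties = c("LD50", "AMES",
                                            "SkinSensitization", "hERG",
                                            "DILI")) {
  stopifnot(abs(sum(distribution) - 1) < 1e-8, length(distribution) == 3)
  levels <- c("Excellent", "Medium", "Poor")
  df <- data.frame(id = as.character(ids), stringsAsFactors = FALSE)
  with_seed(seed, {
    for (p in properties) {
      df[[p]] <- sample(levels, length(ids), replace = TRUE,
                        prob = distribution)
    }
  })
  property_rating_table(df)
}

#' Write a full synthetic study to disk
#'
#' Generates positives, both negative classes, barriers for the
#' positives, and a rating table, writing
#' `positives.csv`, `conventional.csv`, `fluor.csv`, `barriers.csv`,
#' `ratings.csv` under `out_dir`.
#'
#' @param preset `"small"` (100/class) or `"medium"` (500/class).
#' @param seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
simulate_study <- function(preset = c("small", "medium"), seed = 1L,
                           out_dir = ".") {
  preset <- match.arg(preset)
  n <- if (preset == "small") 100 else 500
  spec <- synthetic_spec(n_per_class = n, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pos <- gen_esipt_positives(spec)
  con <- gen_conventional_negatives(spec)
  flu <- gen_fluor_negatives(spec)
  bar <- gen_barriers(pos, spec)
  rat <- gen_rating_table(pos$id, seed = seed)
  paths <- file.path(out_dir, c("positives.csv", "conventional.csv",
                                "fluor.csv", "barriers.csv", "ratings.csv"))
  write_molecules(pos, paths[1])
  write_molecules(con, paths[2])
  write_molecules(flu, paths[3])
  write_molecules(bar, paths[4])
  write.csv(as.data.frame(rat), paths[5], row.names = FALSE)
  invisible(paths)
}
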