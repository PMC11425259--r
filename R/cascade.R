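#' Screening cascade configuration
#'
#' Parameters of the multi-level virtual screen: a physicochemical
#' prefilter (molecular weight 50-200 Da, logP 1-5, closed intervals),
#' probability thresholds for the ESIPT-vs-conventional (E-CM) and
#' ESIPT-vs-fluorophore (E-FL) classifiers (both 0.9 by default;
#' comparisons are `>=`), an internal-similarity deduplication threshold
#' (0.8), and the barrier feasibility cutoff in kcal/mol. Barrier
#' prediction annotates survivors by default; `hard_barrier_filter`
#' additionally rejects molecules with infeasible predicted barriers.
#'
#' @param mw_range,logp_range closed prefilter intervals.
#' @param p_threshold_ecm,p_threshold_efl probability thresholds in
#'   `[0, 1]`.
#' @param dedup_similarity Tanimoto threshold for internal dedup.
#' @param barrier_cutoff feasibility cutoff, kcal/mol.
#' @param hard_barrier_filter reject infeasible-barrier molecules.
#' @return a `cascade_config`.
#' @export
cascade_config <- function(mw_range = c(50, 200), logp_range = c(1, 5),
                           p_threshold_ecm = 0.9, p_threshold_efl = 0.9,
                           dedup_similarity = 0.8, barrier_cutoff = 15,
                           hard_barrier_filter = FALSE) {
  stopifnot(length(mw_range) == 2, mw_range[1] <= mw_range[2],
            length(logp_range) == 2, logp_range[1] <= logp_range[2],
            p_threshold_ecm >= 0, p_threshold_ecm <= 1,
            p_threshold_efl >= 0, p_threshold_efl <= 1,
            dedup_similarity >= 0, dedup_similarity <= 1)
  structure(list(mw_range = mw_range, logp_range = logp_range,
                 p_threshold_ecm = p_threshold_ecm,
                 p_threshold_efl = p_threshold_efl,
                 dedup_similarity = dedup_similarity,
                 barrier_cutoff = barrier_cutoff,
                 hard_barrier_filter = hard_barrier_filter),
            class = "cascade_config")
}

#' Physicochemical prefilter
#'
#' Retains molecules whose molecular weight and computed logP (Open
#' Babel estimate) fall inside the configured closed intervals.
#'
#' @param ms a `molecule_set`.
#' @param config a [cascade_config()].
#' @return the retained `molecule_set`; attribute `rejection_log` is a
#'   data frame of rejected ids with the property that failed.
#' @export
prefilter <- function(ms, config = cascade_config()) {
  if (nrow(ms) == 0) {
    attr(ms, "rejection_log") <- data.frame(id = character(0),
                                            reason = character(0))
    return(ms)
  }
  props <- molecule_properties(ms)
  mw_ok <- props$MW >= config$mw_range[1] & props$MW <= config$mw_range[2]
  lp_ok <- props$logP >= config$logp_range[1] & props$logP <= config$logp_range[2]
  ok <- !is.na(mw_ok) & !is.na(lp_ok) & mw_ok & lp_ok
  reason <- ifelse(is.na(mw_ok) | is.na(lp_ok), "unparseable",
            ifelse(!mw_ok & !lp_ok, "mw+logp", ifelse(!mw_ok, "mw", "logp")))
  out <- ms_subset(ms, ok)
  attr(out, "rejection_log") <- data.frame(id = ms$id[!ok],
                                           reason = reason[!ok],
                                           stringsAsFactors = FALSE)
  out
}

# MW/logP lookup aligned with ms rows (NA for unparseable molecules).
molecule_properties <- function(ms) {
  out <- data.frame(MW = rep(NA_real_, nrow(ms)), logP = NA_real_)
  parsed <- tryCatch(ms_to_sdf(ms), error = function(e) NULL)
  if (is.null(parsed)) return(out)
  rows <- attr(parsed, "ms_rows")
  p <- ChemmineR::propOB(parsed)
  out$MW[rows] <- p$MW
  out$logP[rows] <- p$logP
  out
}

# Featurize molecules the way a trained model expects, selecting and
# ordering columns by its manifest.
featurize_for <- function(model, ms) {
  fz <- model$featurizer
  if (is.null(fz)) {
    stop("model carries no featurizer metadata; fit it from a ",
         "feature_matrix or set `featurizer` in fit_model()")
  }
  fm <- switch(fz$kind,
    ECFP4 = compute_ecfp4(ms, n_bits = fz$n_bits %||% 2048),
    MACCS = compute_maccs(ms),
    DESC2D = compute_descriptors_2d(ms),
    stop("unknown featurizer kind: ", fz$kind))
  missing <- setdiff(model$feature_names, colnames(fm))
  if (length(missing)) {
    stop("featurization lacks model features: ",
         paste(head(missing, 5), collapse = ", "))
  }
  fm_subset(fm, j = model$feature_names)
}

#' Run the multi-level screening cascade
#'
#' Every molecule is traced through prefilter, the E-CM classifier
#' (ESIPT vs conventional), the E-FL classifier (ESIPT vs other
#' fluorophores), and the E-Barrier regressor. A molecule survives iff
#' it passes the prefilter and both classifier probabilities reach
#' their thresholds (`>=`); survivors (and every featurizable molecule)
#' are annotated with the predicted barrier and its feasibility.
#' Molecules that cannot be featurized get a failure record, never an
#' abort.
#'
#' @param ms the molecule library (`molecule_set`).
#' @param ecm,efl trained classifiers carrying featurizer metadata.
#' @param ebarrier trained barrier regressor (or `NULL` to skip
#'   annotation).
#' @param config a [cascade_config()].
#' @return a `cascade_result` data frame, one row per input molecule:
#'   `id`, `passed_prefilter`, `p_ecm`, `p_efl`, `predicted_barrier`,
#'   `feasibility`, `survived`, `stage_of_rejection`
#'   (`"none"`, `"prefilter"`, `"ecm"`, `"efl"`, `"barrier"`,
#'   `"featurization"`).
#' @export
run_cascade <- function(ms, ecm, efl, ebarrier = NULL,
                        config = cascade_config()) {
  n <- nrow(ms)
  trace <- data.frame(
    id = ms$id, passed_prefilter = FALSE, p_ecm = NA_real_, p_efl = NA_real_,
    predicted_barrier = NA_real_, feasibility = NA_character_,
    survived = FALSE, stage_of_rejection = "featurization",
    stringsAsFactors = FALSE)

  pre <- prefilter(ms, config)
  trace$passed_prefilter <- ms$id %in% pre$id

  score_all <- function(model) {
    if (is.null(model)) return(rep(NA_real_, n))
    out <- rep(NA_real_, n)
    fm <- tryCatch(featurize_for(model, ms), error = function(e) NULL)
    if (is.null(fm)) return(out)
    sc <- predict(model, fm)
    out[match(rownames(fm), ms$id)] <- unname(sc)
    out
  }
  trace$p_ecm <- score_all(ecm)
  trace$p_efl <- score_all(efl)
  trace$predicted_barrier <- score_all(ebarrier)
  has_barrier <- !is.na(trace$predicted_barrier)
  trace$feasibility[has_barrier] <-
    barrier_feasibility(trace$predicted_barrier[has_barrier],
                        config$barrier_cutoff)

  featurized <- !is.na(trace$p_ecm) & !is.na(trace$p_efl)
  pass_ecm <- featurized & trace$p_ecm >= config$p_threshold_ecm
  pass_efl <- featurized & trace$p_efl >= config$p_threshold_efl
  surv <- trace$passed_prefilter & pass_ecm & pass_efl
  if (config$hard_barrier_filter) {
    surv <- surv & has_barrier & trace$feasibility == "feasible"
  }
  trace$survived <- surv
  trace$stage_of_rejection <- ifelse(surv, "none",
    ifelse(!featurized, "featurization",
    ifelse(!trace$passed_prefilter, "prefilter",
    ifelse(!pass_ecm, "ecm",
    ifelse(!pass_efl, "efl", "barrier")))))
  class(trace) <- c("cascade_result", "data.frame")
  trace
}

#' Relax the survival threshold and diversify the survivors
#'
#' Re-applies survival at a relaxed probability threshold (applied to
#' both classifiers) on an existing cascade trace, then removes
#' internal near-duplicates by greedy Tanimoto deduplication. The
#' resulting structurally diverse set feeds the structural-innovation
#' scoring strategy.
#'
#' @param ms the molecule library the trace was computed on.
#' @param results a `cascade_result` from [run_cascade()].
#' @param relaxed_threshold probability threshold for both classifiers.
#' @param dedup_similarity Tanimoto threshold for [internal_dedup_by_similarity()].
#' @param fingerprint fingerprint used for deduplication.
#' @return the relaxed, deduplicated `molecule_set`.
#' @export
relax_and_diversify <- function(ms, results, relaxed_threshold = 0.8,
                                dedup_similarity = 0.8,
                                fingerprint = "ECFP4") {
  stopifnot(all(ms$id %in% results$id))
  r <- results[match(ms$id, results$id), ]
  keep <- r$passed_prefilter &
    !is.na(r$p_ecm) & r$p_ecm >= relaxed_threshold &
    !is.na(r$p_efl) & r$p_efl >= relaxed_threshold
  relaxed <- ms_subset(ms, keep)
  if (nrow(relaxed) <= 1) return(relaxed)
  internal_dedup_by_similarity(relaxed, fingerprint = fingerprint,
                               threshold = dedup_similarity)
}

#' Write a cascade trace to CSV
#'
#' @param results a `cascade_result`.
#' @param path output path.
#' @export
write_cascade_result <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE, na = "")
  invisible(path)
}
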