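#' Run configuration for the benchmark scenarios
#'
#' @param scenario `"filling_gaps"` or `"new_ligands"`.
#' @param variants model variants to evaluate (filling-gaps only); the
#'   prior baseline is always included, and the nearest-neighbor baseline
#'   in the new-ligands scenario.
#' @param rho training fraction, default 0.8.
#' @param n_repetitions number of repeated splits (the reference protocol
#'   uses 100; scale down for quick runs), >= 1.
#' @param base_seed repetition `i` uses seed `base_seed + i`.
#' @param threshold decision threshold for per-receptor metrics,
#'   default 0.5.
#' @param completion_threshold threshold for matrix completion (default
#'   0.65, prioritizing precision).
#' @param batch_threshold threshold for batch prediction of external
#'   compounds, default 0.52.
#' @param K recall grid size for curve aggregation, default 200.
#' @param ci `"asymptotic"` or `"bootstrap"` confidence intervals.
#' @param collab_method collaborative similarity method (see
#'   [collaborative_similarity()]).
#' @param recommended_variant variant used for per-receptor metrics and
#'   feature importance in the filling-gaps report.
#' @param hp [hyperparameters()] for the classifier.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = c("filling_gaps", "new_ligands"),
                       variants = c("model1", "model2", "model3", "model4"),
                       rho = 0.8, n_repetitions = 100L, base_seed = 0L,
                       threshold = 0.5, completion_threshold = 0.65,
                       batch_threshold = 0.52, K = 200L,
                       ci = c("asymptotic", "bootstrap"),
                       collab_method = c("matching", "jaccard"),
                       recommended_variant = "model3",
                       hp = hyperparameters()) {
  scenario <- match.arg(scenario)
  ci <- match.arg(ci)
  collab_method <- match.arg(collab_method)
  if (n_repetitions < 1L) stop("`n_repetitions` must be >= 1")
  for (t in c(threshold, completion_threshold, batch_threshold))
    if (!(t > 0 && t < 1)) stop("thresholds must lie in (0, 1)")
  variants <- match.arg(variants, .variants, several.ok = TRUE)
  structure(list(scenario = scenario, variants = variants, rho = rho,
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed), threshold = threshold,
                 completion_threshold = completion_threshold,
                 batch_threshold = batch_threshold, K = as.integer(K),
                 ci = ci, collab_method = collab_method,
                 recommended_variant = recommended_variant, hp = hp),
            class = "run_config")
}

.summarize_curves <- function(curves, config) {
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) >= 2L)
    interpolate_and_band(curves, K = config$K, ci = config$ci)
  else NULL
}

# average per-receptor metrics over repetitions where the receptor has
# >= 1 test pair
.aggregate_receptor_metrics <- function(per_rep) {
  tab <- do.call(rbind, per_rep)
  recs <- sort(unique(tab$receptor))
  do.call(rbind, lapply(recs, function(r) {
    sub <- tab[tab$receptor == r, , drop = FALSE]
    data.frame(receptor = r, n_repetitions = nrow(sub),
               mean_n_known = mean(sub$n_known),
               mean_precision = mean(sub$precision, na.rm = TRUE),
               mean_recall = mean(sub$recall, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Repeated-split evaluation in the filling-the-gaps scenario
#'
#' For each repetition, a balanced per-receptor split is drawn (seed
#' `base_seed + i`), every requested model variant is trained on the
#' leakage-safe design and scored on the held-out pairs, and the prior
#' baseline is computed from the masked training view. Curves are
#' aggregated onto the fixed recall grid; per-receptor metrics at the
#' decision threshold and feature importance are reported for the
#' recommended variant.
#'
#' @param data dataset list (see [generate_synthetic()] /
#'   [read_dataset()]): `associations`, `fingerprints`,
#'   `ligand_descriptors`, `receptor_descriptors`, `alignment`.
#' @param config a [run_config()] with scenario `"filling_gaps"`.
#' @return an evaluation report: list with one `pr_summary` per method
#'   (`prior` plus each variant), per-repetition average precisions,
#'   aggregated per-receptor metrics, mean feature importance, and the
#'   resolved configuration.
#' @export
run_filling_gaps <- function(data, config = run_config("filling_gaps")) {
  stopifnot(config$scenario == "filling_gaps")
  A <- data$associations
  if (!is_gaps_ready(A))
    stop("association matrix is not gaps-ready (empty row or column)")
  sims <- chemistry_similarities(data)
  methods <- c("prior", config$variants)
  curves <- stats::setNames(rep(list(list()), length(methods)), methods)
  receptor_metrics <- list()
  importance <- NULL
  for (i in seq_len(config$n_repetitions)) {
    seed_i <- config$base_seed + i
    split <- make_split(A, "filling_gaps", rho = config$rho, seed = seed_i,
                        repetition = i)
    A_view <- mask_entries(A, split$test)
    phi <- prior_baseline(A_view)
    prior_scores <- phi[split$test$receptor]
    curves$prior[[i]] <- precision_recall(prior_scores, split$test$label)
    for (v in config$variants) {
      design <- build_design(A, split, data$ligand_descriptors,
                             data$receptor_descriptors, sims, v,
                             config$collab_method)
      model <- fit_association_model(design$train, config$hp, seed = seed_i,
                                     threshold = config$threshold)
      scores <- predict_scores(model, design$test)
      curves[[v]][[i]] <- precision_recall(scores, split$test$label)
      if (v == config$recommended_variant) {
        receptor_metrics[[i]] <- per_receptor_metrics(
          scores, split$test$label, split$test, config$threshold)
        imp <- feature_importance(model)
        imp <- imp[order(imp$feature), , drop = FALSE]
        importance <- if (is.null(importance)) imp$average_gain
                      else importance + imp$average_gain
      }
    }
  }
  imp_table <- NULL
  if (!is.null(importance)) {
    imp_table <- data.frame(
      feature = sort(.design_schema(data, config)),
      average_gain = importance / config$n_repetitions,
      stringsAsFactors = FALSE)
    imp_table <- imp_table[order(-imp_table$average_gain), , drop = FALSE]
    rownames(imp_table) <- NULL
  }
  list(scenario = "filling_gaps",
       summaries = lapply(curves, .summarize_curves, config = config),
       average_precision = lapply(curves, function(cs)
         vapply(Filter(Negate(is.null), cs), `[[`, numeric(1),
                "average_precision")),
       per_receptor = if (length(receptor_metrics))
         .aggregate_receptor_metrics(receptor_metrics) else NULL,
       feature_importance = imp_table,
       config = .config_record(config))
}

# column schema of the recommended variant (for importance labelling)
.design_schema <- function(data, config) {
  lig <- setdiff(names(data$ligand_descriptors), "id")
  rec <- setdiff(names(data$receptor_descriptors), "id")
  kinds <- .variant_kinds[[config$recommended_variant]]
  kinds <- kinds[order(match(kinds, .sim_kinds))]
  c(paste0("lig__", lig), paste0("rec__", rec),
    unlist(lapply(kinds, function(k)
      paste0(k, "__", c("M1", "W1", "M0", "W0")))))
}

.config_record <- function(config) {
  rec <- unclass(config)
  rec$hp <- unclass(rec$hp)
  rec
}

#' Repeated-split evaluation in the new-ligands (cold start) scenario
#'
#' In each repetition a fraction `rho` of the ligands is sampled into
#' training; all known associations of the held-out ligands form the test
#' set and their rows are masked when computing features. The cold-start
#' model (chemical descriptors plus fingerprint-based ligand neighbor
#' features only) is compared with the prior and the nearest-neighbor
#' baselines, and the tests-to-first-hit counts of the model are compared
#' against the prior's.
#'
#' Nearest-neighbor predictions are binary; test pairs for which no
#' eligible neighbor exists are dropped from that baseline's curve and
#' counted in `nn_missing`.
#'
#' @param data dataset list (see [run_filling_gaps()]).
#' @param config a [run_config()] with scenario `"new_ligands"`.
#' @return evaluation report: `pr_summary` per method (`model`, `prior`,
#'   `nearest_neighbor`), per-repetition average precisions, pooled
#'   tests-to-first-hit counts with the least-squares comparison
#'   (`first_hit`), and the resolved configuration.
#' @export
run_new_ligands <- function(data, config = run_config("new_ligands")) {
  stopifnot(config$scenario == "new_ligands")
  A <- data$associations
  sims <- chemistry_similarities(data)
  S_linear <- sims$ligand_linear_fp
  methods <- c("model", "prior", "nearest_neighbor")
  curves <- stats::setNames(rep(list(list()), length(methods)), methods)
  nn_missing <- 0L
  hits_model <- numeric(0)
  hits_prior <- numeric(0)
  for (i in seq_len(config$n_repetitions)) {
    seed_i <- config$base_seed + i
    split <- make_split(A, "new_ligands", rho = config$rho, seed = seed_i,
                        repetition = i)
    stopifnot(!any(split$train$ligand %in% split$test_ligands))
    A_view <- mask_entries(A, split$test)
    design <- build_design(A, split, data$ligand_descriptors,
                           data$receptor_descriptors, sims, "new_ligands",
                           config$collab_method)
    model <- fit_association_model(design$train, config$hp, seed = seed_i,
                                   threshold = config$threshold)
    scores <- predict_scores(model, design$test)
    curves$model[[i]] <- precision_recall(scores, split$test$label)

    phi <- prior_baseline(A_view)
    prior_scores <- phi[split$test$receptor]
    curves$prior[[i]] <- precision_recall(prior_scores, split$test$label)

    nn <- nearest_neighbor_baseline(A_view, S_linear, split$test)
    ok <- !is.na(nn)
    nn_missing <- nn_missing + sum(!ok)
    if (any(split$test$label[ok] == 1L))
      curves$nearest_neighbor[[i]] <-
        precision_recall(nn[ok], split$test$label[ok])

    rec_order <- colnames(A)
    h_m <- tests_to_first_hit(scores, split$test$label, split$test, rec_order)
    h_p <- tests_to_first_hit(prior_scores, split$test$label, split$test,
                              rec_order)
    shared <- intersect(names(h_m), names(h_p))
    hits_model <- c(hits_model, unname(h_m[shared]))
    hits_prior <- c(hits_prior, unname(h_p[shared]))
  }
  first_hit <- list(
    model_counts = hits_model, prior_counts = hits_prior,
    mean_model = mean(hits_model), mean_prior = mean(hits_prior),
    regression = if (length(hits_model) >= 2L)
      compare_test_counts(hits_model, hits_prior) else NULL)
  list(scenario = "new_ligands",
       summaries = lapply(curves, .summarize_curves, config = config),
       average_precision = lapply(curves, function(cs)
         vapply(Filter(Negate(is.null), cs), `[[`, numeric(1),
                "average_precision")),
       first_hit = first_hit, nn_missing = nn_missing,
       config = .config_record(config))
}

#' Complete an association matrix with thresholded predictions
#'
#' Predicts every unknown cell with a trained model (features computed on
#' the full known matrix) and fills it with the thresholded call (positive
#' when score >= `threshold`). The returned provenance mask distinguishes
#' measured (`"measured"`) from predicted (`"predicted"`) entries.
#'
#' @param A an `assoc_matrix`.
#' @param model a trained `bitter_model`.
#' @param ligand_descriptors,receptor_descriptors descriptor tables.
#' @param similarities precomputed chemistry/sequence similarity list.
#' @param threshold completion threshold, default 0.65 (prioritizing
#'   precision).
#' @param collab_method collaborative similarity method.
#' @return list with `completed` (fully known `assoc_matrix`),
#'   `provenance` (character matrix), `scores` (per filled pair).
#' @export
complete_matrix <- function(A, model, ligand_descriptors,
                            receptor_descriptors, similarities = list(),
                            threshold = 0.65,
                            collab_method = "matching") {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  targets <- unknown_pairs(A)
  provenance <- matrix("measured", nrow(A), ncol(A), dimnames = dimnames(A))
  if (nrow(targets) == 0L)
    return(list(completed = A, provenance = provenance,
                scores = numeric(0)))
  design <- prediction_design(A, ligand_descriptors, receptor_descriptors,
                              similarities, model$variant, targets,
                              collab_method)
  scores <- predict_scores(model, design)
  calls <- as.integer(scores >= threshold)
  completed <- unclass(A)
  idx <- cbind(match(targets$ligand, rownames(A)),
               match(targets$receptor, colnames(A)))
  completed[idx] <- calls
  provenance[idx] <- "predicted"
  list(completed = association_matrix(completed,
                                      species = receptor_species(A)),
       provenance = provenance,
       scores = stats::setNames(scores,
                                paste(targets$ligand, targets$receptor,
                                      sep = "|")))
}

#' Functional analog analysis across species
#'
#' On a fully known association matrix, computes receptor-to-receptor
#' profile similarity over all ligands (agreement of both positive and
#' negative associations by default; strict positive-class Jaccard via
#' `method = "jaccard"`) and reports, per receptor, the most similar
#' receptor of the other species.
#'
#' @param A_complete a fully known `assoc_matrix`.
#' @param method `"matching"` or `"jaccard"`.
#' @return list with `similarity` (receptor `sim_matrix`) and
#'   `cross_species` (data frame: receptor, species, best cross-species
#'   match and its similarity).
#' @export
functional_analogs <- function(A_complete, method = c("matching", "jaccard")) {
  method <- match.arg(method)
  if (anyNA(A_complete))
    stop("functional analog analysis requires a fully known matrix")
  S <- collaborative_similarity(A_complete, "receptors", method)
  sp <- receptor_species(A_complete)
  rows <- lapply(colnames(A_complete), function(r) {
    other <- names(sp)[sp != sp[[r]]]
    if (length(other) == 0L)
      return(data.frame(receptor = r, species = sp[[r]],
                        best_match = NA_character_,
                        best_similarity = NA_real_,
                        stringsAsFactors = FALSE))
    vals <- S[r, other]
    best <- which.max(vals)
    data.frame(receptor = r, species = sp[[r]],
               best_match = other[best],
               best_similarity = unname(vals[best]),
               stringsAsFactors = FALSE)
  })
  list(similarity = S, cross_species = do.call(rbind, rows))
}

#' Batch prediction of receptor associations for external compounds
#'
#' Scores every (compound, receptor) pair with a cold-start
#' (`new_ligands`) model: compounds contribute fingerprints and ligand
#' descriptors but no associations. Calls are positive when score >=
#' `threshold` (default 0.52). The per-receptor summary compares the
#' proportion of compounds called positive with the receptor's training
#' hit rate (known positives / known tested).
#'
#' @param compounds list with `fingerprints` (list of `fingerprint_set`s
#'   keyed `linear`, `atom_environment` covering every compound) and
#'   `descriptors` (a `descriptor_table` with the same schema as the
#'   training ligand descriptors).
#' @param model a `bitter_model` of variant `"new_ligands"`.
#' @param data training dataset list (associations, fingerprints,
#'   descriptors).
#' @param threshold batch decision threshold, default 0.52.
#' @return list with `scores` and `calls` (compound x receptor matrices)
#'   and `per_receptor` (data frame: n_calls, call_proportion, hit_rate).
#' @export
batch_predict <- function(compounds, model, data, threshold = 0.52) {
  if (model$variant != "new_ligands")
    stop("batch prediction requires a 'new_ligands' variant model")
  A <- data$associations
  comp_ids <- compounds$descriptors$id
  if (length(comp_ids) == 0L) {
    empty <- matrix(numeric(0), 0L, ncol(A),
                    dimnames = list(NULL, colnames(A)))
    return(list(scores = empty, calls = empty,
                per_receptor = data.frame()))
  }
  clash <- intersect(comp_ids, rownames(A))
  if (length(clash))
    stop("compound identifier(s) collide with training ligands: ",
         paste(clash, collapse = ", "))
  for (kind in c("linear", "atom_environment")) {
    fps <- compounds$fingerprints[[kind]]
    missing_fp <- setdiff(comp_ids, names(fps$bits))
    if (length(missing_fp))
      stop("compound(s) without ", kind, " fingerprints: ",
           paste(missing_fp, collapse = ", "))
  }
  merge_fps <- function(kind) {
    fingerprint_set(c(data$fingerprints[[kind]]$bits,
                      compounds$fingerprints[[kind]]$bits[comp_ids]),
                    kind = data$fingerprints[[kind]]$kind)
  }
  sims <- list(tanimoto_matrix(merge_fps("linear")),
               tanimoto_matrix(merge_fps("atom_environment")))
  lig_desc <- descriptor_table(rbind(data$ligand_descriptors,
                                     compounds$descriptors))
  targets <- expand.grid(ligand = comp_ids, receptor = colnames(A),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- prediction_design(A, lig_desc, data$receptor_descriptors,
                              sims, "new_ligands", targets)
  scores <- predict_scores(model, design)
  score_m <- matrix(scores, nrow = length(comp_ids),
                    dimnames = list(comp_ids, colnames(A)))
  calls <- (score_m >= threshold) * 1L
  s <- association_summary(A)
  per_receptor <- data.frame(
    receptor = colnames(A),
    n_calls = colSums(calls),
    call_proportion = colSums(calls) / length(comp_ids),
    hit_rate = s$per_receptor$n_positive /
      pmax(s$per_receptor$n_known, 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(scores = score_m, calls = calls, per_receptor = per_receptor)
}

#' Write an evaluation report as canonical JSON
#'
#' The serialization contains no timestamps or absolute paths, so two runs
#' with an identical configuration produce byte-identical files.
#'
#' @param report a report list from [run_filling_gaps()] /
#'   [run_new_ligands()].
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", null = "null",
                       matrix = "rowmajor")
  invisible(path)
}
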