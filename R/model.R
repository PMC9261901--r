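#' Hyperparameters for the boosted-tree classifier
#'
#' Only the tree count (1000) and the binary logistic objective are fixed
#' by design; the remaining learner settings keep this package's
#' documented defaults -- the conservative classical gradient-boosting
#' values (shrinkage 0.1, depth-3 trees, L2 regularization 1, minimum
#' child hessian weight 1), appropriate for training sets of a few hundred
#' to a few thousand pairs -- and are frozen into every fitted model for
#' reproducibility. No hyperparameter is ever tuned on the data.
#'
#' @param nrounds number of boosting rounds (trees), >= 1.
#' @param eta learning rate (shrinkage) in (0, 1].
#' @param max_depth maximum tree depth.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum sum of hessians in a child.
#' @param objective objective name; only `"binary:logistic"` is supported.
#' @return a `hyperparameters` list.
#' @export
hyperparameters <- function(nrounds = 1000L, eta = 0.1, max_depth = 3L,
                            lambda = 1, min_child_weight = 1,
                            objective = "binary:logistic") {
  if (nrounds < 1L) stop("`nrounds` must be >= 1")
  if (objective != "binary:logistic")
    stop("only the binary logistic objective is supported")
  structure(list(nrounds = as.integer(nrounds), eta = as.numeric(eta),
                 max_depth = as.integer(max_depth),
                 lambda = as.numeric(lambda),
                 min_child_weight = as.numeric(min_child_weight),
                 objective = objective),
            class = "hyperparameters")
}

#' Fit the gradient-boosted association classifier
#'
#' Trains a boosted ensemble of decision trees with the binary logistic
#' objective on a labeled [pair feature matrix][build_design()]. Missing
#' feature values are handled natively: each split learns a default
#' direction for missing values from the training gradients. Training is
#' deterministic given the data (there is no row or column subsampling);
#' `seed` is recorded in the model for provenance.
#'
#' @param train a labeled `pair_feature_matrix`.
#' @param hp a [hyperparameters()] record.
#' @param seed integer seed recorded in the model.
#' @param threshold default decision threshold stored with the model
#'   (calls are positive when score >= threshold).
#' @return a `bitter_model`.
#' @export
fit_association_model <- function(train, hp = hyperparameters(), seed = 1L,
                                  threshold = 0.5) {
  if (is.null(train$y)) stop("training matrix carries no labels")
  y <- as.numeric(train$y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; need both positives and negatives")
  fit <- .gbt_train_cpp(train$x, y, hp$nrounds, hp$eta, hp$max_depth,
                        hp$lambda, hp$min_child_weight, 0.0)
  structure(list(booster = fit, schema = train$schema,
                 variant = train$variant, hyperparameters = hp,
                 seed = as.integer(seed), threshold = threshold),
            class = "bitter_model")
}

#' @export
print.bitter_model <- function(x, ...) {
  cat(sprintf("bitter_model [%s]: %d trees, %d features, threshold %.2f\n",
              x$variant, x$hyperparameters$nrounds, length(x$schema),
              x$threshold))
  invisible(x)
}

#' Predict association scores for ligand-receptor pairs
#'
#' @param model a `bitter_model`.
#' @param X a `pair_feature_matrix` whose schema matches the model's.
#' @return numeric score in (0, 1) per pair.
#' @export
predict_scores <- function(model, X) {
  if (!identical(model$schema, X$schema)) {
    diff <- c(setdiff(model$schema, X$schema), setdiff(X$schema, model$schema))
    stop("feature schema mismatch; differing columns: ",
         paste(unique(diff), collapse = ", "))
  }
  if (nrow(X$x) == 0L) return(numeric(0))
  margin <- .gbt_margin_cpp(model$booster$trees, X$x,
                            model$booster$base_margin)
  stats::plogis(margin)
}

#' @export
predict.bitter_model <- function(object, newdata, ...)
  predict_scores(object, newdata)

#' Per-feature importance as average gain across splits
#'
#' The importance of a feature is the average regularized gain over all
#' tree splits that use it; features never used in a split have gain 0.
#'
#' @param model a `bitter_model`.
#' @return data frame with `feature`, `average_gain`, `n_splits`, sorted by
#'   decreasing gain.
#' @export
feature_importance <- function(model) {
  tg <- model$booster$total_gain
  sc <- model$booster$split_count
  avg <- ifelse(sc > 0, tg / sc, 0)
  out <- data.frame(feature = model$schema, average_gain = avg,
                    n_splits = as.integer(sc), stringsAsFactors = FALSE)
  out[order(-out$average_gain, out$feature), , drop = FALSE]
}

#' Prior baseline: per-receptor positive proportion
#'
#' The naive baseline scores every ligand at receptor `r` with the same
#' value: the proportion of known training associations of `r` that are
#' positive.
#'
#' @param A_train_view an `assoc_matrix` holding only the training view
#'   (test pairs masked).
#' @return named numeric vector over receptors.
#' @export
prior_baseline <- function(A_train_view) {
  known <- colSums(!is.na(A_train_view))
  if (any(known == 0L))
    stop("receptor(s) with zero known training associations: ",
         paste(colnames(A_train_view)[known == 0L], collapse = ", "))
  pos <- colSums(!is.na(A_train_view) & A_train_view == 1L)
  pos / known
}

#' Nearest-neighbor baseline (cold start)
#'
#' Predicts the association of a pair `(l, r)` as the known association of
#' the ligand most similar to `l` among those whose association with `r` is
#' known and whose similarity to `l` is defined. Ties are broken by the
#' smallest ligand index (row order of the similarity matrix). Pairs with
#' no eligible neighbor receive `NA`.
#'
#' @param A_train_view an `assoc_matrix` (training view).
#' @param S ligand `sim_matrix`.
#' @param pairs data frame with columns `ligand`, `receptor`.
#' @return numeric vector of predictions in `{0, 1, NA}` per pair.
#' @export
nearest_neighbor_baseline <- function(A_train_view, S, pairs) {
  pairs <- .as_pairs(pairs)
  Sm <- unclass(S)
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    l <- pairs$ligand[k]
    r <- pairs$receptor[k]
    if (!(r %in% colnames(A_train_view)))
      stop("unknown receptor identifier: ", r)
    if (!(l %in% rownames(Sm)))
      stop("ligand absent from the similarity matrix: ", l)
    col <- A_train_view[, r]
    elig <- names(col)[!is.na(col)]
    elig <- setdiff(elig, l)                    # self never its own neighbor
    sims <- Sm[l, elig]
    elig <- elig[!is.na(sims)]
    sims <- sims[!is.na(sims)]
    if (length(elig) == 0L) {
      out[k] <- NA_real_
    } else {
      # ties by smallest row index of the similarity matrix
      ord <- order(-sims, match(elig, rownames(Sm)))
      out[k] <- as.numeric(A_train_view[elig[ord[1L]], r])
    }
  }
  out
}

#' Save / load a fitted model as a directory of plain-text files
#'
#' The bundle holds the tree ensemble (JSON) and a metadata file (schema,
#' variant, hyperparameters, seed, threshold). Loading round-trips to an
#' identical predictor.
#'
#' @param model a `bitter_model`.
#' @param dir directory path (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(schema = model$schema, variant = model$variant,
         hyperparameters = unclass(model$hyperparameters),
         seed = model$seed, threshold = model$threshold,
         base_margin = model$booster$base_margin,
         total_gain = model$booster$total_gain,
         split_count = model$booster$split_count),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(model$booster$trees, function(t)
    as.data.frame(t)), file.path(dir, "trees.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  trees <- jsonlite::fromJSON(file.path(dir, "trees.json"),
                              simplifyDataFrame = TRUE)
  trees <- lapply(trees, function(df) {
    m <- as.matrix(df)
    colnames(m) <- c("feature", "threshold", "default_left", "left",
                     "right", "value", "gain")
    m
  })
  hp <- do.call(hyperparameters, meta$hyperparameters)
  structure(list(booster = list(trees = trees,
                                total_gain = meta$total_gain,
                                split_count = meta$split_count,
                                base_margin = meta$base_margin),
                 schema = meta$schema, variant = meta$variant,
                 hyperparameters = hp, seed = meta$seed,
                 threshold = meta$threshold),
            class = "bitter_model")
}
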