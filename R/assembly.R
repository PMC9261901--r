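#' Descriptor tables
#'
#' A descriptor table holds named chemical descriptors per ligand or
#' receptor. Values are numeric (missing allowed; the boosted-tree learner
#' consumes them natively, no imputation is performed). Non-numeric columns
#' (e.g. receptor organism or chromosome) are kept and later encoded as
#' integer codes with a persisted level mapping.
#'
#' @param df data frame whose first column (or the column named by
#'   `id_col`) holds unique entity identifiers; remaining columns are
#'   descriptors.
#' @param id_col name of the identifier column, default `"id"`.
#' @return a `descriptor_table` (data frame with the id column first).
#' @export
descriptor_table <- function(df, id_col = "id") {
  if (!id_col %in% names(df)) stop("missing identifier column '", id_col, "'")
  ids <- as.character(df[[id_col]])
  .check_unique(ids, "entity")
  desc <- df[setdiff(names(df), id_col)]
  if (ncol(desc) < 1L) stop("descriptor table needs at least one descriptor")
  .check_unique(names(desc), "descriptor column")
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), desc)
  class(out) <- c("descriptor_table", "data.frame")
  out
}

# integer-code all non-numeric descriptor columns; mapping attached as
# attribute "levels" (sorted unique values per column) for persistence
.encode_categoricals <- function(desc) {
  levels_map <- list()
  for (col in setdiff(names(desc), "id")) {
    if (!is.numeric(desc[[col]])) {
      lv <- sort(unique(as.character(desc[[col]])))
      levels_map[[col]] <- lv
      desc[[col]] <- match(as.character(desc[[col]]), lv)
    }
  }
  attr(desc, "levels") <- levels_map
  desc
}

# round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Seeded train/test split of an association matrix
#'
#' In the *filling-the-gaps* scenario, known pairs are split per receptor in
#' a balanced manner: within each receptor, a fraction `rho` of its positives
#' and `rho` of its negatives (rounded half away from zero) go to the
#' training set, the rest to the test set. A class with a single example for
#' a receptor always goes to training (a class never seen in training would
#' make its neighbor features degenerate). In the *new-ligands* (cold start)
#' scenario, `rho` of the ligands are sampled into training; all known pairs
#' of the held-out ligands form the test set.
#'
#' @param A an `assoc_matrix` (gaps-ready for `"filling_gaps"`).
#' @param scenario `"filling_gaps"` or `"new_ligands"`.
#' @param rho training fraction in (0, 1), default 0.8.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param repetition optional repetition index recorded in the plan.
#' @return a `split_plan`: list with `scenario`, `rho`, `seed`,
#'   `repetition`, `train` and `test` (pair data frames with `ligand`,
#'   `receptor`, `label`), and for new-ligands also `test_ligands`.
#' @export
make_split <- function(A, scenario = c("filling_gaps", "new_ligands"),
                       rho = 0.8, seed = 1L, repetition = NA_integer_) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  if (!(rho > 0 && rho < 1)) stop("`rho` must be in (0, 1)")
  kp <- known_pairs(A)
  if (scenario == "filling_gaps") {
    s <- association_summary(A)
    empty <- s$per_receptor$receptor[s$per_receptor$n_known == 0L]
    if (length(empty))
      stop("receptor(s) with zero known associations: ",
           paste(empty, collapse = ", "))
    train_idx <- .with_seed(seed, {
      idx <- integer(0)
      for (r in colnames(A)) {
        for (cls in c(1L, 0L)) {
          rows <- which(kp$receptor == r & kp$label == cls)
          n <- length(rows)
          if (n == 0L) next
          n_tr <- if (n == 1L) 1L else min(n, .round_half_up(rho * n))
          idx <- c(idx, if (n_tr == n) rows else sample(rows, n_tr))
        }
      }
      idx
    })
    train <- kp[sort(train_idx), , drop = FALSE]
    test <- kp[setdiff(seq_len(nrow(kp)), train_idx), , drop = FALSE]
    test_ligands <- NULL
  } else {
    ligands <- rownames(A)
    if (length(ligands) < 5L) stop("new-ligands splits need at least 5 ligands")
    n_tr <- .round_half_up(rho * length(ligands))
    if (n_tr >= length(ligands) || n_tr < 1L)
      stop("`rho` leaves no test (or no train) ligands")
    train_ligands <- .with_seed(seed, sample(ligands, n_tr))
    test_ligands <- setdiff(ligands, train_ligands)
    train <- kp[kp$ligand %in% train_ligands, , drop = FALSE]
    test <- kp[kp$ligand %in% test_ligands, , drop = FALSE]
  }
  rownames(train) <- rownames(test) <- NULL
  structure(list(scenario = scenario, rho = rho, seed = seed,
                 repetition = repetition, train = train, test = test,
                 test_ligands = test_ligands),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan [%s]: seed %d, rho %.2f, %d train / %d test pairs\n",
              x$scenario, x$seed, x$rho, nrow(x$train), nrow(x$test)))
  invisible(x)
}

#' Serialize / load a split plan as JSON
#' @param split a `split_plan`.
#' @param path file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE,
                       dataframe = "columns", null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$train <- as.data.frame(x$train, stringsAsFactors = FALSE)
  x$test <- as.data.frame(x$test, stringsAsFactors = FALSE)
  x$repetition <- if (is.null(x$repetition)) NA_integer_ else x$repetition
  structure(x, class = "split_plan")
}

.variants <- c("model1", "model2", "model3", "model4", "new_ligands")

# similarity kinds each model variant consumes for neighbor features;
# collaborative kinds are always derived internally from the masked view
.variant_kinds <- list(
  model1 = character(0),
  model2 = c("ligand_collab", "receptor_collab"),
  model3 = c("ligand_linear_fp", "ligand_atom_env_fp",
             "receptor_seq_identity", "receptor_seq_blosum",
             "receptor_site_identity", "receptor_site_blosum"),
  model4 = c("ligand_linear_fp", "ligand_atom_env_fp", "ligand_collab",
             "receptor_collab", "receptor_seq_identity",
             "receptor_seq_blosum", "receptor_site_identity",
             "receptor_site_blosum"),
  new_ligands = c("ligand_linear_fp", "ligand_atom_env_fp"))

# resolve the similarity inputs a variant needs; collaborative kinds are
# marked for pair-adjusted computation from the masked view
.collect_variant_sims <- function(similarities, variant) {
  needed <- .variant_kinds[[variant]]
  have <- vapply(similarities, similarity_kind, character(1))
  sims <- list()
  for (k in needed) {
    if (k %in% c("ligand_collab", "receptor_collab")) {
      sims[[k]] <- "collab"
    } else {
      hit <- which(have == k)
      if (length(hit) == 0L)
        stop(sprintf("variant '%s' requires a similarity of kind '%s'",
                     variant, k))
      sims[[k]] <- similarities[[hit[1L]]]
    }
  }
  sims[order(match(names(sims), .sim_kinds))]
}

.pair_feature_matrix <- function(pairs, X, y, variant) {
  structure(list(pairs = pairs[c("ligand", "receptor")], x = X, y = y,
                 variant = variant, schema = colnames(X)),
            class = "pair_feature_matrix")
}

#' @export
print.pair_feature_matrix <- function(x, ...) {
  cat(sprintf("pair_feature_matrix [%s]: %d pairs x %d features%s\n",
              x$variant, nrow(x$x), ncol(x$x),
              if (is.null(x$y)) " (unlabeled)" else ""))
  invisible(x)
}

.descriptor_features <- function(desc, ids, prefix, what) {
  missing_ids <- setdiff(ids, desc$id)
  if (length(missing_ids))
    stop(sprintf("%s descriptor table is missing: %s", what,
                 paste(missing_ids, collapse = ", ")))
  desc <- .encode_categoricals(desc)
  m <- as.matrix(desc[match(ids, desc$id), setdiff(names(desc), "id"),
                      drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- paste0(prefix, "__", colnames(m))
  rownames(m) <- NULL
  m
}

.assemble_rows <- function(A_view, pairs, ligand_descriptors,
                           receptor_descriptors, sims, variant,
                           collab_method = "matching") {
  Xl <- .descriptor_features(ligand_descriptors, pairs$ligand, "lig", "ligand")
  Xr <- .descriptor_features(receptor_descriptors, pairs$receptor, "rec",
                             "receptor")
  X <- cbind(Xl, Xr)
  li <- match(pairs$ligand, rownames(A_view))
  ri <- match(pairs$receptor, colnames(A_view))
  for (k in names(sims)) {
    axis <- if (k %in% .ligand_kinds) "ligands" else "receptors"
    blk <- if (identical(sims[[k]], "collab"))
      collaborative_neighbor_features(A_view, axis, collab_method)
    else
      neighbor_feature_block(A_view, sims[[k]], axis)
    for (f in c("m1", "w1", "m0", "w0")) {
      col <- matrix(blk[[f]][cbind(li, ri)], ncol = 1,
                    dimnames = list(NULL, paste0(k, "__", toupper(f))))
      X <- cbind(X, col)
    }
  }
  X
}

#' Build leakage-safe train/test design matrices for a model variant
#'
#' Collaborative similarities and all neighbor-informed features are
#' computed on a view of the association matrix with every test pair masked
#' to `NA`, so no test label can reach a training feature. Fingerprint and
#' sequence similarity matrices are pure functions of chemistry/sequence
#' and are used as supplied. Train and test matrices share one schema:
#' ligand descriptors, receptor descriptors, then 4 neighbor features per
#' similarity kind in canonical order.
#'
#' @param A an `assoc_matrix`.
#' @param split a `split_plan` from [make_split()].
#' @param ligand_descriptors,receptor_descriptors `descriptor_table`s
#'   covering every entity of `A`.
#' @param similarities list of precomputed `sim_matrix` objects
#'   (fingerprint and sequence kinds; collaborative kinds are derived
#'   internally from the masked view).
#' @param variant one of `"model1"`, `"model2"`, `"model3"`, `"model4"`,
#'   `"new_ligands"`.
#' @param collab_method passed to [collaborative_similarity()].
#' @return list with `train` and `test` `pair_feature_matrix` objects.
#' @export
build_design <- function(A, split, ligand_descriptors, receptor_descriptors,
                         similarities = list(), variant = "model4",
                         collab_method = "matching") {
  variant <- match.arg(variant, .variants)
  A_view <- mask_entries(A, split$test)
  sims <- .collect_variant_sims(similarities, variant)
  all_pairs <- rbind(split$train, split$test)
  X <- .assemble_rows(A_view, all_pairs, ligand_descriptors,
                      receptor_descriptors, sims, variant, collab_method)
  n_tr <- nrow(split$train)
  idx_tr <- seq_len(n_tr)
  idx_te <- setdiff(seq_len(nrow(all_pairs)), idx_tr)
  list(train = .pair_feature_matrix(split$train,
                                    X[idx_tr, , drop = FALSE],
                                    split$train$label, variant),
       test = .pair_feature_matrix(split$test,
                                   X[idx_te, , drop = FALSE],
                                   split$test$label, variant))
}

#' Build an unlabeled design matrix for prediction
#'
#' Features are computed on the full known association matrix (there is
#' nothing to leak at prediction time). For filling-the-gaps variants the
#' default targets are exactly the unknown cells of `A`. For the
#' new-ligands variant, `target_pairs` may reference ligands absent from
#' `A` (cold start); they contribute no associations and only require
#' fingerprint similarities and descriptors.
#'
#' @inheritParams build_design
#' @param target_pairs data frame with columns `ligand`, `receptor`;
#'   defaults to [unknown_pairs()] of `A`.
#' @return an unlabeled `pair_feature_matrix`.
#' @export
prediction_design <- function(A, ligand_descriptors, receptor_descriptors,
                              similarities = list(), variant = "model4",
                              target_pairs = NULL,
                              collab_method = "matching") {
  variant <- match.arg(variant, .variants)
  if (is.null(target_pairs)) target_pairs <- unknown_pairs(A)
  target_pairs <- .as_pairs(target_pairs)
  new_ligands <- setdiff(target_pairs$ligand, rownames(A))
  if (length(new_ligands)) {
    if (variant != "new_ligands")
      stop("ligands absent from the association matrix require the ",
           "'new_ligands' variant: ", paste(new_ligands, collapse = ", "))
    pad <- matrix(NA_integer_, length(new_ligands), ncol(A),
                  dimnames = list(new_ligands, colnames(A)))
    A <- association_matrix(rbind(unclass(A), pad),
                            species = receptor_species(A))
  }
  if (!all(target_pairs$receptor %in% colnames(A)))
    stop("unknown receptor identifier(s): ",
         paste(setdiff(target_pairs$receptor, colnames(A)), collapse = ", "))
  sims <- .collect_variant_sims(similarities, variant)
  X <- .assemble_rows(A, target_pairs, ligand_descriptors,
                      receptor_descriptors, sims, variant, collab_method)
  .pair_feature_matrix(target_pairs, X, NULL, variant)
}
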