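#' Neighbor-informed features from a similarity matrix
#'
#' For a ligand-receptor pair and a ligand similarity matrix `S`, four
#' features summarize the known associations in the ligand's neighborhood:
#'
#' * `M1`: similarity to the closest other ligand known to activate the
#'   receptor (max over positive neighbors),
#' * `W1`: sum of similarities to all other ligands known to activate it,
#' * `M0` / `W0`: the same over ligands known *not* to activate it.
#'
#' The receptor-side features swap the roles (closest other receptor
#' activated / not activated by the ligand). The entity itself is always
#' excluded from its own neighbor pool (`S[l,l] = 1` would otherwise leak
#' the pair's own label), undefined similarity entries are skipped, and an
#' empty neighbor pool yields `NA` rather than 0, which the boosted-tree
#' learner handles natively.
#'
#' `neighbor_feature_block()` computes all four features for every cell of
#' the association view at once, returning four L-by-R (matrices over the
#' view's ligands and receptors).
#'
#' @param A_view an `assoc_matrix`: the association view the features may
#'   legally see (test pairs already masked).
#' @param S a `sim_matrix` whose kind matches `axis`.
#' @param axis `"ligands"` (features from ligand-to-ligand similarity, Mx/Wx
#'   vary per receptor column) or `"receptors"`.
#' @return a list of four matrices `m1`, `w1`, `m0`, `w0`, each with the
#'   dimensions and dimnames of `A_view`.
#' @export
neighbor_feature_block <- function(A_view, S,
                                   axis = c("ligands", "receptors")) {
  axis <- match.arg(axis)
  M <- unclass(A_view)
  if (axis == "receptors") M <- t(M)
  ids <- rownames(M)
  if (!all(ids %in% rownames(S)))
    stop("similarity matrix is missing entities: ",
         paste(setdiff(ids, rownames(S)), collapse = ", "))
  Sm <- unclass(S)[ids, ids, drop = FALSE]
  diag(Sm) <- NA_real_                      # self-exclusion
  defined <- !is.na(Sm)
  S0 <- ifelse(defined, Sm, 0)
  out <- list()
  for (cls in c(1L, 0L)) {
    Ind <- (!is.na(M) & M == cls) * 1       # n x p indicator of class members
    w_sum <- S0 %*% Ind
    n_def <- (defined * 1) %*% Ind          # defined similarities to members
    w <- ifelse(n_def > 0, w_sum, NA_real_)
    m <- matrix(NA_real_, nrow(M), ncol(M))
    for (j in seq_len(ncol(M))) {
      members <- which(Ind[, j] > 0)
      if (length(members) == 0L) next
      sub <- Sm[, members, drop = FALSE]
      mx <- matrixStats::rowMaxs(sub, na.rm = TRUE)
      mx[is.infinite(mx)] <- NA_real_
      m[, j] <- mx
    }
    dimnames(w) <- dimnames(m) <- dimnames(M)
    out[[paste0("m", cls)]] <- m
    out[[paste0("w", cls)]] <- w
  }
  res <- list(m1 = out$m1, w1 = out$w1, m0 = out$m0, w0 = out$w0)
  if (axis == "receptors") res <- lapply(res, t)
  res
}

#' @describeIn neighbor_feature_block the four ligand-side features for one
#'   pair, returned as a named vector `c(M1, W1, M0, W0)`.
#' @param ligand,receptor identifiers of the pair.
#' @export
ligand_neighbor_features <- function(A_view, S, ligand, receptor) {
  .pair_features(A_view, S, ligand, receptor, "ligands")
}

#' @describeIn neighbor_feature_block the four receptor-side features for
#'   one pair.
#' @export
receptor_neighbor_features <- function(A_view, S, ligand, receptor) {
  .pair_features(A_view, S, ligand, receptor, "receptors")
}

.pair_features <- function(A_view, S, ligand, receptor, axis) {
  if (!(ligand %in% rownames(A_view)))
    stop("unknown ligand identifier: ", ligand)
  if (!(receptor %in% colnames(A_view)))
    stop("unknown receptor identifier: ", receptor)
  blk <- neighbor_feature_block(A_view, S, axis)
  c(M1 = blk$m1[ligand, receptor], W1 = blk$w1[ligand, receptor],
    M0 = blk$m0[ligand, receptor], W0 = blk$w0[ligand, receptor])
}

#' Neighbor-informed feature table for a set of pairs
#'
#' Computes the four features per supplied similarity matrix for every
#' requested pair, with a deterministic column order (similarity kind in
#' the canonical kind order, then `M1, W1, M0, W0`) and the stable naming
#' scheme `{kind}__{M1|W1|M0|W0}`.
#'
#' @param A_view an `assoc_matrix` (test pairs already masked).
#' @param similarities list of `sim_matrix` objects (ligand and/or receptor
#'   kinds).
#' @param pairs data frame with columns `ligand`, `receptor`; zero rows
#'   allowed.
#' @return data frame with `ligand`, `receptor` and 4 columns per
#'   similarity matrix.
#' @export
neighbor_feature_table <- function(A_view, similarities, pairs) {
  pairs <- .as_pairs(pairs)
  kinds <- vapply(similarities, similarity_kind, character(1))
  similarities <- similarities[order(match(kinds, .sim_kinds))]
  kinds <- kinds[order(match(kinds, .sim_kinds))]
  .check_unique(kinds, "similarity kind")
  li <- match(pairs$ligand, rownames(A_view))
  ri <- match(pairs$receptor, colnames(A_view))
  if (anyNA(li) || anyNA(ri))
    stop("pairs reference identifiers absent from the association matrix")
  out <- pairs
  for (k in seq_along(similarities)) {
    S <- similarities[[k]]
    axis <- if (kinds[k] %in% .ligand_kinds) "ligands" else "receptors"
    blk <- neighbor_feature_block(A_view, S, axis)
    for (f in c("m1", "w1", "m0", "w0")) {
      col <- paste0(kinds[k], "__", toupper(f))
      out[[col]] <- blk[[f]][cbind(li, ri)]
    }
  }
  out
}

#' Leakage-consistent collaborative neighbor features
#'
#' Neighbor-informed features whose underlying similarity is itself derived
#' from the association matrix need one extra precaution: for a pair
#' `(l, r)` with a known label, that label contributes to the collaborative
#' similarity between `l` and every neighbor (they agree or disagree at
#' `r`), so a training pair's own label would leak into its own features
#' and inflate them relative to (masked) test pairs. This function
#' therefore computes, for every cell of the view, the four neighbor
#' features using a collaborative similarity from which the cell's own
#' entry has been removed (the agreement term at `r` and the co-known
#' count are decremented for that pair only). For cells whose label is
#' unknown in the view (test pairs, prediction targets) this coincides
#' exactly with features from [collaborative_similarity()] of the view.
#'
#' @param A_view an `assoc_matrix` (test pairs already masked).
#' @param axis `"ligands"` or `"receptors"`: which collaborative
#'   similarity the features derive from.
#' @param method `"matching"` (proportion of agreeing known associations)
#'   or `"jaccard"` (strict positive-class Jaccard).
#' @return list of four matrices `m1`, `w1`, `m0`, `w0` shaped like
#'   `A_view`.
#' @export
collaborative_neighbor_features <- function(A_view,
                                            axis = c("ligands", "receptors"),
                                            method = c("matching",
                                                       "jaccard")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  M <- unclass(A_view)
  if (axis == "receptors") M <- t(M)
  known <- !is.na(M)
  P <- (known & M == 1L) * 1
  Q <- (known & M == 0L) * 1
  n <- nrow(M)
  if (method == "matching") {
    agree <- tcrossprod(P) + tcrossprod(Q)
    N <- tcrossprod(known * 1)
  } else {
    inter <- tcrossprod(P)
    sizes <- rowSums(P)
    uni <- outer(sizes, sizes, `+`) - inter
  }
  m1 <- w1 <- m0 <- w0 <- matrix(NA_real_, nrow(M), ncol(M),
                                 dimnames = dimnames(M))
  for (j in seq_len(ncol(M))) {
    kcol <- known[, j] * 1
    for (cls in c(1L, 0L)) {
      nb <- which(if (cls == 1L) P[, j] == 1 else Q[, j] == 1)
      if (length(nb) == 0L) next
      if (method == "matching") {
        # remove this cell's own agreement/co-known contribution per row
        d <- if (cls == 1L) P[, j] else Q[, j]
        num <- agree[, nb, drop = FALSE] - d
        den <- N[, nb, drop = FALSE] - kcol
        s <- ifelse(den > 0, num / den, NA_real_)
      } else {
        p <- P[, j]
        num <- inter[, nb, drop = FALSE] - if (cls == 1L) p else 0
        den <- uni[, nb, drop = FALSE] - if (cls == 1L) 0 else p
        s <- ifelse(den > 0, num / den, NA_real_)
      }
      s[cbind(nb, seq_along(nb))] <- NA_real_   # self-exclusion
      n_def <- rowSums(!is.na(s))
      wv <- ifelse(n_def > 0, rowSums(s, na.rm = TRUE), NA_real_)
      mv <- suppressWarnings(matrixStats::rowMaxs(s, na.rm = TRUE))
      mv[is.infinite(mv)] <- NA_real_
      if (cls == 1L) { m1[, j] <- mv; w1[, j] <- wv }
      else { m0[, j] <- mv; w0[, j] <- wv }
    }
  }
  res <- list(m1 = m1, w1 = w1, m0 = m0, w0 = w0)
  if (axis == "receptors") res <- lapply(res, t)
  res
}
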