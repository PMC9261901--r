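# Independent brute-force oracles. These deliberately use naive loops and
# stay separate from the package's vectorized implementations.

bf_tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(0)
  c_ <- length(intersect(a, b))
  c_ / (length(a) + length(b) - c_)
}

# collaborative similarity between rows i and j of a ternary matrix
bf_collab_matching <- function(M, i, j) {
  both <- !is.na(M[i, ]) & !is.na(M[j, ])
  if (!any(both)) return(NA_real_)
  sum(M[i, both] == M[j, both]) / sum(both)
}

# neighbor features for pair (l, r) on the ligand axis: loop over l' != l
bf_ligand_neighbors <- function(M, S, l, r) {
  vals1 <- c(); vals0 <- c()
  for (lp in seq_len(nrow(M))) {
    if (lp == l || is.na(S[l, lp])) next
    a <- M[lp, r]
    if (is.na(a)) next
    if (a == 1) vals1 <- c(vals1, S[l, lp]) else vals0 <- c(vals0, S[l, lp])
  }
  c(M1 = if (length(vals1)) max(vals1) else NA_real_,
    W1 = if (length(vals1)) sum(vals1) else NA_real_,
    M0 = if (length(vals0)) max(vals0) else NA_real_,
    W0 = if (length(vals0)) sum(vals0) else NA_real_)
}

bf_receptor_neighbors <- function(M, S, l, r) {
  out <- bf_ligand_neighbors(t(M), S, r, l)
  out
}

# nearest-neighbor prediction, ties by smallest ligand index
bf_nearest_neighbor <- function(M, S, l, r) {
  best <- NA_integer_; best_s <- -Inf
  for (lp in seq_len(nrow(M))) {
    if (lp == l || is.na(M[lp, r]) || is.na(S[l, lp])) next
    if (S[l, lp] > best_s) { best_s <- S[l, lp]; best <- lp }
  }
  if (is.na(best)) NA_real_ else as.numeric(M[best, r])
}

# average precision by explicit threshold sweep
bf_average_precision <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    call <- scores >= t
    tp <- sum(call & labels == 1)
    fp <- sum(call & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / n_pos
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# tests-to-first-hit by explicit scan
bf_first_hit <- function(scores, labels, tie_rank) {
  ord <- order(-scores, tie_rank)
  which(labels[ord] == 1)[1L]
}

# random fixtures -----------------------------------------------------------

random_ternary <- function(L, R, p_na = 0.4, prefix = TRUE) {
  v <- sample(c(0L, 1L, NA_integer_), L * R, replace = TRUE,
              prob = c((1 - p_na) * 0.6, (1 - p_na) * 0.4, p_na))
  m <- matrix(v, L, R)
  rownames(m) <- sprintf("l%02d", seq_len(L))
  colnames(m) <- sprintf("r%02d", seq_len(R))
  m
}

random_similarity <- function(n, p_na = 0.1) {
  S <- matrix(runif(n * n), n)
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  nas <- matrix(runif(n * n) < p_na, n)
  nas[upper.tri(nas)] <- t(nas)[upper.tri(nas)]
  diag(nas) <- FALSE
  S[nas] <- NA_real_
  diag(S) <- 1
  S
}

as_assoc <- function(m) association_matrix(m)

as_sim <- function(S, kind = "ligand_linear_fp", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("l%02d", seq_len(nrow(S)))
  dimnames(S) <- list(ids, ids)
  similarity_matrix(S, kind)
}

# small labeled feature matrix for learner tests
toy_design <- function(X, y, variant = "model1") {
  pairs <- data.frame(ligand = sprintf("l%d", seq_len(nrow(X))),
                      receptor = rep("r1", nrow(X)),
                      stringsAsFactors = FALSE)
  bitterrec:::.pair_feature_matrix(pairs, X, y, variant)
}

# small gaps-ready synthetic dataset for pipeline tests
small_dataset <- function(seed = 11, L = 24L, R = 6L) {
  generate_synthetic(synthetic_spec(
    n_ligands = L, n_receptors = R, n_ligand_clusters = 3L,
    n_receptor_groups = 2L, fraction_observed = 0.6,
    fingerprint_bits = 128L, core_bits_per_cluster = 20L,
    sequence_length = 40L, n_binding_site_columns = 10L, seed = seed))
}
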