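test_that("ligand neighbor features reproduce hand-computed values", {
  # S row for l1: similarities 0.5 and 0.2 to l2, l3; receptor column
  # holds (NA, 1, 1): both neighbors positive, none negative
  S <- as_sim(rbind(c(1, 0.5, 0.2), c(0.5, 1, 0.9), c(0.2, 0.9, 1)),
              ids = c("l1", "l2", "l3"))
  m <- cbind(c(NA, 1L, 1L))
  dimnames(m) <- list(c("l1", "l2", "l3"), "r1")
  f <- ligand_neighbor_features(as_assoc(m), S, "l1", "r1")
  expect_equal(unname(f), c(0.5, 0.7, NA, NA))
  # no positive neighbor for the receptor: M1/W1 missing, M0/W0 defined
  m2 <- cbind(c(NA, 0L, 0L))
  dimnames(m2) <- dimnames(m)
  f2 <- ligand_neighbor_features(as_assoc(m2), S, "l1", "r1")
  expect_equal(unname(f2), c(NA, NA, 0.5, 0.7))
})

test_that("receptor neighbor features mirror the ligand case", {
  S <- as_sim(rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.4), c(0.1, 0.4, 1)),
              kind = "receptor_collab", ids = c("r1", "r2", "r3"))
  m <- rbind(c(NA, 0L, 1L))
  dimnames(m) <- list("l1", c("r1", "r2", "r3"))
  f <- receptor_neighbor_features(as_assoc(m), S, "l1", "r1")
  expect_equal(unname(f), c(0.1, 0.1, 0.9, 0.9))
  # ligand whose only known association is the pair itself (excluded)
  m2 <- rbind(c(1L, NA, NA))
  dimnames(m2) <- dimnames(m)
  f2 <- receptor_neighbor_features(as_assoc(m2), S, "l1", "r1")
  expect_true(all(is.na(f2)))
})

test_that("neighbor features equal a brute-force loop on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    L <- sample(3:10, 1); R <- sample(2:10, 1)
    m <- random_ternary(L, R)
    A <- as_assoc(m)
    Sl <- as_sim(random_similarity(L), "ligand_linear_fp", rownames(m))
    Sr <- as_sim(random_similarity(R), "receptor_collab", colnames(m))
    bl <- neighbor_feature_block(A, Sl, "ligands")
    br <- neighbor_feature_block(A, Sr, "receptors")
    for (k in 1:4) {
      l <- sample(L, 1); r <- sample(R, 1)
      expect_equal(c(M1 = bl$m1[l, r], W1 = bl$w1[l, r],
                     M0 = bl$m0[l, r], W0 = bl$w0[l, r]),
                   bf_ligand_neighbors(m, unclass(Sl), l, r))
      expect_equal(c(M1 = br$m1[l, r], W1 = br$w1[l, r],
                     M0 = br$m0[l, r], W0 = br$w0[l, r]),
                   bf_receptor_neighbors(m, unclass(Sr), l, r))
    }
  }
})

test_that("masking a pair equals self-exclusion with the pair present", {
  set.seed(32)
  for (rep in 1:20) {
    m <- random_ternary(6, 5, p_na = 0.3)
    A <- as_assoc(m)
    kp <- known_pairs(A)
    if (nrow(kp) == 0) next
    cell <- kp[sample(nrow(kp), 1), ]
    S <- as_sim(random_similarity(6), ids = rownames(m))
    with_self <- ligand_neighbor_features(A, S, cell$ligand, cell$receptor)
    masked <- ligand_neighbor_features(
      mask_entries(A, cell[c("ligand", "receptor")]), S,
      cell$ligand, cell$receptor)
    expect_identical(with_self, masked)
  }
})

test_that("adding a positive neighbor can only raise W1 and M1", {
  set.seed(33)
  m <- random_ternary(6, 4, p_na = 0.3)
  m[3, 1] <- NA_integer_            # guarantee an unknown candidate cell
  S <- as_sim(random_similarity(6, p_na = 0), ids = rownames(m))
  r <- "r01"
  before <- ligand_neighbor_features(as_assoc(m), S, "l01", r)
  m2 <- m
  m2[3, r] <- 1L
  after <- ligand_neighbor_features(as_assoc(m2), S, "l01", r)
  expect_gte(after[["W1"]], ifelse(is.na(before[["W1"]]), 0, before[["W1"]]))
  expect_gte(after[["M1"]], ifelse(is.na(before[["M1"]]), 0, before[["M1"]]))
})

test_that("feature tables have 4 deterministic columns per similarity", {
  set.seed(34)
  m <- random_ternary(5, 4)
  A <- as_assoc(m)
  lig_sims <- list(
    as_sim(random_similarity(5), "ligand_linear_fp", rownames(m)),
    as_sim(random_similarity(5), "ligand_atom_env_fp", rownames(m)),
    as_sim(random_similarity(5), "ligand_collab", rownames(m)))
  rec_sims <- lapply(c("receptor_collab", "receptor_seq_identity",
                       "receptor_seq_blosum", "receptor_site_identity",
                       "receptor_site_blosum"), function(k)
    as_sim(random_similarity(4), k, colnames(m)))
  kp <- known_pairs(A)[c("ligand", "receptor")]
  t3 <- neighbor_feature_table(A, lig_sims, kp)
  expect_identical(ncol(t3), 2L + 12L)   # 4 features x 3 ligand similarities
  t5 <- neighbor_feature_table(A, rec_sims, kp)
  expect_identical(ncol(t5), 2L + 20L)   # 4 features x 5 receptor similarities
  # canonical ordering and naming scheme, independent of input order
  t3b <- neighbor_feature_table(A, rev(lig_sims), kp)
  expect_identical(names(t3b), names(t3))
  expect_match(names(t3)[3], "^ligand_linear_fp__M1$")
  # zero pairs keep the full schema
  t0 <- neighbor_feature_table(A, lig_sims, kp[0, ])
  expect_identical(names(t0), names(t3))
  expect_identical(nrow(t0), 0L)
})

test_that("pair-adjusted collaborative features match a leave-cell-out oracle", {
  set.seed(35)
  for (rep in 1:20) {
    m <- random_ternary(7, 5, p_na = 0.35)
    A <- as_assoc(m)
    blk <- collaborative_neighbor_features(A, "ligands")
    l <- sample(7, 1); r <- sample(5, 1)
    # oracle: recompute the collaborative similarity with cell (l, r)
    # removed, then run the brute-force neighbor loop
    m_loo <- m
    m_loo[l, r] <- NA_integer_
    S_loo <- matrix(NA_real_, 7, 7)
    for (lp in 1:7) S_loo[l, lp] <- bf_collab_matching(m_loo, l, lp)
    S_loo[, l] <- S_loo[l, ]
    want <- bf_ligand_neighbors(m, S_loo, l, r)
    got <- c(M1 = blk$m1[l, r], W1 = blk$w1[l, r],
             M0 = blk$m0[l, r], W0 = blk$w0[l, r])
    expect_equal(got, want)
  }
})

test_that("collaborative features at unknown cells equal the plain view", {
  set.seed(36)
  m <- random_ternary(6, 5, p_na = 0.4)
  A <- as_assoc(m)
  blk <- collaborative_neighbor_features(A, "ligands")
  S <- collaborative_similarity(A, "ligands")
  ref <- neighbor_feature_block(A, S, "ligands")
  na_cells <- which(is.na(m), arr.ind = TRUE)
  for (f in c("m1", "w1", "m0", "w0"))
    expect_equal(blk[[f]][na_cells], ref[[f]][na_cells])
})
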