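test_that("Tanimoto similarity matches the set formula", {
  fps <- fingerprint_set(list(a = 1:4, b = 3:8, c = 1:4, d = integer(0),
                              e = integer(0)))
  S <- tanimoto_matrix(fps)
  expect_equal(S["a", "b"], 2 / 8)    # c=2, a=4, b=6
  expect_equal(S["a", "c"], 1)        # identical non-empty
  expect_equal(S["d", "e"], 0)        # two empty fingerprints
  expect_equal(S["a", "d"], 0)
  expect_true(all(diag(S) == 1))
})

test_that("Tanimoto matrix equals a brute-force loop on random fingerprints", {
  set.seed(21)
  bits <- lapply(1:20, function(i) which(runif(64) < 0.3))
  names(bits) <- sprintf("m%02d", 1:20)
  S <- tanimoto_matrix(fingerprint_set(bits))
  for (i in 1:20) for (j in 1:20)
    expect_equal(S[i, j], if (i == j) 1 else bf_tanimoto(bits[[i]], bits[[j]]))
})

test_that("collaborative similarity implements the matching proportion", {
  m <- rbind(c(1L, 0L, NA), c(1L, 1L, 0L), c(NA, NA, 1L))
  dimnames(m) <- list(c("a", "b", "c"), c("r1", "r2", "r3"))
  S <- collaborative_similarity(as_assoc(m), "ligands")
  expect_equal(S["a", "b"], 0.5)          # co-known r1,r2; match on r1 only
  expect_true(is.na(S["a", "c"]))         # disjoint known receptors
  expect_equal(S["a", "a"], 1)
  # identical fully-known rows
  m2 <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L))
  dimnames(m2) <- list(c("a", "b"), c("r1", "r2", "r3"))
  expect_equal(collaborative_similarity(as_assoc(m2), "ligands")["a", "b"], 1)
})

test_that("receptor-axis collaborative similarity is the transpose analogue", {
  set.seed(22)
  m <- random_ternary(6, 5)
  S_rec <- collaborative_similarity(as_assoc(m), "receptors")
  for (i in 1:5) for (j in 1:5)
    expect_equal(S_rec[i, j], bf_collab_matching(t(m), i, j))
  expect_identical(similarity_kind(S_rec), "receptor_collab")
})

test_that("collaborative similarity is invariant to partner permutation", {
  set.seed(23)
  m <- random_ternary(6, 5)
  S1 <- collaborative_similarity(as_assoc(m), "ligands")
  S2 <- collaborative_similarity(as_assoc(m[, sample(5)]), "ligands")
  expect_equal(unclass(S1), unclass(S2))
})

test_that("masking only perturbs collaborative entries touching the cell", {
  set.seed(24)
  m <- random_ternary(7, 5, p_na = 0.2)
  A <- as_assoc(m)
  kp <- known_pairs(A)
  cell <- kp[1, ]
  S0 <- collaborative_similarity(A, "ligands")
  S1 <- collaborative_similarity(
    mask_entries(A, cell[c("ligand", "receptor")]), "ligands")
  li <- match(cell$ligand, rownames(m))
  untouched <- setdiff(seq_len(nrow(m)), li)
  expect_equal(S0[untouched, untouched], S1[untouched, untouched])
})

test_that("sequence identity counts identical both-non-gap columns", {
  aln <- aligned_sequences(c(x = "ACDE", y = "ACDF", z = "AC-E"))
  S <- sequence_identity_matrix(aln)
  expect_equal(S["x", "y"], 0.75)
  expect_equal(S["x", "z"], 1)        # overlap columns 1,2,4 all identical
  expect_equal(S["x", "x"], 1)
  # all-gap overlap is undefined
  aln2 <- aligned_sequences(c(x = "AC--", y = "--DE"))
  expect_true(is.na(sequence_identity_matrix(aln2)["x", "y"]))
})

test_that("column subsets restrict the identity computation", {
  aln <- aligned_sequences(c(x = "ACDE", y = "ACDF"),
                           binding_site_columns = c(1, 4))
  S <- sequence_identity_matrix(aln, columns = aln$binding_site_columns)
  expect_equal(S["x", "y"], 0.5)
  expect_identical(similarity_kind(S), "receptor_site_identity")
})

test_that("BLOSUM62 similarity counts positive-scoring columns", {
  # I/L scores +2 (> 0) at both columns; K/D scores -1 at both
  S1 <- blosum_similarity_matrix(aligned_sequences(c(x = "IL", y = "LI")))
  expect_equal(S1["x", "y"], 1)
  S2 <- blosum_similarity_matrix(aligned_sequences(c(x = "KD", y = "DK")))
  expect_equal(S2["x", "y"], 0)
  S3 <- blosum_similarity_matrix(aligned_sequences(c(x = "ACDE", y = "ACDE")))
  expect_equal(S3["x", "y"], 1)
  expect_error(
    blosum_similarity_matrix(aligned_sequences(c(x = "A1", y = "AA"))),
    "unknown residue")
})

test_that("BLOSUM similarity dominates identity on the same column set", {
  set.seed(25)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(1:6, function(i)
    paste(sample(aa, 30, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("s%d", 1:6)
  aln <- aligned_sequences(seqs)
  Si <- sequence_identity_matrix(aln)
  Sb <- blosum_similarity_matrix(aln)
  expect_true(all(Sb >= Si - 1e-12))
})

test_that("similarity matrices validate symmetry, range and identifiers", {
  expect_error(similarity_matrix(matrix(c(1, 0.5, 0.2, 1), 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b"))),
                                 "ligand_collab"),
               "symmetric")
  expect_error(similarity_matrix(matrix(2, 1, 1, dimnames = list("a", "a")),
                                 "ligand_collab"),
               "\\[0, 1\\]")
})

test_that("fingerprint and similarity files round-trip", {
  set.seed(26)
  fps <- fingerprint_set(list(a = c(3L, 9L), b = integer(0), c = 1:5),
                         kind = "atom_environment")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, path)
  fps2 <- read_fingerprints(path)
  expect_identical(fps2$bits, fps$bits)
  expect_identical(fps2$kind, "atom_environment")
  S <- as_sim(random_similarity(4), "receptor_seq_blosum",
              sprintf("r%d", 1:4))
  sp <- withr::local_tempfile(fileext = ".csv")
  write_similarity(S, sp)
  S2 <- read_similarity(sp)
  expect_equal(unclass(S2), unclass(S))
  expect_identical(similarity_kind(S2), "receptor_seq_blosum")
})

test_that("alignment FASTA and binding-site JSON round-trip", {
  aln <- aligned_sequences(c(r1 = "ACDE-", r2 = "ACDFG"),
                           binding_site_columns = c(2, 5))
  fa <- withr::local_tempfile(fileext = ".fasta")
  js <- withr::local_tempfile(fileext = ".json")
  write_alignment(aln, fa, js)
  back <- read_alignment(fa, js)
  expect_identical(back$sequences, aln$sequences)
  expect_identical(back$binding_site_columns, c(2L, 5L))
})
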