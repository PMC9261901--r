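test_that("balanced splits follow the per-receptor rounding rules", {
  # receptor r1: 5 positives + 5 negatives -> 4 + 4 train at rho = 0.8
  m <- matrix(NA_integer_, 10, 2,
              dimnames = list(sprintf("l%02d", 1:10), c("r1", "r2")))
  m[1:5, "r1"] <- 1L
  m[6:10, "r1"] <- 0L
  m[1, "r2"] <- 1L          # single positive -> always train
  m[2:4, "r2"] <- 0L
  A <- as_assoc(m)
  sp <- make_split(A, "filling_gaps", rho = 0.8, seed = 1)
  tr1 <- sp$train[sp$train$receptor == "r1", ]
  te1 <- sp$test[sp$test$receptor == "r1", ]
  expect_identical(c(sum(tr1$label == 1), sum(tr1$label == 0)), c(4L, 4L))
  expect_identical(c(sum(te1$label == 1), sum(te1$label == 0)), c(1L, 1L))
  tr2 <- sp$train[sp$train$receptor == "r2", ]
  te2 <- sp$test[sp$test$receptor == "r2", ]
  expect_identical(sum(tr2$label == 1), 1L)
  expect_identical(sum(te2$label == 1), 0L)
})

test_that("splits are deterministic in the seed and vary across seeds", {
  d <- small_dataset()
  a <- make_split(d$associations, "filling_gaps", seed = 5)
  b <- make_split(d$associations, "filling_gaps", seed = 5)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  tests <- vapply(1:10, function(s)
    paste(sort(paste(make_split(d$associations, "filling_gaps",
                                seed = s)$test$ligand,
                     make_split(d$associations, "filling_gaps",
                                seed = s)$test$receptor)),
          collapse = ";"), character(1))
  expect_gt(length(unique(tests)), 1L)
})

test_that("splits partition the known pairs and stratify per receptor", {
  d <- small_dataset()
  A <- d$associations
  sp <- make_split(A, "filling_gaps", seed = 2)
  key <- function(p) paste(p$ligand, p$receptor)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(known_pairs(A)))
  # train positive fraction within one count unit of the full matrix
  s <- association_summary(A)
  for (r in colnames(A)) {
    n_pos <- s$per_receptor$n_positive[s$per_receptor$receptor == r]
    tr <- sp$train[sp$train$receptor == r, ]
    expect_lte(abs(sum(tr$label == 1) - 0.8 * n_pos), 1)
  }
})

test_that("new-ligands splits hold out whole ligands", {
  d <- small_dataset()
  sp <- make_split(d$associations, "new_ligands", rho = 0.8, seed = 4)
  expect_length(intersect(sp$train$ligand, sp$test_ligands), 0L)
  expect_setequal(sp$test$ligand,
                  intersect(sp$test_ligands,
                            known_pairs(d$associations)$ligand))
  held_known <- known_pairs(d$associations)
  held_known <- held_known[held_known$ligand %in% sp$test_ligands, ]
  expect_identical(nrow(sp$test), nrow(held_known))
})

test_that("split plans serialize to JSON and back", {
  d <- small_dataset()
  sp <- make_split(d$associations, "filling_gaps", seed = 9, repetition = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_identical(sp2$train, sp$train)
  expect_identical(sp2$seed, sp$seed)
  expect_identical(sp2$scenario, sp$scenario)
})

test_that("design schemas are variant-determined and nested", {
  d <- small_dataset()
  sims <- chemistry_similarities(d)
  sp <- make_split(d$associations, "filling_gaps", seed = 1)
  mk <- function(v) build_design(d$associations, sp, d$ligand_descriptors,
                                 d$receptor_descriptors, sims, v)
  d1 <- mk("model1"); d2 <- mk("model2"); d3 <- mk("model3"); d4 <- mk("model4")
  n_desc <- (ncol(d$ligand_descriptors) - 1L) +
    (ncol(d$receptor_descriptors) - 1L)
  expect_identical(ncol(d1$train$x), n_desc)
  expect_identical(ncol(d2$train$x), n_desc + 8L)
  expect_identical(ncol(d3$train$x), n_desc + 24L)
  expect_identical(ncol(d4$train$x), n_desc + 32L)  # 4 x 3 + 4 x 5 similarities
  expect_true(all(d3$train$schema %in% d4$train$schema))
  expect_true(all(d1$train$schema %in% d3$train$schema))
  expect_identical(d1$train$schema, d1$test$schema)
  # byte-identical schema on recomputation
  expect_identical(mk("model4")$train$schema, d4$train$schema)
  # cold-start design carries no receptor-similarity or collaborative block
  dn <- build_design(d$associations, sp, d$ligand_descriptors,
                     d$receptor_descriptors, sims, "new_ligands")
  expect_false(any(grepl("collab|receptor_seq|receptor_site",
                         dn$train$schema)))
})

test_that("missing required similarity kinds and descriptors error by name", {
  d <- small_dataset()
  sims <- chemistry_similarities(d)
  sp <- make_split(d$associations, "filling_gaps", seed = 1)
  expect_error(build_design(d$associations, sp, d$ligand_descriptors,
                            d$receptor_descriptors, sims["ligand_linear_fp"],
                            "model3"),
               "ligand_atom_env_fp")
  short <- d$ligand_descriptors[-1, ]
  expect_error(build_design(d$associations, sp, short,
                            d$receptor_descriptors, sims, "model1"),
               d$ligand_descriptors$id[1])
})

test_that("training features never see test labels (leakage suite)", {
  d <- small_dataset()
  sims <- chemistry_similarities(d)
  for (scenario in c("filling_gaps", "new_ligands")) {
    variant <- if (scenario == "filling_gaps") "model4" else "new_ligands"
    sp <- make_split(d$associations, scenario, seed = 6)
    base <- build_design(d$associations, sp, d$ligand_descriptors,
                         d$receptor_descriptors, sims, variant)
    # flip every hidden test label in the underlying matrix
    flipped <- unclass(d$associations)
    idx <- cbind(match(sp$test$ligand, rownames(flipped)),
                 match(sp$test$receptor, colnames(flipped)))
    flipped[idx] <- 1L - flipped[idx]
    A_flip <- association_matrix(flipped,
                                 species = receptor_species(d$associations))
    relab <- build_design(A_flip, sp, d$ligand_descriptors,
                          d$receptor_descriptors, sims, variant)
    expect_identical(relab$train$x, base$train$x)
    expect_identical(relab$test$x, base$test$x)
    # baselines read only the masked view
    expect_identical(prior_baseline(mask_entries(A_flip, sp$test)),
                     prior_baseline(mask_entries(d$associations, sp$test)))
  }
})

test_that("prediction designs target the unknown cells by default", {
  d <- small_dataset()
  sims <- chemistry_similarities(d)
  pd <- prediction_design(d$associations, d$ligand_descriptors,
                          d$receptor_descriptors, sims, "model4")
  expect_identical(nrow(pd$x), sum(is.na(d$associations)))
  expect_null(pd$y)
  # a fully known matrix yields zero targets
  full <- d$truth
  pdf <- prediction_design(full, d$ligand_descriptors,
                           d$receptor_descriptors, sims, "model4")
  expect_identical(nrow(pdf$x), 0L)
  # cold-start targets may reference new ligands, but only with fingerprints
  targets <- data.frame(ligand = "novel1",
                        receptor = colnames(d$associations)[1])
  expect_error(prediction_design(d$associations, d$ligand_descriptors,
                                 d$receptor_descriptors, sims,
                                 "new_ligands", targets),
               "novel1")
})
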