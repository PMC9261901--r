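test_that("the filling-gaps report covers every method", {
  d <- small_dataset(seed = 12)
  cfg <- run_config("filling_gaps", n_repetitions = 2, base_seed = 10,
                    K = 25, hp = hyperparameters(nrounds = 40))
  rep <- run_filling_gaps(d, cfg)
  expect_named(rep$summaries,
               c("prior", "model1", "model2", "model3", "model4"))
  expect_length(rep$summaries, 5L)
  for (s in rep$summaries) {
    expect_s3_class(s, "pr_summary")
    expect_identical(s$n_reps, 2L)
  }
  expect_true(all(lengths(rep$average_precision) == 2L))
  expect_s3_class(rep$per_receptor, "data.frame")
  expect_s3_class(rep$feature_importance, "data.frame")
  expect_setequal(rep$feature_importance$feature,
                  bitterrec:::.design_schema(d, cfg))
})

test_that("the new-ligands report compares model, prior and nearest neighbor", {
  d <- small_dataset(seed = 13)
  cfg <- run_config("new_ligands", n_repetitions = 2, base_seed = 20,
                    K = 25, hp = hyperparameters(nrounds = 40))
  rep <- run_new_ligands(d, cfg)
  expect_named(rep$summaries, c("model", "prior", "nearest_neighbor"))
  expect_true(rep$first_hit$mean_model >= 1)
  expect_identical(length(rep$first_hit$model_counts),
                   length(rep$first_hit$prior_counts))
  expect_true(is.numeric(rep$first_hit$regression$slope))
})

test_that("identical configurations produce byte-identical reports", {
  d <- small_dataset(seed = 14)
  cfg <- run_config("filling_gaps", variants = c("model1", "model3"),
                    n_repetitions = 2, base_seed = 30, K = 20,
                    hp = hyperparameters(nrounds = 30))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(run_filling_gaps(d, cfg), p1)
  write_evaluation_report(run_filling_gaps(d, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_gt(file.size(p1), 0)
})

test_that("matrix completion fills exactly the unknown cells", {
  d <- small_dataset(seed = 15)
  sims <- chemistry_similarities(d)
  sp <- make_split(d$associations, "filling_gaps", seed = 1)
  des <- build_design(d$associations, sp, d$ligand_descriptors,
                      d$receptor_descriptors, sims, "model3")
  m <- fit_association_model(des$train, hyperparameters(nrounds = 60))
  cm <- complete_matrix(d$associations, m, d$ligand_descriptors,
                        d$receptor_descriptors, sims, threshold = 0.65)
  expect_false(anyNA(cm$completed))
  n_na <- sum(is.na(d$associations))
  expect_identical(sum(cm$provenance == "predicted"), n_na)
  filled <- unclass(cm$completed)[is.na(unclass(d$associations))]
  expect_identical(sum(filled == 1L) + sum(filled == 0L), n_na)
  # measured entries are untouched
  known <- !is.na(d$associations)
  expect_identical(unclass(cm$completed)[known],
                   unclass(d$associations)[known])
  # fully known input is returned unchanged with an empty predicted mask
  cm2 <- complete_matrix(cm$completed, m, d$ligand_descriptors,
                         d$receptor_descriptors, sims)
  expect_identical(unclass(cm2$completed), unclass(cm$completed))
  expect_identical(sum(cm2$provenance == "predicted"), 0L)
  # calls are positive exactly when score >= threshold
  expect_identical(unname(filled[order(names(cm$scores))]),
                   as.integer(cm$scores[order(names(cm$scores))] >= 0.65))
})

test_that("functional analogs score profile agreement across species", {
  m <- rbind(c(1L, 1L, 0L, 1L), c(0L, 0L, 1L, 0L), c(1L, 1L, 0L, 1L))
  dimnames(m) <- list(paste0("l", 1:3),
                      c("human:a", "human:b", "mouse:a", "mouse:b"))
  # receptor human:a duplicated as mouse:b; mouse:a is its complement
  A <- association_matrix(m)
  fa <- functional_analogs(A)
  expect_equal(fa$similarity["human:a", "mouse:b"], 1)
  expect_equal(fa$similarity["human:a", "mouse:a"], 0)
  cs <- fa$cross_species
  expect_identical(cs$best_match[cs$receptor == "human:a"], "mouse:b")
  expect_equal(cs$best_similarity[cs$receptor == "human:a"], 1)
  expect_error(functional_analogs(small_dataset()$associations), "fully")
})

test_that("functional analog similarity equals brute-force profile matching", {
  set.seed(61)
  for (rep in 1:10) {
    R <- sample(3:6, 1)
    m <- matrix(sample(0:1, 8 * R, TRUE), 8, R,
                dimnames = list(sprintf("l%d", 1:8), sprintf("r%d", 1:R)))
    fa <- functional_analogs(association_matrix(m))
    i <- sample(R, 1); j <- sample(R, 1)
    expect_equal(fa$similarity[i, j], mean(m[, i] == m[, j]))
  }
})

test_that("batch prediction scores external compounds against all receptors", {
  d <- small_dataset(seed = 16)
  sims <- chemistry_similarities(d)
  sp <- make_split(d$associations, "new_ligands", seed = 2)
  des <- build_design(d$associations, sp, d$ligand_descriptors,
                      d$receptor_descriptors, sims, "new_ligands")
  m <- fit_association_model(des$train, hyperparameters(nrounds = 60))
  # build two external compounds with fingerprints + descriptors
  set.seed(99)
  comp_ids <- c("cmpA", "cmpB")
  mk_fp <- function(kind) fingerprint_set(
    stats::setNames(lapply(comp_ids, function(i) sample(128, 25)), comp_ids),
    kind = kind)
  desc <- d$ligand_descriptors[1:2, ]
  desc$id <- comp_ids
  compounds <- list(fingerprints = list(linear = mk_fp("linear"),
                                        atom_environment =
                                          mk_fp("atom_environment")),
                    descriptors = descriptor_table(desc))
  out <- batch_predict(compounds, m, d, threshold = 0.52)
  expect_identical(dim(out$scores), c(2L, ncol(d$associations)))
  expect_true(all(out$scores > 0 & out$scores < 1))
  expect_identical(unname(out$calls), unname((out$scores >= 0.52) * 1L))
  expect_equal(out$per_receptor$call_proportion,
               out$per_receptor$n_calls / 2)
  expect_true(all(out$per_receptor$hit_rate >= 0 &
                    out$per_receptor$hit_rate <= 1))
  # missing fingerprints are reported by compound
  broken <- compounds
  broken$fingerprints$linear <- fingerprint_set(
    broken$fingerprints$linear$bits["cmpA"], kind = "linear")
  expect_error(batch_predict(broken, m, d), "cmpB")
  # zero compounds give an empty call table
  empty <- list(fingerprints = compounds$fingerprints,
                descriptors = compounds$descriptors[0, ])
  out0 <- batch_predict(empty, m, d)
  expect_identical(nrow(out0$scores), 0L)
})
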