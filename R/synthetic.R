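#' Specification of a synthetic ligand-receptor benchmark dataset
#'
#' The generator plants the statistical structure the algorithm exploits:
#' ligands fall into clusters sharing fingerprint bits, receptors into
#' groups sharing sequence blocks, and the probability that a ligand
#' activates a receptor depends only on its cluster and the receptor's
#' group. Neighbor-informed features are therefore genuinely informative:
#' similar ligands (same cluster) tend to share receptor associations.
#'
#' Defaults echo the regime of the real association data at desk scale:
#' 120 ligands by 20 receptors, about 35% of entries observed, and an
#' activation probability table whose mean is about 16% (one preferred
#' receptor group per ligand cluster at 0.42, background 0.03) -- sparse
#' and strongly unbalanced, without claiming to reproduce the curated
#' data.
#'
#' @param n_ligands,n_receptors matrix dimensions (>= 2 each).
#' @param n_ligand_clusters,n_receptor_groups number of planted blocks.
#' @param activation_prob cluster x group matrix of activation
#'   probabilities in `[0, 1]`; default: 0.42 on a cyclic "preferred group"
#'   diagonal pattern, 0.03 elsewhere.
#' @param fraction_observed fraction of entries revealed, in (0, 1].
#' @param n_ligand_descriptors,n_receptor_descriptors descriptor
#'   dimensions.
#' @param ligand_descriptor_noise standard deviation of ligand descriptor
#'   noise around the cluster means (cluster means are drawn from
#'   N(0, 1)). The default (2.5) makes ligand chemistry a weak proxy of
#'   cluster identity, mirroring the empirical regime where ligand
#'   chemical features carry little direct signal (bitter molecules are
#'   chemically very diverse) and the neighbor-informed features do the
#'   heavy lifting.
#' @param receptor_descriptor_noise standard deviation of receptor
#'   descriptor noise around the group means; receptors are less diverse
#'   and their properties carry real signal, hence the moderate default
#'   (0.6).
#' @param descriptor_missing_rate fraction of ligand descriptor cells set
#'   missing (the learner handles missingness natively).
#' @param fingerprint_bits hashed fingerprint address space.
#' @param core_bits_per_cluster size of each cluster's core bit set.
#' @param bit_share_rate probability a ligand carries each core bit of its
#'   cluster.
#' @param background_bit_rate probability of each non-core bit.
#' @param sequence_length aligned sequence length (no indels within a
#'   dataset; group ancestors may differ at any column).
#' @param mutation_rate per-residue mutation probability away from the
#'   group ancestor.
#' @param n_binding_site_columns number of alignment columns marked as the
#'   orthosteric binding site.
#' @param fraction_mouse fraction of receptors tagged as mouse.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_ligands = 120L, n_receptors = 20L,
                           n_ligand_clusters = 4L, n_receptor_groups = 3L,
                           activation_prob = NULL,
                           fraction_observed = 0.35,
                           n_ligand_descriptors = 8L,
                           n_receptor_descriptors = 6L,
                           ligand_descriptor_noise = 2.5,
                           receptor_descriptor_noise = 0.6,
                           descriptor_missing_rate = 0.02,
                           fingerprint_bits = 512L,
                           core_bits_per_cluster = 40L,
                           bit_share_rate = 0.85,
                           background_bit_rate = 0.02,
                           sequence_length = 120L,
                           mutation_rate = 0.05,
                           n_binding_site_columns = 25L,
                           fraction_mouse = 0.5,
                           seed = 1L) {
  if (n_ligands < 2L || n_receptors < 2L)
    stop("need at least 2 ligands and 2 receptors")
  if (!(fraction_observed > 0 && fraction_observed <= 1))
    stop("`fraction_observed` must be in (0, 1]")
  if (is.null(activation_prob)) {
    activation_prob <- matrix(0.03, n_ligand_clusters, n_receptor_groups)
    for (k in seq_len(n_ligand_clusters))
      activation_prob[k, 1L + (k - 1L) %% n_receptor_groups] <- 0.42
  }
  if (nrow(activation_prob) != n_ligand_clusters ||
      ncol(activation_prob) != n_receptor_groups)
    stop("`activation_prob` must be n_ligand_clusters x n_receptor_groups")
  if (any(activation_prob < 0 | activation_prob > 1))
    stop("activation probabilities must lie in [0, 1]")
  spec <- list(n_ligands = as.integer(n_ligands),
               n_receptors = as.integer(n_receptors),
               n_ligand_clusters = as.integer(n_ligand_clusters),
               n_receptor_groups = as.integer(n_receptor_groups),
               activation_prob = activation_prob,
               fraction_observed = fraction_observed,
               n_ligand_descriptors = as.integer(n_ligand_descriptors),
               n_receptor_descriptors = as.integer(n_receptor_descriptors),
               ligand_descriptor_noise = ligand_descriptor_noise,
               receptor_descriptor_noise = receptor_descriptor_noise,
               descriptor_missing_rate = descriptor_missing_rate,
               fingerprint_bits = as.integer(fingerprint_bits),
               core_bits_per_cluster = as.integer(core_bits_per_cluster),
               bit_share_rate = bit_share_rate,
               background_bit_rate = background_bit_rate,
               sequence_length = as.integer(sequence_length),
               mutation_rate = mutation_rate,
               n_binding_site_columns = as.integer(n_binding_site_columns),
               fraction_mouse = fraction_mouse,
               seed = as.integer(seed))
  structure(spec, class = "synthetic_spec")
}

.amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a synthetic benchmark dataset
#'
#' Draws a complete ground-truth association matrix from the planted
#' cluster x group Bernoulli model, reveals a `fraction_observed` subset
#' (re-revealing one entry per empty row/column so the observed matrix is
#' gaps-ready), and emits every input the pipeline consumes: two
#' fingerprint sets (cluster-core bits plus background), ligand and
#' receptor descriptor tables (block means plus noise, receptor organism
#' and chromosome metadata included), and an aligned sequence set derived
#' from group ancestors by point mutations, with binding-site columns.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `associations` (observed `assoc_matrix`), `truth`
#'   (complete `assoc_matrix`), `fingerprints` (list `linear`,
#'   `atom_environment`), `ligand_descriptors`, `receptor_descriptors`,
#'   `alignment` (an `aligned_sequences` with binding-site columns),
#'   `ligand_clusters`, `receptor_groups`, and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_synthetic_impl(spec))
}

.generate_synthetic_impl <- function(spec) {
  L <- spec$n_ligands
  R <- spec$n_receptors
  ligand_ids <- sprintf("lig%03d", seq_len(L))
  n_mouse <- round(spec$fraction_mouse * R)
  species <- c(rep("human", R - n_mouse), rep("mouse", n_mouse))
  receptor_ids <- sprintf("%s:rec%02d", species, seq_len(R))

  clusters <- sample(rep_len(seq_len(spec$n_ligand_clusters), L))
  groups <- sample(rep_len(seq_len(spec$n_receptor_groups), R))

  # ground truth labels
  pmat <- spec$activation_prob[cbind(rep(clusters, R),
                                     rep(groups, each = L))]
  truth_v <- matrix(as.integer(stats::runif(L * R) < pmat), L, R,
                    dimnames = list(ligand_ids, receptor_ids))
  truth <- association_matrix(truth_v, species = species)

  # reveal a subset, keep gaps-ready
  observed <- matrix(stats::runif(L * R) < spec$fraction_observed, L, R)
  for (i in which(rowSums(observed) == 0L))
    observed[i, sample.int(R, 1L)] <- TRUE
  for (j in which(colSums(observed) == 0L))
    observed[sample.int(L, 1L), j] <- TRUE
  obs_v <- truth_v
  obs_v[!observed] <- NA_integer_
  associations <- association_matrix(obs_v, species = species)

  # fingerprints: per kind, cluster core bits + random background
  make_fps <- function(kind) {
    nb <- spec$fingerprint_bits
    cores <- lapply(seq_len(spec$n_ligand_clusters), function(k)
      sample.int(nb, spec$core_bits_per_cluster))
    bits <- lapply(seq_len(L), function(i) {
      core <- cores[[clusters[i]]]
      on_core <- core[stats::runif(length(core)) < spec$bit_share_rate]
      bg <- setdiff(seq_len(nb), core)
      on_bg <- bg[stats::runif(length(bg)) < spec$background_bit_rate]
      sort(c(on_core, on_bg))
    })
    names(bits) <- ligand_ids
    fingerprint_set(bits, kind = kind)
  }
  fps_linear <- make_fps("linear")
  fps_env <- make_fps("atom_environment")

  # descriptors: block mean + gaussian noise; some ligand cells missing
  lig_means <- matrix(stats::rnorm(spec$n_ligand_clusters *
                                     spec$n_ligand_descriptors),
                      spec$n_ligand_clusters)
  lig_x <- lig_means[clusters, , drop = FALSE] +
    matrix(stats::rnorm(L * spec$n_ligand_descriptors,
                        sd = spec$ligand_descriptor_noise), L)
  if (spec$descriptor_missing_rate > 0)
    lig_x[matrix(stats::runif(length(lig_x)) < spec$descriptor_missing_rate,
                 nrow(lig_x))] <- NA_real_
  colnames(lig_x) <- sprintf("ldesc%02d", seq_len(spec$n_ligand_descriptors))
  ligand_descriptors <- descriptor_table(
    cbind(data.frame(id = ligand_ids, stringsAsFactors = FALSE),
          as.data.frame(lig_x)))

  rec_means <- matrix(stats::rnorm(spec$n_receptor_groups *
                                     spec$n_receptor_descriptors),
                      spec$n_receptor_groups)
  rec_x <- rec_means[groups, , drop = FALSE] +
    matrix(stats::rnorm(R * spec$n_receptor_descriptors,
                        sd = spec$receptor_descriptor_noise), R)
  colnames(rec_x) <- sprintf("rdesc%02d", seq_len(spec$n_receptor_descriptors))
  receptor_descriptors <- descriptor_table(
    cbind(data.frame(id = receptor_ids, organism = species,
                     chromosome = sample(1:22, R, replace = TRUE),
                     stringsAsFactors = FALSE),
          as.data.frame(rec_x)))

  # aligned sequences: group ancestor + point mutations
  ancestors <- replicate(spec$n_receptor_groups,
                         sample(.amino_acids, spec$sequence_length,
                                replace = TRUE),
                         simplify = FALSE)
  seqs <- vapply(seq_len(R), function(j) {
    s <- ancestors[[groups[j]]]
    mut <- stats::runif(length(s)) < spec$mutation_rate
    s[mut] <- sample(.amino_acids, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- receptor_ids
  site_cols <- sort(sample.int(spec$sequence_length,
                               min(spec$n_binding_site_columns,
                                   spec$sequence_length)))
  alignment <- aligned_sequences(seqs, binding_site_columns = site_cols)

  list(associations = associations, truth = truth,
       fingerprints = list(linear = fps_linear, atom_environment = fps_env),
       ligand_descriptors = ligand_descriptors,
       receptor_descriptors = receptor_descriptors,
       alignment = alignment,
       ligand_clusters = stats::setNames(clusters, ligand_ids),
       receptor_groups = stats::setNames(groups, receptor_ids),
       spec = spec)
}

#' Write / read a synthetic (or real) dataset as plain-text files
#'
#' Emits exactly the formats the pipeline consumes: `associations.csv`
#' (wide ternary CSV), `fingerprints_linear.tsv` and
#' `fingerprints_atom_environment.tsv` (sparse bit lists),
#' `ligand_descriptors.tsv`, `receptor_descriptors.tsv`, `alignment.fasta`
#' plus `binding_site_columns.json` (0-based).
#'
#' @param data a dataset list as returned by [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_matrix(data$associations,
                           file.path(dir, "associations.csv"))
  write_fingerprints(data$fingerprints$linear,
                     file.path(dir, "fingerprints_linear.tsv"))
  write_fingerprints(data$fingerprints$atom_environment,
                     file.path(dir, "fingerprints_atom_environment.tsv"))
  utils::write.table(data$ligand_descriptors,
                     file.path(dir, "ligand_descriptors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data$receptor_descriptors,
                     file.path(dir, "receptor_descriptors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_alignment(data$alignment, file.path(dir, "alignment.fasta"),
                  file.path(dir, "binding_site_columns.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  list(associations = read_association_matrix(
         file.path(dir, "associations.csv")),
       fingerprints = list(
         linear = read_fingerprints(file.path(dir, "fingerprints_linear.tsv")),
         atom_environment = read_fingerprints(
           file.path(dir, "fingerprints_atom_environment.tsv"))),
       ligand_descriptors = descriptor_table(
         utils::read.delim(file.path(dir, "ligand_descriptors.tsv"))),
       receptor_descriptors = descriptor_table(
         utils::read.delim(file.path(dir, "receptor_descriptors.tsv"))),
       alignment = read_alignment(
         file.path(dir, "alignment.fasta"),
         file.path(dir, "binding_site_columns.json")))
}

#' Precompute the chemistry/sequence similarity matrices of a dataset
#'
#' Convenience wrapper producing the six precomputable similarity kinds
#' (two fingerprint Tanimoto matrices, full-sequence and binding-site
#' identity and BLOSUM62-based similarity). Collaborative similarities are
#' association-derived and are computed per split by [build_design()].
#'
#' @param data a dataset list (see [generate_synthetic()] /
#'   [read_dataset()]).
#' @return named list of `sim_matrix` objects.
#' @export
chemistry_similarities <- function(data) {
  aln <- data$alignment
  list(
    ligand_linear_fp = tanimoto_matrix(data$fingerprints$linear),
    ligand_atom_env_fp = tanimoto_matrix(data$fingerprints$atom_environment),
    receptor_seq_identity = sequence_identity_matrix(aln),
    receptor_seq_blosum = blosum_similarity_matrix(aln),
    receptor_site_identity = sequence_identity_matrix(
      aln, columns = aln$binding_site_columns),
    receptor_site_blosum = blosum_similarity_matrix(
      aln, columns = aln$binding_site_columns))
}
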