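#' Similarity matrices
#'
#' A `sim_matrix` is a square symmetric matrix of entity-to-entity
#' similarities in `[0, 1]`, with `NA` for undefined entries (e.g. a
#' collaborative similarity between two ligands with no co-tested receptor).
#' The `kind` tag records which of the model's similarity channels the
#' matrix represents and drives the column naming of neighbor-informed
#' feature blocks.
#'
#' @param values square numeric matrix with dimnames; entries in `[0,1]` or
#'   `NA`.
#' @param kind one of `"ligand_linear_fp"`, `"ligand_atom_env_fp"`,
#'   `"ligand_collab"`, `"receptor_collab"`, `"receptor_seq_identity"`,
#'   `"receptor_seq_blosum"`, `"receptor_site_identity"`,
#'   `"receptor_site_blosum"`.
#' @return a `sim_matrix`.
#' @export
similarity_matrix <- function(values, kind) {
  kind <- match.arg(kind, .sim_kinds)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix")
  if (is.null(rownames(values)))
    stop("similarity matrices need entity identifiers as dimnames")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("similarity values must lie in [0, 1]")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9 ||
      !identical(is.na(values), is.na(t(values))))
    stop("similarity matrix must be symmetric (including NA pattern)")
  structure(values, kind = kind,
            class = c("sim_matrix", "matrix", "array"))
}

.sim_kinds <- c("ligand_linear_fp", "ligand_atom_env_fp", "ligand_collab",
                "receptor_collab", "receptor_seq_identity",
                "receptor_seq_blosum", "receptor_site_identity",
                "receptor_site_blosum")

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix [%s]: %d x %d, %d undefined entries\n",
              similarity_kind(x), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Kind tag of a similarity matrix
#' @param S a `sim_matrix`.
#' @return character scalar.
#' @export
similarity_kind <- function(S) attr(S, "kind")

.ligand_kinds <- c("ligand_linear_fp", "ligand_atom_env_fp", "ligand_collab")
.receptor_kinds <- c("receptor_collab", "receptor_seq_identity",
                     "receptor_seq_blosum", "receptor_site_identity",
                     "receptor_site_blosum")

#' Binary molecular fingerprints stored as on-bit sets
#'
#' Only "on" bits are stored, as sparse integer sets per molecule, mirroring
#' how hashed structural fingerprints are produced in practice.
#'
#' @param bits named list of integer vectors (0-based or 1-based bit indices,
#'   treated opaquely); names are ligand identifiers.
#' @param kind `"linear"` (path-based) or `"atom_environment"` (circular).
#' @return a `fingerprint_set`.
#' @export
fingerprint_set <- function(bits, kind = c("linear", "atom_environment")) {
  kind <- match.arg(kind)
  if (is.null(names(bits)) || any(names(bits) == ""))
    stop("every fingerprint needs an identifier")
  .check_unique(names(bits), "ligand")
  bits <- lapply(bits, function(b) sort(unique(as.integer(b))))
  structure(list(bits = bits, kind = kind), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set [%s]: %d molecules, median %d on-bits\n",
              x$kind, length(x$bits),
              as.integer(stats::median(lengths(x$bits)))))
  invisible(x)
}

#' Write / read fingerprints as a sparse TSV (id, space-separated on-bits)
#' @param fps a `fingerprint_set`.
#' @param path file path.
#' @export
write_fingerprints <- function(fps, path) {
  lines <- c(paste0("# kind=", fps$kind),
             vapply(names(fps$bits), function(id)
               paste0(id, "\t", paste(fps$bits[[id]], collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  kind <- sub("^# kind=", "", lines[1L])
  lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  bits <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) integer(0)
    else as.integer(strsplit(p[2L], " ", fixed = TRUE)[[1L]])
  })
  names(bits) <- ids
  fingerprint_set(bits, kind = kind)
}

#' Tanimoto similarity matrix from binary fingerprints
#'
#' For molecules with `a` and `b` on-bits of which `c` are shared, the
#' Tanimoto similarity is `c / (a + b - c)`. A pair of two empty
#' fingerprints is defined as 0 (avoiding 0/0).
#'
#' @param fps a `fingerprint_set`.
#' @param kind similarity kind tag; defaults to the tag matching the
#'   fingerprint kind.
#' @return a `sim_matrix` over the molecules.
#' @examples
#' fps <- fingerprint_set(list(a = c(1, 2, 3, 4), b = c(3, 4, 5, 6, 7, 8)))
#' tanimoto_matrix(fps)["a", "b"]  # 2/8 = 0.25
#' @export
tanimoto_matrix <- function(fps, kind = NULL) {
  if (is.null(kind))
    kind <- if (fps$kind == "linear") "ligand_linear_fp" else "ligand_atom_env_fp"
  ids <- names(fps$bits)
  n <- length(ids)
  all_bits <- sort(unique(unlist(fps$bits, use.names = FALSE)))
  if (length(all_bits)) {
    # dense 0/1 incidence; c = B %*% t(B)
    B <- matrix(0, n, length(all_bits))
    for (i in seq_len(n))
      B[i, match(fps$bits[[i]], all_bits)] <- 1
    cmat <- tcrossprod(B)
    sizes <- lengths(fps$bits)
    denom <- outer(sizes, sizes, `+`) - cmat
    S <- ifelse(denom > 0, cmat / denom, 0)
  } else {
    S <- matrix(0, n, n)
  }
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  similarity_matrix(S, kind)
}

#' Collaborative similarity from known associations
#'
#' The collaborative similarity between two ligands is the proportion of
#' matching associations over the receptors for which both ligands have a
#' known association; the receptor version swaps the roles. Pairs with no
#' co-known partner are undefined (`NA`). The diagonal is 1 whenever the
#' entity has at least one known association (it always matches itself),
#' and `NA` otherwise.
#'
#' @param A an `assoc_matrix` (already masked for the current split, if
#'   applicable).
#' @param axis `"ligands"` or `"receptors"`.
#' @param method `"matching"` (proportion of agreeing known associations,
#'   the canonical definition) or `"jaccard"` (strict positive-class
#'   Jaccard: shared positives / union of positives).
#' @return a `sim_matrix` of kind `ligand_collab` or `receptor_collab`.
#' @examples
#' A <- association_matrix(rbind(c(1, 0, NA), c(1, 1, 0)),
#'                         ligand_ids = c("l1", "l2"),
#'                         receptor_ids = c("r1", "r2", "r3"))
#' collaborative_similarity(A, "ligands")["l1", "l2"]  # 0.5
#' @export
collaborative_similarity <- function(A, axis = c("ligands", "receptors"),
                                     method = c("matching", "jaccard")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  M <- if (axis == "ligands") unclass(A) else t(unclass(A))
  known <- !is.na(M)
  K <- known * 1
  if (method == "matching") {
    P <- ifelse(known, M == 1L, FALSE) * 1
    Q <- ifelse(known, M == 0L, FALSE) * 1
    agree <- tcrossprod(P) + tcrossprod(Q)
    N <- tcrossprod(K)
    S <- ifelse(N > 0, agree / N, NA_real_)
  } else {
    P <- ifelse(known, M == 1L, FALSE) * 1
    inter <- tcrossprod(P)
    sizes <- rowSums(P)
    uni <- outer(sizes, sizes, `+`) - inter
    S <- ifelse(uni > 0, inter / uni, NA_real_)
    # diagonal defined whenever the entity has >= 1 known association
    has_known <- rowSums(K) > 0
    diag(S)[has_known & sizes == 0] <- 1
  }
  dimnames(S) <- list(rownames(M), rownames(M))
  kind <- if (axis == "ligands") "ligand_collab" else "receptor_collab"
  similarity_matrix(S, kind)
}

#' Aligned receptor protein sequences
#'
#' Holds equal-length aligned amino-acid sequences (gap `-`) plus an
#' optional set of alignment columns marking the orthosteric binding site.
#'
#' @param sequences named character vector of aligned sequences.
#' @param binding_site_columns optional integer vector of 1-based alignment
#'   column indices.
#' @return an `aligned_sequences` object.
#' @export
aligned_sequences <- function(sequences, binding_site_columns = NULL) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("aligned sequences must be named")
  .check_unique(names(sequences), "receptor")
  nm <- names(sequences)
  sequences <- stats::setNames(toupper(as.character(sequences)), nm)
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("all aligned sequences must have the same length")
  if (!is.null(binding_site_columns)) {
    binding_site_columns <- sort(unique(as.integer(binding_site_columns)))
    if (length(binding_site_columns) == 0L)
      stop("binding_site_columns must be non-empty when given")
    if (min(binding_site_columns) < 1L || max(binding_site_columns) > len)
      stop("binding-site columns out of alignment range")
  }
  structure(list(sequences = sequences, width = len,
                 binding_site_columns = binding_site_columns),
            class = "aligned_sequences")
}

#' @export
print.aligned_sequences <- function(x, ...) {
  cat(sprintf("aligned_sequences: %d sequences, width %d%s\n",
              length(x$sequences), x$width,
              if (is.null(x$binding_site_columns)) ""
              else sprintf(", %d binding-site columns",
                           length(x$binding_site_columns))))
  invisible(x)
}

#' Read an aligned FASTA file (plus optional binding-site column JSON)
#'
#' @param fasta path to an aligned FASTA file.
#' @param binding_site_json optional path to a JSON array of 0-based
#'   alignment column indices (converted to 1-based internally).
#' @return an `aligned_sequences` object.
#' @export
read_alignment <- function(fasta, binding_site_json = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  seqs <- stats::setNames(as.character(aa), names(aa))
  cols <- NULL
  if (!is.null(binding_site_json))
    cols <- as.integer(jsonlite::fromJSON(binding_site_json)) + 1L
  aligned_sequences(seqs, binding_site_columns = cols)
}

#' Write an aligned FASTA file (plus binding-site column JSON)
#' @param seqs an `aligned_sequences` object.
#' @param fasta output FASTA path.
#' @param binding_site_json optional output path for the 0-based
#'   binding-site column list.
#' @export
write_alignment <- function(seqs, fasta, binding_site_json = NULL) {
  writeLines(as.vector(rbind(paste0(">", names(seqs$sequences)),
                             unname(seqs$sequences))), fasta)
  if (!is.null(binding_site_json)) {
    if (is.null(seqs$binding_site_columns))
      stop("no binding-site columns to write")
    jsonlite::write_json(seqs$binding_site_columns - 1L, binding_site_json)
  }
  invisible(fasta)
}

.seq_char_matrix <- function(seqs, columns = NULL) {
  m <- do.call(rbind, strsplit(unname(seqs$sequences), ""))
  rownames(m) <- names(seqs$sequences)
  if (!is.null(columns)) {
    columns <- as.integer(columns)
    if (length(columns) == 0L) stop("column subset must be non-empty")
    if (min(columns) < 1L || max(columns) > ncol(m))
      stop("column subset out of alignment range")
    m <- m[, columns, drop = FALSE]
  }
  m
}

# shared engine: count columns where both residues are non-gap and
# score_fun(res_i, res_j) is TRUE, over both-non-gap columns
.pairwise_column_fraction <- function(cm, match_fun) {
  n <- nrow(cm)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(cm), rownames(cm)))
  gap <- cm == "-" | cm == "."
  for (i in seq_len(n)) {
    for (j in i:n) {
      both <- !gap[i, ] & !gap[j, ]
      nb <- sum(both)
      S[i, j] <- S[j, i] <-
        if (nb == 0L) NA_real_ else sum(match_fun(cm[i, both], cm[j, both])) / nb
    }
  }
  S
}

#' Pairwise sequence identity from a multiple alignment
#'
#' Identity between two aligned sequences is the fraction of alignment
#' columns, restricted to `columns` if given, where both residues are
#' non-gap and identical, out of the columns where both are non-gap. A pair
#' whose non-gap columns do not overlap is undefined (`NA`).
#'
#' @param seqs an `aligned_sequences` object.
#' @param columns optional 1-based alignment column subset (e.g. the
#'   binding-site columns).
#' @param denominator `"overlap"` (default: both-non-gap columns),
#'   `"alignment"` (all columns in the subset) or `"shorter"` (non-gap
#'   length of the shorter sequence).
#' @param kind similarity kind tag (defaults to `receptor_seq_identity`, or
#'   `receptor_site_identity` when `columns` is given).
#' @return a `sim_matrix`.
#' @export
sequence_identity_matrix <- function(seqs, columns = NULL,
                                     denominator = c("overlap", "alignment",
                                                     "shorter"),
                                     kind = NULL) {
  denominator <- match.arg(denominator)
  if (length(seqs$sequences) < 2L) stop("need at least two sequences")
  cm <- .seq_char_matrix(seqs, columns)
  if (is.null(kind))
    kind <- if (is.null(columns)) "receptor_seq_identity" else "receptor_site_identity"
  S <- .column_fraction_with_denominator(cm, function(a, b) a == b, denominator)
  similarity_matrix(S, kind)
}

#' BLOSUM62-based pairwise sequence similarity from a multiple alignment
#'
#' Two residues are "similar" when their substitution score is strictly
#' positive; identical residues always count (the BLOSUM62 diagonal is
#' positive). The similarity between two sequences is the fraction of
#' both-non-gap columns (in the optional subset) whose residue pair scores
#' `> 0`.
#'
#' @inheritParams sequence_identity_matrix
#' @param substitution_matrix amino-acid substitution score matrix; defaults
#'   to BLOSUM62.
#' @return a `sim_matrix`.
#' @export
blosum_similarity_matrix <- function(seqs, columns = NULL,
                                     substitution_matrix = NULL,
                                     denominator = c("overlap", "alignment",
                                                     "shorter"),
                                     kind = NULL) {
  denominator <- match.arg(denominator)
  if (length(seqs$sequences) < 2L) stop("need at least two sequences")
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  cm <- .seq_char_matrix(seqs, columns)
  residues <- setdiff(unique(as.vector(cm)), c("-", "."))
  unknown <- setdiff(residues, rownames(substitution_matrix))
  if (length(unknown)) {
    hit <- which(matrix(cm %in% unknown, nrow(cm)), arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown residue '%s' in sequence '%s' at column %d",
                 cm[hit[1L], hit[2L]], rownames(cm)[hit[1L]], hit[2L]))
  }
  sm <- substitution_matrix
  S <- .column_fraction_with_denominator(
    cm, function(a, b) sm[cbind(a, b)] > 0, denominator)
  if (is.null(kind))
    kind <- if (is.null(columns)) "receptor_seq_blosum" else "receptor_site_blosum"
  similarity_matrix(S, kind)
}

.column_fraction_with_denominator <- function(cm, match_fun, denominator) {
  if (denominator == "overlap")
    return(.pairwise_column_fraction(cm, match_fun))
  n <- nrow(cm)
  gap <- cm == "-" | cm == "."
  nongap_len <- rowSums(!gap)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(cm), rownames(cm)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      both <- !gap[i, ] & !gap[j, ]
      hits <- sum(match_fun(cm[i, both], cm[j, both]))
      den <- switch(denominator,
                    alignment = ncol(cm),
                    shorter = min(nongap_len[i], nongap_len[j]))
      S[i, j] <- S[j, i] <- if (den == 0L) NA_real_ else hits / den
    }
  }
  S
}

#' The BLOSUM62 substitution matrix
#' @return the 25x25 BLOSUM62 score matrix.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Write / read a similarity matrix as square CSV
#' @param S a `sim_matrix`.
#' @param path file path.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(id = rownames(S), unclass(S), check.names = FALSE)
  colnames(df) <- c(paste0("#kind=", similarity_kind(S)), colnames(S))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  kind <- sub("^#kind=", "", colnames(df)[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  similarity_matrix(m, kind)
}
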