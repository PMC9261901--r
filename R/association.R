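#' Ternary ligand-receptor association matrices
#'
#' An `assoc_matrix` stores the known activation data between bitter ligands
#' (rows) and bitter taste receptors (columns) as a ternary matrix: `1` when
#' the ligand is known to activate the receptor (positive association), `0`
#' when it is known not to (negative association), and `NA` when the pair has
#' not been tested or has been hidden for evaluation purposes. Receptors may
#' carry a species tag (`"human"` or `"mouse"`), used by the functional
#' analog analysis and carried through all downstream tables.
#'
#' @param values integer or numeric matrix with entries in `{0, 1, NA}`;
#'   `dimnames` supply ligand and receptor identifiers unless `ligand_ids` /
#'   `receptor_ids` are given.
#' @param ligand_ids,receptor_ids optional identifier vectors overriding
#'   `dimnames(values)`. Must be unique within each axis.
#' @param species optional character vector of length `ncol(values)` with
#'   entries in `{"human", "mouse"}`; defaults to a `"human:"` / `"mouse:"`
#'   prefix convention on receptor identifiers when present, else `"human"`.
#' @return an object of class `assoc_matrix`: an integer matrix with a
#'   `species` attribute.
#' @examples
#' A <- association_matrix(rbind(c(1, NA), c(0, 1)),
#'                         ligand_ids = c("quinine", "caffeine"),
#'                         receptor_ids = c("TAS2R10", "TAS2R14"))
#' association_summary(A)$n_known
#' @export
association_matrix <- function(values, ligand_ids = NULL, receptor_ids = NULL,
                               species = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(ligand_ids)) ligand_ids <- rownames(values)
  if (is.null(receptor_ids)) receptor_ids <- colnames(values)
  if (is.null(ligand_ids) || is.null(receptor_ids))
    stop("ligand and receptor identifiers are required (dimnames or arguments)")
  ligand_ids <- as.character(ligand_ids)
  receptor_ids <- as.character(receptor_ids)
  .check_unique(ligand_ids, "ligand")
  .check_unique(receptor_ids, "receptor")
  if (length(ligand_ids) != nrow(values) || length(receptor_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  v <- suppressWarnings(as.integer(values))
  bad <- which(!is.na(v) & !(v %in% c(0L, 1L)))
  if (length(bad) || any(!is.na(values) & is.na(v)))
    stop("association values must be 1, 0 or NA")
  m <- matrix(v, nrow(values), ncol(values),
              dimnames = list(ligand_ids, receptor_ids))
  if (is.null(species)) species <- .species_from_ids(receptor_ids)
  species <- as.character(species)
  if (length(species) == 1L) species <- rep(species, ncol(m))
  if (length(species) != ncol(m))
    stop("`species` must have one entry per receptor")
  if (!all(species %in% c("human", "mouse")))
    stop("species tags must be 'human' or 'mouse'")
  structure(m, species = stats::setNames(species, receptor_ids),
            class = c("assoc_matrix", "matrix", "array"))
}

.check_unique <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(d, collapse = ", ")))
}

.species_from_ids <- function(ids) {
  sp <- rep("human", length(ids))
  sp[startsWith(ids, "mouse:")] <- "mouse"
  sp
}

#' @export
print.assoc_matrix <- function(x, ...) {
  s <- association_summary(x)
  cat(sprintf(
    "assoc_matrix: %d ligands x %d receptors; %d known (%d+/%d-), %.1f%% known\n",
    nrow(x), ncol(x), s$n_known, s$n_positive, s$n_negative,
    100 * s$fraction_known))
  invisible(x)
}

#' Species tags of the receptors
#' @param A an `assoc_matrix`.
#' @return named character vector over receptors.
#' @export
receptor_species <- function(A) attr(A, "species")

#' Read a ternary association matrix from a wide CSV/TSV file
#'
#' Expects a header row naming the receptors and a first column naming the
#' ligands. Cells hold `1` (activates), `0` (does not activate) or are empty
#' (unknown); the token `na` (any case) is also accepted for unknown.
#'
#' @param path file path.
#' @param delim field delimiter, `","` by default.
#' @param species optional explicit species vector (see
#'   [association_matrix()]).
#' @return an `assoc_matrix`.
#' @export
read_association_matrix <- function(path, delim = ",", species = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = delim, row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("association file needs a ligand column and at least one receptor")
  lig <- as.character(df[[1L]])
  .check_unique(lig, "ligand")
  rec <- colnames(df)[-1L]
  .check_unique(rec, "receptor")
  cells <- as.matrix(df[, -1L, drop = FALSE])
  v <- matrix(NA_integer_, nrow(cells), ncol(cells))
  txt <- trimws(cells)
  ok_na <- txt == "" | tolower(txt) == "na"
  v[txt == "1"] <- 1L
  v[txt == "0"] <- 0L
  bad <- which(!ok_na & !(txt %in% c("0", "1")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("cannot parse cell at ligand '%s', receptor '%s': '%s'",
                 lig[bad[1L, 1L]], rec[bad[1L, 2L]],
                 txt[bad[1L, , drop = FALSE]]))
  association_matrix(v, ligand_ids = lig, receptor_ids = rec,
                     species = species)
}

#' Write an association matrix as wide CSV/TSV
#'
#' Unknown entries are written as empty cells so that
#' `read_association_matrix()` round-trips the matrix exactly.
#'
#' @param A an `assoc_matrix`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_association_matrix <- function(A, path, delim = ",") {
  out <- matrix("", nrow(A), ncol(A))
  out[!is.na(A)] <- as.character(A[!is.na(A)])
  df <- data.frame(ligand = rownames(A), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("ligand", colnames(A))
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize known associations
#'
#' @param A an `assoc_matrix`.
#' @return a list with totals (`n_known`, `n_positive`, `n_negative`,
#'   `fraction_known`) and per-receptor / per-ligand count tables.
#' @examples
#' A <- association_matrix(rbind(c(1, 0), c(NA, 1)),
#'                         ligand_ids = c("l1", "l2"),
#'                         receptor_ids = c("r1", "r2"))
#' association_summary(A)$fraction_known  # 0.75
#' @export
association_summary <- function(A) {
  known <- !is.na(A)
  pos <- !is.na(A) & A == 1L
  neg <- !is.na(A) & A == 0L
  per_receptor <- data.frame(
    receptor = colnames(A),
    species = unname(receptor_species(A)),
    n_known = as.integer(colSums(known)),
    n_positive = as.integer(colSums(pos)),
    n_negative = as.integer(colSums(neg)), row.names = NULL,
    stringsAsFactors = FALSE)
  per_ligand <- data.frame(
    ligand = rownames(A),
    n_known = as.integer(rowSums(known)),
    n_positive = as.integer(rowSums(pos)),
    n_negative = as.integer(rowSums(neg)), row.names = NULL,
    stringsAsFactors = FALSE)
  list(n_known = sum(known), n_positive = sum(pos), n_negative = sum(neg),
       fraction_known = sum(known) / length(A),
       per_receptor = per_receptor, per_ligand = per_ligand)
}

#' @export
summary.assoc_matrix <- function(object, ...) association_summary(object)

#' Is a matrix ready for the filling-the-gaps scenario?
#'
#' The filling-the-gaps scenario requires at least one known association in
#' every row (ligand) and every column (receptor), so that neighbor-informed
#' features can be extracted for every pair.
#'
#' @param A an `assoc_matrix`.
#' @return `TRUE`/`FALSE`.
#' @export
is_gaps_ready <- function(A) {
  known <- !is.na(A)
  all(rowSums(known) >= 1L) && all(colSums(known) >= 1L)
}

#' Hide a set of pairs from an association matrix
#'
#' Returns a copy of `A` in which the listed (ligand, receptor) pairs are set
#' to `NA`. This is the masking primitive behind leakage-safe evaluation:
#' collaborative similarities and neighbor-informed features for a split are
#' computed on a view of `A` with every test pair masked.
#'
#' @param A an `assoc_matrix`.
#' @param pairs data frame with character columns `ligand` and `receptor`.
#' @return an `assoc_matrix` with the pairs set to `NA`; `A` is unchanged.
#' @export
mask_entries <- function(A, pairs) {
  pairs <- .as_pairs(pairs)
  li <- match(pairs$ligand, rownames(A))
  ri <- match(pairs$receptor, colnames(A))
  if (anyNA(li))
    stop("unknown ligand identifier(s): ",
         paste(unique(pairs$ligand[is.na(li)]), collapse = ", "))
  if (anyNA(ri))
    stop("unknown receptor identifier(s): ",
         paste(unique(pairs$receptor[is.na(ri)]), collapse = ", "))
  B <- A
  B[cbind(li, ri)] <- NA_integer_
  B
}

.as_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("ligand", "receptor") %in% names(pairs)))
    stop("`pairs` must be a data frame with columns 'ligand' and 'receptor'")
  data.frame(ligand = as.character(pairs$ligand),
             receptor = as.character(pairs$receptor),
             stringsAsFactors = FALSE)
}

# all (ligand, receptor) index pairs of a logical selection matrix
.which_pairs <- function(A, sel) {
  idx <- which(sel, arr.ind = TRUE)
  data.frame(ligand = rownames(A)[idx[, 1L]],
             receptor = colnames(A)[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' All unknown (ligand, receptor) pairs of a matrix
#' @param A an `assoc_matrix`.
#' @return data frame with columns `ligand`, `receptor`.
#' @export
unknown_pairs <- function(A) .which_pairs(A, is.na(A))

#' All known (ligand, receptor) pairs of a matrix
#' @param A an `assoc_matrix`.
#' @return data frame with columns `ligand`, `receptor`, `label`.
#' @export
known_pairs <- function(A) {
  p <- .which_pairs(A, !is.na(A))
  p$label <- A[cbind(match(p$ligand, rownames(A)),
                     match(p$receptor, colnames(A)))]
  p
}
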