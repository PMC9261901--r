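#' Hashed binary fingerprints from SMILES strings
#'
#' Open-source stand-in for proprietary structural fingerprints. Two kinds
#' are produced from the molecular graph parsed out of a SMILES string:
#'
#' * `"linear"`: every simple path of 1..`max_path` atoms, labelled by its
#'   atom and bond symbols (canonicalized by taking the lexicographically
#'   smaller reading direction), hashed into an `n_bits` address space.
#' * `"atom_environment"`: for every atom, its circular environment at
#'   topological radii 0..`max_radius`, labelled by the sorted multiset of
#'   atom types at each distance (MOLPRINT2D-like), hashed likewise.
#'
#' Both labellings depend only on the molecular graph, not on the order
#' atoms appear in the SMILES string, so equivalent SMILES of the same
#' molecule yield identical fingerprints. The parser covers the organic
#' subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic lowercase atoms,
#' bracket atoms (isotope/charge/stereo annotations ignored), branches,
#' ring closures (including `%nn`) and bond symbols `- = # :` (`/` and
#' `\` are read as single bonds). Kekulized six-membered rings with
#' alternating single/double bonds over C/N/O/S atoms are perceived as
#' aromatic. Hydrogens are implicit and ignored.
#'
#' @param smiles character vector of SMILES strings; names (if present)
#'   become molecule identifiers, else `mol1`, `mol2`, ...
#' @param kind `"linear"` or `"atom_environment"`.
#' @param n_bits fingerprint address space (default 1024).
#' @param max_path maximum atoms per linear path (default 7).
#' @param max_radius maximum topological radius for atom environments
#'   (default 2).
#' @return a [fingerprint_set()].
#' @examples
#' fps <- fingerprints_from_smiles(c(benzene = "c1ccccc1", hexane = "CCCCCC"))
#' tanimoto_matrix(fps)["benzene", "hexane"] < 1
#' @export
fingerprints_from_smiles <- function(smiles,
                                     kind = c("linear", "atom_environment"),
                                     n_bits = 1024L, max_path = 7L,
                                     max_radius = 2L) {
  kind <- match.arg(kind)
  ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  parsed <- lapply(smiles, function(s) tryCatch(.parse_smiles(s),
                                                error = function(e) NULL))
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("unparseable SMILES: ", paste(smiles[bad], collapse = ", "))
  bits <- lapply(parsed, function(mol) {
    labels <- if (kind == "linear")
      .path_labels(mol, max_path) else .environment_labels(mol, max_radius)
    sort(unique(.hash_string(labels) %% as.integer(n_bits)))
  })
  names(bits) <- ids
  fingerprint_set(bits, kind = kind)
}

# deterministic polynomial rolling hash over bytes, modulus prime < 2^26
# (keeps double arithmetic exact)
.hash_string <- function(x) {
  p <- 67108859
  vapply(x, function(s) {
    h <- 5381
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% p
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# --- SMILES parsing ---------------------------------------------------------

.organic <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

.parse_smiles <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  atoms_el <- character(0)   # element symbol
  atoms_ar <- logical(0)     # aromatic flag
  bonds <- list()            # list of c(i, j, order); order 1,2,3 or 4=aromatic
  prev <- NA_integer_
  pending_bond <- NA_real_
  stack <- integer(0)
  ring_open <- list()        # ring-closure digit -> c(atom, pending bond)
  i <- 1L
  add_atom <- function(el, ar) {
    atoms_el[[length(atoms_el) + 1L]] <<- el
    atoms_ar[[length(atoms_ar) + 1L]] <<- ar
    idx <- length(atoms_el)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (ar && atoms_ar[prev]) 4 else 1
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pending_bond <<- NA_real_
    prev <<- idx
  }
  close_ring <- function(tag) {
    if (!is.null(ring_open[[tag]])) {
      open <- ring_open[[tag]]
      ord <- pending_bond
      if (is.na(ord)) ord <- open[2L]
      if (is.na(ord)) ord <- if (atoms_ar[open[1L]] && atoms_ar[prev]) 4 else 1
      bonds[[length(bonds) + 1L]] <<- c(open[1L], prev, ord)
      ring_open[[tag]] <<- NULL
      pending_bond <<- NA_real_
    } else {
      ring_open[[tag]] <<- c(prev, pending_bond)
      pending_bond <<- NA_real_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # strip isotope, stereo, explicit H, charge
      core <- sub("^[0-9]*", "", body)
      m <- regmatches(core, regexpr("^([A-Z][a-z]?|[bcnops]|\\*)", core))
      if (length(m) == 0L) stop("cannot read bracket atom: ", body)
      el <- m
      ar <- el %in% .aromatic_organic
      if (ar) el <- toupper(el)
      add_atom(el, ar)
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); i <- i + 2L
    } else if (ch %in% .organic) {
      add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% .aromatic_organic) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "-") { pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") { pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") { pending_bond <- 3; i <- i + 1L
    } else if (ch == ":") { pending_bond <- 4; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pending_bond <- 1; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad ring closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1L
    } else {
      stop("unexpected character '", ch, "'")
    }
  }
  if (length(stack)) stop("unbalanced parenthesis")
  if (length(Filter(Negate(is.null), ring_open))) stop("unclosed ring bond")
  if (length(atoms_el) == 0L) stop("empty molecule")
  mol <- list(element = atoms_el, aromatic = atoms_ar,
              bonds = if (length(bonds)) do.call(rbind, bonds)
                      else matrix(numeric(0), 0, 3))
  .perceive_aromatic_rings(mol)
}

# adjacency list with bond orders
.adjacency <- function(mol) {
  n <- length(mol$element)
  adj <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      adj[[b[1L]]] <- c(adj[[b[1L]]], b[2L])
      adj[[b[2L]]] <- c(adj[[b[2L]]], b[1L])
      ord[[b[1L]]] <- c(ord[[b[1L]]], b[3L])
      ord[[b[2L]]] <- c(ord[[b[2L]]], b[3L])
    }
  }
  list(nb = adj, ord = ord)
}

# mark six-membered rings of C/N/O/S with alternating single/double bonds
# as aromatic (covers kekulized aromatic ring notation)
.perceive_aromatic_rings <- function(mol) {
  n <- length(mol$element)
  if (n < 6L || nrow(mol$bonds) < 6L) return(mol)
  adj <- .adjacency(mol)
  bond_order <- function(a, b) {
    k <- which(adj$nb[[a]] == b)[1L]
    adj$ord[[a]][k]
  }
  rings <- .find_rings6(adj$nb, n)
  for (ring in rings) {
    if (!all(mol$element[ring] %in% c("C", "N", "O", "S"))) next
    ords <- vapply(seq_along(ring), function(k) {
      bond_order(ring[k], ring[if (k == length(ring)) 1L else k + 1L])
    }, numeric(1))
    if (all(ords == 4)) next  # already aromatic
    alternating <- all(ords %in% c(1, 2)) &&
      all(abs(diff(c(ords, ords[1L]))) == 1)
    if (alternating) {
      mol$aromatic[ring] <- TRUE
      for (k in seq_along(ring)) {
        a <- ring[k]; b <- ring[if (k == length(ring)) 1L else k + 1L]
        hit <- (mol$bonds[, 1L] == a & mol$bonds[, 2L] == b) |
               (mol$bonds[, 1L] == b & mol$bonds[, 2L] == a)
        mol$bonds[hit, 3L] <- 4
      }
    }
  }
  mol
}

# enumerate simple 6-cycles by DFS, deduplicated by atom set
.find_rings6 <- function(nb, n) {
  rings <- list()
  seen <- character(0)
  dfs <- function(path) {
    last <- path[length(path)]
    for (nxt in nb[[last]]) {
      if (length(path) == 6L && nxt == path[1L]) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (length(path) < 6L && !(nxt %in% path) && nxt > path[1L]) {
        dfs(c(path, nxt))
      }
    }
  }
  for (start in seq_len(n)) dfs(start)
  rings
}

.atom_label <- function(mol, i)
  if (mol$aromatic[i]) tolower(mol$element[i]) else mol$element[i]

.bond_symbol <- function(order) c("-", "=", "#", ":")[order]

.path_labels <- function(mol, max_path) {
  adj <- .adjacency(mol)
  n <- length(mol$element)
  labels <- character(0)
  emit <- function(path, bond_orders) {
    al <- vapply(path, function(i) .atom_label(mol, i), character(1))
    bs <- .bond_symbol(bond_orders)
    fwd <- paste0(al[1L], if (length(bs))
      paste0(paste0(bs, al[-1L]), collapse = "") else "")
    rev_ <- paste0(al[length(al)], if (length(bs))
      paste0(paste0(rev(bs), rev(al)[-1L]), collapse = "") else "")
    labels[[length(labels) + 1L]] <<- min(fwd, rev_)
  }
  dfs <- function(path, bond_orders) {
    emit(path, bond_orders)
    if (length(path) == max_path) return()
    last <- path[length(path)]
    for (k in seq_along(adj$nb[[last]])) {
      nxt <- adj$nb[[last]][k]
      if (!(nxt %in% path))
        dfs(c(path, nxt), c(bond_orders, adj$ord[[last]][k]))
    }
  }
  for (start in seq_len(n)) dfs(start, numeric(0))
  unique(labels)
}

.environment_labels <- function(mol, max_radius) {
  adj <- .adjacency(mol)
  n <- length(mol$element)
  labels <- character(0)
  for (center in seq_len(n)) {
    # BFS topological distances
    dist <- rep(NA_integer_, n)
    dist[center] <- 0L
    frontier <- center
    d <- 0L
    while (length(frontier) && d < max_radius) {
      d <- d + 1L
      nxt <- unique(unlist(adj$nb[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    for (r in 0:max_radius) {
      shells <- vapply(0:r, function(dd) {
        at <- which(!is.na(dist) & dist == dd)
        paste(sort(vapply(at, function(i) .atom_label(mol, i),
                          character(1))), collapse = ",")
      }, character(1))
      labels[[length(labels) + 1L]] <-
        paste0("E", r, "|", paste(shells, collapse = ";"))
    }
  }
  unique(labels)
}
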