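## Morgan (circular) fingerprints, Tanimoto similarity, Murcko scaffolds.

.HASH_MOD <- 2147483647  # 2^31 - 1; polynomial hashing stays exact in doubles

.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 1000003 + x + 7) %% .HASH_MOD
  h
}

#' Morgan circular fingerprint
#'
#' Hashed binary fingerprint of circular atom environments, the standard
#' similarity representation for small-molecule libraries. Initial atom
#' invariants are (atomic element, heavy-atom degree, total hydrogen count,
#' formal charge, ring membership); identifiers are refined over bond
#' neighborhoods up to `radius` (aromatic ring bonds contribute order 1.5,
#' which makes the bit vector independent of the kekule structure chosen by
#' the SMILES writer), and every identifier at every radius is hashed onto
#' `nbits` bits.
#'
#' Always fingerprint *standardized* SMILES (see [standardize_structure()]):
#' two spellings of the same molecule share a canonical SMILES and therefore
#' a fingerprint.
#'
#' @param smiles character vector of valid SMILES.
#' @param radius maximum environment radius in bonds (default 2).
#' @param nbits fingerprint length (default 1024).
#' @return 0/1 integer matrix, one row per molecule, `nbits` columns.
#' @export
#' @examples
#' fp <- morgan_fingerprint(c("CCO", "c1ccccc1"))
#' rowSums(fp)
morgan_fingerprint <- function(smiles, radius = 2, nbits = 1024) {
  stopifnot(radius >= 0, nbits >= 2)
  graphs <- parse_mol_graphs(smiles)
  fp <- matrix(0L, nrow = length(smiles), ncol = nbits)
  rownames(fp) <- names(smiles)
  for (i in seq_along(graphs)) {
    ids <- .morgan_ids(graphs[[i]], radius)
    if (length(ids)) fp[i, unique(ids %% nbits) + 1L] <- 1L
  }
  fp
}

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

.morgan_ids <- function(g, radius) {
  n <- length(g$element)
  if (n == 0) return(numeric(0))
  deg <- .degree(g)
  z <- .ELEMENT_Z[g$element]
  z[is.na(z)] <- 99
  cur <- vapply(seq_len(n), function(i) {
    .hash_ints(c(z[i], deg[i], g$n_h[i], g$charge[i] + 8, as.integer(g$ring[i])))
  }, numeric(1))
  all_ids <- cur
  if (radius == 0 || nrow(g$bonds) == 0) return(all_ids)
  ord10 <- as.integer(round(.bond_orders_aromatic(g) * 10))
  nb <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    a <- g$bonds[r, 1]; b <- g$bonds[r, 2]
    nb[[a]] <- rbind(nb[[a]], c(ord10[r], b))
    nb[[b]] <- rbind(nb[[b]], c(ord10[r], a))
  }
  for (iter in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      if (is.null(nb[[i]])) { nxt[i] <- .hash_ints(c(iter, cur[i])); next }
      pairs <- cbind(nb[[i]][, 1], cur[nb[[i]][, 2]])
      o <- order(pairs[, 1], pairs[, 2])
      nxt[i] <- .hash_ints(c(iter, cur[i], as.vector(t(pairs[o, , drop = FALSE]))))
    }
    cur <- nxt
    all_ids <- c(all_ids, cur)
  }
  all_ids
}

#' Tanimoto similarity of two binary fingerprints
#'
#' Intersection over union of the on-bit sets, in \eqn{[0, 1]}. Two all-zero
#' vectors are defined to have similarity 0 (a convention that only affects
#' molecules with no hashed environments).
#'
#' @param a,b 0/1 vectors of identical length.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch", call. = FALSE)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

#' All-vs-all Tanimoto similarity matrix
#'
#' @param fp 0/1 fingerprint matrix (rows = molecules).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "double"
  inter <- fp %*% t(fp)
  on <- rowSums(fp)
  uni <- outer(on, on, "+") - inter
  tc <- ifelse(uni > 0, inter / uni, 0)
  diag(tc) <- 1
  rownames(tc) <- colnames(tc) <- rownames(fp)
  tc
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them; side chains are removed by
#' iteratively deleting terminal atoms attached through single bonds (so
#' exocyclic multiple bonds, e.g. a ketone oxygen on a ring, are retained).
#' Acyclic molecules have an empty scaffold.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @export
#' @examples
#' murcko_scaffold(c("Cc1ccccc1", "CCCCCC"))
murcko_scaffold <- function(smiles) {
  graphs <- parse_mol_graphs(smiles)
  vapply(graphs, function(g) {
    if (!any(g$ring)) return("")
    keep <- seq_along(g$element)
    repeat {
      deg <- integer(length(g$element))
      bsel <- g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep
      bonds <- g$bonds[bsel, , drop = FALSE]
      for (r in seq_len(nrow(bonds))) {
        deg[bonds[r, 1]] <- deg[bonds[r, 1]] + 1L
        deg[bonds[r, 2]] <- deg[bonds[r, 2]] + 1L
      }
      # terminal atoms hanging off a single bond are side-chain atoms
      drop <- keep[vapply(keep, function(i) {
        if (deg[i] != 1L) return(FALSE)
        r <- which(bsel & (g$bonds[, 1] == i | g$bonds[, 2] == i))
        length(r) == 1 && g$bonds[r, "order"] == 1L
      }, logical(1))]
      if (length(drop) == 0) break
      keep <- setdiff(keep, drop)
    }
    if (length(keep) == 0 || !any(g$ring[keep])) return("")
    graph_subset_to_smiles(g, keep)
  }, character(1))
}
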