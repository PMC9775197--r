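## Low-level molecular graph backend on top of ChemmineR / ChemmineOB (OpenBabel).
## Everything downstream (fingerprints, scaffolds, MCS, descriptors) consumes the
## graph representation built here.

# old-style SDF atom-block charge codes -> formal charge
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                 `6` = -2L, `7` = -3L)

# default valences used for implicit hydrogen assignment; S/P/Se pick the
# smallest standard valence that accommodates the bond-order sum
.DEFAULT_VALENCE <- list(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
                         S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1)

.ORGANIC_SUBSET <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se",
                     "Br", "I")

#' Convert a vector of SMILES one molecule at a time
#'
#' OpenBabel batch conversion silently drops unparsable entries, so anything
#' whose validity is unknown goes through this per-molecule path; invalid
#' entries come back as `NA` and keep their position.
#'
#' @param smiles character vector of SMILES strings.
#' @param to output format understood by OpenBabel (e.g. `"CAN"`,
#'   `"INCHIKEY"`).
#' @param neutralize apply OpenBabel's neutralize transformation (protonate
#'   anions / deprotonate cations) before writing.
#' @return character vector, `NA` where the input did not parse.
#' @keywords internal
ob_convert_each <- function(smiles, to = "CAN", neutralize = FALSE) {
  convert <- if (neutralize) {
    opts <- data.frame(names = "neutralize", args = "")
    function(src) ChemmineOB::convertFormat("SMI", to, source = src,
                                            options = opts)
  } else {
    function(src) ChemmineOB::convertFormat("SMI", to, source = src)
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- suppressWarnings(try(convert(paste0(s, "\n")), silent = TRUE))
    if (inherits(out, "try-error")) return(NA_character_)
    out <- sub("\t.*$", "", sub("\n$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Parse SMILES into molecular graphs
#'
#' Builds, per molecule: element symbols, formal charges, implicit hydrogen
#' counts, a bond table with kekulized orders, ring membership and aromatic
#' flags (an atom/bond is aromatic when it belongs to an aromatic ring as
#' perceived by [ChemmineR::rings()]).
#'
#' @param smiles character vector of valid SMILES (caller guarantees validity;
#'   use [ob_convert_each()] to screen first).
#' @return list of `mol_graph` lists with elements `element`, `charge`,
#'   `n_h`, `ring`, `aromatic`, `bonds` (matrix: a, b, order columns),
#'   `bond_aromatic`, `smiles`.
#' @keywords internal
parse_mol_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  nm <- paste0("m", seq_along(smiles))
  single <- grepl(.SINGLE_ATOM_RE, smiles)
  out <- vector("list", length(smiles))
  if (any(!single)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles[!single], nm[!single])))
    out[!single] <- lapply(seq_len(sum(!single)), function(j)
      .graph_from_sdf(sdf[[j]], smiles[!single][[j]]))
  }
  out[single] <- lapply(smiles[single], .single_atom_graph)
  out
}

# one heavy atom, optionally bracketed with H count and charge
.SINGLE_ATOM_RE <- "^(\\[([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]|[A-IK-Za-ik-z][a-z]?)$"

.single_atom_graph <- function(smi) {
  m <- regmatches(smi, regexec(.SINGLE_ATOM_RE, smi))[[1]]
  elem <- if (nzchar(m[3])) m[3] else m[2]
  elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  charge <- 0L
  if (nzchar(m[5])) {
    sgn <- if (substr(m[5], 1, 1) == "+") 1L else -1L
    mag <- if (nchar(m[5]) > 1) as.integer(substring(m[5], 2)) else 1L
    charge <- sgn * mag
  }
  n_h <- if (nzchar(m[4])) {
    if (nchar(m[4]) > 1) as.integer(substring(m[4], 2)) else 1L
  } else {
    .implicit_h(elem, charge,
                matrix(integer(0), ncol = 3,
                       dimnames = list(NULL, c("a", "b", "order"))), 1L)
  }
  list(element = elem, charge = charge, n_h = n_h, ring = FALSE,
       aromatic = FALSE, n_aromatic_rings = 0L,
       bonds = matrix(integer(0), ncol = 3,
                      dimnames = list(NULL, c("a", "b", "order"))),
       bond_aromatic = logical(0), smiles = smi)
}

.graph_from_sdf <- function(sdfobj, smi) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge <- .sdf_charges(sdfobj, n)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
  } else {
    bonds <- cbind(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  ring <- logical(n); arom <- logical(n)
  bond_arom <- logical(nrow(bonds))
  n_arom_rings <- 0L
  if (nrow(bonds) > 0 && n >= 3) {
    rng <- suppressWarnings(try(ChemmineR::rings(sdfobj, upper = 14,
                                                 type = "all", arom = TRUE),
                                silent = TRUE))
    if (!inherits(rng, "try-error") && length(rng$RINGS) > 0) {
      for (k in seq_along(rng$RINGS)) {
        idx <- as.integer(sub("^.*_", "", rng$RINGS[[k]]))
        ring[idx] <- TRUE
        is_ar <- isTRUE(rng$AROMATIC[[k]])
        if (is_ar) arom[idx] <- TRUE
        # simple aromatic rings; fused envelopes excluded from the count
        if (is_ar && length(idx) <= 7) n_arom_rings <- n_arom_rings + 1L
        m <- length(idx)
        pairs <- cbind(idx, idx[c(2:m, 1)])
        for (p in seq_len(m)) {
          hit <- which((bonds[, 1] == pairs[p, 1] & bonds[, 2] == pairs[p, 2]) |
                       (bonds[, 1] == pairs[p, 2] & bonds[, 2] == pairs[p, 1]))
          if (length(hit) && is_ar) bond_arom[hit] <- TRUE
        }
      }
    }
  }
  n_h <- .implicit_h(element, charge, bonds, n)
  list(element = element, charge = charge, n_h = n_h, ring = ring,
       aromatic = arom, bonds = bonds, bond_aromatic = bond_arom,
       n_aromatic_rings = n_arom_rings, smiles = smi)
}

.sdf_charges <- function(sdfobj, n) {
  lines <- ChemmineR::sdf2str(sdfobj)
  charge <- integer(n)
  atom_lines <- lines[5:(4 + n)]
  for (i in seq_len(n)) {
    f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    if (length(f) >= 6) {
      code <- f[6]
      if (code %in% names(.SDF_CHARGE)) charge[i] <- .SDF_CHARGE[[code]]
    }
  }
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (l in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  charge
}

.implicit_h <- function(element, charge, bonds, n) {
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds[r, 1]] <- bsum[bonds[r, 1]] + bonds[r, 3]
      bsum[bonds[r, 2]] <- bsum[bonds[r, 2]] + bonds[r, 3]
    }
  }
  vapply(seq_len(n), function(i) {
    val <- .DEFAULT_VALENCE[[element[i]]]
    if (is.null(val)) return(0L)             # metals etc.: no implicit H
    val <- val[val >= bsum[i]][1]
    if (is.na(val)) return(0L)
    as.integer(max(0, val + charge[i] - bsum[i]))
  }, integer(1))
}

#' Heavy-atom degree per atom
#' @keywords internal
.degree <- function(g) {
  d <- integer(length(g$element))
  if (nrow(g$bonds) > 0) {
    t1 <- table(factor(g$bonds[, 1], levels = seq_along(d)))
    t2 <- table(factor(g$bonds[, 2], levels = seq_along(d)))
    d <- as.integer(t1 + t2)
  }
  d
}

#' Effective bond orders (aromatic ring bonds counted as 1.5)
#' @keywords internal
.bond_orders_aromatic <- function(g) {
  ord <- as.numeric(g$bonds[, "order"])
  ord[g$bond_aromatic] <- 1.5
  ord
}

#' Split a SMILES into dot-separated fragments
#' @keywords internal
split_fragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

#' Element symbols occurring in a molecule
#' @keywords internal
mol_elements <- function(smiles) {
  g <- try(parse_mol_graphs(smiles)[[1]], silent = TRUE)
  if (inherits(g, "try-error")) return(character(0))
  unique(g$element)
}

#' Rebuild an SDF text block from a pruned atom subset of a graph
#'
#' Used by the Murcko scaffold extraction: keeps the original 2-D coordinates
#' irrelevant (zeros), element symbols, charges and kekulized bond orders, so
#' OpenBabel can re-perceive the fragment and emit canonical SMILES.
#'
#' @keywords internal
graph_subset_to_smiles <- function(g, keep) {
  keep <- sort(keep)
  n <- length(keep)
  if (n == 0) return("")
  remap <- integer(length(g$element)); remap[keep] <- seq_len(n)
  bsel <- g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  hdr <- c("scaffold", "  ureascape", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  atoms <- vapply(keep, function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$element[i])
  }, character(1))
  bl <- character(nrow(bonds))
  if (nrow(bonds) > 0) {
    bl <- vapply(seq_len(nrow(bonds)), function(r) {
      sprintf("%3d%3d%3d  0  0  0  0", remap[bonds[r, 1]], remap[bonds[r, 2]],
              bonds[r, 3])
    }, character(1))
  }
  chg <- which(g$charge[keep] != 0)
  chg_lines <- if (length(chg))
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, g$charge[keep][chg]), collapse = ""))
  else character(0)
  sdf_txt <- paste(c(hdr, atoms, bl, chg_lines, "M  END", "$$$$"), collapse = "\n")
  out <- suppressWarnings(try(ChemmineOB::convertFormat(
    "SDF", "CAN", source = paste0(sdf_txt, "\n")), silent = TRUE))
  if (inherits(out, "try-error")) return("")
  sub("\t.*$", "", sub("\n$", "", out))
}

#' Parse SMILES into OpenBabel molecule references
#'
#' The reference list feeds [smarts_count()] and [ChemmineOB::prop_OB()];
#' unlike the SDF route it handles single-atom molecules.
#'
#' @param smiles character vector of valid SMILES.
#' @return list of OBMol external references.
#' @keywords internal
ob_mols <- function(smiles) {
  suppressWarnings(ChemmineOB::forEachMol(
    "SMILES", paste0(paste(smiles, collapse = "\n"), "\n"), identity))
}

#' Count SMARTS matches per molecule
#'
#' @param mols list of OBMol references (see [ob_mols()]).
#' @param smarts single SMARTS pattern.
#' @param unique count unique atom sets (`TRUE`) or raw directed matches.
#' @return integer vector of match counts, one per molecule.
#' @keywords internal
smarts_count <- function(mols, smarts, unique = TRUE) {
  out <- try(suppressWarnings(ChemmineOB::smartsSearch_OB(
    mols, smarts, uniqueMatches = unique)), silent = TRUE)
  if (inherits(out, "try-error") || length(out) != length(mols))
    stop("malformed SMARTS pattern: ", smarts, call. = FALSE)
  as.integer(out)
}
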