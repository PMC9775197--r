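## Maximum common substructure between molecules: connected induced common
## subgraph maximizing atom count, found by label-constrained backtracking.
## Ring atoms only match ring atoms, and matched bonds must agree on order
## (aromatic ring bonds are order 1.5). Search is strict; the rendered SMARTS
## is deliberately permissive on bonds ("~") so the guarantee "matches every
## member" survives kekulization differences in the substructure matcher.

# compact label graph used by the search: elements, ring flags, bond matrix
# with order*10 (aromatic 15)
.mcs_graph <- function(g) {
  ord10 <- as.integer(round(.bond_orders_aromatic(g) * 10))
  list(element = g$element, ring = g$ring,
       bonds = cbind(a = g$bonds[, 1], b = g$bonds[, 2], ord = ord10))
}

.mcs_adj <- function(mg) {
  n <- length(mg$element)
  adj <- matrix(0L, n, n)
  for (r in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds[r, 1]; b <- mg$bonds[r, 2]; o <- mg$bonds[r, 3]
    adj[a, b] <- o; adj[b, a] <- o
  }
  adj
}

# pairwise connected induced MCS between label graphs; returns atom index
# vectors (map1 in mg1, map2 in mg2) or empty on timeout
.mcs_pair <- function(mg1, mg2, deadline) {
  n1 <- length(mg1$element); n2 <- length(mg2$element)
  adj1 <- .mcs_adj(mg1); adj2 <- .mcs_adj(mg2)
  lab1 <- paste(mg1$element, mg1$ring)
  lab2 <- paste(mg2$element, mg2$ring)
  compat <- outer(lab1, lab2, "==")

  best <- list(m1 = integer(0), m2 = integer(0))
  timed_out <- FALSE

  # upper bound on how large the current mapping can still grow: unmapped
  # atoms on either side that retain at least one compatible partner
  upper_bound <- function(m1, m2) {
    free1 <- setdiff(seq_len(n1), m1)
    free2 <- setdiff(seq_len(n2), m2)
    if (!length(free1) || !length(free2)) return(length(m1))
    sub <- compat[free1, free2, drop = FALSE]
    length(m1) + min(sum(rowSums(sub) > 0), sum(colSums(sub) > 0))
  }

  extend <- function(m1, m2) {
    if (Sys.time() > deadline) { timed_out <<- TRUE; return() }
    if (length(m1) > length(best$m1)) best <<- list(m1 = m1, m2 = m2)
    if (upper_bound(m1, m2) <= length(best$m1)) return()
    # frontier: unmapped atoms of g1 adjacent to the mapped core
    cand1 <- setdiff(which(colSums(adj1[m1, , drop = FALSE] > 0) > 0), m1)
    saved <- list()
    for (a in cand1) {
      for (b in setdiff(which(compat[a, ]), m2)) {
        # induced consistency: bonds to every mapped atom must agree
        if (all(adj1[a, m1] == adj2[b, m2])) {
          extend(c(m1, a), c(m2, b))
          if (timed_out) break
        }
      }
      if (timed_out) break
      # branch where a stays outside the common subgraph: bar it from the
      # rest of this subtree (keeps the enumeration exhaustive, no repeats)
      saved[[length(saved) + 1]] <- list(a = a, row = compat[a, ])
      compat[a, ] <<- FALSE
    }
    for (s in saved) compat[s$a, ] <<- s$row
  }

  seeds <- which(compat, arr.ind = TRUE)
  # rarest labels first shrink the search tree
  if (nrow(seeds) > 0) {
    freq <- table(lab1)[lab1[seeds[, 1]]]
    seeds <- seeds[order(freq, seeds[, 1], seeds[, 2]), , drop = FALSE]
  }
  done1 <- integer(0)
  for (s in seq_len(nrow(seeds))) {
    if (Sys.time() > deadline) { timed_out <- TRUE; break }
    a <- seeds[s, 1]
    if (a %in% done1) next
    extend(a, seeds[s, 2])
    if (timed_out) break
    # all subgraphs containing atom a were enumerated while a was the seed
    if (s == nrow(seeds) || seeds[s + 1, 1] != a) {
      done1 <- c(done1, a)
      compat[a, ] <- FALSE
    }
  }
  list(m1 = best$m1, m2 = best$m2, timed_out = timed_out)
}

# restrict a label graph to an atom subset (indices remapped)
.mcs_subgraph <- function(mg, keep) {
  remap <- integer(length(mg$element)); remap[keep] <- seq_along(keep)
  sel <- mg$bonds[, 1] %in% keep & mg$bonds[, 2] %in% keep
  b <- mg$bonds[sel, , drop = FALSE]
  list(element = mg$element[keep], ring = mg$ring[keep],
       bonds = cbind(a = remap[b[, 1]], b = remap[b[, 2]], ord = b[, 3]))
}

#' Maximum common substructure of a set of molecules
#'
#' Largest connected substructure (by atom count) shared by every molecule,
#' with ring atoms matched only to ring atoms and bond orders required to
#' agree during the search. The result is rendered as a SMARTS pattern with
#' per-atom element + ring-membership constraints and order-agnostic (`~`)
#' bonds, so it matches each member molecule as a substructure. Multi-way
#' search folds pairwise: the running common pattern is intersected with
#' each next molecule (smallest first).
#'
#' @param smiles character vector (>= 2) of valid SMILES.
#' @param timeout seconds allowed for the whole search; on expiry an empty
#'   flagged result is returned rather than an error.
#' @return list with `mcs_smarts` (`""` when empty), `mcs_n_atoms`, and
#'   `timed_out` flag.
#' @export
#' @examples
#' cluster_mcs(c("Cc1ccccc1", "CCc1ccccc1"))
cluster_mcs <- function(smiles, timeout = 60) {
  stopifnot(length(smiles) >= 2)
  deadline <- Sys.time() + timeout
  graphs <- lapply(parse_mol_graphs(smiles), .mcs_graph)
  sizes <- vapply(graphs, function(g) length(g$element), integer(1))
  graphs <- graphs[order(sizes)]
  pattern <- graphs[[1]]
  for (i in 2:length(graphs)) {
    res <- .mcs_pair(pattern, graphs[[i]], deadline)
    if (res$timed_out)
      return(list(mcs_smarts = "", mcs_n_atoms = 0L, timed_out = TRUE))
    if (length(res$m1) == 0)
      return(list(mcs_smarts = "", mcs_n_atoms = 0L, timed_out = FALSE))
    pattern <- .mcs_subgraph(pattern, res$m1)
  }
  list(mcs_smarts = .mcs_to_smarts(pattern),
       mcs_n_atoms = length(pattern$element), timed_out = FALSE)
}

.ELEMENT_Z_SMARTS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                       P = 15, S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

# render a connected label graph as SMARTS (DFS with ring-closure digits)
.mcs_to_smarts <- function(mg) {
  n <- length(mg$element)
  if (n == 0) return("")
  adj <- vector("list", n)
  for (r in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds[r, 1]; b <- mg$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(n)
  parent <- integer(n)
  closure_at <- vector("list", n)  # ring-closure digit strings per atom
  tree_children <- vector("list", n)
  n_digit <- 0L
  seen_edge <- matrix(FALSE, n, n)

  order_dfs <- function(a) {
    visited[a] <<- TRUE
    for (b in adj[[a]]) {
      if (seen_edge[a, b]) next
      seen_edge[a, b] <<- TRUE; seen_edge[b, a] <<- TRUE
      if (!visited[b]) {
        parent[b] <<- a
        tree_children[[a]] <<- c(tree_children[[a]], b)
        order_dfs(b)
      } else {
        n_digit <<- n_digit + 1L
        d <- if (n_digit < 10) as.character(n_digit)
             else paste0("%", n_digit)
        closure_at[[a]] <<- c(closure_at[[a]], d)
        closure_at[[b]] <<- c(closure_at[[b]], d)
      }
    }
  }
  order_dfs(1L)

  atom_expr <- function(a) {
    z <- .ELEMENT_Z_SMARTS[mg$element[a]]
    if (is.na(z)) z <- 0
    sprintf("[#%d;%s]", z, if (mg$ring[a]) "R" else "!R")
  }
  emit <- function(a) {
    s <- paste0(atom_expr(a),
                paste0(vapply(closure_at[[a]], function(d) paste0("~", d),
                              character(1)), collapse = ""))
    kids <- tree_children[[a]]
    if (length(kids) > 1) {
      for (b in kids[-length(kids)]) s <- paste0(s, "(~", emit(b), ")")
    }
    if (length(kids) >= 1) s <- paste0(s, "~", emit(kids[length(kids)]))
    s
  }
  emit(1L)
}
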