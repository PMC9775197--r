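# Independent brute-force oracles used to cross-check the package's
# implementations on tiny fixtures, plus a cached default synthetic library
# (several files exercise the same study conditions; generating it once
# keeps the suite fast).

.cache <- new.env(parent = emptyenv())

cached_library <- function(seed = 1, noise_sd = 0) {
  key <- sprintf("lib_%d_%g", seed, noise_sd)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_library(synth_config(seed = seed,
                                                   noise_sd = noise_sd))
  .cache[[key]]
}

cached_curated <- function(seed = 1, noise_sd = 0) {
  key <- sprintf("cur_%d_%g", seed, noise_sd)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- curate_bioassay(cached_library(seed, noise_sd)$records)
  .cache[[key]]
}

cached_descriptors <- function(seed = 1) {
  key <- sprintf("desc_%d", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- compute_descriptors(
      cached_curated(seed)$compounds$canonical_smiles)
  .cache[[key]]
}

# naive pairwise Tanimoto, double loop
naive_tanimoto_matrix <- function(fp) {
  n <- nrow(fp)
  out <- matrix(0, n, n, dimnames = list(rownames(fp), rownames(fp)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- fp[i, ]; b <- fp[j, ]
      uni <- sum(a | b)
      out[i, j] <- if (uni == 0) 0 else sum(a & b) / uni
    }
  }
  diag(out) <- 1
  out
}

# naive agglomerative complete-linkage clustering cut at height h:
# repeatedly merge the two clusters with the smallest maximum cross
# distance while that distance stays <= h
naive_complete_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(j, i) }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# naive all-vs-all similar-pair enumeration with SAR categories
naive_similar_pairs <- function(fp, classes, threshold) {
  keys <- rownames(fp)
  rows <- list()
  for (i in seq_len(nrow(fp) - 1)) {
    for (j in (i + 1):nrow(fp)) {
      a <- fp[i, ]; b <- fp[j, ]
      uni <- sum(a | b)
      tc <- if (uni == 0) 0 else sum(a & b) / uni
      if (tc > threshold) {
        ka <- min(keys[i], keys[j]); kb <- max(keys[i], keys[j])
        cat_ab <- if (classes[keys[i]] != classes[keys[j]]) "cliff"
                  else if (classes[keys[i]] == "active") "both_active"
                  else "both_inactive"
        rows[[length(rows) + 1]] <- data.frame(
          inchikey_a = ka, inchikey_b = kb, tc = tc, category = cat_ab,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(inchikey_a = character(0), inchikey_b = character(0),
                      tc = numeric(0), category = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$inchikey_a, out$inchikey_b), , drop = FALSE]
}

# exhaustive maximum common substructure size (atom count) between two tiny
# molecules: enumerate connected atom subsets of the smaller graph and test
# label-preserving induced embedding into the other by brute-force search
naive_mcs_size <- function(smiles_a, smiles_b) {
  gs <- ureascape:::parse_mol_graphs(c(smiles_a, smiles_b))
  sizes <- vapply(gs, function(g) length(g$element), integer(1))
  if (sizes[1] > sizes[2]) gs <- gs[c(2, 1)]
  g1 <- gs[[1]]; g2 <- gs[[2]]
  adj <- function(g) {
    n <- length(g$element)
    m <- matrix(0, n, n)
    ord <- ureascape:::.bond_orders_aromatic(g)
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]
      m[a, b] <- ord[r]; m[b, a] <- ord[r]
    }
    m
  }
  a1 <- adj(g1); a2 <- adj(g2)
  lab1 <- paste(g1$element, g1$ring); lab2 <- paste(g2$element, g2$ring)
  n1 <- length(lab1)
  connected <- function(sub) {
    if (length(sub) == 1) return(TRUE)
    seen <- sub[1]
    repeat {
      nxt <- sub[sub %in% which(colSums(a1[seen, , drop = FALSE] > 0) > 0)]
      nxt <- union(seen, nxt)
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(sub)
  }
  embeds <- function(sub, partial) {
    if (length(partial) == length(sub)) return(TRUE)
    a <- sub[length(partial) + 1]
    for (b in setdiff(which(lab2 == lab1[a]), partial)) {
      ok <- TRUE
      for (k in seq_along(partial)) {
        if (a1[a, sub[k]] != a2[b, partial[k]]) { ok <- FALSE; break }
      }
      if (ok && embeds(sub, c(partial, b))) return(TRUE)
    }
    FALSE
  }
  best <- 0L
  for (mask in seq_len(2^n1 - 1)) {
    sub <- which(bitwAnd(mask, 2^(seq_len(n1) - 1)) > 0)
    if (length(sub) <= best) next
    if (!connected(sub)) next
    if (embeds(sub, integer(0))) best <- length(sub)
  }
  best
}
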