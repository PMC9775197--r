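## Hierarchical clustering of the compound library: spontaneous threshold
## clustering (diversity statistic) and fixed-k structural families.

#' Spontaneous threshold clustering
#'
#' Complete-linkage agglomerative clustering on Tanimoto distance (1 - Tc),
#' cut so that every intra-cluster pairwise distance is at most `max_dist`.
#' The number of clusters produced is the library's diversity statistic: the
#' more clusters, the more diverse the set.
#'
#' @param tc symmetric Tanimoto similarity matrix (see [tanimoto_matrix()]).
#' @param max_dist maximum intra-cluster Tanimoto distance (default 0.6).
#' @return list with `assignment` (integer cluster ids from 0, named by the
#'   matrix rownames) and `n_clusters`.
#' @export
spontaneous_clustering <- function(tc, max_dist = 0.6) {
  n <- nrow(tc)
  if (n == 1) {
    asg <- stats::setNames(0L, rownames(tc))
    return(list(assignment = asg, n_clusters = 1L))
  }
  hc <- stats::hclust(stats::as.dist(1 - tc), method = "complete")
  cl <- stats::cutree(hc, h = max_dist)
  asg <- stats::setNames(as.integer(factor(cl, levels = unique(cl[hc$order]))) - 1L,
                         rownames(tc))
  list(assignment = asg, n_clusters = length(unique(asg)))
}

#' Fixed-k structural family clustering
#'
#' Ward-linkage agglomerative clustering (ward.D2, equivalent to the usual
#' Euclidean-Ward formulation) on the raw fingerprint bit vectors, cut into
#' exactly `k` families.
#'
#' @param fp 0/1 fingerprint matrix, rows = compounds.
#' @param k number of clusters, `2 <= k <= nrow(fp)`.
#' @return integer cluster ids from 0, named by fingerprint rownames.
#' @export
family_clustering <- function(fp, k) {
  n <- nrow(fp)
  if (k > n) stop("k exceeds the number of compounds", call. = FALSE)
  stopifnot(k >= 2)
  hc <- stats::hclust(stats::dist(fp, method = "euclidean"), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  stats::setNames(as.integer(factor(cl, levels = unique(cl[hc$order]))) - 1L,
                  rownames(fp))
}

#' Choose the number of structural families
#'
#' Codified stand-in for manual inspection of cluster size and cohesion:
#' among candidate `k` whose smallest cluster has at least `min_size`
#' members, pick the `k` with the most clusters of minimum intra-cluster
#' similarity >= `cohesion`; ties go to the smallest `k`. If no candidate
#' satisfies the size constraint it is dropped. The full per-k diagnostics
#' table is returned so the choice can be overridden by eye.
#'
#' @param fp fingerprint matrix.
#' @param k_range candidate cluster counts (default 20:80).
#' @param min_size smallest acceptable cluster size (default 3).
#' @param cohesion minimum intra-cluster Tc defining a cohesive cluster.
#' @param override if non-NULL, forces the returned `k` (diagnostics still
#'   computed).
#' @return list with `k` and `diagnostics` (data.frame: k, n_clusters,
#'   min_cluster_size, max_cluster_size, n_cohesive).
#' @export
select_k <- function(fp, k_range = 20:80, min_size = 3, cohesion = 0.5,
                     override = NULL) {
  n <- nrow(fp)
  if (n <= max(k_range)) stop("need more compounds than max(k_range)",
                              call. = FALSE)
  tc <- tanimoto_matrix(fp)
  hc <- stats::hclust(stats::dist(fp, method = "euclidean"), method = "ward.D2")
  rows <- lapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    sizes <- table(cl)
    min_tc <- vapply(split(seq_len(n), cl), function(idx) {
      if (length(idx) == 1) return(1.0)
      sub <- tc[idx, idx]
      min(sub[upper.tri(sub)])
    }, numeric(1))
    data.frame(k = k, n_clusters = length(sizes),
               min_cluster_size = min(sizes), max_cluster_size = max(sizes),
               n_cohesive = sum(min_tc >= cohesion))
  })
  diag_tab <- do.call(rbind, rows)
  if (!is.null(override)) return(list(k = override, diagnostics = diag_tab))
  ok <- diag_tab[diag_tab$min_cluster_size >= min_size, , drop = FALSE]
  pool <- if (nrow(ok) > 0) ok else diag_tab
  chosen <- pool$k[order(-pool$n_cohesive, pool$k)][1]
  list(k = chosen, diagnostics = diag_tab)
}

#' Per-cluster cohesion and activity summary
#'
#' Minimum and median pairwise intra-cluster Tanimoto similarity (singletons
#' use the convention min = median = 1.0), size and active percentage.
#'
#' @param assignment integer cluster ids named by compound key.
#' @param tc Tanimoto similarity matrix over the same keys.
#' @param classes character vector (`active`/`inactive`) named by key, or
#'   unnamed in matching order.
#' @return data.frame: `cluster_id`, `size`, `min_intra_tc`,
#'   `median_intra_tc`, `pct_active`.
#' @export
cluster_summary <- function(assignment, tc, classes) {
  keys <- names(assignment)
  if (!is.null(names(classes))) classes <- classes[keys]
  rows <- lapply(sort(unique(assignment)), function(cid) {
    idx <- which(assignment == cid)
    if (length(idx) == 1) {
      mn <- md <- 1.0
    } else {
      sub <- tc[keys[idx], keys[idx]]
      pair_tc <- sub[upper.tri(sub)]
      mn <- min(pair_tc); md <- stats::median(pair_tc)
    }
    data.frame(cluster_id = cid, size = length(idx),
               min_intra_tc = mn, median_intra_tc = md,
               pct_active = round_half_up(
                 100 * mean(classes[idx] == "active"), 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
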