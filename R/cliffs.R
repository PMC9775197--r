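## Similar compound pairs, SAR categories, activity-cliff landscape profiling.

#' Enumerate similar compound pairs and categorize their SAR
#'
#' All unordered compound pairs with Tanimoto similarity strictly above
#' `threshold`, each allocated to one of three groups: both active or both
#' inactive (linear SAR pairs) or opposite classes (activity cliff). The
#' activity contrast of a pair is the fold change of the normalized ratios.
#'
#' @param curated `urea_curated` object, or a data.frame with `inchikey`,
#'   `canonical_smiles`, `ratio`, `activity_class`.
#' @param threshold minimum (strict) Tanimoto similarity (default 0.6).
#' @param fp optional precomputed fingerprint matrix with rows named by
#'   inchikey.
#' @return data.frame of class `urea_pairs`: `inchikey_a`, `inchikey_b`
#'   (lexically ordered within a pair), `tc`, `category`, `ratio_fold`; the
#'   per-category counts are attached as attribute `"category_counts"`.
#' @export
enumerate_similar_pairs <- function(curated, threshold = 0.6, fp = NULL) {
  comp <- if (inherits(curated, "urea_curated")) curated$compounds else curated
  if (is.null(fp)) {
    fp <- morgan_fingerprint(stats::setNames(comp$canonical_smiles,
                                             comp$inchikey))
  }
  fp <- fp[comp$inchikey, , drop = FALSE]
  tc <- tanimoto_matrix(fp)
  hits <- which(upper.tri(tc) & tc > threshold, arr.ind = TRUE)
  ratio <- stats::setNames(comp$ratio, comp$inchikey)
  cls <- stats::setNames(comp$activity_class, comp$inchikey)
  if (nrow(hits) == 0) {
    out <- data.frame(inchikey_a = character(0), inchikey_b = character(0),
                      tc = numeric(0), category = character(0),
                      ratio_fold = numeric(0), stringsAsFactors = FALSE)
  } else {
    ka <- rownames(tc)[hits[, 1]]; kb <- rownames(tc)[hits[, 2]]
    swap <- ka > kb
    tmp <- ka[swap]; ka[swap] <- kb[swap]; kb[swap] <- tmp
    cat_ab <- ifelse(cls[ka] != cls[kb], "cliff",
                     ifelse(cls[ka] == "active", "both_active", "both_inactive"))
    rf <- pmax(ratio[ka], ratio[kb]) / pmin(ratio[ka], ratio[kb])
    out <- data.frame(inchikey_a = ka, inchikey_b = kb,
                      tc = tc[hits], category = cat_ab, ratio_fold = rf,
                      stringsAsFactors = FALSE)
    out <- out[order(out$inchikey_a, out$inchikey_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "category_counts") <- c(
    both_active = sum(out$category == "both_active"),
    both_inactive = sum(out$category == "both_inactive"),
    cliff = sum(out$category == "cliff"))
  attr(out, "threshold") <- threshold
  class(out) <- c("urea_pairs", class(out))
  out
}

#' @export
print.urea_pairs <- function(x, ...) {
  cc <- attr(x, "category_counts")
  cat(sprintf("%d similar pairs (Tc > %g): %d both-active, %d both-inactive, %d cliffs\n",
              nrow(x), attr(x, "threshold"), cc[["both_active"]],
              cc[["both_inactive"]], cc[["cliff"]]))
  NextMethod()
}

#' Safe-bet and dead-end compound profiles
#'
#' A compound's cliff degree is its number of opposite-class partners among
#' the activity-cliff pairs. Actives with at least `min_degree` inactive
#' partners are "dead ends" (small modifications usually lose activity);
#' inactives with at least `min_degree` active partners are "safe bets"
#' (modifications often gain activity).
#'
#' @param pairs output of [enumerate_similar_pairs()].
#' @param classes activity classes named by inchikey.
#' @param min_degree minimum cliff degree to assign a role (default 10).
#' @return data.frame sorted by degree (descending): `inchikey`, `role`
#'   (`dead_end` / `safe_bet` / `none`), `cliff_degree`.
#' @export
cliff_profiles <- function(pairs, classes, min_degree = 10) {
  cl <- pairs[pairs$category == "cliff", , drop = FALSE]
  keys <- unique(c(cl$inchikey_a, cl$inchikey_b))
  deg <- table(factor(c(cl$inchikey_a, cl$inchikey_b), levels = keys))
  out <- data.frame(inchikey = keys,
                    cliff_degree = as.integer(deg[keys]),
                    stringsAsFactors = FALSE)
  out$role <- ifelse(out$cliff_degree < min_degree, "none",
                     ifelse(classes[out$inchikey] == "active",
                            "dead_end", "safe_bet"))
  out <- out[order(-out$cliff_degree, out$inchikey),
             c("inchikey", "role", "cliff_degree")]
  rownames(out) <- NULL
  out
}

#' Most significant activity cliffs
#'
#' Cliff pairs ranked by activity fold change, ties broken by Tc
#' (descending) then by pair key — a stable, deterministic ranking.
#'
#' @param pairs output of [enumerate_similar_pairs()].
#' @param n number of pairs to return.
#' @return the top `n` cliff rows of `pairs`.
#' @export
top_cliffs <- function(pairs, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (nrow(pairs) == 0) stop("no pairs to rank", call. = FALSE)
  cl <- pairs[pairs$category == "cliff", , drop = FALSE]
  o <- order(-cl$ratio_fold, -cl$tc, cl$inchikey_a, cl$inchikey_b)
  out <- cl[o[seq_len(min(n, nrow(cl)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
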