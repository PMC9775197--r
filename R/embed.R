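## 2-D chemical-space embedding (exact t-SNE) and reference-library
## comparison.

#' t-SNE embedding of fingerprint space
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding of
#' the 1024-bit fingerprint vectors into two dimensions, for visual
#' inspection of chemical-space structure. Coordinates are for reporting
#' only and never feed downstream statistics: axes are arbitrary, only the
#' neighborhood structure is meaningful.
#'
#' @param fp 0/1 fingerprint matrix (>= 3 rows).
#' @param seed RNG seed; the embedding is deterministic given the seed.
#' @param perplexity neighborhood-size parameter (default 30, automatically
#'   capped at `(n - 1) / 3`).
#' @param n_iter gradient-descent iterations (default 500, the first 100
#'   with early exaggeration 12).
#' @param learning_rate gradient step size (default 200).
#' @return data.frame with columns `x`, `y`, rownames from `fp`.
#' @export
embed_2d <- function(fp, seed = 42, perplexity = 30, n_iter = 500,
                     learning_rate = 200) {
  n <- nrow(fp)
  if (n < 3) stop("need at least 3 compounds to embed", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)
  # pairwise squared Jaccard-style distances on bits (Euclidean on 0/1 rows)
  d2 <- as.matrix(stats::dist(fp))^2
  P <- .tsne_affinities(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * 12 else P
    dy2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + dy2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  out <- data.frame(x = Y[, 1], y = Y[, 2])
  rownames(out) <- rownames(fp)
  out
}

# binary-search conditional affinities to match the target perplexity
.tsne_affinities <- function(d2, perplexity, tol = 1e-5) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- -Inf; hi <- Inf; beta <- 1
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p); sp <- 1 }
      else H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P
}

#' Compare a compound set against a reference library
#'
#' Counts exact overlaps (identical InChIKey after standardization) and near
#' neighbors (maximum Tc strictly above `threshold` to any reference
#' compound, excluding exact overlaps), e.g. against an approved-drug
#' library.
#'
#' @param curated `urea_curated` object or data.frame with
#'   `canonical_smiles` + `inchikey`.
#' @param reference either a path to a SMILES file (one SMILES per line,
#'   optional tab-separated name) or a character vector of SMILES.
#' @param threshold near-neighbor Tc threshold (default 0.6, strict).
#' @return list: `n_exact_overlap`, `n_near_neighbors`, `max_tc` (named
#'   numeric per dataset compound; `NA` when the reference is empty).
#' @export
compare_to_reference <- function(curated, reference, threshold = 0.6) {
  comp <- if (inherits(curated, "urea_curated")) curated$compounds else curated
  smi <- if (length(reference) == 1 && file.exists(reference)) {
    lines <- readLines(reference, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  } else as.character(reference)
  if (length(smi) == 0) {
    warning("empty reference library")
    return(list(n_exact_overlap = 0L, n_near_neighbors = 0L,
                max_tc = stats::setNames(rep(NA_real_, nrow(comp)),
                                         comp$inchikey)))
  }
  std <- standardize_structure(smi)
  std <- std[!std$parse_error, , drop = FALSE]
  exact <- comp$inchikey %in% std$inchikey

  fp_d <- morgan_fingerprint(comp$canonical_smiles)
  fp_r <- morgan_fingerprint(std$canonical_smiles)
  inter <- fp_d %*% t(fp_r)
  uni <- outer(rowSums(fp_d), rowSums(fp_r), "+") - inter
  tc <- ifelse(uni > 0, inter / uni, 0)
  max_tc <- stats::setNames(apply(tc, 1, max), comp$inchikey)
  near <- !exact & max_tc > threshold
  list(n_exact_overlap = sum(exact), n_near_neighbors = sum(near),
       max_tc = max_tc)
}
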