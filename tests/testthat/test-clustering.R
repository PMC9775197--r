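test_that("spontaneous clustering bounds every intra-cluster distance", {
  # all identical: one cluster
  tc1 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(spontaneous_clustering(tc1)$n_clusters, 1)
  # Tc 0.3 (distance 0.7) exceeds the 0.6 cut: two clusters
  tc2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  expect_equal(spontaneous_clustering(tc2)$n_clusters, 2)
})

test_that("spontaneous clustering matches a brute-force complete-linkage oracle", {
  smi <- c("O=C(NC(=O)Nc1ccc(Cl)cc1)c1ccccc1",
           "O=C(NC(=O)Nc1ccc(Br)cc1)c1ccccc1",
           "NC(=S)Nc1ccc(CC)cc1",
           "NC(=S)Nc1ccc(CCC)cc1",
           "Cc1ccc2ncc(F)cc2c1",
           "Cc1ccc2ncc(Cl)cc2c1")
  fp <- morgan_fingerprint(stats::setNames(smi, paste0("m", 1:6)))
  tc <- tanimoto_matrix(fp)
  sp <- spontaneous_clustering(tc, 0.6)
  oracle <- naive_complete_linkage(1 - tc, 0.6)
  expect_equal(sp$n_clusters, length(unique(oracle)))
  expect_equal(sp$n_clusters, 3)   # three planted analogue pairs
  # identical partitions up to relabeling
  expect_equal(length(unique(paste(sp$assignment, oracle))), sp$n_clusters)
  # every intra-cluster distance respects the threshold
  for (cid in unique(sp$assignment)) {
    idx <- which(sp$assignment == cid)
    if (length(idx) > 1) expect_lte(max(1 - tc[idx, idx]), 0.6)
  }
})

test_that("spontaneous cluster count is invariant to input permutation", {
  cur <- cached_curated()
  sub <- head(cur$compounds, 60)
  fp <- morgan_fingerprint(stats::setNames(sub$canonical_smiles,
                                           sub$inchikey))
  tc <- tanimoto_matrix(fp)
  n0 <- spontaneous_clustering(tc)$n_clusters
  set.seed(9)
  for (i in 1:3) {
    p <- sample(nrow(tc))
    expect_equal(spontaneous_clustering(tc[p, p])$n_clusters, n0)
  }
})

test_that("threshold extremes give singleton-per-fingerprint and one cluster", {
  smi <- c("CCO", "CCN", "CCC", "c1ccccc1")
  fp <- morgan_fingerprint(stats::setNames(smi, paste0("m", 1:4)))
  tc <- tanimoto_matrix(fp)
  expect_equal(spontaneous_clustering(tc, 0)$n_clusters, 4)
  expect_equal(spontaneous_clustering(tc, 1)$n_clusters, 1)
})

test_that("family clustering partitions and recovers separated families", {
  cur <- cached_curated()
  truth <- cached_library()$truth$compounds
  sel <- truth$family_id %in% c(1, 2)      # two well-separated cores
  fp <- morgan_fingerprint(stats::setNames(
    truth$canonical_smiles[sel], truth$inchikey[sel]))
  fam <- family_clustering(fp, 2)
  expect_equal(sort(unique(fam)), c(0L, 1L))
  expect_equal(length(fam), sum(sel))      # a partition: each compound once
  agree <- table(fam, truth$family_id[sel])
  expect_equal(sum(apply(agree, 1, max)), sum(sel))  # exact recovery
  # k = n: all singletons
  sub <- fp[1:8, ]
  expect_equal(sort(unique(family_clustering(sub, 8))), 0:7)
  expect_error(family_clustering(sub, 9), "exceeds")
})

test_that("select_k reports diagnostics per k and honors the override", {
  cur <- cached_curated()
  fp <- morgan_fingerprint(stats::setNames(cur$compounds$canonical_smiles,
                                           cur$compounds$inchikey))
  sel <- select_k(fp, k_range = 5:12)
  expect_equal(sel$diagnostics$k, 5:12)
  expect_true(sel$k %in% 5:12)
  # max cluster size non-increasing in k on fixed data
  expect_true(all(diff(sel$diagnostics$max_cluster_size) <= 0))
  forced <- select_k(fp, k_range = 5:12, override = 50)
  expect_equal(forced$k, 50)
})

test_that("cluster summaries match the exhaustive pair oracle", {
  keys <- paste0("m", 1:4)
  tc <- diag(4); dimnames(tc) <- list(keys, keys)
  vals <- c(0.9, 0.5, 0.4, 0.8, 0.3, 0.7)
  tc[upper.tri(tc)] <- vals
  tc <- pmax(tc, t(tc)); diag(tc) <- 1
  classes <- stats::setNames(c("active", "active", "inactive", "active"), keys)
  s <- cluster_summary(stats::setNames(rep(0L, 4), keys), tc, classes)
  pair_vals <- tc[upper.tri(tc)]
  expect_equal(s$min_intra_tc, min(pair_vals))
  expect_equal(s$median_intra_tc, median(pair_vals))
  expect_equal(s$pct_active, 75)
  # singleton convention and two-member case
  s1 <- cluster_summary(stats::setNames(c(0L, 1L, 1L), keys[1:3]),
                        tc[1:3, 1:3], classes[1:3])
  expect_equal(s1$min_intra_tc[1], 1)
  expect_equal(s1$median_intra_tc[1], 1)
  expect_equal(s1$min_intra_tc[2], tc[2, 3])
  expect_equal(s1$median_intra_tc[2], tc[2, 3])
})

test_that("MCS matches the exhaustive common-subgraph oracle on tiny pairs", {
  cases <- list(c("Cc1ccccc1", "CCc1ccccc1"),    # methylbenzene core: 7
                c("CCO", "CCN"),                  # CC fragment: 2
                c("CCCC", "CC(C)C"))              # propyl into isobutane: 3
  for (cs in cases) {
    got <- cluster_mcs(cs)
    expect_equal(got$mcs_n_atoms, naive_mcs_size(cs[1], cs[2]))
  }
})

test_that("MCS of identical molecules is the whole molecule and degenerate
           pairs are flagged empty", {
  same <- cluster_mcs(c("NC(=S)Nc1ccccc1", "NC(=S)Nc1ccccc1"))
  expect_equal(same$mcs_n_atoms, 10)
  none <- cluster_mcs(c("C", "c1ccccc1"))
  expect_equal(none$mcs_n_atoms, 0)
  expect_equal(none$mcs_smarts, "")
  expect_false(none$timed_out)
})

test_that("every cluster member matches its reported MCS SMARTS", {
  truth <- cached_library()$truth$compounds
  for (famid in c(1, 4)) {
    members <- truth$canonical_smiles[truth$family_id == famid][1:8]
    res <- cluster_mcs(members, timeout = 30)
    expect_gt(res$mcs_n_atoms, 3)
    hits <- ureascape:::smarts_count(ureascape:::ob_mols(members),
                                     res$mcs_smarts)
    expect_true(all(hits > 0))
  }
})
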