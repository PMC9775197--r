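## End-to-end orchestration: curate -> profile -> space -> cluster -> cliffs
## -> rules, driven by one config, producing stage CSVs plus a consolidated
## JSON report. Every number in the report is recomputable from the CSVs.

.PIPELINE_DEFAULTS <- list(
  stages = c("curate", "profile", "space", "cluster", "cliffs", "rules"),
  seed = 1,
  default_control_um = 20,
  excess_um = 1000,
  tc_threshold = 0.6,
  max_dist = 0.6,
  k = "auto",
  k_range = c(20, 80),
  min_degree = 10,
  max_depth = 10,
  precision_threshold = 0.80,
  perplexity = 30,
  catalogs = c("pains", "brenk"),
  reference = NULL,
  mcs_timeout = 60,
  run_embedding = TRUE,
  run_mcs = TRUE)

#' Run the full chemical-space analysis pipeline
#'
#' Executes the enabled stages in dependency order on a raw bioassay table:
#' curation; descriptor/filter/census profiling; 2-D embedding and optional
#' reference-library comparison; spontaneous and family clustering with
#' per-cluster cohesion statistics and MCS scaffolds; similar-pair and
#' activity-cliff analysis; decision-tree rule extraction with interaction
#' scores. Stage outputs are written as CSV files under `outdir` together
#' with `report.json`; re-running with the same config and seed reproduces
#' identical values.
#'
#' @param config named list (or path to a YAML file with the same fields):
#'   `input` (raw CSV path) or `raw` (data.frame), `outdir`, and any of the
#'   stage parameters `stages`, `seed`, `default_control_um`,
#'   `tc_threshold`, `max_dist`, `k` (`"auto"` or integer), `k_range`,
#'   `min_degree`, `max_depth`, `precision_threshold`, `perplexity`,
#'   `catalogs`, `reference`, `mcs_timeout`, `run_embedding`, `run_mcs`.
#' @return object of class `ureascape_report` (the report list), invisibly
#'   written to `outdir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config)
  if (is.null(cfg$raw) && is.null(cfg$input))
    stop("config needs 'input' (CSV path) or 'raw' (data.frame)", call. = FALSE)
  if (is.null(cfg$raw)) {
    if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input,
                                      call. = FALSE)
    cfg$raw <- read_bioassay_csv(cfg$input)
  }
  if (is.null(cfg$outdir)) stop("config needs 'outdir'", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out_csv <- function(df, name) {
    utils::write.csv(df, file.path(cfg$outdir, name), row.names = FALSE)
  }
  stage_seed <- function(stage) derive_seed(cfg$seed, stage)
  report <- list(parameters = cfg[setdiff(names(cfg), c("raw"))],
                 seeds = list(master = cfg$seed))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## curate (always; everything depends on it)
  curated <- run_stage("curate", function()
    curate_bioassay(cfg$raw, default_control_um = cfg$default_control_um,
                    excess_um = cfg$excess_um))
  comp <- curated$compounds
  out_csv(comp, "curated.csv")
  out_csv(curated$rejects, "rejects.csv")
  report$dataset <- list(
    n_records = nrow(curated$records) + nrow(curated$rejects),
    n_rejected = nrow(curated$rejects),
    n_compounds = nrow(comp),
    n_active = sum(comp$activity_class == "active"),
    n_inactive = sum(comp$activity_class == "inactive"))

  fp <- morgan_fingerprint(stats::setNames(comp$canonical_smiles,
                                           comp$inchikey))
  tc <- tanimoto_matrix(fp)
  classes <- stats::setNames(comp$activity_class, comp$inchikey)

  if ("profile" %in% cfg$stages) run_stage("profile", function() {
    desc <- compute_descriptors(comp$canonical_smiles)
    out_csv(cbind(inchikey = comp$inchikey, desc), "descriptors.csv")
    lip <- lipinski_filter(desc)
    alerts <- lapply(cfg$catalogs, function(cat_name) {
      a <- structural_alerts(comp$canonical_smiles, cat_name)
      vapply(a, paste, character(1), collapse = ";")
    })
    names(alerts) <- cfg$catalogs
    filt <- data.frame(inchikey = comp$inchikey, lipinski_pass = lip$pass,
                       lipinski_violations = lip$violations, alerts,
                       stringsAsFactors = FALSE)
    out_csv(filt, "filters.csv")
    census <- group_census(comp, default_group_map())
    out_csv(census, "census.csv")
    trends <- temporal_trends(comp)
    out_csv(trends, "trends.csv")
    conc <- species_concordance(curated$records)
    report$profile <<- list(
      n_lipinski_pass = sum(lip$pass),
      n_alert_free = sum(Reduce(`&`, lapply(alerts, function(a) a == ""))),
      species_concordance = conc)
    report$descriptors_schema <<- names(desc)
  })

  if ("space" %in% cfg$stages) run_stage("space", function() {
    if (isTRUE(cfg$run_embedding)) {
      emb <- embed_2d(fp, seed = stage_seed("embed"),
                      perplexity = cfg$perplexity)
      out_csv(cbind(inchikey = comp$inchikey, emb,
                    activity_class = comp$activity_class), "embedding.csv")
      report$seeds$embed <<- stage_seed("embed")
    }
    if (!is.null(cfg$reference)) {
      ref <- compare_to_reference(comp, cfg$reference,
                                  threshold = cfg$tc_threshold)
      out_csv(data.frame(inchikey = comp$inchikey, max_tc = ref$max_tc),
              "reference_similarity.csv")
      report$reference <<- list(n_exact_overlap = ref$n_exact_overlap,
                                n_near_neighbors = ref$n_near_neighbors)
    }
  })

  if ("cluster" %in% cfg$stages) run_stage("cluster", function() {
    sp <- spontaneous_clustering(tc, max_dist = cfg$max_dist)
    out_csv(data.frame(inchikey = names(sp$assignment),
                       cluster_id = sp$assignment), "clusters_spontaneous.csv")
    k <- cfg$k
    k_diag <- NULL
    if (identical(k, "auto")) {
      k_range <- seq(cfg$k_range[1], min(cfg$k_range[2], nrow(comp) - 1))
      sel <- select_k(fp, k_range = k_range)
      k <- sel$k; k_diag <- sel$diagnostics
      out_csv(k_diag, "k_diagnostics.csv")
    }
    fam <- family_clustering(fp, k)
    out_csv(data.frame(inchikey = names(fam), cluster_id = fam),
            "clusters_family.csv")
    summ <- cluster_summary(fam, tc, classes)
    if (isTRUE(cfg$run_mcs)) {
      mcs <- lapply(sort(unique(fam)), function(cid) {
        keys <- names(fam)[fam == cid]
        if (length(keys) < 2)
          return(list(mcs_smarts = "", mcs_n_atoms = 0L, timed_out = FALSE))
        cluster_mcs(comp$canonical_smiles[match(keys, comp$inchikey)],
                    timeout = cfg$mcs_timeout)
      })
      summ$mcs_smarts <- vapply(mcs, `[[`, character(1), "mcs_smarts")
      summ$mcs_n_atoms <- vapply(mcs, `[[`, integer(1), "mcs_n_atoms")
      summ$mcs_timed_out <- vapply(mcs, `[[`, logical(1), "timed_out")
    }
    out_csv(summ, "cluster_summary.csv")
    report$clustering <<- list(n_clusters_spontaneous = sp$n_clusters,
                               k_family = k,
                               n_cohesive_families =
                                 sum(summ$min_intra_tc >= 0.5))
  })

  if ("cliffs" %in% cfg$stages) run_stage("cliffs", function() {
    pairs <- enumerate_similar_pairs(comp, threshold = cfg$tc_threshold,
                                     fp = fp)
    out_csv(as.data.frame(pairs), "pairs.csv")
    prof <- cliff_profiles(pairs, classes, min_degree = cfg$min_degree)
    out_csv(prof, "cliff_profiles.csv")
    cc <- attr(pairs, "category_counts")
    report$cliffs <<- list(
      n_pairs = nrow(pairs),
      n_both_active = unname(cc[["both_active"]]),
      n_both_inactive = unname(cc[["both_inactive"]]),
      n_cliff = unname(cc[["cliff"]]),
      n_dead_ends = sum(prof$role == "dead_end"),
      n_safe_bets = sum(prof$role == "safe_bet"))
  })

  if ("rules" %in% cfg$stages) run_stage("rules", function() {
    desc <- compute_descriptors(comp$canonical_smiles)
    tree <- train_activity_tree(desc, comp$activity_class,
                                max_depth = cfg$max_depth,
                                seed = stage_seed("tree"))
    rules <- extract_rules(tree, desc, comp$activity_class,
                           precision_threshold = cfg$precision_threshold)
    out_csv(as.data.frame(rules), "rules.csv")
    inter <- vapply(names(desc), function(f)
      feature_interaction(tree, desc, f, seed = stage_seed("interaction")),
      numeric(1))
    out_csv(data.frame(feature = names(inter), h_statistic = inter),
            "interactions.csv")
    top <- utils::head(as.data.frame(rules), 10)
    report$rules <<- list(
      n_rules = nrow(rules),
      n_at_threshold = sum(!rules$below_threshold),
      training_accuracy = tree$training_accuracy,
      top_rules = top[, c("rule_id", "conditions", "predicted_class",
                          "n_active", "n_inactive", "n_total",
                          "precision_pct")])
    report$seeds$tree <<- stage_seed("tree")
  })

  class(report) <- "ureascape_report"
  jsonlite::write_json(unclass(report),
                       file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' @export
print.ureascape_report <- function(x, ...) {
  d <- x$dataset
  cat("ureascape pipeline report\n")
  cat(sprintf("  compounds: %d (%d active / %d inactive), %d records rejected\n",
              d$n_compounds, d$n_active, d$n_inactive, d$n_rejected))
  if (!is.null(x$clustering))
    cat(sprintf("  clusters: %d spontaneous, %d families (k)\n",
                x$clustering$n_clusters_spontaneous, x$clustering$k_family))
  if (!is.null(x$cliffs))
    cat(sprintf("  similar pairs: %d (%d activity cliffs)\n",
                x$cliffs$n_pairs, x$cliffs$n_cliff))
  if (!is.null(x$rules))
    cat(sprintf("  rules: %d extracted, %d at precision threshold\n",
                x$rules$n_rules, x$rules$n_at_threshold))
  invisible(x)
}
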