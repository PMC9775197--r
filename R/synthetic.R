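## Synthetic bioassay libraries with planted ground truth: scaffold families
## (core x substituent enumeration), planted activity cliffs, a planted
## descriptor rule, duplicates, qualitative-inactive records, heterogeneous
## controls and species labels. Emulates the structure of a literature-
## curated urease-inhibition table; it makes no attempt to mimic any real
## compound set.

# aryl cores with a single ring substitution slot (all carbon-attached, so
# substituent chemistry is independent of the core); deliberately mixed
# cohesion — the large amide/urea cores form tight families whose analogue
# pairs clear Tc 0.6, the small bicyclics form loose ones
.SYNTH_CORES <- c(
  arylsulfonylurea  = "O=C(NC(=O)Nc1ccc(%s)cc1)c1ccccc1",
  benzoylpiperazine = "O=C(c1ccccc1)N1CCN(c2ccc(%s)cc2)CC1",
  cyclohexylanilide = "O=C(Nc1ccc(%s)cc1)C1CCCCC1",
  phenylthiourea    = "NC(=S)Nc1ccc(%s)cc1",
  benzenesulfonamide = "NS(=O)(=O)c1ccc(%s)cc1",
  benzohydroxamate  = "O=C(NO)c1ccc(%s)cc1",
  naphthyl          = "c1ccc2cc(%s)ccc2c1",
  dibenzofuran      = "c1ccc2c(c1)oc1ccc(%s)cc12",
  benzylpyridine    = "c1ccc(Cc2ccnc(%s)c2)cc1",
  methylquinoline   = "Cc1ccc2ncc(%s)cc2c1")

.SYNTH_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "NN", "NNC", "Cl", "Br", "F", "I", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N",
  "C=O", "CO", "CCO", "S", "SC", "S(=O)(=O)N", "S(=O)(=O)C",
  "[N+](=O)[O-]", "C(F)(F)F")

# per-family base log-ratios (natural log of activity/control): small
# offsets — activity is substituent-driven, the scaffold only modulates it
.SYNTH_BASE_LOG_RATIO <- c(-0.3, 0.25, -0.2, 0.3, -0.25, 0.2, -0.3, 0.25,
                           -0.2, 0.3)

.default_substituent_effects <- function(substituents) {
  k <- length(substituents)
  # alternating sign with growing magnitude: substituent identity, not any
  # monotone physicochemical trend, decides activity
  eff <- stats::setNames(
    round((-1)^seq_len(k) * seq(0.6, 1.2, length.out = k), 3), substituents)
  # hydrazine-type substituents are strongly activating: they carry the
  # planted descriptor rule fr_hdrzine > 0 => active
  eff[grepl("^NN", substituents)] <- -2.0
  eff
}

#' Configuration for the synthetic library generator
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 10 scaffold families x 30 substituents (300 compounds), planted
#' activity cliffs on 5% of compounds, a planted rule (hydrazine-bearing
#' compounds are active), 10% duplicated records, 5% qualitative-inactive
#' reports, species labels drawn with literature-like weights, thiourea-like
#' controls around 20 uM (15% of references not reporting one).
#'
#' @param n_families number of scaffold cores used (2..10).
#' @param substituents substituent SMILES fragments.
#' @param family_base_log_ratio per-family base log activity ratio.
#' @param substituent_effects named log-ratio shifts per substituent.
#' @param cliff_fraction fraction of compounds whose activity is flipped to
#'   plant cliffs.
#' @param noise_sd assay noise on the log-ratio scale.
#' @param duplicate_rate fraction of compounds reported twice.
#' @param qualitative_inactive_rate fraction of inactive compounds that also
#'   get a value-free "inactive" report.
#' @param species_weights named sampling weights for species labels.
#' @param control_um typical control IC50 in uM.
#' @param missing_control_rate fraction of references not reporting a
#'   control.
#' @param year_range publication year span.
#' @param seed master RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_families = 10,
                         substituents = .SYNTH_SUBSTITUENTS,
                         family_base_log_ratio = .SYNTH_BASE_LOG_RATIO,
                         substituent_effects =
                           .default_substituent_effects(substituents),
                         cliff_fraction = 0.05,
                         noise_sd = 0,
                         duplicate_rate = 0.1,
                         qualitative_inactive_rate = 0.05,
                         species_weights = c(C_ensiformis = 0.68,
                                             unknown = 0.12,
                                             H_pylori = 0.10,
                                             S_pasteurii = 0.07,
                                             other = 0.03),
                         control_um = 20,
                         missing_control_rate = 0.15,
                         year_range = c(1990, 2021),
                         seed = 1) {
  stopifnot(n_families >= 2, n_families <= length(.SYNTH_CORES),
            cliff_fraction >= 0, cliff_fraction <= 1, noise_sd >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            qualitative_inactive_rate >= 0, qualitative_inactive_rate <= 1,
            length(family_base_log_ratio) >= n_families,
            all(substituents %in% names(substituent_effects)),
            control_um > 0)
  structure(list(
    n_families = n_families, substituents = substituents,
    family_base_log_ratio = family_base_log_ratio[seq_len(n_families)],
    substituent_effects = substituent_effects,
    cliff_fraction = cliff_fraction, noise_sd = noise_sd,
    duplicate_rate = duplicate_rate,
    qualitative_inactive_rate = qualitative_inactive_rate,
    species_weights = species_weights, control_um = control_um,
    missing_control_rate = missing_control_rate,
    year_range = year_range, seed = seed), class = "synth_config")
}

#' Generate a synthetic raw bioassay table with planted truth
#'
#' Compounds are built by substituting each fragment into each core's slot;
#' every generated SMILES is standardized through the curation machinery so
#' the frozen truth is keyed by final InChIKey. Activity values are
#' simulated on the log-ratio scale (`value = control * exp(log_ratio +
#' noise)`), which keeps the planted class aligned with the downstream
#' ratio < 1 cutoff. Cliffs are planted by flipping the sign of selected
#' compounds' log-ratios (hydrazine-bearing compounds are exempt so the
#' planted rule stays exact); planted cliff pairs are the same-family
#' opposite-class pairs whose Tanimoto similarity, recomputed here, exceeds
#' 0.6.
#'
#' @param config a [synth_config()].
#' @return list with `records` (raw bioassay data.frame matching the
#'   curation input contract) and `truth` (list: `compounds` data.frame with
#'   `inchikey`, `family_id`, `true_log_ratio`, `true_class`;
#'   `cliff_pairs` data.frame; `rule` description; `config`).
#' @export
generate_library <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cores <- .SYNTH_CORES[seq_len(config$n_families)]
  subs <- config$substituents

  grid <- expand.grid(family = seq_along(cores), sub = seq_along(subs))
  smiles <- sprintf(cores[grid$family], subs[grid$sub])
  std <- standardize_structure(smiles)
  if (any(std$parse_error))
    stop("internal: generated SMILES failed to parse", call. = FALSE)
  dup_key <- duplicated(std$inchikey)
  if (any(dup_key)) {  # distinct core x sub collapsing to one structure
    grid <- grid[!dup_key, , drop = FALSE]
    std <- std[!dup_key, , drop = FALSE]
    smiles <- smiles[!dup_key]
  }
  n <- nrow(grid)

  lr <- config$family_base_log_ratio[grid$family] +
    unname(config$substituent_effects[subs[grid$sub]])
  rule_bearing <- grepl("^NN", subs[grid$sub])
  n_flip <- round(config$cliff_fraction * n)
  flip_pool <- which(!rule_bearing)
  flipped <- sort(sample(flip_pool, min(n_flip, length(flip_pool))))
  lr[flipped] <- -sign(lr[flipped]) * pmax(abs(lr[flipped]), 0.5)
  true_class <- ifelse(lr < 0, "active", "inactive")

  # references: ~10 compounds each, with own control, year, citation id
  n_ref <- max(1, ceiling(n / 10))
  ref_of <- sample(rep(seq_len(n_ref), length.out = n))
  ref_control <- sample(c(15, 18, 20, 22, 25), n_ref, replace = TRUE,
                        prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  ref_control[stats::runif(n_ref) < config$missing_control_rate] <- NA
  ref_year <- sample(seq(config$year_range[1], config$year_range[2]), n_ref,
                     replace = TRUE)

  effective_control <- ifelse(is.na(ref_control[ref_of]), config$control_um,
                              ref_control[ref_of])
  noise <- stats::rnorm(n, 0, config$noise_sd)
  value_um <- effective_control * exp(lr + noise)

  mk_records <- function(idx, value, type, ref, note_species = NULL) {
    k <- length(idx)
    if (k == 0) return(NULL)
    in_nm <- stats::runif(k) < 0.3
    species <- if (is.null(note_species))
      sample(names(config$species_weights), k, replace = TRUE,
             prob = config$species_weights) else note_species
    data.frame(
      smiles = smiles[idx],
      activity_value = ifelse(is.na(value), NA,
                              ifelse(in_nm, value * 1000, value)),
      activity_unit = ifelse(in_nm, "nM", "uM"),
      activity_type = type,
      control_value = ref_control[ref],
      control_unit = "uM",
      species = species,
      year = ref_year[ref],
      reference_id = sprintf("REF%03d", ref),
      stringsAsFactors = FALSE)
  }

  primary_type <- sample(c("IC50", "Ki"), n, replace = TRUE, prob = c(0.8, 0.2))
  recs <- mk_records(seq_len(n), value_um, primary_type, ref_of)

  dup_idx <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup_idx)) {
    dup_ref <- sample(seq_len(n_ref), length(dup_idx), replace = TRUE)
    dup_control <- ifelse(is.na(ref_control[dup_ref]), config$control_um,
                          ref_control[dup_ref])
    dup_value <- dup_control * exp(lr[dup_idx] + noise[dup_idx] +
                                   stats::rnorm(length(dup_idx), 0, 0.15))
    recs <- rbind(recs, mk_records(dup_idx, dup_value,
                                   sample(c("IC50", "Ki"), length(dup_idx),
                                          replace = TRUE, prob = c(0.8, 0.2)),
                                   dup_ref))
  }

  qual_pool <- which(true_class == "inactive")
  qual_idx <- qual_pool[stats::runif(length(qual_pool)) <
                          config$qualitative_inactive_rate]
  if (length(qual_idx)) {
    qual_ref <- sample(seq_len(n_ref), length(qual_idx), replace = TRUE)
    recs <- rbind(recs, mk_records(qual_idx, NA_real_, "qualitative_inactive",
                                   qual_ref))
  }
  recs <- cbind(record_id = sprintf("R%05d", seq_len(nrow(recs))), recs)
  rownames(recs) <- NULL

  # planted cliff pairs: same family, opposite class, Tc > 0.6, at least one
  # member flipped
  fp <- morgan_fingerprint(std$canonical_smiles)
  cliff_pairs <- list()
  for (i in flipped) {
    mates <- which(grid$family == grid$family[i] &
                   true_class != true_class[i])
    for (j in mates) {
      tc <- tanimoto(fp[i, ], fp[j, ])
      if (tc > 0.6) {
        a <- std$inchikey[i]; b <- std$inchikey[j]
        cliff_pairs[[length(cliff_pairs) + 1]] <-
          data.frame(inchikey_a = min(a, b), inchikey_b = max(a, b), tc = tc,
                     stringsAsFactors = FALSE)
      }
    }
  }
  cliff_pairs <- if (length(cliff_pairs)) {
    cp <- unique(do.call(rbind, cliff_pairs))
    cp[order(cp$inchikey_a, cp$inchikey_b), , drop = FALSE]
  } else data.frame(inchikey_a = character(0), inchikey_b = character(0),
                    tc = numeric(0))

  truth <- list(
    compounds = data.frame(
      inchikey = std$inchikey, canonical_smiles = std$canonical_smiles,
      family_id = grid$family, true_log_ratio = lr, true_class = true_class,
      flipped = seq_len(n) %in% flipped, rule_bearing = rule_bearing,
      stringsAsFactors = FALSE),
    cliff_pairs = cliff_pairs,
    rule = list(feature = "fr_hdrzine", op = ">", threshold = 0,
                predicted_class = "active"),
    config = config)
  list(records = recs, truth = truth)
}

#' Compare pipeline outputs with the planted truth
#'
#' @param outputs list with any of: `curated` (a `urea_curated`), `pairs`
#'   (from [enumerate_similar_pairs()]), `families` (assignment from
#'   [family_clustering()]), `rules` (from [extract_rules()]).
#' @param truth the `truth` element of [generate_library()].
#' @return list of recovery metrics: `class_accuracy`, `confusion`
#'   (2x2 table), `cliff_recall`, `cliff_precision`, `family_ari`,
#'   `rule_recovered` (any supplied component missing gives `NA` for its
#'   metrics).
#' @export
evaluate_recovery <- function(outputs, truth) {
  tc <- truth$compounds
  res <- list(class_accuracy = NA_real_, confusion = NULL,
              cliff_recall = NA_real_, cliff_precision = NA_real_,
              family_ari = NA_real_, rule_recovered = NA)
  if (!is.null(outputs$curated)) {
    comp <- outputs$curated$compounds
    if (!all(comp$inchikey %in% tc$inchikey))
      stop("curated set contains compounds unknown to the truth", call. = FALSE)
    m <- match(comp$inchikey, tc$inchikey)
    res$confusion <- table(truth = tc$true_class[m],
                           observed = comp$activity_class)
    res$class_accuracy <- mean(tc$true_class[m] == comp$activity_class)
  }
  if (!is.null(outputs$pairs)) {
    found <- outputs$pairs[outputs$pairs$category == "cliff", , drop = FALSE]
    found_key <- paste(found$inchikey_a, found$inchikey_b)
    planted_key <- paste(truth$cliff_pairs$inchikey_a,
                         truth$cliff_pairs$inchikey_b)
    res$cliff_recall <- if (length(planted_key))
      mean(planted_key %in% found_key) else NA_real_
    if (nrow(found)) {
      m1 <- match(found$inchikey_a, tc$inchikey)
      m2 <- match(found$inchikey_b, tc$inchikey)
      res$cliff_precision <-
        mean(tc$true_class[m1] != tc$true_class[m2], na.rm = TRUE)
    }
  }
  if (!is.null(outputs$families)) {
    keys <- names(outputs$families)
    m <- match(keys, tc$inchikey)
    res$family_ari <- mclust::adjustedRandIndex(outputs$families,
                                                tc$family_id[m])
  }
  if (!is.null(outputs$rules)) {
    planted <- sprintf("%s %s %d", truth$rule$feature, truth$rule$op,
                       truth$rule$threshold)
    hit <- outputs$rules$conditions == planted &
      outputs$rules$predicted_class == truth$rule$predicted_class &
      !outputs$rules$below_threshold
    res$rule_recovered <- any(hit)
  }
  res
}
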