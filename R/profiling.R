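## Physicochemical descriptors, drug-likeness and structural-alert filters,
## functional-group census, temporal trends, cross-species concordance.

# functional-group count descriptors (SMARTS, unique-match counts); compact
# definitions in the spirit of the usual fragment-count descriptor sets
.FR_SMARTS <- c(
  fr_NH2         = "[NX3;H2;!$(N=O)]",
  fr_NH1         = "[NX3;H1;!$(N=O)]",
  fr_NH0         = "[NX3;H0;!$(N=O);!$([NX3](=O))]",
  fr_Ar_OH       = "[OX2H][c]",
  fr_Al_OH       = "[OX2H][CX4]",
  fr_N_O         = "[NX3;!$([NX3](=[OX1]));!$([NX3+])][OX2]",
  fr_Ar_N        = "[nX2,nX3]",
  fr_aryl_methyl = "[CX4H3][c]",
  fr_hdrzine     = "[NX3;!$(N=O)][NX3;!$(N=O)]",
  fr_sulfonamd   = "[#16X4](=[OX1])(=[OX1])[#7]",
  fr_SH          = "[#16X2H]",
  fr_urea        = "[NX3][CX3](=[OX1])[NX3]",
  fr_thiourea    = "[NX3][CX3](=[SX1])[NX3]",
  fr_nitro       = "[$([NX3](=O)=O),$([NX3+](=[OX1])[OX1-])]",
  fr_halogen     = "[F,Cl,Br,I]"
)

.LIPINSKI_HBD_SMARTS <- "[$([#7,#8;!H0])]"
.LIPINSKI_HBA_SMARTS <- "[#7,#8]"
.ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' 2-D molecular descriptors
#'
#' Computes the descriptor vector used throughout the package: molecular
#' weight (Da), calculated logP, Lipinski hydrogen-bond donor and acceptor
#' counts (N/O-H donors; N+O acceptors), topological polar surface area
#' (A^2), rotatable bonds, aromatic ring count, molar refractivity, a
#' Bertz-style graph-complexity score, an ESOL-style aqueous solubility
#' estimate (log mol/L), and functional-group counts (`fr_*`). Bulk
#' properties come from OpenBabel; ring, complexity and fragment counts are
#' computed here.
#'
#' @param smiles character vector of valid, standardized SMILES.
#' @return data.frame, one row per molecule, fixed column schema.
#' @export
#' @examples
#' compute_descriptors("CCO")[, c("mw", "hbd", "hba")]
compute_descriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  mols <- ob_mols(smiles)
  props <- suppressWarnings(ChemmineOB::prop_OB(mols))
  graphs <- parse_mol_graphs(smiles)

  n_arom_rings <- vapply(graphs, function(g) g$n_aromatic_rings, integer(1))
  bertz <- vapply(graphs, .bertz_complexity, numeric(1))
  n_heavy <- vapply(graphs, function(g) length(g$element), integer(1))
  arom_frac <- vapply(graphs, function(g) {
    if (length(g$element) == 0) return(0)
    mean(g$aromatic)
  }, numeric(1))

  hbd <- smarts_count(mols, .LIPINSKI_HBD_SMARTS)
  hba <- smarts_count(mols, .LIPINSKI_HBA_SMARTS)
  rot <- smarts_count(mols, .ROTOR_SMARTS, unique = FALSE) %/% 2L

  out <- data.frame(
    mw = props$MW,
    logp = props$logP,
    hbd = hbd,
    hba = hba,
    tpsa = props$TPSA,
    rot_bonds = rot,
    n_aromatic_rings = n_arom_rings,
    bertz_ct = bertz,
    mol_mr = props$MR,
    n_heavy = n_heavy,
    stringsAsFactors = FALSE)
  # Delaney-style ESOL estimate from computed properties
  out$log_s <- 0.16 - 0.63 * out$logp - 0.0062 * out$mw +
    0.066 * out$rot_bonds - 0.74 * arom_frac
  for (nm in names(.FR_SMARTS))
    out[[nm]] <- smarts_count(mols, .FR_SMARTS[[nm]])
  rownames(out) <- names(smiles)
  out
}


# Bertz-style complexity: bond-connection information content plus an
# element-distribution information term (heteroatom diversity)
.bertz_complexity <- function(g) {
  deg <- .degree(g)
  n_conn <- sum(choose(deg, 2))
  c_bonds <- if (n_conn > 0) 2 * n_conn * log2(n_conn) else 0
  n <- length(g$element)
  if (n == 0) return(0)
  tab <- table(g$element)
  c_elem <- n * log2(n) - sum(tab * log2(tab))
  c_bonds + c_elem
}

#' Rule-of-5 drug-likeness filter
#'
#' Violations of MW <= 500, logP <= 5, hbd <= 5, hba <= 10 (values exactly at
#' the limit are compliant). By default a compound passes with zero
#' violations (strict variant); `max_violations = 1` gives the common
#' one-violation-allowed variant.
#'
#' @param descriptors data.frame from [compute_descriptors()].
#' @param max_violations violations tolerated while still passing.
#' @return data.frame with `pass` (logical) and `violations` (semicolon
#'   string over `MW>500`, `logP>5`, `hbd>5`, `hba>10`).
#' @export
lipinski_filter <- function(descriptors, max_violations = 0) {
  v <- cbind(`MW>500` = descriptors$mw > 500,
             `logP>5` = descriptors$logp > 5,
             `hbd>5` = descriptors$hbd > 5,
             `hba>10` = descriptors$hba > 10)
  n_viol <- rowSums(v)
  viol_str <- apply(v, 1, function(r) paste(colnames(v)[r], collapse = ";"))
  data.frame(pass = n_viol <= max_violations, n_violations = n_viol,
             violations = viol_str, stringsAsFactors = FALSE)
}

#' Load a structural-alert catalog
#'
#' Catalogs are tab-separated text files (`name<TAB>SMARTS`); the bundled
#' `brenk` and `pains` catalogs are compact defaults written from the
#' published alert descriptions and can be replaced by full files.
#'
#' @param catalog `"brenk"`, `"pains"`, or a path to a catalog file.
#' @return named character vector of SMARTS.
#' @export
load_alert_catalog <- function(catalog) {
  path <- if (file.exists(catalog)) catalog else
    system.file("extdata", "alerts", paste0(catalog, ".smarts"),
                package = "ureascape")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown alert catalog: ", catalog, call. = FALSE)
  # '#' appears inside SMARTS ([#6]); only full-line comments are stripped
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smarts <- stats::setNames(vapply(parts, `[`, character(1), 2),
                            vapply(parts, `[`, character(1), 1))
  # validate at load time
  probe <- ob_mols("CCO")
  for (nm in names(smarts)) smarts_count(probe, smarts[[nm]])
  smarts
}

#' Structural alerts (PAINS / Brenk style)
#'
#' Matches every catalog pattern against every molecule and returns the alert
#' names that hit, in catalog order.
#'
#' @param smiles character vector of valid SMILES.
#' @param catalog catalog name or file (see [load_alert_catalog()]), or a
#'   named SMARTS vector.
#' @return list (one element per molecule) of character vectors of alert
#'   names; and, as attribute `"n_alerts"`, the per-molecule alert count.
#' @export
#' @examples
#' structural_alerts("Oc1ccccc1O", "brenk")
structural_alerts <- function(smiles, catalog = "brenk") {
  smarts <- if (is.character(catalog) && length(catalog) == 1)
    load_alert_catalog(catalog) else catalog
  mols <- ob_mols(smiles)
  hit <- vapply(smarts, function(p) smarts_count(mols, p) > 0,
                logical(length(smiles)))
  if (length(smiles) == 1) hit <- matrix(hit, nrow = 1,
                                         dimnames = list(NULL, names(smarts)))
  res <- lapply(seq_along(smiles), function(i) names(smarts)[hit[i, ]])
  attr(res, "n_alerts") <- vapply(res, length, integer(1))
  res
}

#' Functional-group census over a curated set
#'
#' For each named SMARTS group, counts compounds containing it (once per
#' compound regardless of match multiplicity) and the active share.
#'
#' @param curated `urea_curated` object or a data.frame with
#'   `canonical_smiles` and `activity_class` columns.
#' @param smarts_map named character vector of SMARTS patterns.
#' @return data.frame: `group`, `n_compounds`, `n_active`, `pct_active`.
#' @export
group_census <- function(curated, smarts_map) {
  comp <- if (inherits(curated, "urea_curated")) curated$compounds else curated
  if (nrow(comp) == 0)
    return(data.frame(group = character(0), n_compounds = integer(0),
                      n_active = integer(0), pct_active = numeric(0)))
  mols <- ob_mols(comp$canonical_smiles)
  active <- comp$activity_class == "active"
  rows <- lapply(names(smarts_map), function(nm) {
    has <- smarts_count(mols, smarts_map[[nm]]) > 0
    n <- sum(has); na <- sum(has & active)
    data.frame(group = nm, n_compounds = n, n_active = na,
               pct_active = if (n > 0) round_half_up(100 * na / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default functional-group census map
#'
#' Compact, editable defaults for the family census (urea/thiourea analogues,
#' hydroxamic acids, long carbon chains, aryl halides, diphenols, ...).
#' @export
default_group_map <- function() c(
  urea_analogue = "[NX3][CX3](=[OX1])[NX3]",
  thiourea_analogue = "[NX3][CX3](=[SX1])[NX3]",
  hydroxamic_acid = "[CX3](=[OX1])[NX3][OX2H1]",
  hydrazine = "[NX3;!$(N=O)][NX3;!$(N=O)]",
  sulfonamide = "[#16X4](=[OX1])(=[OX1])[#7]",
  aryl_halogen = "c[F,Cl,Br,I]",
  aryl_thiol = "c[SX2H]",
  diphenol = "[OX2H]c1ccccc1[OX2H]",
  long_carbon_chain = "[CH2R0][CH2R0][CH2R0][CH2R0][CH2R0][CH2R0]",
  pyridine = "c1ccncc1",
  nitro = "[$([NX3](=O)=O),$([NX3+](=[OX1])[OX1-])]"
)

#' Temporal publication trends
#'
#' Per-year compound counts and active percentage; compounds without a year
#' are aggregated under `"unknown"`.
#'
#' @inheritParams group_census
#' @return data.frame: `year`, `n_compounds`, `pct_active`.
#' @export
temporal_trends <- function(curated) {
  comp <- if (inherits(curated, "urea_curated")) curated$compounds else curated
  yr <- ifelse(is.na(comp$first_year), "unknown", as.character(comp$first_year))
  groups <- split(comp$activity_class == "active", yr)
  out <- data.frame(
    year = names(groups),
    n_compounds = vapply(groups, length, integer(1)),
    pct_active = vapply(groups, function(a) round_half_up(100 * mean(a), 1),
                        numeric(1)),
    stringsAsFactors = FALSE)
  known <- suppressWarnings(as.integer(out$year))
  out <- out[order(is.na(known), known), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species activity concordance
#'
#' Runs on the pre-deduplication record table: a compound measured in two or
#' more distinct species is discordant when it is classified active in one
#' species and inactive in another.
#'
#' @param records pre-dedup standardized record table (`$records` of a
#'   `urea_curated` object) with `inchikey`, `species`, `activity_class`.
#' @return list with `n_multi_species`, `n_discordant`, `pct_discordant`.
#' @export
species_concordance <- function(records) {
  if (inherits(records, "urea_curated")) records <- records$records
  by_cmp <- split(records, records$inchikey)
  multi <- Filter(function(g) length(unique(g$species)) >= 2, by_cmp)
  disc <- vapply(multi, function(g) {
    per_species <- vapply(split(g$activity_class, g$species),
                          function(cl) ("active" %in% cl), logical(1))
    any(per_species) && !all(per_species)
  }, logical(1))
  n_multi <- length(multi)
  n_disc <- sum(disc)
  list(n_multi_species = n_multi, n_discordant = n_disc,
       pct_discordant = if (n_multi > 0)
         round_half_up(100 * n_disc / n_multi, 1) else NA_real_)
}
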