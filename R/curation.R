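## Bioassay curation: structure standardization, exclusion rules, activity
## normalization against the assay control, classification, deduplication.

#' Standardize a structure and derive its InChIKey
#'
#' Standardization rules, in order: (1) OpenBabel canonicalization; (2) salt
#' stripping — of the dot-separated fragments, keep the largest
#' carbon-containing fragment (ties broken by canonical SMILES order);
#' (3) charge neutralization (protonate anions, deprotonate cations).
#' Tautomers are *not* canonicalized. Two inputs denoting the same molecule
#' under these rules map to the same InChIKey.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `smiles` (input), `canonical_smiles`,
#'   `inchikey`, `parse_error` (logical).
#' @export
#' @examples
#' standardize_structure(c("c1ccccc1", "C1=CC=CC=C1"))
standardize_structure <- function(smiles) {
  can <- ob_convert_each(smiles, "CAN")
  parent <- vapply(can, function(s) {
    if (is.na(s)) return(NA_character_)
    .largest_organic_fragment(s)
  }, character(1), USE.NAMES = FALSE)
  std <- ob_convert_each(parent, "CAN", neutralize = TRUE)
  ik <- ob_convert_each(std, "INCHIKEY")
  data.frame(smiles = smiles, canonical_smiles = std, inchikey = ik,
             parse_error = is.na(ik), stringsAsFactors = FALSE)
}

.largest_organic_fragment <- function(can_smiles) {
  frags <- split_fragments(can_smiles)
  if (length(frags) == 1) return(can_smiles)
  has_c <- vapply(frags, .fragment_has_carbon, logical(1))
  pool <- if (any(has_c)) frags[has_c] else frags
  sizes <- vapply(pool, .fragment_heavy_atoms, numeric(1))
  pool <- pool[order(-sizes, pool)]
  pool[[1]]
}

.fragment_has_carbon <- function(frag) {
  # carbon token: C not followed by lowercase (Cl, Ca...), or aromatic c
  grepl("C(?![a-z])", frag, perl = TRUE) || grepl("c", frag, fixed = TRUE)
}

.fragment_heavy_atoms <- function(frag) {
  toks <- gregexpr("\\[[^]]+\\]|Cl|Br|Si|Se|[BCNOFPSI]|[bcnops]", frag)[[1]]
  sum(attr(toks, "match.length") > 0 & toks > 0)
}

# elements considered compatible with an organic small molecule; anything
# else in a bonded fragment flags a metal complex (overridable)
#' @rdname exclude_structure
#' @export
default_allowed_elements <- function() .ORGANIC_SUBSET

#' Structure exclusion rules
#'
#' Classifies each structure as kept or dropped. Metal complexes (any atom
#' outside `allowed_elements` remaining after counterion stripping) and
#' mixtures (more than one distinct carbon-containing fragment) are dropped,
#' as are unparsable SMILES.
#'
#' @param smiles character vector of SMILES.
#' @param allowed_elements element symbols that do not trigger the
#'   metal-complex rule.
#' @return character vector with values `"keep"`, `"metal_complex"`,
#'   `"mixture"`, `"parse_error"`.
#' @export
#' @examples
#' exclude_structure(c("CCO", "CC[Ni]CC", "CCO.OCCC"))
exclude_structure <- function(smiles, allowed_elements = default_allowed_elements()) {
  can <- ob_convert_each(smiles, "CAN")
  vapply(seq_along(smiles), function(i) {
    s <- can[i]
    if (is.na(s)) return("parse_error")
    frags <- split_fragments(s)
    has_c <- vapply(frags, .fragment_has_carbon, logical(1))
    organic <- unique(frags[has_c])
    if (length(organic) > 1) return("mixture")
    probe <- if (length(organic) == 1) organic else s
    elems <- mol_elements(probe)
    if (length(elems) == 0) return("parse_error")
    if (any(!elems %in% allowed_elements)) return("metal_complex")
    "keep"
  }, character(1))
}

#' Impute an excess value for qualitative "inactive" records
#'
#' Records reported only as inactive, with no measured concentration, receive
#' an excess value of 1000 uM before normalization; all other records pass
#' through unchanged.
#'
#' @param records data.frame with at least `activity_value` and
#'   `activity_type` columns.
#' @param excess_um imputed concentration in uM (default 1000).
#' @return the records with `activity_value` filled in.
#' @export
impute_qualitative_inactive <- function(records, excess_um = 1000) {
  sel <- records$activity_type == "qualitative_inactive" &
    is.na(records$activity_value)
  records$activity_value[sel] <- excess_um
  records
}

#' Normalize activity against the assay control
#'
#' The dimensionless activity ratio is `activity_value / control_value`; when
#' no control was reported, a fallback control (default 20 uM, a typical
#' thiourea IC50) is used.
#'
#' @param activity_value activity in uM (IC50 or Ki), positive.
#' @param control_value control activity in uM, or `NA`.
#' @param default_control_um fallback control in uM.
#' @return numeric ratio vector.
#' @export
#' @examples
#' normalize_activity(c(40, 10), c(20, NA))
normalize_activity <- function(activity_value, control_value = NA,
                               default_control_um = 20) {
  if (any(!is.na(activity_value) & activity_value <= 0))
    stop("activity_value must be positive", call. = FALSE)
  control <- ifelse(is.na(control_value), default_control_um, control_value)
  if (any(control <= 0)) stop("control value must be positive", call. = FALSE)
  activity_value / control
}

#' Classify normalized activity
#'
#' A compound more potent than the assay control (ratio strictly below 1) is
#' active; otherwise inactive. The boundary ratio 1.0 is inactive.
#'
#' @param ratio positive numeric vector of normalized ratios.
#' @return factor with levels `active`, `inactive`.
#' @export
classify_activity <- function(ratio) {
  stopifnot(all(ratio > 0))
  factor(ifelse(ratio < 1, "active", "inactive"),
         levels = c("active", "inactive"))
}

.UNIT_TO_UM <- c(nM = 1e-3, uM = 1, mM = 1e3, M = 1e6)

#' Convert concentration columns to uM
#' @param value numeric vector.
#' @param unit character vector over `nM`, `uM`, `mM`, `M` (NA treated as uM).
#' @keywords internal
convert_to_um <- function(value, unit) {
  unit[is.na(unit) | unit == ""] <- "uM"
  unit <- sub("µ", "u", unit)
  bad <- !unit %in% names(.UNIT_TO_UM)
  if (any(bad)) stop("unknown concentration unit: ",
                     paste(unique(unit[bad]), collapse = ", "), call. = FALSE)
  value * unname(.UNIT_TO_UM[unit])
}

#' Deduplicate standardized, normalized records by InChIKey
#'
#' One compound per InChIKey is retained, keeping the most potent activity
#' (minimum ratio; ties broken by lexicographically smallest `reference_id`).
#' Species labels are unioned, the first publication year kept, and the merge
#' count recorded. Output rows are sorted by InChIKey.
#'
#' @param records data.frame with columns `inchikey`, `canonical_smiles`,
#'   `ratio`, `activity_value`, `species`, `year`, `reference_id`.
#' @return data.frame with one row per unique InChIKey: `inchikey`,
#'   `canonical_smiles`, `ratio`, `activity_class`, `best_value_um`,
#'   `species`, `first_year`, `n_merged`.
#' @export
deduplicate <- function(records) {
  stopifnot(all(c("inchikey", "canonical_smiles", "ratio") %in% names(records)))
  if (is.null(records$species)) records$species <- "unknown"
  if (is.null(records$year)) records$year <- NA_integer_
  if (is.null(records$reference_id)) records$reference_id <- ""
  if (is.null(records$activity_value)) records$activity_value <- NA_real_
  groups <- split(seq_len(nrow(records)), records$inchikey)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    o <- order(g$ratio, g$reference_id)
    best <- g[o[1], , drop = FALSE]
    yrs <- g$year[!is.na(g$year)]
    data.frame(
      inchikey = best$inchikey,
      canonical_smiles = best$canonical_smiles,
      ratio = best$ratio,
      activity_class = as.character(classify_activity(best$ratio)),
      best_value_um = best$activity_value,
      species = paste(sort(unique(g$species)), collapse = ";"),
      first_year = if (length(yrs)) min(yrs) else NA_integer_,
      n_merged = nrow(g),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inchikey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate a raw bioassay table into an analysis-ready compound set
#'
#' Runs the full curation chain: unit conversion to uM, qualitative-inactive
#' imputation (1000 uM), structure exclusion (metal complexes, mixtures,
#' parse errors), standardization to canonical SMILES + InChIKey,
#' normalization against the assay control (fallback 20 uM), activity
#' classification (ratio < 1 active) and InChIKey deduplication keeping the
#' most potent record. IC50 and Ki records are pooled on the ratio scale;
#' records with other activity types are rejected.
#'
#' @param raw data.frame with columns `record_id`, `smiles`,
#'   `activity_value`, `activity_unit`, `activity_type`, `control_value`,
#'   `control_unit`, `species`, `year`, `reference_id` (missing optional
#'   columns are tolerated).
#' @param default_control_um fallback control concentration in uM.
#' @param excess_um imputed value for qualitative inactives in uM.
#' @param allowed_elements see [exclude_structure()].
#' @return object of class `urea_curated`: list with `compounds` (the curated
#'   data.frame), `records` (per-record standardized pre-dedup table, used
#'   for species-concordance analysis), `rejects` (record_id + reason), and
#'   `params`.
#' @export
curate_bioassay <- function(raw, default_control_um = 20, excess_um = 1000,
                            allowed_elements = default_allowed_elements()) {
  required <- c("record_id", "smiles", "activity_value", "activity_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("activity_unit", "control_unit", "species", "year",
                "reference_id", "control_value"))
    if (is.null(raw[[col]]))
      raw[[col]] <- if (col == "year") NA_integer_ else
        if (col == "control_value") NA_real_ else NA_character_
  raw$species[is.na(raw$species) | raw$species == ""] <- "unknown"

  rejects <- data.frame(record_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  bad_type <- !raw$activity_type %in% c("IC50", "Ki", "qualitative_inactive")
  if (any(bad_type)) {
    rejects <- rbind(rejects, data.frame(record_id = raw$record_id[bad_type],
                                         reason = "unsupported_activity_type"))
    raw <- raw[!bad_type, , drop = FALSE]
  }

  raw$activity_value <- convert_to_um(raw$activity_value, raw$activity_unit)
  raw$control_value <- convert_to_um(raw$control_value, raw$control_unit)
  raw <- impute_qualitative_inactive(raw, excess_um = excess_um)

  no_value <- is.na(raw$activity_value) | raw$activity_value <= 0
  if (any(no_value)) {
    rejects <- rbind(rejects, data.frame(record_id = raw$record_id[no_value],
                                         reason = "missing_activity_value"))
    raw <- raw[!no_value, , drop = FALSE]
  }

  fate <- exclude_structure(raw$smiles, allowed_elements = allowed_elements)
  dropped <- fate != "keep"
  if (any(dropped)) {
    rejects <- rbind(rejects, data.frame(record_id = raw$record_id[dropped],
                                         reason = fate[dropped]))
    raw <- raw[!dropped, , drop = FALSE]
  }

  std <- standardize_structure(raw$smiles)
  bad_std <- std$parse_error
  if (any(bad_std)) {
    rejects <- rbind(rejects, data.frame(record_id = raw$record_id[bad_std],
                                         reason = "parse_error"))
    raw <- raw[!bad_std, , drop = FALSE]
    std <- std[!bad_std, , drop = FALSE]
  }
  raw$canonical_smiles <- std$canonical_smiles
  raw$inchikey <- std$inchikey
  raw$ratio <- normalize_activity(raw$activity_value, raw$control_value,
                                  default_control_um = default_control_um)
  raw$activity_class <- as.character(classify_activity(raw$ratio))

  compounds <- deduplicate(raw)
  structure(list(compounds = compounds, records = raw, rejects = rejects,
                 params = list(default_control_um = default_control_um,
                               excess_um = excess_um)),
            class = "urea_curated")
}

#' @export
print.urea_curated <- function(x, ...) {
  cls <- table(x$compounds$activity_class)
  cat("Curated bioassay compound set\n")
  cat(sprintf("  %d compounds from %d records (%d rejected)\n",
              nrow(x$compounds), nrow(x$records), nrow(x$rejects)))
  n_of <- function(k) if (k %in% names(cls)) cls[[k]] else 0L
  cat(sprintf("  active: %d  inactive: %d\n", n_of("active"), n_of("inactive")))
  invisible(x)
}

#' @export
summary.urea_curated <- function(object, ...) {
  comp <- object$compounds
  out <- list(
    n_compounds = nrow(comp),
    n_records = nrow(object$records),
    n_rejected = nrow(object$rejects),
    class_counts = table(comp$activity_class),
    reject_reasons = if (nrow(object$rejects)) table(object$rejects$reason)
                     else table(character(0)),
    ratio_range = range(comp$ratio))
  class(out) <- "summary.urea_curated"
  out
}

#' @export
print.summary.urea_curated <- function(x, ...) {
  cat("Curated set:", x$n_compounds, "compounds |", x$n_records, "records |",
      x$n_rejected, "rejected\n")
  print(x$class_counts)
  if (length(x$reject_reasons)) print(x$reject_reasons)
  cat(sprintf("ratio range: %.3g .. %.3g\n", x$ratio_range[1], x$ratio_range[2]))
  invisible(x)
}

#' Read / write curation tables
#'
#' CSV interfaces matching the documented column contracts.
#' @param path file path.
#' @export
read_bioassay_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param curated a `urea_curated` object.
#' @param rejects_path optional path for the rejection log.
#' @rdname read_bioassay_csv
#' @export
write_curated_csv <- function(curated, path, rejects_path = NULL) {
  utils::write.csv(curated$compounds, path, row.names = FALSE)
  if (!is.null(rejects_path))
    utils::write.csv(curated$rejects, rejects_path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
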