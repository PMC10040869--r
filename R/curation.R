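# Bioactivity curation: record retrieval, assay-type selection, unit
# normalization, and active/inactive labeling.

VALUE_TYPES <- c("Ki", "IC50", "EC50", "INH", "other")
CONC_TYPES <- c("Ki", "IC50", "EC50")

normalize_value_type <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[x %in% c("KI", "K_I")] <- "Ki"
  out[x == "IC50"] <- "IC50"
  out[x == "EC50"] <- "EC50"
  out[x %in% c("INH", "%INH", "INHIBITION", "PERCENT INHIBITION")] <- "INH"
  out
}

#' Retrieve bioactivity records for an expanded target list
#'
#' The bioactivity source is either a CSV file or a data frame with the record
#' schema `smiles`, `target_uniprot`, `value_type`, `standard_value`,
#' `standard_units` (an `inchikey` column, if present, is ignored and
#' recomputed from the standardized structure so that compound identity is
#' consistent package-wide). Molecules are standardized; unparseable
#' structures are skipped and counted. Value types are normalized to the
#' controlled vocabulary Ki / IC50 / EC50 / INH / other.
#'
#' @param source CSV path or data frame.
#' @param targets optional tibble of homolog hits (from [filter_homologs()]);
#'   when given, records are restricted to those targets and targets with zero
#'   records produce a warning.
#' @return tibble of activity records (one row per measurement) with columns
#'   `inchikey`, `smiles`, `target_uniprot`, `value_type`, `standard_value`,
#'   `standard_units`; the number of skipped structures is in the
#'   `"n_skipped"` attribute.
#' @export
read_activity_records <- function(source, targets = NULL) {
  df <- if (is.character(source)) {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(source)
  }
  names(df) <- tolower(names(df))
  need <- c("smiles", "target_uniprot", "value_type", "standard_value", "standard_units")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("bioactivity source lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(targets)) {
    found <- unique(df$target_uniprot)
    absent <- setdiff(targets$uniprot_id, found)
    if (length(absent)) {
      warning("no bioactivity records for target(s): ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    df <- df[df$target_uniprot %in% targets$uniprot_id, , drop = FALSE]
  }
  if (!nrow(df)) stop("no bioactivity records to curate", call. = FALSE)

  std <- suppressWarnings(
    standardize_molecules(df$smiles, source_id = as.character(seq_len(nrow(df))))
  )
  keep <- as.integer(std$source_id)
  n_skipped <- nrow(df) - nrow(std)
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) with unparseable structures skipped", call. = FALSE)
  }
  out <- tibble::tibble(
    inchikey = std$inchikey,
    smiles = std$smiles,
    target_uniprot = as.character(df$target_uniprot[keep]),
    value_type = normalize_value_type(df$value_type[keep]),
    standard_value = as.numeric(df$standard_value[keep]),
    standard_units = as.character(df$standard_units[keep])
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Tabulate assay value types and select the dominant one
#'
#' The value type with the greatest record count over the whole expanded
#' corpus is selected for labeling. Ties are broken by the fixed priority
#' Ki > IC50 > EC50 > INH > other (binding assays first).
#'
#' @param records tibble from [read_activity_records()].
#' @return the selected value type (string); the full count table is attached
#'   as attribute `"counts"`.
#' @export
select_primary_value_type <- function(records) {
  stopifnot(nrow(records) > 0)
  counts <- table(factor(records$value_type, levels = VALUE_TYPES))
  counts_tbl <- tibble::tibble(value_type = names(counts),
                               n_records = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$n_records))
  # which.max on the priority-ordered table implements the tie-break
  chosen <- VALUE_TYPES[which.max(as.integer(counts))]
  structure(chosen, counts = counts_tbl)
}

#' Normalize concentration measurements to nanomolar
#'
#' @param value numeric vector of measurements.
#' @param units unit strings; recognized: pM, nM, uM (also \enc{µ}{u}M), mM, M.
#' @return values in nM; `NA` (non-normalizable) for unknown units.
#' @export
normalize_to_nm <- function(value, units) {
  scale <- c(pm = 1e-3, nm = 1, um = 1e3, "µm" = 1e3, "μm" = 1e3,
             mm = 1e6, m = 1e9)
  f <- scale[tolower(trimws(units))]
  as.numeric(value) * as.numeric(f)
}

#' Label compounds active / inactive
#'
#' Records of the chosen value type are aggregated per compound (InChI key) and
#' labeled. For concentration types (Ki / IC50 / EC50) measurements are
#' normalized to nM and a compound is active when its aggregated value is at or
#' below `potency_cutoff_nm`; for percent inhibition a compound is active when
#' its aggregated value is at or above `inhibition_cutoff_pct`. Both boundaries
#' are inclusive. Replicate measurements are aggregated by the median.
#'
#' Two cross-target conflict policies are available: `"pooled-median"` (the
#' default) pools all measurements across the expanded target list before
#' taking the median; `"any-active"` labels a compound active if its per-target
#' median passes the cutoff on any target.
#'
#' @param records tibble from [read_activity_records()].
#' @param value_type value type to label on; default: the majority type from
#'   [select_primary_value_type()].
#' @param potency_cutoff_nm activity cutoff for concentration types (default
#'   1000 nM).
#' @param inhibition_cutoff_pct activity cutoff for percent inhibition
#'   (default 50).
#' @param conflict_policy `"pooled-median"` or `"any-active"`.
#' @return an `lvs_labeled` tibble (`inchikey`, `smiles`, `label`,
#'   `evidence_count`), one row per compound. Attributes: `"per_target"`
#'   (per-compound, per-target medians and pass flags, used by the
#'   retrospective protocol), `"value_type"`, `"n_nonnormalizable"`.
#' @export
label_compounds <- function(records, value_type = NULL,
                            potency_cutoff_nm = 1000,
                            inhibition_cutoff_pct = 50,
                            conflict_policy = c("pooled-median", "any-active")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(potency_cutoff_nm > 0, inhibition_cutoff_pct > 0)
  if (is.null(value_type)) value_type <- as.character(select_primary_value_type(records))
  stopifnot(value_type %in% VALUE_TYPES)

  rec <- records[records$value_type == value_type, , drop = FALSE]
  if (value_type %in% CONC_TYPES) {
    rec$norm_value <- normalize_to_nm(rec$standard_value, rec$standard_units)
    is_active <- function(v) v <= potency_cutoff_nm
  } else if (value_type == "INH") {
    # %INH used as-is; the distinct concentration annotations, when present in
    # the unit strings, are reported for the user to review.
    conc_notes <- unique(rec$standard_units)
    rec$norm_value <- as.numeric(rec$standard_value)
    is_active <- function(v) v >= inhibition_cutoff_pct
  } else {
    stop("cannot label on value type 'other'", call. = FALSE)
  }
  n_bad <- sum(is.na(rec$norm_value))
  if (n_bad > 0) {
    warning(n_bad, " record(s) with non-normalizable units excluded from labeling",
            call. = FALSE)
  }
  rec <- rec[!is.na(rec$norm_value), , drop = FALSE]
  if (!nrow(rec)) {
    stop("zero labelable records for value type ", value_type,
         " (", n_bad, " non-normalizable)", call. = FALSE)
  }

  per_target <- rec |>
    dplyr::group_by(.data$inchikey, .data$target_uniprot) |>
    dplyr::summarise(median_value = stats::median(.data$norm_value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(passes = is_active(.data$median_value))

  pooled <- rec |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(smiles = dplyr::first(.data$smiles),
                     pooled_median = stats::median(.data$norm_value),
                     evidence_count = dplyr::n(), .groups = "drop")

  if (conflict_policy == "pooled-median") {
    pooled$label <- ifelse(is_active(pooled$pooled_median), "active", "inactive")
  } else {
    any_active <- per_target |>
      dplyr::group_by(.data$inchikey) |>
      dplyr::summarise(any = any(.data$passes), .groups = "drop")
    pooled$label <- ifelse(any_active$any[match(pooled$inchikey, any_active$inchikey)],
                           "active", "inactive")
  }
  n_conflict <- per_target |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(conflict = dplyr::n_distinct(.data$passes) > 1, .groups = "drop")
  out <- tibble::tibble(
    inchikey = pooled$inchikey,
    smiles = pooled$smiles,
    label = pooled$label,
    evidence_count = pooled$evidence_count
  )
  structure(out, class = c("lvs_labeled", class(out)),
            per_target = per_target,
            value_type = value_type,
            n_nonnormalizable = n_bad,
            n_conflicting = sum(n_conflict$conflict),
            inh_concentration_notes = if (value_type == "INH") conc_notes else NULL)
}
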