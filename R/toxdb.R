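#' Taxon groups and acute-duration windows
#'
#' The recognized taxon groups of the ecotoxicity-record schema and the
#' acute exposure-duration windows (hours, inclusive) accepted for each
#' during screening: vertebrates 48-96 h, amphipods 48-168 h, insects,
#' annelids, ostracods and unassigned invertebrates up to 96 h, cladocerans
#' 48 h, molluscs 96 h (glochidia life stage 48 h), anostraca 24 h, algae
#' 72 h, plants 96-168 h.
#'
#' @return `taxon_groups()`: character vector of recognized groups.
#' @export
taxon_groups <- function() names(.duration_windows)

.duration_windows <- list(
  algae = c(72, 72), plant = c(96, 168),
  cladoceran = c(48, 48), amphipod = c(48, 168),
  annelid = c(0, 96), insect = c(0, 96), ostracod = c(0, 96),
  mollusc = c(96, 96), anostraca = c(24, 24),
  fish = c(48, 96), amphibian = c(48, 96),
  other_invertebrate = c(0, 96))

#' @rdname taxon_groups
#' @param taxon_group taxon group of a record.
#' @param life_stage optional life stage (`"glochidia"` switches molluscs to
#'   the 48 h window).
#' @return `duration_window()`: numeric `c(lower, upper)` in hours.
#' @export
duration_window <- function(taxon_group, life_stage = NA_character_) {
  if (!taxon_group %in% names(.duration_windows))
    stop("unknown taxon group '", taxon_group, "'; valid groups: ",
         paste(names(.duration_windows), collapse = ", "))
  if (taxon_group == "mollusc" && !is.na(life_stage) &&
      tolower(life_stage) == "glochidia") return(c(48, 48))
  .duration_windows[[taxon_group]]
}

#' Assign the bioavailability model for a taxon group
#'
#' Algae are normalized with the pH extended algae model, all vertebrates
#' (fish, amphibians) with the fish model, and all invertebrate groups and
#' plants with the pH extended average invertebrate model.
#'
#' @param taxon_group one of [taxon_groups()] (vectorized).
#' @return Model id(s): `"algae"`, `"fish"` or `"avg_invertebrate"`.
#' @examples
#' assign_model("amphibian")  # "fish"
#' assign_model("plant")      # "avg_invertebrate"
#' @export
assign_model <- function(taxon_group) {
  vapply(taxon_group, function(tg) {
    if (!tg %in% names(.duration_windows))
      stop("unknown taxon group '", tg, "'; valid groups: ",
           paste(names(.duration_windows), collapse = ", "))
    if (tg == "algae") "algae"
    else if (tg %in% c("fish", "amphibian")) "fish"
    else "avg_invertebrate"
  }, character(1), USE.NAMES = FALSE)
}

.toxdb_columns <- c("record_id", "species", "taxon_group", "endpoint",
                    "duration_h", "lc50_ug_l", "basis", "medium",
                    "reliable", "life_stage", "source",
                    "ph", "doc_mg_l", "ca_mol_l", "mg_mol_l", "na_mol_l",
                    "k_mol_l", "so4_mol_l", "cl_mol_l", "alkalinity_eq_l",
                    "dic_mol_l", "hardness_mg_caco3_l", "temp_c")

#' Validate / coerce an ecotoxicity record table
#'
#' Ensures the toxicity table carries the full record schema (one acute
#' L(E)C50 entry per row with its test-water chemistry), adding absent
#' optional columns as `NA` and checking basic invariants (positive L(E)C50
#' and duration, recognized basis/medium). Species names are normalized
#' case-insensitively (first letter capitalized), optionally through a
#' synonym map.
#'
#' @param df a data.frame with at least `species`, `taxon_group`,
#'   `endpoint`, `duration_h`, `lc50_ug_l` and chemistry columns (`ph`,
#'   `doc_mg_l`, and ions/hardness as available).
#' @param synonyms optional named character vector mapping species synonyms
#'   to accepted names (matched case-insensitively).
#' @return The completed data.frame.
#' @export
tox_records <- function(df, synonyms = NULL) {
  need <- c("species", "taxon_group", "endpoint", "duration_h", "lc50_ug_l", "ph")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("toxicity table lacks columns: ",
                            paste(missing, collapse = ", "))
  for (col in .toxdb_columns) if (!col %in% names(df)) df[[col]] <- NA
  if (all(is.na(df$record_id))) df$record_id <- seq_len(nrow(df))
  df$basis[is.na(df$basis)] <- "dissolved"
  df$medium[is.na(df$medium)] <- "natural"
  df$reliable[is.na(df$reliable)] <- TRUE
  df$temp_c[is.na(df$temp_c)] <- 20
  if (any(!is.na(df$lc50_ug_l) & df$lc50_ug_l <= 0))
    stop("lc50_ug_l must be > 0")
  if (any(!is.na(df$duration_h) & df$duration_h <= 0))
    stop("duration_h must be > 0")
  bad <- setdiff(unique(df$basis), c("dissolved", "total"))
  if (length(bad)) stop("unknown basis: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$medium), c("natural", "artificial"))
  if (length(bad)) stop("unknown medium: ", paste(bad, collapse = ", "))
  norm_name <- function(s) {
    s <- trimws(s)
    paste0(toupper(substring(s, 1, 1)), tolower(substring(s, 2)))
  }
  sp <- norm_name(df$species)
  if (!is.null(synonyms)) {
    idx <- match(tolower(sp), tolower(names(synonyms)))
    sp[!is.na(idx)] <- unname(synonyms[idx[!is.na(idx)]])
  }
  df$species <- sp
  df[, union(.toxdb_columns, names(df))]
}

#' Fill derivable chemistry fields of a record table
#'
#' Applies the chemistry-completion rules record by record: Ca and Mg are
#' filled from hardness (3:1 molar split) when absent; Mg alone is derived
#' as the hardness remainder (or the 3:1 ratio when no hardness is stored);
#' hardness is computed from the ions when absent; DIC is derived from pH
#' and alkalinity (open system); DOC is set to 0 for artificial media with
#' no DOC reported. The provenance of every filled field is recorded in a
#' `filled_fields` column.
#'
#' @param df a record table (see [tox_records()]).
#' @return The table with derivable fields filled.
#' @export
complete_chemistry <- function(df) {
  df <- tox_records(df)
  filled <- character(nrow(df))
  add <- function(i, what) {
    filled[i] <<- ifelse(nzchar(filled[i]), paste(filled[i], what, sep = ";"),
                         what)
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(df$doc_mg_l[i]) && identical(df$medium[i], "artificial")) {
      df$doc_mg_l[i] <- 0
      add(i, "doc=0 (artificial medium)")
    }
    if (is.na(df$ca_mol_l[i]) && is.na(df$mg_mol_l[i]) &&
        !is.na(df$hardness_mg_caco3_l[i])) {
      sp <- split_hardness(df$hardness_mg_caco3_l[i])
      df$ca_mol_l[i] <- sp[["ca"]]; df$mg_mol_l[i] <- sp[["mg"]]
      add(i, "ca,mg from hardness 3:1")
    } else if (!is.na(df$ca_mol_l[i]) && is.na(df$mg_mol_l[i])) {
      df$mg_mol_l[i] <- if (!is.na(df$hardness_mg_caco3_l[i]))
        max(df$hardness_mg_caco3_l[i] / (.MW_CACO3 * 1000) - df$ca_mol_l[i], 0)
      else df$ca_mol_l[i] / 3
      add(i, "mg derived")
    }
    if (is.na(df$hardness_mg_caco3_l[i]) && !is.na(df$ca_mol_l[i]) &&
        !is.na(df$mg_mol_l[i])) {
      df$hardness_mg_caco3_l[i] <- hardness_from_ions(df$ca_mol_l[i],
                                                      df$mg_mol_l[i])
      add(i, "hardness from ions")
    }
    if (is.na(df$dic_mol_l[i]) && !is.na(df$ph[i])) {
      alk <- if (!is.na(df$alkalinity_eq_l[i])) df$alkalinity_eq_l[i] else 0
      ok <- df$ph[i] > 2 && df$ph[i] < 12
      if (ok) {
        df$dic_mol_l[i] <- dic_from_alkalinity(df$ph[i], alk, df$temp_c[i])
        add(i, if (!is.na(df$alkalinity_eq_l[i]))
          "dic from ph+alkalinity" else "dic open-system (no alkalinity)")
      }
    }
  }
  if (is.null(df$filled_fields)) df$filled_fields <- filled
  else df$filled_fields <- ifelse(nzchar(filled),
                                  paste(df$filled_fields, filled, sep = ";"),
                                  df$filled_fields)
  df
}

#' Screen ecotoxicity records for retention
#'
#' Applies the retention rules in order and annotates each record with a
#' `retained` flag and (for rejections) a single machine-readable
#' `rejection_reason`: (0) pre-screened reliability flag; (1) toxicity
#' expressed on a total basis is accepted only in artificial media, where
#' total is assumed equal to dissolved; (2) the exposure duration must fall
#' in the taxon's acute window (see [duration_window()]); (3) pH, DOC and Ca
#' or hardness must be present after chemistry completion; (4) pH and
#' hardness must lie within the assigned bioavailability model's
#' applicability range. Screening never raises on a record; it annotates,
#' and is idempotent.
#'
#' @param df a record table; [complete_chemistry()] is applied first.
#' @return The table with `retained` and `rejection_reason` columns set.
#' @export
screen_records <- function(df) {
  df <- complete_chemistry(df)
  models <- gbam_models()
  n <- nrow(df)
  retained <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    reject <- function(code) { retained[i] <<- FALSE; reason[i] <<- code }
    tg <- df$taxon_group[i]
    if (!tg %in% names(.duration_windows)) { reject("unknown_taxon"); next }
    if (!isTRUE(as.logical(df$reliable[i]))) { reject("unreliable"); next }
    if (identical(df$basis[i], "total") && !identical(df$medium[i], "artificial")) {
      reject("total_basis_in_natural_medium"); next
    }
    win <- duration_window(tg, df$life_stage[i])
    if (is.na(df$duration_h[i]) || df$duration_h[i] < win[1] ||
        df$duration_h[i] > win[2]) { reject("duration_window"); next }
    if (is.na(df$ph[i]) || is.na(df$doc_mg_l[i]) ||
        (is.na(df$ca_mol_l[i]) && is.na(df$hardness_mg_caco3_l[i]))) {
      reject("missing_chemistry"); next
    }
    m <- models[[assign_model(tg)]]
    hard <- df$hardness_mg_caco3_l[i]
    if (df$ph[i] < m$applicability$ph[1] || df$ph[i] > m$applicability$ph[2] ||
        is.na(hard) || hard < m$applicability$hardness[1] ||
        hard > m$applicability$hardness[2]) {
      reject("outside_model_range"); next
    }
  }
  df$retained <- retained
  df$rejection_reason <- reason
  df
}

#' Read / write toxicity record tables
#'
#' `read_toxdb()` reads a record CSV (the documented column set; see
#' [tox_records()]). `write_toxdb()` writes retained and rejected records to
#' separate CSV files.
#'
#' @param file,file_retained,file_rejected CSV paths.
#' @param df a screened record table.
#' @return `read_toxdb()`: a validated record table.
#' @export
read_toxdb <- function(file) {
  tox_records(read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_toxdb
#' @export
write_toxdb <- function(df, file_retained, file_rejected = NULL) {
  if (is.null(df$retained)) stop("records must be screened first")
  write.csv(df[df$retained, , drop = FALSE], file_retained, row.names = FALSE)
  if (!is.null(file_rejected))
    write.csv(df[!df$retained, , drop = FALSE], file_rejected,
              row.names = FALSE)
  invisible(df)
}

#' Summary statistics of a retained record set
#'
#' @param df a screened record table.
#' @return List with `n_entries`, `n_species`, `min_lc50` and `max_lc50`
#'   (ug dissolved Ni/L) over the retained records.
#' @export
db_summary <- function(df) {
  if (!is.null(df$retained)) df <- df[df$retained, , drop = FALSE]
  list(n_entries = nrow(df),
       n_species = length(unique(df$species)),
       min_lc50 = if (nrow(df)) min(df$lc50_ug_l) else NA_real_,
       max_lc50 = if (nrow(df)) max(df$lc50_ug_l) else NA_real_)
}

# water_sample from one record row (chemistry must be complete)
.record_water <- function(df, i) {
  water_sample(ph = df$ph[i], doc = df$doc_mg_l[i],
               ca = df$ca_mol_l[i], mg = df$mg_mol_l[i],
               na = if (is.na(df$na_mol_l[i])) 0 else df$na_mol_l[i],
               k = if (is.na(df$k_mol_l[i])) 0 else df$k_mol_l[i],
               so4 = if (is.na(df$so4_mol_l[i])) 0 else df$so4_mol_l[i],
               cl = if (is.na(df$cl_mol_l[i])) 0 else df$cl_mol_l[i],
               alkalinity = if (is.na(df$alkalinity_eq_l[i])) NULL else df$alkalinity_eq_l[i],
               dic = if (is.na(df$dic_mol_l[i])) NULL else df$dic_mol_l[i],
               hardness = if (is.na(df$hardness_mg_caco3_l[i])) NULL else df$hardness_mg_caco3_l[i],
               temp = df$temp_c[i], id = df$record_id[i])
}

#' Intrinsic sensitivity of each record (Direction 1)
#'
#' Speciates each record's test water at its observed L(E)C50 and inverts
#' the taxon's bioavailability model to obtain the record-level intrinsic
#' sensitivity Q50.
#'
#' @param df a chemistry-complete record table (typically the retained set).
#' @param engine a [speciation_engine()].
#' @return Numeric vector of Q50 values (one per row).
#' @export
record_q50 <- function(df, engine = speciation_engine()) {
  df <- complete_chemistry(df)
  models <- gbam_models()
  vapply(seq_len(nrow(df)), function(i) {
    w <- .record_water(df, i)
    s <- speciate(w, df$lc50_ug_l[i], engine)
    m <- models[[assign_model(df$taxon_group[i])]]
    q50_from_observation(m, s$activity_ni2, w$ph,
                         activity_ca2 = s$activity_ca2,
                         activity_mg2 = s$activity_mg2, override = TRUE)
  }, numeric(1))
}
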