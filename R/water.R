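#' Construct a water sample
#'
#' A `water_sample` holds the measured or derived chemistry of one toxicity
#' test water or one target water: pH, dissolved organic carbon, the major
#' cations and anions, and the carbonate system. Ion concentrations are in
#' mol/L, DOC in mg C/L, alkalinity in eq/L, DIC in mol C/L, hardness in
#' mg CaCO3/L. When only hardness is supplied, Ca and Mg are filled on a 3:1
#' molar basis (see [split_hardness()]); when both ions and hardness are
#' supplied they must agree within 5 %.
#'
#' @param ph pH of the water (must lie in (0, 14)).
#' @param doc dissolved organic carbon, mg C/L.
#' @param ca,mg,na,k calcium, magnesium, sodium, potassium, mol/L.
#' @param so4,cl sulfate and chloride, mol/L.
#' @param alkalinity carbonate alkalinity, eq/L; `NULL` if unknown.
#' @param dic dissolved inorganic carbon, mol C/L; derived from pH and
#'   alkalinity when `NULL` (open-system assumption, see
#'   [dic_from_alkalinity()]).
#' @param hardness total hardness, mg CaCO3/L; derivable from Ca and Mg.
#' @param temp temperature, degrees C.
#' @param id optional identifier.
#' @return An object of class `water_sample` (a named list).
#' @examples
#' w <- water_sample(ph = 7.5, doc = 2, hardness = 100, alkalinity = 1e-3)
#' w$ca / w$mg  # 3:1 molar split
#' @export
water_sample <- function(ph, doc = 0, ca = NULL, mg = NULL, na = 0, k = 0,
                         so4 = 0, cl = 0, alkalinity = NULL, dic = NULL,
                         hardness = NULL, temp = 20, id = NULL) {
  if (!is.numeric(ph) || length(ph) != 1L || is.na(ph) || ph <= 0 || ph >= 14)
    stop("pH must be a single number in (0, 14)")
  num_or_null <- function(x, name) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(NULL)
    if (!is.numeric(x) || length(x) != 1L) stop(name, " must be a single number")
    if (x < 0) stop(name, " must be >= 0")
    x
  }
  doc <- num_or_null(doc, "doc") %||% 0
  ca <- num_or_null(ca, "ca"); mg <- num_or_null(mg, "mg")
  na <- num_or_null(na, "na") %||% 0; k <- num_or_null(k, "k") %||% 0
  so4 <- num_or_null(so4, "so4") %||% 0; cl <- num_or_null(cl, "cl") %||% 0
  alkalinity <- num_or_null(alkalinity, "alkalinity")
  dic <- num_or_null(dic, "dic")
  hardness <- num_or_null(hardness, "hardness")

  if (is.null(ca) && is.null(mg)) {
    if (is.null(hardness))
      stop("supply either hardness or Ca (and Mg) concentrations")
    sp <- split_hardness(hardness)
    ca <- sp[["ca"]]; mg <- sp[["mg"]]
  } else {
    ca <- ca %||% 0
    if (is.null(mg)) {
      # derive Mg from hardness when available, else assume the 3:1 molar ratio
      mg <- if (!is.null(hardness)) max(hardness / (.MW_CACO3 * 1000) - ca, 0)
            else ca / 3
    }
    if (!is.null(hardness)) {
      h_ions <- hardness_from_ions(ca, mg)
      if (hardness > 0 && abs(h_ions - hardness) > 0.05 * hardness)
        stop(sprintf(
          "hardness (%.3g mg CaCO3/L) disagrees with Ca+Mg (%.3g) by > 5%%",
          hardness, h_ions))
    }
  }
  if (is.null(hardness)) hardness <- hardness_from_ions(ca, mg)

  structure(list(id = id, ph = ph, doc = doc, ca = ca, mg = mg, na = na,
                 k = k, so4 = so4, cl = cl, alkalinity = alkalinity,
                 dic = dic, hardness = hardness, temp = temp),
            class = "water_sample")
}

#' @export
print.water_sample <- function(x, ...) {
  cat("Water sample", if (!is.null(x$id)) paste0("'", x$id, "'") else "", "\n")
  cat(sprintf("  pH %.2f, DOC %.2f mg/L, hardness %.1f mg CaCO3/L, %g C\n",
              x$ph, x$doc, x$hardness, x$temp))
  cat(sprintf("  Ca %.3g, Mg %.3g, Na %.3g, K %.3g, SO4 %.3g, Cl %.3g mol/L\n",
              x$ca, x$mg, x$na, x$k, x$so4, x$cl))
  cat(sprintf("  alkalinity %s eq/L, DIC %s mol/L\n",
              if (is.null(x$alkalinity)) "-" else format(x$alkalinity),
              if (is.null(x$dic)) "(derived at use)" else format(x$dic)))
  invisible(x)
}

#' Split hardness into calcium and magnesium
#'
#' Converts total hardness (mg CaCO3/L) into Ca and Mg concentrations using a
#' 3:1 Ca:Mg molar ratio, the convention applied when a study reports only
#' hardness.
#'
#' @param hardness total hardness, mg CaCO3/L (>= 0).
#' @return Named numeric vector with elements `ca` and `mg` (mol/L).
#' @examples
#' split_hardness(100)  # c(ca = 7.49e-4, mg = 2.50e-4)
#' @export
split_hardness <- function(hardness) {
  if (!is.numeric(hardness) || any(is.na(hardness)) || any(hardness < 0))
    stop("hardness must be >= 0")
  total <- hardness / (.MW_CACO3 * 1000)  # mol/L of Ca+Mg
  c(ca = unname(0.75 * total), mg = unname(0.25 * total))
}

#' Hardness from calcium and magnesium
#'
#' @param ca,mg concentrations in mol/L.
#' @return Hardness in mg CaCO3/L.
#' @export
hardness_from_ions <- function(ca, mg) (ca + mg) * .MW_CACO3 * 1000

# carbonate system constants at 25 C (temperature correction is off by
# default; the van 't Hoff option is deliberately not applied here)
.carb_k <- function() {
  sc <- stability_constants()
  list(k1 = 10^(sc$reactions$HCO3$logk - sc$reactions$`H2CO3*`$logk),  # H2CO3* -> H + HCO3
       k2 = 10^(-sc$reactions$HCO3$logk),                               # HCO3 -> H + CO3
       kw = 10^(-sc$reactions$H2O$logk),
       co2aq = 10^sc$co2$log_kh * sc$co2$pco2_atm)
}

#' Dissolved inorganic carbon from pH and alkalinity
#'
#' Estimates DIC for a water assuming an open system: dissolved CO2 is fixed
#' by equilibrium with atmospheric pCO2, while bicarbonate and carbonate are
#' partitioned from the carbonate alkalinity at the stated pH using the
#' carbonate equilibrium constants (25 C values). With zero alkalinity the
#' estimate reduces to atmospheric CO2(aq) alone.
#'
#' @param ph pH, must lie in (2, 12).
#' @param alkalinity carbonate alkalinity, eq/L (>= 0).
#' @param temp temperature, degrees C (accepted for interface symmetry;
#'   constants are 25 C values, see Details).
#' @return DIC in mol C/L.
#' @details The carbonate alkalinity available to HCO3-/CO32- is
#'   `alkalinity + [H+] - [OH-]`, floored at zero. The function is strictly
#'   increasing in alkalinity at fixed pH.
#' @export
dic_from_alkalinity <- function(ph, alkalinity, temp = 20) {
  if (!is.numeric(ph) || ph <= 2 || ph >= 12)
    stop("pH must lie in (2, 12) for the carbonate-system estimate")
  if (!is.numeric(alkalinity) || alkalinity < 0)
    stop("alkalinity must be >= 0")
  k <- .carb_k()
  ah <- 10^(-ph)
  ca_alk <- max(alkalinity + ah - k$kw / ah, 0)
  r <- k$k2 / ah                      # [CO3]/[HCO3]
  hco3 <- ca_alk / (1 + 2 * r)
  co3 <- r * hco3
  k$co2aq + hco3 + co3
}

# resolve the DIC of a water sample, deriving it if necessary
.water_dic <- function(water) {
  if (!is.null(water$dic)) return(water$dic)
  dic_from_alkalinity(water$ph, water$alkalinity %||% 0, water$temp)
}

#' Read water samples from CSV
#'
#' Reads the water CSV dialect: one row per water with required columns `ph`
#' and `doc_mg_l`, plus either `ca_mol_l`/`mg_mol_l` or
#' `hardness_mg_caco3_l`. Optional columns: `water_id`, `na_mol_l`,
#' `k_mol_l`, `so4_mol_l`, `cl_mol_l`, `alkalinity_eq_l`, `dic_mol_l`,
#' `temp_c`.
#'
#' @param file path to a CSV file.
#' @return A list of [water_sample()] objects, named by `water_id` when
#'   present.
#' @export
read_waters <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  required <- c("ph", "doc_mg_l")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("water CSV lacks columns: ",
                            paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) water_from_row(df[i, ]))
  if ("water_id" %in% names(df)) names(out) <- as.character(df$water_id)
  out
}

#' Build a water sample from one row of the water CSV dialect
#'
#' @param row a one-row data.frame using the water CSV column names.
#' @return A [water_sample()].
#' @export
water_from_row <- function(row) {
  g <- function(col) if (col %in% names(row) && !is.na(row[[col]])) row[[col]] else NULL
  water_sample(ph = row$ph,
               doc = g("doc_mg_l") %||% 0,
               ca = g("ca_mol_l"), mg = g("mg_mol_l"),
               na = g("na_mol_l") %||% 0, k = g("k_mol_l") %||% 0,
               so4 = g("so4_mol_l") %||% 0, cl = g("cl_mol_l") %||% 0,
               alkalinity = g("alkalinity_eq_l"), dic = g("dic_mol_l"),
               hardness = g("hardness_mg_caco3_l"),
               temp = g("temp_c") %||% 20,
               id = g("water_id"))
}
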