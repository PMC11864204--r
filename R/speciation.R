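#' Davies activity coefficient
#'
#' Single-ion activity coefficient from the Davies equation,
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)`, with A = 0.509 at
#' 25 C and a small linear temperature adjustment.
#'
#' @param charge integer ionic charge (0 for neutral species).
#' @param ionic_strength ionic strength, mol/L (>= 0).
#' @param temp temperature, degrees C.
#' @return Activity coefficient (1 at infinite dilution or zero charge).
#' @examples
#' davies_gamma(2, 0.01)
#' @export
davies_gamma <- function(charge, ionic_strength, temp = 25) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  a <- 0.509 + 4.6e-4 * (temp - 25)
  sqi <- sqrt(ionic_strength)
  10^(-a * charge^2 * (sqi / (1 + sqi) - 0.3 * ionic_strength))
}

#' Reference speciation engine configuration
#'
#' Bundles the shipped stability-constants table with the (overridable)
#' single-site DOC binding parameters into the engine configuration used by
#' [speciate()]. The reference engine solves the inorganic Ni/Ca/Mg carbonate,
#' sulfate, chloride and hydroxide equilibria with Davies activity
#' corrections; DOC binding is a conditional single-site model whose default
#' constants are documented stand-ins for a full humic-ion binding model
#' (the engine id tags all results for provenance).
#'
#' @param logk_nifa intrinsic log10 K for Ni binding to the deprotonated
#'   fulvic site.
#' @param pka_h effective pKa of the fulvic site; proton competition makes
#'   the conditional binding constant `K / (1 + aH / Ka)` increase with pH,
#'   as humic binding models predict.
#' @param doc_sites_mol_per_mg binding-site density, mol sites per mg DOC.
#' @return A list with class `speciation_engine`.
#' @export
speciation_engine <- function(logk_nifa = NULL, pka_h = NULL,
                              doc_sites_mol_per_mg = NULL) {
  sc <- stability_constants()
  structure(list(
    constants = sc,
    logk_nifa = logk_nifa %||% sc$doc_binding$logk_nifa,
    pka_h = pka_h %||% sc$doc_binding$pka_h,
    doc_sites_mol_per_mg = doc_sites_mol_per_mg %||% sc$doc_binding$sites_mol_per_mg_c,
    engine_id = "nibam-reference-1"
  ), class = "speciation_engine")
}

#' Assemble a speciation result from externally computed activities
#'
#' Adapter for activities computed outside the package (for example with a
#' humic speciation code): the resulting object passes through the
#' normalization pipeline identically to internally computed ones.
#'
#' @param dissolved_ni dissolved Ni, ug/L.
#' @param activity_ni2 free Ni2+ activity, mol/L.
#' @param activity_ca2,activity_mg2 free Ca2+ and Mg2+ activities, mol/L.
#' @param ionic_strength ionic strength, mol/L (may be `NA`).
#' @param species_table optional named vector of species concentrations, mol/L.
#' @param engine_id provenance tag.
#' @param ph optional pH carried for downstream model evaluation.
#' @return An object of class `speciation_result`.
#' @export
speciation_result <- function(dissolved_ni, activity_ni2, activity_ca2,
                              activity_mg2, ionic_strength = NA_real_,
                              species_table = NULL, engine_id = "external",
                              ph = NA_real_) {
  if (any(c(activity_ni2, activity_ca2, activity_mg2) < 0))
    stop("activities must be >= 0")
  if (activity_ni2 > dissolved_ni * 1e-6 / .MW_NI * (1 + 1e-9))
    stop("free Ni2+ activity exceeds total dissolved Ni")
  structure(list(dissolved_ni = dissolved_ni, activity_ni2 = activity_ni2,
                 activity_ca2 = activity_ca2, activity_mg2 = activity_mg2,
                 ionic_strength = ionic_strength,
                 species_table = species_table, engine_id = engine_id,
                 ph = ph),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("Speciation result [%s]\n", x$engine_id))
  cat(sprintf("  dissolved Ni %.4g ug/L -> free Ni2+ activity %.4g mol/L\n",
              x$dissolved_ni, x$activity_ni2))
  cat(sprintf("  Ca2+ %.4g, Mg2+ %.4g mol/L; I = %.4g mol/L\n",
              x$activity_ca2, x$activity_mg2, x$ionic_strength))
  invisible(x)
}

#' Speciate dissolved nickel in a water
#'
#' Solves the inorganic chemical equilibrium of a water sample at a stated
#' dissolved Ni concentration: Ni2+ with OH-, CO32-, HCO3-, SO42- and Cl-,
#' plus the Ca and Mg carbonate/bicarbonate/sulfate ion pairs, with Davies
#' activity corrections and (for DOC > 0) a saturable single-site organic
#' binding term. Mass balances are solved by a damped multiplicative update
#' (Newton-type in log space for the 1:1 complex stoichiometry used here) to
#' a relative residual of 1e-12; the ionic strength is iterated to
#' self-consistency in an outer loop. `DOC = 0` bypasses organic binding.
#'
#' @param water a [water_sample()].
#' @param dissolved_ni dissolved Ni concentration, ug/L (>= 0).
#' @param engine a [speciation_engine()].
#' @return A `speciation_result` with free-ion activities (mol/L), ionic
#'   strength and the full species table (concentrations, mol/L).
#' @examples
#' w <- water_sample(ph = 7.5, doc = 0, hardness = 100, alkalinity = 1e-3)
#' speciate(w, 100)
#' @export
speciate <- function(water, dissolved_ni, engine = speciation_engine()) {
  stopifnot(inherits(water, "water_sample"))
  if (!is.numeric(dissolved_ni) || length(dissolved_ni) != 1L || dissolved_ni < 0)
    stop("dissolved_ni must be a single number >= 0")

  totals <- c(Ni = dissolved_ni * 1e-6 / .MW_NI,
              Ca = water$ca, Mg = water$mg,
              CO3 = .water_dic(water), SO4 = water$so4)
  t_cl <- water$cl
  ah <- 10^(-water$ph)
  sc <- engine$constants$reactions
  kw <- 10^(-sc$H2O$logk)
  aoh <- kw / ah
  k <- vapply(sc, function(r) 10^r$logk, numeric(1))
  sites <- water$doc * engine$doc_sites_mol_per_mg
  # conditional fulvic-site constant with proton competition
  kfa <- 10^engine$logk_nifa / (1 + ah / 10^(-engine$pka_h))

  # initial ionic strength from totals (HCO3 approximated by alkalinity)
  i_now <- 0.5 * (4 * (water$ca + water$mg + water$so4) + water$na + water$k +
                  t_cl + (water$alkalinity %||% 0) + ah + aoh)
  free <- totals
  # start carbonate at its inorganic alpha fraction
  if (totals[["CO3"]] > 0) {
    r2 <- 10^(-sc$HCO3$logk) / ah
    free[["CO3"]] <- totals[["CO3"]] * r2 / (1 + r2 + ah * r2 * 10^(sc$`H2CO3*`$logk - sc$HCO3$logk))
  }
  active <- names(totals)[totals > 0]

  sol <- NULL
  for (outer in 1:30) {
    g1 <- davies_gamma(1, i_now, water$temp)
    g2 <- davies_gamma(2, i_now, water$temp)
    acl <- g1 * t_cl

    calc <- function(fr) {
      a_ni <- g2 * fr[["Ni"]]; a_ca <- g2 * fr[["Ca"]]; a_mg <- g2 * fr[["Mg"]]
      a_co3 <- g2 * fr[["CO3"]]; a_so4 <- g2 * fr[["SO4"]]
      a_hco3 <- k[["HCO3"]] * ah * a_co3
      sp <- c(
        Ni2   = fr[["Ni"]], Ca2 = fr[["Ca"]], Mg2 = fr[["Mg"]],
        CO3   = fr[["CO3"]], SO4 = fr[["SO4"]], Cl = t_cl,
        HCO3  = a_hco3 / g1,
        H2CO3 = k[["H2CO3*"]] * ah^2 * a_co3,
        NiOH  = k[["NiOH"]] * a_ni * aoh / g1,
        NiCO3 = k[["NiCO3"]] * a_ni * a_co3,
        NiHCO3 = k[["NiHCO3"]] * a_ni * ah * a_co3 / g1,
        NiSO4 = k[["NiSO4"]] * a_ni * a_so4,
        NiCl  = k[["NiCl"]] * a_ni * acl / g1,
        NiFA  = if (sites > 0) sites * kfa * a_ni / (1 + kfa * a_ni) else 0,
        CaHCO3 = k[["CaHCO3"]] * a_ca * ah * a_co3 / g1,
        CaCO3 = k[["CaCO3"]] * a_ca * a_co3,
        CaSO4 = k[["CaSO4"]] * a_ca * a_so4,
        MgHCO3 = k[["MgHCO3"]] * a_mg * ah * a_co3 / g1,
        MgCO3 = k[["MgCO3"]] * a_mg * a_co3,
        MgSO4 = k[["MgSO4"]] * a_mg * a_so4)
      tot <- c(
        Ni = sp[["Ni2"]] + sp[["NiOH"]] + sp[["NiCO3"]] + sp[["NiHCO3"]] +
             sp[["NiSO4"]] + sp[["NiCl"]] + sp[["NiFA"]],
        Ca = sp[["Ca2"]] + sp[["CaHCO3"]] + sp[["CaCO3"]] + sp[["CaSO4"]],
        Mg = sp[["Mg2"]] + sp[["MgHCO3"]] + sp[["MgCO3"]] + sp[["MgSO4"]],
        CO3 = sp[["CO3"]] + sp[["HCO3"]] + sp[["H2CO3"]] + sp[["NiCO3"]] +
              sp[["NiHCO3"]] + sp[["CaHCO3"]] + sp[["CaCO3"]] +
              sp[["MgHCO3"]] + sp[["MgCO3"]],
        SO4 = sp[["SO4"]] + sp[["NiSO4"]] + sp[["CaSO4"]] + sp[["MgSO4"]])
      list(species = sp, totals = tot)
    }

    converged <- FALSE
    for (iter in 1:1000) {
      cc <- calc(free)
      if (length(active) == 0L) { converged <- TRUE; break }
      ratio <- totals[active] / cc$totals[active]
      if (all(abs(ratio - 1) < 1e-12)) { converged <- TRUE; break }
      # damped multiplicative mass-balance update
      free[active] <- free[active] * pmin(pmax(ratio, 0.1), 10)
    }
    if (!converged)
      stop("speciation solver failed to converge; residuals: ",
           paste(sprintf("%s=%.2e", active, totals[active] / cc$totals[active] - 1),
                 collapse = ", "))

    # self-consistent ionic strength from the converged species table
    sp <- cc$species
    z2 <- c(Ni2 = 4, Ca2 = 4, Mg2 = 4, CO3 = 4, SO4 = 4, Cl = 1, HCO3 = 1,
            H2CO3 = 0, NiOH = 1, NiCO3 = 0, NiHCO3 = 1, NiSO4 = 0, NiCl = 1,
            NiFA = 0, CaHCO3 = 1, CaCO3 = 0, CaSO4 = 0, MgHCO3 = 1,
            MgCO3 = 0, MgSO4 = 0)
    i_new <- 0.5 * (sum(sp * z2[names(sp)]) + water$na + water$k + ah + aoh)
    sol <- list(species = sp, g2 = g2, i = i_new)
    if (abs(i_new - i_now) < 1e-8 + 1e-6 * i_now) break
    i_now <- i_new
  }

  structure(list(dissolved_ni = dissolved_ni,
                 activity_ni2 = sol$g2 * free[["Ni"]],
                 activity_ca2 = sol$g2 * free[["Ca"]],
                 activity_mg2 = sol$g2 * free[["Mg"]],
                 ionic_strength = sol$i,
                 species_table = sol$species,
                 engine_id = engine$engine_id,
                 ph = water$ph),
            class = "speciation_result")
}

#' Dissolved nickel required to reach a target free-ion activity
#'
#' Inverse of [speciate()]: finds the dissolved Ni concentration (ug/L) whose
#' speciation in `water` gives the requested free Ni2+ activity, by a
#' monotone fixed-point iteration on the dissolved concentration (the free
#' activity is strictly increasing in dissolved Ni).
#'
#' @param water a [water_sample()].
#' @param target_activity_ni2 target free Ni2+ activity, mol/L (>= 0).
#' @param engine a [speciation_engine()].
#' @param tol relative convergence tolerance on the achieved activity.
#' @return Dissolved Ni in ug/L.
#' @export
dissolved_from_activity <- function(water, target_activity_ni2,
                                    engine = speciation_engine(),
                                    tol = 1e-9) {
  if (!is.numeric(target_activity_ni2) || target_activity_ni2 < 0)
    stop("target activity must be >= 0")
  if (target_activity_ni2 == 0) return(0)
  # free <= total, so the molar-equivalent dissolved level is a lower bound
  d <- target_activity_ni2 * .MW_NI * 1e6
  for (iter in 1:100) {
    a <- speciate(water, d, engine)$activity_ni2
    ratio <- target_activity_ni2 / a
    if (abs(ratio - 1) < tol) return(d)
    d <- d * min(max(ratio, 0.05), 20)
  }
  stop("dissolved_from_activity failed to converge (last relative error ",
       format(ratio - 1), ")")
}

#' Read externally computed activities from CSV
#'
#' Reads the activity-import dialect with columns `water_id`,
#' `dissolved_ni_ug_l`, `activity_ni2`, `activity_ca2`, `activity_mg2` and
#' returns one [speciation_result()] per row (engine id `"external"`).
#'
#' @param file path to a CSV file.
#' @return A list of `speciation_result` objects named by `water_id`.
#' @export
read_activities <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("water_id", "dissolved_ni_ug_l", "activity_ni2",
            "activity_ca2", "activity_mg2")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("activity CSV lacks columns: ",
                            paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    speciation_result(df$dissolved_ni_ug_l[i], df$activity_ni2[i],
                      df$activity_ca2[i], df$activity_mg2[i],
                      ph = if ("ph" %in% names(df)) df$ph[i] else NA_real_))
  names(out) <- as.character(df$water_id)
  out
}
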