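.default_taxa_mix <- c(cladoceran = 0.25, algae = 0.20, mollusc = 0.125,
                       fish = 0.10, insect = 0.075, amphipod = 0.075,
                       annelid = 0.05, anostraca = 0.05, amphibian = 0.05,
                       plant = 0.025)

.taxon_defaults <- list(
  algae = list(duration = 72, endpoint = "growth_rate"),
  plant = list(duration = 96, endpoint = "frond_count"),
  cladoceran = list(duration = 48, endpoint = "immobilization"),
  amphipod = list(duration = 96, endpoint = "mortality"),
  annelid = list(duration = 96, endpoint = "mortality"),
  insect = list(duration = 96, endpoint = "mortality"),
  ostracod = list(duration = 96, endpoint = "mortality"),
  mollusc = list(duration = 96, endpoint = "mortality"),
  anostraca = list(duration = 24, endpoint = "mortality"),
  fish = list(duration = 96, endpoint = "mortality"),
  amphibian = list(duration = 96, endpoint = "mortality"),
  other_invertebrate = list(duration = 96, endpoint = "mortality"))

# minor-ion recipe for synthetic waters (reconstituted-water-style defaults,
# mol/L); alkalinity scales with hardness as in typical calcareous media
.synthetic_minor_ions <- function(hardness) {
  list(na = 5e-4, k = 5e-5, so4 = 2.5e-4, cl = 5e-4,
       alkalinity = 0.8 * 2 * hardness / (.MW_CACO3 * 1000))
}

#' Generate a synthetic acute toxicity database with known ground truth
#'
#' Emulates the structure of a multi-species acute Ni ecotoxicity database:
#' per-species intrinsic sensitivities drawn from a normal Q50 distribution,
#' heterogeneous test-water chemistry per record, exact dissolved L(E)C50s
#' computed through the forward bioavailability chain (gBAM Direction 2 plus
#' speciation), and multiplicative log-normal replicate noise. The default
#' noise sd, `log10(2)/qnorm(0.95)`, makes the 95 % replicate range a factor
#' of two — the random variability expected of repeated acute tests. A truth
#' table (species, model, true Q50) accompanies the records, so every
#' pipeline stage can be checked against known parameters.
#'
#' @param n_species number of species.
#' @param records_per_species records generated per species.
#' @param q50_mean,q50_sd mean and sd of the species Q50 distribution.
#' @param noise_sd replicate noise sd on the log10 scale (0 for noise-free).
#' @param ph_range,hardness_range,doc_range chemistry sampler ranges (must
#'   lie within the combined applicability window).
#' @param taxa_mix named vector of taxon-group proportions.
#' @param seed integer seed (mandatory; generation is deterministic per
#'   seed).
#' @return List with `records` (a [tox_records()] table), `truth`
#'   (species-level ground truth) and the generator settings.
#' @export
synthetic_toxdb <- function(n_species = 40, records_per_species = 3,
                            q50_mean = 5.5, q50_sd = 0.7,
                            noise_sd = log10(2) / qnorm(0.95),
                            ph_range = c(5.7, 8.7),
                            hardness_range = c(12, 290),
                            doc_range = c(0, 20),
                            taxa_mix = .default_taxa_mix,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  comb <- combined_applicability(
    gbam_models()[c("avg_invertebrate", "algae", "fish")])
  if (ph_range[1] < comb$ph[1] || ph_range[2] > comb$ph[2])
    stop("ph_range outside the combined applicability window")
  if (hardness_range[1] < comb$hardness[1] ||
      hardness_range[2] > comb$hardness[2])
    stop("hardness_range outside the combined applicability window")
  if (doc_range[1] < 0) stop("doc_range must be non-negative")

  taxa_mix <- taxa_mix / sum(taxa_mix)
  counts <- diff(c(0, round(cumsum(taxa_mix) * n_species)))
  taxa <- rep(names(taxa_mix), counts)

  models <- gbam_models()
  engine <- speciation_engine()

  with_seed(seed, {
    q50 <- rnorm(n_species, q50_mean, q50_sd)
    species <- sprintf("Synthetic species %02d", seq_len(n_species))
    truth <- data.frame(species = species, taxon_group = taxa,
                        model_id = assign_model(taxa), q50_true = q50,
                        stringsAsFactors = FALSE)
    rows <- vector("list", n_species * records_per_species)
    rid <- 0L
    for (s in seq_len(n_species)) {
      m <- models[[truth$model_id[s]]]
      td <- .taxon_defaults[[taxa[s]]]
      for (r in seq_len(records_per_species)) {
        rid <- rid + 1L
        ph <- runif(1, ph_range[1], ph_range[2])
        hardness <- runif(1, hardness_range[1], hardness_range[2])
        doc <- runif(1, doc_range[1], doc_range[2])
        ions <- .synthetic_minor_ions(hardness)
        w <- water_sample(ph = ph, doc = doc, hardness = hardness,
                          na = ions$na, k = ions$k, so4 = ions$so4,
                          cl = ions$cl, alkalinity = ions$alkalinity)
        dissolved <- predict_lc50_dissolved(m, q50[s], w, engine)$dissolved
        observed <- dissolved * 10^rnorm(1, 0, noise_sd)
        rows[[rid]] <- data.frame(
          record_id = rid, species = species[s], taxon_group = taxa[s],
          endpoint = td$endpoint, duration_h = td$duration,
          lc50_ug_l = observed, basis = "dissolved", medium = "natural",
          reliable = TRUE, life_stage = NA_character_,
          source = "synthetic generator",
          ph = ph, doc_mg_l = doc, ca_mol_l = w$ca, mg_mol_l = w$mg,
          na_mol_l = w$na, k_mol_l = w$k, so4_mol_l = w$so4,
          cl_mol_l = w$cl, alkalinity_eq_l = ions$alkalinity,
          dic_mol_l = NA_real_, hardness_mg_caco3_l = hardness,
          temp_c = 20, stringsAsFactors = FALSE)
      }
    }
    records <- tox_records(do.call(rbind, rows))
    list(records = records, truth = truth,
         settings = list(n_species = n_species,
                         records_per_species = records_per_species,
                         q50_mean = q50_mean, q50_sd = q50_sd,
                         noise_sd = noise_sd, ph_range = ph_range,
                         hardness_range = hardness_range,
                         doc_range = doc_range, seed = seed))
  })
}

#' European ecoregion target waters
#'
#' The seven named European freshwater scenarios used as regulatory target
#' waters, with their pH, DOC and hardness; hardness is split into Ca and Mg
#' on the 3:1 molar basis and minor ions follow the documented
#' reconstituted-water-style defaults.
#'
#' @param as_waters if `TRUE` (default) return a named list of
#'   [water_sample()] objects; otherwise a data.frame in the water CSV
#'   dialect.
#' @return Seven target waters.
#' @examples
#' ecoregion_waters(as_waters = FALSE)[, 1:4]
#' @export
ecoregion_waters <- function(as_waters = TRUE) {
  df <- data.frame(
    water_id = c("Lake Monate (Italy)", "Rhine (Netherlands)",
                 "Otter (United Kingdom)", "Teme (United Kingdom)",
                 "Swedish Lake (Sweden)", "Ebro (Spain)",
                 "Ditches (Netherlands)"),
    ph = c(7.7, 7.8, 8.1, 7.6, 6.7, 8.2, 6.9),
    doc_mg_l = c(2.5, 2.8, 3.2, 8.0, 3.8, 3.7, 12.0),
    hardness_mg_caco3_l = c(48, 217, 165, 160, 28, 273, 260),
    stringsAsFactors = FALSE)
  ions <- lapply(df$hardness_mg_caco3_l, .synthetic_minor_ions)
  df$na_mol_l <- vapply(ions, `[[`, 0, "na")
  df$k_mol_l <- vapply(ions, `[[`, 0, "k")
  df$so4_mol_l <- vapply(ions, `[[`, 0, "so4")
  df$cl_mol_l <- vapply(ions, `[[`, 0, "cl")
  df$alkalinity_eq_l <- vapply(ions, `[[`, 0, "alkalinity")
  sp <- lapply(df$hardness_mg_caco3_l, split_hardness)
  df$ca_mol_l <- vapply(sp, `[[`, 0, "ca")
  df$mg_mol_l <- vapply(sp, `[[`, 0, "mg")
  if (!as_waters) return(df)
  out <- lapply(seq_len(nrow(df)), function(i) water_from_row(df[i, ]))
  names(out) <- df$water_id
  out
}
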