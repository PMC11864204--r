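# shared fixtures: built in code, no stored data

std_water <- function(ph = 7.5, doc = 0, hardness = 100, alkalinity = 1e-3,
                      ...) {
  water_sample(ph = ph, doc = doc, hardness = hardness,
               alkalinity = alkalinity, ...)
}

# minimal one-row record; override any field
make_record <- function(species = "Daphnia magna", taxon_group = "cladoceran",
                        endpoint = "immobilization", duration_h = 48,
                        lc50_ug_l = 1000, basis = "dissolved",
                        medium = "artificial", reliable = TRUE,
                        ph = 7.5, doc_mg_l = 0, hardness_mg_caco3_l = 100,
                        alkalinity_eq_l = 1e-3, ...) {
  data.frame(species = species, taxon_group = taxon_group,
             endpoint = endpoint, duration_h = duration_h,
             lc50_ug_l = lc50_ug_l, basis = basis, medium = medium,
             reliable = reliable, ph = ph, doc_mg_l = doc_mg_l,
             hardness_mg_caco3_l = hardness_mg_caco3_l,
             alkalinity_eq_l = alkalinity_eq_l, ...,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- lapply(list(...), function(r) do.call(make_record, r))
  cols <- Reduce(union, lapply(rows, names))
  out <- do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[cols]
  }))
  out$record_id <- seq_len(nrow(out))
  out
}

# random but valid water within the combined applicability window
random_water <- function() {
  water_sample(ph = runif(1, 5.7, 8.7),
               doc = runif(1, 0, 15),
               hardness = runif(1, 12, 290),
               alkalinity = runif(1, 1e-4, 3e-3),
               na = 5e-4, cl = 5e-4, so4 = 2.5e-4)
}
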