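test_that("hardness splits into Ca and Mg at a 3:1 molar ratio", {
  expect_equal(split_hardness(0), c(ca = 0, mg = 0))
  sp <- split_hardness(100)
  # 100 mg CaCO3/L = 100/100.087 mmol/L total, split 3:1
  expect_equal(sp[["ca"]], 7.4935e-4, tolerance = 1e-4)
  expect_equal(sp[["mg"]], 2.4978e-4, tolerance = 1e-4)
  expect_equal(split_hardness(290)[["ca"]] / split_hardness(290)[["mg"]], 3)
  expect_equal(hardness_from_ions(sp[["ca"]], sp[["mg"]]), 100)
  expect_error(split_hardness(-1), "hardness")
})

test_that("water_sample validates and derives its chemistry", {
  w <- water_sample(ph = 7.5, hardness = 100)
  expect_equal(w$ca / w$mg, 3)
  expect_error(water_sample(ph = 15, hardness = 100), "pH")
  expect_error(water_sample(ph = 7, ca = -1, mg = 1e-4), ">= 0")
  # stored hardness must agree with ions within 5 %
  expect_error(water_sample(ph = 7, ca = 1e-3, mg = 1e-4, hardness = 200),
               "disagrees")
  expect_silent(water_sample(ph = 7, ca = 7.5e-4, mg = 2.5e-4,
                             hardness = 100))
  # Mg derived as hardness remainder when only Ca is given
  w2 <- water_sample(ph = 7, ca = 6e-4, hardness = 100)
  expect_equal(w2$mg, 100 / (100.087 * 1000) - 6e-4)
})

test_that("DIC from pH and alkalinity follows open-system carbonate algebra", {
  # no carbonate alkalinity at neutral pH: atmospheric CO2 only
  sc <- stability_constants()
  co2aq <- 10^sc$co2$log_kh * sc$co2$pco2_atm
  expect_equal(dic_from_alkalinity(7, 0), co2aq, tolerance = 1e-6)

  # independent oracle: root-find the bicarbonate concentration that
  # reproduces the carbonate alkalinity, then assemble DIC
  ph <- 8.3; alk <- 2e-3
  k2 <- 10^(-sc$reactions$HCO3$logk)
  kw <- 10^(-sc$reactions$H2O$logk)
  h <- 10^(-ph)
  ca_alk <- alk + h - kw / h
  hco3 <- uniroot(function(x) x + 2 * (k2 / h) * x - ca_alk,
                  c(0, alk), tol = 1e-15)$root
  dic_oracle <- co2aq + hco3 + (k2 / h) * hco3
  expect_equal(dic_from_alkalinity(ph, alk), dic_oracle, tolerance = 1e-9)

  # strictly increasing in alkalinity at fixed pH
  alks <- seq(0, 5e-3, length.out = 20)
  dics <- vapply(alks, function(a) dic_from_alkalinity(7.8, a), numeric(1))
  expect_true(all(diff(dics) > 0))
  expect_error(dic_from_alkalinity(1.5, 1e-3), "pH")
})

test_that("Davies activity coefficients match the closed form", {
  expect_equal(davies_gamma(2, 0), 1)
  expect_equal(davies_gamma(0, 0.5), 1)
  # direct evaluation of the Davies formula at I = 0.01, z = 2
  i <- 0.01
  expected <- 10^(-0.509 * 4 * (sqrt(i) / (1 + sqrt(i)) - 0.3 * i))
  expect_equal(davies_gamma(2, i), expected)
  expect_equal(davies_gamma(1, i), expected^(1 / 4), tolerance = 1e-12)
  expect_error(davies_gamma(2, -1), "ionic strength")
})

test_that("speciation conserves mass and behaves in the dilute limit", {
  # ideal dilute limit: no ligands, no DOC -> activity equals dissolved
  w0 <- water_sample(ph = 7, doc = 0, ca = 1e-9, mg = 1e-9, dic = 0)
  s0 <- speciate(w0, 100)
  expect_equal(s0$activity_ni2, 100e-6 / 58.6934, tolerance = 1e-4)

  # mass balance within 0.1 % for a hard, carbonate-rich, DOC-bearing water
  w <- std_water(ph = 8.3, doc = 10, hardness = 250, alkalinity = 2.5e-3,
                 so4 = 5e-4, cl = 1e-3, na = 1e-3)
  s <- speciate(w, 500)
  ni_species <- c("Ni2", "NiOH", "NiCO3", "NiHCO3", "NiSO4", "NiCl", "NiFA")
  expect_equal(sum(s$species_table[ni_species]),
               500e-6 / 58.6934, tolerance = 1e-3)
  expect_true(s$activity_ni2 <= 500e-6 / 58.6934)
  expect_true(all(unlist(s$species_table) >= 0))

  # trace-level linearity: doubling dissolved Ni doubles the free activity
  a1 <- speciate(w, 0.5)$activity_ni2
  a2 <- speciate(w, 1.0)$activity_ni2
  expect_equal(a2 / a1, 2, tolerance = 1e-3)

  # deterministic: same inputs, same outputs
  expect_identical(speciate(w, 500)$species_table, s$species_table)
})

test_that("free Ni fraction decreases with DOC", {
  docs <- c(0, 1, 2, 5, 10, 20)
  frac <- vapply(docs, function(d) {
    w <- std_water(ph = 7.5, doc = d)
    speciate(w, 50)$activity_ni2
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("dissolved_from_activity inverts speciate", {
  expect_equal(dissolved_from_activity(std_water(), 0), 0)
  set.seed(101)
  for (rep in 1:10) {
    w <- random_water()
    d <- 10^runif(1, 0, 4)
    a <- speciate(w, d)$activity_ni2
    expect_equal(dissolved_from_activity(w, a), d, tolerance = 1e-6)
  }
  # DOC raises the dissolved Ni needed for a given free activity
  target <- 1e-6
  d0 <- dissolved_from_activity(std_water(doc = 0), target)
  d5 <- dissolved_from_activity(std_water(doc = 5), target)
  expect_gt(d5, d0)
})

test_that("externally supplied activities pass through the adapter", {
  ext <- speciation_result(dissolved_ni = 100, activity_ni2 = 8e-7,
                           activity_ca2 = 5e-4, activity_mg2 = 2e-4,
                           ph = 7.5)
  expect_s3_class(ext, "speciation_result")
  expect_identical(ext$engine_id, "external")
  # usable in the gBAM exactly like an internal result
  m <- gbam_model("avg_invertebrate")
  q <- q50_from_observation(m, ext$activity_ni2, ext$ph,
                            activity_ca2 = ext$activity_ca2,
                            activity_mg2 = ext$activity_mg2)
  expect_true(is.finite(q))
  # invariant: free cannot exceed total
  expect_error(speciation_result(1, 1e-3, 0, 0), "exceeds")

  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(water_id = "w1", dissolved_ni_ug_l = 100,
                       activity_ni2 = 8e-7, activity_ca2 = 5e-4,
                       activity_mg2 = 2e-4, ph = 7.5), tmp,
            row.names = FALSE)
  imp <- read_activities(tmp)
  expect_equal(imp[["w1"]]$activity_ni2, 8e-7)
})

test_that("water CSV dialect round-trips", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(water_id = c("a", "b"), ph = c(7.2, 8.1),
                       doc_mg_l = c(2, 0), hardness_mg_caco3_l = c(50, 250),
                       alkalinity_eq_l = c(1e-3, 2e-3)), tmp,
            row.names = FALSE)
  ws <- read_waters(tmp)
  expect_length(ws, 2)
  expect_equal(ws[["b"]]$ph, 8.1)
  expect_equal(ws[["a"]]$ca / ws[["a"]]$mg, 3)
})
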