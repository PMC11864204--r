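test_that("gumbel functions are mutually consistent", {
  p <- c(0.05, 0.5, 0.95)
  expect_equal(pgumbel(qgumbel(p, 2, 0.5), 2, 0.5), p)
  # density integrates the CDF
  expect_equal(integrate(dgumbel, -10, 3, loc = 1, scale = 0.4)$value,
               pgumbel(3, 1, 0.4), tolerance = 1e-6)
})

test_that("species aggregation picks the most sensitive endpoint group", {
  # two endpoints for one species: the higher mean Q50 (lower LC50) wins
  base <- list(species = "Hyalella azteca", taxon_group = "amphipod",
               endpoint = "mortality", duration_h = 96)
  db <- make_records(
    modifyList(base, list(lc50_ug_l = 1000)),
    modifyList(base, list(lc50_ug_l = 1200)),
    modifyList(base, list(endpoint = "immobilization", lc50_ug_l = 300)),
    modifyList(base, list(endpoint = "immobilization", lc50_ug_l = 400)))
  db <- screen_records(db)
  agg <- aggregate_species(db)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$endpoint, "immobilization")
  q <- record_q50(db)
  expect_equal(agg$mean_q50, mean(q[3:4]))
  expect_equal(agg$n_records, 2)

  # multiple durations resolve toward the most sensitive (highest Q50)
  db2 <- make_records(
    modifyList(base, list(lc50_ug_l = 1000, duration_h = 96)),
    modifyList(base, list(lc50_ug_l = 200, duration_h = 168)))
  agg2 <- aggregate_species(screen_records(db2))
  expect_equal(agg2$duration_h, 168)

  # duplicate identical records: averaging is idempotent
  db3 <- screen_records(make_records(base, base))
  agg3 <- aggregate_species(db3)
  expect_equal(agg3$mean_q50, record_q50(db3)[1], tolerance = 1e-12)
})

test_that("normalization to the source water round-trips a single record", {
  sim <- synthetic_toxdb(n_species = 3, records_per_species = 1,
                         noise_sd = 0, seed = 31)
  db <- screen_records(sim$records)
  agg <- aggregate_species(db)
  # normalize back to each record's own test water
  for (i in seq_len(nrow(db))) {
    w <- water_sample(ph = db$ph[i], doc = db$doc_mg_l[i],
                      ca = db$ca_mol_l[i], mg = db$mg_mol_l[i],
                      na = db$na_mol_l[i], k = db$k_mol_l[i],
                      so4 = db$so4_mol_l[i], cl = db$cl_mol_l[i],
                      alkalinity = db$alkalinity_eq_l[i])
    norm <- normalize_to_water(agg[agg$species == db$species[i], ], w)
    expect_equal(norm$lc50_dissolved_ug_l, db$lc50_ug_l[i],
                 tolerance = 1e-6)
  }
})

test_that("normalization responds monotonically to DOC and warns out of range", {
  sim <- synthetic_toxdb(n_species = 4, records_per_species = 1,
                         noise_sd = 0, seed = 33)
  agg <- aggregate_species(screen_records(sim$records))
  waters <- lapply(c(0, 5, 15), function(d) std_water(doc = d))
  norms <- lapply(waters, function(w) normalize_to_water(agg, w))
  for (i in 2:3)
    expect_true(all(norms[[i]]$lc50_dissolved_ug_l >=
                    norms[[i - 1]]$lc50_dissolved_ug_l))
  # species order invariance
  rev_norm <- normalize_to_water(agg[rev(seq_len(nrow(agg))), ], waters[[1]])
  expect_equal(rev_norm$lc50_dissolved_ug_l,
               rev(norms[[1]]$lc50_dissolved_ug_l))
  # out-of-range target: warning-tagged result, not a failure
  expect_warning(out <- normalize_to_water(agg, water_sample(
    ph = 5.0, doc = 1, hardness = 100, alkalinity = 1e-4)),
    "applicability")
  expect_false(is.null(attr(out, "applicability_warning")))
})

test_that("a normal sample on the log scale is recognized among the six families", {
  set.seed(42)
  x <- 10^rnorm(5000, 2, 0.5)
  fit <- ssd_fit(x)
  expect_s3_class(fit, "ni_ssd")
  expect_equal(fit$best_family, "norm")
  # heavier-tailed mis-specified families score a larger AD statistic
  expect_lt(fit$fits$norm$ad, fit$fits$gumbel$ad)
  expect_lt(fit$fits$norm$ad, fit$fits$logis$ad)
  # all converged AD statistics are finite and positive
  for (f in fit$fits) if (isTRUE(f$ok)) expect_gt(f$ad, 0)
})

test_that("the AD statistic agrees with the fitdistrplus reference", {
  set.seed(43)
  y <- rnorm(200, 1.5, 0.4)
  for (fam in c("norm", "logis")) {
    ref_fit <- fitdistrplus::fitdist(y, fam)
    ref_ad <- fitdistrplus::gofstat(ref_fit)$ad
    fit <- ssd_fit(10^y, families = fam)
    expect_equal(unname(fit$fits[[fam]]$ad), unname(ref_ad),
                 tolerance = 1e-6)
  }
})

test_that("location-scale fits are equivariant under location shifts", {
  set.seed(44)
  x <- 10^rnorm(60, 2, 0.4)
  f1 <- ssd_fit(x)
  f2 <- ssd_fit(x * 10)  # +1 on the log10 scale
  for (fam in c("norm", "logis", "gumbel")) {
    expect_equal(unname(coef(f2, fam)[1]), unname(coef(f1, fam)[1]) + 1,
                 tolerance = 1e-4)
    expect_equal(unname(coef(f2, fam)[2]), unname(coef(f1, fam)[2]),
                 tolerance = 1e-4)
  }
  # AD statistics unchanged by the shift
  expect_equal(f1$fits$norm$ad, f2$fits$norm$ad, tolerance = 1e-6)
})

test_that("positivity-restricted families are marked inapplicable, not shifted", {
  set.seed(45)
  x <- 10^rnorm(20, 0.1, 0.5)   # some values below 1 ug/L
  stopifnot(any(log10(x) <= 0))
  fit <- ssd_fit(x)
  expect_false(isTRUE(fit$fits$gamma$ok))
  expect_match(fit$fits$gamma$error, "inapplicable")
  expect_true(isTRUE(fit$fits$norm$ok))
})

test_that("hazard concentrations follow the fitted quantiles", {
  # closed-form check: normal(mu = 2, sigma = 0.5) on the log10 scale
  fit <- structure(list(data = numeric(0), log10_data = numeric(0), n = 0,
                        fits = list(norm = list(family = "norm", ok = TRUE,
                                                estimate = c(mean = 2, sd = 0.5),
                                                ad = 1)),
                        best_family = "norm"), class = "ni_ssd")
  expect_equal(hc5(fit), 10^(2 - qnorm(0.95) * 0.5), tolerance = 1e-12)
  expect_equal(hc5(fit), 15.0499, tolerance = 1e-4)
  # degenerate limit: sd -> 0 gives 10^mu
  fit$fits$norm$estimate <- c(mean = 2, sd = 1e-12)
  expect_equal(hc5(fit), 100, tolerance = 1e-6)
  # HC5 below the median of the fitted distribution
  set.seed(46)
  f <- ssd_fit(10^rnorm(40, 2, 0.6))
  expect_lt(hc5(f), hc(f, 0.5))
})

test_that("bootstrap CIs are ordered, seeded and reproducible", {
  set.seed(47)
  x <- 10^rnorm(30, 2, 0.5)
  ci1 <- bootstrap_hc5(x, family = "norm", B = 200, seed = 1)
  ci2 <- bootstrap_hc5(x, family = "norm", B = 200, seed = 1)
  ci3 <- bootstrap_hc5(x, family = "norm", B = 200, seed = 2)
  expect_true(ci1$hc5_5 <= ci1$hc5_50 && ci1$hc5_50 <= ci1$hc5_95)
  expect_identical(ci1$hc5_50, ci2$hc5_50)
  expect_false(identical(ci1$hc5_50, ci3$hc5_50))
  expect_false(ci1$unreliable)
  expect_error(bootstrap_hc5(x, family = "norm", B = 50, seed = 1), "100")
  # parametric mode also works and is seeded
  cp <- bootstrap_hc5(ssd_fit(x, min_n = 10), B = 150, seed = 3,
                      method = "parametric")
  expect_true(cp$hc5_5 <= cp$hc5_50 && cp$hc5_50 <= cp$hc5_95)
  # gumbel path exercises the generic refit loop
  cg <- bootstrap_hc5(x, family = "gumbel", B = 120, seed = 4)
  expect_true(is.finite(cg$hc5_50))
})

test_that("ni_ssd methods expose the fitted model", {
  set.seed(48)
  fit <- ssd_fit(10^rnorm(25, 2, 0.4))
  expect_output(print(fit), "Best fit")
  s <- summary(fit)
  expect_true(all(c("family", "ad", "hc5", "best") %in% names(s)))
  expect_equal(sum(s$best), 1)
  expect_named(coef(fit, "norm"), c("mean", "sd"))
  # predict returns affected fractions, monotone in concentration
  pr <- predict(fit, c(10, 100, 1000))
  expect_true(all(diff(pr) > 0) && all(pr >= 0 & pr <= 1))
  sims <- simulate(fit, seed = 9)
  expect_length(sims, fit$n)
  expect_true(all(sims > 0))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, show_all = TRUE))
})

test_that("identical target waters give identical HC5 results", {
  sim <- synthetic_toxdb(n_species = 12, records_per_species = 1,
                         noise_sd = 0, seed = 51)
  db <- screen_records(sim$records)
  w <- std_water(ph = 7.8, doc = 3, hardness = 150, alkalinity = 2e-3)
  w2 <- std_water(ph = 7.8, doc = 3, hardness = 150, alkalinity = 2e-3)
  res <- derive_hc5(db, list(a = w, b = w2), B = 150, seed = 5)
  expect_equal(res[["a"]]$hc5_best, res[["b"]]$hc5_best)
  s <- summary(res)
  expect_equal(nrow(s), 2)
  expect_true(all(s$hc5_5 <= s$hc5_50 & s$hc5_50 <= s$hc5_95))
})
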