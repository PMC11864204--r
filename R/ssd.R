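#' The Gumbel distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Gumbel (maximum extreme value) distribution with location `loc`
#' and scale `scale`; supplied because base R lacks it and it is one of the
#' six candidate SSD families.
#'
#' @param x,q,p numeric vectors.
#' @param n number of draws.
#' @param loc location parameter.
#' @param scale scale parameter (> 0).
#' @return `dgumbel` the density, `pgumbel` the CDF, `qgumbel` quantiles,
#'   `rgumbel` random draws.
#' @export
dgumbel <- function(x, loc = 0, scale = 1) {
  z <- (x - loc) / scale
  exp(-(z + exp(-z))) / scale
}

#' @rdname dgumbel
#' @export
pgumbel <- function(q, loc = 0, scale = 1) exp(-exp(-(q - loc) / scale))

#' @rdname dgumbel
#' @export
qgumbel <- function(p, loc = 0, scale = 1) loc - scale * log(-log(p))

#' @rdname dgumbel
#' @export
rgumbel <- function(n, loc = 0, scale = 1) qgumbel(runif(n), loc, scale)

.ssd_families <- c("norm", "lnorm", "logis", "gamma", "weibull", "gumbel")
# deterministic tie-break preference when AD statistics coincide
.family_preference <- c("norm", "lnorm", "logis", "gamma", "weibull", "gumbel")

.fam_fun <- function(family, what) {
  get(paste0(what, family), mode = "function")
}

# closed-form or fitdistrplus MLE of one family on the log10 data
.fit_family <- function(y, family, start = NULL) {
  if (family == "norm") {
    n <- length(y)
    return(list(estimate = c(mean = mean(y),
                             sd = sqrt(sum((y - mean(y))^2) / n))))
  }
  if (family == "gumbel" && is.null(start)) {
    b <- sd(y) * sqrt(6) / pi
    start <- list(loc = mean(y) - 0.5772157 * b, scale = b)
  }
  fit <- if (is.null(start))
    fitdistrplus::fitdist(y, family, method = "mle", keepdata = FALSE)
  else
    fitdistrplus::fitdist(y, family, method = "mle", start = start,
                          keepdata = FALSE)
  list(estimate = fit$estimate)
}

#' Anderson-Darling statistic of a sample against a fitted CDF
#'
#' Standard A-squared formula on the probability-integral transform of the
#' (sorted) sample under the fitted distribution; parameters are estimated
#' from the same data, and the statistic is used for relative comparison
#' across candidate families, not for formal significance.
#'
#' @param y numeric sample.
#' @param cdf a function of one argument returning the fitted CDF.
#' @return The A-squared statistic (finite and positive for non-degenerate
#'   fits).
#' @export
ad_statistic <- function(y, cdf) {
  n <- length(y)
  u <- pmin(pmax(cdf(sort(y)), 1e-12), 1 - 1e-12)
  -n - mean((2 * seq_len(n) - 1) * (log(u) + log(1 - rev(u))))
}

#' Fit a species sensitivity distribution
#'
#' Fits the six candidate families (normal, log-normal, logistic, gamma,
#' Weibull, Gumbel) by maximum likelihood to the log10-transformed
#' normalized toxicity values and selects the best-fitting family by the
#' minimum Anderson-Darling statistic (ties broken by a fixed preference
#' order). Families requiring positive support (log-normal, gamma, Weibull
#' on the log10 values) are marked inapplicable when any log10 value is
#' <= 0 — values are never shifted, since shifting silently changes
#' quantiles. Non-converged fits are recorded as failed, not fatal.
#'
#' The returned object is the package's central fitted model; see
#' [hc()] for hazard concentrations, and the `print`, `summary`, `coef`,
#' `predict`, `plot` and `simulate` methods.
#'
#' @param x normalized toxicity values, ug dissolved Ni/L (one per species).
#' @param families candidate families (subset of the six).
#' @param min_n minimum number of species required (regulatory floor).
#' @return Object of class `ni_ssd`.
#' @examples
#' fit <- ssd_fit(10^rnorm(20, 2, 0.5), min_n = 10)
#' hc(fit)
#' @export
ssd_fit <- function(x, families = .ssd_families, min_n = 10) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("normalized toxicity values must be positive and finite")
  if (length(x) < min_n)
    stop("need at least ", min_n, " species (got ", length(x), ")")
  if (length(unique(x)) < 2) stop("need at least two distinct values")
  families <- match.arg(families, .ssd_families, several.ok = TRUE)
  y <- log10(x)

  fits <- list()
  for (fam in families) {
    if (fam %in% c("lnorm", "gamma", "weibull") && any(y <= 0)) {
      fits[[fam]] <- list(family = fam, ok = FALSE,
                          error = "inapplicable: log10 values <= 0")
      next
    }
    res <- tryCatch({
      f <- .fit_family(y, fam)
      p <- .fam_fun(fam, "p")
      ad <- ad_statistic(y, function(q) do.call(p, c(list(q), as.list(f$estimate))))
      list(family = fam, ok = TRUE, estimate = f$estimate, ad = ad)
    }, error = function(e) list(family = fam, ok = FALSE,
                                error = conditionMessage(e)))
    fits[[fam]] <- res
  }
  ok <- vapply(fits, function(f) isTRUE(f$ok) && is.finite(f$ad), logical(1))
  if (!any(ok)) stop("no candidate family could be fitted")
  ads <- vapply(fits[ok], function(f) f$ad, numeric(1))
  cand <- names(ads)[ads <= min(ads) + 1e-12]
  best <- .family_preference[.family_preference %in% cand][1]

  structure(list(data = x, log10_data = y, n = length(x), fits = fits,
                 best_family = best),
            class = "ni_ssd")
}

#' @export
print.ni_ssd <- function(x, ...) {
  cat(sprintf("Species sensitivity distribution: %d species\n", x$n))
  s <- summary(x)
  print(s, row.names = FALSE, digits = 4)
  cat(sprintf("Best fit: %s (min Anderson-Darling); HC5 = %.4g ug/L\n",
              x$best_family, hc(x)))
  invisible(x)
}

#' @export
summary.ni_ssd <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    data.frame(family = f$family,
               converged = isTRUE(f$ok),
               ad = if (isTRUE(f$ok)) f$ad else NA_real_,
               hc5 = if (isTRUE(f$ok))
                 10^do.call(.fam_fun(f$family, "q"),
                            c(list(0.05), as.list(f$estimate)))
               else NA_real_,
               note = if (isTRUE(f$ok)) "" else f$error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best <- out$family == object$best_family
  out[order(out$ad), ]
}

#' @export
coef.ni_ssd <- function(object, family = object$best_family, ...) {
  f <- object$fits[[family]]
  if (is.null(f) || !isTRUE(f$ok))
    stop("family '", family, "' was not successfully fitted")
  f$estimate
}

#' Fraction of species affected at given concentrations
#'
#' Evaluates the fitted SSD's CDF: the potentially affected fraction of
#' species at each dissolved Ni concentration.
#'
#' @param object a fitted `ni_ssd`.
#' @param newdata dissolved Ni concentrations, ug/L (defaults to the data).
#' @param family family to evaluate (defaults to the best fit).
#' @param ... unused.
#' @return Numeric vector of affected fractions in [0, 1].
#' @export
predict.ni_ssd <- function(object, newdata = object$data,
                           family = object$best_family, ...) {
  est <- coef(object, family)
  p <- .fam_fun(family, "p")
  do.call(p, c(list(log10(newdata)), as.list(est)))
}

#' @export
simulate.ni_ssd <- function(object, nsim = 1, seed = NULL,
                            family = object$best_family, ...) {
  est <- coef(object, family)
  r <- .fam_fun(family, "r")
  with_seed(seed, 10^do.call(r, c(list(nsim * object$n), as.list(est))))
}

#' @export
plot.ni_ssd <- function(x, family = x$best_family, show_all = FALSE, ...) {
  xs <- sort(x$data)
  emp <- (seq_along(xs) - 0.5) / length(xs)
  plot(xs, emp, log = "x", xlab = "normalized L(E)C50 (ug dissolved Ni/L)",
       ylab = "fraction of species affected", ylim = c(0, 1), pch = 19, ...)
  grid_x <- 10^seq(min(x$log10_data) - 0.5, max(x$log10_data) + 0.5,
                   length.out = 200)
  fams <- if (show_all) names(Filter(function(f) isTRUE(f$ok), x$fits))
          else family
  cols <- seq_along(fams) + 1
  for (i in seq_along(fams))
    lines(grid_x, predict(x, grid_x, family = fams[i]), col = cols[i])
  abline(h = 0.05, lty = 3)
  legend("topleft", legend = fams, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Hazard concentration from a fitted SSD
#'
#' The concentration affecting a fraction `p` of species: `10^` the p-th
#' quantile of the fitted distribution on the log10 scale. The default
#' p = 0.05 is the acute HC5.
#'
#' @param object a fitted `ni_ssd`.
#' @param p protection quantile (default 0.05).
#' @param family family to use (defaults to the best fit).
#' @return Hazard concentration, ug dissolved Ni/L.
#' @export
hc <- function(object, p = 0.05, family = object$best_family) {
  est <- coef(object, family)
  q <- .fam_fun(family, "q")
  10^do.call(q, c(list(p), as.list(est)))
}

#' @rdname hc
#' @export
hc5 <- function(object, family = object$best_family) hc(object, 0.05, family)

#' Bootstrap confidence interval on the HC5
#'
#' Resamples the n species values with replacement (default) or from the
#' fitted distribution (parametric mode), refits the selected family to each
#' resample (the family is held fixed across resamples) and reports the 5th,
#' 50th and 95th percentiles of the resampled HC5: the bootstrap median
#' HC5-50 is the reported point estimate and (HC5-5, HC5-95) the 90 %
#' confidence interval. Fully reproducible given `seed`; a result with more
#' than 20 % resample fit failures is flagged unreliable.
#'
#' @param x normalized toxicity values (ug/L), or a fitted `ni_ssd`.
#' @param family family to refit (defaults to the best fit for `ni_ssd`
#'   input).
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed (required for reproducibility).
#' @param method `"nonparametric"` (resample the data) or `"parametric"`
#'   (sample n values from the fitted distribution).
#' @param p protection quantile (default 0.05).
#' @return Object of class `hc5_ci`: list with `hc5_5`, `hc5_50`, `hc5_95`,
#'   `family`, `B`, `seed`, `method`, `n_fail`, `unreliable`.
#' @export
bootstrap_hc5 <- function(x, family = NULL, B = 1000, seed = NULL,
                          method = c("nonparametric", "parametric"),
                          p = 0.05) {
  method <- match.arg(method)
  if (B < 100) stop("B must be >= 100")
  if (inherits(x, "ni_ssd")) {
    family <- family %||% x$best_family
    start <- as.list(coef(x, family))
    y <- x$log10_data
  } else {
    if (is.null(family)) stop("family must be given for raw input")
    y <- log10(as.numeric(x))
    start <- NULL
  }
  n <- length(y)
  qf <- .fam_fun(family, "q")

  hc_vals <- with_seed(seed, {
    draw <- function() {
      if (method == "nonparametric") sample(y, n, replace = TRUE)
      else do.call(.fam_fun(family, "r"), c(list(n), start))
    }
    if (family == "norm" && method == "nonparametric") {
      # closed-form normal MLE, vectorized over resamples
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      ys <- matrix(y[idx], nrow = n)
      mu <- colMeans(ys)
      sdv <- sqrt(colMeans(ys^2) - mu^2)
      qnorm(p, mu, sdv)
    } else {
      vapply(seq_len(B), function(b) {
        yb <- draw()
        tryCatch({
          est <- .fit_family(yb, family, start = start)$estimate
          do.call(qf, c(list(p), as.list(est)))
        }, error = function(e) NA_real_)
      }, numeric(1))
    }
  })
  n_fail <- sum(!is.finite(hc_vals))
  qs <- quantile(hc_vals[is.finite(hc_vals)], c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(hc5_5 = 10^qs[1], hc5_50 = 10^qs[2], hc5_95 = 10^qs[3],
                 family = family, B = B, seed = seed, method = method, p = p,
                 n_fail = n_fail, unreliable = n_fail > 0.2 * B),
            class = "hc5_ci")
}

#' @export
print.hc5_ci <- function(x, ...) {
  cat(sprintf("HC5-50 = %.4g ug/L (90%% CI %.4g-%.4g), %s family, B = %d%s\n",
              x$hc5_50, x$hc5_5, x$hc5_95, x$family, x$B,
              if (x$unreliable) " [UNRELIABLE: >20% refit failures]" else ""))
  invisible(x)
}

#' Species-level aggregation of intrinsic sensitivities
#'
#' Collapses a screened, chemistry-complete record table to one intrinsic
#' sensitivity per species: record-level Q50s (Direction 1) are grouped by
#' endpoint and duration and averaged arithmetically; within a species, the
#' group with the highest mean Q50 — the most sensitive endpoint (for
#' multiple durations, the most sensitive duration, equivalent to the
#' lowest LC50) — is selected. Life stages are pooled. Species with no
#' retained records are omitted with a message.
#'
#' @param df a screened record table (only `retained` rows are used when
#'   the column is present).
#' @param engine a [speciation_engine()].
#' @return Data.frame with one row per species: `species`, `model_id`,
#'   `endpoint`, `duration_h`, `mean_q50`, `n_records`.
#' @export
aggregate_species <- function(df, engine = speciation_engine()) {
  all_species <- unique(df$species)
  if (!is.null(df$retained)) df <- df[df$retained, , drop = FALSE]
  dropped <- setdiff(all_species, unique(df$species))
  if (length(dropped))
    message("omitting species with no retained records: ",
            paste(dropped, collapse = ", "))
  if (!nrow(df)) stop("no retained records to aggregate")
  df$q50 <- record_q50(df, engine)
  df$model_id <- assign_model(df$taxon_group)
  key <- interaction(df$species, df$endpoint, df$duration_h, drop = TRUE)
  grp <- do.call(rbind, lapply(split(df, key), function(g)
    data.frame(species = g$species[1], model_id = g$model_id[1],
               endpoint = g$endpoint[1], duration_h = g$duration_h[1],
               mean_q50 = mean(g$q50), n_records = nrow(g),
               stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(split(grp, grp$species), function(g)
    g[which.max(g$mean_q50), , drop = FALSE]))
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

# self-consistent Direction-2 prediction of the dissolved LC50 in a water:
# the Ca2+/Mg2+ activities entering the gBAM are evaluated at the predicted
# dissolved Ni level itself (it contributes to ionic strength and ligand
# competition), so predict/speciate are iterated to a joint fixed point
predict_lc50_dissolved <- function(model, q50, water,
                                   engine = speciation_engine(),
                                   tol = 1e-9) {
  d <- 1  # ug/L; activities depend only weakly on the Ni level
  for (iter in 1:50) {
    s <- speciate(water, d, engine)
    free <- predict_lc50_free(model, q50, water$ph,
                              activity_ca2 = s$activity_ca2,
                              activity_mg2 = s$activity_mg2, override = TRUE)
    d_new <- dissolved_from_activity(water, free, engine)
    if (abs(d_new / d - 1) < tol) return(list(dissolved = d_new, free = free))
    d <- d_new
  }
  stop("Direction-2 prediction did not reach self-consistency")
}

#' Normalize species sensitivities to a target water (Direction 2)
#'
#' Predicts each species' free-ion L(E)C50 in the target water from its mean
#' intrinsic sensitivity (via its assigned bioavailability model and the
#' target's free Ca2+/Mg2+ activities), then translates the free-ion value
#' back to a dissolved Ni concentration with the speciation engine. Target
#' waters outside the combined applicability window of the model set yield a
#' warning-tagged result, not a failure.
#'
#' @param sensitivities output of [aggregate_species()].
#' @param water the target [water_sample()].
#' @param engine a [speciation_engine()].
#' @return Data.frame with `species`, `model_id`, `mean_q50`,
#'   `lc50_free_mol_l`, `lc50_dissolved_ug_l`; attribute
#'   `"applicability_warning"` is set when the target is out of range.
#' @export
normalize_to_water <- function(sensitivities, water,
                               engine = speciation_engine()) {
  models <- gbam_models()
  comb <- combined_applicability(models[c("avg_invertebrate", "algae", "fish")])
  warn <- NULL
  if (water$ph < comb$ph[1] || water$ph > comb$ph[2] ||
      water$hardness < comb$hardness[1] || water$hardness > comb$hardness[2]) {
    warn <- sprintf(
      "target water (pH %.2f, hardness %.3g) outside combined applicability (pH %.1f-%.1f, hardness %.0f-%.0f)",
      water$ph, water$hardness, comb$ph[1], comb$ph[2],
      comb$hardness[1], comb$hardness[2])
    warning(warn, call. = FALSE)
  }
  pred <- lapply(seq_len(nrow(sensitivities)), function(i)
    predict_lc50_dissolved(models[[sensitivities$model_id[i]]],
                           sensitivities$mean_q50[i], water, engine))
  free <- vapply(pred, `[[`, numeric(1), "free")
  dissolved <- vapply(pred, `[[`, numeric(1), "dissolved")
  out <- data.frame(species = sensitivities$species,
                    model_id = sensitivities$model_id,
                    mean_q50 = sensitivities$mean_q50,
                    lc50_free_mol_l = free,
                    lc50_dissolved_ug_l = dissolved,
                    stringsAsFactors = FALSE)
  attr(out, "applicability_warning") <- warn
  out
}

#' Site-specific acute HC5 derivation (full pipeline)
#'
#' Runs the whole normalization chain for one or more target waters:
#' screening (when not already done), species aggregation, Direction-2
#' normalization, SSD fitting with best-family selection, and the bootstrap
#' confidence interval on the HC5.
#'
#' @param records a toxicity record table.
#' @param waters a [water_sample()] or list of them.
#' @param B bootstrap resamples.
#' @param seed integer seed; target water i uses `seed + i - 1`.
#' @param engine a [speciation_engine()].
#' @param min_n minimum species count for SSD fitting.
#' @param bootstrap_method passed to [bootstrap_hc5()].
#' @return Object of class `hc5_result_set`: list of per-water results
#'   (`water_id`, `normalized`, `fit`, `best_family`, `hc5_best`, `hc5_5`,
#'   `hc5_50`, `hc5_95`, `B`, `seed`, `engine_id`, `warning`), with a
#'   `summary` data.frame attached.
#' @export
derive_hc5 <- function(records, waters, B = 1000, seed = 1,
                       engine = speciation_engine(), min_n = 10,
                       bootstrap_method = "nonparametric") {
  if (inherits(waters, "water_sample")) waters <- list(waters)
  if (is.null(records$retained)) records <- screen_records(records)
  sens <- aggregate_species(records, engine)
  results <- lapply(seq_along(waters), function(i) {
    w <- waters[[i]]
    wid <- w$id %||% names(waters)[i] %||% paste0("water_", i)
    norm <- withCallingHandlers(
      normalize_to_water(sens, w, engine),
      warning = function(cond) invokeRestart("muffleWarning"))
    fit <- ssd_fit(norm$lc50_dissolved_ug_l, min_n = min_n)
    ci <- bootstrap_hc5(fit, B = B, seed = seed + i - 1L,
                        method = bootstrap_method)
    list(water_id = wid, normalized = norm, fit = fit,
         best_family = fit$best_family, hc5_best = hc5(fit),
         hc5_5 = ci$hc5_5, hc5_50 = ci$hc5_50, hc5_95 = ci$hc5_95,
         B = B, seed = seed + i - 1L, engine_id = engine$engine_id,
         warning = attr(norm, "applicability_warning"))
  })
  names(results) <- vapply(results, `[[`, "", "water_id")
  summary_df <- do.call(rbind, lapply(results, function(r)
    data.frame(water_id = r$water_id, n_species = r$fit$n,
               best_family = r$best_family, hc5_best = r$hc5_best,
               hc5_50 = r$hc5_50, hc5_5 = r$hc5_5, hc5_95 = r$hc5_95,
               stringsAsFactors = FALSE)))
  rownames(summary_df) <- NULL
  structure(results, summary = summary_df, class = "hc5_result_set")
}

#' @export
print.hc5_result_set <- function(x, ...) {
  cat("Site-specific acute HC5 thresholds (ug dissolved Ni/L)\n")
  print(attr(x, "summary"), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.hc5_result_set <- function(object, ...) attr(object, "summary")
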