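#' Acute Ni bioavailability model parameter sets
#'
#' `gbam_models()` returns the shipped parameter sets (read from the package
#' configuration): the pH extended average invertebrate model, the pH
#' extended algae model, the fish model, and the three pre-existing
#' species-specific crustacean models. `gbam_model(id)` retrieves one of
#' them; `gbam_model()` with explicit arguments builds a custom model.
#'
#' Each model is the gBAM
#' `LC50(Ni2+) = 10^-(Q50 + pH term) * (1 + sum K_CatBL * a_Cat)`,
#' where the pH term accumulates the piecewise slopes `S_pH` over the pH
#' segments below the water's pH (which keeps the predicted free-ion LC50
#' continuous across segment boundaries) and the competition sum runs over
#' the cations the model parameterizes.
#'
#' @param id model identifier (one of `names(gbam_models())`), or a label for
#'   a custom model when the remaining arguments are given.
#' @param logk_cabl,logk_mgbl biotic-ligand stability constants, log10 L/mol
#'   (`NULL` for a cation the model does not parameterize; values must lie in
#'   `[0, 10]`).
#' @param ph_segments list (or matrix) of `(pH_lower, pH_upper, S_pH)`
#'   segments; segments must be contiguous, non-overlapping and have
#'   non-negative slopes.
#' @param applicability list with elements `ph` and `hardness`, each a
#'   `(lower, upper)` range.
#' @param label human-readable model name.
#' @return An object of class `gbam_model`.
#' @examples
#' m <- gbam_model("avg_invertebrate")
#' m$logk_cabl  # 3.80
#' @export
gbam_model <- function(id, logk_cabl = NULL, logk_mgbl = NULL,
                       ph_segments = NULL, applicability = NULL,
                       label = id) {
  if (is.null(ph_segments)) {
    models <- gbam_models()
    if (!id %in% names(models))
      stop("unknown model id '", id, "'; available: ",
           paste(names(models), collapse = ", "))
    return(models[[id]])
  }
  seg <- do.call(rbind, lapply(ph_segments, function(s) as.numeric(unlist(s))))
  colnames(seg) <- c("lower", "upper", "slope")
  if (any(seg[, "slope"] < 0)) stop("pH slopes must be >= 0")
  if (any(seg[, "upper"] <= seg[, "lower"])) stop("empty pH segment")
  if (nrow(seg) > 1 &&
      any(abs(seg[-1, "lower"] - seg[-nrow(seg), "upper"]) > 1e-9))
    stop("pH segments must be contiguous and non-overlapping")
  for (kk in c(logk_cabl, logk_mgbl))
    if (!is.null(kk) && (kk < 0 || kk > 10))
      stop("log K values must lie in [0, 10]")
  applicability <- applicability %||%
    list(ph = unname(c(seg[1, "lower"], seg[nrow(seg), "upper"])),
         hardness = c(0, Inf))
  if (diff(applicability$ph) <= 0 || diff(applicability$hardness) <= 0)
    stop("applicability ranges must be non-empty")
  structure(list(model_id = id, label = label, logk_cabl = logk_cabl,
                 logk_mgbl = logk_mgbl, ph_segments = seg,
                 applicability = applicability),
            class = "gbam_model")
}

#' @rdname gbam_model
#' @export
gbam_models <- function() {
  if (is.null(.nibam_env$gbam_models)) {
    cfg <- .cached_json("gbam_models.json")$models
    .nibam_env$gbam_models <- lapply(names(cfg), function(id) {
      m <- cfg[[id]]
      gbam_model(id,
                 logk_cabl = m$logk_cabl, logk_mgbl = m$logk_mgbl,
                 ph_segments = m$ph_segments,
                 applicability = list(
                   ph = as.numeric(unlist(m$applicability$ph)),
                   hardness = as.numeric(unlist(m$applicability$hardness))),
                 label = m$label)
    })
    names(.nibam_env$gbam_models) <- names(cfg)
  }
  .nibam_env$gbam_models
}

#' @export
print.gbam_model <- function(x, ...) {
  cat(sprintf("gBAM '%s' (%s)\n", x$model_id, x$label))
  cat(sprintf("  log K_CaBL = %s, log K_MgBL = %s (log L/mol)\n",
              x$logk_cabl %||% "-", x$logk_mgbl %||% "-"))
  for (i in seq_len(nrow(x$ph_segments)))
    cat(sprintf("  S_pH = %.4g over pH %.1f-%.1f\n",
                x$ph_segments[i, "slope"], x$ph_segments[i, "lower"],
                x$ph_segments[i, "upper"]))
  cat(sprintf("  applicability: pH %.1f-%.1f, hardness %.1f-%.0f mg CaCO3/L\n",
              x$applicability$ph[1], x$applicability$ph[2],
              x$applicability$hardness[1], x$applicability$hardness[2]))
  invisible(x)
}

#' Average biotic-ligand constants on the linear scale
#'
#' Combines log10 stability constants by averaging on the linear K scale
#' (arithmetic mean of `10^x`), the rule that produced the average
#' invertebrate model's constants from the three cladoceran models.
#'
#' @param logk_values numeric vector of log10 stability constants.
#' @return log10 of the arithmetic mean of the linear-scale constants.
#' @examples
#' round(average_constants(c(2.47, 3.60, 3.30)), 2)  # 3.32
#' round(average_constants(c(3.10, 4.20, 3.30)), 2)  # 3.80
#' @export
average_constants <- function(logk_values) {
  if (length(logk_values) == 0L || !is.numeric(logk_values))
    stop("logk_values must be a non-empty numeric vector")
  log10(mean(10^logk_values))
}

# cumulative pH contribution to the exponent (0 below the first segment)
.ph_term <- function(model, ph) {
  seg <- model$ph_segments
  sum(seg[, "slope"] * pmax(0, pmin(ph, seg[, "upper"]) - seg[, "lower"]))
}

.check_ph <- function(model, ph, override) {
  rng <- model$applicability$ph
  if (!override && (ph < rng[1] || ph > rng[2]))
    stop(sprintf("pH %.2f outside applicability range %.1f-%.1f of model '%s' (use override = TRUE to force)",
                 ph, rng[1], rng[2], model$model_id))
}

#' Effective toxicity exponent of a gBAM at a given pH
#'
#' Returns `Q50 + sum_seg S_pH,seg * overlap(segment, (-Inf, pH])`, the
#' exponent of the free-ion LC50 before cation competition. The piecewise
#' slopes accumulate from each segment's lower bound, so the exponent (and
#' hence the predicted LC50) is continuous in pH.
#'
#' @param model a [gbam_model()].
#' @param q50 intrinsic sensitivity (unitless, -log10 mol/L scale).
#' @param ph pH of the water.
#' @param override if `TRUE`, evaluate outside the model's pH applicability
#'   range instead of raising an error.
#' @return The effective exponent (unitless).
#' @examples
#' effective_exponent(gbam_model("avg_invertebrate"), 5, 8.5)  # 5 + 1.006 * 0.5
#' @export
effective_exponent <- function(model, q50, ph, override = FALSE) {
  stopifnot(inherits(model, "gbam_model"))
  .check_ph(model, ph, override)
  q50 + .ph_term(model, ph)
}

# competition factor 1 + sum K * activity over parameterized cations
.competition <- function(model, activity_ca2, activity_mg2) {
  f <- 1
  if (!is.null(model$logk_cabl)) {
    if (is.na(activity_ca2)) stop("model '", model$model_id,
                                  "' requires a Ca2+ activity")
    f <- f + 10^model$logk_cabl * activity_ca2
  }
  if (!is.null(model$logk_mgbl)) {
    if (is.na(activity_mg2)) stop("model '", model$model_id,
                                  "' requires a Mg2+ activity")
    f <- f + 10^model$logk_mgbl * activity_mg2
  }
  f
}

#' Predict the free-ion LC50 in a target water (Direction 2)
#'
#' Evaluates the gBAM forward: given a species' intrinsic sensitivity Q50 and
#' the target water's pH and free Ca2+/Mg2+ activities, predicts the free
#' Ni2+ L(E)C50 (mol/L).
#'
#' @inheritParams effective_exponent
#' @param activity_ca2,activity_mg2 free-ion activities, mol/L (ignored for
#'   cations the model does not parameterize).
#' @return Predicted free-ion L(E)C50, mol/L.
#' @export
predict_lc50_free <- function(model, q50, ph, activity_ca2 = 0,
                              activity_mg2 = 0, override = FALSE) {
  if (any(c(activity_ca2, activity_mg2) < 0, na.rm = TRUE))
    stop("activities must be >= 0")
  10^(-effective_exponent(model, q50, ph, override)) *
    .competition(model, activity_ca2, activity_mg2)
}

#' Intrinsic sensitivity from an observed free-ion LC50 (Direction 1)
#'
#' Exact algebraic inversion of [predict_lc50_free()]: recovers the Q50 that
#' makes the gBAM reproduce an observed free-ion L(E)C50 under the test
#' water's pH and competing-cation activities.
#'
#' @inheritParams predict_lc50_free
#' @param observed_lc50_free observed free Ni2+ L(E)C50, mol/L (> 0).
#' @return The intrinsic sensitivity Q50 (unitless).
#' @export
q50_from_observation <- function(model, observed_lc50_free, ph,
                                 activity_ca2 = 0, activity_mg2 = 0,
                                 override = FALSE) {
  if (!is.numeric(observed_lc50_free) || observed_lc50_free <= 0)
    stop("observed free-ion LC50 must be > 0")
  .check_ph(model, ph, override)
  comp <- .competition(model, activity_ca2, activity_mg2)
  -log10(observed_lc50_free / comp) - .ph_term(model, ph)
}

#' Competition-corrected free-ion LC50
#'
#' Strips the Ca2+/Mg2+ competition factor from an observed free-ion LC50,
#' leaving the pH dependence intact; used to visualize the pH effect on Ni2+
#' toxicity.
#'
#' @inheritParams q50_from_observation
#' @return Corrected free-ion L(E)C50, mol/L (always <= the observed value).
#' @export
competition_corrected_lc50 <- function(model, observed_lc50_free,
                                       activity_ca2 = 0, activity_mg2 = 0) {
  if (!is.numeric(observed_lc50_free) || any(observed_lc50_free <= 0))
    stop("observed free-ion LC50 must be > 0")
  observed_lc50_free / .competition(model, activity_ca2, activity_mg2)
}

#' Combined applicability window of a model set
#'
#' Intersects the pH and hardness applicability ranges of several models:
#' the chemistry window over which the whole normalization approach is
#' considered valid. An empty intersection is reported (`empty = TRUE`), not
#' raised as an error.
#'
#' @param models list of [gbam_model()] objects (at least one).
#' @return List with elements `ph`, `hardness` (each `c(lower, upper)`) and
#'   `empty`.
#' @examples
#' combined_applicability(gbam_models()[c("avg_invertebrate", "algae", "fish")])
#' @export
combined_applicability <- function(models) {
  if (length(models) == 0L) stop("need at least one model")
  if (inherits(models, "gbam_model")) models <- list(models)
  ph <- c(max(vapply(models, function(m) m$applicability$ph[1], 0)),
          min(vapply(models, function(m) m$applicability$ph[2], 0)))
  hard <- c(max(vapply(models, function(m) m$applicability$hardness[1], 0)),
            min(vapply(models, function(m) m$applicability$hardness[2], 0)))
  list(ph = ph, hardness = hard, empty = ph[1] >= ph[2] || hard[1] >= hard[2])
}
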