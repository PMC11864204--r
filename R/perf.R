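#' Coefficient of determination for toxicity predictions
#'
#' `r^2 = 1 - SSR/SST` on log10-transformed L(E)C50s, with `SSR` the sum of
#' squared prediction residuals and `SST` the total sum of squares of the
#' observations around their mean. A model doing worse than the null model
#' (predicting the dataset mean) gives a negative ratio; such values are
#' clamped to 0 so the metric stays in [0, 1].
#'
#' @param observed_log10,predicted_log10 equal-length numeric vectors
#'   (log10 ug/L), n >= 2.
#' @return r-squared in [0, 1], or `NA` when the observations are constant
#'   (SST = 0, undefined).
#' @export
r_squared <- function(observed_log10, predicted_log10) {
  if (length(observed_log10) != length(predicted_log10))
    stop("observed and predicted must have equal length")
  if (length(observed_log10) < 2) stop("need at least two observations")
  sst <- sum((observed_log10 - mean(observed_log10))^2)
  if (sst == 0) return(NA_real_)
  ssr <- sum((predicted_log10 - observed_log10)^2)
  max(0, 1 - ssr / sst)
}

#' Factor of agreement
#'
#' Fraction of toxicity data predicted within a 2-fold error; the 2-fold
#' boundary counts as within.
#'
#' @param observed,predicted positive concentrations (same units).
#' @return Fraction in [0, 1].
#' @export
factor_agreement <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (any(observed <= 0) || any(predicted <= 0))
    stop("values must be positive")
  mean(abs(log10(predicted / observed)) <= log10(2) + 1e-12)
}

#' Residual scores against toxicity modifying factors
#'
#' Per-factor residual score `RS_f = 1 - |Pearson cor(residuals, f)|` and
#' their arithmetic mean `Tot RS`, quantifying residual bias of the model
#' predictions with respect to the main toxicity modifying factors (pH, DOC,
#' Ca, Mg). A score of 1 means no linear residual trend in that factor.
#' This bounded [0, 1] formulation preserves the semantics of the residual
#' score used in bioavailability-model evaluation; it is the package's own
#' definition, so printed Tot RS values from other implementations are not
#' comparison targets.
#'
#' @param residuals_log10 prediction residuals, log10(pred) - log10(obs).
#' @param tmf data.frame of factor values (columns among pH, DOC, Ca, Mg;
#'   raw scale), n >= 3 rows; zero-variance factors are skipped.
#' @return List with `rs` (named per-factor scores) and `tot_rs`.
#' @export
residual_scores <- function(residuals_log10, tmf) {
  tmf <- as.data.frame(tmf)
  if (nrow(tmf) != length(residuals_log10))
    stop("residuals and factor table must have equal length")
  if (length(residuals_log10) < 3) stop("need at least three records")
  rs <- c()
  for (f in names(tmf)) {
    x <- tmf[[f]]
    if (length(unique(x)) < 2 || var(x) == 0 || var(residuals_log10) == 0) next
    rs[f] <- 1 - abs(cor(residuals_log10, x))
  }
  if (length(rs) == 0)
    return(list(rs = rs, tot_rs = NA_real_))
  list(rs = rs, tot_rs = mean(rs))
}

#' Model performance score
#'
#' Arithmetic mean of r-squared, the factor of agreement and the total
#' residual score, reported by default to two decimals. All components must
#' lie in [0, 1], so the MPS does too.
#'
#' @param r2,fa,tot_rs the three component metrics, each in [0, 1].
#' @param digits decimals for reporting (`NULL` for full precision).
#' @return The MPS.
#' @examples
#' mps(0.90, 1.00, 0.78)  # 0.89
#' @export
mps <- function(r2, fa, tot_rs, digits = 2) {
  comp <- c(r2, fa, tot_rs)
  if (any(is.na(comp))) return(NA_real_)
  if (any(comp < 0 | comp > 1)) stop("MPS components must lie in [0, 1]")
  m <- mean(comp)
  if (is.null(digits)) m else round(m, digits)
}

#' Performance report for one dataset
#'
#' Computes the full metric set (r-squared, factor of agreement, residual
#' scores, MPS) for observed versus model-predicted L(E)C50s of one dataset.
#'
#' @param observed,predicted positive dissolved L(E)C50s, ug/L.
#' @param tmf optional data.frame of toxicity-modifying-factor values (see
#'   [residual_scores()]); without it Tot RS and MPS are `NA`.
#' @param dataset_id optional label.
#' @return Object of class `performance_report`: list with `dataset_id`,
#'   `n`, `r2`, `fa`, `rs_per_tmf`, `tot_rs`, `mps` (the MPS is stored at
#'   full precision; `print()` displays two decimals).
#' @export
model_performance <- function(observed, predicted, tmf = NULL,
                              dataset_id = NULL) {
  lo <- log10(observed); lp <- log10(predicted)
  r2 <- r_squared(lo, lp)
  fa <- factor_agreement(observed, predicted)
  rs <- if (!is.null(tmf)) residual_scores(lp - lo, tmf)
        else list(rs = c(), tot_rs = NA_real_)
  m <- if (!is.na(r2) && !is.na(rs$tot_rs)) mps(r2, fa, rs$tot_rs, digits = NULL)
       else NA_real_
  structure(list(dataset_id = dataset_id, n = length(observed), r2 = r2,
                 fa = fa, rs_per_tmf = rs$rs, tot_rs = rs$tot_rs, mps = m),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Model performance", if (!is.null(x$dataset_id))
    paste0("for '", x$dataset_id, "'") else "", sprintf("(n = %d)\n", x$n))
  cat(sprintf("  r2 = %.2f, FA = %.2f, Tot RS = %.2f, MPS = %.2f\n",
              x$r2, x$fa, x$tot_rs, x$mps))
  if (length(x$rs_per_tmf))
    cat("  RS per factor:",
        paste(sprintf("%s = %.2f", names(x$rs_per_tmf), x$rs_per_tmf),
              collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate the intrinsic sensitivity of a dataset
#'
#' Arithmetic mean of the Direction-1 Q50 over the records of one dataset,
#' restricted to waters with Ca and Mg each below 3 mmol/L (the calibration
#' rule used when validating the average invertebrate model; high-hardness
#' media are excluded from the mean).
#'
#' @param df a chemistry-complete record table for one dataset.
#' @param model a [gbam_model()] used for all records (defaults to each
#'   record's assigned model when `NULL`).
#' @param engine a [speciation_engine()].
#' @return The calibrated Q50 (arithmetic mean).
#' @export
calibrate_q50 <- function(df, model = NULL, engine = speciation_engine()) {
  df <- complete_chemistry(df)
  eligible <- !is.na(df$ca_mol_l) & !is.na(df$mg_mol_l) &
    df$ca_mol_l < 3e-3 & df$mg_mol_l < 3e-3
  if (!any(eligible))
    stop("no records with Ca and Mg < 3 mmol/L; cannot calibrate Q50")
  df <- df[eligible, , drop = FALSE]
  q <- if (is.null(model)) record_q50(df, engine)
  else vapply(seq_len(nrow(df)), function(i) {
    w <- .record_water(df, i)
    s <- speciate(w, df$lc50_ug_l[i], engine)
    q50_from_observation(model, s$activity_ni2, w$ph,
                         activity_ca2 = s$activity_ca2,
                         activity_mg2 = s$activity_mg2, override = TRUE)
  }, numeric(1))
  mean(q)
}
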