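# Observed-vs-predicted assessment: mixed-model regression with random
# study effects, agreement statistics (RMSE, R2, Lin's CCC, ICC), and a
# synthetic multi-study dataset generator for parameter-recovery testing.

#' Root mean square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return RMSE, in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0 || length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must be non-empty and equal length.",
         call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two vectors against the identity line, using population
#' (divide-by-n) moments:
#' CCC = 2 cov(o, p) / (var(o) + var(p) + (mean(o) - mean(p))^2).
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 2, at least
#'   one with non-zero variance.
#' @return CCC in \[-1, 1\], or NA with a warning when both inputs are
#'   constant.
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(1, 2, 3)) # 1
#' ccc(c(1, 2, 3), c(2, 3, 4)) # 4/7
ccc <- function(observed, predicted) {
  if (length(observed) < 2 || length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must be equal length, n >= 2.",
         call. = FALSE)
  }
  mo <- mean(observed)
  mp <- mean(predicted)
  vo <- mean((observed - mo)^2)
  vp <- mean((predicted - mp)^2)
  cv <- mean((observed - mo) * (predicted - mp))
  denom <- vo + vp + (mo - mp)^2
  if (denom == 0) {
    warning("both vectors are constant and equal; CCC undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  2 * cv / denom
}

#' Intraclass correlation from variance components
#'
#' ICC = sigma2_study / (sigma2_study + sigma2_res): the share of
#' residual-free variance attributable to study-level grouping.
#'
#' @param sigma2_study Study-level variance component (>= 0).
#' @param sigma2_res Residual variance component (>= 0).
#' @return ICC in \[0, 1\], or NA with a warning if both are zero.
#' @export
icc <- function(sigma2_study, sigma2_res) {
  if (sigma2_study < 0 || sigma2_res < 0) {
    stop("variance components must be >= 0.", call. = FALSE)
  }
  if (sigma2_study + sigma2_res == 0) {
    warning("both variance components are zero; ICC undefined.", call. = FALSE)
    return(NA_real_)
  }
  sigma2_study / (sigma2_study + sigma2_res)
}

# ---- observed-record sets --------------------------------------------------

# flat column schema for delimited-text interchange of observed records
OBSERVED_RECORD_COLUMNS <- c(
  "study", "treatment", "age_d", "observed_bw",
  "initial_bw", "temperature", "weaning_age", "allowance_l", "horizon",
  "liquid_kind", "liquid_dm_fraction", "liquid_me_density",
  "liquid_solids_per_litre", "liquid_cost_per_litre",
  "starter_cp", "starter_ndf", "starter_fat", "starter_ash", "starter_dm",
  "starter_form", "starter_cost_per_kg",
  "k_g", "fp_unit", "first_starter_offer_day"
)

#' Rebuild a simulation scenario from one observed-record row
#'
#' Observed-record tables carry the scenario inputs as flat columns (see
#' [write_observed_records()] for the schema); this reassembles the
#' [calf_scenario()] for one study-by-treatment group.
#'
#' @param row A one-row data frame with the observed-record columns.
#' @return A [calf_scenario()].
#' @export
scenario_from_record <- function(row) {
  liquid <- liquid_diet(
    kind = row$liquid_kind,
    dm_fraction = row$liquid_dm_fraction,
    me_density = row$liquid_me_density,
    cost_per_litre = row$liquid_cost_per_litre,
    solids_per_litre = row$liquid_solids_per_litre
  )
  starter <- starter_composition(
    cp_fraction = row$starter_cp, ndf_fraction = row$starter_ndf,
    fat_fraction = row$starter_fat, ash_fraction = row$starter_ash,
    dm_fraction = row$starter_dm, form = row$starter_form,
    cost_per_kg = row$starter_cost_per_kg
  )
  calf_scenario(
    initial_bw = row$initial_bw, temperature = row$temperature,
    weaning_age = row$weaning_age, liquid = liquid, starter = starter,
    allowance = row$allowance_l, horizon = row$horizon, k_g = row$k_g,
    fp_unit = row$fp_unit,
    first_starter_offer_day = row$first_starter_offer_day,
    label = paste(row$study, row$treatment, sep = ":")
  )
}

#' Write / read observed-record sets as CSV
#'
#' Observed-record sets are plain delimited text with one row per observed
#' BW point and flat scenario columns, so a set is fully self-describing:
#' `study`, `treatment`, `age_d`, `observed_bw`, then the scenario inputs
#' (`initial_bw`, `temperature`, `weaning_age`, `allowance_l`, `horizon`,
#' liquid-diet and starter-composition fields, `k_g`, `fp_unit`,
#' `first_starter_offer_day`).
#'
#' @param records A tibble of observed records.
#' @param path File path.
#' @return `read_observed_records()` returns the tibble;
#'   `write_observed_records()` returns `path` invisibly.
#' @export
write_observed_records <- function(records, path) {
  missing_cols <- setdiff(OBSERVED_RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[, union(OBSERVED_RECORD_COLUMNS,
                                   names(records))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observed_records
#' @export
read_observed_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Predict BW for every observed record
#'
#' Runs the simulator once per study-by-treatment group and extracts the
#' predicted BW at each observed age. Ages beyond the group's simulation
#' horizon are dropped with a warning.
#'
#' @param records Observed-record tibble (see [write_observed_records()]).
#' @return The records with a `predicted_bw` column added, restricted to
#'   ages within the horizon.
#' @export
predict_dataset <- function(records) {
  key <- paste(records$study, records$treatment, sep = "\r")
  records$predicted_bw <- NA_real_
  for (k in unique(key)) {
    rows <- which(key == k)
    scenario <- scenario_from_record(records[rows[1], , drop = FALSE])
    bw_end <- simulate_bw(scenario)$bw_end
    ages <- records$age_d[rows]
    pred <- ifelse(ages == 0, scenario$initial_bw,
                   ifelse(ages >= 1 & ages <= length(bw_end),
                          bw_end[pmax(pmin(ages, length(bw_end)), 1)],
                          NA_real_))
    records$predicted_bw[rows] <- pred
  }
  dropped <- is.na(records$predicted_bw)
  if (any(dropped)) {
    warning(sum(dropped), " record(s) at ages beyond the simulation ",
            "horizon were skipped.", call. = FALSE)
    records <- records[!dropped, , drop = FALSE]
  }
  records
}

# ---- mixed-model fit -------------------------------------------------------

#' Regress observed on predicted BW with random study effects
#'
#' Fits the assessment model: observed BW on predicted BW with a fixed
#' intercept and slope and random study intercepts. A treatment-within-study
#' variance component is first tested against zero by likelihood ratio
#' (ML fits, p-value from the boundary mixture 0.5 chi2(0) + 0.5 chi2(1))
#' and dropped when non-significant at `alpha`; the reported model is then
#' refit by REML.
#'
#' Accuracy is summarised by Wald tests of intercept = 0 and slope = 1
#' (normal approximation), precision by RMSE, R-squared and Lin's CCC, and
#' study-level heterogeneity by the variance components and the ICC
#' sigma2_study / (sigma2_study + sigma2_res). R2 and RMSE are reported
#' both on the raw observed-vs-predicted pairs and conditionally on the
#' fitted study effects; CCC both raw and after within-study centering.
#'
#' When observed and predicted agree to machine precision given study
#' shifts (zero residual variance), a degenerate-fit shortcut returns the
#' analytic answer instead of forcing the mixed model onto a boundary it
#' cannot represent.
#'
#' @param data A data frame with columns `observed_bw`, `predicted_bw`,
#'   `study`, and optionally `treatment`.
#' @param alpha LRT significance level for keeping the treatment component
#'   (default 0.05).
#' @return An object of class `calf_assessment`: a list of coefficients,
#'   variance components, agreement statistics, test p-values and fit
#'   diagnostics (see Details).
#' @export
fit_obs_on_pred <- function(data, alpha = 0.05) {
  need <- c("observed_bw", "predicted_bw", "study")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)
  data$study <- factor(data$study)
  n_studies <- nlevels(data$study)
  if (n_studies < 2) stop("need >= 2 studies.", call. = FALSE)
  if (nrow(data) < 10) stop("need >= 10 observed/predicted pairs.",
                            call. = FALSE)
  has_treatment <- "treatment" %in% names(data) &&
    length(unique(paste(data$study, data$treatment))) > n_studies
  obs <- data$observed_bw
  pred <- data$predicted_bw

  out <- list(
    n_obs = nrow(data), n_studies = n_studies,
    rmse = rmse(obs, pred),
    r2_marginal = stats::cor(obs, pred)^2,
    ccc = ccc(obs, pred),
    ccc_study_centered = {
      sm_o <- stats::ave(obs, data$study)
      sm_p <- stats::ave(pred, data$study)
      ccc(obs - sm_o + mean(obs), pred - sm_p + mean(pred))
    }
  )

  # degenerate shortcut: zero residual variance once study shifts are out
  ols_study <- stats::lm(observed_bw ~ predicted_bw + study, data = data)
  if (max(abs(stats::resid(ols_study))) < 1e-8 * max(1, max(abs(obs)))) {
    beta1 <- unname(stats::coef(ols_study)["predicted_bw"])
    study_shift <- tapply(obs - beta1 * pred, data$study, mean)
    sigma2_study <- stats::var(as.numeric(study_shift))
    if (sigma2_study < 1e-12) sigma2_study <- 0
    out <- c(out, list(
      beta0 = if (sigma2_study == 0) unname(study_shift[1]) else
        mean(study_shift),
      beta1 = beta1,
      se_beta0 = NA_real_, se_beta1 = NA_real_,
      p_beta0_eq_0 = NA_real_, p_beta1_eq_1 = NA_real_,
      sigma2_study = sigma2_study,
      sigma2_treatment = NA_real_, sigma2_res = 0,
      lrt_treatment_p = NA_real_, treatment_kept = FALSE,
      singular = TRUE, degenerate = TRUE,
      r2_conditional = 1, rmse_study_adjusted = 0
    ))
    out$icc <- if (sigma2_study > 0) 1 else NA_real_
    class(out) <- "calf_assessment"
    return(out)
  }

  f_red <- observed_bw ~ predicted_bw + (1 | study)
  if (has_treatment) {
    f_full <- observed_bw ~ predicted_bw + (1 | study) + (1 | study:treatment)
    m_full <- lme4::lmer(f_full, data = data, REML = FALSE)
    m_red <- lme4::lmer(f_red, data = data, REML = FALSE)
    lrt_stat <- max(0, 2 * (as.numeric(stats::logLik(m_full)) -
                              as.numeric(stats::logLik(m_red))))
    # boundary mixture 0.5 chi2(0) + 0.5 chi2(1)
    lrt_p <- 0.5 * stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)
    keep_treatment <- lrt_p <= alpha
  } else {
    lrt_p <- NA_real_
    keep_treatment <- FALSE
  }
  formula_final <- if (keep_treatment) f_full else f_red
  fit <- lme4::lmer(formula_final, data = data, REML = TRUE)

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) NA_real_ else v
  }
  sigma2_study <- get_vc("study")
  sigma2_treatment <- get_vc("study:treatment")
  sigma2_res <- get_vc("Residual")
  fitted_cond <- stats::fitted(fit)

  out <- c(out, list(
    beta0 = unname(fe[1]), beta1 = unname(fe[2]),
    se_beta0 = unname(se[1]), se_beta1 = unname(se[2]),
    p_beta0_eq_0 = 2 * stats::pnorm(-abs(fe[1] / se[1])),
    p_beta1_eq_1 = 2 * stats::pnorm(-abs((fe[2] - 1) / se[2])),
    sigma2_study = sigma2_study,
    sigma2_treatment = sigma2_treatment,
    sigma2_res = sigma2_res,
    icc = icc(sigma2_study, sigma2_res),
    lrt_treatment_p = lrt_p,
    treatment_kept = keep_treatment,
    singular = lme4::isSingular(fit),
    degenerate = FALSE,
    r2_conditional = stats::cor(obs, fitted_cond)^2,
    rmse_study_adjusted = sqrt(mean((obs - fitted_cond)^2)),
    model = fit
  ))
  class(out) <- "calf_assessment"
  out
}

#' @export
print.calf_assessment <- function(x, digits = 4, ...) {
  cat("Observed-vs-predicted BW assessment\n")
  cat(sprintf("  n = %d observations, %d studies\n", x$n_obs, x$n_studies))
  cat(sprintf("  intercept beta0 = %.*f (P[beta0=0] = %s)\n", digits, x$beta0,
              format.pval(x$p_beta0_eq_0, digits = 3)))
  cat(sprintf("  slope     beta1 = %.*f (P[beta1=1] = %s)\n", digits, x$beta1,
              format.pval(x$p_beta1_eq_1, digits = 3)))
  cat(sprintf("  sigma2_study = %.*f, sigma2_res = %.*f, ICC = %.*f\n",
              digits, x$sigma2_study, digits, x$sigma2_res, digits, x$icc))
  cat(sprintf("  RMSE = %.*f kg, R2 (conditional) = %.*f, CCC = %.*f\n",
              digits, x$rmse, digits, x$r2_conditional, digits, x$ccc))
  if (!is.na(x$lrt_treatment_p)) {
    cat(sprintf("  treatment-within-study LRT p = %s (%s)\n",
                format.pval(x$lrt_treatment_p, digits = 3),
                if (x$treatment_kept) "kept" else "dropped"))
  }
  if (isTRUE(x$singular)) cat("  note: fit is singular/degenerate\n")
  invisible(x)
}

#' Serialize an assessment result
#'
#' @param x A `calf_assessment` object.
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
write_assessment <- function(x, path) {
  keep <- x[setdiff(names(x), "model")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# ---- synthetic multi-study generator --------------------------------------

#' Generate a synthetic multi-study observed-BW dataset
#'
#' Emulates the structure of a multi-study calf-nutrition literature
#' dataset: studies with treatments nested inside, each treatment a milk
#' allowance plan simulated by the package's own engine, and BW observed at
#' several ages. Scenario inputs are sampled within the ranges typical of
#' the published literature (initial BW 34.1-48.9 kg, weaning age 42-90 d,
#' liquid-diet ME 3.67-5.76 Mcal/kg DM, milk allowance 1-13.5 L/d); ambient
#' temperature defaults to 20 degrees C. Observed BW is the simulator's
#' prediction plus a study-level intercept shift N(0, sigma_study^2) and
#' residual noise N(0, sigma_res^2).
#'
#' @param n_studies Number of studies (default 27).
#' @param treatments_per_study Treatments nested in each study (default 3).
#' @param sigma_study Study-level SD of observed BW around predictions, kg
#'   (default 9, i.e. variance about 81).
#' @param sigma_res Residual SD, kg (default 7.5, variance about 56).
#' @param seed Optional integer seed for reproducibility.
#' @param temperature Ambient temperature used for every scenario, degrees
#'   C (default 20).
#' @return An observed-record tibble (flat schema of
#'   [write_observed_records()]) with the additional column `predicted_bw`
#'   holding the noise-free simulator prediction.
#' @export
#' @examples
#' recs <- generate_synthetic_studies(n_studies = 4, seed = 1)
#' head(recs[, c("study", "treatment", "age_d", "observed_bw")])
generate_synthetic_studies <- function(n_studies = 27,
                                       treatments_per_study = 3,
                                       sigma_study = 9,
                                       sigma_res = 7.5,
                                       seed = NULL,
                                       temperature = 20) {
  stopifnot(n_studies >= 1, treatments_per_study >= 1,
            sigma_study >= 0, sigma_res >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (k in seq_len(n_studies)) {
    initial_bw <- stats::runif(1, 34.1, 48.9)
    weaning_age <- round(stats::runif(1, 42, 90))
    liquid_me <- stats::runif(1, 3.67, 5.76)
    horizon <- min(100, weaning_age + 14)
    study_shift <- stats::rnorm(1, 0, sigma_study)
    for (j in seq_len(treatments_per_study)) {
      allowance <- stats::runif(1, 1, 13.5)
      rec <- tibble::tibble(
        study = sprintf("S%02d", k),
        treatment = sprintf("T%d", j),
        age_d = NA_real_, observed_bw = NA_real_,
        initial_bw = initial_bw, temperature = temperature,
        weaning_age = weaning_age, allowance_l = allowance,
        horizon = horizon,
        liquid_kind = "whole_milk", liquid_dm_fraction = 0.125,
        liquid_me_density = liquid_me,
        liquid_solids_per_litre = 0.125 * 1.03,
        liquid_cost_per_litre = 0.45,
        starter_cp = 0.22, starter_ndf = 0.15, starter_fat = 0.04,
        starter_ash = 0.07, starter_dm = 0.90,
        starter_form = "texturized", starter_cost_per_kg = 0.5,
        k_g = 0.60, fp_unit = "weeks", first_starter_offer_day = 3
      )
      scenario <- scenario_from_record(rec)
      bw_end <- simulate_bw(scenario)$bw_end
      ages <- sort(unique(pmin(c(28, 56, weaning_age, horizon), horizon)))
      pred <- bw_end[ages]
      obs <- pred + study_shift + stats::rnorm(length(ages), 0, sigma_res)
      out <- rec[rep(1, length(ages)), ]
      out$age_d <- ages
      out$predicted_bw <- pred
      out$observed_bw <- pmax(obs, 1)
      rows[[length(rows) + 1L]] <- out
    }
  }
  do.call(rbind, rows)
}
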