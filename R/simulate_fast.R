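# Inlined daily recurrence used where only the BW trajectory is needed
# (dataset prediction, synthetic generation, parameter-recovery loops).
# Must agree with step_day()/simulate_calf() to machine precision; the test
# suite asserts the equivalence on a scenario grid.

#' Fast body-weight trajectory for a scenario
#'
#' Computes the same daily recurrence as [simulate_calf()] but returns only
#' the end-of-day body weight and cumulative starter-NFC vectors, skipping
#' per-day record assembly and per-call validation. Out-of-range
#' maintenance efficiencies are clamped silently (the full engine warns).
#'
#' @param scenario A [calf_scenario()].
#' @return A list with numeric vectors `bw_end` and `cum_nfc`, one element
#'   per simulated day.
#' @export
simulate_bw <- function(scenario) {
  stopifnot(inherits(scenario, "calf_scenario"))
  horizon <- scenario$horizon
  offered_l <- scenario$plan$offered_l
  weaning_age <- scenario$weaning_age
  first_offer <- scenario$first_starter_offer_day
  fp_week <- scenario$fp_unit == "weeks"
  semitrop <- scenario$temperature > 35
  spl <- scenario$liquid$solids_per_litre
  me_liq <- scenario$liquid$me_density
  st <- scenario$starter
  pel <- as.numeric(st$form == "pelleted")
  tex <- as.numeric(st$form == "texturized")
  k_g <- scenario$k_g

  bw <- scenario$initial_bw
  cum <- 0
  weaned <- FALSE
  bw_end <- numeric(horizon)
  cum_nfc <- numeric(horizon)

  for (day in seq_len(horizon)) {
    offered <- offered_l[day]
    if (!weaned && day >= weaning_age && offered == 0) weaned <- TRUE
    consumed <- min(offered, LIQUID_CAP_L)
    ldm <- consumed * spl
    meld <- ldm * me_liq

    si_dm <- 0
    if (day >= first_offer) {
      fp <- day - first_offer
      if (fp_week) fp <- fp / 7
      si <- if (semitrop) {
        600.053 / (1 + 14863.651 * exp(-1.553 * fp)) +
          9.951 * bw - 130.434 * meld
      } else {
        -652.525 + bw * 14.734 + meld * 18.896 + fp * 73.303 +
          fp^2 * 13.496 - 29.614 * fp * meld
      }
      si_dm <- max(si, 0) / 1000
    }

    ln <- log(min(max(cum, NFC_LN_FLOOR_KG), NFC_PLATEAU_KG))
    d_cp <- min(max(0.707 + 0.0268 * ln - 0.329 * pel - 0.042 * tex +
                      0.107 * pel * ln - 0.013 * tex * ln, 0), 1)
    d_fat <- min(max(0.883 - 0.021 * ln - 0.212 * pel - 0.380 * tex +
                       0.091 * pel * ln + 0.122 * tex * ln, 0), 1)
    d_ndf <- min(max(0.390 + 0.026 * ln - 0.090 * pel - 0.263 * tex +
                       0.078 * pel * ln + 0.082 * tex * ln, 0), 1)
    d_nfc <- min(max(0.935 + 0.004 * ln - 0.348 * pel - 0.322 * tex +
                       0.134 * pel * ln + 0.127 * tex * ln, 0), 1)
    de <- 4.2 * (d_nfc * st$nfc_fraction) + 4.2 * (d_ndf * st$ndf_fraction) +
      5.6 * (d_cp * st$cp_fraction) + 9.4 * (d_fat * st$fat_fraction) - 0.3
    me_dens <- max(1.01 * de - 0.45, 0)
    me_total <- meld + si_dm * me_dens

    if (weaned) {
      f <- 0.85
      ebw <- f * bw
      nem <- 97.0 * ebw^0.75 / 1000
      km <- (1.1104 * me_dens - 0.0946 * me_dens^2 +
               0.0065 * me_dens^3 - 0.7783) / me_dens
      if (!is.finite(km) || km <= 0) km <- 0.01 else if (km > 1) km <- 1
    } else {
      f <- 0.91
      ebw <- f * bw
      nem <- 76.9 * ebw^0.75 / 1000
      km <- 0.69
    }
    ne <- (me_total - nem / km) * k_g
    gain <- sign(ne) * (abs(ne) / ebw^0.205)^(1 / 1.1)
    bw <- max(bw + gain / f, 1)
    cum <- cum + si_dm * st$nfc_fraction
    bw_end[day] <- bw
    cum_nfc[day] <- cum
  }
  list(bw_end = bw_end, cum_nfc = cum_nfc)
}
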