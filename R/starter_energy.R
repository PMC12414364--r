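# Digestibility maturation of starter nutrients and starter ME density.
#
# A young calf's reticulorumen has limited fermentative capacity, so the
# digestibility of starter components rises with gut development, indexed
# here by the cumulative intake of non-fibrous carbohydrate (NFC) from
# starter. Each digestibility is linear in ln(cumulative NFC, kg) with
# physical-form effects, and plateaus once cumulative intake passes 15 kg.

NFC_PLATEAU_KG <- 15
NFC_LN_FLOOR_KG <- 0.1

#' Describe a starter (calf starter) feed
#'
#' Chemical composition on a DM basis plus physical form and cost. The NFC
#' fraction is derived as 1 - CP - NDF - fat - ash and must be positive.
#'
#' @param cp_fraction Crude protein, kg/kg DM.
#' @param ndf_fraction Neutral detergent fiber, kg/kg DM.
#' @param fat_fraction Crude fat, kg/kg DM.
#' @param ash_fraction Ash, kg/kg DM.
#' @param dm_fraction Dry matter of the feed as fed, kg DM/kg.
#' @param form Physical form: `"texturized"`, `"pelleted"`, or `"tmr"`
#'   (total mixed ration, the indicator baseline).
#' @param cost_per_kg Cost, currency/kg as fed.
#' @return An object of class `starter_composition` including the derived
#'   `nfc_fraction`.
#' @export
#' @examples
#' starter_composition(cp = 0.22, ndf = 0.15, fat = 0.04, ash = 0.07)
starter_composition <- function(cp_fraction = 0.22, ndf_fraction = 0.15,
                                fat_fraction = 0.04, ash_fraction = 0.07,
                                dm_fraction = 0.90,
                                form = c("texturized", "pelleted", "tmr"),
                                cost_per_kg = 0.5) {
  form <- match.arg(form)
  fr <- c(cp = cp_fraction, ndf = ndf_fraction, fat = fat_fraction,
          ash = ash_fraction, dm = dm_fraction)
  if (any(fr < 0) || any(fr > 1)) {
    stop("all composition fractions must lie in [0, 1].", call. = FALSE)
  }
  nfc <- 1 - cp_fraction - ndf_fraction - fat_fraction - ash_fraction
  if (nfc <= 0) {
    stop("CP + NDF + fat + ash must be < 1 so that NFC > 0.", call. = FALSE)
  }
  structure(
    list(cp_fraction = cp_fraction, ndf_fraction = ndf_fraction,
         fat_fraction = fat_fraction, ash_fraction = ash_fraction,
         nfc_fraction = nfc, dm_fraction = dm_fraction, form = form,
         cost_per_kg = cost_per_kg),
    class = "starter_composition"
  )
}

#' Log cumulative starter-NFC intake driving digestibility
#'
#' Returns ln of the cumulative NFC intake clamped into
#' \[0.1, 15\] kg. The 15-kg ceiling encodes the digestibility plateau (gut
#' maturation complete); the 0.1-kg floor keeps the logarithm finite at
#' zero intake while leaving first-days digestibility deliberately poor.
#'
#' @param cum_nfc Cumulative starter-NFC intake, kg. Must be >= 0.
#' @return Dimensionless log value.
#' @export
ln_ccs_nfci <- function(cum_nfc) {
  if (!is.numeric(cum_nfc) || any(!is.finite(cum_nfc)) || any(cum_nfc < 0)) {
    stop("`cum_nfc` must be a non-negative finite number (kg).", call. = FALSE)
  }
  log(pmin(pmax(cum_nfc, NFC_LN_FLOOR_KG), NFC_PLATEAU_KG))
}

#' Starter-nutrient digestibilities
#'
#' Evaluates the four digestibility equations at a given log cumulative NFC
#' value, with pelleted (PEL) and texturized (TEX) indicator effects and
#' TMR as the all-zero baseline:
#' * dCP  = 0.707 + 0.0268 ln - 0.329 PEL - 0.042 TEX + 0.107 PEL ln - 0.013 TEX ln
#' * dFat = 0.883 - 0.021  ln - 0.212 PEL - 0.380 TEX + 0.091 PEL ln + 0.122 TEX ln
#' * dNDF = 0.390 + 0.026  ln - 0.090 PEL - 0.263 TEX + 0.078 PEL ln + 0.082 TEX ln
#' * dNFC = 0.935 + 0.004  ln - 0.348 PEL - 0.322 TEX + 0.134 PEL ln + 0.127 TEX ln
#'
#' Each value is clamped into \[0, 1\] after evaluation, since the linear
#' forms can stray outside physical bounds at extreme log values.
#'
#' @param ln_val Log cumulative NFC intake, from [ln_ccs_nfci()].
#' @param form `"texturized"`, `"pelleted"`, or `"tmr"`.
#' @return A list with `d_cp`, `d_fat`, `d_ndf`, `d_nfc` (fractions) and
#'   the `ln_ccs_nfci` value used.
#' @export
#' @examples
#' digestibilities(0, "tmr") # the four intercepts
#' digestibilities(ln_ccs_nfci(20), "texturized") # at the plateau
digestibilities <- function(ln_val, form = c("texturized", "pelleted", "tmr")) {
  form <- match.arg(form)
  if (!is.numeric(ln_val) || length(ln_val) != 1L || !is.finite(ln_val)) {
    stop("`ln_val` must be a finite number.", call. = FALSE)
  }
  pel <- as.numeric(form == "pelleted")
  tex <- as.numeric(form == "texturized")
  clamp01 <- function(x) min(max(x, 0), 1)
  list(
    d_cp = clamp01(0.707 + 0.0268 * ln_val - 0.329 * pel - 0.042 * tex +
                     0.107 * pel * ln_val - 0.013 * tex * ln_val),
    d_fat = clamp01(0.883 - 0.021 * ln_val - 0.212 * pel - 0.380 * tex +
                      0.091 * pel * ln_val + 0.122 * tex * ln_val),
    d_ndf = clamp01(0.390 + 0.026 * ln_val - 0.090 * pel - 0.263 * tex +
                      0.078 * pel * ln_val + 0.082 * tex * ln_val),
    d_nfc = clamp01(0.935 + 0.004 * ln_val - 0.348 * pel - 0.322 * tex +
                      0.134 * pel * ln_val + 0.127 * tex * ln_val),
    ln_ccs_nfci = ln_val
  )
}

#' Starter ME density from digestible fractions
#'
#' Summative digestible-fraction energy, a standard dairy-NRC-style
#' convention (coefficients stated here so the contract is self-contained,
#' fractions on a DM basis, energies Mcal/kg DM):
#'
#' DE = 4.2 (dNFC x NFC) + 4.2 (dNDF x NDF) + 5.6 (dCP x CP)
#'    + 9.4 (dFat x Fat) - 0.3;  ME = 1.01 DE - 0.45, clamped at >= 0.
#'
#' @param comp A [starter_composition()] object.
#' @param d A digestibility set from [digestibilities()].
#' @return Starter ME density, Mcal/kg DM.
#' @export
starter_me_density <- function(comp, d) {
  stopifnot(inherits(comp, "starter_composition"))
  de <- 4.2 * (d$d_nfc * comp$nfc_fraction) +
    4.2 * (d$d_ndf * comp$ndf_fraction) +
    5.6 * (d$d_cp * comp$cp_fraction) +
    9.4 * (d$d_fat * comp$fat_fraction) - 0.3
  max(1.01 * de - 0.45, 0)
}

#' Accumulate starter NFC intake
#'
#' @param cum_nfc Cumulative NFC intake so far, kg.
#' @param si_dm Starter DM intake for the day, kg/d. Must be >= 0.
#' @param comp A [starter_composition()] object.
#' @return Updated cumulative NFC intake, kg.
#' @export
nfc_accumulate <- function(cum_nfc, si_dm, comp) {
  stopifnot(inherits(comp, "starter_composition"))
  if (si_dm < 0) stop("`si_dm` must be >= 0 (kg/d).", call. = FALSE)
  cum_nfc + si_dm * comp$nfc_fraction
}
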