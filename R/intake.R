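# Liquid-diet consumption and starter (solid feed) intake prediction.

#' Maximum daily liquid-diet consumption, L/d
#'
#' Calves under ad libitum liquid feeding do not exceed roughly 14 L/d, so
#' consumption is capped at that volume regardless of the amount offered.
#' @export
LIQUID_CAP_L <- 14

#' Describe a liquid diet
#'
#' Builds the liquid-diet descriptor used throughout the simulator. The
#' litre-to-DM conversion depends on the kind of liquid:
#' * `whole_milk`: solids per litre = `dm_fraction` x 1.03 kg/L (milk
#'   density);
#' * `milk_replacer`: solids per litre = `mixing_rate_g_l` / 1000 x
#'   `dm_fraction`, i.e. powder mixed at a declared rate, with
#'   `dm_fraction` the DM content of the powder (default 0.96).
#'
#' `solids_per_litre` may also be given directly, overriding the derivation.
#'
#' @param kind `"whole_milk"` or `"milk_replacer"`.
#' @param dm_fraction Dry-matter fraction of the liquid (whole milk) or of
#'   the powder (milk replacer), kg DM/kg.
#' @param me_density ME density of the liquid DM, Mcal/kg DM. Typical range
#'   for milk and replacers is about 3.7-5.8.
#' @param cost_per_litre Cost of the liquid as fed, currency/L.
#' @param mixing_rate_g_l Milk-replacer mixing rate, g powder/L. Required
#'   for `kind = "milk_replacer"` unless `solids_per_litre` is given.
#' @param solids_per_litre Optional direct kg DM/L override.
#' @return An object of class `liquid_diet`.
#' @export
#' @examples
#' liquid_diet("whole_milk", dm_fraction = 0.125, me_density = 5.37)
#' liquid_diet("milk_replacer", me_density = 4.6, mixing_rate_g_l = 130)
liquid_diet <- function(kind = c("whole_milk", "milk_replacer"),
                        dm_fraction = if (kind == "whole_milk") 0.125 else 0.96,
                        me_density = 4.6,
                        cost_per_litre = 0.5,
                        mixing_rate_g_l = NULL,
                        solids_per_litre = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dm_fraction) || dm_fraction <= 0 || dm_fraction >= 1) {
    stop("`dm_fraction` must lie in (0, 1).", call. = FALSE)
  }
  if (!is.numeric(me_density) || me_density <= 0) {
    stop("`me_density` must be positive (Mcal/kg DM).", call. = FALSE)
  }
  if (is.null(solids_per_litre)) {
    solids_per_litre <- if (kind == "whole_milk") {
      dm_fraction * 1.03
    } else {
      if (is.null(mixing_rate_g_l)) {
        stop("milk replacer needs `mixing_rate_g_l` (g powder/L) or ",
             "`solids_per_litre`.", call. = FALSE)
      }
      mixing_rate_g_l / 1000 * dm_fraction
    }
  }
  if (solids_per_litre <= 0) {
    stop("`solids_per_litre` must be positive (kg DM/L).", call. = FALSE)
  }
  structure(
    list(kind = kind, dm_fraction = dm_fraction,
         solids_per_litre = solids_per_litre, me_density = me_density,
         cost_per_litre = cost_per_litre),
    class = "liquid_diet"
  )
}

#' Liquid diet actually consumed
#'
#' All offered liquid is assumed consumed, capped at the biological maximum
#' of 14 L/d.
#'
#' @param offered Litres offered, L/d. Must be >= 0.
#' @return Litres consumed, L/d.
#' @export
liquid_consumed <- function(offered) {
  if (!is.numeric(offered) || any(!is.finite(offered)) || any(offered < 0)) {
    stop("`offered` must be a non-negative finite number (L/d).", call. = FALSE)
  }
  pmin(offered, LIQUID_CAP_L)
}

#' Liquid DM intake and ME intake
#'
#' @param consumed Litres consumed, L/d.
#' @param diet A [liquid_diet()] object.
#' @return A list with `dm` (kg DM/d) and `me_i_ld` (Mcal/d), the ME intake
#'   from the liquid diet.
#' @export
liquid_dm_and_me <- function(consumed, diet) {
  stopifnot(inherits(diet, "liquid_diet"))
  if (!is.numeric(consumed) || any(consumed < 0)) {
    stop("`consumed` must be >= 0 (L/d).", call. = FALSE)
  }
  dm <- consumed * diet$solids_per_litre
  list(dm = dm, me_i_ld = dm * diet$me_density)
}

#' Starter-intake predictors
#'
#' Bundle of the covariates the starter-intake regressions use: body weight
#' (kg), current ME intake from the liquid diet (Mcal/d), and time since
#' starter was first offered.
#'
#' The regression coefficients are only biologically plausible when the
#' starter-exposure clock runs in weeks (at day scale the quadratic term
#' dominates within the first weeks), so `fp_unit = "weeks"` is the default
#' and `fp_starter` is then days-since-first-offer / 7. Setting
#' `fp_unit = "days"` preserves the literal day-scale reading.
#'
#' @param bw Body weight, kg.
#' @param me_i_ld ME intake from the liquid diet, Mcal/d.
#' @param fp_days Days since starter was first offered (>= 0).
#' @param fp_unit `"weeks"` (default) or `"days"`.
#' @return An object of class `starter_inputs` with element `fp_starter`
#'   already on the requested scale.
#' @export
starter_inputs <- function(bw, me_i_ld, fp_days, fp_unit = c("weeks", "days")) {
  fp_unit <- match.arg(fp_unit)
  if (fp_days < 0) stop("`fp_days` must be >= 0.", call. = FALSE)
  if (bw <= 0) stop("`bw` must be positive (kg).", call. = FALSE)
  if (me_i_ld < 0) stop("`me_i_ld` must be >= 0 (Mcal/d).", call. = FALSE)
  structure(
    list(bw = bw, me_i_ld = me_i_ld,
         fp_starter = if (fp_unit == "weeks") fp_days / 7 else fp_days,
         fp_unit = fp_unit),
    class = "starter_inputs"
  )
}

#' Starter intake, temperate conditions (<= 35 degrees C)
#'
#' SI (g/d) = -652.525 + 14.734 BW + 18.896 MEiLD + 73.303 FP
#'          + 13.496 FP^2 - 29.614 FP x MEiLD,
#' clamped at >= 0 (negative regression output in the first days of life is
#' a model artifact).
#'
#' @param x A [starter_inputs()] object.
#' @return Predicted starter DM intake, g/d.
#' @export
starter_intake_temperate <- function(x) {
  stopifnot(inherits(x, "starter_inputs"))
  fp <- x$fp_starter
  si <- -652.525 + x$bw * 14.734 + x$me_i_ld * 18.896 +
    fp * 73.303 + fp^2 * 13.496 - 29.614 * fp * x$me_i_ld
  max(si, 0)
}

#' Starter intake, semitropical conditions (> 35 degrees C)
#'
#' SI (g/d) = 600.053 x {1 + 14863.651 exp(-1.553 FP)}^-1
#'          + 9.951 BW - 130.434 MEiLD,
#' clamped at >= 0. The first term is a logistic ramp from near zero at
#' first starter offer towards an asymptote of 600.053 g/d.
#'
#' @param x A [starter_inputs()] object.
#' @return Predicted starter DM intake, g/d.
#' @export
starter_intake_semitropical <- function(x) {
  stopifnot(inherits(x, "starter_inputs"))
  si <- 600.053 / (1 + 14863.651 * exp(-1.553 * x$fp_starter)) +
    9.951 * x$bw - 130.434 * x$me_i_ld
  max(si, 0)
}

#' Select the climate-appropriate starter-intake equation
#'
#' The semitropical equation applies when the ambient temperature declared
#' by the user exceeds 35 degrees C; the temperate equation otherwise.
#'
#' @param temperature Ambient temperature, degrees C, in \[-30, 50\].
#' @return `"temperate"` or `"semitropical"`.
#' @export
select_starter_equation <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature < -30 || temperature > 50) {
    stop("`temperature` must lie in [-30, 50] degrees C.", call. = FALSE)
  }
  if (temperature > 35) "semitropical" else "temperate"
}

#' Predicted starter intake under the declared climate
#'
#' Dispatches on [select_starter_equation()].
#'
#' @inheritParams starter_intake_temperate
#' @param temperature Ambient temperature, degrees C.
#' @return Predicted starter DM intake, g/d.
#' @export
starter_intake <- function(x, temperature) {
  switch(select_starter_equation(temperature),
    temperate = starter_intake_temperate(x),
    semitropical = starter_intake_semitropical(x)
  )
}

#' Describe a milk allowance plan
#'
#' A milk plan gives the litres of liquid diet offered on each day of life
#' until weaning. `allowance` may be a single constant, a full numeric
#' vector indexed by day, or a two-column data frame `(day, litres)` read as
#' a step schedule: the allowance changes to `litres` from `day` onward.
#' Allowance is forced to zero from `weaning_age` on.
#'
#' @param allowance Constant, daily vector, or step-schedule data frame.
#' @param weaning_age Weaning age, days, in \[10, 120\].
#' @param horizon Number of days to expand the plan over.
#' @param first_starter_offer_day Day of life starter is first offered
#'   (default 3).
#' @return An object of class `milk_plan` with the expanded daily
#'   `offered_l` vector.
#' @export
#' @examples
#' milk_plan(6, weaning_age = 56)
#' milk_plan(data.frame(day = c(1, 43, 50), litres = c(8, 4, 2)),
#'           weaning_age = 56)
milk_plan <- function(allowance, weaning_age, horizon = 100,
                      first_starter_offer_day = 3) {
  if (!is.numeric(weaning_age) || length(weaning_age) != 1L ||
      weaning_age < 10 || weaning_age > 120) {
    stop("`weaning_age` must lie in [10, 120] d.", call. = FALSE)
  }
  if (horizon < 1) stop("`horizon` must be >= 1 d.", call. = FALSE)
  days <- seq_len(horizon)
  if (is.data.frame(allowance)) {
    if (!all(c("day", "litres") %in% names(allowance))) {
      stop("step-schedule allowance needs columns `day` and `litres`.",
           call. = FALSE)
    }
    sched <- allowance[order(allowance$day), , drop = FALSE]
    idx <- findInterval(days, sched$day)
    offered <- ifelse(idx == 0, 0, sched$litres[pmax(idx, 1)])
  } else if (length(allowance) == 1L) {
    offered <- rep(as.numeric(allowance), horizon)
  } else {
    offered <- rep_len(as.numeric(allowance), horizon)
  }
  if (any(offered < 0)) stop("milk allowance must be >= 0 L/d.", call. = FALSE)
  offered[days >= weaning_age] <- 0
  structure(
    list(offered_l = offered, weaning_age = weaning_age,
         first_starter_offer_day = first_starter_offer_day),
    class = "milk_plan"
  )
}
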