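# Bioenergetic core: maintenance requirements and energy-allowable growth.
#
# All energy flows are expressed in Mcal/d at the function boundary; the
# maintenance equations are denominated in kcal internally and divided by
# 1000 on the way out.

#' Feeding stages
#'
#' A calf is in exactly one of two feeding stages on any simulated day:
#' `"preweaning"` (liquid diet, alone or with solid feed) or `"weaned"`
#' (fully transitioned to solid feed). The stage selects the empty-body-weight
#' conversion factor, the maintenance coefficient, and the efficiency of ME
#' use for maintenance.
#'
#' @format Character vector of the two valid stage labels.
#' @export
feeding_stages <- c("preweaning", "weaned")

check_stage <- function(stage) {
  if (!(is.character(stage) && length(stage) == 1L && stage %in% feeding_stages)) {
    stop("`stage` must be one of: ", paste(feeding_stages, collapse = ", "),
         call. = FALSE)
  }
  stage
}

#' Empty body weight from body weight
#'
#' Converts live body weight (BW) to empty body weight (EBW, gut-fill-free
#' mass) using the stage-specific factor: 0.91 for calves receiving milk or
#' milk replacer plus solid feed, 0.85 for fully weaned calves.
#'
#' @param bw Body weight, kg. Must be positive.
#' @param stage Feeding stage, one of [feeding_stages].
#' @return Empty body weight, kg.
#' @export
#' @examples
#' empty_body_weight(100, "preweaning") # 91
#' empty_body_weight(100, "weaned")     # 85
empty_body_weight <- function(bw, stage) {
  check_stage(stage)
  if (!is.numeric(bw) || any(!is.finite(bw)) || any(bw <= 0)) {
    stop("`bw` must be a positive finite number (kg).", call. = FALSE)
  }
  ebw_bw_factor(stage) * bw
}

#' @rdname empty_body_weight
#' @export
ebw_bw_factor <- function(stage) {
  check_stage(stage)
  if (stage == "preweaning") 0.91 else 0.85
}

#' Net energy required for maintenance
#'
#' NEM = 76.9 x EBW^0.75 kcal/d for preweaning calves and
#' NEM = 97.0 x EBW^0.75 kcal/d for weaned calves, returned in Mcal/d.
#'
#' @param ebw Empty body weight, kg. Must be positive.
#' @param stage Feeding stage, one of [feeding_stages].
#' @return Net energy for maintenance, Mcal/d.
#' @export
#' @examples
#' nem_requirement(1, "preweaning") # 0.0769 Mcal/d
#' nem_requirement(16, "preweaning") # 76.9 * 8 / 1000
nem_requirement <- function(ebw, stage) {
  check_stage(stage)
  if (!is.numeric(ebw) || any(!is.finite(ebw)) || any(ebw <= 0)) {
    stop("`ebw` must be a positive finite number (kg).", call. = FALSE)
  }
  coef <- if (stage == "preweaning") 76.9 else 97.0
  coef * ebw^0.75 / 1000
}

#' Efficiency of ME use for maintenance, preweaning
#'
#' Constant at 0.69 for calves on a liquid diet, so that MEm = NEM / 0.69.
#'
#' @return The fixed preweaning efficiency, 0.69.
#' @export
km_preweaning <- function() 0.69

#' Efficiency of ME use for maintenance, weaned
#'
#' For fully weaned calves the efficiency depends on the energy density of
#' the (solid) diet:
#' k_m = (1.1104 ME - 0.0946 ME^2 + 0.0065 ME^3 - 0.7783) / ME.
#'
#' The cubic is only meaningful over the dietary ME range typical of calf
#' starters (roughly 2.9-3.6 Mcal/kg DM). Outside that range it can escape
#' the physical interval, so the result is clamped into (0, 1] -- floor
#' 0.01, ceiling 1 -- with a warning.
#'
#' @param me_density Dietary metabolizable-energy density, Mcal/kg DM.
#'   Must be positive.
#' @return Efficiency of ME use for maintenance, a fraction in (0, 1].
#' @export
#' @examples
#' km_weaned(3.0) # about 0.6257
km_weaned <- function(me_density) {
  if (!is.numeric(me_density) || length(me_density) != 1L ||
      !is.finite(me_density) || me_density <= 0) {
    stop("`me_density` must be a positive finite number (Mcal/kg DM).",
         call. = FALSE)
  }
  km <- (1.1104 * me_density - 0.0946 * me_density^2 +
           0.0065 * me_density^3 - 0.7783) / me_density
  if (km > 1 || km <= 0) {
    warning("k_m = ", signif(km, 4), " at ME = ", me_density,
            " Mcal/kg DM is outside (0, 1]; clamped.", call. = FALSE)
    km <- min(max(km, 0.01), 1)
  }
  km
}

#' Metabolizable energy required for maintenance
#'
#' MEm = NEM / k_m.
#'
#' @param nem_value Net energy for maintenance, Mcal/d. Must be >= 0.
#' @param k_m Efficiency of ME use for maintenance, in (0, 1].
#' @return Metabolizable energy for maintenance, Mcal/d.
#' @export
mem_requirement <- function(nem_value, k_m) {
  if (!is.numeric(nem_value) || any(!is.finite(nem_value)) || any(nem_value < 0)) {
    stop("`nem_value` must be a non-negative finite number (Mcal/d).",
         call. = FALSE)
  }
  if (!is.numeric(k_m) || any(!is.finite(k_m)) || any(k_m <= 0) || any(k_m > 1)) {
    stop("`k_m` must lie in (0, 1].", call. = FALSE)
  }
  nem_value / k_m
}

#' Retained energy for a given empty-body-weight gain
#'
#' Forward form of the energy-retention equation:
#' RE (Mcal/d) = EBW gain^1.1 x EBW^0.205, with gain in kg/d and EBW in kg.
#' This is the algebraic inverse of [ebw_gain_from_ne()] and serves as its
#' round-trip oracle.
#'
#' @param ebw_gain Empty-body-weight gain, kg/d. Must be >= 0.
#' @param ebw Empty body weight, kg. Must be positive.
#' @return Retained energy, Mcal/d.
#' @export
retained_energy <- function(ebw_gain, ebw) {
  if (!is.numeric(ebw_gain) || any(!is.finite(ebw_gain)) || any(ebw_gain < 0)) {
    stop("`ebw_gain` must be a non-negative finite number (kg/d).", call. = FALSE)
  }
  if (!is.numeric(ebw) || any(!is.finite(ebw)) || any(ebw <= 0)) {
    stop("`ebw` must be a positive finite number (kg).", call. = FALSE)
  }
  ebw_gain^1.1 * ebw^0.205
}

#' Energy-allowable empty-body-weight gain
#'
#' Inverts the retention equation to get daily gain from the net energy
#' available for gain: gain = (NE / EBW^0.205)^(1/1.1).
#'
#' For a negative energy balance (NE < 0) the fractional power is undefined;
#' the odd-symmetric extension gain = -(|NE| / EBW^0.205)^(1/1.1) is used so
#' that restrictive feeding plans produce plausible weight loss. Callers that
#' need to flag the condition should test `ne_gain < 0` themselves.
#'
#' @param ne_gain Net energy available for gain, Mcal/d (may be negative).
#' @param ebw Empty body weight, kg. Must be positive.
#' @return Empty-body-weight gain, kg/d (negative under energy deficit).
#' @export
#' @examples
#' ebw_gain_from_ne(2.0, 50)
#' retained_energy(ebw_gain_from_ne(2.0, 50), 50) # 2.0, round trip
ebw_gain_from_ne <- function(ne_gain, ebw) {
  if (!is.numeric(ne_gain) || any(!is.finite(ne_gain))) {
    stop("`ne_gain` must be a finite number (Mcal/d).", call. = FALSE)
  }
  if (!is.numeric(ebw) || any(!is.finite(ebw)) || any(ebw <= 0)) {
    stop("`ebw` must be a positive finite number (kg).", call. = FALSE)
  }
  sign(ne_gain) * (abs(ne_gain) / ebw^0.205)^(1 / 1.1)
}

#' Daily energy budget
#'
#' Assembles the maintenance and gain side of one simulated day into a
#' single record: NEM, the stage-appropriate k_m, MEm, and the net energy
#' available for gain, ne_gain = (MEI - MEm) * k_g. The efficiency of ME use
#' for gain, k_g, is a configuration parameter (default 0.60) applied
#' symmetrically to surpluses and deficits.
#'
#' @param ebw Empty body weight, kg.
#' @param stage Feeding stage, one of [feeding_stages].
#' @param me_intake_total Total ME intake, Mcal/d.
#' @param diet_me_density Diet ME density, Mcal/kg DM; used only to evaluate
#'   the weaned-stage k_m. Ignored (may be `NA`) preweaning.
#' @param k_g Efficiency of ME use for gain, in (0, 1]. Default 0.60.
#' @return A list with elements `nem`, `k_m`, `mem`, `me_intake_total`,
#'   `ne_gain` (all energies Mcal/d).
#' @export
energy_budget <- function(ebw, stage, me_intake_total, diet_me_density = NA_real_,
                          k_g = 0.60) {
  check_stage(stage)
  if (!is.numeric(k_g) || length(k_g) != 1L || !is.finite(k_g) ||
      k_g <= 0 || k_g > 1) {
    stop("`k_g` must lie in (0, 1].", call. = FALSE)
  }
  nem <- nem_requirement(ebw, stage)
  k_m <- if (stage == "preweaning") {
    km_preweaning()
  } else {
    km_weaned(diet_me_density)
  }
  mem <- mem_requirement(nem, k_m)
  list(
    nem = nem,
    k_m = k_m,
    mem = mem,
    me_intake_total = me_intake_total,
    ne_gain = (me_intake_total - mem) * k_g
  )
}
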