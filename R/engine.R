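# Daily time-step simulation engine: scenario validation, the one-day state
# transition, full-horizon simulation, KPIs and scenario comparison.

#' Assemble a simulation scenario
#'
#' A scenario bundles everything needed to simulate one calf under one milk
#' allowance plan: the animal and environment, the liquid diet, the starter
#' feed, the plan itself, and the two configuration parameters the model
#' equations do not pin down (the efficiency of ME use for gain `k_g` and
#' the unit of the starter-exposure clock `fp_unit`).
#'
#' Input bounds are enforced at construction: initial BW 20-60 kg, ambient
#' temperature -30 to 50 degrees C, weaning age 10-120 d, horizon at most
#' 100 d. All violations are reported together.
#'
#' @param initial_bw Initial body weight, kg (20-60).
#' @param temperature Average ambient temperature, degrees C (-30 to 50).
#' @param weaning_age Weaning age, d (10-120).
#' @param liquid A [liquid_diet()].
#' @param starter A [starter_composition()].
#' @param allowance Milk allowance passed to [milk_plan()]: constant L/d,
#'   daily vector, or step-schedule data frame.
#' @param horizon Simulation horizon, d (1-100). Default 100.
#' @param k_g Efficiency of ME use for gain, in (0, 1]. Default 0.60.
#' @param fp_unit Unit of the starter-exposure clock, `"weeks"` (default)
#'   or `"days"`; see [starter_inputs()].
#' @param first_starter_offer_day Day of life starter is first offered.
#' @param label Scenario label used in comparisons.
#' @return An object of class `calf_scenario`.
#' @export
#' @examples
#' sc <- calf_scenario(initial_bw = 40, temperature = 20, weaning_age = 56,
#'                     liquid = liquid_diet("whole_milk"),
#'                     starter = starter_composition(),
#'                     allowance = 6)
calf_scenario <- function(initial_bw, temperature, weaning_age,
                          liquid = liquid_diet("whole_milk"),
                          starter = starter_composition(),
                          allowance = 6,
                          horizon = 100, k_g = 0.60,
                          fp_unit = c("weeks", "days"),
                          first_starter_offer_day = 3,
                          label = "scenario") {
  fp_unit <- match.arg(fp_unit)
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(initial_bw) && initial_bw >= 20 && initial_bw <= 60,
      sprintf("initial_bw = %s outside acceptable range 20 to 60 kg",
              format(initial_bw)))
  chk(is.numeric(temperature) && temperature >= -30 && temperature <= 50,
      sprintf("temperature = %s outside acceptable range -30 to 50 degrees C",
              format(temperature)))
  chk(is.numeric(weaning_age) && weaning_age >= 10 && weaning_age <= 120,
      sprintf("weaning_age = %s outside acceptable range 10 to 120 d",
              format(weaning_age)))
  chk(is.numeric(horizon) && horizon >= 1 && horizon <= 100,
      sprintf("horizon = %s outside acceptable range 1 to 100 d",
              format(horizon)))
  chk(is.numeric(k_g) && k_g > 0 && k_g <= 1,
      sprintf("k_g = %s outside (0, 1]", format(k_g)))
  chk(inherits(liquid, "liquid_diet"), "`liquid` is not a liquid_diet object")
  chk(inherits(starter, "starter_composition"),
      "`starter` is not a starter_composition object")
  if (length(problems) > 0) {
    stop("invalid scenario:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  plan <- milk_plan(allowance, weaning_age = weaning_age, horizon = horizon,
                    first_starter_offer_day = first_starter_offer_day)
  structure(
    list(initial_bw = initial_bw, temperature = temperature,
         weaning_age = weaning_age, liquid = liquid, starter = starter,
         plan = plan, horizon = horizon, k_g = k_g, fp_unit = fp_unit,
         first_starter_offer_day = first_starter_offer_day, label = label),
    class = "calf_scenario"
  )
}

#' Initial calf state for a scenario
#'
#' @param scenario A [calf_scenario()].
#' @return A list holding the recurrence state: `day`, `bw`, `cum_nfc`,
#'   `weaned`.
#' @export
initial_state <- function(scenario) {
  stopifnot(inherits(scenario, "calf_scenario"))
  list(day = 1L, bw = scenario$initial_bw, cum_nfc = 0, weaned = FALSE)
}

#' Advance the simulation by one day
#'
#' Composes the model equations into one day, in the order intake ->
#' digestion -> requirements -> gain, with body weight updated at day end:
#' liquid consumed (capped at 14 L) -> liquid DM and ME -> starter intake
#' under the climate-selected equation -> digestibilities at the current
#' cumulative NFC -> starter ME density -> energy budget (NEM, stage k_m,
#' MEm, NE for gain) -> EBW gain -> BW update -> cumulative NFC update ->
#' feed cost.
#'
#' The weaned stage (EBW factor 0.85, NEM coefficient 97.0, diet-dependent
#' k_m) begins on the first day with zero milk allowance at or after
#' `weaning_age`, and never reverts.
#'
#' @param state State list as returned by [initial_state()] or a previous
#'   `step_day()` call.
#' @param scenario A [calf_scenario()].
#' @return A list with `state` (advanced) and `record` (a one-row daily
#'   record as a list).
#' @export
step_day <- function(state, scenario) {
  stopifnot(inherits(scenario, "calf_scenario"))
  day <- state$day
  if (day > scenario$horizon) stop("state is past the scenario horizon.",
                                   call. = FALSE)
  offered <- scenario$plan$offered_l[day]
  weaned <- state$weaned || (day >= scenario$weaning_age && offered == 0)
  stage <- if (weaned) "weaned" else "preweaning"

  consumed <- liquid_consumed(offered)
  lq <- liquid_dm_and_me(consumed, scenario$liquid)

  first_offer <- scenario$first_starter_offer_day
  si_dm <- 0
  if (day >= first_offer) {
    fp_days <- day - first_offer
    si_g <- starter_intake(
      starter_inputs(state$bw, lq$me_i_ld, fp_days, scenario$fp_unit),
      scenario$temperature
    )
    si_dm <- si_g / 1000
  }

  d <- digestibilities(ln_ccs_nfci(state$cum_nfc), scenario$starter$form)
  me_dens_starter <- starter_me_density(scenario$starter, d)
  me_starter <- si_dm * me_dens_starter
  me_total <- lq$me_i_ld + me_starter
  total_dmi <- lq$dm + si_dm

  ebw <- empty_body_weight(state$bw, stage)
  budget <- energy_budget(ebw, stage, me_total,
                          diet_me_density = me_dens_starter,
                          k_g = scenario$k_g)
  ebw_gain <- ebw_gain_from_ne(budget$ne_gain, ebw)
  bw_gain <- ebw_gain / ebw_bw_factor(stage)
  # floor at 1 kg so the allometric terms stay defined under pathological
  # starvation scenarios
  bw_end <- max(state$bw + bw_gain, 1)

  cum_nfc <- nfc_accumulate(state$cum_nfc, si_dm, scenario$starter)
  cost <- consumed * scenario$liquid$cost_per_litre +
    si_dm / scenario$starter$dm_fraction * scenario$starter$cost_per_kg

  record <- list(
    day = day, stage = stage, bw = state$bw, bw_end = bw_end,
    liquid_offered = offered, liquid_consumed = consumed,
    liquid_dm = lq$dm, starter_dm = si_dm, total_dmi = total_dmi,
    me_liquid = lq$me_i_ld, me_starter = me_starter, me_total = me_total,
    starter_me_density = me_dens_starter,
    nem = budget$nem, mem = budget$mem, k_m = budget$k_m,
    ne_gain = budget$ne_gain, ebw_gain = ebw_gain, bw_gain = bw_gain,
    cum_nfc = cum_nfc, cost = cost,
    negative_balance = budget$ne_gain < 0
  )
  state <- list(day = day + 1L, bw = bw_end, cum_nfc = cum_nfc,
                weaned = weaned)
  list(state = state, record = record)
}

#' Simulate a calf over the scenario horizon
#'
#' Runs [step_day()] from day 1 to the horizon. The model is fully
#' deterministic: identical scenarios give identical trajectories.
#'
#' @param scenario A [calf_scenario()].
#' @return A tibble with one row per day (class `calf_trajectory`); the
#'   scenario is attached as attribute `"scenario"`. Column `bw` is body
#'   weight at the start of the day and `bw_end` at its end.
#' @export
#' @examples
#' sc <- calf_scenario(initial_bw = 40, temperature = 20, weaning_age = 56,
#'                     allowance = 6, horizon = 70)
#' traj <- simulate_calf(sc)
#' traj[traj$day %in% c(1, 56, 70), c("day", "bw", "starter_dm", "cum_nfc")]
simulate_calf <- function(scenario) {
  stopifnot(inherits(scenario, "calf_scenario"))
  state <- initial_state(scenario)
  records <- vector("list", scenario$horizon)
  for (day in seq_len(scenario$horizon)) {
    out <- step_day(state, scenario)
    records[[day]] <- out$record
    state <- out$state
  }
  traj <- tibble::as_tibble(do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
  attr(traj, "scenario") <- scenario
  class(traj) <- c("calf_trajectory", class(traj))
  traj
}

#' Predicted body weight at a given age
#'
#' Age 0 is the initial BW; age `a` (days) is BW at the end of day `a`.
#'
#' @param trajectory A [simulate_calf()] trajectory.
#' @param age Age in days (vectorised), within the simulated horizon.
#' @return Predicted BW, kg (NA for ages beyond the horizon).
#' @export
bw_at_age <- function(trajectory, age) {
  scenario <- attr(trajectory, "scenario")
  vapply(age, function(a) {
    if (a == 0) return(scenario$initial_bw)
    if (a < 0 || a > nrow(trajectory)) return(NA_real_)
    trajectory$bw_end[a]
  }, numeric(1))
}

#' Weaning-window and full-horizon KPIs
#'
#' Computes the four dashboard KPIs -- final BW (kg), average daily gain
#' (kg/d), the age at which cumulative starter-NFC intake reaches 15 kg
#' (d), and feed cost per kg of gain (currency/kg) -- plus total feed cost,
#' over two windows: days 1 to the weaning age ("until_weaning") and the
#' full simulated horizon ("full_horizon"). The 15-kg NFC age is a property
#' of the whole trajectory and is reported identically in both rows; it is
#' NA when never reached. Cost per kg gain is NA when total gain is not
#' positive.
#'
#' @param trajectory A [simulate_calf()] trajectory.
#' @param scenario The scenario; defaults to the one attached to the
#'   trajectory.
#' @return A tibble with columns `window`, `final_bw`, `adg`,
#'   `age_at_15kg_nfc`, `total_cost`, `cost_per_kg_gain`.
#' @export
calf_kpis <- function(trajectory, scenario = attr(trajectory, "scenario")) {
  stopifnot(nrow(trajectory) > 0, inherits(scenario, "calf_scenario"))
  nfc_day <- trajectory$day[trajectory$cum_nfc >= NFC_PLATEAU_KG]
  age_nfc <- if (length(nfc_day) > 0) min(nfc_day) else NA_real_
  one_window <- function(name, rows) {
    sub <- trajectory[rows, , drop = FALSE]
    final_bw <- sub$bw_end[nrow(sub)]
    gain <- final_bw - scenario$initial_bw
    total_cost <- sum(sub$cost)
    tibble::tibble(
      window = name,
      final_bw = final_bw,
      adg = gain / nrow(sub),
      age_at_15kg_nfc = age_nfc,
      total_cost = total_cost,
      cost_per_kg_gain = if (gain > 0) total_cost / gain else NA_real_
    )
  }
  wean_end <- min(scenario$weaning_age, nrow(trajectory))
  rbind(
    one_window("until_weaning", seq_len(wean_end)),
    one_window("full_horizon", seq_len(nrow(trajectory)))
  )
}

#' Compare up to four milk-plan scenarios
#'
#' Simulates each scenario and returns side-by-side KPI and trajectory
#' tables keyed by scenario label.
#'
#' @param scenarios A list of 1 to 4 [calf_scenario()] objects.
#' @return A list of class `calf_comparison` with elements `kpis` (tibble,
#'   one row per scenario x window) and `trajectories` (tibble, one row per
#'   scenario x day), both carrying a `label` column.
#' @export
compare_scenarios <- function(scenarios) {
  if (inherits(scenarios, "calf_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) < 1 || length(scenarios) > 4) {
    stop("between 1 and 4 scenarios can be compared (maximum of 4).",
         call. = FALSE)
  }
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  trajs <- lapply(scenarios, simulate_calf)
  kpis <- do.call(rbind, Map(function(tr, lab) {
    k <- calf_kpis(tr)
    k$label <- lab
    k[, c("label", setdiff(names(k), "label"))]
  }, trajs, labels))
  all_traj <- do.call(rbind, Map(function(tr, lab) {
    tr <- tibble::as_tibble(tr)
    tr$label <- lab
    tr[, c("label", setdiff(names(tr), "label"))]
  }, trajs, labels))
  structure(list(kpis = kpis, trajectories = all_traj,
                 labels = labels),
            class = "calf_comparison")
}

#' @export
print.calf_comparison <- function(x, ...) {
  cat("Comparison of", length(x$labels), "scenario(s):",
      paste(x$labels, collapse = ", "), "\n\n")
  print(x$kpis)
  invisible(x)
}
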