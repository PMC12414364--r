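# Shared fixtures: a default mid-range scenario and small variations.

default_scenario <- function(allowance = 6, weaning_age = 56, horizon = 84,
                             temperature = 20, initial_bw = 40,
                             form = "texturized", ...) {
  calf_scenario(
    initial_bw = initial_bw, temperature = temperature,
    weaning_age = weaning_age,
    liquid = liquid_diet("whole_milk", dm_fraction = 0.125,
                         me_density = 5.37, cost_per_litre = 0.45),
    starter = starter_composition(cp_fraction = 0.22, ndf_fraction = 0.15,
                                  fat_fraction = 0.04, ash_fraction = 0.07,
                                  dm_fraction = 0.90, form = form,
                                  cost_per_kg = 0.5),
    allowance = allowance, horizon = horizon, ...
  )
}

# a small flat observed-record row matching the interchange schema
flat_record <- function(study = "S01", treatment = "T1", age_d = 28,
                        observed_bw = 55, allowance_l = 6,
                        weaning_age = 56, horizon = 84) {
  tibble::tibble(
    study = study, treatment = treatment, age_d = age_d,
    observed_bw = observed_bw,
    initial_bw = 40, temperature = 20, weaning_age = weaning_age,
    allowance_l = allowance_l, horizon = horizon,
    liquid_kind = "whole_milk", liquid_dm_fraction = 0.125,
    liquid_me_density = 5.37, liquid_solids_per_litre = 0.125 * 1.03,
    liquid_cost_per_litre = 0.45,
    starter_cp = 0.22, starter_ndf = 0.15, starter_fat = 0.04,
    starter_ash = 0.07, starter_dm = 0.90, starter_form = "texturized",
    starter_cost_per_kg = 0.5,
    k_g = 0.60, fp_unit = "weeks", first_starter_offer_day = 3
  )
}
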