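# Daily time-step engine: state transition, trajectory, KPIs, comparison.

test_that("scenario validation reports every violated bound at once", {
  err <- tryCatch(
    calf_scenario(initial_bw = 19, temperature = 60, weaning_age = 5,
                  allowance = 6),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "20 to 60 kg")
  expect_match(err, "-30 to 50")
  expect_match(err, "10 to 120 d")
  expect_error(calf_scenario(40, 20, 56, horizon = 150), "1 to 100")
  expect_error(calf_scenario(40, 20, 56, k_g = 1.5), "0, 1")
  expect_silent(calf_scenario(40, 20, 56, allowance = 6))
})

test_that("one step equals the hand-composition of the module operations", {
  sc <- default_scenario(allowance = 6)
  st <- initial_state(sc)
  st$day <- 10L; st$bw <- 45; st$cum_nfc <- 0.8
  out <- step_day(st, sc)
  r <- out$record

  # hand composition on identical inputs
  consumed <- min(6, 14)
  lq <- liquid_dm_and_me(consumed, sc$liquid)
  si_g <- starter_intake_temperate(
    starter_inputs(45, lq$me_i_ld, 10 - 3, "weeks"))
  si_dm <- si_g / 1000
  d <- digestibilities(ln_ccs_nfci(0.8), "texturized")
  me_dens <- starter_me_density(sc$starter, d)
  me_total <- lq$me_i_ld + si_dm * me_dens
  ebw <- empty_body_weight(45, "preweaning")
  nem <- nem_requirement(ebw, "preweaning")
  mem <- mem_requirement(nem, 0.69)
  ne <- (me_total - mem) * 0.60
  gain <- ebw_gain_from_ne(ne, ebw)

  expect_equal(r$liquid_consumed, consumed)
  expect_equal(r$liquid_dm, lq$dm)
  expect_equal(r$me_liquid, lq$me_i_ld)
  expect_equal(r$starter_dm, si_dm)
  expect_equal(r$me_total, me_total)
  expect_equal(r$nem, nem)
  expect_equal(r$mem, mem)
  expect_equal(r$ne_gain, ne)
  expect_equal(r$ebw_gain, gain)
  expect_equal(r$bw_gain, gain / 0.91)
  expect_equal(r$cum_nfc, 0.8 + si_dm * 0.52)
  expect_equal(r$total_dmi, r$liquid_dm + r$starter_dm)
  expect_equal(r$cost, consumed * 0.45 + si_dm / 0.90 * 0.5)
})

test_that("oversized milk offers are consumed at the 14 L cap in the engine", {
  sc <- default_scenario(allowance = 20)
  r <- step_day(initial_state(sc), sc)$record
  expect_equal(r$liquid_offered, 20)
  expect_equal(r$liquid_consumed, 14)
})

test_that("a starvation day sets the negative-balance flag and loses weight", {
  sc <- default_scenario(allowance = 0, first_starter_offer_day = 90,
                         horizon = 30, weaning_age = 56)
  r <- step_day(initial_state(sc), sc)$record
  expect_true(r$negative_balance)
  expect_lt(r$bw_gain, 0)
  expect_lt(r$bw_end, sc$initial_bw)
})

test_that("simulation is deterministic and day-to-day changes stay bounded", {
  sc <- default_scenario()
  t1 <- simulate_calf(sc)
  t2 <- simulate_calf(sc)
  expect_identical(t1, t2)
  expect_true(all(abs(t1$bw_gain) < 3))
  expect_true(all(diff(t1$cum_nfc) >= 0))
  expect_equal(t1$bw[-1], t1$bw_end[-nrow(t1)]) # BW is continuous
  # per-day energy conservation: me_total - mem = ne_gain / k_g
  expect_equal(t1$me_total - t1$mem, t1$ne_gain / sc$k_g, tolerance = 1e-9)
})

test_that("the weaned stage switches every stage-dependent coefficient at once", {
  sc <- default_scenario(weaning_age = 56, horizon = 70)
  tr <- simulate_calf(sc)
  expect_true(all(tr$stage[tr$day < 56] == "preweaning"))
  expect_true(all(tr$stage[tr$day >= 56] == "weaned"))
  d55 <- tr[tr$day == 55, ]
  d56 <- tr[tr$day == 56, ]
  expect_equal(d55$k_m, 0.69)
  expect_equal(d56$k_m, km_weaned(d56$starter_me_density))
  expect_equal(d55$nem, nem_requirement(0.91 * d55$bw, "preweaning"))
  expect_equal(d56$nem, nem_requirement(0.85 * d56$bw, "weaned"))
})

test_that("milk still offered at the weaning age delays the stage switch", {
  # allowance vector that keeps milk flowing through day 60: weaning logic
  # only trips on the first zero-allowance day at/after weaning_age, but
  # milk_plan() itself zeroes allowance from weaning_age on
  sc <- default_scenario(weaning_age = 56, horizon = 60)
  expect_equal(sc$plan$offered_l[56], 0)
  tr <- simulate_calf(sc)
  expect_equal(tr$stage[tr$day == 56], "weaned")
})

test_that("more milk below the cap never reduces BW at weaning", {
  finals <- vapply(c(3, 4.5, 6, 9, 12), function(litres) {
    tr <- simulate_calf(default_scenario(allowance = litres, horizon = 56))
    tr$bw_end[56]
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("the fast trajectory path agrees with the full engine exactly", {
  grid <- list(
    default_scenario(allowance = 4, weaning_age = 42, horizon = 60),
    default_scenario(allowance = 10, weaning_age = 70, horizon = 90),
    default_scenario(allowance = 8, temperature = 40, horizon = 80),
    default_scenario(allowance = 6, form = "pelleted", horizon = 70),
    default_scenario(allowance = 13.5, weaning_age = 90, horizon = 100)
  )
  for (sc in grid) {
    tr <- simulate_calf(sc)
    fast <- simulate_bw(sc)
    expect_identical(fast$bw_end, tr$bw_end)
    expect_identical(fast$cum_nfc, tr$cum_nfc)
  }
})

test_that("BW extraction by age uses day-end weights with age 0 = initial", {
  sc <- default_scenario(horizon = 30)
  tr <- simulate_calf(sc)
  expect_equal(bw_at_age(tr, 0), 40)
  expect_equal(bw_at_age(tr, 7), tr$bw_end[7])
  expect_true(is.na(bw_at_age(tr, 31)))
})

test_that("KPIs compute the dashboard metrics from the trajectory", {
  sc <- default_scenario(weaning_age = 56, horizon = 84)
  tr <- simulate_calf(sc)
  k <- calf_kpis(tr)
  expect_setequal(k$window, c("until_weaning", "full_horizon"))
  uw <- k[k$window == "until_weaning", ]
  fh <- k[k$window == "full_horizon", ]
  expect_equal(uw$final_bw, tr$bw_end[56])
  expect_equal(uw$adg, (tr$bw_end[56] - 40) / 56)
  expect_equal(fh$final_bw, tr$bw_end[84])
  expect_equal(uw$total_cost, sum(tr$cost[1:56]))
  expect_equal(uw$cost_per_kg_gain, sum(tr$cost[1:56]) / (tr$bw_end[56] - 40))
  expect_equal(uw$age_at_15kg_nfc, min(tr$day[tr$cum_nfc >= 15]))
})

test_that("degenerate KPI cases are reported as undefined, not errors", {
  # hand-built flat trajectory: no gain, no starter
  sc <- default_scenario(weaning_age = 56, horizon = 10)
  tr <- simulate_calf(sc)
  tr$bw_end <- rep(40, 10)
  tr$cum_nfc <- rep(0, 10)
  k <- calf_kpis(tr, sc)
  expect_equal(k$adg, c(0, 0))
  expect_true(all(is.na(k$cost_per_kg_gain)))
  expect_true(all(is.na(k$age_at_15kg_nfc)))
  # hand-built linear 10-day trajectory 40 -> 45
  tr$bw_end <- seq(40.5, 45, by = 0.5)
  k2 <- calf_kpis(tr, sc)
  expect_equal(k2$adg[k2$window == "full_horizon"], 0.5)
})

test_that("comparison accepts 1-4 scenarios and is order-invariant", {
  scs <- lapply(c(4, 6, 8, 10), function(l) {
    default_scenario(allowance = l, horizon = 70,
                     label = paste0("plan_", l, "L"))
  })
  expect_error(compare_scenarios(c(scs, scs[1])), "maximum of 4")
  one <- compare_scenarios(scs[[1]])
  expect_equal(nrow(one$kpis), 2)
  cmp <- compare_scenarios(scs)
  rev_cmp <- compare_scenarios(rev(scs))
  expect_setequal(cmp$labels, rev_cmp$labels)
  for (lab in cmp$labels) {
    expect_equal(cmp$kpis[cmp$kpis$label == lab, ],
                 rev_cmp$kpis[rev_cmp$kpis$label == lab, ])
  }
})
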