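test_that("discounting at rate zero leaves accumulated time unchanged", {
  p <- base_params
  p$settings$discount_rate_annual <- param(0, "user")
  tr <- run_cohort(p, "lpd")
  for (st in c("pre_dialysis", "dialysis"))
    expect_equal(accumulate_time(tr, st, discounted = TRUE, params = p),
                 accumulate_time(tr, st, discounted = FALSE, params = p))
  expect_error(accumulate_time(tr, "limbo", params = p), "unknown state")
})

test_that("positive discounting strictly shrinks times, QALYs and every positive cost item", {
  p0 <- base_params
  p0$settings$discount_rate_annual <- param(0, "user")
  tr <- run_cohort(base_params, "svlpd")  # same trace either way: discounting is a reporting layer
  t_disc <- accumulate_time(tr, "dialysis", discounted = TRUE, params = base_params)
  t_undisc <- accumulate_time(tr, "dialysis", discounted = FALSE, params = base_params)
  expect_lt(t_disc, t_undisc)
  expect_lt(compute_qalys(tr, base_params), compute_qalys(tr, p0))
  c_disc <- strategy_costs(tr, base_params, "svlpd", "societal")
  c_undisc <- strategy_costs(tr, p0, "svlpd", "societal")
  pos <- c_undisc > 0
  expect_true(all(c_disc[pos] < c_undisc[pos]))
})

test_that("QALYs degenerate correctly at utility extremes", {
  p <- base_params
  for (u in names(p$utilities)) p$utilities[[u]] <- param(1, "user")
  p$settings$discount_rate_annual <- param(0, "user")
  tr <- run_cohort(p, "lpd")
  expect_equal(compute_qalys(tr, p),
               accumulate_time(tr, "pre_dialysis", params = p) +
                 accumulate_time(tr, "dialysis", params = p))
  for (u in names(p$utilities)) p$utilities[[u]] <- param(0, "user")
  expect_equal(compute_qalys(tr, p), 0)
})

test_that("dialysis monthly cost is the mix-weighted tariff plus amortized PD maintenance", {
  p <- base_params
  uc <- p$unit_costs; mx <- p$dialysis_mix
  expected <- mx$share_hd$value * uc$tariff_hd_monthly$value +
    mx$share_capd$value * uc$tariff_capd_monthly$value +
    mx$share_apd$value * uc$tariff_apd_monthly$value +
    uc$pd_annual_maintenance$value * (mx$share_capd$value + mx$share_apd$value) / 12
  expect_equal(dialysis_monthly_cost(p), expected)
  # pure-HD mix: the HD tariff exactly (no PD maintenance)
  p2 <- p
  p2$dialysis_mix$share_hd <- param(1, "user")
  p2$dialysis_mix$share_capd <- param(0, "user")
  p2$dialysis_mix$share_apd <- param(0, "user")
  expect_equal(dialysis_monthly_cost(p2), uc$tariff_hd_monthly$value)
  # equal tariffs: weighted mean collapses to the tariff plus amortization
  p3 <- p
  for (t in c("tariff_hd_monthly", "tariff_capd_monthly", "tariff_apd_monthly"))
    p3$unit_costs[[t]] <- param(1000, "user")
  expect_equal(dialysis_monthly_cost(p3),
               1000 + uc$pd_annual_maintenance$value * 0.162 / 12)
})

test_that("supplement monthly cost follows usage x dose x period x price arithmetic", {
  dpm <- 365.25 / 12
  zero <- base_params
  for (strat in c("lpd", "svlpd")) for (agent in names(zero$supplements[[strat]]))
    zero$supplements[[strat]][[agent]]$usage <- param(0, "user")
  expect_equal(supplement_monthly_cost(zero, "lpd"), 0)
  expect_equal(supplement_monthly_cost(zero, "svlpd"), 0)

  # LPD bicarbonate alone: 0.51 x 6.4 tablets/day x days/month x price
  p <- zero
  p$supplements$lpd$bicarbonate$usage <- param(0.51, "user")
  price_b <- p$unit_costs$price_bicarbonate$value
  expect_equal(supplement_monthly_cost(p, "lpd"), 0.51 * 6.4 * dpm * price_b)

  # s-VLPD vitamin D alone: 0.22 x 1 tablet/week x weeks/month x price
  p <- zero
  p$supplements$svlpd$vitamin_d$usage <- param(0.22, "user")
  price_v <- p$unit_costs$price_vitamin_d$value
  expect_equal(supplement_monthly_cost(p, "svlpd"), 0.22 * 1 * (dpm / 7) * price_v)

  # full default profile: sum over the three agents
  full <- base_params
  expected_lpd <- 0.51 * 6.4 * dpm * full$unit_costs$price_bicarbonate$value +
    0.54 * 1 * (dpm / 7) * full$unit_costs$price_vitamin_d$value +
    0.50 * 6.9 * dpm * full$unit_costs$price_calcium$value
  expect_equal(supplement_monthly_cost(full, "lpd"), expected_lpd)
})

test_that("cost accrual rules: ketoanalogues only for s-VLPD in pre-dialysis, items additive", {
  lpd <- base_run$lpd; svlpd <- base_run$svlpd
  expect_identical(unname(lpd$cost_items["ketoanalogue"]), 0)
  expect_gt(svlpd$cost_items[["ketoanalogue"]], 0)
  # monitoring: s-VLPD visits monthly vs bimonthly for LPD, scaled by pre-dialysis time
  expect_gt(svlpd$cost_items[["monitoring"]], lpd$cost_items[["monitoring"]])
  for (o in list(lpd, svlpd)) {
    expect_equal(o$total_cost, sum(o$cost_items))
    expect_equal(o$survival_years,
                 o$time_pre_dialysis_years + o$time_dialysis_years)
  }
  # no dialysis occupancy -> no dialysis cost
  p0 <- base_params
  p0$transitions$p_dialysis_annual_lpd <- param(0, "user")
  tr0 <- run_cohort(p0, "lpd")
  items0 <- strategy_costs(tr0, p0, "lpd", "nhs")
  expect_identical(unname(items0["dialysis"]), 0)
})

test_that("societal totals nest above payer totals and indirect costs favour s-VLPD", {
  soc <- run_societal(base_params)
  expect_gte(soc$lpd$total_cost, base_run$lpd$total_cost)
  expect_gte(soc$svlpd$total_cost, base_run$svlpd$total_cost)
  expect_gt(soc$lpd$cost_items[["indirect"]], soc$svlpd$cost_items[["indirect"]])
  # supplements are perspective-invariant by construction
  expect_equal(soc$lpd$cost_items[["other_supplements"]],
               base_run$lpd$cost_items[["other_supplements"]])
})

test_that("work-value lookup resolves gender/age bands and errors on a miss", {
  wv <- base_params$indirect$work_value$value
  expect_equal(work_value_lookup(base_params, "male", 70),
               wv$value[wv$gender == "male" & wv$age_min <= 70 & wv$age_max > 70])
  expect_error(work_value_lookup(base_params, "male", 500), "age = 500")
  expect_error(work_value_lookup(base_params, "unknown", 50), "gender = unknown")
})

test_that("indirect monthly cost matches its productivity + caregiver decomposition", {
  p <- base_params
  # no time lost and no caregivers: zero
  p0 <- p
  for (nm in c("time_lost_hd", "time_lost_capd", "time_lost_apd"))
    p0$indirect[[nm]] <- param(0, "user")
  p0$indirect$caregiver_need_fraction <- param(0, "user")
  expect_equal(indirect_monthly_cost(p0, 0), 0)
  # pure-HD mix, no caregiver: half the patient work value
  p1 <- p
  p1$dialysis_mix$share_hd <- param(1, "user")
  p1$dialysis_mix$share_capd <- param(0, "user")
  p1$dialysis_mix$share_apd <- param(0, "user")
  p1$indirect$caregiver_need_fraction <- param(0, "user")
  w <- p1$demographics$fraction_male$value * work_value_lookup(p1, "male", 70) +
    (1 - p1$demographics$fraction_male$value) * work_value_lookup(p1, "female", 72)
  expect_equal(indirect_monthly_cost(p1, 0), 0.5 * w)
  # caregiver term: need x (hours/reference week) x caregiver work value
  p2 <- p1
  for (nm in c("time_lost_hd", "time_lost_capd", "time_lost_apd"))
    p2$indirect[[nm]] <- param(0, "user")
  p2$indirect$caregiver_need_fraction <- param(0.245, "user")
  cg_w <- 0.58 * work_value_lookup(p2, "male", 51.7) +
    0.42 * work_value_lookup(p2, "female", 51.7)
  expect_equal(indirect_monthly_cost(p2, 0), 0.245 * (12 / 40) * cg_w)
  # patient ages advance with model time: the work value drops across bands
  expect_lt(indirect_monthly_cost(p1, 10 * 12), indirect_monthly_cost(p1, 0))
})
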