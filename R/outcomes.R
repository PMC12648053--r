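# From a cohort trace to life-years, QALYs and itemized discounted costs.

# per-interval discount factors, (1 + r)^(-months_elapsed/12), one per cycle,
# evaluated at the start of the interval
.disc_factors <- function(n_cycles, params, discounted = TRUE) {
  if (!discounted) return(rep(1, n_cycles))
  r <- params$settings$discount_rate_annual$value
  cl <- params$settings$cycle_length_months$value
  (1 + r)^(-((seq_len(n_cycles) - 1) * cl) / 12)
}

# per-interval occupancy weights for a set of state columns; with half-cycle
# correction the trapezoid of boundary occupancies, otherwise end-of-cycle
# occupancy
.occ_weights <- function(trace, cols, params) {
  occ <- trace$occupancy[, cols, drop = FALSE]
  tot <- rowSums(occ)
  n <- length(tot) - 1
  if (isTRUE(params$settings$half_cycle_correction$value))
    (tot[seq_len(n)] + tot[seq_len(n) + 1]) / 2
  else
    tot[seq_len(n) + 1]
}

# resolve a state name to trace columns ("pre_dialysis" aggregates every
# pre-dialysis compartment, e.g. the split compartments of the adherence arm)
.state_cols <- function(trace, state) {
  cols <- colnames(trace$occupancy)
  if (state %in% cols) return(state)
  if (state == "pre_dialysis") {
    hit <- grep("^pre", cols, value = TRUE)
    if (length(hit)) return(hit)
  }
  stop(sprintf("unknown state '%s'; trace has: %s", state, paste(cols, collapse = ", ")))
}

#' Expected time in a state from a cohort trace
#'
#' Sums corrected state occupancy over cycles, in years, optionally discounted
#' at the annual rate in the settings. With half-cycle correction (the
#' default) occupancy over a cycle is credited as the average of its start and
#' end boundary values, approximating mid-cycle transitions.
#'
#' @param trace A `cohort_trace`.
#' @param state `"pre_dialysis"`, `"dialysis"` or `"dead"` (pre-dialysis
#'   aggregates split pre-dialysis compartments where present).
#' @param discounted Apply the annual discount rate per cycle?
#' @param params The parameter set the trace was run under.
#' @return Expected years in the state.
#' @export
accumulate_time <- function(trace, state, discounted = FALSE, params) {
  cols <- .state_cols(trace, state)
  w <- .occ_weights(trace, cols, params)
  cl <- trace$cycle_months
  sum(w * (cl / 12) * .disc_factors(length(w), params, discounted))
}

#' Mix-weighted dialysis utility
#'
#' @param params A `ckdcea_params` object.
#' @return The dialysis-state utility: modality utilities weighted by the
#'   HD/CAPD/APD shares.
#' @export
dialysis_utility <- function(params) {
  mx <- params$dialysis_mix
  u <- params$utilities
  mx$share_hd$value * u$u_hd$value +
    mx$share_capd$value * u$u_capd$value +
    mx$share_apd$value * u$u_apd$value
}

#' Quality-adjusted life years from a cohort trace
#'
#' Discounted sum of occupancy times state utility times cycle length. The
#' dialysis utility is the modality-mix-weighted mean of the HD, CAPD and APD
#' utilities.
#'
#' @inheritParams accumulate_time
#' @return QALYs (discounted at the settings rate).
#' @export
compute_qalys <- function(trace, params) {
  u_pre <- params$utilities$u_pre$value
  u_dial <- dialysis_utility(params)
  u_pre * accumulate_time(trace, "pre_dialysis", discounted = TRUE, params = params) +
    u_dial * accumulate_time(trace, "dialysis", discounted = TRUE, params = params)
}

#' Monthly cost of the dialysis state
#'
#' Modality-share-weighted mean of the HD/CAPD/APD monthly tariffs, plus the
#' annual peritoneal-dialysis maintenance cost amortized monthly over the PD
#' share. The one-off catheter placement is charged separately on dialysis
#' entry (see [strategy_costs()]).
#'
#' @param params A `ckdcea_params` object.
#' @return EUR per patient-month in dialysis.
#' @export
dialysis_monthly_cost <- function(params) {
  mx <- params$dialysis_mix
  uc <- params$unit_costs
  pd_share <- mx$share_capd$value + mx$share_apd$value
  mx$share_hd$value * uc$tariff_hd_monthly$value +
    mx$share_capd$value * uc$tariff_capd_monthly$value +
    mx$share_apd$value * uc$tariff_apd_monthly$value +
    uc$pd_annual_maintenance$value * pd_share / 12
}

.days_per_month <- 365.25 / 12

#' Monthly cost of non-ketoanalogue supplements
#'
#' Sodium bicarbonate, vitamin D and calcium: usage fraction times dose per
#' month times unit price, summed over agents. Daily doses scale by 365.25/12
#' days per month, weekly doses by (365.25/12)/7 weeks per month.
#'
#' @param params A `ckdcea_params` object.
#' @param strategy `"lpd"` or `"svlpd"` (usage and doses differ by diet).
#' @return EUR per patient-month in the pre-dialysis state.
#' @export
supplement_monthly_cost <- function(params, strategy = c("lpd", "svlpd")) {
  strategy <- match.arg(strategy)
  prof <- params$supplements[[strategy]]
  uc <- params$unit_costs
  prices <- c(bicarbonate = uc$price_bicarbonate$value,
              vitamin_d = uc$price_vitamin_d$value,
              calcium = uc$price_calcium$value)
  total <- 0
  for (agent in names(prof)) {
    s <- prof[[agent]]
    per_month <- switch(s$period$value,
                        day = .days_per_month,
                        week = .days_per_month / 7,
                        stop(sprintf("unknown dose period '%s'", s$period$value)))
    total <- total + s$usage$value * s$dose$value * per_month * prices[[agent]]
  }
  total
}

#' Look up the monthly value of paid and unpaid work
#'
#' @param params A `ckdcea_params` object.
#' @param gender `"male"` or `"female"`.
#' @param age Age in years.
#' @return EUR per month.
#' @export
work_value_lookup <- function(params, gender, age) {
  wv <- params$indirect$work_value$value
  hit <- wv$gender == gender & wv$age_min <= age & age < wv$age_max
  if (!any(hit))
    stop(sprintf("no work value for (gender = %s, age = %.1f)", gender, age))
  wv$value[which(hit)[1]]
}

# cohort-weighted patient work value at a given model cycle (ages advance
# with model time)
.patient_work_value <- function(params, cycle) {
  dg <- params$demographics
  fm <- dg$fraction_male$value
  dt <- cycle * params$settings$cycle_length_months$value / 12
  fm * work_value_lookup(params, "male", dg$age_male$value + dt) +
    (1 - fm) * work_value_lookup(params, "female", dg$age_female$value + dt)
}

.caregiver_work_value <- function(params) {
  ind <- params$indirect
  fm <- ind$caregiver_fraction_male$value
  fm * work_value_lookup(params, "male", ind$caregiver_age$value) +
    (1 - fm) * work_value_lookup(params, "female", ind$caregiver_age$value)
}

#' Monthly indirect cost of the dialysis state (societal perspective)
#'
#' Productivity loss: modality-share-weighted fraction of the week lost to
#' dialysis times the cohort-weighted patient work value (patient ages advance
#' with model time). Informal care: the fraction of dialysis patients needing
#' a caregiver times the modality-weighted weekly care hours, expressed as a
#' fraction of the reference working week, valued at the caregiver work value.
#'
#' @param params A `ckdcea_params` object.
#' @param cycle Cycle index (0-based) at which the patient work value is
#'   looked up.
#' @return EUR per patient-month in dialysis.
#' @export
indirect_monthly_cost <- function(params, cycle = 0) {
  mx <- params$dialysis_mix
  ind <- params$indirect
  shares <- c(hd = mx$share_hd$value, capd = mx$share_capd$value, apd = mx$share_apd$value)
  lost <- c(hd = ind$time_lost_hd$value, capd = ind$time_lost_capd$value,
            apd = ind$time_lost_apd$value)
  productivity <- sum(shares * lost) * .patient_work_value(params, cycle)
  hours <- c(hd = ind$caregiver_hours_week_hd$value,
             capd = ind$caregiver_hours_week_pd$value,
             apd = ind$caregiver_hours_week_pd$value)
  caregiver <- ind$caregiver_need_fraction$value *
    sum(shares * hours / ind$reference_weekly_hours$value) *
    .caregiver_work_value(params)
  productivity + caregiver
}

# pre-dialysis cost-profile columns: which compartments accrue s-VLPD-profile
# costs (ketoanalogues, monthly monitoring, s-VLPD supplements) and which the
# LPD profile
.pre_profiles <- function(trace, strategy) {
  cols <- colnames(trace$occupancy)
  if ("pre_dialysis" %in% cols) {
    if (strategy == "svlpd") list(svlpd = "pre_dialysis", lpd = character(0))
    else list(svlpd = character(0), lpd = "pre_dialysis")
  } else {
    list(svlpd = intersect("pre_svlpd", cols), lpd = intersect("pre_switched", cols))
  }
}

# discounted patient-months in a set of columns (sum of corrected occupancy x
# discount factor); returns 0 for an empty column set
.disc_months <- function(trace, cols, params, weights = NULL) {
  if (!length(cols)) return(0)
  w <- .occ_weights(trace, cols, params)
  d <- .disc_factors(length(w), params)
  if (is.null(weights)) sum(w * d) * trace$cycle_months
  else sum(w * d * weights) * trace$cycle_months
}

#' Itemized discounted costs for one strategy arm
#'
#' Accrual rules: ketoanalogue supplementation (18 tablets/day) only while in
#' a pre-dialysis compartment on the s-VLPD regimen; diet monitoring in
#' pre-dialysis at one visit per month (s-VLPD) or one visit every two months
#' (LPD); the dialysis tariff while in dialysis; peritoneal-dialysis catheter
#' placement once per new dialysis entrant, weighted by the PD share and
#' discounted at the entry cycle; non-ketoanalogue supplements in
#' pre-dialysis; indirect costs (productivity loss and informal care) in
#' dialysis, only under the societal perspective. All items are discounted
#' per cycle at the settings rate.
#'
#' @param trace A `cohort_trace` for the arm.
#' @param params A `ckdcea_params` object.
#' @param strategy `"lpd"` or `"svlpd"`.
#' @param perspective `"nhs"` or `"societal"`.
#' @return Named numeric vector of cost items
#'   (ketoanalogue, monitoring, dialysis, other_supplements, indirect) in EUR.
#' @export
strategy_costs <- function(trace, params, strategy = c("lpd", "svlpd"),
                           perspective = c("nhs", "societal")) {
  strategy <- match.arg(strategy)
  perspective <- match.arg(perspective)
  uc <- params$unit_costs
  prof <- .pre_profiles(trace, strategy)

  months_svlpd <- .disc_months(trace, prof$svlpd, params)
  months_lpd <- .disc_months(trace, prof$lpd, params)
  months_dial <- .disc_months(trace, "dialysis", params)

  keto <- uc$ketoanalogue_per_tablet$value * uc$tablets_per_day_keto$value *
    .days_per_month * months_svlpd

  monitoring <- uc$monitoring_visit$value *
    (months_svlpd / uc$monitoring_interval_svlpd_months$value +
     months_lpd / uc$monitoring_interval_lpd_months$value)

  pd_share <- params$dialysis_mix$share_capd$value + params$dialysis_mix$share_apd$value
  n <- length(trace$new_dialysis)
  entry_disc <- .disc_factors(n, params)
  dialysis <- dialysis_monthly_cost(params) * months_dial +
    uc$pd_catheter_placement$value * pd_share * sum(trace$new_dialysis * entry_disc)

  other <- supplement_monthly_cost(params, "svlpd") * months_svlpd +
    supplement_monthly_cost(params, "lpd") * months_lpd

  indirect <- 0
  if (perspective == "societal") {
    w <- .occ_weights(trace, "dialysis", params)
    d <- .disc_factors(length(w), params)
    ind_m <- vapply(seq_along(w) - 1L, function(k) indirect_monthly_cost(params, k),
                    numeric(1))
    indirect <- sum(w * d * ind_m) * trace$cycle_months
  }

  c(ketoanalogue = keto, monitoring = monitoring, dialysis = dialysis,
    other_supplements = other, indirect = indirect)
}

#' Full outcome summary for one strategy arm
#'
#' @param trace A `cohort_trace`.
#' @param params A `ckdcea_params` object.
#' @param strategy `"lpd"` or `"svlpd"`.
#' @param perspective `"nhs"` or `"societal"`.
#' @return An `outcome_summary`: survival and per-state years (undiscounted by
#'   default; set `settings$discount_life_years` to discount them), discounted
#'   QALYs, itemized discounted costs and their total, and the perspective.
#' @export
strategy_outcomes <- function(trace, params, strategy = c("lpd", "svlpd"),
                              perspective = c("nhs", "societal")) {
  strategy <- match.arg(strategy)
  perspective <- match.arg(perspective)
  disc_ly <- isTRUE(params$settings$discount_life_years$value)
  t_pre <- accumulate_time(trace, "pre_dialysis", discounted = disc_ly, params = params)
  t_dial <- accumulate_time(trace, "dialysis", discounted = disc_ly, params = params)
  items <- strategy_costs(trace, params, strategy, perspective)
  structure(list(
    strategy = strategy,
    perspective = perspective,
    survival_years = t_pre + t_dial,
    time_pre_dialysis_years = t_pre,
    time_dialysis_years = t_dial,
    qalys = compute_qalys(trace, params),
    cost_items = items,
    total_cost = sum(items)
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %s arm, %s perspective\n", x$strategy, x$perspective))
  cat(sprintf("  survival %.2f y (pre-dialysis %.2f, dialysis %.2f), QALYs %.2f\n",
              x$survival_years, x$time_pre_dialysis_years, x$time_dialysis_years, x$qalys))
  cat(sprintf("  total cost EUR %.2f (%s)\n", x$total_cost,
              paste(sprintf("%s %.0f", names(x$cost_items), x$cost_items), collapse = ", ")))
  invisible(x)
}
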