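# Randomized-but-valid parameter sets for property-based testing.

# multiply a leaf's value by f, preserving its relative sensitivity range
.jitter_leaf <- function(p, f, clip = NULL, integer = FALSE) {
  v0 <- p$value
  v <- v0 * f
  if (integer) v <- max(1, round(v))
  if (!is.null(clip)) v <- min(max(v, clip[1]), clip[2])
  low <- high <- NULL
  if (!is.null(p$low) && v0 != 0) {
    low <- v * (p$low / v0)
    high <- v * (p$high / v0)
    if (!is.null(clip)) { low <- max(low, clip[1]); high <- min(high, clip[2]) }
    low <- min(low, v); high <- max(high, v)
  }
  param(v, p$provenance, low = low, high = high)
}

#' Generate a randomized valid parameter set
#'
#' Perturbs every substantive numeric input of the default set (transition
#' probabilities, hazard ratio, demographics, modality mix, unit costs,
#' supplement usage and doses, utilities, indirect-cost inputs, the adherence
#' fraction) by an independent multiplicative factor drawn uniformly from
#' `[1 - jitter, 1 + jitter]`, then clips and renormalizes so that every
#' structural invariant still holds: probabilities and utilities stay inside
#' their ranges, modality shares are renormalized to sum to one, monitoring
#' intervals stay positive integers. Model settings (cycle length, horizon,
#' discounting flags) are left untouched. The draw is fully determined by
#' `seed`; the caller's RNG state is restored on exit.
#'
#' @param seed Integer seed controlling the perturbation.
#' @param jitter Relative half-width of the perturbation, in `[0, 0.5]`.
#'   `jitter = 0` returns the default set exactly.
#' @return A validated `ckdcea_params` object with attribute
#'   `"perturbation_log"`: a data.frame of (parameter, base, factor, value).
#' @export
random_valid_parameters <- function(seed, jitter = 0.2) {
  stopifnot(jitter >= 0, jitter <= 0.5)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  params <- default_parameters()
  log_rows <- list()
  jit <- function(path, clip = NULL, integer = FALSE) {
    p <- params[[path]]
    f <- stats::runif(1, 1 - jitter, 1 + jitter)
    out <- .jitter_leaf(p, f, clip = clip, integer = integer)
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      parameter = paste(path, collapse = "$"), base = p$value,
      factor = f, value = out$value, stringsAsFactors = FALSE)
    params[[path]] <<- out
  }

  p_clip <- c(0, 0.99)   # keep annual probabilities strictly below 1
  u_clip <- c(0, 1)
  jit(c("transitions", "p_dialysis_annual_lpd"), clip = p_clip)
  jit(c("transitions", "hr_dialysis_svlpd"))
  jit(c("transitions", "p_death_pre_annual"), clip = p_clip)
  jit(c("transitions", "p_death_dialysis_annual"), clip = p_clip)
  jit(c("transitions", "p_death_dialysis_annual_scenario"), clip = p_clip)
  jit(c("demographics", "fraction_male"), clip = u_clip)
  jit(c("demographics", "age_male"))
  jit(c("demographics", "age_female"))
  for (s in c("share_hd", "share_capd", "share_apd"))
    jit(c("dialysis_mix", s), clip = u_clip)
  # renormalize the modality mix
  tot <- sum(vapply(c("share_hd", "share_capd", "share_apd"),
                    function(s) params$dialysis_mix[[s]]$value, numeric(1)))
  for (s in c("share_hd", "share_capd", "share_apd")) {
    p <- params$dialysis_mix[[s]]
    params$dialysis_mix[[s]] <- param(p$value / tot, p$provenance,
                                      low = if (is.null(p$low)) NULL else min(p$low / tot, p$value / tot),
                                      high = if (is.null(p$high)) NULL else max(p$high / tot, p$value / tot))
  }
  for (nm in setdiff(names(params$unit_costs),
                     c("monitoring_interval_svlpd_months", "monitoring_interval_lpd_months")))
    jit(c("unit_costs", nm))
  jit(c("unit_costs", "monitoring_interval_svlpd_months"), integer = TRUE)
  jit(c("unit_costs", "monitoring_interval_lpd_months"), integer = TRUE)
  for (strat in c("lpd", "svlpd")) for (agent in names(params$supplements[[strat]])) {
    jit(c("supplements", strat, agent, "usage"), clip = u_clip)
    jit(c("supplements", strat, agent, "dose"))
  }
  for (nm in names(params$utilities)) jit(c("utilities", nm), clip = u_clip)
  for (nm in c("time_lost_hd", "time_lost_capd", "time_lost_apd",
               "caregiver_need_fraction", "caregiver_employed_fraction",
               "caregiver_fraction_male"))
    jit(c("indirect", nm), clip = u_clip)
  for (nm in c("caregiver_hours_week_hd", "caregiver_hours_week_pd", "caregiver_age"))
    jit(c("indirect", nm))
  jit(c("adherence", "switch_fraction"), clip = u_clip)

  validate_parameters(params)
  attr(params, "perturbation_log") <- do.call(rbind, log_rows)
  attr(params, "seed") <- as.integer(seed)
  params
}
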