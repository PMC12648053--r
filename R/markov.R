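# Transition machinery: annual probabilities -> constant hazards -> per-cycle
# competing-risk transition matrices -> lifetime cohort trace.

#' Convert an annual probability to a constant hazard rate
#'
#' Under a constant-hazard (exponential) assumption the annual event
#' probability `p` corresponds to the rate `-log(1 - p)` per year.
#'
#' @param p_annual Probability per year in `[0, 1)`.
#' @return Rate per year.
#' @seealso [rate_to_prob()], its inverse.
#' @export
annual_prob_to_rate <- function(p_annual) {
  if (any(p_annual < 0) || any(p_annual >= 1))
    stop("annual probability must lie in [0, 1)")
  -log(1 - p_annual)
}

#' Convert a hazard rate to an event probability over a given period
#'
#' @param rate Rate per year, `>= 0`.
#' @param years Exposure period in years (default 1).
#' @return Probability of at least one event in the period.
#' @export
rate_to_prob <- function(rate, years = 1) {
  if (any(rate < 0)) stop("rate must be >= 0")
  1 - exp(-rate * years)
}

#' Apply a hazard ratio to an annual probability
#'
#' The ratio acts on the hazard scale: `p' = 1 - (1 - p)^hr`. A ratio of 1
#' leaves the probability unchanged; 0 removes the risk.
#'
#' @param p_annual Probability per year in `[0, 1)`.
#' @param hr Hazard ratio, `>= 0`.
#' @return Adjusted probability per year.
#' @export
apply_hazard_ratio <- function(p_annual, hr) {
  if (any(p_annual < 0) || any(p_annual >= 1))
    stop("annual probability must lie in [0, 1)")
  if (any(hr < 0)) stop("hazard ratio must be >= 0")
  1 - (1 - p_annual)^hr
}

#' Split competing exits within one cycle
#'
#' Competing risks within a cycle are handled by summing the annual hazards,
#' converting the summed hazard to a single per-cycle exit probability, and
#' allocating exits to destinations proportionally to their hazards — the
#' standard result for competing exponential risks.
#'
#' @param rates Numeric vector of competing annual rates, `>= 0`.
#' @param cycle_months Cycle length in months, `> 0`.
#' @return List with `p_exit` (total exit probability over the cycle) and
#'   `shares` (allocation proportions per destination; `NA` with
#'   `degenerate = TRUE` when all rates are zero).
#' @export
per_cycle_exit_split <- function(rates, cycle_months = 1) {
  if (any(rates < 0)) stop("rates must be >= 0")
  if (cycle_months <= 0) stop("cycle length must be > 0")
  total <- sum(rates)
  p_exit <- 1 - exp(-total * cycle_months / 12)
  if (total == 0)
    return(list(p_exit = 0, shares = rep(NA_real_, length(rates)), degenerate = TRUE))
  list(p_exit = p_exit, shares = rates / total, degenerate = FALSE)
}

# annual hazards for one strategy
.strategy_rates <- function(params, strategy = c("lpd", "svlpd"),
                            dialysis_mortality_annual = NULL) {
  strategy <- match.arg(strategy)
  tr <- params$transitions
  p_dial <- tr$p_dialysis_annual_lpd$value
  if (strategy == "svlpd")
    p_dial <- apply_hazard_ratio(p_dial, tr$hr_dialysis_svlpd$value)
  p_md <- if (is.null(dialysis_mortality_annual)) tr$p_death_dialysis_annual$value
          else dialysis_mortality_annual
  list(r_dialysis = annual_prob_to_rate(p_dial),
       r_death_pre = annual_prob_to_rate(tr$p_death_pre_annual$value),
       r_death_dialysis = annual_prob_to_rate(p_md))
}

#' Build the per-cycle transition matrix for one strategy
#'
#' Three states: pre-dialysis, dialysis, dead. Dead is absorbing; dialysis
#' allows no return to pre-dialysis. For the s-VLPD strategy the
#' pre-dialysis-to-dialysis probability is first scaled by the hazard ratio
#' (on the hazard scale), then converted to a rate; pre-dialysis exits compete
#' via [per_cycle_exit_split()].
#'
#' @param params A `ckdcea_params` object.
#' @param strategy `"lpd"` or `"svlpd"`.
#' @param dialysis_mortality_annual Optional override of the annual dialysis
#'   mortality probability (used by the mortality-benefit scenario).
#' @return A row-stochastic 3x3 matrix with dimnames
#'   `c("pre_dialysis", "dialysis", "dead")`.
#' @export
build_cycle_matrix <- function(params, strategy = c("lpd", "svlpd"),
                               dialysis_mortality_annual = NULL) {
  strategy <- match.arg(strategy)
  r <- .strategy_rates(params, strategy, dialysis_mortality_annual)
  cl <- params$settings$cycle_length_months$value
  sp <- per_cycle_exit_split(c(r$r_dialysis, r$r_death_pre), cl)
  p_pre_dial <- if (sp$degenerate) 0 else sp$p_exit * sp$shares[1]
  p_pre_dead <- if (sp$degenerate) 0 else sp$p_exit * sp$shares[2]
  p_dial_dead <- rate_to_prob(r$r_death_dialysis, cl / 12)
  states <- c("pre_dialysis", "dialysis", "dead")
  m <- matrix(0, 3, 3, dimnames = list(states, states))
  m["pre_dialysis", ] <- c(1 - p_pre_dial - p_pre_dead, p_pre_dial, p_pre_dead)
  m["dialysis", ] <- c(0, 1 - p_dial_dead, p_dial_dead)
  m["dead", "dead"] <- 1
  m
}

#' Run the lifetime cohort trace
#'
#' Starts the whole cohort in pre-dialysis and iterates the per-cycle matrix
#' until the alive fraction drops below `settings$stop_threshold_alive`
#' (default 1e-4) or `settings$horizon_max_cycles` (default 1440 cycles =
#' 120 years) is reached. The per-cycle flow of new dialysis entrants is
#' recorded — one-off peritoneal-dialysis costs are charged on it.
#'
#' @param params A `ckdcea_params` object.
#' @param strategy `"lpd"` or `"svlpd"`.
#' @param dialysis_mortality_annual Optional override passed to
#'   [build_cycle_matrix()].
#' @return A `cohort_trace` object: list with `occupancy` (matrix,
#'   `n_cycles + 1` rows of state fractions at cycle boundaries),
#'   `new_dialysis` (vector of length `n_cycles`, entrants during each cycle),
#'   `cycle_months`, `strategy` and `converged` (FALSE when the horizon cap
#'   was hit with the alive fraction still above threshold).
#' @export
run_cohort <- function(params, strategy = c("lpd", "svlpd"),
                       dialysis_mortality_annual = NULL) {
  strategy <- match.arg(strategy)
  m <- build_cycle_matrix(params, strategy, dialysis_mortality_annual)
  st <- params$settings
  horizon <- st$horizon_max_cycles$value
  thr <- st$stop_threshold_alive$value

  # the chain is time-homogeneous, so the trace has a closed recursion:
  # pre-dialysis decays geometrically and dialysis follows a linear
  # first-order recursion over the inflow
  a <- m["pre_dialysis", "pre_dialysis"]
  p12 <- m["pre_dialysis", "dialysis"]
  qd <- m["dialysis", "dialysis"]
  pre <- a^(0:horizon)                          # occupancy at cycle boundaries
  new_dial <- pre[seq_len(horizon)] * p12       # entrants during each cycle
  dial <- c(0, as.numeric(stats::filter(new_dial, qd, method = "recursive")))
  alive <- pre + dial
  hit <- which(alive < thr)
  n <- if (length(hit)) min(hit) - 1L else horizon
  idx <- seq_len(n + 1)
  occ <- cbind(pre_dialysis = pre[idx], dialysis = dial[idx],
               dead = 1 - alive[idx])
  structure(list(
    occupancy = occ,
    new_dialysis = new_dial[seq_len(n)],
    cycle_months = st$cycle_length_months$value,
    strategy = strategy,
    converged = alive[n + 1] < thr
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace> %s strategy, %d monthly cycles%s\n",
              x$strategy, n, if (x$converged) "" else " (horizon cap reached)"))
  cat(sprintf("  final occupancy: pre %.4g, dialysis %.4g, dead %.4g\n",
              x$occupancy[n + 1, 1], x$occupancy[n + 1, 2], x$occupancy[n + 1, 3]))
  invisible(x)
}

#' Export a cohort trace as a data.frame
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return Data frame with cycle index, month, state occupancies, new dialysis
#'   entrants during the preceding cycle, and cumulative deaths.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- nrow(x$occupancy)
  data.frame(
    cycle = seq_len(n) - 1L,
    month = (seq_len(n) - 1L) * x$cycle_months,
    x$occupancy,
    new_dialysis = c(0, x$new_dialysis),
    cum_deaths = x$occupancy[, "dead"],
    row.names = NULL
  )
}
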