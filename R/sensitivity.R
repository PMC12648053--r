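# One-way deterministic sensitivity analysis and probabilistic sensitivity
# analysis with CE plane, confidence ellipse and acceptability curve.

# Catalogue of sensitivity-eligible parameters. type:
#   "ci"   clinical efficacy / quality-of-life parameter varied at its 95% CI
#   "cost" cost-type parameter varied +/-20% (its stored range)
#   "mix"  dialysis-modality share, perturbed +/-20% then renormalized
.sensitivity_catalogue <- function() {
  rbind(
    data.frame(name = "p_dialysis_annual_lpd",
               path = I(list(c("transitions", "p_dialysis_annual_lpd"))), type = "ci"),
    data.frame(name = "hr_dialysis_svlpd",
               path = I(list(c("transitions", "hr_dialysis_svlpd"))), type = "hr"),
    data.frame(name = "p_death_pre_annual",
               path = I(list(c("transitions", "p_death_pre_annual"))), type = "ci"),
    data.frame(name = "p_death_dialysis_annual",
               path = I(list(c("transitions", "p_death_dialysis_annual"))), type = "ci"),
    data.frame(name = c("u_pre", "u_hd", "u_capd", "u_apd"),
               path = I(lapply(c("u_pre", "u_hd", "u_capd", "u_apd"),
                               function(u) c("utilities", u))), type = "ci"),
    data.frame(name = c("ketoanalogue_per_tablet", "monitoring_visit",
                        "tariff_hd_monthly", "tariff_capd_monthly",
                        "tariff_apd_monthly", "pd_catheter_placement",
                        "pd_annual_maintenance", "price_bicarbonate",
                        "price_vitamin_d", "price_calcium"),
               path = I(lapply(c("ketoanalogue_per_tablet", "monitoring_visit",
                                 "tariff_hd_monthly", "tariff_capd_monthly",
                                 "tariff_apd_monthly", "pd_catheter_placement",
                                 "pd_annual_maintenance", "price_bicarbonate",
                                 "price_vitamin_d", "price_calcium"),
                               function(u) c("unit_costs", u))), type = "cost"),
    data.frame(name = c("share_hd", "share_capd", "share_apd"),
               path = I(lapply(c("share_hd", "share_capd", "share_apd"),
                               function(s) c("dialysis_mix", s))), type = "mix")
  )
}

# set one share to a target value and renormalize the other two
# proportionally; the target is capped into [0, 1]
.perturb_mix <- function(params, share, value) {
  shares <- c("share_hd", "share_capd", "share_apd")
  value <- min(max(value, 0), 1)
  others <- setdiff(shares, share)
  rest <- sum(vapply(others, function(s) params$dialysis_mix[[s]]$value, numeric(1)))
  scale <- if (rest > 0) (1 - value) / rest else 0
  for (s in others) {
    p <- params$dialysis_mix[[s]]
    params$dialysis_mix[[s]] <- param(p$value * scale, p$provenance)
  }
  p <- params$dialysis_mix[[share]]
  params$dialysis_mix[[share]] <- param(value, p$provenance)
  params
}

# return a parameter set with one catalogue entry set to `value`
.apply_perturbation <- function(params, entry, value) {
  if (entry$type == "mix") return(.perturb_mix(params, entry$name, value))
  p <- params[[entry$path[[1]]]]
  params[[entry$path[[1]]]] <- param(value, p$provenance)
  params
}

#' One-way deterministic sensitivity analysis
#'
#' Varies one parameter at a time while holding the others at base case:
#' clinical efficacy and quality-of-life parameters across their 95% CI
#' limits, cost-type parameters and the dialysis-modality shares by +/-20%
#' (shares renormalized so the mix still sums to one). Parameters whose range
#' collapses to the point estimate are skipped with a message. Entries are
#' sorted by the incremental-cost swing for tornado display.
#'
#' @param params A `ckdcea_params` object.
#' @param perspective `"nhs"` or `"societal"`.
#' @return A `ckdcea_dsa` data.frame: parameter, type, low/high input values,
#'   and delta cost / delta QALY / delta survival at each bound, plus the
#'   base-case deltas as attributes.
#' @export
run_dsa <- function(params = default_parameters(), perspective = "nhs") {
  base <- run_base_case(params, perspective)$cea
  cat_df <- .sensitivity_catalogue()
  rows <- list()
  for (i in seq_len(nrow(cat_df))) {
    entry <- cat_df[i, ]
    p <- params[[entry$path[[1]]]]
    if (entry$type %in% c("cost", "mix") && is.null(p$low)) {
      lo <- p$value * 0.8; hi <- p$value * 1.2
    } else if (!is.null(p$low)) {
      lo <- p$low; hi <- p$high
    } else {
      message(sprintf("DSA: '%s' has no range; skipped", entry$name))
      next
    }
    if (lo == hi && lo == p$value) {
      rows[[length(rows) + 1]] <- data.frame(
        parameter = entry$name, type = entry$type, low = lo, high = hi,
        delta_cost_low = base$delta_cost, delta_cost_high = base$delta_cost,
        delta_qaly_low = base$delta_qaly, delta_qaly_high = base$delta_qaly,
        delta_survival_low = base$delta_survival,
        delta_survival_high = base$delta_survival)
      next
    }
    cea_lo <- run_base_case(.apply_perturbation(params, entry, lo), perspective)$cea
    cea_hi <- run_base_case(.apply_perturbation(params, entry, hi), perspective)$cea
    rows[[length(rows) + 1]] <- data.frame(
      parameter = entry$name, type = entry$type, low = lo, high = hi,
      delta_cost_low = cea_lo$delta_cost, delta_cost_high = cea_hi$delta_cost,
      delta_qaly_low = cea_lo$delta_qaly, delta_qaly_high = cea_hi$delta_qaly,
      delta_survival_low = cea_lo$delta_survival,
      delta_survival_high = cea_hi$delta_survival)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta_cost_high - out$delta_cost_low)), ]
  rownames(out) <- NULL
  attr(out, "base") <- base
  attr(out, "perspective") <- perspective
  class(out) <- c("ckdcea_dsa", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# probabilistic sensitivity analysis

# draw n values for one catalogue entry; the (low, high) range is read as a
# 95% interval, sd = (high - low)/3.92; a collapsed range gives a fixed draw
.draw_param <- function(entry, p, n) {
  m <- p$value
  if (is.null(p$low)) {
    if (entry$type %in% c("cost", "mix")) { lo <- m * 0.8; hi <- m * 1.2 }
    else return(rep(m, n))
  } else { lo <- p$low; hi <- p$high }
  s <- (hi - lo) / 3.92
  if (s == 0 || m == 0) return(rep(m, n))
  switch(entry$type,
    ci = {
      if (m <= 0 || m >= 1 || s^2 >= m * (1 - m))
        stop(sprintf("cannot moment-match a beta distribution for '%s'", entry$name))
      a <- m * (m * (1 - m) / s^2 - 1)
      b <- (1 - m) * (m * (1 - m) / s^2 - 1)
      stats::rbeta(n, a, b)
    },
    hr = {
      sdlog <- (log(hi) - log(lo)) / 3.92
      stats::rlnorm(n, meanlog = log(m), sdlog = sdlog)
    },
    cost = {
      shape <- (m / s)^2
      stats::rgamma(n, shape = shape, rate = shape / m)
    },
    stop(sprintf("no draw rule for type '%s'", entry$type))
  )
}

#' Sample probabilistic-sensitivity parameter draws
#'
#' Distribution families per parameter class: beta for probabilities and
#' utilities (moment-matched to the point estimate and its 95% interval),
#' log-normal for the hazard ratio, gamma for costs (the +/-20% range read as
#' a 95% interval), and Dirichlet for the dialysis-modality mix (concentration
#' matched so the HD share's spread equals its interval). A parameter whose
#' range collapses to the point estimate is held fixed, so fully degenerate
#' ranges reproduce the base case draw-for-draw. Draws are reproducible from
#' `seed`; the caller's RNG state is restored.
#'
#' @param params A `ckdcea_params` object.
#' @param n Number of draws (the reference analysis uses 1000).
#' @param seed Integer seed.
#' @return A `psa_draws` data.frame, one column per sampled parameter, with
#'   attributes `seed` and `n`.
#' @export
sample_psa <- function(params = default_parameters(), n = 1000, seed = 1) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cat_df <- .sensitivity_catalogue()
  draws <- list()
  mix_rows <- cat_df$type == "mix"
  for (i in which(!mix_rows)) {
    entry <- cat_df[i, ]
    draws[[entry$name]] <- .draw_param(entry, params[[entry$path[[1]]]], n)
  }
  # Dirichlet for the modality mix, concentration matched to the HD share's
  # 95% interval: sd^2 = p(1-p)/(k+1)
  shares <- vapply(c("share_hd", "share_capd", "share_apd"),
                   function(s) params$dialysis_mix[[s]]$value, numeric(1))
  hd <- params$dialysis_mix$share_hd
  s_hd <- if (is.null(hd$low)) 0 else (hd$high - hd$low) / 3.92
  if (s_hd > 0 && hd$value > 0 && hd$value < 1) {
    k <- hd$value * (1 - hd$value) / s_hd^2 - 1
    if (k <= 0) stop("cannot match a Dirichlet concentration for the dialysis mix")
    g <- vapply(shares * k, function(a) stats::rgamma(n, shape = a, rate = 1),
                numeric(n))
    g <- matrix(g, nrow = n)
    g <- g / rowSums(g)
    draws$share_hd <- g[, 1]; draws$share_capd <- g[, 2]; draws$share_apd <- g[, 3]
  } else {
    draws$share_hd <- rep(shares[1], n)
    draws$share_capd <- rep(shares[2], n)
    draws$share_apd <- rep(shares[3], n)
  }
  out <- as.data.frame(draws)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("psa_draws", "data.frame")
  out
}

# apply one PSA draw (a named row) to a parameter set
.apply_draw <- function(params, draw) {
  cat_df <- .sensitivity_catalogue()
  for (i in which(cat_df$type != "mix")) {
    entry <- cat_df[i, ]
    p <- params[[entry$path[[1]]]]
    params[[entry$path[[1]]]] <- param(draw[[entry$name]], p$provenance)
  }
  shares <- c(draw[["share_hd"]], draw[["share_capd"]], draw[["share_apd"]])
  shares <- shares / sum(shares)
  for (j in seq_along(shares)) {
    s <- c("share_hd", "share_capd", "share_apd")[j]
    p <- params$dialysis_mix[[s]]
    params$dialysis_mix[[s]] <- param(shares[j], p$provenance)
  }
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n` parameter draws with [sample_psa()], re-runs both strategy arms
#' for each draw and records the incremental (cost, QALY, survival) triple.
#'
#' @param params A `ckdcea_params` object.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @param perspective `"nhs"` or `"societal"`.
#' @return A `psa_result`: list with `draws` (the sampled parameters),
#'   `deltas` (per-draw data.frame of delta_cost, delta_qaly, delta_survival),
#'   `base` (the base-case `cea_result`), `seed`, `n`, `perspective`.
#' @export
run_psa <- function(params = default_parameters(), n = 1000, seed = 1,
                    perspective = "nhs") {
  draws <- sample_psa(params, n, seed)
  base <- run_base_case(params, perspective)$cea
  dc <- dq <- ds <- numeric(n)
  for (i in seq_len(n)) {
    cea_i <- run_base_case(.apply_draw(params, draws[i, , drop = FALSE]),
                           perspective)$cea
    dc[i] <- cea_i$delta_cost; dq[i] <- cea_i$delta_qaly; ds[i] <- cea_i$delta_survival
  }
  structure(list(
    draws = draws,
    deltas = data.frame(delta_cost = dc, delta_qaly = dq, delta_survival = ds),
    base = base, seed = as.integer(seed), n = as.integer(n),
    perspective = perspective
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d, %s perspective\n",
              x$n, x$seed, x$perspective))
  cat(sprintf("  delta cost: median %.0f [%.0f, %.0f] EUR\n",
              stats::median(x$deltas$delta_cost),
              stats::quantile(x$deltas$delta_cost, 0.025),
              stats::quantile(x$deltas$delta_cost, 0.975)))
  cat(sprintf("  delta QALY: median %.3f [%.3f, %.3f]\n",
              stats::median(x$deltas$delta_qaly),
              stats::quantile(x$deltas$delta_qaly, 0.025),
              stats::quantile(x$deltas$delta_qaly, 0.975)))
  cat(sprintf("  dominant in %.1f%% of draws\n",
              100 * mean(x$deltas$delta_cost < 0 & x$deltas$delta_qaly > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA draws with a
#' positive net monetary benefit.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid, EUR per QALY.
#' @return A `ckdcea_ceac` data.frame with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(nrow(psa$deltas) >= 1)
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$deltas$delta_qaly - psa$deltas$delta_cost > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("ckdcea_ceac", "data.frame")
  out
}

#' Confidence ellipse on the cost-effectiveness plane
#'
#' Normal-theory ellipse from the sample mean and covariance of the
#' (delta QALY, delta cost) pairs, scaled by the chi-square (2 df) quantile at
#' the coverage level. Axis lengths are the square roots of the scaled
#' covariance eigenvalues.
#'
#' @param psa A `psa_result` (needs at least 3 draws).
#' @param coverage Coverage probability (default 0.95).
#' @return List with `centre` (delta_qaly, delta_cost), `radii` (semi-axes,
#'   decreasing), `angle_rad` (orientation of the major axis), `cov`,
#'   `coverage` and `degenerate` (TRUE when the covariance is singular).
#' @export
confidence_ellipse <- function(psa, coverage = 0.95) {
  pts <- cbind(psa$deltas$delta_qaly, psa$deltas$delta_cost)
  if (nrow(pts) < 3) stop("need at least 3 draws for an ellipse")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- any(ev$values <= .Machine$double.eps * max(abs(ev$values), 1))
  q <- stats::qchisq(coverage, df = 2)
  radii <- sqrt(pmax(ev$values, 0) * q)
  list(centre = c(delta_qaly = ctr[1], delta_cost = ctr[2]),
       radii = radii,
       angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       cov = S, coverage = coverage, degenerate = degenerate)
}

#' Is a point inside a confidence ellipse?
#'
#' Mahalanobis test against the chi-square quantile backing the ellipse.
#'
#' @param ellipse Result of [confidence_ellipse()].
#' @param delta_qaly,delta_cost Coordinates of the point(s).
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, delta_qaly, delta_cost) {
  if (ellipse$degenerate) stop("ellipse is degenerate; containment undefined")
  pts <- cbind(delta_qaly - ellipse$centre[1], delta_cost - ellipse$centre[2])
  d2 <- rowSums((pts %*% solve(ellipse$cov)) * pts)
  d2 <= stats::qchisq(ellipse$coverage, df = 2)
}
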