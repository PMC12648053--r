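# Shared fixtures: the default parameter set and cached base-case runs.

base_params <- default_parameters()
base_run <- run_base_case(base_params, perspective = "nhs")

# continuous-time competing-risk closed forms used as the independent oracle:
# expected pre-dialysis time 1/(r_d + r_m), dialysis entry share
# r_d/(r_d + r_m), expected dialysis time share/r_md
closed_form_times <- function(p_dial_annual, p_death_pre_annual,
                              p_death_dial_annual, hr = 1) {
  r_d <- -log(1 - (1 - (1 - p_dial_annual)^hr))
  r_m <- -log(1 - p_death_pre_annual)
  r_md <- -log(1 - p_death_dial_annual)
  pre <- 1 / (r_d + r_m)
  share <- r_d / (r_d + r_m)
  list(pre = pre, share = share, dialysis = share / r_md)
}

# a parameter set with every sensitivity range collapsed onto the point
# estimate (fully degenerate uncertainty)
degenerate_params <- function(params = default_parameters()) {
  squash <- function(x) {
    if (inherits(x, "ckdcea_param")) {
      if (is.numeric(x$value) && length(x$value) == 1) {
        x$low <- x$value; x$high <- x$value
      } else {
        x$low <- NULL; x$high <- NULL
      }
      return(x)
    }
    lapply_keep <- lapply(x, squash)
    attributes(lapply_keep) <- attributes(x)
    lapply_keep
  }
  out <- squash(params)
  class(out) <- "ckdcea_params"
  out
}
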