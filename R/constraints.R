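#' Biophysical constraint specification
#'
#' The two default constraints of the checkpoint: (C1) the survival
#' probability at the end of the attachment phase must stay high,
#' `P(tau1) >= p_threshold` with `tau1` = 20 min and threshold 0.95; and
#' (C2) once the checkpoint lifts, the mean time to activate all targets
#' must be short, `tau <= tau_prime` with `tau_prime` = 10 min.
#'
#' @param tau1_s Checkpoint duration (s), default 1200.
#' @param p_threshold Minimum survival probability at `tau1_s`,
#'   default 0.95.
#' @param tau_prime_s Maximum admissible mean activation time (s),
#'   default 600.
#' @return A one-row tibble of class `constraint_spec`.
#' @export
constraint_spec <- function(tau1_s = 1200, p_threshold = 0.95,
                            tau_prime_s = 600) {
  check_scalar(tau1_s, "tau1_s")
  check_scalar(tau_prime_s, "tau_prime_s")
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold >= 1) {
    stop_invalid("`p_threshold` must lie in (0, 1).")
  }
  one_row("constraint_spec", tau1_s = tau1_s, p_threshold = p_threshold,
          tau_prime_s = tau_prime_s)
}

as_constraint_spec <- function(spec) {
  if (is.null(spec)) return(constraint_spec())
  if (!is.data.frame(spec) || nrow(spec) != 1L) {
    stop_invalid("`spec` must be a one-row `constraint_spec`.")
  }
  constraint_spec(field(spec, "tau1_s"), field(spec, "p_threshold"),
                  field(spec, "tau_prime_s"))
}

# tau with the divergent case mapped to Inf
activation_time_or_inf <- function(params) {
  tryCatch(
    mean_activation_time(params),
    sacr_divergent_mean_time = function(e) Inf
  )
}

#' Evaluate the checkpoint constraints at one parameter point
#'
#' Computes the survival probability at the checkpoint duration and the
#' mean activation time at anaphase onset, and tests them against the two
#' constraints C1 (`survival >= p_threshold`) and C2
#' (`tau <= tau_prime_s`). A divergent activation time (`lambda = 0`) is
#' reported as `Inf` and fails C2.
#'
#' @param params A [rate_parameters()] row.
#' @param spec A [constraint_spec()]; `NULL` for the defaults.
#' @return A one-row tibble with columns `lambdaS`, `k_minus1`,
#'   `survival_at_tau1`, `tau_s`, `c1`, `c2`, `in_omega`, `rho`.
#' @examples
#' evaluate_constraints(default_ptk2_parameters())
#' @export
evaluate_constraints <- function(params, spec = NULL) {
  p <- as_sac_params(params)
  cs <- as_constraint_spec(spec)
  surv <- survival_probability(p, cs$tau1_s)
  tau <- activation_time_or_inf(p)
  tibble(
    lambdaS = p$lambdaS,
    k_minus1 = p$k_minus1,
    survival_at_tau1 = surv,
    tau_s = tau,
    c1 = surv >= cs$p_threshold,
    c2 = tau <= cs$tau_prime_s,
    in_omega = surv >= cs$p_threshold && tau <= cs$tau_prime_s,
    rho = if (p$lambdaS > 0) p$k_minus1 / p$lambdaS else NA_real_
  )
}

#' Scan the (lambda*S, k_minus1) admissibility domain
#'
#' Evaluates both constraints on the grid of aggregate production rates
#' `lambdaS_axis` by inhibition rates `k_minus1_axis`, holding `mu`, `N`,
#' `S` fixed at `base_params` (internally `lambda = lambdaS/S`). The
#' admissible domain Omega is the intersection of the C1 and C2 regions;
#' along each fixed-`k_minus1` row it is an interval in `lambdaS`, since
#' survival decreases and `tau` decreases with `lambda`.
#'
#' The default axes cover `lambdaS` in `[0.01, 2]` and `k_minus1` in
#' `[0.1, 100]` with 41 log-spaced points each.
#'
#' @param lambdaS_axis Strictly increasing positive grid of `lambda*S`
#'   values (s^-1).
#' @param k_minus1_axis Strictly increasing positive grid of `k_minus1`
#'   values (s^-1).
#' @param base_params A [rate_parameters()] row supplying `mu`, `N`, `S`.
#' @param spec A [constraint_spec()]; `NULL` for defaults.
#' @return A long-format tibble of class `sac_domain` with one row per grid
#'   node: `lambdaS`, `k_minus1`, `survival_at_tau1`, `tau_s`, `c1`, `c2`,
#'   `in_omega`, `rho`.
#' @examples
#' \donttest{
#' scan_domain(c(0.1, 0.3, 1), c(10, 24, 50))
#' }
#' @export
scan_domain <- function(lambdaS_axis = NULL, k_minus1_axis = NULL,
                        base_params = default_ptk2_parameters(),
                        spec = NULL) {
  if (is.null(lambdaS_axis)) {
    lambdaS_axis <- exp(seq(log(0.01), log(2), length.out = 41L))
  }
  if (is.null(k_minus1_axis)) {
    k_minus1_axis <- exp(seq(log(0.1), log(100), length.out = 41L))
  }
  for (ax in list(lambdaS_axis, k_minus1_axis)) {
    if (length(ax) < 1L || any(ax <= 0) || is.unsorted(ax, strictly = TRUE)) {
      stop_invalid("axes must be strictly increasing and positive.")
    }
  }
  bp <- as_sac_params(base_params)
  cs <- as_constraint_spec(spec)

  grid <- tidyr::expand_grid(k_minus1 = k_minus1_axis, lambdaS = lambdaS_axis)
  rows <- purrr::pmap(grid, function(k_minus1, lambdaS) {
    p <- rate_parameters(lambda = lambdaS / bp$S, k_minus1 = k_minus1,
                         mu = bp$mu, N = bp$N, S = bp$S)
    evaluate_constraints(p, cs)
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    base_params = bp, spec = cs,
    lambdaS_axis = lambdaS_axis, k_minus1_axis = k_minus1_axis,
    class = c("sac_domain", class(tibble()))
  )
}

#' Level-curve boundary of a constraint at fixed k_minus1
#'
#' Locates, by bisection on `lambdaS`, the level line of one constraint at
#' a fixed inhibition rate: for `which = "c1"` the production rate at which
#' `P(tau1) = p_threshold`, and for `which = "c2"` the rate at which
#' `tau = tau_prime_s`. Bisection is used deliberately (rather than a
#' superlinear root finder) so the returned bracket width is exactly
#' `bracket_width / 2^n`: halving `tol` adds one step.
#'
#' @param k_minus1 Inhibition rate (s^-1) at which to slice the domain.
#' @param which `"c1"` (survival level line) or `"c2"` (timing level line).
#' @param spec A [constraint_spec()]; `NULL` for defaults.
#' @param base_params A [rate_parameters()] row supplying `mu`, `N`, `S`.
#' @param tol Absolute tolerance on `lambdaS` (s^-1).
#' @param bracket Search interval for `lambdaS` (s^-1); the constraint must
#'   change truth value across it.
#' @return The boundary `lambdaS` value (midpoint of the final bracket).
#' @export
boundary_lambdaS <- function(k_minus1, which = c("c1", "c2"), spec = NULL,
                             base_params = default_ptk2_parameters(),
                             tol = 1e-4, bracket = c(1e-3, 5)) {
  which <- match.arg(which)
  check_scalar(k_minus1, "k_minus1", allow_zero = TRUE)
  check_scalar(tol, "tol")
  if (length(bracket) != 2L || bracket[1] <= 0 || bracket[2] <= bracket[1]) {
    stop_invalid("`bracket` must be an increasing positive pair.")
  }
  bp <- as_sac_params(base_params)
  cs <- as_constraint_spec(spec)

  f <- function(lambdaS) {
    p <- rate_parameters(lambda = lambdaS / bp$S, k_minus1 = k_minus1,
                         mu = bp$mu, N = bp$N, S = bp$S)
    if (which == "c1") {
      survival_probability(p, cs$tau1_s) - cs$p_threshold
    } else {
      tau <- activation_time_or_inf(p)
      if (!is.finite(tau)) return(-Inf) # below boundary: too slow
      cs$tau_prime_s - tau
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    abort(sprintf(
      "constraint `%s` does not change sign on [%g, %g] at k_minus1 = %g.",
      which, lo, hi, k_minus1
    ), class = "sacr_bracket_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Inhibition-to-production ratio rho
#'
#' The dimensionless ratio `rho = k_minus1 / (lambda*S)` summarising
#' inhibition strength relative to the aggregate production rate; the
#' admissible domain is (approximately) a band in `rho`.
#'
#' @param params A [rate_parameters()] row.
#' @return `rho` (dimensionless).
#' @examples
#' rho(default_ptk2_parameters()) # 80
#' @export
rho <- function(params) {
  p <- as_sac_params(params)
  if (p$lambdaS <= 0) {
    abort("rho is undefined for lambda = 0.", class = "sacr_undefined_ratio")
  }
  p$k_minus1 / p$lambdaS
}

#' @export
glance.sac_domain <- function(x, ...) {
  inside <- dplyr::filter(as_tibble(x), .data$in_omega)
  tibble(
    n_nodes = nrow(x),
    n_in_omega = nrow(inside),
    lambdaS_min = if (nrow(inside)) min(inside$lambdaS) else NA_real_,
    lambdaS_max = if (nrow(inside)) max(inside$lambdaS) else NA_real_,
    rho_min = if (nrow(inside)) min(inside$rho) else NA_real_,
    rho_max = if (nrow(inside)) max(inside$rho) else NA_real_
  )
}

#' @export
tidy.sac_domain <- function(x, ...) {
  as_tibble(x)
}

#' @export
autoplot.sac_domain <- function(object, ...) {
  d <- dplyr::mutate(
    as_tibble(object),
    region = dplyr::case_when(
      .data$in_omega ~ "Omega (C1 & C2)",
      .data$c1 ~ "C1 only",
      .data$c2 ~ "C2 only",
      TRUE ~ "neither"
    )
  )
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$lambdaS, y = .data$k_minus1,
                    fill = .data$region)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda * S ~ (s^-1)),
                  y = expression(k[-1] ~ (s^-1)), fill = NULL)
}
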