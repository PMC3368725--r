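#' Equilibrium distribution of free Cdc20 under the checkpoint
#'
#' While the checkpoint holds (conditioned on no activation having
#' occurred), free Cdc20 follows a birth-death chain with birth rate
#' `lambda*(S-k)` and death rate `k_minus1*k`; the absorption channel drops
#' out of the conditioned dynamics. Its stationary law is binomial with `S`
#' trials and success probability `lambda/(lambda + k_minus1)`, with mean
#' `S*lambda/(lambda + k_minus1)`. This distribution is the initial
#' condition for the activation phase at anaphase onset
#' (see [occupation_times()]).
#'
#' Probabilities are computed through [stats::dbinom()] (log-gamma path),
#' which is overflow-safe at `S` in the thousands.
#'
#' @param params A [rate_parameters()] row with `k_minus1 > 0`.
#' @param degenerate_ok If `TRUE` and `k_minus1 = 0` with `lambda > 0`,
#'   return the degenerate point mass at `k = S` instead of erroring (with
#'   no destruction, all complexes eventually dissociate).
#' @return A tibble of class `sac_equilibrium` with columns `k` (0..S) and
#'   `probability`; attributes `params`, `mean`, `success_prob`.
#' @examples
#' eq <- equilibrium_distribution(default_ptk2_parameters())
#' glance(eq) # mean ~ 0.0125 molecules
#' @export
equilibrium_distribution <- function(params, degenerate_ok = FALSE) {
  p <- as_sac_params(params)
  if (p$k_minus1 == 0 && p$lambda > 0) {
    if (!degenerate_ok) {
      abort(paste0(
        "no stationary distribution: k_minus1 = 0 with lambda > 0 drives ",
        "all mass to k = S (set `degenerate_ok = TRUE` for the point mass)."
      ), class = "sacr_no_stationary_distribution")
    }
    prob <- 1
  } else if (p$lambda == 0) {
    prob <- 0
  } else {
    prob <- p$lambda / (p$lambda + p$k_minus1)
  }
  pmf <- dbinom(0:p$S, p$S, prob)
  structure(
    tibble(k = 0:p$S, probability = pmf),
    params = p,
    mean = p$S * prob,
    success_prob = prob,
    class = c("sac_equilibrium", class(tibble()))
  )
}

#' Stationarity residual of an equilibrium distribution
#'
#' Verifies that a probability vector annihilates the generator of the
#' conditioned birth-death chain: for each state the net probability flow
#' `lambda*(S-k+1) p[k-1] + k_minus1*(k+1) p[k+1] - (lambda*(S-k) + k_minus1*k) p[k]`
#' must vanish. Returns the maximum absolute row residual divided by the
#' largest total exit rate, so a correct stationary law scores at
#' floating-point rounding level (<= 1e-10) regardless of rate units.
#'
#' @param dist A [equilibrium_distribution()] result (or any tibble with
#'   columns `k`, `probability` plus a `params` attribute).
#' @return The relative stationarity residual (dimensionless scalar).
#' @export
stationarity_residual <- function(dist) {
  p <- attr(dist, "params")
  if (is.null(p)) stop_invalid("`dist` must carry a `params` attribute.")
  pmf <- dist$probability
  S <- p$S
  k <- 0:S
  out_rate <- p$lambda * (S - k) + p$k_minus1 * k
  flow_in <- numeric(S + 1)
  flow_in[-1L] <- flow_in[-1L] + p$lambda * (S - k[-1L] + 1) * pmf[-(S + 1L)]
  flow_in[-(S + 1L)] <- flow_in[-(S + 1L)] + p$k_minus1 * (k[-(S + 1L)] + 1) * pmf[-1L]
  resid <- abs(flow_in - out_rate * pmf)
  max(resid) / max(out_rate)
}

#' Relaxation time of the conditioned Cdc20 chain
#'
#' The conditioned birth-death chain relaxes to its binomial equilibrium
#' with slowest eigenvalue `lambda + k_minus1`; the associated e-folding
#' time `1/(lambda + k_minus1)` indicates how long the checkpoint must last
#' for the equilibrium initial condition of the activation phase to be
#' adequate. No hard threshold is imposed; this is a diagnostic.
#'
#' @param params A [rate_parameters()] row.
#' @return Relaxation time (s).
#' @export
equilibrium_relaxation_time <- function(params) {
  p <- as_sac_params(params)
  if (p$lambda + p$k_minus1 <= 0) return(Inf)
  1 / (p$lambda + p$k_minus1)
}

#' @export
tidy.sac_equilibrium <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sac_equilibrium <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    mean = attr(x, "mean"),
    success_prob = attr(x, "success_prob"),
    S = p$S, lambda = p$lambda, k_minus1 = p$k_minus1,
    relaxation_time_s = equilibrium_relaxation_time(p)
  )
}

#' @export
autoplot.sac_equilibrium <- function(object, max_k = NULL, ...) {
  d <- as_tibble(object)
  if (is.null(max_k)) {
    nz <- which(d$probability > 1e-12)
    max_k <- min(max(d$k), max(d$k[nz]) + 2L)
  }
  ggplot2::ggplot(
    dplyr::filter(d, .data$k <= max_k),
    ggplot2::aes(x = .data$k, y = .data$probability)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "free Cdc20 molecules", y = "stationary probability")
}
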