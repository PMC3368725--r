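#' Characteristic roots of the checkpoint generating-function ODE
#'
#' The probability generating function of the inhibition-phase chain
#' propagates along characteristics governed by a Riccati equation whose
#' linearisation has the quadratic characteristic polynomial
#' `X^2 - (-lambda + mu*N + k_minus1) X - k_minus1*lambda`. Its two real
#' roots `r1 >= r2` determine the closed-form survival probability.
#'
#' The smaller root is evaluated through the product relation
#' `r1*r2 = -k_minus1*lambda` (and `lambda + r2` through
#' `(lambda+r1)(lambda+r2) = lambda*mu*N`) rather than by subtracting the
#' discriminant, which would cancel catastrophically when
#' `k_minus1 >> lambda` — exactly the biologically relevant regime.
#'
#' @param params A [rate_parameters()] row.
#' @return A list of class `sac_roots` with elements `r1`, `r2`,
#'   `lambda_plus_r1`, `lambda_plus_r2`, `sum`, `product`, `discriminant`.
#' @examples
#' characteristic_roots(default_ptk2_parameters())
#' @export
characteristic_roots <- function(params) {
  p <- as_sac_params(params)
  lam <- p$lambda; k1 <- p$k_minus1; muN <- p$mu * p$N
  b <- -lam + muN + k1 # sum of roots
  disc <- b^2 + 4 * k1 * lam
  sq <- sqrt(disc)
  if (k1 * lam > 0) {
    r1 <- (b + sq) / 2
    r2 <- -k1 * lam / r1
  } else {
    # product of roots is zero: one root is b, the other 0
    r1 <- max(b, 0)
    r2 <- min(b, 0)
  }
  lp1 <- lam + r1 # positive whenever any rate is non-zero
  lp2 <- if (lp1 > 0) lam * muN / lp1 else 0 # lambda + r2, no cancellation
  structure(
    list(
      r1 = r1, r2 = r2,
      lambda_plus_r1 = lp1, lambda_plus_r2 = lp2,
      sum = b, product = -k1 * lam, discriminant = disc
    ),
    class = "sac_roots"
  )
}

#' @export
print.sac_roots <- function(x, ...) {
  cat(sprintf("<sac_roots>  r1 = %.10g, r2 = %.10g\n", x$r1, x$r2))
  invisible(x)
}

#' @export
tidy.sac_roots <- function(x, ...) {
  tibble(term = c("r1", "r2"), estimate = c(x$r1, x$r2), unit = "1/s")
}

# log of the single-complex survival factor B(t); P(t) = B(t)^S.
# B(t) = ((l+r1) e^{-(l+r2)t} - (l+r2) e^{-(l+r1)t}) / (r1 - r2), rewritten
# as e^{-(l+r2)t} (1 + (l+r2)(1 - e^{-(r1-r2)t})/(r1-r2)) so that t = 0
# gives exactly 0 and S ~ 3000 never amplifies cancellation noise.
log_survival_factor <- function(roots, t) {
  lp2 <- roots$lambda_plus_r2
  gap <- roots$r1 - roots$r2
  if (gap > 0) {
    -lp2 * t + log1p(lp2 * (-expm1(-gap * t)) / gap)
  } else {
    # degenerate double root (only when k_minus1*lambda = 0 and
    # -lambda + mu*N + k_minus1 = 0): analytic limit of the quotient
    -lp2 * t + log1p(lp2 * t)
  }
}

#' Probability of no APC/C activation by time t (closed form)
#'
#' Survival probability of the checkpoint: the probability that no Cdc20
#' molecule has reached any of the `N` APC/C targets by time `t`, starting
#' from zero free Cdc20. In closed form
#' `P(t) = [((lambda+r1) e^{-(lambda+r2)t} - (lambda+r2) e^{-(lambda+r1)t}) / (r1-r2)]^S`,
#' evaluated in log space because the base is raised to the pool size
#' `S` (thousands). `P` is identically 1 when `lambda = 0` (no Cdc20 ever
#' produced) or `mu = 0` (targets unreachable), equals 1 at `t = 0`, and is
#' non-increasing in `t` and `lambda` and non-decreasing in `k_minus1`
#' (stronger inhibition preserves the checkpoint).
#'
#' @param params A [rate_parameters()] row.
#' @param t Time(s) since checkpoint start (s), vectorised, `>= 0`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' survival_probability(default_ptk2_parameters(), 1200) # 0.9618
#' @export
survival_probability <- function(params, t) {
  p <- as_sac_params(params)
  if (length(t) == 0L) stop_invalid("`t` must contain at least one time.")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_invalid("`t` must be finite and non-negative.")
  }
  if (p$lambda == 0 || p$mu == 0) {
    # no Cdc20 is ever produced, or targets are unreachable: the
    # checkpoint survives with certainty
    return(rep(1, length(t)))
  }
  roots <- characteristic_roots(p)
  logp <- p$S * vapply(t, function(ti) log_survival_factor(roots, ti), 0)
  out <- exp(logp)
  # excursions beyond [0, 1] can only be rounding-level; anything larger
  # indicates a bug upstream and must not be silently hidden
  hi <- out - 1
  if (any(hi > 1e-12)) {
    abort("survival probability exceeded 1 beyond rounding tolerance.",
          class = "sacr_numerical_error")
  }
  pmin(pmax(out, 0), 1)
}

#' Survival curve on a time grid
#'
#' Evaluates [survival_probability()] on an ordered grid and returns a tidy
#' result carrying the parameters and characteristic roots.
#'
#' @param params A [rate_parameters()] row.
#' @param times Sorted non-negative time grid (s).
#' @return A tibble of class `sac_survival` with columns `time_s`,
#'   `survival`, and `method = "closed_form"`; attributes `params` and
#'   `roots`.
#' @examples
#' survival_curve(default_ptk2_parameters(), seq(0, 1200, by = 60))
#' @export
survival_curve <- function(params, times) {
  p <- as_sac_params(params)
  if (length(times) == 0L) stop_invalid("`times` must be a non-empty grid.")
  if (is.unsorted(times)) stop_invalid("`times` must be sorted increasing.")
  s <- survival_probability(p, times)
  new_sac_survival(
    tibble(time_s = as.numeric(times), survival = s, method = "closed_form"),
    params = p, roots = characteristic_roots(p)
  )
}

new_sac_survival <- function(data, params, roots = NULL, diagnostics = NULL) {
  structure(
    data,
    params = params, roots = roots, diagnostics = diagnostics,
    class = c("sac_survival", class(tibble()))
  )
}

#' @export
tidy.sac_survival <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sac_survival <- function(x, ...) {
  p <- attr(x, "params")
  roots <- attr(x, "roots")
  tibble(
    lambda = p$lambda, k_minus1 = p$k_minus1, mu = p$mu, N = p$N, S = p$S,
    r1 = roots$r1 %||% NA_real_, r2 = roots$r2 %||% NA_real_,
    t_end = max(x$time_s), survival_end = x$survival[which.max(x$time_s)]
  )
}

#' @export
autoplot.sac_survival <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$time_s, y = .data$survival,
                 colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time since checkpoint start (s)",
      y = "P(no APC/C activation)", colour = NULL
    )
}
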