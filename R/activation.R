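# state indexing for the activation-phase chain: transient states are
# (k, m) with m = 0..N-1 activated targets and k = m..S total Cdc20; the
# layer m = N is absorbing. k and m never decrease, so the chain is acyclic.

resolve_initial_pmf <- function(params, initial_pmf) {
  if (is.null(initial_pmf)) {
    initial_pmf <- equilibrium_distribution(params)$probability
  }
  if (length(initial_pmf) != params$S + 1L) {
    stop_invalid("`initial_pmf` must have length S + 1 (states k = 0..S).")
  }
  if (any(initial_pmf < 0) || abs(sum(initial_pmf) - 1) > 1e-12) {
    stop_invalid("`initial_pmf` must be a probability vector summing to 1.")
  }
  initial_pmf
}

#' Occupation times and mean activation time of the anaphase-onset chain
#'
#' After the checkpoint is lifted, inhibition stops (`k_minus1` drops to 0,
#' entering only through the equilibrium initial law) and the cell state
#' follows the acyclic Markov chain on `(k, m)` — `k` total Cdc20 produced,
#' `m` activated APC/C targets — with production `(k,m) -> (k+1,m)` at rate
#' `lambda*(S-k)` and activation `(k,m) -> (k,m+1)` at rate
#' `mu*(N-m)*(k-m)` (only the `k-m` free molecules can bind one of the
#' `N-m` remaining targets). Anaphase onset is the absorption into the
#' layer `m = N`, and its mean time `tau` equals the sum of expected
#' occupation times `a(k,m)` over all transient states.
#'
#' Integrating the forward equations over all time turns them into a linear
#' system for the `a(k,m)`: with exit rate
#' `out(k,m) = lambda*(S-k) + mu*(N-m)*(k-m)`,
#' `out(k,m)*a(k,m) = init[k]*1(m=0) + lambda*(S-k+1)*a(k-1,m) + mu*(N-m+1)*(k-m+1)*a(k,m-1)`.
#' Because `k` and `m` never decrease, a single sweep in increasing
#' `(m, k)` solves the system exactly — no iteration, cost linear in the
#' number of states (about `N*(S+1)`). `method = "matrix"` instead builds
#' the full sparse generator over the transient states and solves
#' `t(-Q) a = init`; it is an independent route kept for cross-checking
#' and requires `lambda > 0`.
#'
#' @param params A [rate_parameters()] row (`k_minus1` used only through
#'   the default initial law).
#' @param initial_pmf Probability vector over `k = 0..S` at `m = 0`;
#'   defaults to the checkpoint equilibrium
#'   ([equilibrium_distribution()]).
#' @param method `"sweep"` (single topological-order pass, default) or
#'   `"matrix"` (sparse fundamental-matrix solve).
#' @return A tibble of class `sac_occupation` with columns `k`, `m`,
#'   `time_s` (the occupation times, zero for unreachable `k < m`);
#'   attributes `tau` (mean activation time, s), `params`, `method`,
#'   `n_states`.
#' @examples
#' p <- rate_parameters(lambda = 0.2, k_minus1 = 1, mu = 0.1, N = 2, S = 6)
#' occ <- occupation_times(p, initial_pmf = c(1, rep(0, 6)))
#' glance(occ)$tau_s
#' @export
occupation_times <- function(params, initial_pmf = NULL,
                             method = c("sweep", "matrix")) {
  p <- as_sac_params(params)
  method <- match.arg(method)
  init <- resolve_initial_pmf(p, initial_pmf)
  lam <- p$lambda; mu <- p$mu; N <- p$N; S <- p$S

  if (lam == 0 && sum(init[seq_len(N)]) > 1e-15) {
    abort(paste0(
      "mean activation time diverges: lambda = 0 and initial mass below ",
      "k = N can never activate all targets (tau = Inf)."
    ), class = "sacr_divergent_mean_time")
  }

  if (method == "matrix") {
    return(occupation_times_matrix(p, init))
  }

  rows_k <- integer(0); rows_m <- integer(0); rows_a <- numeric(0)
  aprev <- numeric(S + 1L)
  tau <- 0
  for (m in 0:(N - 1L)) {
    a <- numeric(S + 1L)
    act_in <- mu * (N - m + 1) # inflow factor from layer m-1, times (k-m+1)
    for (k in m:S) {
      src <- if (m == 0L) init[k + 1L] else act_in * (k - m + 1) * aprev[k + 1L]
      inflow <- if (k > m) lam * (S - k + 1) * a[k] else 0
      out <- lam * (S - k) + mu * (N - m) * (k - m)
      if (out == 0) {
        if (src + inflow > 0) {
          abort(sprintf(
            "state (k = %d, m = %d) is reachable but has no exit rate.",
            k, m
          ), class = "sacr_model_degeneracy")
        }
        a[k + 1L] <- 0
      } else {
        a[k + 1L] <- (src + inflow) / out
      }
    }
    tau <- tau + sum(a)
    rows_k <- c(rows_k, m:S)
    rows_m <- c(rows_m, rep.int(m, S - m + 1L))
    rows_a <- c(rows_a, a[(m + 1L):(S + 1L)])
    aprev <- a
  }

  new_sac_occupation(
    tibble(k = rows_k, m = rows_m, time_s = rows_a),
    params = p, tau = tau, method = "sweep",
    initial_pmf = init
  )
}

occupation_times_matrix <- function(p, init) {
  lam <- p$lambda; mu <- p$mu; N <- p$N; S <- p$S
  if (lam == 0) {
    stop_invalid("`method = \"matrix\"` requires lambda > 0 (stalled states make the generator singular); use the sweep.")
  }
  # enumerate transient states (k, m), m = 0..N-1, k = m..S
  m_of <- unlist(lapply(0:(N - 1L), function(m) rep.int(m, S - m + 1L)))
  k_of <- unlist(lapply(0:(N - 1L), function(m) m:S))
  n <- length(k_of)
  id <- matrix(NA_integer_, nrow = S + 1L, ncol = N)
  id[cbind(k_of + 1L, m_of + 1L)] <- seq_len(n)

  out_rate <- lam * (S - k_of) + mu * (N - m_of) * (k_of - m_of)
  ii <- seq_len(n); jj <- seq_len(n); xx <- -out_rate
  has_prod <- k_of < S
  ii <- c(ii, id[cbind(k_of[has_prod] + 2L, m_of[has_prod] + 1L)])
  jj <- c(jj, which(has_prod))
  xx <- c(xx, lam * (S - k_of[has_prod]))
  has_act <- (m_of < N - 1L) & (k_of > m_of)
  ii <- c(ii, id[cbind(k_of[has_act] + 1L, m_of[has_act] + 2L)])
  jj <- c(jj, which(has_act))
  xx <- c(xx, mu * (N - m_of[has_act]) * (k_of[has_act] - m_of[has_act]))
  # Qt[i, j] = rate j -> i; solve (-Qt) a = pi0
  Qt <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  pi0 <- numeric(n)
  pi0[id[cbind(seq_len(S + 1L), 1L)]] <- init
  a <- as.numeric(Matrix::solve(-Qt, pi0))

  new_sac_occupation(
    tibble(k = k_of, m = m_of, time_s = a),
    params = p, tau = sum(a), method = "matrix", initial_pmf = init
  )
}

new_sac_occupation <- function(data, params, tau, method, initial_pmf) {
  structure(
    data,
    params = params, tau = tau, method = method, initial_pmf = initial_pmf,
    n_states = nrow(data),
    class = c("sac_occupation", class(tibble()))
  )
}

#' Mean time to activate all APC/C targets
#'
#' Convenience wrapper around [occupation_times()]: builds the equilibrium
#' initial law from `params` (or uses the one supplied) and returns the
#' mean absorption time `tau` in seconds.
#'
#' @inheritParams occupation_times
#' @return Mean activation time (s).
#' @examples
#' mean_activation_time(default_ptk2_parameters()) # ~345 s
#' @export
mean_activation_time <- function(params, initial_pmf = NULL,
                                 method = c("sweep", "matrix")) {
  attr(occupation_times(params, initial_pmf, method), "tau")
}

#' Transient distribution of the activation chain
#'
#' Integrates the forward master equations of the `(k, m)` activation chain
#' (including the absorbing layer `m = N`) to `t_end`, starting from
#' `initial_pmf` at `m = 0`. Intended for small instances as an independent
#' oracle for [occupation_times()]; the state space is dense-enumerated and
#' the instance is refused above 20000 states.
#'
#' @inheritParams occupation_times
#' @param t_end Final time (s), `>= 0`.
#' @param times Optional full output grid; defaults to `c(0, t_end)`.
#' @param rel_tol Relative integration tolerance.
#' @return A tibble with columns `k`, `m`, `probability` (the distribution
#'   at `t_end`); attributes `params`, `p_absorbed` (total mass at
#'   `m = N`), and `trajectory` (matrix of all states over `times`, with
#'   state labels in attribute `state_index`).
#' @export
transient_distribution <- function(params, t_end, initial_pmf = NULL,
                                   times = NULL, rel_tol = 1e-8) {
  p <- as_sac_params(params)
  check_scalar(t_end, "t_end", allow_zero = TRUE)
  init <- resolve_initial_pmf(p, initial_pmf)
  lam <- p$lambda; mu <- p$mu; N <- p$N; S <- p$S

  m_of <- unlist(lapply(0:N, function(m) rep.int(m, S - m + 1L)))
  k_of <- unlist(lapply(0:N, function(m) m:S))
  n <- length(k_of)
  if (n > 20000L) {
    stop_invalid("instance too large for dense transient integration (> 20000 states); use occupation_times() or the SSA.")
  }
  id <- matrix(NA_integer_, nrow = S + 1L, ncol = N + 1L)
  id[cbind(k_of + 1L, m_of + 1L)] <- seq_len(n)

  out_rate <- lam * (S - k_of) + mu * (N - m_of) * (k_of - m_of)
  ii <- seq_len(n); jj <- seq_len(n); xx <- -out_rate
  has_prod <- k_of < S
  ii <- c(ii, id[cbind(k_of[has_prod] + 2L, m_of[has_prod] + 1L)])
  jj <- c(jj, which(has_prod))
  xx <- c(xx, lam * (S - k_of[has_prod]))
  has_act <- (m_of < N) & (k_of > m_of)
  ii <- c(ii, id[cbind(k_of[has_act] + 1L, m_of[has_act] + 2L)])
  jj <- c(jj, which(has_act))
  xx <- c(xx, mu * (N - m_of[has_act]) * (k_of[has_act] - m_of[has_act]))
  Qt <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  y0 <- numeric(n)
  y0[id[cbind(seq_len(S + 1L), 1L)]] <- init
  if (is.null(times)) times <- c(0, t_end)
  times <- sort(unique(c(0, times)))

  if (t_end == 0 && length(times) == 1L) {
    traj <- matrix(y0, nrow = 1L)
  } else {
    sol <- tryCatch(
      deSolve::ode(
        y = y0, times = times,
        func = function(t, y, parms) list(as.numeric(Qt %*% y)),
        parms = NULL, method = "lsoda", rtol = rel_tol, atol = rel_tol * 1e-4
      ),
      warning = function(w) {
        abort(paste0("transient integration failed: ", conditionMessage(w)),
              class = "sacr_integration_error")
      }
    )
    traj <- unname(sol[, -1L, drop = FALSE])
  }

  final <- traj[nrow(traj), ]
  p_abs <- sum(final[m_of == N])
  if (p_abs > 1 && p_abs - 1 < 1e-8) p_abs <- 1 # integrator rounding only
  structure(
    tibble(k = k_of, m = m_of, probability = final),
    params = p,
    p_absorbed = p_abs,
    trajectory = structure(traj, state_index = tibble(k = k_of, m = m_of),
                           times = times),
    class = c("sac_transient", class(tibble()))
  )
}

#' @export
tidy.sac_occupation <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sac_occupation <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    tau_s = attr(x, "tau"),
    n_states = attr(x, "n_states"),
    method = attr(x, "method"),
    initial_mean_cdc20 = sum((0:p$S) * attr(x, "initial_pmf")),
    lambda = p$lambda, mu = p$mu, N = p$N, S = p$S
  )
}

#' @export
autoplot.sac_occupation <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$time_s > 0)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$k, y = .data$m, fill = .data$time_s)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "total Cdc20 (k)", y = "activated targets (m)",
                  fill = "occupation (s)")
}
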