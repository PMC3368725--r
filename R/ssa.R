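# Exact stochastic simulation (direct method) of the two reaction phases.
# Channels are few (2-3), so the direct method with one uniform pair per
# event is used; uniforms are drawn from R's RNG in refillable blocks to
# keep the interpreted event loop cheap while preserving the exact draw
# order for a given seed.

new_uniform_buffer <- function(block = 512L) {
  buf <- runif(block)
  ptr <- 0L
  function() {
    if (ptr == block) {
      buf <<- runif(block)
      ptr <<- 0L
    }
    ptr <<- ptr + 1L
    buf[ptr]
  }
}

# counter-based per-trajectory seed derivation: reproducible regardless of
# execution order of the ensemble members
derive_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) + as.numeric(i) * 1140671485) %% 2147483647)
}

sim_inhibition_core <- function(lam, k1, muN, S, t_max, record) {
  k <- 0L
  t <- 0
  absorbed <- FALSE
  t_abs <- NA_real_
  nxt <- new_uniform_buffer()
  if (record) {
    cap <- 256L
    ev_t <- numeric(cap); ev_k <- integer(cap); ev_e <- character(cap)
    n_ev <- 0L
    push <- function(tt, kk, ee) {
      if (n_ev == cap) {
        cap <<- cap * 2L
        length(ev_t) <<- cap; length(ev_k) <<- cap; length(ev_e) <<- cap
      }
      n_ev <<- n_ev + 1L
      ev_t[n_ev] <<- tt; ev_k[n_ev] <<- kk; ev_e[n_ev] <<- ee
    }
  }
  repeat {
    a1 <- lam * (S - k)
    a2 <- k1 * k
    a3 <- muN * k
    a0 <- a1 + a2 + a3
    if (a0 <= 0) break # lambda = 0 from k = 0: frozen forever
    t <- t - log(nxt()) / a0
    if (t > t_max) break
    u <- nxt() * a0
    if (u < a1) {
      k <- k + 1L
      if (record) push(t, k, "production")
    } else if (u < a1 + a2) {
      k <- k - 1L
      if (record) push(t, k, "inhibition")
    } else {
      absorbed <- TRUE
      t_abs <- t
      if (record) push(t, k, "activation")
      break
    }
  }
  list(
    final_k = k, absorbed = absorbed, absorption_time_s = t_abs,
    events = if (record) {
      tibble(time_s = ev_t[seq_len(n_ev)], k = ev_k[seq_len(n_ev)],
             event = ev_e[seq_len(n_ev)])
    }
  )
}

sim_activation_core <- function(lam, mu, N, S, k0, record) {
  k <- as.integer(k0)
  m <- 0L
  t <- 0
  nxt <- new_uniform_buffer()
  if (record) {
    cap <- 256L
    ev_t <- numeric(cap); ev_k <- integer(cap); ev_m <- integer(cap)
    ev_e <- character(cap)
    n_ev <- 0L
    push <- function(tt, kk, mm, ee) {
      if (n_ev == cap) {
        cap <<- cap * 2L
        length(ev_t) <<- cap; length(ev_k) <<- cap
        length(ev_m) <<- cap; length(ev_e) <<- cap
      }
      n_ev <<- n_ev + 1L
      ev_t[n_ev] <<- tt; ev_k[n_ev] <<- kk; ev_m[n_ev] <<- mm
      ev_e[n_ev] <<- ee
    }
  }
  repeat {
    a1 <- lam * (S - k)
    a2 <- mu * (N - m) * (k - m)
    a0 <- a1 + a2
    t <- t - log(nxt()) / a0
    u <- nxt() * a0
    if (u < a1) {
      k <- k + 1L
      if (record) push(t, k, m, "production")
    } else {
      m <- m + 1L
      if (record) push(t, k, m, "activation")
      if (m == N) break
    }
  }
  list(
    final_k = k, final_m = m, absorption_time_s = t,
    events = if (record) {
      tibble(time_s = ev_t[seq_len(n_ev)], k = ev_k[seq_len(n_ev)],
             m = ev_m[seq_len(n_ev)], event = ev_e[seq_len(n_ev)])
    }
  )
}

new_sac_trajectory <- function(phase, params, seed, core, t_max = NA_real_,
                               initial_k = 0L) {
  structure(
    list(
      phase = phase, seed = seed, params = params, t_max = t_max,
      initial_k = initial_k,
      events = core$events,
      final_k = core$final_k,
      final_m = core$final_m %||% NA_integer_,
      absorbed = core$absorbed %||% TRUE,
      absorption_time_s = core$absorption_time_s
    ),
    class = "sac_trajectory"
  )
}

#' @export
print.sac_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sac_trajectory> phase = %s, seed = %d, %d events, %s\n",
    x$phase, x$seed, nrow(x$events),
    if (isTRUE(x$absorbed)) {
      sprintf("absorbed at t = %.4g s", x$absorption_time_s)
    } else {
      sprintf("unabsorbed by t_max = %g s", x$t_max)
    }
  ))
  invisible(x)
}

#' @export
tidy.sac_trajectory <- function(x, ...) {
  x$events
}

#' Simulate one checkpoint (inhibition-phase) trajectory
#'
#' Exact Gillespie simulation of the inhibition-phase reaction network
#' starting from zero free Cdc20: production at `lambda*(S-k)`, inhibition
#' at `k_minus1*k`, and APC/C activation (absorbing) at `mu*N*k`. The run
#' stops at the first activation or at `t_max`. A given `(params, seed)`
#' pair fully determines the trajectory.
#'
#' @param params A [rate_parameters()] row.
#' @param t_max Time horizon (s), `> 0`.
#' @param seed Integer seed for this trajectory.
#' @param record If `FALSE`, skip per-event recording (used by ensemble
#'   runners; only the outcome fields are kept).
#' @return A `sac_trajectory` object: fields `events` (tibble `time_s`,
#'   `k`, `event`), `absorbed`, `absorption_time_s`, `final_k`.
#' @examples
#' simulate_inhibition(default_ptk2_parameters(), t_max = 60, seed = 1)
#' @export
simulate_inhibition <- function(params, t_max, seed, record = TRUE) {
  p <- as_sac_params(params)
  check_scalar(t_max, "t_max")
  check_scalar(seed, "seed", positive = FALSE, integerish = TRUE)
  core <- withr::with_seed(
    as.integer(seed),
    sim_inhibition_core(p$lambda, p$k_minus1, p$mu * p$N, p$S, t_max, record)
  )
  new_sac_trajectory("inhibition", p, as.integer(seed), core, t_max = t_max)
}

#' Simulate one anaphase-onset (activation-phase) trajectory
#'
#' Exact Gillespie simulation of the activation phase from `initial_k`
#' Cdc20 molecules and no activated target: production at `lambda*(S-k)`
#' and activation at `mu*(N-m)*(k-m)`; the run terminates when all `N`
#' targets are activated and records the absorption time.
#'
#' @inheritParams simulate_inhibition
#' @param initial_k Initial Cdc20 count, `0 <= initial_k <= S`.
#' @return A `sac_trajectory` with fields `events` (tibble `time_s`, `k`,
#'   `m`, `event`), `absorption_time_s`, `final_k`, `final_m`.
#' @export
simulate_activation <- function(params, initial_k, seed, record = TRUE) {
  p <- as_sac_params(params)
  check_scalar(initial_k, "initial_k", allow_zero = TRUE, integerish = TRUE)
  check_scalar(seed, "seed", positive = FALSE, integerish = TRUE)
  if (initial_k > p$S) stop_invalid("`initial_k` must not exceed S.")
  if (p$lambda == 0 && initial_k < p$N) {
    abort("lambda = 0 with initial_k < N can never activate all targets.",
          class = "sacr_divergent_mean_time")
  }
  core <- withr::with_seed(
    as.integer(seed),
    sim_activation_core(p$lambda, p$mu, p$N, p$S, initial_k, record)
  )
  new_sac_trajectory("activation", p, as.integer(seed), core,
                     initial_k = as.integer(initial_k))
}

#' Simulate a reproducible trajectory ensemble
#'
#' Runs `n_runs` independent trajectories of one phase. Each trajectory
#' `i` uses a seed derived from `seed` by a counter-based scheme, so the
#' ensemble is reproducible and insensitive to execution order. Per-event
#' histories are not kept; the compact per-run outcomes are returned.
#'
#' For the activation phase, `initial_k = "equilibrium"` draws each run's
#' starting Cdc20 count from the checkpoint equilibrium binomial law
#' (using the run's own seed); an integer fixes it for all runs.
#'
#' @inheritParams simulate_inhibition
#' @param phase `"inhibition"` or `"activation"`.
#' @param n_runs Number of trajectories (`>= 1`).
#' @param t_max Horizon for the inhibition phase (s); ignored for
#'   activation.
#' @param initial_k Activation phase start: `"equilibrium"` or an integer.
#' @return A tibble of class `sac_ensemble` with one row per run:
#'   `run_id`, `seed`, `initial_k`, `absorbed`, `absorption_time_s`,
#'   `final_k`, `final_m`; attributes `phase`, `params`, `t_max`.
#' @examples
#' simulate_ensemble(default_ptk2_parameters(), "inhibition",
#'                   n_runs = 10, seed = 1, t_max = 300)
#' @export
simulate_ensemble <- function(params, phase = c("inhibition", "activation"),
                              n_runs, seed, t_max = NULL,
                              initial_k = "equilibrium") {
  p <- as_sac_params(params)
  phase <- match.arg(phase)
  check_scalar(n_runs, "n_runs", integerish = TRUE)
  check_scalar(seed, "seed", positive = FALSE, integerish = TRUE)
  n_runs <- as.integer(n_runs)

  if (phase == "inhibition") {
    if (is.null(t_max)) stop_invalid("`t_max` is required for the inhibition phase.")
    check_scalar(t_max, "t_max")
  } else {
    eq_prob <- NULL
    if (identical(initial_k, "equilibrium")) {
      eq_prob <- attr(equilibrium_distribution(p), "success_prob")
    } else {
      check_scalar(initial_k, "initial_k", allow_zero = TRUE,
                   integerish = TRUE)
      if (initial_k > p$S) stop_invalid("`initial_k` must not exceed S.")
      if (p$lambda == 0 && initial_k < p$N) {
        abort("lambda = 0 with initial_k < N can never activate all targets.",
              class = "sacr_divergent_mean_time")
      }
    }
  }

  seeds <- vapply(seq_len(n_runs), function(i) derive_seed(seed, i), 0L)
  run_init <- integer(n_runs)
  absorbed <- logical(n_runs)
  abs_time <- numeric(n_runs)
  final_k <- integer(n_runs)
  final_m <- rep(NA_integer_, n_runs)

  for (i in seq_len(n_runs)) {
    if (phase == "inhibition") {
      core <- withr::with_seed(
        seeds[i],
        sim_inhibition_core(p$lambda, p$k_minus1, p$mu * p$N, p$S, t_max,
                            record = FALSE)
      )
      run_init[i] <- 0L
      absorbed[i] <- core$absorbed
      abs_time[i] <- core$absorption_time_s %||% NA_real_
      final_k[i] <- core$final_k
    } else {
      core <- withr::with_seed(seeds[i], {
        k0 <- if (is.null(eq_prob)) as.integer(initial_k) else {
          rbinom(1L, p$S, eq_prob)
        }
        c(sim_activation_core(p$lambda, p$mu, p$N, p$S, k0, record = FALSE),
          list(k0 = k0))
      })
      run_init[i] <- core$k0
      absorbed[i] <- TRUE
      abs_time[i] <- core$absorption_time_s
      final_k[i] <- core$final_k
      final_m[i] <- core$final_m
    }
  }

  structure(
    tibble(
      run_id = seq_len(n_runs), seed = seeds, initial_k = run_init,
      absorbed = absorbed, absorption_time_s = abs_time,
      final_k = final_k, final_m = final_m
    ),
    phase = phase, params = p,
    t_max = if (phase == "inhibition") t_max else NA_real_,
    class = c("sac_ensemble", class(tibble()))
  )
}

#' Summarise a trajectory ensemble
#'
#' For an inhibition-phase ensemble, returns the empirical survival
#' fraction at each checkpoint time with its binomial standard error; for
#' an activation-phase ensemble, the mean absorption time with its sample
#' standard error. Accepts either a [simulate_ensemble()] result or a list
#' of single-phase [simulate_inhibition()] / [simulate_activation()]
#' trajectories.
#'
#' @param x A `sac_ensemble` tibble or a list of `sac_trajectory` objects
#'   of one phase (`>= 2` trajectories).
#' @param checkpoint_times Time grid (s) for the survival fractions
#'   (inhibition phase only).
#' @return A tibble: `time_s`, `survival`, `se`, `n_runs` (inhibition) or
#'   `mean_absorption_time_s`, `se`, `n_runs` (activation).
#' @export
ensemble_summary <- function(x, checkpoint_times = NULL) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "sac_trajectory"))) {
    phases <- unique(vapply(x, function(tr) tr$phase, ""))
    if (length(phases) != 1L) {
      stop_invalid("all trajectories must belong to a single phase.")
    }
    if (length(x) < 2L) stop_invalid("need at least 2 trajectories.")
    x <- structure(
      tibble(
        run_id = seq_along(x),
        seed = vapply(x, function(tr) tr$seed, 0L),
        initial_k = vapply(x, function(tr) tr$initial_k, 0L),
        absorbed = vapply(x, function(tr) isTRUE(tr$absorbed), TRUE),
        absorption_time_s = vapply(x, function(tr) tr$absorption_time_s %||% NA_real_, 0),
        final_k = vapply(x, function(tr) tr$final_k, 0L),
        final_m = vapply(x, function(tr) tr$final_m %||% NA_integer_, 0L)
      ),
      phase = phases, class = c("sac_ensemble", class(tibble()))
    )
  }
  if (!inherits(x, "sac_ensemble")) {
    stop_invalid("`x` must be a sac_ensemble or a list of sac_trajectory objects.")
  }
  if (nrow(x) < 2L) stop_invalid("need at least 2 runs.")
  phase <- attr(x, "phase")

  if (phase == "inhibition") {
    if (is.null(checkpoint_times)) {
      stop_invalid("`checkpoint_times` is required for the inhibition phase.")
    }
    n <- nrow(x)
    tabs <- ifelse(x$absorbed, x$absorption_time_s, Inf)
    purrr::map_dfr(checkpoint_times, function(tc) {
      s <- mean(tabs > tc)
      tibble(time_s = tc, survival = s,
             se = sqrt(s * (1 - s) / n), n_runs = n)
    })
  } else {
    n <- nrow(x)
    tibble(
      mean_absorption_time_s = mean(x$absorption_time_s),
      se = stats::sd(x$absorption_time_s) / sqrt(n),
      n_runs = n
    )
  }
}
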