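#' Resolve and validate an analysis configuration
#'
#' Accepts a named list (or a path to a YAML/JSON file) describing the cell
#' and the kinetic rates, fills in the PTK2 defaults for missing fields,
#' and returns the resolved [rate_parameters()] and [constraint_spec()].
#' Rates can be given directly (`lambda_per_s` or `lambdaS_per_s`,
#' `k_minus1_per_s`, `mu_per_s`) or derived from geometry
#' (`derive_mu: true` uses [mu_from_geometry()], `derive_k_minus1: true`
#' uses [k_minus1_smoluchowski()]); contradictory specifications (both a
#' direct value and its derive flag, or both forms of one quantity) are
#' rejected with the offending field named.
#'
#' Recognised keys: `volume_um3`, `apc_radius_um`,
#' `binding_site_radius_um`, `diffusion_um2_s`, `mcc_copies` or
#' `mcc_conc_nM`, `n_chromosomes`, `pool_size`, `lambda_per_s` or
#' `lambdaS_per_s`, `k_minus1_per_s` or `derive_k_minus1`, `mu_per_s` or
#' `derive_mu`, and the constraint keys `tau1_s`, `p_threshold`,
#' `tau_prime_s`.
#'
#' @param config Named list, or path to a `.yaml`/`.yml`/`.json` file, or
#'   `NULL`/empty for all defaults.
#' @return A list with elements `params` (a `sac_params` row), `spec` (a
#'   `constraint_spec` row), and `geometry` (a `cell_geometry` row).
#' @examples
#' validate_config(list(lambdaS_per_s = 0.3, k_minus1_per_s = 24))
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  config <- config %||% list()
  if (!is.list(config)) {
    abort("`config` must be a named list or a file path.",
          class = "sacr_config_error")
  }
  known <- c(
    "volume_um3", "apc_radius_um", "binding_site_radius_um",
    "diffusion_um2_s", "mcc_copies", "mcc_conc_nM", "n_chromosomes",
    "pool_size", "lambda_per_s", "lambdaS_per_s", "k_minus1_per_s",
    "derive_k_minus1", "mu_per_s", "derive_mu", "tau1_s", "p_threshold",
    "tau_prime_s"
  )
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "sacr_config_error")
  }
  bad_pairs <- list(
    c("lambda_per_s", "lambdaS_per_s"),
    c("mcc_copies", "mcc_conc_nM"),
    c("k_minus1_per_s", "derive_k_minus1"),
    c("mu_per_s", "derive_mu")
  )
  for (pair in bad_pairs) {
    if (!is.null(config[[pair[1]]]) && isTRUE(config[[pair[2]]]) ||
        (!is.null(config[[pair[1]]]) && !is.null(config[[pair[2]]]) &&
         !is.logical(config[[pair[2]]]))) {
      abort(sprintf("config fields `%s` and `%s` contradict each other; give only one.",
                    pair[1], pair[2]),
            class = "sacr_config_error")
    }
  }

  geom <- withCallingHandlers(
    tryCatch(
      cell_geometry(
        volume_um3 = config$volume_um3 %||% 100,
        apc_radius_um = config$apc_radius_um %||% 0.01,
        binding_site_radius_um = config$binding_site_radius_um %||% 0.002,
        diffusion_um2_s = config$diffusion_um2_s %||% 20,
        mcc_copies = if (is.null(config$mcc_conc_nM)) {
          config$mcc_copies %||% 10000
        },
        mcc_conc_nM = config$mcc_conc_nM
      ),
      error = function(e) {
        abort(conditionMessage(e), class = "sacr_config_error", parent = e)
      }
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )

  S <- round(config$pool_size %||% 3000)
  N <- round(config$n_chromosomes %||% 13)
  mu <- if (isTRUE(config$derive_mu)) {
    mu_from_geometry(geom)
  } else {
    config$mu_per_s %||% 2e-4
  }
  k1 <- if (isTRUE(config$derive_k_minus1)) {
    k_minus1_smoluchowski(geom)
  } else {
    config$k_minus1_per_s %||% 24
  }
  lambda <- if (!is.null(config$lambda_per_s)) {
    config$lambda_per_s
  } else {
    (config$lambdaS_per_s %||% 0.3) / S
  }

  params <- tryCatch(
    rate_parameters(lambda = lambda, k_minus1 = k1, mu = mu, N = N, S = S),
    error = function(e) {
      abort(conditionMessage(e), class = "sacr_config_error", parent = e)
    }
  )
  spec <- tryCatch(
    constraint_spec(
      tau1_s = config$tau1_s %||% 1200,
      p_threshold = config$p_threshold %||% 0.95,
      tau_prime_s = config$tau_prime_s %||% 600
    ),
    error = function(e) {
      abort(conditionMessage(e), class = "sacr_config_error", parent = e)
    }
  )
  list(params = params, spec = spec, geometry = geom)
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file `%s` does not exist.", path),
          class = "sacr_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config file must be .yaml, .yml or .json.",
          class = "sacr_config_error")
  }
}

#' Run the full checkpoint analysis
#'
#' Executes the whole analysis chain for one configuration: parameter
#' resolution, survival probability at the checkpoint duration,
#' equilibrium Cdc20 distribution, mean activation time, constraint
#' evaluation, and (optionally) a domain scan. Returns a report list and,
#' if `out_dir` is given, writes `report.json`, `survival.csv`,
#' `equilibrium.csv` (and `domain.csv` when scanning) there.
#'
#' The report's `manifest` element records the resolved parameters,
#' constraint specification, seed, package version and timestamp, so a run
#' can be reproduced exactly (the timestamp is informative only).
#'
#' @param config As in [validate_config()].
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @param out_dir Optional output directory (created if needed).
#' @param scan If `TRUE`, include a domain scan over the default axes (or
#'   supply `lambdaS_axis`/`k_minus1_axis`).
#' @param lambdaS_axis,k_minus1_axis Optional scan axes, see
#'   [scan_domain()].
#' @param grid_step Survival-curve grid step (s).
#' @return A list of class `sac_report`: `params`, `spec`,
#'   `survival_at_tau1`, `tau_s`, `c1`, `c2`, `in_omega`, `rho`,
#'   `equilibrium_mean`, `survival` (a `sac_survival` tibble), `domain`
#'   (or `NULL`), `manifest`.
#' @examples
#' report <- run_full_analysis()
#' report$survival_at_tau1
#' report$tau_s
#' @export
run_full_analysis <- function(config = NULL, seed = 1L, out_dir = NULL,
                              scan = FALSE, lambdaS_axis = NULL,
                              k_minus1_axis = NULL, grid_step = 60) {
  resolved <- validate_config(config)
  params <- resolved$params
  spec <- resolved$spec

  times <- seq(0, field(spec, "tau1_s"), by = grid_step)
  if (max(times) < field(spec, "tau1_s")) {
    times <- c(times, field(spec, "tau1_s"))
  }
  surv_curve <- survival_curve(params, times)
  eq <- tryCatch(
    equilibrium_distribution(params),
    sacr_no_stationary_distribution = function(e) NULL
  )
  constraints <- evaluate_constraints(params, spec)
  domain <- if (scan) {
    scan_domain(lambdaS_axis, k_minus1_axis, base_params = params,
                spec = spec)
  }

  report <- structure(
    list(
      params = params,
      spec = spec,
      survival_at_tau1 = constraints$survival_at_tau1,
      tau_s = constraints$tau_s,
      c1 = constraints$c1,
      c2 = constraints$c2,
      in_omega = constraints$in_omega,
      rho = constraints$rho,
      equilibrium_mean = if (is.null(eq)) NA_real_ else attr(eq, "mean"),
      survival = surv_curve,
      equilibrium = eq,
      domain = domain,
      manifest = list(
        package = "sacr",
        version = as.character(packageVersion("sacr")),
        seed = as.integer(seed),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        params = as.list(as_tibble(params)),
        constraint_spec = as.list(as_tibble(spec)),
        config = config %||% list()
      )
    ),
    class = "sac_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- report[c("survival_at_tau1", "tau_s", "c1", "c2", "in_omega",
                     "rho", "equilibrium_mean")]
    json$tau_s <- if (is.finite(json$tau_s)) json$tau_s else "Inf"
    json$manifest <- report$manifest
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(as_tibble(surv_curve), file.path(out_dir, "survival.csv"),
              row.names = FALSE)
    if (!is.null(eq)) {
      write.csv(as_tibble(eq), file.path(out_dir, "equilibrium.csv"),
                row.names = FALSE)
    }
    if (!is.null(domain)) {
      write.csv(as_tibble(domain), file.path(out_dir, "domain.csv"),
                row.names = FALSE)
    }
  }
  report
}

#' @export
print.sac_report <- function(x, ...) {
  cat("<sac_report>  spindle assembly checkpoint analysis\n")
  cat(sprintf("  lambda*S = %g /s, k_minus1 = %g /s, mu = %g /s, N = %d, S = %d\n",
              x$params$lambdaS, x$params$k_minus1, x$params$mu,
              x$params$N, x$params$S))
  cat(sprintf("  P(no activation by %g s) = %.4f  [C1 %s]\n",
              field(x$spec, "tau1_s"), x$survival_at_tau1,
              if (x$c1) "satisfied" else "violated"))
  cat(sprintf("  mean activation time tau = %s  [C2 %s]\n",
              if (is.finite(x$tau_s)) sprintf("%.1f s", x$tau_s) else "Inf",
              if (x$c2) "satisfied" else "violated"))
  cat(sprintf("  in admissible domain Omega: %s;  rho = %s\n",
              x$in_omega,
              if (is.na(x$rho)) "undefined" else signif(x$rho, 4)))
  invisible(x)
}

#' @export
glance.sac_report <- function(x, ...) {
  tibble(
    lambdaS = x$params$lambdaS, k_minus1 = x$params$k_minus1,
    survival_at_tau1 = x$survival_at_tau1, tau_s = x$tau_s,
    c1 = x$c1, c2 = x$c2, in_omega = x$in_omega, rho = x$rho,
    equilibrium_mean = x$equilibrium_mean
  )
}
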