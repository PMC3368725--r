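AVOGADRO <- 6.02214076e23

# 1 nM expressed as molecules per um^3 (1e-9 mol/L * N_A / 1e15 um^3/L)
NM_PER_UM3 <- 1e-9 * AVOGADRO * 1e-15

#' Physical cell geometry for rate derivation
#'
#' Bundles the physical quantities from which the two diffusion-limited
#' kinetic rates can be derived: the Cdc20 arrival rate at an APC/C target
#' (`mu = 4aD/V`) and the Smoluchowski capture rate by the mitotic
#' checkpoint complex (`k_minus1 = 2*pi*b*D*[MCC]`). MCC abundance is given
#' either as a copy number or as a nanomolar concentration, never both.
#'
#' @param volume_um3 Cell volume (um^3).
#' @param apc_radius_um Radius `a` of the APC/C target (um).
#' @param binding_site_radius_um Radius `b` of the Cdc20 binding site on the
#'   MCC (um).
#' @param diffusion_um2_s Cdc20 diffusion coefficient `D` (um^2/s).
#' @param mcc_copies MCC copy number in the cell (integer), or `NULL`.
#' @param mcc_conc_nM MCC concentration (nM), or `NULL`.
#'
#' @return A one-row tibble of class `cell_geometry`.
#' @details The derivations assume the small-target regime: both radii must
#'   be small against the linear cell size `V^(1/3)`. A violation is
#'   reported as a warning, not an error, since the formulas remain defined.
#' @examples
#' geom <- cell_geometry(100, 0.01, 0.002, 20, mcc_copies = 10000)
#' mu_from_geometry(geom)
#' k_minus1_smoluchowski(geom)
#' @export
cell_geometry <- function(volume_um3, apc_radius_um, binding_site_radius_um,
                          diffusion_um2_s, mcc_copies = NULL,
                          mcc_conc_nM = NULL) {
  check_scalar(volume_um3, "volume_um3")
  check_scalar(apc_radius_um, "apc_radius_um")
  check_scalar(binding_site_radius_um, "binding_site_radius_um")
  check_scalar(diffusion_um2_s, "diffusion_um2_s")
  if (!is.null(mcc_copies) && !is.null(mcc_conc_nM)) {
    stop_invalid("give exactly one of `mcc_copies` and `mcc_conc_nM`, not both.")
  }
  if (!is.null(mcc_copies)) {
    check_scalar(mcc_copies, "mcc_copies", allow_zero = TRUE, integerish = TRUE)
  }
  if (!is.null(mcc_conc_nM)) {
    check_scalar(mcc_conc_nM, "mcc_conc_nM", allow_zero = TRUE)
  }
  lin <- volume_um3^(1 / 3)
  if (apc_radius_um > 0.1 * lin || binding_site_radius_um > 0.1 * lin) {
    warn(paste0(
      "target radii should be small against the cell size V^(1/3) = ",
      signif(lin, 3), " um; the diffusion-limited rate formulas degrade ",
      "outside the small-target regime."
    ))
  }
  one_row(
    "cell_geometry",
    volume_um3 = volume_um3,
    apc_radius_um = apc_radius_um,
    binding_site_radius_um = binding_site_radius_um,
    diffusion_um2_s = diffusion_um2_s,
    mcc_copies = if (is.null(mcc_copies)) NA_real_ else round(mcc_copies),
    mcc_conc_nM = mcc_conc_nM %||% NA_real_
  )
}

#' Cdc20 arrival rate at one APC/C target from cell geometry
#'
#' Diffusion-limited rate for one Cdc20 molecule to find one small APC/C
#' target of radius `a` in a cell of volume `V`: `mu = 4aD/V` (s^-1). For a
#' spherical cell of radius `R` (so `V = 4*pi*R^3/3`) this is identical to
#' the narrow-target form `3aD/(pi R^3)`.
#'
#' Note that with the default PTK2 physical values (`a` = 0.01 um, `D` = 20
#' um^2/s, `V` = 100 um^3) this formula gives 8e-3 s^-1, whereas the
#' package-wide default rate set ([default_ptk2_parameters()]) carries
#' `mu` = 2e-4 s^-1, the value the rest of the worked analysis is built on.
#' The two are inconsistent by a factor of 40; both are exposed so the user
#' can choose deliberately.
#'
#' @param geom A [cell_geometry()] object.
#' @return Arrival rate `mu` per free Cdc20 molecule per target (s^-1).
#' @export
mu_from_geometry <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  4 * field(geom, "apc_radius_um") * field(geom, "diffusion_um2_s") /
    field(geom, "volume_um3")
}

#' Cdc20 inhibition rate from the Smoluchowski formula
#'
#' Capture rate of a diffusing Cdc20 molecule by the homogeneously
#' distributed mitotic checkpoint complex: `k_minus1 = 2*pi*b*D*[MCC]`, with
#' `[MCC]` in molecules/um^3 (copies divided by cell volume).
#'
#' @inheritParams mu_from_geometry
#' @return Inhibition rate `k_minus1` per free Cdc20 molecule (s^-1).
#' @examples
#' # 10^4 MCC copies in 100 um^3 at D = 20 um^2/s, b = 2 nm -> 8*pi = 25.13 s^-1
#' k_minus1_smoluchowski(cell_geometry(100, 0.01, 0.002, 20, mcc_copies = 1e4))
#' @export
k_minus1_smoluchowski <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  copies <- field(geom, "mcc_copies")
  if (is.na(copies)) {
    conc <- field(geom, "mcc_conc_nM")
    if (is.na(conc)) {
      stop_invalid("MCC abundance is required: set `mcc_copies` or `mcc_conc_nM`.")
    }
    copies <- nanomolar_to_copies(conc, field(geom, "volume_um3"))
  }
  density <- copies / field(geom, "volume_um3") # molecules / um^3
  2 * pi * field(geom, "binding_site_radius_um") *
    field(geom, "diffusion_um2_s") * density
}

#' Convert between nanomolar concentration and copy number
#'
#' `nanomolar_to_copies()` returns the molecule count corresponding to a
#' concentration in a given volume, rounded to the nearest integer (counts
#' feed discrete-state formulas); `copies_to_nanomolar()` is its inverse
#' (unrounded).
#'
#' @param conc_nM Concentration (nM).
#' @param volume_um3 Volume (um^3).
#' @param copies Molecule count.
#' @return A count (integer-valued double) or a concentration (nM).
#' @examples
#' nanomolar_to_copies(50, 100) # 3011 molecules
#' @export
nanomolar_to_copies <- function(conc_nM, volume_um3) {
  check_scalar(conc_nM, "conc_nM", allow_zero = TRUE)
  check_scalar(volume_um3, "volume_um3")
  round(conc_nM * NM_PER_UM3 * volume_um3)
}

#' @rdname nanomolar_to_copies
#' @export
copies_to_nanomolar <- function(copies, volume_um3) {
  check_scalar(copies, "copies", allow_zero = TRUE)
  check_scalar(volume_um3, "volume_um3")
  copies / (NM_PER_UM3 * volume_um3)
}

#' Kinetic rate parameters of the checkpoint model
#'
#' The five quantities every formula in the package consumes: the
#' per-free-complex Cdc20 production rate `lambda` (s^-1), the per-molecule
#' inhibition rate `k_minus1` (s^-1), the per-molecule per-target APC/C
#' arrival rate `mu` (s^-1), the number of chromosomes / APC/C targets `N`,
#' and the size `S` of the Cdc20-sequestering complex pool. The aggregate
#' production rate at checkpoint start (`k = 0`) is `lambda * S`, the scale
#' on which results are usually reported.
#'
#' @param lambda Per-complex production rate (s^-1), `>= 0`.
#' @param k_minus1 Inhibition/ubiquitylation rate (s^-1), `>= 0`.
#' @param mu Arrival rate at one APC/C target (s^-1), `>= 0` (zero
#'   disables the activation channel, giving the conditioned
#'   inhibition-phase chain).
#' @param N Number of chromosomes (positive integer, `N <= S`).
#' @param S Initial number of Cdc20:complex units (positive integer).
#' @return A one-row tibble of class `sac_params` with columns `lambda`,
#'   `k_minus1`, `mu`, `N`, `S`, `lambdaS`.
#' @examples
#' rate_parameters(lambda = 1e-4, k_minus1 = 24, mu = 2e-4, N = 13, S = 3000)
#' @export
rate_parameters <- function(lambda, k_minus1, mu, N, S) {
  check_scalar(lambda, "lambda", allow_zero = TRUE)
  check_scalar(k_minus1, "k_minus1", allow_zero = TRUE)
  check_scalar(mu, "mu", allow_zero = TRUE)
  check_scalar(N, "N", integerish = TRUE)
  check_scalar(S, "S", integerish = TRUE)
  N <- round(N)
  S <- round(S)
  if (N < 1 || N > S) {
    stop_invalid(sprintf("need 1 <= N <= S (got N = %d, S = %d).", N, S))
  }
  one_row(
    "sac_params",
    lambda = lambda, k_minus1 = k_minus1, mu = mu,
    N = N, S = S, lambdaS = lambda * S
  )
}

#' Default PTK2-cell parameter set
#'
#' The rate set used throughout the worked analysis of PTK2 (rat-kangaroo
#' kidney) cells: `mu` = 2e-4 s^-1, `N` = 13 chromosomes, `S` = 3000
#' complexes (50 nM in 100 um^3), `k_minus1` = 24 s^-1 (Smoluchowski rate at
#' roughly 10^4 MCC copies), and `lambda` = 0.3/S = 1e-4 s^-1 so that the
#' aggregate production rate is `lambda*S` = 0.3 s^-1.
#'
#' `mu` here is the tabulated effective value, not the geometric
#' `4aD/V` (see [mu_from_geometry()] for the discrepancy).
#'
#' @return A `sac_params` one-row tibble.
#' @export
default_ptk2_parameters <- function() {
  rate_parameters(lambda = 0.3 / 3000, k_minus1 = 24, mu = 2e-4,
                  N = 13, S = 3000)
}

# validate + unpack a parameter row (accepts any one-row data frame with the
# right columns, so plain tibbles pipe through)
as_sac_params <- function(params) {
  if (!is.data.frame(params) || nrow(params) != 1L) {
    stop_invalid("`params` must be a one-row data frame of rate parameters.")
  }
  rate_parameters(
    lambda = field(params, "lambda"),
    k_minus1 = field(params, "k_minus1"),
    mu = field(params, "mu"),
    N = field(params, "N"),
    S = field(params, "S")
  )
}

#' @export
print.sac_params <- function(x, ...) {
  cat("<sac_params>  checkpoint rate parameters\n")
  cat(sprintf(
    "  lambda = %g /s  (lambda*S = %g /s)\n  k_minus1 = %g /s\n  mu = %g /s\n  N = %d targets, S = %d complexes\n",
    x$lambda, x$lambdaS, x$k_minus1, x$mu, x$N, x$S
  ))
  invisible(x)
}

#' @export
tidy.sac_params <- function(x, ...) {
  tibble(
    term = c("lambda", "k_minus1", "mu", "N", "S", "lambdaS"),
    estimate = c(x$lambda, x$k_minus1, x$mu, x$N, x$S, x$lambdaS),
    unit = c("1/s", "1/s", "1/s", "count", "count", "1/s")
  )
}
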