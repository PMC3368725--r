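# shared fixtures: parameter sets are always built in code

ptk2 <- default_ptk2_parameters()

ptk2_geometry <- function(mcc_copies = 10000) {
  cell_geometry(
    volume_um3 = 100, apc_radius_um = 0.01, binding_site_radius_um = 0.002,
    diffusion_um2_s = 20, mcc_copies = mcc_copies
  )
}

# reproducible random parameter sets spanning the kinetically relevant
# ranges, at pool sizes small enough for dense oracles
random_params <- function(n, seed, S_range = c(30L, 150L), N_max = 5L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      S <- sample(S_range[1]:S_range[2], 1L)
      rate_parameters(
        lambda = 10^runif(1, -4, -1),
        k_minus1 = 10^runif(1, -1, 1.5),
        mu = 10^runif(1, -4, -1),
        N = sample(1:N_max, 1L),
        S = S
      )
    })
  })
}

point_mass_at <- function(k0, S) {
  init <- numeric(S + 1L)
  init[k0 + 1L] <- 1
  init
}

# dense matrix-exponential survival oracle for the inhibition-phase chain:
# explicit (S+2)-state generator (k = 0..S plus the absorbing state),
# propagated with Matrix::expm -- fully independent of cme_survival()
expm_survival_oracle <- function(params, t) {
  S <- params$S
  k <- 0:S
  n <- S + 2L
  Q <- matrix(0, n, n) # Q[i, j] = rate i -> j, states 1..S+1 = k, S+2 = absorbed
  for (i in seq_len(S + 1L)) {
    ki <- i - 1L
    if (ki < S) Q[i, i + 1L] <- params$lambda * (S - ki)
    if (ki > 0) Q[i, i - 1L] <- params$k_minus1 * ki
    Q[i, n] <- params$mu * params$N * ki
  }
  diag(Q) <- -rowSums(Q)
  p0 <- c(1, numeric(n - 1L))
  vapply(t, function(ti) {
    pt <- as.numeric(p0 %*% Matrix::expm(Q * ti))
    sum(pt[seq_len(S + 1L)])
  }, 0)
}
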