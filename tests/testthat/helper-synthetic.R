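# shared fixtures, all generated in code

# Rodrigues rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# an rt_curve holding a pure sum of sinusoids around a resting radius
tone_curve <- function(fs, n, R0, tones, fT = NA_real_, pnp = NA_real_,
                       noise_sd = 0, seed = NULL) {
  t <- (seq_len(n) - 1) / fs
  r <- rep(R0, n)
  for (tn in tones) r <- r + tn$a * sin(2 * pi * tn$f * t + (tn$phase %||% 0))
  if (noise_sd > 0) {
    r <- r + bubblespec:::with_local_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  rt_curve(t, r, fT = fT, pnp = pnp)
}

# reference shell-parameter sets: per-type median elasticity (N/m) and
# viscosity (kg/s) of directly vs indirectly prepared DSPC coatings and
# the cholesterol-doped indirect formulation
shell_param_sets <- list(
  direct_dspc = c(chi = 0.14, kappa_s = 0.43e-8),
  indirect_dspc = c(chi = 0.03, kappa_s = 0.99e-8),
  indirect_dspc_chol = c(chi = 0.01, kappa_s = 1.39e-8)
)
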